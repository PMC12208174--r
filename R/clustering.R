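# Separation-enforced clustering and optimal-transport cluster comparison.
#
# The partition at threshold t is the set of connected components of the
# graph with an edge wherever d < t (strictly). This is exactly the
# single-linkage cut, and it carries a structural guarantee: any two
# pockets in different clusters are at distance >= t. Implemented as
# union-find over the epsilon-graph rather than a dendrogram cut so the
# guarantee holds by construction.

#' Cluster pockets with a strict minimum separation
#'
#' @param D a \code{pocket_dist}.
#' @param t separation threshold on the native scale of \code{D}; pockets
#'   closer than \code{t} (strictly) end up in the same cluster, and every
#'   cross-cluster pair is at distance at least \code{t}. \code{t = 0}
#'   yields all singletons.
#' @return A \code{pocket_clustering}: list with \code{ids},
#'   \code{labels} (0-based integers, clusters numbered by their smallest
#'   member index), \code{t}, \code{n_clusters}.
#' @export
cluster_single_linkage <- function(D, t) {
  ps_assert(t >= 0, "bad_arg", "t must be >= 0")
  n <- nrow(D)
  ids <- rownames(D) %||% as.character(seq_len(n))
  hit <- which(upper.tri(D) & D < t, arr.ind = TRUE)
  comp <- components_from_edges(n, hit)
  labels <- comp - 1L
  structure(list(ids = ids, labels = as.integer(labels), t = t,
                 n_clusters = max(comp)),
            class = "pocket_clustering")
}

#' @export
print.pocket_clustering <- function(x, ...) {
  sizes <- table(x$labels)
  cat("<pocket_clustering>", length(x$ids), "pockets in", x$n_clusters,
      "clusters at t =", x$t, "\n")
  cat("  cluster sizes:", paste(head(sort(as.integer(sizes),
                                          decreasing = TRUE), 10),
                                collapse = ","),
      if (length(sizes) > 10) "...", "\n")
  invisible(x)
}

cluster_members <- function(C) split(C$ids, C$labels)

# Drop singleton clusters from both partitions and remove their member ids
# globally from both sides; then drop clusters that became empty.
drop_singletons <- function(A, B) {
  mA <- cluster_members(A); mB <- cluster_members(B)
  S <- union(unlist(mA[lengths(mA) == 1]), unlist(mB[lengths(mB) == 1]))
  mA <- lapply(mA, setdiff, S); mB <- lapply(mB, setdiff, S)
  list(A = mA[lengths(mA) > 0], B = mB[lengths(mB) > 0])
}

#' Optimal-transport similarity between two clusterings
#'
#' Builds the Jaccard matrix over cluster pairs, finds the one-to-one
#' assignment maximizing total Jaccard (Hungarian assignment), and reports
#' the matched total divided by \code{max(K_A, K_B)} (unmatched clusters
#' contribute zero; with \code{denominator = "matched"} the divisor is the
#' number of matched pairs instead). \code{include_singletons = FALSE}
#' removes singleton clusters from both partitions, and their members from
#' the other side, before matching.
#'
#' @param A,B \code{pocket_clustering} objects over the same id set.
#' @param include_singletons keep size-1 clusters (default TRUE).
#' @param denominator \code{"max"} (default; identity is the unique
#'   maximizer) or \code{"matched"}.
#' @return An \code{ot_comparison}: list with \code{similarity},
#'   \code{matched_pairs} (data.frame cluster_a, cluster_b, jaccard),
#'   \code{include_singletons}.
#' @export
ot_cluster_similarity <- function(A, B, include_singletons = TRUE,
                                  denominator = c("max", "matched")) {
  denominator <- match.arg(denominator)
  if (!setequal(A$ids, B$ids))
    ps_stop("id_mismatch", "clusterings do not partition the same id set")
  if (include_singletons) {
    mA <- cluster_members(A); mB <- cluster_members(B)
  } else {
    dropped <- drop_singletons(A, B)
    mA <- dropped$A; mB <- dropped$B
  }
  empty_pairs <- data.frame(cluster_a = character(0),
                            cluster_b = character(0), jaccard = numeric(0))
  if (length(mA) == 0 && length(mB) == 0)
    return(structure(list(similarity = 1.0, matched_pairs = empty_pairs,
                          include_singletons = include_singletons),
                     class = "ot_comparison"))
  if (length(mA) == 0 || length(mB) == 0)
    return(structure(list(similarity = 0.0, matched_pairs = empty_pairs,
                          include_singletons = include_singletons),
                     class = "ot_comparison"))
  J <- matrix(0, length(mA), length(mB))
  for (i in seq_along(mA)) for (j in seq_along(mB)) {
    inter <- length(intersect(mA[[i]], mB[[j]]))
    if (inter > 0)
      J[i, j] <- inter / length(union(mA[[i]], mB[[j]]))
  }
  flip <- nrow(J) > ncol(J)
  Jm <- if (flip) t(J) else J
  sol <- clue::solve_LSAP(Jm, maximum = TRUE)
  rows <- seq_len(nrow(Jm)); cols <- as.integer(sol)
  ai <- if (flip) cols else rows
  bj <- if (flip) rows else cols
  jac <- J[cbind(ai, bj)]
  keep <- jac > 0
  total <- sum(jac)
  denom <- if (denominator == "max") max(length(mA), length(mB))
           else max(sum(keep), 1L)
  pairs <- data.frame(cluster_a = names(mA)[ai[keep]],
                      cluster_b = names(mB)[bj[keep]],
                      jaccard = jac[keep], stringsAsFactors = FALSE)
  structure(list(similarity = total / denom, matched_pairs = pairs,
                 include_singletons = include_singletons),
            class = "ot_comparison")
}

#' @export
print.ot_comparison <- function(x, ...) {
  cat("<ot_comparison> similarity =", format(x$similarity, digits = 3),
      if (!x$include_singletons) "(singletons excluded)", "\n")
  cat("  matched cluster pairs:", nrow(x$matched_pairs), "\n")
  invisible(x)
}

#' Scrambled-clustering null for the OT similarity
#'
#' Cluster sizes of \code{B} are retained while the pocket ids are
#' reshuffled uniformly at random across all clusters; the OT similarity
#' against \code{A} is averaged over \code{reps} scrambles.
#'
#' @param A,B \code{pocket_clustering} objects over the same id set.
#' @param reps number of scrambles (default 100).
#' @param seed integer seed (deterministic for a fixed seed).
#' @param include_singletons passed to [ot_cluster_similarity()].
#' @return Mean null similarity (numeric scalar), with the per-scramble
#'   similarities attached as attribute \code{"values"}.
#' @export
scrambled_null <- function(A, B, reps = 100, seed = 1,
                           include_singletons = TRUE) {
  ps_assert(reps >= 1, "bad_arg", "reps must be >= 1")
  with_seed(seed, {
    vals <- vapply(seq_len(reps), function(r) {
      Bp <- B
      Bp$ids <- sample(B$ids)
      ot_cluster_similarity(A, Bp,
                            include_singletons = include_singletons)$similarity
    }, numeric(1))
    structure(mean(vals), values = vals)
  })
}
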