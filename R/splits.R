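# Debiased train/test splits: whole similarity clusters (at threshold t) or
# whole MST branches are allocated to one side, so that no pair of
# near-duplicate pockets straddles the split.

split_spec <- function(train_ids, test_ids, method, t, provenance,
                       infeasible = FALSE) {
  ps_assert(length(intersect(train_ids, test_ids)) == 0, "bad_arg",
            "train and test overlap")
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 method = method, t = t, provenance = provenance,
                 infeasible = infeasible),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  n <- length(x$train_ids) + length(x$test_ids)
  cat(sprintf("<split_spec> %s split: %d train / %d test (%.1f%% test)%s\n",
              x$method, length(x$train_ids), length(x$test_ids),
              100 * length(x$test_ids) / n,
              if (x$infeasible) " [target fraction infeasible]" else ""))
  invisible(x)
}

#' Cluster-based train/test split
#'
#' Clusters are shuffled with the seed and assigned whole to the test side
#' until the test pocket count first reaches the target fraction; the
#' remainder goes to train. With \code{t = 0} (all singletons) this reduces
#' to a plain random split.
#'
#' @param C a \code{pocket_clustering}.
#' @param test_fraction target test fraction in (0, 1).
#' @param seed integer seed.
#' @return A \code{split_spec}; if a single cluster holds more than
#'   \code{(1 - test_fraction) * n} pockets the achievable fraction is
#'   flagged via \code{infeasible = TRUE}.
#' @export
cluster_split <- function(C, test_fraction, seed = 1) {
  ps_assert(test_fraction > 0 && test_fraction < 1, "bad_arg",
            "test_fraction must be in (0, 1)")
  members <- cluster_members(C)
  if (length(members) < 2)
    ps_stop("size_infeasible",
            "cannot split a single cluster without breaking it")
  n <- length(C$ids)
  target <- test_fraction * n
  ord <- with_seed(seed, sample(length(members)))
  test_clusters <- integer(0)
  count <- 0
  for (k in ord) {
    if (count >= target) break
    test_clusters <- c(test_clusters, k)
    count <- count + length(members[[k]])
  }
  if (length(test_clusters) == length(members)) {
    # keep the last-added cluster on the train side so both are non-empty
    test_clusters <- test_clusters[-length(test_clusters)]
  }
  test_ids <- unlist(members[test_clusters], use.names = FALSE)
  train_ids <- setdiff(C$ids, test_ids)
  infeasible <- max(lengths(members)) > (1 - test_fraction) * n
  split_spec(train_ids, test_ids, method = "cluster", t = C$t,
             provenance = list(seed = seed,
                               test_clusters = names(members)[test_clusters]),
             infeasible = infeasible)
}

#' Tree-based train/test split
#'
#' Removes entire branches of the pocket-atlas MST: each cut edge (u, v)
#' detaches the side containing v; cuts are applied sequentially on the
#' shrinking remainder. The test set is the union of the pockets of all
#' removed branches.
#'
#' @param tree a \code{pocket_tree} over the clusters of \code{C}.
#' @param C the \code{pocket_clustering} the tree was built from.
#' @param cut_edges list of length-2 character vectors (u, v).
#' @return A \code{split_spec}.
#' @export
tree_split <- function(tree, C, cut_edges) {
  if (length(cut_edges) == 0)
    ps_stop("empty_test", "no cut edges: test set would be empty")
  if (is.character(cut_edges) && length(cut_edges) == 2)
    cut_edges <- list(cut_edges)
  members <- cluster_members(C)
  removed <- character(0)
  cur <- tree
  for (ce in cut_edges) {
    part <- tree_branch(cur, ce)
    removed <- c(removed, part$branch)
    keep <- cur$nodes$label %in% part$remainder
    cur <- structure(list(nodes = cur$nodes[keep, , drop = FALSE],
                          edges = cur$edges[cur$edges$u %in% part$remainder &
                                              cur$edges$v %in% part$remainder,
                                            , drop = FALSE]),
                     class = "pocket_tree")
  }
  if (length(cur$nodes$label) == 0 ||
      setequal(removed, names(members)))
    ps_stop("empty_train", "cuts removed every cluster")
  test_ids <- unlist(members[removed], use.names = FALSE)
  train_ids <- unlist(members[cur$nodes$label], use.names = FALSE)
  split_spec(train_ids, test_ids, method = "tree", t = C$t,
             provenance = list(cut_edges = cut_edges, branches = removed))
}

#' Rebalance a split toward a target test fraction
#'
#' Whole clusters are moved between the sides (never splitting a cluster)
#' to bring the test fraction within +/- \code{tol} of the target; moves
#' are chosen greedily to minimize the count deviation, ties broken by the
#' smallest cluster label. When no sequence of whole-cluster moves can
#' reach the band, the best achievable split is returned with
#' \code{infeasible = TRUE} - a cluster is never broken silently.
#'
#' @param split a \code{split_spec}.
#' @param C the underlying \code{pocket_clustering}.
#' @param target_test_fraction target in (0, 1).
#' @param tol half-width of the acceptable band (default 0.05).
#' @return A \code{split_spec}.
#' @export
balance_to_size <- function(split, C, target_test_fraction, tol = 0.05) {
  members <- cluster_members(C)
  n <- length(C$ids)
  in_test <- vapply(members, function(m) all(m %in% split$test_ids),
                    logical(1))
  straddle <- vapply(members, function(m)
    any(m %in% split$test_ids) && !all(m %in% split$test_ids), logical(1))
  ps_assert(!any(straddle), "bad_arg",
            "split does not respect the clustering")
  sizes <- lengths(members)
  frac <- function(flags) sum(sizes[flags]) / n
  repeat {
    dev <- abs(frac(in_test) - target_test_fraction)
    if (dev <= tol) break
    cand_dev <- rep(Inf, length(members))
    for (k in seq_along(members)) {
      flags <- in_test
      flags[k] <- !flags[k]
      if (!any(flags) || all(flags)) next
      cand_dev[k] <- abs(frac(flags) - target_test_fraction)
    }
    best <- min(cand_dev)
    if (best >= dev - 1e-12) break  # no whole-cluster move improves
    k <- which(cand_dev <= best + 1e-12)
    k <- k[order(names(members)[k])][1]
    in_test[k] <- !in_test[k]
  }
  infeasible <- abs(frac(in_test) - target_test_fraction) > tol
  test_ids <- unlist(members[in_test], use.names = FALSE)
  split_spec(setdiff(C$ids, test_ids), test_ids, method = split$method,
             t = split$t,
             provenance = c(split$provenance, list(balanced_to =
                                                     target_test_fraction)),
             infeasible = infeasible)
}

#' Suggest a branch cut yielding a target test fraction
#'
#' Scans every tree edge in both orientations and returns the cut whose
#' detached branch holds the pocket fraction closest to the target; ties
#' are broken by the lexicographically smaller (u, v) pair.
#'
#' @param tree a \code{pocket_tree}.
#' @param C the underlying \code{pocket_clustering}.
#' @param target_fraction desired test (branch) fraction.
#' @return length-2 character vector (u, v) usable as a [tree_split()] cut.
#' @export
suggest_branch_cut <- function(tree, C, target_fraction = 0.25) {
  ps_assert(nrow(tree$edges) >= 1, "bad_arg", "tree has no edges")
  members <- cluster_members(C)
  n <- length(C$ids)
  best <- NULL
  best_dev <- Inf
  for (k in seq_len(nrow(tree$edges))) {
    for (or in list(c(tree$edges$u[k], tree$edges$v[k]),
                    c(tree$edges$v[k], tree$edges$u[k]))) {
      part <- tree_branch(tree, or)
      frac <- sum(lengths(members[part$branch])) / n
      dev <- abs(frac - target_fraction)
      if (dev < best_dev - 1e-12 ||
          (dev < best_dev + 1e-12 && !is.null(best) &&
             paste(or, collapse = "\r") < paste(best, collapse = "\r"))) {
        best <- or
        best_dev <- dev
      }
    }
  }
  best
}

#' Count train-test leakage under a distance threshold
#'
#' A violating pair is a train pocket and a test pocket with distance
#' strictly below \code{t}. Splits built from whole clusters at threshold
#' \code{t} have zero violating pairs at that \code{t} by the separation
#' guarantee.
#'
#' @param split a \code{split_spec}.
#' @param D a \code{pocket_dist} covering the split ids.
#' @param t leakage threshold on the native scale of \code{D}.
#' @param max_examples cap on the reported example pairs.
#' @return A \code{leakage_report}: list with \code{n_violating_pairs},
#'   \code{min_cross_distance}, \code{violating_examples}.
#' @export
validate_split <- function(split, D, t, max_examples = 20) {
  ids <- rownames(D)
  if (!all(c(split$train_ids, split$test_ids) %in% ids))
    ps_stop("id_mismatch", "split ids missing from the distance matrix")
  cross <- D[split$train_ids, split$test_ids, drop = FALSE]
  viol <- which(cross < t, arr.ind = TRUE)
  ex <- head(data.frame(train_id = split$train_ids[viol[, 1]],
                        test_id = split$test_ids[viol[, 2]],
                        d = cross[viol], stringsAsFactors = FALSE),
             max_examples)
  structure(list(n_violating_pairs = nrow(viol),
                 min_cross_distance = min(cross),
                 violating_examples = ex, t = t),
            class = "leakage_report")
}

#' @export
print.leakage_report <- function(x, ...) {
  cat(sprintf("<leakage_report> %d train-test pairs below t = %g (min cross distance %.4f)\n",
              x$n_violating_pairs, x$t, x$min_cross_distance))
  invisible(x)
}
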