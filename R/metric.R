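# Pocket-pocket distance matrices and the onset/global correlation analysis.

#' Pairwise Euclidean distances between pocket embeddings
#'
#' @param vectors a list of \code{pocket_embedding} objects, or a numeric
#'   matrix with one pocket per row (rownames as ids, optionally an
#'   \code{embedder_id} attribute).
#' @return A \code{pocket_dist}: symmetric n x n matrix with zero diagonal,
#'   id dimnames, and attributes \code{metric_id} and \code{normalized}.
#' @export
pairwise_distances <- function(vectors) {
  if (is.list(vectors) && !is.matrix(vectors)) {
    embedders <- unique(vapply(vectors, function(v) v$embedder_id,
                               character(1)))
    dims <- unique(vapply(vectors, function(v) length(v$vector), integer(1)))
    if (length(embedders) > 1 || length(dims) > 1)
      ps_stop("embedder_mismatch",
              "pocket vectors come from different embedders: %s",
              paste(embedders, collapse = " vs "))
    ids <- vapply(vectors, function(v) v$pocket_id, character(1))
    M <- do.call(rbind, lapply(vectors, function(v) v$vector))
    rownames(M) <- ids
    attr(M, "embedder_id") <- embedders
    vectors <- M
  }
  ps_assert(nrow(vectors) >= 2, "bad_arg", "need at least 2 pockets")
  ids <- rownames(vectors) %||% as.character(seq_len(nrow(vectors)))
  D <- as.matrix(stats::dist(vectors))  # one computation per unordered pair
  dimnames(D) <- list(ids, ids)
  structure(D, metric_id = paste0("euclidean/",
                                  attr(vectors, "embedder_id") %||% "raw"),
            normalized = FALSE, class = c("pocket_dist", "matrix", "array"))
}

#' Wrap an externally produced distance matrix
#'
#' @param D symmetric numeric matrix with zero diagonal.
#' @param ids pocket ids (defaults to rownames).
#' @param metric_id label for the metric that produced \code{D}.
#' @return A \code{pocket_dist}.
#' @export
as_pocket_dist <- function(D, ids = rownames(D), metric_id = "external") {
  D <- as.matrix(D)
  ps_assert(nrow(D) == ncol(D) && all(abs(D - t(D)) < 1e-9) &&
              all(diag(D) == 0) && all(is.finite(D)) && all(D >= 0),
            "bad_arg", "D must be symmetric, non-negative, zero-diagonal")
  ids <- ids %||% as.character(seq_len(nrow(D)))
  dimnames(D) <- list(ids, ids)
  structure(D, metric_id = metric_id, normalized = FALSE,
            class = c("pocket_dist", "matrix", "array"))
}

#' Min-max normalize a distance matrix
#'
#' Maps the off-diagonal entries linearly onto [0, 1]; the diagonal stays
#' zero. The native-to-normalized threshold map is attached as attribute
#' \code{scale} (c(min, max)); see [normalize_threshold()].
#'
#' @param D a \code{pocket_dist}.
#' @return The normalized \code{pocket_dist}.
#' @export
minmax_normalize <- function(D) {
  off <- D[upper.tri(D)]
  lo <- min(off); hi <- max(off)
  if (hi <= lo)
    ps_stop("degenerate_scale", "all off-diagonal distances are equal")
  out <- (D - lo) / (hi - lo)
  diag(out) <- 0
  attributes(out) <- attributes(D)
  attr(out, "normalized") <- TRUE
  attr(out, "scale") <- c(min = lo, max = hi)
  out
}

#' Map a native-scale threshold onto the normalized scale
#' @param D a normalized \code{pocket_dist} (output of [minmax_normalize()]).
#' @param t threshold on the native scale of the metric.
#' @return The threshold on the min-max normalized scale.
#' @export
normalize_threshold <- function(D, t) {
  s <- attr(D, "scale")
  ps_assert(!is.null(s), "bad_arg", "D carries no normalization scale")
  unname((t - s["min"]) / (s["max"] - s["min"]))
}

#' @export
print.pocket_dist <- function(x, ...) {
  cat("<pocket_dist>", nrow(x), "pockets |", attr(x, "metric_id"),
      if (isTRUE(attr(x, "normalized"))) "| min-max normalized", "\n")
  invisible(x)
}

#' Flatten a distance matrix to the canonical pair vector
#'
#' Row-major upper triangle (i < j) of the id-sorted matrix, so that two
#' metrics over the same id set align pair for pair.
#'
#' @param D a \code{pocket_dist}.
#' @return Named numeric vector of n(n-1)/2 pair distances.
#' @export
pair_vector <- function(D) {
  ord <- order(rownames(D))
  M <- D[ord, ord]
  n <- nrow(M)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(2:n, function(k) k:n))
  out <- M[cbind(i, j)]
  names(out) <- paste(rownames(M)[i], rownames(M)[j], sep = "|")
  out
}

#' Global-alignment sequence distance
#'
#' One minus the global (Needleman-Wunsch) alignment identity, where
#' identity is the number of identical aligned positions divided by the
#' alignment length including gaps (the EMBOSS Needle convention), scored
#' with BLOSUM62 and affine gap penalties.
#'
#' @param seq_a,seq_b one-letter amino-acid strings.
#' @param gap_open,gap_extend affine gap penalties (defaults 10 / 0.5).
#' @return Distance in [0, 1]; 0 iff the sequences are identical.
#' @export
sequence_distance <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a %||% "") || !nzchar(seq_b %||% ""))
    ps_stop("empty_input", "sequences must be non-empty")
  mat <- get_blosum62()
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b,
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend,
                                       type = "global")
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  # aligned strings clip terminal gaps; add the unaligned overhang back so
  # the denominator is the full alignment length including end gaps
  res_p <- nchar(gsub("-", "", p))
  res_s <- nchar(gsub("-", "", s))
  len <- nchar(p) + (nchar(seq_a) - res_p) + (nchar(seq_b) - res_s)
  1 - Biostrings::nmatch(aln) / len
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Onset and global rank correlation between two metrics
#'
#' The onset region contains the pocket pairs that at least one of the two
#' metrics deems similar: pairs with \code{dist_a < t_max_a} OR
#' \code{dist_b < t_max_b} (strictly below, on each metric's native scale).
#' Spearman rank correlation (ties by average rank) is reported on the
#' onset subset and on all pairs; an onset subset smaller than 3 yields an
#' NA onset correlation.
#'
#' @param dist_a,dist_b aligned pair-distance vectors (see [pair_vector()]).
#' @param t_max_a,t_max_b maximum clustering thresholds of the two metrics,
#'   native scale.
#' @return A \code{correlation_report}: list with \code{rho_onset},
#'   \code{rho_global}, \code{n_onset}, \code{n_total}, \code{thresholds}.
#' @export
onset_correlation <- function(dist_a, dist_b, t_max_a, t_max_b) {
  if (length(dist_a) != length(dist_b))
    ps_stop("shape_error", "pair vectors have different lengths")
  ps_assert(length(dist_a) >= 3, "bad_arg", "need at least 3 pairs")
  onset <- dist_a < t_max_a | dist_b < t_max_b
  rho_global <- suppressWarnings(cor(dist_a, dist_b, method = "spearman"))
  rho_onset <- if (sum(onset) < 3) NA_real_ else
    suppressWarnings(cor(dist_a[onset], dist_b[onset], method = "spearman"))
  structure(list(rho_onset = rho_onset, rho_global = rho_global,
                 n_onset = sum(onset), n_total = length(dist_a),
                 thresholds = c(t_max_a = t_max_a, t_max_b = t_max_b)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>\n")
  cat(sprintf("  rho_onset  = %s  (n = %d of %d pairs below t_max = %g / %g)\n",
              format(x$rho_onset, digits = 3), x$n_onset, x$n_total,
              x$thresholds[1], x$thresholds[2]))
  cat(sprintf("  rho_global = %s\n", format(x$rho_global, digits = 3)))
  invisible(x)
}

#' Pick a clustering threshold from the distance distribution
#'
#' Heuristic used by the end-to-end examples: the single-linkage merge
#' heights of the pocket set are the edge weights of its minimum spanning
#' tree; the threshold is placed in the middle of the largest jump of the
#' sorted merge heights (the knee of the single-linkage dendrogram). Raw
#' pairwise-distance gaps are dominated by sparse tails; merge heights are
#' not.
#'
#' @param D a \code{pocket_dist}.
#' @return A threshold on the native scale.
#' @export
choose_threshold <- function(D) {
  M <- unclass(D)
  w <- sort(build_mst(M)$edges$weight)
  if (length(w) == 1) return(w)
  gaps <- diff(w)
  k <- which.max(gaps)
  (w[k] + w[k + 1]) / 2
}
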