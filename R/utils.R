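# Internal helpers shared across modules.

# Classed error conditions; `class` is a short snake_case tag, e.g.
# "ligand_not_found" -> condition classes c("pocketsim_ligand_not_found",
# "pocketsim_error", "error", "condition").
ps_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("pocketsim_", class), "pocketsim_error")))
}

ps_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) ps_stop(class, msg, ...)
  invisible(TRUE)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Union-find with path halving; `edges` is a 2-column integer matrix (1-based
# vertex indices). Returns 1-based component labels, canonicalized so that
# components are numbered by their smallest member index.
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

# Pairwise Euclidean distances between rows of A and rows of B (dense, small n).
cross_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
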