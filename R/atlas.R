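# The pocket atlas: a minimum spanning tree over clusters, weighted by the
# minimum distance of approach between clusters, plus spatial coherence
# statistics (Moran's I) of cluster annotations.

#' Minimum distance of approach between clusters
#'
#' Entry (A, B) is the minimum of the pocket-pocket distance over all pairs
#' with one pocket in each cluster; the diagonal is zero. With an
#' all-singleton clustering this is the pocket matrix itself.
#'
#' @param D a \code{pocket_dist}.
#' @param C a \code{pocket_clustering} over the ids of \code{D}.
#' @return Symmetric cluster-level distance matrix with cluster labels
#'   (as characters) for dimnames and cluster sizes as attribute
#'   \code{sizes}.
#' @export
cluster_min_distances <- function(D, C) {
  if (!setequal(C$ids, rownames(D)))
    ps_stop("id_mismatch", "clustering does not partition D's ids")
  members <- cluster_members(C)
  K <- length(members)
  CD <- matrix(0, K, K, dimnames = list(names(members), names(members)))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (j <= i) next
      CD[i, j] <- CD[j, i] <- min(D[members[[i]], members[[j]]])
    }
  }
  attr(CD, "sizes") <- lengths(members)
  CD
}

#' Build the pocket-atlas minimum spanning tree
#'
#' Kruskal's algorithm over the complete cluster graph; ties are broken by
#' preferring the edge with the lexicographically smaller (u, v) label
#' pair, making the tree deterministic.
#'
#' @param cluster_D cluster-level distance matrix (see
#'   [cluster_min_distances()]).
#' @return A \code{pocket_tree}: list with \code{nodes} (data.frame label,
#'   size) and \code{edges} (data.frame u, v, weight; |edges| = |nodes| - 1).
#' @export
build_mst <- function(cluster_D) {
  K <- nrow(cluster_D)
  labels <- rownames(cluster_D) %||% as.character(seq_len(K) - 1L)
  sizes <- attr(cluster_D, "sizes") %||% rep(NA_integer_, K)
  nodes <- data.frame(label = labels, size = as.integer(sizes),
                      stringsAsFactors = FALSE)
  if (K == 1) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(u = character(0),
                                             v = character(0),
                                             weight = numeric(0))),
                     class = "pocket_tree"))
  }
  iu <- rep(seq_len(K - 1), times = (K - 1):1)
  iv <- unlist(lapply(2:K, function(k) k:K))
  w <- cluster_D[cbind(iu, iv)]
  ord <- order(w, labels[iu], labels[iv])
  parent <- seq_len(K)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- integer(0)
  for (e in ord) {
    ra <- find(iu[e]); rb <- find(iv[e])
    if (ra != rb) {
      parent[max(ra, rb)] <- min(ra, rb)
      keep <- c(keep, e)
      if (length(keep) == K - 1) break
    }
  }
  edges <- data.frame(u = labels[iu[keep]], v = labels[iv[keep]],
                      weight = w[keep], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "pocket_tree")
}

#' @export
print.pocket_tree <- function(x, ...) {
  cat("<pocket_tree>", nrow(x$nodes), "clusters,", nrow(x$edges),
      "edges, total weight", format(sum(x$edges$weight), digits = 4), "\n")
  invisible(x)
}

tree_adjacency <- function(tree, drop_edge = NULL) {
  e <- tree$edges
  if (!is.null(drop_edge)) e <- e[-drop_edge, , drop = FALSE]
  adj <- lapply(setNames(vector("list", nrow(tree$nodes)),
                         tree$nodes$label), function(x) character(0))
  for (k in seq_len(nrow(e))) {
    adj[[e$u[k]]] <- c(adj[[e$u[k]]], e$v[k])
    adj[[e$v[k]]] <- c(adj[[e$v[k]]], e$u[k])
  }
  adj
}

reachable_from <- function(adj, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Split a tree at one edge into branch and remainder
#'
#' Deleting \code{cut_edge = c(u, v)} disconnects the tree; the branch is
#' the side containing \code{v} (the child side of the directed cut), the
#' remainder the side containing \code{u}.
#'
#' @param tree a \code{pocket_tree}.
#' @param cut_edge length-2 character vector (u, v); the unordered pair
#'   must be an edge of the tree.
#' @return list with \code{branch} and \code{remainder} label vectors.
#' @export
tree_branch <- function(tree, cut_edge) {
  u <- as.character(cut_edge[1]); v <- as.character(cut_edge[2])
  k <- which((tree$edges$u == u & tree$edges$v == v) |
               (tree$edges$u == v & tree$edges$v == u))
  if (length(k) != 1)
    ps_stop("edge_not_found", "(%s, %s) is not an edge of the tree", u, v)
  adj <- tree_adjacency(tree, drop_edge = k)
  branch <- sort(reachable_from(adj, v))
  list(branch = branch, remainder = sort(setdiff(tree$nodes$label, branch)))
}

#' Moran's I spatial coherence of cluster annotations
#'
#' Measures whether a numeric cluster property varies smoothly over the
#' pocket metric space:
#' \deqn{I = (n/W) \sum_{i \ne j} w_{ij} (x_i - \bar x)(x_j - \bar x) /
#'       \sum_i (x_i - \bar x)^2}
#' with weights \eqn{w_{ij} = 1/d_{ij}} (inverse inter-cluster distance,
#' the default) or \eqn{w_{ij} = 1} on MST edges. The null distribution is
#' estimated from uniform random permutations of the values; its analytic
#' mean is \eqn{-1/(n-1)}.
#'
#' @param values numeric vector, one value per cluster (names, if present,
#'   must match the cluster labels of \code{cluster_D}).
#' @param cluster_D cluster-level distance matrix.
#' @param weight_scheme \code{"inverse-distance"} or \code{"mst-adjacency"}.
#' @param null_reps permutations for the null (default 1000).
#' @param seed integer seed for the permutations.
#' @param tree optional \code{pocket_tree} for the MST scheme (built from
#'   \code{cluster_D} when absent).
#' @return A \code{moran_report}: list with \code{I}, \code{I_null_mean},
#'   \code{null_reps}, \code{n_used}, \code{weight_scheme},
#'   \code{null_values}.
#' @export
morans_i <- function(values, cluster_D,
                     weight_scheme = c("inverse-distance", "mst-adjacency"),
                     null_reps = 1000, seed = 1, tree = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  n <- nrow(cluster_D)
  ps_assert(n >= 3, "bad_arg", "need at least 3 clusters")
  ps_assert(length(values) == n, "id_mismatch",
            "one value per cluster required")
  if (!is.null(names(values)) && !is.null(rownames(cluster_D)))
    values <- values[rownames(cluster_D)]
  if (sd(values) == 0)
    ps_stop("degenerate_variance", "values are constant across clusters")
  off <- upper.tri(cluster_D) | lower.tri(cluster_D)
  if (weight_scheme == "inverse-distance") {
    if (any(cluster_D[off] <= 0))
      ps_stop("weight_error",
              "zero inter-cluster distance: duplicate pockets across clusters")
    W <- 1 / cluster_D
    diag(W) <- 0
  } else {
    if (is.null(tree)) tree <- build_mst(cluster_D)
    W <- matrix(0, n, n, dimnames = dimnames(cluster_D))
    for (k in seq_len(nrow(tree$edges)))
      W[tree$edges$u[k], tree$edges$v[k]] <-
        W[tree$edges$v[k], tree$edges$u[k]] <- 1
  }
  Wsum <- sum(W)
  stat <- function(x) {
    z <- x - mean(x)
    (n / Wsum) * sum(W * outer(z, z)) / sum(z^2)
  }
  I <- stat(values)
  nulls <- with_seed(seed, vapply(seq_len(null_reps),
                                  function(r) stat(sample(values)),
                                  numeric(1)))
  structure(list(I = I, I_null_mean = mean(nulls), null_reps = null_reps,
                 n_used = n, weight_scheme = weight_scheme,
                 null_values = nulls),
            class = "moran_report")
}

#' @export
print.moran_report <- function(x, ...) {
  cat(sprintf("<moran_report> I = %.4f (null mean %.4f over %d perms, n = %d, %s)\n",
              x$I, x$I_null_mean, x$null_reps, x$n_used, x$weight_scheme))
  invisible(x)
}

#' Export the pocket atlas for external layout tools
#'
#' Nodes carry cluster size plus any annotation columns; edges carry the
#' minimum-distance weights. GraphML output is suitable for topological
#' layout or network tools; \code{"edge-tsv"} writes a plain u/v/weight
#' table.
#'
#' @param tree a \code{pocket_tree}.
#' @param path output file.
#' @param metadata optional data.frame of per-cluster annotations, either
#'   with a \code{label} column or rownames matching node labels.
#' @param format \code{"graphml"} or \code{"edge-tsv"}.
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(tree, path, metadata = NULL,
                         format = c("graphml", "edge-tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) ps_stop("format_error",
                                                 "unknown format '%s'",
                                                 format[1]))
  if (format == "edge-tsv") {
    write.table(tree$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    tree$edges[, c("u", "v")],
    directed = FALSE,
    vertices = data.frame(name = tree$nodes$label,
                          stringsAsFactors = FALSE))
  if (nrow(tree$edges))
    igraph::E(g)$weight <- tree$edges$weight
  igraph::V(g)$size <- tree$nodes$size[match(igraph::V(g)$name,
                                             tree$nodes$label)]
  if (!is.null(metadata)) {
    meta <- as.data.frame(metadata)
    key <- if ("label" %in% names(meta)) as.character(meta$label)
           else rownames(meta)
    for (col in setdiff(names(meta), "label")) {
      vals <- meta[[col]][match(igraph::V(g)$name, key)]
      g <- igraph::set_vertex_attr(g, col, value = vals)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
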