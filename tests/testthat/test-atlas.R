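three_cluster_setup <- function() {
  M <- matrix(c(0, 0.5, 2, 5, 0.5, 0, 2.2, 5.5, 2, 2.2, 0, 3, 5, 5.5, 3, 0),
              4, dimnames = list(sprintf("p%d", 1:4), sprintf("p%d", 1:4)))
  D <- as_pocket_dist(M)
  C <- make_clustering(rownames(M), c(0, 0, 1, 2), t = 1)
  list(D = D, C = C)
}

test_that("cluster-level distances are minima of approach", {
  s <- three_cluster_setup()
  CD <- cluster_min_distances(s$D, s$C)
  expect_equal(dim(CD), c(3L, 3L))
  expect_equal(CD["0", "1"], 2)    # min(d13, d23)
  expect_equal(CD["0", "2"], 5)
  expect_equal(CD["1", "2"], 3)
  expect_equal(unname(diag(CD)), c(0, 0, 0))
  # all-singleton clustering reproduces the pocket matrix
  Cs <- make_clustering(rownames(s$D), 0:3)
  CDs <- cluster_min_distances(s$D, Cs)
  expect_equal(unname(CDs[1:4, 1:4]), unname(unclass(s$D)[1:4, 1:4]))
  # single cluster: 1 x 1 zero matrix
  C1 <- make_clustering(rownames(s$D), rep(0, 4))
  expect_equal(unname(cluster_min_distances(s$D, C1)[1, 1]), 0)
  expect_equal(dim(cluster_min_distances(s$D, C1)), c(1L, 1L))
})

test_that("MST picks the lightest spanning edges deterministically", {
  W <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3,
              dimnames = list(c("0", "1", "2"), c("0", "1", "2")))
  tree <- build_mst(W)
  expect_equal(nrow(tree$edges), 2)
  expect_equal(sum(tree$edges$weight), 3)  # edges of weight 1 and 2
  # single node: empty edge set
  expect_equal(nrow(build_mst(matrix(0, 1, 1,
                                     dimnames = list("0", "0")))$edges), 0)
  # all-equal weights: any tree is minimal; the tie rule makes it stable
  E <- matrix(1, 4, 4); diag(E) <- 0
  dimnames(E) <- list(letters[1:4], letters[1:4])
  t1 <- build_mst(E); t2 <- build_mst(E)
  expect_identical(t1$edges, t2$edges)
  expect_equal(sum(t1$edges$weight), 3)
})

test_that("MST weight equals the brute-force minimum over all spanning trees", {
  for (s in 1:6) {
    n <- 4 + s %% 3
    M <- pocketsim:::with_seed(200 + s,
                               as.matrix(dist(matrix(rnorm(n * 3), n))))
    dimnames(M) <- list(as.character(seq_len(n) - 1),
                        as.character(seq_len(n) - 1))
    tree <- build_mst(M)
    expect_equal(sum(tree$edges$weight), oracle_mst_weight(M),
                 tolerance = 1e-12)
    expect_equal(nrow(tree$edges), n - 1)
  }
})

test_that("tree branches partition the nodes at the cut", {
  tree <- build_mst(matrix(c(0, 1, 9, 1, 0, 2, 9, 2, 0), 3,
                           dimnames = list(c("a", "b", "c"),
                                           c("a", "b", "c"))))
  # path a - b - c
  part <- tree_branch(tree, c("a", "b"))
  expect_equal(part$branch, c("b", "c"))
  expect_equal(part$remainder, "a")
  rev_ <- tree_branch(tree, c("b", "a"))
  expect_equal(rev_$branch, "a")
  expect_setequal(c(part$branch, part$remainder), tree$nodes$label)
  expect_error(tree_branch(tree, c("a", "c")),
               class = "pocketsim_edge_not_found")
  # star: cutting a leaf edge detaches exactly that leaf
  star <- build_mst(matrix(c(0, 1, 1, 1, 1, 0, 9, 9, 1, 9, 0, 9, 1, 9, 9, 0),
                           4, dimnames = list(c("s", "x", "y", "z"),
                                              c("s", "x", "y", "z"))))
  expect_equal(tree_branch(star, c("s", "y"))$branch, "y")
})

test_that("Moran's I permutation null matches the analytic mean", {
  n <- 10
  CD <- pocketsim:::with_seed(55, as.matrix(dist(matrix(rnorm(n * 2), n))))
  dimnames(CD) <- list(as.character(1:n - 1), as.character(1:n - 1))
  vals <- pocketsim:::with_seed(56, rnorm(n))
  rep_ <- morans_i(vals, CD, null_reps = 2000, seed = 3)
  se <- sd(rep_$null_values) / sqrt(rep_$null_reps)
  expect_lt(abs(rep_$I_null_mean - (-1 / (n - 1))), 3 * se)
})

test_that("block-structured values are spatially coherent; degenerate input errors", {
  # two tight value-blocks at the ends of a path-like geometry
  pos <- matrix(c(1:10, rep(0, 10)), 10)
  CD <- as.matrix(dist(pos))
  dimnames(CD) <- list(as.character(0:9), as.character(0:9))
  vals <- c(rep(0, 5), rep(1, 5))
  rep_ <- morans_i(vals, CD, null_reps = 500, seed = 7)
  expect_gt(rep_$I, rep_$I_null_mean)
  expect_error(morans_i(rep(1, 10), CD),
               class = "pocketsim_degenerate_variance")
  CD0 <- CD; CD0[1, 2] <- CD0[2, 1] <- 0
  expect_error(morans_i(vals, CD0), class = "pocketsim_weight_error")
})

test_that("Moran's I is affine invariant and consistent across weight paths", {
  n <- 8
  CD <- pocketsim:::with_seed(60, as.matrix(dist(matrix(rnorm(n * 2), n))))
  dimnames(CD) <- list(as.character(1:n - 1), as.character(1:n - 1))
  vals <- pocketsim:::with_seed(61, rnorm(n))
  a <- morans_i(vals, CD, null_reps = 10, seed = 1)
  b <- morans_i(3 * vals - 7, CD, null_reps = 10, seed = 1)
  expect_equal(a$I, b$I, tolerance = 1e-12)
  # mst-adjacency equals the same statistic computed from the 0/1 matrix
  tree <- build_mst(CD)
  m <- morans_i(vals, CD, weight_scheme = "mst-adjacency", null_reps = 5,
                seed = 1, tree = tree)
  W <- matrix(0, n, n)
  for (k in seq_len(nrow(tree$edges))) {
    i <- as.integer(tree$edges$u[k]) + 1
    j <- as.integer(tree$edges$v[k]) + 1
    W[i, j] <- W[j, i] <- 1
  }
  z <- vals - mean(vals)
  expect_equal(m$I, (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2),
               tolerance = 1e-12)
})

test_that("graph export produces valid GraphML and edge tables", {
  s <- three_cluster_setup()
  CD <- cluster_min_distances(s$D, s$C)
  tree <- build_mst(CD)
  meta <- data.frame(label = c("0", "1", "2"),
                     ec_class = c("hydrolase", "kinase", "kinase"))
  gml <- tempfile(fileext = ".graphml")
  export_graph(tree, gml, metadata = meta)
  doc <- xml2::read_xml(gml)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:node", ns)), 3)
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:edge", ns)), 2)
  keys <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:key", ns), "attr.name")
  expect_true(all(c("weight", "size", "ec_class") %in% keys))
  tsv <- tempfile(fileext = ".tsv")
  export_graph(tree, tsv, format = "edge-tsv")
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 2)
  expect_equal(names(tab), c("u", "v", "weight"))
  expect_error(export_graph(tree, tempfile(), format = "gexf"),
               class = "pocketsim_format_error")
})
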