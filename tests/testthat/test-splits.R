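test_that("cluster splits allocate whole clusters to the target fraction", {
  ids <- sprintf("p%02d", 1:10)
  singl <- make_clustering(ids, 0:9)
  sp <- cluster_split(singl, 0.2, seed = 3)
  expect_length(sp$test_ids, 2)
  expect_length(sp$train_ids, 8)
  expect_false(sp$infeasible)
  # two equal clusters at fraction 0.5: one cluster per side
  two <- make_clustering(ids, rep(0:1, each = 5))
  sp2 <- cluster_split(two, 0.5, seed = 1)
  expect_length(sp2$test_ids, 5)
  # giant cluster: infeasible flagged but a split is still returned
  giant <- make_clustering(ids, c(rep(0, 9), 1))
  sp3 <- cluster_split(giant, 0.2, seed = 1)
  expect_true(sp3$infeasible)
  expect_true(length(sp3$test_ids) %in% c(1, 9))
  expect_length(c(sp3$test_ids, sp3$train_ids), 10)
  expect_error(cluster_split(singl, 1.2, seed = 1), class = "pocketsim_error")
})

test_that("cluster splits are deterministic per seed", {
  ids <- sprintf("p%02d", 1:20)
  C <- make_clustering(ids, rep(0:4, each = 4))
  expect_identical(cluster_split(C, 0.3, seed = 5)$test_ids,
                   cluster_split(C, 0.3, seed = 5)$test_ids)
  expect_false(identical(cluster_split(C, 0.3, seed = 5)$test_ids,
                         cluster_split(C, 0.3, seed = 6)$test_ids))
})

path_tree_setup <- function() {
  # path a - b - c with 2 pockets per cluster
  W <- matrix(c(0, 1, 9, 1, 0, 2, 9, 2, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- build_mst(W)
  ids <- sprintf("p%d", 1:6)
  C <- make_clustering(ids, rep(0:2, each = 2))
  C$labels <- rep(c("a", "b", "c"), each = 2)
  # make labels integer-compatible with cluster_members: use named mapping
  C <- structure(list(ids = ids, labels = rep(0:2, each = 2), t = 1,
                      n_clusters = 3), class = "pocket_clustering")
  # relabel tree nodes to the clustering labels 0,1,2
  map <- c(a = "0", b = "1", c = "2")
  tree$nodes$label <- unname(map[tree$nodes$label])
  tree$edges$u <- unname(map[tree$edges$u])
  tree$edges$v <- unname(map[tree$edges$v])
  list(tree = tree, C = C)
}

test_that("tree splits remove whole branches sequentially", {
  s <- path_tree_setup()
  sp <- tree_split(s$tree, s$C, list(c("0", "1")))
  expect_setequal(sp$test_ids, sprintf("p%d", 3:6))  # clusters 1 and 2
  expect_setequal(sp$train_ids, sprintf("p%d", 1:2))
  expect_error(tree_split(s$tree, s$C, list()), class = "pocketsim_empty_test")
  expect_error(tree_split(s$tree, s$C, list(c("0", "2"))),
               class = "pocketsim_edge_not_found")
  # a cut inside an already-removed branch is gone from the shrinking tree
  expect_error(tree_split(s$tree, s$C, list(c("0", "1"), c("1", "2"))),
               class = "pocketsim_edge_not_found")
  # no cluster straddles the split
  members <- split(s$C$ids, s$C$labels)
  for (m in members)
    expect_true(all(m %in% sp$test_ids) || all(m %in% sp$train_ids))
})

test_that("balance_to_size moves whole clusters toward the target", {
  ids <- sprintf("p%02d", 1:20)
  C <- make_clustering(ids, rep(0:9, each = 2))
  sp <- cluster_split(C, 0.35, seed = 2)
  bal <- balance_to_size(sp, C, 0.20)
  frac <- length(bal$test_ids) / 20
  expect_gte(frac, 0.15)
  expect_lte(frac, 0.25)
  expect_false(bal$infeasible)
  # idempotence when already within tolerance
  bal2 <- balance_to_size(bal, C, 0.20)
  expect_setequal(bal2$test_ids, bal$test_ids)
  # two clusters only: best achievable is flagged
  C2 <- make_clustering(ids, rep(0:1, each = 10))
  sp2 <- cluster_split(C2, 0.5, seed = 1)
  bal3 <- balance_to_size(sp2, C2, 0.2)
  expect_true(bal3$infeasible)
  expect_length(c(bal3$test_ids, bal3$train_ids), 20)
})

test_that("splits built at threshold t show no leakage below t", {
  for (s in 1:10) {
    D <- random_pocket_dist(30, dim = 3, seed = 300 + s)
    t <- quantile(D[upper.tri(D)], 0.2)
    C <- cluster_single_linkage(D, t)
    if (C$n_clusters < 2) next
    sp <- cluster_split(C, 0.3, seed = s)
    rep_ <- validate_split(sp, D, t)
    expect_equal(rep_$n_violating_pairs, 0)
    expect_gte(rep_$min_cross_distance, t)
  }
})

test_that("random splits of a tight cluster do leak at generous thresholds", {
  D <- random_pocket_dist(20, dim = 3, seed = 12)
  C0 <- cluster_single_linkage(D, 0)
  sp <- cluster_split(C0, 0.5, seed = 1)
  big_t <- max(D) * 1.01
  expect_gt(validate_split(sp, D, big_t)$n_violating_pairs, 0)
  expect_equal(validate_split(sp, D, 0)$n_violating_pairs, 0)
  expect_error(validate_split(sp, random_pocket_dist(5, seed = 1), 1),
               class = "pocketsim_id_mismatch")
})

test_that("suggest_branch_cut returns a tree edge near the target fraction", {
  bench <- generate_split_benchmark(seed = 2)
  D <- pairwise_distances(bench$vectors)
  C <- cluster_single_linkage(D, 2.4)
  tree <- build_mst(cluster_min_distances(D, C))
  cut <- suggest_branch_cut(tree, C, 0.25)
  expect_true(any((tree$edges$u == cut[1] & tree$edges$v == cut[2]) |
                    (tree$edges$u == cut[2] & tree$edges$v == cut[1])))
  sp <- tree_split(tree, C, list(cut))
  frac <- length(sp$test_ids) / length(C$ids)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.45)
})
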