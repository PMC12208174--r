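# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive quantities by brute force (enumeration, closed
# form, exhaustive search) and never call the production code paths they
# are checking.

# --- Delaunay / Voronoi adjacency oracle --------------------------------
# Points i and j are Voronoi-facet neighbours iff some tetrahedron
# (i, j, k, l) has an empty circumsphere (general-position point sets).
circumsphere <- function(P) {
  # P: 4 x 3; returns list(center, r2) or NULL when degenerate
  A <- 2 * (P[2:4, , drop = FALSE] -
              matrix(P[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(P[2:4, , drop = FALSE]^2) - sum(P[1, ]^2)
  det_a <- det(A)
  if (!is.finite(det_a) || abs(det_a) < 1e-10) return(NULL)
  c0 <- solve(A, b)
  list(center = c0, r2 = sum((P[1, ] - c0)^2))
}

oracle_delaunay_neighbors <- function(X, i, j, tol = 1e-7) {
  n <- nrow(X)
  others <- setdiff(seq_len(n), c(i, j))
  d2 <- function(c0) colSums((t(X) - c0)^2)
  # order candidate third/fourth points near the pair first: a witness
  # tetrahedron, when it exists, is usually local
  mid <- (X[i, ] + X[j, ]) / 2
  others <- others[order(colSums((t(X[others, , drop = FALSE]) - mid)^2))]
  m <- length(others)
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      cs <- circumsphere(X[c(i, j, others[a], others[b]), ])
      if (is.null(cs)) next
      if (all(d2(cs$center)[setdiff(seq_len(n),
                                    c(i, j, others[a], others[b]))] >=
                cs$r2 - tol * max(cs$r2, 1)))
        return(TRUE)
    }
  }
  FALSE
}

# Interface residues by brute-force tessellation: all ligand-protein atom
# pairs within the radius, facet sharing decided by the tetrahedron oracle.
oracle_interface <- function(complex, radius) {
  P <- cbind(complex$atoms$x, complex$atoms$y, complex$atoms$z)
  G <- cbind(complex$ligand$x, complex$ligand$y, complex$ligand$z)
  X <- rbind(P, G)
  d <- pocketsim:::cross_dist(P, G)
  cand <- which(d <= radius, arr.ind = TRUE)
  hit <- logical(nrow(cand))
  for (r in seq_len(nrow(cand)))
    hit[r] <- oracle_delaunay_neighbors(X, cand[r, 1], nrow(P) + cand[r, 2])
  sort(unique(complex$atoms$seq_index[cand[hit, 1]]))
}

# --- global alignment oracle --------------------------------------------
# Exhaustive enumeration of all global alignments of two short sequences
# under BLOSUM62 + affine gaps; returns the identity (matches / columns)
# of a maximum-score alignment.
oracle_alignment_identity <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  sub <- pocketsim:::get_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$ident <- NA_real_
  rec <- function(i, j, score, ncol, nmatch, state) {
    if (i > length(av) && j > length(bv)) {
      if (score > best$score + 1e-9 ||
          (abs(score - best$score) <= 1e-9 && !is.na(best$ident) &&
             nmatch / ncol > best$ident)) {
        best$score <- score
        best$ident <- nmatch / ncol
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, score + sub[av[i], bv[j]], ncol + 1,
          nmatch + (av[i] == bv[j]), "m")
    if (i <= length(av))
      rec(i + 1, j, score - (if (state == "a") gap_extend
                             else gap_open + gap_extend), ncol + 1, nmatch, "a")
    if (j <= length(bv))
      rec(i, j + 1, score - (if (state == "b") gap_extend
                             else gap_open + gap_extend), ncol + 1, nmatch, "b")
  }
  rec(1, 1, 0, 0, 0, "m")
  best$ident
}

# --- OT cluster similarity oracle ---------------------------------------
# Exhaustive maximization over all one-to-one assignments between the
# clusters of two partitions (lists of id vectors).
oracle_ot_similarity <- function(mA, mB, denominator = "max") {
  jac <- function(x, y) {
    i <- length(intersect(x, y))
    if (i == 0) 0 else i / length(union(x, y))
  }
  KA <- length(mA); KB <- length(mB)
  if (KA == 0 && KB == 0) return(1)
  if (KA == 0 || KB == 0) return(0)
  k <- min(KA, KB)
  big <- max(KA, KB)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (x in seq_along(v))
      for (p in perms(v[-x])) out <- c(out, list(c(v[x], p)))
    out
  }
  best <- 0
  subsets <- combn(big, k, simplify = FALSE)
  for (s in subsets) {
    for (p in perms(s)) {
      tot <- 0
      for (q in seq_len(k)) {
        tot <- tot + if (KA <= KB) jac(mA[[q]], mB[[p[q]]])
                     else jac(mA[[p[q]]], mB[[q]])
      }
      best <- max(best, tot)
    }
  }
  best / (if (denominator == "max") max(KA, KB) else k)
}

# Exact scrambled-null expectation for partitions of n ids by enumeration
# of all assignments of ids to B's cluster slots (uniform over the n!
# permutations; equivalently over distinct id-to-cluster allocations).
oracle_scrambled_null_exact <- function(mA, sizesB, ids) {
  n <- length(ids)
  stopifnot(n <= 8)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (x in seq_along(v))
      for (p in perms(v[-x])) out <- c(out, list(c(v[x], p)))
    out
  }
  allp <- perms(seq_len(n))
  cuts <- cumsum(sizesB)
  starts <- c(1, head(cuts, -1) + 1)
  vals <- vapply(allp, function(p) {
    mB <- lapply(seq_along(sizesB),
                 function(k) ids[p[starts[k]:cuts[k]]])
    oracle_ot_similarity(mA, mB)
  }, numeric(1))
  mean(vals)
}

# --- spanning tree oracle -----------------------------------------------
# Minimum spanning tree weight by enumerating all n^(n-2) labelled trees
# via Pruefer sequences (n <= 7).
prufer_to_edges <- function(seq_, n) {
  degree <- rep(1L, n)
  for (s in seq_) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, 0, 2)
  for (s in seq_) {
    leaf <- which(degree == 1L)[1]
    edges <- rbind(edges, c(leaf, s))
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  u <- which(degree == 1L)
  rbind(edges, u)
}

oracle_mst_weight <- function(W) {
  n <- nrow(W)
  if (n == 1) return(0)
  if (n == 2) return(W[1, 2])
  seqs <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_to_edges(as.integer(seqs[r, ]), n)
    best <- min(best, sum(W[e]))
  }
  best
}

# --- misc helpers -------------------------------------------------------
random_pocket_dist <- function(n, dim = 5, seed = 1) {
  M <- pocketsim:::with_seed(seed, matrix(rnorm(n * dim), n))
  rownames(M) <- sprintf("p%03d", seq_len(n))
  pairwise_distances(M)
}

make_clustering <- function(ids, labels, t = 0) {
  labels <- as.integer(labels)
  structure(list(ids = ids, labels = labels, t = t,
                 n_clusters = length(unique(labels))),
            class = "pocket_clustering")
}

random_rigid_motion <- function() {
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid_motion <- function(complex, motion) {
  tr <- function(df) {
    xyz <- cbind(df$x, df$y, df$z) %*% t(motion$R)
    df$x <- xyz[, 1] + motion$t[1]
    df$y <- xyz[, 2] + motion$t[2]
    df$z <- xyz[, 3] + motion$t[3]
    df
  }
  complex$atoms <- tr(complex$atoms)
  complex$ligand <- tr(complex$ligand)
  complex
}

tiny_pdb_fixture <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.685   7.161  -4.922  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.271   7.683  -5.880  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      12.217   4.682  -4.890  1.00  0.00           C",
    "ATOM      6  N   GLY A   2      12.912   7.490  -3.649  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2      13.891   8.513  -3.294  1.00  0.00           C",
    "ATOM      8  C   GLY A   2      13.267   9.903  -3.310  1.00  0.00           C",
    "ATOM      9  O   GLY A   2      12.062  10.058  -3.533  1.00  0.00           O",
    "HETATM   10  C1  LIG A 101      14.100   5.500  -4.000  1.00  0.00           C",
    "HETATM   11  O1  LIG A 101      15.200   5.900  -4.600  1.00  0.00           O",
    "HETATM   12  C2  LIG A 101      14.300   4.100  -3.700  1.00  0.00           C",
    "HETATM   13  O   HOH A 201      20.000  20.000  20.000  1.00  0.00           O",
    "END"), collapse = "\n")
}

two_chain_atp_fixture <- function() {
  paste(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA B   1       0.000  30.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY B   2       3.800  30.000   0.000  1.00  0.00           C",
    "HETATM    5  PA  ATP A 101       2.000   2.000   0.000  1.00  0.00           P",
    "HETATM    6  PA  ATP B 102       2.000  32.000   0.000  1.00  0.00           P",
    "END"), collapse = "\n")
}
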