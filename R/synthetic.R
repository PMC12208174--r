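# Synthetic protein-ligand complexes with planted interface ground truth.
#
# The scaffold is an idealized alpha-helix (CA radius 2.3 A, rise 1.5 A,
# 100 degrees per residue, giving CA-CA spacing ~3.8 A) with one outward
# side-chain pseudo-atom (CB, 2 A radial) per residue. Ligand atoms are
# placed just outside the side chains of the requested interface residues,
# so that planted residues are in unobstructed tessellation contact, all
# other residues stay strictly beyond the truncation radius, and optional
# "buried decoy" residues get a side-chain atom that lies within the radius
# but directly behind a first-shell atom on the segment to its nearest
# ligand atom (so distance-based selection includes them while the Voronoi
# facet condition does not).

HELIX_RADIUS <- 2.3
HELIX_RISE <- 1.5
HELIX_TURN <- 100 * pi / 180
CB_OFFSET <- 2.0

helix_backbone <- function(n) {
  i <- seq_len(n) - 1
  ca <- cbind(HELIX_RADIUS * cos(i * HELIX_TURN),
              HELIX_RADIUS * sin(i * HELIX_TURN),
              i * HELIX_RISE)
  radial <- cbind(cos(i * HELIX_TURN), sin(i * HELIX_TURN), 0)
  list(ca = ca, radial = radial)
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

# Verify the generator's distance post-conditions by an all-pairs check.
check_synthetic_constraints <- function(truth) {
  cx <- truth$complex
  r <- truth$truncation_radius
  P <- protein_coords(cx)
  G <- ligand_coords(cx)
  d <- cross_dist(P, G)
  res_min <- tapply(apply(d, 1, min), cx$atoms$seq_index, min)
  idx <- as.integer(names(res_min))
  planted <- idx %in% truth$planted_interface
  decoy <- idx %in% truth$buried_decoys
  msgs <- character(0)
  if (any(res_min[planted] > 0.6 * r))
    msgs <- c(msgs, "an interface residue is farther than 0.6*radius")
  if (any(res_min[!planted & !decoy] <= r))
    msgs <- c(msgs, "a background residue is within the truncation radius")
  for (dd in truth$buried_decoys) {
    rows <- which(cx$atoms$seq_index == dd & cx$atoms$atom_name == "CB")
    xd <- P[rows[1], ]
    dg <- cross_dist(rbind(xd), G)
    if (min(dg) > 0.95 * r) msgs <- c(msgs, "decoy atom not within radius")
    g <- G[which.min(dg), ]
    ca_rows <- which(cx$atoms$seq_index == dd & cx$atoms$atom_name == "CA")
    if (min(cross_dist(P[ca_rows, , drop = FALSE], G)) <= r)
      msgs <- c(msgs, "decoy CA not clear of the radius")
    shell_rows <- which(cx$atoms$seq_index %in% truth$planted_interface)
    occl <- vapply(shell_rows, function(k)
      point_segment_distance(P[k, ], g, xd), numeric(1))
    seg_len <- sqrt(sum((xd - g)^2))
    ok <- any(occl < 0.25 &
                cross_dist(P[shell_rows, , drop = FALSE], rbind(g)) <
                  seg_len - 0.5)
    if (!ok) msgs <- c(msgs, "decoy atom is not occluded by the first shell")
  }
  list(ok = length(msgs) == 0, messages = msgs)
}

build_synthetic_once <- function(n_residues, interface_positions, r,
                                 n_decoys, res3, rng_seed) {
  with_seed(rng_seed, {
    hb <- helix_backbone(n_residues)
    jit <- function(m, s = 0.05) m + matrix(runif(length(m), -s, s), nrow(m))
    ca <- jit(hb$ca)
    cb <- jit(hb$ca + CB_OFFSET * hb$radial)
    iface <- sort(interface_positions)
    lig_offset <- min(2.5, 0.55 * r)
    lig_dir <- hb$radial[iface + 1L, , drop = FALSE] +
      matrix(rep(c(0, 0, 0.5), each = length(iface)), ncol = 3)
    lig_dir <- lig_dir / sqrt(rowSums(lig_dir^2))
    G <- cb[iface + 1L, , drop = FALSE] + lig_offset * lig_dir
    # pad to >= 3 ligand atoms by extending outward along the first
    # placement ray, away from the protein
    j <- 0
    while (nrow(G) < 3) {
      j <- j + 1
      G <- rbind(G, G[1, ] + (1.0 + 0.8 * j) * lig_dir[1, ] +
                   runif(3, -0.05, 0.05))
    }

    decoys <- integer(0)
    if (n_decoys > 0) {
      eligible <- setdiff(seq_len(n_residues) - 1L, iface)
      eligible <- eligible[order(vapply(eligible, function(p)
        min(abs(p - iface)), numeric(1)), eligible)]
      eligible <- eligible[vapply(eligible, function(p)
        min(abs(p - iface)), numeric(1)) >= 1]
      anchors <- rep(iface, length.out = n_decoys)
      cand_frac <- c(0.80, 0.72, 0.88, 0.65)
      for (k in seq_len(min(n_decoys, length(eligible)))) {
        d_res <- eligible[k]
        gi <- G[match(anchors[k], iface), ]
        cbi <- cb[anchors[k] + 1L, ]
        u <- (cbi - gi) / sqrt(sum((cbi - gi)^2))
        placed <- FALSE
        for (fr in cand_frac) {
          dist_d <- fr * r
          if (dist_d < sqrt(sum((cbi - gi)^2)) + 0.8 || dist_d > 0.95 * r)
            next
          # jitter along the ray only: an exactly collinear first-shell
          # blocker occludes the facet robustly (any sphere through the
          # endpoints contains every strictly-between point on the line),
          # whereas lateral offsets reopen it
          xd <- gi + (dist_d + runif(1, -0.05, 0.05)) * u
          others <- rbind(ca, cb[-(d_res + 1L), , drop = FALSE], G)
          if (min(cross_dist(rbind(xd), others)) < 0.8) next
          cb[d_res + 1L, ] <- xd
          decoys <- c(decoys, d_res)
          placed <- TRUE
          break
        }
        if (!placed) next
      }
    }

    atoms <- data.frame(
      seq_index = rep(seq_len(n_residues) - 1L, each = 2),
      chain = "A",
      resno = rep(seq_len(n_residues), each = 2),
      icode = "",
      res_name = rep(res3, each = 2),
      atom_name = rep(c("CA", "CB"), n_residues),
      element = "C",
      is_backbone = rep(c(TRUE, FALSE), n_residues),
      x = as.vector(rbind(ca[, 1], cb[, 1])),
      y = as.vector(rbind(ca[, 2], cb[, 2])),
      z = as.vector(rbind(ca[, 3], cb[, 3])),
      stringsAsFactors = FALSE)
    ligand <- data.frame(atom_name = paste0("C", seq_len(nrow(G))),
                         element = "C", x = G[, 1], y = G[, 2], z = G[, 3],
                         res_name = "LIG", chain = "X",
                         resno = 900L, stringsAsFactors = FALSE)
    list(atoms = atoms, ligand = ligand, decoys = sort(decoys))
  })
}

#' Generate a synthetic complex with planted interface ground truth
#'
#' Builds a helix-like chain with one side-chain pseudo-atom per residue and
#' places 3-8 ligand atoms so that exactly the requested residues are in
#' unobstructed contact within the truncation radius, all other residues lie
#' strictly outside it, and (optionally) decoy residues carry a buried
#' side-chain atom that is within the radius but occluded by a first-shell
#' atom. All distance constraints are re-verified by an all-pairs check
#' before returning; construction is deterministic for a fixed seed.
#'
#' @param n_residues chain length (>= 8).
#' @param interface_positions 0-based residue indices to plant as interface
#'   (1-8 positions).
#' @param truncation_radius contact truncation radius in Angstrom.
#' @param seed integer seed; identical seeds give byte-identical coordinates.
#' @param n_decoys number of buried decoy residues to plant (default 2).
#' @param res_names optional residue identities: a one-letter sequence
#'   string or a vector of 3-letter codes of length \code{n_residues}.
#' @param max_tries bounded retries before giving up on the geometry.
#' @return An object of class \code{synthetic_truth}: list with elements
#'   \code{complex} (a [pocket_complex()]), \code{planted_interface},
#'   \code{buried_decoys}, \code{truncation_radius}, \code{seed}.
#' @export
generate_synthetic_complex <- function(n_residues, interface_positions,
                                       truncation_radius = 6.0, seed = 1,
                                       n_decoys = 2, res_names = NULL,
                                       max_tries = 20) {
  ps_assert(n_residues >= 8, "bad_arg", "n_residues must be >= 8")
  ps_assert(truncation_radius > 0, "bad_arg", "truncation_radius must be > 0")
  interface_positions <- sort(unique(as.integer(interface_positions)))
  ps_assert(length(interface_positions) >= 1 &&
              length(interface_positions) <= 8,
            "bad_arg", "between 1 and 8 interface positions are supported")
  ps_assert(all(interface_positions >= 0 &
                  interface_positions < n_residues),
            "bad_arg", "interface_positions out of range")
  if (is.null(res_names)) {
    res3 <- with_seed(seed + 104729L,
                      sample(STANDARD_AA3, n_residues, replace = TRUE))
  } else if (length(res_names) == 1 && nchar(res_names[1]) == n_residues) {
    res3 <- aa_one_to_three(strsplit(res_names, "")[[1]])
  } else {
    ps_assert(length(res_names) == n_residues, "bad_arg",
              "res_names must match n_residues")
    res3 <- res_names
  }

  for (try in seq_len(max_tries)) {
    built <- build_synthetic_once(n_residues, interface_positions,
                                  truncation_radius, n_decoys, res3,
                                  rng_seed = (seed + (try - 1L) * 7919L) %%
                                    .Machine$integer.max)
    cx <- pocket_complex(sprintf("synth_s%d", seed), built$atoms,
                         built$ligand)
    truth <- structure(list(complex = cx,
                            planted_interface = interface_positions,
                            buried_decoys = built$decoys,
                            truncation_radius = truncation_radius,
                            seed = seed),
                       class = "synthetic_truth")
    chk <- check_synthetic_constraints(truth)
    if (chk$ok && (n_decoys == 0 || length(built$decoys) > 0))
      return(truth)
  }
  ps_stop("generation_error",
          "could not satisfy interface geometry after %d tries", max_tries)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> seed", x$seed, "\n")
  cat("  planted interface:", paste(x$planted_interface, collapse = ","),
      "| buried decoys:", paste(x$buried_decoys, collapse = ","),
      "| radius:", x$truncation_radius, "A\n")
  print(x$complex)
  invisible(x)
}

#' Generate families of related synthetic pockets
#'
#' Emulates a pocketome with planted cluster structure: each family shares a
#' base sequence and a base interface-position set; members differ by a
#' single substitution at one interface position (each member a distinct
#' mutation), so pockets within a family are close in embedding space while
#' pockets from different families are far.
#'
#' @param n_complexes total number of complexes (split evenly over families).
#' @param n_families number of planted families.
#' @param n_residues chain length per complex.
#' @param interface_size interface residues per family.
#' @param truncation_radius contact radius used for generation.
#' @param seed integer seed.
#' @return list with \code{truths} (list of \code{synthetic_truth}),
#'   \code{ids}, \code{family} (integer labels, 1-based).
#' @export
generate_pocket_families <- function(n_complexes = 30, n_families = 3,
                                     n_residues = 40, interface_size = 6,
                                     truncation_radius = 6.0, seed = 1) {
  per <- ceiling(n_complexes / n_families)
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  plan <- with_seed(seed, {
    # disjoint interface-position sets: families are distinct pockets, not
    # variants of one site
    pool <- sample(4:(n_residues - 5), n_families * interface_size)
    lapply(seq_len(n_families), function(f) {
      base <- sample(letters20, n_residues, replace = TRUE)
      iface <- sort(pool[((f - 1) * interface_size + 1):(f * interface_size)])
      # members vary at one designated interface position (a different
      # substitution each), so any two members differ in exactly one
      # pooled row -- a tight, well-separated family
      vpos <- sample(iface, 1)
      muts <- data.frame(pos = vpos,
                         aa = sample(setdiff(letters20, base[vpos + 1L])),
                         stringsAsFactors = FALSE)
      list(base = base, iface = iface, muts = muts)
    })
  })
  truths <- list()
  ids <- character(0)
  family <- integer(0)
  k <- 0L
  for (f in seq_len(n_families)) {
    for (m in seq_len(per)) {
      if (k >= n_complexes) break
      k <- k + 1L
      letters_m <- plan[[f]]$base
      mut <- plan[[f]]$muts[m, ]
      letters_m[mut$pos + 1L] <- mut$aa
      tr <- generate_synthetic_complex(
        n_residues, plan[[f]]$iface, truncation_radius,
        seed = (seed + 1000L * k) %% .Machine$integer.max, n_decoys = 0,
        res_names = paste(letters_m, collapse = ""))
      tr$complex$complex_id <- sprintf("fam%d_m%d", f, m)
      truths[[k]] <- tr
      ids <- c(ids, tr$complex$complex_id)
      family <- c(family, f)
    }
  }
  list(truths = truths, ids = ids, family = family, n_families = n_families)
}

#' Synthetic benchmark for split-hardness experiments
#'
#' Emulates a hierarchically structured pocketome for the druggability
#' harness: complexes belong to families nested in superfamilies, and the
#' per-residue embedding signal that separates contact from non-contact
#' residues has a weak globally shared component, a medium
#' superfamily-specific component and a strong family-specific component.
#' Classifiers therefore generalize well across a random split (family
#' leakage), less well across cluster-based splits and worst across
#' branch-based splits that hold out whole superfamilies.
#'
#' @param n_super number of superfamilies.
#' @param families_per_super families per superfamily.
#' @param members_per_family complexes per family.
#' @param n_residues residues per complex.
#' @param dim embedding dimension.
#' @param beta_shared,beta_super,beta_family signal magnitudes of the
#'   shared, superfamily and family components.
#' @param noise_sd per-component Gaussian noise.
#' @param contact_fraction fraction of residues labelled 1 per complex.
#' @param seed integer seed.
#' @return list with per-complex \code{embeddings} and \code{labels},
#'   a pocket \code{vectors} matrix (one row per complex), \code{ids},
#'   \code{family} and \code{super} labels.
#' @export
generate_split_benchmark <- function(n_super = 3, families_per_super = 4,
                                     members_per_family = 5,
                                     n_residues = 40, dim = 24,
                                     beta_shared = 0.5, beta_super = 1.5,
                                     beta_family = 2.0, noise_sd = 0.7,
                                     contact_fraction = 0.3, seed = 1) {
  n_dirs <- 1 + n_super + n_super * families_per_super
  ps_assert(dim >= n_dirs, "bad_arg",
            "dim must be >= 1 + n_super + n_super * families_per_super")
  with_seed(seed, {
    # mutually orthonormal signal directions: the shared, superfamily and
    # family components are exactly decorrelated, so the planted hierarchy
    # has deterministic separations
    Q <- qr.Q(qr(matrix(rnorm(dim * n_dirs), dim)))
    w0 <- Q[, 1]
    ws <- lapply(seq_len(n_super), function(s) Q[, 1 + s])
    wf <- lapply(seq_len(n_super * families_per_super),
                 function(f) Q[, 1 + n_super + f])
    embeddings <- list()
    labels <- list()
    ids <- character(0)
    family <- integer(0)
    super <- integer(0)
    vectors <- NULL
    n_contact <- max(2L, round(contact_fraction * n_residues))
    fidx <- 0L
    for (s in seq_len(n_super)) {
      for (f in seq_len(families_per_super)) {
        fidx <- fidx + 1L
        signal <- beta_shared * w0 + beta_super * ws[[s]] +
          beta_family * wf[[fidx]]
        for (m in seq_len(members_per_family)) {
          id <- sprintf("s%df%dm%d", s, f, m)
          y <- integer(n_residues)
          y[sample(n_residues, n_contact)] <- 1L
          X <- matrix(rnorm(n_residues * dim, sd = noise_sd), n_residues)
          X <- X + outer(y, signal)
          emb <- structure(X, embedder_id = sprintf("synthetic-bench-d%d", dim),
                           complex_id = id, class = "residue_embedding")
          embeddings[[id]] <- emb
          labels[[id]] <- residue_labels(id, y, contact_radius = NA_real_)
          vectors <- rbind(vectors, colMeans(X[y == 1L, , drop = FALSE]))
          ids <- c(ids, id)
          family <- c(family, fidx)
          super <- c(super, s)
        }
      }
    }
    rownames(vectors) <- ids
    attr(vectors, "embedder_id") <- sprintf("synthetic-bench-d%d", dim)
    list(embeddings = embeddings, labels = labels, vectors = vectors,
         ids = ids, family = family, super = super)
  })
}
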