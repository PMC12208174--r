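# Radially truncated Voronoi tessellation of the protein-ligand interface.
#
# Two atoms are in tessellation contact iff (a) their Voronoi cells in the
# diagram of the union point set (all protein heavy atoms + all ligand heavy
# atoms) share a facet AND (b) their Euclidean distance is at most the
# truncation radius. Facet sharing is decided exactly: cells of points a and
# b share a facet iff there is a point x on their bisector plane that is
# strictly closer to a (and b) than to every other point, i.e. iff the
# linear program
#   max s  s.t.  2(p_k - p_a).x + s <= |p_k|^2 - |p_a|^2  (all k != a,b)
#                2(p_b - p_a).x = |p_b|^2 - |p_a|^2
# has a strictly positive optimum (s is the empty-sphere margin in squared
# Angstrom, capped so the LP is bounded).

#' Do the Voronoi cells of two points share a facet?
#'
#' Exact test via a small feasibility linear program on the bisector plane
#' of points \code{i} and \code{j} of the set; used as the adjacency
#' primitive of the truncated tessellation.
#'
#' @param points numeric matrix (n x 3) of distinct points.
#' @param i,j row indices (1-based).
#' @param cap bound on the margin variable (squared Angstrom).
#' @param eps strict-positivity tolerance for the margin.
#' @return TRUE iff the two Voronoi cells share a (positive-area) facet.
#' @export
voronoi_facet_shared <- function(points, i, j, cap = 1.0, eps = 1e-7) {
  n <- nrow(points)
  if (n == 2) return(TRUE)
  mid <- (points[i, ] + points[j, ]) / 2
  X <- sweep(points, 2, mid)
  pa <- X[i, ]; pb <- X[j, ]
  others <- setdiff(seq_len(n), c(i, j))
  Dk <- X[others, , drop = FALSE] - matrix(pa, length(others), 3, byrow = TRUE)
  q <- rowSums(X[others, , drop = FALSE]^2) - sum(pa^2)
  # variables: u(3), v(3) with x = u - v, and margin s; all >= 0
  rows_ineq <- cbind(2 * Dk, -2 * Dk, 1)
  rhs <- q
  cap_row <- c(rep(0, 6), 1)
  neg <- rhs < 0
  A1 <- rbind(rows_ineq[!neg, , drop = FALSE], cap_row)
  b1 <- c(rhs[!neg], cap)
  A2 <- -rows_ineq[neg, , drop = FALSE]
  b2 <- -rhs[neg]
  db <- pb - pa
  e_rhs <- sum(pb^2) - sum(pa^2)  # ~0 after centering
  A3 <- matrix(c(2 * db, -2 * db, 0), nrow = 1)
  b3 <- e_rhs
  if (b3 < 0) {
    A3 <- -A3
    b3 <- -b3
  }
  res <- tryCatch(
    boot::simplex(a = c(rep(0, 6), 1), A1 = A1, b1 = b1,
                  A2 = if (nrow(A2)) A2 else NULL,
                  b2 = if (nrow(A2)) b2 else NULL,
                  A3 = A3, b3 = b3, maxi = TRUE, n.iter = 50 * (n + 10)),
    error = function(e) NULL)
  if (is.null(res) || res$solved == -1) return(FALSE)
  isTRUE(res$value > eps)
}

check_nondegenerate <- function(X) {
  if (nrow(X) < 5)
    ps_stop("degenerate_geometry",
            "need at least 5 points for a 3D tessellation")
  sv <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    ps_stop("degenerate_geometry", "point set is (nearly) coplanar")
}

interface_set <- function(complex_id, residue_indices, contacts,
                          truncation_radius, mode) {
  structure(list(complex_id = complex_id,
                 residue_indices = sort(as.integer(residue_indices)),
                 contacts = contacts,
                 truncation_radius = truncation_radius,
                 mode = mode),
            class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  cat("<interface_set>", x$complex_id, sprintf("(%s, r = %g A)\n",
                                               x$mode, x$truncation_radius))
  cat("  residues:", paste(x$residue_indices, collapse = ","), "\n")
  cat("  contact pairs:", nrow(x$contacts), "\n")
  invisible(x)
}

#' Pocket interface residues by radially truncated Voronoi tessellation
#'
#' A protein atom is in contact with a ligand atom iff their Voronoi cells
#' (in the diagram over all protein plus ligand heavy atoms) share a facet
#' and their distance does not exceed the truncation radius; a residue is an
#' interface residue iff at least one of its atoms is in contact. The
#' \code{"distance-only"} mode drops the facet condition and serves as a
#' fallback (and upper bound) when the geometry is degenerate.
#'
#' @param complex a [pocket_complex()].
#' @param truncation_radius contact radius in Angstrom (default 6).
#' @param mode \code{"voronoi"} (default) or \code{"distance-only"}.
#' @return An \code{interface_set}: the 0-based interface residue indices
#'   plus the contributing (ligand atom, protein atom, distance) contact
#'   pairs.
#' @export
compute_interface_residues <- function(complex, truncation_radius = 6.0,
                                       mode = c("voronoi", "distance-only")) {
  mode <- match.arg(mode)
  ps_assert(truncation_radius > 0, "bad_arg", "truncation_radius must be > 0")
  P <- protein_coords(complex)
  G <- ligand_coords(complex)
  d <- cross_dist(P, G)
  cand <- which(d <= truncation_radius, arr.ind = TRUE)
  if (nrow(cand) == 0)
    ps_stop("empty_interface",
            "no protein atom within %g A of the ligand", truncation_radius)
  if (mode == "distance-only") {
    contacts <- data.frame(lig_atom = cand[, 2], atom_row = cand[, 1],
                           seq_index = complex$atoms$seq_index[cand[, 1]],
                           dist = d[cand])
  } else {
    X <- rbind(P, G)
    check_nondegenerate(X)
    np <- nrow(P)
    keep <- vapply(seq_len(nrow(cand)), function(r)
      voronoi_facet_shared(X, cand[r, 1], np + cand[r, 2]), logical(1))
    if (!any(keep))
      ps_stop("empty_interface", "no tessellation contact within %g A",
              truncation_radius)
    cand <- cand[keep, , drop = FALSE]
    contacts <- data.frame(lig_atom = cand[, 2], atom_row = cand[, 1],
                           seq_index = complex$atoms$seq_index[cand[, 1]],
                           dist = d[cand])
  }
  contacts <- contacts[order(contacts$seq_index, contacts$lig_atom), ]
  rownames(contacts) <- NULL
  interface_set(complex$complex_id, unique(contacts$seq_index), contacts,
                truncation_radius, mode)
}

#' Distance-only interface extraction
#'
#' A residue is included iff any of its heavy atoms is within \code{radius}
#' of any ligand heavy atom; upper-bound oracle for the tessellation mode.
#'
#' @inheritParams compute_interface_residues
#' @param radius contact radius in Angstrom.
#' @return An \code{interface_set}.
#' @export
interface_distance_only <- function(complex, radius = 6.0) {
  ps_assert(radius >= 0, "bad_arg", "radius must be >= 0")
  P <- protein_coords(complex)
  G <- ligand_coords(complex)
  d <- cross_dist(P, G)
  cand <- which(d <= radius & d > 0, arr.ind = TRUE)
  if (nrow(cand) == 0)
    ps_stop("empty_interface", "no protein atom within %g A of the ligand",
            radius)
  contacts <- data.frame(lig_atom = cand[, 2], atom_row = cand[, 1],
                         seq_index = complex$atoms$seq_index[cand[, 1]],
                         dist = d[cand])
  contacts <- contacts[order(contacts$seq_index, contacts$lig_atom), ]
  rownames(contacts) <- NULL
  interface_set(complex$complex_id, unique(contacts$seq_index), contacts,
                radius, "distance-only")
}
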