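# Per-residue embeddings and pocket pooling.
#
# The built-in mock embedder is a deterministic stand-in for a protein
# language model: component k of residue (letter a, position p) is the
# 64-bit FNV-1a hash of the byte triple (a, p mod 64, k), passed through a
# Murmur3-style avalanche finalizer and mapped linearly to [-1, 1]. It is platform-independent (integer limb arithmetic, no float
# accumulation-order dependence), position-sensitive, and needs no model
# download. An external PLM plugs in through `embedder_spec(kind =
# "external-plm", fun = ...)` returning final-layer per-residue rows with
# special tokens stripped.

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

# 64-bit hashing on 4 x 16-bit limbs held in doubles (all intermediate
# products stay below 2^53, so the arithmetic is exact and identical on
# every IEEE-754 platform).

limb_mul64 <- function(h, m) {
  r0 <- h[[1]] * m[1]
  r1 <- h[[2]] * m[1] + h[[1]] * m[2] + floor(r0 / 65536)
  r2 <- h[[3]] * m[1] + h[[2]] * m[2] + h[[1]] * m[3] + floor(r1 / 65536)
  r3 <- h[[4]] * m[1] + h[[3]] * m[2] + h[[2]] * m[3] + h[[1]] * m[4] +
    floor(r2 / 65536)
  list(r0 %% 65536, r1 %% 65536, r2 %% 65536, r3 %% 65536)
}

limb_xor_shr33 <- function(h) {
  s0 <- floor(h[[3]] / 2) + (h[[4]] %% 2) * 32768  # bits 33..48
  s1 <- floor(h[[4]] / 2)                          # bits 49..63
  list(bitwXor(as.integer(h[[1]]), as.integer(s0)),
       bitwXor(as.integer(h[[2]]), as.integer(s1)),
       h[[3]], h[[4]])
}

# FNV-1a over parallel byte streams followed by a Murmur3-style 64-bit
# finalizer; plain FNV barely avalanches over 3-byte inputs, so the
# finalizer is what makes neighbouring (residue, component) cells
# decorrelated. `bytes` is a list of integer vectors (one per hash step).
fnv1a64 <- function(bytes) {
  n <- length(bytes[[1]])
  h <- list(rep(8997, n), rep(33826, n), rep(40164, n), rep(52210, n))
  fnv_prime <- c(435, 0, 256, 0)          # 2^40 + 0x1B3
  mix1 <- c(0x8ccd, 0xed55, 0xafd7, 0xff51)  # 0xff51afd7ed558ccd
  mix2 <- c(0xec53, 0x1a85, 0xb9fe, 0xc4ce)  # 0xc4ceb9fe1a85ec53
  for (b in bytes) {
    h[[1]] <- bitwXor(as.integer(h[[1]]), as.integer(b))
    h <- limb_mul64(h, fnv_prime)
  }
  h <- limb_xor_shr33(h)
  h <- limb_mul64(h, mix1)
  h <- limb_xor_shr33(h)
  h <- limb_mul64(h, mix2)
  h <- limb_xor_shr33(h)
  (((h[[4]] * 65536 + h[[3]]) * 65536 + h[[2]]) * 65536 + h[[1]]) /
    2^64 * 2 - 1
}

#' Describe an embedder
#'
#' @param kind \code{"mock"} (deterministic hash embedder) or
#'   \code{"external-plm"} (adapter around a real protein language model).
#' @param dim embedding dimension.
#' @param window for the mock: rows are averaged over positions
#'   \code{p - window .. p + window}, giving the mock weak context
#'   sensitivity (default 0, no context).
#' @param model_id identifier of the external model (external-plm only).
#' @param fun adapter function \code{function(sequence) -> L x dim matrix}
#'   of final-layer per-residue representations with special tokens removed
#'   (external-plm only).
#' @return An \code{embedder_spec} object.
#' @export
embedder_spec <- function(kind = c("mock", "external-plm"), dim = 32,
                          window = 0, model_id = NULL, fun = NULL) {
  kind <- match.arg(kind)
  ps_assert(dim >= 1, "bad_arg", "dim must be >= 1")
  id <- if (kind == "mock") sprintf("mock-d%d-w%d", dim, window)
        else sprintf("plm:%s-d%d", model_id %||% "unspecified", dim)
  structure(list(kind = kind, dim = as.integer(dim),
                 window = as.integer(window), model_id = model_id,
                 fun = fun, embedder_id = id),
            class = "embedder_spec")
}

mock_embed <- function(sequence, dim, window = 0) {
  letters_ <- strsplit(sequence, "")[[1]]
  L <- length(letters_)
  a <- utf8ToInt(sequence)
  idx_p <- rep(seq_len(L), times = dim)
  idx_k <- rep(seq_len(dim), each = L)
  vals <- fnv1a64(list(a[idx_p], (idx_p - 1L) %% 64L, idx_k - 1L))
  M <- matrix(vals, nrow = L, ncol = dim)
  if (window > 0) {
    M2 <- M
    for (p in seq_len(L)) {
      lo <- max(1, p - window); hi <- min(L, p + window)
      M2[p, ] <- colMeans(M[lo:hi, , drop = FALSE])
    }
    M <- M2
  }
  M
}

#' Embed a protein sequence per residue
#'
#' Produces the L x D matrix of per-residue embedding vectors for a full
#' chain sequence. Embeddings are always computed on the complete sequence
#' and later indexed by interface positions (never on an interface
#' subsequence), so each row carries global sequence context.
#'
#' @param sequence one-letter amino-acid string (20 standard letters + X).
#' @param spec an [embedder_spec()].
#' @param complex_id optional id recorded on the result.
#' @return A \code{residue_embedding}: L x D numeric matrix with attributes
#'   \code{embedder_id} and \code{complex_id}.
#' @export
embed_sequence <- function(sequence, spec = embedder_spec(),
                           complex_id = NULL) {
  ps_assert(is.character(sequence) && length(sequence) == 1 &&
              nchar(sequence) >= 1, "alphabet_error",
            "sequence must be a non-empty string")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    ps_stop("alphabet_error", "unknown residue letter(s): %s",
            paste(bad, collapse = ","))
  if (spec$kind == "mock") {
    M <- mock_embed(sequence, spec$dim, spec$window)
  } else {
    if (!is.function(spec$fun))
      ps_stop("embedder_unavailable",
              "external embedder '%s' has no adapter function",
              spec$embedder_id)
    M <- spec$fun(sequence)
    ps_assert(is.matrix(M) && nrow(M) == nchar(sequence) &&
                ncol(M) == spec$dim && all(is.finite(M)),
              "embedder_unavailable",
              "adapter must return a finite L x dim matrix")
  }
  structure(M, embedder_id = spec$embedder_id, complex_id = complex_id,
            class = "residue_embedding")
}

#' @export
print.residue_embedding <- function(x, ...) {
  cat("<residue_embedding>", attr(x, "complex_id") %||% "",
      sprintf("%d residues x %d dims (%s)\n", nrow(x), ncol(x),
              attr(x, "embedder_id")))
  invisible(x)
}

#' Pool per-residue embeddings into a pocket vector
#'
#' The pocket representation is the arithmetic mean of the per-residue
#' embedding rows at the interface positions.
#'
#' @param embedding a \code{residue_embedding} (L x D matrix).
#' @param interface an \code{interface_set} or an integer vector of 0-based
#'   residue indices.
#' @param pocket_id optional id (defaults to the interface's complex id).
#' @return A \code{pocket_embedding}: list with \code{pocket_id},
#'   \code{vector} (length D), \code{n_interface_residues},
#'   \code{embedder_id}.
#' @export
pool_pocket_embedding <- function(embedding, interface, pocket_id = NULL) {
  idx <- if (inherits(interface, "interface_set")) interface$residue_indices
         else as.integer(interface)
  if (length(idx) == 0)
    ps_stop("empty_interface", "cannot pool over an empty interface")
  if (any(idx < 0) || any(idx >= nrow(embedding)))
    ps_stop("index_mismatch",
            "interface index out of range for a %d-residue embedding",
            nrow(embedding))
  if (is.null(pocket_id)) {
    pocket_id <- if (inherits(interface, "interface_set"))
      interface$complex_id else attr(embedding, "complex_id")
  }
  v <- colMeans(unclass(embedding)[idx + 1L, , drop = FALSE])
  structure(list(pocket_id = pocket_id %||% "pocket",
                 vector = as.numeric(v),
                 n_interface_residues = length(idx),
                 embedder_id = attr(embedding, "embedder_id")),
            class = "pocket_embedding")
}

#' @export
print.pocket_embedding <- function(x, ...) {
  cat("<pocket_embedding>", x$pocket_id,
      sprintf("dim %d, pooled over %d residues (%s)\n",
              length(x$vector), x$n_interface_residues, x$embedder_id))
  invisible(x)
}
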