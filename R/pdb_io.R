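#' @importFrom stats cor predict quantile rnorm runif sd setNames
#' @importFrom utils head write.table
NULL

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
WATER_CODES <- c("HOH", "WAT", "DOD")
DEFAULT_BUFFER_CODES <- c("SO4", "GOL", "EDO", "PO4", "ACT", "DMS", "PEG")

aa_three_to_one <- function(res_name) {
  out <- suppressWarnings(bio3d::aa321(res_name))
  out[is.na(out) | !out %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])] <- "X"
  out
}

aa_one_to_three <- function(letters1) {
  map <- setNames(STANDARD_AA3, aa_three_to_one(STANDARD_AA3))
  out <- map[letters1]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Protein-ligand complex container
#'
#' Bundles the protein heavy atoms of one (or several concatenated) chains,
#' grouped into residues with 0-based sequence indices, together with the
#' heavy atoms of one selected ligand group and the one-letter sequence
#' derived from the residues. This is the input unit for interface
#' extraction, embedding pooling and residue labelling.
#'
#' @param complex_id character identifier.
#' @param atoms data.frame of protein atoms with columns \code{seq_index}
#'   (0-based), \code{chain}, \code{resno}, \code{icode}, \code{res_name},
#'   \code{atom_name}, \code{element}, \code{is_backbone}, \code{x,y,z}.
#' @param ligand data.frame of ligand heavy atoms with columns
#'   \code{atom_name}, \code{element}, \code{x,y,z} (and optionally
#'   \code{res_name}, \code{chain}, \code{resno} for round-tripping).
#' @return An object of class \code{pocket_complex}.
#' @export
pocket_complex <- function(complex_id, atoms, ligand) {
  ps_assert(nrow(ligand) >= 1, "empty_ligand", "ligand has no heavy atoms")
  ps_assert(nrow(atoms) >= 1, "empty_protein", "no protein atoms")
  ps_assert(all(is.finite(c(atoms$x, atoms$y, atoms$z,
                            ligand$x, ligand$y, ligand$z))),
            "bad_coords", "non-finite coordinates")
  idx <- sort(unique(atoms$seq_index))
  ps_assert(identical(idx, seq(0L, length(idx) - 1L)),
            "bad_index", "seq_index must be contiguous 0-based")
  first <- atoms[!duplicated(atoms$seq_index), ]
  first <- first[order(first$seq_index), ]
  residue_table <- data.frame(seq_index = first$seq_index,
                              chain = first$chain, resno = first$resno,
                              icode = first$icode, res_name = first$res_name,
                              letter = aa_three_to_one(first$res_name),
                              stringsAsFactors = FALSE)
  obj <- structure(list(complex_id = complex_id,
                        atoms = atoms,
                        ligand = ligand,
                        residue_table = residue_table,
                        sequence = paste(residue_table$letter, collapse = ""),
                        n_nonstandard = sum(residue_table$letter == "X")),
                   class = "pocket_complex")
  obj
}

#' @export
print.pocket_complex <- function(x, ...) {
  cat("<pocket_complex>", x$complex_id, "\n")
  cat("  residues:", nrow(x$residue_table),
      "| chains:", paste(unique(x$atoms$chain), collapse = ","),
      "| protein atoms:", nrow(x$atoms),
      "| ligand atoms:", nrow(x$ligand), "\n")
  s <- x$sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  sequence:", s, "\n")
  if (x$n_nonstandard > 0)
    cat("  nonstandard residues mapped to X:", x$n_nonstandard, "\n")
  invisible(x)
}

n_residues <- function(complex) nrow(complex$residue_table)

protein_coords <- function(complex)
  cbind(complex$atoms$x, complex$atoms$y, complex$atoms$z)

ligand_coords <- function(complex)
  cbind(complex$ligand$x, complex$ligand$y, complex$ligand$z)

read_pdb_atoms <- function(pdb_source) {
  path <- pdb_source
  if (!is.character(pdb_source) || length(pdb_source) != 1)
    ps_stop("parse_error", "pdb_source must be a path or PDB text")
  if (grepl("\n", pdb_source) || !file.exists(pdb_source)) {
    if (!grepl("\n", pdb_source))
      ps_stop("parse_error", "no such file: %s", pdb_source)
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(pdb_source, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) ps_stop("parse_error",
                                              "cannot parse PDB: %s",
                                              conditionMessage(e)))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  if (is.null(at$elesy)) at$elesy <- NA_character_
  miss <- is.na(at$elesy) | at$elesy == ""
  at$elesy[miss] <- substr(gsub("[^A-Za-z].*", "", at$elety[miss]), 1, 1)
  at
}

# Keep the highest-occupancy altloc per (record, chain, resno, icode, residue,
# atom name); ties resolved toward altloc "" then "A" then lexicographic.
resolve_altloc <- function(at) {
  key <- paste(at$type, at$chain, at$resno, at$insert, at$resid, at$elety,
               sep = "\r")
  ord <- order(key, -at$o, at$alt)
  keep <- seq_len(nrow(at))[ord][!duplicated(key[ord])]
  at[sort(keep), , drop = FALSE]  # winners, in original file order
}

het_groups <- function(at) {
  het <- at[at$type == "HETATM" & !(at$resid %in% WATER_CODES) &
              !(toupper(at$elesy) %in% c("H", "D")), , drop = FALSE]
  if (nrow(het) == 0)
    return(data.frame(code = character(), chain = character(),
                      resno = integer(), n_atoms = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(het$resid, het$chain, het$resno, het$insert, sep = "\r")
  tab <- table(key)[unique(key)]
  parts <- do.call(rbind, strsplit(names(tab), "\r"))
  g <- data.frame(code = parts[, 1], chain = parts[, 2],
                  resno = as.integer(parts[, 3]),
                  n_atoms = as.integer(tab), stringsAsFactors = FALSE)
  g[order(g$chain, g$resno, g$code), , drop = FALSE]
}

#' List candidate probe ligands in a PDB file
#'
#' Enumerates all non-water HETATM groups (heavy atoms only), ordered by
#' chain and residue number.
#'
#' @param pdb_source path to a PDB file, or PDB text.
#' @return data.frame with columns \code{code}, \code{chain}, \code{resno},
#'   \code{n_atoms}.
#' @export
list_ligands <- function(pdb_source) {
  at <- resolve_altloc(read_pdb_atoms(pdb_source))
  g <- het_groups(at)
  rownames(g) <- NULL
  g
}

parse_ligand_selector <- function(ligand) {
  if (is.list(ligand))
    return(list(code = toupper(ligand$code),
                chain = ligand$chain %||% NA_character_,
                resno = ligand$resno %||% NA_integer_))
  parts <- strsplit(ligand, ":")[[1]]
  list(code = toupper(parts[1]),
       chain = if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else NA,
       resno = if (length(parts) >= 3) as.integer(parts[3]) else NA)
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses protein heavy atoms grouped into residues (0-based sequence
#' indices over the extracted chain concatenation) plus the heavy atoms of
#' one selected HETATM group. Alternate locations are resolved to the
#' highest-occupancy conformer; hydrogens are dropped unless requested;
#' waters and a configurable buffer-component list are never selectable as
#' the probe ligand.
#'
#' @param pdb_source path to a PDB file, or PDB text.
#' @param ligand selector \code{"CODE"}, \code{"CODE:CHAIN"} or
#'   \code{"CODE:CHAIN:RESNO"} (or a list with those fields).
#' @param chains optional character vector restricting the protein chains.
#' @param multi_chain when \code{chains} is NULL: \code{"best"} keeps the
#'   single chain with the most ligand contacts (heavy-atom pairs within
#'   4.5 A); \code{"near"} concatenates, in chain-id order, all chains with
#'   an atom within 10 A of the ligand.
#' @param keep_hydrogens keep hydrogen/deuterium atoms (default drop).
#' @param exclude_ligands HET codes never selectable as probe ligand
#'   (waters are always excluded).
#' @param complex_id identifier for the returned object.
#' @return A [pocket_complex()].
#' @export
read_complex <- function(pdb_source, ligand, chains = NULL,
                         multi_chain = c("best", "near"),
                         keep_hydrogens = FALSE,
                         exclude_ligands = DEFAULT_BUFFER_CODES,
                         complex_id = NULL) {
  multi_chain <- match.arg(multi_chain)
  sel <- parse_ligand_selector(ligand)
  if (sel$code %in% c(WATER_CODES, toupper(exclude_ligands)))
    ps_stop("ligand_not_found",
            "'%s' is on the water/buffer exclusion list", sel$code)
  at <- resolve_altloc(read_pdb_atoms(pdb_source))
  if (!keep_hydrogens)
    at <- at[!(toupper(at$elesy) %in% c("H", "D")), , drop = FALSE]

  groups <- het_groups(at)
  hit <- groups[groups$code == sel$code, , drop = FALSE]
  if (!is.na(sel$chain)) hit <- hit[hit$chain == sel$chain, , drop = FALSE]
  if (!is.na(sel$resno)) hit <- hit[hit$resno == sel$resno, , drop = FALSE]
  if (nrow(hit) == 0)
    ps_stop("ligand_not_found", "no HETATM group matches '%s'", sel$code)
  if (nrow(hit) > 1)
    ps_stop("ambiguous_ligand",
            "%d groups match '%s'; disambiguate with CODE:CHAIN:RESNO",
            nrow(hit), sel$code)
  lig_rows <- at$type == "HETATM" & at$resid == hit$code &
    at$chain == hit$chain & at$resno == hit$resno
  lig <- at[lig_rows, , drop = FALSE]
  ligand_df <- data.frame(atom_name = lig$elety, element = lig$elesy,
                          x = lig$x, y = lig$y, z = lig$z,
                          res_name = lig$resid, chain = lig$chain,
                          resno = lig$resno, stringsAsFactors = FALSE)

  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) {
    prot <- prot[prot$chain %in% chains, , drop = FALSE]
  } else if (length(unique(prot$chain)) > 1) {
    lxyz <- cbind(lig$x, lig$y, lig$z)
    per_chain <- split(seq_len(nrow(prot)), prot$chain)
    mind <- vapply(per_chain, function(i)
      min(cross_dist(cbind(prot$x[i], prot$y[i], prot$z[i]), lxyz)),
      numeric(1))
    ncontact <- vapply(per_chain, function(i)
      sum(cross_dist(cbind(prot$x[i], prot$y[i], prot$z[i]), lxyz) <= 4.5),
      numeric(1))
    keep <- if (multi_chain == "best") {
      names(per_chain)[order(-ncontact, mind, names(per_chain))][1]
    } else {
      sort(names(per_chain)[mind <= 10])
    }
    prot <- prot[prot$chain %in% keep, , drop = FALSE]
  }
  if (nrow(prot) == 0)
    ps_stop("empty_protein", "no protein residues after chain filtering")
  prot <- prot[order(match(prot$chain, sort(unique(prot$chain)))), , drop = FALSE]

  rkey <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  seq_index <- match(rkey, unique(rkey)) - 1L
  is_bb <- prot$elety %in% c("N", "CA", "C", "O") &
    prot$resid %in% STANDARD_AA3
  atoms <- data.frame(seq_index = seq_index, chain = prot$chain,
                      resno = prot$resno, icode = prot$insert,
                      res_name = prot$resid, atom_name = prot$elety,
                      element = prot$elesy, is_backbone = is_bb,
                      x = prot$x, y = prot$y, z = prot$z,
                      stringsAsFactors = FALSE)
  if (is.null(complex_id)) {
    base <- if (file.exists(pdb_source)) {
      sub("\\.pdb$", "", basename(pdb_source))
    } else "complex"
    complex_id <- paste0(base, "_", hit$code, "_", hit$chain, hit$resno)
  }
  pocket_complex(complex_id, atoms, ligand_df)
}

pdb_atom_line <- function(record, serial, name, res_name, chain, resno,
                          icode, x, y, z, element) {
  name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4)
              else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, res_name, chain, resno,
          ifelse(nzchar(icode), icode, " "), x, y, z, 1, 0,
          toupper(element))
}

#' Serialize a complex to PDB text
#'
#' Fixed-width ATOM/HETATM records (coordinates to 3 decimals); intended for
#' round-tripping complexes through standard tools.
#'
#' @param complex a [pocket_complex()].
#' @param path optional output file; when NULL the text is returned.
#' @return PDB text (invisibly when written to \code{path}).
#' @export
write_pdb <- function(complex, path = NULL) {
  a <- complex$atoms
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(a))) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line("ATOM", serial, a$atom_name[i],
                                    a$res_name[i], a$chain[i], a$resno[i],
                                    a$icode[i], a$x[i], a$y[i], a$z[i],
                                    a$element[i]))
  }
  l <- complex$ligand
  lcode <- l$res_name %||% rep("LIG", nrow(l))
  lchain <- l$chain %||% rep("X", nrow(l))
  lresno <- l$resno %||% rep(900L, nrow(l))
  if (is.null(l$res_name)) lcode <- rep("LIG", nrow(l))
  for (i in seq_len(nrow(l))) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line("HETATM", serial, l$atom_name[i],
                                    lcode[i], lchain[i], lresno[i], "",
                                    l$x[i], l$y[i], l$z[i], l$element[i]))
  }
  lines <- c(lines, "END")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}
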