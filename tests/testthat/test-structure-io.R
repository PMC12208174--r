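test_that("a minimal complex parses with residues, sequence and ligand", {
  cx <- read_complex(tiny_pdb_fixture(), ligand = "LIG")
  expect_s3_class(cx, "pocket_complex")
  expect_equal(nrow(cx$residue_table), 2)
  expect_equal(cx$sequence, "AG")
  expect_equal(nrow(cx$ligand), 3)
  expect_equal(cx$residue_table$seq_index, c(0L, 1L))
  expect_true(all(cx$atoms$is_backbone[cx$atoms$atom_name %in%
                                         c("N", "CA", "C", "O")]))
})

test_that("waters and buffer components are never selectable as ligand", {
  expect_error(read_complex(tiny_pdb_fixture(), ligand = "HOH"),
               class = "pocketsim_ligand_not_found")
  expect_error(read_complex(tiny_pdb_fixture(), ligand = "GOL"),
               class = "pocketsim_ligand_not_found")
  expect_error(read_complex(tiny_pdb_fixture(), ligand = "XYZ"),
               class = "pocketsim_ligand_not_found")
})

test_that("an undisambiguated multi-copy ligand is ambiguous", {
  expect_error(read_complex(two_chain_atp_fixture(), ligand = "ATP"),
               class = "pocketsim_ambiguous_ligand")
  cx <- read_complex(two_chain_atp_fixture(), ligand = "ATP:B")
  expect_equal(unique(cx$ligand$chain), "B")
  cx2 <- read_complex(two_chain_atp_fixture(), ligand = "ATP:A:101")
  expect_equal(unique(cx2$ligand$resno), 101)
})

test_that("chain selection keeps the contacting chain by default", {
  cx <- read_complex(two_chain_atp_fixture(), ligand = "ATP:A")
  expect_equal(unique(cx$atoms$chain), "A")
  cx_all <- read_complex(two_chain_atp_fixture(), ligand = "ATP:A",
                         chains = c("A", "B"))
  expect_equal(sort(unique(cx_all$atoms$chain)), c("A", "B"))
  expect_error(read_complex(two_chain_atp_fixture(), ligand = "ATP:A",
                            chains = "Z"),
               class = "pocketsim_empty_protein")
})

test_that("list_ligands enumerates non-water HET groups in order", {
  lig <- list_ligands(tiny_pdb_fixture())
  expect_equal(nrow(lig), 1)
  expect_equal(lig$code, "LIG")
  expect_equal(lig$n_atoms, 3)
  lig2 <- list_ligands(two_chain_atp_fixture())
  expect_equal(nrow(lig2), 2)
  expect_equal(lig2$chain, c("A", "B"))
  # protein-only file: empty listing, not an error
  prot_only <- paste(strsplit(tiny_pdb_fixture(), "\n")[[1]][1:9],
                     collapse = "\n")
  expect_equal(nrow(list_ligands(prot_only)), 0)
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  txt <- paste(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "HETATM    4  C1  LIG A 101       2.000   2.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  cx <- read_complex(txt, ligand = "LIG")
  ca1 <- cx$atoms[cx$atoms$seq_index == 0 & cx$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 9.0)
})

test_that("nonstandard residues map to X and are counted", {
  txt <- paste(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  XQZ A   2       3.800   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C1  LIG A 101       2.000   2.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  cx <- read_complex(txt, ligand = "LIG")
  expect_equal(cx$sequence, "AX")
  expect_equal(cx$n_nonstandard, 1)
})

test_that("PDB round trip preserves residues, sequence and coordinates", {
  tr <- generate_synthetic_complex(15, c(4, 7), seed = 11)
  cx <- tr$complex
  back <- read_complex(write_pdb(cx), ligand = "LIG", complex_id = cx$complex_id)
  expect_equal(back$sequence, cx$sequence)
  expect_equal(back$residue_table$res_name, cx$residue_table$res_name)
  expect_equal(nrow(back$ligand), nrow(cx$ligand))
  expect_equal(cbind(back$atoms$x, back$atoms$y, back$atoms$z),
               round(cbind(cx$atoms$x, cx$atoms$y, cx$atoms$z), 3))
  expect_equal(cbind(back$ligand$x, back$ligand$y, back$ligand$z),
               round(cbind(cx$ligand$x, cx$ligand$y, cx$ligand$z), 3))
})

test_that("synthetic generator plants interfaces that satisfy the distance contract", {
  for (seed in c(7, 21)) {
    tr <- generate_synthetic_complex(20, c(5, 6, 9), 6.0, seed = seed)
    expect_equal(tr$planted_interface, c(5L, 6L, 9L))
    P <- cbind(tr$complex$atoms$x, tr$complex$atoms$y, tr$complex$atoms$z)
    G <- cbind(tr$complex$ligand$x, tr$complex$ligand$y, tr$complex$ligand$z)
    d <- pocketsim:::cross_dist(P, G)
    res_min <- tapply(apply(d, 1, min), tr$complex$atoms$seq_index, min)
    idx <- as.integer(names(res_min))
    expect_true(all(res_min[idx %in% tr$planted_interface] <= 0.6 * 6))
    background <- !(idx %in% c(tr$planted_interface, tr$buried_decoys))
    expect_true(all(res_min[background] > 6))
    expect_true(all(res_min[idx %in% tr$buried_decoys] <= 6))
    expect_true(length(tr$buried_decoys) > 0)
    expect_length(intersect(tr$planted_interface, tr$buried_decoys), 0)
  }
})

test_that("synthetic generator is deterministic and validates preconditions", {
  a <- generate_synthetic_complex(20, c(5, 6, 9), 6.0, seed = 7)
  b <- generate_synthetic_complex(20, c(5, 6, 9), 6.0, seed = 7)
  expect_identical(a$complex$atoms, b$complex$atoms)
  expect_identical(a$complex$ligand, b$complex$ligand)
  c_ <- generate_synthetic_complex(20, c(5, 6, 9), 6.0, seed = 8)
  expect_false(identical(a$complex$atoms, c_$complex$atoms))
  expect_error(generate_synthetic_complex(20, c(50), 6.0, seed = 1),
               class = "pocketsim_error")
  expect_error(generate_synthetic_complex(5, c(1), 6.0, seed = 1),
               class = "pocketsim_error")
})
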