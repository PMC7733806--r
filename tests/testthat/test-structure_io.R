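test_that("a handcrafted PDB file is read back verbatim", {
  path <- write_mini_pdb(c(
    pdb_line(1, "N", "ALA", "A", 1, 1.0, 2.0, 3.0),
    pdb_line(2, "CA", "ALA", "A", 1, 2.0, 2.5, 3.0),
    pdb_line(3, "C", "ALA", "A", 1, 3.0, 2.0, 3.5)))
  s <- read_structure(path)
  expect_equal(n_atoms(s), 3)
  expect_equal(s$atoms$name, c("N", "CA", "C"))
  expect_equal(coords(s),
               matrix(c(1, 2, 3, 2, 2.5, 2, 3, 3, 3.5), 3, 3),
               ignore_attr = TRUE)
})

test_that("altloc policy keeps the highest-occupancy conformer, tie -> A", {
  path <- write_mini_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6, altloc = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.4, altloc = "B"),
    pdb_line(3, "CA", "ALA", "A", 2, 0, 0, 0, occ = 0.5, altloc = "B"),
    pdb_line(4, "CA", "ALA", "A", 2, 9, 0, 0, occ = 0.5, altloc = "A")))
  s <- read_structure(path)
  expect_equal(n_atoms(s), 2)
  expect_equal(s$atoms$x[s$atoms$resseq == 1], 0)   # occ 0.6 wins
  expect_equal(s$atoms$x[s$atoms$resseq == 2], 9)   # tie -> altloc A
})

test_that("mmCIF atom_site loops parse to the same structure as PDB", {
  cif <- c("data_fixture", "#", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
      "label_atom_id", "label_alt_id", "label_comp_id", "label_asym_id",
      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
      "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
      "pdbx_formal_charge", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num")),
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 3.000 2.000 3.500 1.00 0.00 ? 1 ALA A C 1")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  s <- read_structure(path)
  expect_equal(n_atoms(s), 3)
  expect_equal(s$atoms$name, c("N", "CA", "C"))
  expect_equal(s$atoms$x, c(1, 2, 3))
})

test_that("read -> write -> read round trip preserves keys and coordinates", {
  set.seed(7)
  rp <- make_rigid_pair(40, 25, c(0, 1, 1), c(3, -2, 1), 0.3, seed = 7)
  path <- tempfile(fileext = ".pdb")
  write_structure(rp$b, path)
  s2 <- read_structure(path)
  expect_equal(n_atoms(s2), n_atoms(rp$b))
  expect_equal(s2$atoms$resseq, rp$b$atoms$resseq)
  expect_equal(s2$atoms$name, rp$b$atoms$name)
  # PDB stores 3 decimals
  expect_lt(max(abs(coords(s2) - coords(rp$b))), 1e-3)
})

test_that("missing model index and unreadable files raise clear errors", {
  path <- write_mini_pdb(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0))
  expect_error(read_structure(path, model_index = 5), "model_index")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("selection arithmetic and idempotence hold", {
  s <- poly_ala(1000)
  sel <- atom_selection(ranges = list(c(750, 994)))
  expect_equal(n_atoms(select_atoms(s, sel)), 245)
  # select all -> identical
  expect_equal(select_atoms(s, atom_selection())$atoms, s$atoms)
  # empty result allowed, no error
  expect_equal(n_atoms(select_atoms(s, atom_selection(chains = "Z"))), 0)
  # idempotence over random selections
  set.seed(11)
  for (i in 1:10) {
    a <- sample(1000, 1)
    b <- min(1000, a + sample(200, 1))
    sel <- atom_selection(ranges = list(c(a, b)),
                          atom_names = sample(c("CA", "N"), 1))
    once <- select_atoms(s, sel)
    expect_identical(select_atoms(once, sel)$atoms, once$atoms)
  }
})

test_that("atom pairing matches a set-intersection oracle and is symmetric", {
  pair <- pump_pair_fixture()
  pr <- pair_common_atoms(pair$wt, pair$mut)
  # independent oracle: plain set intersection over key strings
  key_of <- function(s) paste(s$atoms$chain, s$atoms$resseq, s$atoms$icode,
                              s$atoms$name)
  expect_equal(nrow(pr$xyz_a), length(intersect(key_of(pair$wt),
                                                key_of(pair$mut))))
  # self-pairing: everything pairs, nothing dropped
  self <- pair_common_atoms(pair$wt, pair$wt)
  expect_equal(nrow(self$xyz_a), n_atoms(pair$wt))
  expect_length(self$dropped_a, 0)
  # wild type has the Glu340 side-chain oxygens the mutant lacks
  expect_true(any(grepl("OE1", pr$dropped_a)))
  # symmetry: swapping inputs swaps arrays but preserves the pair set
  pr2 <- pair_common_atoms(pair$mut, pair$wt)
  expect_equal(nrow(pr2$xyz_a), nrow(pr$xyz_a))
  k1 <- paste(pr$keys$chain, pr$keys$resseq, pr$keys$name)
  k2 <- paste(pr2$keys$chain, pr2$keys$resseq, pr2$keys$name)
  expect_setequal(k1, k2)
})

test_that("pairing reports the dropped residue and rejects zero overlap", {
  a <- poly_ala(10)
  b <- poly_ala(9)
  pr <- pair_common_atoms(a, b)
  expect_equal(nrow(pr$xyz_a), 9)
  expect_match(pr$dropped_a, "10")
  expect_length(pr$dropped_b, 0)
  shifted <- b
  shifted$atoms$resseq <- shifted$atoms$resseq + 100
  expect_error(pair_common_atoms(a, shifted), "no atoms in common")
})
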