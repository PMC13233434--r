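test_that("PDB parsing keeps author numbering and excludes hetero-atoms", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(crystalLikePdbText(), path)
  rec <- parseStructure(path)
  expect_s4_class(rec, "ProteinRecord")
  expect_identical(residueNumbers(rec)[1], 22L)
  expect_identical(seqLength(rec), 420L)           # NAG excluded
  expect_false(grepl("X", aaSequence(rec), fixed = TRUE))
  # sequence-index <-> author-number duality round-trips everywhere
  idx <- seq_len(seqLength(rec))
  expect_identical(authorToSeq(rec, seqToAuthor(rec, idx)), idx)
})

test_that("residues lacking a C-alpha stay in sequence with NA coordinates", {
  lines <- c(
    pdbLine("ATOM", 1, "CA", "ALA", 10, 1, 0, 0),
    pdbLine("ATOM", 2, "N",  "GLY", 11, 4, 0, 0),   # no CA for residue 11
    pdbLine("ATOM", 3, "CA", "VAL", 12, 8, 0, 0),
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  rec <- parseStructure(path)
  expect_identical(aaSequence(rec), "AGV")
  expect_true(anyNA(caCoords(rec)[2, ]))
  expect_false(anyNA(caCoords(rec)[1, ]))
})

test_that("selenomethionine is kept as M, unknown residues are skipped", {
  lines <- c(
    pdbLine("ATOM",   1, "CA", "ALA", 1, 0, 0, 0),
    pdbLine("HETATM", 2, "CA", "MSE", 2, 4, 0, 0),
    pdbLine("ATOM",   3, "CA", "XYZ", 3, 8, 0, 0),
    pdbLine("ATOM",   4, "CA", "CYS", 4, 12, 0, 0),
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_warning(rec <- parseStructure(path), "unknown")
  expect_identical(aaSequence(rec), "AMC")
})

test_that("mmCIF atom_site loops parse by tag name, not column position", {
  # deliberately unusual field order: a correct reader must follow the
  # self-describing header
  cif <- c(
    "data_toy", "#", "loop_",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num",
    "1.0 0.0 0.0 ATOM 1 C CA . ALA A 1 ? 22 A 1",
    "4.8 0.0 0.0 ATOM 2 C CA . CYS A 2 ? 23 A 1",
    "8.1 0.0 0.0 HETATM 3 O O . HOH A . ? 24 A 1",
    "#")
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, path)
  rec <- parseStructure(path)
  expect_identical(aaSequence(rec), "AC")
  expect_identical(residueNumbers(rec), c(22L, 23L))
  expect_equal(caCoords(rec)[, "x"], c(1.0, 4.8), ignore_attr = TRUE)
})

test_that("DSSP 8-state codes reduce to 3 states and gaps fill with coil", {
  rec <- ProteinRecord("d", "ACDEFGHIKLMNPQ", residueNumbers = 22:35)
  dssp <- c("== header ==", "   14 residues",
            "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
            sprintf("%5d%5d %1s %1s  %1s", 1:7, 22:28, "A",
                    strsplit("ACDEFGH", "")[[1]],
                    c("H", "H", "H", "H", "G", "G", "G")))
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(dssp, path)
  out <- parseDssp(path, rec)
  expect_identical(substr(ss3(out), 1, 7), "HHHHHHH")   # G -> H
  expect_identical(substr(ss3(out), 8, 14), "CCCCCCC")  # uncovered -> C

  dssp2 <- c("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
             sprintf("%5d%5d %1s %1s  %1s", 1:7, 22:28, "A",
                     strsplit("ACDEFGH", "")[[1]],
                     c("E", "E", "B", "T", "T", "S", " ")))
  writeLines(dssp2, path)
  expect_identical(substr(ss3(parseDssp(path, rec)), 1, 7), "EEECCCC")
})

test_that("DSSP files with no overlapping residues are an error", {
  rec <- ProteinRecord("d", "ACD", residueNumbers = 100:102)
  dssp <- c("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
            sprintf("%5d%5d %1s %1s  %1s", 1:2, 1:2, "A", c("A", "C"), "H"))
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(dssp, path)
  expect_error(parseDssp(path, rec), "overlap")
})

test_that("FASTA round-trips ids and sequences, preserving file order", {
  recs <- list(ProteinRecord("P11142", "MSKGPAVGIDLGTTYS"),
               ProteinRecord("Q86IA3", "ACDEFGHIKLMNPQRSTVWY"))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(recs, path)
  back <- parseFasta(path)
  expect_identical(vapply(back, recordId, character(1)),
                   c("P11142", "Q86IA3"))
  expect_identical(vapply(back, aaSequence, character(1)),
                   vapply(recs, aaSequence, character(1)))
  expect_identical(residueNumbers(back[[1]]), 1:16)
})

test_that("lowercase FASTA sequences are uppercased and empty files error", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "mskgpa"), path)
  expect_identical(aaSequence(parseFasta(path)[[1]]), "MSKGPA")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(parseFasta(empty))
})

test_that("ProteinRecord validity enforces aligned slots and numbering", {
  expect_error(ProteinRecord("x", "ACD", residueNumbers = c(1L, 1L, 2L)),
               "increasing")
  expect_error(ProteinRecord("x", "AXD"), "non-standard")
  expect_error(ProteinRecord("x", "ACD", residueNumbers = 1:2), "length")
})
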