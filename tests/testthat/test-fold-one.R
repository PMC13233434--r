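toyWindows <- function(seqs) {
  # bare windows with a fake 1-letter motif centred arbitrarily: only the
  # paddedSeq matters for Fold One, so build minimal valid objects
  lapply(seq_along(seqs), function(i) {
    rec <- ProteinRecord(paste0("t", i), gsub("X", "A", seqs[i]))
    s <- list(seq_start = 1L, seq_end = nchar(seqs[i]))
    w <- expandWindow(rec, s, 0L)
    w@paddedSeq <- seqs[i]
    w@motif <- seqs[i]
    w
  })
}

test_that("frequency matrices tally symbols per position", {
  fm <- frequencyMatrix(toyWindows(c("CAC", "CGC")))
  expect_identical(fm$n_windows, 2L)
  expect_identical(unname(fm$counts["C", ]), c(2L, 0L, 2L))
  expect_identical(unname(fm$counts["A", 2]), 1L)
  expect_identical(unname(fm$counts["G", 2]), 1L)
  expect_true(all(colSums(fm$counts) == fm$n_windows))
  expect_error(frequencyMatrix(toyWindows(c("CAC", "CGCC"))), "length")
})

test_that("column sums equal window count on a generated family", {
  fam <- smallFamily()
  sets <- buildExpansionSets(fam$records, cxxc(), radii = c(10, 150))
  for (len in names(sets)) {
    fm <- frequencyMatrix(sets[[len]])
    expect_true(all(colSums(fm$counts) == length(sets[[len]])))
    expect_identical(sum(fm$counts),
                     fm$n_windows * fm$window_length)
  }
})

test_that("consensus applies the threshold and alphabetical tie-break", {
  fm <- frequencyMatrix(toyWindows(c("CAC", "CGC")))
  expect_identical(as.character(consensusSequence(fm, 1)), "CXC")
  expect_message(c05 <- consensusSequence(fm, 0.5), "tie")
  expect_identical(as.character(c05), "CAC")
})

test_that("raising the consensus threshold never un-masks a position", {
  fam <- smallFamily(seed = 11)
  sets <- buildExpansionSets(fam$records, cxxc(), radii = c(30, 60))
  for (len in names(sets)) {
    fm <- frequencyMatrix(sets[[len]])
    lo <- strsplit(as.character(suppressMessages(
      consensusSequence(fm, 0.6))), "")[[1]]
    hi <- strsplit(as.character(suppressMessages(
      consensusSequence(fm, 0.9))), "")[[1]]
    expect_true(all(hi == "X" | hi == lo))
  }
})

test_that("Chou-Fasman classes equal the propensity-table argmax", {
  tab <- chouFasmanTable()
  # independent re-derivation: argmax of the three propensities with the
  # declared H > E > T tie priority
  expected <- apply(tab[, c("p_helix", "p_sheet", "p_turn")], 1,
                    function(p) c("H", "E", "T")[which.max(p)])
  expect_identical(tab$class, unname(expected))
  expect_identical(chouFasmanClasses("E"), "H")   # Glu: helix former
  expect_identical(chouFasmanClasses("V"), "E")   # Val: sheet former
  expect_identical(chouFasmanClasses("G"), "T")   # Gly: turn former
  expect_identical(chouFasmanClasses("X"), "x")
  expect_identical(chouFasmanClasses("EVGX"), "HETx")
  expect_error(chouFasmanClasses("EB"), "unknown")
})

test_that("class translation never increases Hamming distance (property)", {
  set.seed(42)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  for (i in 1:50) {
    a <- paste(sample(aa, 30, TRUE), collapse = "")
    b <- paste(sample(aa, 30, TRUE), collapse = "")
    dRes <- sequenceIdentity(a, b)$hamming
    dCls <- sequenceIdentity(chouFasmanClasses(a),
                             chouFasmanClasses(b))$hamming
    expect_lte(dCls, dRes)
  }
})

test_that("sequence identity follows SI = 100 (1 - D/L)", {
  expect_equal(sequenceIdentity("AAAA", "AAAT"),
               list(si = 75, hamming = 1L, length = 4L))
  id <- sequenceIdentity(strrep("Q", 24), strrep("Q", 24))
  expect_identical(id$si, 100)
  expect_identical(id$hamming, 0L)
  worst <- sequenceIdentity("AAAA", "TTTT")
  expect_identical(worst$si, 0)
  expect_error(sequenceIdentity("AA", "AAA"), "equal length")
  # padding X is an ordinary symbol unless excluded
  expect_identical(sequenceIdentity("AX", "AX")$si, 100)
  expect_identical(sequenceIdentity("AXB", "AXA",
                                    excludePad = FALSE)$length, 3L)
})

test_that("formula SI equals direct position counting on random pairs", {
  set.seed(99)
  syms <- c(LETTERS[1:20], "X")
  for (i in 1:200) {
    L <- sample(3:60, 1)
    a <- sample(syms, L, TRUE); b <- sample(syms, L, TRUE)
    si <- sequenceIdentity(paste(a, collapse = ""),
                           paste(b, collapse = ""))$si
    expect_equal(si, 100 * sum(a == b) / L, tolerance = 1e-12)
  }
})

test_that("conservation curve is flat at 100 for identical windows and
           decays on divergent flanks", {
  # identical homologs: zero substitution everywhere
  fam0 <- generateFamily(familySpec(nProteins = 4, length = 150,
                                    anchorsPerProtein = 1,
                                    pattern = "C..C", flankRate = 0,
                                    coordNoise = 0, seed = 8))
  sets0 <- buildExpansionSets(fam0$records, cxxc(), radii = c(10, 30, 50))
  cc0 <- conservationCurve(sets0)
  expect_true(all(cc0$mean_si == 100))

  fam <- generateFamily(familySpec(nProteins = 6, length = 300,
                                   anchorsPerProtein = 1,
                                   pattern = "C..C", seed = 9))
  sets <- buildExpansionSets(fam$records, cxxc(),
                             radii = c(10, 40, 80, 120))
  cc <- conservationCurve(sets)
  expect_identical(cc$window_length, c(24L, 84L, 164L, 244L))
  expect_true(all(diff(cc$mean_si) < 0))
  expect_identical(cc$n_pairs, rep(choose(6L, 2L), 4))
  # independent check at one length: mean over explicit pairs
  wins <- sets[["84"]]
  sis <- combn(length(wins), 2, function(ij)
    sequenceIdentity(paddedSeq(wins[[ij[1]]]),
                     paddedSeq(wins[[ij[2]]]))$si)
  expect_equal(cc$mean_si[cc$window_length == 84], mean(sis))
})

test_that("single-pair curve gives the pair's SI and short sets warn", {
  w <- toyWindows(c("AAAAAAAAAAAAGGGGGGGGGGGG",
                    "AAAAAAAAAAAACCCCCCCCCCCC"))  # D = 12, L = 24
  cc <- conservationCurve(list("24" = w))
  expect_equal(cc$mean_si, 50)
  expect_warning(conservationCurve(list("24" = w[1])), "fewer than 2")
})
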