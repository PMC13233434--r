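# expected overlap counts below were derived by enumerating every
# fixed-length substring against the pattern by hand

test_that("anchors are reported in both coordinate spaces", {
  rec <- crystalLikeRecord()   # chain starts at author residue 22
  sites <- findAnchors(rec, cxxc())
  expect_identical(nrow(sites), 2L)
  expect_identical(sites$seq_start, c(40L, 385L))
  expect_identical(sites$res_start, c(61L, 406L))
  expect_identical(sites$res_end, c(64L, 409L))
  expect_identical(sites$matched, c("CGHC", "CPYC"))
})

test_that("overlapping scan finds adjacent occurrences; plain scan does not", {
  rec <- ProteinRecord("toy", "CACCAC")
  # enumeration of length-4 substrings against C..C: CACC (pos 1) and
  # CCAC (pos 3) match; the left-to-right non-overlapping scan stops at 1
  both <- findAnchors(rec, cxxc(), overlapping = TRUE)
  expect_identical(both$seq_start, c(1L, 3L))
  one <- findAnchors(rec, cxxc(), overlapping = FALSE)
  expect_identical(one$seq_start, 1L)
})

test_that("sequences without the motif yield an empty site table", {
  sites <- findAnchors(ProteinRecord("a", "AAAA"), cxxc())
  expect_identical(nrow(sites), 0L)
  expect_error(findAnchors(ProteinRecord("a", "AAAA"),
                           motifPattern("bad", "C[(")), "invalid")
})

test_that("every reported site regex-matches its subsequence (property)", {
  fam <- smallFamily()
  for (rec in fam$records) {
    sites <- findAnchors(rec, cxxc())
    expect_true(all(grepl("^C..C$", sites$matched)))
    expect_identical(sites$res_start,
                     seqToAuthor(rec, sites$seq_start))
    expect_identical(substring(aaSequence(rec), sites$seq_start,
                               sites$seq_end), sites$matched)
  }
})

test_that("windows pad symmetrically with X at chain bounds", {
  rec <- ProteinRecord("p", "MKVCGHCAAKLMNPQ")   # L = 15, site at 4..7
  site <- findAnchors(rec, cxxc())[1, ]
  w <- expandWindow(rec, site, 10)
  expect_identical(nchar(paddedSeq(w)), 24L)
  expect_identical(substr(paddedSeq(w), 11, 14), "CGHC")
  # 10 - 3 leading and (7 + 10) - 15 trailing overruns
  expect_identical(sum(w@padMask), 7L + 2L)
  expect_identical(substr(paddedSeq(w), 1, 7), "XXXXXXX")
  expect_identical(substr(paddedSeq(w), 23, 24), "XX")

  w0 <- expandWindow(rec, site, 0)
  expect_identical(paddedSeq(w0), "CGHC")
  expect_false(any(w0@padMask))
})

test_that("padding count matches the boundary formula (property)", {
  set.seed(7)
  fam <- smallFamily()
  rec <- fam$records[[1]]
  L <- seqLength(rec)
  sites <- findAnchors(rec, cxxc())
  for (i in seq_len(50)) {
    s <- sites[sample(nrow(sites), 1), ]
    r <- sample(0:250, 1)
    w <- expandWindow(rec, s, r)
    m <- nchar(s$matched)
    expected <- max(0, r - (s$seq_start - 1)) +
      max(0, (s$seq_start + m - 1 + r) - L)
    expect_identical(sum(w@padMask), as.integer(expected))
    expect_true(w@coordComplete == (expected == 0 &&
                                      !anyNA(caCoords(w))))
  }
})

test_that("expansion sets group one window per site per radius", {
  fam <- smallFamily()                       # 5 proteins x 2 anchors
  sets <- buildExpansionSets(fam$records, cxxc(), radii = c(10, 20, 30))
  expect_identical(sort(as.integer(names(sets))), c(24L, 44L, 64L))
  expect_true(all(vapply(sets, length, integer(1)) == 10L))
  # deterministic ordering: record order then anchor position
  ids <- vapply(sets[["24"]], recordId, character(1))
  expect_identical(ids, rep(vapply(fam$records, recordId, character(1)),
                            each = 2))
  expect_warning(
    out <- buildExpansionSets(list(ProteinRecord("a", "AAAA")), cxxc()),
    "no anchor")
  expect_identical(out, list())
})

test_that("representativeness filter drops lengths missing a subgroup", {
  spec <- familySpec(nProteins = 2, length = 120, anchorsPerProtein = 1,
                     terminalVariation = 0, pattern = "C..C", seed = 5)
  fam <- generateFamily(spec)
  short <- fam$records[[2]]
  # truncate protein 2 so large radii cannot be coordinate-complete
  anchor <- fam$truth$anchorStarts[1]
  keep <- seq_len(anchor + 20)
  short <- ProteinRecord(recordId(short),
                         substr(aaSequence(short), 1, max(keep)),
                         residueNumbers = residueNumbers(short)[keep],
                         caCoords = caCoords(short)[keep, ],
                         ss3 = substr(ss3(short), 1, max(keep)),
                         group = "grpB", source = "synthetic")
  recs <- list(fam$records[[1]], short)
  gm <- c(SYN01 = "grpA", SYN02 = "grpB")
  sets <- buildExpansionSets(recs, cxxc(), radii = c(10, 40))
  filtered <- filterRepresentative(sets, gm)
  expect_true("24" %in% names(filtered))    # both subgroups complete
  expect_false("84" %in% names(filtered))   # grpB window incomplete
  # sequence-level analyses keep everything (padding guarantees coverage)
  expect_identical(names(filterRepresentative(sets, gm,
                                              structural = FALSE)),
                   names(sets))
  expect_error(filterRepresentative(sets, c(SYN01 = "grpA")), "group map")
})
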