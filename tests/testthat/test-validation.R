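test_that("null anchors preserve motif composition and safety margins", {
  fam <- smallFamily(seed = 61)
  sites <- findAnchorsAll(fam$records, cxxc())
  lens <- vapply(fam$records, seqLength, integer(1))
  names(lens) <- vapply(fam$records, recordId, character(1))
  minN <- min(sites$seq_start - 1)
  minC <- min(lens[sites$protein_id] - sites$seq_end)
  trials <- sampleNullAnchors(fam$records, sites, n = 200, seed = 3)
  expect_length(trials, 200)
  m <- nchar(sites$matched[1])
  for (tr in trials) {
    expect_identical(sort(strsplit(tr$motif, "")[[1]]),
                     sort(strsplit(sites$matched[1], "")[[1]]))
    expect_false(tr$motif == sites$matched[1])   # identity rejected
    for (id in names(tr$positions)) {
      p <- tr$positions[[id]]
      expect_gte(p - 1, minN)
      expect_gte(lens[[id]] - (p + m - 1), minC)
    }
  }
})

test_that("null sampling is reproducible under a seed", {
  fam <- smallFamily(seed = 62)
  sites <- findAnchorsAll(fam$records, cxxc())
  a <- sampleNullAnchors(fam$records, sites, n = 10, seed = 7)
  b <- sampleNullAnchors(fam$records, sites, n = 10, seed = 7)
  expect_identical(a, b)
  c <- sampleNullAnchors(fam$records, sites, n = 10, seed = 8)
  expect_false(identical(a, c))
})

test_that("null experiment output is byte-stable and envelope bounds hold", {
  fam <- generateFamily(familySpec(nProteins = 5, length = 200,
                                   anchorsPerProtein = 1,
                                   pattern = "C..C", seed = 63))
  sites <- findAnchorsAll(fam$records, cxxc())
  e1 <- nullDecayExperiment(fam$records, sites, n = 8, seed = 5,
                            radii = c(10, 30, 50))
  e2 <- nullDecayExperiment(fam$records, sites, n = 8, seed = 5,
                            radii = c(10, 30, 50))
  expect_identical(e1, e2)
  expect_true(all(e1$envelope$null_min <= e1$envelope$null_mean))
  expect_true(all(e1$envelope$null_mean <= e1$envelope$null_max))
  expect_identical(nrow(e1$envelope), 3L)
})

test_that("planted conservation separates biological from null curves", {
  fam <- generateFamily(familySpec(nProteins = 8, length = 260,
                                   anchorsPerProtein = 1,
                                   pattern = "C..C", seed = 64))
  sites <- findAnchorsAll(fam$records, cxxc())
  ex <- nullDecayExperiment(fam$records, sites, n = 15, seed = 9,
                            radii = c(10, 20))
  cmp <- merge(ex$biological, ex$envelope, by = "window_length")
  expect_true(all(cmp$mean_si >= cmp$null_mean))
})

test_that("without conservation the biological advantage shrinks to the
           planted motif itself", {
  fam <- generateFamily(familySpec(nProteins = 6, length = 220,
                                   anchorsPerProtein = 1, coreRadius = 0,
                                   pattern = "C..C", flankRate = 0.95,
                                   seed = 65))
  sites <- findAnchorsAll(fam$records, cxxc())
  ex <- nullDecayExperiment(fam$records, sites, n = 20, seed = 11,
                            radii = c(20, 40))
  cmp <- merge(ex$biological, ex$envelope, by = "window_length")
  # residual edge is bounded by the 4 identical motif residues: at window
  # length W the motif can contribute at most 400/W identity points
  margin <- cmp$mean_si - cmp$null_mean
  expect_true(all(margin <= 400 / cmp$window_length + 5))
  expect_true(all(margin >= -5))
})

test_that("interval IoU matching follows closed-interval arithmetic", {
  p <- data.frame(protein_id = "a", start = 10, end = 14)
  r <- data.frame(protein_id = "a", start = 12, end = 16)
  # overlap 12..14 = 3 residues, union 10..16 = 7: IoU 3/7 < 0.5
  out <- matchSitesIoU(p, r)
  expect_identical(out$TP, 0L)
  expect_identical(out$FP, 1L)
  expect_identical(out$FN, 1L)
  out2 <- matchSitesIoU(p, r, iouMin = 3 / 7)
  expect_identical(out2$TP, 1L)
  expect_equal(out2$mean_iou, 3 / 7)
  expect_error(matchSitesIoU(data.frame(protein_id = "a", start = 5,
                                        end = 3), r), "malformed")
})

test_that("identical site tables give perfect metrics", {
  fam <- smallFamily(seed = 66)
  pred <- scanPrositePattern(fam$records, "C-x(2)-C")
  out <- matchSitesIoU(pred, pred)
  expect_identical(out$TP, nrow(pred))
  expect_equal(out$precision, 1)
  expect_equal(out$recall, 1)
  expect_equal(out$f1, 1)
  expect_equal(out$mean_iou, 1)
})

test_that("empty predictions yield zero recall (and logged conventions)", {
  ref <- data.frame(protein_id = "a", start = c(1, 10, 20, 30),
                    end = c(4, 13, 23, 33))
  none <- ref[0, ]
  expect_message(out <- matchSitesIoU(none, ref), "precision")
  expect_identical(out$FN, 4L)
  expect_identical(out$recall, 0)
  expect_identical(out$precision, 1)
})

test_that("greedy matching attains the optimal TP count (oracle, <=6/side)", {
  set.seed(77)
  for (i in 1:60) {
    np <- sample(0:6, 1); nr <- sample(0:6, 1)
    mk <- function(n) {
      if (n == 0) return(data.frame(protein_id = character(0),
                                    start = numeric(0), end = numeric(0)))
      s <- sample(1:40, n, TRUE)
      data.frame(protein_id = sample(c("p", "q"), n, TRUE),
                 start = s, end = s + sample(3:8, n, TRUE))
    }
    pred <- mk(np); ref <- mk(nr)
    got <- suppressMessages(matchSitesIoU(pred, ref))$TP
    expect_identical(got, bruteForceTP(pred, ref))
  }
})

test_that("micro-average pools counts across motifs", {
  perfect <- function(n) list(TP = n, FP = 0L, FN = 0L)
  micro <- microAverage(list(a = perfect(25), b = perfect(7),
                             c = perfect(4)))
  expect_equal(micro$TP, 36)
  expect_equal(micro$f1, 1)
  # one perfect + one all-missed: micro recall strictly between them
  mixed <- microAverage(list(a = perfect(10),
                             b = list(TP = 0L, FP = 0L, FN = 5L)))
  expect_gt(mixed$recall, 0)
  expect_lt(mixed$recall, 1)
  # single result: micro equals the per-motif metrics
  one <- list(TP = 3L, FP = 1L, FN = 2L)
  m1 <- microAverage(list(one))
  expect_equal(m1$precision, 3 / 4)
  expect_equal(m1$recall, 3 / 5)
})

test_that("PROSITE patterns compile to equivalent regular expressions", {
  expect_identical(prositeToRegex("C-x(2)-C"), "C.{2}C")
  expect_identical(prositeToRegex("C-x-x-C."), "C..C")
  expect_identical(prositeToRegex("[AC]-x-V-x(4)-{ED}"),
                   "[AC].V.{4}[^ED]")
  expect_identical(prositeToRegex("<A-x(2,4)-G>"), "^A.{2,4}G$")
  expect_error(prositeToRegex("C-??-C"), "unsupported")
  # compiled pattern scans like the native motif regex
  fam <- smallFamily(seed = 67)
  a <- scanPrositePattern(fam$records, "C-x(2)-C")
  b <- findAnchorsAll(fam$records, cxxc())
  expect_identical(a$start, b$res_start)
  expect_identical(a$end, b$res_end)
})
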