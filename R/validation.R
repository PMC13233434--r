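# Validation layer: (i) a composition-preserving permutation null model --
# "non-biological anchors" with the same residue multiset as the real motif,
# placed at margin-matched random positions -- showing that sustained
# conservation is a property of the motif's sequential organisation rather
# than of composition or position; (ii) a site-level intersection-over-union
# benchmark of detected motif sites against reference annotations (e.g. a
# PROSITE pattern scan).

.permuteDistinct <- function(letters1) {
  # random permutation, rejecting the identity when any distinct one exists
  if (length(unique(letters1)) == 1L) return(letters1)
  repeat {
    p <- sample(letters1)
    if (any(p != letters1)) return(p)
  }
}

#' Sample composition-preserving null anchors
#'
#' Builds \code{n} null trials. Each trial permutes the letters of the
#' biological motif (same amino-acid multiset, different order, identity
#' permutation rejected whenever an alternative exists) and, for every
#' record, draws an anchor start uniformly among positions satisfying the
#' safety margin: the distance to each terminus must be at least the
#' minimum over the family's biological anchors of the corresponding
#' terminal distance. This keeps the null anchors in a structurally
#' equivalent window of the chain, controlling for positional bias and
#' protein length.
#'
#' @param records list of ProteinRecord or ProteinFamily.
#' @param bioSites data.frame of biological anchors
#'   (\code{\link{findAnchorsAll}} output).
#' @param n number of trials (50 in the reference analysis).
#' @param seed RNG seed; trials are reproducible given (records, bioSites,
#'   n, seed).
#' @return List of trials; each has \code{trial}, \code{motif} (permuted),
#'   \code{positions} (named integer vector protein_id -> 1-based anchor
#'   start). Records with no admissible position are skipped with a
#'   warning.
#' @export
sampleNullAnchors <- function(records, bioSites, n = 50L, seed = 1L) {
  records <- .asRecordList(records)
  stopifnot(n >= 1L, nrow(bioSites) >= 1L)
  m <- nchar(bioSites$matched[1L])
  motif0 <- strsplit(bioSites$matched[1L], "", fixed = TRUE)[[1L]]
  lens <- stats::setNames(vapply(records, seqLength, integer(1)),
                          vapply(records, recordId, character(1)))
  # terminal distances of biological anchors (residues before / after site)
  distN <- bioSites$seq_start - 1L
  distC <- lens[bioSites$protein_id] - bioSites$seq_end
  minN <- min(distN); minC <- min(distC)
  set.seed(seed)
  lapply(seq_len(n), function(t) {
    perm <- paste(.permuteDistinct(motif0), collapse = "")
    pos <- integer(0)
    for (r in records) {
      L <- seqLength(r)
      starts <- seq_len(L - m + 1L)
      ok <- (starts - 1L) >= minN & (L - (starts + m - 1L)) >= minC
      if (!any(ok)) {
        warning("record '", recordId(r),
                "' has no admissible null-anchor position in trial ", t)
        next
      }
      cand <- starts[ok]
      pos[recordId(r)] <- cand[sample.int(length(cand), 1L)]
    }
    list(trial = t, motif = perm, positions = pos)
  })
}

# expansion sets from fixed (protein -> start) positions, mirroring
# buildExpansionSets but anchoring at given sites of width m
.setsFromPositions <- function(records, positions, m, radii) {
  records <- .asRecordList(records)
  ids <- vapply(records, recordId, character(1))
  sets <- list()
  for (r in sort(unique(as.integer(radii)))) {
    wins <- list()
    for (i in seq_along(records)) {
      id <- ids[i]
      if (!id %in% names(positions)) next
      s <- positions[[id]]
      site <- list(seq_start = s, seq_end = s + m - 1L)
      wins[[length(wins) + 1L]] <- expandWindow(records[[i]], site, r)
    }
    if (length(wins) >= 1L)
      sets[[as.character(m + 2L * r)]] <- wins
  }
  sets
}

#' Conservation decay under biological vs null anchoring
#'
#' Computes the sequence-identity conservation curve for the biological
#' anchors and, with the identical procedure, one curve per null trial
#' anchored at that trial's sampled positions. The per-length minimum,
#' mean and maximum over trials form the null envelope against which the
#' biological curve is compared: a biological anchor marking a real
#' functional scaffold stays above the envelope mean well beyond the motif
#' itself, while null curves collapse shortly after the seed.
#'
#' @param records list of ProteinRecord or ProteinFamily.
#' @param bioSites biological anchor table (\code{\link{findAnchorsAll}}).
#' @param n number of null trials (default 50).
#' @param seed RNG seed.
#' @param radii per-side expansion radii (default 10..200 step 10).
#' @return List with \code{biological} (conservation curve data.frame),
#'   \code{null_curves} (long data.frame trial, window_length, mean_si),
#'   \code{envelope} (per length: null_min, null_mean, null_max) and
#'   \code{trials} (the sampled null anchors).
#' @export
nullDecayExperiment <- function(records, bioSites, n = 50L, seed = 1L,
                                radii = seq(10L, 200L, 10L)) {
  records <- .asRecordList(records)
  m <- nchar(bioSites$matched[1L])
  bioSets <- .setsFromAnchors(records, bioSites, radii)
  biological <- conservationCurve(bioSets)
  trials <- sampleNullAnchors(records, bioSites, n = n, seed = seed)
  nullCurves <- do.call(rbind, lapply(trials, function(tr) {
    sets <- .setsFromPositions(records, tr$positions, m, radii)
    cc <- suppressWarnings(conservationCurve(sets))
    if (nrow(cc) == 0L) return(NULL)
    data.frame(trial = tr$trial, window_length = cc$window_length,
               mean_si = cc$mean_si)
  }))
  env <- stats::aggregate(mean_si ~ window_length, data = nullCurves,
                          FUN = function(x) c(min = min(x), mean = mean(x),
                                              max = max(x)))
  envelope <- data.frame(window_length = env$window_length,
                         null_min = env$mean_si[, "min"],
                         null_mean = env$mean_si[, "mean"],
                         null_max = env$mean_si[, "max"])
  list(biological = biological, null_curves = nullCurves,
       envelope = envelope, trials = trials)
}

# windows at the biological anchor rows themselves
.setsFromAnchors <- function(records, sites, radii) {
  records <- .asRecordList(records)
  ids <- vapply(records, recordId, character(1))
  m <- nchar(sites$matched[1L])
  sets <- list()
  for (r in sort(unique(as.integer(radii)))) {
    wins <- list()
    for (j in seq_len(nrow(sites))) {
      rec <- records[[match(sites$protein_id[j], ids)]]
      wins[[length(wins) + 1L]] <- expandWindow(rec, sites[j, ], r)
    }
    sets[[as.character(m + 2L * r)]] <- wins
  }
  sets
}

# -- IoU benchmark ----------------------------------------------------------

.intervalIoU <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  union <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - inter
  inter / union
}

#' Match predicted against reference motif sites by IoU
#'
#' Sites are closed intervals in author (PDB) residue space, one table row
#' per site (columns protein_id, start, end). Candidate pairs within the
#' same protein whose intersection-over-union (residue overlap / residue
#' union) reaches \code{iouMin} are matched greedily by descending IoU,
#' one-to-one, ties broken by (protein_id, start). Matched pairs are true
#' positives; unmatched predictions false positives; unmatched references
#' false negatives.
#'
#' Degenerate cases: with zero predictions and zero references on a side,
#' the corresponding rate (precision/recall) is reported as 1.0 (with a
#' message), keeping perfect-agreement tables well defined.
#'
#' @param predicted,reference data.frames with columns protein_id, start,
#'   end.
#' @param iouMin matching threshold (default 0.5).
#' @return List: n_pred, n_ref, TP, FP, FN, precision, recall, f1,
#'   mean_iou (over true positives; NA if none), matches (data.frame).
#' @examples
#' p <- data.frame(protein_id = "a", start = 10, end = 14)
#' r <- data.frame(protein_id = "a", start = 12, end = 16)
#' matchSitesIoU(p, r)$TP  # 0: IoU = 3/7 < 0.5
#' @export
matchSitesIoU <- function(predicted, reference, iouMin = 0.5) {
  for (tab in list(predicted, reference)) {
    if (nrow(tab) && any(tab$end < tab$start))
      stop("malformed interval: end < start")
  }
  cand <- NULL
  if (nrow(predicted) && nrow(reference)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(predicted)), function(i) {
      sameProt <- which(reference$protein_id == predicted$protein_id[i])
      if (!length(sameProt)) return(NULL)
      iou <- vapply(sameProt, function(j)
        .intervalIoU(predicted$start[i], predicted$end[i],
                     reference$start[j], reference$end[j]), numeric(1))
      keep <- iou >= iouMin
      if (!any(keep)) return(NULL)
      data.frame(pred = i, ref = sameProt[keep], iou = iou[keep],
                 protein_id = predicted$protein_id[i],
                 start = predicted$start[i])
    }))
  }
  matches <- data.frame(pred = integer(0), ref = integer(0),
                        iou = numeric(0))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(-cand$iou, cand$protein_id, cand$start), ]
    usedP <- logical(nrow(predicted)); usedR <- logical(nrow(reference))
    for (i in seq_len(nrow(cand))) {
      if (usedP[cand$pred[i]] || usedR[cand$ref[i]]) next
      usedP[cand$pred[i]] <- TRUE; usedR[cand$ref[i]] <- TRUE
      matches <- rbind(matches, cand[i, c("pred", "ref", "iou")])
    }
  }
  TP <- nrow(matches)
  FP <- nrow(predicted) - TP
  FN <- nrow(reference) - TP
  precision <- if (TP + FP == 0L) {
    message("no predictions: precision reported as 1.0 by convention")
    1
  } else TP / (TP + FP)
  recall <- if (TP + FN == 0L) {
    message("no references: recall reported as 1.0 by convention")
    1
  } else TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(n_pred = nrow(predicted), n_ref = nrow(reference),
       TP = TP, FP = FP, FN = FN, precision = precision, recall = recall,
       f1 = f1, mean_iou = if (TP) mean(matches$iou) else NA_real_,
       matches = matches)
}

#' Micro-average benchmark results across motifs
#'
#' Pools TP/FP/FN over the per-motif results and recomputes precision,
#' recall and F1 from the pooled counts.
#'
#' @param results named list of \code{\link{matchSitesIoU}} results.
#' @return List with pooled counts and metrics.
#' @export
microAverage <- function(results) {
  stopifnot(length(results) >= 1L)
  TP <- sum(vapply(results, `[[`, numeric(1), "TP"))
  FP <- sum(vapply(results, `[[`, numeric(1), "FP"))
  FN <- sum(vapply(results, `[[`, numeric(1), "FN"))
  precision <- if (TP + FP == 0) 1 else TP / (TP + FP)
  recall <- if (TP + FN == 0) 1 else TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(TP = TP, FP = FP, FN = FN, precision = precision, recall = recall,
       f1 = f1)
}

#' Compile a PROSITE pattern into a regular expression
#'
#' Supports the standard PROSITE pattern syntax: elements separated by
#' "-", \code{x} for any residue, \code{x(n)} and \code{x(n,m)} repeats,
#' \code{[ABC]} alternatives, \code{\{ABC\}} exclusions, \code{<}/\code{>}
#' terminal anchors and a trailing period. E.g. \code{"C-x(2)-C"} compiles
#' to \code{"C.\{2\}C"}.
#'
#' @param pattern PROSITE pattern string.
#' @return Regular expression string.
#' @export
prositeToRegex <- function(pattern) {
  p <- sub("\\.$", "", trimws(pattern))
  anchorStart <- grepl("^<", p); p <- sub("^<", "", p)
  anchorEnd <- grepl(">$", p); p <- sub(">$", "", p)
  parts <- strsplit(p, "-", fixed = TRUE)[[1L]]
  rx <- vapply(parts, function(el) {
    rep <- ""
    repm <- regmatches(el, regexec("\\(([0-9]+)(,([0-9]+))?\\)$", el))[[1L]]
    if (length(repm)) {
      rep <- if (nzchar(repm[4L]))
        sprintf("{%s,%s}", repm[2L], repm[4L])
      else sprintf("{%s}", repm[2L])
      el <- sub("\\([0-9,]+\\)$", "", el)
    }
    core <- if (el == "x") "."
      else if (grepl("^\\[[A-Z]+\\]$", el)) el
      else if (grepl("^\\{[A-Z]+\\}$", el))
        paste0("[^", substr(el, 2L, nchar(el) - 1L), "]")
      else if (grepl("^[A-Z]$", el)) el
      else stop("unsupported PROSITE element: ", el)
    paste0(core, rep)
  }, character(1))
  paste0(if (anchorStart) "^" else "", paste(rx, collapse = ""),
         if (anchorEnd) "$" else "")
}

#' Scan records with a PROSITE-style pattern into a reference site table
#'
#' Offline stand-in for a ScanProsite export: compiles the pattern and
#' reports every (overlapping) occurrence as a closed author-residue
#' interval, the format consumed by \code{\link{matchSitesIoU}}.
#'
#' @param records list of ProteinRecord or ProteinFamily.
#' @param pattern PROSITE pattern (e.g. "C-x(2)-C") or plain regex.
#' @param prosite treat \code{pattern} as PROSITE syntax (default TRUE).
#' @return data.frame protein_id, start, end, matched (author residue
#'   space).
#' @export
scanPrositePattern <- function(records, pattern, prosite = TRUE) {
  rx <- if (prosite) prositeToRegex(pattern) else pattern
  sites <- findAnchorsAll(records, motifPattern(pattern, rx))
  data.frame(protein_id = sites$protein_id, start = sites$res_start,
             end = sites$res_end, matched = sites$matched,
             stringsAsFactors = FALSE)
}
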