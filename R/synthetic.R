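# Synthetic protein-family fixtures: homolog sets derived from a common
# ancestor with a planted anchor motif, a tunable per-position substitution
# profile (conserved core, variable flanks), an idealized secondary-structure
# layout around each anchor, and C-alpha coordinates built from ideal
# helix/strand geometry plus distance-scaled isotropic noise. Everything is
# deterministic under the spec seed, and ground truth (sites, ancestor,
# topology) is returned alongside the records so detector output can be
# checked exactly.

#' Specification of a synthetic protein family
#'
#' The defaults emulate a disulfide-isomerase-like study family: eleven
#' homologs of ~480 residues carrying a CGHC redox motif (detected with the
#' CXXC pattern) at two active sites, a thioredoxin-like
#' beta-alpha-beta-alpha-beta secondary-structure layout around each
#' anchor, substitution-free conservation within 20 residues of an anchor
#' and a 0.5 per-position substitution rate beyond it, and coordinate noise
#' that is zero in the core and a few Angstrom in the flanks.
#'
#' @param nProteins number of homologs.
#' @param length chain length in residues.
#' @param motif exact planted motif string (e.g. "CGHC").
#' @param pattern regex used for detection and for spurious-occurrence
#'   rejection; defaults to the literal motif.
#' @param anchorsPerProtein planted anchors per homolog.
#' @param layout data.frame (element in H/E/C, length) of the
#'   secondary-structure elements planted around each anchor, in order.
#' @param layoutStartOffset offset of the layout's first residue relative
#'   to the anchor start (negative = into the N-terminal flank).
#' @param coreRadius residues around an anchor with core substitution rate.
#' @param coreRate,flankRate per-position substitution probabilities inside
#'   / outside the core.
#' @param coordNoise Angstrom scale of isotropic coordinate noise; the
#'   per-position standard deviation is coordNoise x substitution
#'   probability, so the core superposes exactly and flanks degrade.
#' @param terminalVariation maximum number of extra random residues
#'   prepended and appended per homolog (drawn uniformly per terminus),
#'   emulating the chain-length variation of real families; 0 makes all
#'   homologs exactly colinear.
#' @param numberingOffset author residue number of the first residue
#'   (e.g. 22 to emulate crystal chains that start after an excluded
#'   hetero-group).
#' @param nGroups number of taxonomic subgroups, assigned round-robin.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return List of class \code{FamilySpec}.
#' @export
familySpec <- function(nProteins = 11L, length = 480L, motif = "CGHC",
                       pattern = NULL, anchorsPerProtein = 2L,
                       layout = data.frame(
                         element = c("E", "C", "H", "C", "E", "C", "H",
                                     "C", "E"),
                         length = c(5L, 3L, 9L, 3L, 5L, 3L, 9L, 3L, 5L)),
                       layoutStartOffset = -13L,
                       coreRadius = 20L, coreRate = 0, flankRate = 0.5,
                       coordNoise = 8, terminalVariation = 30L,
                       numberingOffset = 1L,
                       nGroups = 2L, seed = 42L) {
  if (nchar(motif) > length) stop("motif longer than chain length")
  stopifnot(coreRate >= 0, coreRate <= 1, flankRate >= 0, flankRate <= 1,
            anchorsPerProtein >= 1L, nProteins >= 1L)
  if (is.null(pattern)) pattern <- motif
  structure(list(nProteins = as.integer(nProteins),
                 length = as.integer(length), motif = toupper(motif),
                 pattern = pattern,
                 anchorsPerProtein = as.integer(anchorsPerProtein),
                 layout = layout,
                 layoutStartOffset = as.integer(layoutStartOffset),
                 coreRadius = as.integer(coreRadius),
                 coreRate = coreRate, flankRate = flankRate,
                 coordNoise = coordNoise,
                 terminalVariation = as.integer(terminalVariation),
                 numberingOffset = as.integer(numberingOffset),
                 nGroups = as.integer(nGroups), seed = as.integer(seed)),
            class = "FamilySpec")
}

# distance of each position to the nearest planted motif (0 inside one)
.anchorDistance <- function(L, starts, m) {
  d <- rep(Inf, L)
  for (s in starts) {
    idx <- seq_len(L)
    inside <- idx >= s & idx <= s + m - 1L
    d <- pmin(d, ifelse(inside, 0L,
                        pmin(abs(idx - s), abs(idx - (s + m - 1L)))))
  }
  d
}

.substProfile <- function(spec, dist) {
  ifelse(dist <= spec$coreRadius, spec$coreRate, spec$flankRate)
}

# overlapping regex scan returning match starts
.regexStarts <- function(seqstr, regex) {
  m <- gregexpr(paste0("(?=(", regex, "))"), seqstr, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# redraw letters until the pattern occurs only at planted starts; an
# optional hook maps a chosen position to its mutation site and
# re-normalizes the sequence (used for ancestral core duplication)
.rejectSpurious <- function(letters1, regex, plantedStarts, m, mutable,
                            mapToSource = identity,
                            normalize = identity) {
  letters1 <- normalize(letters1)
  for (iter in 1:200) {
    starts <- .regexStarts(paste(letters1, collapse = ""), regex)
    spurious <- setdiff(starts, plantedStarts)
    if (!length(spurious)) return(letters1)
    for (s in spurious) {
      span <- s:(s + m - 1L)
      ok <- span[mutable[span]]
      if (!length(ok))
        stop("cannot remove spurious motif occurrence at ", s)
      p <- mapToSource(ok[sample.int(length(ok), 1L)])
      letters1[p] <- sample(setdiff(AA20, letters1[p]), 1L)
    }
    letters1 <- normalize(letters1)
  }
  stop("spurious-occurrence rejection did not converge")
}

# ideal C-alpha template from a 3-state string: helix 1.5 A rise and 100
# deg/residue on a 2.3 A radius; strand 3.3 A rise with a small zigzag;
# coil extended at 3.0 A rise. Segments are laid out consecutively along
# x, and helix phase / strand zigzag restart at each element run, so a
# shared core region produces congruent geometry no matter how much coil
# precedes it.
.idealCoords <- function(ss) {
  v <- strsplit(ss, "", fixed = TRUE)[[1L]]
  L <- length(v)
  out <- matrix(0, nrow = L, ncol = 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  r <- rle(v)
  x <- 0; i <- 0L
  for (e in seq_along(r$lengths)) {
    for (j in seq_len(r$lengths[e])) {
      i <- i + 1L
      if (r$values[e] == "H") {
        x <- x + 1.5
        out[i, ] <- c(x, 2.3 * cos(j * 100 * pi / 180),
                      2.3 * sin(j * 100 * pi / 180))
      } else if (r$values[e] == "E") {
        x <- x + 3.3
        out[i, ] <- c(x, 0.5 * (-1)^j, 0)
      } else {
        x <- x + 3.0
        out[i, ] <- c(x, 0, 0)
      }
    }
  }
  out
}

#' Generate a synthetic protein family with ground truth
#'
#' Draws an ancestor sequence, plants the motif at evenly spaced anchor
#' positions (spurious pattern occurrences are removed by targeted
#' resampling so the planted sites are exactly the true sites; with
#' several anchors per protein the core context of the first anchor is
#' duplicated to the others, emulating domain duplication), then
#' derives each homolog by per-position substitution at the profile rate
#' (core vs flank). Secondary structure follows the planted element layout
#' around each anchor (coil elsewhere) and is identical across homologs;
#' coordinates are the ideal-geometry template plus isotropic Gaussian
#' noise with standard deviation coordNoise x substitution rate at each
#' position.
#'
#' @param spec a \code{\link{familySpec}}.
#' @return List with \code{records} (list of
#'   \code{\linkS4class{ProteinRecord}}, source "synthetic"),
#'   \code{truth} (sites table in both coordinate spaces, the detection
#'   pattern, ancestor sequence, planted anchor starts, secondary-structure
#'   string and element topology) and \code{spec}.
#' @examples
#' fam <- generateFamily(familySpec(nProteins = 3, length = 120, seed = 1))
#' nrow(fam$truth$sites)  # 3 proteins x 2 anchors
#' @export
generateFamily <- function(spec) {
  stopifnot(inherits(spec, "FamilySpec"))
  set.seed(spec$seed)
  L <- spec$length; m <- nchar(spec$motif); k <- spec$anchorsPerProtein
  motifLetters <- strsplit(spec$motif, "", fixed = TRUE)[[1L]]
  rx <- spec$pattern

  # planted anchor starts: evenly spaced, clear of the termini by the
  # core radius plus the layout extent
  pre <- max(0L, -spec$layoutStartOffset)
  post <- max(0L, spec$layoutStartOffset + sum(spec$layout$length) - m)
  edge <- max(spec$coreRadius, pre, post) + 2L
  if (L - m - 2L * edge < 0L) stop("chain too short for anchor placement")
  starts <- if (k == 1L) as.integer(round((L - m) / 2))
    else as.integer(round(seq(edge, L - m - edge + 1L, length.out = k)))
  if (k > 1L && any(diff(starts) < m + 2L * spec$coreRadius))
    stop("chain too short to separate ", k,
         " anchors with non-overlapping cores")

  dist <- .anchorDistance(L, starts, m)
  prob <- .substProfile(spec, dist)
  planted <- rep(FALSE, L)
  for (s in starts) planted[s:(s + m - 1L)] <- TRUE
  prob[planted] <- 0                 # the motif itself is never mutated
  mutable <- !planted

  # core context is duplicated from the first anchor to all others,
  # emulating the domain duplication that makes multi-anchor families
  # (e.g. the two redox sites of disulfide isomerases) share homologous
  # motif surroundings; so all same-length windows are comparable
  coreOff <- (-spec$coreRadius):(m - 1L + spec$coreRadius)
  copyCores <- function(v) {
    if (k > 1L) for (s in starts[-1L]) v[s + coreOff] <- v[starts[1L] + coreOff]
    v
  }
  mapToSource <- function(p) {
    for (s in starts[-1L]) {
      o <- p - s
      if (o >= coreOff[1L] && o <= coreOff[length(coreOff)])
        return(starts[1L] + o)
    }
    p
  }

  ancestor <- sample(AA20, L, replace = TRUE)
  for (s in starts) ancestor[s:(s + m - 1L)] <- motifLetters
  ancestor <- .rejectSpurious(ancestor, rx, starts, m, mutable,
                              mapToSource = mapToSource,
                              normalize = copyCores)

  # secondary structure: planted layout around each anchor, coil elsewhere
  ssv <- rep("C", L)
  for (s in starts) {
    pos <- s + spec$layoutStartOffset
    for (e in seq_len(nrow(spec$layout))) {
      len <- spec$layout$length[e]
      span <- pos:(pos + len - 1L)
      span <- span[span >= 1L & span <= L]
      ssv[span] <- spec$layout$element[e]
      pos <- pos + len
    }
  }
  ssStr <- paste(ssv, collapse = "")
  noiseSd <- spec$coordNoise * .substProfile(spec, dist)
  noiseSd[planted] <- 0
  flankSd <- spec$coordNoise * spec$flankRate

  records <- vector("list", spec$nProteins)
  sites <- list()
  for (i in seq_len(spec$nProteins)) {
    letters1 <- ancestor
    hit <- stats::runif(L) < prob
    if (any(hit))
      letters1[hit] <- vapply(letters1[hit], function(a)
        sample(setdiff(AA20, a), 1L), character(1))
    # per-homolog terminal extensions (random coil) shift the anchors and
    # vary the chain length, as in real families
    pre <- if (spec$terminalVariation > 0L)
      sample.int(spec$terminalVariation + 1L, 1L) - 1L else 0L
    suf <- if (spec$terminalVariation > 0L)
      sample.int(spec$terminalVariation + 1L, 1L) - 1L else 0L
    full <- c(sample(AA20, pre, replace = TRUE), letters1,
              sample(AA20, suf, replace = TRUE))
    iStarts <- starts + pre
    # new spurious occurrences necessarily involve a substituted or
    # terminal (mutable) position, so rejection only touches those
    mutableFull <- c(rep(TRUE, pre), prob > 0, rep(TRUE, suf))
    full <- .rejectSpurious(full, rx, iStarts, m, mutableFull)
    ssFull <- c(rep("C", pre), ssv, rep("C", suf))
    sdFull <- c(rep(flankSd, pre), noiseSd, rep(flankSd, suf))
    Lf <- length(full)
    coords <- .idealCoords(paste(ssFull, collapse = "")) +
      matrix(stats::rnorm(3L * Lf, sd = rep(sdFull, 3L)), ncol = 3L)
    resno <- spec$numberingOffset + seq_len(Lf) - 1L
    id <- sprintf("SYN%02d", i)
    records[[i]] <- ProteinRecord(
      id = id, sequence = paste(full, collapse = ""),
      residueNumbers = resno, caCoords = coords,
      ss3 = paste(ssFull, collapse = ""),
      group = sprintf("grp%s", LETTERS[((i - 1L) %% spec$nGroups) + 1L]),
      source = "synthetic")
    sites[[i]] <- data.frame(
      protein_id = id, seq_start = iStarts, seq_end = iStarts + m - 1L,
      res_start = resno[iStarts], res_end = resno[iStarts + m - 1L],
      matched = spec$motif, stringsAsFactors = FALSE)
  }

  elems <- spec$layout$element[spec$layout$element %in% c("H", "E")]
  list(records = records,
       truth = list(sites = do.call(rbind, sites), pattern = rx,
                    motif = spec$motif,
                    anchorStarts = starts,
                    ancestor = paste(ancestor, collapse = ""),
                    ss = ssStr, topology = elems,
                    coreRadius = spec$coreRadius),
       spec = spec)
}

.aa123 <- function(a) bio3d::aa123(a)

# one C-alpha ATOM record per residue with a coordinate
.writePdbFile <- function(record, path) {
  lines <- character(0)
  serial <- 0L
  co <- caCoords(record)
  seqv <- strsplit(aaSequence(record), "", fixed = TRUE)[[1L]]
  for (i in seq_len(seqLength(record))) {
    if (anyNA(co[i, ])) next
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, .aa123(seqv[i]), residueNumbers(record)[i],
      co[i, 1L], co[i, 2L], co[i, 3L]))
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# DSSP-style output (header + fixed-column residue rows) readable by
# parseDssp; coil is written as the blank 8-state code
.writeDsspFile <- function(record, path) {
  ss3v <- strsplit(ss3(record), "", fixed = TRUE)[[1L]]
  ss8 <- ifelse(ss3v == "C", " ", ss3v)
  seqv <- strsplit(aaSequence(record), "", fixed = TRUE)[[1L]]
  rows <- sprintf("%5d%5d %1s %1s  %1s", seq_len(seqLength(record)),
                  residueNumbers(record), "A", seqv, ss8)
  writeLines(c(
    "==== Secondary Structure Definition, synthetic fixture ====",
    sprintf("%5d residues", seqLength(record)),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    rows), path)
  invisible(path)
}

#' Write a synthetic family to fixture files
#'
#' Emits, under \code{outDir}: one minimal PDB file per record (C-alpha
#' ATOM records only), one DSSP-style secondary-structure file per record,
#' a family FASTA, a two-column group map TSV and the ground truth as
#' JSON. \code{\link{parseStructure}} / \code{\link{parseDssp}} /
#' \code{\link{parseFasta}} read these files back exactly (coordinates to
#' PDB format precision).
#'
#' @param records list of \code{\linkS4class{ProteinRecord}}.
#' @param truth ground-truth list from \code{\link{generateFamily}}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
emitFixtureFiles <- function(records, truth, outDir) {
  records <- .asRecordList(records)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (r in records) {
    p <- file.path(outDir, paste0(recordId(r), ".pdb"))
    .writePdbFile(r, p); paths <- c(paths, p)
    if (!is.na(ss3(r))) {
      d <- file.path(outDir, paste0(recordId(r), ".dssp"))
      .writeDsspFile(r, d); paths <- c(paths, d)
    }
  }
  fa <- file.path(outDir, "family.fasta")
  writeFasta(records, fa); paths <- c(paths, fa)
  gm <- file.path(outDir, "groups.tsv")
  utils::write.table(
    data.frame(protein_id = vapply(records, recordId, character(1)),
               group = vapply(records, proteinGroup, character(1))),
    gm, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, gm)
  tj <- file.path(outDir, "truth.json")
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, tj)
  invisible(paths)
}
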