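#' Anchor motif patterns
#'
#' An anchor motif is a short, functionally critical pattern (e.g. the CXXC
#' redox site of disulfide isomerases, or the EEVD C-terminal tail of HSP70
#' chaperones) used as the fixed origin of all window expansions.
#' \code{motifPattern} builds a pattern object from a name and a regular
#' expression over amino-acid letters; \code{motifToRegex} converts the
#' common motif shorthand in which "X" means "any residue" (so "CXXC"
#' becomes \code{C..C}).
#'
#' @param name short motif label used in reports.
#' @param regex regular expression; must match only fixed-length strings.
#' @return A list with elements \code{name} and \code{regex}, class
#'   \code{MotifPattern}.
#' @examples
#' motifPattern("CXXC", motifToRegex("CXXC"))
#' @export
motifPattern <- function(name, regex) {
  ok <- tryCatch({
    suppressWarnings(grepl(regex, "ACDEFG", perl = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("invalid motif regular expression: ", regex)
  structure(list(name = name, regex = regex), class = "MotifPattern")
}

#' @param motif motif shorthand such as "CXXC" or "EEVD".
#' @rdname motifPattern
#' @export
motifToRegex <- function(motif) {
  gsub("X", ".", toupper(motif), fixed = TRUE)
}

.asPattern <- function(pattern) {
  if (inherits(pattern, "MotifPattern")) return(pattern)
  if (is.character(pattern) && length(pattern) == 1L) {
    if (grepl("^[A-WYZ]+$|X", pattern) && !grepl("[.\\[\\(\\{]", pattern))
      return(motifPattern(pattern, motifToRegex(pattern)))
    return(motifPattern(pattern, pattern))
  }
  stop("pattern must be a MotifPattern or a single character string")
}

#' Find anchor motif occurrences in a record
#'
#' Scans the sequence with the motif regular expression and returns every
#' occurrence in both coordinate spaces: 1-based sequence indices (closed
#' interval) and author (PDB) residue numbers. Reporting in author space is
#' essential for crystal structures with non-contiguous numbering; a naive
#' position-in-string report would misplace sites in chains that start
#' above residue 1.
#'
#' By default overlapping occurrences are all returned (via a lookahead
#' scan), so adjacent active sites of multi-domain proteins are not lost;
#' set \code{overlapping = FALSE} for the conventional left-to-right
#' non-overlapping scan.
#'
#' @param record a \code{\linkS4class{ProteinRecord}}.
#' @param pattern a \code{\link{motifPattern}} or a string (motif shorthand
#'   or plain regex).
#' @param overlapping return all overlapping occurrences (default TRUE).
#' @return data.frame with columns protein_id, seq_start, seq_end (1-based,
#'   closed), res_start, res_end (author numbers), matched.
#' @examples
#' r <- ProteinRecord("toy", "CCAACC")
#' findAnchors(r, "CXXC")                      # two overlapping sites
#' findAnchors(r, "CXXC", overlapping = FALSE) # one
#' @export
findAnchors <- function(record, pattern, overlapping = TRUE) {
  pattern <- .asPattern(pattern)
  seqs <- aaSequence(record)
  if (overlapping) {
    rx <- paste0("(?=(", pattern$regex, "))")
    m <- gregexpr(rx, seqs, perl = TRUE)[[1L]]
    if (m[1L] == -1L) starts <- integer(0)
    else {
      starts <- as.integer(m)
      lens <- attr(m, "capture.length")[, 1L]
    }
  } else {
    m <- gregexpr(pattern$regex, seqs, perl = TRUE)[[1L]]
    if (m[1L] == -1L) starts <- integer(0)
    else {
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
    }
  }
  if (length(starts) == 0L) {
    return(data.frame(protein_id = character(0), seq_start = integer(0),
                      seq_end = integer(0), res_start = integer(0),
                      res_end = integer(0), matched = character(0),
                      stringsAsFactors = FALSE))
  }
  ends <- starts + lens - 1L
  data.frame(
    protein_id = recordId(record),
    seq_start = starts, seq_end = ends,
    res_start = seqToAuthor(record, starts),
    res_end = seqToAuthor(record, ends),
    matched = substring(seqs, starts, ends),
    stringsAsFactors = FALSE)
}

#' @param records list of ProteinRecord or a ProteinFamily.
#' @rdname findAnchors
#' @export
findAnchorsAll <- function(records, pattern, overlapping = TRUE) {
  records <- .asRecordList(records)
  out <- lapply(records, findAnchors, pattern = pattern,
                overlapping = overlapping)
  do.call(rbind, out)
}

#' Build a padded expansion window around one anchor site
#'
#' Expands an anchor symmetrically by \code{radius} residues toward each
#' terminus. Positions beyond the chain are filled with the neutral padding
#' symbol "X" and flagged, so windows of the same radius are directly
#' comparable across proteins of different lengths. The window also carries
#' the per-position secondary structure ("x" at pads) and C-alpha
#' coordinates (NA rows at pads or missing atoms); \code{coordComplete} is
#' TRUE only when there is no padding and every position has a coordinate,
#' the eligibility condition for geometric (RMSD) comparisons.
#'
#' @param record source \code{\linkS4class{ProteinRecord}}.
#' @param site one row of \code{\link{findAnchors}} output (or a list with
#'   seq_start, seq_end, matched).
#' @param radius residues per side, >= 0.
#' @return An \code{\linkS4class{ExpansionWindow}}.
#' @export
expandWindow <- function(record, site, radius) {
  radius <- as.integer(radius)
  stopifnot(radius >= 0L)
  s <- as.integer(site$seq_start); e <- as.integer(site$seq_end)
  m <- e - s + 1L
  L <- seqLength(record)
  lo <- s - radius; hi <- e + radius
  idx <- lo:hi
  inside <- idx >= 1L & idx <= L
  letters1 <- rep(PAD, length(idx))
  letters1[inside] <- substring(aaSequence(record), idx[inside], idx[inside])
  sschar <- rep("x", length(idx))
  if (!is.na(ss3(record)))
    sschar[inside] <- substring(ss3(record), idx[inside], idx[inside])
  coords <- matrix(NA_real_, nrow = length(idx), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  coords[inside, ] <- caCoords(record)[idx[inside], , drop = FALSE]
  complete <- all(inside) && !anyNA(coords)
  new("ExpansionWindow",
      proteinId = recordId(record), group = proteinGroup(record),
      anchorSeqStart = s,
      anchorResStart = seqToAuthor(record, s),
      anchorResEnd = seqToAuthor(record, e),
      motif = paste(letters1[(radius + 1L):(radius + m)], collapse = ""),
      radius = radius,
      paddedSeq = paste(letters1, collapse = ""),
      padMask = !inside,
      ss = if (is.na(ss3(record))) NA_character_
           else paste(sschar, collapse = ""),
      coords = coords, coordComplete = complete)
}

#' Build length-grouped expansion sets for a family
#'
#' Detects anchors in every record and expands each by every radius in
#' \code{radii} (default: discrete increments of 10 residues per side up to
#' 200). The result is grouped by window length m + 2r, the unit on which
#' all three analysis layers operate. Ordering within a group is
#' deterministic: record order, then anchor position.
#'
#' @param records list of ProteinRecord or ProteinFamily.
#' @param pattern motif pattern (see \code{\link{findAnchors}}).
#' @param radii integer vector of per-side radii.
#' @param overlapping passed to \code{\link{findAnchors}}.
#' @return Named list: window length (as character) -> list of
#'   \code{\linkS4class{ExpansionWindow}}.
#' @export
buildExpansionSets <- function(records, pattern, radii = seq(10L, 200L, 10L),
                               overlapping = TRUE) {
  records <- .asRecordList(records)
  pattern <- .asPattern(pattern)
  anchors <- lapply(records, findAnchors, pattern = pattern,
                    overlapping = overlapping)
  if (sum(vapply(anchors, nrow, integer(1))) == 0L) {
    warning("no anchor sites found for motif '", pattern$name,
            "' in any record")
    return(list())
  }
  sets <- list()
  for (r in sort(unique(as.integer(radii)))) {
    wins <- list()
    for (i in seq_along(records)) {
      a <- anchors[[i]]
      if (nrow(a) == 0L) next
      for (j in seq_len(nrow(a)))
        wins[[length(wins) + 1L]] <- expandWindow(records[[i]], a[j, ], r)
    }
    if (length(wins))
      sets[[as.character(nchar(wins[[1L]]@paddedSeq))]] <- wins
  }
  sets
}

#' Filter length categories for phylogenetic representativeness
#'
#' For structural (coordinate-based) analyses a length category is retained
#' only if every taxonomic subgroup contributes at least one
#' coordinate-complete window; categories failing this are dropped. For
#' sequence-level analyses the padding scheme already guarantees that every
#' subgroup is represented at every length, so the sets are returned
#' unchanged.
#'
#' @param sets output of \code{\link{buildExpansionSets}}.
#' @param groupMap named character vector protein_id -> subgroup, or a
#'   two-column data.frame (protein_id, group).
#' @param structural apply the coordinate-completeness rule (default TRUE).
#' @return Filtered sets (same shape).
#' @export
filterRepresentative <- function(sets, groupMap, structural = TRUE) {
  if (is.data.frame(groupMap))
    groupMap <- stats::setNames(as.character(groupMap[[2L]]),
                                as.character(groupMap[[1L]]))
  if (!structural) return(sets)
  allGroups <- unique(unname(groupMap))
  keep <- vapply(sets, function(wins) {
    ids <- vapply(wins, function(w) w@proteinId, character(1))
    if (any(!ids %in% names(groupMap)))
      stop("protein id(s) missing from group map: ",
           paste(unique(ids[!ids %in% names(groupMap)]), collapse = ", "))
    comp <- vapply(wins, function(w) w@coordComplete, logical(1))
    covered <- unique(groupMap[ids[comp]])
    all(allGroups %in% covered)
  }, logical(1))
  sets[keep]
}

#' Tabulate expansion windows
#'
#' Flat data.frame view of one or more window groups, convenient for TSV
#' export.
#'
#' @param sets output of \code{\link{buildExpansionSets}}.
#' @return data.frame with one row per window.
#' @export
windowTable <- function(sets) {
  rows <- lapply(names(sets), function(len) {
    do.call(rbind, lapply(sets[[len]], function(w) {
      data.frame(window_length = as.integer(len), protein_id = w@proteinId,
                 group = w@group, anchor_seq_start = w@anchorSeqStart,
                 anchor_res_start = w@anchorResStart,
                 anchor_res_end = w@anchorResEnd, radius = w@radius,
                 padded_seq = w@paddedSeq, n_pad = sum(w@padMask),
                 coord_complete = w@coordComplete, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
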