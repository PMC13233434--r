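#' @import methods
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PAD <- "X"

#' ProteinRecord: one homolog of a family
#'
#' Normalized representation of a single protein chain: its one-letter amino
#' acid sequence, the author (PDB) residue numbers deposited with the
#' structure, optional C-alpha coordinates and an optional 3-state secondary
#' structure string. All per-residue slots are index-aligned: position
#' \code{i} of the sequence corresponds to \code{residueNumbers(x)[i]},
#' row \code{i} of \code{caCoords(x)} and character \code{i} of
#' \code{ss3(x)}.
#'
#' Author numbering need not start at 1 and may contain gaps (crystal
#' structures frequently start above 1, e.g. at residue 22 after an excluded
#' hetero-group); the bidirectional sequence-index / author-number map is
#' exposed through \code{\link{seqToAuthor}} and \code{\link{authorToSeq}}.
#'
#' @slot id character(1), UniProt or PDB identifier.
#' @slot group character(1), taxonomic subgroup label (default "all").
#' @slot sequence character(1) over the 20-letter amino-acid alphabet; never
#'   contains the padding symbol "X" (padding exists only inside expansion
#'   windows).
#' @slot residueNumbers integer vector of author residue numbers, strictly
#'   increasing, same length as the sequence.
#' @slot caCoords numeric matrix (L x 3) of C-alpha coordinates in Angstrom;
#'   rows of NA mark residues without a C-alpha (or entirely sequence-only
#'   records).
#' @slot ss3 character(1) over {H,E,C} of length L, or NA when no secondary
#'   structure has been assigned.
#' @slot source character(1), one of "pdb", "mmcif", "fasta_only",
#'   "synthetic".
#'
#' @seealso \code{\link{parseStructure}}, \code{\link{parseFasta}},
#'   \code{\link{parseDssp}}
#' @export
setClass("ProteinRecord",
  representation(
    id = "character",
    group = "character",
    sequence = "character",
    residueNumbers = "integer",
    caCoords = "matrix",
    ss3 = "character",
    source = "character"
  ),
  prototype(group = "all", ss3 = NA_character_, source = "fasta_only")
)

setValidity("ProteinRecord", function(object) {
  msg <- character(0)
  L <- nchar(object@sequence)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a non-empty character(1)")
  if (L == 0L)
    msg <- c(msg, "sequence must be non-empty")
  if (length(object@residueNumbers) != L)
    msg <- c(msg, "residueNumbers length must equal sequence length")
  if (anyNA(object@residueNumbers) ||
      any(diff(object@residueNumbers) <= 0L))
    msg <- c(msg, "residueNumbers must be strictly increasing with no NA")
  if (!is.numeric(object@caCoords) || ncol(object@caCoords) != 3L ||
      nrow(object@caCoords) != L)
    msg <- c(msg, "caCoords must be a numeric L x 3 matrix")
  letters1 <- strsplit(object@sequence, "", fixed = TRUE)[[1L]]
  if (any(!letters1 %in% AA20))
    msg <- c(msg, sprintf("sequence contains non-standard letters: %s",
                          paste(unique(setdiff(letters1, AA20)), collapse = "")))
  if (!is.na(object@ss3)) {
    if (nchar(object@ss3) != L)
      msg <- c(msg, "ss3 length must equal sequence length")
    ssl <- strsplit(object@ss3, "", fixed = TRUE)[[1L]]
    if (any(!ssl %in% c("H", "E", "C")))
      msg <- c(msg, "ss3 must use only H, E, C")
  }
  if (!object@source %in% c("pdb", "mmcif", "fasta_only", "synthetic"))
    msg <- c(msg, "source must be pdb, mmcif, fasta_only or synthetic")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinRecord
#'
#' @param id identifier (UniProt/PDB code).
#' @param sequence one-letter amino-acid string.
#' @param residueNumbers author residue numbers; defaults to contiguous
#'   numbering from 1.
#' @param caCoords L x 3 coordinate matrix or NULL (all-NA).
#' @param ss3 3-state secondary structure string or NA.
#' @param group taxonomic subgroup label.
#' @param source provenance tag.
#' @return A \code{\linkS4class{ProteinRecord}}.
#' @examples
#' r <- ProteinRecord("P11142", "MSKGPAVGIDLGTTYS")
#' seqLength(r)
#' @export
ProteinRecord <- function(id, sequence,
                          residueNumbers = seq_len(nchar(sequence)),
                          caCoords = NULL, ss3 = NA_character_,
                          group = "all", source = "fasta_only") {
  L <- nchar(sequence)
  if (is.null(caCoords))
    caCoords <- matrix(NA_real_, nrow = L, ncol = 3L,
                       dimnames = list(NULL, c("x", "y", "z")))
  new("ProteinRecord", id = as.character(id), group = as.character(group),
      sequence = toupper(sequence),
      residueNumbers = as.integer(residueNumbers),
      caCoords = caCoords, ss3 = ss3, source = source)
}

#' ProteinFamily: an ordered collection of ProteinRecord objects
#'
#' Thin list container with identity checking; most pipeline entry points
#' accept either a ProteinFamily or a plain list of records.
#'
#' @slot records list of \code{\linkS4class{ProteinRecord}}.
#' @export
setClass("ProteinFamily", representation(records = "list"))

setValidity("ProteinFamily", function(object) {
  ok <- vapply(object@records, is, logical(1), class2 = "ProteinRecord")
  if (!all(ok)) return("all elements must be ProteinRecord objects")
  ids <- vapply(object@records, function(r) r@id, character(1))
  if (anyDuplicated(ids)) return("record ids must be unique")
  TRUE
})

#' @param records list of ProteinRecord objects.
#' @rdname ProteinFamily-class
#' @export
ProteinFamily <- function(records) {
  if (is(records, "ProteinFamily")) return(records)
  new("ProteinFamily", records = unname(records))
}

#' ExpansionWindow: a padded, anchor-centred subsequence
#'
#' A symmetric window of \code{radius} residues on each side of an anchor
#' motif occurrence. Positions falling outside the chain are filled with the
#' neutral padding symbol "X" and flagged in \code{padMask}; this keeps all
#' windows of a given radius dimensionally homogeneous across proteins of
#' differing lengths. Per-position secondary structure (padded with "x") and
#' C-alpha coordinates (padded with NA) travel with the window so the three
#' analysis layers can operate on windows alone.
#'
#' @slot proteinId id of the source record.
#' @slot group subgroup label of the source record.
#' @slot anchorSeqStart 1-based sequence index of the motif start.
#' @slot anchorResStart,anchorResEnd author residue numbers of the motif.
#' @slot motif matched motif string (length m).
#' @slot radius residues per side.
#' @slot paddedSeq string of length m + 2*radius over amino acids + "X".
#' @slot padMask logical, TRUE exactly where the window exceeds the chain.
#' @slot ss string over {H,E,C,x} aligned to the window, "x" at pads and
#'   where no assignment exists; NA when the record had no ss3.
#' @slot coords (m+2r) x 3 C-alpha matrix, NA rows at pads/absent atoms.
#' @slot coordComplete TRUE iff there is no padding and every position has
#'   a C-alpha coordinate.
#' @export
setClass("ExpansionWindow",
  representation(
    proteinId = "character",
    group = "character",
    anchorSeqStart = "integer",
    anchorResStart = "integer",
    anchorResEnd = "integer",
    motif = "character",
    radius = "integer",
    paddedSeq = "character",
    padMask = "logical",
    ss = "character",
    coords = "matrix",
    coordComplete = "logical"
  )
)

setValidity("ExpansionWindow", function(object) {
  m <- nchar(object@motif)
  W <- m + 2L * object@radius
  msg <- character(0)
  if (nchar(object@paddedSeq) != W)
    msg <- c(msg, "paddedSeq length must be motif length + 2*radius")
  if (length(object@padMask) != W)
    msg <- c(msg, "padMask length mismatch")
  if (substr(object@paddedSeq, object@radius + 1L, object@radius + m) !=
      object@motif)
    msg <- c(msg, "central positions of paddedSeq must equal the motif")
  if (nrow(object@coords) != W)
    msg <- c(msg, "coords must have one row per window position")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinRecord", function(object) {
  L <- nchar(object@sequence)
  nca <- sum(stats::complete.cases(object@caCoords))
  cat(sprintf(
    "ProteinRecord '%s' (%s, group '%s')\n  %d residues, author numbering %d..%d\n  C-alpha: %d/%d, ss3: %s\n",
    object@id, object@source, object@group, L,
    object@residueNumbers[1L], object@residueNumbers[L],
    nca, L, if (is.na(object@ss3)) "absent" else "assigned"))
  invisible(object)
})

setMethod("show", "ProteinFamily", function(object) {
  cat(sprintf("ProteinFamily of %d records: %s\n", length(object@records),
              paste(vapply(object@records, function(r) r@id, character(1)),
                    collapse = ", ")))
  invisible(object)
})

setMethod("show", "ExpansionWindow", function(object) {
  cat(sprintf(
    "ExpansionWindow %s@%d (author %d-%d), radius %d, length %d%s\n  %s\n",
    object@proteinId, object@anchorSeqStart, object@anchorResStart,
    object@anchorResEnd, object@radius, nchar(object@paddedSeq),
    if (object@coordComplete) ", coord-complete" else "",
    object@paddedSeq))
  invisible(object)
})

setMethod("length", "ProteinFamily", function(x) length(x@records))

setMethod("[[", "ProteinFamily", function(x, i) {
  if (is.character(i)) {
    ids <- vapply(x@records, function(r) r@id, character(1))
    i <- match(i, ids)
  }
  x@records[[i]]
})

# normalize ProteinFamily | list -> plain list of records
.asRecordList <- function(records) {
  if (is(records, "ProteinFamily")) records@records else records
}
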