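#' Accessors for ProteinRecord and ExpansionWindow objects
#'
#' Slot access for the package's S4 containers. \code{aaSequence} returns
#' the one-letter sequence string, \code{residueNumbers} the author (PDB)
#' numbering, \code{caCoords} the L x 3 C-alpha matrix, \code{ss3} the
#' 3-state secondary-structure string (NA if unassigned) and
#' \code{proteinGroup} the taxonomic subgroup label.
#'
#' @param x a \code{\linkS4class{ProteinRecord}} (or, where documented, an
#'   \code{\linkS4class{ExpansionWindow}}).
#' @param value replacement value.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))
#' @rdname accessors
#' @export
setGeneric("aaSequence", function(x) standardGeneric("aaSequence"))
#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))
#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setGeneric("ss3", function(x) standardGeneric("ss3"))
#' @rdname accessors
#' @export
setGeneric("ss3<-", function(x, value) standardGeneric("ss3<-"))
#' @rdname accessors
#' @export
setGeneric("proteinGroup", function(x) standardGeneric("proteinGroup"))
#' @rdname accessors
#' @export
setGeneric("proteinGroup<-", function(x, value) standardGeneric("proteinGroup<-"))
#' @rdname accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @rdname accessors
#' @export
setGeneric("coordComplete", function(x) standardGeneric("coordComplete"))
#' @rdname accessors
#' @export
setGeneric("paddedSeq", function(x) standardGeneric("paddedSeq"))

#' @rdname accessors
setMethod("recordId", "ProteinRecord", function(x) x@id)
#' @rdname accessors
setMethod("aaSequence", "ProteinRecord", function(x) x@sequence)
#' @rdname accessors
setMethod("residueNumbers", "ProteinRecord", function(x) x@residueNumbers)
#' @rdname accessors
setMethod("caCoords", "ProteinRecord", function(x) x@caCoords)
#' @rdname accessors
setMethod("ss3", "ProteinRecord", function(x) x@ss3)
#' @rdname accessors
setMethod("ss3<-", "ProteinRecord", function(x, value) {
  x@ss3 <- value
  validObject(x)
  x
})
#' @rdname accessors
setMethod("proteinGroup", "ProteinRecord", function(x) x@group)
#' @rdname accessors
setMethod("proteinGroup<-", "ProteinRecord", function(x, value) {
  x@group <- as.character(value)
  x
})
#' @rdname accessors
setMethod("seqLength", "ProteinRecord", function(x) nchar(x@sequence))

#' @rdname accessors
setMethod("recordId", "ExpansionWindow", function(x) x@proteinId)
#' @rdname accessors
setMethod("coordComplete", "ExpansionWindow", function(x) x@coordComplete)
#' @rdname accessors
setMethod("paddedSeq", "ExpansionWindow", function(x) x@paddedSeq)
#' @rdname accessors
setMethod("caCoords", "ExpansionWindow", function(x) x@coords)

#' Sequence-index / author-residue-number mapping
#'
#' Structures deposited in the PDB carry "author" residue numbers that may
#' start above 1 or contain gaps, while all internal window arithmetic uses
#' 1-based sequence indices. \code{seqToAuthor} maps a 1-based sequence
#' index to the author number; \code{authorToSeq} is its inverse. The two
#' satisfy \code{authorToSeq(r, seqToAuthor(r, i)) == i} for every position.
#'
#' @param record a \code{\linkS4class{ProteinRecord}}.
#' @param index 1-based sequence index (vectorized).
#' @param author author residue number (vectorized).
#' @return Integer vector; \code{authorToSeq} returns NA for author numbers
#'   absent from the record.
#' @examples
#' r <- ProteinRecord("x", "ACDEF", residueNumbers = 22:26)
#' seqToAuthor(r, 1)   # 22
#' authorToSeq(r, 26)  # 5
#' @export
seqToAuthor <- function(record, index) {
  stopifnot(all(index >= 1L), all(index <= seqLength(record)))
  record@residueNumbers[index]
}

#' @rdname seqToAuthor
#' @export
authorToSeq <- function(record, author) {
  match(as.integer(author), record@residueNumbers)
}
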