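# Canonical Chou-Fasman conformational propensities (P_alpha, P_beta,
# P_turn, x100). Each residue's structural equivalence class is the argmax;
# ties are broken by the fixed priority H > E > T (relevant only for Cys,
# whose sheet and turn propensities are equal, making it a sheet-former).
.CF_TABLE <- data.frame(
  residue = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  p_helix = c(142, 98, 67, 101, 70, 111, 151, 57, 100, 108,
              121, 114, 145, 113, 57, 77, 83, 108, 69, 106),
  p_sheet = c(83, 93, 89, 54, 119, 110, 37, 75, 87, 160,
              130, 74, 105, 138, 55, 75, 119, 137, 147, 170),
  p_turn = c(66, 95, 156, 146, 119, 98, 74, 156, 95, 47,
             59, 101, 60, 60, 152, 143, 96, 96, 114, 50),
  stringsAsFactors = FALSE)

.cfClass <- local({
  p <- as.matrix(.CF_TABLE[, c("p_helix", "p_sheet", "p_turn")])
  cls <- c("H", "E", "T")[apply(p, 1L, which.max)]  # which.max: first of ties
  stats::setNames(cls, .CF_TABLE$residue)
})

#' Chou-Fasman propensities and structural equivalence classes
#'
#' Returns the canonical Chou-Fasman conformational propensity table
#' together with the derived per-residue class: helix-former (H),
#' sheet-former (E) or turn-former (T), i.e. the argmax over the three
#' propensities with ties broken by the priority H > E > T. The table is
#' exported verbatim so the mapping used throughout the package can be
#' audited.
#'
#' @return data.frame with columns residue, p_helix, p_sheet, p_turn, class.
#' @examples
#' chouFasmanTable()
#' @export
chouFasmanTable <- function() {
  out <- .CF_TABLE
  out$class <- unname(.cfClass[out$residue])
  out
}

#' Translate a sequence into Chou-Fasman structural equivalence classes
#'
#' Maps each residue to its dominant secondary-structure propensity class:
#' H (helix-former), E (sheet-former) or T (turn-former); the padding
#' symbol "X" maps to lowercase "x". Grouping residues this way exposes
#' structural conservation hidden behind sequence divergence: positions
#' occupied by different residues of the same folding tendency translate
#' to the same class letter.
#'
#' @param seq amino-acid string, possibly containing the padding symbol "X".
#' @return String of equal length over \{H, E, T, x\}.
#' @examples
#' chouFasmanClasses("EVGX")  # "HETx"
#' @export
chouFasmanClasses <- function(seq) {
  letters1 <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  out <- character(length(letters1))
  isPad <- letters1 == PAD
  out[isPad] <- "x"
  cls <- .cfClass[letters1[!isPad]]
  if (anyNA(cls))
    stop("unknown residue letter(s): ",
         paste(unique(letters1[!isPad][is.na(cls)]), collapse = ""))
  out[!isPad] <- cls
  paste(out, collapse = "")
}
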