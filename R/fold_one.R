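# Fold One: primary-structure layer. Positional frequency matrices over the
# 21-symbol alphabet (20 residues + padding X), threshold consensus strings,
# and the sequence-identity conservation curve
#   SI = 100 * (1 - D/L),  D = Hamming distance, L = window length.

.ALPHABET21 <- c(AA20, PAD)

.windowCharMatrix <- function(windows) {
  seqs <- vapply(windows, function(w) w@paddedSeq, character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("windows must all have the same length; got lengths ",
         paste(unique(lens), collapse = ", "))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

#' Positional frequency matrix of an expansion set
#'
#' Tallies, for each window position relative to the anchor, how often each
#' of the 21 symbols (20 amino acids plus the padding symbol "X") occurs
#' across all same-length windows. Every position column sums to the number
#' of windows.
#'
#' @param windows list of equal-length \code{\linkS4class{ExpansionWindow}}.
#' @return List of class \code{FrequencyMatrix} with elements \code{counts}
#'   (21 x window_length integer matrix, rows named by symbol),
#'   \code{n_windows} and \code{window_length}.
#' @export
frequencyMatrix <- function(windows) {
  if (length(windows) < 1L) stop("need at least one window")
  chars <- .windowCharMatrix(windows)
  W <- ncol(chars)
  counts <- vapply(seq_len(W), function(j)
    table(factor(chars[, j], levels = .ALPHABET21)),
    integer(length(.ALPHABET21)))
  dimnames(counts) <- list(.ALPHABET21, NULL)
  structure(list(counts = counts, n_windows = nrow(chars),
                 window_length = W),
            class = "FrequencyMatrix")
}

#' Threshold consensus of a frequency matrix
#'
#' A position receives a residue letter when that residue's relative
#' frequency (padding excluded as a candidate) reaches the threshold;
#' otherwise it is labelled "X", marking a variable or functionally
#' tolerant position. With the default threshold of 1 the consensus keeps
#' only residues conserved in every window. At thresholds below 1 a tie at
#' threshold is broken alphabetically (with a message).
#'
#' @param fm a \code{\link{frequencyMatrix}} result.
#' @param threshold fraction in (0, 1]; default 1.
#' @return Consensus string (character(1)) with attribute "threshold".
#' @examples
#' fam <- generateFamily(familySpec(nProteins = 4, length = 80, seed = 7))
#' sets <- buildExpansionSets(fam$records, fam$truth$pattern, radii = 10)
#' consensusSequence(frequencyMatrix(sets[[1]]))
#' @export
consensusSequence <- function(fm, threshold = 1) {
  stopifnot(inherits(fm, "FrequencyMatrix"),
            threshold > 0, threshold <= 1)
  counts <- fm$counts[AA20, , drop = FALSE]     # padding never wins a slot
  out <- vapply(seq_len(fm$window_length), function(j) {
    freq <- counts[, j] / fm$n_windows
    top <- max(freq)
    if (top < threshold) return(PAD)
    winners <- rownames(counts)[freq == top]
    if (length(winners) > 1L)
      message("consensus tie at position ", j, " among ",
              paste(winners, collapse = ","), "; choosing ",
              sort(winners)[1L], " (alphabetical)")
    sort(winners)[1L]
  }, character(1))
  structure(paste(out, collapse = ""), threshold = threshold)
}

#' Sequence identity between two equal-length windows
#'
#' SI = 100 x (1 - D/L), where D is the Hamming distance (count of
#' non-identical symbols) and L the segment length. The padding symbol "X"
#' participates as an ordinary 21st symbol, so two padded positions count
#' as identical; set \code{excludePad = TRUE} to drop positions padded in
#' either string from both D and L instead.
#'
#' @param a,b equal-length strings over amino acids + "X".
#' @param excludePad exclude pad positions from the comparison.
#' @return List with elements \code{si} (0-100), \code{hamming} and
#'   \code{length}.
#' @examples
#' sequenceIdentity("AAAA", "AAAT")$si  # 75
#' @export
sequenceIdentity <- function(a, b, excludePad = FALSE) {
  if (nchar(a) != nchar(b) || nchar(a) == 0L)
    stop("sequences must be non-empty and of equal length")
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (excludePad) {
    keep <- av != PAD & bv != PAD
    if (!any(keep)) stop("no unpadded positions to compare")
    av <- av[keep]; bv <- bv[keep]
  }
  D <- sum(av != bv)
  L <- length(av)
  list(si = 100 * (1 - D / L), hamming = D, length = L)
}

# mean SI over all unordered pairs of rows of a character matrix
.meanPairwiseSI <- function(chars) {
  n <- nrow(chars); L <- ncol(chars)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + (1 - sum(chars[i, ] != chars[j, ]) / L)
    }
  }
  100 * tot / (n * (n - 1L) / 2L)
}

#' Sequence-identity conservation curve across window lengths
#'
#' For each window length, the mean SI over all unordered pairs of
#' same-length windows (no self-pairs). The decay of this curve with
#' window length quantifies how conservation concentrates around the
#' anchor: high plateaus indicate that flanking context is still
#' family-invariant, while a drop marks entry into variable regions.
#'
#' @param sets output of \code{\link{buildExpansionSets}}.
#' @return data.frame with columns window_length, n_windows, n_pairs,
#'   mean_si, ordered by ascending length. Lengths with fewer than two
#'   windows are omitted with a warning.
#' @export
conservationCurve <- function(sets) {
  lens <- sort(as.integer(names(sets)))
  rows <- lapply(lens, function(len) {
    wins <- sets[[as.character(len)]]
    if (length(wins) < 2L) {
      warning("window length ", len, " has fewer than 2 windows; omitted")
      return(NULL)
    }
    chars <- .windowCharMatrix(wins)
    data.frame(window_length = len, n_windows = length(wins),
               n_pairs = choose(length(wins), 2L),
               mean_si = .meanPairwiseSI(chars))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(window_length = integer(0), n_windows = integer(0),
                      n_pairs = integer(0), mean_si = numeric(0))
  out
}
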