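# Fold Two: secondary-structure layer. Windows are aligned on the anchor,
# per-column modal 3-state labels form a consensus at a recurrence
# threshold (>= 50% partial, 100% complete), and the consensus is searched
# for element-level topology patterns such as the beta-alpha-beta-alpha-beta
# arrangement of thioredoxin-like domains.

#' Anchor-aligned secondary-structure alignment
#'
#' Stacks the 3-state secondary structure of same-length windows into an
#' n_windows x window_length character matrix over \{H, E, C, x\}; "x"
#' marks padded positions. Column k corresponds to anchor-relative offset
#' k - radius - 1 (offset 0 = first motif residue).
#'
#' @param windows list of equal-length \code{\linkS4class{ExpansionWindow}}
#'   whose source records had secondary structure assigned.
#' @return Character matrix with rownames "<protein>@<anchor_seq_start>"
#'   and attribute "radius".
#' @export
alignSecondary <- function(windows) {
  if (length(windows) == 0L) stop("empty window list")
  noss <- vapply(windows, function(w) is.na(w@ss), logical(1))
  if (any(noss))
    stop("window(s) without secondary structure: ",
         paste(unique(vapply(windows[noss], function(w) w@proteinId,
                             character(1))), collapse = ", "))
  seqs <- vapply(windows, function(w) w@ss, character(1))
  if (length(unique(nchar(seqs))) != 1L)
    stop("windows must all have the same length")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- vapply(windows, function(w)
    paste0(w@proteinId, "@", w@anchorSeqStart), character(1))
  attr(m, "radius") <- windows[[1L]]@radius
  m
}

#' Secondary-structure consensus at a recurrence threshold
#'
#' Per column, among rows with a real assignment (non-"x"), the modal label
#' is emitted when its fraction reaches the threshold; otherwise the column
#' is "x". Exact ties at threshold 0.5 yield "x" (a strict majority is
#' required for a label), and columns covered by fewer than
#' \code{minCoverage} assigned rows are "x" regardless. Padded rows are
#' excluded from the denominator, so terminal columns are judged only on
#' the proteins long enough to reach them.
#'
#' @param alignment output of \code{\link{alignSecondary}}.
#' @param threshold recurrence fraction; 0.5 (partial) and 1 (complete) are
#'   the standard choices, other values are accepted with a warning.
#' @param minCoverage minimum assigned rows per column (default 2).
#' @return List of class \code{SSConsensus}: \code{labels} (string over
#'   H,E,C,x), \code{support} (modal fraction per column, NA where
#'   uncovered), \code{threshold}.
#' @export
ssConsensus <- function(alignment, threshold = 0.5, minCoverage = 2L) {
  if (!is.matrix(alignment) || nrow(alignment) == 0L)
    stop("empty alignment")
  if (!threshold %in% c(0.5, 1))
    warning("non-standard consensus threshold ", threshold)
  labs <- character(ncol(alignment))
  supp <- rep(NA_real_, ncol(alignment))
  for (j in seq_len(ncol(alignment))) {
    col <- alignment[, j]
    col <- col[col != "x"]
    if (length(col) < minCoverage) { labs[j] <- "x"; next }
    tab <- table(col)
    frac <- max(tab) / length(col)
    supp[j] <- frac
    modal <- names(tab)[tab == max(tab)]
    # a label needs a unique mode (ties such as exact 50/50 yield "x") at
    # or above the recurrence threshold
    labs[j] <- if (length(modal) == 1L && frac >= threshold) modal else "x"
  }
  structure(list(labels = paste(labs, collapse = ""), support = supp,
                 threshold = threshold), class = "SSConsensus")
}

# run-length encode a consensus label string
.ssRuns <- function(labels) {
  v <- strsplit(labels, "", fixed = TRUE)[[1L]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values, start = ends - r$lengths + 1L, end = ends,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Search a consensus for an element-level topology pattern
#'
#' Run-length encodes the consensus, discards coil and unassigned runs as
#' well as H/E runs shorter than \code{minRun} (single-residue calls are
#' treated as noise), and reports every contiguous subsequence of the
#' remaining element runs whose labels equal \code{elementPattern}. Coil
#' stretches may separate matched elements; only the order of H/E elements
#' matters, which is what makes the search a topology comparison.
#'
#' @param consensus an \code{\link{ssConsensus}} result or a plain label
#'   string.
#' @param elementPattern character vector over \{"H","E"\}, e.g.
#'   \code{c("E","H","E","H","E")} for a thioredoxin-like core.
#' @param minRun minimum element run length (default 2).
#' @return List of matches; each match is a data.frame of the matched runs
#'   (label, start, end in 1-based window columns). Empty list if no match.
#' @examples
#' findTopologyPattern("EEECHHHHCEEECHHHHCEEE", c("E","H","E","H","E"))
#' @export
findTopologyPattern <- function(consensus, elementPattern, minRun = 2L) {
  labels <- if (inherits(consensus, "SSConsensus")) consensus$labels
            else as.character(consensus)
  stopifnot(all(elementPattern %in% c("H", "E")))
  runs <- .ssRuns(labels)
  runs <- runs[runs$label %in% c("H", "E") & runs$length >= minRun, ,
               drop = FALSE]
  k <- length(elementPattern)
  out <- list()
  if (nrow(runs) >= k) {
    for (i in seq_len(nrow(runs) - k + 1L)) {
      sel <- runs[i:(i + k - 1L), , drop = FALSE]
      if (all(sel$label == elementPattern))
        out[[length(out) + 1L]] <- sel[, c("label", "start", "end")]
    }
  }
  out
}
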