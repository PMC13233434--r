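# Fold Three: geometric layer. Optimal rigid-body superposition (Kabsch,
# SVD with reflection guard) of C-alpha traces of same-length windows,
# pairwise RMSD summaries per window length, and the conservation radius:
# the largest expansion length whose mean RMSD stays below the cutoff
# (default 15 Angstrom), separating the rigid scaffold from flexible flanks.

#' Optimal-superposition RMSD of two C-alpha traces
#'
#' Least-squares rigid-body superposition (rotation + translation, proper
#' rotations only: a reflection is corrected via the determinant sign of
#' the SVD cross-covariance) followed by the root-mean-square deviation
#' over paired atoms. Invariant under any rigid motion of either input.
#'
#' @param coordsA,coordsB numeric n x 3 matrices, n >= 3, no missing
#'   values, rows paired by index.
#' @return RMSD in Angstrom.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' superimposeRMSD(a, a + 5)  # ~0: translation removed
#' @export
superimposeRMSD <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L)
    stop("coordinate sets must be equal-size n x 3 matrices")
  if (nrow(A) < 3L) stop("need at least 3 atoms for superposition")
  if (anyNA(A) || anyNA(B)) stop("missing coordinates not allowed")
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  H <- crossprod(Bc, Ac)            # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Brot <- Bc %*% t(R)
  sqrt(sum((Ac - Brot)^2) / nrow(A))
}

#' Pairwise RMSD records and per-length summary
#'
#' Scores every unordered pair of coordinate-complete windows within each
#' window length (pairs are formed across proteins and across multiple
#' anchors of the same protein), then summarizes per length (pair count,
#' mean RMSD, fraction of pairs below the cutoff) and globally (median,
#' standard deviation, integer-binned histogram).
#'
#' @param sets output of \code{\link{buildExpansionSets}} (typically after
#'   \code{\link{filterRepresentative}}).
#' @param cutoff conserved/flexible boundary in Angstrom (default 15).
#' @param binWidth histogram bin width in Angstrom (default 1).
#' @return List with \code{records} (data.frame window_length, id_a, id_b,
#'   rmsd), \code{summary} (data.frame window_length, n_pairs, mean_rmsd,
#'   fraction_below), and \code{global} (median, sd, histogram counts).
#' @export
pairwiseRMSD <- function(sets, cutoff = 15, binWidth = 1) {
  lens <- sort(as.integer(names(sets)))
  recs <- list(); summ <- list()
  for (len in lens) {
    wins <- sets[[as.character(len)]]
    wins <- wins[vapply(wins, function(w) w@coordComplete, logical(1))]
    k <- length(wins)
    if (k < 2L) {
      warning("window length ", len,
              " has fewer than 2 coordinate-complete windows; omitted")
      next
    }
    ids <- vapply(wins, function(w)
      paste0(w@proteinId, "@", w@anchorSeqStart), character(1))
    pr <- utils::combn(k, 2L)
    rmsds <- vapply(seq_len(ncol(pr)), function(p)
      superimposeRMSD(wins[[pr[1L, p]]]@coords, wins[[pr[2L, p]]]@coords),
      numeric(1))
    recs[[length(recs) + 1L]] <- data.frame(
      window_length = len, id_a = ids[pr[1L, ]], id_b = ids[pr[2L, ]],
      rmsd = rmsds, stringsAsFactors = FALSE)
    summ[[length(summ) + 1L]] <- data.frame(
      window_length = len, n_pairs = ncol(pr), mean_rmsd = mean(rmsds),
      fraction_below = mean(rmsds < cutoff))
  }
  records <- do.call(rbind, recs)
  summary <- do.call(rbind, summ)
  global <- if (is.null(records)) NULL else {
    breaks <- seq(0, binWidth * ceiling(max(records$rmsd) / binWidth + 1),
                  by = binWidth)
    h <- graphics::hist(records$rmsd, breaks = breaks, plot = FALSE)
    list(median = stats::median(records$rmsd), sd = stats::sd(records$rmsd),
         histogram = data.frame(bin_lo = utils::head(h$breaks, -1L),
                                bin_hi = h$breaks[-1L], count = h$counts))
  }
  list(records = records, summary = summary, global = global,
       cutoff = cutoff)
}

#' Conservation radius from an RMSD summary
#'
#' Scans window lengths in ascending order and returns the largest length
#' whose mean pairwise RMSD is below the cutoff, stopping at the first
#' length that crosses it. Inside this radius structures superpose within
#' the cutoff and are classified as the conserved scaffold; beyond it lie
#' the flexible, adaptive flanks.
#'
#' @param summary the \code{summary} element of \code{\link{pairwiseRMSD}}
#'   (or the whole result list).
#' @param cutoff Angstrom threshold (default 15).
#' @return List with \code{cutoff} and \code{radius_window_length} (NA, with
#'   a message, when even the shortest analysed length exceeds the cutoff).
#' @export
conservationRadius <- function(summary, cutoff = 15) {
  if (is.list(summary) && !is.data.frame(summary)) summary <- summary$summary
  if (is.null(summary) || nrow(summary) == 0L)
    stop("empty RMSD summary")
  s <- summary[order(summary$window_length), ]
  radius <- NA_integer_
  for (i in seq_len(nrow(s))) {
    if (s$mean_rmsd[i] < cutoff) radius <- s$window_length[i] else break
  }
  if (is.na(radius))
    message("no analysed window length has mean RMSD below ", cutoff,
            " Angstrom; conservation radius undefined")
  list(cutoff = cutoff, radius_window_length = radius)
}

#' Mean-RMSD matrix between proteins at one window length
#'
#' Convenience view for heatmap-style reports: average RMSD of all window
#' pairs between each pair of proteins at the given length.
#'
#' @param rmsdRecords the \code{records} element of
#'   \code{\link{pairwiseRMSD}}.
#' @param windowLength length to extract.
#' @return Symmetric numeric matrix (protein x protein), NA where no pair
#'   exists.
#' @export
rmsdMatrix <- function(rmsdRecords, windowLength) {
  r <- rmsdRecords[rmsdRecords$window_length == windowLength, , drop = FALSE]
  pa <- sub("@.*", "", r$id_a); pb <- sub("@.*", "", r$id_b)
  prot <- sort(unique(c(pa, pb)))
  m <- matrix(NA_real_, length(prot), length(prot),
              dimnames = list(prot, prot))
  agg <- stats::aggregate(r$rmsd, list(a = pa, b = pb), mean)
  for (i in seq_len(nrow(agg))) {
    m[agg$a[i], agg$b[i]] <- agg$x[i]
    m[agg$b[i], agg$a[i]] <- agg$x[i]
  }
  m
}
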