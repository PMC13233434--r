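# shared fixtures and independent oracles

# fixed-column PDB ATOM/HETATM line (only the fields the parser consumes)
pdbLine <- function(type, serial, elety, res3, resno, x, y, z,
                    chain = "A") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          type, serial, paste0(" ", elety), res3, chain, resno, x, y, z)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent superposition oracle: Horn's closed-form quaternion method
# (eigen-decomposition of the 4x4 key matrix), a different algorithm from
# the package's SVD-based Kabsch implementation
quaternionRmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  M <- crossprod(Bc, Ac)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lambda) / nrow(A)
  sqrt(max(msd, 0))
}

# small deterministic synthetic family shared across files
smallFamily <- function(seed = 101, n = 5, len = 200, anchors = 2) {
  generateFamily(familySpec(nProteins = n, length = len, motif = "CGHC",
                            pattern = "C..C",
                            anchorsPerProtein = anchors, seed = seed))
}

cxxc <- function() motifPattern("CXXC", "C..C")

# brute-force optimal one-to-one matcher used as the IoU oracle: maximizes
# the number of matched pairs with IoU >= iouMin by exhaustive assignment
bruteForceTP <- function(pred, ref, iouMin = 0.5) {
  iou <- function(p, r) {
    inter <- max(0, min(p[2], r[2]) - max(p[1], r[1]) + 1)
    inter / ((p[2] - p[1] + 1) + (r[2] - r[1] + 1) - inter)
  }
  np <- nrow(pred); nr <- nrow(ref)
  if (np == 0 || nr == 0) return(0L)
  ok <- matrix(FALSE, np, nr)
  for (i in seq_len(np)) for (j in seq_len(nr)) {
    ok[i, j] <- pred$protein_id[i] == ref$protein_id[j] &&
      iou(c(pred$start[i], pred$end[i]), c(ref$start[j], ref$end[j])) >=
        iouMin
  }
  best <- 0L
  assign <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    assign(i + 1, used, count)
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      assign(i + 1, used, count + 1L)
      used[j] <- FALSE
    }
  }
  assign(1L, rep(FALSE, nr), 0L)
  best
}

# synthetic crystal-like fixture: hetero-group at position 1, chain
# beginning at author residue 22, CXXC sites at 1-based polymer positions
# 40..43 and 385..388 (author 61..64 and 406..409); poly-alanine elsewhere
# so the planted sites are the only C..C occurrences
crystalLikeRecord <- function() {
  L <- 420
  v <- rep("A", L)
  v[40:43] <- c("C", "G", "H", "C")
  v[385:388] <- c("C", "P", "Y", "C")
  ProteinRecord("synth2b5e", paste(v, collapse = ""),
                residueNumbers = 22:(22 + L - 1), source = "synthetic")
}

crystalLikePdbText <- function() {
  r <- crystalLikeRecord()
  seqv <- strsplit(aaSequence(r), "")[[1]]
  lines <- pdbLine("HETATM", 1, "C1", "NAG", 1, 0, 0, 0)
  for (i in seq_len(seqLength(r))) {
    lines <- c(lines, pdbLine("ATOM", i + 1, "CA",
                              bio3d::aa123(seqv[i]),
                              residueNumbers(r)[i], i * 3.8, 0, 0))
  }
  c(lines, "TER", "END")
}
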