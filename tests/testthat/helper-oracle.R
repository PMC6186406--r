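# Independent brute-force affine-gap global alignment oracle, written as a
# plain R dynamic program with the same scoring conventions and tie-break
# policy (M > X > Y on equal scores; a length-k gap costs open + k * ext).
# Deliberately independent of the package's compiled implementation.
oracle_align <- function(a, b, submat, alphabet, gap_open, gap_ext) {
  ai <- unname(alphabet[strsplit(a, "")[[1]]]) + 1L
  bi <- unname(alphabet[strsplit(b, "")[[1]]]) + 1L
  n <- length(ai); m <- length(bi)
  NEG <- -1e30
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- gap_open + (i - 1) * gap_ext
    tX[i, 1] <- if (i == 2) 0L else 1L
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- gap_open + (j - 1) * gap_ext
    tY[1, j] <- if (j == 2) 0L else 2L
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[ai[i - 1], bi[j - 1]]
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)          # first max: prefers M, then X, then Y
      M[i, j] <- cand[k] + s; tM[i, j] <- k - 1L
      ox <- M[i - 1, j] + gap_open + gap_ext; ex <- X[i - 1, j] + gap_ext
      if (ox >= ex) { X[i, j] <- ox; tX[i, j] <- 0L }
      else          { X[i, j] <- ex; tX[i, j] <- 1L }
      oy <- M[i, j - 1] + gap_open + gap_ext; ey <- Y[i, j - 1] + gap_ext
      if (oy >= ey) { Y[i, j] <- oy; tY[i, j] <- 0L }
      else          { Y[i, j] <- ey; tY[i, j] <- 2L }
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  st <- which.max(fin) - 1L
  score <- fin[st + 1L]
  i <- n + 1L; j <- m + 1L
  ident <- 0L; ncol <- 0L
  while (i > 1L || j > 1L) {
    ncol <- ncol + 1L
    if (st == 0L && i > 1L && j > 1L) {
      prev <- tM[i, j]
      if (ai[i - 1L] == bi[j - 1L]) ident <- ident + 1L
      i <- i - 1L; j <- j - 1L; st <- prev
    } else if (st == 1L || (st == 0L && j == 1L)) {
      prev <- tX[i, j]; i <- i - 1L; st <- prev
    } else {
      prev <- tY[i, j]; j <- j - 1L; st <- prev
    }
  }
  list(score = score, pi = ident / ncol, n_identical = ident, n_columns = ncol)
}

oracle_pi_nt <- function(a, b) {
  p <- align_params("nt")
  oracle_align(a, b, p$submat, p$alphabet, p$gap_open, p$gap_ext)$pi
}

oracle_pi_aa <- function(a, b) {
  p <- align_params("aa")
  oracle_align(a, b, p$submat, p$alphabet, p$gap_open, p$gap_ext)$pi
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_aa <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}
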