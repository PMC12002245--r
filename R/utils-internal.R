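# Column medians via an odd-even transposition sorting network of pmin/pmax
# over row vectors: O(r^2) vectorised passes, fast for the small row counts
# (6-20) that arise from frequency-band bins. Falls back to apply() for
# larger matrices.
colMedians <- function(m) {
  r <- nrow(m)
  if (r == 1) return(m[1, ])
  if (r > 24) return(apply(m, 2, median))
  rows <- lapply(seq_len(r), function(i) m[i, ])
  for (pass in seq_len(r)) {
    start <- if (pass %% 2 == 1) 1L else 2L
    i <- start
    while (i + 1L <= r) {
      lo <- pmin(rows[[i]], rows[[i + 1L]])
      hi <- pmax(rows[[i]], rows[[i + 1L]])
      rows[[i]] <- lo; rows[[i + 1L]] <- hi
      i <- i + 2L
    }
  }
  if (r %% 2 == 1) rows[[(r + 1L) %/% 2L]]
  else (rows[[r %/% 2L]] + rows[[r %/% 2L + 1L]]) / 2
}

# Biased sample ACF (lags 1..nLags) of every column of xm at once, via
# zero-padded FFTs; identical to stats::acf(demean = TRUE) per column.
fftAcf <- function(xm, nLags) {
  n <- nrow(xm)
  xm <- sweep(xm, 2, colMeans(xm))
  m <- stats::nextn(n + nLags)
  X <- mvfft(rbind(xm, matrix(0, m - n, ncol(xm))))
  ac <- Re(mvfft(X * Conj(X), inverse = TRUE))[seq_len(nLags + 1L), ,
                                               drop = FALSE] / m
  sweep(ac[-1L, , drop = FALSE], 2, ac[1L, ], "/")
}
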