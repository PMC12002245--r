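# Shared fixture builders; everything is generated in code, seeded.

# PowerSeries with given values (vector or channels x bins matrix)
makePowerSeries <- function(values, binRate = 8) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  new("PowerSeries", values = values, binRate = binRate,
      valid = matrix(TRUE, nrow(values), ncol(values)),
      labels = paste0("ch", seq_len(nrow(values))))
}

whiteNoisePowerSeries <- function(nBins, seed, nChannels = 1) {
  set.seed(seed)
  makePowerSeries(matrix(rnorm(nChannels * nBins), nChannels))
}

ar1Series <- function(n, phi, seed, sd = 1) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd)
  innov <- rnorm(n - 1, sd = sd * sqrt(1 - phi^2))
  for (k in 2:n) x[k] <- phi * x[k - 1] + innov[k - 1]
  x
}

# WeightMatrix with all-zero weights on an L x L grid
zeroWeightMatrix <- function(L) {
  N <- L * L
  pos <- cbind(rep(0:(L - 1), each = L), rep(0:(L - 1), times = L))
  new("WeightMatrix", weights = matrix(0, N, N),
      inhibitory = rep(FALSE, N), positions = pos, gridSide = L,
      lambdaTarget = 0)
}

smallModelConfig <- function(L = 8, nSteps = 600L, transient = 100L,
                             lambda = 1) {
  modelConfig(nNeurons = as.integer(L * L), gridSide = as.integer(L),
              lambdaTarget = lambda, nSteps = nSteps, transient = transient)
}

# Crafted AcfSet from a single ACF vector (lags 1..480 at 8 bins/s)
craftedAcfSet <- function(a) {
  new("AcfSet", acfs = matrix(a, ncol = 1), lagSeconds = seq_along(a) / 8,
      channelOf = "ch1", startSeconds = 0)
}
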