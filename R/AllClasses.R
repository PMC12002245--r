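#' @import methods
#' @import stats
#' @importFrom utils read.csv write.csv combn
#' @useDynLib criticalTC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Configuration of the branching-style network model
#'
#' Holds the structural and run-length parameters of the probabilistic
#' neuronal network: neurons on a periodic square grid, all-to-all coupled
#' with a Gaussian distance profile, a target spectral radius (the control
#' parameter of the phase transition), and the simulation horizon.
#'
#' @slot nNeurons number of neurons; must be a perfect square of `gridSide`.
#' @slot gridSide side length of the periodic square grid.
#' @slot fracInhibitory fraction of neurons whose outgoing weights are
#'   negative (inhibitory).
#' @slot sigma width (in grid units) of the Gaussian distance profile.
#' @slot lambdaTarget target spectral radius (largest absolute eigenvalue)
#'   of the weight matrix; the distance-to-criticality control parameter.
#' @slot nSteps number of simulated time steps.
#' @slot transient initial steps discarded before computing summary
#'   statistics.
#' @slot backgroundActive neurons forced active per step as background drive.
#' @export
setClass("ModelConfig", representation(
  nNeurons = "numeric", gridSide = "numeric", fracInhibitory = "numeric",
  sigma = "numeric", lambdaTarget = "numeric", nSteps = "numeric",
  transient = "numeric", backgroundActive = "numeric"
))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@nNeurons != object@gridSide^2)
    msg <- c(msg, "nNeurons must equal gridSide^2 (periodic square grid)")
  if (object@fracInhibitory <= 0 || object@fracInhibitory >= 1)
    msg <- c(msg, "fracInhibitory must lie strictly in (0, 1)")
  if (object@lambdaTarget <= 0)
    msg <- c(msg, "lambdaTarget must be positive")
  if (object@transient >= object@nSteps)
    msg <- c(msg, "transient must be smaller than nSteps")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (length(msg)) msg else TRUE
})

#' @param nNeurons,gridSide,fracInhibitory,sigma,lambdaTarget,nSteps,transient,backgroundActive
#'   see the corresponding slots.
#' @return `modelConfig()` returns a validated [ModelConfig-class] object.
#' @rdname ModelConfig-class
#' @examples
#' cfg <- modelConfig(lambdaTarget = 1)
#' @export
modelConfig <- function(nNeurons = 1024L, gridSide = as.integer(sqrt(nNeurons)),
                        fracInhibitory = 0.2, sigma = 4,
                        lambdaTarget = 1, nSteps = 5000L, transient = 500L,
                        backgroundActive = 1L) {
  new("ModelConfig", nNeurons = nNeurons, gridSide = gridSide,
      fracInhibitory = fracInhibitory, sigma = sigma,
      lambdaTarget = lambdaTarget, nSteps = nSteps, transient = transient,
      backgroundActive = backgroundActive)
}

#' Perturbation mechanisms of the network model
#'
#' The three mechanisms that move the network away from its tuned operating
#' point: medication-like scaling of outgoing excitatory weights (`fExc`),
#' sleep-like whole-network off-steps (`pOff`), and interictal-spike-like
#' forced activation of a local patch (`pIed`).
#'
#' @slot fExc multiplicative factor in (0, 1] applied to outgoing excitatory
#'   weights; 1 = unperturbed.
#' @slot pOff per-step probability of silencing the whole network.
#' @slot pIed per-step probability of a spike event activating a local patch.
#' @slot iedPatchFrac fraction of all neurons forced active during a spike
#'   event (the event centre plus its nearest neighbours on the torus).
#' @export
setClass("PerturbationConfig", representation(
  fExc = "numeric", pOff = "numeric", pIed = "numeric",
  iedPatchFrac = "numeric"
))

setValidity("PerturbationConfig", function(object) {
  msg <- character()
  if (object@fExc <= 0 || object@fExc > 1)
    msg <- c(msg, "fExc must lie in (0, 1]")
  for (p in c("pOff", "pIed"))
    if (slot(object, p) < 0 || slot(object, p) > 1)
      msg <- c(msg, paste(p, "must lie in [0, 1]"))
  if (object@iedPatchFrac <= 0 || object@iedPatchFrac > 1)
    msg <- c(msg, "iedPatchFrac must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param fExc,pOff,pIed,iedPatchFrac see the corresponding slots.
#' @return `perturbationConfig()` returns a validated
#'   [PerturbationConfig-class] object; the default is the unperturbed model.
#' @rdname PerturbationConfig-class
#' @export
perturbationConfig <- function(fExc = 1, pOff = 0, pIed = 0,
                               iedPatchFrac = 0.2) {
  new("PerturbationConfig", fExc = fExc, pOff = pOff, pIed = pIed,
      iedPatchFrac = iedPatchFrac)
}

#' Signed, distance-modulated network weight matrix
#'
#' All-to-all connectivity on a periodic square grid. `weights[i, j]` is the
#' outgoing weight from neuron i onto neuron j, so inhibitory neurons have
#' non-positive rows. The matrix is rescaled by a single scalar so its
#' spectral radius equals the configured control parameter.
#'
#' @slot weights numeric matrix (nNeurons x nNeurons), zero diagonal.
#' @slot inhibitory logical per neuron.
#' @slot positions integer grid coordinates (nNeurons x 2, 0-based).
#' @slot gridSide side length of the periodic grid.
#' @slot lambdaTarget spectral radius the matrix was rescaled to.
#' @export
setClass("WeightMatrix", representation(
  weights = "matrix", inhibitory = "logical", positions = "matrix",
  gridSide = "numeric", lambdaTarget = "numeric"
))

setValidity("WeightMatrix", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (length(object@inhibitory) != nrow(w))
    msg <- c(msg, "inhibitory flag length must match nNeurons")
  if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be zero (no self-connections)")
  if (any(w[object@inhibitory, , drop = FALSE] > 0))
    msg <- c(msg, "outgoing weights of inhibitory neurons must be <= 0")
  if (any(w[!object@inhibitory, , drop = FALSE] < 0))
    msg <- c(msg, "outgoing weights of excitatory neurons must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WeightMatrix", function(object) {
  cat(sprintf("WeightMatrix: %d neurons on a %dx%d periodic grid\n",
              nrow(object@weights), object@gridSide, object@gridSide))
  cat(sprintf("  inhibitory: %d (%.1f%%)   lambda target: %g   realised: %g\n",
              sum(object@inhibitory),
              100 * mean(object@inhibitory), object@lambdaTarget,
              spectralRadius(object@weights)))
})

#' Simulated network activity
#'
#' Binary raster of neuron activity plus the derived population activity
#' (fraction of active neurons per step) and per-step event flags.
#'
#' @slot raster integer 0/1 matrix, neurons x time steps.
#' @slot populationActivity numeric vector, mean activity per step.
#' @slot offStep logical per step: whole-network off-step.
#' @slot iedStep logical per step: spike event occurred.
#' @slot transient number of initial steps regarded as transient.
#' @export
setClass("ActivityTrace", representation(
  raster = "matrix", populationActivity = "numeric",
  offStep = "logical", iedStep = "logical", transient = "numeric"
))

setValidity("ActivityTrace", function(object) {
  msg <- character()
  if (length(object@populationActivity) != ncol(object@raster))
    msg <- c(msg, "populationActivity length must equal number of steps")
  if (any(object@populationActivity < 0 | object@populationActivity > 1))
    msg <- c(msg, "populationActivity must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ActivityTrace", function(object) {
  cat(sprintf("ActivityTrace: %d neurons x %d steps (transient %d)\n",
              nrow(object@raster), ncol(object@raster), object@transient))
  cat(sprintf("  mean activity: %.4f   off-steps: %d   spike events: %d\n",
              mean(object@populationActivity), sum(object@offStep),
              sum(object@iedStep)))
})

#' Multichannel recording
#'
#' A channels-by-time matrix of samples with a sampling rate, channel labels,
#' seizure annotations, bad-channel flags, and masked time intervals
#' (seconds) excluded from all downstream power/ACF computation.
#'
#' @slot samples numeric matrix, channels x time.
#' @slot rate sampling rate in Hz.
#' @slot labels channel labels.
#' @slot seizures data.frame with columns `start_s`, `end_s`.
#' @slot bad logical per channel.
#' @slot maskIntervals two-column matrix of masked `[start_s, end_s]`.
#' @slot preprocessed logical flag set by [preprocessRecording()].
#' @export
setClass("Recording", representation(
  samples = "matrix", rate = "numeric", labels = "character",
  seizures = "data.frame", bad = "logical", maskIntervals = "matrix",
  preprocessed = "logical"
))

setValidity("Recording", function(object) {
  msg <- character()
  if (object@rate <= 0) msg <- c(msg, "rate must be positive")
  if (length(object@labels) != nrow(object@samples))
    msg <- c(msg, "one label per channel required")
  dur <- ncol(object@samples) / object@rate
  if (nrow(object@seizures) &&
      any(object@seizures$start_s < 0 | object@seizures$end_s > dur))
    msg <- c(msg, "seizure intervals must lie within the recording span")
  if (length(msg)) msg else TRUE
})

#' @param samples,rate,labels,seizures,bad,maskIntervals,preprocessed see the
#'   corresponding slots; sensible defaults are supplied for all metadata.
#' @return `recording()` returns a validated [Recording-class] object.
#' @rdname Recording-class
#' @examples
#' rec <- recording(matrix(rnorm(512), 1), rate = 256)
#' @export
recording <- function(samples, rate,
                      labels = paste0("ch", seq_len(nrow(samples))),
                      seizures = data.frame(start_s = numeric(),
                                            end_s = numeric()),
                      bad = rep(FALSE, nrow(samples)),
                      maskIntervals = matrix(numeric(), ncol = 2),
                      preprocessed = FALSE) {
  new("Recording", samples = samples, rate = rate, labels = labels,
      seizures = seizures, bad = bad, maskIntervals = maskIntervals,
      preprocessed = preprocessed)
}

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s), %.1f s at %g Hz%s\n",
              nrow(object@samples), ncol(object@samples) / object@rate,
              object@rate,
              if (object@preprocessed) " (preprocessed)" else ""))
  if (any(object@bad))
    cat("  bad channels:", paste(object@labels[object@bad], collapse = ", "), "\n")
  if (nrow(object@maskIntervals))
    cat(sprintf("  masked time: %.1f s in %d interval(s)\n",
                sum(object@maskIntervals[, 2] - object@maskIntervals[, 1]),
                nrow(object@maskIntervals)))
})

#' Tuning constants of the temporal-correlation statistic
#'
#' @slot powerWindow power bin length in seconds (0.125 s, i.e. 8 bins/s).
#' @slot hgBand high-gamma frequency band in Hz used for the power series.
#' @slot acfWindow ACF window length in seconds.
#' @slot acfOverlap overlap of consecutive ACF windows in seconds.
#' @slot maxLag maximum ACF lag in seconds.
#' @slot baselineBand lag range (seconds) whose median ACF is the baseline.
#' @export
setClass("TcParams", representation(
  powerWindow = "numeric", hgBand = "numeric", acfWindow = "numeric",
  acfOverlap = "numeric", maxLag = "numeric", baselineBand = "numeric"
))

setValidity("TcParams", function(object) {
  msg <- character()
  if (object@acfOverlap >= object@acfWindow)
    msg <- c(msg, "acfOverlap must be smaller than acfWindow")
  if (object@baselineBand[1] <= 0 || object@baselineBand[2] > object@maxLag)
    msg <- c(msg, "baselineBand must be a subinterval of (0, maxLag]")
  if (length(msg)) msg else TRUE
})

#' @param powerWindow,hgBand,acfWindow,acfOverlap,maxLag,baselineBand see the
#'   corresponding slots.
#' @return `tcParams()` returns a validated [TcParams-class] object holding
#'   the defaults used throughout: 125 ms high-gamma (56-96 Hz) power bins,
#'   120 s ACF windows with 90 s overlap, lags up to 60 s and a 40-60 s
#'   baseline band.
#' @rdname TcParams-class
#' @export
tcParams <- function(powerWindow = 0.125, hgBand = c(56, 96),
                     acfWindow = 120, acfOverlap = 90, maxLag = 60,
                     baselineBand = c(40, 60)) {
  new("TcParams", powerWindow = powerWindow, hgBand = hgBand,
      acfWindow = acfWindow, acfOverlap = acfOverlap, maxLag = maxLag,
      baselineBand = baselineBand)
}

#' Log high-gamma power series
#'
#' Per-channel log10 band power in non-overlapping 125 ms bins (8 bins per
#' second), with a validity mask: bins overlapping masked time or with
#' degenerate (zero-variance) samples are invalid and excluded from all ACFs.
#'
#' @slot values numeric matrix, channels x bins (log10 power).
#' @slot binRate bins per second (1 / powerWindow).
#' @slot valid logical matrix, channels x bins.
#' @slot labels channel labels.
#' @export
setClass("PowerSeries", representation(
  values = "matrix", binRate = "numeric", valid = "matrix",
  labels = "character"
))

setValidity("PowerSeries", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@valid)))
    msg <- c(msg, "values and valid mask must have identical dimensions")
  if (object@binRate <= 0) msg <- c(msg, "binRate must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PowerSeries", function(object) {
  cat(sprintf("PowerSeries: %d channel(s) x %d bins at %g bins/s (%.1f s)\n",
              nrow(object@values), ncol(object@values), object@binRate,
              ncol(object@values) / object@binRate))
  cat(sprintf("  invalid bins: %d\n", sum(!object@valid)))
})

#' Set of per-window autocorrelation functions
#'
#' One column per accepted window; windows from several channels may be
#' pooled, tracked by `channelOf`. Lags run from one bin up to `maxLag`.
#'
#' @slot acfs numeric matrix, lags x windows, values in [-1, 1].
#' @slot lagSeconds lag of each row in seconds.
#' @slot channelOf channel label of each window (column).
#' @slot startSeconds window start time of each column, seconds.
#' @export
setClass("AcfSet", representation(
  acfs = "matrix", lagSeconds = "numeric", channelOf = "character",
  startSeconds = "numeric"
))

setValidity("AcfSet", function(object) {
  msg <- character()
  if (nrow(object@acfs) != length(object@lagSeconds))
    msg <- c(msg, "one lag per ACF row required")
  if (ncol(object@acfs) != length(object@channelOf) ||
      ncol(object@acfs) != length(object@startSeconds))
    msg <- c(msg, "per-window metadata must match the number of columns")
  if (ncol(object@acfs) && any(abs(object@acfs) > 1 + 1e-8))
    msg <- c(msg, "ACF values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AcfSet", function(object) {
  cat(sprintf("AcfSet: %d window(s) over %d channel(s), lags %g-%g s\n",
              ncol(object@acfs), length(unique(object@channelOf)),
              if (length(object@lagSeconds)) min(object@lagSeconds) else NA,
              if (length(object@lagSeconds)) max(object@lagSeconds) else NA))
})

#' Temporal-correlation statistic
#'
#' Half-decay time of the aggregated power autocorrelation, in seconds.
#' The floor is one power bin (0.125 s); values that never cross the decay
#' threshold are capped at the maximum lag and flagged.
#'
#' @slot tc the statistic in seconds.
#' @slot nWindows number of ACF windows aggregated.
#' @slot capped TRUE if the ACF never crossed the threshold.
#' @slot degenerate TRUE if the lag-1 ACF did not exceed the baseline.
#' @export
setClass("TcValue", representation(
  tc = "numeric", nWindows = "numeric", capped = "logical",
  degenerate = "logical"
))

setMethod("show", "TcValue", function(object) {
  cat(sprintf("TC = %g (from %d window(s)%s%s)\n", object@tc,
              object@nWindows, if (object@capped) ", capped" else "",
              if (object@degenerate) ", degenerate" else ""))
})

#' Result of a nonparametric two-group or paired test
#'
#' @slot statistic test statistic.
#' @slot pValue two-sided p-value.
#' @slot relativeEffect nonparametric relative effect P(X<Y) + 0.5 P(X=Y)
#'   (NA for paired tests).
#' @slot nX,nY group sizes.
#' @slot method descriptive label.
#' @export
setClass("TestResult", representation(
  statistic = "numeric", pValue = "numeric", relativeEffect = "numeric",
  nX = "numeric", nY = "numeric", method = "character"
))

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, relative effect = %.3f (n = %d/%d)\n",
              object@method, object@statistic, object@pValue,
              object@relativeEffect, object@nX, object@nY))
})
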