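#' Spectral radius of a matrix
#'
#' Largest eigenvalue modulus; eigenvalues of the signed weight matrix may be
#' complex.
#'
#' @param w numeric matrix.
#' @return the spectral radius (non-negative scalar).
#' @export
spectralRadius <- function(w) {
  max(Mod(eigen(w, only.values = TRUE)$values))
}

# Pairwise squared torus (periodic grid) distances for positions on an
# L x L grid; pos is an n x 2 matrix of 0-based coordinates.
torusDist2 <- function(pos, L) {
  dx <- abs(outer(pos[, 1], pos[, 1], "-")); dx <- pmin(dx, L - dx)
  dy <- abs(outer(pos[, 2], pos[, 2], "-")); dy <- pmin(dy, L - dy)
  dx^2 + dy^2
}

#' Build a distance-modulated random network
#'
#' Constructs the all-to-all weight matrix of the branching-style model:
#' uniform random magnitudes on `[0, 1)` scaled by a Gaussian profile of the
#' periodic (torus) grid distance, `exp(-r^2 / (2 sigma^2))`; a uniformly
#' random fraction of neurons is inhibitory (their outgoing rows negated);
#' self-connections are removed; finally the whole matrix is rescaled by a
#' single scalar so its spectral radius equals `lambdaTarget`.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer seed; network construction is deterministic given it.
#' @return a [WeightMatrix-class].
#' @examples
#' w <- buildNetwork(modelConfig(nNeurons = 64L, lambdaTarget = 1), seed = 1)
#' spectralRadius(networkWeights(w))
#' @export
buildNetwork <- function(config, seed) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  if (missing(seed)) stop("seed is required: network construction must be reproducible")
  set.seed(seed)
  N <- config@nNeurons
  L <- config@gridSide
  pos <- cbind(rep(0:(L - 1), each = L), rep(0:(L - 1), times = L))
  r2 <- torusDist2(pos, L)
  w <- matrix(runif(N * N), N, N) * exp(-r2 / (2 * config@sigma^2))
  diag(w) <- 0
  inh <- rep(FALSE, N)
  inh[sample.int(N, round(config@fracInhibitory * N))] <- TRUE
  w[inh, ] <- -w[inh, ]
  rad <- spectralRadius(w)
  if (rad == 0) stop("cannot rescale an all-zero weight matrix")
  w <- w * (config@lambdaTarget / rad)
  new("WeightMatrix", weights = w, inhibitory = inh, positions = pos,
      gridSide = L, lambdaTarget = config@lambdaTarget)
}

#' Scale outgoing excitatory weights
#'
#' Models the effect of excitability-reducing medication: every outgoing
#' weight of each excitatory neuron is multiplied by `fExc` in (0, 1].
#' Inhibitory rows are untouched and the matrix is deliberately NOT
#' re-normalised afterwards — the induced shift of the spectral radius is
#' the perturbation.
#'
#' @param w a [WeightMatrix-class] already rescaled to its target radius.
#' @param fExc multiplicative factor in `[0, 1]` (0 is the boundary case in
#'   which only inhibition remains).
#' @return a [WeightMatrix-class] with scaled excitatory rows.
#' @export
applyAsm <- function(w, fExc) {
  stopifnot(is(w, "WeightMatrix"))
  if (!is.numeric(fExc) || length(fExc) != 1 || fExc < 0 || fExc > 1)
    stop("fExc must be a single value in [0, 1]")
  w@weights[!w@inhibitory, ] <- w@weights[!w@inhibitory, ] * fExc
  w
}

# Neighbour table for spike events: column c holds the 1-based indices of
# neuron c and its nearest ceiling(frac * N) - 1 neighbours by torus
# distance, ties broken by neuron index (order() is stable).
iedNeighbourTable <- function(w, frac) {
  N <- nrow(w@weights)
  npatch <- ceiling(frac * N)
  r2 <- torusDist2(w@positions, w@gridSide)
  vapply(seq_len(N), function(c) order(r2[c, ])[seq_len(npatch)],
         integer(npatch))
}

#' Simulate network activity
#'
#' Runs the probabilistic update for `nSteps` steps: each neuron activates
#' with probability equal to its weighted input sum clipped to `[0, 1]`;
#' one uniformly chosen neuron per step is forced active as background
#' drive; with probability `pIed` a spike event forces a local patch
#' (`iedPatchFrac` of all neurons, centred on a random neuron) active; with
#' probability `pOff` the whole network — including drive and spike events —
#' is silenced for that step.
#'
#' @param config a [ModelConfig-class] consistent with `w`.
#' @param perturb a [PerturbationConfig-class]; `fExc` is applied to the
#'   weights via [applyAsm()] before simulation.
#' @param w a [WeightMatrix-class].
#' @param seed integer seed (required; runs are bit-reproducible given it).
#' @return an [ActivityTrace-class].
#' @examples
#' cfg <- modelConfig(nNeurons = 64L, lambdaTarget = 1, nSteps = 500L,
#'                    transient = 100L)
#' tr <- simulateActivity(cfg, perturbationConfig(), buildNetwork(cfg, 1), seed = 2)
#' orderParameter(tr)
#' @export
simulateActivity <- function(config, perturb = perturbationConfig(), w, seed) {
  stopifnot(is(config, "ModelConfig"), is(perturb, "PerturbationConfig"),
            is(w, "WeightMatrix"))
  validObject(perturb)
  if (missing(seed)) stop("seed is required: simulation must be reproducible")
  if (nrow(w@weights) != config@nNeurons)
    stop("weight matrix size does not match config")
  if (perturb@fExc < 1) w <- applyAsm(w, perturb@fExc)
  nbr <- if (perturb@pIed > 0) {
    iedNeighbourTable(w, perturb@iedPatchFrac)
  } else {
    matrix(1L, nrow = 1, ncol = config@nNeurons)
  }
  set.seed(seed)
  res <- simulateCore(t(w@weights), as.integer(config@nSteps),
                      perturb@pOff, perturb@pIed, nbr)
  new("ActivityTrace", raster = res$raster,
      populationActivity = as.numeric(res$pop),
      offStep = as.logical(res$offStep), iedStep = as.logical(res$iedStep),
      transient = config@transient)
}

#' Order parameter of a simulation
#'
#' Mean population activity (fraction of active neurons) after discarding
#' the initial transient; distinguishes sub-, super- and critical regimes.
#'
#' @param trace an [ActivityTrace-class].
#' @param transient steps to discard (defaults to the trace's own setting).
#' @return mean activity, a fraction in [0, 1].
#' @export
orderParameter <- function(trace, transient = trace@transient) {
  n <- length(trace@populationActivity)
  if (transient >= n) stop("no steps remain after the transient")
  mean(trace@populationActivity[(transient + 1):n])
}

#' Temporal correlation of simulated population activity
#'
#' Sample autocorrelation of the post-transient population activity up to
#' `maxLag` steps (lag 0 excluded); baseline is the median ACF over the last
#' fifth of computed lags; the threshold sits halfway between the lag-1 ACF
#' and the baseline; the statistic is `(first lag >= 2 below threshold) - 1`
#' time steps. If the ACF never crosses, the value is capped at `maxLag`.
#'
#' @param trace an [ActivityTrace-class].
#' @param transient steps to discard (defaults to the trace's own setting).
#' @param maxLag maximum lag in steps.
#' @return a [TcValue-class]; `tc` is in time steps here (model clock).
#' @export
populationTc <- function(trace, transient = trace@transient, maxLag = 500L) {
  n <- length(trace@populationActivity)
  if (transient >= n) stop("no steps remain after the transient")
  x <- trace@populationActivity[(transient + 1):n]
  if (var(x) == 0)
    stop("population activity has zero variance; temporal correlation undefined")
  maxLag <- min(maxLag, length(x) - 1L)
  a <- as.vector(acf(x, lag.max = maxLag, plot = FALSE, demean = TRUE)$acf)[-1]
  tcFromAcfVector(a, baselineIdx = (maxLag - floor(maxLag / 5) + 1):maxLag,
                  lagUnit = 1, maxValue = maxLag, nWindows = 1L)
}

# Shared crossing rule: a is the ACF at lags 1..K (lag 0 excluded),
# baselineIdx indexes the baseline lags, lagUnit converts lags to output
# units. Returns a TcValue with tc = (first lag >= 2 below threshold - 1)
# * lagUnit, capped at maxValue when no crossing occurs.
tcFromAcfVector <- function(a, baselineIdx, lagUnit, maxValue, nWindows) {
  baseline <- median(a[baselineIdx])
  a1 <- a[1]
  if (a1 <= baseline)
    return(new("TcValue", tc = lagUnit, nWindows = as.numeric(nWindows),
               capped = FALSE, degenerate = TRUE))
  threshold <- baseline + (a1 - baseline) / 2
  idx <- which(a < threshold)
  idx <- idx[idx >= 2]
  if (!length(idx))
    return(new("TcValue", tc = maxValue * lagUnit, nWindows = as.numeric(nWindows),
               capped = TRUE, degenerate = FALSE))
  new("TcValue", tc = (idx[1] - 1) * lagUnit, nWindows = as.numeric(nWindows),
      capped = FALSE, degenerate = FALSE)
}

#' Sweep the control parameter and perturbations
#'
#' For each value of the spectral-radius control parameter, builds `reps`
#' independent networks, simulates each, and aggregates the order parameter
#' and the population temporal correlation. Deterministic given `seed`.
#'
#' @param lambdas numeric vector of spectral-radius values.
#' @param perturb a [PerturbationConfig-class] applied to every run.
#' @param reps independent networks/runs per value (>= 1).
#' @param seed integer seed; per-run seeds are derived deterministically.
#' @param config a [ModelConfig-class] template; its `lambdaTarget` is
#'   replaced by each grid value in turn.
#' @param detail if TRUE, also return the per-run table.
#' @return a data.frame with one row per lambda: `lambda`,
#'   `order_parameter` (mean), `tc_steps` (mean), `tc_sd`, `n_capped`;
#'   with `detail = TRUE` the per-run table is attached as
#'   `attr(x, "runs")` with columns (lambda, f_exc, p_off, p_ied, rep,
#'   order_parameter, tc_steps).
#' @export
phaseSweep <- function(lambdas, perturb = perturbationConfig(), reps, seed,
                       config = modelConfig(), detail = FALSE) {
  if (!length(lambdas)) stop("empty lambda grid")
  if (reps < 1) stop("reps must be >= 1")
  if (missing(seed)) stop("seed is required")
  runs <- do.call(rbind, lapply(seq_along(lambdas), function(i) {
    lam <- lambdas[i]
    cfg <- config
    cfg@lambdaTarget <- lam
    do.call(rbind, lapply(seq_len(reps), function(r) {
      # distinct, deterministic seeds per (grid point, rep)
      sBuild <- (seed + 7919L * i + 104729L * r) %% .Machine$integer.max
      sRun <- (seed + 15485863 + 7919L * i + 104729L * r) %% .Machine$integer.max
      w <- buildNetwork(cfg, seed = sBuild)
      tr <- simulateActivity(cfg, perturb, w, seed = sRun)
      # a fully ordered run (constant activity, e.g. saturated
      # supercritical dynamics) has no decay to measure: floor of 1 step
      tcv <- tryCatch(populationTc(tr), error = function(e) NULL)
      data.frame(lambda = lam, f_exc = perturb@fExc, p_off = perturb@pOff,
                 p_ied = perturb@pIed, rep = r,
                 order_parameter = orderParameter(tr),
                 tc_steps = if (is.null(tcv)) 1 else tcv@tc,
                 capped = if (is.null(tcv)) FALSE else tcv@capped)
    }))
  }))
  out <- do.call(rbind, lapply(split(runs, runs$lambda), function(d) {
    data.frame(lambda = d$lambda[1],
               order_parameter = mean(d$order_parameter),
               tc_steps = mean(d$tc_steps), tc_sd = sd(d$tc_steps),
               n_capped = sum(d$capped))
  }))
  out <- out[order(out$lambda), ]
  rownames(out) <- NULL
  if (detail) attr(out, "runs") <- runs
  out
}
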