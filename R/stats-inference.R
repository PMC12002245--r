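#' Cognitive domain impairment flags
#'
#' Scores are standardised against the norm population (`z = (score -
#' norm_mean) / norm_sd`); a domain is impaired iff at least two of its
#' tests score at least one standard deviation below the norm mean
#' (`z <= -1`, boundary inclusive).
#'
#' @param scores data.frame with columns `domain`, `test`, `score`,
#'   `norm_mean`, `norm_sd` (each domain with >= 2 tests, `norm_sd > 0`).
#' @return a list with `domains` (data.frame: domain, n_tests, n_below,
#'   impaired) and `tests` (the input with a `z` column).
#' @export
impairmentFlags <- function(scores) {
  stopifnot(all(c("domain", "test", "score", "norm_mean", "norm_sd") %in%
                names(scores)))
  if (any(is.na(scores$norm_sd)) || any(scores$norm_sd <= 0))
    stop("norm_sd must be positive for every test")
  scores$z <- (scores$score - scores$norm_mean) / scores$norm_sd
  domains <- do.call(rbind, lapply(split(scores, scores$domain), function(d) {
    if (nrow(d) < 2)
      stop("each domain needs at least two tests: ", d$domain[1])
    nBelow <- sum(d$z <= -1)
    data.frame(domain = d$domain[1], n_tests = nrow(d), n_below = nBelow,
               impaired = nBelow >= 2)
  }))
  rownames(domains) <- NULL
  list(domains = domains, tests = scores)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for within-subject state contrasts (same
#' subjects measured in two states). Zero differences are dropped per the
#' standard procedure; at least five non-zero differences are required.
#'
#' @param x,y equal-length paired samples.
#' @return a [TestResult-class] (relative effect is NA for paired tests).
#' @export
pairedWilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  nz <- sum(d != 0, na.rm = TRUE)
  if (nz == 0) stop("all differences are zero: test degenerate")
  if (nz < 5) stop("need at least 5 non-zero differences, got ", nz)
  wt <- wilcox.test(x, y, paired = TRUE, alternative = "two.sided",
                    exact = nz < 50, correct = TRUE)
  new("TestResult", statistic = unname(wt$statistic), pValue = wt$p.value,
      relativeEffect = NA_real_, nX = length(x), nY = length(y),
      method = "paired Wilcoxon signed-rank")
}

#' Brunner-Munzel test
#'
#' Nonparametric two-sample test for stochastic equality, robust to
#' non-normal and heteroscedastic data. The relative effect
#' `p = P(X < Y) + 0.5 P(X = Y)` is estimated from midranks; the default
#' p-value uses the t-approximation with Satterthwaite-type degrees of
#' freedom. For small samples (both groups <= 10) an exact permutation
#' variant of the studentised statistic is available.
#'
#' @param x,y samples of the two groups (>= 5 each for the approximation).
#' @param method `"t"` (default) or `"permutation"` (n <= 10 per group).
#' @return a [TestResult-class]. If both within-group rank variances are
#'   zero (complete separation), the p-value is NA (flagged by warning) but
#'   the relative effect is still reported.
#' @export
brunnerMunzel <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  nx <- length(x); ny <- length(y)
  if (method == "t" && (nx < 5 || ny < 5))
    stop("t-approximation requires at least 5 observations per group")
  if (method == "permutation" && (nx > 10 || ny > 10))
    stop("exact permutation variant is offered for groups of at most 10")
  N <- nx + ny
  r <- rank(c(x, y))              # midranks
  rx <- r[seq_len(nx)]; ry <- r[-seq_len(nx)]
  mx <- mean(rx); my <- mean(ry)
  # P(X<Y) + 0.5 P(X=Y); computed from the exact rank sum (midranks are
  # multiples of 1/2) so it is bitwise identical to the pairwise count
  pHat <- (sum(ry) - ny * (ny + 1) / 2) / (nx * ny)
  rxi <- rank(x); ryi <- rank(y)            # internal ranks
  vx <- sum((rx - rxi - mx + (nx + 1) / 2)^2) / (nx - 1)
  vy <- sum((ry - ryi - my + (ny + 1) / 2)^2) / (ny - 1)
  sig <- nx * vx + ny * vy
  if (sig == 0) {
    warning("zero rank variance in both groups (complete separation); ",
            "p-value undefined")
    return(new("TestResult", statistic = NA_real_, pValue = NA_real_,
               relativeEffect = pHat, nX = nx, nY = ny,
               method = "Brunner-Munzel"))
  }
  stat <- nx * ny * (my - mx) / (N * sqrt(sig))
  if (method == "t") {
    dfree <- sig^2 / ((nx * vx)^2 / (nx - 1) + (ny * vy)^2 / (ny - 1))
    p <- 2 * pt(-abs(stat), dfree)
  } else {
    idx <- utils::combn(N, nx)
    z <- c(x, y)
    stats <- apply(idx, 2, function(ii) {
      xs <- z[ii]; ys <- z[-ii]
      rr <- rank(c(xs, ys))
      rxs <- rr[seq_len(nx)]; rys <- rr[-seq_len(nx)]
      mxs <- mean(rxs); mys <- mean(rys)
      vxs <- sum((rxs - rank(xs) - mxs + (nx + 1) / 2)^2) / (nx - 1)
      vys <- sum((rys - rank(ys) - mys + (ny + 1) / 2)^2) / (ny - 1)
      ss <- nx * vxs + ny * vys
      if (ss == 0) Inf * sign(mys - mxs) else
        nx * ny * (mys - mxs) / (N * sqrt(ss))
    })
    p <- mean(abs(stats) >= abs(stat) - 1e-12)
  }
  new("TestResult", statistic = stat, pValue = p, relativeEffect = pHat,
      nX = nx, nY = ny,
      method = paste0("Brunner-Munzel (", method, ")"))
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control across a family of p-values.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param alpha corrected significance level.
#' @return a list with `significant` (logical), `adjusted` (BH-adjusted
#'   p-values) and `alpha`.
#' @export
bhCorrect <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(significant = !is.na(adj) & adj <= alpha, adjusted = adj,
       alpha = alpha)
}

#' Kolmogorov-Smirnov uniformity check of a p-value set
#'
#' One-sided KS test of the empirical p-value distribution against
#' Uniform(0, 1); the alternative is an excess of small p-values (the
#' empirical CDF lying above the uniform CDF), the signature of a genuine
#' effect in the family.
#'
#' @param p numeric p-values (>= 5 values, all in `[0, 1]`).
#' @return the KS p-value.
#' @export
ksUniform <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 5) stop("need at least 5 p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  suppressWarnings(ks.test(p, "punif", alternative = "greater")$p.value)
}

#' Run the full feature-by-domain comparison grid
#'
#' For every (feature, context, domain) cell, subjects with an impaired
#' domain are compared to non-impaired subjects by the Brunner-Munzel test
#' on the feature values observed in that context. Cells where either
#' group has fewer than `minN` subjects are reported empty. P-values are
#' Benjamini-Hochberg corrected across the whole grid (one family per run),
#' and per feature the raw cell p-values are checked against uniformity.
#'
#' @param cohort data.frame with columns `subject`, `feature`, `context`,
#'   `value` (one row per subject, feature and sampling context).
#' @param impairment data.frame with columns `subject`, `domain`,
#'   `impaired` (logical), e.g. assembled from [impairmentFlags()].
#' @param alpha corrected significance level for the BH step.
#' @param minN minimum subjects per group for a cell to be testable.
#' @return a list with `cells` (data.frame: feature, context, domain, n_x,
#'   n_y, relative_effect, statistic, p, p_bh, significant_raw,
#'   significant_bh; untestable cells keep NA statistics) and `ks`
#'   (data.frame: feature, n_cells, ks_p).
#' @export
runComparisonGrid <- function(cohort, impairment, alpha = 0.05, minN = 5) {
  stopifnot(all(c("subject", "feature", "context", "value") %in% names(cohort)),
            all(c("subject", "domain", "impaired") %in% names(impairment)))
  feats <- unique(cohort$feature)
  ctxs <- unique(cohort$context)
  doms <- unique(impairment$domain)
  cells <- list()
  for (f in feats) for (cx in ctxs) for (dm in doms) {
    vals <- cohort[cohort$feature == f & cohort$context == cx, ]
    imp <- impairment[impairment$domain == dm, ]
    dat <- merge(vals, imp, by = "subject")
    dat <- dat[!is.na(dat$value) & !is.na(dat$impaired), ]
    x <- dat$value[dat$impaired]       # impaired group
    y <- dat$value[!dat$impaired]
    row <- data.frame(feature = f, context = cx, domain = dm,
                      n_x = length(x), n_y = length(y),
                      relative_effect = NA_real_, statistic = NA_real_,
                      p = NA_real_)
    if (length(x) >= minN && length(y) >= minN) {
      tr <- suppressWarnings(brunnerMunzel(x, y))
      row$relative_effect <- tr@relativeEffect
      row$statistic <- tr@statistic
      row$p <- tr@pValue
    }
    cells[[length(cells) + 1L]] <- row
  }
  cells <- do.call(rbind, cells)
  bh <- bhCorrect(cells$p, alpha)
  cells$p_bh <- bh$adjusted
  cells$significant_raw <- !is.na(cells$p) & cells$p < alpha
  cells$significant_bh <- bh$significant
  ks <- do.call(rbind, lapply(feats, function(f) {
    pv <- cells$p[cells$feature == f & !is.na(cells$p)]
    data.frame(feature = f, n_cells = length(pv),
               ks_p = if (length(pv) >= 5) ksUniform(pv) else NA_real_)
  }))
  list(cells = cells, ks = ks)
}
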