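test_that("domain impairment requires two tests at or below one SD under the norm", {
  mk <- function(z) data.frame(domain = "language",
                               test = paste0("t", seq_along(z)),
                               score = 100 + 15 * z, norm_mean = 100,
                               norm_sd = 15)
  expect_true(impairmentFlags(mk(c(-1.2, -1.5, 0.3)))$domains$impaired)
  expect_false(impairmentFlags(mk(c(-1.2, -0.9, -0.9)))$domains$impaired)
  expect_true(impairmentFlags(mk(c(-1, -1)))$domains$impaired)  # inclusive
  bad <- mk(c(-1, -1)); bad$norm_sd <- 0
  expect_error(impairmentFlags(bad), "norm_sd")
})

test_that("paired Wilcoxon matches exhaustive sign enumeration at n = 6", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 4.4)
  y <- c(0.8, 4.1, 1.1, 3.9, 1.5, 2.0)
  res <- pairedWilcoxon(x, y)
  d <- x - y
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  wNull <- vapply(0:63, function(m) {
    signs <- as.integer(intToBits(m))[1:6]
    sum(r[signs == 1])
  }, numeric(1))
  pExact <- min(1, 2 * min(mean(wNull <= w), mean(wNull >= w)))
  expect_equal(pValue(res), pExact)
  # consistent shift is detected
  set.seed(1)
  z <- rnorm(20)
  expect_lt(pValue(pairedWilcoxon(z + 1, z + rnorm(20, sd = 0.2))), 0.01)
  expect_error(pairedWilcoxon(z, z), "all differences are zero")
  expect_error(pairedWilcoxon(1:4, c(1, 2, 3, 5)), "at least 5")
})

test_that("relative effect from midranks equals the pairwise-count oracle", {
  set.seed(2)
  for (k in 1:25) {
    nx <- sample(5:9, 1); ny <- sample(5:9, 1)
    x <- sample(rep(rnorm(6), 2), nx)   # duplicates force ties
    y <- sample(rep(rnorm(6), 2), ny)
    res <- suppressWarnings(brunnerMunzel(x, y))
    oracle <- mean(outer(x, y, "<") + 0.5 * outer(x, y, "=="))
    expect_identical(relativeEffect(res), oracle)
  }
})

test_that("Brunner-Munzel handles symmetry, separation and small samples", {
  x <- c(1, 2, 3, 4, 5, 6)
  res <- brunnerMunzel(x, x)
  expect_equal(relativeEffect(res), 0.5)
  expect_equal(pValue(res), 1)
  expect_warning(resSep <- brunnerMunzel(x, x + 10), "separation")
  expect_equal(relativeEffect(resSep), 1)
  expect_true(is.na(pValue(resSep)))
  # permutation variant agrees in order of magnitude with the t-approximation
  set.seed(3)
  a <- rnorm(7); b <- rnorm(7) + 1.2
  pT <- pValue(brunnerMunzel(a, b))
  pPerm <- pValue(brunnerMunzel(a, b, method = "permutation"))
  expect_true(pPerm > 0 && pPerm <= 1)
  expect_lt(abs(log10(pPerm) - log10(pT)), 1)
  expect_error(brunnerMunzel(1:3, 1:6), "at least 5")
  expect_error(brunnerMunzel(rnorm(12), rnorm(12), method = "permutation"),
               "at most 10")
})

test_that("Benjamini-Hochberg step-up reproduces hand examples and is coherent", {
  out <- bhCorrect(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_identical(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(!bhCorrect(rep(1, 6))$significant))
  expect_true(bhCorrect(0.04)$significant)
  # never rejects more than raw alpha-level testing; monotone in alpha
  set.seed(4)
  for (k in 1:20) {
    p <- runif(30)^sample(1:3, 1)
    bh <- bhCorrect(p, 0.05)
    expect_true(sum(bh$significant) <= sum(p < 0.05))
    expect_true(all(bhCorrect(p, 0.01)$significant <= bh$significant))
    expect_true(all(bh$significant <= bhCorrect(p, 0.2)$significant))
  }
})

test_that("KS uniformity check flags skewed p-value sets and passes uniform ones", {
  expect_lt(ksUniform(rep(0.001, 20)), 1e-6)
  expect_error(ksUniform(numeric()), "at least 5")
  expect_error(ksUniform(c(0.5, 0.2, 1.3, 0.1, 0.4)), "lie in")
  hits <- vapply(1:100, function(s) {
    set.seed(s); ksUniform(runif(1000)) > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("comparison grid tests cells, corrects across the family, and skips small cells", {
  set.seed(5)
  n <- 30
  subjects <- sprintf("S%02d", 1:n)
  impairment <- rbind(
    data.frame(subject = subjects, domain = "language",
               impaired = rep(c(TRUE, FALSE), each = n / 2)),
    data.frame(subject = subjects, domain = "attention",
               impaired = c(rep(TRUE, 3), rep(FALSE, n - 3))))  # tiny group
  linked <- ifelse(impairment$impaired[impairment$domain == "language"],
                   rnorm(n, 0), rnorm(n, 1.5))
  cohort <- rbind(
    data.frame(subject = subjects, feature = "linked", context = "first",
               value = linked),
    data.frame(subject = subjects, feature = "noise", context = "first",
               value = rnorm(n)))
  g <- runComparisonGrid(cohort, impairment)
  expect_equal(nrow(g$cells), 4)      # 2 features x 1 context x 2 domains
  lang <- g$cells[g$cells$feature == "linked" &
                  g$cells$domain == "language", ]
  expect_lt(lang$p, 0.01)
  expect_gt(lang$relative_effect, 0.8)   # impaired values lower
  att <- g$cells[g$cells$domain == "attention", ]
  expect_true(all(is.na(att$p)))         # insufficient group size
  expect_true(all(g$cells$n_x[g$cells$domain == "attention"] == 3))
})

test_that("a cohort with no links yields almost no corrected rejections", {
  rejections <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 40
    subjects <- sprintf("S%02d", 1:n)
    impairment <- do.call(rbind, lapply(c("language", "memory"), function(d)
      data.frame(subject = subjects, domain = d,
                 impaired = sample(c(TRUE, FALSE), n, replace = TRUE))))
    cohort <- do.call(rbind, lapply(c("f1", "f2"), function(f)
      data.frame(subject = subjects, feature = f, context = "first",
                 value = rnorm(n))))
    sum(runComparisonGrid(cohort, impairment)$cells$significant_bh,
        na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(rejections > 0), 0.15)
})
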