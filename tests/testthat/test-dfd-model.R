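# Coefficients of the published two-variable logistic score, used here as a
# fixed parameterisation for closed-form checks.
ref_model <- function() dfd_model(c(-0.1228, 10.3044, -1.4177))

test_that("dfd_score evaluates the logistic formula in closed form", {
  m <- ref_model()
  expect_equal(dfd_score(m, 0, 0), plogis(-0.1228))
  expect_equal(dfd_score(m, 0, 0), 0.4693, tolerance = 1e-4)
  expect_equal(dfd_score(m, 1, 0), plogis(-0.1228 + 10.3044))
  expect_equal(dfd_score(m, 1, 0), 0.99996, tolerance = 1e-5)

  # monotone in each feature per coefficient sign, always in (0,1)
  ka <- seq(0, 2, by = 0.1)
  s <- dfd_score(m, ka, rep(0.5, length(ka)))
  expect_true(all(diff(s) > 0))
  re <- seq(-2, 2, by = 0.1)
  s2 <- dfd_score(m, rep(0.3, length(re)), re)
  expect_true(all(diff(s2) < 0))
  expect_true(all(s > 0 & s < 1) && all(s2 > 0 & s2 < 1))
})

test_that("fit_dfd recovers generating coefficients and rejects degenerate input", {
  dat <- simulate_lr_dataset(4000, beta = c(-0.5, 8, -1.2), seed = 101)
  m <- fit_dfd(dat)
  expect_true(m$converged)
  expect_true(all(abs(m$coef - c(-0.5, 8, -1.2)) < 3 * m$se))

  one_class <- data.frame(label = rep("high", 10), ka_ks = rnorm(10),
                          re_ks = rnorm(10))
  expect_error(fit_dfd(one_class), "each class")
})

test_that("perfect separation triggers the ridge fallback", {
  dat <- data.frame(
    label = rep(c("high", "low"), each = 20),
    ka_ks = c(rnorm(20, 5), rnorm(20, -5)),
    re_ks = rnorm(40)
  )
  m <- fit_dfd(dat)
  expect_true(m$ridge)
  expect_true(all(is.finite(m$coef)))
  expect_gt(m$coef["ka_ks"], 0)
})

test_that("threshold calibration uses linearly interpolated class percentiles", {
  scores <- seq(0.05, 1.00, by = 0.05)
  feats <- data.frame(
    label = rep("high", 20),
    x = qlogis(scores)
  )
  feats <- rbind(feats, data.frame(label = "low", x = qlogis(0.5)),
                 data.frame(label = "low", x = qlogis(0.6)))
  m <- dfd_model(c(0, 1), variables = "x")
  m <- calibrate_thresholds(m, feats)
  expect_equal(m$thr_low, 0.0975)  # 5th percentile of the 20 high scores
  expect_equal(m$thr_low, oracle_percentile(scores, 0.05))

  # perfectly separated classes invert the thresholds (5th percentile of the
  # highs above the 95th of the lows) and must be flagged
  sep <- data.frame(label = rep(c("high", "low"), each = 10),
                    x = rep(c(10, -10), each = 10))
  expect_warning(mb <- calibrate_thresholds(m, sep), "do not separate")
  expect_true(mb$non_separating)
  expect_gt(mb$thr_low, mb$thr_high)
})

test_that("three-way calls use strict threshold inequalities and partition the input", {
  m <- ref_model()
  m$thr_low <- 0.54
  # put thr_high exactly at the score of the fourth pair: a score equal to
  # the threshold must stay unclassified
  m$thr_high <- dfd_score(m, 0.25, 0)
  feats <- data.frame(
    pair = c("p1", "p2", "p3", "p4"),
    ka_ks = c(0.9, 0.02, 0.22, 0.25),
    re_ks = c(0, 0.5, 0.2, 0)
  )
  calls <- classify_pairs(m, feats)
  expect_equal(calls$call[1], "high")        # dfd ~ 0.9999
  expect_equal(calls$call[2], "low")         # dfd ~ 0.37
  expect_equal(calls$call[3], "unclassified")
  expect_equal(calls$call[4], "unclassified")
  cnt <- attr(calls, "counts")
  expect_equal(sum(cnt), nrow(feats))
  expect_error(classify_pairs(ref_model(), feats), "not calibrated")
})

test_that("ROC AUC equals the pairwise-comparison U statistic", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c("high", "high", "low", "low")), 1.0)
  expect_equal(roc_auc(rep(1, 10), rep(c("high", "low"), 5)), 0.5)

  set.seed(5)
  for (i in 1:20) {
    s <- sample(1:8, 12, replace = TRUE)  # ties included
    l <- sample(c("high", "low"), 12, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), oracle_auc(s, l), tolerance = 1e-12)
    # complement relation holds exactly on tie-free data
    sf <- rank(rnorm(12), ties.method = "first")
    expect_equal(roc_auc(sf, l), 1 - roc_auc(-sf, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("high", 3)), "both classes")

  # independent cross-check against an established ROC implementation
  set.seed(6)
  s <- rnorm(60)
  l <- sample(c("high", "low"), 60, replace = TRUE)
  expect_equal(
    roc_auc(s, l),
    as.numeric(pROC::auc(pROC::roc(l, s, levels = c("low", "high"),
                                   direction = "<", quiet = TRUE)))
  )
})

test_that("PR AUC behaves at the boundaries", {
  expect_equal(pr_auc(c(3, 4, 1, 2), c("high", "high", "low", "low")), 1.0)
  # uninformative scores give precision ~ prevalence
  set.seed(9)
  l <- rep(c("high", "low"), c(300, 700))
  s <- rnorm(1000)
  expect_equal(pr_auc(s, l), 0.3, tolerance = 0.08)
})

test_that("cross-validation is deterministic under a seed and handles 0 rounds", {
  dat <- simulate_features(120, 120, seed = 3)
  a <- cross_validate(dat, n_rounds = 5, seed = 42)
  b <- cross_validate(dat, n_rounds = 5, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a$rounds), 5L)
  expect_true(all(a$rounds$thr_low > 0 & a$rounds$thr_low < 1))
  expect_true(all(a$rounds$thr_high > 0 & a$rounds$thr_high < 1))

  empty <- cross_validate(dat, n_rounds = 0)
  expect_equal(nrow(empty$rounds), 0L)
})

test_that("deviance-drop importance ranks an informative variable above noise", {
  set.seed(13)
  n <- 600
  x <- rnorm(n)
  noise <- rnorm(n)
  lab <- ifelse(runif(n) < plogis(2.5 * x), "high", "low")
  dat <- data.frame(label = lab, signal = x, noise = noise)
  imp <- relative_importance(dat, c("noise", "signal"))
  expect_equal(imp$variable[1], "signal")
  expect_gt(imp$importance[1], imp$importance[2])

  # exact duplicates tie; deterministic order by name
  dat$signal2 <- dat$signal
  imp2 <- relative_importance(dat, c("signal2", "signal"))
  expect_equal(imp2$variable, sort(imp2$variable))
})

test_that("single-variable models score a separating feature at AUC 1 and noise at 0.5", {
  set.seed(17)
  n <- 400
  lab <- rep(c("high", "low"), each = n / 2)
  dat <- data.frame(
    label = lab,
    perfect = ifelse(lab == "high", rnorm(n, 10), rnorm(n, -10)),
    noise = rnorm(n)
  )
  tab <- single_variable_models(dat, c("perfect", "noise"))
  expect_equal(tab$roc_auc[tab$variable == "perfect"], 1.0)
  expect_equal(tab$roc_auc[tab$variable == "noise"], 0.5, tolerance = 0.08)
})

test_that("model files round-trip through the plain-text format", {
  m <- ref_model()
  m$thr_low <- 0.54
  m$thr_high <- 0.91
  m$n <- 574L
  f <- tempfile(fileext = ".txt")
  write_dfd_model(m, f)
  m2 <- read_dfd_model(f)
  expect_equal(m2$coef, m$coef)
  expect_equal(m2$thr_low, m$thr_low)
  expect_equal(m2$thr_high, m$thr_high)
  expect_equal(m2$n, m$n)
})
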