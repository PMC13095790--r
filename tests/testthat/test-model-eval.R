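test_that("AUC equals the all-pairs Mann-Whitney count", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  set.seed(91)
  for (i in 1:15) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    outcomes <- rbinom(n, 1, 0.4)
    if (sum(outcomes) %in% c(0, n)) next
    expect_equal(roc_auc(scores, outcomes), auc_bruteforce(scores, outcomes))
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(qlogis(pmin(pmax(scores, 1e-3), 1 - 1e-3)), outcomes),
                 roc_auc(pmin(pmax(scores, 1e-3), 1 - 1e-3), outcomes))
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "non-event")
})

test_that("Brier score reproduces its closed forms", {
  y <- c(1, 0, 1, 1, 0)
  expect_equal(brier_score(y, y), 0)
  expect_equal(brier_score(rep(0.5, 5), y), 0.25)
  set.seed(92)
  p <- runif(50)
  yy <- rbinom(50, 1, 0.5)
  expect_lte(brier_score(p, yy), 1)
  expect_equal(brier_score(p, yy), mean((p - yy)^2))
})

test_that("Wilson interval matches the closed form and contains p-hat", {
  ci <- wilson_interval(5, 10)
  expect_equal(unname(ci["lo"]), 0.2366, tolerance = 1e-4)
  expect_equal(unname(ci["hi"]), 0.7634, tolerance = 1e-4)
  expect_equal(unname(wilson_interval(0, 7)["lo"]), 0)
  set.seed(93)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    e <- sample(0:n, 1)
    ci <- wilson_interval(e, n)
    # independent closed form
    z <- qnorm(0.975)
    p <- e / n
    lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n)
    hi <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n)
    expect_equal(unname(ci), c(max(0, lo), min(1, hi)), tolerance = 1e-12)
    expect_true(ci["lo"] <= p && p <= ci["hi"])
    expect_true(ci["lo"] >= 0 && ci["hi"] <= 1)
  }
})

test_that("bootstrap intervals are percentile order statistics and reproducible", {
  coh <- make_fit_cohort(60, seed = 11)
  fit_fn <- function(sub) c(rate = mean(sub$outcomes))
  b1 <- bootstrap_ci(coh, fit_fn, n_boot = 200, seed = 5)
  b2 <- bootstrap_ci(coh, fit_fn, n_boot = 200, seed = 5)
  expect_identical(b1$estimates, b2$estimates)
  expect_equal(b1$ci$lo, unname(quantile(b1$estimates[, 1], 0.025)))
  expect_equal(b1$ci$hi, unname(quantile(b1$estimates[, 1], 0.975)))

  # identical records: zero-width intervals
  dvh <- differential_dvh(c(1, 2), c(0.5, 0.5))
  # mix of identical patients but both classes present so resampling is
  # non-degenerate in expectation; statistic on a constant covariate
  const_fn <- function(sub) c(g = cohort_geud(sub, 2)[1])
  coh2 <- lkb_cohort(rep(list(dvh), 12), rep(c(0, 1), 6))
  b3 <- bootstrap_ci(coh2, const_fn, n_boot = 50, seed = 1)
  expect_equal(b3$ci$lo, b3$ci$hi)
})

test_that("stratified folds partition the cohort with exact class balance", {
  coh <- make_fit_cohort(120, seed = 23)
  # force exactly 40 events in 100 patients for the exact-balance check
  out <- c(rep(1L, 40), rep(0L, 60))
  dvhs <- coh$dvhs[1:100]
  coh100 <- lkb_cohort(dvhs, out)
  fast_fit <- function(train) {
    function(test) cohort_geud(test, 2)  # score by gEUD, no refit
  }
  cv <- stratified_kfold_cv(coh100, k = 5, fit_fn = fast_fit, seed = 31)
  all_idx <- sort(unname(unlist(cv$folds)))
  expect_identical(all_idx, 1:100)
  for (f in cv$folds) {
    expect_equal(sum(out[f]), 8)
    expect_equal(length(f), 20)
  }
  expect_equal(cv$mean_auc, mean(cv$fold_auc))

  # reproducibility
  cv2 <- stratified_kfold_cv(coh100, k = 5, fit_fn = fast_fit, seed = 31)
  expect_identical(cv$folds, cv2$folds)
  expect_error(stratified_kfold_cv(lkb_cohort(dvhs[1:8],
                                              c(1, 1, 1, 0, 0, 0, 0, 0)),
                                   k = 5, fit_fn = fast_fit), "at least k")
})

test_that("chi-square GOF bins by mean dose and is zero for perfect agreement", {
  # bin sizes for n = 94 and 5 bins
  expect_equal(lymphodose:::equal_count_sizes(94, 5), c(19, 19, 19, 19, 18))
  expect_equal(sum(lymphodose:::equal_count_sizes(94, 5)), 94)

  # a cohort whose outcomes match predictions bin-by-bin gives chi2 = 0:
  # identical DVH pairs with one event and one non-event and p = 0.5
  dvh_list <- lapply(seq(1, 10), function(d) differential_dvh(d, 1))
  dvhs <- rep(dvh_list, each = 2)
  outcomes <- rep(c(1, 0), 10)
  coh <- lkb_cohort(dvhs, outcomes)
  params <- lkb_params(5.5, 10, 1)  # nearly flat: p close to 0.5 everywhere
  g <- chisq_gof(coh, lkb_params(5.5, 1e6 / 5.5, 1), n_bins = 5)
  # with m enormous every p is exactly 0.5 -> E = O in every bin of size 4
  expect_equal(g$chi2, 0, tolerance = 1e-6)
  expect_equal(g$df, 2)
  expect_equal(sum(g$binning$n), 20)

  # ordering invariance within the cohort
  coh_perm <- cohort_subset(coh, sample(20))
  g2 <- chisq_gof(coh_perm, lkb_params(5.5, 1e6 / 5.5, 1), n_bins = 5)
  expect_equal(g2$chi2, g$chi2, tolerance = 1e-9)
})

test_that("lowess reproduces exact local-linear cases and the reference fit", {
  x <- seq(0, 10, length.out = 40)
  sm <- lowess_smooth(x, 2 * x)
  expect_equal(sm$y, 2 * sm$x, tolerance = 1e-8)
  smc <- lowess_smooth(x, rep(3, 40))
  expect_equal(smc$y, rep(3, 40), tolerance = 1e-12)

  set.seed(101)
  xr <- runif(80, 0, 5)
  yr <- sin(xr) + rnorm(80, 0, 0.3)
  mine <- lowess_smooth(xr, yr, frac = 2 / 3, robust_iters = 3)
  ref <- stats::lowess(xr, yr, f = 2 / 3, iter = 3, delta = 0)
  expect_equal(mine$x, ref$x)
  expect_equal(mine$y, ref$y, tolerance = 1e-6)
})

test_that("calibration report recovers slope 1 / intercept 0 on calibrated data", {
  set.seed(111)
  n <- 2000
  p <- plogis(rnorm(n, -0.5, 1.2))
  y <- rbinom(n, 1, p)
  rep <- calibration_report(p, y)
  expect_lt(abs(rep$slope - 1), 0.15)
  expect_lt(abs(rep$intercept), 0.15)
  expect_equal(sum(rep$bins$n), n)
  expect_equal(rep$prevalence, mean(y))
  expect_true(all(rep$bins$wilson_lo >= 0 & rep$bins$wilson_hi <= 1))
  expect_true(rep$brier >= 0 && rep$brier <= 1)
  expect_true(rep$auc >= 0 && rep$auc <= 1)

  # a known logit shift is recovered in the intercept
  c_shift <- 0.8
  p_shift <- plogis(qlogis(p) + c_shift)
  rep2 <- calibration_report(p_shift, y)
  expect_lt(abs(rep2$slope - 1), 0.15)
  expect_lt(abs(rep2$intercept + c_shift), 0.2)
})

test_that("calibration errors on single-class outcomes and merges sparse bins", {
  expect_error(calibration_report(runif(20), rep(1, 20)), "both outcome")
  # heavy ties in predictions: bins still partition the cohort
  set.seed(121)
  p <- rep(c(0.2, 0.4, 0.6), length.out = 30)
  y <- rbinom(30, 1, p)
  if (sum(y) %in% c(0, 30)) y[1:2] <- c(0, 1)
  rep <- calibration_report(p, y, n_bins = 10)
  expect_equal(sum(rep$bins$n), 30)
})

test_that("external validation transfers frozen parameters", {
  truth <- truth_spec(lkb = lkb_params(7.44, 0.42, 2))
  coh <- make_fit_cohort(200, truth = truth, seed = 41)
  fit <- fit_lkb(coh)
  rep_self <- external_validate(fit, coh)
  probs <- ntcp_probit(cohort_geud(coh, fit$params$a), fit$params)
  expect_equal(rep_self$auc, roc_auc(probs, coh$outcomes))
  expect_equal(rep_self$brier, brier_score(probs, coh$outcomes))
  expect_equal(rep_self$prevalence, mean(coh$outcomes))

  # target generated from a shifted D50: miscalibration shows up as slope != 1
  shifted <- truth_spec(lkb = lkb_params(7.44 * 0.6, 0.42, 2))
  target <- make_fit_cohort(500, truth = shifted, seed = 43)
  rep_shift <- external_validate(fit, target)
  expect_equal(rep_shift$prevalence, mean(target$outcomes))
  expect_gt(abs(rep_shift$slope - 1), 0.2)
})
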