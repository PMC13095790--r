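#' Area under the ROC curve
#'
#' Mann-Whitney probability form: the probability that a randomly chosen
#' event outranks a randomly chosen non-event, with ties given half credit.
#' Equals trapezoidal integration of the empirical ROC curve, and is
#' invariant under any strictly increasing transform of the scores.
#'
#' @param scores Numeric risk scores (higher = more likely event).
#' @param outcomes Binary 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, outcomes) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(scores) == length(outcomes),
            all(outcomes %in% c(0L, 1L)))
  n1 <- sum(outcomes)
  n0 <- length(outcomes) - n1
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires at least one event and one non-event")
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; 0 is perfect, 0.25 is an uninformative constant 0.5.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param outcomes Binary 0/1 outcomes.
#' @return Brier score in `[0, 1]`.
#' @export
brier_score <- function(probs, outcomes) {
  stopifnot(length(probs) == length(outcomes),
            all(probs >= 0 & probs <= 1))
  mean((probs - as.numeric(outcomes))^2)
}

#' Wilson score interval for a binomial proportion
#'
#' @param events Number of events, `0 <= events <= n`.
#' @param n Number of trials, `> 0`.
#' @param level Confidence level (default 0.95); the normal quantile is
#'   used exactly, not rounded to 1.96.
#' @return Named numeric `c(lo, hi)`, contained in `[0, 1]` and always
#'   containing `events/n`.
#' @export
wilson_interval <- function(events, n, level = 0.95) {
  stopifnot(n > 0, events >= 0, events <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- events / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

# equal-count partition: n into n_bins sizes differing by <= 1, larger
# bins first (n = 94, 5 bins -> 19 19 19 19 18)
equal_count_sizes <- function(n, n_bins) {
  base <- n %/% n_bins
  extra <- n %% n_bins
  rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
}

#' Bootstrap percentile confidence intervals for fitted parameters
#'
#' Patient-level resampling with replacement; `fit_fn` is refit on each
#' resample and percentile intervals are taken per parameter. Resamples
#' containing a single outcome class are redrawn (and counted); more than
#' 50% degenerate draws aborts.
#'
#' @param cohort An [lkb_cohort()] (or any object supported by
#'   [cohort_subset()]).
#' @param fit_fn Function taking a resampled cohort, returning a named
#'   numeric vector of parameter estimates.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List with `ci` (data frame: parameter, lo, hi), `estimates`
#'   (matrix of resample estimates) and `n_degenerate`.
#' @export
bootstrap_ci <- function(cohort, fit_fn, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  n <- cohort$n
  out <- cohort$outcomes
  with_seed(seed, {
    n_degenerate <- 0L
    est <- NULL
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        s <- sum(out[idx])
        if (s > 0L && s < n) break
        n_degenerate <- n_degenerate + 1L
        if (n_degenerate > n_boot / 2)
          stop("more than 50% of bootstrap resamples were degenerate")
      }
      th <- fit_fn(cohort_subset(cohort, idx))
      if (is.null(est)) est <- matrix(NA_real_, n_boot, length(th),
                                      dimnames = list(NULL, names(th)))
      est[b, ] <- th
    }
    alpha <- (1 - level) / 2
    ci <- data.frame(
      parameter = colnames(est),
      lo = apply(est, 2, stats::quantile, probs = alpha, names = FALSE),
      hi = apply(est, 2, stats::quantile, probs = 1 - alpha, names = FALSE),
      row.names = NULL
    )
    list(ci = ci, estimates = est, n_degenerate = n_degenerate)
  })
}

#' Subset an LKB cohort by patient index
#'
#' @param cohort An [lkb_cohort()].
#' @param idx Integer indices (duplicates allowed, e.g. bootstrap draws).
#' @return An [lkb_cohort()] restricted to `idx`.
#' @export
cohort_subset <- function(cohort, idx) {
  stopifnot(inherits(cohort, "lkb_cohort"))
  structure(
    list(dvhs = cohort$dvhs[idx],
         outcomes = cohort$outcomes[idx],
         log_v = cohort$log_v[idx],
         log_d = cohort$log_d[idx],
         n = length(idx),
         grid = if (!is.null(cohort$grid))
           list(la = cohort$grid$la,
                G = cohort$grid$G[idx, , drop = FALSE])),
    class = "lkb_cohort"
  )
}

# bootstrap CIs for an LKB fit: warm-started single-start refits over the
# cohort's precomputed gEUD grid (subset per resample)
bootstrap_lkb <- function(cohort, fit, n_boot = 1000, level = 0.95,
                          seed = 1L) {
  if (is.null(cohort$grid)) cohort$grid <- geud_grid(cohort)
  a_fixed <- fit$a_fixed
  fit_fn <- function(sub) {
    r <- refit_lkb_warm(sub, fit$params, a_fixed = a_fixed)
    c(d50 = r$params$d50, m = r$params$m, a = r$params$a)
  }
  res <- bootstrap_ci(cohort, fit_fn, n_boot = n_boot, level = level,
                      seed = seed)
  list(ci = res$ci, n_degenerate = res$n_degenerate)
}

#' Stratified k-fold cross-validation of an NTCP model
#'
#' Outcome-stratified folds (event counts per fold differ by at most one),
#' model refit on each training split and AUC evaluated on the held-out
#' split.
#'
#' @param cohort An [lkb_cohort()].
#' @param k Number of folds (default 5); each class must have `>= k`
#'   members.
#' @param fit_fn Function taking a training [lkb_cohort()] and returning a
#'   prediction function `function(test_cohort) -> probs`. The default
#'   refits all three LKB parameters with [fit_lkb()].
#' @param seed Integer seed (fold shuffling).
#' @return List with `fold_auc`, `mean_auc`, and `folds` (list of test
#'   index vectors partitioning the cohort).
#' @export
stratified_kfold_cv <- function(cohort, k = 5, fit_fn = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "lkb_cohort"))
  out <- cohort$outcomes
  if (min(sum(out), sum(1 - out)) < k)
    stop("each outcome class needs at least k members")
  if (is.null(fit_fn)) {
    fit_fn <- function(train) {
      f <- fit_lkb(train)
      function(test) ntcp_probit(cohort_geud(test, f$params$a), f$params)
    }
  }
  folds <- with_seed(seed, {
    fold_of <- integer(cohort$n)
    for (cls in c(0L, 1L)) {
      idx <- sample(which(out == cls))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    split(seq_len(cohort$n), fold_of)
  })
  fold_auc <- vapply(folds, function(test_idx) {
    train <- cohort_subset(cohort, setdiff(seq_len(cohort$n), test_idx))
    test <- cohort_subset(cohort, test_idx)
    roc_auc(fit_fn(train)(test), test$outcomes)
  }, numeric(1))
  list(fold_auc = unname(fold_auc), mean_auc = mean(fold_auc), folds = folds)
}

#' Chi-square goodness of fit on mean-blood-dose bins
#'
#' Patients are sorted by mean blood dose and split into equal-count bins
#' (sizes differing by at most one, larger bins at the low-dose end of the
#' sort order). Per bin, the observed event rate `o_k = O_k / n_k` is
#' compared with the mean predicted NTCP `e_k = E_k / n_k` via the Pearson
#' statistic on rates, `sum (o_k - e_k)^2 / e_k`, referred to a chi-square
#' with `n_bins - 3` degrees of freedom (three fitted model parameters).
#' For a well-calibrated model on ~100 patients this statistic sits close
#' to zero (of order `(1 - e) / n_k` per bin) with p near 1 — a value near
#' zero indicates good agreement. The raw per-bin observed/expected count
#' table is always returned so alternative statistics can be recomputed.
#' Bins whose expected count hits 0 or `n_k` are clipped to 0.5 events from
#' the boundary, with a warning.
#'
#' @param cohort An [lkb_cohort()] of size `>= 2 * n_bins`.
#' @param params An [lkb_params()] to evaluate.
#' @param n_bins Number of bins (default 5).
#' @return List with `chi2`, `p`, `df` and `binning` (data frame: per-bin
#'   `n`, `observed`, `expected`, `mean_dose`).
#' @export
chisq_gof <- function(cohort, params, n_bins = 5) {
  stopifnot(inherits(cohort, "lkb_cohort"), inherits(params, "lkb_params"))
  if (cohort$n < 2 * n_bins)
    stop("cohort must have at least 2 * n_bins patients")
  md <- vapply(cohort$dvhs, mean_dose, numeric(1))
  p <- ntcp_probit(cohort_geud(cohort, params$a), params)
  ord <- order(md)
  sizes <- equal_count_sizes(cohort$n, n_bins)
  bin_id <- factor(rep(seq_len(n_bins), sizes), levels = seq_len(n_bins))
  O <- tapply(cohort$outcomes[ord], bin_id, sum)
  E <- tapply(p[ord], bin_id, sum)
  nk <- as.numeric(sizes)
  clip <- E <= 0 | E >= nk
  if (any(clip)) {
    warning("expected counts at 0 or n in ", sum(clip), " bin(s); clipped")
    E <- pmin(pmax(E, 0.5), nk - 0.5)
  }
  chi2 <- sum((O / nk - E / nk)^2 / (E / nk))
  df <- n_bins - 3
  list(
    chi2 = unname(chi2),
    p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
    df = df,
    binning = data.frame(
      bin = seq_len(n_bins), n = sizes,
      observed = as.numeric(O), expected = as.numeric(E),
      mean_dose = as.numeric(tapply(md[ord], bin_id, mean))
    )
  )
}

#' LOWESS scatterplot smoother
#'
#' Cleveland's locally weighted regression: at each point, a linear fit
#' weighted by the tricube kernel over the nearest `frac * n` neighbours,
#' followed by bisquare robustness reweighting. This is the flexible curve
#' used in calibration plots.
#'
#' @param x,y Numeric vectors, `>= 5` points.
#' @param frac Neighbourhood fraction (default `2/3`).
#' @param robust_iters Robustness iterations (default 3).
#' @return List with sorted `x` and smoothed `y`.
#' @export
lowess_smooth <- function(x, y, frac = 2 / 3, robust_iters = 3) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  ord <- order(x)
  xs <- as.numeric(x[ord])
  yo <- as.numeric(y[ord])
  n <- length(xs)
  ns <- max(2L, min(n, as.integer(floor(frac * n + 1e-7))))
  rng <- xs[n] - xs[1]
  rw <- rep(1, n)
  fitted <- numeric(n)
  for (it in 0:robust_iters) {
    nleft <- 1L
    nright <- ns
    for (i in seq_len(n)) {
      while (nright < n && xs[nright + 1] - xs[i] < xs[i] - xs[nleft]) {
        nleft <- nleft + 1L
        nright <- nright + 1L
      }
      fitted[i] <- lowess_fit_one(xs, yo, i, nleft, nright, rw,
                                  userw = it > 0, rng = rng)
    }
    if (it == robust_iters) break
    res <- yo - fitted
    cmad <- 6 * stats::median(abs(res))
    if (cmad <= 1e-12 * (max(abs(yo)) + 1)) break  # essentially exact fit
    c1 <- 0.001 * cmad
    c9 <- 0.999 * cmad
    ar <- abs(res)
    rw <- ifelse(ar <= c1, 1,
                 ifelse(ar >= c9, 0, (1 - (ar / cmad)^2)^2))
  }
  list(x = xs, y = fitted)
}

# one local weighted-linear evaluation at x[i] over window [nleft, nright]
lowess_fit_one <- function(x, y, i, nleft, nright, rw, userw, rng) {
  n <- length(x)
  xsi <- x[i]
  h <- max(xsi - x[nleft], x[nright] - xsi)
  h9 <- 0.999 * h
  h1 <- 0.001 * h
  w <- numeric(n)
  a <- 0
  j <- nleft
  while (j <= n) {
    r <- abs(x[j] - xsi)
    if (r <= h9) {
      w[j] <- if (r > h1) (1 - (r / h)^3)^3 else 1
      if (userw) w[j] <- w[j] * rw[j]
      a <- a + w[j]
    } else if (x[j] > xsi) break
    j <- j + 1L
  }
  if (a <= 0) return(y[i])
  w <- w / a
  if (h > 0) {
    ac <- sum(w * x)
    b <- xsi - ac
    cc <- sum(w * (x - ac)^2)
    if (sqrt(cc) > 0.001 * rng) {
      b <- b / cc
      w <- w * (b * (x - ac) + 1)
    }
  }
  sum(w * y)
}

#' Calibration analysis of predicted probabilities
#'
#' Equal-count prediction bins (deciles by default) with Wilson 95%
#' intervals on the observed event rate, a LOWESS curve of outcome against
#' prediction, and the calibration slope and intercept from a logistic fit
#' of outcomes on the logit-transformed predictions (slope 1, intercept 0
#' indicate perfect calibration). Bins containing fewer than two distinct
#' predicted values are merged with their neighbour.
#'
#' @param probs Predicted probabilities; clipped to `[1e-6, 1 - 1e-6]` for
#'   the logit transform.
#' @param outcomes Binary 0/1 outcomes (both classes required).
#' @param n_bins Number of prediction bins (default 10).
#' @param level Confidence level for the Wilson intervals (default 0.95).
#' @param lowess_frac Neighbourhood fraction for the LOWESS curve.
#' @return An object of class `calibration_report`: list with `bins`
#'   (data frame `n, observed_rate, wilson_lo, wilson_hi, mean_predicted`),
#'   `lowess_curve`, `slope`, `intercept`, `brier`, `auc`, `prevalence`.
#' @export
calibration_report <- function(probs, outcomes, n_bins = 10, level = 0.95,
                               lowess_frac = 2 / 3) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(probs) == length(outcomes),
            all(outcomes %in% c(0L, 1L)))
  if (sum(outcomes) == 0L || sum(outcomes) == length(outcomes))
    stop("calibration requires both outcome classes")
  n <- length(probs)
  pc <- pmin(pmax(probs, 1e-6), 1 - 1e-6)
  ord <- order(pc)
  n_bins <- min(n_bins, n %/% 2)
  sizes <- equal_count_sizes(n, n_bins)
  bin_id <- rep(seq_len(n_bins), sizes)

  # merge bins with < 2 distinct predictions into their right neighbour
  # (left neighbour for the last bin)
  repeat {
    nb <- max(bin_id)
    fb <- factor(bin_id, levels = seq_len(nb))
    distinct <- tapply(pc[ord], fb, function(z) length(unique(z)))
    bad <- which(distinct < 2)
    if (!length(bad) || nb == 1L) break
    b <- bad[1]
    target <- if (b < nb) b + 1L else b - 1L
    bin_id[bin_id == b] <- target
    bin_id <- match(bin_id, sort(unique(bin_id)))  # relabel 1..nb-1
  }
  fb <- factor(bin_id, levels = sort(unique(bin_id)))
  ob <- tapply(outcomes[ord], fb, sum)
  nk <- tapply(rep(1L, n), fb, sum)
  wi <- t(mapply(function(e, m) wilson_interval(e, m, level), ob, nk))
  bins <- data.frame(
    n = as.integer(nk),
    observed_rate = as.numeric(ob / nk),
    wilson_lo = as.numeric(wi[, "lo"]),
    wilson_hi = as.numeric(wi[, "hi"]),
    mean_predicted = as.numeric(tapply(pc[ord], fb, mean)),
    row.names = NULL
  )
  lg <- log(pc / (1 - pc))
  fit <- stats::glm(outcomes ~ lg, family = stats::binomial())
  structure(
    list(bins = bins,
         lowess_curve = lowess_smooth(pc, outcomes, frac = lowess_frac),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         brier = brier_score(probs, outcomes),
         auc = roc_auc(probs, outcomes),
         prevalence = mean(outcomes)),
    class = "calibration_report"
  )
}

#' External validation of a frozen LKB fit on a new cohort
#'
#' Applies the fitted parameters (including the volume-effect exponent)
#' unchanged to the target cohort's blood DVHs and returns the full
#' calibration report — the cross-modality transfer analysis when the fit
#' comes from one treatment modality and the target cohort from another.
#'
#' @param fit An `lkb_fit` (from [fit_lkb()] or [fit_lkb_fixed_a()]).
#' @param target_cohort An [lkb_cohort()] with blood DVHs and outcomes.
#' @param n_bins Prediction bins for the calibration report.
#' @return A [calibration_report()].
#' @export
external_validate <- function(fit, target_cohort, n_bins = 10) {
  stopifnot(inherits(fit, "lkb_fit"), inherits(target_cohort, "lkb_cohort"))
  probs <- ntcp_probit(cohort_geud(target_cohort, fit$params$a), fit$params)
  calibration_report(probs, target_cohort$outcomes, n_bins = n_bins)
}
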