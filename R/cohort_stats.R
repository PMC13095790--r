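#' CTCAE v5.0 lymphopenia grade from an absolute lymphocyte count
#'
#' Grade 0 for ALC >= 1000 cells/uL, grade 1 for 800 to < 1000, grade 2 for
#' 500 to < 800, grade 3 for 200 to < 500, grade 4 for < 200. Severe
#' radiation-induced lymphopenia (SRIL) is grade >= 3, i.e. ALC < 500.
#'
#' @param alc Absolute lymphocyte count(s) in cells/uL, `>= 0`.
#' @return Integer grade(s) 0-4.
#' @export
grade_ril <- function(alc) {
  if (anyNA(alc) || any(alc < 0)) stop("ALC must be non-negative")
  g <- integer(length(alc))
  g[alc < 1000] <- 1L
  g[alc < 800] <- 2L
  g[alc < 500] <- 3L
  g[alc < 200] <- 4L
  g
}

#' Is a lymphopenia grade severe (SRIL)?
#'
#' @param grade Integer grade(s) 0-4.
#' @return Logical; `TRUE` for grade >= 3 (ALC < 500 cells/uL).
#' @export
is_sril <- function(grade) grade >= 3L

#' SRIL incidence from a grade count table
#'
#' @param grade_counts Data frame with columns `grade` (0-4) and `n`
#'   (patient counts), e.g. one modality's rows of the grade table shipped
#'   in `extdata/lung_ril_grade_counts.csv`.
#' @return Incidence of grade >= 3 lymphopenia as a percentage.
#' @export
sril_incidence_from_grades <- function(grade_counts) {
  stopifnot(all(c("grade", "n") %in% names(grade_counts)))
  100 * sum(grade_counts$n[grade_counts$grade >= 3]) / sum(grade_counts$n)
}

#' Cohort summary
#'
#' Event counts, SRIL incidence, the lymphopenia grade table and
#' median/IQR summaries of requested numeric variables.
#'
#' @param patients Data frame with one row per patient, containing at least
#'   `sril` (0/1) and `ril_grade` (0-4).
#' @param summarize Character vector of numeric column names to summarize
#'   as median (IQR).
#' @return List with `n`, `events`, `sril_incidence_percent`,
#'   `grade_table` (data frame grade/n) and `variables` (data frame of
#'   median/q25/q75).
#' @export
cohort_summary <- function(patients, summarize = character()) {
  stopifnot(is.data.frame(patients), nrow(patients) > 0,
            all(c("sril", "ril_grade") %in% names(patients)))
  grades <- factor(patients$ril_grade, levels = 0:4)
  vars <- NULL
  if (length(summarize)) {
    qs <- t(vapply(summarize, function(v)
      stats::quantile(patients[[v]], c(0.5, 0.25, 0.75), na.rm = TRUE,
                      names = FALSE),
      numeric(3)))
    vars <- data.frame(variable = summarize, median = qs[, 1],
                       q25 = qs[, 2], q75 = qs[, 3], row.names = NULL)
  }
  list(
    n = nrow(patients),
    events = sum(patients$sril),
    sril_incidence_percent = 100 * mean(patients$sril),
    grade_table = data.frame(grade = 0:4, n = as.integer(table(grades))),
    variables = vars
  )
}

#' Exponential decay fit of cohort-mean ALC trajectories
#'
#' Pools all trajectories, bins measurements into weekly bins, and fits
#' `log(mean ALC per bin)` against the mean day per bin by least squares.
#' The decay rate is minus the slope; the half-time is `ln 2 / lambda`.
#' Non-positive ALC values cannot enter the log fit and are excluded with
#' a warning.
#'
#' @param trajectories A list of data frames with columns `day` and `alc`,
#'   or a single long data frame with those columns.
#' @param window Optional numeric `c(min_day, max_day)` restricting the
#'   fit.
#' @return An object of class `alc_decay_fit`: list with `lambda_per_day`,
#'   `half_time_days`, `fit_rmse` (on the log scale), `n_points` and
#'   `bins` (data frame day/mean_alc).
#' @export
fit_alc_decay <- function(trajectories, window = NULL) {
  df <- if (is.data.frame(trajectories)) trajectories
        else do.call(rbind, lapply(trajectories, function(t)
          data.frame(day = t$day, alc = t$alc)))
  stopifnot(all(c("day", "alc") %in% names(df)))
  if (!is.null(window)) df <- df[df$day >= window[1] & df$day <= window[2], ]
  if (any(df$alc <= 0)) {
    warning("excluding ", sum(df$alc <= 0), " non-positive ALC value(s)")
    df <- df[df$alc > 0, ]
  }
  if (nrow(df) < 2) stop("need at least two time points")
  week <- floor(df$day / 7)
  fw <- factor(week, levels = sort(unique(week)))
  mean_alc <- as.numeric(tapply(df$alc, fw, mean))
  mean_day <- as.numeric(tapply(df$day, fw, mean))
  if (length(mean_alc) < 2) stop("need at least two time bins")
  fit <- stats::lm(log(mean_alc) ~ mean_day)
  lambda <- -unname(stats::coef(fit)[2])
  structure(
    list(lambda_per_day = lambda,
         half_time_days = log(2) / lambda,
         fit_rmse = sqrt(mean(stats::residuals(fit)^2)),
         n_points = nrow(df),
         bins = data.frame(day = mean_day, mean_alc = mean_alc)),
    class = "alc_decay_fit"
  )
}

#' Logistic regression with odds ratios and Wald intervals
#'
#' IRLS fit (via `stats::glm`) of a binary outcome on a design matrix;
#' reports coefficients, standard errors, Wald p-values and odds ratios
#' with symmetric 95% Wald confidence intervals. Complete or
#' quasi-complete separation is flagged and the estimates marked unusable
#' rather than returned as finite-looking numbers.
#'
#' @param x Design matrix or data frame of covariates (no intercept
#'   column; one is added).
#' @param y Binary 0/1 outcomes.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol IRLS convergence tolerance (default `1e-10`).
#' @param level Confidence level for the OR intervals (default 0.95).
#' @return List with `coefficients` (data frame: term, estimate, se, z, p,
#'   or, or_lo, or_hi), `converged`, `separation`.
#' @export
logistic_fit <- function(x, y, max_iter = 100, tol = 1e-10, level = 0.95) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  df <- if (is.null(x) || (!is.null(dim(x)) && ncol(as.data.frame(x)) == 0))
    data.frame(.y = y) else cbind(data.frame(.y = y), as.data.frame(x))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(maxit = max_iter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  se <- sm[, "Std. Error"]
  est <- sm[, "Estimate"]
  if (any(se > 100) || any(abs(est) > 15)) sep <- TRUE
  z <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- data.frame(
    term = rownames(sm),
    estimate = est,
    se = se,
    z = sm[, "z value"],
    p = sm[, "Pr(>|z|)"],
    or = exp(est),
    or_lo = exp(est - z * se),
    or_hi = exp(est + z * se),
    row.names = NULL
  )
  list(coefficients = coefs, converged = fit$converged && !sep,
       separation = sep)
}

#' Median dichotomization of a continuous variable
#'
#' Values at or above the threshold (the sample median by default) map to
#' 1 ("high"); the median itself belongs to the high group, matching the
#' ">= median vs. < median" grouping convention.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param threshold Split point (default `median(values)`).
#' @return Integer 0/1 vector.
#' @export
dichotomize <- function(values, threshold = stats::median(values)) {
  if (length(unique(values)) < 2)
    stop("cannot dichotomize a constant variable")
  as.integer(values >= threshold)
}

#' Bonferroni adjustment
#'
#' @param p_values P-values in `[0, 1]`.
#' @param k Number of comparisons.
#' @return `min(1, k * p)` elementwise.
#' @export
bonferroni <- function(p_values, k) {
  stopifnot(all(p_values >= 0 & p_values <= 1), k >= 1)
  pmin(1, k * p_values)
}

#' One-way ANOVA of mean blood dose across lymphopenia grade groups
#'
#' Grades are grouped as <=1, 2, 3 and 4 (the grouping used when testing
#' whether mean blood dose differs across severity levels).
#'
#' @param mean_blood_doses Numeric vector of per-patient mean blood doses.
#' @param grades Integer lymphopenia grades 0-4, same length.
#' @return List with `F`, `p`, `df_between`, `df_within`, `group_means`.
#' @export
anova_by_grade <- function(mean_blood_doses, grades) {
  stopifnot(length(mean_blood_doses) == length(grades),
            all(grades %in% 0:4))
  grp <- factor(ifelse(grades <= 1, "<=1", as.character(grades)),
                levels = c("<=1", "2", "3", "4"))
  grp <- droplevels(grp)
  if (nlevels(grp) < 2) stop("need at least two grade groups")
  if (max(table(grp)) < 2) stop("at least one group needs >= 2 members")
  fit <- stats::aov(mean_blood_doses ~ grp)
  sm <- summary(fit)[[1]]
  list(
    F = sm[["F value"]][1],
    p = sm[["Pr(>F)"]][1],
    df_between = sm[["Df"]][1],
    df_within = sm[["Df"]][2],
    group_means = tapply(mean_blood_doses, grp, mean)
  )
}
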