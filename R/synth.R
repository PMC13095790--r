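#' Calibrate a lognormal distribution from a median and IQR
#'
#' The log-scale location matches the median exactly; the log-scale sigma
#' is found by root search so that the interquartile width
#' `2 * median * sinh(z_.75 * sigma)` matches the requested width.
#'
#' @param median Target median (> 0).
#' @param iqr Numeric `c(q25, q75)` giving the target interquartile range.
#' @return List with `meanlog` and `sdlog`.
#' @export
lognormal_from_median_iqr <- function(median, iqr) {
  stopifnot(median > 0, length(iqr) == 2, iqr[2] > iqr[1])
  width <- iqr[2] - iqr[1]
  z <- stats::qnorm(0.75)
  f <- function(s) 2 * median * sinh(z * s) - width
  sdlog <- stats::uniroot(f, c(1e-8, 10), tol = 1e-12)$root
  list(meanlog = log(median), sdlog = sdlog)
}

#' Modality profile for synthetic blood-dose cohorts
#'
#' Encodes the statistical shape of a treatment modality's blood dose
#' distribution: the lognormal median/IQR of the mean blood dose, a DVH
#' shape parameter (the low-dose bath mean as a fraction of the overall
#' mean dose — broad bath for photon-like plans, steep fall-off for
#' proton-like plans), beam-delivery-time and fraction-count ranges, and
#' the grade mix used to label non-severe patients.
#'
#' Defaults: photon-like mean blood dose median 4.17 Gy, IQR 3.44-5.36,
#' bath fraction 0.6, BDT 360-480 s; proton-like median 2.38 Gy(RBE),
#' IQR 0.88-3.20, bath fraction 0.25, BDT 120-180 s; both 24-30 fractions.
#'
#' @param name `"photon_like"` or `"proton_like"`.
#' @return An object of class `modality_profile`.
#' @export
modality_profile <- function(name = c("photon_like", "proton_like")) {
  name <- match.arg(name)
  if (name == "photon_like") {
    prof <- list(
      name = name,
      blood_mean_dose_median = 4.17,
      blood_mean_dose_iqr = c(3.44, 5.36),
      dvh_shape = 0.6,
      bdt_range = c(360, 480),
      fractions_range = c(24L, 30L),
      dose_unit = "Gy",
      nonsril_grade_probs = c(`0` = 2, `1` = 9, `2` = 25) / 36,
      grade4_given_sril = 4 / 58,
      stage3_prob = 0.87,
      chemo_prob = 0.71,
      male_prob = 0.81
    )
  } else {
    prof <- list(
      name = name,
      blood_mean_dose_median = 2.38,
      blood_mean_dose_iqr = c(0.88, 3.20),
      dvh_shape = 0.25,
      bdt_range = c(120, 180),
      fractions_range = c(24L, 30L),
      dose_unit = "Gy(RBE)",
      nonsril_grade_probs = c(`0` = 8, `1` = 6, `2` = 11) / 25,
      grade4_given_sril = 0.05,
      stage3_prob = 0.65,
      chemo_prob = 0.49,
      male_prob = 0.86
    )
  }
  structure(prof, class = "modality_profile")
}

#' Ground-truth specification for synthetic cohorts
#'
#' @param lkb True [lkb_params()] generating the Bernoulli SRIL outcomes;
#'   defaults to the photon-like anchor D50 = 7.44 Gy, m = 0.42, a = 2.
#' @param alc0_median,alc0_iqr Lognormal calibration of the pre-treatment
#'   ALC (cells/uL); defaults median 1440, IQR 1110-1770.
#' @param lambda_per_day True daily exponential ALC decay rate (default
#'   0.067, the photon-like value; 0.047 is the proton-like value).
#' @param noise_cv Lognormal coefficient of variation of ALC measurement
#'   noise (default 0.2).
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(lkb = lkb_params(7.44, 0.42, 2),
                       alc0_median = 1440, alc0_iqr = c(1110, 1770),
                       lambda_per_day = 0.067, noise_cv = 0.2) {
  stopifnot(inherits(lkb, "lkb_params"), alc0_median > 0,
            lambda_per_day >= 0, noise_cv >= 0)
  structure(
    list(lkb = lkb, alc0_median = alc0_median, alc0_iqr = alc0_iqr,
         lambda_per_day = lambda_per_day, noise_cv = noise_cv),
    class = "truth_spec"
  )
}

# two-component mixture blood DVH: a low-dose bath (truncated exponential
# with mean shape * target) plus a narrow high-dose in-field peak placed so
# the overall mean equals the target exactly (bin doses are rescaled to
# remove discretization error). Bin width defaults to the 0.05 Gy export grid.
make_blood_dvh <- function(target_mean, shape, bin_width = NULL,
                           w_hot = 0.2) {
  stopifnot(target_mean > 0, shape > 0, shape < 1)
  bath_mean <- shape * target_mean
  d_hot <- target_mean * (1 - (1 - w_hot) * shape) / w_hot
  d_max <- d_hot * 1.3
  if (is.null(bin_width)) bin_width <- 0.05
  edges <- seq(0, d_max, by = bin_width)
  mids <- edges + bin_width / 2
  bath <- exp(-mids / bath_mean)
  bath <- bath / sum(bath) * (1 - w_hot)
  hot <- exp(-0.5 * ((mids - d_hot) / (0.08 * d_hot))^2)
  hot <- hot / sum(hot) * w_hot
  frac <- bath + hot
  keep <- frac > 1e-12
  dose <- edges[keep]
  frac <- frac[keep] / sum(frac[keep])
  dose[1] <- max(dose[1], bin_width / 100)  # keep the cold bin strictly positive dose
  m <- sum(dose * frac)
  differential_dvh(dose * target_mean / m, frac)
}

#' Generate a synthetic longitudinal ALC series
#'
#' `ALC(t) = alc0 * exp(-lambda t) * eps_t` with lognormal multiplicative
#' noise of coefficient of variation `noise_cv` (mean 1), sampled at the
#' given measurement days (weekly by default).
#'
#' @param alc0 Pre-treatment ALC in cells/uL, `> 0`.
#' @param lambda_per_day Daily decay rate, `>= 0`.
#' @param noise_cv Noise coefficient of variation (`0` gives the exact
#'   exponential).
#' @param measurement_days Sampling days (default weekly over 6 weeks).
#' @param seed Optional integer seed.
#' @return Data frame with columns `day` and `alc`.
#' @export
generate_alc_series <- function(alc0, lambda_per_day, noise_cv = 0.2,
                                measurement_days = seq(0, 42, by = 7),
                                seed = NULL) {
  stopifnot(alc0 > 0, lambda_per_day >= 0, noise_cv >= 0)
  with_seed(seed, {
    mu <- alc0 * exp(-lambda_per_day * measurement_days)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      eps <- stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      mu <- mu * eps
    }
    data.frame(day = measurement_days, alc = mu)
  })
}

#' Generate a synthetic photon-like or proton-like cohort
#'
#' Per patient: a mean blood dose is drawn from the profile's calibrated
#' lognormal; a blood differential DVH is constructed as a two-component
#' mixture (low-dose bath plus in-field peak) whose mean equals that draw
#' exactly; the gEUD is computed at the truth's volume-effect exponent and
#' the SRIL outcome drawn as Bernoulli of the true probit NTCP; an ALC
#' series decays exponentially with lognormal noise; covariates are drawn
#' independently from modality-typical margins. Deterministic per seed.
#'
#' @param n Number of patients, `>= 10`.
#' @param profile A [modality_profile()].
#' @param truth A [truth_spec()].
#' @param seed Integer seed.
#' @return An object of class `ld_cohort`: list with `patients` (data
#'   frame), `blood_dvhs` (named list of [differential_dvh()]), `alc`
#'   (long data frame `id, day, alc`), `profile`, `truth`, `seed`.
#' @export
generate_cohort <- function(n, profile, truth, seed = 1L) {
  stopifnot(inherits(profile, "modality_profile"),
            inherits(truth, "truth_spec"))
  if (n < 10) stop("n must be >= 10")
  ln <- lognormal_from_median_iqr(profile$blood_mean_dose_median,
                                  profile$blood_mean_dose_iqr)
  ln_alc <- lognormal_from_median_iqr(truth$alc0_median, truth$alc0_iqr)
  modality <- if (profile$name == "photon_like") "photon" else "proton"
  with_seed(seed, {
    mean_doses <- stats::rlnorm(n, ln$meanlog, ln$sdlog)
    # per-patient anatomical variation in bath breadth and in-field volume;
    # without it every DVH is a scale copy of one template and the
    # volume-effect exponent is not identifiable from the cohort
    shapes <- pmin(pmax(profile$dvh_shape * exp(stats::rnorm(n, 0, 0.5)),
                        0.05), 0.9)
    w_hots <- stats::runif(n, 0.05, 0.45)
    dvhs <- vector("list", n)
    for (i in seq_len(n))
      dvhs[[i]] <- make_blood_dvh(mean_doses[i], shape = shapes[i],
                                  w_hot = w_hots[i])
    names(dvhs) <- sprintf("%s_%04d", modality, seq_len(n))
    g <- vapply(dvhs, geud, numeric(1), a = truth$lkb$a)
    p <- ntcp_probit(g, truth$lkb)
    sril <- stats::rbinom(n, 1L, p)
    grade <- integer(n)
    for (i in seq_len(n)) {
      grade[i] <- if (sril[i] == 1L) {
        if (stats::runif(1) < profile$grade4_given_sril) 4L else 3L
      } else {
        sample(0:2, 1, prob = profile$nonsril_grade_probs)
      }
    }
    alc0 <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        alc0[i] <- stats::rlnorm(1, ln_alc$meanlog, ln_alc$sdlog)
        if (alc0[i] > 500) break  # cohort exclusion: pre-RT ALC must exceed 500
      }
    }
    n_fractions <- sample(seq(profile$fractions_range[1],
                              profile$fractions_range[2]), n, replace = TRUE)
    n_weeks <- ceiling(max(profile$fractions_range) / 5)
    days <- seq(0, 7 * n_weeks, by = 7)
    alc_list <- vector("list", n)
    for (i in seq_len(n)) {
      s <- generate_alc_series(alc0[i], truth$lambda_per_day,
                               truth$noise_cv, measurement_days = days)
      alc_list[[i]] <- cbind(id = names(dvhs)[i], s)
    }
    patients <- data.frame(
      id = names(dvhs),
      modality = modality,
      sril = sril,
      ril_grade = grade,
      pre_rt_alc = alc0,
      bdt_s = stats::runif(n, profile$bdt_range[1], profile$bdt_range[2]),
      n_fractions = n_fractions,
      stage = ifelse(stats::runif(n) < profile$stage3_prob, "III", "I/II"),
      tstage = sample(c("T1-2", "T3-4"), n, replace = TRUE),
      nstage = sample(c("N0", "N1", "N2", "N3"), n, replace = TRUE,
                      prob = c(0.15, 0.12, 0.38, 0.35)),
      sex = ifelse(stats::runif(n) < profile$male_prob, "M", "F"),
      age = pmin(pmax(round(stats::rnorm(n, 66, 8)), 30), 90),
      chemo = as.integer(stats::runif(n) < profile$chemo_prob),
      ctv_cc = stats::rlnorm(n, log(130), 0.6),
      mean_blood_dose = mean_doses,
      geud = unname(g),
      true_ntcp = unname(p),
      row.names = NULL
    )
    structure(
      list(patients = patients,
           blood_dvhs = dvhs,
           alc = do.call(rbind, alc_list),
           profile = profile,
           truth = truth,
           seed = seed),
      class = "ld_cohort"
    )
  })
}

#' Convert a synthetic (or read) cohort to an LKB fitting cohort
#'
#' @param cohort An `ld_cohort`.
#' @return An [lkb_cohort()] pairing each patient's blood DVH with the
#'   SRIL outcome.
#' @export
as_lkb_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ld_cohort"))
  lkb_cohort(cohort$blood_dvhs[cohort$patients$id], cohort$patients$sril)
}
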