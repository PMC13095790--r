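#' Differential dose-volume histogram
#'
#' A differential DVH stores the fraction of a structure's volume falling in
#' each dose bin. Bins are labelled by their left edge and treated as
#' half-open `[d_i, d_{i+1})`; for metric purposes each bin contributes at
#' its labelled dose.
#'
#' @param dose Numeric vector of bin doses in Gy (or Gy(RBE)), strictly
#'   increasing, all `>= 0`.
#' @param volume_fraction Numeric vector of dimensionless volume fractions,
#'   all `>= 0`, summing to 1 within `1e-9`.
#' @return An object of class `differential_dvh`: a data frame with columns
#'   `dose` and `volume_fraction`.
#' @examples
#' dvh <- differential_dvh(c(2, 4), c(0.5, 0.5))
#' mean_dose(dvh)
#' @export
differential_dvh <- function(dose, volume_fraction) {
  dose <- as.numeric(dose)
  volume_fraction <- as.numeric(volume_fraction)
  if (length(dose) != length(volume_fraction) || length(dose) == 0L)
    stop("dose and volume_fraction must be non-empty vectors of equal length")
  if (anyNA(dose) || anyNA(volume_fraction))
    stop("DVH must not contain missing values")
  if (any(dose < 0)) stop("bin doses must be >= 0")
  if (is.unsorted(dose, strictly = TRUE))
    stop("bin doses must be strictly increasing")
  if (any(volume_fraction < 0)) stop("volume fractions must be >= 0")
  if (abs(sum(volume_fraction) - 1) > 1e-9)
    stop("volume fractions must sum to 1 (within 1e-9); got ",
         format(sum(volume_fraction), digits = 12))
  structure(
    data.frame(dose = dose, volume_fraction = volume_fraction),
    class = c("differential_dvh", "data.frame")
  )
}

#' Cumulative dose-volume histogram
#'
#' Stores, for each dose threshold, the volume fraction receiving at least
#' that dose. The curve always starts at 1 at dose 0; if the supplied
#' thresholds omit dose 0, a `(0, 1)` point is prepended.
#'
#' @param dose_threshold Ascending numeric dose thresholds (Gy).
#' @param volume_fraction_at_or_above Non-increasing volume fractions in
#'   `[0, 1]`.
#' @return An object of class `cumulative_dvh`.
#' @export
cumulative_dvh <- function(dose_threshold, volume_fraction_at_or_above) {
  d <- as.numeric(dose_threshold)
  v <- as.numeric(volume_fraction_at_or_above)
  if (length(d) != length(v) || length(d) == 0L)
    stop("thresholds and fractions must be non-empty vectors of equal length")
  if (anyNA(d) || anyNA(v)) stop("cumulative DVH must not contain missing values")
  if (any(d < 0)) stop("dose thresholds must be >= 0")
  if (is.unsorted(d, strictly = TRUE))
    stop("dose thresholds must be strictly increasing")
  if (any(diff(v) > 1e-12))
    stop("cumulative volume fractions must be non-increasing in dose")
  if (any(v < -1e-12 | v > 1 + 1e-12))
    stop("cumulative volume fractions must lie in [0, 1]")
  if (d[1] > 0) {
    d <- c(0, d)
    v <- c(1, v)
  }
  if (abs(v[1] - 1) > 1e-9)
    stop("cumulative DVH must start at volume fraction 1 at dose 0")
  structure(
    data.frame(dose_threshold = d, volume_fraction_at_or_above = v),
    class = c("cumulative_dvh", "data.frame")
  )
}

#' Convert a cumulative DVH to a differential DVH
#'
#' Each bin's volume fraction is the drop in cumulative volume across the
#' bin; the final threshold keeps whatever volume remains at or above it.
#' Zero-fraction bins are dropped. Total volume is conserved.
#'
#' @param cdvh A [cumulative_dvh()].
#' @return A [differential_dvh()].
#' @export
cumulative_to_differential <- function(cdvh) {
  stopifnot(inherits(cdvh, "cumulative_dvh"))
  d <- cdvh$dose_threshold
  v <- cdvh$volume_fraction_at_or_above
  frac <- c(-diff(v), v[length(v)])
  keep <- frac > 1e-12  # discard float-noise bins, e.g. from a prepended (0, 1)
  if (!any(keep)) stop("cumulative DVH carries no volume")
  differential_dvh(d[keep], frac[keep] / sum(frac[keep]))
}

#' Convert a differential DVH to a cumulative DVH
#'
#' @param dvh A [differential_dvh()].
#' @return A [cumulative_dvh()] whose thresholds are the bin doses (with a
#'   `(0, 1)` point prepended when the lowest bin is above 0).
#' @export
differential_to_cumulative <- function(dvh) {
  stopifnot(inherits(dvh, "differential_dvh"))
  at_or_above <- rev(cumsum(rev(dvh$volume_fraction)))
  cumulative_dvh(dvh$dose, at_or_above)
}

#' Mean dose of a differential DVH
#'
#' @param dvh A [differential_dvh()].
#' @return Mean dose in Gy, `sum(v_i * D_i)`.
#' @export
mean_dose <- function(dvh) {
  stopifnot(inherits(dvh, "differential_dvh"))
  sum(dvh$volume_fraction * dvh$dose)
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' Reduces a differential DVH to a single dose by the power-law mean
#' `gEUD = (sum_i v_i D_i^a)^(1/a)`. Large volume-effect exponents weight
#' the hottest bins (serial-organ behaviour); `a = 1` gives the mean dose.
#' Evaluation is carried out in log space so that large `a` (e.g. the
#' photon-cohort estimate near 20) does not overflow.
#'
#' @param dvh A [differential_dvh()].
#' @param a Volume-effect exponent; any non-zero real. Negative `a` requires
#'   strictly positive doses in every occupied bin.
#' @return gEUD in Gy; always between the minimum and maximum bin dose.
#' @export
geud <- function(dvh, a) {
  stopifnot(inherits(dvh, "differential_dvh"), length(a) == 1L, is.finite(a))
  if (a == 0) stop("a = 0 is not defined for the gEUD power mean")
  v <- dvh$volume_fraction
  d <- dvh$dose
  occ <- v > 0
  v <- v[occ]
  d <- d[occ]
  if (a < 0 && any(d == 0))
    stop("negative a is undefined when occupied bins have zero dose")
  if (a > 0) {
    pos <- d > 0
    if (!any(pos)) return(0)
    v <- v[pos]
    d <- d[pos]
  }
  # log-sum-exp: gEUD = exp((1/a) * log(sum v exp(a log d)))
  lt <- log(v) + a * log(d)
  m <- max(lt)
  exp((m + log(sum(exp(lt - m)))) / a)
}

#' Minimum dose to the hottest n% of the volume (D_n%)
#'
#' The smallest bin dose `d` such that the volume receiving at least `d` is
#' at least `n/100`. When `n` falls exactly on a cumulative-volume step the
#' hotter bin's dose is returned (conservative convention).
#'
#' @param dvh A [differential_dvh()].
#' @param n_percent Percentage of volume in `(0, 100]`.
#' @return Dose in Gy.
#' @export
dose_at_hottest_fraction <- function(dvh, n_percent) {
  stopifnot(inherits(dvh, "differential_dvh"))
  if (!is.finite(n_percent) || n_percent <= 0 || n_percent > 100)
    stop("n_percent must lie in (0, 100]")
  at_or_above <- rev(cumsum(rev(dvh$volume_fraction)))
  ok <- at_or_above >= n_percent / 100 - 1e-12
  max(dvh$dose[ok])
}

#' Volume percentage receiving more than a threshold dose (V_nGy)
#'
#' @param dvh A [differential_dvh()].
#' @param threshold_gy Dose threshold in Gy, `>= 0`. Strictly-greater
#'   convention: bins at exactly the threshold do not count.
#' @return Volume percentage in `[0, 100]`.
#' @export
volume_above <- function(dvh, threshold_gy) {
  stopifnot(inherits(dvh, "differential_dvh"))
  if (!is.finite(threshold_gy) || threshold_gy < 0)
    stop("threshold must be >= 0")
  100 * sum(dvh$volume_fraction[dvh$dose > threshold_gy])
}

#' Fractionation parameters for linear-quadratic conversion
#'
#' @param dose_per_fraction Dose per fraction in Gy, `> 0`.
#' @param n_fractions Number of fractions, `> 0`.
#' @param alpha_beta Alpha/beta ratio in Gy; 10 Gy is the conventional value
#'   for acute effects and is the default here.
#' @return An object of class `fractionation_params`.
#' @export
fractionation_params <- function(dose_per_fraction, n_fractions, alpha_beta = 10) {
  if (!all(is.finite(c(dose_per_fraction, n_fractions, alpha_beta))) ||
      dose_per_fraction <= 0 || n_fractions <= 0 || alpha_beta <= 0)
    stop("fractionation parameters must all be strictly positive")
  structure(
    list(dose_per_fraction = dose_per_fraction,
         n_fractions = n_fractions,
         alpha_beta = alpha_beta),
    class = "fractionation_params"
  )
}

#' Linear-quadratic dose conversion (BED and EQD2)
#'
#' `BED = D (1 + d / (alpha/beta))`; `EQD2 = D (d + alpha/beta) / (2 + alpha/beta)`
#' with `D` the total physical dose and `d` the dose per fraction. At
#' `d = 2` Gy the EQD2 equals the physical dose.
#'
#' @param total_dose Total physical dose in Gy.
#' @param fx A [fractionation_params()].
#' @return A list with elements `bed` and `eqd2` (Gy).
#' @export
lq_convert <- function(total_dose, fx) {
  stopifnot(inherits(fx, "fractionation_params"))
  d <- fx$dose_per_fraction
  ab <- fx$alpha_beta
  list(
    bed = total_dose * (1 + d / ab),
    eqd2 = total_dose * (d + ab) / (2 + ab)
  )
}

#' Read a DVH from the package CSV dialect
#'
#' The dialect is a two-column CSV `dose_gy,volume_fraction` preceded by a
#' metadata comment line `# type=cumulative` or `# type=differential`.
#' The type is auto-detected from that line and monotonicity is validated by
#' the corresponding constructor.
#'
#' @param path Path to the CSV file.
#' @return A [differential_dvh()] or [cumulative_dvh()].
#' @export
read_dvh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  type <- sub(".*type=([a-z]+).*", "\\1", meta[grepl("type=", meta)][1])
  if (is.na(type) || !type %in% c("cumulative", "differential"))
    stop("DVH file must carry a '# type=cumulative|differential' metadata line: ", path)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("dose_gy", "volume_fraction") %in% names(df)))
    stop("DVH file must have columns dose_gy,volume_fraction: ", path)
  if (type == "differential") {
    differential_dvh(df$dose_gy, df$volume_fraction)
  } else {
    cumulative_dvh(df$dose_gy, df$volume_fraction)
  }
}

#' Write a DVH in the package CSV dialect
#'
#' @param dvh A [differential_dvh()] or [cumulative_dvh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  if (inherits(dvh, "differential_dvh")) {
    type <- "differential"
    df <- data.frame(dose_gy = dvh$dose, volume_fraction = dvh$volume_fraction)
  } else if (inherits(dvh, "cumulative_dvh")) {
    type <- "cumulative"
    df <- data.frame(dose_gy = dvh$dose_threshold,
                     volume_fraction = dvh$volume_fraction_at_or_above)
  } else stop("not a DVH object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# type=%s", type), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
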