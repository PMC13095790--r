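#' Lyman-Kutcher-Burman model parameters
#'
#' @param d50 Dose (Gy) at 50% complication probability, `> 0`.
#' @param m Dimensionless slope parameter, `> 0`; smaller `m` means a
#'   steeper dose-response curve.
#' @param a Volume-effect exponent used to reduce the DVH to a gEUD;
#'   constrained to `[0.1, 50]` for fitting.
#' @return An object of class `lkb_params`.
#' @export
lkb_params <- function(d50, m, a) {
  if (!all(is.finite(c(d50, m, a))) || d50 <= 0 || m <= 0)
    stop("D50 and m must be strictly positive")
  if (a < 0.1 || a > 50)
    stop("a must lie within the fit bounds [0.1, 50]")
  structure(list(d50 = d50, m = m, a = a), class = "lkb_params")
}

#' Probit NTCP dose-response
#'
#' `NTCP = Phi(x)` with `x = (gEUD - D50) / (m * D50)` and `Phi` the
#' standard normal CDF. By construction the curve passes through 0.5 at
#' `gEUD = D50` for every slope `m`, and is strictly increasing in gEUD.
#'
#' @param geud Blood gEUD in Gy (vectorized).
#' @param params An [lkb_params()] (the `a` field is not used here; the
#'   caller chooses the gEUD reduction).
#' @return Complication probability in `(0, 1)`.
#' @export
ntcp_probit <- function(geud, params) {
  stopifnot(inherits(params, "lkb_params"))
  stats::pnorm((geud - params$d50) / (params$m * params$d50))
}

#' Cohort container for LKB fitting
#'
#' Bundles per-patient blood differential DVHs with binary SRIL outcomes
#' and precomputes the log-space bin representation used by the likelihood.
#'
#' @param dvhs List of [differential_dvh()] objects, one per patient.
#' @param outcomes Binary vector (0/1) of SRIL outcomes, same length.
#' @return An object of class `lkb_cohort`.
#' @export
lkb_cohort <- function(dvhs, outcomes) {
  outcomes <- as.integer(outcomes)
  if (length(dvhs) != length(outcomes) || length(dvhs) == 0L)
    stop("dvhs and outcomes must be non-empty and of equal length")
  if (!all(outcomes %in% c(0L, 1L))) stop("outcomes must be binary 0/1")
  lapply(dvhs, function(d) stopifnot(inherits(d, "differential_dvh")))
  logs <- lapply(dvhs, function(d) {
    keep <- d$volume_fraction > 0 & d$dose > 0
    list(log_v = log(d$volume_fraction[keep]), log_d = log(d$dose[keep]))
  })
  structure(
    list(dvhs = dvhs,
         outcomes = outcomes,
         log_v = lapply(logs, `[[`, "log_v"),
         log_d = lapply(logs, `[[`, "log_d"),
         n = length(outcomes),
         grid = NULL),
    class = "lkb_cohort"
  )
}

#' Per-patient gEUD of a cohort at a common exponent
#'
#' @param cohort An [lkb_cohort()].
#' @param a Volume-effect exponent, `> 0`.
#' @return Numeric vector of gEUDs (Gy).
#' @export
cohort_geud <- function(cohort, a) {
  stopifnot(inherits(cohort, "lkb_cohort"), a > 0)
  geud_cohort_cpp(cohort$log_v, cohort$log_d, a)
}

#' Negative log-likelihood of an LKB model on a cohort
#'
#' `NLL = -sum_n [R_n log p_n + (1 - R_n) log(1 - p_n)]` with
#' `p_n = Phi((gEUD_n(a) - D50) / (m D50))`. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` before taking logs, so perfect separation yields a
#' large finite value rather than infinity.
#'
#' @param params An [lkb_params()].
#' @param cohort An [lkb_cohort()] with at least one event and one
#'   non-event.
#' @return The NLL (dimensionless, `>= 0`).
#' @export
lkb_nll <- function(params, cohort) {
  stopifnot(inherits(params, "lkb_params"), inherits(cohort, "lkb_cohort"))
  if (cohort$n == 0L) stop("empty cohort")
  p <- ntcp_probit(cohort_geud(cohort, params$a), params)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(cohort$outcomes * log(p) + (1 - cohort$outcomes) * log1p(-p))
}

nll_core <- function(g, d50, m, outcomes) {
  p <- stats::pnorm((g - d50) / (m * d50))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(outcomes * log(p) + (1 - outcomes) * log1p(-p))
}

# Per-patient gEUD tabulated on a dense log-a grid. Inside the optimizer,
# gEUD(a) is linearly interpolated in log a (relative error ~1e-5 with 601
# knots, far below the statistical scale); reported NLLs at fit endpoints
# are recomputed exactly. The grid is built once per cohort and subset by
# row for bootstrap resamples.
geud_grid <- function(cohort, n_grid = 601) {
  la <- seq(log(0.1), log(50), length.out = n_grid)
  G <- vapply(la, function(l)
    geud_cohort_cpp(cohort$log_v, cohort$log_d, exp(l)),
    numeric(cohort$n))
  if (cohort$n == 1L) G <- matrix(G, nrow = 1L)
  list(la = la, G = G)
}

geud_at <- function(grid, a) {
  l <- log(min(max(a, 0.1), 50))
  i <- findInterval(l, grid$la, all.inside = TRUE)
  w <- (l - grid$la[i]) / (grid$la[i + 1] - grid$la[i])
  grid$G[, i] * (1 - w) + grid$G[, i + 1] * w
}

# objective factory on (log d50, log m[, log a]) with a soft barrier
# holding a in [0.1, 50]
make_nll_fn <- function(cohort, a_fixed = NULL, grid = NULL) {
  outcomes <- cohort$outcomes
  geud_of <- if (is.null(grid)) {
    function(a) geud_cohort_cpp(cohort$log_v, cohort$log_d, a)
  } else {
    function(a) geud_at(grid, a)
  }
  if (!is.null(a_fixed)) {
    g_fixed <- geud_of(a_fixed)
    function(theta) nll_core(g_fixed, exp(theta[1]), exp(theta[2]), outcomes)
  } else {
    function(theta) {
      a <- exp(theta[3])
      pen <- 0
      if (a < 0.1) { pen <- 1e4 * (log(0.1) - log(a))^2; a <- 0.1 }
      if (a > 50) { pen <- 1e4 * (log(a) - log(50))^2; a <- 50 }
      nll_core(geud_of(a), exp(theta[1]), exp(theta[2]), outcomes) + pen
    }
  }
}

check_fit_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "lkb_cohort"))
  ev <- sum(cohort$outcomes)
  if (ev == 0L || ev == cohort$n)
    stop("fitting requires at least one event and one non-event")
}

# gEUD spread across patients over a grid of exponents; a flat design
# (all patients identical) makes (D50, m, a) unidentifiable
geud_spread <- function(cohort) {
  max(vapply(c(0.5, 2, 8, 32),
             function(a) diff(range(cohort_geud(cohort, a))), numeric(1)))
}

lkb_restart_grid <- function(cohort, grid = NULL) {
  starts <- list()
  for (a0 in c(0.5, 1, 2, 4, 8, 16, 32)) {
    g <- if (is.null(grid)) cohort_geud(cohort, a0) else geud_at(grid, a0)
    q <- stats::quantile(g, c(0.2, 0.5, 0.8), names = FALSE)
    q <- pmax(q, 1e-3)
    for (d0 in unique(q)) for (m0 in c(0.2, 0.5))
      starts[[length(starts) + 1L]] <- c(log(d0), log(m0), log(a0))
  }
  starts
}

#' Fit the LKB model by maximum likelihood
#'
#' Nelder-Mead minimization of the negative log-likelihood over
#' `(log D50, log m, log a)` from a deterministic restart grid
#' (`a` in \{0.5, 1, 2, 4, 8, 16, 32\} crossed with D50 starts at the
#' 20th/50th/80th gEUD percentiles and m starts \{0.2, 0.5\}); the best
#' endpoint over all restarts is returned. The log parameterization
#' enforces positivity; a soft barrier keeps `a` within `[0.1, 50]`.
#'
#' @param cohort An [lkb_cohort()] with both outcome classes present.
#' @param n_boot Number of bootstrap resamples for 95% parameter CIs
#'   (0 to skip; the clinical analysis convention is 1000).
#' @param seed Integer seed (drives the bootstrap only; the fit itself is
#'   deterministic).
#' @param reltol Simplex convergence tolerance on the NLL (default `1e-8`).
#' @param maxit Maximum iterations per restart (default 2000).
#' @return An object of class `lkb_fit`: list with `params`
#'   ([lkb_params()]), `nll`, `converged`, `identifiable`,
#'   `n_restarts_used`, `restart_table` (data frame of all endpoints),
#'   `bootstrap_ci` (data frame or `NULL`), `n_boot_degenerate`, `seed`.
#' @export
fit_lkb <- function(cohort, n_boot = 0, seed = 1L,
                    reltol = 1e-8, maxit = 2000) {
  check_fit_cohort(cohort)
  identifiable <- geud_spread(cohort) > 1e-8
  grid <- if (is.null(cohort$grid)) geud_grid(cohort) else cohort$grid
  fn <- make_nll_fn(cohort, grid = grid)
  starts <- lkb_restart_grid(cohort, grid)
  best <- NULL
  rt <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    o <- stats::optim(starts[[i]], fn, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
    rt[[i]] <- data.frame(d50 = exp(o$par[1]), m = exp(o$par[2]),
                          a = exp(o$par[3]), nll = o$value,
                          converged = o$convergence == 0L)
    if (is.null(best) || o$value < best$value) best <- o
  }
  restart_table <- do.call(rbind, rt)
  # polish the best grid-interpolated endpoint on the exact objective
  polish <- stats::optim(best$par, make_nll_fn(cohort),
                         method = "Nelder-Mead",
                         control = list(reltol = reltol, maxit = maxit))
  if (polish$value <= best$value) best <- polish
  pars <- exp(best$par)
  pars[3] <- min(max(pars[3], 0.1), 50)
  params <- lkb_params(pars[1], pars[2], pars[3])
  fit <- structure(
    list(params = params,
         nll = lkb_nll(params, cohort),  # exact recompute at the endpoint
         converged = any(restart_table$converged) && best$convergence == 0L,
         identifiable = identifiable,
         n_restarts_used = length(starts),
         restart_table = restart_table,
         bootstrap_ci = NULL,
         n_boot_degenerate = 0L,
         seed = seed),
    class = "lkb_fit"
  )
  if (n_boot > 0) {
    bs <- bootstrap_lkb(cohort, fit, n_boot = n_boot, seed = seed)
    fit$bootstrap_ci <- bs$ci
    fit$n_boot_degenerate <- bs$n_degenerate
  }
  fit
}

#' Fit the LKB model with the volume-effect exponent held fixed
#'
#' Constrained refit used for cross-modality analyses (e.g. fixing `a` to a
#' photon-derived value and reoptimizing D50 and m on a proton cohort).
#' Optimization runs over `(log D50, log m)` only, from the same restart
#' grid restricted to the fixed `a`.
#'
#' @inheritParams fit_lkb
#' @param a_fixed The fixed volume-effect exponent, within `[0.1, 50]`.
#' @return An `lkb_fit` whose `params$a` equals `a_fixed`.
#' @export
fit_lkb_fixed_a <- function(cohort, a_fixed, n_boot = 0, seed = 1L,
                            reltol = 1e-8, maxit = 2000) {
  check_fit_cohort(cohort)
  if (a_fixed < 0.1 || a_fixed > 50) stop("a_fixed must lie in [0.1, 50]")
  identifiable <- geud_spread(cohort) > 1e-8
  fn <- make_nll_fn(cohort, a_fixed = a_fixed)
  g <- cohort_geud(cohort, a_fixed)
  q <- unique(pmax(stats::quantile(g, c(0.2, 0.5, 0.8), names = FALSE), 1e-3))
  starts <- list()
  for (d0 in q) for (m0 in c(0.2, 0.5))
    starts[[length(starts) + 1L]] <- c(log(d0), log(m0))
  best <- NULL
  rt <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    o <- stats::optim(starts[[i]], fn, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
    rt[[i]] <- data.frame(d50 = exp(o$par[1]), m = exp(o$par[2]),
                          a = a_fixed, nll = o$value,
                          converged = o$convergence == 0L)
    if (is.null(best) || o$value < best$value) best <- o
  }
  restart_table <- do.call(rbind, rt)
  params <- lkb_params(exp(best$par[1]), exp(best$par[2]), a_fixed)
  structure(
    list(params = params,
         nll = lkb_nll(params, cohort),
         converged = any(restart_table$converged) && best$convergence == 0L,
         identifiable = identifiable,
         n_restarts_used = length(starts),
         restart_table = restart_table,
         bootstrap_ci = NULL,
         n_boot_degenerate = 0L,
         seed = seed,
         a_fixed = a_fixed),
    class = "lkb_fit"
  )
}

# single warm-started Nelder-Mead refit, used for resampling; uses the
# cohort's attached gEUD grid when present
refit_lkb_warm <- function(cohort, start_params, a_fixed = NULL,
                           reltol = 1e-8, maxit = 2000) {
  fn <- make_nll_fn(cohort, a_fixed = a_fixed, grid = cohort$grid)
  theta <- if (is.null(a_fixed))
    log(c(start_params$d50, start_params$m, start_params$a))
  else log(c(start_params$d50, start_params$m))
  o <- stats::optim(theta, fn, method = "Nelder-Mead",
                    control = list(reltol = reltol, maxit = maxit))
  a <- if (is.null(a_fixed)) min(max(exp(o$par[3]), 0.1), 50) else a_fixed
  list(params = lkb_params(exp(o$par[1]), exp(o$par[2]), a), nll = o$value)
}

#' @export
print.lkb_fit <- function(x, ...) {
  cat("LKB probit NTCP fit\n")
  cat(sprintf("  D50 = %.3f Gy, m = %.3f, a = %.3f\n",
              x$params$d50, x$params$m, x$params$a))
  cat(sprintf("  NLL = %.4f; converged: %s; identifiable: %s; restarts: %d\n",
              x$nll, x$converged, x$identifiable, x$n_restarts_used))
  if (!is.null(x$bootstrap_ci)) {
    cat("  bootstrap 95% CIs:\n")
    print(x$bootstrap_ci)
  }
  invisible(x)
}
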