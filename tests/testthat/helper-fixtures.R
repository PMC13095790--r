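# shared fixture builders; all randomness seeded by callers

random_differential_dvh <- function(n_bins = 20, max_dose = 10) {
  d <- sort(runif(n_bins, 0.01, max_dose))
  while (any(diff(d) <= 0)) d <- sort(runif(n_bins, 0.01, max_dose))
  v <- rexp(n_bins)
  differential_dvh(d, v / sum(v))
}

# brute-force power mean, deliberately naive (no log-space tricks)
geud_bruteforce <- function(dvh, a) {
  sum(dvh$volume_fraction * dvh$dose^a)^(1 / a)
}

# all-pairs Mann-Whitney AUC with half credit for ties
auc_bruteforce <- function(scores, outcomes) {
  ev <- scores[outcomes == 1]
  nev <- scores[outcomes == 0]
  tot <- 0
  for (e in ev) for (x in nev)
    tot <- tot + if (e > x) 1 else if (e == x) 0.5 else 0
  tot / (length(ev) * length(nev))
}

# small synthetic fitting cohort built directly from the mixture DVHs
make_fit_cohort <- function(n, truth = truth_spec(), seed = 1,
                            profile = modality_profile("photon_like")) {
  cohort <- generate_cohort(n, profile, truth, seed = seed)
  as_lkb_cohort(cohort)
}
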