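test_that("cumulative-differential conversion differences volume and round-trips", {
  cd <- cumulative_dvh(c(0, 2, 4), c(1.0, 0.5, 0.0))
  dd <- cumulative_to_differential(cd)
  expect_equal(dd$dose, c(0, 2))
  expect_equal(dd$volume_fraction, c(0.5, 0.5))

  # uniform-dose step: all volume at or above D, none above
  step <- cumulative_dvh(c(0, 5), c(1, 1))
  dd <- cumulative_to_differential(step)
  expect_equal(dd$dose, 5)
  expect_equal(dd$volume_fraction, 1)

  # round trip differential -> cumulative -> differential is the identity
  set.seed(11)
  for (i in 1:20) {
    dvh <- random_differential_dvh(sample(3:30, 1))
    back <- cumulative_to_differential(differential_to_cumulative(dvh))
    expect_equal(back$dose, dvh$dose, tolerance = 1e-12)
    expect_equal(back$volume_fraction, dvh$volume_fraction, tolerance = 1e-12)
  }
})

test_that("DVH validation rejects malformed inputs", {
  expect_error(differential_dvh(c(2, 2), c(0.5, 0.5)), "strictly increasing")
  expect_error(differential_dvh(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(differential_dvh(c(-1, 2), c(0.5, 0.5)), ">= 0")
  expect_error(cumulative_dvh(c(0, 2), c(0.5, 0.9)), "non-increasing")
})

test_that("mean dose is the volume-weighted bin dose and equals gEUD at a = 1", {
  dvh <- differential_dvh(c(2, 4), c(0.5, 0.5))
  expect_equal(mean_dose(dvh), 3.0)
  expect_equal(mean_dose(differential_dvh(7.3, 1)), 7.3)
  set.seed(21)
  for (i in 1:10) {
    dvh <- random_differential_dvh()
    expect_equal(geud(dvh, 1), mean_dose(dvh), tolerance = 1e-12)
  }
})

test_that("gEUD matches the naive power mean and honours its limits", {
  dvh <- differential_dvh(c(2, 4), c(0.5, 0.5))
  expect_equal(geud(dvh, 2), sqrt(10), tolerance = 1e-12)
  # large a approaches the maximum dose
  expect_equal(geud(dvh, 100), 4.0, tolerance = 0.03)
  expect_equal(geud(dvh, 100), geud_bruteforce(dvh, 100), tolerance = 1e-10)

  # log-space evaluation agrees with brute force wherever brute force works
  set.seed(31)
  for (i in 1:25) {
    dvh <- random_differential_dvh()
    for (a in c(0.3, 1, 2, 5, 9, 19.85)) {
      expect_equal(geud(dvh, a), geud_bruteforce(dvh, a), tolerance = 1e-10)
    }
  }
  expect_error(geud(dvh, 0), "a = 0")
  z <- differential_dvh(c(0, 3), c(0.4, 0.6))
  expect_error(geud(z, -1), "negative a")
  expect_equal(geud(z, 2), geud_bruteforce(z, 2), tolerance = 1e-12)
})

test_that("gEUD is a non-decreasing power mean bounded by the dose range", {
  set.seed(41)
  a_grid <- c(0.2, 0.5, 1, 2, 4, 8, 16, 32)
  for (i in 1:15) {
    dvh <- random_differential_dvh()
    g <- vapply(a_grid, function(a) geud(dvh, a), numeric(1))
    expect_true(all(diff(g) >= -1e-10))
    expect_true(all(g >= min(dvh$dose) - 1e-10))
    expect_true(all(g <= max(dvh$dose) + 1e-10))
  }
})

test_that("D_n% takes the hotter dose at boundaries and V_nGy uses strict excess", {
  dvh <- differential_dvh(c(2, 4), c(0.5, 0.5))
  expect_equal(dose_at_hottest_fraction(dvh, 10), 4)
  expect_equal(dose_at_hottest_fraction(dvh, 60), 2)
  expect_equal(dose_at_hottest_fraction(dvh, 50), 4)  # boundary: hotter bin
  expect_equal(dose_at_hottest_fraction(dvh, 100), 2)
  expect_error(dose_at_hottest_fraction(dvh, 0), "0, 100")
  expect_error(dose_at_hottest_fraction(dvh, 101), "0, 100")

  expect_equal(volume_above(dvh, 3), 50)
  expect_equal(volume_above(dvh, 0), 100)
  expect_equal(volume_above(dvh, 5), 0)

  # brute-force check over the cumulative curve on random DVHs
  set.seed(51)
  for (i in 1:10) {
    d <- random_differential_dvh()
    cum <- rev(cumsum(rev(d$volume_fraction)))
    for (n in c(5, 25, 50, 75, 95)) {
      expect_equal(dose_at_hottest_fraction(d, n),
                   max(d$dose[cum >= n / 100 - 1e-12]))
    }
  }
})

test_that("D_n% and V_nGy are mutually consistent", {
  set.seed(61)
  for (i in 1:10) {
    dvh <- random_differential_dvh()
    for (n in c(10, 30, 50, 70, 90)) {
      dn <- dose_at_hottest_fraction(dvh, n)
      # volume at or above D_n% must reach n (strict-excess V needs the
      # bin just below)
      v_at_or_above <- 100 * sum(dvh$volume_fraction[dvh$dose >= dn - 1e-12])
      expect_gte(v_at_or_above, n - 1e-9)
    }
  }
})

test_that("linear-quadratic conversion reproduces closed forms", {
  fx2 <- fractionation_params(2, 30)
  expect_equal(lq_convert(60, fx2)$eqd2, 60)
  fx3 <- fractionation_params(3, 20)
  expect_equal(lq_convert(60, fx3)$bed, 78)
  expect_equal(lq_convert(60, fx3)$eqd2, 65)
  # d -> 0 limit
  fx0 <- fractionation_params(1e-9, 1)
  expect_equal(lq_convert(60, fx0)$eqd2, 60 * 10 / 12, tolerance = 1e-8)
  expect_error(fractionation_params(-1, 30), "positive")
})

test_that("DVH CSV dialect round-trips both representations", {
  tmp <- tempfile(fileext = ".csv")
  dvh <- differential_dvh(c(1, 2.5, 4), c(0.2, 0.3, 0.5))
  write_dvh(dvh, tmp)
  back <- read_dvh(tmp)
  expect_s3_class(back, "differential_dvh")
  expect_equal(back$dose, dvh$dose)
  expect_equal(back$volume_fraction, dvh$volume_fraction)

  cd <- differential_to_cumulative(dvh)
  write_dvh(cd, tmp)
  back <- read_dvh(tmp)
  expect_s3_class(back, "cumulative_dvh")
  expect_equal(back$volume_fraction_at_or_above, cd$volume_fraction_at_or_above)

  writeLines(c("dose_gy,volume_fraction", "1,1"), tmp)
  expect_error(read_dvh(tmp), "metadata")
})
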