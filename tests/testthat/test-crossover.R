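test_that("interpolated crossover solves the two-point intersection", {
  cvd <- make_curve(c(7.5, 12.5), c(10, 25), cause = "cvd")
  can <- make_curve(c(7.5, 12.5), c(20, 15), cause = "primary_cancer")
  est <- find_crossover(cvd, can, horizon = 20)
  expect_equal(est$status, "crossed")
  expect_equal(est$time, 10.0)
  expect_equal(est$time,
               grid_crossover(c(7.5, 12.5), c(10, 25), c(20, 15)),
               tolerance = 1e-4)
})

test_that("crossover statuses cover domination, no-crossing and undefined cells", {
  m <- c(1.5, 2.5, 3.5, 4.5, 7.5, 12.5, 20)
  can <- make_curve(m, rep(10, 7), cause = "primary_cancer")
  above <- make_curve(m, rep(11, 7), cause = "cvd")
  expect_equal(find_crossover(above, can)$status,
               "already_overtaken_at_first_midpoint")
  expect_true(is.na(find_crossover(above, can)$time))
  below <- make_curve(m, rep(9, 7), cause = "cvd")
  expect_equal(find_crossover(below, can)$status, "never_within_horizon")
  undef <- make_curve(m, rep(NA_real_, 7), cause = "cvd", defined = FALSE)
  expect_equal(find_crossover(undef, can)$status, "undefined_cells")
  # crossing after the reporting horizon is not reported: here the lines
  # intersect at 12.5 + 7.5 * 4 / 4.5 = 19.17 years
  late <- make_curve(m, c(1, 2, 3, 4, 5, 6, 10.5), cause = "cvd")
  expect_equal(find_crossover(late, can, horizon = 15)$status,
               "never_within_horizon")
  est_late <- find_crossover(late, can, horizon = 20)
  expect_equal(est_late$status, "crossed")
  expect_equal(est_late$time, 12.5 + 7.5 * 4 / 4.5)
  # exact equality at a midpoint yields that midpoint
  touch <- make_curve(m, c(5, 10, 12, 13, 14, 15, 16), cause = "cvd")
  expect_equal(find_crossover(touch, can)$time, 2.5)
})

test_that("mismatched curves are rejected", {
  cvd <- make_curve(c(7.5, 12.5), c(10, 25), cause = "cvd")
  other_stratum <- make_curve(c(7.5, 12.5), c(20, 15),
                              cause = "primary_cancer", age_group = "80+")
  expect_error(find_crossover(cvd, other_stratum), "different strata")
  other_mid <- make_curve(c(7.5, 13.5), c(20, 15), cause = "primary_cancer")
  expect_error(find_crossover(cvd, other_mid), "mismatched band midpoints")
})

test_that("interpolation matches a brute-force grid intersection on random curves", {
  set.seed(53)
  m <- band_scheme()$midpoint
  n_checked <- 0
  for (i in 1:200) {
    cvd_r <- cumsum(runif(7, 0, 6)) + runif(1, 0, 5)
    can_r <- rev(cumsum(runif(7, 0, 8))) + runif(1, 0, 5)
    est <- find_crossover(make_curve(m, cvd_r, cause = "cvd"),
                          make_curve(m, can_r, cause = "primary_cancer"),
                          horizon = 20)
    ref <- grid_crossover(m, cvd_r, can_r, horizon = 20)
    if (est$status == "crossed") {
      n_checked <- n_checked + 1
      expect_lt(abs(est$time - ref), 1e-4)
    } else {
      expect_true(is.na(ref), label = sprintf("case %d agrees on no crossing", i))
    }
  }
  expect_gt(n_checked, 50)  # the generator produces plenty of true crossings
})

test_that("log-scale interpolation brackets the same crossing", {
  cvd <- make_curve(c(7.5, 12.5), c(10, 25), cause = "cvd")
  can <- make_curve(c(7.5, 12.5), c(20, 15), cause = "primary_cancer")
  nat <- find_crossover(cvd, can)
  lg <- find_crossover(cvd, can, scale = "log")
  expect_equal(lg$status, "crossed")
  expect_true(lg$time > 7.5 && lg$time < 12.5)
  # log-scale solution of 10*2.5^u = 20*0.75^u over the 5-year bracket
  u <- log(2) / (log(2.5) - log(0.75))
  expect_equal(lg$time, 7.5 + 5 * u)
  expect_false(isTRUE(all.equal(lg$time, nat$time)))
  # multiplying both curves by a constant leaves the log-scale answer too
  lg2 <- find_crossover(make_curve(c(7.5, 12.5), c(10, 25) * 3, cause = "cvd"),
                        make_curve(c(7.5, 12.5), c(20, 15) * 3,
                                   cause = "primary_cancer"), scale = "log")
  expect_equal(lg2$time, lg$time)
})

test_that("the crossover point is scale- and shift-equivariant", {
  m <- band_scheme()$midpoint
  cvd_r <- c(2, 3, 5, 8, 12, 20, 30)
  can_r <- c(40, 30, 22, 16, 11, 9, 8)
  t0 <- find_crossover(make_curve(m, cvd_r, cause = "cvd"),
                       make_curve(m, can_r, cause = "primary_cancer"))$time
  t_scaled <- find_crossover(make_curve(m, cvd_r * 7.3, cause = "cvd"),
                             make_curve(m, can_r * 7.3,
                                        cause = "primary_cancer"))$time
  t_shift <- find_crossover(make_curve(m, cvd_r + 4.2, cause = "cvd"),
                            make_curve(m, can_r + 4.2,
                                       cause = "primary_cancer"))$time
  expect_equal(t_scaled, t0)
  expect_equal(t_shift, t0)
})

test_that("bootstrap recovers a known crossover and is deterministic", {
  hz <- linear_crossing_hazards(8)
  coh <- simulate_cohort(hz$specs, 30000, seed = 61, cens_window = NULL)
  est <- bootstrap_crossover(coh, site = "site1", age_group = "60-79",
                             comparison = "primary_cancer", B = 30, seed = 71)
  expect_equal(est$status, "crossed")
  expect_lt(abs(est$time - 8), 0.75)
  expect_true(est$ci_lower <= est$time && est$time <= est$ci_upper)
  est2 <- bootstrap_crossover(coh, site = "site1", age_group = "60-79",
                              comparison = "primary_cancer", B = 30, seed = 71)
  expect_identical(est[], est2[])
  # age-stratified resampling is recorded and also deterministic
  est3 <- bootstrap_crossover(coh, site = "site1", age_group = "60-79",
                              comparison = "primary_cancer", B = 10, seed = 71,
                              stratify_age = TRUE)
  expect_true(attr(est3, "stratified"))
  expect_equal(est3$status, "crossed")
})

test_that("fast weighted bootstrap equals explicit resample-and-refit", {
  # both replicates done by hand through the public pipeline (resample
  # records, re-tabulate, saturated fit, interpolate) must reproduce the
  # bootstrap CI exactly at the same seed
  hz <- linear_crossing_hazards(8)
  coh <- simulate_cohort(hz$specs, 2000, seed = 83, cens_window = NULL)
  set.seed(91)
  t_hand <- vapply(1:2, function(b) {
    idx <- sample.int(nrow(coh), nrow(coh), replace = TRUE)
    res <- coh[idx, ]
    res$person_id <- seq_len(nrow(res))
    pt <- tabulate_person_time(res)
    cv <- fit_rates(pt, "site1", "cvd")
    cc <- fit_rates(pt, "site1", "primary_cancer")
    find_crossover(cv, cc, horizon = 20)$time
  }, numeric(1))
  est <- bootstrap_crossover(coh, site = "site1", age_group = "60-79",
                             comparison = "primary_cancer", B = 2, seed = 91)
  expect_false(any(is.na(t_hand)))
  q <- quantile(t_hand, c(0.025, 0.975), type = 7, names = FALSE)
  expect_equal(est$ci_lower, q[1])
  expect_equal(est$ci_upper, q[2])
})

test_that("indistinguishable hazards yield an unstable or uncrossed estimate", {
  specs <- const_specs(cvd = 0.01, primary_cancer = 0.01)
  coh <- simulate_cohort(specs, 4000, seed = 101)
  est <- bootstrap_crossover(coh, site = "site1", age_group = "60-79",
                             comparison = "primary_cancer", B = 40, seed = 3)
  expect_true(est$status != "crossed" || isTRUE(est$unstable) ||
                (est$ci_upper - est$ci_lower) > 5)
})

test_that("raising the cardiovascular hazard moves the crossover earlier", {
  base <- linear_crossing_hazards(10, cvd_at_entry = 2, cancer_at_entry = 40)
  shift <- 4 / 1000
  shifted <- base$specs
  cv <- shifted[[1]]
  shifted[[1]] <- hazard_spec("cvd", cv$breaks, cv$values + shift,
                              site = cv$site, age_group = cv$age_group,
                              sex = cv$sex)
  t_base <- true_crossover(base$specs[[1]], base$specs[[2]])
  t_shift <- true_crossover(shifted[[1]], shifted[[2]])
  expect_lt(t_shift, t_base)  # analytic monotonicity

  coh_b <- simulate_cohort(base$specs, 40000, seed = 7, cens_window = NULL)
  coh_s <- simulate_cohort(shifted, 40000, seed = 7, cens_window = NULL)
  xo_b <- crossover_table(coh_b, comparisons = "primary_cancer")
  xo_s <- crossover_table(coh_s, comparisons = "primary_cancer")
  expect_lt(xo_s$time, xo_b$time)
})

test_that("crossover_table covers all strata and tolerates failing ones", {
  pr <- preset_hazards(n_scale = 0.02)
  coh <- simulate_cohort(pr$specs, pr$n_per_stratum, seed = 5,
                         p_female = pr$p_female)
  xo <- crossover_table(coh)
  expect_equal(nrow(xo), 9 * 3 * 2)
  expect_true(all(xo$status %in% c("crossed", "never_within_horizon",
                                   "already_overtaken_at_first_midpoint",
                                   "undefined_cells", "error")))
  expect_true(all(!is.na(xo$time) == (xo$status == "crossed")))
  # sex-restricted secondary analysis runs on the same interface
  xo_f <- crossover_table(coh, sex = "female", comparisons = "primary_cancer")
  expect_true(all(xo_f$sex == "female"))
  expect_false(any(xo_f$site == "prostate"))
})
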