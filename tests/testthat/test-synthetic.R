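test_that("trial schedules honour the printed structure and the n-back rule", {
  s <- generate_trial_schedule("2-back", 3, 40, 39, seed = 1)
  expect_equal(nrow(s), 120)
  expect_equal(sum(s$is_match), 39)
  expect_equal(diff(s$onset_s), rep(5.0, 119))
  expect_equal(s$onset_s[1], 0.5)

  tiny <- generate_trial_schedule("2-back", 1, 3, 0, seed = 1)
  expect_equal(nrow(tiny), 3)
  expect_equal(sum(tiny$is_match), 0)

  # independent re-scan of the emitted sequence (lag-2 equality)
  s7 <- generate_trial_schedule("2-back", 1, 10, 4, seed = 7)
  stim <- s7$stimulus_id
  rescan <- c(FALSE, FALSE, stim[3:10] == stim[1:8])
  expect_equal(sum(rescan), 4)
  expect_equal(rescan, s7$is_match)

  z <- generate_trial_schedule("0-back", 2, 10, 12, seed = 3)
  expect_equal(sum(z$is_match), 12)
  expect_true(all(z$stimulus_id[!z$is_match] == "*"))
})

test_that("schedule validity and determinism hold across seeds", {
  for (seed in 1:20) {
    s <- generate_trial_schedule("2-back", 2, 15, sample(0:13, 1), seed = seed)
    expect_equal(rederive_matches(s), s$is_match)
  }
  a <- generate_trial_schedule("2-back", 3, 40, 39, seed = 42)
  b <- generate_trial_schedule("2-back", 3, 40, 39, seed = 42)
  expect_identical(a, b)
})

test_that("infeasible match counts raise a parameter error", {
  expect_error(generate_trial_schedule("2-back", 1, 3, 2, seed = 1), "infeasible")
  expect_error(generate_trial_schedule("0-back", 1, 5, 6, seed = 1), "infeasible")
  expect_error(generate_trial_schedule("2-back", 1, 5, 1, seed = 1, n_stimuli = 10),
               "alphabet")
})

test_that("coupled pairs reproduce the closed-form PLI ground truth", {
  # perfect coupling: constant-sign phase difference
  cp <- generate_coupled_pair(2.5, 250, 6, target_pli = 1, lag_angle = pi / 4,
                              seed = 1)
  ph <- analytic_phase(rbind(cp$a, cp$b))$phases
  expect_equal(pli_pair(ph[1, ], ph[2, ]), 1)

  # Monte-Carlo oracle over the binomial sign model: the pooled mean sign
  # over R realizations has SE sqrt((1 - pli^2) / R)
  est_mean_sign <- function(target, R, seed0) {
    mean(vapply(seq_len(R), function(r) {
      cp <- generate_coupled_pair(0.4, 125, 6, target, pi / 4, seed = seed0 + r)
      ph <- analytic_phase(rbind(cp$a, cp$b))$phases
      mean(sign(sin(ph[1, ] - ph[2, ])))
    }, numeric(1)))
  }
  R <- 200
  est <- abs(est_mean_sign(0.5, R, 1000))
  expect_lt(abs(est - 0.5), 3 * sqrt((1 - 0.5^2) / R))
  est0 <- abs(est_mean_sign(0, R, 3000))
  expect_lt(est0, 3 * sqrt(1 / R))
})

test_that("recordings have the documented shape, null level and determinism", {
  rec <- generate_recording(59, 3.5, 500, seed = 2)
  expect_equal(dim(rec$data), c(59, 1750))
  expect_equal(rec$labels, default_montage())

  # null pair: single 2.5-s broadband segment stays below 0.2
  rec2 <- generate_recording(2, 2.5, 500, seed = 5)
  ph <- analytic_phase(rec2$data)$phases
  expect_lt(pli_pair(ph[1, ], ph[2, ]), 0.2)

  expect_identical(generate_recording(4, 1, 250, seed = 9)$data,
                   generate_recording(4, 1, 250, seed = 9)$data)
  expect_error(generate_recording(2, 1, 250, specs = list(
    coupling_spec(band_definition("theta", 4, 8),
                  data.frame(i = 1, j = 5, target_pli = 0.5, lag_angle = 1),
                  6)), seed = 1), "missing channel")
})

test_that("coupling spec invariants are enforced", {
  th <- band_definition("theta", 4, 8)
  expect_error(coupling_spec(th, data.frame(i = 1, j = 1, target_pli = .5,
                                            lag_angle = 1), 6), "distinct")
  expect_error(coupling_spec(th, data.frame(i = 1, j = 2, target_pli = 1.2,
                                            lag_angle = 1), 6), "\\[0, 1\\]")
  expect_error(coupling_spec(th, data.frame(i = 1, j = 2, target_pli = .5,
                                            lag_angle = pi), 6), "strictly inside")
  expect_error(coupling_spec(th, data.frame(i = 1, j = 2, target_pli = .5,
                                            lag_angle = 1), 12), "inside the band")
})

test_that("cohorts have the calibrated group structure", {
  # demo-size world for speed: counts and container shape only
  sp <- cohort_spec(n_young = 2, n_senior = 2, n_channels = 4, fs = 125,
                    rest_duration = 8, n_sequences = 1,
                    trials_per_sequence = 2, n_match_total = 0)
  co <- generate_cohort(sp, seed = 3)
  expect_equal(nrow(co$table), 4)
  expect_equal(sum(lengths(co$recordings)), 12)  # 4 subjects x 3 conditions
  expect_equal(co$table$group, c(0L, 0L, 1L, 1L))

  d <- cohort_spec()
  expect_equal(d$n_young, 15)
  expect_equal(d$n_senior, 10)
  expect_error(cohort_spec(n_young = 0), ">= 1")
  expect_error(cohort_spec(pli_mean = list(theta = list(rest = c(young = 1.5, senior = .2))),
                           pli_sd = list(theta = list(rest = c(young = .1, senior = .1)))),
               "\\[0, 1\\]")
})

test_that("a planted theta group difference (d = 1.5) orders recovered group means", {
  # 100 replicate cohorts at the documented demo scale; recovery uses the
  # generator's own pooled-sign calibration estimator on the coupled pairs
  sdv <- 0.028
  sp <- cohort_spec(n_channels = 8, fs = 125, rest_duration = 60,
                    pli_mean = list(theta = list(
                      "rest" = c(young = 0.20, senior = 0.20 + 1.5 * sdv))),
                    pli_sd = list(theta = list(
                      "rest" = c(young = sdv, senior = sdv))))
  band <- default_bands()$theta
  ok <- vapply(seq_len(100), function(r) {
    co <- generate_cohort(sp, seed = 5000 + r, conditions = "rest")
    est <- vapply(seq_len(nrow(co$table)), function(si) {
      f <- bandpass_filter(co$recordings[[si]]$rest, band)
      ph <- analytic_phase(f$data)$phases
      mean(vapply(seq_len(nrow(sp$coupled_pairs)), function(k)
        pli_pair(ph[sp$coupled_pairs[k, 1], ], ph[sp$coupled_pairs[k, 2], ]),
        numeric(1)))
    }, numeric(1))
    mean(est[co$table$group == 1]) > mean(est[co$table$group == 0])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
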