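# Seeded generators: glucose curves, OGTT cases with condition-dependent
# drift, arm-elevation pairs and the analytic fixtures.

test_that("chromophore and scattering fixtures have the expected shapes", {
  ch <- gen_chromophore_fixture()
  expect_true(all(ch$mu_a_water > 0) && all(ch$mu_a_blood > 0) &&
                all(ch$mu_a_other > 0))
  peak <- ch$wavelengths[which.max(ch$mu_a_water)]
  expect_gte(peak, 1400); expect_lte(peak, 1500)
  for (k in c("stratum_corneum", "dermal", "subcutaneous")) {
    ms <- gen_mu_s_fixture(k)
    expect_true(all(ms > 0))
    expect_lt(ms[length(ms)], ms[1])
  }
  expect_error(gen_chromophore_fixture(seq(900, 1700, 50)), "within")
})

test_that("glucose curves start at baseline, end below 6 mmol/L and are
           reproducible per seed", {
  p <- ogtt_gen_params()
  for (s in 1:8) {
    g <- gen_glucose_curve(p, seed = s)
    # recording stops below 6 mmol/L or at the 3 h protocol cap
    expect_true(g$cg_true[nrow(g)] < 6 || max(g$time_min) == p$max_duration)
    expect_identical(g, gen_glucose_curve(p, seed = s))
  }
  # at the default (population-mean) parameters the curve is back below 6
  p_mean <- ogtt_gen_params(baseline_sd = 1e-12, peak_amp_sd = 1e-12,
                            t_peak_sd = 1e-12)
  gm <- gen_glucose_curve(p_mean, seed = 1)
  expect_lt(gm$cg_true[nrow(gm)], 6)
  # deterministic baseline: curve at t = 0 equals the subject baseline
  p0 <- ogtt_gen_params(baseline_sd = 1e-12)
  expect_equal(gen_glucose_curve(p0, seed = 3)$cg_true[1], 5.0,
               tolerance = 1e-6)
  # zero excursion amplitude: flat at baseline
  pz <- ogtt_gen_params(peak_amp = 0)
  gz <- gen_glucose_curve(pz, seed = 3)
  expect_equal(diff(range(gz$cg_true)), 0)
})

test_that("noiseless pre-stimulated cases are perfectly linear in glucose", {
  p <- ogtt_gen_params(noise_sigma_ad = 0, glucometer_sigma = 1e-12)
  case <- gen_ogtt_case(p, "pre_stimulated", seed = 4)
  expect_equal(abs(fit_case(case)$r), 1, tolerance = 1e-6)
  expect_equal(attr(case, "truth")$drift, rep(0, length(case$time)))
})

test_that("insulin-coupled drift degrades the glucose correlation on the
           same seed", {
  p <- ogtt_gen_params()
  worse <- 0
  for (s in 1:10) {
    r_pre <- abs(fit_case(gen_ogtt_case(p, "pre_stimulated", seed = s))$r)
    r_ctl <- abs(fit_case(gen_ogtt_case(p, "control", seed = s))$r)
    worse <- worse + (r_ctl < r_pre)
  }
  expect_gte(worse, 8)
  ctl <- gen_ogtt_case(p, "control", seed = 2)
  expect_gt(max(abs(attr(ctl, "truth")$drift)), 0)
})

test_that("two averaged meter readings halve the reference variance", {
  p <- ogtt_gen_params(noise_sigma_ad = 0, glucometer_sigma = 0.3,
                       peak_amp = 0, baseline_sd = 1e-12)
  errs <- unlist(lapply(1:60, function(s) {
    case <- gen_ogtt_case(p, "pre_stimulated", seed = s)
    case$cg - attr(case, "truth")$cg_true
  }))
  expect_equal(var(errs), 0.3^2 / 2, tolerance = 0.15)
})

test_that("generated cases are deterministic given the seed", {
  p <- ogtt_gen_params()
  a <- gen_ogtt_case(p, "control", seed = 99)
  b <- gen_ogtt_case(p, "control", seed = 99)
  expect_identical(a$ad_1550, b$ad_1550)
  expect_identical(a$cg, b$cg)
  coh <- gen_ogtt_cohort(3, "pre_stimulated", p, seed = 12)
  expect_length(coh, 3)
  expect_identical(coh[[2]]$ad_1550,
                   gen_ogtt_case(p, "pre_stimulated", 12 * 1000L + 2)$ad_1550)
})

test_that("arm-raise pairs reflect the perturbation and the noise model", {
  m <- default_skin_model()
  ch <- gen_chromophore_fixture()
  null_spec <- perturbation_spec(delta_CB_rel = 0)
  pairs <- gen_arm_raise_pair(m, ch, null_spec, noise_sigma = 0, seed = 1)
  expect_length(pairs, 3)
  for (p in pairs) expect_equal(p$ad0$ad, p$ad1$ad, tolerance = 1e-12)

  # with the blood perturbation the averaged difference converges to the
  # clean perturbation spectrum as repeats grow (law of large numbers)
  spec <- perturbation_spec()
  clean <- suppressWarnings(
    gen_arm_raise_pair(m, ch, spec, noise_sigma = 0, seed = 1,
                       n_repeats = 1))[[1]]
  truth <- clean$ad0$ad - clean$ad1$ad
  many <- suppressWarnings(
    gen_arm_raise_pair(m, ch, spec, noise_sigma = 5e-4, seed = 2,
                       n_repeats = 100))
  avg <- average_repeats(Map(blood_spectrum,
                             lapply(many, `[[`, "ad0"),
                             lapply(many, `[[`, "ad1")))
  # mean of 100 noisy repeats is within 3 standard errors of the truth
  expect_lt(max(abs(avg$mean_ad - truth)), 3 * sqrt(2) * 5e-4 / sqrt(100))

  # repeat-to-repeat spread scales with the injected noise
  lo <- suppressWarnings(gen_arm_raise_pair(m, ch, spec, noise_sigma = 1e-4,
                                            seed = 3, n_repeats = 50))
  hi <- suppressWarnings(gen_arm_raise_pair(m, ch, spec, noise_sigma = 1e-3,
                                            seed = 3, n_repeats = 50))
  sd_of <- function(reps) mean(average_repeats(lapply(reps, `[[`, "ad0"))$sd_ad)
  expect_gt(sd_of(hi), 5 * sd_of(lo))
})
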