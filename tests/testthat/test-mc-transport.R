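# Photon transport engine: conservation, reproducibility, detector
# behaviour, and agreement with the diffusion-dipole oracle.

test_that("diffusion dipole reflectance matches an independent evaluation
           and behaves monotonically", {
  # independently typed evaluation of the dipole sum at mu_a=0.1, mu_s'=10,
  # n_rel=1.4 (A = 3.2506975 from the Groenhuis polynomial)
  mu_t <- 10.1; z0 <- 1 / mu_t; mu_eff <- sqrt(3 * 0.1 * 10.1)
  zb <- 2 * 3.2506975 / (3 * 10.1)
  dip <- function(rho_cm) {
    r1 <- sqrt(z0^2 + rho_cm^2); r2 <- sqrt((z0 + 2 * zb)^2 + rho_cm^2)
    (10 / 10.1) / (4 * pi) *
      (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
         (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2)
  }
  expect_equal(farrell_reflectance(0.1, 10, 1.4, c(2, 4, 6)),
               dip(c(0.2, 0.4, 0.6)), tolerance = 1e-6)
  # frozen regression values
  expect_equal(farrell_reflectance(0.1, 10, 1.4, c(2, 4, 6)),
               c(0.83225468, 0.19068964, 0.07323921), tolerance = 1e-7)
  rho <- seq(1, 8, by = 0.5)
  R <- farrell_reflectance(0.1, 10, 1.4, rho)
  expect_true(all(diff(R) < 0))
  expect_true(all(farrell_reflectance(0.5, 10, 1.4, rho) < R))
  expect_warning(farrell_reflectance(5, 10, 1.4, 2), "diffusion")
})

test_that("the weight budget closes exactly with roulette disabled", {
  m <- default_skin_model()
  ch <- gen_chromophore_fixture()
  for (lam in c(1050, 1550)) {
    res <- run_mc(m, ch, source_spec(lam),
                  config = mc_config(n_photons = 2e4, seed = 17,
                                     roulette = FALSE))
    expect_lt(res$budget_rel_error, 1e-6)
    total <- sum(res$detected$weight) + sum(res$absorbed) +
      res$transmitted + res$escaped
    expect_equal(total, res$n_photons, tolerance = 1e-9)
  }
})

test_that("the budget stays closed in expectation with roulette on", {
  res <- run_mc(default_skin_model(), gen_chromophore_fixture(),
                source_spec(1550),
                config = mc_config(n_photons = 1e5, seed = 23))
  expect_lt(res$budget_rel_error, 1e-3)
})

test_that("identical configuration reproduces results bit for bit", {
  m <- default_skin_model(); ch <- gen_chromophore_fixture()
  cfg <- mc_config(n_photons = 2e4, seed = 31)
  a <- run_mc(m, ch, source_spec(1550), config = cfg)
  b <- run_mc(m, ch, source_spec(1550), config = cfg)
  expect_identical(a$detected, b$detected)
  expect_identical(a$absorbed, b$absorbed)
  c2 <- run_mc(m, ch, source_spec(1550),
               config = mc_config(n_photons = 2e4, seed = 32))
  expect_false(identical(a$detected$weight, c2$detected$weight))
})

test_that("an opaque first tissue layer kills all detection", {
  ch <- toy_chromophores(water = rep(1e6, length(toy_grid)))
  m <- skin_model(list(
    skin_layer("block", "living_epidermis", 0.05, 0, 1),  # pure water, huge mu_a
    skin_layer("derm", "dermal", 1, 0.1, 0.6)))
  res <- run_mc(m, ch, source_spec(1550),
                config = mc_config(n_photons = 5e3, seed = 3))
  expect_equal(sum(res$detected$weight), 0)
  expect_gt(sum(res$absorbed), 0.9 * res$n_photons * (1 - 0.03))
})

test_that("detected weight decreases with ring radius on the default skin", {
  res <- run_mc(default_skin_model(), gen_chromophore_fixture(),
                source_spec(1050),
                config = mc_config(n_photons = 2e5, seed = 41))
  w <- res$detected$weight; se <- res$detected$se
  for (i in seq_len(length(w) - 1))
    expect_gt(w[i] - w[i + 1], -3 * sqrt(se[i]^2 + se[i + 1]^2))
  expect_gt(w[1], w[5])  # strict decrease end to end
})

test_that("standard errors shrink as sqrt of the photon budget", {
  m <- default_skin_model(); ch <- gen_chromophore_fixture()
  se_at <- function(n, seed) {
    r <- run_mc(m, ch, source_spec(1550),
                config = mc_config(n_photons = n, seed = seed))
    r$detected$fraction_se[1]
  }
  ratio <- se_at(4e4, 7) / se_at(1.6e5, 8)
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("Monte Carlo reflectance agrees with the diffusion oracle on a
           homogeneous matched-geometry medium", {
  det <- detector_spec(ring_centers_mm = c(2, 3, 4, 5, 6), ring_width_mm = 0.4)
  res <- run_mc_homogeneous(0.1, 10, g = 0, n = 1.4, detectors = det,
                            config = mc_config(n_photons = 4e5, seed = 7))
  mc <- mc_radial_reflectance(res, det)
  oracle <- farrell_reflectance(0.1, 10, 1.4, mc$rho_mm)
  expect_true(all(abs(mc$R_per_cm2 / oracle - 1) < 0.15))
})

test_that("differential absorbance from simulated weights matches its
           definition and flags empty channels", {
  m <- default_skin_model(); ch <- gen_chromophore_fixture()
  cfg <- mc_config(n_photons = 5e4, seed = 19)
  ad <- simulate_ad_spectrum(m, ch, list(source_spec(1550)), config = cfg,
                             pair = c(0.9, 2.3))
  res <- run_mc(m, ch, source_spec(1550), config = cfg)
  expect_equal(ad$ad,
               differential_absorbance(res$detected$weight[1],
                                       res$detected$weight[5]),
               tolerance = 1e-12)
  expect_error(simulate_ad_spectrum(m, ch, list(source_spec(1550)),
                                    config = cfg, pair = c(2.3, 0.9)),
               "near < far")
  # an opaque model detects nothing and reports the budget hint
  chx <- toy_chromophores(water = rep(1e6, length(toy_grid)))
  mx <- skin_model(list(skin_layer("b", "living_epidermis", 0.05, 0, 1),
                        skin_layer("d", "dermal", 1, 0.1, 0.6)))
  expect_error(simulate_ad_spectrum(mx, chx, list(source_spec(1550)),
                                    config = mc_config(n_photons = 2e3,
                                                       seed = 2)),
               "photon budget")
})

test_that("a null perturbation yields an identically zero spectrum and the
           two channels add at first order", {
  m <- default_skin_model(); ch <- gen_chromophore_fixture()
  null <- blood_perturbation_spectrum(
    m, ch, perturbation_spec(delta_CB_rel = 0),
    sources = list(source_spec(1550)),
    config = mc_config(n_photons = 2e4, seed = 5), n_blocks = 2)
  expect_equal(null$delta_ad, 0, tolerance = 1e-12)

  # small perturbation: both-channel response equals the sum of the two
  # single-channel responses within Monte Carlo error
  small <- perturbation_spec(delta_CB_rel = 0.05)
  cfg <- mc_config(n_photons = 2e5, seed = 9)
  src <- list(source_spec(1550))
  d_both <- blood_perturbation_spectrum(m, ch, small, "both", src,
                                        config = cfg)
  d_abs <- blood_perturbation_spectrum(m, ch, small, "absorption_only", src,
                                       config = cfg)
  d_sca <- blood_perturbation_spectrum(m, ch, small, "scattering_only", src,
                                       config = cfg)
  tol <- 3 * sqrt(d_both$se^2 + d_abs$se^2 + d_sca$se^2)
  expect_lt(abs(d_both$delta_ad - (d_abs$delta_ad + d_sca$delta_ad)), tol)
})

test_that("gaussian band sampling spreads the budget and stays conservative", {
  m <- default_skin_model(); ch <- gen_chromophore_fixture()
  res <- run_mc(m, ch, source_spec(1550, 52, "gaussian_band", n_samples = 3),
                config = mc_config(n_photons = 3e4, seed = 13,
                                   roulette = FALSE))
  expect_lt(res$budget_rel_error, 1e-6)
  expect_gt(sum(res$detected$weight), 0)
})
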