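# Absorption mixing, Mie scattering perturbation, stack assembly and the
# blood-volume perturbation machinery.

test_that("stratum corneum absorption follows the linear-plus-mixing form", {
  # micron convention for the linear term: 0.1 - 8.3e-4 * 1.55 + 0
  expect_equal(mu_a_stratum_corneum(1550, 0), 0.1 - 8.3e-4 * 1.55,
               tolerance = 1e-12)
  expect_equal(mu_a_stratum_corneum(1000, 0.8),
               0.1 - 8.3e-4 * 1.0 + 0.125 * 0.8, tolerance = 1e-12)
  # constant term only when the linear coefficient is switched off
  expect_equal(mu_a_stratum_corneum(1300, 0, linear_coef = 0), 0.1)
  expect_error(mu_a_stratum_corneum(1550, -0.1), "non-negative")
  expect_error(mu_a_stratum_corneum(900, 0), "within")
  # the nm reading of the linear term is negative band-wide: floor + warning
  expect_warning(v <- mu_a_stratum_corneum(1550, 0, lambda_unit = "nm"),
                 "floor")
  expect_identical(v, 0)
})

test_that("living epidermis absorption mixes the power law with water", {
  expect_equal(mu_a_living_epidermis(1000, 0, 99), 0.5e10 * 1000^(-3.33),
               tolerance = 1e-12)
  expect_equal(0.5e10 * 1000^(-3.33), 0.5117, tolerance = 2e-4)
  # pure-water limit
  expect_equal(mu_a_living_epidermis(1234, 1, 7.7), 7.7)
  # mixed case against an independently written scalar expression
  x <- 12.3
  expect_equal(mu_a_living_epidermis(1550, 0.2, x),
               0.8 * 0.5e10 * 1550^(-3.33) + 0.2 * x, tolerance = 1e-12)
  expect_error(mu_a_living_epidermis(1550, 1.2, 1), "\\[0, 1\\]")
})

test_that("dermal absorption is the volume-fraction mixture of components", {
  ch <- toy_chromophores()
  lam <- 1400
  expect_equal(mu_a_dermal(lam, 0, 1, ch), chromophore_mu_a(ch, lam, "water"))
  expect_equal(mu_a_dermal(lam, 1, 0, ch), chromophore_mu_a(ch, lam, "blood"))
  expect_equal(mu_a_dermal(lam, 0.3, 0.6, ch),
               0.3 * chromophore_mu_a(ch, lam, "blood") +
                 0.6 * chromophore_mu_a(ch, lam, "water") +
                 0.1 * chromophore_mu_a(ch, lam, "other"))
  expect_error(mu_a_dermal(lam, 0.6, 0.6, ch), "C_B")
})

test_that("dermal absorption lies within the component envelope", {
  ch <- toy_chromophores()
  set.seed(42)
  for (i in 1:50) {
    cb <- runif(1); ch2o <- runif(1, 0, 1 - cb)
    lam <- runif(1, 1000, 1700)
    comp <- c(chromophore_mu_a(ch, lam, "water"),
              chromophore_mu_a(ch, lam, "blood"),
              chromophore_mu_a(ch, lam, "other"))
    v <- mu_a_dermal(lam, cb, ch2o, ch)
    expect_gte(v, min(comp) - 1e-12)
    expect_lte(v, max(comp) + 1e-12)
  }
})

test_that("absorption perturbation is linear and matches the mixture
           finite difference at fixed water content", {
  ch <- toy_chromophores()
  expect_equal(delta_mu_a(0, ch), rep(0, length(toy_grid)))
  d1 <- delta_mu_a(0.07, ch)
  expect_equal(delta_mu_a(0.14, ch), 2 * d1, tolerance = 1e-14)
  # explicit form at the default coupling
  expect_equal(delta_mu_a(0.15, ch),
               0.15 * (ch$mu_a_blood - ch$mu_a_other), tolerance = 1e-14)
  # exact agreement with the finite difference of the mixing rule
  set.seed(7)
  for (i in 1:25) {
    cb <- runif(1, 0.05, 0.4); ch2o <- runif(1, 0, 0.5)
    dcb <- runif(1, -cb / 2, min(0.2, 1 - ch2o - cb))
    lam <- sample(toy_grid, 1)
    fd <- mu_a_dermal(lam, cb + dcb, ch2o, ch) - mu_a_dermal(lam, cb, ch2o, ch)
    expect_equal(delta_mu_a(dcb, ch, k = -1, lambda = lam), fd,
                 tolerance = 1e-12)
  }
})

test_that("Mie power-law scattering behaves as its closed form dictates", {
  base <- mu_s_prime_mie(0.3e-4, 1e9, 1.55e-4, 1.49, 1.37)
  # linear in the particle density
  expect_equal(mu_s_prime_mie(0.3e-4, 2e9, 1.55e-4, 1.49, 1.37), 2 * base)
  # unit index factor when n_s / n_0 = 2
  r <- 0.3e-4; lam <- 1.55e-4; rho <- 1e9
  expect_equal(mu_s_prime_mie(r, rho, lam, 2, 1),
               3.28 * pi * r^2 * rho * (2 * pi * r / lam)^0.37)
  # frozen value from an independent scalar evaluation of the formula
  expect_equal(base, 3.28 * pi * 9e-10 * 1e9 * (2 * pi * 0.3 / 1.55)^0.37 *
                 (1.49 / 1.37 - 1)^2.09, tolerance = 1e-12)
  expect_error(mu_s_prime_mie(0.3e-4, 1e9, 1.55e-4, 1.3, 1.37), "exceed")
})

test_that("scattering change equals mu_s' times the relative blood change", {
  expect_equal(delta_mu_s_prime(12, -0.25), -3)
  expect_equal(delta_mu_s_prime(7.7, 0), 0)
  expect_equal(delta_mu_s_prime(20, 0.5) / 20, 0.5)
})

test_that("optical stack dispatches per layer kind", {
  ch <- toy_chromophores()
  m <- toy_model(g = 0)
  st <- build_optical_stack(m, ch, 1200)
  expect_equal(st$mu_s, st$mu_s_prime)  # isotropic limit
  # epidermal mu_a does not involve blood
  expect_equal(st$mu_a[1],
               mu_a_living_epidermis(1200, 0.2,
                                     chromophore_mu_a(ch, 1200, "water")))
  # off-grid wavelength within range interpolates; outside errors
  expect_silent(build_optical_stack(m, ch, 1250))
  expect_error(build_optical_stack(m, ch, 1750), "1700")
})

test_that("blood-volume perturbation scales C_B and mu_s' together", {
  m <- default_skin_model()
  expect_warning(p <- apply_perturbation(m, perturbation_spec()),
                 "first-order")
  expect_equal(p$layers$upper_blood_net_dermis$C_B, 0.45)
  expect_equal(p$layers$deep_blood_net_dermis$C_B, 0.15)
  lam <- c(1050, 1380, 1609)
  for (nm in c("upper_blood_net_dermis", "deep_blood_net_dermis")) {
    ratio <- layer_mu_s_prime(p$layers[[nm]], lam) /
      layer_mu_s_prime(m$layers[[nm]], lam)
    expect_equal(ratio, rep(1.5, 3), tolerance = 1e-15)
  }
  # untargeted layers bit-identical
  for (nm in setdiff(names(m$layers), c("upper_blood_net_dermis",
                                        "deep_blood_net_dermis")))
    expect_identical(p$layers[[nm]], m$layers[[nm]])
  # null perturbation is the identity
  expect_identical(apply_perturbation(m, perturbation_spec(delta_CB_rel = 0)),
                   m)
})

test_that("perturbation inverts and rejects non-physical targets", {
  m <- default_skin_model()
  r <- 0.5
  p <- suppressWarnings(
    apply_perturbation(m, perturbation_spec(delta_CB_rel = r)))
  back <- suppressWarnings(
    apply_perturbation(p, perturbation_spec(delta_CB_rel = -r / (1 + r))))
  for (nm in names(m$layers)) {
    expect_equal(back$layers[[nm]]$C_B, m$layers[[nm]]$C_B, tolerance = 1e-12)
    expect_equal(back$layers[[nm]]$musp_scale, m$layers[[nm]]$musp_scale,
                 tolerance = 1e-12)
  }
  expect_error(apply_perturbation(
    m, perturbation_spec(target_layers = "stratum_corneum")), "no blood")
  expect_error(apply_perturbation(
    m, perturbation_spec("upper_blood_net_dermis", delta_CB_rel = 3)),
    "out of \\[0, 1\\]")
})

test_that("epidermal layers refuse blood and fractions must be feasible", {
  expect_error(skin_layer("sc", "stratum_corneum", 0.002, 0.1, 0.05),
               "no blood")
  expect_error(skin_layer("d", "dermal", 0.01, 0.5, 0.6), "exceed")
  expect_error(skin_layer("d", "dermal", -1, 0.1, 0.6), "thickness")
})
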