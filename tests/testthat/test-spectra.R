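# Absorbance algebra, blood-spectrum extraction and spectral comparison.

test_that("absorbance and differential absorbance follow their log forms", {
  expect_equal(absorbance(1, 1), 0)
  expect_equal(absorbance(exp(-1), 1), 1)
  expect_equal(absorbance(0.25, 1), log(4))
  expect_equal(differential_absorbance(1, 1), 0)
  expect_equal(differential_absorbance(3, 1), log(3))
  expect_error(absorbance(0, 1), "positive")
  expect_error(differential_absorbance(1, -2), "positive")
})

test_that("differential absorbance rejects common-mode factors and equals
           the absorbance difference for any reference intensity", {
  set.seed(11)
  for (i in 1:100) {
    I1 <- runif(1, 1e-6, 1e3); I2 <- runif(1, 1e-6, 1e3)
    c0 <- runif(1, 1e-3, 1e3); I0 <- runif(1, 1e-3, 1e3)
    expect_equal(differential_absorbance(c0 * I1, c0 * I2),
                 differential_absorbance(I1, I2), tolerance = 1e-9)
    expect_equal(differential_absorbance(I1, I2),
                 absorbance(I2, I0) - absorbance(I1, I0), tolerance = 1e-9)
  }
})

test_that("blood spectrum is the elementwise paired difference", {
  lam <- c(1050, 1550)
  a0 <- ad_spectrum(lam, c(0.504, 0.608), pair = c(0.9, 2.3))
  a1 <- ad_spectrum(lam, c(0.500, 0.604), pair = c(0.9, 2.3))
  bs <- blood_spectrum(a0, a1)
  expect_equal(bs$ad, c(0.004, 0.004))
  expect_equal(blood_spectrum(a1, a0)$ad, -bs$ad)
  expect_equal(blood_spectrum(a0, a0)$ad, c(0, 0))
  a2 <- ad_spectrum(c(1050, 1609), c(1, 2), pair = c(0.9, 2.3))
  expect_error(blood_spectrum(a0, a2), "grids differ")
  a3 <- ad_spectrum(lam, c(1, 2), pair = c(0.9, 1.7))
  expect_error(blood_spectrum(a0, a3), "pairs differ")
})

test_that("repeat averaging gives per-wavelength mean and sample SD", {
  lam <- c(1050, 1550, 1609)
  reps <- list(ad_spectrum(lam, c(0, 0, 1)), ad_spectrum(lam, c(1, 0, 3)))
  avg <- average_repeats(reps)
  expect_equal(avg$mean_ad, c(0.5, 0, 2))
  expect_equal(avg$sd_ad, c(sd(c(0, 1)), 0, sd(c(1, 3))))
  expect_equal(avg$sd_ad[1], 0.7071068, tolerance = 1e-6)
  expect_equal(attr(avg, "n_repeats"), 2L)
  # permutation invariance and the identical-repeat degenerate case
  expect_equal(average_repeats(rev(reps))$mean_ad, avg$mean_ad)
  same <- average_repeats(list(reps[[1]], reps[[1]], reps[[1]]))
  expect_equal(same$sd_ad, c(0, 0, 0))
  expect_error(average_repeats(list()), "empty")
})

test_that("averaging repeats commutes with taking paired differences", {
  set.seed(3)
  lam <- c(1050, 1219, 1550)
  reps0 <- replicate(3, ad_spectrum(lam, rnorm(3)), simplify = FALSE)
  reps1 <- replicate(3, ad_spectrum(lam, rnorm(3)), simplify = FALSE)
  diffs <- Map(blood_spectrum, reps0, reps1)
  lhs <- average_repeats(diffs)$mean_ad
  rhs <- average_repeats(reps0)$mean_ad - average_repeats(reps1)$mean_ad
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("glucose equivalent scales as delta_ad over sensitivity", {
  sens <- glucose_sensitivity_fixture()
  da <- ad_spectrum(sens$wavelength_nm, sens$sensitivity)
  expect_equal(glucose_equivalent(da, sens, at = 1550), 1)
  expect_equal(glucose_equivalent(da, sens, at = 1219), 1)
  da2 <- ad_spectrum(sens$wavelength_nm, 2 * sens$sensitivity)
  expect_equal(glucose_equivalent(da2, sens, at = 1550), 2)
  zero <- ad_spectrum(sens$wavelength_nm, rep(0, nrow(sens)))
  expect_equal(glucose_equivalent(zero, sens, at = 1550), 0)
  # 1-homogeneity at an arbitrary scale
  expect_equal(glucose_equivalent(ad_spectrum(sens$wavelength_nm,
                                              3.7 * sens$sensitivity),
                                  sens, at = 1380), 3.7, tolerance = 1e-12)
  bad <- data.frame(wavelength_nm = sens$wavelength_nm,
                    sensitivity = rep(0, nrow(sens)))
  expect_error(glucose_equivalent(da, bad), "zero sensitivity")
})

test_that("spectral similarity is the Pearson correlation across bands", {
  a <- c(1, 2, 5, 3)
  expect_equal(spectral_similarity(a, 4 * a), 1)
  expect_equal(spectral_similarity(a, -a), -1)
  # constructed orthogonal-after-centering pair
  b <- c(1, -1, 0, 0); d <- c(0, 0, 1, -1)
  expect_equal(spectral_similarity(b, d), 0)
  expect_error(spectral_similarity(a, rep(1, 4)), "zero-variance")
})
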