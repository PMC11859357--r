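# R-level surface of the Monte Carlo transport engine: configuration objects,
# the per-wavelength driver, ring-detector bookkeeping, differential
# absorbance spectra and paired blood-perturbation runs.

#' Source band specification
#'
#' @param center_wavelength_nm Band centre (nm).
#' @param bandwidth_3db_nm 3 dB (FWHM) bandwidth (nm); >= 0.
#' @param spectral_mode `"monochromatic"` (simulate the centre wavelength
#'   only, the default) or `"gaussian_band"` (split the photon budget over
#'   `n_samples` wavelengths with Gaussian weights, sigma = FWHM / 2.355).
#' @param n_samples Number of band sample wavelengths in `gaussian_band` mode.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(center_wavelength_nm, bandwidth_3db_nm = 0,
                        spectral_mode = c("monochromatic", "gaussian_band"),
                        n_samples = 5) {
  spectral_mode <- match.arg(spectral_mode)
  if (bandwidth_3db_nm < 0) stop("bandwidth must be >= 0", call. = FALSE)
  structure(list(center_wavelength_nm = center_wavelength_nm,
                 bandwidth_3db_nm = bandwidth_3db_nm,
                 spectral_mode = spectral_mode,
                 n_samples = as.integer(n_samples)),
            class = "source_spec")
}

#' The six default instrument source bands
#'
#' Superluminescent-diode bands centred at 1050, 1219, 1314, 1380, 1550 and
#' 1609 nm with 3 dB bandwidths of 51, 32, 36, 58, 52 and 57 nm.
#'
#' @param spectral_mode,n_samples Passed to [source_spec()].
#' @return List of six [source_spec()] objects.
#' @export
default_sources <- function(spectral_mode = "monochromatic", n_samples = 5) {
  centers <- c(1050, 1219, 1314, 1380, 1550, 1609)
  bw <- c(51, 32, 36, 58, 52, 57)
  Map(function(c, b) source_spec(c, b, spectral_mode, n_samples), centers, bw)
}

#' Ring detector specification
#'
#' Concentric annular detectors on the probe surface. A ring centred at
#' source-detector separation `s` spans `[s - w/2, s + w/2]`.
#'
#' @param ring_centers_mm Ring centre radii (mm); default the instrument's
#'   five separations 0.9, 1.25, 1.7, 2.0, 2.3 mm.
#' @param ring_width_mm Radial width of each ring (mm), default 0.2.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(ring_centers_mm = c(0.9, 1.25, 1.7, 2.0, 2.3),
                          ring_width_mm = 0.2) {
  r <- sort(as.numeric(ring_centers_mm))
  if (any(r - ring_width_mm / 2 < 0))
    stop("ring inner radii must be positive", call. = FALSE)
  if (length(r) > 1 &&
      any(r[-length(r)] + ring_width_mm / 2 > r[-1] - ring_width_mm / 2 + 1e-12))
    stop("detector rings overlap", call. = FALSE)
  structure(list(ring_centers_mm = r, ring_width_mm = ring_width_mm),
            class = "detector_spec")
}

#' Monte Carlo run configuration
#'
#' @param n_photons Photon budget per run. The reference instrument
#'   simulation used 1e10 photons; desk-scale defaults of 1e5-1e7 give the
#'   same expectations with standard errors scaling as 1/sqrt(N).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param roulette_threshold Weight below which termination is considered.
#' @param roulette_survival Russian-roulette survival probability.
#' @param roulette If `TRUE` (default) use unbiased Russian roulette; if
#'   `FALSE`, residual weight below the threshold is banked as absorbed so
#'   the energy budget closes exactly per history.
#' @param max_steps Safety cap on steps per photon.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_photons = 1e6, seed = 1,
                      roulette_threshold = 1e-4, roulette_survival = 0.1,
                      roulette = TRUE, max_steps = 1e7) {
  if (n_photons < 1) stop("`n_photons` must be >= 1", call. = FALSE)
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("`roulette_survival` must lie in (0, 1)", call. = FALSE)
  structure(list(n_photons = n_photons, seed = seed,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 roulette = isTRUE(roulette), max_steps = max_steps),
            class = "mc_config")
}

# Run the engine once on explicit per-layer coefficients (cm units).
# mu_a_alt / mu_s_alt switch on perturbation-MC reweighting of detected
# photons for a second coefficient set sharing the same paths.
mc_engine <- function(mu_a, mu_s, g, n, thickness_cm, n_above, n_below,
                      detectors, config, n_photons = config$n_photons,
                      seed = config$seed, mu_a_alt = NULL, mu_s_alt = NULL) {
  if (any(mu_a < 0)) stop("mu_a must be non-negative", call. = FALSE)
  if (any(mu_s < 0)) stop("mu_s must be non-negative", call. = FALSE)
  lo <- (detectors$ring_centers_mm - detectors$ring_width_mm / 2) / 10
  hi <- (detectors$ring_centers_mm + detectors$ring_width_mm / 2) / 10
  mc_run_cpp(mu_a, mu_s, g, n, thickness_cm,
             n_above, n_below, lo, hi,
             n_photons, seed,
             config$roulette_threshold, config$roulette_survival,
             config$roulette, config$max_steps, mu_a_alt, mu_s_alt)
}

# Assemble engine layers from a skin model stack (prepends the glass window).
stack_to_engine_layers <- function(model, stack) {
  glass <- model$superstrate_thickness_cm > 0
  list(
    mu_a = c(if (glass) 0, stack$mu_a),
    mu_s = c(if (glass) 0, stack$mu_s),
    g = c(if (glass) 0, stack$g),
    n = c(if (glass) model$superstrate_n, stack$n),
    thickness_cm = c(if (glass) model$superstrate_thickness_cm,
                     stack$thickness_cm),
    layer_names = c(if (glass) "glass_superstrate", stack$name))
}

mc_result_from_raw <- function(raw, layer_names, detectors, wavelength_nm,
                               config, seed) {
  N <- raw$n_photons
  w <- raw$detected_w
  var_tot <- pmax(raw$detected_w2 - w^2 / N, 0)
  detected <- data.frame(
    ring_center_mm = detectors$ring_centers_mm,
    weight = w, se = sqrt(var_tot),
    fraction = w / N, fraction_se = sqrt(var_tot) / N)
  budget <- sum(w) + sum(raw$absorbed) + raw$transmitted + raw$escaped
  structure(list(
    wavelength_nm = wavelength_nm,
    detected = detected,
    absorbed = setNames(raw$absorbed, layer_names),
    transmitted = raw$transmitted,
    escaped = raw$escaped,
    n_photons = N,
    seed = seed,
    budget_rel_error = abs(budget - N) / N,
    config = config), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> lambda=%g nm, N=%g photons, budget closes to %.2e\n",
              x$wavelength_nm, x$n_photons, x$budget_rel_error))
  print(x$detected, row.names = FALSE)
  invisible(x)
}

#' Simulate diffuse reflectance of a skin model at one source band
#'
#' Launches a pencil beam normally onto the glass window of the probe and
#' records the weight of photons re-emerging through the window within each
#' detector ring, together with per-layer absorption, bottom-boundary
#' transmission and undetected escape, so the weight budget can be audited.
#'
#' @param model A [skin_model()].
#' @param chromophores A [chromophore_set()].
#' @param source A [source_spec()].
#' @param detectors A [detector_spec()].
#' @param config An [mc_config()].
#' @return An `mc_result`: per-ring detected weights with standard errors,
#'   per-layer absorbed weight, transmitted and escaped weight, seed and
#'   energy-budget closure.
#' @export
run_mc <- function(model, chromophores, source = source_spec(1550),
                   detectors = detector_spec(), config = mc_config()) {
  stopifnot(inherits(model, "skin_model"), inherits(source, "source_spec"),
            inherits(detectors, "detector_spec"),
            inherits(config, "mc_config"))
  samples <- .allocate_photons(band_samples(source, chromophores),
                               config$n_photons)
  agg <- NULL
  for (j in seq_len(nrow(samples))) {
    stack <- build_optical_stack(model, chromophores, samples$lambda[j])
    eng <- stack_to_engine_layers(model, stack)
    raw <- mc_engine(eng$mu_a, eng$mu_s, eng$g, eng$n, eng$thickness_cm,
                     model$ambient_n, eng$n[length(eng$n)],
                     detectors, config,
                     n_photons = samples$n_photons[j],
                     seed = config$seed + (j - 1))
    agg <- if (is.null(agg)) raw else {
      raw$detected_w <- raw$detected_w + agg$detected_w
      raw$detected_w2 <- raw$detected_w2 + agg$detected_w2
      raw$absorbed <- raw$absorbed + agg$absorbed
      raw$transmitted <- raw$transmitted + agg$transmitted
      raw$escaped <- raw$escaped + agg$escaped
      raw$n_photons <- raw$n_photons + agg$n_photons
      raw
    }
  }
  stack <- build_optical_stack(model, chromophores,
                               source$center_wavelength_nm)
  eng <- stack_to_engine_layers(model, stack)
  mc_result_from_raw(agg, eng$layer_names, detectors,
                     source$center_wavelength_nm, config, config$seed)
}

# Wavelengths and photon allocation for a source band.
band_samples <- function(source, chromophores) {
  if (source$spectral_mode == "monochromatic" ||
      source$bandwidth_3db_nm == 0) {
    return(data.frame(lambda = source$center_wavelength_nm, weight = 1,
                      n_photons = NA))
  }
  sigma <- source$bandwidth_3db_nm / 2.355
  lam <- source$center_wavelength_nm +
    sigma * seq(-2, 2, length.out = source$n_samples)
  w <- exp(-0.5 * ((lam - source$center_wavelength_nm) / sigma)^2)
  w <- w / sum(w)
  data.frame(lambda = lam, weight = w, n_photons = NA)
}

# Fill photon allocation lazily (needs config); called from run_mc.
# (Allocation is proportional to the Gaussian weight, at least 1 photon.)
.allocate_photons <- function(samples, n_total) {
  if (nrow(samples) == 1L) { samples$n_photons <- n_total; return(samples) }
  n <- pmax(1, round(samples$weight * n_total))
  samples$n_photons <- n
  samples
}

#' Homogeneous-medium Monte Carlo run
#'
#' Convenience driver for validation studies: a single homogeneous layer of
#' given optical properties with no glass window, observed through arbitrary
#' detector rings. Used to compare against the diffusion-dipole closed form.
#'
#' @param mu_a Absorption coefficient (cm^-1).
#' @param mu_s_prime Reduced scattering coefficient (cm^-1).
#' @param g Anisotropy (default 0: isotropic scattering with
#'   mu_s = mu_s', exploiting the similarity relation).
#' @param n Medium refractive index (default 1.4).
#' @param ambient_n Index above the surface (default 1.0).
#' @param thickness_cm Slab thickness (default 20 cm, effectively
#'   semi-infinite).
#' @param detectors A [detector_spec()].
#' @param config An [mc_config()].
#' @return An `mc_result`.
#' @export
run_mc_homogeneous <- function(mu_a, mu_s_prime, g = 0, n = 1.4,
                               ambient_n = 1.0, thickness_cm = 20,
                               detectors = detector_spec(), config = mc_config()) {
  if (mu_s_prime <= 0) stop("`mu_s_prime` must be positive", call. = FALSE)
  mu_s <- mu_s_prime / (1 - g)
  raw <- mc_engine(mu_a, mu_s, g, n, thickness_cm, ambient_n, n,
                   detectors, config)
  mc_result_from_raw(raw, "medium", detectors, NA_real_, config, config$seed)
}

#' Spatially resolved reflectance from an MC result
#'
#' Converts per-ring detected fractions into reflectance per unit area
#' (cm^-2), the quantity the diffusion dipole model predicts.
#'
#' @param result An `mc_result`.
#' @param detectors The [detector_spec()] used for the run.
#' @return data.frame with `rho_mm`, `R_per_cm2`, `se`.
#' @export
mc_radial_reflectance <- function(result, detectors) {
  lo <- (detectors$ring_centers_mm - detectors$ring_width_mm / 2) / 10
  hi <- (detectors$ring_centers_mm + detectors$ring_width_mm / 2) / 10
  area <- pi * (hi^2 - lo^2)
  data.frame(rho_mm = detectors$ring_centers_mm,
             R_per_cm2 = result$detected$fraction / area,
             se = result$detected$fraction_se / area)
}

#' Differential absorbance spectrum from Monte Carlo runs
#'
#' For each source band, simulates the model and forms
#' A_D = ln(I_near / I_far) from the detected weights of the selected ring
#' pair, propagating Monte Carlo standard errors.
#'
#' @param model A [skin_model()].
#' @param chromophores A [chromophore_set()].
#' @param sources List of [source_spec()] (default the six instrument bands).
#' @param detectors A [detector_spec()].
#' @param config An [mc_config()].
#' @param pair Length-2 vector of ring centre radii (mm), near then far.
#' @return An [ad_spectrum()] with a `se` column.
#' @export
simulate_ad_spectrum <- function(model, chromophores,
                                 sources = default_sources(),
                                 detectors = detector_spec(),
                                 config = mc_config(),
                                 pair = c(0.9, 2.3)) {
  if (length(pair) != 2 || pair[1] >= pair[2])
    stop("`pair` must be (near, far) ring radii with near < far",
         call. = FALSE)
  res <- lapply(seq_along(sources), function(i) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1) * 1000L
    run_mc(model, chromophores, sources[[i]], detectors, cfg)
  })
  ad_from_mc_results(res, detectors, pair,
                     condition = "mc_simulation")
}

ad_from_mc_results <- function(results, detectors, pair, condition) {
  idx <- match(pair, detectors$ring_centers_mm)
  if (anyNA(idx))
    stop("`pair` radii must match detector ring centres", call. = FALSE)
  lam <- vapply(results, `[[`, 0, "wavelength_nm")
  vals <- vapply(results, function(r) {
    I1 <- r$detected$weight[idx[1]]; I2 <- r$detected$weight[idx[2]]
    if (I1 <= 0 || I2 <= 0)
      stop(sprintf(paste0(
        "zero detected weight at lambda=%g nm (rings %g/%g mm); ",
        "increase the photon budget"), r$wavelength_nm, pair[1], pair[2]),
        call. = FALSE)
    se <- sqrt((r$detected$se[idx[1]] / I1)^2 + (r$detected$se[idx[2]] / I2)^2)
    c(log(I1 / I2), se)
  }, c(0, 0))
  ad_spectrum(lam, vals[1, ], pair = pair, condition = condition,
              se = vals[2, ])
}

#' Differential-absorbance change under a blood-volume perturbation
#'
#' Returns delta A_D = A_D(baseline) - A_D(perturbed) per source band, with
#' the absorption and scattering consequences of the blood-volume change
#' individually switchable to decompose the spectrum into its two physical
#' channels. Two estimators are available:
#'
#' * `method = "reweight"` (default): a single simulation per band; every
#'   detected photon also contributes a perturbation-MC reweighted estimate
#'   of the perturbed detected weight (likelihood ratio over its recorded
#'   collisions and path lengths in the perturbed layers). Baseline and
#'   perturbed arms share identical photon paths, so band-to-band structure
#'   of the difference is resolvable at desk photon budgets.
#' * `method = "paired"`: two simulations with common per-photon seeds.
#'   Paths diverge at the first scattering difference, so this estimator
#'   needs far more photons for the same precision; it serves as an
#'   independent cross-check of the reweighted one.
#'
#' The photon budget is split into `n_blocks` seed blocks; the spread of the
#' per-block differences provides the standard error, honouring the
#' correlation between arms.
#'
#' @param model A [skin_model()].
#' @param chromophores A [chromophore_set()].
#' @param spec A [perturbation_spec()].
#' @param channels `"both"` (default), `"absorption_only"` or
#'   `"scattering_only"`.
#' @param sources,detectors,config,pair As in [simulate_ad_spectrum()].
#' @param n_blocks Number of seed blocks (>= 2 for an SE estimate).
#' @param method `"reweight"` (perturbation MC, default) or `"paired"`
#'   (common-seed paired runs).
#' @return data.frame with `wavelength_nm`, `delta_ad`, `se`.
#' @export
blood_perturbation_spectrum <- function(model, chromophores, spec,
                                        channels = c("both", "absorption_only",
                                                     "scattering_only"),
                                        sources = default_sources(),
                                        detectors = detector_spec(),
                                        config = mc_config(),
                                        pair = c(0.9, 2.3),
                                        n_blocks = 8,
                                        method = c("reweight", "paired")) {
  channels <- match.arg(channels)
  method <- match.arg(method)
  perturbed <- apply_perturbation(model, spec)
  idx <- match(pair, detectors$ring_centers_mm)
  if (length(pair) != 2 || anyNA(idx) || pair[1] >= pair[2])
    stop("`pair` must be two detector ring centres with near < far",
         call. = FALSE)
  n_per_block <- max(1, round(config$n_photons / n_blocks))
  rows <- lapply(seq_along(sources), function(i) {
    lam <- sources[[i]]$center_wavelength_nm
    base_stack <- build_optical_stack(model, chromophores, lam)
    pert_stack <- build_optical_stack(perturbed, chromophores, lam)
    if (channels == "absorption_only") {
      pert_stack$mu_s <- base_stack$mu_s
      pert_stack$mu_s_prime <- base_stack$mu_s_prime
    } else if (channels == "scattering_only") {
      pert_stack$mu_a <- base_stack$mu_a
    }
    eng_b <- stack_to_engine_layers(model, base_stack)
    eng_p <- stack_to_engine_layers(model, pert_stack)
    run_block <- function(eng, seed, alt = NULL) {
      mc_engine(eng$mu_a, eng$mu_s, eng$g, eng$n, eng$thickness_cm,
                model$ambient_n, eng$n[length(eng$n)],
                detectors, config, n_photons = n_per_block, seed = seed,
                mu_a_alt = alt$mu_a, mu_s_alt = alt$mu_s)
    }
    wb <- wp <- c(0, 0)
    d_blk <- numeric(n_blocks)
    for (b in seq_len(n_blocks)) {
      seed_b <- config$seed + (i - 1) * 1000L + (b - 1)
      if (method == "reweight") {
        raw <- run_block(eng_b, seed_b, alt = eng_p)
        Ib <- raw$detected_w[idx]
        Ip <- raw$detected_w_alt[idx]
      } else {
        Ib <- run_block(eng_b, seed_b)$detected_w[idx]
        Ip <- run_block(eng_p, seed_b)$detected_w[idx]
      }
      wb <- wb + Ib; wp <- wp + Ip
      d_blk[b] <- if (all(Ib > 0) && all(Ip > 0))
        log(Ib[1] / Ib[2]) - log(Ip[1] / Ip[2]) else NA_real_
    }
    if (any(wb <= 0) || any(wp <= 0))
      stop(sprintf(paste0("zero detected weight at lambda=%g nm; ",
                          "increase the photon budget"), lam), call. = FALSE)
    delta <- log(wb[1] / wb[2]) - log(wp[1] / wp[2])
    ok <- !is.na(d_blk)
    se <- if (sum(ok) >= 2) sd(d_blk[ok]) / sqrt(sum(ok)) else NA_real_
    data.frame(wavelength_nm = lam, delta_ad = delta, se = se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
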