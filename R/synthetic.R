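# Seeded synthetic-data generators: OGTT glucose excursions and optical
# time series with condition-dependent blood-flow drift, and arm-elevation
# paired spectra. Together with the chromophore / scattering fixtures these
# let every analysis stage run without any external data.

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic OGTT generator
#'
#' Defaults encode the study conditions: fasting baseline glucose
#' 5.0 +/- 0.6 mmol/L across subjects, fingertip reference readings every
#' 5 min from two meters whose average is the reference value, recordings of
#' 1-3 h ending once glucose falls below 6 mmol/L, and an optical coupling
#' such that a 1 mmol/L glucose change moves A_D by about 1e-3 a.u. (the
#' order of the instrument's stability criterion). The insulin-coupled drift
#' is a logistic onset (amplitude drawn per subject, lognormal around
#' 0.004 a.u. -- the scale of the observed blood-flow spectral change at
#' 1550 nm) with a lag after ingestion; under the pre-stimulated condition
#' the drift is suppressed entirely.
#'
#' @param baseline_cg Mean fasting glucose (mmol/L).
#' @param baseline_sd Between-subject SD of fasting glucose (mmol/L).
#' @param peak_amp Mean excursion amplitude above baseline (mmol/L).
#' @param peak_amp_sd Between-subject SD of the amplitude (mmol/L).
#' @param t_peak Mean time-to-peak (min).
#' @param t_peak_sd Between-subject SD of time-to-peak (min).
#' @param shape Gamma-variate shape exponent of the excursion.
#' @param alpha_ad Baseline A_D offset (a.u.).
#' @param beta A_D-glucose coupling (a.u. per mmol/L).
#' @param noise_sigma_ad Optical white-noise SD (a.u.).
#' @param glucometer_sigma Single-meter reading SD (mmol/L); two meters are
#'   averaged.
#' @param drift_amp_meanlog,drift_amp_sdlog Lognormal parameters of the
#'   per-subject drift amplitude (a.u.), control condition only.
#' @param drift_lag,drift_lag_sd Mean and SD of the drift onset lag (min).
#' @param drift_width Logistic transition width of the onset (min).
#' @param duration Nominal recording duration (min); extended in
#'   `sample_interval` steps (up to `max_duration`) until glucose has
#'   returned below 6 mmol/L, mirroring the protocol's stopping rule.
#' @param max_duration Hard cap on the recording (min).
#' @param sample_interval Sampling interval (min).
#' @return An object of class `ogtt_gen_params`.
#' @export
ogtt_gen_params <- function(baseline_cg = 5.0, baseline_sd = 0.6,
                            peak_amp = 4.5, peak_amp_sd = 1.0,
                            t_peak = 35, t_peak_sd = 8, shape = 2,
                            alpha_ad = 0.6, beta = 1.2e-3,
                            noise_sigma_ad = 4e-4, glucometer_sigma = 0.3,
                            drift_amp_meanlog = log(0.004),
                            drift_amp_sdlog = 0.6,
                            drift_lag = 30, drift_lag_sd = 10,
                            drift_width = 15,
                            duration = 120, max_duration = 180,
                            sample_interval = 5) {
  p <- as.list(environment())
  scales <- c("baseline_cg", "t_peak", "shape", "beta",
              "sample_interval", "duration", "max_duration")
  for (nm in scales)
    if (p[[nm]] <= 0) stop("`", nm, "` must be positive", call. = FALSE)
  if (p$peak_amp < 0) stop("`peak_amp` must be >= 0", call. = FALSE)
  if (p$duration < 60 || p$max_duration > 1e4)
    stop("`duration` must be at least 60 min", call. = FALSE)
  structure(p, class = "ogtt_gen_params")
}

# Gamma-variate excursion: 0 at t = 0, peak `amp` at t = tp, decaying back.
gamma_excursion <- function(t, amp, tp, shape) {
  x <- pmax(t, 0) / tp
  amp * x^shape * exp(shape * (1 - x))
}

#' Generate a synthetic OGTT glucose curve
#'
#' Fasting baseline plus a gamma-variate excursion (rise to a peak near
#' 30-45 min, smooth decay toward baseline). Subject-level parameters
#' (baseline, amplitude, time-to-peak) are drawn once per seed; the record
#' is extended in sampling steps until glucose has fallen back below
#' 6 mmol/L, up to the maximum duration.
#'
#' @param params An [ogtt_gen_params()].
#' @param seed Integer seed.
#' @return data.frame with `time_min`, `cg_true` (mmol/L).
#' @export
gen_glucose_curve <- function(params = ogtt_gen_params(), seed = 1) {
  stopifnot(inherits(params, "ogtt_gen_params"))
  with_seed(seed, {
    base <- rnorm(1, params$baseline_cg, params$baseline_sd)
    amp <- if (params$peak_amp == 0) 0 else
      max(rnorm(1, params$peak_amp, params$peak_amp_sd), 1.5)
    tp <- max(rnorm(1, params$t_peak, params$t_peak_sd), 15)
    t <- seq(0, params$duration, by = params$sample_interval)
    cg <- base + gamma_excursion(t, amp, tp, params$shape)
    while (cg[length(cg)] >= 6 &&
           t[length(t)] + params$sample_interval <= params$max_duration) {
      t <- c(t, t[length(t)] + params$sample_interval)
      cg <- c(cg, base + gamma_excursion(t[length(t)], amp, tp, params$shape))
    }
    data.frame(time_min = t, cg_true = cg)
  })
}

#' Generate a synthetic OGTT case
#'
#' Builds the optical channel on top of [gen_glucose_curve()]:
#' `ad_1550(t) = alpha + beta * cg_true(t) + drift(t) + N(0, sigma_ad)`, and
#' the glucose reference as the truth plus the mean of two independent meter
#' errors. Under `condition = "pre_stimulated"` the blood-flow drift is
#' identically zero (pre-heated, saturated vasodilation); under `"control"`
#' it is a logistic onset with per-subject amplitude and lag, emulating
#' insulin-driven blood-flow change after glucose ingestion.
#'
#' @param params An [ogtt_gen_params()].
#' @param condition `"pre_stimulated"` or `"control"`.
#' @param seed Integer seed.
#' @return An [ogtt_case()]; the drawn truth (true glucose, drift series,
#'   coupling) is attached as attribute `"truth"` for parameter-recovery
#'   checks.
#' @export
gen_ogtt_case <- function(params = ogtt_gen_params(),
                          condition = c("pre_stimulated", "control"),
                          seed = 1) {
  condition <- match.arg(condition)
  curve <- gen_glucose_curve(params, seed)
  with_seed(seed + 484001L, {
    t <- curve$time_min
    drift <- if (condition == "control") {
      amp_d <- exp(rnorm(1, params$drift_amp_meanlog, params$drift_amp_sdlog))
      lag <- max(rnorm(1, params$drift_lag, params$drift_lag_sd), 5)
      -amp_d * plogis((t - lag) / (params$drift_width / 4))
    } else rep(0, length(t))
    ad <- params$alpha_ad + params$beta * curve$cg_true + drift +
      rnorm(length(t), 0, params$noise_sigma_ad)
    meters <- matrix(rnorm(2 * length(t), 0, params$glucometer_sigma), ncol = 2)
    cg_ref <- pmax(curve$cg_true + rowMeans(meters), 0.5)
    case <- ogtt_case(t, cg_ref, ad, condition = condition)
    attr(case, "truth") <- list(cg_true = curve$cg_true, drift = drift,
                                beta = params$beta, alpha = params$alpha_ad)
    case
  })
}

#' Generate a synthetic OGTT cohort
#'
#' @param n_cases Number of cases.
#' @param condition `"pre_stimulated"` or `"control"`.
#' @param params An [ogtt_gen_params()].
#' @param seed Integer seed; case i uses `seed * 1000 + i`.
#' @return List of [ogtt_case()] objects.
#' @export
gen_ogtt_cohort <- function(n_cases, condition, params = ogtt_gen_params(),
                            seed = 1) {
  lapply(seq_len(n_cases), function(i)
    gen_ogtt_case(params, condition, seed = seed * 1000L + i))
}

#' Generate paired arm-elevation spectra
#'
#' Emulates the blood-spectrum protocol: A_D0 measured with the forearm at
#' heart level (baseline model) and A_D1 with the forearm raised (blood
#' fraction perturbed in the two blood-net layers), repeated `n_repeats`
#' times with i.i.d. measurement noise per wavelength. Spectra come either
#' from the fast diffusion surrogate (default) or from full Monte Carlo
#' transport.
#'
#' @param model A [skin_model()].
#' @param chromophores A [chromophore_set()].
#' @param spec A [perturbation_spec()]; the default encodes the arm-raise
#'   blood-volume drop/rise of +/-50% relative in the blood-net layers.
#' @param noise_sigma Measurement noise SD (a.u.), default 2e-4.
#' @param seed Integer seed.
#' @param n_repeats Number of paired repeats (protocol default 3).
#' @param wavelengths Band centres (nm).
#' @param pair (near, far) ring radii (mm).
#' @param engine `"diffusion"` (fast surrogate) or `"mc"`.
#' @param config [mc_config()] for `engine = "mc"`.
#' @return List of length `n_repeats`; each element is a list with
#'   [ad_spectrum()] entries `ad0` and `ad1`.
#' @export
gen_arm_raise_pair <- function(model, chromophores,
                               spec = perturbation_spec(),
                               noise_sigma = 2e-4, seed = 1, n_repeats = 3,
                               wavelengths = c(1050, 1219, 1314, 1380,
                                               1550, 1609),
                               pair = c(0.9, 2.3),
                               engine = c("diffusion", "mc"),
                               config = mc_config(n_photons = 2e5)) {
  engine <- match.arg(engine)
  perturbed <- apply_perturbation(model, spec)
  clean <- if (engine == "diffusion") {
    list(ad0 = ad_diffusion_surrogate(model, chromophores, wavelengths, pair),
         ad1 = ad_diffusion_surrogate(perturbed, chromophores, wavelengths,
                                      pair))
  } else {
    src <- lapply(wavelengths, source_spec)
    list(ad0 = simulate_ad_spectrum(model, chromophores, src,
                                    config = config, pair = pair),
         ad1 = simulate_ad_spectrum(perturbed, chromophores, src,
                                    config = config, pair = pair))
  }
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(i) {
      list(ad0 = ad_spectrum(wavelengths,
                             clean$ad0$ad + rnorm(length(wavelengths), 0,
                                                  noise_sigma),
                             pair = pair, condition = "arm_at_heart_level"),
           ad1 = ad_spectrum(wavelengths,
                             clean$ad1$ad + rnorm(length(wavelengths), 0,
                                                  noise_sigma),
                             pair = pair, condition = "arm_raised"))
    })
  })
}
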