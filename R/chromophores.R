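#' Chromophore absorption spectra on a common wavelength grid
#'
#' A `chromophore_set` bundles the absorption coefficient spectra of the three
#' constituents used by the layered skin absorption model: pure water,
#' whole blood, and the remaining ("other") tissue components, all in cm^-1 on
#' one ascending wavelength grid (nm).
#'
#' @param wavelengths Ascending numeric wavelength grid in nm.
#' @param mu_a_water,mu_a_blood,mu_a_other Non-negative absorption coefficient
#'   spectra (cm^-1), one value per grid point.
#' @return An object of class `chromophore_set`.
#' @export
chromophore_set <- function(wavelengths, mu_a_water, mu_a_blood, mu_a_other) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2L || is.unsorted(wavelengths, strictly = TRUE))
    stop("`wavelengths` must be a strictly ascending grid of length >= 2",
         call. = FALSE)
  spectra <- list(mu_a_water = as.numeric(mu_a_water),
                  mu_a_blood = as.numeric(mu_a_blood),
                  mu_a_other = as.numeric(mu_a_other))
  for (nm in names(spectra)) {
    v <- spectra[[nm]]
    if (length(v) != length(wavelengths))
      stop(sprintf("`%s` must match the wavelength grid length", nm),
           call. = FALSE)
    if (anyNA(v) || any(v < 0))
      stop(sprintf("`%s` must be non-negative and finite", nm), call. = FALSE)
  }
  structure(c(list(wavelengths = wavelengths), spectra),
            class = "chromophore_set")
}

#' @export
print.chromophore_set <- function(x, ...) {
  cat(sprintf("<chromophore_set> %d points, %g-%g nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# Linear interpolation on the grid; extrapolation is forbidden.
interp_on_grid <- function(grid, values, lambda, what = "spectrum") {
  if (any(lambda < min(grid)) || any(lambda > max(grid)))
    stop(sprintf("wavelength outside the %s grid [%g, %g] nm",
                 what, min(grid), max(grid)), call. = FALSE)
  approx(grid, values, xout = lambda, method = "linear")$y
}

#' Evaluate a chromophore spectrum at arbitrary wavelengths
#'
#' Linear interpolation on the stored grid; requests outside the grid error.
#'
#' @param chromophores A [chromophore_set()].
#' @param lambda Wavelengths (nm).
#' @param which One of `"water"`, `"blood"`, `"other"`.
#' @return Absorption coefficients (cm^-1) at `lambda`.
#' @export
chromophore_mu_a <- function(chromophores, lambda,
                             which = c("water", "blood", "other")) {
  stopifnot(inherits(chromophores, "chromophore_set"))
  which <- match.arg(which)
  interp_on_grid(chromophores$wavelengths,
                 chromophores[[paste0("mu_a_", which)]],
                 lambda, "chromophore")
}

#' Synthetic chromophore absorption fixture
#'
#' Builds smooth, strictly positive literature-shaped analytic absorption
#' spectra for water, whole blood and "other" tissue components over
#' 1000-1700 nm. These are synthetic stand-ins shaped like published NIR
#' spectra. The water curve is an asymmetric 1450 nm band (steep blue edge,
#' broad red tail) plus the small 1190 nm band and the rising edge of the
#' 1940 nm band, anchored to the standard water absorption levels (about
#' 1.2 cm^-1 at 1300 nm, 3 at 1350, 29 at the 1450 peak, 10 at 1550 and
#' 5-7 beyond 1600 nm). Blood is modelled as a water-rich suspension (75%
#' water) plus a broad haemoglobin feature near 1070 nm; "other"
#' (protein/lipid background) is a gentle curve with a 1210 nm lipid
#' shoulder. Real tabulated spectra can be substituted via
#' [load_spectra_csv()] anywhere a `chromophore_set` is accepted.
#'
#' @param grid Wavelength grid (nm) within \[1000, 1700\]; default 5 nm steps.
#' @return A [chromophore_set()].
#' @export
gen_chromophore_fixture <- function(grid = seq(1000, 1700, by = 5)) {
  if (any(grid < 1000) || any(grid > 1700))
    stop("fixture grid must lie within [1000, 1700] nm", call. = FALSE)
  gauss <- function(l, c, s) exp(-((l - c) / s)^2)
  agauss <- function(l, c, s_lo, s_hi)
    exp(-((l - c) / ifelse(l < c, s_lo, s_hi))^2)
  water <- 0.15 + 1.0 * gauss(grid, 1190, 45) + 1.0 * gauss(grid, 1300, 90) +
    29 * agauss(grid, 1450, 65, 110) + 120 * gauss(grid, 1940, 140)
  blood <- 0.35 + 0.75 * water + 1.1 * gauss(grid, 1070, 120)
  other <- 0.45 + 0.35 * gauss(grid, 1210, 55) + 0.6 * gauss(grid, 1720, 100)
  chromophore_set(grid, water, blood, other)
}

#' Synthetic reduced-scattering fixture
#'
#' Power-law decay mu_s'(lambda) = a * (lambda / 1000 nm)^(-b), the standard
#' parameterisation for tissue reduced scattering in the NIR. Amplitudes and
#' exponents are per-layer-kind defaults in the range reported for skin.
#'
#' @param kind Layer kind (see [skin_layer()]); controls the default a, b.
#' @param grid Wavelength grid (nm).
#' @param a Reduced scattering at 1000 nm (cm^-1); overrides the kind default.
#' @param b Scattering power-law exponent; overrides the kind default.
#' @return Numeric vector of mu_s' (cm^-1) on `grid`.
#' @export
gen_mu_s_fixture <- function(kind = c("dermal", "stratum_corneum",
                                      "living_epidermis", "subcutaneous"),
                             grid = seq(1000, 1700, by = 5),
                             a = NULL, b = NULL) {
  kind <- match.arg(kind)
  def <- switch(kind,
                stratum_corneum = c(30, 1.4),
                living_epidermis = c(28, 1.4),
                dermal = c(22, 1.3),
                subcutaneous = c(15, 0.8))
  if (is.null(a)) a <- def[1]
  if (is.null(b)) b <- def[2]
  a * (grid / 1000)^(-b)
}

#' Synthetic glucose sensitivity spectrum
#'
#' Differential-absorbance response to a 1 mmol/L glucose concentration change
#' (a.u. per mmol/L) as a function of wavelength. The true in vivo response
#' spectrum is instrument- and subject-specific; this synthetic fixture peaks
#' at 1550 nm with a peak amplitude equal to the OGTT generator's default
#' coupling (1.2e-3 a.u. per mmol/L) so that the spectral and time-series
#' branches of the package are mutually consistent. Replaceable via CSV.
#'
#' @param grid Wavelength grid (nm).
#' @param peak Peak sensitivity (a.u. per mmol/L) at 1550 nm.
#' @return data.frame with columns `wavelength_nm`, `sensitivity`.
#' @export
glucose_sensitivity_fixture <- function(grid = seq(1000, 1700, by = 5),
                                        peak = 1.2e-3) {
  s <- peak * exp(-((grid - 1550) / 80)^2) + 0.05 * peak
  data.frame(wavelength_nm = grid, sensitivity = s)
}
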