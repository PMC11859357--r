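# Measurement algebra for diffuse-reflectance glucose sensing: absorbance,
# differential absorbance, arm-elevation blood-spectrum extraction, repeat
# averaging and spectral comparison.

#' Differential absorbance spectrum container
#'
#' @param wavelengths Wavelengths (nm).
#' @param ad Differential absorbance values (a.u.), finite.
#' @param pair Detector ring pair (near, far) in mm.
#' @param condition Free-text condition label.
#' @param se Optional standard errors.
#' @return An object of class `ad_spectrum` (a data.frame with columns
#'   `wavelength_nm`, `ad` and optionally `se`, plus `pair` / `condition`
#'   attributes).
#' @export
ad_spectrum <- function(wavelengths, ad, pair = c(NA_real_, NA_real_),
                        condition = "unspecified", se = NULL) {
  if (length(wavelengths) != length(ad))
    stop("`wavelengths` and `ad` must have equal length", call. = FALSE)
  if (!all(is.finite(ad)))
    stop("`ad` must be finite", call. = FALSE)
  df <- data.frame(wavelength_nm = as.numeric(wavelengths),
                   ad = as.numeric(ad))
  if (!is.null(se)) df$se <- as.numeric(se)
  structure(df, pair = as.numeric(pair), condition = condition,
            class = c("ad_spectrum", "data.frame"))
}

#' @export
print.ad_spectrum <- function(x, ...) {
  p <- attr(x, "pair")
  cat(sprintf("<ad_spectrum> pair %g/%g mm, condition '%s'\n",
              p[1], p[2], attr(x, "condition")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Absorbance from detected and incident intensity
#'
#' A = -ln(I / I0).
#'
#' @param I Detected intensity, > 0.
#' @param I0 Incident intensity, > 0.
#' @return Absorbance (a.u.).
#' @export
absorbance <- function(I, I0) {
  if (any(I <= 0) || any(I0 <= 0))
    stop("intensities must be positive", call. = FALSE)
  -log(I / I0)
}

#' Differential absorbance between two detector channels
#'
#' A_D = A_far - A_near = ln(I_near / I_far). The incident intensity cancels,
#' so any common-mode factor (source drift, coupling changes) applied to both
#' channels leaves A_D unchanged -- the property the two-channel measurement
#' exists for.
#'
#' @param I1 Intensity at the nearer ring, > 0.
#' @param I2 Intensity at the farther ring, > 0.
#' @return A_D (a.u.).
#' @export
differential_absorbance <- function(I1, I2) {
  if (any(I1 <= 0) || any(I2 <= 0))
    stop("intensities must be positive", call. = FALSE)
  log(I1 / I2)
}

#' Blood spectrum from paired arm-position measurements
#'
#' The arm-elevation protocol measures A_D0 with the forearm at heart level
#' and A_D1 with the forearm raised; the blood-volume signature is their
#' difference A_D,blood = A_D0 - A_D1, evaluated per wavelength.
#'
#' @param ad0,ad1 [ad_spectrum()] objects on identical wavelength grids and
#'   detector pairs.
#' @return An [ad_spectrum()] of the difference.
#' @export
blood_spectrum <- function(ad0, ad1) {
  stopifnot(inherits(ad0, "ad_spectrum"), inherits(ad1, "ad_spectrum"))
  if (!identical(ad0$wavelength_nm, ad1$wavelength_nm))
    stop("wavelength grids differ", call. = FALSE)
  p0 <- attr(ad0, "pair"); p1 <- attr(ad1, "pair")
  if (!isTRUE(all.equal(p0, p1)))
    stop("detector pairs differ", call. = FALSE)
  ad_spectrum(ad0$wavelength_nm, ad0$ad - ad1$ad, pair = p0,
              condition = "blood_spectrum")
}

#' Average repeated blood spectra
#'
#' Per-wavelength mean and sample (n-1) standard deviation over repeated
#' measurements; the protocol default is three arm-elevation repeats.
#'
#' @param spectra List of [ad_spectrum()] objects (or plain numeric vectors
#'   on a shared grid).
#' @return An object of class `blood_spectrum_summary`: data.frame with
#'   `wavelength_nm`, `mean_ad`, `sd_ad` and an `n_repeats` attribute.
#' @export
average_repeats <- function(spectra) {
  if (!length(spectra)) stop("empty repeat list", call. = FALSE)
  if (inherits(spectra[[1]], "ad_spectrum")) {
    grid <- spectra[[1]]$wavelength_nm
    for (s in spectra)
      if (!identical(s$wavelength_nm, grid))
        stop("repeats are on different wavelength grids", call. = FALSE)
    mat <- vapply(spectra, `[[`, numeric(length(grid)), "ad")
  } else {
    grid <- seq_along(spectra[[1]])
    mat <- vapply(spectra, as.numeric, numeric(length(spectra[[1]])))
    grid <- as.numeric(grid)
  }
  mat <- matrix(mat, nrow = length(grid))
  structure(data.frame(
    wavelength_nm = grid,
    mean_ad = rowMeans(mat),
    sd_ad = if (ncol(mat) > 1) apply(mat, 1, sd) else rep(0, nrow(mat))),
    n_repeats = ncol(mat),
    class = c("blood_spectrum_summary", "data.frame"))
}

#' Glucose-equivalent concentration of a spectral change
#'
#' Expresses a differential-absorbance change as the glucose concentration
#' change that would produce an equal A_D change at the query wavelength:
#' delta_ad(at) / sensitivity(at), in mmol/L.
#'
#' @param delta_ad An [ad_spectrum()] (or data.frame with `wavelength_nm`,
#'   `ad`) of the spectral change.
#' @param sensitivity data.frame with `wavelength_nm`, `sensitivity` (a.u.
#'   per mmol/L), e.g. [glucose_sensitivity_fixture()].
#' @param at Query wavelength (nm), default 1550.
#' @return Equivalent glucose change (mmol/L).
#' @export
glucose_equivalent <- function(delta_ad, sensitivity, at = 1550) {
  da <- interp_on_grid(delta_ad$wavelength_nm, delta_ad$ad, at, "spectrum")
  s <- interp_on_grid(sensitivity$wavelength_nm, sensitivity$sensitivity, at,
                      "sensitivity")
  if (any(s == 0)) stop("zero sensitivity at the query wavelength",
                        call. = FALSE)
  da / s
}

#' Pearson spectral similarity
#'
#' Pearson correlation of two spectra across their common wavelength grid;
#' 1 for proportional spectra, -1 for sign-flipped ones.
#'
#' @param a,b Numeric vectors (or `ad_spectrum` objects) on a common grid
#'   with at least two points.
#' @return Correlation in \[-1, 1\].
#' @export
spectral_similarity <- function(a, b) {
  va <- if (inherits(a, "ad_spectrum")) a$ad else as.numeric(a)
  vb <- if (inherits(b, "ad_spectrum")) b$ad else as.numeric(b)
  if (length(va) != length(vb) || length(va) < 2)
    stop("spectra must share a grid of length >= 2", call. = FALSE)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("similarity undefined for a zero-variance spectrum", call. = FALSE)
  cor(va, vb)
}
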