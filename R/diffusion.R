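#' Diffusion-dipole spatially resolved diffuse reflectance
#'
#' Steady-state closed-form reflectance R(rho) of a semi-infinite homogeneous
#' turbid medium (the Farrell dipole solution): an isotropic point source at
#' depth z0 = 1/(mu_a + mu_s') and its negative image above the extrapolated
#' boundary at z_b = 2 A D, with the internal-reflection parameter A computed
#' from the relative refractive index by the Groenhuis polynomial
#' approximation. Used here as an independent validation oracle for the Monte
#' Carlo engine; valid when mu_s' >> mu_a and rho is at least about one
#' transport mean free path.
#'
#' @param mu_a Absorption coefficient (cm^-1), >= 0.
#' @param mu_s_prime Reduced scattering coefficient (cm^-1), > 0.
#' @param n_rel Refractive index of the medium relative to the ambient.
#' @param rho_mm Radial distance(s) from the source (mm).
#' @return Diffuse reflectance per unit area (cm^-2) at each `rho_mm`.
#' @export
farrell_reflectance <- function(mu_a, mu_s_prime, n_rel, rho_mm) {
  if (mu_s_prime <= 0) stop("`mu_s_prime` must be positive", call. = FALSE)
  if (mu_a < 0) stop("`mu_a` must be non-negative", call. = FALSE)
  if (mu_s_prime < 5 * mu_a)
    warning("mu_s' is not >> mu_a; diffusion approximation is questionable",
            call. = FALSE)
  mu_t <- mu_a + mu_s_prime
  albedo <- mu_s_prime / mu_t
  mu_eff <- sqrt(3 * mu_a * mu_t)
  z0 <- 1 / mu_t
  A <- internal_reflection_A(n_rel)
  D <- 1 / (3 * mu_t)
  zb <- 2 * A * D
  rho <- rho_mm / 10
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  (albedo / (4 * pi)) *
    (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
       (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2)
}

# Groenhuis approximation to the internal-reflection boundary parameter.
internal_reflection_A <- function(n_rel) {
  r_id <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + r_id) / (1 - r_id)
}

#' Differential absorbance of a layer stack via diffusion theory
#'
#' Fast analytic surrogate for the Monte Carlo engine: the layered model is
#' homogenised (thickness-weighted mean mu_a and mu_s' over the layers within
#' the probed depth) and A_D = ln(R(rho_near) / R(rho_far)) is evaluated from
#' the diffusion dipole. Used by the arm-elevation generator where thousands
#' of spectra are needed; accurate at first order in the property changes and
#' smooth in wavelength, but not a substitute for transport where layer
#' structure matters.
#'
#' @param model A [skin_model()].
#' @param chromophores A [chromophore_set()].
#' @param wavelengths Wavelengths (nm).
#' @param pair Length-2 vector (near, far) ring radii in mm.
#' @param probe_depth_cm Depth over which layer properties are averaged
#'   (default 0.22 cm, through the deep blood net dermis).
#' @return An [ad_spectrum()].
#' @export
ad_diffusion_surrogate <- function(model, chromophores,
                                   wavelengths = c(1050, 1219, 1314, 1380,
                                                   1550, 1609),
                                   pair = c(0.9, 2.3),
                                   probe_depth_cm = 0.22) {
  if (length(pair) != 2 || pair[1] >= pair[2])
    stop("`pair` must be (near, far) with near < far", call. = FALSE)
  ad <- vapply(wavelengths, function(lam) {
    st <- build_optical_stack(model, chromophores, lam)
    top <- cumsum(st$thickness_cm) - st$thickness_cm
    w <- pmax(pmin(cumsum(st$thickness_cm), probe_depth_cm) - top, 0)
    w <- w / sum(w)
    mu_a <- sum(w * st$mu_a)
    msp <- sum(w * st$mu_s_prime)
    n_rel <- sum(w * st$n) / model$ambient_n
    R <- suppressWarnings(farrell_reflectance(mu_a, msp, n_rel, pair))
    log(R[1] / R[2])
  }, 0)
  ad_spectrum(wavelengths, ad, pair = pair, condition = "diffusion_surrogate")
}
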