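#' A single skin layer
#'
#' Layers carry the composition (blood and interstitial-water volume
#' fractions), geometry and scattering parameters needed to evaluate the
#' layer's absorption and reduced-scattering coefficients at any wavelength.
#' The epidermal kinds (`stratum_corneum`, `living_epidermis`) must be
#' bloodless; dermal and subcutaneous layers mix blood, water and "other"
#' components with C_Other = 1 - C_H2O - C_B.
#'
#' Reduced scattering follows the power law
#' mu_s'(lambda) = musp_scale * musp_a * (lambda/1000 nm)^(-musp_b);
#' `musp_scale` is the handle through which blood-volume perturbations scale
#' scattering (see [apply_perturbation()]).
#'
#' @param name Layer name (unique within a model).
#' @param kind One of `"stratum_corneum"`, `"living_epidermis"`, `"dermal"`,
#'   `"subcutaneous"`; selects the absorption formula in
#'   [build_optical_stack()].
#' @param thickness_cm Layer thickness in cm (> 0).
#' @param C_B Blood volume fraction in \[0, 1\].
#' @param C_H2O Interstitial water volume fraction in \[0, 1\].
#' @param g Scattering anisotropy in (-1, 1).
#' @param n Refractive index (> 1).
#' @param musp_a Reduced scattering at 1000 nm (cm^-1); default per kind from
#'   [gen_mu_s_fixture()].
#' @param musp_b Scattering power-law exponent.
#' @param musp_scale Multiplicative scattering scale (perturbation handle).
#' @param delta_CB_abs Absolute blood-fraction change already applied to this
#'   layer (perturbation bookkeeping; `C_B` includes it). Absorption is
#'   evaluated as the baseline mixture plus the linear perturbation term, so
#'   the modelled change stays first-order even where the displaced "other"
#'   volume would be exhausted.
#' @param perturb_k Coupling of the "other"-fraction change to the blood
#'   change in the perturbation term (default -1).
#' @return An object of class `skin_layer`.
#' @export
skin_layer <- function(name, kind, thickness_cm, C_B, C_H2O,
                       g = 0.9, n = 1.37,
                       musp_a = NULL, musp_b = NULL, musp_scale = 1,
                       delta_CB_abs = 0, perturb_k = -1) {
  kind <- match.arg(kind, c("stratum_corneum", "living_epidermis",
                            "dermal", "subcutaneous"))
  if (!is.numeric(thickness_cm) || thickness_cm <= 0)
    stop("`thickness_cm` must be > 0", call. = FALSE)
  if (C_B < 0 || C_B > 1 || C_H2O < 0 || C_H2O > 1)
    stop("volume fractions must lie in [0, 1]", call. = FALSE)
  if (C_B - delta_CB_abs + C_H2O > 1 + 1e-12)
    stop(sprintf("layer '%s': C_B + C_H2O must not exceed 1", name),
         call. = FALSE)
  if (kind %in% c("stratum_corneum", "living_epidermis") && C_B != 0)
    stop(sprintf("layer '%s': epidermal layers carry no blood (C_B must be 0)",
                 name), call. = FALSE)
  if (abs(g) >= 1) stop("`g` must lie in (-1, 1)", call. = FALSE)
  if (n <= 1) stop("`n` must exceed 1", call. = FALSE)
  def <- switch(kind,
                stratum_corneum = c(30, 1.4),
                living_epidermis = c(28, 1.4),
                dermal = c(22, 1.3),
                subcutaneous = c(15, 0.8))
  if (is.null(musp_a)) musp_a <- def[1]
  if (is.null(musp_b)) musp_b <- def[2]
  if (musp_a <= 0 || musp_scale <= 0)
    stop("reduced scattering must be positive", call. = FALSE)
  structure(list(name = name, kind = kind, thickness_cm = thickness_cm,
                 C_B = C_B, C_H2O = C_H2O, g = g, n = n,
                 musp_a = musp_a, musp_b = musp_b, musp_scale = musp_scale,
                 delta_CB_abs = delta_CB_abs, perturb_k = perturb_k),
            class = "skin_layer")
}

#' Reduced scattering coefficient of a layer
#'
#' @param layer A [skin_layer()].
#' @param lambda Wavelengths (nm).
#' @return mu_s' (cm^-1) at `lambda`.
#' @export
layer_mu_s_prime <- function(layer, lambda) {
  layer$musp_scale * layer$musp_a * (lambda / 1000)^(-layer$musp_b)
}

#' A layered skin model with glass superstrate
#'
#' Ordered layer stack, top to bottom, optionally topped by a clear glass
#' superstrate representing the probe window.
#'
#' @param layers List of [skin_layer()] objects, top first.
#' @param superstrate_n Glass refractive index (default 1.4).
#' @param superstrate_thickness_cm Glass thickness in cm (default 0.02); set
#'   to 0 for a bare tissue surface.
#' @param ambient_n Refractive index above the probe (default 1.0, air).
#' @return An object of class `skin_model`.
#' @export
skin_model <- function(layers, superstrate_n = 1.4,
                       superstrate_thickness_cm = 0.02, ambient_n = 1.0) {
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "skin_layer")))
    stop("`layers` must be a non-empty list of skin_layer objects",
         call. = FALSE)
  nm <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("layer names must be unique", call. = FALSE)
  if (superstrate_thickness_cm < 0 || superstrate_n <= 0 || ambient_n <= 0)
    stop("invalid superstrate/ambient parameters", call. = FALSE)
  structure(list(layers = setNames(layers, nm),
                 superstrate_n = superstrate_n,
                 superstrate_thickness_cm = superstrate_thickness_cm,
                 ambient_n = ambient_n),
            class = "skin_model")
}

#' @export
print.skin_model <- function(x, ...) {
  cat(sprintf("<skin_model> %d layers, total depth %.4f cm",
              length(x$layers), total_depth(x)))
  if (x$superstrate_thickness_cm > 0)
    cat(sprintf(", glass n=%.2f (%.3f cm)", x$superstrate_n,
                x$superstrate_thickness_cm))
  cat("\n")
  for (l in x$layers)
    cat(sprintf("  %-24s %-16s t=%.3f cm  C_B=%.2f  C_H2O=%.2f\n",
                l$name, l$kind, l$thickness_cm, l$C_B, l$C_H2O))
  invisible(x)
}

#' Total tissue depth of a model
#' @param model A [skin_model()].
#' @return Sum of layer thicknesses (cm), excluding the superstrate.
#' @export
total_depth <- function(model) {
  sum(vapply(model$layers, `[[`, 0, "thickness_cm"))
}

#' The default seven-layer skin model
#'
#' Loads the shipped seven-layer forearm skin configuration (stratum corneum,
#' living epidermis, papillary dermis, upper blood net dermis, reticular
#' dermis, deep blood net dermis, subcutaneous tissue) with its standard
#' thicknesses and blood/water volume fractions, under a 0.2 mm glass window
#' of refractive index 1.4.
#'
#' @return A [skin_model()].
#' @export
default_skin_model <- function() {
  load_skin_model(system.file("extdata", "default_skin.yaml",
                              package = "nirglucosim", mustWork = TRUE))
}

# ---- absorption formulas ----------------------------------------------------

#' Stratum corneum absorption coefficient
#'
#' mu_a = 0.1 - 8.3e-4 * lambda + 0.125 * mu_a_other(lambda). The linear term
#' is dimensionally ambiguous in its published form; evaluated with lambda in
#' nm it is negative across the whole 1000-1700 nm band, so the default
#' convention here expresses lambda in micrometres, which yields a physically
#' plausible ~0.1 cm^-1 baseline. The convention is switchable and a
#' non-negativity floor is applied (with a warning) either way.
#'
#' @param lambda Wavelength in nm, within \[1000, 1700\].
#' @param mu_a_other Absorption of the non-water, non-blood components
#'   (cm^-1) at `lambda`.
#' @param lambda_unit Unit in which the linear term consumes lambda:
#'   `"um"` (default) or `"nm"` (the published, negative-valued reading).
#' @param floor Minimum returned value (default 0).
#' @param linear_coef Coefficient of the linear term (default 8.3e-4; set to
#'   0 to drop the term).
#' @return mu_a (cm^-1).
#' @export
mu_a_stratum_corneum <- function(lambda, mu_a_other,
                                 lambda_unit = c("um", "nm"),
                                 floor = 0, linear_coef = 8.3e-4) {
  lambda_unit <- match.arg(lambda_unit)
  check_lambda_band(lambda)
  if (any(mu_a_other < 0))
    stop("`mu_a_other` must be non-negative", call. = FALSE)
  lam <- if (lambda_unit == "um") lambda / 1000 else lambda
  out <- 0.1 - linear_coef * lam + 0.125 * mu_a_other
  if (any(out < floor)) {
    warning("stratum corneum mu_a fell below the floor; floor applied",
            call. = FALSE)
    out <- pmax(out, floor)
  }
  out
}

#' Living epidermis absorption coefficient
#'
#' mu_a = 0.5e10 * lambda^-3.33 * (1 - C_H2O) + C_H2O * mu_a_water(lambda),
#' with lambda in nm in the power-law term.
#'
#' @param lambda Wavelength in nm, within \[1000, 1700\].
#' @param C_H2O Water volume fraction in \[0, 1\].
#' @param mu_a_water Water absorption (cm^-1) at `lambda`.
#' @return mu_a (cm^-1).
#' @export
mu_a_living_epidermis <- function(lambda, C_H2O, mu_a_water) {
  check_lambda_band(lambda)
  if (any(C_H2O < 0) || any(C_H2O > 1))
    stop("`C_H2O` must lie in [0, 1]", call. = FALSE)
  0.5e10 * lambda^(-3.33) * (1 - C_H2O) + C_H2O * mu_a_water
}

#' Dermal / subcutaneous absorption coefficient
#'
#' Volume-fraction mixing of the three constituents:
#' mu_a = C_B * mu_a_blood + C_H2O * mu_a_water +
#' (1 - C_H2O - C_B) * mu_a_other.
#'
#' @param lambda Wavelength(s) in nm, on the chromophore grid range.
#' @param C_B Blood volume fraction.
#' @param C_H2O Interstitial water volume fraction; `C_B + C_H2O <= 1`.
#' @param chromophores A [chromophore_set()].
#' @return mu_a (cm^-1) at `lambda`.
#' @export
mu_a_dermal <- function(lambda, C_B, C_H2O, chromophores) {
  if (C_B < 0 || C_H2O < 0 || C_B + C_H2O > 1 + 1e-12)
    stop("require C_B >= 0, C_H2O >= 0 and C_B + C_H2O <= 1", call. = FALSE)
  C_B * chromophore_mu_a(chromophores, lambda, "blood") +
    C_H2O * chromophore_mu_a(chromophores, lambda, "water") +
    (1 - C_H2O - C_B) * chromophore_mu_a(chromophores, lambda, "other")
}

#' Absorption change under a blood-volume change
#'
#' delta_mu_a = dCB * mu_a_blood + k * dCB * mu_a_other, where `delta_CB_abs`
#' is the ABSOLUTE change in blood volume fraction and the displaced volume is
#' taken from the "other" compartment (dC_Other = k * dCB, k = -1 by default)
#' while the interstitial water fraction stays fixed.
#'
#' @param delta_CB_abs Absolute change in C_B (e.g. 0.15 for an upper blood
#'   net dermis at C_B = 0.30 undergoing a +50% relative change).
#' @param chromophores A [chromophore_set()].
#' @param k Coupling of the "other"-fraction change to the blood change
#'   (default -1).
#' @param lambda Wavelengths (nm); default the full chromophore grid.
#' @return delta mu_a (cm^-1) per wavelength.
#' @export
delta_mu_a <- function(delta_CB_abs, chromophores, k = -1,
                       lambda = chromophores$wavelengths) {
  if (!is.finite(k)) stop("`k` must be finite", call. = FALSE)
  delta_CB_abs * chromophore_mu_a(chromophores, lambda, "blood") +
    k * delta_CB_abs * chromophore_mu_a(chromophores, lambda, "other")
}

#' Mie power-law reduced scattering coefficient
#'
#' mu_s' = 3.28 * pi * r^2 * rho_s * (2 pi r / lambda)^0.37 *
#' (n_s/n_0 - 1)^2.09, the power-law approximation to Mie theory for a
#' suspension of spherical scatterers of radius `r` (cm), number density
#' `rho_s` (cm^-3) and refractive index `n_s` in a medium of index `n_0`.
#' `r` and `lambda` must share units (cm here; pass `lambda` in cm).
#'
#' @param r Particle radius (cm), > 0.
#' @param rho_s Particle number density (cm^-3), > 0.
#' @param lambda Wavelength (cm), > 0.
#' @param n_s Particle refractive index; must exceed `n_0`.
#' @param n_0 Medium refractive index, > 0.
#' @return mu_s' (cm^-1).
#' @export
mu_s_prime_mie <- function(r, rho_s, lambda, n_s, n_0) {
  if (any(r <= 0) || any(rho_s <= 0) || any(lambda <= 0) || any(n_0 <= 0))
    stop("`r`, `rho_s`, `lambda`, `n_0` must be positive", call. = FALSE)
  if (any(n_s <= n_0))
    stop("`n_s` must exceed `n_0` (fractional power of a negative base)",
         call. = FALSE)
  3.28 * pi * r^2 * rho_s * (2 * pi * r / lambda)^0.37 * (n_s / n_0 - 1)^2.09
}

#' Reduced-scattering change under a blood-volume change
#'
#' Under the assumption that only the scatterer number density follows the
#' blood fraction (drho_s/rho_s = dC_B/C_B), the Mie power law gives
#' delta mu_s' = mu_s' * (dC_B / C_B): the relative scattering change equals
#' the relative blood-fraction change exactly.
#'
#' @param mu_s_prime Baseline mu_s' (cm^-1), > 0.
#' @param delta_CB_rel Relative blood-fraction change dC_B / C_B.
#' @return delta mu_s' (cm^-1).
#' @export
delta_mu_s_prime <- function(mu_s_prime, delta_CB_rel) {
  if (any(mu_s_prime <= 0)) stop("`mu_s_prime` must be positive", call. = FALSE)
  mu_s_prime * delta_CB_rel
}

# ---- stack assembly and perturbation ---------------------------------------

#' Transport-ready optical coefficients for every layer
#'
#' Dispatches on layer kind to the appropriate absorption formula and converts
#' reduced scattering to the scattering coefficient via the similarity
#' relation mu_s = mu_s' / (1 - g).
#'
#' @param model A [skin_model()].
#' @param chromophores A [chromophore_set()].
#' @param lambda A single wavelength (nm) within the chromophore grid.
#' @param sc_lambda_unit Passed to [mu_a_stratum_corneum()].
#' @return data.frame with one row per layer: `name`, `kind`, `thickness_cm`,
#'   `mu_a`, `mu_s_prime`, `mu_s`, `g`, `n`.
#' @export
build_optical_stack <- function(model, chromophores, lambda,
                                sc_lambda_unit = "um") {
  stopifnot(inherits(model, "skin_model"),
            inherits(chromophores, "chromophore_set"),
            length(lambda) == 1L)
  rows <- lapply(model$layers, function(l) {
    mu_a <- switch(
      l$kind,
      stratum_corneum = mu_a_stratum_corneum(
        lambda, chromophore_mu_a(chromophores, lambda, "other"),
        lambda_unit = sc_lambda_unit),
      living_epidermis = mu_a_living_epidermis(
        lambda, l$C_H2O, chromophore_mu_a(chromophores, lambda, "water")),
      mu_a_dermal(lambda, l$C_B - l$delta_CB_abs, l$C_H2O, chromophores) +
        delta_mu_a(l$delta_CB_abs, chromophores, k = l$perturb_k,
                   lambda = lambda))
    msp <- layer_mu_s_prime(l, lambda)
    data.frame(name = l$name, kind = l$kind, thickness_cm = l$thickness_cm,
               mu_a = mu_a, mu_s_prime = msp, mu_s = msp / (1 - l$g),
               g = l$g, n = l$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Blood-volume perturbation specification
#'
#' Describes a relative blood-volume change in the vascularised dermal layers.
#' The default reproduces the modelled arm-elevation / blood-flow event: a
#' +50% relative change of C_B in the upper and deep blood net dermis, with
#' the displaced volume exchanged against the "other" compartment (k = -1)
#' and interstitial water held fixed.
#'
#' @param target_layers Names of layers to perturb.
#' @param delta_CB_rel Relative change of C_B (dC_B / C_B), default +0.5.
#' @param k Coupling of dC_Other to dC_B (default -1).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(target_layers = c("upper_blood_net_dermis",
                                                "deep_blood_net_dermis"),
                              delta_CB_rel = 0.5, k = -1) {
  if (!length(target_layers)) stop("no target layers given", call. = FALSE)
  if (!is.finite(delta_CB_rel) || !is.finite(k))
    stop("`delta_CB_rel` and `k` must be finite", call. = FALSE)
  structure(list(target_layers = target_layers,
                 delta_CB_rel = delta_CB_rel, k = k),
            class = "perturbation_spec")
}

#' Apply a blood-volume perturbation to a skin model
#'
#' Returns a new model in which each targeted layer has its blood fraction
#' scaled by (1 + delta_CB_rel) and its reduced scattering scaled by the same
#' factor (the Mie power-law identity), with C_H2O unchanged. The absorption
#' consequence is carried as the linear perturbation term
#' dCB * (mu_a_blood + k * mu_a_other), first-order in the blood change; if
#' the implied "other"-fraction change exceeds the available C_Other a
#' warning notes that the linearisation has left the physically mixable
#' range. All untargeted layers are returned untouched.
#'
#' @param model A [skin_model()].
#' @param spec A [perturbation_spec()].
#' @return A perturbed [skin_model()].
#' @export
apply_perturbation <- function(model, spec) {
  stopifnot(inherits(model, "skin_model"), inherits(spec, "perturbation_spec"))
  missing <- setdiff(spec$target_layers, names(model$layers))
  if (length(missing))
    stop("unknown target layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- model
  for (nm in spec$target_layers) {
    l <- out$layers[[nm]]
    if (l$C_B <= 0)
      stop(sprintf("layer '%s' has no blood to perturb (C_B = 0)", nm),
           call. = FALSE)
    dCB <- l$C_B * spec$delta_CB_rel
    new_CB <- l$C_B + dCB
    if (new_CB < 0 || new_CB > 1)
      stop(sprintf("perturbation drives layer '%s' C_B out of [0, 1] (%.3f)",
                   nm, new_CB), call. = FALSE)
    base_other <- 1 - l$C_H2O - (l$C_B - l$delta_CB_abs)
    if (base_other + spec$k * (l$delta_CB_abs + dCB) < -1e-12)
      warning(sprintf(
        paste0("layer '%s': implied C_Other change exceeds the available ",
               "fraction; treating the absorption change as a first-order ",
               "perturbation"), nm), call. = FALSE)
    l$C_B <- new_CB
    l$delta_CB_abs <- l$delta_CB_abs + dCB
    l$perturb_k <- spec$k
    l$musp_scale <- l$musp_scale * (1 + spec$delta_CB_rel)
    out$layers[[nm]] <- l
  }
  out
}

check_lambda_band <- function(lambda) {
  if (any(lambda < 1000) || any(lambda > 1700))
    stop("wavelength must lie within [1000, 1700] nm", call. = FALSE)
  invisible(lambda)
}
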