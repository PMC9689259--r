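#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient \eqn{\mu_a} and the reduced scattering
#' coefficient \eqn{\mu_s' = (1-g)\mu_s} of a tissue-like turbid medium,
#' optionally with the anisotropy factor \eqn{g} and the inside-to-outside
#' refractive-index ratio \eqn{n}.  Units are cm\eqn{^{-1}} throughout.
#'
#' A property set is "physically valid" for the two-flux (Kubelka-Munk)
#' parametrization when \eqn{\mu_s' > \mu_a/3}, which guarantees a positive
#' two-flux scattering coefficient \eqn{S_{KM} = (3/4)\mu_s' - (1/4)\mu_a}.
#'
#' @param mua absorption coefficient, cm^-1 (>= 0).
#' @param musp reduced scattering coefficient, cm^-1 (> 0).
#' @param g optional anisotropy factor in [-1, 1].  Carried for bookkeeping
#'   only; all computations use `musp`.
#' @param n_rel optional refractive-index ratio n_inside / n_outside (> 0).
#' @return An object of class `"optical_properties"`.
#' @examples
#' optical_properties(0.84, 26.2, n_rel = 1.4)
#' @export
optical_properties <- function(mua, musp, g = NA_real_, n_rel = NA_real_) {
  stopifnot(is.numeric(mua), length(mua) == 1L, is.finite(mua),
            is.numeric(musp), length(musp) == 1L, is.finite(musp))
  if (mua < 0) stop("`mua` must be >= 0, got ", mua)
  if (musp <= 0) stop("`musp` must be > 0, got ", musp)
  if (!is.na(g) && (g < -1 || g > 1)) stop("`g` must lie in [-1, 1]")
  if (!is.na(n_rel) && n_rel <= 0) stop("`n_rel` must be > 0")
  structure(list(mua = as.numeric(mua), musp = as.numeric(musp),
                 g = as.numeric(g), n_rel = as.numeric(n_rel)),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("Optical properties: mua = %g cm^-1, musp = %g cm^-1", x$mua, x$musp))
  if (!is.na(x$g)) cat(sprintf(", g = %g", x$g))
  if (!is.na(x$n_rel)) cat(sprintf(", n_rel = %g", x$n_rel))
  cat(sprintf("\n  mueff = %g cm^-1, d_diff = %g cm%s\n",
              effective_attenuation(x), diffusion_constant(x),
              if (is_km_valid(x)) "" else "  [NOT two-flux valid: musp <= mua/3]"))
  invisible(x)
}

#' Two-flux validity of an optical property set
#'
#' @param props an [optical_properties()] object.
#' @return `TRUE` when `musp > mua/3` (positive two-flux scattering
#'   coefficient), else `FALSE`.
#' @export
is_km_valid <- function(props) {
  props$musp > props$mua / 3
}

#' Diffusion constant of the diffusion approximation
#'
#' \eqn{D = 1/(3(\mu_a + \mu_s'))}, in cm.
#'
#' @param props an [optical_properties()] object.
#' @return diffusion constant, cm.
#' @export
diffusion_constant <- function(props) {
  1 / (3 * (props$mua + props$musp))
}

#' Effective attenuation coefficient
#'
#' \eqn{\mu_{eff} = \sqrt{\mu_a / D} = \sqrt{3 \mu_a (\mu_a + \mu_s')}},
#' the asymptotic exponential decay rate of diffuse fluence, in cm^-1.
#' Algebraically identical to \eqn{S_{KM} y} of the two-flux
#' parametrization (see [km_coeffs_from_optical()]).
#'
#' @param props an [optical_properties()] object.
#' @return effective attenuation coefficient, cm^-1.
#' @examples
#' effective_attenuation(optical_properties(0.84, 26.2)) # ~ 8.25 cm^-1
#' @export
effective_attenuation <- function(props) {
  sqrt(3 * props$mua * (props$mua + props$musp))
}

#' A single diffuse reflectance/transmittance measurement
#'
#' Integrating-sphere observables of a slab: diffuse reflectance `rd` and
#' total transmittance `td` (fractions of incident power), slab thickness
#' in cm, and the probing wavelength in nm.  An absorbing sample must obey
#' energy conservation, `rd + td < 1`.
#'
#' @param rd diffuse reflectance, in (0, 1).
#' @param td total transmittance, in (0, 1).
#' @param thickness_cm slab thickness, cm (> 0).
#' @param wavelength_nm probing wavelength, nm (optional bookkeeping).
#' @return An object of class `"diffuse_measurement"`.
#' @export
diffuse_measurement <- function(rd, td, thickness_cm, wavelength_nm = NA_real_) {
  stopifnot(is.numeric(rd), length(rd) == 1L, is.numeric(td), length(td) == 1L,
            is.numeric(thickness_cm), length(thickness_cm) == 1L)
  if (!is.finite(rd) || rd <= 0 || rd >= 1)
    stop("`rd` must lie in (0, 1), got ", rd)
  if (!is.finite(td) || td <= 0 || td >= 1)
    stop("`td` must lie in (0, 1), got ", td)
  if (rd + td >= 1)
    stop("energy conservation violated: rd + td = ", rd + td, " must be < 1")
  if (!is.finite(thickness_cm) || thickness_cm <= 0)
    stop("`thickness_cm` must be > 0, got ", thickness_cm)
  structure(list(rd = rd, td = td, thickness_cm = thickness_cm,
                 wavelength_nm = as.numeric(wavelength_nm)),
            class = "diffuse_measurement")
}

#' @export
print.diffuse_measurement <- function(x, ...) {
  cat(sprintf("Diffuse measurement: Rd = %g, Td = %g, D = %g cm", x$rd, x$td, x$thickness_cm))
  if (!is.na(x$wavelength_nm)) cat(sprintf(" @ %g nm", x$wavelength_nm))
  cat("\n")
  invisible(x)
}
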