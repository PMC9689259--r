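#' Effective reflection coefficient from the refractive-index ratio
#'
#' Empirical polynomial for the effective (internal) reflection coefficient
#' at a diffusing-medium/air interface,
#' \deqn{R_{eff} = -1.44 n^{-2} + 0.7 n^{-1} + 0.063 n + 0.668,}
#' where \eqn{n = n_{in}/n_{out}} is the inside-to-outside refractive-index
#' ratio.  The polynomial is evaluated exactly as printed, with no
#' clamping: at index match (\eqn{n = 1}) the fit is slightly negative
#' (\eqn{-0.009}), which propagates to an internal-reflectance factor just
#' below 1.
#'
#' @param n_rel refractive-index ratio (> 0).
#' @return effective reflection coefficient (dimensionless, < 1 for
#'   physically sensible `n_rel`).
#' @examples
#' effective_reflectance(1.4) # ~ 0.5215
#' @export
effective_reflectance <- function(n_rel) {
  if (!is.numeric(n_rel) || length(n_rel) != 1L || !is.finite(n_rel) || n_rel <= 0)
    stop("`n_rel` must be a single positive number")
  -1.44 * n_rel^-2 + 0.7 / n_rel + 0.063 * n_rel + 0.668
}

#' Internal-reflectance factor and boundary impedance term
#'
#' \eqn{A = (1 + R_{eff}) / (1 - R_{eff})} and \eqn{q = 1/(2A)}.  `q` is
#' the coefficient of the Robin (impedance) boundary condition
#' \eqn{D\,\partial\Phi/\partial n + q\,\Phi = 0} used by [solve_fluence()].
#'
#' @param reff effective reflection coefficient, in (-1, 1).
#' @return A list with elements `a_factor` and `q`.
#' @examples
#' impedance_from_reff(0.52151) # a_factor ~ 3.18, q ~ 0.157
#' impedance_from_reff(0)       # matched boundary: A = 1, q = 0.5
#' @export
impedance_from_reff <- function(reff) {
  if (!is.numeric(reff) || length(reff) != 1L || !is.finite(reff))
    stop("`reff` must be a single finite number")
  if (reff >= 1) stop("singular boundary: `reff` >= 1 gives infinite A")
  if (reff <= -1) stop("`reff` must be > -1")
  a_factor <- (1 + reff) / (1 - reff)
  if (a_factor > 1e6)
    warning("near-singular boundary: internal-reflectance factor A = ",
            format(a_factor), " (reff close to 1)")
  list(a_factor = a_factor, q = 1 / (2 * a_factor))
}

#' Robin boundary condition for the fluence solver
#'
#' Convenience composition of [effective_reflectance()] and
#' [impedance_from_reff()]: either supply the refractive-index ratio
#' `n_rel` (typical soft tissue against air: 1.4) or override `reff`
#' directly.
#'
#' @param n_rel refractive-index ratio; default 1.4.
#' @param reff optional direct override of the effective reflection
#'   coefficient (bypasses the polynomial).
#' @return An object of class `"boundary_condition"` with fields `n_rel`,
#'   `reff`, `a_factor`, `q`.
#' @examples
#' boundary_condition(1.4)
#' @export
boundary_condition <- function(n_rel = 1.4, reff = NULL) {
  if (is.null(reff)) {
    reff <- effective_reflectance(n_rel)
  } else {
    n_rel <- NA_real_
  }
  imp <- impedance_from_reff(reff)
  structure(list(n_rel = n_rel, reff = reff,
                 a_factor = imp$a_factor, q = imp$q),
            class = "boundary_condition")
}

#' @export
print.boundary_condition <- function(x, ...) {
  cat(sprintf("Robin boundary: n_rel = %s, Reff = %.5f, A = %.5g, q = %.5g\n",
              if (is.na(x$n_rel)) "(direct reff)" else format(x$n_rel),
              x$reff, x$a_factor, x$q))
  invisible(x)
}
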