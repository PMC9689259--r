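#' Two-flux (Kubelka-Munk) coefficients
#'
#' Container for the two-flux parametrization of a slab: the KM absorption
#' and scattering coefficients \eqn{A_{KM}, S_{KM}} (cm^-1) and the
#' dimensionless auxiliaries \eqn{x = 1 + A_{KM}/S_{KM}} and
#' \eqn{y = \sqrt{x^2 - 1}}.
#'
#' @param a_km KM absorption coefficient, cm^-1 (>= 0).
#' @param s_km KM scattering coefficient, cm^-1 (> 0).
#' @return An object of class `"km_coefficients"` with fields `a_km`,
#'   `s_km`, `x`, `y`.
#' @seealso [km_coeffs_from_optical()], [km_forward()]
#' @export
km_coefficients <- function(a_km, s_km) {
  stopifnot(is.numeric(a_km), length(a_km) == 1L, is.finite(a_km),
            is.numeric(s_km), length(s_km) == 1L, is.finite(s_km))
  if (s_km <= 0) stop("`s_km` must be > 0, got ", s_km)
  if (a_km < 0) stop("`a_km` must be >= 0, got ", a_km)
  x <- 1 + a_km / s_km
  y <- sqrt((x - 1) * (x + 1))
  structure(list(a_km = a_km, s_km = s_km, x = x, y = y),
            class = "km_coefficients")
}

#' @export
print.km_coefficients <- function(x, ...) {
  cat(sprintf("KM coefficients: A_KM = %g, S_KM = %g cm^-1 (x = %.6g, y = %.6g)\n",
              x$a_km, x$s_km, x$x, x$y))
  invisible(x)
}

#' Two-flux coefficients from optical properties
#'
#' Maps \eqn{(\mu_a, \mu_s')} to the two-flux pair via
#' \eqn{A_{KM} = 2\mu_a} and \eqn{S_{KM} = (3/4)\mu_s' - (1/4)\mu_a},
#' then forms \eqn{x = 1 + A_{KM}/S_{KM}}, \eqn{y = \sqrt{x^2-1}}.
#'
#' @param props an [optical_properties()] object with `musp > mua/3`.
#' @return A [km_coefficients()] object.
#' @examples
#' km_coeffs_from_optical(optical_properties(0.84, 26.2))
#' @export
km_coeffs_from_optical <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  s_km <- 0.75 * props$musp - 0.25 * props$mua
  if (s_km <= 0)
    stop("non-physical input: S_KM = (3/4)*musp - (1/4)*mua = ", s_km,
         " <= 0; requires musp > mua/3")
  km_coefficients(a_km = 2 * props$mua, s_km = s_km)
}

#' Optical properties from two-flux coefficients
#'
#' Inverse of [km_coeffs_from_optical()]: \eqn{\mu_a = A_{KM}/2},
#' \eqn{\mu_s' = (4/3) S_{KM} + \mu_a/3}.
#'
#' @param coeffs a [km_coefficients()] object.
#' @return An [optical_properties()] object.
#' @export
optical_from_km_coeffs <- function(coeffs) {
  stopifnot(inherits(coeffs, "km_coefficients"))
  mua <- coeffs$a_km / 2
  optical_properties(mua = mua, musp = (4 / 3) * coeffs$s_km + mua / 3)
}

# Stable evaluation of the slab closed forms.  With u = S*y*D and the
# shift t (paper: t = arcosh(x); classical: t = arsinh(y)) the denominators
# collapse to cosh(u+t) resp. sinh(u+t), so everything is computed from
# exp(-(.)) terms only -- no overflow for any u, and expm1 keeps the
# classical y -> 0 limit accurate.
.km_rt_eval <- function(x, y, u, dialect) {
  if (dialect == "paper") {
    t <- acosh(x)
    em <- exp(-2 * (u + t))
    rd <- exp(-t) * (-expm1(-2 * u)) / (1 + em)
    td <- 2 * y * exp(-(u + t)) / (1 + em)
  } else {
    t <- asinh(y)
    num <- -expm1(-2 * u)
    den <- -expm1(-2 * (u + t))
    rd <- exp(-t) * num / den
    td <- 2 * y * exp(-(u + t)) / den
  }
  list(rd = rd, td = td)
}

#' Forward two-flux model: coefficients to reflectance/transmittance
#'
#' Evaluates the slab closed forms for diffuse reflectance and total
#' transmittance at thickness `thickness_cm`, in one of two equation
#' dialects:
#' \describe{
#'   \item{`"paper"`}{\eqn{R_d = \sinh(SyD) / (x\cosh(SyD) + y\sinh(SyD))},
#'     \eqn{T_d = y / (x\cosh(SyD) + y\sinh(SyD))}.}
#'   \item{`"classical"`}{the textbook Kubelka solution with the hyperbolic
#'     terms exchanged: \eqn{R_d = \sinh(SyD) / (x\sinh(SyD) + y\cosh(SyD))},
#'     \eqn{T_d = y / (x\sinh(SyD) + y\cosh(SyD))}.}
#' }
#' Only the classical dialect satisfies the vanishing-slab limit
#' (\eqn{T_d \to 1} as \eqn{D \to 0}) and energy conservation as
#' \eqn{\mu_a \to 0}; the paper dialect is the printed form and the default
#' for fidelity.  Hyperbolics are evaluated through exponentially scaled
#' expressions, so large \eqn{S y D} never produces overflow or NaN.
#'
#' @param coeffs a [km_coefficients()] object.
#' @param thickness_cm slab thickness, cm (> 0).
#' @param dialect `"paper"` (default) or `"classical"`.
#' @return A list with elements `rd` and `td`.
#' @examples
#' cf <- km_coeffs_from_optical(optical_properties(0.84, 26.2))
#' km_forward(cf, 0.2)                        # rd ~ 0.627, td ~ 0.106
#' km_forward(cf, 0.2, dialect = "classical") # rd ~ 0.648, td ~ 0.110
#' @export
km_forward <- function(coeffs, thickness_cm, dialect = c("paper", "classical")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(coeffs, "km_coefficients"))
  if (!is.numeric(thickness_cm) || length(thickness_cm) != 1L || thickness_cm <= 0)
    stop("`thickness_cm` must be a single positive number")
  y <- coeffs$y
  if (y < 1e-12) {
    # conservative slab (a_km = 0): series limit
    if (dialect == "paper")
      stop("paper-dialect closed forms are degenerate at zero absorption (y = 0); ",
           "use dialect = \"classical\"")
    sd <- coeffs$s_km * thickness_cm
    return(list(rd = sd / (1 + sd), td = 1 / (1 + sd)))
  }
  u <- coeffs$s_km * y * thickness_cm
  .km_rt_eval(coeffs$x, y, u, dialect)
}

#' Dimensionless slab parameters from reflectance and transmittance
#'
#' The extraction \eqn{x = (1 + R_d^2 - T_d^2) / (2 R_d)},
#' \eqn{y = \sqrt{x^2 - 1}}.  This pair is the exact inverse of the
#' classical-dialect closed forms; applied to paper-dialect values it is
#' only approximate (see [km_invert()]).  `x - 1` is computed as
#' \eqn{(1 - R_d - T_d)(1 - R_d + T_d) / (2 R_d)} to avoid cancellation
#' near the conservative limit.
#'
#' @param rd diffuse reflectance, in (0, 1).
#' @param td total transmittance, with `rd + td <= 1`.
#' @return A list with elements `x` and `y`.
#' @examples
#' xy_from_rt(0.6479, 0.1096) # x ~ 1.0864, y ~ 0.4246
#' xy_from_rt(0.5, 0.5)       # conservative slab: x = 1, y = 0
#' @export
xy_from_rt <- function(rd, td) {
  stopifnot(is.numeric(rd), length(rd) == 1L, is.numeric(td), length(td) == 1L)
  if (rd <= 0) stop("`rd` must be > 0 (division by 2*Rd)")
  if (rd >= 1) stop("`rd` must be < 1")
  if (td <= 0) stop("`td` must be > 0")
  if (rd + td > 1)
    stop("energy conservation violated: rd + td = ", rd + td, " > 1")
  xm1 <- (1 - rd - td) * (1 - rd + td) / (2 * rd)
  x <- 1 + xm1
  list(x = x, y = sqrt(xm1 * (x + 1)))
}

# Closed-form S_KM from (x, y, td, D) in either dialect.
# paper:      S = (arcosh(y/td) - arcosh(x)) / (y D)
# classical:  S = (arsinh(y/td) - arsinh(y)) / (y D)
# with the y -> 0 series branch S = rd / (td D) (classical limit).
.s_km_closed_form <- function(x, y, rd, td, thickness_cm, dialect) {
  if (y < 1e-6) return(rd / (td * thickness_cm))
  if (dialect == "paper") {
    ratio <- y / td
    if (ratio < 1)
      stop("inversion-domain error: y/td = ", ratio,
           " < 1, arcosh undefined (paper dialect)")
    u <- acosh(ratio) - acosh(x)
  } else {
    u <- asinh(y / td) - asinh(y)
  }
  u / (y * thickness_cm)
}

# Real positive roots of the paper-dialect inversion cubic
#   2 Rd y^3 - (1 - Rd^2 - Td^2) y^2 + Td^2 = 0,
# polished by a few Newton steps.
.paper_inversion_roots <- function(rd, td) {
  b <- (1 - rd - td) * (1 + rd + td) + 2 * rd * td  # 1 - rd^2 - td^2, stable
  co <- c(td^2, 0, -b, 2 * rd)
  r <- polyroot(co)
  r <- Re(r[abs(Im(r)) < 1e-7 * (abs(r) + 1)])
  r <- r[r > 0]
  for (i in seq_along(r)) {
    for (k in 1:4) {
      yv <- r[i]
      f <- ((2 * rd * yv - b) * yv) * yv + td^2
      fp <- (6 * rd * yv - 2 * b) * yv
      if (fp != 0) r[i] <- yv - f / fp
    }
  }
  sort(unique(r))
}

#' Invert a diffuse measurement to optical properties
#'
#' Recovers \eqn{(\mu_a, \mu_s')} from a single (Rd, Td, D) triple under
#' the chosen equation dialect.
#'
#' \describe{
#'   \item{classical}{`x`, `y` from [xy_from_rt()] (the exact inverse of
#'     the classical closed forms), then \eqn{S_{KM} =
#'     (\mathrm{arsinh}(y/T_d) - \mathrm{arsinh}(y)) / (yD)}; for
#'     \eqn{y < 10^{-6}} the conservative series branch \eqn{S_{KM} =
#'     R_d/(T_d D)} is used.  This inversion is unique and round-trips
#'     [km_forward()] to machine precision.}
#'   \item{paper}{the printed closed forms are *not* consistent with the
#'     `xy_from_rt` extraction; instead `y` solves the exact inversion
#'     cubic \eqn{2 R_d y^3 - (1-R_d^2-T_d^2) y^2 + T_d^2 = 0}, then
#'     \eqn{S_{KM} = (\mathrm{arcosh}(y/T_d) - \mathrm{arcosh}(x)) /
#'     (yD)}.  Over much of the physical range the cubic has *two*
#'     admissible roots and both reproduce (Rd, Td) exactly: the printed
#'     equation pair is a two-to-one map, so a single slab measurement
#'     does not identify \eqn{(\mu_a, \mu_s')} under this dialect.  The
#'     returned solution is, by convention, the smallest-`y`
#'     (scattering-dominated) exact branch; every exact preimage is
#'     attached as attribute `"alternates"` (a list of
#'     [optical_properties()], including the returned one), and an
#'     optional prior `near` selects the admissible branch closest to it
#'     in log-coefficient distance.}
#' }
#' Finally \eqn{A_{KM} = S_{KM}(x - 1)}, \eqn{\mu_a = A_{KM}/2} and
#' \eqn{\mu_s' = (4/3) S_{KM} + \mu_a/3}.  As a consistency check the Rd
#' closed form is re-evaluated at the recovered coefficients and a warning
#' is raised if it misses the input by more than 1e-6 relative.
#'
#' @param meas a [diffuse_measurement()] object.
#' @param dialect `"paper"` (default) or `"classical"`.
#' @param near optional [optical_properties()] prior used to select among
#'   multiple exact paper-dialect branches (ignored for classical).
#' @return An [optical_properties()] object; for the paper dialect with
#'   attribute `"alternates"` listing all exact preimages.
#' @examples
#' cf <- km_coeffs_from_optical(optical_properties(0.84, 26.2))
#' rt <- km_forward(cf, 0.2, "classical")
#' km_invert(diffuse_measurement(rt$rd, rt$td, 0.2), "classical")
#' @export
km_invert <- function(meas, dialect = c("paper", "classical"), near = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(meas, "diffuse_measurement"))
  rd <- meas$rd; td <- meas$td; D <- meas$thickness_cm

  if (dialect == "classical") {
    xy <- xy_from_rt(rd, td)
    x <- xy$x; y <- xy$y
    s_km <- .s_km_closed_form(x, y, rd, td, D, "classical")
    sol <- list(list(x = x, y = y, s = s_km))
    pick <- 1L
  } else {
    roots <- .paper_inversion_roots(rd, td)
    roots <- roots[roots / td >= 1 - 1e-12]
    if (length(roots) == 0L)
      stop("inversion-domain error: no admissible root of the paper-dialect ",
           "cubic with y/td >= 1")
    cand <- list()
    for (yv in roots) {
      xv <- sqrt(1 + yv^2)
      u <- acosh(max(1, yv / td)) - acosh(xv)
      if (u <= 0) next
      sv <- u / (yv * D)
      rt <- .km_rt_eval(xv, yv, sv * yv * D, "paper")
      cand[[length(cand) + 1L]] <-
        list(x = xv, y = yv, s = sv,
             res = abs(rt$rd - rd) / rd + abs(rt$td - td) / td)
    }
    if (length(cand) == 0L)
      stop("inversion-domain error: no paper-dialect root gives S_KM > 0")
    res <- vapply(cand, `[[`, numeric(1), "res")
    exact <- res < 1e-9
    sol <- if (any(exact)) cand[exact] else cand[which.min(res)]
    pick <- if (!is.null(near)) {
      stopifnot(inherits(near, "optical_properties"))
      dist <- vapply(sol, function(sl) {
        mua <- sl$s * (sl$x - 1) / 2
        musp <- (4 / 3) * sl$s + mua / 3
        abs(log(max(mua, 1e-12) / max(near$mua, 1e-12))) +
          abs(log(musp / near$musp))
      }, numeric(1))
      which.min(dist)
    } else {
      which.min(vapply(sol, `[[`, numeric(1), "y"))
    }
  }

  to_props <- function(sl) {
    if (sl$s <= 0)
      stop("inversion produced S_KM = ", sl$s, " <= 0; measurement outside ",
           "the ", dialect, "-dialect model range")
    mua <- sl$s * (sl$x - 1) / 2
    optical_properties(mua = mua, musp = (4 / 3) * sl$s + mua / 3)
  }
  props <- to_props(sol[[pick]])

  rt_chk <- km_forward(km_coeffs_from_optical(props), D, dialect)
  if (abs(rt_chk$rd - rd) > 1e-6 * rd)
    warning(sprintf(paste0("Rd consistency check failed: re-evaluated Rd = %.8g",
                           " vs measured %.8g (relative %.2e)"),
                    rt_chk$rd, rd, abs(rt_chk$rd - rd) / rd))
  if (dialect == "paper")
    attr(props, "alternates") <- lapply(sol, to_props)
  props
}
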