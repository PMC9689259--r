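# Independent oracles used across the suite.  These deliberately avoid the
# package's own closed forms: plain hyperbolic evaluation plus bisection.

# Td closed form evaluated directly (safe for the argument ranges used in
# tests; the package's own implementation uses scaled exponentials)
oracle_td <- function(x, y, s, d, dialect) {
  u <- s * y * d
  if (dialect == "paper") y / (x * cosh(u) + y * sinh(u))
  else y / (x * sinh(u) + y * cosh(u))
}

# bisection root of oracle_td(S) = td in S
oracle_bisect_s <- function(x, y, td, d, dialect, tol = 1e-13) {
  lo <- 1e-9; hi <- 1
  while (oracle_td(x, y, hi, d, dialect) > td) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (oracle_td(x, y, mid, d, dialect) > td) lo <- mid else hi <- mid
    if (hi - lo < tol * hi) break
  }
  (lo + hi) / 2
}

# e-fold radius of the infinite-medium K0 profile with the reference value
# taken at r0 (mirrors the field_summary definition)
oracle_k0_efold <- function(mueff, r0) {
  target <- besselK(mueff * r0, 0) / exp(1)
  stats::uniroot(function(r) besselK(mueff * r, 0) - target,
                 c(r0, 100 / mueff), tol = 1e-12)$root
}

# the four tissue conditions at 808 nm (mua, musp)
panel_808 <- function() {
  p <- make_phantom_panel()
  p[p$wavelength_nm == 808, ]
}

expect_rel <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected), 1e-300)),
              label = sprintf("relative error %.3e within %.1e",
                              max(abs(actual - expected) /
                                  pmax(abs(expected), 1e-300)), tol))
}
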