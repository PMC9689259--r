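# P1 finite-element machinery for the steady-state diffusion (Helmholtz)
# problem  -div(D grad phi) + mua phi = f  on a triangulated disk, with the
# impedance (Robin) condition  D dphi/dn + q phi = 0  on the outer boundary.

# Element geometry: areas and P1 shape-function gradients.
.fem_geometry <- function(mesh) {
  nd <- mesh$nodes; tr <- mesh$triangles
  p1 <- nd[tr[, 1], , drop = FALSE]
  p2 <- nd[tr[, 2], , drop = FALSE]
  p3 <- nd[tr[, 3], , drop = FALSE]
  a2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
        (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  list(area = a2 / 2,
       bx = cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / a2,
       by = cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / a2,
       p1 = p1, p2 = p2, p3 = p3)
}

# Sparse system matrix: D * stiffness + mua * mass + q * boundary mass.
.fem_system_matrix <- function(mesh, d_diff, mua, q) {
  g <- .fem_geometry(mesh)
  tr <- mesh$triangles
  nn <- nrow(mesh$nodes)
  I <- rep(1:3, times = 3); J <- rep(1:3, each = 3)
  ke <- matrix(0, nrow(tr), 9)
  for (s in 1:9) {
    i <- I[s]; j <- J[s]
    ke[, s] <- d_diff * g$area * (g$bx[, i] * g$bx[, j] + g$by[, i] * g$by[, j]) +
      mua * g$area / 12 * (1 + (i == j))
  }
  K <- Matrix::sparseMatrix(i = as.vector(tr[, I]), j = as.vector(tr[, J]),
                            x = as.vector(ke), dims = c(nn, nn))
  be <- mesh$boundary_edges
  L <- sqrt(rowSums((mesh$nodes[be[, 1], , drop = FALSE] -
                     mesh$nodes[be[, 2], , drop = FALSE])^2))
  K + Matrix::sparseMatrix(i = c(be[, 1], be[, 2], be[, 1], be[, 2]),
                           j = c(be[, 1], be[, 2], be[, 2], be[, 1]),
                           x = c(q * L / 3, q * L / 3, q * L / 6, q * L / 6),
                           dims = c(nn, nn))
}

# accumulate values into a length-n vector by index
.accum <- function(idx, val, n) {
  v <- numeric(n)
  s <- tapply(val, idx, sum)
  v[as.integer(names(s))] <- s
  v
}

#' Solve the steady-state diffusion equation for the fluence rate
#'
#' Discretizes \eqn{-\nabla\cdot(D\nabla\Phi) + \mu_a\Phi = f} with linear
#' (P1) triangular elements on a graded disk mesh, with the Robin condition
#' \eqn{D\,\partial\Phi/\partial n + q\Phi = 0} on the outer boundary and a
#' point source discretized as a nodal load of strength `power` at the
#' source node.  The sparse symmetric system is solved by direct
#' factorization.  By construction the discrete flux balance
#' \eqn{\int \mu_a \Phi\, d\Omega + \oint q \Phi\, d\Gamma =} source power
#' holds to solver precision (see [flux_balance()]).
#'
#' @param mesh a [build_disk_mesh()] mesh.
#' @param props an [optical_properties()] object; sets \eqn{\mu_a} and
#'   \eqn{D = 1/(3(\mu_a + \mu_s'))}.
#' @param bc a [boundary_condition()]; supplies the impedance term `q`.
#' @param source a [source_spec()]; only the central source of the mesh is
#'   supported, `power` scales the solution linearly.
#' @return An object of class `"fluence_field"`: list with `mesh`, `phi`
#'   (per-node fluence rate), `d_diff`, `mueff`, `mua`, `q`, `power`.
#' @examples
#' m <- build_disk_mesh(2, 0.2, 0.02)
#' f <- solve_fluence(m, optical_properties(0.84, 26.2), boundary_condition(1.4))
#' summary(f)
#' @export
solve_fluence <- function(mesh, props, bc, source = source_spec()) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(props, "optical_properties"),
            inherits(bc, "boundary_condition"), inherits(source, "source_spec"))
  if (any(abs(source$location) > 1e-12))
    stop("only the central source node of the mesh is supported")
  if (props$mua <= 0 && bc$q <= 0)
    stop("singular system: mua = 0 with q = 0 leaves the constant mode ",
         "unconstrained (pure Neumann Laplace problem)")
  d_diff <- diffusion_constant(props)
  K <- .fem_system_matrix(mesh, d_diff, props$mua, bc$q)
  f <- numeric(nrow(mesh$nodes))
  f[mesh$source_node] <- source$power
  phi <- as.numeric(Matrix::solve(Matrix::forceSymmetric(K), f))
  if (any(!is.finite(phi))) stop("solver produced non-finite fluence values")
  # roundoff guard only; the discrete solution is non-negative for these
  # coefficient signs on all audited meshes
  tol <- 1e-12 * max(abs(phi))
  if (any(phi < -tol))
    stop("negative fluence values in the solution; mesh quality suspect")
  phi[phi < 0] <- 0
  structure(list(mesh = mesh, phi = phi, d_diff = d_diff,
                 mueff = effective_attenuation(props), mua = props$mua,
                 q = bc$q, power = source$power),
            class = "fluence_field")
}

#' Discrete flux balance of a fluence field
#'
#' @param field a [solve_fluence()] result.
#' @return A list with `absorbed` (\eqn{\int \mu_a \Phi}), `outflow`
#'   (\eqn{\oint q \Phi}), `source` (injected power) and `relative_error`
#'   of `absorbed + outflow` against `source`.
#' @export
flux_balance <- function(field) {
  stopifnot(inherits(field, "fluence_field"))
  mesh <- field$mesh
  g <- .fem_geometry(mesh)
  tr <- mesh$triangles
  ph <- field$phi
  # int mua * phi over each element: mua * area * mean of vertex values
  absorbed <- field$mua *
    sum(g$area * (ph[tr[, 1]] + ph[tr[, 2]] + ph[tr[, 3]]) / 3)
  be <- mesh$boundary_edges
  L <- sqrt(rowSums((mesh$nodes[be[, 1], , drop = FALSE] -
                     mesh$nodes[be[, 2], , drop = FALSE])^2))
  outflow <- field$q * sum(L * (ph[be[, 1]] + ph[be[, 2]]) / 2)
  src <- field$power
  list(absorbed = absorbed, outflow = outflow, source = src,
       relative_error = if (src > 0) abs(absorbed + outflow - src) / src
                        else abs(absorbed + outflow))
}

#' Infinite-medium Green's function of the 2-D diffusion equation
#'
#' The analytic point-source solution
#' \deqn{\Phi(r) = P \, K_0(\mu_{eff} r) / (2\pi D),}
#' with \eqn{K_0} the modified Bessel function of the second kind.  Serves
#' as the independent oracle for [solve_fluence()] away from the boundary.
#'
#' @param r radial distance(s) from the source, cm (> 0; the Green's
#'   function is logarithmically singular at r = 0).
#' @param props an [optical_properties()] object.
#' @param power source strength.
#' @return Fluence rate at each `r`.
#' @examples
#' analytic_fluence_2d(0.2, optical_properties(0.84, 26.2)) # ~ 2.274
#' @export
analytic_fluence_2d <- function(r, props, power = 1) {
  stopifnot(inherits(props, "optical_properties"))
  if (any(r <= 0)) stop("`r` must be > 0 (logarithmic singularity at the source)")
  mueff <- effective_attenuation(props)
  power * besselK(mueff * r, 0) / (2 * pi * diffusion_constant(props))
}

# Azimuthally averaged radial profile: per node ring, the field is linearly
# interpolated in angle at `n_bins` equally spaced angles and averaged.
.azimuthal_profile <- function(field, n_bins = 72) {
  mesh <- field$mesh
  rings <- mesh$rings
  K <- length(rings$radius) - 1
  th_q <- 2 * pi * (seq_len(n_bins) - 1) / n_bins
  r_out <- numeric(K); v_out <- numeric(K)
  for (k in 1:K) {
    n_k <- rings$n[k + 1]; s_k <- rings$start[k + 1]
    idx <- s_k + seq_len(n_k) - 1L
    th <- atan2(mesh$nodes[idx, 2], mesh$nodes[idx, 1]) %% (2 * pi)
    o <- order(th)
    th <- th[o]; val <- field$phi[idx][o]
    # periodic linear interpolation
    thp <- c(th, th[1] + 2 * pi)
    vp <- c(val, val[1])
    pos <- findInterval((th_q - th[1]) %% (2 * pi) + th[1], thp,
                        rightmost.closed = TRUE)
    pos[pos < 1] <- 1; pos[pos > n_k] <- n_k
    w <- (((th_q - th[1]) %% (2 * pi) + th[1]) - thp[pos]) /
      (thp[pos + 1] - thp[pos])
    v_out[k] <- mean(vp[pos] * (1 - w) + vp[pos + 1] * w)
    r_out[k] <- rings$radius[k + 1]
  }
  list(r = r_out, phi = v_out)
}

#' Summary metrics of a fluence field
#'
#' Reports the base-10 log range of the field (excluding the singular
#' source node) and the e-fold radius: the radius at which the azimuthally
#' averaged fluence (72 angular bins, linear interpolation) first falls to
#' 1/e of its value at \eqn{r = 2 h_{near}}.  A field that never decays
#' below that threshold reports `efold_radius = Inf`.
#'
#' @param field a [solve_fluence()] result (or a compatible list with
#'   `mesh` and positive `phi`).
#' @param n_bins number of angular bins for the azimuthal average.
#' @return A list with `log_min`, `log_max`, `efold_radius`.
#' @export
field_summary <- function(field, n_bins = 72) {
  stopifnot(inherits(field, "fluence_field"))
  keep <- setdiff(seq_along(field$phi), field$mesh$source_node)
  bad <- keep[field$phi[keep] <= 0]
  if (length(bad))
    stop("non-positive fluence at node(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         "; log summary undefined")
  prof <- .azimuthal_profile(field, n_bins)
  r0 <- 2 * field$mesh$h_near
  phi0 <- stats::approx(prof$r, prof$phi, xout = r0, rule = 2)$y
  target <- phi0 / exp(1)
  below <- which(prof$phi <= target & prof$r > r0)
  efold <- if (length(below) == 0L) Inf else {
    i <- below[1]
    if (i == 1L) prof$r[1] else {
      # linear interpolation between the bracketing rings
      r1 <- prof$r[i - 1]; r2 <- prof$r[i]
      v1 <- prof$phi[i - 1]; v2 <- prof$phi[i]
      r1 + (target - v1) * (r2 - r1) / (v2 - v1)
    }
  }
  list(log_min = log10(min(field$phi[keep])),
       log_max = log10(max(field$phi[keep])),
       efold_radius = efold)
}

#' @export
print.fluence_field <- function(x, ...) {
  cat(sprintf(paste0("Fluence field: %d nodes, mua = %g cm^-1, D = %.5g cm, ",
                     "mueff = %.4g cm^-1, q = %.4g\n"),
              length(x$phi), x$mua, x$d_diff, x$mueff, x$q))
  invisible(x)
}

#' @export
summary.fluence_field <- function(object, ...) {
  s <- field_summary(object)
  fb <- flux_balance(object)
  structure(c(s, list(flux_relative_error = fb$relative_error,
                      mueff = object$mueff)),
            class = "summary.fluence_field")
}

#' @export
print.summary.fluence_field <- function(x, ...) {
  cat(sprintf(paste0("log10(phi) range [%.3f, %.3f], e-fold radius %.4g cm ",
                     "(1/mueff = %.4g cm)\nflux balance relative error %.2e\n"),
              x$log_min, x$log_max, x$efold_radius, 1 / x$mueff,
              x$flux_relative_error))
  invisible(x)
}

#' @export
as.data.frame.fluence_field <- function(x, ...) {
  data.frame(x_cm = x$mesh$nodes[, 1], y_cm = x$mesh$nodes[, 2], phi = x$phi)
}

#' Plot a fluence field on the log10 scale
#'
#' Renders the triangulation filled by the per-element mean of
#' \eqn{\log_{10}\Phi}, mirroring the usual log-colour-scale surface maps.
#'
#' @param x a `"fluence_field"` object.
#' @param n_colors palette resolution.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fluence_field <- function(x, n_colors = 64, ...) {
  nd <- x$mesh$nodes; tr <- x$mesh$triangles
  lv <- log10(pmax(x$phi, .Machine$double.xmin))
  z <- (lv[tr[, 1]] + lv[tr[, 2]] + lv[tr[, 3]]) / 3
  pal <- grDevices::hcl.colors(n_colors, "viridis")
  ci <- pmin(n_colors, pmax(1L, 1L + as.integer((n_colors - 1) *
         (z - min(z)) / max(1e-300, diff(range(z))))))
  graphics::plot(NA, xlim = range(nd[, 1]), ylim = range(nd[, 2]), asp = 1,
                 xlab = "x [cm]", ylab = "y [cm]", ...)
  px <- cbind(nd[tr[, 1], 1], nd[tr[, 2], 1], nd[tr[, 3], 1], NA)
  py <- cbind(nd[tr[, 1], 2], nd[tr[, 2], 2], nd[tr[, 3], 2], NA)
  graphics::polygon(as.vector(t(px)), as.vector(t(py)),
                    col = pal[ci], border = NA)
  invisible(x)
}

#' Manufactured-solution error study for the FEM solver
#'
#' Method-of-manufactured-solutions verification: on a disk of radius 1 the
#' exact field \eqn{u^*(x, y) = \cos(kx)\cos(ky)} defines the interior
#' forcing \eqn{f = (2Dk^2 + \mu_a)u^*} and the (inhomogeneous) Robin data
#' \eqn{g = D\,\partial u^*/\partial n + q u^*} on the polygonal boundary,
#' so the discretization error is exactly computable.  The interior load
#' uses the mid-edge quadrature rule, the boundary load 2-point Gauss.
#'
#' @param h vector of target element sizes (each mesh uses `h_near = h/2`).
#' @param k wavenumber of the manufactured field.
#' @param d_diff,mua,q PDE coefficients.
#' @return A data frame with columns `h`, `l2_error`, and the observed
#'   order between consecutive meshes (`NA` for the first).
#' @examples
#' manufactured_solution_errors(c(0.2, 0.1))
#' @export
manufactured_solution_errors <- function(h, k = 2, d_diff = 0.05,
                                         mua = 0.5, q = 0.2) {
  ue <- function(x, y) cos(k * x) * cos(k * y)
  ux <- function(x, y) -k * sin(k * x) * cos(k * y)
  uy <- function(x, y) -k * cos(k * x) * sin(k * y)
  ff <- function(x, y) (2 * d_diff * k^2 + mua) * ue(x, y)

  errs <- vapply(h, function(hh) {
    mesh <- build_disk_mesh(1, hh, hh / 2)
    nn <- nrow(mesh$nodes)
    K <- .fem_system_matrix(mesh, d_diff, mua, q)
    g <- .fem_geometry(mesh)
    tr <- mesh$triangles
    m12 <- (g$p1 + g$p2) / 2; m23 <- (g$p2 + g$p3) / 2; m13 <- (g$p1 + g$p3) / 2
    f1 <- ff(m12[, 1], m12[, 2]); f2 <- ff(m23[, 1], m23[, 2]); f3 <- ff(m13[, 1], m13[, 2])
    # P1 shape functions are 1/2 on the two adjacent edge midpoints
    F <- .accum(tr[, 1], g$area / 3 * (f1 + f3) / 2, nn) +
         .accum(tr[, 2], g$area / 3 * (f1 + f2) / 2, nn) +
         .accum(tr[, 3], g$area / 3 * (f2 + f3) / 2, nn)
    be <- mesh$boundary_edges
    pa <- mesh$nodes[be[, 1], , drop = FALSE]
    pb <- mesh$nodes[be[, 2], , drop = FALSE]
    ev <- pb - pa
    L <- sqrt(rowSums(ev^2))
    nrm <- cbind(ev[, 2], -ev[, 1]) / L
    mid <- (pa + pb) / 2
    nrm <- nrm * sign(rowSums(nrm * mid))  # outward on the disk
    for (gp in (1 + c(-1, 1) / sqrt(3)) / 2) {
      pt <- pa + gp * ev
      gv <- d_diff * (ux(pt[, 1], pt[, 2]) * nrm[, 1] +
                      uy(pt[, 1], pt[, 2]) * nrm[, 2]) + q * ue(pt[, 1], pt[, 2])
      F <- F + .accum(be[, 1], L / 2 * gv * (1 - gp), nn) +
               .accum(be[, 2], L / 2 * gv * gp, nn)
    }
    uh <- as.numeric(Matrix::solve(Matrix::forceSymmetric(K), F))
    e12 <- (uh[tr[, 1]] + uh[tr[, 2]]) / 2 - ue(m12[, 1], m12[, 2])
    e23 <- (uh[tr[, 2]] + uh[tr[, 3]]) / 2 - ue(m23[, 1], m23[, 2])
    e13 <- (uh[tr[, 1]] + uh[tr[, 3]]) / 2 - ue(m13[, 1], m13[, 2])
    sqrt(sum(g$area / 3 * (e12^2 + e23^2 + e13^2)))
  }, numeric(1))

  data.frame(h = h, l2_error = errs,
             order = c(NA, log(errs[-length(errs)] / errs[-1]) /
                           log(h[-length(h)] / h[-1])))
}
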