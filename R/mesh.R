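#' Point-source specification
#'
#' @param location numeric length-2 source position, cm.  Only the domain
#'   centre `c(0, 0)` is supported by the disk mesher.
#' @param power source strength, arbitrary units (> 0 unless explicitly 0
#'   for linearity checks).
#' @return An object of class `"source_spec"`.
#' @export
source_spec <- function(location = c(0, 0), power = 1) {
  stopifnot(is.numeric(location), length(location) == 2L,
            is.numeric(power), length(power) == 1L, is.finite(power))
  if (power < 0) stop("`power` must be >= 0")
  structure(list(location = as.numeric(location), power = power),
            class = "source_spec")
}

#' Graded triangular mesh of a disk with central refinement
#'
#' Builds a 2-D triangulation of a disk of the given radius from concentric
#' node rings whose spacing grows linearly from `h_near` at the source
#' (centre) to `h_far` at the boundary, mimicking a mesh that "becomes
#' finer at the centre".  Adjacent rings are stitched by an angular-sweep
#' (zipper) triangulation; alternate rings are staggered by half a node
#' spacing to keep triangles close to equilateral.
#'
#' @param radius disk radius, cm (> 0).
#' @param h_far target element size at the boundary, cm.
#' @param h_near target element size at the source, cm; `0 < h_near <
#'   h_far < radius`.
#' @param source a [source_spec()]; its location must be the disk centre
#'   and becomes `source_node` (node 1, placed there exactly).
#' @return An object of class `"tri_mesh"`: list with `nodes` (N x 2
#'   matrix, cm), `triangles` (T x 3 integer matrix, positively oriented),
#'   `boundary_edges` (B x 2), `source_node`, `rings` (list with `radius`,
#'   `start`, `n` per ring), and the generating parameters.
#' @examples
#' m <- build_disk_mesh(2, h_far = 0.4, h_near = 0.1)
#' mesh_quality(m)
#' @export
build_disk_mesh <- function(radius, h_far, h_near, source = source_spec()) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("`radius` must be a single positive number")
  if (!(is.numeric(h_near) && is.numeric(h_far) &&
        h_near > 0 && h_near < h_far && h_far < radius))
    stop("element sizes must satisfy 0 < h_near < h_far < radius")
  stopifnot(inherits(source, "source_spec"))
  if (any(abs(source$location) > 1e-12))
    stop("only a central source is supported: location must be c(0, 0)")

  hfun <- function(r) h_near + (h_far - h_near) * r / radius
  radii <- 0; r <- 0
  while (r < radius) {
    step <- hfun(r)
    if (!is.finite(step) || step <= 0) stop("mesh-generation error: bad grading step")
    r <- r + step
    radii <- c(radii, r)
    if (length(radii) > 2e5)
      stop("mesh-generation error: grading produced more than 2e5 rings; ",
           "h_near is too small for this radius")
  }
  radii <- radii * radius / max(radii)
  K <- length(radii) - 1
  if (K < 2) stop("mesh-generation error: fewer than 2 rings; shrink h_far")

  ring_n <- integer(K + 1); ring_n[1] <- 1L
  ring_th <- vector("list", K + 1); ring_th[[1]] <- 0
  for (k in 1:K) {
    n_k <- max(6L, as.integer(round(2 * pi * radii[k + 1] / hfun(radii[k + 1]))))
    ring_n[k + 1] <- n_k
    ring_th[[k + 1]] <- 2 * pi * ((seq_len(n_k) - 1) + 0.5 * (k %% 2)) / n_k
  }
  ring_start <- cumsum(c(1L, ring_n[-(K + 1)]))
  nodes <- matrix(0, sum(ring_n), 2)
  for (k in 0:K) {
    idx <- ring_start[k + 1] + seq_len(ring_n[k + 1]) - 1L
    nodes[idx, 1] <- radii[k + 1] * cos(ring_th[[k + 1]])
    nodes[idx, 2] <- radii[k + 1] * sin(ring_th[[k + 1]])
  }

  tris <- vector("list", K)
  n1 <- ring_n[2]; s1 <- ring_start[2]
  tris[[1]] <- cbind(1L, s1 + (0:(n1 - 1)), s1 + (1:n1) %% n1)
  if (K >= 2) for (k in 2:K) {
    m <- ring_n[k]; n <- ring_n[k + 1]
    si <- ring_start[k]; so <- ring_start[k + 1]
    ai <- ring_th[[k]]; ao <- ring_th[[k + 1]]
    Aseq <- c(ai, ai[1] + 2 * pi)
    Aidx <- c(si + 0:(m - 1), si)
    dd <- (ao - ai[1]) %% (2 * pi)
    j0 <- which.min(pmin(dd, 2 * pi - dd))
    Bseq <- ao[((j0 - 1 + 0:(n - 1)) %% n) + 1]
    Bseq <- Bseq + 2 * pi * cumsum(c(0, diff(Bseq) < 0))
    Bseq <- Bseq + 2 * pi * round((Aseq[1] - Bseq[1]) / (2 * pi))
    Bseq <- c(Bseq, Bseq[1] + 2 * pi)
    Bidx <- c(so + ((j0 - 1 + 0:(n - 1)) %% n), so + (j0 - 1L))
    p <- 1L; q2 <- 1L
    tr <- matrix(0L, m + n, 3); cnt <- 0L
    while (p <= m || q2 <= n) {
      advB <- if (q2 > n) FALSE else if (p > m) TRUE else (Bseq[q2 + 1] <= Aseq[p + 1])
      cnt <- cnt + 1L
      if (advB) { tr[cnt, ] <- c(Aidx[p], Bidx[q2], Bidx[q2 + 1]); q2 <- q2 + 1L }
      else      { tr[cnt, ] <- c(Aidx[p], Bidx[q2], Aidx[p + 1]); p <- p + 1L }
    }
    tris[[k]] <- tr[seq_len(cnt), , drop = FALSE]
  }
  tri <- do.call(rbind, tris)

  a2 <- .tri_signed_areas2(nodes, tri)
  sw <- a2 < 0
  if (any(sw)) { tmp <- tri[sw, 2]; tri[sw, 2] <- tri[sw, 3]; tri[sw, 3] <- tmp }
  if (any(.tri_signed_areas2(nodes, tri) <= 0))
    stop("mesh-generation error: degenerate (zero-area) triangle produced")

  sb <- ring_start[K + 1]; nb <- ring_n[K + 1]
  bedges <- cbind(sb + 0:(nb - 1), sb + (1:nb) %% nb)

  structure(list(nodes = nodes, triangles = tri, boundary_edges = bedges,
                 source_node = 1L,
                 rings = list(radius = radii, start = ring_start, n = ring_n),
                 radius = radius, h_far = h_far, h_near = h_near),
            class = "tri_mesh")
}

# twice the signed area of each triangle
.tri_signed_areas2 <- function(nodes, tri) {
  p1 <- nodes[tri[, 1], , drop = FALSE]
  p2 <- nodes[tri[, 2], , drop = FALSE]
  p3 <- nodes[tri[, 3], , drop = FALSE]
  (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
}

#' Mesh quality audit
#'
#' @param mesh a [build_disk_mesh()] mesh.
#' @return Named vector: number of nodes and triangles, minimum triangle
#'   area (cm^2), minimum interior angle (degrees), and the largest element
#'   diameter adjacent to the source node.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  nd <- mesh$nodes; tr <- mesh$triangles
  p1 <- nd[tr[, 1], , drop = FALSE]
  p2 <- nd[tr[, 2], , drop = FALSE]
  p3 <- nd[tr[, 3], , drop = FALSE]
  e1 <- sqrt(rowSums((p2 - p3)^2))
  e2 <- sqrt(rowSums((p1 - p3)^2))
  e3 <- sqrt(rowSums((p1 - p2)^2))
  ang <- function(a, b, c) acos(pmin(1, pmax(-1, (b^2 + c^2 - a^2) / (2 * b * c))))
  th <- pmin(ang(e1, e2, e3), ang(e2, e1, e3), ang(e3, e1, e2))
  diam <- pmax(e1, e2, e3)
  at_src <- rowSums(tr == mesh$source_node) > 0
  c(n_nodes = nrow(nd), n_triangles = nrow(tr),
    min_area = min(.tri_signed_areas2(nd, tr)) / 2,
    min_angle_deg = min(th) * 180 / pi,
    source_diameter = max(diam[at_src]),
    max_diameter = max(diam))
}

#' @export
print.tri_mesh <- function(x, ...) {
  q <- mesh_quality(x)
  cat(sprintf(paste0("Graded disk mesh: radius %g cm, %d nodes, %d triangles\n",
                     "  h_near = %g, h_far = %g cm; min angle %.1f deg\n"),
              x$radius, q["n_nodes"], q["n_triangles"],
              x$h_near, x$h_far, q["min_angle_deg"]))
  invisible(x)
}

#' @export
plot.tri_mesh <- function(x, ...) {
  nd <- x$nodes; tr <- x$triangles
  graphics::plot(NA, xlim = range(nd[, 1]), ylim = range(nd[, 2]), asp = 1,
                 xlab = "x [cm]", ylab = "y [cm]", ...)
  i <- c(t(cbind(tr, tr[, 1], NA)))
  graphics::lines(nd[i, 1], nd[i, 2], col = "grey50", lwd = 0.3)
  invisible(x)
}
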