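# shared moderate-size mesh for the solver tests
local_mesh <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_disk_mesh(2, 0.1, 0.005)
    m
  }
})

test_that("fluence solver balances source power against absorption and outflow", {
  mesh <- local_mesh()
  props <- optical_properties(0.84, 26.2)
  fld <- solve_fluence(mesh, props, boundary_condition(1.4))
  fb <- flux_balance(fld)
  expect_lt(fb$relative_error, 1e-9)
  expect_true(all(fld$phi >= 0))
  # maximum attained at the source node
  expect_identical(which.max(fld$phi), mesh$source_node)
  expect_equal(fld$d_diff, 1 / (3 * 27.04), tolerance = 1e-12)
})

test_that("solution is linear in the source power and zero without a source", {
  mesh <- build_disk_mesh(1, 0.15, 0.02)
  props <- optical_properties(0.5, 10)
  bc <- boundary_condition(1.4)
  f1 <- solve_fluence(mesh, props, bc, source_spec(power = 1))
  f3 <- solve_fluence(mesh, props, bc, source_spec(power = 3))
  expect_rel(f3$phi[-mesh$source_node], 3 * f1$phi[-mesh$source_node], 1e-9)
  f0 <- solve_fluence(mesh, props, bc, source_spec(power = 0))
  expect_identical(max(abs(f0$phi)), 0)
})

test_that("singular pure-Neumann problem is rejected with a named null mode", {
  mesh <- build_disk_mesh(1, 0.2, 0.05)
  bc <- boundary_condition(reff = 0)
  bc$q <- 0
  expect_error(solve_fluence(mesh, optical_properties(0, 5), bc),
               "constant mode")
})

test_that("FEM field matches the infinite-medium Green's function off the source", {
  mesh <- local_mesh()
  props <- optical_properties(0.84, 26.2)
  fld <- solve_fluence(mesh, props, boundary_condition(1.4))
  r <- sqrt(rowSums(mesh$nodes^2))
  sel <- r >= 0.15 & r <= 0.5
  phi_exact <- analytic_fluence_2d(r[sel], props)
  expect_lt(max(abs(fld$phi[sel] - phi_exact) / phi_exact), 0.05)
})

test_that("increasing absorption depresses the field everywhere off the source", {
  mesh <- build_disk_mesh(1, 0.15, 0.02)
  bc <- boundary_condition(1.4)
  lo <- solve_fluence(mesh, optical_properties(0.5, 15), bc)
  hi <- solve_fluence(mesh, optical_properties(1.0, 15), bc)
  off <- -mesh$source_node
  expect_true(all(hi$phi[off] < lo$phi[off]))
})

test_that("analytic point-source profile has the K0 form and decays", {
  props <- optical_properties(0.84, 26.2)
  expect_equal(analytic_fluence_2d(0.2, props), 2.273848, tolerance = 1e-5)
  r <- seq(0.05, 2, by = 0.05)
  phi <- analytic_fluence_2d(r, props)
  expect_true(all(diff(phi) < 0))
  expect_true(all(phi[-length(r)] / analytic_fluence_2d(2 * r[-length(r)], props) > 1))
  expect_lt(analytic_fluence_2d(10, props), 1e-30)
  expect_error(analytic_fluence_2d(0, props), "singularity")
  # linear in power
  expect_equal(analytic_fluence_2d(0.3, props, power = 2.5),
               2.5 * analytic_fluence_2d(0.3, props))
})

test_that("manufactured solution converges at second order in L2", {
  conv <- manufactured_solution_errors(c(0.2, 0.1, 0.05))
  expect_true(all(diff(conv$l2_error) < 0))
  expect_true(all(conv$order[-1] >= 1.9))
})

test_that("field summary reports log range and the K0-consistent e-fold radius", {
  mesh <- local_mesh()
  props <- optical_properties(0.84, 26.2)
  fld <- solve_fluence(mesh, props, boundary_condition(1.4))
  fs <- field_summary(fld)
  expect_lt(fs$log_min, fs$log_max)
  # oracle: radius where the K0 profile drops to 1/e of its 2*h_near value
  r_e_exact <- oracle_k0_efold(fld$mueff, 2 * mesh$h_near)
  expect_rel(fs$efold_radius, r_e_exact, 0.05)

  # a uniform field never decays: +Inf sentinel, zero log range
  unif <- structure(list(mesh = mesh, phi = rep(2, nrow(mesh$nodes)),
                         d_diff = 0.01, mueff = 1, mua = 0.1, q = 0.1,
                         power = 1), class = "fluence_field")
  fsu <- field_summary(unif)
  expect_identical(fsu$efold_radius, Inf)
  expect_equal(fsu$log_max - fsu$log_min, 0)

  # non-positive nodes are reported, not silently logged
  bad <- unif; bad$phi[5] <- 0
  expect_error(field_summary(bad), "node")
})

test_that("field exports round-trip through CSV and write valid VTK", {
  mesh <- build_disk_mesh(1, 0.25, 0.05)
  fld <- solve_fluence(mesh, optical_properties(0.5, 10), boundary_condition(1.4))
  csv <- tempfile(fileext = ".csv")
  export_field_csv(fld, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$phi, fld$phi, tolerance = 1e-9)
  vtk <- tempfile(fileext = ".vtk")
  export_field_vtk(fld, vtk)
  lines <- readLines(vtk)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^DATASET UNSTRUCTURED_GRID", lines)))
  expect_identical(sum(grepl("^3 ", lines)), nrow(mesh$triangles))
  np <- tempfile(); ep <- tempfile()
  export_mesh_csv(mesh, np, ep)
  expect_equal(nrow(utils::read.csv(np)), nrow(mesh$nodes))
  expect_equal(nrow(utils::read.csv(ep)), nrow(mesh$triangles))
})
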