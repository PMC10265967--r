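test_that("the myocardial tensor has the requested eigenstructure", {
  sig <- conductivity_map()
  ## fibre along x: diagonal tensor (sigma_long, sigma_trans, sigma_trans)
  Tx <- myocardial_tensor(c(1, 0, 0), sig)
  expect_equal(unname(diag(Tx)), c(0.799, 0.255, 0.255), tolerance = 1e-12)
  expect_equal(max(abs(Tx[upper.tri(Tx)])), 0, tolerance = 1e-14)

  set.seed(7)
  for (k in 1:25) {
    f <- unitv_test(rnorm(3))
    Tk <- myocardial_tensor(f, sig)
    ## trace is rotation invariant; eigenvalues match the requested pair
    expect_equal(sum(diag(Tk)), 0.799 + 2 * 0.255, tolerance = 1e-12)
    ev <- sort(eigen(Tk, symmetric = TRUE)$values)
    expect_equal(ev, c(0.255, 0.255, 0.799), tolerance = 1e-12)
  }
  ## extracellular-only mode
  Te <- myocardial_tensor(c(0, 0, 1),
                          conductivity_map(myocardium_mode = "extracellular"))
  expect_equal(unname(diag(Te)), c(0.236, 0.236, 0.625), tolerance = 1e-12)
  expect_error(myocardial_tensor(c(0, 0, 0), sig), "non-zero")
})

test_that("per-element tensors are symmetric positive definite everywhere", {
  ph <- generate_base_anatomy(anatomy_params(1))
  mesh <- tetrahedralize(ph, NULL, h = 6)
  mesh <- suppressWarnings(assign_fibers(mesh, ph))
  tens <- torsodft:::element_conductivity_tensors(mesh, conductivity_map())
  set.seed(2)
  for (e in sample(nrow(tens), 200)) {
    Tm <- matrix(c(tens[e, 1], tens[e, 4], tens[e, 5],
                   tens[e, 4], tens[e, 2], tens[e, 6],
                   tens[e, 5], tens[e, 6], tens[e, 3]), 3, 3)
    expect_gt(min(eigen(Tm, symmetric = TRUE)$values), 0)
  }
})

test_that("plate-electrode slab reproduces the affine solution exactly", {
  slab <- make_slab(L = 20, side = 10, h = 2.5)
  sol <- solve_shock(slab$mesh, slab$sigma, v_applied = 10, method = "direct")
  exact <- 10 * (1 - (slab$mesh$nodes[, 1] - slab$x0) / slab$Lx)
  expect_lt(max(abs(sol$ve - exact)), 1e-9)
  expect_lt(max(abs(sol$e_mag - 10 / slab$Lx)), 1e-12)
})

test_that("concentric-sphere potentials match the closed form", {
  sp <- make_sphere_problem(a = 8, b = 32, h = 2)
  sol <- solve_shock(sp$mesh, sp$sigma, v_applied = 10, method = "direct")
  r <- sqrt(rowSums(sp$mesh$nodes^2))
  mid <- !sol$dirichlet & r > sp$a + 3 * sp$h & r < 0.8 * sp$b
  err <- abs(sol$ve[mid] - sp$exact(r[mid])) / sp$exact(r[mid])
  expect_lt(max(err), 0.02)
})

test_that("solutions scale linearly with the applied voltage", {
  sp <- make_sphere_problem(a = 8, b = 32, h = 4)
  s10 <- solve_shock(sp$mesh, sp$sigma, v_applied = 10, method = "direct")
  s20 <- solve_shock(sp$mesh, sp$sigma, v_applied = 20, method = "direct")
  expect_lt(max(abs(s20$ve - 2 * s10$ve)), 1e-6)
  expect_lt(max(abs(s20$e_mag - 2 * s10$e_mag)), 1e-8)
})

test_that("the discrete maximum principle holds", {
  sp <- make_sphere_problem(a = 8, b = 32, h = 2)
  sol <- solve_shock(sp$mesh, sp$sigma, v_applied = 10, method = "direct")
  expect_gte(min(sol$ve), 0 - 1e-9)
  expect_lte(max(sol$ve), 10 + 1e-9)
})

test_that("the solution is invariant under node reordering", {
  slab <- make_slab(L = 10, side = 5, h = 2.5)
  mesh <- slab$mesh
  set.seed(5)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes[perm, , drop = FALSE]
  mesh2$elems[] <- inv[mesh$elems]
  mesh2$electrode_nodes <- lapply(mesh$electrode_nodes, function(s) inv[s])
  mesh2$lattice <- NULL # reordered mesh is no longer lattice-addressable
  mesh2$volumes <- torsodft:::tet_volumes_cpp(mesh2$nodes, mesh2$elems)
  s1 <- solve_shock(mesh, slab$sigma, 10, method = "direct")
  s2 <- solve_shock(mesh2, slab$sigma, 10, method = "direct")
  expect_lt(max(abs(s2$ve[inv] - s1$ve)), 1e-9)
})

test_that("field error decreases monotonically under mesh refinement", {
  errs <- vapply(c(4, 2, 1), function(h) {
    sp <- make_sphere_problem(a = 8, b = 24, h = h)
    sol <- solve_shock(sp$mesh, sp$sigma, 10, method = "auto", tol = 1e-10)
    r <- sqrt(rowSums(sp$mesh$nodes^2))
    mid <- !sol$dirichlet & r > sp$a + 2 * h & r < 0.8 * sp$b
    sqrt(mean((sol$ve[mid] - sp$exact(r[mid]))^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("multigrid and direct solves agree", {
  sp <- make_sphere_problem(a = 8, b = 32, h = 2)
  sd <- solve_shock(sp$mesh, sp$sigma, 10, method = "direct")
  sm <- solve_shock(sp$mesh, sp$sigma, 10, method = "mg", tol = 1e-10)
  expect_lt(max(abs(sd$ve - sm$ve)), 1e-5)
})

test_that("electrode currents conserve charge and match the closed form", {
  sp <- make_sphere_problem(a = 8, b = 32, h = 2)
  sys <- assemble_system(sp$mesh, sp$sigma)
  sol <- solve_shock(sp$mesh, sp$sigma, 10, system = sys, method = "direct")
  cur <- electrode_currents(sol, sp$mesh, sp$sigma, method = "reaction",
                            system = sys)
  expect_lt(abs(sum(cur)) / abs(cur[["inner"]]), 1e-6)
  R <- 10 / cur[["inner"]]
  expect_lt(abs(R - sp$R_exact) / sp$R_exact, 0.02)
})

test_that("a grounds-free system is rejected", {
  slab <- make_slab(h = 5)
  mesh <- slab$mesh
  mesh$electrode_roles["plate_lo"] <- "shock"
  expect_error(solve_shock(mesh, slab$sigma), "no ground")
})
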