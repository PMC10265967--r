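## Fabricated field solutions let the metric layer be tested against
## brute-force oracles without running the solver.
fake_field <- function(e_mag_V_per_mm, v_applied = 10) {
  structure(list(e_mag = e_mag_V_per_mm, v_applied = v_applied,
                 shock_electrodes = "coil"), class = "field_solution")
}
fake_mesh <- function(e_n, region = "lv_wall", volumes = NULL) {
  list(region = rep(region, length.out = e_n),
       volumes = if (is.null(volumes)) rep(1, e_n) else volumes)
}

test_that("DFT equals the applied voltage when the field sits on threshold", {
  mesh <- fake_mesh(50)
  sol <- fake_field(rep(0.5, 50)) # 5 V/cm everywhere at 10 V
  expect_equal(compute_dft(sol, mesh), 10, tolerance = 1e-12)
})

test_that("the volume-weighted tail value matches a replication oracle", {
  set.seed(11)
  for (k in 1:10) {
    n <- 40
    e <- runif(n, 0.1, 2)
    w_int <- sample(1:5, n, replace = TRUE)
    mesh <- fake_mesh(n, volumes = as.numeric(w_int))
    sol <- fake_field(e)
    ## oracle: replicate each element by its integer volume, then walk the
    ## sorted values until 5% of the replicated mass is passed
    rep_e <- sort(rep(e, w_int))
    k5 <- ceiling(0.05 * length(rep_e))
    g_oracle <- rep_e[k5] * 10 # V/cm
    dft <- compute_dft(sol, mesh)
    expect_equal(dft, 10 * 5 / g_oracle, tolerance = 1e-9)
  }
})

test_that("DFT ignores atrial, scar and electrode-labelled elements", {
  region <- c(rep("lv_wall", 10), rep("rv_wall", 10),
              rep("scar", 5), rep("la_wall", 5))
  mesh <- list(region = region, volumes = rep(1, 30))
  e <- c(rep(1, 20), rep(1e-6, 10)) # non-ventricular elements are tiny
  sol <- fake_field(e)
  expect_equal(compute_dft(sol, mesh), 10 * 5 / 10, tolerance = 1e-12)
})

test_that("capacitive energy follows C V^2 / 2", {
  expect_identical(dft_energy(0), 0)
  v <- 137.5
  expect_equal(dft_energy(2 * v), 4 * dft_energy(v), tolerance = 1e-12)
  expect_equal(dft_energy(1000), 0.5 * 1e-4 * 1000^2, tolerance = 1e-12)
  expect_equal(dft_energy(500, capacitance = 2e-4), 25, tolerance = 1e-12)
  expect_error(dft_energy(-1))
})

test_that("slab impedance equals L/(sigma A) for both current rules", {
  slab <- make_slab(L = 20, side = 10, h = 2.5)
  sys <- assemble_system(slab$mesh, slab$sigma)
  sol <- solve_shock(slab$mesh, slab$sigma, 10, system = sys,
                     method = "direct")
  R_exact <- (slab$Lx * 1e-3) / (slab$sigma0 * (slab$area_mm2 * 1e-6))
  R_reaction <- compute_impedance(sol, slab$mesh, slab$sigma,
                                  method = "reaction", system = sys)
  R_surface <- compute_impedance(sol, slab$mesh, slab$sigma,
                                 method = "surface")
  expect_equal(R_reaction, R_exact, tolerance = 1e-9)
  expect_equal(R_surface, R_exact, tolerance = 1e-9)
})

test_that("impedance does not depend on the applied voltage", {
  slab <- make_slab(L = 20, side = 10, h = 2.5)
  sys <- assemble_system(slab$mesh, slab$sigma)
  R <- vapply(c(5, 10, 40), function(v) {
    sol <- solve_shock(slab$mesh, slab$sigma, v, system = sys,
                       method = "direct")
    compute_impedance(sol, slab$mesh, slab$sigma, system = sys)
  }, numeric(1))
  expect_lt(diff(range(R)) / R[1], 1e-9)
})

test_that("mean E-field is the volume-weighted elementwise mean", {
  mesh <- fake_mesh(4, volumes = c(1, 2, 3, 4))
  sol <- fake_field(c(0.1, 0.2, 0.3, 0.4))
  oracle <- sum(c(0.1, 0.2, 0.3, 0.4) * c(1, 2, 3, 4)) / 10
  expect_equal(mean_e_field(sol, mesh), oracle, tolerance = 1e-12)
  ## uniform field: the mean is the field
  u <- fake_field(rep(0.5, 4))
  expect_equal(mean_e_field(u, mesh), 0.5, tolerance = 1e-12)
})

test_that("metric tables round-trip through CSV", {
  df <- data.frame(model_id = "m1_healthy", variant = "healthy",
                   configuration = "left_apical", dft_voltage_V = 321.5,
                   dft_energy_J = 5.17, impedance_ohm = 44.2,
                   mean_e_field_V_per_mm = 0.041)
  f <- tempfile(fileext = ".csv")
  write_metrics_csv(df, f)
  back <- utils::read.csv(f)
  expect_equal(back$dft_energy_J, df$dft_energy_J)
  expect_equal(back$configuration, df$configuration)
})
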