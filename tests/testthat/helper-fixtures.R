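## Shared verification geometries, built in code.

## Homogeneous conductive slab with full-face plate electrodes on the
## lattice boundary planes (P1 FEM is exact for the resulting affine
## potential).  The lattice pads the phantom box by half a cell, so the
## effective slab spans [x0, x0 + Lx].
make_slab <- function(L = 20, side = 10, h = 2.5, sigma0 = 0.2) {
  ph <- phantom_from_solids(
    list(solid_box("bath", c(0, 0, 0), c(L, side, side))),
    rbind(c(0, 0, 0), c(L, side, side)))
  eset <- electrode_set(
    plate_hi = electrode("plate_hi", "shock",
                         solid_box("plate_hi", c(-3 * h, -5 * L, -5 * L),
                                   c(-h / 2, 5 * L, 5 * L))),
    plate_lo = electrode("plate_lo", "ground",
                         solid_box("plate_lo", c(L + h / 2, -5 * L, -5 * L),
                                   c(L + 3 * h, 5 * L, 5 * L))))
  mesh <- tetrahedralize(ph, eset, h = h)
  x0 <- min(mesh$nodes[, 1])
  Lx <- max(mesh$nodes[, 1]) - x0
  wy <- max(mesh$nodes[, 2]) - min(mesh$nodes[, 2])
  wz <- max(mesh$nodes[, 3]) - min(mesh$nodes[, 3])
  list(phantom = ph, eset = eset, mesh = mesh, sigma0 = sigma0,
       sigma = conductivity_map(bath = sigma0),
       x0 = x0, Lx = Lx, area_mm2 = wy * wz)
}

## Concentric spherical electrodes (inner shock at radius a, grounded shell
## at radius b) in a homogeneous medium; the closed-form potential is
## V (1/r - 1/b) / (1/a - 1/b).
make_sphere_problem <- function(a = 8, b = 32, h = 2, sigma0 = 0.2) {
  ph <- phantom_from_solids(
    list(solid_sphere("bath", c(0, 0, 0), b + h)),
    rbind(rep(-b - h, 3), rep(b + h, 3)))
  eset <- electrode_set(
    inner = electrode("inner", "shock", solid_sphere("inner", c(0, 0, 0), a)),
    outer = electrode("outer", "ground",
                      solid_shell_sphere("outer", c(0, 0, 0), b, b + 3 * h)))
  mesh <- tetrahedralize(ph, eset, h = h)
  exact <- function(r, V = 10) V * (1 / pmax(r, a) - 1 / b) / (1 / a - 1 / b)
  R_exact <- (1 / (4 * pi * sigma0)) * (1 / (a * 1e-3) - 1 / (b * 1e-3))
  list(phantom = ph, eset = eset, mesh = mesh, a = a, b = b, h = h,
       sigma0 = sigma0, sigma = conductivity_map(bath = sigma0),
       exact = exact, R_exact = R_exact)
}

unitv_test <- function(v) v / sqrt(sum(v^2))

## Deterministic per-element fibre field for I/O tests (NA on the first two
## elements to exercise the zero-fill convention of .lon files).
assign_fibers_stub <- function(mesh) {
  m <- nrow(mesh$elems)
  f <- matrix(rep(c(3, 4, 12) / 13, each = m), m, 3)
  f[1:2, ] <- NA_real_
  mesh$fibers <- f
  mesh
}

## Exact volume of a prolate-ellipsoid cap-truncated solid of revolution
## (semi-axes b radial, L axial, truncated at zeta = zb): the closed-form
## oracle for LV shell volumes.
truncated_ellipsoid_volume <- function(b, L, zb) {
  f <- function(z) pi * b^2 * (z - z^3 / (3 * L^2))
  f(zb) - f(-L)
}
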