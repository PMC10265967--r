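test_that("a unit cube cell decomposes into 6 tets of total volume 1", {
  ph <- phantom_from_solids(list(solid_box("bath", c(0, 0, 0), c(1, 1, 1))),
                            rbind(c(0.25, 0.25, 0.25), c(0.75, 0.75, 0.75)))
  mesh <- tetrahedralize(ph, NULL, h = 1)
  expect_equal(nrow(mesh$elems), 6L)
  expect_true(all(mesh$volumes > 0))
  expect_equal(sum(mesh$volumes), 1, tolerance = 1e-12)
})

test_that("tet volumes sum exactly to the lattice-domain volume", {
  ph <- generate_base_anatomy(anatomy_params(1))
  h <- 6
  mesh <- tetrahedralize(ph, NULL, h = h)
  n_cells <- nrow(mesh$elems) / 6
  expect_equal(sum(mesh$volumes), n_cells * h^3, tolerance = 1e-9)
  expect_true(all(mesh$volumes > 0))
})

test_that("halving h grows the myocardial element count about 8-fold", {
  ph <- generate_base_anatomy(anatomy_params(1))
  n_myo <- function(h) {
    m <- tetrahedralize(ph, NULL, h = h)
    sum(m$region %in% c("lv_wall", "rv_wall"))
  }
  ratio <- n_myo(2.5) / n_myo(5)
  expect_gt(ratio, 8 * 0.8)
  expect_lt(ratio, 8 * 1.2)
})

test_that("label volume fractions converge under refinement", {
  ph <- phantom_from_solids(
    list(solid_box("bath", c(-30, -30, -30), c(30, 30, 30)),
         solid_sphere("blood", c(0, 0, 0), 15),
         solid_sphere("lv_wall", c(8, 0, 0), 9, only_over = NULL)),
    rbind(rep(-30, 3), rep(30, 3)))
  frac <- function(h) {
    m <- tetrahedralize(ph, NULL, h = h)
    v <- region_volumes(m)
    v / sum(v)
  }
  f2 <- frac(2); f1 <- frac(1)
  for (lab in names(f2))
    expect_lt(abs(f2[[lab]] - f1[[lab]]) / f1[[lab]], 0.05)
})

test_that("openCARP text meshes round-trip bit-exactly", {
  slab <- make_slab(h = 2.5)
  mesh <- slab$mesh
  mesh$region[1:3] <- "lungs" # exercise >1 label
  mesh <- assign_fibers_stub(mesh)
  base <- file.path(tempdir(), "rt_mesh")
  write_mesh(mesh, base, "openCARP")
  back <- read_mesh(base, "openCARP")
  expect_identical(back$nodes, mesh$nodes)
  expect_identical(back$elems, mesh$elems)
  expect_identical(back$region, mesh$region)
  expect_equal(unname(back$fibers), unname(replace(mesh$fibers,
                                                   is.na(mesh$fibers), 0)))
})

test_that("malformed openCARP files give located parse errors", {
  slab <- make_slab(h = 5)
  base <- file.path(tempdir(), "bad_mesh")
  write_mesh(slab$mesh, base, "openCARP")
  ## truncate the .pts payload
  lines <- readLines(paste0(base, ".pts"))
  writeLines(lines[-length(lines)], paste0(base, ".pts"))
  expect_error(read_mesh(base, "openCARP"), "declares")
  writeLines(lines, paste0(base, ".pts"))
  ## corrupt an element tag
  el <- readLines(paste0(base, ".elem"))
  el[2] <- sub("^Tt", "Py", el[2])
  writeLines(el, paste0(base, ".elem"))
  expect_error(read_mesh(base, "openCARP"), "unsupported element tag")
})

test_that("VTK unstructured grids round-trip nodes, elements and labels", {
  slab <- make_slab(h = 5)
  f <- file.path(tempdir(), "rt.vtk")
  labs <- sort(unique(slab$mesh$region))
  lmap <- stats::setNames(seq_along(labs) - 1L, labs)
  write_mesh(slab$mesh, f, "VTK", label_map = lmap)
  back <- read_mesh(f, "VTK", label_map = lmap)
  expect_equal(back$nodes, slab$mesh$nodes)
  expect_identical(back$elems, slab$mesh$elems)
  expect_identical(back$region, slab$mesh$region)
})

test_that("electrodes that the lattice cannot resolve raise meshing errors", {
  ph <- phantom_from_solids(list(solid_box("bath", c(0, 0, 0), c(20, 20, 20))),
                            rbind(c(0, 0, 0), c(20, 20, 20)))
  eset <- electrode_set(
    probe = electrode("probe", "shock",
                      solid_sphere("probe", c(200, 200, 200), 2)))
  expect_error(tetrahedralize(ph, eset, h = 5), "captures no nodes")
})

test_that("electrode snapping keeps all elements valid", {
  ## plates offset from the lattice planes force genuine node motion
  ph <- phantom_from_solids(list(solid_box("bath", c(0, 0, 0), c(20, 10, 10))),
                            rbind(c(0, 0, 0), c(20, 10, 10)))
  eset <- electrode_set(
    p1 = electrode("p1", "shock",
                   solid_box("p1", c(-5, -50, -50), c(-0.4, 60, 60))),
    p2 = electrode("p2", "ground",
                   solid_box("p2", c(20.4, -50, -50), c(25, 60, 60))))
  mesh <- tetrahedralize(ph, eset, h = 2.5)
  expect_true(isTRUE(attr(mesh, "snapped")))
  expect_true(all(mesh$volumes > 0))
  expect_gt(length(mesh$electrode_nodes$p1), 0)
  ## snapped boundary nodes now lie on the analytic plate faces
  snapped <- mesh$nodes[mesh$electrode_nodes$p1, 1]
  expect_true(all(abs(snapped + 0.4) < 1e-6 | snapped < -0.4))
})
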