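test_that("measured heart dimensions hit the cohort reference targets", {
  dims <- cohort_heart_dimensions()
  for (m in c(1L, 2L, 5L)) {
    ph <- generate_base_anatomy(anatomy_params(m))
    expect_equal(measure_lvedd(ph), dims$lvedd[m], tolerance = 1e-3)
    expect_equal(measure_wall_thickness(ph), dims$wall[m], tolerance = 1e-3)

    hcm <- apply_pathology(ph, pathology("HCM"))
    expect_equal(measure_wall_thickness(hcm), dims$hcm_wall[m],
                 tolerance = 1e-3)

    dcm <- apply_pathology(ph, pathology("DCM"))
    expect_equal(measure_lvedd(dcm), dims$dcm_lvedd[m], tolerance = 1e-3)
    expect_equal(measure_wall_thickness(dcm), dims$wall[m], tolerance = 1e-3)
  }
})

test_that("pathology remodelling moves measurements in the right direction", {
  ph <- generate_base_anatomy(anatomy_params(3))
  hcm <- apply_pathology(ph, pathology("HCM"))
  dcm <- apply_pathology(ph, pathology("DCM"))
  expect_gt(measure_wall_thickness(hcm), measure_wall_thickness(ph))
  expect_gt(measure_lvedd(dcm), measure_lvedd(ph))
  ## HCM thickens inward, so its cavity shrinks
  expect_lt(measure_lvedd(hcm), measure_lvedd(ph))
  ## identity case
  expect_identical(apply_pathology(ph, pathology("healthy")), ph)
})

test_that("phantom generation is deterministic", {
  p <- anatomy_params(2, seed = 7L)
  expect_identical(generate_base_anatomy(p), generate_base_anatomy(p))
  c1 <- build_cohort(2, seed = 3)
  c2 <- build_cohort(2, seed = 3)
  expect_identical(cohort_manifest(c1), cohort_manifest(c2))
})

test_that("LV wall voxel volume agrees with the closed-form shell volume", {
  ph <- generate_base_anatomy(anatomy_params(1))
  lm <- ph$landmarks
  ## voxelize a box around the heart at 1 mm
  lo <- lm$center - (lm$L_out + 12)
  hi <- lm$center + (lm$L_out + 12)
  g <- expand.grid(x = seq(lo[1], hi[1], by = 1),
                   y = seq(lo[2], hi[2], by = 1),
                   z = seq(lo[3], hi[3], by = 1))
  lab <- label_at_points(ph, as.matrix(g))
  vox <- sum(lab == "lv_wall") # 1 mm^3 voxels
  shell <- truncated_ellipsoid_volume(lm$b_out, lm$L_out, lm$zb) -
    truncated_ellipsoid_volume(lm$b_in, lm$L_in, lm$zb)
  expect_lt(abs(vox - shell) / shell, 0.05)
})

test_that("every torso-interior point resolves to exactly one known label", {
  ph <- generate_base_anatomy(anatomy_params(4))
  set.seed(42)
  n <- 4000
  pts <- cbind(runif(n, ph$bbox[1, 1], ph$bbox[2, 1]),
               runif(n, ph$bbox[1, 2], ph$bbox[2, 2]),
               runif(n, ph$bbox[1, 3], ph$bbox[2, 3]))
  lab <- label_at_points(ph, pts)
  expect_length(lab, n)
  expect_true(all(lab %in% c("air", region_labels())))
  ## points inside the torso shell are never unlabelled
  torso <- ph$solids[[1]]
  inside <- point_in_solid(torso, pts)
  expect_true(all(lab[inside] != "air"))
})

test_that("ICM scars are carved strictly out of the LV wall", {
  ph <- generate_base_anatomy(anatomy_params(1))
  for (terr in c("LAD", "LCx", "RCA")) {
    icm <- apply_pathology(ph, pathology("ICM", terr))
    set.seed(1)
    lm <- ph$landmarks
    pts <- matrix(rnorm(3000 * 3, sd = lm$L_out), ncol = 3)
    pts <- sweep(pts, 2, lm$center, "+")
    lab_icm <- label_at_points(icm, pts)
    lab_healthy <- label_at_points(ph, pts)
    scar <- lab_icm == "scar"
    expect_gt(sum(scar), 0)
    expect_true(all(lab_healthy[scar] == "lv_wall"))
    ## outside the scar the phantoms agree
    expect_identical(lab_icm[!scar], lab_healthy[!scar])
  }
})

test_that("cohorts have the expected composition and manifests", {
  co <- build_cohort(5, seed = 1)
  expect_length(co, 20)
  man <- cohort_manifest(co)
  expect_equal(sort(unique(man$variant)),
               sort(c("healthy", "HCM", "DCM", "ICM")))
  expect_equal(as.integer(table(man$variant)[c("healthy", "HCM", "DCM", "ICM")]),
               rep(5L, 4))
  co1 <- build_cohort(1, seed = 1)
  expect_length(co1, 4)
  ## manifest JSON round-trips
  f <- tempfile(fileext = ".json")
  write_cohort_manifest(co1, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$model_id, cohort_manifest(co1)$model_id)
})

test_that("geometrically impossible anatomies are rejected", {
  expect_error(anatomy_params(1, lvedd = 20, wall_thickness = 12),
               "impossible")
  expect_error(anatomy_params(1, lvedd = -5), "positive")
  expect_error(anatomy_params(1, hcm_wall_thickness = 5), "exceed")
})
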