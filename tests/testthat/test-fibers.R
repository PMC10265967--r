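## Fibre rule checks run on a coarse full-torso mesh: the wall is several
## cells thick at h = 4, which is enough to probe the transmural rule.
local_fiber_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_base_anatomy(anatomy_params(1))
      mesh <- tetrahedralize(ph, NULL, h = 4)
      mesh <- assign_fibers(mesh, ph)
      cache <<- list(ph = ph, mesh = mesh,
                     depth = transmural_depth(mesh, ph))
    }
    cache
  }
})

test_that("fibre vectors are unit length on myocardium and absent elsewhere", {
  fx <- local_fiber_mesh()
  myo <- fx$mesh$region %in% c("lv_wall", "rv_wall", "scar")
  f <- fx$mesh$fibers
  expect_true(all(is.na(f[!myo, 1])))
  nrm <- sqrt(rowSums(f[myo, , drop = FALSE]^2))
  expect_lt(max(abs(nrm - 1)), 1e-12)
})

test_that("the helix angle interpolates linearly across the wall", {
  fx <- local_fiber_mesh()
  mesh <- fx$mesh; ph <- fx$ph; depth <- fx$depth
  lv <- which(mesh$region == "lv_wall")
  cent <- (mesh$nodes[mesh$elems[lv, 1], ] + mesh$nodes[mesh$elems[lv, 2], ] +
             mesh$nodes[mesh$elems[lv, 3], ] + mesh$nodes[mesh$elems[lv, 4], ]) / 4
  lm <- ph$landmarks
  d <- sweep(cent, 2, lm$center)
  zeta <- as.vector(d %*% lm$axis)
  radial <- d - outer(zeta, lm$axis)
  radial <- radial / sqrt(rowSums(radial^2))
  e_long <- t(vapply(seq_len(nrow(radial)), function(k)
    torsodft:::cross3(radial[k, ], torsodft:::cross3(lm$axis, radial[k, ])), numeric(3)))
  e_long <- e_long / sqrt(rowSums(e_long^2))
  ## recover the helix angle from the longitudinal component
  sina <- rowSums(mesh$fibers[lv, ] * e_long)
  ang <- asin(pmin(1, pmax(-1, sina))) * 180 / pi
  dl <- depth[lv]

  mid <- abs(dl - 0.5) < 0.04
  expect_gt(sum(mid), 10)
  expect_lt(max(abs(ang[mid])), 5)

  endo <- dl < 0.08
  expect_gt(sum(endo), 10)
  expect_lt(max(abs(ang[endo] - 60)), 10)

  epi <- dl > 0.92
  expect_gt(sum(epi), 10)
  expect_lt(max(abs(ang[epi] + 60)), 10)
})

test_that("fibres are tangential to the wall surface", {
  fx <- local_fiber_mesh()
  mesh <- fx$mesh; ph <- fx$ph
  lv <- which(mesh$region == "lv_wall")
  cent <- (mesh$nodes[mesh$elems[lv, 1], ] + mesh$nodes[mesh$elems[lv, 2], ] +
             mesh$nodes[mesh$elems[lv, 3], ] + mesh$nodes[mesh$elems[lv, 4], ]) / 4
  lm <- ph$landmarks
  d <- sweep(cent, 2, lm$center)
  zeta <- as.vector(d %*% lm$axis)
  radial <- d - outer(zeta, lm$axis)
  radial <- radial / sqrt(rowSums(radial^2))
  transmural <- abs(rowSums(mesh$fibers[lv, ] * radial))
  expect_lt(max(transmural), 0.2)
})

test_that("Laplace-Dirichlet depth agrees with the analytic shell depth", {
  ## compared on the LV free wall away from base and septum: at the septum
  ## the Laplace rule (blood interface = endocardium) sees the RV blood
  ## pool, which the analytic LV-shell coordinate counts as epicardial, so
  ## the two conventions legitimately differ there
  ph <- generate_base_anatomy(anatomy_params(1))
  mesh <- tetrahedralize(ph, NULL, h = 4)
  d_an <- transmural_depth(mesh, ph, method = "analytic")
  d_lp <- transmural_depth(mesh, method = "laplace")
  lm <- ph$landmarks
  lv <- which(mesh$region == "lv_wall")
  cent <- (mesh$nodes[mesh$elems[lv, 1], ] + mesh$nodes[mesh$elems[lv, 2], ] +
             mesh$nodes[mesh$elems[lv, 3], ] + mesh$nodes[mesh$elems[lv, 4], ]) / 4
  d <- sweep(cent, 2, lm$center)
  zeta <- as.vector(d %*% lm$axis)
  radial <- d - outer(zeta, lm$axis)
  toward_rv <- as.vector(radial %*% lm$e_rv) / sqrt(rowSums(radial^2))
  free_wall <- lv[toward_rv < -0.2 & zeta < 0.3 * lm$zb]
  expect_gt(length(free_wall), 100)
  expect_gt(stats::cor(d_an[free_wall], d_lp[free_wall]), 0.85)
  expect_lt(mean(abs(d_an[free_wall] - d_lp[free_wall])), 0.15)
})

test_that("custom helix-angle bounds are honoured", {
  ph <- generate_base_anatomy(anatomy_params(1))
  mesh <- tetrahedralize(ph, NULL, h = 4)
  m0 <- assign_fibers(mesh, ph, alpha_endo = 0, alpha_epi = 0)
  lv <- which(m0$region == "lv_wall")
  ## all-zero helix angle = purely circumferential: no longitudinal component
  lm <- ph$landmarks
  axial <- abs(as.vector(m0$fibers[lv, ] %*% lm$axis))
  expect_lt(stats::quantile(axial, 0.95), 0.25)
})
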