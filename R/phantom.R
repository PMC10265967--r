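## Parametric torso phantoms.
##
## The phantom module generates labelled analytic torso/heart geometries that
## stand in for CT-derived anatomies: an ellipsoidal torso with skin, spine,
## sternum, lungs and abdominal organs, a two-ventricle heart built from
## truncated prolate-ellipsoid shells, atrial and great-vessel shells, and
## optional cardiomyopathy remodelling (HCM wall thickening, DCM cavity
## dilation, ICM scar patches).  Every point inside the torso resolves to
## exactly one region label via the painter's algorithm.

REGION_LABELS <- c("bath", "skin", "bones", "kidneys", "liver", "stomach",
                   "spleen", "lungs", "lv_wall", "rv_wall", "la_wall",
                   "ra_wall", "aorta_wall", "svc_wall", "blood", "valves",
                   "scar")

#' Region labels used by torso phantoms
#'
#' @return Character vector of all region labels a phantom can produce
#'   (outside points are labelled `"air"`).
#' @export
region_labels <- function() REGION_LABELS

#' Reference heart dimensions of the five-model cohort
#'
#' Left-ventricular end-diastolic diameter (LVEDD) and ventricular wall
#' thickness of the five base anatomies, with the hypertrophic (HCM) wall
#' and dilated (DCM) LVEDD remodelling targets.
#'
#' @return A data.frame with columns `model`, `lvedd`, `wall`, `hcm_wall`,
#'   `dcm_lvedd` (all lengths in mm).
#' @export
cohort_heart_dimensions <- function() {
  data.frame(
    model = 1:5,
    lvedd = c(48, 45, 42, 46, 54),
    wall = c(13.5, 11.7, 12.5, 12, 11),
    hcm_wall = c(19.5, 20, 22, 18, 17),
    dcm_lvedd = c(68, 65, 62, 65, 74)
  )
}

#' Anatomy parameters for one torso phantom
#'
#' @param model Base anatomy index (1-5); sets the reference heart
#'   dimensions and a per-model body-size scale.
#' @param lvedd Healthy LV end-diastolic diameter (mm).
#' @param wall_thickness Healthy LV wall thickness (mm).
#' @param hcm_wall_thickness HCM remodelling target wall thickness (mm).
#' @param dcm_lvedd DCM remodelling target LVEDD (mm).
#' @param rv_wall_thickness RV free-wall thickness (mm, default 3.5).
#' @param atrial_wall_thickness Atrial wall thickness (mm, default 2).
#' @param aorta_wall_thickness Aortic/SVC wall thickness (mm, default 2).
#' @param torso_scale Isotropic body-size scale factor.
#' @param seed Integer seed recorded with the phantom (phantom geometry is
#'   a deterministic function of the parameters; the seed participates in
#'   cohort-level sampling such as scar-territory assignment).
#' @return An object of class `anatomy_params`.
#' @export
anatomy_params <- function(model = 1L,
                           lvedd = NULL,
                           wall_thickness = NULL,
                           hcm_wall_thickness = NULL,
                           dcm_lvedd = NULL,
                           rv_wall_thickness = 3.5,
                           atrial_wall_thickness = 2,
                           aorta_wall_thickness = 2,
                           torso_scale = NULL,
                           seed = 1L) {
  dims <- cohort_heart_dimensions()
  row <- dims[((model - 1L) %% 5L) + 1L, ]
  if (is.null(lvedd)) lvedd <- row$lvedd
  if (is.null(wall_thickness)) wall_thickness <- row$wall
  if (is.null(hcm_wall_thickness)) hcm_wall_thickness <- row$hcm_wall
  if (is.null(dcm_lvedd)) dcm_lvedd <- row$dcm_lvedd
  if (is.null(torso_scale))
    torso_scale <- c(1.00, 0.96, 0.93, 0.99, 1.05)[((model - 1L) %% 5L) + 1L]
  p <- list(model = as.integer(model), lvedd = lvedd, wall = wall_thickness,
            hcm_wall = hcm_wall_thickness, dcm_lvedd = dcm_lvedd,
            rv_wall = rv_wall_thickness, atrial_wall = atrial_wall_thickness,
            aorta_wall = aorta_wall_thickness, scale = torso_scale,
            seed = as.integer(seed))
  validate_anatomy_params(p)
  class(p) <- "anatomy_params"
  p
}

validate_anatomy_params <- function(p) {
  if (p$lvedd <= 0 || p$wall <= 0 || p$rv_wall <= 0 || p$atrial_wall <= 0 ||
      p$aorta_wall <= 0)
    stop("all heart dimensions must be positive")
  if (p$hcm_wall <= p$wall)
    stop("HCM wall thickness must exceed the healthy wall thickness")
  if (p$dcm_lvedd <= p$lvedd)
    stop("DCM LVEDD must exceed the healthy LVEDD")
  if (p$hcm_wall - p$wall >= p$lvedd / 2)
    stop("geometrically impossible parameters: wall thickening >= cavity radius")
  if (p$wall >= p$lvedd / 2)
    stop("geometrically impossible parameters: wall thickness >= LVEDD/2")
  invisible(p)
}

#' Pathology descriptor
#'
#' @param kind One of `"healthy"`, `"HCM"`, `"DCM"`, `"ICM"`.
#' @param scar_territory For ICM, the coronary perfusion territory of the
#'   scar: `"LAD"` (anterior), `"LCx"` (lateral) or `"RCA"` (inferior).
#' @param scar_radius Scar patch radius in mm (transmural spheroidal patch;
#'   a modelling assumption, see the package vignette).
#' @return An object of class `pathology`.
#' @export
pathology <- function(kind = c("healthy", "HCM", "DCM", "ICM"),
                      scar_territory = c("LAD", "LCx", "RCA"),
                      scar_radius = 25) {
  kind <- match.arg(kind)
  scar_territory <- match.arg(scar_territory)
  structure(list(kind = kind, scar_territory = scar_territory,
                 scar_radius = scar_radius), class = "pathology")
}

## Unit vector helper.
unitv <- function(v) v / sqrt(sum(v^2))

## Internal: build the full phantom for one anatomy/variant combination.
build_phantom <- function(params, variant = "healthy",
                          scar_territory = "LAD", scar_radius = 25) {
  p <- params
  sc <- p$scale

  ## --- torso shell -------------------------------------------------------
  half <- c(112, 85, 205) * sc
  tcen <- c(0, 0, -15 * sc)
  clip <- c(-150, 122) * sc
  skin_t <- 3
  solids <- list(
    solid_ellipsoid("skin", tcen, half, clip_z = clip),
    solid_ellipsoid("bath", tcen, half - skin_t, clip_z = clip)
  )

  ## --- bones, lungs, abdominal organs ------------------------------------
  solids <- c(solids, list(
    solid_cylinder("bones", c(0, -55 * sc, clip[1]), c(0, -55 * sc, clip[2]), 14 * sc),
    solid_cylinder("bones", c(0, 64 * sc, -20 * sc), c(0, 64 * sc, 95 * sc), 7 * sc),
    solid_ellipsoid("lungs", c(57 * sc, -16 * sc, 16 * sc), c(35, 45, 88) * sc),
    solid_ellipsoid("lungs", c(-57 * sc, -16 * sc, 16 * sc), c(35, 45, 88) * sc),
    solid_ellipsoid("liver", c(-45 * sc, 8 * sc, -92 * sc), c(50, 56, 42) * sc),
    solid_ellipsoid("stomach", c(42 * sc, 15 * sc, -95 * sc), c(30, 34, 32) * sc),
    solid_ellipsoid("spleen", c(72 * sc, -18 * sc, -100 * sc), c(20, 25, 28) * sc),
    solid_ellipsoid("kidneys", c(42 * sc, -42 * sc, -122 * sc), c(18, 24, 36) * sc),
    solid_ellipsoid("kidneys", c(-42 * sc, -42 * sc, -122 * sc), c(18, 24, 36) * sc)
  ))

  ## --- heart frame --------------------------------------------------------
  cen <- c(18, 10, -15) * sc                  # heart centre
  u <- unitv(c(-0.45, -0.28, 0.85))           # long axis, apex -> base
  e2h <- unitv(c(0, 1, 0) - sum(c(0, 1, 0) * u) * u)   # anterior in heart frame
  e1h <- unitv(cross3(e2h, u))                # leftward-lateral; (e1h,e2h,u) right-handed
  if (sum(e1h * c(1, 0, 0)) < 0) e1h <- -e1h
  e_rv <- unitv(c(-1, 0.55, 0) - sum(c(-1, 0.55, 0) * u) * u)  # toward the RV

  ## --- LV dimensions per variant -----------------------------------------
  b_in <- p$lvedd / 2
  L_in <- 1.6 * b_in
  w <- p$wall
  bump <- 0
  if (variant == "HCM") {
    delta <- p$hcm_wall - p$wall
    b_in <- b_in - delta
    L_in <- L_in - delta
    w <- p$hcm_wall
  } else if (variant == "DCM") {
    bump <- (p$dcm_lvedd - p$lvedd) / 2
  }
  b_out <- b_in + w
  L_out <- L_in + w
  zb <- 0.35 * L_in

  ## --- RV dimensions (healthy-referenced; DCM shifts it outward) ----------
  b_out_ref <- p$lvedd / 2 + p$wall
  d_rv <- 0.58 * (b_out + bump)
  b_rv_out <- 0.85 * b_out_ref + 0.5 * bump
  L_rv_out <- 0.93 * (1.6 * p$lvedd / 2 + p$wall)
  c_rv <- cen + d_rv * e_rv

  ## --- atria, vessels ----------------------------------------------------
  la_r <- 0.35 * b_out_ref + 13
  ra_r <- la_r - 2
  la_c <- cen + (zb + 0.55 * la_r) * u - 0.55 * la_r * e2h + 0.2 * la_r * e1h
  ra_c <- cen + (zb + 0.5 * ra_r) * u + (0.9 * ra_r) * e_rv
  aw <- p$atrial_wall

  base_c <- cen + zb * u
  aorta_pts <- rbind(base_c + 2 * u,
                     c(0.4 * base_c[1], base_c[2] - 6, 55 * sc),
                     c(2 * sc, -14 * sc, 103 * sc))
  svc_p0 <- ra_c + c(0, 0, 0.5 * ra_r)
  svc_p1 <- c(ra_c[1], ra_c[2], 106 * sc)

  solids <- c(solids, list(
    solid_sphere("la_wall", la_c, la_r),
    solid_sphere("blood", la_c, la_r - aw),
    solid_sphere("ra_wall", ra_c, ra_r),
    solid_sphere("blood", ra_c, ra_r - aw),
    solid_capsule("aorta_wall", aorta_pts, 10 + p$aorta_wall),
    solid_capsule("blood", aorta_pts, 10),
    solid_capsule("svc_wall", rbind(svc_p0, svc_p1), 6 + p$aorta_wall),
    solid_capsule("blood", rbind(svc_p0, svc_p1), 6)
  ))

  ## --- valve plate (same conductivity class as blood) ---------------------
  solids <- c(solids, list(
    solid_cylinder("valves", base_c - 2 * u, base_c + 6 * u, d_rv + b_rv_out)
  ))

  ## --- ventricles (RV first so the later LV shells carve the septum) ------
  solids <- c(solids, list(
    solid_revolve("rv_wall", c_rv, u, b_rv_out, L_rv_out, -L_rv_out, zb),
    solid_revolve("blood", c_rv, u, b_rv_out - p$rv_wall, L_rv_out - p$rv_wall,
                  -(L_rv_out - p$rv_wall), zb),
    solid_revolve("lv_wall", cen, u, b_out, L_out, -L_out, zb, bump = bump),
    solid_revolve("blood", cen, u, b_in, L_in, -L_in, zb, bump = bump)
  ))

  ## --- coronary sinus course (vein in the AV groove, posterior LV base) ---
  theta <- seq(-160, -20, by = 10) * pi / 180
  cs_r <- b_out + bump + 4
  cs_pts <- t(vapply(theta, function(th)
    cen + (zb - 2) * u + cs_r * (cos(th) * e1h + sin(th) * e2h), numeric(3)))
  solids <- c(solids, list(solid_capsule("blood", cs_pts, 2.8)))

  ## --- scar (ICM) ---------------------------------------------------------
  if (variant == "ICM") {
    dir_t <- switch(scar_territory,
                    LAD = e2h, LCx = e1h, RCA = -e2h)
    scar_c <- cen + ((b_in + bump) + w / 2) * dir_t - 0.15 * L_in * u
    solids <- c(solids, list(
      solid_sphere("scar", scar_c, scar_radius, only_over = "lv_wall")))
  }

  ## --- landmarks ----------------------------------------------------------
  lv_outer <- solids[[which(vapply(solids, function(s)
    identical(s$label, "lv_wall") && s$type == "revolve", logical(1)))[1]]]
  rv_inner <- solid_revolve("tmp", c_rv, u, b_rv_out - p$rv_wall,
                            L_rv_out - p$rv_wall, -(L_rv_out - p$rv_wall), zb)
  lv_inner <- solid_revolve("tmp", cen, u, b_in, L_in, -L_in, zb, bump = bump)

  rho_out <- function(z) revolve_radius(lv_outer, pmax(pmin(z, L_out), -L_out))
  rho_rvin <- function(z) revolve_radius(rv_inner, pmax(pmin(z, rv_inner$L), -rv_inner$L))

  zgrid <- seq(-rv_inner$L, zb, length.out = 60)
  gap <- d_rv + rho_rvin(zgrid) - rho_out(zgrid)
  feas <- which(gap > 5)
  z_apex <- zgrid[min(feas)] + 1
  zpath <- seq(z_apex, zb, length.out = 12)
  mid <- pmax(0.5 * (rho_out(zpath) + d_rv + rho_rvin(zpath)), rho_out(zpath) + 3)
  apical_pts <- t(vapply(seq_along(zpath), function(k)
    cen + mid[k] * e_rv + zpath[k] * u, numeric(3)))
  ## beyond the tricuspid plane the lead bows inside the right atrium
  ## (never up the SVC, where an SVC coil may sit): a generous RA loop
  ## gives the pulled-back septal position its full coil length
  d1 <- unitv(cross3(u, e_rv))
  tail_pts <- rbind(ra_c, ra_c + 0.62 * ra_r * d1, ra_c - 0.62 * ra_r * d1)
  rv_apical_path <- rbind(apical_pts, tail_pts)

  ## the septal position is the same lead course pulled back basally
  rv_septal_path <- rv_apical_path

  ## subcutaneous can sites on the upper chest
  can_site <- function(side) {
    z_can <- 80 * sc
    t_ang <- 48 * pi / 180
    zrel <- (z_can - tcen[3]) / half[3]
    s <- sqrt(max(0, 1 - zrel^2))
    p0 <- c(side * half[1] * s * sin(t_ang), half[2] * s * cos(t_ang), z_can)
    n <- unitv(c(p0[1] / half[1]^2, p0[2] / half[2]^2,
                 (z_can - tcen[3]) / half[3]^2))
    list(center = p0 - (skin_t + 5 + 6.5) * n, normal = n)
  }

  landmarks <- list(
    center = cen, axis = u, e1 = e1h, e2 = e2h, e_rv = e_rv,
    b_in = b_in, b_out = b_out, L_in = L_in, L_out = L_out, zb = zb,
    bump = bump, wall = w, c_rv = c_rv, d_rv = d_rv,
    b_rv_out = b_rv_out, L_rv_out = L_rv_out, rv_wall = p$rv_wall,
    apex = cen - L_out * u, base_center = base_c,
    ra_center = ra_c, la_center = la_c,
    svc_axis = rbind(svc_p0, svc_p1), cs_course = cs_pts,
    rv_apical_path = rv_apical_path, rv_septal_path = rv_septal_path,
    can_left = can_site(+1), can_right = can_site(-1),
    lv_outer = lv_outer, lv_inner = lv_inner, rv_inner = rv_inner
  )

  structure(list(
    solids = solids, landmarks = landmarks, params = p, variant = variant,
    scar_territory = if (variant == "ICM") scar_territory else NA_character_,
    scar_radius = if (variant == "ICM") scar_radius else NA_real_,
    bbox = rbind(lo = c(-half[1], -half[2], clip[1]),
                 hi = c(half[1], half[2], clip[2]))
  ), class = "torso_phantom")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a healthy base torso anatomy
#'
#' Builds the labelled analytic torso phantom for one anatomy: torso shell
#' with skin, spine and sternum, lungs, liver, stomach, spleen, kidneys,
#' two-ventricle heart (truncated prolate-ellipsoid shells; RV free wall
#' 3.5 mm), atrial shells, aorta and SVC, coronary sinus course, and the
#' landmark frame used for electrode placement.
#'
#' @param params An [anatomy_params()] object.
#' @return A `torso_phantom` object (ordered solid list + landmarks).
#' @export
generate_base_anatomy <- function(params) {
  validate_anatomy_params(params)
  build_phantom(params, "healthy")
}

#' Apply a cardiomyopathy variant to a healthy phantom
#'
#' HCM thickens the LV wall homogeneously inward into the blood pool to the
#' target thickness; DCM dilates the LV cavity radially to the target LVEDD
#' with a smooth attenuation of the dilation towards apex and base, keeping
#' the wall thickness; ICM inserts a spheroidal transmural scar patch into
#' the LV wall at the requested coronary territory.
#'
#' @param phantom A healthy `torso_phantom`.
#' @param p A [pathology()] descriptor.
#' @return A `torso_phantom` of the requested variant.
#' @export
apply_pathology <- function(phantom, p) {
  stopifnot(inherits(phantom, "torso_phantom"), inherits(p, "pathology"))
  if (!identical(phantom$variant, "healthy"))
    stop("apply_pathology() expects a healthy base phantom")
  if (p$kind == "healthy") return(phantom)
  build_phantom(phantom$params, p$kind, p$scar_territory, p$scar_radius)
}

#' Build the synthetic study cohort
#'
#' Produces `n_anatomies` base anatomies, each in four variants (healthy,
#' HCM, DCM, ICM), mirroring the five-anatomy, twenty-model study cohort.
#' Scar territories for the ICM variants are sampled (seeded) from the three
#' coronary territories so that the cohort covers a variety of typical
#' perfusion territories.
#'
#' @param n_anatomies Number of base anatomies (default 5).
#' @param seed Integer seed controlling cohort-level sampling.
#' @return A list of entries `list(phantom, model_id, anatomy, variant)`.
#' @export
build_cohort <- function(n_anatomies = 5L, seed = 1L) {
  stopifnot(n_anatomies >= 1)
  territories <- with_local_seed(seed, sample(c("LAD", "LCx", "RCA"),
                                              n_anatomies, replace = TRUE))
  variants <- c("healthy", "HCM", "DCM", "ICM")
  cohort <- list()
  for (a in seq_len(n_anatomies)) {
    params <- anatomy_params(model = a, seed = seed)
    healthy <- generate_base_anatomy(params)
    for (v in variants) {
      ph <- if (v == "healthy") healthy else
        apply_pathology(healthy, pathology(v, territories[a]))
      cohort[[length(cohort) + 1L]] <- list(
        phantom = ph,
        model_id = sprintf("m%d_%s", a, tolower(v)),
        anatomy = a, variant = v)
    }
  }
  cohort
}

## Evaluate an expression under a temporary RNG seed, restoring the caller's
## RNG state afterwards.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cohort manifest
#'
#' @param cohort A cohort from [build_cohort()].
#' @return A data.frame with one row per model: `model_id`, `anatomy`,
#'   `variant`, `seed`, heart dimensions, scar descriptor.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(m) {
    p <- m$phantom$params
    data.frame(model_id = m$model_id, anatomy = m$anatomy,
               variant = m$variant, seed = p$seed, lvedd = p$lvedd,
               wall_thickness = p$wall, hcm_wall = p$hcm_wall,
               dcm_lvedd = p$dcm_lvedd, torso_scale = p$scale,
               scar_territory = m$phantom$scar_territory,
               scar_radius = m$phantom$scar_radius,
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort manifest as JSON
#'
#' @param cohort A cohort from [build_cohort()].
#' @param path Output file path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  jsonlite::write_json(cohort_manifest(cohort), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' Assemble a phantom from raw solids
#'
#' Lower-level constructor used for benchmark and verification geometries
#' (slabs, concentric spheres): an ordered solid list plus a bounding box
#' is everything the mesher needs.
#'
#' @param solids Ordered list of solids (painter's algorithm).
#' @param bbox 2 x 3 matrix `rbind(lo, hi)` in mm.
#' @return A `torso_phantom` without heart landmarks.
#' @export
phantom_from_solids <- function(solids, bbox) {
  structure(list(solids = solids, landmarks = NULL, params = NULL,
                 variant = "custom", scar_territory = NA_character_,
                 scar_radius = NA_real_,
                 bbox = rbind(lo = as.numeric(bbox[1, ]),
                              hi = as.numeric(bbox[2, ]))),
            class = "torso_phantom")
}

#' Resolve region labels at points
#'
#' Applies the painter's algorithm over the phantom's ordered solid list:
#' the last solid containing a point determines its label; solids with an
#' `only_over` constraint only repaint points currently carrying that label.
#' Points outside every solid are labelled `"air"`.
#'
#' @param phantom A `torso_phantom`.
#' @param pts Numeric matrix (n x 3) of query points in mm.
#' @return Character vector of labels, length n.
#' @export
label_at_points <- function(phantom, pts) {
  pts <- rbind(pts)
  lab <- rep("air", nrow(pts))
  for (s in phantom$solids) {
    inside <- point_in_solid(s, pts)
    if (!is.null(s$only_over)) inside <- inside & lab == s$only_over
    if (any(inside)) lab[inside] <- s$label
  }
  lab
}

## March along a ray from `origin` in direction `dir` and return the signed
## extent of the contiguous run of `labels` starting at `from` (mm), located
## by bisection to `tol`.
ray_extent <- function(phantom, origin, dir, labels, from = 0, tmax = 120,
                       tol = 1e-3) {
  dir <- unitv(dir)
  at <- function(t) label_at_points(phantom, rbind(origin + t * dir))
  if (!(at(from) %in% labels)) return(c(from, from))
  step <- 0.5
  t_hi <- from
  while (t_hi < tmax && at(t_hi + step) %in% labels) t_hi <- t_hi + step
  lo <- t_hi; hi <- min(t_hi + step, tmax)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (at(mid) %in% labels) lo <- mid else hi <- mid
  }
  c(from, lo)
}

#' Measure the LV end-diastolic diameter of a phantom
#'
#' Casts rays from the LV centre along the short axis through the equator
#' and measures the blood-pool extent, i.e. the quantity a sonographer
#' would report as LVEDD.
#'
#' @param phantom A `torso_phantom`.
#' @return LVEDD in mm.
#' @export
measure_lvedd <- function(phantom) {
  lm <- phantom$landmarks
  plus <- ray_extent(phantom, lm$center, lm$e1, "blood")[2]
  minus <- ray_extent(phantom, lm$center, -lm$e1, "blood")[2]
  plus + minus
}

#' Measure the LV wall thickness of a phantom
#'
#' Continues the equatorial short-axis ray beyond the blood pool and
#' measures the myocardial (wall or scar) extent, averaged over both sides.
#'
#' @param phantom A `torso_phantom`.
#' @return Wall thickness in mm.
#' @export
measure_wall_thickness <- function(phantom) {
  lm <- phantom$landmarks
  one_side <- function(dir) {
    cav <- ray_extent(phantom, lm$center, dir, "blood")[2]
    wall <- ray_extent(phantom, lm$center, dir, c("lv_wall", "scar"),
                       from = cav + 1e-2)
    wall[2] - cav
  }
  (one_side(lm$e1) + one_side(-lm$e1)) / 2
}

#' @export
print.torso_phantom <- function(x, ...) {
  cat(sprintf("torso_phantom: model %d, variant %s, %d solids\n",
              x$params$model, x$variant, length(x$solids)))
  cat(sprintf("  LVEDD target %.1f mm, wall %.1f mm, torso scale %.2f\n",
              x$params$lvedd, x$params$wall, x$params$scale))
  if (!is.na(x$scar_territory))
    cat(sprintf("  scar: %s territory, radius %.0f mm\n",
                x$scar_territory, x$scar_radius))
  invisible(x)
}
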