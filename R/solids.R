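## Analytic solid primitives.
##
## A solid is a plain list: list(type = ..., label = ..., only_over = NULL,
## <geometry fields>).  Phantoms are ordered lists of solids resolved by the
## painter's algorithm: later solids override earlier ones at overlapping
## points, optionally restricted to points currently carrying the
## `only_over` label (used for scar patches that must stay inside the LV
## wall).  All lengths are in mm.

solid <- function(type, label, ..., only_over = NULL) {
  s <- list(type = type, label = label, only_over = only_over, ...)
  class(s) <- "torso_solid"
  s
}

#' Solid primitives
#'
#' Constructors for the analytic solids phantoms are painted from:
#' ellipsoids (optionally truncated in z), spheres and spherical shells,
#' axis-aligned boxes, finite cylinders, capsules (tubes around a
#' polyline) and truncated surfaces of revolution (the ventricular
#' shells).  `point_in_solid()` tests membership, `solid_sdf()` gives the
#' signed distance to electrode-grade solids (negative inside).
#'
#' @param label Region label the solid paints.
#' @param center,half,clip_z Ellipsoid centre, half-axes and optional z
#'   truncation interval (mm).
#' @param radius,r_in,r_out Radii (mm).
#' @param lo,hi Box corners (mm).
#' @param p0,p1 Cylinder end points (mm).
#' @param pts Polyline vertices (k x 3, mm) for capsules.
#' @param axis Revolution axis (unit vector, apex towards `-axis`).
#' @param b,L,zeta0,zeta1,bump Revolve profile: equatorial radius, long
#'   semi-axis, axial truncation range, equatorial bump amplitude (mm).
#' @param only_over Restrict painting to points currently carrying this
#'   label.
#' @param s A solid.
#' @name solids
NULL

#' @rdname solids
#' @export
solid_ellipsoid <- function(label, center, half, clip_z = NULL, only_over = NULL) {
  solid("ellipsoid", label, center = as.numeric(center), half = as.numeric(half),
        clip_z = clip_z, only_over = only_over)
}

#' @rdname solids
#' @export
solid_sphere <- function(label, center, radius, only_over = NULL) {
  solid("sphere", label, center = as.numeric(center), radius = radius,
        only_over = only_over)
}

#' @rdname solids
#' @export
solid_shell_sphere <- function(label, center, r_in, r_out, only_over = NULL) {
  solid("shell_sphere", label, center = as.numeric(center), r_in = r_in,
        r_out = r_out, only_over = only_over)
}

#' @rdname solids
#' @export
solid_box <- function(label, lo, hi, only_over = NULL) {
  solid("box", label, lo = as.numeric(lo), hi = as.numeric(hi),
        only_over = only_over)
}

## Finite cylinder with flat caps from p0 to p1.
#' @rdname solids
#' @export
solid_cylinder <- function(label, p0, p1, radius, only_over = NULL) {
  solid("cylinder", label, p0 = as.numeric(p0), p1 = as.numeric(p1),
        radius = radius, only_over = only_over)
}

## Tube of given radius around a polyline (round caps); used for vessels,
## shock coils and the CS course.
#' @rdname solids
#' @export
solid_capsule <- function(label, pts, radius, only_over = NULL) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  solid("capsule", label, pts = pts, radius = radius, only_over = only_over)
}

## Truncated surface of revolution around the axis `u` through `center`:
## local long-axis coordinate zeta in [zeta0, zeta1], radial coordinate rho
## inside when rho <= profile(zeta).  Profiles are truncated ellipses with an
## optional smooth equatorial bump (the DCM dilation).
## profile fields: b (equatorial radius), L (long semi-axis; apex at -L),
## bump (additive mm at the equator, tapering C1-smoothly to zero at apex
## and base).
#' @rdname solids
#' @export
solid_revolve <- function(label, center, axis, b, L, zeta0, zeta1, bump = 0,
                          only_over = NULL) {
  solid("revolve", label, center = as.numeric(center),
        axis = as.numeric(axis) / sqrt(sum(axis^2)),
        b = b, L = L, zeta0 = zeta0, zeta1 = zeta1, bump = bump,
        only_over = only_over)
}

## C1 bump profile: 1 at the equator (zeta = 0), 0 at apex (-L) and base (zb).
revolve_bump <- function(zeta, L, zb) {
  g <- numeric(length(zeta))
  lo <- zeta < 0
  g[lo] <- sin(pmax(0, (zeta[lo] + L) / L) * pi / 2)
  if (zb > 0) g[!lo] <- cos(pmin(1, zeta[!lo] / zb) * pi / 2)
  g
}

revolve_radius <- function(s, zeta) {
  rho <- s$b * sqrt(pmax(0, 1 - (zeta / s$L)^2))
  if (s$bump != 0) rho <- rho + s$bump * revolve_bump(zeta, s$L, s$zeta1)
  rho
}

#' @rdname solids
#' @param pts Numeric matrix (n x 3) of query points (mm).
#' @export
point_in_solid <- function(s, pts) {
  pts <- rbind(pts) # tolerate a single point given as a vector
  switch(s$type,
    ellipsoid = {
      d1 <- (pts[, 1] - s$center[1]) / s$half[1]
      d2 <- (pts[, 2] - s$center[2]) / s$half[2]
      d3 <- (pts[, 3] - s$center[3]) / s$half[3]
      inside <- d1 * d1 + d2 * d2 + d3 * d3 <= 1
      if (!is.null(s$clip_z))
        inside <- inside & pts[, 3] >= s$clip_z[1] & pts[, 3] <= s$clip_z[2]
      inside
    },
    sphere = {
      r2 <- (pts[, 1] - s$center[1])^2 + (pts[, 2] - s$center[2])^2 +
        (pts[, 3] - s$center[3])^2
      r2 <= s$radius^2
    },
    shell_sphere = {
      r2 <- (pts[, 1] - s$center[1])^2 + (pts[, 2] - s$center[2])^2 +
        (pts[, 3] - s$center[3])^2
      r2 >= s$r_in^2 & r2 <= s$r_out^2
    },
    box = {
      pts[, 1] >= s$lo[1] & pts[, 1] <= s$hi[1] &
        pts[, 2] >= s$lo[2] & pts[, 2] <= s$hi[2] &
        pts[, 3] >= s$lo[3] & pts[, 3] <= s$hi[3]
    },
    cylinder = {
      ax <- s$p1 - s$p0
      L2 <- sum(ax^2)
      d1 <- pts[, 1] - s$p0[1]; d2 <- pts[, 2] - s$p0[2]; d3 <- pts[, 3] - s$p0[3]
      t <- (d1 * ax[1] + d2 * ax[2] + d3 * ax[3]) / L2
      px <- d1 - t * ax[1]; py <- d2 - t * ax[2]; pz <- d3 - t * ax[3]
      t >= 0 & t <= 1 & (px^2 + py^2 + pz^2) <= s$radius^2
    },
    capsule = dist_to_polyline(pts, s$pts) <= s$radius,
    revolve = {
      d <- sweep(pts, 2, s$center)
      zeta <- d %*% s$axis
      rho2 <- rowSums(d * d) - zeta^2
      ok <- zeta >= s$zeta0 & zeta <= s$zeta1
      r <- revolve_radius(s, pmin(pmax(zeta, -s$L), s$L))
      ok & rho2 <= r^2 & abs(zeta) <= s$L
    },
    stop("unknown solid type: ", s$type)
  )
}

## Minimum distance from points to a polyline (mm).
dist_to_polyline <- function(pts, poly) {
  pts <- rbind(pts)
  d2min <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(poly) - 1)) {
    a <- poly[k, ]; b <- poly[k + 1, ]
    ab <- b - a
    L2 <- sum(ab^2)
    d1 <- pts[, 1] - a[1]; d2 <- pts[, 2] - a[2]; d3 <- pts[, 3] - a[3]
    t <- if (L2 > 0) pmin(1, pmax(0, (d1 * ab[1] + d2 * ab[2] + d3 * ab[3]) / L2)) else 0
    px <- d1 - t * ab[1]; py <- d2 - t * ab[2]; pz <- d3 - t * ab[3]
    d2min <- pmin(d2min, px^2 + py^2 + pz^2)
  }
  if (nrow(poly) == 1) {
    d2min <- (pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2 +
      (pts[, 3] - poly[1, 3])^2
  }
  sqrt(d2min)
}

## Signed distance (negative inside) for electrode-grade primitives, and the
## projection of near-surface points onto the analytic surface.  Only the
## types used as electrodes or field-oracle boundaries need these.
#' @rdname solids
#' @export
solid_sdf <- function(s, pts) {
  pts <- rbind(pts)
  switch(s$type,
    sphere = {
      r <- sqrt((pts[, 1] - s$center[1])^2 + (pts[, 2] - s$center[2])^2 +
                  (pts[, 3] - s$center[3])^2)
      r - s$radius
    },
    shell_sphere = {
      r <- sqrt((pts[, 1] - s$center[1])^2 + (pts[, 2] - s$center[2])^2 +
                  (pts[, 3] - s$center[3])^2)
      pmax(s$r_in - r, r - s$r_out)
    },
    capsule = dist_to_polyline(pts, s$pts) - s$radius,
    cylinder = {
      ax <- s$p1 - s$p0
      len <- sqrt(sum(ax^2))
      axu <- ax / len
      d1 <- pts[, 1] - s$p0[1]; d2 <- pts[, 2] - s$p0[2]; d3 <- pts[, 3] - s$p0[3]
      t <- d1 * axu[1] + d2 * axu[2] + d3 * axu[3]
      px <- d1 - t * axu[1]; py <- d2 - t * axu[2]; pz <- d3 - t * axu[3]
      rho <- sqrt(px^2 + py^2 + pz^2)
      dr <- rho - s$radius
      dz <- pmax(-t, t - len)
      ifelse(dr <= 0 & dz <= 0, pmax(dr, dz),
             sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2))
    },
    box = {
      qx <- pmax(s$lo[1] - pts[, 1], pts[, 1] - s$hi[1])
      qy <- pmax(s$lo[2] - pts[, 2], pts[, 2] - s$hi[2])
      qz <- pmax(s$lo[3] - pts[, 3], pts[, 3] - s$hi[3])
      inside <- qx <= 0 & qy <= 0 & qz <= 0
      ifelse(inside, pmax(qx, qy, qz),
             sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2 + pmax(qz, 0)^2))
    },
    stop("no signed distance for solid type: ", s$type)
  )
}

## Axis-aligned bounding box of an electrode-grade solid (2 x 3, lo/hi).
solid_bbox <- function(s) {
  switch(s$type,
    sphere = rbind(s$center - s$radius, s$center + s$radius),
    shell_sphere = rbind(s$center - s$r_out, s$center + s$r_out),
    capsule = rbind(apply(s$pts, 2, min) - s$radius,
                    apply(s$pts, 2, max) + s$radius),
    cylinder = rbind(pmin(s$p0, s$p1) - s$radius, pmax(s$p0, s$p1) + s$radius),
    box = rbind(s$lo, s$hi),
    stop("no bounding box for solid type: ", s$type)
  )
}

## Project points onto the surface of an electrode-grade solid by stepping
## along the numerical gradient of the signed distance.  Exact enough for the
## sub-half-cell moves used by mesh snapping.
project_to_surface <- function(s, pts, iter = 3L) {
  pts <- rbind(pts)
  eps <- 1e-4
  for (it in seq_len(iter)) {
    d <- solid_sdf(s, pts)
    if (all(abs(d) < 1e-9)) break
    gx <- (solid_sdf(s, sweep(pts, 2, c(eps, 0, 0), "+")) - d) / eps
    gy <- (solid_sdf(s, sweep(pts, 2, c(0, eps, 0), "+")) - d) / eps
    gz <- (solid_sdf(s, sweep(pts, 2, c(0, 0, eps), "+")) - d) / eps
    nrm <- pmax(sqrt(gx^2 + gy^2 + gz^2), 1e-12)
    pts <- pts - cbind(d * gx / nrm, d * gy / nrm, d * gz / nrm)
  }
  pts
}
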