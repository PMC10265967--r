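## Rule-based myocardial fibre architecture.
##
## Fibres are assigned per element from the transmural depth d (0 at the
## endocardium, 1 at the epicardium): the helix angle interpolates linearly
## from alpha_endo to alpha_epi with depth and the fibre vector is laid in
## the local tangent plane, fibre = cos(a) e_circ + sin(a) e_long.  For
## lattice meshes built from a phantom the depth comes from the analytic
## shell geometry; for imported meshes a Laplace-Dirichlet depth solve is
## available.

#' Transmural depth per myocardial element
#'
#' @param mesh A `fem_mesh`.
#' @param phantom The source `torso_phantom` (required for
#'   `method = "analytic"`).
#' @param method `"analytic"` (interpolated shell coordinate of the
#'   phantom's LV/RV revolve surfaces) or `"laplace"` (finite-element
#'   Laplace-Dirichlet solve on the wall subdomain with endocardial
#'   boundary 0 and epicardial boundary 1).
#' @return Numeric vector, length = number of elements; depth in `[0, 1]`
#'   for LV/RV wall (and scar) elements, `NA` elsewhere.
#' @export
transmural_depth <- function(mesh, phantom = NULL,
                             method = c("analytic", "laplace")) {
  method <- match.arg(method)
  if (method == "analytic") {
    if (is.null(phantom)) stop("analytic depth requires the source phantom")
    analytic_depth(mesh, phantom)
  } else {
    laplace_depth(mesh)
  }
}

## Interpolated shell coordinate: for a point with heart-frame coordinates
## (rho, zeta), find s in [0,1] such that the point lies on the ellipse
## profile with semi-axes linearly interpolated between the inner and outer
## shell; bisection, vectorized.
shell_coordinate <- function(pts, center, axis, b_in, L_in, b_out, L_out,
                             bump = 0, zb = Inf) {
  d <- sweep(rbind(pts), 2, center)
  zeta <- as.vector(d %*% axis)
  rho <- sqrt(pmax(0, rowSums(d * d) - zeta^2))
  if (bump != 0) rho <- pmax(0, rho - bump * revolve_bump(zeta, L_in, zb))
  lo <- rep(0, length(zeta)); hi <- rep(1, length(zeta))
  gfun <- function(s) {
    b <- b_in + s * (b_out - b_in)
    L <- L_in + s * (L_out - L_in)
    (rho / b)^2 + (zeta / L)^2 - 1
  }
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    g <- gfun(mid)
    inside <- g <= 0 # point inside the mid-shell => depth smaller
    hi[inside] <- mid[inside]
    lo[!inside] <- mid[!inside]
  }
  pmin(1, pmax(0, (lo + hi) / 2))
}

analytic_depth <- function(mesh, phantom) {
  lm <- phantom$landmarks
  depth <- rep(NA_real_, nrow(mesh$elems))
  sub_centroids <- function(which_idx) {
    (mesh$nodes[mesh$elems[which_idx, 1], , drop = FALSE] +
       mesh$nodes[mesh$elems[which_idx, 2], , drop = FALSE] +
       mesh$nodes[mesh$elems[which_idx, 3], , drop = FALSE] +
       mesh$nodes[mesh$elems[which_idx, 4], , drop = FALSE]) / 4
  }
  lv <- which(mesh$region %in% c("lv_wall", "scar"))
  if (length(lv)) {
    depth[lv] <- shell_coordinate(sub_centroids(lv), lm$center, lm$axis,
                                  lm$b_in, lm$L_in, lm$b_out, lm$L_out,
                                  bump = lm$bump, zb = lm$zb)
  }
  rv <- which(mesh$region == "rv_wall")
  if (length(rv)) {
    rvi <- lm$rv_inner
    depth[rv] <- shell_coordinate(sub_centroids(rv), lm$c_rv, lm$axis,
                                  rvi$b, rvi$L, lm$b_rv_out, lm$L_rv_out)
  }
  depth
}

## Laplace-Dirichlet depth: endocardial wall nodes (shared with blood or
## valve elements) at 0, epicardial wall nodes (shared with any other
## non-wall region) at 1.
laplace_depth <- function(mesh) {
  wall <- mesh$region %in% c("lv_wall", "rv_wall", "scar")
  if (!any(wall)) stop("mesh has no myocardial wall elements")
  wall_nodes <- unique(as.vector(mesh$elems[wall, ]))
  endo_reg <- mesh$region %in% c("blood", "valves")
  endo_nodes <- intersect(unique(as.vector(mesh$elems[endo_reg, ])), wall_nodes)
  other <- !wall & !endo_reg
  epi_nodes <- setdiff(intersect(unique(as.vector(mesh$elems[other, ])),
                                 wall_nodes), endo_nodes)
  if (!length(endo_nodes) || !length(epi_nodes))
    stop("cannot identify endo/epi boundaries for the Laplace depth solve")

  ## submesh of wall elements with renumbered nodes
  sub_elems <- mesh$elems[wall, , drop = FALSE]
  sub_nodes_idx <- sort(unique(as.vector(sub_elems)))
  remap <- integer(nrow(mesh$nodes))
  remap[sub_nodes_idx] <- seq_along(sub_nodes_idx)
  sub_elems[] <- remap[sub_elems]
  sub_nodes <- mesh$nodes[sub_nodes_idx, , drop = FALSE]
  tensors <- matrix(rep(c(1, 1, 1, 0, 0, 0), each = nrow(sub_elems)),
                    nrow(sub_elems), 6)
  trip <- assemble_triplets_cpp(sub_nodes, sub_elems, tensors)
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = rep(length(sub_nodes_idx), 2))
  ud <- rep(NA_real_, length(sub_nodes_idx))
  ud[remap[endo_nodes]] <- 0
  ud[remap[epi_nodes]] <- 1
  fixed <- !is.na(ud)
  ud0 <- ifelse(fixed, ud, 0)
  b <- -(K %*% ud0)[!fixed]
  Kff <- Matrix::forceSymmetric(K[!fixed, !fixed])
  uf <- as.vector(Matrix::solve(Kff, b))
  u <- ud0
  u[!fixed] <- uf
  node_depth <- rep(NA_real_, nrow(mesh$nodes))
  node_depth[sub_nodes_idx] <- pmin(1, pmax(0, u))
  depth <- rep(NA_real_, nrow(mesh$elems))
  depth[wall] <- rowMeans(matrix(node_depth[mesh$elems[wall, ]], ncol = 4))
  depth
}

element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
     mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
}

#' Assign rule-based fibre orientations
#'
#' @param mesh A `fem_mesh` with LV/RV wall labels.
#' @param phantom Source phantom for the analytic transmural depth
#'   (optional if `depth` is supplied or `method = "laplace"`).
#' @param alpha_endo,alpha_epi Helix angles (degrees) at the endocardium
#'   and epicardium; the angle interpolates linearly with transmural depth.
#' @param method Depth method, see [transmural_depth()].
#' @param depth Optional precomputed per-element depth.
#' @return The mesh with an `m x 3` `fibers` matrix of unit vectors
#'   (`NA` rows for non-myocardial elements).
#' @export
assign_fibers <- function(mesh, phantom = NULL, alpha_endo = 60,
                          alpha_epi = -60, method = c("analytic", "laplace"),
                          depth = NULL) {
  method <- match.arg(method)
  myo <- mesh$region %in% c("lv_wall", "rv_wall", "scar")
  if (!any(myo)) stop("mesh has no myocardial wall elements")
  if (is.null(depth)) depth <- transmural_depth(mesh, phantom, method)

  idx <- which(myo)
  cent <- (mesh$nodes[mesh$elems[idx, 1], ] + mesh$nodes[mesh$elems[idx, 2], ] +
             mesh$nodes[mesh$elems[idx, 3], ] +
             mesh$nodes[mesh$elems[idx, 4], ]) / 4
  if (!is.null(phantom)) {
    ctr <- phantom$landmarks$center
    axis <- phantom$landmarks$axis
    ## RV elements take the transmural direction about the RV shell centre
    rv <- mesh$region[idx] == "rv_wall"
    ctrm <- matrix(ctr, nrow(cent), 3, byrow = TRUE)
    if (any(rv)) ctrm[rv, ] <- matrix(phantom$landmarks$c_rv, sum(rv), 3,
                                      byrow = TRUE)
  } else {
    ## centroid of the wall as a generic axis origin
    ctr <- colMeans(cent)
    axis <- c(0, 0, 1)
    ctrm <- matrix(ctr, nrow(cent), 3, byrow = TRUE)
  }

  d <- cent - ctrm
  zeta <- as.vector(d %*% axis)
  radial <- d - outer(zeta, axis)
  rn <- sqrt(rowSums(radial^2))
  thin <- rn < 1e-9
  radial <- radial / pmax(rn, 1e-12)

  e_circ <- cbind(axis[2] * radial[, 3] - axis[3] * radial[, 2],
                  axis[3] * radial[, 1] - axis[1] * radial[, 3],
                  axis[1] * radial[, 2] - axis[2] * radial[, 1])
  e_circ <- e_circ / pmax(sqrt(rowSums(e_circ^2)), 1e-12)
  e_long <- cbind(radial[, 2] * e_circ[, 3] - radial[, 3] * e_circ[, 2],
                  radial[, 3] * e_circ[, 1] - radial[, 1] * e_circ[, 3],
                  radial[, 1] * e_circ[, 2] - radial[, 2] * e_circ[, 1])
  e_long <- e_long / pmax(sqrt(rowSums(e_long^2)), 1e-12)

  dd <- depth[idx]
  missing_depth <- is.na(dd) | thin
  if (any(missing_depth)) {
    warning(sum(missing_depth), " myocardial elements lack a usable ",
            "transmural depth; falling back to circumferential fibres there")
    dd[missing_depth] <- 0.5
  }
  alpha <- (alpha_endo + dd * (alpha_epi - alpha_endo)) * pi / 180
  fib <- matrix(NA_real_, nrow(mesh$elems), 3)
  fv <- cos(alpha) * e_circ + sin(alpha) * e_long
  fib[idx, ] <- fv / sqrt(rowSums(fv^2))
  mesh$fibers <- fib
  attr(mesh$fibers, "alpha") <- c(endo = alpha_endo, epi = alpha_epi)
  mesh
}
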