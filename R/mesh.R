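## Region-labelled tetrahedral meshes on a structured lattice.
##
## Phantoms are discretized on a regular cubic lattice of spacing h: every
## cell whose centroid lies inside the torso (non-air label) is split into
## the six Kuhn tetrahedra sharing the cell's main diagonal, which yields a
## conforming mesh.  Element labels are the phantom label at the cell
## centroid.  Electrode surfaces are optionally "snapped": lattice nodes
## within 0.45 h of an electrode surface are projected onto the analytic
## surface, giving smooth electrode boundaries (stair-stepped voxel
## electrodes bias the effective electrode size by O(h) and with it every
## impedance; snapping restores O(h^2) geometric accuracy).

KUHN_TETS <- rbind(
  c(1, 2, 4, 8), # 000 100 110 111
  c(1, 2, 6, 8), # 000 100 101 111
  c(1, 3, 4, 8), # 000 010 110 111
  c(1, 3, 7, 8), # 000 010 011 111
  c(1, 5, 6, 8), # 000 001 101 111
  c(1, 5, 7, 8)  # 000 001 011 111
)
CORNER_OFFSETS <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))

#' Tetrahedralize a phantom on a structured lattice
#'
#' @param phantom A `torso_phantom` (or any object with `$solids` and
#'   `$bbox`), voxelized at centroid resolution.
#' @param electrodes Optional `electrode_set` from [build_configuration()];
#'   electrode nodes are identified and (by default) snapped onto the
#'   analytic electrode surfaces.
#' @param h Lattice spacing in mm.
#' @param snap_electrodes Snap near-surface nodes onto electrode surfaces
#'   (default TRUE).  With snapping disabled the mesh is an exact lattice
#'   decomposition and the sum of element volumes equals the lattice-domain
#'   volume exactly.
#' @return An object of class `fem_mesh` with fields `nodes` (n x 3, mm),
#'   `elems` (m x 4 node indices), `region` (character per element),
#'   `volumes`, `h`, `lattice` (dims/origin/per-node integer coordinates)
#'   and per-electrode node sets.
#' @export
tetrahedralize <- function(phantom, electrodes = NULL, h,
                           snap_electrodes = TRUE) {
  stopifnot(h > 0)
  lo <- phantom$bbox[1, ] - h / 2
  hi <- phantom$bbox[2, ] + h / 2
  ncell <- pmax(1L, as.integer(ceiling((hi - lo) / h)))
  ## cell centroids
  cx <- lo[1] + (seq_len(ncell[1]) - 0.5) * h
  cy <- lo[2] + (seq_len(ncell[2]) - 0.5) * h
  cz <- lo[3] + (seq_len(ncell[3]) - 0.5) * h
  cent <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  lab <- label_at_points(phantom, cent)
  keep <- which(lab != "air")
  if (!length(keep)) stop("no lattice cell falls inside the phantom at h = ", h)
  lab <- lab[keep]
  ## integer cell coordinates (0-based)
  kc <- keep - 1L
  ci <- kc %% ncell[1]
  cj <- (kc %/% ncell[1]) %% ncell[2]
  ck <- kc %/% (ncell[1] * ncell[2])

  nd <- ncell + 1L
  nid <- function(i, j, k) 1L + i + nd[1] * (j + nd[2] * k)
  corner_ids <- matrix(0L, length(keep), 8L)
  for (c8 in 1:8) {
    corner_ids[, c8] <- nid(ci + CORNER_OFFSETS[c8, 1],
                            cj + CORNER_OFFSETS[c8, 2],
                            ck + CORNER_OFFSETS[c8, 3])
  }
  used <- sort(unique(as.vector(corner_ids)))
  rank_of <- integer(nd[1] * nd[2] * nd[3])
  rank_of[used] <- seq_along(used)
  u0 <- used - 1L
  node_ijk <- cbind(i = u0 %% nd[1],
                    j = (u0 %/% nd[1]) %% nd[2],
                    k = u0 %/% (nd[1] * nd[2]))
  nodes <- cbind(lo[1] + node_ijk[, 1] * h,
                 lo[2] + node_ijk[, 2] * h,
                 lo[3] + node_ijk[, 3] * h)

  m6 <- nrow(KUHN_TETS)
  elems <- matrix(0L, length(keep) * m6, 4L)
  for (t in seq_len(m6)) {
    rows <- seq.int(t, by = m6, length.out = length(keep))
    for (a in 1:4) elems[rows, a] <- rank_of[corner_ids[, KUHN_TETS[t, a]]]
  }
  region <- rep(lab, each = m6)

  ## fix element orientation pattern-wise (all cells are congruent)
  vol1 <- tet_volumes_cpp(nodes, elems[seq_len(m6), , drop = FALSE])
  for (t in which(vol1 < 0)) {
    rows <- seq.int(t, by = m6, length.out = length(keep))
    tmp <- elems[rows, 3L]
    elems[rows, 3L] <- elems[rows, 4L]
    elems[rows, 4L] <- tmp
  }

  mesh <- structure(list(
    nodes = nodes, elems = elems, region = region,
    region_under = region, h = h,
    lattice = list(dims = nd, origin = lo, node_ijk = node_ijk),
    electrode_nodes = list(), electrode_roles = character(),
    fibers = NULL
  ), class = "fem_mesh")
  mesh$volumes <- tet_volumes_cpp(mesh$nodes, mesh$elems)

  if (!is.null(electrodes))
    mesh <- attach_electrodes(mesh, electrodes, snap = snap_electrodes)
  mesh
}

#' Attach an electrode set to a mesh
#'
#' Identifies the lattice nodes of every electrode (interior nodes by
#' point-in-solid capture; near-surface nodes within 0.45 h are snapped
#' onto the analytic surface when `snap = TRUE`), relabels fully captured
#' elements with the electrode name, and validates that each electrode is
#' resolvable at this lattice spacing.
#'
#' @param mesh A `fem_mesh` without electrodes.
#' @param eset An `electrode_set`.
#' @param snap Snap near-surface nodes onto electrode surfaces.
#' @return The mesh with electrode node sets and updated labels/volumes.
#' @export
attach_electrodes <- function(mesh, eset, snap = TRUE) {
  band <- 0.45 * mesh$h
  moved <- logical(nrow(mesh$nodes))
  for (el in eset$electrodes) {
    ## restrict the signed-distance test to nodes near the solid's box
    bb <- solid_bbox(el$solid)
    cand <- which(mesh$nodes[, 1] >= bb[1, 1] - band &
                    mesh$nodes[, 1] <= bb[2, 1] + band &
                    mesh$nodes[, 2] >= bb[1, 2] - band &
                    mesh$nodes[, 2] <= bb[2, 2] + band &
                    mesh$nodes[, 3] >= bb[1, 3] - band &
                    mesh$nodes[, 3] <= bb[2, 3] + band)
    sdf <- solid_sdf(el$solid, mesh$nodes[cand, , drop = FALSE])
    inside <- sdf <= 1e-9
    near <- !inside & sdf <= band
    if (snap) {
      snap_idx <- cand[(near | (inside & sdf >= -band)) & !moved[cand]]
      if (length(snap_idx)) {
        mesh$nodes[snap_idx, ] <- project_to_surface(el$solid,
                                                     mesh$nodes[snap_idx, , drop = FALSE])
        moved[snap_idx] <- TRUE
      }
      set <- cand[inside | near]
    } else {
      set <- cand[inside]
    }
    if (!length(set))
      stop("meshing error: electrode '", el$name,
           "' captures no nodes at h = ", mesh$h)
    for (nm in names(mesh$electrode_nodes)) {
      if (any(set %in% mesh$electrode_nodes[[nm]]))
        stop("electrodes '", el$name, "' and '", nm, "' capture shared nodes")
    }
    mesh$electrode_nodes[[el$name]] <- set
    mesh$electrode_roles[el$name] <- el$role
  }

  if (any(moved)) mesh <- repair_snapped_elements(mesh, moved)
  attr(mesh, "snapped") <- any(moved)

  ## overlay labels: elements entirely inside one electrode's node set
  member <- logical(nrow(mesh$nodes))
  for (nm in names(mesh$electrode_nodes)) {
    member[] <- FALSE
    member[mesh$electrode_nodes[[nm]]] <- TRUE
    cnt <- elem_node_counts_cpp(mesh$elems, member)
    if (!any(cnt == 3L))
      stop("meshing error: electrode '", nm,
           "' exposes no surface facets at h = ", mesh$h)
    mesh$region[cnt == 4L] <- nm
  }
  ## volumes change only for elements with snapped nodes
  if (any(moved)) {
    touch <- which(moved[mesh$elems[, 1]] | moved[mesh$elems[, 2]] |
                     moved[mesh$elems[, 3]] | moved[mesh$elems[, 4]])
    mesh$volumes[touch] <- tet_volumes_cpp(mesh$nodes,
                                           mesh$elems[touch, , drop = FALSE])
  }
  mesh
}

## After snapping, make sure no tetrahedron degenerates: displacements of
## nodes involved in (nearly) inverted elements are halved until all volumes
## are safely positive.
repair_snapped_elements <- function(mesh, moved) {
  ## reconstruct original lattice positions from integer coordinates
  lat <- mesh$lattice
  orig <- cbind(lat$origin[1] + lat$node_ijk[, 1] * mesh$h,
                lat$origin[2] + lat$node_ijk[, 2] * mesh$h,
                lat$origin[3] + lat$node_ijk[, 3] * mesh$h)
  floor_vol <- 0.02 * mesh$h^3 / 6
  touch <- which(moved[mesh$elems[, 1]] | moved[mesh$elems[, 2]] |
                   moved[mesh$elems[, 3]] | moved[mesh$elems[, 4]])
  for (it in 1:10) {
    vols <- tet_volumes_cpp(mesh$nodes, mesh$elems[touch, , drop = FALSE])
    bad <- touch[vols < floor_vol]
    if (!length(bad)) break
    nodes_bad <- unique(as.vector(mesh$elems[bad, ]))
    nodes_bad <- nodes_bad[moved[nodes_bad]]
    mesh$nodes[nodes_bad, ] <- (mesh$nodes[nodes_bad, , drop = FALSE] +
                                  orig[nodes_bad, , drop = FALSE]) / 2
  }
  mesh
}

#' Total mesh volume and per-region volumes
#'
#' @param mesh A `fem_mesh`.
#' @return Named numeric vector of summed element volumes (mm^3) per region.
#' @export
region_volumes <- function(mesh) {
  vapply(split(mesh$volumes, mesh$region), sum, numeric(1))
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("fem_mesh: %d nodes, %d tetrahedra, h = %g mm\n",
              nrow(x$nodes), nrow(x$elems), x$h))
  cat("  regions:", paste(sort(unique(x$region)), collapse = ", "), "\n")
  if (length(x$electrode_nodes))
    cat("  electrodes:", paste(sprintf("%s[%d]", names(x$electrode_nodes),
                                       vapply(x$electrode_nodes, length, 1L)),
                               collapse = ", "), "\n")
  invisible(x)
}
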