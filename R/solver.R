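## Finite-element solution of the shock-field Laplace problem
## div(sigma grad Ve) = 0 with Dirichlet electrodes (shock coil at the
## applied voltage, grounds at 0) and natural no-flux conditions on the
## torso boundary.  P1 elements on the lattice tet mesh; the reduced SPD
## system is solved either directly (CHOLMOD) or by conjugate gradients
## preconditioned with a geometric multigrid V-cycle built on the lattice.

#' Assemble the FEM system for a mesh
#'
#' @param mesh A `fem_mesh` with fibre vectors on myocardial elements.
#' @param sigma A [conductivity_map()].
#' @return An object of class `fem_system`: stiffness matrix `K`
#'   (dgCMatrix, S), per-element `tensors` (S/mm).
#' @export
assemble_system <- function(mesh, sigma = conductivity_map()) {
  tensors <- element_conductivity_tensors(mesh, sigma)
  csc <- assemble_csc_cpp(mesh$nodes, mesh$elems, tensors)
  n <- nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = csc$i, p = csc$p, x = csc$x,
                            dims = c(n, n), index1 = FALSE, check = FALSE)
  structure(list(K = K, dK = NULL, tensors = tensors), class = "fem_system")
}

## Local stiffness update after electrode snapping: re-assemble only the
## elements whose nodes moved, as a sparse correction dK.
delta_stiffness <- function(system, mesh_ref, mesh_new) {
  moved <- which(rowSums(abs(mesh_new$nodes - mesh_ref$nodes)) > 0)
  if (!length(moved)) return(NULL)
  is_moved <- logical(nrow(mesh_new$nodes))
  is_moved[moved] <- TRUE
  el <- mesh_new$elems
  aff <- which(is_moved[el[, 1]] | is_moved[el[, 2]] |
                 is_moved[el[, 3]] | is_moved[el[, 4]])
  if (!length(aff)) return(NULL)
  sub <- el[aff, , drop = FALSE]
  tn <- system$tensors[aff, , drop = FALSE]
  t_new <- assemble_triplets_cpp(mesh_new$nodes, sub, tn)
  t_old <- assemble_triplets_cpp(mesh_ref$nodes, sub, tn)
  Matrix::sparseMatrix(i = t_new$i, j = t_new$j, x = t_new$x - t_old$x,
                       dims = dim(system$K))
}

apply_K <- function(system, v) {
  y <- system$K %*% v
  if (!is.null(system$dK)) y <- y + system$dK %*% v
  as.vector(y)
}

#' Solve the shock-field problem
#'
#' @param mesh A `fem_mesh` with electrodes attached (see
#'   [attach_electrodes()]) and fibres assigned.
#' @param sigma A [conductivity_map()].
#' @param v_applied Applied shock voltage on the shocking coil (V);
#'   grounds are held at 0 V.
#' @param system Optional pre-assembled `fem_system` (with optional sparse
#'   correction `dK` for snapped electrode geometry).
#' @param mg Optional pre-built multigrid hierarchy from [mg_hierarchy()].
#' @param method `"auto"` (direct below 150k nodes or without lattice
#'   metadata, multigrid-PCG otherwise), `"direct"`, or `"mg"`.
#' @param tol Relative residual tolerance of the iterative solve.
#' @param maxit Maximum PCG iterations.
#' @param x0 Optional initial guess for the iterative solve (e.g. the
#'   potential of a related configuration on the same mesh).
#' @return A `field_solution`: `ve` (V per node), `grad` (per-element
#'   gradient of Ve, V/mm), `e_mag` (`||grad Ve||`, V/mm), applied voltage,
#'   Dirichlet mask and solver diagnostics.
#' @export
solve_shock <- function(mesh, sigma = conductivity_map(), v_applied = 10,
                        system = NULL, mg = NULL,
                        method = c("auto", "direct", "mg"),
                        tol = 1e-8, maxit = 500, x0 = NULL) {
  method <- match.arg(method)
  roles <- mesh$electrode_roles
  shock <- names(roles)[roles == "shock"]
  grounds <- names(roles)[roles == "ground"]
  if (!length(shock)) stop("mesh has no shock electrode node set")
  if (!length(grounds)) stop("singular system: no ground electrode")
  shock_nodes <- sort(unique(unlist(mesh$electrode_nodes[shock])))
  ground_nodes <- sort(unique(unlist(mesh$electrode_nodes[grounds])))

  if (is.null(system)) system <- assemble_system(mesh, sigma)
  n <- nrow(mesh$nodes)
  mask <- logical(n)
  mask[shock_nodes] <- TRUE
  mask[ground_nodes] <- TRUE
  ud <- numeric(n)
  ud[shock_nodes] <- v_applied

  b <- -apply_K(system, ud)
  b[mask] <- 0

  if (method == "auto")
    method <- if (is.null(mesh$lattice) || n <= 150000) "direct" else "mg"

  if (method == "direct") {
    free <- which(!mask)
    K <- system$K
    if (!is.null(system$dK)) K <- K + system$dK
    Kff <- Matrix::forceSymmetric(K[free, free])
    uf <- as.vector(Matrix::solve(Kff, b[free]))
    u <- ud
    u[free] <- uf
    iters <- NA_integer_
    relres <- sqrt(sum((apply_K(system, u)[free])^2)) /
      max(sqrt(sum(b[free]^2)), 1e-300)
  } else {
    if (is.null(mesh$lattice))
      stop("multigrid needs lattice metadata; use method = 'direct'")
    if (is.null(mg)) mg <- mg_hierarchy(system$K, mesh)
    pre <- mg_preconditioner(mg, mask)
    opA <- function(v) {
      v[mask] <- 0
      y <- apply_K(system, v)
      y[mask] <- 0
      y
    }
    if (!is.null(x0)) x0[mask] <- 0
    sol <- pcg(opA, b, pre, tol = tol, maxit = maxit, x0 = x0)
    if (sol$relres > tol)
      stop(sprintf("shock solve did not converge: relative residual %.3e after %d iterations",
                   sol$relres, sol$iters))
    u <- ud
    u[!mask] <- sol$x[!mask]
    iters <- sol$iters
    relres <- sol$relres
  }

  grad <- elem_gradients_cpp(mesh$nodes, mesh$elems, u)
  e_mag <- sqrt(grad[, 1]^2 + grad[, 2]^2 + grad[, 3]^2)
  structure(list(ve = u, grad = grad, e_mag = e_mag, v_applied = v_applied,
                 dirichlet = mask, shock_electrodes = shock,
                 ground_electrodes = grounds, iters = iters, relres = relres),
            class = "field_solution")
}

## Preconditioned conjugate gradients for an SPD operator.
pcg <- function(opA, b, opM, tol = 1e-8, maxit = 500, x0 = NULL) {
  if (is.null(x0)) {
    x <- numeric(length(b))
    r <- b
  } else {
    x <- x0
    r <- b - opA(x)
  }
  nb <- sqrt(sum(b * b))
  if (nb == 0) return(list(x = numeric(length(b)), iters = 0L, relres = 0))
  z <- opM(r)
  p <- z
  rz <- sum(r * z)
  relres <- 1
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    Ap <- opA(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r * r)) / nb
    if (relres <= tol) break
    z <- opM(r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x, iters = it, relres = relres)
}

#' Build a geometric multigrid hierarchy on the mesh lattice
#'
#' Coarse levels take every second lattice node per dimension; prolongation
#' is trilinear interpolation restricted to existing nodes (rows
#' renormalized), and coarse operators are Galerkin products `P' K P`.
#'
#' @param K Assembled stiffness matrix (without Dirichlet elimination).
#' @param mesh The lattice `fem_mesh` the matrix was assembled on.
#' @param coarse_n Stop coarsening below this many nodes.
#' @param max_levels Maximum number of levels.
#' @return A hierarchy object for [solve_shock()].
#' @export
mg_hierarchy <- function(K, mesh, coarse_n = 4000, max_levels = 6) {
  stopifnot(!is.null(mesh$lattice))
  levels <- list(list(K = methods::as(K, "generalMatrix"),
                      ijk = mesh$lattice$node_ijk))
  while (nrow(levels[[length(levels)]]$K) > coarse_n &&
         length(levels) < max_levels) {
    cur <- levels[[length(levels)]]
    nxt <- mg_coarsen(cur$K, cur$ijk)
    if (is.null(nxt) || nrow(nxt$K) >= nrow(cur$K)) break
    levels[[length(levels)]]$P <- nxt$P
    levels[[length(levels)]]$coarse_sel <- nxt$coarse_sel
    levels[[length(levels) + 1]] <- list(K = nxt$K, ijk = nxt$ijk)
  }
  ## cache CSC slots for the C++ smoother
  for (l in seq_along(levels)) {
    Kl <- levels[[l]]$K
    levels[[l]]$slots <- list(p = Kl@p, i = Kl@i, x = Kl@x)
  }
  structure(list(levels = levels), class = "mg_hierarchy")
}

mg_coarsen <- function(K, ijk) {
  even <- ijk %% 2L == 0L
  coarse_sel <- which(even[, 1] & even[, 2] & even[, 3])
  if (length(coarse_sel) < 8) return(NULL)
  cijk <- ijk[coarse_sel, , drop = FALSE] %/% 2L
  cdims <- apply(cijk, 2, max) + 2L
  cgrid <- integer(prod(cdims))
  clin <- 1L + cijk[, 1] + cdims[1] * (cijk[, 2] + cdims[2] * cijk[, 3])
  cgrid[clin] <- seq_along(coarse_sel)

  n <- nrow(ijk)
  base <- ijk %/% 2L
  odd <- ijk %% 2L
  ti <- integer(0); tj <- integer(0); tw <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (ifelse(odd[, 1] == 1L, 0.5, 1 - dx)) *
      (ifelse(odd[, 2] == 1L, 0.5, 1 - dy)) *
      (ifelse(odd[, 3] == 1L, 0.5, 1 - dz))
    sel <- which(w > 0)
    if (!length(sel)) next
    ci <- base[sel, 1] + dx * odd[sel, 1]
    cj <- base[sel, 2] + dy * odd[sel, 2]
    ck <- base[sel, 3] + dz * odd[sel, 3]
    ok <- ci < cdims[1] & cj < cdims[2] & ck < cdims[3]
    lin <- 1L + ci + cdims[1] * (cj + cdims[2] * ck)
    cr <- integer(length(sel))
    cr[ok] <- cgrid[lin[ok]]
    keep <- which(cr > 0)
    if (!length(keep)) next
    ti <- c(ti, sel[keep]); tj <- c(tj, cr[keep]); tw <- c(tw, w[sel][keep])
  }
  P <- Matrix::sparseMatrix(i = ti, j = tj, x = tw,
                            dims = c(n, length(coarse_sel)))
  rs <- Matrix::rowSums(P)
  nz <- rs > 0
  Dinv <- Matrix::Diagonal(n, x = ifelse(nz, 1 / pmax(rs, 1e-300), 0))
  P <- Dinv %*% P
  Kc <- methods::as(Matrix::crossprod(P, K %*% P), "generalMatrix")
  list(K = Kc, P = P, ijk = cijk, coarse_sel = coarse_sel)
}

## Per-configuration preconditioner: Dirichlet masks restricted through the
## levels (a coarse node is masked when any fine node in its neighbourhood
## is masked, so thin coils stay represented on coarse grids), one
## symmetric V(1,1) cycle with Gauss-Seidel smoothing, and a direct solve
## of the masked coarsest system.
mg_preconditioner <- function(mg, mask) {
  levels <- mg$levels
  nl <- length(levels)
  masks <- vector("list", nl)
  masks[[1]] <- mask
  for (l in seq_len(nl - 1)) {
    P <- levels[[l]]$P
    spread <- as.vector(Matrix::crossprod(P, as.numeric(masks[[l]])))
    masks[[l + 1]] <- spread > 1e-12
  }
  cl <- levels[[nl]]
  cfree <- which(!masks[[nl]])
  Kc <- cl$K[cfree, cfree, drop = FALSE]
  if (length(cfree) == nrow(cl$K)) {
    ## unconstrained coarsest level (pure Neumann): regularize the constant
    Kc <- Kc + Matrix::Diagonal(nrow(Kc), 1e-8 * mean(Matrix::diag(cl$K)))
  }
  cfac <- Matrix::Cholesky(Matrix::forceSymmetric(Kc), LDL = FALSE, perm = TRUE)

  vcycle <- function(l, r) {
    lev <- levels[[l]]
    msk <- masks[[l]]
    if (l == nl) {
      z <- numeric(length(r))
      if (length(cfree))
        z[cfree] <- as.vector(Matrix::solve(cfac, r[cfree]))
      return(z)
    }
    x <- numeric(length(r))
    gs_sweep_cpp(lev$slots$p, lev$slots$i, lev$slots$x, r, x, msk, TRUE)
    rr <- r - masked_matvec_cpp(lev$slots$p, lev$slots$i, lev$slots$x, x, msk)
    rc <- as.vector(Matrix::crossprod(lev$P, rr))
    rc[masks[[l + 1]]] <- 0
    zc <- vcycle(l + 1, rc)
    zc[masks[[l + 1]]] <- 0
    x <- x + as.vector(lev$P %*% zc)
    x[msk] <- 0
    gs_sweep_cpp(lev$slots$p, lev$slots$i, lev$slots$x, r, x, msk, FALSE)
    x[msk] <- 0
    x
  }
  function(r) vcycle(1, r)
}

#' Electrode boundary currents
#'
#' Integrates the current over the discrete electrode surfaces: for every
#' surface triangle (a tet face whose three nodes belong to the electrode
#' and whose opposite node is free), current = area x conductivity of the
#' adjacent tissue x (mean E-field vector of the three nodes) . outward
#' normal.  Nodal E-fields are volume-weighted averages of adjacent element
#' gradients, excluding electrode-interior elements (no field inside the
#' metal).  Positive sign = current flowing out of the electrode.
#'
#' @param solution A `field_solution`.
#' @param mesh The mesh the solution was computed on.
#' @param sigma A [conductivity_map()].
#' @param method `"reaction"` (default: discrete nodal reactions
#'   `sum_i (K u)_i`, the standard conservative FEM flux extraction; exact
#'   for affine fields and conservative to solver tolerance) or
#'   `"surface"` (the surface-triangle rule above, which is first-order
#'   and biased on strongly curved electrodes at coarse h).
#' @param system Optional pre-assembled `fem_system` (required for
#'   `"reaction"` unless re-assembly is acceptable).
#' @return Named numeric vector: current in A per electrode.
#' @export
electrode_currents <- function(solution, mesh, sigma = conductivity_map(),
                               method = c("reaction", "surface"),
                               system = NULL) {
  method <- match.arg(method)
  enames <- names(mesh$electrode_nodes)
  if (!length(enames)) stop("mesh has no electrodes")
  if (method == "reaction") {
    if (is.null(system)) system <- assemble_system(mesh, sigma)
    r <- apply_K(system, solution$ve)
    out <- vapply(enames, function(nm) sum(r[mesh$electrode_nodes[[nm]]]),
                  numeric(1))
    return(out)
  }

  grad <- solution$grad
  vols <- mesh$volumes
  currents <- stats::setNames(numeric(length(enames)), enames)
  for (nm in enames) {
    member <- logical(nrow(mesh$nodes))
    member[mesh$electrode_nodes[[nm]]] <- TRUE
    mm <- cbind(member[mesh$elems[, 1]], member[mesh$elems[, 2]],
                member[mesh$elems[, 3]], member[mesh$elems[, 4]])
    cnt <- rowSums(mm)
    sel <- which(cnt == 3L)
    if (!length(sel))
      stop("electrode '", nm, "' has no surface triangles")
    ## nodal E at the electrode's surface nodes (exclude interior elements)
    need <- which(member)
    node_map <- integer(nrow(mesh$nodes))
    node_map[need] <- seq_along(need)
    esel <- cnt < 4L
    acc <- accumulate_nodal_gradients_cpp(mesh$elems, grad, vols, esel,
                                          node_map, length(need))
    w <- pmax(acc[, 4], 1e-300)
    nodal_e <- -acc[, 1:3, drop = FALSE] / w   # E = -grad Ve

    total <- 0
    el <- mesh$elems[sel, , drop = FALSE]
    mmsel <- mm[sel, , drop = FALSE]
    sig <- region_iso_sigma(sigma, mesh$region_under[sel]) * 1e-3 # S/mm
    for (r in seq_along(sel)) {
      face <- el[r, mmsel[r, ]]
      opp <- el[r, !mmsel[r, ]]
      p1 <- mesh$nodes[face[1], ]; p2 <- mesh$nodes[face[2], ]
      p3 <- mesh$nodes[face[3], ]
      nvec <- cross3(p2 - p1, p3 - p1) / 2  # area-weighted normal
      fc <- (p1 + p2 + p3) / 3
      if (sum(nvec * (mesh$nodes[opp, ] - fc)) < 0) nvec <- -nvec
      Ebar <- colMeans(nodal_e[node_map[face], , drop = FALSE])
      total <- total + sig[r] * sum(Ebar * nvec)
    }
    currents[nm] <- total
  }
  currents
}

#' Export a field solution to VTK for inspection
#'
#' @param solution A `field_solution`.
#' @param mesh The mesh it was computed on.
#' @param path Output `.vtk` path.
#' @export
export_field_vtk <- function(solution, mesh, path) {
  write_vtk(mesh, path, point_data = list(Ve = solution$ve),
            cell_data = list(E = solution$e_mag))
}
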