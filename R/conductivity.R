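## Region conductivities and per-element conductivity tensors.
##
## All user-facing values are in S/m; tensors handed to the assembler are
## converted to S/mm (x 1e-3) so that, with node coordinates in mm and
## potentials in V, assembled conductances come out in S and electrode
## currents in A.

#' Conductivity map for the torso model
#'
#' Isotropic conductivities for every torso region, plus the myocardial
#' intra-/extra-cellular eigen-conductivities used to build the anisotropic
#' ventricular tensor.  The default static-shock myocardial tensor is the
#' bulk (monodomain-equivalent) combination sigma_long = sigma_il +
#' sigma_el, sigma_trans = sigma_it + sigma_et; set
#' `myocardium_mode = "extracellular"` to use the extracellular pair only.
#' Aortic/SVC wall conductivity defaults to the atrial-wall value and scar
#' to a low bone-like value; both are modelling assumptions (see vignette).
#'
#' @param ... Named overrides for any isotropic region value (S/m), e.g.
#'   `bath = 0.2`.
#' @param sigma_il,sigma_el,sigma_it,sigma_et Myocardial intracellular /
#'   extracellular conductivities along (`l`) and transverse (`t`) to the
#'   fibre direction, in S/m.
#' @param scar Scar conductivity (S/m, isotropic).
#' @param myocardium_mode `"bulk"` or `"extracellular"`.
#' @return An object of class `conductivity_map`.
#' @export
conductivity_map <- function(...,
                             sigma_il = 0.174, sigma_el = 0.625,
                             sigma_it = 0.019, sigma_et = 0.236,
                             scar = 0.05,
                             myocardium_mode = c("bulk", "extracellular")) {
  myocardium_mode <- match.arg(myocardium_mode)
  iso <- c(bath = 0.24725, skin = 0.117, bones = 0.05,
           kidneys = 0.1667, liver = 0.1667, stomach = 0.1, spleen = 0.1,
           lungs = 0.0714, la_wall = 0.25, ra_wall = 0.25,
           aorta_wall = 0.25, svc_wall = 0.25,
           blood = 0.6667, valves = 0.6667, scar = scar)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(iso)) stop("unknown region: ", nm)
    iso[nm] <- dots[[nm]]
  }
  sm <- structure(list(iso = iso,
                       sigma_il = sigma_il, sigma_el = sigma_el,
                       sigma_it = sigma_it, sigma_et = sigma_et,
                       myocardium_mode = myocardium_mode),
                  class = "conductivity_map")
  sm
}

## Effective myocardial eigen-conductivities (S/m) for the static solve.
myocardial_eigenvalues <- function(sigma) {
  if (sigma$myocardium_mode == "bulk") {
    c(long = sigma$sigma_il + sigma$sigma_el,
      trans = sigma$sigma_it + sigma$sigma_et)
  } else {
    c(long = sigma$sigma_el, trans = sigma$sigma_et)
  }
}

#' Anisotropic myocardial conductivity tensor
#'
#' Builds the rank-1-anisotropic tensor `sigma_trans I + (sigma_long -
#' sigma_trans) f f'` for a unit fibre direction `f`.
#'
#' @param fibre Unit fibre vector (length 3).
#' @param sigma A [conductivity_map()].
#' @return 3 x 3 symmetric positive definite tensor in S/m.
#' @export
myocardial_tensor <- function(fibre, sigma = conductivity_map()) {
  nrm <- sqrt(sum(fibre^2))
  if (nrm < 1e-12) stop("fibre vector must be non-zero")
  f <- fibre / nrm
  ev <- myocardial_eigenvalues(sigma)
  ev["trans"] * diag(3) + (ev["long"] - ev["trans"]) * tcrossprod(f)
}

## Per-element symmetric tensors (m x 6: xx, yy, zz, xy, xz, yz) in S/mm.
## Electrode-labelled elements use the conductivity of the region they are
## embedded in (`region_under`).
element_conductivity_tensors <- function(mesh, sigma) {
  m <- nrow(mesh$elems)
  reg <- mesh$region_under
  tensors <- matrix(0, m, 6)
  iso_val <- sigma$iso[reg]
  myo <- reg %in% c("lv_wall", "rv_wall")
  iso_idx <- which(!myo)
  s_mm <- iso_val[iso_idx] * 1e-3
  if (anyNA(s_mm))
    stop("no conductivity for region(s): ",
         paste(unique(reg[iso_idx][is.na(s_mm)]), collapse = ", "))
  tensors[iso_idx, 1] <- s_mm
  tensors[iso_idx, 2] <- s_mm
  tensors[iso_idx, 3] <- s_mm
  if (any(myo)) {
    ev <- myocardial_eigenvalues(sigma) * 1e-3
    f <- mesh$fibers
    if (is.null(f) || anyNA(f[myo, ])) {
      warning("myocardial elements without fibre vectors; using isotropic ",
              "mean conductivity for them")
      if (is.null(f)) f <- matrix(NA_real_, m, 3)
      miss <- myo & (is.na(f[, 1]) | is.na(f[, 2]) | is.na(f[, 3]))
      s_iso <- (ev["long"] + 2 * ev["trans"]) / 3
      tensors[miss, 1:3] <- s_iso
      myo <- myo & !miss
    }
    idx <- which(myo)
    fx <- f[idx, 1]; fy <- f[idx, 2]; fz <- f[idx, 3]
    dl <- ev["long"] - ev["trans"]
    tensors[idx, 1] <- ev["trans"] + dl * fx * fx
    tensors[idx, 2] <- ev["trans"] + dl * fy * fy
    tensors[idx, 3] <- ev["trans"] + dl * fz * fz
    tensors[idx, 4] <- dl * fx * fy
    tensors[idx, 5] <- dl * fx * fz
    tensors[idx, 6] <- dl * fy * fz
  }
  tensors
}

## Isotropic equivalent (S/m) used for the electrode-surface current rule
## (the host is always bath or a blood pool in practice).
region_iso_sigma <- function(sigma, regions) {
  v <- sigma$iso[regions]
  if (anyNA(v)) {
    ev <- myocardial_eigenvalues(sigma)
    v[is.na(v)] <- (ev["long"] + 2 * ev["trans"]) / 3
  }
  unname(v)
}
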