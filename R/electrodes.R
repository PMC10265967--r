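## ICD electrode catalogue and placement.
##
## Electrode dimensions follow the clinical hardware modelled in the study:
## RV and SVC shock/ground coils 2 mm diameter x 8 cm, CS coil 2 mm x 4 cm,
## pectoral can 6 cm diameter x 1.3 cm.  The RV coil is the single shocking
## electrode; the can and any SVC/CS coils are grounds held at 0 V.
## Electrodes absent from a configuration are absent from the model
## entirely (their volume keeps the conductivity of the surrounding
## region), which is the field-model equivalent of "electrically removed".

COIL_RADIUS <- 1      # mm (2 mm diameter)
RV_COIL_LENGTH <- 80  # mm
SVC_COIL_LENGTH <- 80 # mm
CS_COIL_LENGTH <- 40  # mm
CAN_RADIUS <- 30      # mm (6 cm diameter)
CAN_THICKNESS <- 13   # mm

#' ICD configuration descriptor
#'
#' @param can_side `"left"` (conventional pectoral pocket) or `"right"`.
#' @param rv_position `"apical"` (coil tip at the RV apex) or `"septal"`
#'   (coil centred at 50% of the apex-to-base distance along the septum).
#' @param extra_coils Character subset of `c("SVC", "CS")`: additional
#'   ground coils in the superior vena cava / coronary sinus.
#' @return An object of class `icd_configuration`.
#' @export
icd_configuration <- function(can_side = c("left", "right"),
                              rv_position = c("apical", "septal"),
                              extra_coils = character()) {
  can_side <- match.arg(can_side)
  rv_position <- match.arg(rv_position)
  stopifnot(all(extra_coils %in% c("SVC", "CS")))
  structure(list(can_side = can_side, rv_position = rv_position,
                 extra_coils = sort(extra_coils)),
            class = "icd_configuration")
}

#' Stable name of a configuration
#'
#' @param cfg An `icd_configuration`.
#' @return A string such as `"right_apical_svc_cs"`.
#' @export
configuration_name <- function(cfg) {
  nm <- paste(cfg$can_side, cfg$rv_position, sep = "_")
  if (length(cfg$extra_coils))
    nm <- paste(nm, paste(tolower(sort(cfg$extra_coils)), collapse = "_"),
                sep = "_")
  nm
}

#' The ten ICD configurations analysed in the study design
#'
#' Left- and right-sided can with apical or septal RV coil, plus the
#' right-sided-can configurations augmented with SVC, CS, and SVC+CS
#' ground coils.
#'
#' @return A named list of `icd_configuration` objects (length 10).
#' @export
enumerate_study_configurations <- function() {
  cfgs <- list(
    icd_configuration("left", "apical"),
    icd_configuration("right", "apical"),
    icd_configuration("right", "apical", "SVC"),
    icd_configuration("right", "apical", "CS"),
    icd_configuration("right", "apical", c("SVC", "CS")),
    icd_configuration("left", "septal"),
    icd_configuration("right", "septal"),
    icd_configuration("right", "septal", "SVC"),
    icd_configuration("right", "septal", "CS"),
    icd_configuration("right", "septal", c("SVC", "CS"))
  )
  stats::setNames(cfgs, vapply(cfgs, configuration_name, character(1)))
}

## Resample a polyline to the sub-curve between arc lengths s0 and s1.
polyline_section <- function(pts, s0, s1, n_out = 16) {
  seg <- diff(pts[, 1])^2 + diff(pts[, 2])^2 + diff(pts[, 3])^2
  s <- c(0, cumsum(sqrt(seg)))
  total <- s[length(s)]
  s0 <- max(0, min(s0, total))
  s1 <- max(s0, min(s1, total))
  ss <- seq(s0, s1, length.out = n_out)
  t(vapply(ss, function(si) {
    k <- max(1L, findInterval(si, s, rightmost.closed = TRUE))
    k <- min(k, nrow(pts) - 1L)
    w <- if (s[k + 1] > s[k]) (si - s[k]) / (s[k + 1] - s[k]) else 0
    pts[k, ] * (1 - w) + pts[k + 1, ] * w
  }, numeric(3)))
}

polyline_length <- function(pts) {
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2 + diff(pts[, 3])^2))
}

#' Build the electrode set for one configuration in one phantom
#'
#' Places the RV shocking coil inside the RV blood pool (tip at the apex
#' for `apical`, centred mid-septum for `septal`), the pectoral can
#' subcutaneously in the upper chest on the requested side, and any SVC/CS
#' ground coils inside the SVC lumen / along the coronary sinus course.
#' Placement is validated against the phantom labels: coils must lie in
#' blood-pool/valve labels and the can in the subcutaneous bath.
#'
#' @param cfg An [icd_configuration()].
#' @param phantom A `torso_phantom`.
#' @return An object of class `electrode_set`: list of electrodes with
#'   `name`, `role` (`"shock"`/`"ground"`) and `solid`.
#' @export
build_configuration <- function(cfg, phantom) {
  stopifnot(inherits(cfg, "icd_configuration"),
            inherits(phantom, "torso_phantom"))
  lm <- phantom$landmarks
  els <- list()

  ## RV shocking coil
  path <- if (cfg$rv_position == "apical") lm$rv_apical_path else lm$rv_septal_path
  if (cfg$rv_position == "apical") {
    coil_pts <- polyline_section(path, 0, RV_COIL_LENGTH, n_out = 64)
  } else {
    ## septal: lead pulled back so the coil tip sits at 50% of the
    ## apex-to-base arc (the coil body runs on towards the RA/SVC)
    n_vent <- nrow(path) - 2L        # last two points run on towards the SVC
    s_base <- polyline_length(path[seq_len(n_vent), , drop = FALSE])
    coil_pts <- polyline_section(path, s_base / 2,
                                 s_base / 2 + RV_COIL_LENGTH, n_out = 64)
  }
  els$rv_coil <- list(name = "rv_coil", role = "shock",
                      solid = solid_capsule("rv_coil", coil_pts, COIL_RADIUS))

  ## pectoral can
  site <- if (cfg$can_side == "left") lm$can_left else lm$can_right
  can_name <- paste0("can_", cfg$can_side)
  els[[can_name]] <- list(
    name = can_name, role = "ground",
    solid = solid_cylinder(can_name,
                           site$center - CAN_THICKNESS / 2 * site$normal,
                           site$center + CAN_THICKNESS / 2 * site$normal,
                           CAN_RADIUS))

  if ("SVC" %in% cfg$extra_coils) {
    ax <- lm$svc_axis
    svc_pts <- polyline_section(ax, 2, 2 + SVC_COIL_LENGTH, n_out = 64)
    els$svc_coil <- list(name = "svc_coil", role = "ground",
                         solid = solid_capsule("svc_coil", svc_pts, COIL_RADIUS))
  }
  if ("CS" %in% cfg$extra_coils) {
    s_tot <- polyline_length(lm$cs_course)
    cs_pts <- polyline_section(lm$cs_course, s_tot / 2 - CS_COIL_LENGTH / 2,
                               s_tot / 2 + CS_COIL_LENGTH / 2, n_out = 64)
    els$cs_coil <- list(name = "cs_coil", role = "ground",
                        solid = solid_capsule("cs_coil", cs_pts, COIL_RADIUS))
  }

  eset <- structure(list(electrodes = els, configuration = cfg,
                         name = configuration_name(cfg)),
                    class = "electrode_set")
  validate_electrode_placement(eset, phantom)
  eset
}

## Electrodes must sit in their host regions: coils in blood-pool/valve
## labels, the can in the subcutaneous bath.  Myocardial wall labels are
## never acceptable hosts.
validate_electrode_placement <- function(eset, phantom) {
  hosts <- list(shock = c("blood", "valves"),
                ground = c("blood", "valves", "bath"))
  for (el in eset$electrodes) {
    probe <- electrode_probe_points(el$solid)
    lab <- label_at_points(phantom, probe)
    allowed <- if (grepl("^can", el$name)) "bath" else c("blood", "valves")
    frac_ok <- mean(lab %in% allowed)
    if (any(lab %in% c("lv_wall", "rv_wall", "scar")))
      stop("placement error: electrode '", el$name,
           "' intersects myocardial wall labels")
    if (frac_ok < 0.9)
      stop("placement error: electrode '", el$name,
           "' is not contained in its host region (",
           round(100 * frac_ok), "% contained; labels seen: ",
           paste(unique(lab), collapse = ", "), ")")
  }
  invisible(eset)
}

## Representative interior points of an electrode solid (axis samples for
## coils, axis + rim samples for the can).
electrode_probe_points <- function(solid) {
  if (solid$type == "capsule") {
    polyline_section(solid$pts, 0, polyline_length(solid$pts), n_out = 24)
  } else if (solid$type == "cylinder") {
    ax <- solid$p1 - solid$p0
    mid <- (solid$p0 + solid$p1) / 2
    axu <- ax / sqrt(sum(ax^2))
    ref <- if (abs(axu[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- unitv(cross3(axu, ref))
    t2 <- cross3(axu, t1)
    r <- 0.8 * solid$radius
    th <- seq(0, 2 * pi, length.out = 9)[-9]
    rim <- t(vapply(th, function(a) mid + r * (cos(a) * t1 + sin(a) * t2),
                    numeric(3)))
    rbind(mid, solid$p0 + 0.1 * ax, solid$p0 + 0.9 * ax, rim)
  } else {
    rbind((if (!is.null(solid$center)) solid$center else (solid$p0 + solid$p1) / 2))
  }
}

#' Assemble an electrode set from raw solids
#'
#' Lower-level constructor used for verification problems (plate and
#' spherical electrodes) and custom lead geometries.
#'
#' @param ... Electrodes given as `name = list(role, solid)` or created
#'   inline via `electrode(name, role, solid)`.
#' @param name Set name.
#' @return An `electrode_set`.
#' @export
electrode_set <- function(..., name = "custom") {
  els <- list(...)
  stopifnot(length(els) > 0)
  for (k in seq_along(els)) {
    el <- els[[k]]
    stopifnot(is.list(el), !is.null(el$role), !is.null(el$solid))
    if (is.null(el$name)) els[[k]]$name <- names(els)[k]
  }
  names(els) <- vapply(els, `[[`, character(1), "name")
  structure(list(electrodes = els, configuration = NULL, name = name),
            class = "electrode_set")
}

#' Define a single electrode
#'
#' @param name Electrode name.
#' @param role `"shock"` or `"ground"`.
#' @param solid An electrode-grade solid (sphere, shell, cylinder, box,
#'   capsule).
#' @return A list usable in [electrode_set()].
#' @export
electrode <- function(name, role = c("shock", "ground"), solid) {
  role <- match.arg(role)
  list(name = name, role = role, solid = solid)
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("electrode_set '%s': %d electrodes (%d ground)\n", x$name,
              length(x$electrodes),
              sum(vapply(x$electrodes, function(e) e$role == "ground", TRUE))))
  invisible(x)
}
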