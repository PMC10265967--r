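## Mesh I/O: openCARP text format (.pts/.elem/.lon) and legacy ASCII VTK
## unstructured grids.  openCARP files are written with 0-based node indices
## and integer region codes, as that format requires; coordinates use full
## double precision so that write/read round-trips are bit-exact.

#' Write a mesh
#'
#' @param mesh A `fem_mesh`.
#' @param path For openCARP, the base path (the `.pts`, `.elem` and
#'   optionally `.lon` files are written next to it); for VTK, the `.vtk`
#'   file path.
#' @param format `"openCARP"` or `"VTK"`.
#' @param label_map Named integer vector mapping region labels to file
#'   codes.  Defaults to alphabetical labels numbered from 0; the map used
#'   is written to `<path>.labels.json` for openCARP output.
#' @return The base path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("openCARP", "VTK"),
                       label_map = NULL) {
  format <- match.arg(format)
  if (is.null(label_map)) {
    labs <- sort(unique(mesh$region))
    label_map <- stats::setNames(seq_along(labs) - 1L, labs)
  }
  codes <- unname(label_map[mesh$region])
  if (anyNA(codes)) stop("label_map does not cover all region labels")
  if (format == "openCARP") {
    pts_lines <- c(sprintf("%d", nrow(mesh$nodes)),
                   sprintf("%.17g %.17g %.17g",
                           mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
    writeLines(pts_lines, paste0(path, ".pts"))
    el <- mesh$elems - 1L
    elem_lines <- c(sprintf("%d", nrow(el)),
                    sprintf("Tt %d %d %d %d %d",
                            el[, 1], el[, 2], el[, 3], el[, 4], codes))
    writeLines(elem_lines, paste0(path, ".elem"))
    if (!is.null(mesh$fibers)) {
      f <- mesh$fibers
      f[is.na(f)] <- 0
      writeLines(c("1", sprintf("%.17g %.17g %.17g", f[, 1], f[, 2], f[, 3])),
                 paste0(path, ".lon"))
    }
    jsonlite::write_json(as.list(label_map), paste0(path, ".labels.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    write_vtk(mesh, path, cell_data = list(region = codes))
  }
  invisible(path)
}

#' Read a mesh
#'
#' @param path Base path (openCARP) or `.vtk` file.
#' @param format `"openCARP"` or `"VTK"`.
#' @param label_map Named integer vector mapping region labels to file
#'   codes.  For openCARP input, defaults to the `<path>.labels.json`
#'   sidecar when present; with no map available the numeric codes are kept
#'   as character labels.
#' @return A `fem_mesh` (without lattice metadata or electrode sets).
#' @export
read_mesh <- function(path, format = c("openCARP", "VTK"), label_map = NULL) {
  format <- match.arg(format)
  if (format == "openCARP") {
    pts_file <- paste0(path, ".pts")
    lines <- readLines(pts_file)
    n <- as.integer(lines[1])
    if (is.na(n)) stop("malformed .pts header at line 1 of ", pts_file)
    if (length(lines) - 1L != n)
      stop(".pts header declares ", n, " points but file has ",
           length(lines) - 1L, " coordinate lines (line ", length(lines), ")")
    nodes <- matrix(scan(text = lines[-1], quiet = TRUE), ncol = 3, byrow = TRUE)

    elem_file <- paste0(path, ".elem")
    elines <- readLines(elem_file)
    m <- as.integer(elines[1])
    if (is.na(m)) stop("malformed .elem header at line 1 of ", elem_file)
    if (length(elines) - 1L != m)
      stop(".elem header declares ", m, " elements but file has ",
           length(elines) - 1L, " element lines (line ", length(elines), ")")
    toks <- strsplit(elines[-1], "[[:space:]]+")
    tags <- vapply(toks, `[[`, character(1), 1L)
    bad <- which(tags != "Tt")
    if (length(bad))
      stop("unsupported element tag '", tags[bad[1]], "' at line ",
           bad[1] + 1L, " of ", elem_file, " (only Tt tetrahedra are supported)")
    nums <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:6))), ncol = 5,
                   byrow = TRUE)
    elems <- matrix(as.integer(nums[, 1:4]) + 1L, ncol = 4)
    codes <- as.integer(nums[, 5])

    if (is.null(label_map) && file.exists(paste0(path, ".labels.json"))) {
      lm <- jsonlite::read_json(paste0(path, ".labels.json"))
      label_map <- stats::setNames(as.integer(unlist(lm)), names(lm))
    }
    region <- if (!is.null(label_map))
      names(label_map)[match(codes, label_map)] else as.character(codes)

    fibers <- NULL
    lon_file <- paste0(path, ".lon")
    if (file.exists(lon_file)) {
      llines <- readLines(lon_file)
      ndir <- as.integer(strsplit(trimws(llines[1]), "[[:space:]]+")[[1]][1])
      vals <- matrix(scan(text = llines[-1], quiet = TRUE),
                     ncol = 3 * ndir, byrow = TRUE)
      fibers <- vals[, 1:3, drop = FALSE]
    }
    mesh <- structure(list(
      nodes = nodes, elems = elems, region = region, region_under = region,
      h = NA_real_, lattice = NULL, electrode_nodes = list(),
      electrode_roles = character(), fibers = fibers
    ), class = "fem_mesh")
    mesh$volumes <- tet_volumes_cpp(nodes, elems)
    mesh
  } else {
    read_vtk(path, label_map = label_map)
  }
}

#' Write a legacy ASCII VTK unstructured grid
#'
#' @param mesh A `fem_mesh`.
#' @param path Output `.vtk` path.
#' @param point_data Named list of per-node numeric vectors (e.g. `Ve`).
#' @param cell_data Named list of per-element numeric vectors (e.g. `E`).
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "torsodft mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  el <- mesh$elems - 1L
  writeLines(sprintf("4 %d %d %d %d", el[, 1], el[, 2], el[, 3], el[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                   con)
        writeLines(sprintf("%.17g", as.numeric(v)), con)
      }
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%.17g", as.numeric(point_data[[nm]])), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid of tetrahedra
#'
#' @param path Input `.vtk` path.
#' @param label_map Optional named integer vector decoding the `region`
#'   cell scalar into labels.
#' @return A `fem_mesh`.
#' @export
read_vtk <- function(path, label_map = NULL) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "[[:space:]]+")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + ceiling(n))], quiet = TRUE,
                       n = 3 * n), ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "[[:space:]]+")[[1]][2])
  cvals <- matrix(scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE, n = 5 * m),
                  ncol = 5, byrow = TRUE)
  if (any(cvals[, 1] != 4)) stop("only tetrahedral cells are supported")
  elems <- matrix(as.integer(cvals[, 2:5]) + 1L, ncol = 4)
  region <- rep(NA_character_, m)
  ir <- grep("^SCALARS region", lines)
  if (length(ir)) {
    codes <- as.integer(scan(text = lines[(ir[1] + 2):(ir[1] + 1 + m)],
                             quiet = TRUE, n = m))
    region <- if (!is.null(label_map))
      names(label_map)[match(codes, label_map)] else as.character(codes)
  }
  mesh <- structure(list(
    nodes = nodes, elems = elems, region = region, region_under = region,
    h = NA_real_, lattice = NULL, electrode_nodes = list(),
    electrode_roles = character(), fibers = NULL
  ), class = "fem_mesh")
  mesh$volumes <- tet_volumes_cpp(nodes, elems)
  mesh
}
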