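#' Write a mesh with fields as a legacy VTK unstructured grid
#'
#' ASCII VTK legacy format, readable by ParaView/VTK and `meshio`.  Point
#' data arrays must have one value (scalar) or three columns (vector) per
#' node; cell data one value per element.  Per-integration-point fields can
#' be reduced to cell data with [gp_to_cell()].
#'
#' @param mesh an [build_explant_mesh()] mesh
#' @param file output path (conventionally `.vtk`)
#' @param point_data named list of per-node scalars/vectors
#' @param cell_data named list of per-element scalars
#' @return `file`, invisibly
#' @export
write_vtk <- function(mesh, file, point_data = list(),
                      cell_data = list()) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# vtk DataFile Version 3.0", "cartdegen explant cross-section",
    "ASCII", "DATASET UNSTRUCTURED_GRID")
  w(sprintf("POINTS %d double", n))
  w(paste(format(mesh$nodes[, 1], digits = 10),
          format(mesh$nodes[, 2], digits = 10), "0"))
  w(sprintf("CELLS %d %d", ne, 5 * ne))
  e0 <- mesh$elems - 1L
  w(paste(4L, e0[, 1], e0[, 2], e0[, 3], e0[, 4]))
  w(sprintf("CELL_TYPES %d", ne))
  w(as.character(rep(9L, ne)))
  if (length(point_data)) {
    w(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) >= 2) {
        if (ncol(v) == 2) v <- cbind(v, 0)
        w(sprintf("VECTORS %s double", nm))
        w(paste(format(v[, 1], digits = 10), format(v[, 2], digits = 10),
                format(v[, 3], digits = 10)))
      } else {
        w(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        w(format(as.numeric(v), digits = 10))
      }
    }
  }
  if (length(cell_data)) {
    w(sprintf("CELL_DATA %d", ne))
    for (nm in names(cell_data)) {
      w(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      w(format(as.numeric(cell_data[[nm]]), digits = 10))
    }
  }
  invisible(file)
}

#' Import a user mesh from a legacy VTK file
#'
#' Reads a quadrilateral unstructured grid (e.g. produced elsewhere or by
#' [write_vtk()]) and turns it into a tagged explant mesh: exterior edges
#' are classified by position (bottom, symmetry axis, lateral surface,
#' top) and every remaining exterior edge — crack faces — is tagged
#' `lesion_surface`.
#'
#' @param file path to a legacy VTK unstructured grid
#' @param radius,thickness nominal explant dimensions used for boundary
#'   classification, mm (defaults: bounding box of the nodes)
#' @param formulation `"axisymmetric"` or `"plane_strain"`
#' @param target_h nominal element size recorded on the mesh (default:
#'   median edge length)
#' @return an `explant_mesh`
#' @export
read_explant_mesh <- function(file, radius = NULL, thickness = NULL,
                              formulation = c("axisymmetric",
                                              "plane_strain"),
                              target_h = NULL) {
  formulation <- match.arg(formulation)
  raw <- read_vtk(file)
  nodes <- raw$nodes
  elems <- raw$elems
  if (is.null(radius)) radius <- max(nodes[, 1])
  if (is.null(thickness)) thickness <- max(nodes[, 2])
  a <- .elem_areas(nodes, elems)
  if (any(a == 0)) stop("degenerate elements in imported mesh")
  # normalize orientation to counter-clockwise
  flip <- a < 0
  elems[flip, ] <- elems[flip, c(4, 3, 2, 1)]
  edges <- .tag_boundary(nodes, elems, radius, thickness, tol = 1e-6)
  if (is.null(target_h)) {
    e1 <- rbind(elems[, c(1, 2)], elems[, c(2, 3)])
    target_h <- median(sqrt(rowSums(
      (nodes[e1[, 1], , drop = FALSE] -
         nodes[e1[, 2], , drop = FALSE])^2)))
  }
  m <- list(nodes = nodes, elems = elems, edges = edges, radius = radius,
            thickness = thickness, target_h = target_h,
            formulation = formulation, cracks = list())
  class(m) <- "explant_mesh"
  m
}

#' Reduce an integration-point field to per-element (cell) values
#' @param x per-integration-point vector (4 Gauss points per element,
#'   element-major)
#' @param fun reduction over the 4 points of each element
#' @return per-element vector
#' @export
gp_to_cell <- function(x, fun = mean) {
  apply(matrix(x, nrow = 4), 2, fun)
}

#' Read a legacy VTK unstructured grid written by [write_vtk()]
#'
#' Minimal reader for round-trip checks: points, quad connectivity, and
#' scalar data arrays.
#'
#' @param file path to a `.vtk` file
#' @return list with `nodes`, `elems`, `point_data`, `cell_data`
#' @export
read_vtk <- function(file) {
  ln <- readLines(file)
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  pts <- scan(text = ln[(ip + 1):(ip + n)], quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE]
  ic <- grep("^CELLS", ln)[1]
  ne <- as.integer(strsplit(ln[ic], " +")[[1]][2])
  cl <- scan(text = ln[(ic + 1):(ic + ne)], quiet = TRUE)
  cl <- matrix(cl, ncol = 5, byrow = TRUE)
  elems <- cl[, 2:5, drop = FALSE] + 1L
  read_scalars <- function(start, count) {
    out <- list()
    i <- start
    while (i <= length(ln)) {
      if (grepl("^(POINT_DATA|CELL_DATA)", ln[i])) break
      if (grepl("^SCALARS", ln[i])) {
        nm <- strsplit(ln[i], " +")[[1]][2]
        vals <- scan(text = ln[(i + 2):length(ln)], n = count,
                     quiet = TRUE)
        out[[nm]] <- vals
        i <- i + 2
      }
      i <- i + 1
    }
    out
  }
  ipd <- grep("^POINT_DATA", ln)
  icd <- grep("^CELL_DATA", ln)
  list(nodes = nodes, elems = elems,
       point_data = if (length(ipd)) read_scalars(ipd[1] + 1, n)
                    else list(),
       cell_data = if (length(icd)) read_scalars(icd[1] + 1, ne)
                   else list())
}
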