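#' Parametric surface crack specification
#'
#' Describes a surface-breaking lesion cut into the explant cross-section.
#' Real injured explants show on average two surface cracks per sample;
#' since segmented histological geometries are not available, cracks are
#' generated parametrically.
#'
#' @param mouth_position distance of the crack mouth centre from the
#'   symmetry axis, mm
#' @param depth crack depth from the articular surface, mm
#' @param opening_width width of the crack mouth, mm
#' @param inclination tilt of the crack tip from vertical, degrees
#' @param profile `"v-notch"` (triangular notch) or `"parallel-walled"`
#'   (rectangular notch)
#' @return object of class `crack_spec`
#' @export
crack_spec <- function(mouth_position, depth, opening_width,
                       inclination = 0,
                       profile = c("v-notch", "parallel-walled")) {
  profile <- match.arg(profile)
  stopifnot(depth > 0, opening_width > 0, mouth_position > 0)
  s <- list(mouth_position = mouth_position, depth = depth,
            opening_width = opening_width, inclination = inclination,
            profile = profile)
  class(s) <- "crack_spec"
  s
}

#' Default injured-explant crack set
#'
#' Two v-notch surface cracks (injured explants show on average two cracks
#' per sample): one mid-surface (mouth at 0.7 mm, 0.4 mm deep) and one
#' peripheral (mouth at 1.25 mm, 0.35 mm deep), both 0.2 mm wide.
#' Peripheral cracking is favoured in unconfined injurious compression,
#' where tensile hoop stresses peak near the edge.
#'
#' @return list of two [crack_spec()] objects
#' @export
default_injured_cracks <- function() {
  list(crack_spec(0.7, 0.4, 0.2), crack_spec(1.25, 0.35, 0.2))
}

# merge crack grid lines into a base grid, dropping base lines that would
# create slivers next to an inserted line
.insert_lines <- function(base, pts, tol) {
  keep <- base
  for (p in pts) {
    ends <- keep %in% range(base)
    keep <- keep[ends | abs(keep - p) > tol]
  }
  sort(unique(c(keep, pts)))
}

#' Build the explant cross-section mesh
#'
#' Generates a conforming 4-node quadrilateral mesh of the half
#' cross-section of a cylindrical cartilage explant (default 3 mm diameter,
#' 1 mm thick), with optional parametric surface cracks.  V-notch cracks are
#' meshed by a graded vertical mapping whose top boundary follows the notch
#' faces; parallel-walled cracks by element removal.  Exterior edges are
#' tagged `platen_top`, `bottom`, `free_lateral`, `symmetry_axis` or
#' `lesion_surface`.
#'
#' @param radius explant radius, mm
#' @param thickness explant thickness, mm
#' @param cracks list of [crack_spec()] objects
#' @param target_h target element edge length, mm
#' @param formulation `"plane_strain"` or `"axisymmetric"`
#' @return object of class `explant_mesh` with fields `nodes` (n x 2, mm),
#'   `elems` (ne x 4, counter-clockwise), `edges` (boundary edge table)
#' @export
build_explant_mesh <- function(radius = 1.5, thickness = 1,
                               cracks = list(), target_h = 0.1,
                               formulation = c("axisymmetric",
                                               "plane_strain")) {
  formulation <- match.arg(formulation)
  stopifnot(radius > 0, thickness > 0, target_h > 0)
  if (inherits(cracks, "crack_spec")) cracks <- list(cracks)
  for (cr in cracks) {
    if (cr$depth >= thickness)
      stop("crack depth must be smaller than the explant thickness")
    if (cr$mouth_position - cr$opening_width / 2 <= 0 ||
        cr$mouth_position + cr$opening_width / 2 >= radius)
      stop("crack mouth must lie strictly inside the top surface")
  }

  nx <- max(2L, ceiling(radius / target_h))
  ny <- max(2L, ceiling(thickness / target_h))
  xs <- seq(0, radius, length.out = nx + 1)
  ys <- seq(0, thickness, length.out = ny + 1)
  tol <- target_h / 4

  crx <- lapply(cracks, function(cr) {
    xl <- cr$mouth_position - cr$opening_width / 2
    xr <- cr$mouth_position + cr$opening_width / 2
    xtip <- cr$mouth_position + cr$depth * tanpi(cr$inclination / 180)
    if (xtip <= xl + 1e-9 || xtip >= xr - 1e-9)
      stop("crack inclination places the tip outside the mouth interval")
    list(xl = xl, xr = xr, xtip = xtip, cr = cr)
  })
  for (cc in crx) {
    pts <- if (cc$cr$profile == "v-notch") c(cc$xl, cc$xtip, cc$xr)
           else c(cc$xl, cc$xr)
    xs <- .insert_lines(xs, pts, tol)
    if (cc$cr$profile == "parallel-walled")
      ys <- .insert_lines(ys, thickness - cc$cr$depth, tol)
  }

  nxn <- length(xs); nyn <- length(ys)
  nodes <- cbind(rep(xs, each = nyn), rep(ys, times = nxn))
  nid <- function(ix, iy) (ix - 1L) * nyn + iy
  ix <- rep(seq_len(nxn - 1L), each = nyn - 1L)
  iy <- rep(seq_len(nyn - 1L), times = nxn - 1L)
  elems <- cbind(nid(ix, iy), nid(ix + 1L, iy),
                 nid(ix + 1L, iy + 1L), nid(ix, iy + 1L))

  # v-notch: scale node columns inside the mouth so the top boundary
  # follows the two notch faces (conforming at the mouth corners)
  for (cc in crx) {
    if (cc$cr$profile != "v-notch") next
    d <- cc$cr$depth
    sel <- nodes[, 1] > cc$xl + 1e-12 & nodes[, 1] < cc$xr - 1e-12
    x <- nodes[sel, 1]
    ytop <- ifelse(x <= cc$xtip,
                   thickness - d * (x - cc$xl) / (cc$xtip - cc$xl),
                   thickness - d * (cc$xr - x) / (cc$xr - cc$xtip))
    nodes[sel, 2] <- nodes[sel, 2] * ytop / thickness
  }

  # parallel-walled: drop elements whose centroid lies inside the notch
  for (cc in crx) {
    if (cc$cr$profile != "parallel-walled") next
    cx <- rowMeans(matrix(nodes[elems, 1], ncol = 4))
    cy <- rowMeans(matrix(nodes[elems, 2], ncol = 4))
    inside <- cx > cc$xl & cx < cc$xr & cy > thickness - cc$cr$depth
    elems <- elems[!inside, , drop = FALSE]
  }

  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  elems <- matrix(remap[elems], ncol = 4)

  a <- .elem_areas(nodes, elems)
  if (any(a <= 0)) stop("meshing produced inverted elements")

  edges <- .tag_boundary(nodes, elems, radius, thickness, tol = 1e-8)
  m <- list(nodes = nodes, elems = elems, edges = edges, radius = radius,
            thickness = thickness, target_h = target_h,
            formulation = formulation, cracks = cracks)
  class(m) <- "explant_mesh"
  m
}

.elem_areas <- function(nodes, elems) {
  x <- matrix(nodes[elems, 1], ncol = 4)
  y <- matrix(nodes[elems, 2], ncol = 4)
  0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
         (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
         (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
         (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

.tag_boundary <- function(nodes, elems, radius, thickness, tol = 1e-8) {
  e1 <- rbind(elems[, c(1, 2)], elems[, c(2, 3)],
              elems[, c(3, 4)], elems[, c(4, 1)])
  key <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
  bnd <- e1[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  x1 <- nodes[bnd[, 1], 1]; y1 <- nodes[bnd[, 1], 2]
  x2 <- nodes[bnd[, 2], 1]; y2 <- nodes[bnd[, 2], 2]
  atol <- tol * max(radius, thickness)
  tag <- rep("lesion_surface", nrow(bnd))
  tag[abs(y1) < atol & abs(y2) < atol] <- "bottom"
  tag[abs(x1) < atol & abs(x2) < atol] <- "symmetry_axis"
  tag[abs(x1 - radius) < atol & abs(x2 - radius) < atol] <- "free_lateral"
  on_top <- pmin(y1, y2) > thickness - atol
  tag[on_top & tag == "lesion_surface"] <- "platen_top"
  data.frame(n1 = bnd[, 1], n2 = bnd[, 2], tag = tag,
             stringsAsFactors = FALSE)
}

#' @export
print.explant_mesh <- function(x, ...) {
  cat(sprintf("explant_mesh: %d nodes, %d quads (%s)\n", nrow(x$nodes),
              nrow(x$elems), x$formulation))
  cat(sprintf("  radius %g mm, thickness %g mm, %d crack(s)\n",
              x$radius, x$thickness, length(x$cracks)))
  print(table(x$edges$tag))
  invisible(x)
}

#' Nodes on a tagged boundary
#' @param mesh an [build_explant_mesh()] mesh
#' @param tags character vector of boundary tags
#' @return integer node indices
#' @export
boundary_nodes <- function(mesh, tags) {
  e <- mesh$edges[mesh$edges$tag %in% tags, ]
  sort(unique(c(e$n1, e$n2)))
}

#' Reference coordinates of the 2x2 Gauss points of every element
#' @param mesh an explant mesh
#' @return (4*ne) x 2 matrix, element-major
#' @export
mesh_gp_coords <- function(mesh) {
  g <- 1 / sqrt(3)
  xi <- c(-g, g, g, -g); et <- c(-g, -g, g, g)
  xn <- matrix(mesh$nodes[mesh$elems, 1], ncol = 4)
  yn <- matrix(mesh$nodes[mesh$elems, 2], ncol = 4)
  out <- matrix(0, nrow(mesh$elems) * 4, 2)
  for (q in 1:4) {
    N <- 0.25 * c((1 - xi[q]) * (1 - et[q]), (1 + xi[q]) * (1 - et[q]),
                  (1 + xi[q]) * (1 + et[q]), (1 - xi[q]) * (1 + et[q]))
    idx <- seq(q, by = 4, length.out = nrow(mesh$elems))
    out[idx, 1] <- xn %*% N
    out[idx, 2] <- yn %*% N
  }
  out
}

#' Uniformly refined copy of a mesh
#'
#' Rebuilds the same geometry with half the target element size.
#' @param mesh an explant mesh
#' @return refined `explant_mesh`
#' @export
refine_mesh <- function(mesh) {
  build_explant_mesh(mesh$radius, mesh$thickness, mesh$cracks,
                     target_h = mesh$target_h / 2,
                     formulation = mesh$formulation)
}

#' Mesh convergence helper
#'
#' Halves the target element size until a user-supplied probe quantity
#' changes by less than `rtol` between refinement levels.
#'
#' @param probe function(mesh) returning a scalar
#' @param radius,thickness,cracks,formulation geometry, as in
#'   [build_explant_mesh()]
#' @param h0 starting element size, mm
#' @param rtol relative change tolerance between levels
#' @param max_levels maximum number of refinements
#' @return list with the converged `mesh`, the probe `values` and `h` sizes
#' @export
converge_mesh <- function(probe, radius = 1.5, thickness = 1,
                          cracks = list(), formulation = "plane_strain",
                          h0 = 0.25, rtol = 0.02, max_levels = 4) {
  hs <- h0 / 2^(0:max_levels)
  vals <- numeric(0)
  mesh <- NULL
  for (i in seq_along(hs)) {
    mesh <- build_explant_mesh(radius, thickness, cracks, target_h = hs[i],
                               formulation = formulation)
    vals[i] <- probe(mesh)
    if (i > 1 &&
        abs(vals[i] - vals[i - 1]) <= rtol * max(abs(vals[i]), 1e-12))
      return(list(mesh = mesh, values = vals, h = hs[seq_len(i)]))
  }
  warning("probe did not converge within ", max_levels, " refinements")
  list(mesh = mesh, values = vals, h = hs)
}
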