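#' Default depth-wise composition polynomials
#'
#' Coefficients (ascending powers of the normalized depth `h`, surface = 0,
#' bottom = 1) of the depth-wise fixed charge density and relative collagen
#' density profiles of young bovine cartilage, and the linear fluid-fraction
#' profile `n_fl(h) = 0.85 - 0.15 h`.
#'
#' @name depth_profile_defaults
#' @keywords internal
NULL

.fcd_poly_default <- c(0.03, 1.1, -5.8, 14.9, -21.0, 15.2, -4.4)
.rhoz_poly_default <- c(0.96, -1.6, 13.4, -45.9, 78.1, -64.4, 20.6)

.polyval <- function(coefs, h) {
  out <- 0
  for (j in rev(seq_along(coefs))) out <- out * h + coefs[j]
  out
}

#' Depth-wise composition profiles
#'
#' Evaluates the fluid fraction, fixed charge density and relative collagen
#' density at normalized depth `h` (articular surface = 0, bottom = 1):
#' `n_fl = 0.85 - 0.15 h`, and sixth-degree polynomials for `c_FCD`
#' (mEq/ml) and `rho_z`.
#'
#' @param h normalized depth in `[0, 1]`, vectorized
#' @param fcd_coefs optional replacement FCD polynomial (ascending
#'   coefficients, e.g. from [od_profile_to_fcd()])
#' @return data.frame with columns `n_fl`, `c_FCD`, `rho_z`
#' @export
depth_profiles <- function(h, fcd_coefs = NULL) {
  if (any(h < -1e-9 | h > 1 + 1e-9)) stop("h must lie in [0, 1]")
  h <- pmin(pmax(h, 0), 1)
  if (is.null(fcd_coefs)) fcd_coefs <- .fcd_poly_default
  data.frame(n_fl = 0.85 - 0.15 * h,
             c_FCD = .polyval(fcd_coefs, h),
             rho_z = .polyval(.rhoz_poly_default, h))
}

#' Fibril architecture of a mesh
#'
#' Assigns primary and secondary collagen fibril directions to every
#' integration point.  The primary family follows the chosen arrangement;
#' the secondary family is a fixed isotropic fan of 8 in-plane unit
#' directions (22.5 degree spacing) plus the out-of-plane axis.
#'
#' Arrangements: `"arcade"` (Benninghoff: tangent to the surface in the
#' superficial zone, bending to depth-normal in the deep zone over the
#' transitional zone), `"parallel_to_surface"`, `"perpendicular"`, and
#' `"isotropic"` (primary density spread evenly over the secondary fan).
#'
#' @param mesh an [build_explant_mesh()] mesh
#' @param arrangement collagen arrangement keyword
#' @param zones superficial/deep zone boundaries of the arcade transition,
#'   fractions of thickness
#' @param n_secondary number of in-plane secondary directions
#' @return list with `dirs` ((4*ne*ndir) x 3 unit vectors), `primary`
#'   (logical per row), `ndir`, and `angle` (primary angle from horizontal
#'   per integration point, radians; NA for isotropic)
#' @export
fibril_architecture <- function(mesh,
                                arrangement = c("arcade",
                                                "parallel_to_surface",
                                                "perpendicular",
                                                "isotropic"),
                                zones = c(0.15, 0.40), n_secondary = 8) {
  arrangement <- match.arg(arrangement)
  gp <- mesh_gp_coords(mesh)
  h <- pmin(pmax((mesh$thickness - gp[, 2]) / mesh$thickness, 0), 1)
  ngp <- nrow(gp)

  th <- (seq_len(n_secondary) - 1) * pi / n_secondary
  sec <- rbind(cbind(cos(th), sin(th), 0), c(0, 0, 1))
  nsec <- nrow(sec)

  if (arrangement == "isotropic") {
    ndir <- nsec
    dirs <- sec[rep(seq_len(nsec), times = ngp), , drop = FALSE]
    return(list(dirs = dirs, primary = rep(FALSE, nrow(dirs)),
                ndir = ndir, angle = rep(NA_real_, ngp),
                arrangement = arrangement, n_secondary = n_secondary))
  }

  ang <- switch(arrangement,
    parallel_to_surface = rep(0, ngp),
    perpendicular = rep(pi / 2, ngp),
    arcade = {
      a <- rep(0, ngp)
      mid <- h > zones[1] & h < zones[2]
      a[mid] <- (h[mid] - zones[1]) / (zones[2] - zones[1]) * pi / 2
      a[h >= zones[2]] <- pi / 2
      a
    })
  ndir <- 1L + nsec
  dirs <- matrix(0, ngp * ndir, 3)
  prim <- rep(c(TRUE, rep(FALSE, nsec)), times = ngp)
  pri_rows <- seq(1, by = ndir, length.out = ngp)
  dirs[pri_rows, ] <- cbind(cos(ang), sin(ang), 0)
  dirs[-pri_rows, ] <- sec[rep(seq_len(nsec), times = ngp), ]
  list(dirs = dirs, primary = prim, ndir = ndir, angle = ang,
       arrangement = arrangement, n_secondary = n_secondary)
}

#' Per-integration-point composition field
#'
#' Populates the depth-wise composition (fluid fraction, reference FCD,
#' relative collagen density) and the fibril architecture on every
#' integration point of a mesh.  This is the mutable state consumed and
#' rewritten by the degeneration loop: `c_fcd0` holds the reference FCD
#' (mEq/ml per unit reference fluid volume) that depletion acts on.
#'
#' @inheritParams fibril_architecture
#' @param params a [material_params()] (for the primary fibril weight `C`)
#' @param fcd_coefs optional replacement FCD polynomial
#' @param rhoz_coefs optional replacement collagen-density polynomial
#'   (ascending coefficients)
#' @param fcd_scale multiplier on the initial FCD profile
#' @param rhoz_scale multiplier on the collagen density profile
#' @return object of class `composition_field` with per-point vectors
#'   `c_fcd0`, `n_fl0`, `rho_z`, `h`, and the fibril table `fib`
#'   ((4*ne*ndir) x 4: direction + weight) used by the FE kernel
#' @export
composition_field <- function(mesh, params = material_params(),
                              arrangement = "arcade", fcd_coefs = NULL,
                              rhoz_coefs = NULL, fcd_scale = 1,
                              rhoz_scale = 1, zones = c(0.15, 0.40),
                              n_secondary = 8) {
  gp <- mesh_gp_coords(mesh)
  h <- pmin(pmax((mesh$thickness - gp[, 2]) / mesh$thickness, 0), 1)
  prof <- depth_profiles(h, fcd_coefs)
  if (!is.null(rhoz_coefs)) prof$rho_z <- .polyval(rhoz_coefs, h)
  arch <- fibril_architecture(mesh, arrangement, zones, n_secondary)
  rho <- pmax(prof$rho_z * rhoz_scale, 0)

  ndir <- arch$ndir
  w_rho <- rep(rho, each = ndir)
  wt <- w_rho * ifelse(arch$primary, params$C, 1)
  if (arch$arrangement == "isotropic")
    wt <- w_rho * (1 + params$C / ndir)
  fib <- cbind(arch$dirs, wt)

  cf <- list(c_fcd0 = pmax(prof$c_FCD * fcd_scale, 0),
             n_fl0 = prof$n_fl, rho_z = rho, h = h,
             fib = fib, ndir = ndir, arrangement = arch$arrangement,
             fcd_coefs = if (is.null(fcd_coefs)) .fcd_poly_default
                         else fcd_coefs,
             fcd_scale = fcd_scale, rhoz_scale = rhoz_scale)
  class(cf) <- "composition_field"
  cf
}

#' @export
print.composition_field <- function(x, ...) {
  cat(sprintf("composition_field: %d integration points (%s fibrils)\n",
              length(x$c_fcd0), x$arrangement))
  cat(sprintf("  c_FCD0 range %.3f..%.3f mEq/ml, n_fl 0 %.2f..%.2f\n",
              min(x$c_fcd0), max(x$c_fcd0), min(x$n_fl0), max(x$n_fl0)))
  invisible(x)
}

#' Fit an FCD depth profile from an optical density record
#'
#' Fits a sixth-degree polynomial by least squares to a measured depth-wise
#' optical density profile and rescales it uniformly so that its
#' depth-averaged value equals a target mean FCD (the literature mean used
#' to convert optical density into charge units).
#'
#' @param od_profile 2-column data.frame or matrix: normalized depth `h`
#'   and optical density
#' @param target_mean_fcd desired depth-averaged FCD, mEq/ml
#' @return ascending polynomial coefficients (length 7), usable as
#'   `fcd_coefs` in [depth_profiles()] and [composition_field()]
#' @export
od_profile_to_fcd <- function(od_profile, target_mean_fcd) {
  od_profile <- as.data.frame(od_profile)
  stopifnot(ncol(od_profile) >= 2, target_mean_fcd > 0)
  names(od_profile)[1:2] <- c("h", "od")
  if (nrow(od_profile) < 7)
    stop("at least 7 depth samples are required for a degree-6 fit")
  fit <- lm(od ~ poly(h, 6, raw = TRUE), data = od_profile)
  co <- as.numeric(coef(fit))
  co[is.na(co)] <- 0
  # depth-average of the polynomial over [0, 1]
  m <- sum(co / seq_along(co))
  if (abs(m) < 1e-12) stop("fitted profile has zero depth-average")
  co * target_mean_fcd / m
}
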