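#' Constitutive parameters of the fibril-reinforced swelling material
#'
#' Builds the full parameter set of the fibril-reinforced porohyperelastic
#' swelling material in the internal mm-N-s-MPa unit system.  Defaults are
#' the calibrated bovine-calf explant values: fibril network modulus
#' `E_f` = 20 MPa, non-fibrillar matrix modulus `E_nf` = 0.16 MPa,
#' Poisson ratio 0.42, hydraulic permeability `k` = 1.3e-3 mm^4/(N s)
#' (i.e. 1.3e-15 m^4/(N s)), primary-to-secondary fibril density ratio
#' `C` = 3.009, external salt concentration 0.15 mEq/ml at 293 K.
#'
#' Osmotic and activity coefficients default to ideal (1) and the chemical
#' expansion constants `a0`, `kappa` to 0 (chemical expansion off); all can
#' be overridden.
#'
#' @param E_f fibril network modulus, MPa
#' @param E_nf non-fibrillar matrix modulus, MPa
#' @param nu_nf Poisson ratio of the non-fibrillar matrix (0 <= nu < 0.5)
#' @param k hydraulic permeability, mm^4/(N s)
#' @param C primary-to-secondary fibril density ratio
#' @param c_ext external salt concentration, mEq/ml
#' @param R molar gas constant, J/(mol K)
#' @param T absolute temperature, K
#' @param phi_int,phi_ext internal/external osmotic coefficients
#' @param gamma_int,gamma_ext internal/external activity coefficients
#' @param a0 chemical-expansion constant, MPa ml/mEq
#' @param kappa chemical-expansion exponent constant, ml/mEq
#' @return object of class `material_params`
#' @export
material_params <- function(E_f = 20, E_nf = 0.16, nu_nf = 0.42,
                            k = 1.3e-3, C = 3.009, c_ext = 0.15,
                            R = 8.3145, T = 293,
                            phi_int = 1, phi_ext = 1,
                            gamma_int = 1, gamma_ext = 1,
                            a0 = 0, kappa = 0) {
  p <- list(E_f = E_f, E_nf = E_nf, nu_nf = nu_nf, k = k, C = C,
            c_ext = c_ext, R = R, T = T, phi_int = phi_int,
            phi_ext = phi_ext, gamma_int = gamma_int,
            gamma_ext = gamma_ext, a0 = a0, kappa = kappa)
  stopifnot(E_f > 0, E_nf > 0, k > 0, C > 0, c_ext > 0, R > 0, T > 0,
            phi_int > 0, phi_ext > 0, gamma_int > 0, gamma_ext > 0,
            a0 >= 0, kappa >= 0)
  if (nu_nf < 0 || nu_nf >= 0.5)
    stop("nu_nf must lie in [0, 0.5): the non-fibrillar matrix cannot be ",
         "fully incompressible")
  class(p) <- "material_params"
  p
}

#' @export
print.material_params <- function(x, ...) {
  cat("Fibril-reinforced porohyperelastic swelling material\n")
  cat(sprintf("  E_f = %g MPa, E_nf = %g MPa, nu_nf = %g\n",
              x$E_f, x$E_nf, x$nu_nf))
  cat(sprintf("  k = %g mm^4/(N s), C = %g\n", x$k, x$C))
  cat(sprintf("  c_ext = %g mEq/ml, T = %g K, RT = %g MPa ml/mEq\n",
              x$c_ext, x$T, rt_constant(x)))
  if (x$a0 > 0) cat(sprintf("  chemical expansion: a0 = %g, kappa = %g\n",
                            x$a0, x$kappa))
  invisible(x)
}

#' Osmotic unit constant RT in MPa ml/mEq
#'
#' One mEq/ml is 1e3 mol/m^3, so `R*T*c` in MPa is `R*T*c*1e-3` with `c` in
#' mEq/ml.  Centralizes the unit handling of every osmotic term.
#' @param params a [material_params()] object
#' @return scalar, MPa ml/mEq
#' @export
rt_constant <- function(params) params$R * params$T * 1e-3

#' Bulk and shear moduli of the non-fibrillar matrix
#'
#' `K_nf = E_nf / (3 (1 - 2 nu))`, `G_nf = E_nf / (2 (1 + nu))`.
#'
#' @param E_nf Young's modulus of the non-fibrillar matrix, MPa
#' @param nu_nf Poisson ratio, must be < 0.5
#' @return named vector `c(K_nf, G_nf)` in MPa
#' @export
bulk_shear_moduli <- function(E_nf, nu_nf) {
  stopifnot(E_nf > 0)
  if (nu_nf >= 0.5) stop("nu_nf >= 0.5: incompressible limit not supported")
  if (nu_nf < 0) stop("nu_nf must be non-negative")
  c(K_nf = unname(E_nf / (3 * (1 - 2 * nu_nf))),
    G_nf = unname(E_nf / (2 * (1 + nu_nf))))
}

#' Neo-Hookean Cauchy stress of the non-fibrillar matrix
#'
#' `sigma_nf = K_nf ln(J)/J I + G_nf/J (F F' - J^(2/3) I)`.
#'
#' @param F deformation gradient, 3x3 matrix (use `diag(3)` for undeformed)
#' @param K_nf,G_nf bulk and shear moduli, MPa
#' @return symmetric 3x3 Cauchy stress, MPa
#' @export
nonfibrillar_stress <- function(F, K_nf, G_nf) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)))
  J <- det(F)
  if (J <= 0) stop("det(F) <= 0: inverted configuration")
  S <- K_nf * log(J) / J * diag(3) +
    G_nf / J * (F %*% t(F) - J^(2 / 3) * diag(3))
  (S + t(S)) / 2
}

#' Tension-only stress of a single collagen fibril
#'
#' `sigma_f = E_f * eps_f` for positive fibril strain, 0 otherwise:
#' collagen fibrils resist only tension.
#'
#' @param eps_f fibril strain (logarithmic), dimensionless; vectorized
#' @param E_f fibril network modulus, MPa
#' @return fibril stress, MPa
#' @export
fibril_stress <- function(eps_f, E_f) {
  ifelse(eps_f > 0, E_f * eps_f, 0)
}

#' Logarithmic fibril strain of a direction under F
#'
#' The fibril strain measure used throughout the package:
#' `eps_f = ln |F e|` for a unit direction `e`.  Isolated here so an
#' alternative measure (e.g. Green strain) can be swapped in one place.
#'
#' @param F 3x3 deformation gradient
#' @param dir unit direction vector, length 3
#' @return scalar logarithmic strain
#' @export
fibril_strain <- function(F, dir) {
  n <- sqrt(sum(dir^2))
  if (n < 1e-12) stop("zero-norm fibril direction")
  log(sqrt(sum((as.matrix(F) %*% (dir / n))^2)))
}

#' Fibril network Cauchy stress
#'
#' Sums tension-only fibril stresses over all direction families at a
#' material point.  Primary fibrils are weighted `rho_z * C * sigma_f` and
#' secondary fibrils `rho_z * sigma_f`; each contributes along its deformed
#' (rotated) direction.
#'
#' @param state a [material_point_state()]
#' @param params a [material_params()]
#' @return symmetric 3x3 Cauchy stress, MPa
#' @export
fibril_network_stress <- function(state, params) {
  F <- state$F
  S <- matrix(0, 3, 3)
  dirs <- state$fibril_dirs
  for (i in seq_len(nrow(dirs$dir))) {
    d <- dirs$dir[i, ]
    n <- sqrt(sum(d^2))
    if (n < 1e-12) stop("zero-norm fibril direction")
    v <- as.vector(as.matrix(F) %*% (d / n))
    lam <- sqrt(sum(v^2))
    eps <- log(lam)
    if (eps <= 0) next
    w <- state$rho_z * (if (dirs$primary[i]) params$C else 1)
    vn <- v / lam
    S <- S + w * fibril_stress(eps, params$E_f) * tcrossprod(vn)
  }
  S
}

#' Donnan osmotic swelling pressure
#'
#' `dpi = phi_int RT sqrt(c_FCD^2 + 4 (g_ext/g_int)^2 c_ext^2)
#'        - 2 phi_ext RT c_ext`, with `RT c` expressed in MPa through
#' [rt_constant()].  With ideal coefficients and `c_FCD = 0` the pressure is
#' exactly zero; it is strictly increasing in `c_FCD`.
#'
#' @param c_FCD fixed charge density, mEq/ml (vectorized, must be >= 0)
#' @param params a [material_params()]
#' @return swelling pressure, MPa
#' @export
donnan_pressure <- function(c_FCD, params) {
  if (any(c_FCD < 0)) stop("c_FCD must be non-negative")
  RT <- rt_constant(params)
  g <- params$gamma_ext / params$gamma_int
  params$phi_int * RT * sqrt(c_FCD^2 + 4 * g^2 * params$c_ext^2) -
    2 * params$phi_ext * RT * params$c_ext
}

#' Mobile anion concentration from ideal Donnan equilibrium
#'
#' `c^- = (sqrt(c_FCD^2 + 4 g^2 c_ext^2) - c_FCD) / 2` with
#' `g = gamma_ext/gamma_int`.
#'
#' @inheritParams donnan_pressure
#' @return anion concentration, mEq/ml
#' @export
mobile_anion_concentration <- function(c_FCD, params) {
  g <- params$gamma_ext / params$gamma_int
  (sqrt(c_FCD^2 + 4 * g^2 * params$c_ext^2) - c_FCD) / 2
}

#' Chemical expansion stress
#'
#' `T_c = a0 c_FCD exp(-kappa (g_ext/g_int) sqrt(c^- (c^- + c_FCD)))` with
#' the mobile anion concentration `c^-` from
#' [mobile_anion_concentration()].  Returns 0 when `a0 = 0` (default:
#' chemical expansion disabled) or `c_FCD = 0`.
#'
#' @inheritParams donnan_pressure
#' @return chemical expansion stress, MPa
#' @export
chemical_expansion_stress <- function(c_FCD, params) {
  if (any(c_FCD < 0)) stop("c_FCD must be non-negative")
  if (params$a0 <= 0) return(0 * c_FCD)
  g <- params$gamma_ext / params$gamma_int
  cm <- mobile_anion_concentration(c_FCD, params)
  params$a0 * c_FCD * exp(-params$kappa * g * sqrt(cm * (cm + c_FCD)))
}

#' Material point state
#'
#' Bundles the kinematic and compositional state at one integration point
#' for the material-level API.
#'
#' @param F 3x3 deformation gradient (det > 0)
#' @param c_FCD fixed charge density at the current state, mEq/ml
#' @param n_fl fluid volume fraction (solid fraction is `1 - n_fl`)
#' @param rho_z relative collagen density
#' @param fibril_dirs list with `dir` (n x 3 matrix of unit vectors) and
#'   `primary` (logical vector)
#' @param p pore pressure (chemical potential of water), MPa
#' @return object of class `material_point_state`
#' @export
material_point_state <- function(F = diag(3), c_FCD = 0, n_fl = 0.8,
                                 rho_z = 1,
                                 fibril_dirs = list(
                                   dir = matrix(c(1, 0, 0), 1, 3),
                                   primary = TRUE),
                                 p = 0) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)), c_FCD >= 0,
            n_fl > 0, n_fl < 1, rho_z >= 0)
  if (det(F) <= 0) stop("det(F) <= 0")
  s <- list(F = F, c_FCD = c_FCD, n_fl = n_fl, n_s = 1 - n_fl,
            rho_z = rho_z, fibril_dirs = fibril_dirs, p = p)
  class(s) <- "material_point_state"
  s
}

#' Total Cauchy stress of the mixture
#'
#' `sigma_tot = sigma_f + sigma_nf - dpi I - mu_f I - T_c I`.  The
#' hydrostatic fluid contribution `p = dpi + mu_f` is split between the
#' constitutive Donnan pressure `dpi` and the FE pressure unknown `mu_f`
#' (the chemical potential of water, stored in `state$p`).
#'
#' @param state a [material_point_state()]
#' @param params a [material_params()]
#' @return symmetric 3x3 Cauchy stress, MPa
#' @export
total_stress <- function(state, params) {
  kg <- bulk_shear_moduli(params$E_nf, params$nu_nf)
  snf <- nonfibrillar_stress(state$F, kg["K_nf"], kg["G_nf"])
  sf <- fibril_network_stress(state, params)
  ph <- donnan_pressure(state$c_FCD, params) +
    chemical_expansion_stress(state$c_FCD, params) + state$p
  sf + snf - ph * diag(3)
}

#' Darcy flux and interstitial fluid velocity
#'
#' `q = -k grad(p)`; the fluid velocity through the pores is
#' `v_fl = q (e + 1) / e` with void ratio `e = n_fl / n_s`.
#'
#' @param grad_p pressure gradient vector, MPa/mm
#' @param k hydraulic permeability, mm^4/(N s)
#' @param e void ratio (> 0)
#' @return list with `q` (Darcy flux, mm/s) and `v_fl` (fluid velocity, mm/s)
#' @export
darcy_velocity <- function(grad_p, k, e) {
  if (e <= 0) stop("void ratio must be positive")
  q <- -k * grad_p
  list(q = q, v_fl = q * (e + 1) / e)
}

#' Void ratio from volume fractions
#'
#' `e = n_fl / n_s`.
#' @param n_fl fluid volume fraction
#' @param n_s solid volume fraction
#' @return void ratio
#' @export
void_ratio <- function(n_fl, n_s) {
  stopifnot(all(n_s > 0))
  n_fl / n_s
}
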