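test_that("bulk and shear moduli follow the isotropic relations", {
  kg <- bulk_shear_moduli(0.16, 0.42)
  expect_equal(kg[["K_nf"]], 0.33333, tolerance = 1e-4)
  expect_equal(kg[["G_nf"]], 0.056338, tolerance = 1e-4)
  kg0 <- bulk_shear_moduli(1, 0)
  expect_equal(unname(kg0), c(1 / 3, 1 / 2))
  expect_gt(bulk_shear_moduli(0.16, 0.49)[["K_nf"]],
            bulk_shear_moduli(0.16, 0.42)[["K_nf"]])
  expect_error(bulk_shear_moduli(0.16, 0.5), "incompressible")
})

test_that("neo-Hookean stress matches a hand evaluation and is symmetric", {
  kg <- bulk_shear_moduli(0.16, 0.42)
  K <- kg[["K_nf"]]; G <- kg[["G_nf"]]
  expect_equal(nonfibrillar_stress(diag(3), K, G), matrix(0, 3, 3))

  # plane compression: componentwise independent evaluation
  F <- diag(c(0.9, 1, 1))
  J <- 0.9
  s <- nonfibrillar_stress(F, K, G)
  expect_equal(s[1, 1], K * log(J) / J + G / J * (0.81 - J^(2 / 3)))
  expect_equal(s[2, 2], K * log(J) / J + G / J * (1 - J^(2 / 3)))
  expect_equal(s[3, 3], s[2, 2])
  expect_equal(s[1, 2], 0)

  # volumetric expansion carries tensile pressure
  expect_gt(sum(diag(nonfibrillar_stress(1.1 * diag(3), K, G))), 0)
  expect_error(nonfibrillar_stress(diag(c(-1, 1, 1)), K, G), "inverted")

  set.seed(42)
  for (i in 1:25) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
    if (det(F) <= 0) next
    s <- nonfibrillar_stress(F, K, G)
    expect_lt(max(abs(s - t(s))), 1e-14)
  }
})

test_that("fibril law resists only tension", {
  expect_identical(fibril_stress(-0.1, 20), 0)
  expect_identical(fibril_stress(0, 20), 0)
  expect_equal(fibril_stress(0.05, 20), 1.0)
  expect_equal(fibril_stress(c(-1, 0.01, 0.3), 10), c(0, 0.1, 3))
})

test_that("fibril strain is logarithmic along the deformed direction", {
  F <- diag(c(1.2, 0.9, 1))
  expect_equal(fibril_strain(F, c(1, 0, 0)), log(1.2))
  expect_equal(fibril_strain(F, c(0, 1, 0)), log(0.9))
  # non-unit input directions are normalized
  expect_equal(fibril_strain(F, c(2, 0, 0)), log(1.2))
  expect_error(fibril_strain(F, c(0, 0, 0)), "zero-norm")
})

test_that("fibril network stress weights primary/secondary correctly", {
  p <- material_params()
  one_x <- list(dir = matrix(c(1, 0, 0), 1, 3), primary = TRUE)
  lam <- exp(0.01)
  st <- material_point_state(F = diag(c(lam, 1, 1)), rho_z = 1,
                             fibril_dirs = one_x)
  s <- fibril_network_stress(st, p)
  expect_equal(s[1, 1], 1 * p$C * p$E_f * 0.01, tolerance = 1e-12)
  expect_equal(s[-1], rep(0, 8))

  # doubling collagen density doubles the tensor
  st2 <- material_point_state(F = diag(c(lam, 1, 1)), rho_z = 2,
                              fibril_dirs = one_x)
  expect_equal(fibril_network_stress(st2, p), 2 * s)

  # every direction compressed -> exactly zero
  dirs <- list(dir = rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0) / sqrt(2)),
               primary = c(TRUE, FALSE, FALSE))
  stc <- material_point_state(F = 0.95 * diag(3), fibril_dirs = dirs)
  expect_identical(fibril_network_stress(stc, p), matrix(0, 3, 3))
})

test_that("Donnan pressure obeys the equilibrium expression", {
  p <- material_params()        # ideal coefficients
  expect_identical(donnan_pressure(0, p), 0)
  # frozen scalar evaluation: RT = 8.3145*293*1e-3 MPa ml/mEq
  expect_equal(donnan_pressure(0.2, p), 0.1475213, tolerance = 1e-6)
  # strictly increasing on a grid
  dpi <- donnan_pressure(seq(0, 0.4, by = 0.01), p)
  expect_true(all(diff(dpi) > 0))
  expect_error(donnan_pressure(-0.1, p), "non-negative")
})

test_that("chemical expansion stress follows its closed form", {
  p0 <- material_params()                        # a0 = 0: disabled
  expect_identical(chemical_expansion_stress(0.2, p0), 0 * 0.2)
  pa <- material_params(a0 = 0.1, kappa = 0)
  expect_identical(chemical_expansion_stress(0, pa), 0)
  expect_equal(chemical_expansion_stress(0.2, pa), 0.02)
  # kappa > 0 attenuates
  pk <- material_params(a0 = 0.1, kappa = 2)
  expect_lt(chemical_expansion_stress(0.2, pk), 0.02)
})

test_that("total stress equals the sum of its independent terms", {
  p <- material_params(a0 = 0.05, kappa = 1)
  kg <- bulk_shear_moduli(p$E_nf, p$nu_nf)
  set.seed(7)
  for (i in 1:100) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.04), 3, 3)
    if (det(F) <= 0) next
    dirs <- list(dir = rbind(c(1, 0, 0), c(0, 1, 0)),
                 primary = c(TRUE, FALSE))
    st <- material_point_state(F = F, c_FCD = runif(1, 0, 0.3),
                               rho_z = runif(1, 0.5, 1.5),
                               fibril_dirs = dirs, p = rnorm(1, 0, 0.1))
    want <- fibril_network_stress(st, p) +
      nonfibrillar_stress(F, kg[["K_nf"]], kg[["G_nf"]]) -
      (donnan_pressure(st$c_FCD, p) +
         chemical_expansion_stress(st$c_FCD, p) + st$p) * diag(3)
    got <- total_stress(st, p)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-12)
  }
  # everything off -> zero stress
  st0 <- material_point_state()
  expect_equal(total_stress(st0, material_params()), matrix(0, 3, 3))
})

test_that("Darcy flux and fluid velocity satisfy the void-ratio relation", {
  out <- darcy_velocity(c(0, 0), 1.3e-3, 5)
  expect_identical(out$q, c(0, 0))
  expect_identical(out$v_fl, c(0, 0))

  e <- void_ratio(0.85, 0.15)
  expect_equal(e, 5.6667, tolerance = 1e-4)
  out <- darcy_velocity(c(0.2, -0.1), 1.3e-3, e)
  expect_equal(out$v_fl, out$q * 1.17647, tolerance = 1e-4)
  expect_true(all(abs(out$v_fl) > abs(out$q)))
  expect_error(darcy_velocity(c(1, 0), 1.3e-3, 0), "positive")
})

test_that("permeability unit conversion m^4 -> mm^4 is 1e12", {
  # 1.3e-15 m^4/(N s) expressed in the internal mm-N-s system
  expect_equal(1.3e-15 * 1e12, 1.3e-3)
  expect_equal(material_params()$k, 1.3e-3)
})
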