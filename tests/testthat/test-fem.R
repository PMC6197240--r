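test_that("strain invariants match their closed forms and are frame
           invariant", {
  hyd <- strain_invariants(0.2 * diag(3))
  expect_equal(hyd$eps_dev, 0)
  expect_equal(hyd$eps_shr, 0)

  uni <- strain_invariants(diag(c(0.3, 0, 0)))
  expect_equal(uni$eps_dev, 0.1414214, tolerance = 1e-6)
  expect_equal(uni$eps_shr, 0.3)

  expect_error(strain_invariants(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)),
               "symmetric")

  set.seed(3)
  for (i in 1:50) {
    A <- matrix(rnorm(9), 3, 3); E <- (A + t(A)) / 2
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    a <- strain_invariants(E)
    b <- strain_invariants(Q %*% E %*% t(Q))
    expect_equal(a$eps_dev, b$eps_dev, tolerance = 1e-10)
    expect_equal(a$eps_shr, b$eps_shr, tolerance = 1e-10)
  }
})

test_that("haversine protocol peaks at half period", {
  pr <- loading_protocol(amplitude = 0.15, frequency = 1)
  expect_equal(protocol_strain(pr, 0), 0)
  expect_equal(protocol_strain(pr, 0.5), 0.15)
  expect_equal(protocol_strain(pr, 1), 0, tolerance = 1e-12)
  expect_error(loading_protocol(dt = 0.2), "dt too coarse")
  expect_error(loading_protocol(amplitude = 0.6))
})

test_that("free swelling: no FCD means no deformation", {
  m <- coarse_intact()
  comp <- linear_comp(m)
  st <- solve_free_swelling(m, comp, material_params())
  expect_lt(max(abs(st$d)), 1e-10)
})

test_that("uniform swelling block matches the single-point oracle", {
  p <- material_params()
  m <- build_explant_mesh(radius = 0.5, thickness = 0.5, target_h = 0.125)
  comp <- composition_field(m, p)
  c0 <- 0.2; n0 <- 0.8
  comp$c_fcd0[] <- c0
  comp$n_fl0[] <- n0
  comp$fib[, 4] <- 0                       # no fibrils
  st <- solve_free_swelling(m, comp, p)
  f <- fem_fields(st$sys, st$d)

  # oracle: isotropic stress balance K ln(J)/J = dpi(c0 n0/(J - ns0))
  kg <- bulk_shear_moduli(p$E_nf, p$nu_nf)
  bal <- function(J) kg[["K_nf"]] * log(J) / J -
    donnan_pressure(c0 * n0 / (J - (1 - n0)), p)
  J_star <- uniroot(bal, c(1.0001, 3))$root
  expect_gt(J_star, 1)
  expect_equal(mean(f$J), J_star, tolerance = 1e-3)
  expect_lt(max(abs(f$J - J_star)), 1e-3 * J_star)
  # interior total stress vanishes at free equilibrium
  expect_lt(max(abs(c(f$sxx, f$syy, f$szz))), 1e-6)

  # doubling FCD swells more
  comp$c_fcd0[] <- 2 * c0
  st2 <- solve_free_swelling(m, comp, p)
  expect_gt(mean(fem_fields(st2$sys, st2$d)$J), mean(f$J))
})

test_that("swollen explant expands where FCD is positive", {
  m <- coarse_intact()
  p <- material_params()
  st <- solve_free_swelling(m, composition_field(m, p), p)
  f <- fem_fields(st$sys, st$d)
  # weakly-charged superficial points can be slightly compressed by their
  # swelling neighbours; well-charged tissue must expand
  expect_true(all(f$J[f$c_fcd > 0.05] > 1))
  expect_gt(mean(f$J), 1)
  expect_lt(st$resnorm, 1e-6)
})

test_that("dynamic cycling drains correctly and settles to periodicity", {
  m <- coarse_intact()
  p <- material_params()
  st <- solve_free_swelling(m, composition_field(m, p), p)
  hist <- solve_dynamic_cycles(st, short_protocol(n_cycles = 4))
  hist3 <- solve_dynamic_cycles(st, short_protocol(n_cycles = 3))

  # peak forces ride a slowly decaying consolidation transient: the
  # cycle-to-cycle drift must shrink monotonically toward periodicity
  pf <- hist$peak_force
  drift <- abs(diff(pf)) / pf[-1]
  expect_true(all(diff(drift) < 0))
  expect_lt(drift[3], 0.05)
  expect_gt(min(pf), 0)

  # what the degeneration criteria consume - the per-point cycle maxima
  # of the strain fields - is already stable to < 2% per cycle
  expect_lt(max(abs(hist$max_eps_dev - hist3$max_eps_dev)) /
              max(hist$max_eps_dev), 0.02)
  expect_lt(max(abs(hist$max_eps_shr - hist3$max_eps_shr)) /
              max(hist$max_eps_shr), 0.02)

  # draining boundaries stay at ambient pressure
  drain <- boundary_nodes(m, "free_lateral")
  expect_lt(max(abs(hist$d[3 * (drain - 1) + 3])), 1e-12)

  # intact explant: peak fluid velocity on the free lateral boundary
  gp <- mesh_gp_coords(m)
  i <- which.max(hist$max_v_fl)
  expect_gt(gp[i, 1], m$radius - 2 * m$target_h)

  # static hold: fluid velocity decays to nothing
  hold <- solve_dynamic_cycles(st, loading_protocol(amplitude = 1e-9,
                                                    n_cycles = 1,
                                                    dt = 0.05))
  expect_lt(max(hold$max_v_fl), 1e-6)
})

test_that("a crack concentrates fluid velocity on the lesion surface", {
  p <- material_params()
  m <- build_explant_mesh(cracks = list(crack_spec(0.75, 0.4, 0.2)),
                          target_h = 0.12)
  st <- solve_free_swelling(m, composition_field(m, p), p)
  hist <- solve_dynamic_cycles(st, short_protocol(2))
  gp <- mesh_gp_coords(m)
  les <- boundary_nodes(m, "lesion_surface")
  dles <- apply(gp, 1, function(pt)
    sqrt(min((pt[1] - m$nodes[les, 1])^2 + (pt[2] - m$nodes[les, 2])^2)))
  near <- dles < 0.2
  expect_gt(max(hist$max_v_fl[near]), 0.04)
  expect_gt(max(hist$max_v_fl[near]), 2 * max(hist$max_v_fl[gp[, 1] < 0.4]))
})

test_that("fluid mass is conserved at free-swelling equilibrium", {
  m <- coarse_intact()
  p <- material_params()
  st <- solve_free_swelling(m, composition_field(m, p), p)
  # at drained equilibrium the pressure field is ambient: all fluxes vanish
  f <- fem_fields(st$sys, st$d)
  expect_lt(max(abs(c(f$qx, f$qy))), 1e-12)
})

test_that("gauss-point stresses agree with the material-level API", {
  # homogeneous affine deformation imposed on a small patch: the compiled
  # kernel and the R constitutive functions must agree componentwise
  p <- material_params()
  m <- build_explant_mesh(radius = 0.4, thickness = 0.4, target_h = 0.2,
                          formulation = "plane_strain")
  comp <- composition_field(m, p, arrangement = "parallel_to_surface")
  c0 <- 0.15; n0 <- 0.8; rho <- 1.1
  comp$c_fcd0[] <- c0; comp$n_fl0[] <- n0
  comp$fib[, 4] <- comp$fib[, 4] / rep(comp$rho_z, each = comp$ndir) * rho
  sys <- fem_system(m, comp, p)

  A <- matrix(c(1.05, 0.02, -0.01, 0.94), 2, 2)   # in-plane F
  pconst <- 0.07
  d <- numeric(sys$ndof)
  for (n in seq_len(nrow(m$nodes))) {
    u <- (A - diag(2)) %*% m$nodes[n, ]
    d[3 * n - 2] <- u[1]; d[3 * n - 1] <- u[2]; d[3 * n] <- pconst
  }
  f <- fem_fields(sys, d)

  F3 <- rbind(cbind(A, 0), c(0, 0, 1))
  J <- det(F3)
  c_cur <- c0 * n0 / (J - (1 - n0))
  th <- (0:7) * pi / 8
  dirs <- list(dir = rbind(c(1, 0, 0), cbind(cos(th), sin(th), 0),
                           c(0, 0, 1)),
               primary = c(TRUE, rep(FALSE, 9)))
  st <- material_point_state(F = F3, c_FCD = c_cur, n_fl = n0,
                             rho_z = rho, fibril_dirs = dirs, p = pconst)
  want <- total_stress(st, p)
  expect_equal(f$sxx, rep(want[1, 1], nrow(f)), tolerance = 1e-10)
  expect_equal(f$syy, rep(want[2, 2], nrow(f)), tolerance = 1e-10)
  expect_equal(f$sxy, rep(want[1, 2], nrow(f)), tolerance = 1e-10)
  expect_equal(f$szz, rep(want[3, 3], nrow(f)), tolerance = 1e-10)
  expect_equal(f$J, rep(J, nrow(f)), tolerance = 1e-12)
})

test_that("probe strain converges under mesh refinement", {
  p <- material_params()
  probe <- function(mesh) {
    st <- solve_free_swelling(mesh, composition_field(mesh, p), p)
    hist <- solve_dynamic_cycles(st, loading_protocol(n_cycles = 1,
                                                      dt = 0.05))
    gp <- mesh_gp_coords(mesh)
    # mean cycle-maximum deviatoric strain in a fixed material disk
    sel <- (gp[, 1] - 0.75)^2 + (gp[, 2] - 0.5)^2 < 0.2^2
    mean(hist$max_eps_dev[sel])
  }
  m1 <- build_explant_mesh(target_h = 0.15)
  m2 <- refine_mesh(m1)
  v1 <- probe(m1); v2 <- probe(m2)
  expect_lt(abs(v2 - v1) / abs(v2), 0.02)
})
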