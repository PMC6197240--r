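test_that("depth profiles reproduce the printed polynomials", {
  d0 <- depth_profiles(0)
  expect_equal(d0$n_fl, 0.85)
  expect_equal(d0$c_FCD, 0.03)
  expect_equal(d0$rho_z, 0.96)
  d1 <- depth_profiles(1)
  expect_equal(d1$n_fl, 0.70)
  expect_equal(d1$c_FCD, 0.03, tolerance = 1e-12)
  expect_equal(d1$rho_z, 1.16, tolerance = 1e-12)
  expect_error(depth_profiles(1.2), "\\[0, 1\\]")
  expect_error(depth_profiles(-0.1), "\\[0, 1\\]")

  # independent power-basis evaluation on a grid
  h <- seq(0, 1, length.out = 1000)
  cf <- c(0.03, 1.1, -5.8, 14.9, -21.0, 15.2, -4.4)
  rf <- c(0.96, -1.6, 13.4, -45.9, 78.1, -64.4, 20.6)
  want_c <- as.vector(outer(h, 0:6, `^`) %*% cf)
  want_r <- as.vector(outer(h, 0:6, `^`) %*% rf)
  d <- depth_profiles(h)
  expect_equal(d$c_FCD, want_c, tolerance = 1e-13)
  expect_equal(d$rho_z, want_r, tolerance = 1e-13)
})

test_that("intact mesh is a tagged rectangle without lesions", {
  m <- build_explant_mesh(radius = 1.5, thickness = 1, target_h = 0.2)
  expect_setequal(unique(m$edges$tag),
                  c("platen_top", "bottom", "free_lateral",
                    "symmetry_axis"))
  expect_equal(sum(.elem_areas(m$nodes, m$elems)), 1.5, tolerance = 1e-10)
  # element count grows monotonically as the target size decreases
  ns <- vapply(c(0.3, 0.2, 0.1), function(h)
    nrow(build_explant_mesh(target_h = h)$elems), numeric(1))
  expect_true(all(diff(ns) > 0))
})

test_that("v-notch cracks are meshed conformingly", {
  cr <- crack_spec(0.75, 0.3, 0.2)
  m <- build_explant_mesh(cracks = list(cr), target_h = 0.1)
  les <- m$edges[m$edges$tag == "lesion_surface", ]
  expect_gt(nrow(les), 0)
  lnode <- unique(c(les$n1, les$n2))
  # notch tip reaches the prescribed depth
  expect_equal(min(m$nodes[lnode, 2]), 1 - 0.3, tolerance = 0.1)
  # cross-section area = rectangle minus the triangular notch
  expect_equal(sum(.elem_areas(m$nodes, m$elems)),
               1.5 - 0.5 * 0.2 * 0.3, tolerance = 1e-9)
  # lesion edges form one connected open curve starting at the surface
  adj <- table(c(les$n1, les$n2))
  expect_equal(sum(adj == 1), 2)          # exactly two end points
  expect_true(all(adj <= 2))
  expect_equal(max(m$nodes[lnode, 2]), 1) # reaches the top surface
})

test_that("parallel-walled cracks remove the notch area", {
  cr <- crack_spec(0.75, 0.3, 0.2, profile = "parallel-walled")
  m <- build_explant_mesh(cracks = list(cr), target_h = 0.1)
  expect_equal(sum(.elem_areas(m$nodes, m$elems)), 1.5 - 0.2 * 0.3,
               tolerance = 1e-9)
  expect_gt(sum(m$edges$tag == "lesion_surface"), 0)
})

test_that("degenerate crack specifications are rejected", {
  expect_error(build_explant_mesh(cracks = list(crack_spec(0.7, 1.2, 0.2))),
               "depth")
  expect_error(build_explant_mesh(cracks = list(crack_spec(1.45, 0.3, 0.2))),
               "mouth")
  expect_error(crack_spec(0.7, -0.1, 0.2))
})

test_that("fibril architecture follows the arrangement keyword", {
  m <- build_explant_mesh(target_h = 0.1)
  gp <- mesh_gp_coords(m)
  h <- (m$thickness - gp[, 2]) / m$thickness

  par <- fibril_architecture(m, "parallel_to_surface")
  expect_true(all(par$angle == 0))
  per <- fibril_architecture(m, "perpendicular")
  expect_true(all(per$angle == pi / 2))

  arc <- fibril_architecture(m, "arcade")
  expect_true(all(arc$angle[h < 0.14] == 0))          # superficial zone
  expect_true(all(arc$angle[h > 0.41] == pi / 2))     # deep zone
  mid <- h > 0.16 & h < 0.39
  expect_true(all(arc$angle[mid] > 0 & arc$angle[mid] < pi / 2))

  # every direction is a unit vector
  expect_equal(rowSums(arc$dirs^2), rep(1, nrow(arc$dirs)),
               tolerance = 1e-12)
  expect_error(fibril_architecture(m, "spiral"))

  iso <- fibril_architecture(m, "isotropic")
  expect_true(all(is.na(iso$angle)))
})

test_that("composition integrals are stable under refinement", {
  p <- material_params()
  m1 <- build_explant_mesh(target_h = 0.2)
  m2 <- refine_mesh(m1)
  int_fcd <- function(m) {
    comp <- composition_field(m, p)
    a <- rep(.elem_areas(m$nodes, m$elems) / 4, each = 4)
    sum(comp$c_fcd0 * a)
  }
  expect_equal(int_fcd(m1), int_fcd(m2), tolerance = 0.01)
})

test_that("optical density profiles convert to FCD polynomials", {
  cf <- c(0.03, 1.1, -5.8, 14.9, -21.0, 15.2, -4.4)
  h <- seq(0, 1, length.out = 40)
  od <- as.vector(outer(h, 0:6, `^`) %*% cf)
  m_true <- sum(cf / (1:7))

  # fixed point: a polynomial profile with its own mean is returned intact
  got <- od_profile_to_fcd(data.frame(h = h, od = od), m_true)
  expect_equal(got, cf, tolerance = 1e-6)

  # constant profile maps to the target constant
  gotc <- od_profile_to_fcd(data.frame(h = h, od = rep(2.5, 40)), 0.1)
  expect_equal(gotc[1], 0.1, tolerance = 1e-8)
  expect_equal(gotc[-1], rep(0, 6), tolerance = 1e-8)

  # regression recovery from 1% noise
  set.seed(11)
  odn <- od * (1 + rnorm(length(od), sd = 0.01))
  gotn <- od_profile_to_fcd(data.frame(h = h, od = odn), m_true)
  hg <- seq(0, 1, length.out = 200)
  fit <- as.vector(outer(hg, 0:6, `^`) %*% gotn)
  ref <- as.vector(outer(hg, 0:6, `^`) %*% cf)
  rms <- sqrt(mean((fit - ref)^2))
  expect_lt(rms, 0.02 * diff(range(ref)))

  expect_error(od_profile_to_fcd(data.frame(h = h[1:5], od = od[1:5]), 0.1),
               "7 depth samples")
})
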