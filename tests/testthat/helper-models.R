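# Shared fixtures: small meshes and parameter sets built in code.

tab_params <- function(...) material_params(...)

# coarse intact explant used by several FE tests
coarse_intact <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_explant_mesh(target_h = 0.15)
    cache
  }
})

# the package's default injured-explant geometry: two surface cracks
# (~2 cracks/sample), one mid-surface and one peripheral
default_cracks <- function() default_injured_cracks()

short_protocol <- function(n_cycles = 2) {
  loading_protocol(amplitude = 0.15, frequency = 1, n_cycles = n_cycles,
                   dt = 0.025)
}

# composition with swelling and fibrils switched off and uniform porosity:
# the linear poroelastic limit used by the consolidation benchmarks
linear_comp <- function(mesh, n_fl = 0.8) {
  comp <- composition_field(mesh, material_params())
  comp$c_fcd0[] <- 0
  comp$n_fl0[] <- n_fl
  comp$fib[, 4] <- 0
  comp
}

# independent series solution for 1D consolidation (step load, single
# drainage): normalized excess pressure at normalized depth z from the
# drained face, time factor Tv
terzaghi_series <- function(z, Tv, nterm = 300) {
  m <- 0:nterm
  M <- (2 * m + 1) * pi / 2
  vapply(z, function(zz)
    sum(2 / M * sin(M * zz) * exp(-M^2 * Tv)), numeric(1))
}

# consistent nodal loads for a uniform vertical traction on tagged edges
# (plane strain, per unit out-of-plane thickness)
traction_loads <- function(mesh, sys, tag, sigma) {
  fext <- numeric(sys$ndof)
  te <- mesh$edges[mesh$edges$tag == tag, ]
  for (i in seq_len(nrow(te))) {
    len <- abs(mesh$nodes[te$n1[i], 1] - mesh$nodes[te$n2[i], 1])
    fext[3 * (te$n1[i] - 1) + 2] <- fext[3 * (te$n1[i] - 1) + 2] -
      sigma * len / 2
    fext[3 * (te$n2[i] - 1) + 2] <- fext[3 * (te$n2[i] - 1) + 2] -
      sigma * len / 2
  }
  fext
}

dof_of <- function(node, comp) 3L * (node - 1L) + comp
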