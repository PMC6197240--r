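#' Cyclic unconfined-compression loading protocol
#'
#' Displacement-controlled haversine compression applied at the platen:
#' `eps(t) = amplitude * sin(pi f t)^2` (zero at cycle start, peak at half
#' period), mimicking the physiological "walking" protocol (15% amplitude
#' at 1 Hz).
#'
#' @param amplitude strain amplitude as a fraction of (swollen) thickness
#' @param frequency loading frequency, Hz
#' @param n_cycles number of cycles simulated per adaptive iteration; the
#'   degeneration criteria are evaluated on the final cycle once the
#'   response is periodic
#' @param dt implicit time step, s (must resolve the cycle: `dt <= 1/(20 f)`)
#' @param pre_strain static offset strain applied before cycling (the
#'   experimental "light contact" is taken as zero offset)
#' @return object of class `loading_protocol`
#' @export
loading_protocol <- function(amplitude = 0.15, frequency = 1,
                             n_cycles = 3, dt = 0.025, pre_strain = 0) {
  stopifnot(amplitude >= 0, amplitude < 0.5, frequency > 0, n_cycles >= 1,
            pre_strain >= 0)
  if (dt > 1 / (20 * frequency))
    stop("dt too coarse: need dt <= 1/(20*frequency) to resolve the cycle")
  p <- list(amplitude = amplitude, frequency = frequency,
            n_cycles = n_cycles, dt = dt, pre_strain = pre_strain,
            waveform = "haversine")
  class(p) <- "loading_protocol"
  p
}

#' Platen strain history of a protocol
#' @param protocol a [loading_protocol()]
#' @param t time, s (vectorized)
#' @return compressive strain fraction at time `t`
#' @export
protocol_strain <- function(protocol, t) {
  protocol$pre_strain +
    protocol$amplitude * sin(pi * protocol$frequency * t)^2
}

.default_control <- function(control = list()) {
  modifyList(list(rtol = 1e-6, atol = 5e-7, max_newton = 30,
                  alpha_stab = 0.1, ramp_steps = 5, verbose = FALSE),
             control)
}

#' Assembled FE system for a mesh + composition + material
#'
#' Precomputes the arrays consumed by the compiled element kernel.  The
#' returned object is reused across time steps and Newton iterations.
#'
#' @param mesh an [build_explant_mesh()] mesh
#' @param comp a [composition_field()]
#' @param params a [material_params()]
#' @param control solver control overrides (`rtol`, `atol`, `max_newton`,
#'   `alpha_stab` for the equal-order pressure stabilization)
#' @return object of class `fem_system`
#' @export
fem_system <- function(mesh, comp, params, control = list()) {
  control <- .default_control(control)
  kg <- bulk_shear_moduli(params$E_nf, params$nu_nf)
  pars <- c(params$E_f, kg[["K_nf"]], kg[["G_nf"]], params$k, params$c_ext,
            rt_constant(params), params$phi_int, params$phi_ext,
            params$gamma_ext / params$gamma_int, params$a0, params$kappa,
            control$alpha_stab)
  sys <- list(mesh = mesh, comp = comp, params = params, pars = pars,
              nodes = mesh$nodes,
              elems = matrix(as.integer(mesh$elems), ncol = 4),
              ndof = 3L * nrow(mesh$nodes),
              axisym = as.integer(mesh$formulation == "axisymmetric"),
              control = control)
  class(sys) <- "fem_system"
  sys
}

.sys_assemble <- function(sys, d, d_old, dt, swell = 1, want_K = TRUE) {
  .assemble_up(sys$nodes, sys$elems, d, d_old, dt, sys$comp$c_fcd0,
               sys$comp$n_fl0, sys$comp$fib, sys$comp$ndir, sys$pars,
               sys$axisym, swell, want_K)
}

#' Gauss-point field extraction
#'
#' Evaluates per-integration-point kinematic and flow fields at a solved
#' state: total volume ratio `J`, current FCD, Donnan pressure, pore
#' pressure, Hencky principal strains, deviatoric and maximum shear strain,
#' Darcy flux, interstitial fluid velocity and total Cauchy stress.
#'
#' @param sys a [fem_system()]
#' @param d,d_old current and previous dof vectors
#' @param dt time step used for rate terms, s
#' @param swell swelling ramp factor (1 = full osmotic pressure)
#' @return data.frame, one row per integration point (element-major)
#' @export
fem_fields <- function(sys, d, d_old = d, dt = 1, swell = 1) {
  m <- .gp_fields(sys$nodes, sys$elems, d, d_old, dt, sys$comp$c_fcd0,
                  sys$comp$n_fl0, sys$comp$fib, sys$comp$ndir, sys$pars,
                  sys$axisym, swell)
  df <- as.data.frame(m)
  df$v_mag <- sqrt(df$vx^2 + df$vy^2)
  df
}

#' One Newton solve of the coupled u-p system
#'
#' Total-Lagrangian Newton iteration with backtracking line search on the
#' residual norm.  Dirichlet constraints are imposed by elimination.
#'
#' @param sys a [fem_system()]
#' @param d initial guess (length `sys$ndof`)
#' @param d_old converged dofs of the previous time step
#' @param dt time step, s
#' @param fixed_dofs integer dof indices held fixed
#' @param fixed_vals their prescribed values
#' @param swell swelling ramp factor
#' @return list with `d`, `converged`, `iters`, `resnorm`, and the full
#'   residual `R` (reactions at fixed dofs)
#' @export
fem_newton <- function(sys, d, d_old, dt, fixed_dofs, fixed_vals,
                       swell = 1) {
  ctl <- sys$control
  d[fixed_dofs] <- fixed_vals
  free <- setdiff(seq_len(sys$ndof), fixed_dofs)
  nr0 <- NA_real_
  out <- NULL
  for (it in seq_len(ctl$max_newton)) {
    out <- .sys_assemble(sys, d, d_old, dt, swell, want_K = TRUE)
    Rf <- out$R[free]
    nr <- sqrt(sum(Rf^2))
    if (it == 1) nr0 <- max(nr, ctl$atol)
    if (ctl$verbose)
      message(sprintf("    newton %d: |R| = %.3e", it, nr))
    if (nr < max(ctl$rtol * nr0, ctl$atol))
      return(list(d = d, converged = TRUE, iters = it, resnorm = nr,
                  R = out$R))
    K <- Matrix::sparseMatrix(i = out$i, j = out$j, x = out$x,
                              dims = c(sys$ndof, sys$ndof))
    dx <- as.numeric(Matrix::solve(K[free, free], -Rf))
    step <- 1
    repeat {
      d_try <- d
      d_try[free] <- d[free] + step * dx
      r2 <- tryCatch(.sys_assemble(sys, d_try, d_old, dt, swell,
                                   want_K = FALSE)$R[free],
                     error = function(e) NULL)
      nr2 <- if (is.null(r2)) Inf else sqrt(sum(r2^2))
      if (nr2 < (1 - 1e-4 * step) * nr || step <= 1 / 32) break
      step <- step / 2
    }
    if (!is.finite(nr2))
      return(list(d = d, converged = FALSE, iters = it, resnorm = nr,
                  R = out$R,
                  diagnostic = "line search hit an inverted configuration"))
    d <- d_try
  }
  list(d = d, converged = FALSE, iters = ctl$max_newton, resnorm = nr,
       R = out$R, diagnostic = sprintf("no convergence, last |R| = %.3e", nr))
}

.node_dofs <- function(nodes, comp) 3L * (nodes - 1L) + comp

#' Free-swelling equilibrium
#'
#' Solves the static Donnan-swelling equilibrium with zero external
#' traction: the pore pressure (chemical potential) is zero everywhere at
#' drained equilibrium, so all pressure dofs are fixed at the ambient value
#' and the osmotic prestress is ramped up in load steps.  Where FCD is
#' positive the tissue expands (`J > 1`).
#'
#' @param mesh,comp,params model definition as in [fem_system()]
#' @param control solver control list
#' @return object of class `fem_state`: converged dof vector `d`, the
#'   system, and convergence diagnostics
#' @export
solve_free_swelling <- function(mesh, comp, params, control = list()) {
  sys <- fem_system(mesh, comp, params, control)
  ctl <- sys$control
  nn <- nrow(mesh$nodes)
  fixed <- c(.node_dofs(seq_len(nn), 3L),
             .node_dofs(boundary_nodes(mesh, "bottom"), 2L),
             .node_dofs(boundary_nodes(mesh, "symmetry_axis"), 1L))
  fixed <- sort(unique(fixed))
  vals <- numeric(length(fixed))
  d <- numeric(sys$ndof)
  sw_done <- 0
  sol <- NULL
  while (sw_done < 1 - 1e-12) {
    dsw <- min(1 / ctl$ramp_steps, 1 - sw_done)
    sol <- fem_newton(sys, d, d_old = d, dt = 1, fixed, vals,
                      swell = sw_done + dsw)
    if (sol$converged) {
      sw_done <- sw_done + dsw
      d <- sol$d
    } else {
      # refine the osmotic load ramp before giving up
      ctl$ramp_steps <- ctl$ramp_steps * 2
      sys$control <- ctl
      if (ctl$ramp_steps > 64)
        stop("free-swelling step did not converge at ramp factor ",
             sw_done + dsw, ": ", sol$diagnostic)
    }
  }
  st <- list(d = d, sys = sys, mesh = mesh, comp = comp, params = params,
             swell = 1, iters = sol$iters, resnorm = sol$resnorm)
  class(st) <- "fem_state"
  st
}

#' @export
print.fem_state <- function(x, ...) {
  f <- fem_fields(x$sys, x$d)
  cat(sprintf("fem_state: %d dofs, mean J = %.4f, |R| = %.2e\n",
              length(x$d), mean(f$J), x$resnorm))
  invisible(x)
}

#' Generic transient u-p marching
#'
#' Backward-Euler implicit marching with time-dependent Dirichlet data and
#' optional external nodal forces.  Building block for the cyclic
#' compression, stress-relaxation and consolidation solvers.
#'
#' @param sys a [fem_system()]
#' @param d0 initial dof vector (typically a converged equilibrium)
#' @param times strictly increasing time grid, s (initial state at
#'   `times[1] - dt0` is `d0`; each entry is solved implicitly)
#' @param dirichlet function(t) returning `list(dofs, vals)`
#' @param forces optional function(t) returning an external nodal force
#'   vector (length `ndof`)
#' @param on_step optional callback `function(step, t, d, d_old, R)` whose
#'   return values are collected in the output `steps` list
#' @return list with final `d`, convergence flag, and `steps`
#' @export
solve_up_transient <- function(sys, d0, times, dirichlet, forces = NULL,
                               on_step = NULL) {
  # one implicit step t_prev -> t, bisecting the interval (up to 3 levels)
  # if Newton fails on a softened/distorted configuration
  advance <- function(d_prev, t_prev, t, depth) {
    bc <- dirichlet(t)
    guess <- d_prev
    guess[bc$dofs] <- bc$vals
    sol <- if (!is.null(forces))
      .newton_with_force(sys, guess, d_prev, t - t_prev, bc$dofs, bc$vals,
                         forces(t))
    else
      fem_newton(sys, guess, d_prev, t - t_prev, bc$dofs, bc$vals)
    if (sol$converged) return(sol)
    if (depth >= 3) return(sol)
    tm <- (t_prev + t) / 2
    mid <- advance(d_prev, t_prev, tm, depth + 1)
    if (!mid$converged) return(mid)
    advance(mid$d, tm, t, depth + 1)
  }

  d <- d0
  out <- vector("list", length(times))
  tprev <- if (length(times) > 1) times[1] - diff(times)[1] else times[1] - 1
  for (i in seq_along(times)) {
    t <- times[i]
    sol <- advance(d, tprev, t, 0)
    if (!sol$converged)
      return(list(d = d, converged = FALSE, step_failed = i, time = t,
                  steps = out[seq_len(i - 1)],
                  diagnostic = sol$diagnostic))
    if (!is.null(on_step))
      out[[i]] <- on_step(i, t, sol$d, d, sol$R)
    d <- sol$d
    tprev <- t
  }
  list(d = d, converged = TRUE, steps = out)
}

# Newton with a constant external force vector added to the residual
.newton_with_force <- function(sys, d, d_old, dt, fixed_dofs, fixed_vals,
                               fext) {
  ctl <- sys$control
  d[fixed_dofs] <- fixed_vals
  free <- setdiff(seq_len(sys$ndof), fixed_dofs)
  nr0 <- NA_real_
  out <- NULL
  for (it in seq_len(ctl$max_newton)) {
    out <- .sys_assemble(sys, d, d_old, dt, 1, want_K = TRUE)
    Rtot <- out$R - fext
    Rf <- Rtot[free]
    nr <- sqrt(sum(Rf^2))
    if (it == 1) nr0 <- max(nr, ctl$atol, sqrt(sum(fext^2)))
    if (nr < max(ctl$rtol * nr0, ctl$atol))
      return(list(d = d, converged = TRUE, iters = it, resnorm = nr,
                  R = Rtot))
    K <- Matrix::sparseMatrix(i = out$i, j = out$j, x = out$x,
                              dims = c(sys$ndof, sys$ndof))
    dx <- as.numeric(Matrix::solve(K[free, free], -Rf))
    step <- 1
    repeat {
      d_try <- d
      d_try[free] <- d[free] + step * dx
      r2 <- tryCatch(.sys_assemble(sys, d_try, d_old, dt, 1,
                                   want_K = FALSE)$R[free] - fext[free],
                     error = function(e) NULL)
      nr2 <- if (is.null(r2)) Inf else sqrt(sum(r2^2))
      if (nr2 < (1 - 1e-4 * step) * nr || step <= 1 / 32) break
      step <- step / 2
    }
    d <- d_try
  }
  list(d = d, converged = FALSE, iters = ctl$max_newton, resnorm = nr,
       R = out$R - fext,
       diagnostic = sprintf("no convergence, last |R| = %.3e", nr))
}

#' Cyclic unconfined compression on a swollen explant
#'
#' Applies the displacement-controlled haversine protocol to a converged
#' free-swelling state.  Boundary conditions: prescribed axial displacement
#' at the platen with free radial sliding (frictionless, impermeable
#' platen), zero axial displacement at the (frictionless, impermeable)
#' bottom, symmetry on the axis, and ambient pressure (free draining) on
#' the free lateral and lesion surfaces.
#'
#' @param state a [solve_free_swelling()] result
#' @param protocol a [loading_protocol()]
#' @param store_fields if `TRUE`, keep the full Gauss-point field table of
#'   every step of the final cycle
#' @return object of class `solution_history`: per-point cycle maxima
#'   (`eps_dev`, `eps_shr`, `v_mag`) over the final cycle, platen reaction
#'   force record, and the final dof vector
#' @export
solve_dynamic_cycles <- function(state, protocol = loading_protocol(),
                                 store_fields = FALSE) {
  sys <- state$sys
  mesh <- state$mesh
  platen <- boundary_nodes(mesh, "platen_top")
  bottom <- boundary_nodes(mesh, "bottom")
  symax <- boundary_nodes(mesh, "symmetry_axis")
  drain <- boundary_nodes(mesh, c("free_lateral", "lesion_surface"))

  uy_sw <- state$d[.node_dofs(platen, 2L)]
  h_sw <- mean(mesh$nodes[platen, 2] + uy_sw)

  fixed0 <- c(.node_dofs(bottom, 2L), .node_dofs(symax, 1L),
              .node_dofs(drain, 3L))
  vals0 <- numeric(length(fixed0))
  pdofs <- .node_dofs(platen, 2L)

  dirichlet <- function(t) {
    eps <- protocol_strain(protocol, t)
    list(dofs = c(fixed0, pdofs),
         vals = c(vals0, uy_sw - eps * h_sw))
  }

  nsteps <- round(protocol$n_cycles / (protocol$frequency * protocol$dt))
  times <- seq_len(nsteps) * protocol$dt
  final_start <- (protocol$n_cycles - 1) / protocol$frequency - 1e-9

  ngp <- 4L * nrow(mesh$elems)
  mx_dev <- numeric(ngp); mx_shr <- numeric(ngp); mx_v <- numeric(ngp)
  force <- numeric(nsteps)
  peak_force <- numeric(protocol$n_cycles)
  fields <- if (store_fields) list() else NULL

  on_step <- function(i, t, d, d_old, R) {
    force[i] <<- -sum(R[pdofs])
    if (t > final_start) {
      f <- fem_fields(sys, d, d_old, dt = protocol$dt)
      mx_dev <<- pmax(mx_dev, f$eps_dev)
      mx_shr <<- pmax(mx_shr, f$eps_shr)
      mx_v <<- pmax(mx_v, f$v_mag)
      if (store_fields) fields[[length(fields) + 1L]] <<- f
    }
    NULL
  }

  res <- solve_up_transient(sys, state$d, times, dirichlet,
                            on_step = on_step)
  if (!res$converged)
    stop("dynamic cycling diverged at t = ", res$time, " s: ",
         res$diagnostic)
  cyc <- ceiling(times * protocol$frequency - 1e-9)
  for (cy in seq_len(protocol$n_cycles))
    peak_force[cy] <- max(force[cyc == cy])

  hist <- list(max_eps_dev = mx_dev, max_eps_shr = mx_shr,
               max_v_fl = mx_v,
               force = data.frame(time = times, force = force),
               peak_force = peak_force, d = res$d,
               swollen_thickness = h_sw, protocol = protocol,
               # unilateral contact is not modelled: flag net tensile
               # platen reaction (lift-off) instead of resolving it
               liftoff = min(force) < -0.01 * max(abs(force)),
               fields = fields)
  class(hist) <- "solution_history"
  hist
}

#' @export
print.solution_history <- function(x, ...) {
  cat(sprintf(paste0("solution_history: %d integration points\n",
                     "  max eps_dev %.3f, max eps_shr %.3f, ",
                     "max |v_fl| %.4f mm/s\n"),
              length(x$max_eps_dev), max(x$max_eps_dev),
              max(x$max_eps_shr), max(x$max_v_fl)))
  invisible(x)
}

#' Principal strains and strain invariants
#'
#' For a symmetric strain tensor returns the principal strains, the
#' deviatoric strain
#' `eps_dev = (1/3) sqrt((e1-e2)^2 + (e1-e3)^2 + (e2-e3)^2)` and the
#' maximum shear strain `eps_shr = eps_max - eps_min`.
#'
#' @param eps symmetric 3x3 strain tensor
#' @return list with `principal` (descending), `eps_dev`, `eps_shr`
#' @export
strain_invariants <- function(eps) {
  eps <- as.matrix(eps)
  stopifnot(identical(dim(eps), c(3L, 3L)))
  if (max(abs(eps - t(eps))) > 1e-10 * max(1, max(abs(eps))))
    stop("strain tensor must be symmetric")
  ev <- sort(eigen((eps + t(eps)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  list(principal = ev,
       eps_dev = sqrt((ev[1] - ev[2])^2 + (ev[1] - ev[3])^2 +
                      (ev[2] - ev[3])^2) / 3,
       eps_shr = ev[1] - ev[3])
}
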