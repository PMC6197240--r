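#' Stepped stress-relaxation protocol
#'
#' The unconfined compression protocol used to characterize explant
#' mechanics: a 10% pre-strain (200 s ramp, 600 s relaxation) followed by
#' two 2.5% compression-stress-relaxation steps (30 s ramp, 300 s
#' relaxation each).
#'
#' @param pre_strain pre-strain fraction
#' @param pre_ramp,pre_hold pre-strain ramp and relaxation durations, s
#' @param step_strain strain increment of each additional step
#' @param n_steps number of additional steps
#' @param step_ramp,step_hold ramp and relaxation durations per step, s
#' @return object of class `stress_relaxation_protocol`
#' @export
stress_relaxation_protocol <- function(pre_strain = 0.10, pre_ramp = 200,
                                       pre_hold = 600, step_strain = 0.025,
                                       n_steps = 2, step_ramp = 30,
                                       step_hold = 300) {
  stopifnot(pre_ramp > 0, pre_hold > 0, step_ramp > 0, step_hold > 0,
            pre_strain > 0, step_strain >= 0, n_steps >= 0)
  total <- pre_strain + n_steps * step_strain
  if (total >= 0.2)
    stop("cumulative strain must stay below 20%")
  dur <- c(pre_ramp, pre_hold, rep(c(step_ramp, step_hold), n_steps))
  eps0 <- deps <- numeric(length(dur))
  ramp <- rep(c(TRUE, FALSE), 1 + n_steps)
  eps0[1] <- 0; deps[1] <- pre_strain
  eps0[2] <- pre_strain
  for (i in seq_len(n_steps)) {
    eps0[2 * i + 1] <- pre_strain + step_strain * (i - 1)
    deps[2 * i + 1] <- step_strain
    eps0[2 * i + 2] <- pre_strain + step_strain * i
  }
  segs <- data.frame(t0 = cumsum(c(0, dur[-length(dur)])), dur = dur,
                     eps0 = eps0, deps = deps, ramp = ramp)
  p <- list(segments = segs, total_strain = total,
            duration = sum(segs$dur))
  class(p) <- "stress_relaxation_protocol"
  p
}

#' Platen strain of a stress-relaxation protocol at time t
#' @param protocol a [stress_relaxation_protocol()]
#' @param t time, s (vectorized)
#' @return compressive strain fraction
#' @export
relaxation_strain <- function(protocol, t) {
  s <- protocol$segments
  vapply(t, function(ti) {
    i <- findInterval(ti, s$t0, rightmost.closed = FALSE)
    i <- max(1, min(i, nrow(s)))
    frac <- min(1, max(0, (ti - s$t0[i]) / s$dur[i]))
    s$eps0[i] + s$deps[i] * frac
  }, numeric(1))
}

#' Graded time grid for a stress-relaxation protocol
#'
#' Uniform steps on ramps; quadratically stretched steps on relaxation
#' holds (fine right after the ramp, coarse near equilibrium).
#'
#' @param protocol a [stress_relaxation_protocol()]
#' @param n_ramp,n_hold steps per ramp / hold segment
#' @return increasing vector of solve times, s
#' @export
relaxation_time_grid <- function(protocol, n_ramp = 8, n_hold = 12) {
  s <- protocol$segments
  tt <- unlist(lapply(seq_len(nrow(s)), function(i) {
    n <- if (s$ramp[i]) n_ramp else n_hold
    frac <- if (s$ramp[i]) seq_len(n) / n else (seq_len(n) / n)^2
    s$t0[i] + s$dur[i] * frac
  }))
  sort(unique(tt))
}

#' Simulate an unconfined stress-relaxation test
#'
#' Swells the explant to equilibrium, then applies the stepped
#' displacement protocol at the impermeable frictionless platen with free
#' lateral draining, recording the axial platen reaction force.
#'
#' @param params a [material_params()]
#' @param mesh explant mesh (defaults to a coarse calibration mesh)
#' @param protocol a [stress_relaxation_protocol()]
#' @param comp composition field (defaults to the standard depth profiles)
#' @param control FE control list
#' @param n_ramp,n_hold time resolution, see [relaxation_time_grid()]
#' @return `force_record`: data.frame with `time` (s) and `force` (N; per
#'   mm out-of-plane for plane strain, per radian for axisymmetric)
#' @export
simulate_stress_relaxation <- function(params,
                                       mesh = NULL,
                                       protocol =
                                         stress_relaxation_protocol(),
                                       comp = NULL, control = list(),
                                       n_ramp = 8, n_hold = 12) {
  if (is.null(mesh))
    mesh <- build_explant_mesh(target_h = 0.25)
  if (is.null(comp))
    comp <- composition_field(mesh, params)
  st <- solve_free_swelling(mesh, comp, params, control)
  sys <- st$sys
  platen <- boundary_nodes(mesh, "platen_top")
  fixed0 <- c(.node_dofs(boundary_nodes(mesh, "bottom"), 2L),
              .node_dofs(boundary_nodes(mesh, "symmetry_axis"), 1L),
              .node_dofs(boundary_nodes(mesh, c("free_lateral",
                                                "lesion_surface")), 3L))
  vals0 <- numeric(length(fixed0))
  pdofs <- .node_dofs(platen, 2L)
  uy_sw <- st$d[pdofs]
  h_sw <- mean(mesh$nodes[platen, 2] + uy_sw)

  dirichlet <- function(t) {
    eps <- relaxation_strain(protocol, t)
    list(dofs = c(fixed0, pdofs), vals = c(vals0, uy_sw - eps * h_sw))
  }
  times <- relaxation_time_grid(protocol, n_ramp, n_hold)
  force <- numeric(length(times))
  res <- solve_up_transient(sys, st$d, times, dirichlet,
                            on_step = function(i, t, d, d_old, R) {
                              force[i] <<- -sum(R[pdofs])
                              NULL
                            })
  if (!res$converged)
    stop("stress-relaxation simulation diverged at t = ", res$time, " s")
  rec <- data.frame(time = times, force = force)
  class(rec) <- c("force_record", "data.frame")
  rec
}

#' Synthetic stress-relaxation force record
#'
#' Simulates the stress-relaxation response at known parameters and adds
#' multiplicative Gaussian noise; the fixture generator for
#' parameter-recovery studies.
#'
#' @param true_params a [material_params()]
#' @param noise_sd multiplicative noise standard deviation (0.01 = 1%)
#' @param seed RNG seed for reproducibility
#' @param ... passed to [simulate_stress_relaxation()]
#' @return `force_record` data.frame
#' @export
generate_synthetic_record <- function(true_params, noise_sd = 0,
                                      seed = 1L, ...) {
  stopifnot(noise_sd >= 0)
  rec <- simulate_stress_relaxation(true_params, ...)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    rec$force <- rec$force * (1 + rnorm(nrow(rec), sd = noise_sd))
  }
  rec
}

#' Normalized mean squared error between force records
#'
#' `NMSE = sum((f_num - f_obs)^2) / sum(f_obs^2)`; invariant to a common
#' rescaling of both records.
#'
#' @param f_num,f_obs numeric vectors of equal length
#' @return scalar NMSE
#' @export
force_nmse <- function(f_num, f_obs) {
  stopifnot(length(f_num) == length(f_obs))
  d <- sum(f_obs^2)
  if (d <= 0) stop("observed record carries no signal")
  sum((f_num - f_obs)^2) / d
}

#' Fit material parameters to a stress-relaxation force record
#'
#' Derivative-free (Nelder-Mead) minimization of the normalized mean
#' squared error `NMSE = sum((f_num - f_obs)^2) / sum(f_obs^2)` between the
#' simulated and observed force records, over the three mechanical
#' parameters (`E_f`, `E_nf`, `k`).  All other parameters are pinned.  The
#' search runs in log-parameter space within box bounds (default 0.1x to
#' 10x the initial guess scale reference).
#'
#' @param observed a `force_record` (columns `time`, `force`)
#' @param initial_guess named vector with `E_f`, `E_nf`, `k`
#' @param bounds 2-row matrix (rows lower/upper, columns `E_f`, `E_nf`,
#'   `k`); default `[0.1x, 10x]` of the reference parameter set
#' @param params_fixed a [material_params()] supplying all pinned values
#' @param mesh coarse calibration mesh (kept small so one objective
#'   evaluation stays fast)
#' @param protocol a [stress_relaxation_protocol()]
#' @param control FE control list
#' @param maxit maximum objective evaluations for the simplex
#' @param n_ramp,n_hold simulation time resolution
#' @return list with `params` (fitted [material_params()]), `estimate`
#'   (named vector), `nmse`, `convergence`, `evaluations`
#' @export
fit_parameters <- function(observed,
                           initial_guess = c(E_f = 10, E_nf = 0.1,
                                             k = 2e-3),
                           bounds = NULL,
                           params_fixed = material_params(),
                           mesh = NULL,
                           protocol = stress_relaxation_protocol(),
                           control = list(), maxit = 400,
                           n_ramp = 8, n_hold = 12) {
  stopifnot(all(c("time", "force") %in% names(observed)),
            nrow(observed) > 3, all(diff(observed$time) > 0))
  if (is.null(mesh)) mesh <- build_explant_mesh(target_h = 0.25)
  ref <- c(E_f = params_fixed$E_f, E_nf = params_fixed$E_nf,
           k = params_fixed$k)
  if (is.null(bounds))
    bounds <- rbind(lower = 0.1 * ref, upper = 10 * ref)
  lb <- log(bounds[1, ]); ub <- log(bounds[2, ])
  comp <- composition_field(mesh, params_fixed)
  denom <- sum(observed$force^2)
  if (denom <= 0) stop("observed record carries no signal")

  make_params <- function(th) {
    p <- params_fixed
    p$E_f <- unname(th[1]); p$E_nf <- unname(th[2]); p$k <- unname(th[3])
    p
  }
  nmse_of <- function(lth) {
    if (any(lth < lb - 1e-12) || any(lth > ub + 1e-12))
      return(1e6 + sum(pmax(lth - ub, 0)^2 + pmax(lb - lth, 0)^2))
    th <- exp(lth)
    rec <- tryCatch(
      simulate_stress_relaxation(make_params(th), mesh, protocol, comp,
                                 control, n_ramp, n_hold),
      error = function(e) NULL)
    if (is.null(rec)) return(1e6)
    fnum <- approx(rec$time, rec$force, xout = observed$time,
                   rule = 2)$y
    v <- force_nmse(fnum, observed$force)
    if (!is.finite(v)) return(1e6)
    v
  }

  opt <- optim(log(pmin(pmax(initial_guess, bounds[1, ]), bounds[2, ])),
               nmse_of, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  est <- setNames(exp(opt$par), c("E_f", "E_nf", "k"))
  list(params = make_params(est), estimate = est, nmse = opt$value,
       convergence = opt$convergence, evaluations = opt$counts[["function"]])
}
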