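#' Degeneration algorithm configuration
#'
#' Thresholds and rate constants of the adaptive FCD-depletion algorithm.
#' FCD loss is triggered wherever, during the loading cycle, the deviatoric
#' strain exceeds 0.20, the maximum shear strain exceeds 0.50, or the
#' interstitial fluid velocity exceeds 0.04 mm/s (one mechanism per run).
#' Between threshold and complete-failure value the piecewise-constant
#' degeneration rate factor is 0.6; above the failure value
#' (`eps_failure = 1`, `v_fl_failure = 1.5 mm/s`) the ground substance
#' fails completely and local FCD is zeroed (set
#' `above_failure = "zero_rate"` for the literal no-op reading).
#'
#' @param mechanism `"fluid_velocity"`, `"deviatoric_strain"` or
#'   `"max_shear_strain"`
#' @param eps_dev_thres deviatoric strain threshold
#' @param eps_shr_thres maximum shear strain threshold
#' @param v_fl_thres fluid velocity threshold, mm/s
#' @param eps_failure strain at complete failure of the ground substance
#' @param v_fl_failure fluid velocity at complete failure, mm/s
#' @param D_r degeneration rate factor between threshold and failure
#' @param n_iterations number of adaptive iterations
#' @param above_failure `"deplete"` (total local FCD loss) or
#'   `"zero_rate"`
#' @return object of class `degeneration_config`
#' @export
degeneration_config <- function(mechanism = c("fluid_velocity",
                                              "deviatoric_strain",
                                              "max_shear_strain"),
                                eps_dev_thres = 0.20, eps_shr_thres = 0.50,
                                v_fl_thres = 0.04, eps_failure = 1.0,
                                v_fl_failure = 1.5, D_r = 0.6,
                                n_iterations = 50,
                                above_failure = c("deplete", "zero_rate")) {
  mechanism <- match.arg(mechanism)
  above_failure <- match.arg(above_failure)
  stopifnot(eps_dev_thres > 0, eps_shr_thres > 0, v_fl_thres > 0,
            D_r > 0, D_r <= 1, n_iterations >= 1,
            eps_dev_thres < eps_failure, eps_shr_thres < eps_failure,
            v_fl_thres < v_fl_failure)
  cfg <- list(mechanism = mechanism, eps_dev_thres = eps_dev_thres,
              eps_shr_thres = eps_shr_thres, v_fl_thres = v_fl_thres,
              eps_failure = eps_failure, v_fl_failure = v_fl_failure,
              D_r = D_r, n_iterations = as.integer(n_iterations),
              above_failure = above_failure)
  class(cfg) <- "degeneration_config"
  cfg
}

.mechanism_bounds <- function(config) {
  switch(config$mechanism,
    fluid_velocity = c(config$v_fl_thres, config$v_fl_failure),
    deviatoric_strain = c(config$eps_dev_thres, config$eps_failure),
    max_shear_strain = c(config$eps_shr_thres, config$eps_failure))
}

#' Piecewise-constant degeneration rate factor
#'
#' Returns 0 below the mechanism threshold, `D_r` (default 0.6) between
#' threshold and failure, and — for the default `"deplete"` reading — 1
#' above the failure value (complete local failure of the ground
#' substance).
#'
#' @param value cycle-maximum field value (strain or fluid speed, >= 0);
#'   vectorized
#' @param mechanism mechanism name (see [degeneration_config()]); defaults
#'   to the one in `config`
#' @param config a [degeneration_config()]
#' @return degeneration rate factor in `[0, 1]`
#' @export
degeneration_rate <- function(value, mechanism = NULL,
                              config = degeneration_config()) {
  if (!is.null(mechanism)) {
    if (!mechanism %in% c("fluid_velocity", "deviatoric_strain",
                          "max_shear_strain"))
      stop("unknown mechanism: ", mechanism)
    config$mechanism <- mechanism
  }
  if (any(value < 0)) stop("criterion values must be non-negative")
  b <- .mechanism_bounds(config)
  out <- numeric(length(value))
  out[value >= b[1] & value <= b[2]] <- config$D_r
  if (config$above_failure == "deplete") out[value > b[2]] <- 1
  out
}

#' Multiplicative FCD depletion
#'
#' `c_new = (1 - D_r) * c_old`, floored at zero; points with zero rate are
#' unchanged.
#'
#' @param c_fcd FCD field (per integration point), mEq/ml
#' @param D_r degeneration rate field, same length
#' @return depleted FCD field
#' @export
update_fcd <- function(c_fcd, D_r) {
  if (length(D_r) != length(c_fcd))
    stop("FCD and rate fields must be co-located")
  if (any(c_fcd < 0) || any(D_r < 0)) stop("negative inputs")
  pmax((1 - D_r) * c_fcd, 0)
}

#' Iterative cartilage degeneration loop
#'
#' The adaptive algorithm: solve the free-swelling equilibrium, apply the
#' cyclic compression protocol, extract cycle maxima of the driving field,
#' convert them to a degeneration rate, deplete the FCD field, and repeat
#' (50 iterations by default).  The loop stops early once an iteration
#' triggers no points (fixed point): with an intact surface no FCD change
#' occurs at all.
#'
#' @param mesh,comp,params model definition (see [fem_system()])
#' @param protocol a [loading_protocol()]
#' @param config a [degeneration_config()]
#' @param control FE solver control list
#' @param snapshot_every store the full FCD field every this many
#'   iterations (1 = every iteration)
#' @param verbose print a per-iteration summary line
#' @return object of class `degeneration_history`: iteration log, initial
#'   and final FCD fields, relative FCD decrease, snapshots, and the last
#'   mechanical solution
#' @export
run_degeneration_loop <- function(mesh, comp, params,
                                  protocol = loading_protocol(),
                                  config = degeneration_config(),
                                  control = list(), snapshot_every = 1,
                                  verbose = FALSE) {
  c_init <- comp$c_fcd0
  snaps <- list()
  log <- data.frame(iteration = integer(), triggered = integer(),
                    mean_fcd = numeric(), min_fcd = numeric(),
                    max_value = numeric(), peak_force = numeric())
  last_hist <- NULL
  failure <- NULL

  for (it in seq_len(config$n_iterations)) {
    res <- tryCatch({
      st <- solve_free_swelling(mesh, comp, params, control)
      solve_dynamic_cycles(st, protocol)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failure <- conditionMessage(res)
      warning("FE failure at iteration ", it, ": ", failure,
              "; returning history up to the failure")
      break
    }
    last_hist <- res
    val <- switch(config$mechanism,
                  fluid_velocity = res$max_v_fl,
                  deviatoric_strain = res$max_eps_dev,
                  max_shear_strain = res$max_eps_shr)
    dr <- degeneration_rate(val, config = config)
    ntrig <- sum(dr > 0)
    comp$c_fcd0 <- update_fcd(comp$c_fcd0, dr)
    log[it, ] <- list(it, ntrig, mean(comp$c_fcd0), min(comp$c_fcd0),
                      max(val), res$peak_force[length(res$peak_force)])
    if (verbose)
      message(sprintf(
        "iter %2d: triggered %4d, mean FCD %.4f, max %s %.4f",
        it, ntrig, mean(comp$c_fcd0), config$mechanism, max(val)))
    if (it %% snapshot_every == 0 || ntrig == 0)
      snaps[[length(snaps) + 1L]] <- list(iteration = it,
                                          c_fcd0 = comp$c_fcd0)
    if (ntrig == 0) break  # fixed point: later iterations are no-ops
  }

  out <- list(log = log, c_fcd_initial = c_init,
              c_fcd_final = comp$c_fcd0,
              rel_decrease = ifelse(c_init > 0,
                                    1 - comp$c_fcd0 / c_init, 0),
              snapshots = snaps, comp = comp, config = config,
              last_solution = last_hist, failure = failure)
  class(out) <- "degeneration_history"
  out
}

#' @export
print.degeneration_history <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("degeneration_history: %d iteration(s), mechanism %s\n",
              n, x$config$mechanism))
  cat(sprintf("  total relative FCD loss %.4f, max local loss %.3f\n",
              1 - sum(x$c_fcd_final) / sum(x$c_fcd_initial),
              max(x$rel_decrease)))
  if (!is.null(x$failure)) cat("  FE failure: ", x$failure, "\n")
  invisible(x)
}

#' Summary metrics of a degeneration run
#'
#' Total relative FCD loss and the near-lesion localization contrast: mean
#' relative FCD decrease of integration points within `near` mm of the
#' lesion surface versus points farther than `far` mm.
#'
#' @param hist a [run_degeneration_loop()] history
#' @param mesh the mesh the history was computed on
#' @param near,far distance bands from the lesion surface, mm
#' @return list with `total_loss`, `near_loss`, `far_loss`,
#'   `corner_loss` (mean loss within 0.25 mm of the upper free corner)
#' @export
degeneration_summary <- function(hist, mesh, near = 0.2, far = 0.6) {
  gp <- mesh_gp_coords(mesh)
  rel <- hist$rel_decrease
  les <- boundary_nodes(mesh, "lesion_surface")
  near_loss <- far_loss <- NA_real_
  if (length(les) > 0) {
    lx <- mesh$nodes[les, 1]; ly <- mesh$nodes[les, 2]
    dmin <- apply(gp, 1, function(pt)
      sqrt(min((pt[1] - lx)^2 + (pt[2] - ly)^2)))
    near_loss <- mean(rel[dmin <= near])
    far_loss <- mean(rel[dmin >= far])
  }
  dcorner <- sqrt((gp[, 1] - mesh$radius)^2 +
                  (gp[, 2] - mesh$thickness)^2)
  list(total_loss = 1 - sum(hist$c_fcd_final) / sum(hist$c_fcd_initial),
       near_loss = near_loss, far_loss = far_loss,
       corner_loss = mean(rel[dcorner <= 0.25]))
}
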