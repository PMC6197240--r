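.config_schema <- list(
  geometry = c("radius", "thickness", "target_h", "formulation", "cracks"),
  crack = c("mouth_position", "depth", "opening_width", "inclination",
            "profile"),
  material = c("E_f", "E_nf", "nu_nf", "k", "C", "c_ext", "R", "T",
               "phi_int", "phi_ext", "gamma_int", "gamma_ext", "a0",
               "kappa"),
  composition = c("arrangement", "fcd_scale", "rhoz_scale", "fcd_coefs",
                  "rhoz_coefs", "n_secondary"),
  protocol = c("amplitude", "frequency", "n_cycles", "dt", "pre_strain"),
  degeneration = c("mechanism", "eps_dev_thres", "eps_shr_thres",
                   "v_fl_thres", "eps_failure", "v_fl_failure", "D_r",
                   "n_iterations", "above_failure"),
  top = c("units", "geometry", "material", "composition", "protocol",
          "degeneration", "output_dir", "seed", "control"))

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Build a validated run configuration
#'
#' Assembles the full description of one degeneration simulation: geometry
#' with cracks, material parameters, composition options, loading protocol
#' and degeneration settings.  Unknown keys are rejected.  All values are
#' in the mm-N-s-MPa unit system.
#'
#' @param geometry list: `radius`, `thickness`, `target_h`, `formulation`,
#'   `cracks` (list of crack argument lists)
#' @param material named overrides for [material_params()]
#' @param composition named overrides for [composition_field()]
#' @param protocol named overrides for [loading_protocol()]
#' @param degeneration named overrides for [degeneration_config()]
#' @param output_dir where [run_simulation()] writes results
#' @param seed integer seed recorded for provenance (the simulation itself
#'   is deterministic)
#' @param control FE solver control overrides
#' @return object of class `run_config`
#' @export
run_config <- function(geometry = list(), material = list(),
                       composition = list(), protocol = list(),
                       degeneration = list(), output_dir = tempfile("run"),
                       seed = 1L, control = list()) {
  .check_keys(geometry, .config_schema$geometry, "geometry")
  .check_keys(material, .config_schema$material, "material")
  .check_keys(composition, .config_schema$composition, "composition")
  .check_keys(protocol, .config_schema$protocol, "protocol")
  .check_keys(degeneration, .config_schema$degeneration, "degeneration")
  # cracks is an unnamed list: merge it manually (modifyList would drop
  # unnamed elements)
  cracks <- geometry$cracks
  geometry$cracks <- NULL
  geometry <- modifyList(list(radius = 1.5, thickness = 1,
                              target_h = 0.1,
                              formulation = "axisymmetric"), geometry)
  geometry$cracks <- if (is.null(cracks)) list() else cracks
  for (cr in geometry$cracks) .check_keys(cr, .config_schema$crack, "crack")
  cfg <- list(units = "mm-N-s-MPa", geometry = geometry,
              material = material, composition = composition,
              protocol = protocol, degeneration = degeneration,
              output_dir = output_dir, seed = as.integer(seed),
              control = control)
  # instantiate once to trigger the constructors' own validation
  do.call(material_params, material)
  do.call(loading_protocol, protocol)
  do.call(degeneration_config, degeneration)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file path
#' @return validated `run_config`
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  .check_keys(raw, .config_schema$top, "top level")
  raw$units <- NULL
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param config a [run_config()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

.config_objects <- function(config) {
  params <- do.call(material_params, config$material)
  g <- config$geometry
  cracks <- lapply(g$cracks, function(cr) do.call(crack_spec, cr))
  mesh <- build_explant_mesh(g$radius, g$thickness, cracks, g$target_h,
                             g$formulation)
  comp <- do.call(composition_field,
                  c(list(mesh = mesh, params = params),
                    config$composition))
  list(params = params, mesh = mesh, comp = comp,
       protocol = do.call(loading_protocol, config$protocol),
       degcfg = do.call(degeneration_config, config$degeneration))
}

#' Execute a full degeneration simulation from a configuration
#'
#' Builds mesh and composition, runs the iterative degeneration loop, and
#' writes a result bundle to `config$output_dir`: the iteration log
#' (`iterations.csv`), the final FCD and relative-decrease map
#' (`final_state.vtk`), the platen force record of the last iteration
#' (`force.csv`), and a JSON summary with provenance (`summary.json`).
#' Deterministic for a given configuration.
#'
#' @param config a [run_config()]
#' @param verbose per-iteration progress
#' @param vtk_every also write a VTK snapshot of the FCD field every this
#'   many degeneration iterations (0 = final state only)
#' @return the summary list, invisibly (fields: total FCD loss, triggered
#'   point counts, localization metrics, runtime, provenance)
#' @export
run_simulation <- function(config, verbose = FALSE, vtk_every = 0) {
  t0 <- proc.time()[["elapsed"]]
  ob <- .config_objects(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hist <- run_degeneration_loop(ob$mesh, ob$comp, ob$params, ob$protocol,
                                ob$degcfg, config$control,
                                snapshot_every = max(1, vtk_every),
                                verbose = verbose)
  mesh <- ob$mesh
  if (vtk_every > 0) {
    for (s in hist$snapshots)
      write_vtk(mesh,
                file.path(config$output_dir,
                          sprintf("iter_%03d.vtk", s$iteration)),
                cell_data = list(c_fcd = gp_to_cell(s$c_fcd0)))
  }
  write.csv(hist$log, file.path(config$output_dir, "iterations.csv"),
            row.names = FALSE)
  if (!is.null(hist$last_solution))
    write.csv(hist$last_solution$force,
              file.path(config$output_dir, "force.csv"),
              row.names = FALSE)
  write_vtk(mesh, file.path(config$output_dir, "final_state.vtk"),
            cell_data = list(
              c_fcd = gp_to_cell(hist$c_fcd_final),
              rel_fcd_decrease = gp_to_cell(hist$rel_decrease)))
  summ <- degeneration_summary(hist, mesh)
  cfile <- file.path(config$output_dir, "config.yaml")
  write_run_config(config, cfile)
  out <- list(
    total_fcd_loss = summ$total_loss,
    near_lesion_loss = summ$near_loss, far_field_loss = summ$far_loss,
    corner_loss = summ$corner_loss,
    iterations_run = nrow(hist$log),
    triggered_points = hist$log$triggered,
    fe_failure = hist$failure,
    runtime_s = proc.time()[["elapsed"]] - t0,
    provenance = list(
      package_version = as.character(utils::packageVersion("cartdegen")),
      formulation = mesh$formulation,
      mechanism = ob$degcfg$mechanism,
      config_md5 = unname(tools::md5sum(cfile)),
      seed = config$seed))
  jsonlite::write_json(out, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(out, "history") <- hist
  invisible(out)
}

#' Parametric sweep specification
#'
#' @param parameter one of `arrangement`, `initial_FCD_scale`,
#'   `collagen_density_scale`, `depth_distribution_variant`, `k`, `E_f`
#' @param values vector/list of values to run
#' @param mechanisms degeneration mechanisms to run per value
#' @return object of class `sweep_spec`
#' @export
sweep_spec <- function(parameter, values,
                       mechanisms = c("fluid_velocity",
                                      "deviatoric_strain")) {
  parameter <- match.arg(parameter,
                         c("arrangement", "initial_FCD_scale",
                           "collagen_density_scale",
                           "depth_distribution_variant", "k", "E_f"))
  if (length(values) == 0) stop("sweep needs a non-empty value list")
  s <- list(parameter = parameter, values = values,
            mechanisms = mechanisms)
  class(s) <- "sweep_spec"
  s
}

.apply_sweep_value <- function(config, parameter, value) {
  switch(parameter,
    arrangement = {
      config$composition$arrangement <- value; config },
    initial_FCD_scale = {
      config$composition$fcd_scale <- value; config },
    collagen_density_scale = {
      config$composition$rhoz_scale <- value; config },
    depth_distribution_variant = {
      if (value == "uniform") {
        # replace the depth-wise collagen profile by its depth average
        m <- sum(.rhoz_poly_default / seq_along(.rhoz_poly_default))
        config$composition$rhoz_coefs <- m
      } else if (value != "default") {
        stop("unknown depth_distribution_variant: ", value)
      }
      config },
    k = { config$material$k <- value; config },
    E_f = { config$material$E_f <- value; config })
}

#' Run a parametric sweep
#'
#' One full degeneration simulation per (value, mechanism) combination of
#' the sweep specification, collating total FCD loss into one table.
#' Failures of individual runs are recorded and the sweep continues.
#'
#' @param base_config a [run_config()] serving as the template
#' @param spec a [sweep_spec()]
#' @param verbose progress output
#' @return data.frame: `parameter`, `value`, `mechanism`,
#'   `total_fcd_loss`, `near_lesion_loss`, `iterations`, `error`
#' @export
run_sweep <- function(base_config, spec, verbose = FALSE) {
  rows <- list()
  for (v in spec$values) {
    for (mech in spec$mechanisms) {
      cfg <- .apply_sweep_value(base_config, spec$parameter, v)
      cfg$degeneration$mechanism <- mech
      cfg$output_dir <- file.path(base_config$output_dir,
                                  paste0(spec$parameter, "_", v, "_",
                                         mech))
      res <- tryCatch(run_simulation(cfg, verbose = verbose),
                      error = function(e) e)
      rows[[length(rows) + 1L]] <-
        if (inherits(res, "error"))
          data.frame(parameter = spec$parameter,
                     value = as.character(v), mechanism = mech,
                     total_fcd_loss = NA, near_lesion_loss = NA,
                     iterations = NA, error = conditionMessage(res))
        else
          data.frame(parameter = spec$parameter,
                     value = as.character(v), mechanism = mech,
                     total_fcd_loss = res$total_fcd_loss,
                     near_lesion_loss = res$near_lesion_loss,
                     iterations = res$iterations_run, error = NA)
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, file.path(base_config$output_dir, "sweep.csv"),
            row.names = FALSE)
  out
}
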