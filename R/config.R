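# Declarative run configuration. A single JSON config describes either a
# bundled model (by builder name and parameters) or a low-level model
# (types, potentials, bindings, particles, bonds, flux rules), plus run
# control (steps, output stride, checkpoint stride, output directory).

.builders <- function() {
  list(oscillator = build_oscillator,
       pendulum = build_pendulum,
       spheroid_fusion = build_spheroid_fusion,
       crypt = build_crypt,
       delta_notch = build_delta_notch,
       membrane_pump = build_membrane_pump,
       signal_grid = build_signal_grid)
}

# resolve a config potential entry; sum nodes reference declared potentials
# by name
.config_potential <- function(x, defined) {
  if (is.character(x) && length(x) == 1) {
    p <- defined[[x]]
    if (is.null(p)) stop(sprintf("config references undeclared potential '%s'", x))
    return(p)
  }
  if (identical(x$kind, "sum")) {
    ch <- lapply(x$children, .config_potential, defined = defined)
    return(potential_sum(ch[[1]], ch[[2]]))
  }
  pot_from_list(x)
}

#' Build a universe from a parsed config list
#'
#' @param cfg parsed configuration (see [run_cli()])
#' @return a [universe]
#' @export
universe_from_config <- function(cfg) {
  if (!is.null(cfg$builder)) {
    b <- .builders()[[cfg$builder$name]]
    if (is.null(b)) stop(sprintf("unknown builder '%s'", cfg$builder$name))
    args <- cfg$builder$params
    if (is.null(args)) args <- list()
    if (!is.null(cfg$seed)) args$seed <- cfg$seed
    return(do.call(b, args))
  }
  uc <- cfg$universe
  if (is.null(uc)) stop("config needs a 'universe' or 'builder' section")
  u <- universe(dims = unlist(uc$dims), cutoff = uc$cutoff, dt = uc$dt,
                boundary = if (is.null(uc$boundary)) "periodic" else unlist(uc$boundary),
                seed = if (is.null(cfg$seed)) 1L else cfg$seed,
                n_substeps = if (is.null(uc$n_substeps)) 1L else uc$n_substeps,
                confine_axis = if (is.null(uc$confine_axis)) 0L else uc$confine_axis)
  for (t in cfg$types) {
    register_type(u, particle_type(t$name,
      mass = if (is.null(t$mass)) 1 else t$mass,
      radius = if (is.null(t$radius)) 0.5 else t$radius,
      dynamics = if (is.null(t$dynamics)) "overdamped" else t$dynamics,
      species = unlist(t$species),
      frozen = isTRUE(t$frozen)))
  }
  pots <- list()
  for (nm in names(cfg$potentials)) {
    pots[[nm]] <- .config_potential(cfg$potentials[[nm]], pots)
  }
  for (b in cfg$bindings) {
    bind_potential(u, b$type_a, b$type_b, .config_potential(b$potential, pots),
                   if (is.null(b$mode)) "all" else b$mode)
  }
  for (x in cfg$explicit_forces) bind_force(u, x$type, force_from_list(x$force))
  for (p in cfg$particles) {
    pos <- if (!is.null(p$positions)) .as_mat(p$positions, length(p$positions), 3)
           else matrix(unlist(p$position), 1, 3, byrow = TRUE)
    vel <- if (is.null(p$velocity)) NULL else unlist(p$velocity)
    ids <- create_particle(u, p$type, pos, vel, frozen = p$frozen)
    for (sp in names(p$species)) set_species(u, ids, sp, unlist(p$species[[sp]]))
  }
  for (b in cfg$bonds) {
    add_bond(u, b$i, b$j, .config_potential(b$potential, pots),
             if (is.null(b$dissociation_energy)) NA_real_ else b$dissociation_energy)
  }
  for (r in cfg$flux_rules) {
    add_flux_rule(u, r$species, r$type_a, r$type_b, r$kind, r$k,
                  r$r_cutoff, if (is.null(r$direction)) "a_to_b" else r$direction)
  }
  for (e in cfg$events) {
    register_event(u, get_callback(e$name),
                   period_steps = if (is.null(e$period_steps)) 1L else e$period_steps,
                   name = e$name)
  }
  u
}

#' Run a simulation from a config file
#'
#' Builds the universe from the declarative config, runs the requested
#' number of steps, and writes XYZ and CSV trajectories, JSON checkpoints
#' and a run log (step, time, kinetic and potential energy, particle count)
#' into the output directory.
#'
#' @param config_path path to a JSON configuration file
#' @param overrides named list overriding `seed`, `steps`, `out_dir`,
#'   `stride`, `checkpoint_stride`
#' @param quiet suppress progress messages
#' @return exit status, invisibly (0 on success)
#' @export
run_cli <- function(config_path, overrides = list(), quiet = FALSE) {
  if (!file.exists(config_path)) {
    message("config file not found: ", config_path)
    return(invisible(1L))
  }
  cfg <- tryCatch(
    jsonlite::fromJSON(config_path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) e)
  if (inherits(cfg, "error")) {
    message("config parse error in ", config_path, ": ", conditionMessage(cfg))
    return(invisible(1L))
  }
  run <- cfg$run
  if (is.null(run)) run <- list()
  for (k in c("steps", "stride", "checkpoint_stride", "out_dir")) {
    if (!is.null(overrides[[k]])) run[[k]] <- overrides[[k]]
  }
  if (!is.null(overrides$seed)) cfg$seed <- overrides$seed
  steps <- if (is.null(run$steps)) 100L else as.integer(run$steps)
  stride <- if (is.null(run$stride)) 10L else as.integer(run$stride)
  ck_stride <- if (is.null(run$checkpoint_stride)) 0L else as.integer(run$checkpoint_stride)
  out_dir <- if (is.null(run$out_dir)) "tissuesim_out" else run$out_dir
  u <- tryCatch(universe_from_config(cfg), error = function(e) e)
  if (inherits(u, "error")) {
    message("config error in ", config_path, ": ", conditionMessage(u))
    return(invisible(1L))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  xyz <- file.path(out_dir, "trajectory.xyz")
  csv <- file.path(out_dir, "trajectory.csv")
  log_path <- file.path(out_dir, "run.log")
  if (file.exists(xyz)) unlink(xyz)
  if (file.exists(csv)) unlink(csv)
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  dump_frame <- function() {
    write_xyz(u, xyz)
    write_traj_csv(u, csv)
    en <- total_energy(u)
    writeLines(sprintf("step=%d time=%.10g kinetic=%.10g potential=%.10g particles=%d",
                       u$step_count, u$time, en$kinetic, en$potential,
                       particle_count(u)), log_con)
  }
  dump_frame()
  done <- 0L
  while (done < steps && !u$stop_flag) {
    chunk <- min(stride, steps - done)
    sim_step(u, chunk)
    done <- done + chunk
    dump_frame()
    if (ck_stride > 0 && done %% ck_stride == 0) {
      save_state(u, file.path(out_dir, sprintf("checkpoint_%06d.json", u$step_count)))
    }
  }
  save_state(u, file.path(out_dir, "final_state.json"))
  if (!quiet) message(sprintf("ran %d steps; outputs in %s", done, out_dir))
  invisible(0L)
}

#' Resume a run from a JSON state file
#'
#' @param state_path path to a state JSON written by [save_state()]
#' @param steps steps to run after resuming
#' @param out_dir output directory
#' @param quiet suppress messages
#' @return exit status, invisibly
#' @export
resume_cli <- function(state_path, steps, out_dir = "tissuesim_out",
                       quiet = FALSE) {
  u <- tryCatch(load_state(state_path), error = function(e) e)
  if (inherits(u, "error")) {
    message("state error in ", state_path, ": ", conditionMessage(u))
    return(invisible(1L))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_step(u, as.integer(steps))
  save_state(u, file.path(out_dir, "final_state.json"))
  write_xyz(u, file.path(out_dir, "trajectory.xyz"), append = FALSE)
  write_traj_csv(u, file.path(out_dir, "trajectory.csv"), append = FALSE)
  if (!quiet) message(sprintf("resumed %s steps; outputs in %s", steps, out_dir))
  invisible(0L)
}
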