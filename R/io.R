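#' Default run configuration
#'
#' The fully expanded configuration tree: mechanics, per-species binder
#' parameters, either a fixed architecture or sampling ranges, protocol and
#' seeds. [load_config()] merges a user file over these defaults.
#' @return nested list of defaults.
#' @keywords internal
default_config <- function() {
  list(
    mechanics = list(kT = 0.0042, drag_per_length = 7.5,
                     extension_stiffness = 2000, dt = 3e-5),
    binders = list(
      crosslinker = list(stiffness = 100, rest_length = 0.05, k_on = 10,
                         binding_range = 0.1, k_off = 0.1),
      arp23 = list(stiffness = 100, rest_length = 0, k_on = 10,
                   binding_range = 0.05, k_off = 0, torsion_k = 0.5,
                   branch_angle = 72),
      motor = list(stiffness = 100, rest_length = 0.2, k_on = 10,
                   binding_range = 0.25, k_off = 2, v0 = 1, f_s = 6)),
    architecture = list(n_nucleators = 160, n_arp23 = 160, n_motors = 960,
                        n_crosslinkers = 1920, polymer_pool = 480,
                        domain_radius = 6, growth_speed = 0.5),
    protocol = list(assembly_duration = 10, contraction_duration = 2,
                    frame_interval = 0.04),
    seeds = list(master = 1L, architecture = 1L, dynamics = 2L),
    output = list(dir = ".", trajectory = TRUE))
}

# recursive merge of user values over defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key: %s", full), call. = FALSE)
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  pos <- list("mechanics.drag_per_length" = cfg$mechanics$drag_per_length,
              "mechanics.extension_stiffness" = cfg$mechanics$extension_stiffness,
              "mechanics.dt" = cfg$mechanics$dt,
              "architecture.polymer_pool" = cfg$architecture$polymer_pool,
              "architecture.domain_radius" = cfg$architecture$domain_radius,
              "architecture.growth_speed" = cfg$architecture$growth_speed,
              "protocol.assembly_duration" = cfg$protocol$assembly_duration,
              "protocol.contraction_duration" = cfg$protocol$contraction_duration,
              "protocol.frame_interval" = cfg$protocol$frame_interval)
  for (nm in names(pos)) {
    v <- pos[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop(sprintf("configuration key %s must be a positive number", nm),
           call. = FALSE)
  }
  nonneg <- list("mechanics.kT" = cfg$mechanics$kT,
                 "architecture.n_nucleators" = cfg$architecture$n_nucleators,
                 "architecture.n_arp23" = cfg$architecture$n_arp23,
                 "architecture.n_motors" = cfg$architecture$n_motors,
                 "architecture.n_crosslinkers" = cfg$architecture$n_crosslinkers)
  for (nm in names(nonneg)) {
    v <- nonneg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop(sprintf("configuration key %s must be a non-negative number", nm),
           call. = FALSE)
  }
  if (cfg$binders$arp23$branch_angle != 72)
    stop("configuration key binders.arp23.branch_angle is fixed at 72",
         call. = FALSE)
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, merges it over the documented defaults,
#' rejects unknown keys (naming the offending key) and validates all
#' invariants. The resolved configuration should be echoed next to any run
#' output (see [simulate_run()]) so every run is self-describing.
#'
#' @param path YAML file path.
#' @return the fully resolved configuration (class `"run_config"`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Write a resolved configuration to YAML
#'
#' `load_config(save_config(cfg, path))` round-trips to an identical
#' resolved configuration.
#'
#' @param cfg a `run_config` (or compatible nested list).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# helpers turning a config into package parameter objects
config_mechanics <- function(cfg) do.call(mechanics_params, cfg$mechanics)

config_binders <- function(cfg) {
  b <- cfg$binders
  binder_param_set(
    crosslinker = do.call(binder_params, c(list(species = "crosslinker"),
                                           b$crosslinker)),
    arp23 = do.call(binder_params, c(list(species = "arp23"), b$arp23)),
    motor = do.call(binder_params, c(list(species = "motor"), b$motor)))
}

config_architecture <- function(cfg) {
  do.call(architecture_params,
          c(cfg$architecture, cfg$protocol,
            list(architecture_seed = cfg$seeds$architecture,
                 dynamics_seed = cfg$seeds$dynamics)))
}

#' Write / read a trajectory as columnar text
#'
#' Frames are written as one CSV with columns `frame`, `time_s`, `fiber`,
#' `vertex`, `x_um`, `y_um`, at full double precision (`%.17g`), so
#' `read_trajectory(write_trajectory(...))` is lossless. An empty frame
#' list yields a valid header-only file.
#'
#' @param frames list of frames, each `list(time =, fibers = list of n x 2
#'   coordinate matrices)` as returned by [run_contraction()] with
#'   `record_frames = TRUE`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frame,time_s,fiber,vertex,x_um,y_um", con)
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    for (bi in seq_along(fr$fibers)) {
      v <- fr$fibers[[bi]]
      if (nrow(v) == 0) next
      writeLines(sprintf("%d,%.17g,%d,%d,%.17g,%.17g",
                         fi, fr$time, bi, seq_len(nrow(v)),
                         v[, 1], v[, 2]), con)
    }
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory()`: the frame list.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric", "integer",
                                             "integer", "numeric", "numeric"))
  if (nrow(df) == 0) return(list())
  if (is.unsorted(df$frame)) stop("corrupt trajectory: frames out of order",
                                  call. = FALSE)
  lapply(split(df, df$frame), function(d) {
    list(time = d$time_s[1],
         fibers = lapply(split(d, d$fiber), function(fd) {
           unname(cbind(fd$x_um, fd$y_um))
         }))
  })
}

#' Run one architecture end-to-end and write all outputs
#'
#' Runs both protocol phases for the configured architecture and writes to
#' `outdir`: the resolved configuration echo (`config_echo.yaml`), the
#' phase-2 trajectory (`trajectory.csv`, if enabled), the radius series
#' (`radius.csv`), the fit summary (`fit.csv`) and a progress log
#' (`run.log`).
#'
#' @param cfg a `run_config` from [load_config()], or `NULL` for defaults.
#' @param outdir output directory (created if missing).
#' @return the [contract_architecture()] result, invisibly.
#' @export
simulate_run <- function(cfg = NULL, outdir = ".") {
  if (is.null(cfg)) cfg <- structure(default_config(), class = "run_config")
  validate_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  cat(sprintf("actomyosim %s\n",
              as.character(utils::packageVersion("actomyosim"))),
      file = logf)
  save_config(cfg, file.path(outdir, "config_echo.yaml"))
  mech <- config_mechanics(cfg)
  binders <- config_binders(cfg)
  arch <- config_architecture(cfg)
  n1 <- round(arch$assembly_duration / mech$dt)
  n2 <- round(arch$contraction_duration / mech$dt)
  logline("assembly: %d steps", n1)
  res <- contract_architecture(arch, mech, binders,
                               record_frames = isTRUE(cfg$output$trajectory))
  logline("contraction: %d steps, %d frames", n2, nrow(res$series))
  utils::write.csv(data.frame(time_s = res$series$time_s,
                              radius_um = res$series$radius_um),
                   file.path(outdir, "radius.csv"), row.names = FALSE)
  utils::write.csv(data.frame(A_um = res$fit$A, B_per_s = res$fit$B,
                              rms_residual_um = res$fit$rms_residual,
                              converged = res$fit$converged,
                              giant_fraction = res$connectivity$giant_fraction,
                              uniform_contraction =
                                res$connectivity$uniform_contraction),
                   file.path(outdir, "fit.csv"), row.names = FALSE)
  if (isTRUE(cfg$output$trajectory) && !is.null(res$frames))
    write_trajectory(res$frames, file.path(outdir, "trajectory.csv"))
  logline("fit: A = %.4f um, B = %.5f 1/s", res$fit$A, res$fit$B)
  invisible(res)
}
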