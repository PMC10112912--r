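#' Create a discretized semiflexible filament
#'
#' A fiber is an ordered polyline of 2D vertices; vertex 1 is the minus
#' (pointed) end and the last vertex the plus (barbed) end. Interior segments
#' share one rest length; the plus-most segment carries the fractional rest
#' length left over by growth (`last_rest`), kept in `[0.5, 1.5)` segment
#' lengths by the vertex-splitting rule of the growth step.
#'
#' @param vertices numeric matrix (n x 2) of vertex positions in micrometres,
#'   minus end first. At least two rows.
#' @param seg_rest rest length of interior segments (um).
#' @param last_rest rest length of the plus-most segment (um); defaults to
#'   `seg_rest`.
#' @param rigidity bending modulus kappa (pN um^2).
#' @param frozen logical; `TRUE` once growth has stopped.
#' @param id integer identifier.
#' @return an object of class `"fiber"`.
#' @export
fiber <- function(vertices, seg_rest = 0.2, last_rest = seg_rest,
                  rigidity = 0.075, frozen = FALSE, id = 1L) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 2,
            seg_rest > 0, last_rest > 0, rigidity >= 0)
  structure(list(vertices = unname(vertices), seg_rest = seg_rest,
                 last_rest = last_rest, rigidity = rigidity,
                 frozen = isTRUE(frozen), id = as.integer(id)),
            class = "fiber")
}

#' @export
print.fiber <- function(x, ...) {
  cat(sprintf("<fiber %d: %d vertices, length %.3f um%s>\n", x$id,
              nrow(x$vertices), fiber_length(x),
              if (x$frozen) ", frozen" else ""))
  invisible(x)
}

#' Total rest-length of a fiber (um)
#' @param fib a [fiber()].
#' @export
fiber_length <- function(fib) {
  (nrow(fib$vertices) - 2) * fib$seg_rest + fib$last_rest
}

#' Per-segment rest lengths of a fiber
#' @param fib a [fiber()].
#' @return numeric vector of length `nrow(vertices) - 1`.
#' @export
fiber_rests <- function(fib) {
  n <- nrow(fib$vertices) - 1
  c(rep(fib$seg_rest, n - 1), fib$last_rest)
}

#' Mechanics parameters for the overdamped Langevin integrator
#'
#' Vertices move by `(dt/gamma) F + sqrt(2 kT dt / gamma) xi` per step, with
#' `gamma = drag_per_length * seg_rest` the per-vertex translational drag and
#' `xi` standard 2D Gaussian noise (explicit Euler-Maruyama). Inextensibility
#' is enforced by stiff penalty springs of stiffness `extension_stiffness`
#' along each segment; defaults keep segment strain within about +-2% under
#' typical motor loads while passing the time-step stability bound
#' `dt < gamma / (10 k_max)`.
#'
#' @param kT thermal energy (pN um); default 0.0042 (room temperature).
#' @param drag_per_length translational drag per unit filament length
#'   (pN s / um^2); default 7.5, i.e. an effective viscosity of order 1 Pa s,
#'   cytoplasm-like.
#' @param extension_stiffness penalty-spring stiffness (pN/um); default 2000.
#' @param dt integration time step (s); default 3e-5.
#' @param rng_seed integer seed for the engine's random stream.
#' @return an object of class `"mechanics_params"`.
#' @export
mechanics_params <- function(kT = 0.0042, drag_per_length = 7.5,
                             extension_stiffness = 2000, dt = 3e-5,
                             rng_seed = 1L) {
  stopifnot(kT >= 0, drag_per_length > 0, extension_stiffness > 0, dt > 0)
  structure(list(kT = kT, drag_per_length = drag_per_length,
                 extension_stiffness = extension_stiffness, dt = dt,
                 rng_seed = as.integer(rng_seed)),
            class = "mechanics_params")
}

#' Assemble a simulation state
#'
#' @param fibers list of [fiber()] objects.
#' @param connectors connector table as built by [connector_table()]; may be
#'   empty.
#' @param time simulation time (s).
#' @param tethers optional data frame of external harmonic traps with columns
#'   `fiber`, `vertex`, `anchor_x`, `anchor_y`, `stiffness` (used for
#'   calibration experiments and point constraints).
#' @return an object of class `"simulation_state"`.
#' @export
simulation_state <- function(fibers = list(), connectors = connector_table(),
                             time = 0, tethers = NULL) {
  stopifnot(is.list(fibers), all(vapply(fibers, inherits, TRUE, "fiber")))
  structure(list(fibers = fibers, connectors = connectors, time = time,
                 tethers = tethers),
            class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state: %d fibers, %d connectors, t = %.4f s>\n",
              length(x$fibers), nrow(x$connectors), x$time))
  invisible(x)
}

#' Bending forces of the discrete worm-like chain
#'
#' Forces are the negative gradient of `E = (kappa / 2 l) * sum(theta_i^2)`
#' where `theta_i` is the angle between consecutive segments and `l` the rest
#' segment length. Internal forces: they sum to zero over the fiber, as does
#' their total torque.
#'
#' @param fib a [fiber()].
#' @param params a [mechanics_params()] (unused beyond the interface; the
#'   bending modulus lives on the fiber).
#' @return numeric matrix (n x 2) of per-vertex forces (pN). Fibers with
#'   fewer than 3 vertices return all zeros.
#' @export
compute_bending_forces <- function(fib, params = mechanics_params()) {
  if (nrow(fib$vertices) < 3) {
    return(matrix(0, nrow(fib$vertices), 2))
  }
  cpp_bending_forces(fib$vertices, fib$rigidity, fib$seg_rest)
}

#' Extension (penalty-spring) forces along a fiber
#'
#' Each segment acts as a Hookean spring of stiffness
#' `params$extension_stiffness` about its rest length; the resulting force
#' pairs sum to zero over the fiber.
#'
#' @inheritParams compute_bending_forces
#' @return numeric matrix (n x 2) of per-vertex forces (pN).
#' @export
compute_extension_forces <- function(fib, params = mechanics_params()) {
  cpp_extension_forces(fib$vertices, fiber_rests(fib),
                       params$extension_stiffness)
}

# Largest total spring stiffness acting on any vertex, for the dt stability
# precheck. Conservative: two penalty springs (interior vertex) plus the
# stiffest connector plus torsion-equivalent, confinement and tether springs.
max_vertex_stiffness <- function(params, binders = binder_param_set(),
                                 confine_k = 0, tether_k = 0) {
  conn_k <- max(binders$crosslinker$stiffness, binders$arp23$stiffness,
                binders$motor$stiffness)
  tors_k <- binders$arp23$torsion_k / 0.2^2  # linear-equivalent at one segment
  bend_k <- 3 * 0.075 / 0.2^3                # worst-case discrete WLC stiffness
  list(value = 2 * params$extension_stiffness + conn_k + tors_k + bend_k +
         confine_k + tether_k,
       dominant = "extension_stiffness")
}

#' Check the explicit-integrator stability bound
#'
#' Requires `dt < gamma_vertex / (10 k_max)` where `k_max` is the largest
#' total spring stiffness acting on any vertex. Called once per run; aborts
#' with a configuration error naming the dominant stiffness if violated.
#'
#' @param params a [mechanics_params()].
#' @param binders a [binder_param_set()].
#' @param confine_k confinement wall stiffness in effect (pN/um).
#' @param tether_k largest tether stiffness in effect (pN/um).
#' @param seg_rest rest segment length used for the per-vertex drag (um).
#' @return invisibly, the maximal admissible dt.
#' @export
check_stability <- function(params, binders = binder_param_set(),
                            confine_k = 0, tether_k = 0, seg_rest = 0.2) {
  gamma_v <- params$drag_per_length * seg_rest
  kmax <- max_vertex_stiffness(params, binders, confine_k, tether_k)
  dt_max <- gamma_v / (10 * kmax$value)
  if (params$dt >= dt_max) {
    stop(sprintf(paste0(
      "time step dt = %g s violates the stability bound dt < gamma/(10 k_max) ",
      "= %g s (k_max = %g pN/um, dominated by %s); reduce dt or the stiffness"),
      params$dt, dt_max, kmax$value, kmax$dominant), call. = FALSE)
  }
  invisible(dt_max)
}

# internal: run the compiled engine for a state
engine_run <- function(state, params, binders, n_steps,
                       grow = FALSE, branch = FALSE, bind = FALSE,
                       confine_radius = -1, confine_k = 100,
                       growth_speed = 0, pool = 0, sample_every = 0L,
                       record_frames = FALSE, seed = 1, arp_remaining = 0L,
                       init_length = 0.1, bind_every = 10L) {
  ctrl <- list(n_steps = as.integer(n_steps), grow = grow, branch = branch,
               bind = bind, confine_radius = confine_radius,
               confine_k = confine_k, growth_speed = growth_speed,
               pool = pool, sample_every = as.integer(sample_every),
               record_frames = record_frames, seed = as.double(seed),
               arp_remaining = as.integer(arp_remaining),
               init_length = init_length, bind_every = as.integer(bind_every))
  st <- list(fibers = lapply(state$fibers, function(f) {
               list(vertices = f$vertices, seg_rest = f$seg_rest,
                    last_rest = f$last_rest, rigidity = f$rigidity,
                    frozen = f$frozen)
             }),
             connectors = state$connectors,
             tethers = state$tethers,
             time = state$time)
  res <- cpp_run(st, unclass(params), binders, ctrl)
  new_fibs <- res$state$fibers
  fibers <- vector("list", length(new_fibs))
  for (i in seq_along(new_fibs)) {
    nf <- new_fibs[[i]]
    old_id <- if (i <= length(state$fibers)) state$fibers[[i]]$id else i
    fibers[[i]] <- fiber(nf$vertices, seg_rest = nf$seg_rest,
                         last_rest = nf$last_rest, rigidity = nf$rigidity,
                         frozen = nf$frozen, id = old_id)
  }
  out_state <- simulation_state(fibers, res$state$connectors,
                                time = res$state$time, tethers = state$tethers)
  list(state = out_state, times = res$times, radii = res$radii,
       max_strain = res$max_strain, strain_series = res$strain_series,
       pool = res$pool, arp_remaining = res$arp_remaining,
       branch_angles = res$branch_angles,
       frames = if (record_frames) res$frames else NULL)
}

#' Advance the overdamped Langevin dynamics
#'
#' Integrates all vertices under bending, extension, connector, tether and
#' thermal forces for `n_steps` explicit Euler-Maruyama steps of length
#' `params$dt`. Identical seeds and inputs give bit-identical trajectories.
#' Stochastic binding/unbinding and motor stepping are active whenever the
#' state holds connectors.
#'
#' @param state a [simulation_state()].
#' @param params a [mechanics_params()].
#' @param n_steps number of steps to take.
#' @param binders a [binder_param_set()].
#' @param bind enable stochastic (un)binding and motor stepping.
#' @param seed engine seed; defaults to `params$rng_seed`.
#' @return the advanced [simulation_state()].
#' @export
step_dynamics <- function(state, params, n_steps = 1L,
                          binders = binder_param_set(),
                          bind = nrow(state$connectors) > 0, seed = NULL) {
  tether_k <- if (!is.null(state$tethers) && nrow(state$tethers) > 0)
    max(state$tethers$stiffness) else 0
  check_stability(params, binders, tether_k = tether_k,
                  seg_rest = if (length(state$fibers))
                    state$fibers[[1]]$seg_rest else 0.2)
  engine_run(state, params, binders, n_steps, bind = bind,
             seed = if (is.null(seed)) params$rng_seed else seed)$state
}
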