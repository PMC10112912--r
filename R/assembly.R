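#' Parameters of one network architecture
#'
#' An architecture is one draw of entity counts and polymer budget: the unit
#' of the perturbation sweep. Networks are assembled inside a circular domain
#' during phase 1 (nucleation, plus-end growth from the finite polymer pool,
#' Arp2/3 branching, soft confinement), then frozen and contracted during
#' phase 2 after motors and crosslinkers are injected.
#'
#' @param n_nucleators number of linear-filament nucleators (initial fibers).
#' @param n_arp23 number of Arp2/3 branching entities.
#' @param n_motors number of two-headed myosin motor complexes.
#' @param n_crosslinkers number of passive crosslinkers.
#' @param polymer_pool total polymer length available for growth (um).
#' @param domain_radius radius of the circular assembly domain (um).
#' @param growth_speed plus-end growth speed (um/s); chosen high enough that
#'   the pool, not the assembly time, limits filament length.
#' @param assembly_duration phase-1 duration (s).
#' @param contraction_duration phase-2 duration (s).
#' @param frame_interval radius sampling interval during phase 2 (s).
#' @param architecture_seed seed controlling nucleator/Arp2/3 placement and
#'   the assembly dynamics.
#' @param dynamics_seed seed controlling binder injection and the contraction
#'   dynamics.
#' @return an object of class `"architecture_params"`.
#' @export
architecture_params <- function(n_nucleators, n_arp23, n_motors,
                                n_crosslinkers, polymer_pool,
                                domain_radius = 6, growth_speed = 0.5,
                                assembly_duration = 10,
                                contraction_duration = 2,
                                frame_interval = 0.04,
                                architecture_seed = 1L, dynamics_seed = 2L) {
  stopifnot(n_nucleators >= 0, n_arp23 >= 0, n_motors >= 0,
            n_crosslinkers >= 0, polymer_pool > 0, domain_radius > 0,
            growth_speed > 0, assembly_duration > 0, contraction_duration > 0,
            frame_interval > 0)
  structure(list(n_nucleators = as.integer(n_nucleators),
                 n_arp23 = as.integer(n_arp23),
                 n_motors = as.integer(n_motors),
                 n_crosslinkers = as.integer(n_crosslinkers),
                 polymer_pool = polymer_pool, domain_radius = domain_radius,
                 growth_speed = growth_speed,
                 assembly_duration = assembly_duration,
                 contraction_duration = contraction_duration,
                 frame_interval = frame_interval,
                 architecture_seed = as.integer(architecture_seed),
                 dynamics_seed = as.integer(dynamics_seed)),
            class = "architecture_params")
}

#' @export
print.architecture_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<architecture: %d nucleators, %d Arp2/3, %d motors, %d crosslinkers,\n",
    "  polymer pool %.1f um, domain radius %.1f um, seeds (%d, %d)>\n"),
    x$n_nucleators, x$n_arp23, x$n_motors, x$n_crosslinkers,
    x$polymer_pool, x$domain_radius, x$architecture_seed, x$dynamics_seed))
  invisible(x)
}

# evaluate expr under a locally set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# uniform points in a disc of radius R (polar inversion)
runif_disc <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Seed the initial linear filaments
#'
#' Places `n_nucleators` two-vertex fibers of minimal length uniformly at
#' random in the disc of `domain_radius`, with isotropically random
#' orientations. Deterministic given `architecture_seed`.
#'
#' @param arch an [architecture_params()].
#' @param init_length initial fiber length (um).
#' @return list of [fiber()] objects.
#' @export
seed_nucleators <- function(arch, init_length = 0.1) {
  with_seed(arch$architecture_seed, {
    n <- arch$n_nucleators
    if (n == 0) return(list())
    p <- runif_disc(n, arch$domain_radius)
    th <- stats::runif(n, 0, 2 * pi)
    lapply(seq_len(n), function(i) {
      v <- rbind(p[i, ], p[i, ] + init_length * c(cos(th[i]), sin(th[i])))
      fiber(v, last_rest = init_length, id = i)
    })
  })
}

#' Grow filament plus ends from the polymer pool
#'
#' Each unfrozen fiber's plus end extends by `growth_speed * dt`, debited
#' from the shared pool; when the pool empties all fibers freeze. The plus
#' segment accumulates fractional rest length and splits into a new vertex
#' once it exceeds 1.5 rest segment lengths, so mean filament length is set
#' by `polymer_pool / filament count` -- the lever behind the polymer-mass
#' perturbations.
#'
#' @param fibers list of [fiber()] objects.
#' @param pool remaining unpolymerized material (um).
#' @param growth_speed growth speed (um/s).
#' @param dt time step (s).
#' @return list with updated `fibers` and `pool`.
#' @export
grow_step <- function(fibers, pool, growth_speed, dt) {
  active <- !vapply(fibers, function(f) f$frozen, TRUE)
  want <- sum(active) * growth_speed * dt
  if (want <= 0 || pool <= 0) {
    return(list(fibers = fibers, pool = max(pool, 0)))
  }
  scale <- if (want >= pool) pool / want else 1
  dl <- growth_speed * dt * scale
  fibers <- lapply(fibers, function(f) {
    if (f$frozen) return(f)
    n <- nrow(f$vertices)
    tang <- f$vertices[n, ] - f$vertices[n - 1, ]
    tn <- sqrt(sum(tang^2))
    if (tn > 1e-12) {
      f$vertices[n, ] <- f$vertices[n, ] + dl * tang / tn
    }
    f$last_rest <- f$last_rest + dl
    if (f$last_rest >= 1.5 * f$seg_rest) {
      frac <- f$seg_rest / f$last_rest
      newv <- f$vertices[n - 1, ] + frac * (f$vertices[n, ] - f$vertices[n - 1, ])
      f$vertices <- rbind(f$vertices[seq_len(n - 1), , drop = FALSE], newv,
                          f$vertices[n, ])
      f$last_rest <- f$last_rest - f$seg_rest
    }
    f
  })
  pool <- pool - dl * sum(active)
  if (scale < 1) {
    pool <- 0
    fibers <- lapply(fibers, function(f) { f$frozen <- TRUE; f })
  }
  list(fibers = fibers, pool = pool)
}

#' One Arp2/3 branch-nucleation attempt
#'
#' Each free Arp2/3 entity binds a nearby filament segment with the standard
#' binder kinetics and, upon binding, nucleates a daughter fiber at exactly
#' 72 degrees to the mother tangent (side chosen uniformly at random). Each
#' Arp2/3 nucleates at most once. This is the step-wise surface; the
#' assembly loop of [assemble_network()] performs the same events in the
#' compiled engine.
#'
#' @param fibers list of [fiber()] objects.
#' @param arp_anchors matrix (m x 2) of free Arp2/3 positions.
#' @param params arp23 [binder_params()].
#' @param dt time step (s).
#' @param init_length daughter initial length (um).
#' @return list with `fibers` (daughters appended), `arp_anchors` (rows of
#'   consumed entities removed) and `branches` (data frame: one row per new
#'   branch with mother, daughter, abscissa, side and realized angle in
#'   degrees).
#' @export
arp_branch_nucleation <- function(fibers, arp_anchors, params, dt,
                                  init_length = 0.1) {
  branches <- data.frame()
  if (is.null(arp_anchors) || nrow(arp_anchors) == 0 || length(fibers) == 0) {
    return(list(fibers = fibers, arp_anchors = arp_anchors,
                branches = branches))
  }
  segs <- segment_table(fibers)
  consumed <- logical(nrow(arp_anchors))
  for (i in seq_len(nrow(arp_anchors))) {
    att <- attempt_binding(arp_anchors[i, ], segs, params, dt)
    if (is.null(att)) next
    mother <- fibers[[which(vapply(fibers, `[[`, 1L, "id") == att$fiber)]]
    rests <- fiber_rests(mother)
    seg_i <- min(findInterval(att$abscissa, cumsum(c(0, rests)),
                              rightmost.closed = TRUE), length(rests))
    tang <- mother$vertices[seg_i + 1, ] - mother$vertices[seg_i, ]
    side <- if (stats::runif(1) < 0.5) "left" else "right"
    dirv <- branch_geometry(tang, side)
    base_u <- (att$abscissa - (seg_i - 1) * mother$seg_rest) / rests[seg_i]
    base <- mother$vertices[seg_i, ] +
      min(max(base_u, 0), 1) * (mother$vertices[seg_i + 1, ] - mother$vertices[seg_i, ])
    newid <- max(vapply(fibers, `[[`, 1L, "id")) + 1L
    daughter <- fiber(rbind(base, base + init_length * dirv),
                      seg_rest = mother$seg_rest, last_rest = init_length,
                      rigidity = mother$rigidity, id = newid)
    fibers <- c(fibers, list(daughter))
    ang <- acos(sum((tang / sqrt(sum(tang^2))) * dirv)) * 180 / pi
    branches <- rbind(branches,
                      data.frame(mother = att$fiber, daughter = newid,
                                 abscissa = att$abscissa, side = side,
                                 angle_deg = ang))
    consumed[i] <- TRUE
  }
  list(fibers = fibers,
       arp_anchors = arp_anchors[!consumed, , drop = FALSE],
       branches = branches)
}

#' Assemble one network architecture (phase 1)
#'
#' Runs [seed_nucleators()] and then the assembly loop -- growth from the
#' polymer pool, Arp2/3 branch nucleation and overdamped Langevin dynamics,
#' softly confined to the circular domain -- for `assembly_duration`, then
#' permanently freezes nucleation, branching and growth. Reproducible from
#' `architecture_seed`.
#'
#' @param arch an [architecture_params()].
#' @param mech a [mechanics_params()].
#' @param binders a [binder_param_set()].
#' @param confine_k confinement wall stiffness (pN/um).
#' @param init_length initial/daughter fiber length (um).
#' @param assembly_connectors optional [connector_table()] of crosslinkers or
#'   motors present (and stochastically binding) already during assembly; by
#'   default motors and crosslinkers only appear in phase 2.
#' @return the frozen [simulation_state()], with an `"assembly"` attribute
#'   holding diagnostics: `pool_remaining`, `n_branches`, `branch_angles`
#'   (angles at creation, degrees), `max_strain`.
#' @export
assemble_network <- function(arch, mech = mechanics_params(),
                             binders = binder_param_set(), confine_k = 100,
                             init_length = 0.1, assembly_connectors = NULL) {
  check_stability(mech, binders, confine_k = confine_k)
  fibers <- seed_nucleators(arch, init_length)
  arp_xy <- with_seed(arch$architecture_seed + 1L,
                      runif_disc(arch$n_arp23, arch$domain_radius))
  conns <- connector_table(species = rep(SP_ARP23, arch$n_arp23),
                           anchor_x = arp_xy[, "x"], anchor_y = arp_xy[, "y"])
  if (!is.null(assembly_connectors) && nrow(assembly_connectors) > 0) {
    conns <- rbind(conns, assembly_connectors)
    class(conns) <- c("connector_table", "data.frame")
  }
  state <- simulation_state(fibers, conns)
  n_steps <- round(arch$assembly_duration / mech$dt)
  res <- engine_run(state, mech, binders, n_steps,
                    grow = TRUE, branch = TRUE,
                    bind = !is.null(assembly_connectors),
                    confine_radius = arch$domain_radius,
                    confine_k = confine_k,
                    growth_speed = arch$growth_speed,
                    pool = arch$polymer_pool,
                    seed = arch$architecture_seed,
                    arp_remaining = arch$n_arp23,
                    init_length = init_length)
  out <- res$state
  out$fibers <- lapply(out$fibers, function(f) { f$frozen <- TRUE; f })
  # drop Arp2/3 entities that never nucleated: they play no further role
  keep <- !(out$connectors$species == SP_ARP23 & is.na(out$connectors$h1_fib))
  out$connectors <- out$connectors[keep, , drop = FALSE]
  attr(out, "assembly") <- list(pool_remaining = res$pool,
                                n_branches = length(res$branch_angles),
                                branch_angles = res$branch_angles,
                                max_strain = res$max_strain)
  out
}
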