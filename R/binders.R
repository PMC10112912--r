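#' Connector species codes
#'
#' Connectors are two-handed Hookean binders. Species are stored as integer
#' codes in the connector table: 0 = passive crosslinker, 1 = Arp2/3 branch
#' link, 2 = two-headed myosin motor.
#' @name species-codes
#' @keywords internal
NULL

SP_CROSSLINKER <- 0L
SP_ARP23 <- 1L
SP_MOTOR <- 2L

#' Parameters of one connector species
#'
#' @param species `"crosslinker"`, `"arp23"` or `"motor"`.
#' @param stiffness Hookean link stiffness (pN/um).
#' @param rest_length link rest length (um); the spring acts in both
#'   extension and compression about it.
#' @param k_on binding rate per eligible target (1/s).
#' @param binding_range capture radius for binding (um).
#' @param k_off unbinding rate (1/s); force-independent.
#' @param v0 unloaded motor speed (um/s; motor only).
#' @param f_s stall force (pN; motor only). Linear force-velocity:
#'   `v = v0 * max(0, 1 - load/f_s)`.
#' @param torsion_k rotational-spring stiffness holding the branch angle
#'   (pN um / rad; arp23 only).
#' @param branch_angle branch angle in degrees (arp23 only; fixed at 72).
#' @param kramers_f characteristic force (pN) for slip-bond unbinding: when
#'   positive, the unbinding rate of a doubly bound connector grows as
#'   `k_off * exp(force / kramers_f)`. Default 0 keeps unbinding
#'   force-independent.
#' @return an object of class `"binder_params"`.
#' @export
binder_params <- function(species = c("crosslinker", "arp23", "motor"),
                          stiffness = 100, rest_length = 0.05, k_on = 10,
                          binding_range = 0.05, k_off = 0.1, v0 = 1, f_s = 6,
                          torsion_k = 0.5, branch_angle = 72, kramers_f = 0) {
  species <- match.arg(species)
  stopifnot(stiffness >= 0, k_on >= 0, k_off >= 0, binding_range >= 0,
            rest_length >= 0, v0 >= 0, f_s > 0, torsion_k >= 0,
            kramers_f >= 0)
  if (species == "arp23" && branch_angle != 72)
    stop("the Arp2/3 branch angle is fixed at 72 degrees", call. = FALSE)
  structure(list(species = species, stiffness = stiffness,
                 rest_length = rest_length, k_on = k_on,
                 binding_range = binding_range, k_off = k_off, v0 = v0,
                 f_s = f_s, torsion_k = torsion_k,
                 branch_angle = branch_angle, kramers_f = kramers_f),
            class = "binder_params")
}

#' Default parameter set for the three connector species
#'
#' Crosslinkers unbind at 0.1/s, motor complexes at 2/s (an engagement
#' lasts ~0.5 s, so motors stroke intermittently rather than acting as
#' long-lived crosslinks); Arp2/3 links are permanent
#' once the branch is nucleated and additionally carry the rotational spring
#' that holds the 72 degree branch angle. The motor complex is given the
#' reach of a bipolar myosin-II minifilament (capture range 0.25 um, rest
#' length 0.2 um), which saturates motor engagement on dense networks.
#'
#' @param crosslinker,arp23,motor [binder_params()] objects per species.
#' @return a named list of class `"binder_param_set"`.
#' @export
binder_param_set <- function(
    crosslinker = binder_params("crosslinker", binding_range = 0.1),
    arp23 = binder_params("arp23", rest_length = 0, k_off = 0),
    motor = binder_params("motor", k_off = 2, binding_range = 0.25,
                          rest_length = 0.2)) {
  structure(list(crosslinker = crosslinker, arp23 = arp23, motor = motor),
            class = "binder_param_set")
}

#' Build a connector table
#'
#' One row per connector. Hands are `(fiber id, abscissa)` pairs; `NA` fiber
#' means unbound. Abscissae are measured in micrometres from the minus end.
#'
#' @param species integer codes (0 crosslinker, 1 arp23, 2 motor).
#' @param h1_fib,h1_abs,h2_fib,h2_abs hand states.
#' @param anchor_x,anchor_y connector position when fully unbound.
#' @param side branch side (+1 left / -1 right; arp23 only).
#' @param phi0 signed target branch angle (rad; arp23 only).
#' @return a data frame of class `"connector_table"`.
#' @export
connector_table <- function(species = integer(0), h1_fib = NA_integer_,
                            h1_abs = NA_real_, h2_fib = NA_integer_,
                            h2_abs = NA_real_, anchor_x = numeric(0),
                            anchor_y = numeric(0), side = NA_integer_,
                            phi0 = NA_real_) {
  n <- length(species)
  df <- data.frame(species = as.integer(species),
                   h1_fib = rep_len(as.integer(h1_fib), n),
                   h1_abs = rep_len(as.numeric(h1_abs), n),
                   h2_fib = rep_len(as.integer(h2_fib), n),
                   h2_abs = rep_len(as.numeric(h2_abs), n),
                   anchor_x = as.numeric(anchor_x),
                   anchor_y = as.numeric(anchor_y),
                   side = rep_len(as.integer(side), n),
                   phi0 = rep_len(as.numeric(phi0), n))
  class(df) <- c("connector_table", "data.frame")
  df
}

#' One stochastic binding attempt for a free hand
#'
#' Each candidate segment whose closest point lies within `binding_range` of
#' the hand binds with probability `1 - exp(-k_on * dt)`, evaluated in
#' randomized order; the hand never binds the fiber already held by the
#' partner hand. Uses R's RNG.
#'
#' @param hand_position numeric length-2 position of the free hand (um).
#' @param segments data frame with columns `fiber`, `x1`, `y1`, `x2`, `y2`,
#'   `abs0` (abscissa of the segment start) and `rest` (segment rest length).
#' @param params a [binder_params()].
#' @param dt time step (s).
#' @param exclude_fiber fiber id held by the partner hand, or `NA`.
#' @return a list `(fiber, abscissa)` or `NULL` if the hand stays unbound.
#' @export
attempt_binding <- function(hand_position, segments, params, dt,
                            exclude_fiber = NA) {
  if (nrow(segments) == 0) return(NULL)
  px <- hand_position[1]; py <- hand_position[2]
  sx <- segments$x2 - segments$x1
  sy <- segments$y2 - segments$y1
  l2 <- sx^2 + sy^2
  u <- ifelse(l2 > 1e-16,
              ((px - segments$x1) * sx + (py - segments$y1) * sy) / l2, 0)
  u <- pmin(1, pmax(0, u))
  cx <- segments$x1 + u * sx
  cy <- segments$y1 + u * sy
  d <- sqrt((px - cx)^2 + (py - cy)^2)
  ok <- d <= params$binding_range & !(segments$fiber %in% exclude_fiber)
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  idx <- if (length(idx) > 1) sample(idx) else idx  # randomized order
  p <- 1 - exp(-params$k_on * dt)
  for (i in idx) {
    if (stats::runif(1) < p) {
      return(list(fiber = segments$fiber[i],
                  abscissa = segments$abs0[i] + u[i] * segments$rest[i]))
    }
  }
  NULL
}

#' One stochastic unbinding attempt for a bound hand
#'
#' Detaches with probability `1 - exp(-k_off * dt)` (force-independent).
#' Motor hands additionally detach deterministically upon reaching the plus
#' end (`abscissa >= fiber_length`).
#'
#' @param params a [binder_params()].
#' @param dt time step (s).
#' @param abscissa current abscissa of the hand (um).
#' @param fiber_length length of the bound fiber (um).
#' @return `TRUE` if the hand stays bound, `FALSE` if it detaches.
#' @export
attempt_unbinding <- function(params, dt, abscissa = 0, fiber_length = Inf) {
  if (params$species == "motor" && abscissa >= fiber_length) return(FALSE)
  stats::runif(1) >= 1 - exp(-params$k_off * dt)
}

#' Hookean force pair of a doubly bound connector
#'
#' Magnitude `stiffness * (separation - rest_length)` along the separation
#' vector; the spring acts in both extension and compression. Newton's third
#' law holds exactly; if either hand is unbound the pair is zero.
#'
#' @param p1,p2 numeric length-2 attachment positions (um); `NULL` = unbound.
#' @param params a [binder_params()].
#' @return list with `f1`, `f2` (forces on the two attachment points, pN).
#' @export
link_force <- function(p1, p2, params) {
  zero <- list(f1 = c(0, 0), f2 = c(0, 0))
  if (is.null(p1) || is.null(p2)) return(zero)
  dv <- p2 - p1
  d <- sqrt(sum(dv^2))
  if (d < 1e-12) return(zero)
  fmag <- params$stiffness * (d - params$rest_length)
  u <- dv / d
  list(f1 = fmag * u, f2 = -fmag * u)
}

#' Advance a motor hand along its fiber
#'
#' Linear force-velocity relation `v = v0 * max(0, 1 - load/f_s)` where
#' `load` is the component of the connector force opposing plus-end motion;
#' the abscissa is clamped at the fiber length (where the end-detachment rule
#' of [attempt_unbinding()] then applies).
#'
#' @param abscissa current abscissa (um).
#' @param load_along_fiber load opposing plus-end motion (pN, >= 0).
#' @param params a [binder_params()] with species `"motor"`.
#' @param dt time step (s).
#' @param fiber_length fiber length for clamping (um).
#' @return the new abscissa (um).
#' @export
advance_motor <- function(abscissa, load_along_fiber, params, dt,
                          fiber_length = Inf) {
  v <- params$v0 * max(0, 1 - load_along_fiber / params$f_s)
  min(abscissa + v * dt, fiber_length)
}

#' Initial direction of an Arp2/3-nucleated daughter filament
#'
#' The daughter branches off the mother at exactly 72 degrees, rotated to the
#' given side (left = counter-clockwise).
#'
#' @param mother_tangent unit 2D tangent of the mother filament at the branch
#'   point (plus-end direction).
#' @param side `"left"` or `"right"`.
#' @param branch_angle branch angle in degrees (default 72).
#' @return unit 2D direction of the daughter filament.
#' @export
branch_geometry <- function(mother_tangent, side = c("left", "right"),
                            branch_angle = 72) {
  side <- match.arg(side)
  n <- sqrt(sum(mother_tangent^2))
  if (n < 1e-12) stop("zero-length mother tangent", call. = FALSE)
  t <- mother_tangent / n
  a <- branch_angle * pi / 180 * if (side == "left") 1 else -1
  c(cos(a) * t[1] - sin(a) * t[2], sin(a) * t[1] + cos(a) * t[2])
}

# internal: segment table of a fiber list, for the R-level binding ops
segment_table <- function(fibers) {
  out <- lapply(fibers, function(f) {
    n <- nrow(f$vertices)
    rests <- fiber_rests(f)
    data.frame(fiber = f$id,
               x1 = f$vertices[-n, 1], y1 = f$vertices[-n, 2],
               x2 = f$vertices[-1, 1], y2 = f$vertices[-1, 2],
               abs0 = cumsum(c(0, rests[-(n - 1)])),
               rest = rests)
  })
  do.call(rbind, out)
}
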