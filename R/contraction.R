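#' Inject motors and crosslinkers into a frozen network
#'
#' Phase 2 begins by adding `n_motors` motor complexes and `n_crosslinkers`
#' passive crosslinkers, placed uniformly at random within the network's
#' bounding disc and initially unbound; binding then proceeds stochastically
#' during the contraction run. Placement is reproducible from
#' `dynamics_seed`.
#'
#' @param frozen_state a frozen [simulation_state()] from
#'   [assemble_network()].
#' @param arch the [architecture_params()] of the network.
#' @return the state with motor and crosslinker rows appended.
#' @export
inject_binders <- function(frozen_state, arch) {
  if (!all(vapply(frozen_state$fibers, function(f) f$frozen, TRUE)))
    stop("binders can only be injected into a frozen network", call. = FALSE)
  n <- arch$n_motors + arch$n_crosslinkers
  if (n == 0) return(frozen_state)
  verts <- do.call(rbind, lapply(frozen_state$fibers, `[[`, "vertices"))
  ctr <- colMeans(verts)
  rad <- max(sqrt((verts[, 1] - ctr[1])^2 + (verts[, 2] - ctr[2])^2), 0.5)
  xy <- with_seed(arch$dynamics_seed, runif_disc(n, rad))
  newc <- connector_table(
    species = c(rep(SP_MOTOR, arch$n_motors),
                rep(SP_CROSSLINKER, arch$n_crosslinkers)),
    anchor_x = xy[, "x"] + ctr[1], anchor_y = xy[, "y"] + ctr[2])
  st <- frozen_state
  st$connectors <- rbind(st$connectors, newc)
  class(st$connectors) <- c("connector_table", "data.frame")
  st
}

#' Radius time series of a contraction run
#'
#' @param times sampling times (s), strictly increasing from 0.
#' @param radii network radii (um), positive.
#' @return an object of class `"radius_series"` (also a data frame with
#'   columns `time_s`, `radius_um`).
#' @export
radius_series <- function(times, radii) {
  stopifnot(length(times) == length(radii), length(times) >= 1,
            all(diff(times) > 0), times[1] >= 0, all(radii > 0))
  structure(data.frame(time_s = times, radius_um = radii),
            class = c("radius_series", "data.frame"))
}

#' RMS network radius, disc-calibrated
#'
#' Returns `sqrt(2 * mean(d^2))` over all fiber vertices, `d` the distance
#' to the vertex centroid. For vertices uniform in a disc of radius R the
#' estimator returns R (since `E[d^2] = R^2/2`), so it reads directly as the
#' radius covered by the network. Translation- and rotation-invariant.
#' Alternative estimators are available via `method`.
#'
#' @param state a [simulation_state()] with at least one fiber.
#' @param method `"rms"` (default, used throughout the package),
#'   `"max"` (bounding radius) or `"hull"` (area-equivalent radius of the
#'   convex hull).
#' @return radius in micrometres.
#' @export
network_radius <- function(state, method = c("rms", "max", "hull")) {
  method <- match.arg(method)
  if (length(state$fibers) == 0)
    stop("network_radius: state has no fibers", call. = FALSE)
  v <- do.call(rbind, lapply(state$fibers, `[[`, "vertices"))
  ctr <- colMeans(v)
  d2 <- (v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2
  switch(method,
         rms = sqrt(2 * mean(d2)),
         max = sqrt(max(d2)),
         hull = {
           h <- grDevices::chull(v)
           poly <- v[h, , drop = FALSE]
           n <- nrow(poly)
           j <- c(2:n, 1)
           area <- abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
           sqrt(area / pi)
         })
}

#' Run the contraction phase (phase 2)
#'
#' Integrates the injected network for `contraction_duration` with growth and
#' branching frozen and no confinement (the patch is free to contract),
#' sampling the RMS radius every `frame_interval`. Sampling is pure
#' observation: it does not perturb the trajectory.
#'
#' @param state a frozen, injected [simulation_state()].
#' @param arch the [architecture_params()].
#' @param mech a [mechanics_params()].
#' @param binders a [binder_param_set()].
#' @param record_frames also keep vertex coordinate snapshots per frame.
#' @return list with `series` (a [radius_series()]), `state` (final),
#'   `max_strain` (largest relative segment strain seen) and, if requested,
#'   `frames`.
#' @export
run_contraction <- function(state, arch, mech = mechanics_params(),
                            binders = binder_param_set(),
                            record_frames = FALSE) {
  check_stability(mech, binders)
  n_steps <- round(arch$contraction_duration / mech$dt)
  sample_every <- max(1L, round(arch$frame_interval / mech$dt))
  res <- engine_run(state, mech, binders, n_steps, bind = TRUE,
                    sample_every = sample_every,
                    record_frames = record_frames,
                    seed = arch$dynamics_seed)
  # series time is measured from the start of the contraction phase, so the
  # fitted amplitude A reads as the initial network size
  list(series = radius_series(res$times - res$times[1], res$radii),
       state = res$state, max_strain = res$max_strain, frames = res$frames)
}

#' Fit the contraction rate B of R(t) = A exp(-B t)
#'
#' Nonlinear least squares initialized from the log-linear regression of
#' `log R` on `t`. `B` is unconstrained in sign (negative for expanding
#' networks). If the nonlinear fit fails to converge the log-linear estimate
#' is returned with `converged = FALSE`.
#'
#' @param series a [radius_series()] (or data frame with `time_s`,
#'   `radius_um`) with at least 5 samples.
#' @return an object of class `"contraction_fit"`: list with `A` (um), `B`
#'   (1/s), `rms_residual` (um) and `converged`.
#' @export
fit_contraction_rate <- function(series) {
  t <- series$time_s
  r <- series$radius_um
  stopifnot(length(t) >= 5)
  ll <- stats::lm(log(pmax(r, 1e-9)) ~ t)
  A0 <- exp(unname(stats::coef(ll)[1]))
  B0 <- -unname(stats::coef(ll)[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ A * exp(-B * t), start = list(A = A0, B = B0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    resid <- r - A0 * exp(-B0 * t)
    out <- list(A = A0, B = B0, rms_residual = sqrt(mean(resid^2)),
                converged = FALSE)
  } else {
    cf <- stats::coef(fit)
    out <- list(A = unname(cf["A"]), B = unname(cf["B"]),
                rms_residual = sqrt(mean(stats::residuals(fit)^2)),
                converged = TRUE)
  }
  structure(out, class = "contraction_fit")
}

#' @export
print.contraction_fit <- function(x, ...) {
  cat(sprintf("<contraction fit: A = %.3f um, B = %.4f 1/s, rms %.3g um%s>\n",
              x$A, x$B, x$rms_residual,
              if (x$converged) "" else " (log-linear fallback)"))
  invisible(x)
}

#' Connectivity of the connector-linked network
#'
#' Builds the graph whose nodes are fibers and whose edges are doubly bound
#' connectors of any species (including Arp2/3 branch links) and reports its
#' components. `uniform_contraction` is the operational percolation
#' criterion used by the sweep: at least 90% of the total polymer length in
#' the largest component.
#'
#' @param state a [simulation_state()].
#' @param giant_threshold fraction of polymer length required for uniform
#'   contraction (default 0.9).
#' @return list with `n_components`, `giant_fraction` and
#'   `uniform_contraction`.
#' @export
connectivity_report <- function(state, giant_threshold = 0.9) {
  nf <- length(state$fibers)
  if (nf == 0) {
    return(list(n_components = 0L, giant_fraction = NA_real_,
                uniform_contraction = FALSE))
  }
  lens <- vapply(state$fibers, fiber_length, 0)
  cn <- state$connectors
  both <- !is.na(cn$h1_fib) & !is.na(cn$h2_fib)
  g <- igraph::make_empty_graph(n = nf, directed = FALSE)
  if (any(both)) {
    g <- igraph::add_edges(g, rbind(cn$h1_fib[both], cn$h2_fib[both]))
  }
  comp <- igraph::components(g)
  gf <- max(tapply(lens, comp$membership, sum)) / sum(lens)
  list(n_components = comp$no, giant_fraction = unname(gf),
       uniform_contraction = unname(gf) >= giant_threshold)
}

#' Assemble, inject and contract one architecture end-to-end
#'
#' Convenience pipeline: [assemble_network()], [inject_binders()],
#' [run_contraction()], [fit_contraction_rate()] and a final-state
#' [connectivity_report()].
#'
#' @inheritParams assemble_network
#' @param record_frames keep coordinate snapshots of the contraction phase.
#' @param frozen optionally, a previously assembled frozen state for this
#'   architecture's phase-1 parameters (reused by the sweep when a
#'   perturbation leaves assembly untouched, e.g. a motor-count change).
#' @return list with `fit`, `series`, `connectivity`, `state` (final),
#'   `frozen_radius` (radius at the start of phase 2, um) and `max_strain`.
#' @export
contract_architecture <- function(arch, mech = mechanics_params(),
                                  binders = binder_param_set(),
                                  record_frames = FALSE, frozen = NULL) {
  if (is.null(frozen)) frozen <- assemble_network(arch, mech, binders)
  injected <- inject_binders(frozen, arch)
  run <- run_contraction(injected, arch, mech, binders,
                         record_frames = record_frames)
  list(fit = fit_contraction_rate(run$series), series = run$series,
       connectivity = connectivity_report(run$state), state = run$state,
       frozen_radius = network_radius(frozen), max_strain = run$max_strain,
       frames = run$frames)
}
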