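# shared oracles and small builders for the test suite

# central-difference gradient of a scalar function of a flat coordinate vector
num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# discrete WLC bending energy (independent of the engine implementation)
bend_energy <- function(coords, kappa, ell) {
  m <- matrix(coords, ncol = 2)
  n <- nrow(m)
  E <- 0
  for (i in 2:(n - 1)) {
    a <- m[i, ] - m[i - 1, ]
    b <- m[i + 1, ] - m[i, ]
    th <- atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
    E <- E + kappa / (2 * ell) * th^2
  }
  E
}

# sum of Hookean segment-spring energies
ext_energy <- function(coords, rests, k) {
  m <- matrix(coords, ncol = 2)
  n <- nrow(m)
  d <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-n, , drop = FALSE])^2))
  sum(0.5 * k * (d - rests)^2)
}

# a tiny contractile architecture for fast end-to-end tests (a few seconds)
tiny_architecture <- function(architecture_seed = 5L, dynamics_seed = 6L, ...) {
  args <- utils::modifyList(
    list(n_nucleators = 14L, n_arp23 = 10L, n_motors = 60L,
         n_crosslinkers = 120L, polymer_pool = 30, domain_radius = 1.8),
    list(...))
  do.call(reference_architecture,
          c(list("desk", architecture_seed = architecture_seed,
                 dynamics_seed = dynamics_seed), args))
}

# a relaxed, stress-free frozen network built directly (no assembly, so no
# residual confinement stress): straight fibers at rest scattered in a disc
relaxed_frozen_state <- function(n_fibers = 12, len = 2, radius = 4,
                                 seed = 71) {
  actomyosim:::with_seed(seed, {
    fibs <- lapply(seq_len(n_fibers), function(i) {
      p <- radius * 0.6 * c(stats::runif(1, -1, 1), stats::runif(1, -1, 1))
      th <- stats::runif(1, 0, 2 * pi)
      dirv <- c(cos(th), sin(th))
      nseg <- round(len / 0.2)
      v <- t(vapply(0:nseg, function(k) p + k * 0.2 * dirv, c(0, 0)))
      fiber(v, frozen = TRUE, id = i)
    })
    simulation_state(fibs)
  })
}

# synthetic exponential radius series
exp_series <- function(A = 5, B = 0.3, n = 50, t_max = 2, noise_sd = 0) {
  t <- seq(0, t_max, length.out = n)
  r <- A * exp(-B * t) + stats::rnorm(n, 0, noise_sd)
  radius_series(t, pmax(r, 1e-6))
}
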