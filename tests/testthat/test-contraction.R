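test_that("network_radius has the stated closed forms", {
  # all vertices at one point
  pt <- simulation_state(list(fiber(rbind(c(1, 2), c(1, 2)))))
  expect_equal(network_radius(pt), 0)
  # four vertices at (+-a, 0), (0, +-a): estimator returns a*sqrt(2)
  a <- 1.7
  cross4 <- simulation_state(list(
    fiber(rbind(c(-a, 0), c(a, 0))), fiber(rbind(c(0, -a), c(0, a)))))
  expect_equal(network_radius(cross4), a * sqrt(2), tolerance = 1e-12)
  # 1e5 vertices uniform in a disc of radius 6: E[d^2] = R^2/2
  set.seed(17)
  th <- runif(5e4, 0, 2 * pi)
  r <- 6 * sqrt(runif(5e4))
  v <- cbind(r * cos(th), r * sin(th))
  disc <- simulation_state(lapply(seq_len(2.5e4), function(i)
    fiber(v[c(2 * i - 1, 2 * i), ], id = i)))
  expect_equal(network_radius(disc), 6, tolerance = 0.05 / 6)
  expect_error(network_radius(simulation_state(list())), "no fibers")
})

test_that("network_radius is translation- and rotation-invariant", {
  set.seed(18)
  fibs <- lapply(1:10, function(i)
    fiber(matrix(rnorm(8), ncol = 2), id = i))
  st <- simulation_state(fibs)
  r0 <- network_radius(st)
  phi <- 0.83
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  moved <- simulation_state(lapply(fibs, function(f) {
    f$vertices <- f$vertices %*% Rm + matrix(c(5, -3), nrow(f$vertices), 2,
                                             byrow = TRUE)
    f
  }))
  expect_equal(network_radius(moved), r0, tolerance = 1e-12)
})

test_that("inject_binders adds the requested counts, reproducibly, only when frozen", {
  arch <- tiny_architecture()
  frozen <- assemble_network(arch)
  inj <- inject_binders(frozen, arch)
  cn <- inj$connectors
  expect_equal(sum(cn$species == 2), arch$n_motors)
  expect_equal(sum(cn$species == 0), arch$n_crosslinkers)
  expect_true(all(is.na(cn$h1_fib[cn$species != 1])))  # initially unbound
  inj2 <- inject_binders(frozen, arch)
  expect_identical(inj, inj2)
  # zero binders: state unchanged
  arch0 <- tiny_architecture(n_motors = 0L, n_crosslinkers = 0L)
  frozen0 <- assemble_network(arch0)
  expect_equal(nrow(inject_binders(frozen0, arch0)$connectors),
               nrow(frozen0$connectors))
  # unfrozen network is rejected
  thawed <- frozen
  thawed$fibers[[1]]$frozen <- FALSE
  expect_error(inject_binders(thawed, arch), "frozen")
})

test_that("fit_contraction_rate recovers exact exponentials and the constant limit", {
  fit <- fit_contraction_rate(exp_series(A = 5, B = 0.3))
  expect_true(fit$converged)
  expect_equal(fit$A, 5, tolerance = 1e-6)
  expect_equal(fit$B, 0.3, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-9)
  flat <- radius_series(seq(0, 2, length.out = 50), rep(4.2, 50))
  ffit <- fit_contraction_rate(flat)
  expect_equal(ffit$A, 4.2, tolerance = 1e-9)
  expect_equal(ffit$B, 0, tolerance = 1e-9)
  expect_error(fit_contraction_rate(exp_series(n = 4)))
  # negative rates (expanding networks) are allowed
  grow <- fit_contraction_rate(exp_series(B = -0.2))
  expect_equal(grow$B, -0.2, tolerance = 1e-6)
})

test_that("fit is unbiased to < 1% at 1% amplitude noise over 100 replicates", {
  set.seed(19)
  Bs <- vapply(seq_len(100), function(i)
    fit_contraction_rate(exp_series(A = 5, B = 0.3, n = 100,
                                    noise_sd = 0.05))$B, 0)
  expect_lt(abs(mean(Bs) - 0.3) / 0.3, 0.01)
})

test_that("connectivity_report implements length-weighted percolation", {
  mkf <- function(i, len = 1) fiber(rbind(c(i, 0), c(i + len, 0)),
                                    seg_rest = len, last_rest = len, id = i)
  fibs <- lapply(1:5, mkf)
  # no connectors: every fiber its own component
  rep0 <- connectivity_report(simulation_state(fibs))
  expect_equal(rep0$n_components, 5)
  expect_equal(rep0$giant_fraction, 1 / 5)
  expect_false(rep0$uniform_contraction)
  # chain of 5: one spanning component
  chain <- connector_table(species = rep(0L, 4), h1_fib = 1:4, h1_abs = 0.5,
                           h2_fib = 2:5, h2_abs = 0.5,
                           anchor_x = 0, anchor_y = 0)
  rep1 <- connectivity_report(simulation_state(fibs, chain))
  expect_equal(rep1$n_components, 1)
  expect_equal(rep1$giant_fraction, 1)
  expect_true(rep1$uniform_contraction)
  # two equal halves
  half <- connector_table(species = rep(0L, 3),
                          h1_fib = c(1L, 1L, 3L), h1_abs = 0.5,
                          h2_fib = c(2L, 2L, 4L), h2_abs = 0.5,
                          anchor_x = 0, anchor_y = 0)
  fibs4 <- lapply(1:4, mkf)
  rep2 <- connectivity_report(simulation_state(fibs4, half))
  expect_equal(rep2$n_components, 2)
  expect_equal(rep2$giant_fraction, 0.5)
  expect_false(rep2$uniform_contraction)
})

test_that("without motors and at kT = 0 the radius stays constant", {
  # a relaxed frozen network (no residual assembly stress): with no motors
  # and no thermal noise there are no forces at all, so nothing moves
  st <- relaxed_frozen_state()
  arch <- tiny_architecture(n_motors = 0L, n_crosslinkers = 0L, n_arp23 = 0L)
  mech <- mechanics_params(kT = 0)
  run <- run_contraction(st, arch, mech)
  expect_lt(diff(range(run$series$radius_um)) / run$series$radius_um[1], 1e-3)
  # passive crosslinkers alone change the radius by well under a percent
  # (binder springs relax from their capture separation to rest length)
  inj <- inject_binders(st, tiny_architecture(n_motors = 0L))
  run2 <- run_contraction(inj, tiny_architecture(n_motors = 0L), mech)
  expect_lt(diff(range(run2$series$radius_um)) / run2$series$radius_um[1],
            0.01)
})

test_that("radius sampling is pure observation: frame rate does not alter the trajectory", {
  # frame intervals chosen as exact multiples of dt so the coarse sampling
  # grid is nested in the fine one
  arch <- tiny_architecture(frame_interval = 0.045)
  frozen <- assemble_network(arch)
  inj <- inject_binders(frozen, arch)
  coarse <- run_contraction(inj, arch)
  arch2 <- arch
  arch2$frame_interval <- 0.0225
  fine <- run_contraction(inj, arch2)
  shared <- match(round(coarse$series$time_s, 9), round(fine$series$time_s, 9))
  expect_false(anyNA(shared))
  expect_identical(coarse$series$radius_um, fine$series$radius_um[shared])
})

test_that("the reference network contracts monotonically after smoothing", {
  arch <- reference_architecture("desk", architecture_seed = 11L,
                                 dynamics_seed = 101L)
  res <- contract_architecture(arch)
  expect_gt(res$fit$B, 0)
  sm <- stats::filter(res$series$radius_um, rep(1 / 9, 9))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 2e-3))  # decreasing trend, thermal jitter aside
  expect_true(res$connectivity$uniform_contraction)
  # penalty-spring inextensibility at default parameters: the great majority
  # of end-state segment strains sit within the 2% tolerance; the tails are
  # thermal (segment rms strain sqrt(kT/k)/l ~ 0.7%, so a 3-4 sigma excursion
  # over ~1e3 segments clears 2%) and the worst instantaneous excursion over
  # all ~1e5 steps stays within a few times the tolerance
  strains <- unlist(lapply(res$state$fibers, function(f) {
    v <- f$vertices
    n <- nrow(v)
    d <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-n, , drop = FALSE])^2))
    abs(d - fiber_rests(f)) / fiber_rests(f)
  }))
  expect_gt(mean(strains <= 0.02), 0.9)
  expect_lt(stats::quantile(strains, 0.5), 0.02)
  expect_lt(max(strains), 0.05)
  expect_lt(res$max_strain, 0.10)
})
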