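one_segment <- function(x1 = 0, y1 = 0, x2 = 0.2, y2 = 0) {
  data.frame(fiber = 1L, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
             abs0 = 0, rest = 0.2)
}

test_that("binding requires a segment in range and a positive rate", {
  xl <- binder_params("crosslinker")
  far <- one_segment(y1 = 1, y2 = 1)  # 1 um away, range 0.05
  expect_null(attempt_binding(c(0.1, 0), far, xl, dt = 1e-3))
  zero_rate <- binder_params("crosslinker", k_on = 0)
  expect_null(attempt_binding(c(0.1, 0.01), one_segment(), zero_rate, 1e-3))
  # partner-fiber exclusion
  expect_null(attempt_binding(c(0.1, 0.01), one_segment(),
                              binder_params("crosslinker"), 1e3,
                              exclude_fiber = 1L))
})

test_that("binding and unbinding match their Bernoulli probabilities", {
  xl <- binder_params("crosslinker", k_on = 10, k_off = 1)
  seg <- one_segment()
  n <- 1e5
  set.seed(21)
  hits <- sum(vapply(seq_len(n), function(i)
    !is.null(attempt_binding(c(0.1, 0.01), seg, xl, dt = 1e-3)), TRUE))
  p <- 1 - exp(-10 * 1e-3)
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
  det <- sum(vapply(seq_len(n), function(i)
    !attempt_unbinding(xl, dt = 1e-3), TRUE))
  q <- 1 - exp(-1 * 1e-3)
  expect_lt(abs(det / n - q), 3 * sqrt(q * (1 - q) / n))
})

test_that("bound abscissa is the closest point on the chosen segment", {
  xl <- binder_params("crosslinker", k_on = 1e9)  # certain binding
  set.seed(4)
  att <- attempt_binding(c(0.13, 0.02), one_segment(), xl, dt = 1)
  expect_equal(att$abscissa, 0.13, tolerance = 1e-12)
  # beyond the plus end (but within range): clamped to the end vertex
  att <- attempt_binding(c(0.24, 0.01), one_segment(), xl, dt = 1)
  expect_equal(att$abscissa, 0.2, tolerance = 1e-12)
})

test_that("unbinding edge cases: k_off = 0 never detaches, motors detach at the plus end", {
  frozen <- binder_params("crosslinker", k_off = 0)
  set.seed(5)
  expect_true(all(vapply(1:1000, function(i)
    attempt_unbinding(frozen, dt = 1), TRUE)))
  mot <- binder_params("motor", k_off = 0)
  expect_false(attempt_unbinding(mot, dt = 1e-3, abscissa = 2,
                                 fiber_length = 2))
})

test_that("link_force is Hookean, Newton-third-law exact, zero when unbound", {
  xl <- binder_params("crosslinker", stiffness = 100, rest_length = 0.05)
  at_rest <- link_force(c(0, 0), c(0.05, 0), xl)
  expect_equal(at_rest$f1, c(0, 0))
  five <- link_force(c(0, 0), c(0.10, 0), xl)
  expect_equal(five$f1, c(5, 0), tolerance = 1e-12)
  expect_equal(five$f2, c(-5, 0), tolerance = 1e-12)
  expect_equal(link_force(NULL, c(1, 1), xl)$f1, c(0, 0))
  # random configurations match the numerical gradient of (k/2)(d - d0)^2
  set.seed(8)
  for (i in 1:20) {
    p1 <- runif(2); p2 <- runif(2) + 0.3
    En <- function(x) {
      d <- sqrt(sum((x[3:4] - x[1:2])^2))
      0.5 * 100 * (d - 0.05)^2
    }
    g <- num_grad(En, c(p1, p2))
    lf <- link_force(p1, p2, xl)
    expect_equal(lf$f1, -g[1:2], tolerance = 1e-6)
    expect_equal(lf$f2, -g[3:4], tolerance = 1e-6)
  }
})

test_that("motor advance follows the linear force-velocity relation", {
  mot <- binder_params("motor", v0 = 1, f_s = 6)
  expect_equal(advance_motor(0.5, 0, mot, 1e-3), 0.501)
  expect_equal(advance_motor(0.5, 6, mot, 1e-3), 0.5)        # stall
  expect_equal(advance_motor(0.5, 3, mot, 1e-3), 0.5005)     # half stall
  expect_equal(advance_motor(0.5, 12, mot, 1e-3), 0.5)       # super-stall clamp
  expect_equal(advance_motor(1.999, 0, mot, 2e-3, fiber_length = 2), 2)
})

test_that("branch geometry puts daughters at exactly 72 degrees", {
  d <- branch_geometry(c(1, 0), "left")
  expect_equal(d, c(cos(72 * pi / 180), sin(72 * pi / 180)), tolerance = 1e-12)
  d <- branch_geometry(c(1, 0), "right")
  expect_equal(d, c(cos(72 * pi / 180), -sin(72 * pi / 180)), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:25) {
    t <- runif(2, -1, 1)
    t <- t / sqrt(sum(t^2))
    side <- sample(c("left", "right"), 1)
    d <- branch_geometry(t, side)
    expect_equal(sum(d * t), cos(72 * pi / 180), tolerance = 1e-12)
    expect_equal(sum(d^2), 1, tolerance = 1e-12)
  }
  expect_error(branch_geometry(c(0, 0), "left"), "zero-length")
})

test_that("one unloaded motor slides two antiparallel filaments at 2 v0", {
  # negligible drag and a huge stall force: the load stays ~0, each head
  # advances at v0, and the filaments translate in opposite directions
  f1 <- fiber(rbind(c(-1, 0.005), c(1, 0.005)), seg_rest = 2, last_rest = 2,
              rigidity = 0, frozen = TRUE, id = 1L)   # plus end at +x
  f2 <- fiber(rbind(c(1, -0.005), c(-1, -0.005)), seg_rest = 2, last_rest = 2,
              rigidity = 0, frozen = TRUE, id = 2L)   # plus end at -x
  conns <- connector_table(species = 2L, h1_fib = 1L, h1_abs = 1,
                           h2_fib = 2L, h2_abs = 1,
                           anchor_x = 0, anchor_y = 0)
  st <- simulation_state(list(f1, f2), conns)
  mech <- mechanics_params(kT = 0, drag_per_length = 0.05,
                           extension_stiffness = 10, dt = 5e-5)
  binders <- binder_param_set(
    motor = binder_params("motor", v0 = 1, f_s = 1e4, k_off = 0,
                          rest_length = 0.01, stiffness = 50))
  out <- step_dynamics(st, mech, n_steps = 4000, binders = binders,
                       bind = TRUE, seed = 3)   # 0.2 s
  dx1 <- mean(out$fibers[[1]]$vertices[, 1]) - 0
  dx2 <- mean(out$fibers[[2]]$vertices[, 1]) - 0
  rel_speed <- abs(dx1 - dx2) / 0.2
  expect_equal(rel_speed, 2, tolerance = 0.05)
})

test_that("the two hands of a connector never share a fiber during contraction", {
  arch <- tiny_architecture()
  res <- contract_architecture(arch)
  cn <- res$state$connectors
  both <- !is.na(cn$h1_fib) & !is.na(cn$h2_fib)
  expect_true(all(cn$h1_fib[both] != cn$h2_fib[both]))
})
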