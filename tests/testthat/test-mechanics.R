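test_that("bending forces vanish on a straight fiber and for < 3 vertices", {
  straight <- fiber(cbind(seq(0, 0.8, by = 0.2), 0))
  expect_equal(compute_bending_forces(straight), matrix(0, 5, 2))
  two <- fiber(rbind(c(0, 0), c(0.2, 0)))
  expect_equal(compute_bending_forces(two), matrix(0, 2, 2))
})

test_that("bending forces equal the numerical gradient of the WLC energy", {
  v <- matrix(c(0, 0, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  fb <- fiber(v, seg_rest = 1, last_rest = 1, rigidity = 0.075)
  Fa <- compute_bending_forces(fb)
  Fn <- -matrix(num_grad(function(x) bend_energy(x, 0.075, 1),
                         as.vector(v)), ncol = 2)
  expect_lt(max(abs(Fa - Fn)) / max(abs(Fn)), 1e-6)
  # and on an irregular 6-vertex fiber
  set.seed(7)
  v <- cbind(cumsum(runif(6, 0.15, 0.25)), cumsum(rnorm(6, 0, 0.08)))
  fb <- fiber(v, seg_rest = 0.2, rigidity = 0.075)
  Fa <- compute_bending_forces(fb)
  Fn <- -matrix(num_grad(function(x) bend_energy(x, 0.075, 0.2),
                         as.vector(v)), ncol = 2)
  expect_lt(max(abs(Fa - Fn)) / max(abs(Fn)), 1e-5)
})

test_that("bending and extension are internal forces: zero total force/torque", {
  set.seed(11)
  v <- cbind(cumsum(runif(7, 0.15, 0.25)), cumsum(rnorm(7, 0, 0.1)))
  fb <- fiber(v, seg_rest = 0.2, last_rest = 0.13, rigidity = 0.075)
  for (Fm in list(compute_bending_forces(fb), compute_extension_forces(fb))) {
    expect_equal(colSums(Fm), c(0, 0), tolerance = 1e-12)
    torque <- sum(v[, 1] * Fm[, 2] - v[, 2] * Fm[, 1])
    expect_equal(torque, 0, tolerance = 1e-12)
  }
})

test_that("extension forces follow Hooke's law and its gradient", {
  # at rest: zero
  rest <- fiber(cbind(seq(0, 0.8, by = 0.2), 0))
  expect_equal(compute_extension_forces(rest), matrix(0, 5, 2))
  # one segment stretched by 0.01 um at 100 pN/um: 1 pN restoring pair
  p <- mechanics_params(extension_stiffness = 100)
  fb <- fiber(rbind(c(0, 0), c(0.21, 0)), last_rest = 0.2)
  Fm <- compute_extension_forces(fb, p)
  expect_equal(Fm[1, ], c(1, 0), tolerance = 1e-12)
  expect_equal(Fm[2, ], c(-1, 0), tolerance = 1e-12)
  # random fiber matches the numerical energy gradient
  set.seed(3)
  v <- cbind(cumsum(runif(5, 0.15, 0.25)), cumsum(rnorm(5, 0, 0.05)))
  fb <- fiber(v, seg_rest = 0.2, last_rest = 0.17, rigidity = 0)
  Fa <- compute_extension_forces(fb, p)
  Fn <- -matrix(num_grad(function(x) ext_energy(x, fiber_rests(fb), 100),
                         as.vector(v)), ncol = 2)
  expect_lt(max(abs(Fa - Fn)) / max(abs(Fn)), 1e-6)
})

test_that("step_dynamics at kT = 0 with no forces only advances time", {
  fb <- fiber(cbind(seq(0, 0.8, by = 0.2), 0))
  st <- simulation_state(list(fb))
  mech <- mechanics_params(kT = 0)
  st2 <- step_dynamics(st, mech, n_steps = 100)
  expect_equal(st2$fibers[[1]]$vertices, fb$vertices)
  expect_equal(st2$time, 100 * mech$dt)
})

test_that("trajectories are bit-reproducible for identical seeds", {
  set.seed(99)
  fibs <- lapply(1:4, function(i)
    fiber(cbind(runif(3, -1, 1), runif(3, -1, 1)) * 0.3 + i, id = i))
  st <- simulation_state(fibs)
  mech <- mechanics_params()
  a <- step_dynamics(st, mech, n_steps = 500, seed = 123)
  b <- step_dynamics(st, mech, n_steps = 500, seed = 123)
  c <- step_dynamics(st, mech, n_steps = 500, seed = 124)
  expect_identical(a$fibers, b$fibers)
  expect_false(identical(a$fibers, c$fibers))
})

test_that("the dt stability precheck rejects too-large steps, naming the culprit", {
  bad <- mechanics_params(dt = 1e-3)
  expect_error(check_stability(bad), "extension_stiffness")
  ok <- mechanics_params()
  expect_silent(check_stability(ok))
})

test_that("a tethered vertex samples the equipartition variance kT/k", {
  # one trap on vertex 1; the free partner vertex integrates out exactly,
  # so the marginal of the trapped vertex is Boltzmann in the trap alone
  k_trap <- 10
  mech <- mechanics_params(kT = 0.0042, drag_per_length = 50,
                           extension_stiffness = 1, dt = 5e-3)
  fb <- fiber(rbind(c(0, 0), c(0.2, 0)), rigidity = 0)
  tether <- data.frame(fiber = 1L, vertex = 1L, anchor_x = 0, anchor_y = 0,
                       stiffness = k_trap)
  st <- simulation_state(list(fb), tethers = tether)
  xs <- numeric(400)
  cur <- st
  # 400 weakly correlated samples, 500 steps (2.5 s ~ 2.5 relaxation times)
  # apart
  for (i in seq_len(400)) {
    cur <- step_dynamics(cur, mech, n_steps = 500, seed = 1000 + i)
    xs[i] <- cur$fibers[[1]]$vertices[1, 1]
  }
  expect_equal(mean(xs^2), 0.0042 / k_trap, tolerance = 0.10)
})
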