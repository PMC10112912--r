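test_that("architecture sampling is deterministic and honours ranges", {
  rg <- sampling_ranges_desk()
  a <- sample_architecture(rg, 3, master_seed = 7)
  b <- sample_architecture(rg, 3, master_seed = 7)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(sample_architecture(rg, 4, 7)$architecture_seed,
                         a$architecture_seed))
  # degenerate range pins the value
  rg1 <- sampling_ranges(n_motors = c(500, 500))
  expect_equal(sample_architecture(rg1, 1, 1)$n_motors, 500L)
  # fields fall inside their ranges
  for (i in 1:20) {
    s <- sample_architecture(rg, i, 99)
    expect_gte(s$n_crosslinkers, rg$n_crosslinkers[1] - 0.5)
    expect_lte(s$n_crosslinkers, rg$n_crosslinkers[2] + 0.5)
    expect_gte(s$polymer_pool, rg$polymer_pool[1])
    expect_lte(s$polymer_pool, rg$polymer_pool[2])
  }
})

test_that("log-uniform draws are uniform in log10", {
  rg <- sampling_ranges(n_motors = c(10, 1000))
  x <- vapply(seq_len(2000), function(i)
    actomyosim:::with_seed(i, exp(stats::runif(1, log(10), log(1000)))), 0)
  lx <- log10(x)
  counts <- table(cut(lx, seq(1, 3, length.out = 11)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 1e-3)
})

test_that("perturbation presets apply the study factors", {
  arch <- architecture_params(100, 300, 250, 400, polymer_pool = 200,
                              domain_radius = 3)
  id <- apply_perturbation(arch, "identity")
  expect_equal(unclass(id), unclass(arch))
  m2 <- apply_perturbation(arch, "myosin_x2")
  expect_equal(m2$n_motors, 500L)
  expect_equal(m2$polymer_pool, 200)
  expect_equal(m2$dynamics_seed, arch$dynamics_seed)   # matched seeds
  a2 <- apply_perturbation(arch, "actin_x2")
  expect_equal(a2$polymer_pool, 400)
  expect_equal(a2$n_nucleators, 100L)                  # filament count fixed
  arp <- apply_perturbation(arch, "arp_x1.33")
  expect_equal(arp$n_arp23, 400L)                      # 300 * 4/3
  p07 <- apply_perturbation(arch, "polymer_x0.7")
  expect_equal(p07$polymer_pool, 140)
  all3 <- apply_perturbation(arch, "all_three")
  expect_equal(c(all3$n_motors, all3$n_arp23, all3$polymer_pool),
               c(500, 400, 400))
  expect_error(perturbation_spec("nope"))
  cust <- perturbation_spec("custom", c(n_crosslinkers = 0.5))
  expect_equal(apply_perturbation(arch, cust)$n_crosslinkers, 200L)
  expect_error(perturbation_spec("custom", c(bogus = 2)), "unknown")
})

test_that("identity perturbation replays bit-identically", {
  arch <- tiny_architecture()
  row <- run_pair(arch, "identity")
  expect_false(row$failed)
  expect_identical(row$B_perturbed, row$B_reference)
})

test_that("run_sweep produces one row per architecture and spec, resumably", {
  outdir <- withr::local_tempdir()
  rg <- sampling_ranges(n_nucleators = c(12, 16), n_arp23 = c(8, 12),
                        n_motors = c(40, 80), n_crosslinkers = c(80, 160),
                        polymer_pool = c(22, 34), domain_radius = 1.8)
  tab <- run_sweep(2, c("identity", "myosin_x2"), ranges = rg,
                   master_seed = 5, outdir = outdir)
  expect_equal(nrow(tab), 4)
  expect_equal(sort(unique(tab$spec)), c("identity", "myosin_x2"))
  expect_true(file.exists(file.path(outdir, "sweep_myosin_x2.csv")))
  expect_true(file.exists(file.path(outdir, "summary.csv")))
  # re-running with the same outdir reuses completed rows (fast, identical)
  t0 <- proc.time()[3]
  tab2 <- run_sweep(2, c("identity", "myosin_x2"), ranges = rg,
                    master_seed = 5, outdir = outdir)
  expect_lt(proc.time()[3] - t0, 2)
  expect_equal(tab2$B_reference, tab$B_reference)
  # determinism without an outdir
  tab3 <- run_sweep(1, list("identity"), ranges = rg, master_seed = 5)
  expect_identical(tab3$B_reference,
                   tab$B_reference[tab$architecture_id == 1][1])
})

test_that("summarize_sweep matches hand-computed statistics", {
  tab <- data.frame(
    architecture_id = 1:4, spec = "myosin_x2",
    density_metric = c(1, 2, 3, 4),
    B_reference = c(0.10, 0.20, 0.10, 0.40),
    B_perturbed = c(0.20, 0.15, 0.20, 0.80),
    uniform_reference = TRUE,
    uniform_perturbed = c(TRUE, FALSE, TRUE, TRUE),
    failed = FALSE)
  s <- summarize_sweep(tab)
  all_row <- s[s$stratum == "all", ]
  expect_equal(all_row$fraction_increased, 0.75)
  # relative changes: +1, -0.25, +1, +1 -> median 1
  expect_equal(all_row$median_rel_change, 1)
  expect_equal(all_row$n_percolation_failures, 1)
  q1 <- s[s$stratum == "q1", ]
  expect_equal(q1$n, 1)
  expect_equal(q1$fraction_increased, 1)
  expect_error(summarize_sweep(tab[tab$failed, ]), "no successful")
})
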