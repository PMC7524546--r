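test_that("replicate batches are deterministic and carry their seeds", {
  p <- sim_params(N = 30, g = 10, mu = 2e-3, generations = 300)
  fm <- fitness_model(g = 10, s = 0.01)
  a <- run_replicates(p, fm, replicates = 3, base_seed = 50)
  b <- run_replicates(p, fm, replicates = 3, base_seed = 50)
  expect_identical(a, b)
  expect_identical(a$seed, c(50L, 51L, 52L))
  expect_identical(a$replicate, 1:3)
})

test_that("without mutation nothing fixes and Text is censored", {
  p <- sim_params(N = 30, g = 10, mu = 0, lambda = 0.2, L = 3,
                  generations = 200)
  fm <- fitness_model(g = 10, s = 0.01)
  df <- run_replicates(p, fm, replicates = 3, base_seed = 9)
  expect_true(all(df$rate_genome == 0))
  expect_true(all(df$censored))
  expect_true(all(df$text_effective == 200))
})

test_that("a single-point sweep reduces to its replicate batch", {
  spec <- sweep_spec(g = 20, L = 4, lambda = 0.1, N = 30, mu = 2e-3,
                     s = 0.01, generations = 300, replicates = 3,
                     base_seed = 77)
  tab <- sweep_genome_size(spec)
  p <- sim_params(N = 30, g = 20, mu = 2e-3, lambda = 0.1, L = 4,
                  generations = 300)
  direct <- run_replicates(p, fitness_model(g = 20, s = 0.01),
                           replicates = 3, base_seed = 77)
  expect_identical(tab$per_replicate[names(direct)], direct)
  expect_identical(nrow(tab$aggregated), 1L)
  expect_identical(tab$aggregated$n_replicates, 3L)
})

test_that("infeasible grid points (L > g) are skipped with a warning", {
  spec <- sweep_spec(g = c(10, 50), L = 20, lambda = 0, N = 20, mu = 1e-3,
                     s = 0.01, generations = 100, replicates = 2,
                     base_seed = 5)
  expect_warning(tab <- sweep_genome_size(spec), "infeasible")
  expect_identical(unique(tab$per_replicate$g), 50L)
})

test_that("aggregated rates preserve the per-locus x g identity", {
  spec <- sweep_spec(g = c(10, 20), L = "0.2g", lambda = c(0, 0.3), N = 25,
                     mu = 5e-3, s = 0.01, generations = 400, replicates = 3,
                     base_seed = 11)
  tab <- sweep_genome_size(spec)
  expect_equal(tab$aggregated$rate_per_locus_mean * tab$aggregated$g,
               tab$aggregated$rate_genome_mean)
  # resolved fraction rule recorded beside its spec
  expect_true(all(tab$per_replicate$L ==
                  pmax(1, round(0.2 * tab$per_replicate$g))))
  expect_true(all(tab$per_replicate$L_spec == "0.2g"))
})

test_that("core/accessory experiments map fixations onto the genome", {
  spec <- sweep_spec(g = 30, L = 5, lambda = c(0, 0.3), N = 40, mu = 4e-3,
                     g_core = 10, s_core = 0.005, s_accessory = 0.001,
                     generations = 800, replicates = 3, base_seed = 13)
  out <- core_accessory_experiment(spec)
  map <- out$fixation_map
  # each replicate's map covers every locus once and flags g_core core loci
  one <- map[map$replicate == 1 & map$lambda == 0, ]
  expect_identical(nrow(one), 30L)
  expect_identical(sum(one$is_core), 10L)
  # map totals agree with the summary rows
  for (lam in c(0, 0.3)) {
    for (r in 1:3) {
      mp <- map[map$replicate == r & map$lambda == lam, ]
      sm <- out$per_replicate[out$per_replicate$replicate == r &
                              out$per_replicate$lambda == lam, ]
      expect_identical(sum(mp$fixed_count), sm$fixed_total)
      expect_identical(sum(mp$fixed_count[mp$is_core]), sm$core_fixed)
    }
  }
})

test_that("equal core and accessory selection gives symmetric compartments", {
  # same s in both compartments: the split is a pure labelling, so pooled
  # per-locus rates should be close (ratio bounded over replicates)
  spec <- sweep_spec(g = 40, L = 1, lambda = 0, N = 60, mu = 5e-3,
                     g_core = 20, s_core = 0.002, s_accessory = 0.002,
                     generations = 2000, replicates = 6, base_seed = 17)
  out <- core_accessory_experiment(spec)
  core <- mean(out$per_replicate$core_rate)
  acc <- mean(out$per_replicate$accessory_rate)
  expect_gt(core, 0)
  expect_gt(acc, 0)
  expect_lt(abs(log(core / acc)), log(1.6))
})
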