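test_that("llc_size counts exactly the all-zero genomes", {
  expect_identical(llc_size(state_of(matrix(0L, 7, 3))), 7L)
  expect_identical(llc_size(state_of(matrix(1L, 4, 2))), 0L)
  expect_identical(llc_size(state_of(matrix(c(0L, 1L, 0L, 0L, 0L, 0L), 3, 2))),
                   2L)
})

test_that("fixed_mutation_vector returns column minima", {
  expect_identical(fixed_mutation_vector(state_of(matrix(0L, 3, 4))),
                   rep(0L, 4))
  m <- matrix(c(1L, 1L, 0L, 1L, 2L, 2L), 2, 3)
  expect_identical(fixed_mutation_vector(state_of(m)), c(1L, 0L, 2L))
  # one mutation-free individual forces every minimum to zero
  m2 <- rbind(m, c(0L, 0L, 0L))
  st2 <- state_of(m2)
  expect_identical(fixed_mutation_vector(st2), rep(0L, 3))
  expect_true(llc_size(st2) >= 1L)
})

test_that("the tracker records first fixations permanently and sets Text", {
  tr <- new_fixation_tracker(3)
  tr <- update_fixation_tracker(tr, state_of(matrix(0L, 2, 3), 311L))
  expect_true(is.na(tr$text))

  s312 <- state_of(matrix(c(0L, 0L, 1L, 2L, 0L, 0L), 2, 3), 312L)
  tr <- update_fixation_tracker(tr, s312) # minima (0, 1, 0)
  expect_identical(tr$first_fixation_generation, c(NA_integer_, 312L, NA_integer_))
  expect_identical(tr$text, 312L)

  s400 <- state_of(matrix(c(0L, 0L, 2L, 3L, 1L, 1L), 2, 3), 400L)
  tr <- update_fixation_tracker(tr, s400) # minima (0, 2, 1)
  expect_identical(tr$first_fixation_generation[2], 312L) # permanence
  expect_identical(tr$first_fixation_generation[3], 400L)
  expect_identical(tr$text, 312L)
  expect_identical(sum(tr$fixed_mutation_count), 3L)

  expect_error(update_fixation_tracker(tr, state_of(matrix(0L, 2, 3), 100L)),
               "decreased")
})

test_that("fixation rates follow their definition and identity", {
  tr <- new_fixation_tracker(100)
  expect_identical(fixation_rates(tr, 1e4, 100)$genome_wide_rate, 0)

  tr$fixed_mutation_count <- c(rep(2L, 5), rep(1L, 10), rep(0L, 85))
  r <- fixation_rates(tr, 1e4, 100) # 20 fixed levels
  expect_equal(r$genome_wide_rate, 2e-3)
  expect_equal(r$per_locus_rate, 2e-5)
  expect_identical(r$per_locus_rate * 100, r$genome_wide_rate)

  r_loci <- fixation_rates(tr, 1e4, 100, count = "loci") # 15 fixed loci
  expect_equal(r_loci$genome_wide_rate, 1.5e-3)

  expect_error(fixation_rates(tr, 0, 100), "elapsed")
})

test_that("compartment summary partitions fixed counts by the core mask", {
  mask <- c(TRUE, FALSE, FALSE)
  fm <- fitness_model(g = 3, g_core = 1, core_mask = mask)
  tr <- new_fixation_tracker(3)
  tr$fixed_mutation_count <- c(1L, 0L, 2L)

  cs <- compartment_fixation_summary(tr, fm, 100)
  expect_identical(cs$fixed_count[cs$compartment == "core"], 1L)
  expect_identical(cs$fixed_count[cs$compartment == "accessory"], 2L)
  expect_identical(sum(cs$fixed_count), sum(tr$fixed_mutation_count))
  expect_equal(cs$per_locus_rate, c(1 / (1 * 100), 2 / (2 * 100)))

  # normalising by total genome size instead
  cs_g <- compartment_fixation_summary(tr, fm, 100, normalise = "total_g")
  expect_equal(cs_g$per_locus_rate, c(1 / (3 * 100), 2 / (3 * 100)))

  # an empty compartment reports NA, not zero
  fm_all <- fitness_model(g = 3, g_core = 3, core_mask = rep(TRUE, 3))
  cs2 <- compartment_fixation_summary(tr, fm_all, 100)
  expect_true(is.na(cs2$per_locus_rate[cs2$compartment == "accessory"]))
})

test_that("tracker outputs match a naive re-scan of the full state history", {
  p <- sim_params(N = 4, g = 3, mu = 0.15, lambda = 0.5, L = 2,
                  generations = 80)
  fm <- fitness_model(g = 3, s = 0.05)
  run <- simulate_run(p, fm, seed = 21, engine = "r", keep_history = TRUE)
  oracle <- brute_rescan(run$history)
  expect_identical(run$llc_size, oracle$llc)
  expect_identical(run$tracker$first_fixation_generation,
                   oracle$first_fixation_generation)
  expect_identical(run$tracker$fixed_mutation_count,
                   oracle$fixed_mutation_count)
  expect_identical(run$text, oracle$text)
})
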