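test_that("the compiled and reference engines produce bit-identical trajectories", {
  cases <- expand.grid(order = c("methods", "figure1"),
                       form = c("linear", "multiplicative"),
                       lambda = c(0, 0.25),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    p <- sim_params(N = 40, g = 15, mu = 3e-3, lambda = cases$lambda[k],
                    L = 4, generations = 300)
    fm <- fitness_model(g = 15, s = 0.02, form = cases$form[k])
    a <- simulate_run(p, fm, seed = 100 + k, event_order = cases$order[k])
    b <- simulate_run(p, fm, seed = 100 + k, event_order = cases$order[k],
                      engine = "r")
    info <- paste(cases[k, ], collapse = "/")
    expect_identical(a$final_state$counts, b$final_state$counts, info = info)
    expect_identical(a$llc_size, b$llc_size, info = info)
    expect_identical(a$mean_load, b$mean_load, info = info)
    expect_identical(a$fixed_total, b$fixed_total, info = info)
    expect_identical(a$tracker$first_fixation_generation,
                     b$tracker$first_fixation_generation, info = info)
    expect_identical(a$text, b$text, info = info)
  }
})

test_that("a fixed seed reproduces a trajectory bit-for-bit", {
  p <- sim_params(N = 60, g = 25, mu = 2e-3, lambda = 0.1, L = 5,
                  generations = 400)
  fm <- fitness_model(g = 25, s = 0.005)
  a <- simulate_run(p, fm, seed = 77)
  b <- simulate_run(p, fm, seed = 77)
  expect_identical(a$final_state$counts, b$final_state$counts)
  expect_identical(a$llc_size, b$llc_size)
  expect_identical(a$tracker, b$tracker)
})

test_that("stop_at_fixation halts the run at Text", {
  p <- sim_params(N = 40, g = 20, mu = 5e-3, generations = 5000)
  fm <- fitness_model(g = 20, s = 1e-3)
  run <- simulate_run(p, fm, seed = 4, stop_at_fixation = TRUE)
  expect_false(is.na(run$text))
  expect_identical(run$generations_run, run$text)
  # the full-length run agrees on Text (same seed, same trajectory up to it)
  full <- simulate_run(p, fm, seed = 4)
  expect_identical(full$text, run$text)
})

test_that("total loss of fitness is flagged as extinction, not an error", {
  # s = 1 makes every mutation lethal; U = 6 mutates everyone almost surely
  p <- sim_params(N = 8, g = 4, U = 6, generations = 50)
  fm <- fitness_model(g = 4, s = 1)
  run <- simulate_run(p, fm, seed = 2)
  expect_true(run$extinct)
  expect_lt(run$generations_run, 50)
  run_r <- simulate_run(p, fm, seed = 2, engine = "r")
  expect_true(run_r$extinct)
  expect_identical(run$generations_run, run_r$generations_run)
})

test_that("summary statistics are invariant under relabelling individuals", {
  p <- sim_params(N = 30, g = 10, mu = 0.01, lambda = 0.2, L = 3,
                  generations = 60)
  fm <- fitness_model(g = 10, s = 0.01)
  run <- simulate_run(p, fm, seed = 12)
  st <- run$final_state
  perm <- population_state(st$counts[sample(nrow(st$counts)), , drop = FALSE],
                           st$generation)
  expect_identical(llc_size(perm), llc_size(st))
  expect_identical(fixed_mutation_vector(perm), fixed_mutation_vector(st))
  expect_equal(sort(compute_fitness(perm, fm)), sort(compute_fitness(st, fm)))
})

test_that("run summaries satisfy the rate and partition identities", {
  p <- sim_params(N = 50, g = 20, mu = 5e-3, lambda = 0.1, L = 4,
                  generations = 1500)
  fmc <- fitness_model(g = 20, g_core = 8, s_core = 0.005, s_accessory = 0.001)
  run <- simulate_run(p, fmc, seed = 31)
  row <- run_summary(run, replicate = 1)
  expect_equal(row$rate_per_locus * p$g, row$rate_genome)
  expect_identical(row$core_fixed + row$accessory_fixed, row$fixed_total)
  expect_identical(row$duration, run$generations_run)
})
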