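test_that("breeding eligibility is strictly above the cutoff", {
  res <- tibble::tibble(id = 1:3, k = 0.5, fitness = c(0.4, 0.5, 0.6))
  eligible <- eligible_parents_general(res, 0.5)
  expect_equal(eligible$fitness, 0.6)
  expect_equal(nrow(eligible_parents_general(res, 0.7)), 0)
})

test_that("parent sampling is fitness-proportionate", {
  parents <- tibble::tibble(id = 1:2, k = c(0.2, 0.8),
                            fitness = c(0.6, 0.9))
  set.seed(10)
  draws <- sample_parents_proportionate(parents, 1e5)
  expect_equal(mean(draws$id == 2), 0.6, tolerance = 0.01 / 0.6)
  # equal fitness: even split
  eq <- tibble::tibble(id = 1:2, k = 0.5, fitness = c(0.7, 0.7))
  set.seed(11)
  draws <- sample_parents_proportionate(eq, 1e5)
  expect_equal(mean(draws$id == 1), 0.5, tolerance = 0.01 / 0.5)
  # single parent fathers everything; empty set signals extinction
  one <- parents[2, ]
  expect_true(all(sample_parents_proportionate(one, 50)$id == 2))
  expect_error(sample_parents_proportionate(parents[0, ], 10), "extinct")
})

test_that("mutation of K is Gaussian, centred, and clamped", {
  expect_equal(mutate_k(0.7, mutation_sd = 0), 0.7)
  set.seed(12)
  ks <- mutate_k(rep(1, 1e4), 0.025)
  expect_true(all(ks <= 1 & ks >= 0))
  set.seed(13)
  ks <- mutate_k(rep(0.5, 1e5), 0.025)
  expect_equal(mean(ks), 0.5, tolerance = 0.0005 / 0.5)
  expect_equal(sd(ks), 0.025, tolerance = 0.0005 / 0.025)
})

test_that("reproduction conserves population size and inherits K", {
  res <- tibble::tibble(id = 1:4, k = 0.7, fitness = c(0.9, 0.8, 0.7, 0.3))
  sel <- selection_config(mutation_sd = 0)
  set.seed(14)
  offspring <- reproduce_general(res, sel, n_ind = 150)
  expect_equal(nrow(offspring), 150)
  expect_true(all(offspring$k == 0.7))
  expect_true(all(offspring$p == 0 & offspring$c == 0))
  # extinction is signalled, not thrown
  dead <- tibble::tibble(id = 1:3, k = 0.5, fitness = c(0.1, 0.2, 0.4))
  expect_null(reproduce_general(dead, sel, n_ind = 150))
})

test_that("without mutation K is conserved across generations", {
  env <- small_env()
  cmp <- no_competition(20)
  sel <- selection_config(mutation_sd = 0)
  set.seed(15)
  traj <- run_evolution(env, cmp, selection = sel, n_generations = 5,
                        n_ind = 20, init_k = 1)
  expect_equal(traj$mean_k, rep(1, 5))
  expect_equal(traj$k_lower, rep(1, 5))
  expect_false(attr(traj, "extinct"))
  expect_equal(nrow(attr(traj, "final_population")), 20)
})

test_that("extinction terminates the run with a flag", {
  env <- small_env()
  cmp <- no_competition(10)
  set.seed(16)
  # one iteration is far too short to reach the breeding threshold
  traj <- run_evolution(env, cmp, n_generations = 10, n_ind = 10,
                        n_iterations = 1)
  expect_equal(nrow(traj), 1)
  expect_true(attr(traj, "extinct"))
  expect_equal(attr(traj, "extinct_generation"), 1L)
  expect_true(traj$extinct[1])
  expect_equal(glance(traj)$extinct, TRUE)
})

test_that("neutral K drift is approximately uniform away from the bounds", {
  # with clamping at [0, 1], the mutation random walk's stationary law
  # is flat in the interior: evolve many independent walks well past the
  # relaxation time (~(1/sd)^2 steps) and bin their endpoints
  set.seed(17)
  n_walks <- 400
  k <- rep(0.5, n_walks)
  for (step in 1:6000) k <- mutate_k(k, 0.025)
  bins <- cut(k, breaks = seq(0.1, 0.9, by = 0.2))
  counts <- table(bins[!is.na(bins)])
  expected <- length(k[k > 0.1 & k <= 0.9]) / 4
  expect_true(all(abs(counts - expected) < 4 * sqrt(expected)))
  expect_equal(mean(k), 0.5, tolerance = 0.1 / 0.5)
})

test_that("truncated selection takes the first tenth to cross the cutoff", {
  env <- small_env()
  cmp <- no_competition(150)
  sel <- selection_config(mode = "truncated", fitness_cutoff = 0.5)
  set.seed(18)
  gen <- run_generation_truncated(new_population(150, k = 1), env, cmp, sel)
  expect_equal(nrow(gen$parents), 15)
  expect_true(all(gen$parents$fitness > 0.5))
  # free access to a balanced rail: arrivals well before 500 iterations
  expect_lt(gen$n_iterations, 500)
  expect_gt(gen$n_iterations, 200)
})

test_that("simultaneous arrivals are pooled then randomly truncated", {
  # one balanced food without competition: all individuals move in
  # lockstep and cross the cutoff at the same iteration
  env <- gf_environment(1)
  cmp <- competition_config(c = 0, n_food = 1, n_ind = 20)
  sel <- selection_config(mode = "truncated", fitness_cutoff = 0.5)
  set.seed(19)
  gen <- run_generation_truncated(new_population(20, k = 1), env, cmp, sel)
  expect_equal(nrow(gen$parents), 2)  # ceiling(0.1 * 20)
  expect_true(all(gen$result$fitness > 0.5))
  # a truncation fraction of one degenerates to threshold-only selection
  sel_all <- selection_config(mode = "truncated", fitness_cutoff = 0.5,
                              truncation_fraction = 1)
  set.seed(19)
  gen_all <- run_generation_truncated(new_population(20, k = 1), env, cmp,
                                      sel_all)
  expect_equal(nrow(gen_all$parents), 20)
})

test_that("a too-high cutoff aborts a truncated generation with a diagnostic", {
  # a lone severely imbalanced food caps fitness below the cutoff
  env <- gf_environment(16)
  cmp <- competition_config(c = 0, n_food = 1, n_ind = 5)
  sel <- selection_config(mode = "truncated", fitness_cutoff = 0.9,
                          max_iterations = 400)
  set.seed(20)
  expect_error(
    run_generation_truncated(new_population(5, k = 1), env, cmp, sel),
    "safety cap")
})

test_that("evolution under truncated selection cannot go extinct", {
  env <- small_env()
  cmp <- competition_config(c = 0.9, n_food = 3, n_ind = 30)
  sel <- selection_config(mode = "truncated", fitness_cutoff = 0.5)
  set.seed(21)
  traj <- run_evolution(env, cmp, selection = sel, n_generations = 3,
                        n_ind = 30)
  expect_equal(nrow(traj), 3)
  expect_false(attr(traj, "extinct"))
  expect_true(all(traj$n_parents == 3))
})
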