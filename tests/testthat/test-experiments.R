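test_that("K summaries use the linear-interpolation quantile convention", {
  s <- summarize_k(rep(0.4, 10))
  expect_equal(unlist(s), c(mean_k = 0.4, k_lower = 0.4, k_upper = 0.4))
  s <- summarize_k(seq(0, 1, length.out = 1001))
  expect_equal(s$k_lower, 0.025)
  expect_equal(s$k_upper, 0.975)
  s <- summarize_k(0.3)
  expect_equal(unlist(s), c(mean_k = 0.3, k_lower = 0.3, k_upper = 0.3))
  expect_error(summarize_k(numeric(0)), "non-empty")
})

test_that("replicate batches are deterministic given the master seed", {
  cfg <- experiment_config(experiment = "single-generation", c = 0.683,
                           n_ind = 20, n_iterations = 50,
                           n_replicates = 3, seed = 7)
  a <- run_replicates(cfg)
  b <- run_replicates(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 3 * 2)  # one row per replicate and K group
  expect_equal(sort(unique(a$seed)), sort(replicate_seeds(7, 3)))
  # a different master seed gives different draws
  cfg2 <- experiment_config(experiment = "single-generation", c = 0.683,
                            n_ind = 20, n_iterations = 50,
                            n_replicates = 3, seed = 8)
  expect_false(isTRUE(all.equal(run_replicates(cfg2)$mean_fitness,
                                a$mean_fitness)))
})

test_that("configuration validation reports itemised errors", {
  expect_error(experiment_config(c = 1.2), "competition levels")
  expect_error(experiment_config(experiment = "nope"), "experiment")
  expect_error(experiment_config(phi = -1), "phi")
  expect_error(
    experiment_config(c = 1.2, phi = -1, n_replicates = 0),
    "`c`.*\n.*phi.*\n.*n_replicates")
  expect_error(experiment_config(environment = "9-food-wild"),
               "unknown environment preset")
})

test_that("YAML configurations load with defaults and validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "experiment: single-generation",
    "environment:",
    "  preset: 3-food-mild",
    "c: 0.683",
    "composition: {k_low: 0.25, k_high: 0.85, prop_high: 0.5}",
    "n_replicates: 2"
  ), path)
  cfg <- load_experiment_config(path)
  expect_s3_class(cfg, "nutlat_config")
  expect_equal(cfg$n_ind, 150L)          # default applied
  expect_equal(cfg$n_iterations, 500L)
  expect_equal(cfg$composition$k_high, 0.85)
  pop <- mixed_population(cfg$n_ind, cfg$composition$k_low,
                          cfg$composition$k_high,
                          cfg$composition$prop_high)
  expect_equal(sum(pop$k == 0.25), 75)
  expect_equal(sum(pop$k == 0.85), 75)

  shipped <- system.file("extdata", "exp2-config.yaml", package = "nutlat")
  cfg2 <- load_experiment_config(shipped)
  expect_equal(cfg2$c, c(0.683, 0.767))
  expect_equal(cfg2$n_replicates, 30L)

  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_error(load_experiment_config(empty), "empty|missing")

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("experiment: sweep", "environment: 3-food-mild", "c: [0.5, 1.5]"),
             bad)
  expect_error(load_experiment_config(bad), "competition levels")
  expect_error(load_experiment_config("/nonexistent/conf.yaml"), "not found")
})

test_that("results round-trip through CSV plus manifest", {
  cfg <- experiment_config(experiment = "single-generation", c = 0.683,
                           n_ind = 20, n_iterations = 50,
                           n_replicates = 2, seed = 3)
  summaries <- run_replicates(cfg)
  dir <- withr::local_tempdir()
  paths <- write_results(summaries, dir, config = cfg)
  expect_true(all(file.exists(paths)))
  back <- read_results(dir)
  merged <- dplyr::left_join(summaries, back$summaries,
                             by = c("c", "k", "group", "replicate", "seed"),
                             suffix = c("", ".rt"))
  for (m in c("mean_fitness", "mean_beta", "mean_iterations_displaced")) {
    expect_equal(merged[[paste0(m, ".rt")]], merged[[m]], tolerance = 1e-12)
  }
  expect_equal(sort(back$manifest$seeds), sort(unique(summaries$seed)))
  expect_equal(back$manifest$config$n_replicates, 2)
  expect_equal(back$manifest$quantile_convention,
               "linear interpolation (R type 7)")
})

test_that("extinct replicates are flagged in sweep records, not dropped", {
  env <- small_env()
  set.seed(30)
  sweep <- run_competition_sweep(c_values = 0, environment = env,
                                 n_generations = 2, n_replicates = 3,
                                 seed = 5, n_ind = 20, n_iterations = 20)
  # 20 iterations cannot reach the breeding threshold: all extinct
  expect_equal(nrow(sweep), 3)
  expect_true(all(sweep$extinct))
  expect_true(all(sweep$extinct_generation == 1))
})

test_that("the command-line interface dispatches and rejects bad input", {
  expect_equal(cli_main(character(0)), 1L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 1L)
  # run with --generations 0 is rejected
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("experiment: sweep", "environment: 3-food-mild", "c: 0.1"),
             path)
  expect_equal(suppressMessages(cli_main(c("run", path, "--generations", "0"))),
               1L)
  # a tiny sweep writes results and a manifest
  out <- withr::local_tempdir()
  status <- suppressMessages(cli_main(c(
    "sweep", "--c", "0.5", "--replicates", "1", "--generations", "2",
    "--iterations", "200", "--seed", "2", "--out", out, "--quiet")))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  back <- read_results(out)
  expect_equal(nrow(back$summaries), 1)
})

test_that("tidiers and plots expose the standard surfaces", {
  env <- small_env()
  cmp <- competition_config(c = 0.683, n_food = 3, n_ind = 20)
  set.seed(40)
  gen <- run_generation(mixed_population(20), env, cmp, n_iterations = 50,
                        record_series = TRUE)
  expect_s3_class(tidy(gen), "tbl_df")
  expect_equal(nrow(glance(gen)), 1)
  expect_s3_class(autoplot(gen), "ggplot")
  set.seed(41)
  traj <- run_evolution(env, cmp, n_generations = 2, n_ind = 20,
                        n_iterations = 200)
  expect_s3_class(tidy(traj), "tbl_df")
  expect_equal(nrow(glance(traj)), 1)
  expect_s3_class(autoplot(traj), "ggplot")
  set.seed(42)
  sweep <- run_competition_sweep(c_values = c(0, 0.5), environment = env,
                                 n_generations = 2, n_replicates = 2,
                                 seed = 1, n_ind = 20, n_iterations = 200)
  expect_s3_class(plot_sweep(sweep), "ggplot")
  freq <- run_frequency_grid(c_values = 0.683, prop_high = c(0.3, 0.7),
                             n_replicates = 2, seed = 1, n_ind = 20,
                             n_iterations = 50)
  expect_s3_class(plot_frequency_grid(freq), "ggplot")
})
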