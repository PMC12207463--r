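tiny_cfg <- function(...) {
  defaults <- list(n_episodes = 3L, arena = 9L, episode_length = c(30L, 40L),
                   probe_every = 60L, probe_episodes = 2L,
                   probe_max_steps = 60L, n_probed = 1L)
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}

test_that("a learned smoke run produces logs, probes, a curve and a manifest", {
  dir <- tempfile("gsrun")
  run <- run_experiment(tiny_cfg(), seed = 31, outdir = dir)
  expect_s3_class(run, "gs_run")
  expect_equal(nrow(run$episodes), 3L)
  expect_false(is.null(run$bias))
  expect_gte(nrow(run$bias), 1L)
  expect_equal(nrow(run$curve), 3L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "bias_by_bin.csv")))
  expect_true(file.exists(file.path(dir, "training_curve.csv")))
  g <- glance(run)
  expect_equal(g$preset, "micro")  # the shrunk preset reports itself honestly
  expect_equal(g$total_steps, run$manifest$total_steps)
  td <- tidy(run)
  expect_true(all(c("group", "bin", "mean_ratio", "bias") %in% names(td)))
})

test_that("the same config and seed reproduce a run exactly", {
  r1 <- run_experiment(tiny_cfg(), seed = 77)
  r2 <- run_experiment(tiny_cfg(), seed = 77)
  expect_identical(r1$events, r2$events)
  expect_identical(tidy(r1$bias), tidy(r2$bias))
  expect_identical(r1$curve, r2$curve)
})

test_that("wall layout under adversarial scripted play yields zero mixed events", {
  cfg <- experiment_config(layout = "wall", policy_kind = "approach_nearest_ready",
                           n_episodes = 4L, episode_length = c(120L, 150L),
                           restock_prob = 0.1)
  run <- run_experiment(cfg, seed = 5)
  expect_gt(nrow(run$events), 0L)  # adversaries do interact within their side
  expect_true(all(run$events$initiator_group == run$events$target_group))
})

test_that("scripted policy construction validates its kind and steers in probes", {
  expect_error(scripted_policy("teleport"), "arg")
  pcfg <- micro_probe_config(max_steps = 300L)
  blue_seeker <- scripted_policy("approach_color", color = c(0, 0, 150))
  res <- dplyr::bind_rows(lapply(1:6, function(e) {
    run_probe_episode(blue_seeker, pcfg, agent_group = "red", seed = 40 + e)
  }))
  decided <- res[res$chosen != "none", ]
  expect_gt(nrow(decided), 3L)
  expect_true(all(decided$chosen_group == "blue"))
})

test_that("figure tables assemble conditions and flag missing ones", {
  runs <- list(run_experiment(tiny_cfg(mixed_ratio = c(8L, 0L),
                                       probe_episodes = 5L,
                                       probe_max_steps = 250L), seed = 51),
               run_experiment(tiny_cfg(mixed_ratio = c(4L, 4L),
                                       probe_episodes = 5L,
                                       probe_max_steps = 250L), seed = 52))
  t2c <- reproduce_figure_table(runs, "fig2c")
  expect_true(all(c("condition", "bin", "bias") %in% names(t2c)))
  expect_setequal(unique(t2c$condition), c("8:0", "4:4"))
  expect_setequal(attr(t2c, "missing_conditions"), c("7:1", "6:2", "5:3"))
  t2d <- reproduce_figure_table(runs, "fig2d")
  expect_equal(nrow(t2d), 2L)
  empty <- reproduce_figure_table(list(), "fig2c")
  expect_equal(nrow(empty), 0L)
  expect_match(attr(empty, "missing_conditions"), "empty")
})

test_that("event logs categorize and chance-normalize end to end", {
  cfg <- experiment_config(policy_kind = "approach_nearest_ready",
                           mixed_ratio = c(6L, 2L), n_episodes = 8L,
                           episode_length = c(100L, 120L), restock_prob = 0.1)
  run <- run_experiment(cfg, seed = 9)
  expect_gt(nrow(run$events), 0L)
  tab <- reproduce_figure_table(list(run), "fig2a")
  expect_setequal(tab$category,
                  c("majority_on_majority", "minority_on_minority", "mixed"))
  expect_equal(sum(tab$percentage), 1)
})

test_that("YAML configs load and validate", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("name: ratio_sweep/7v1", "mixed_ratio: [7, 1]",
               "n_episodes: 2", "preset: micro"), path)
  cfg <- load_experiment_config(path)
  expect_s3_class(cfg, "gs_experiment_config")
  expect_equal(cfg$mixed_ratio, c(7L, 1L))
  expect_true(validate_experiment_config(cfg))
  bad <- cfg; bad$mixed_ratio <- c(5L, 4L)
  expect_error(validate_experiment_config(bad), "majority:minority")
})

test_that("shipped experiment configs cover every named condition and validate", {
  dir <- system.file("configs", package = "groupsim")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  expect_gte(length(files), 12L)
  names <- vapply(files, function(f) load_experiment_config(f)$name, "")
  for (f in files) expect_true(validate_experiment_config(load_experiment_config(f)))
  expect_true(any(grepl("ratio_sweep/8v0", names)))
  expect_true(any(grepl("layout/wall", names)))
  expect_true(any(grepl("layout/eight_cell", names)))
  expect_true(any(grepl("individuation", names)))
  expect_true(any(grepl("single_resource", names)))
  expect_true(any(grepl("colors/purple", names)))
})
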