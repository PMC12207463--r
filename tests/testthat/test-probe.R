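test_that("a scripted approacher chooses its color; noop never decides", {
  pcfg <- micro_probe_config(max_steps = 400L)
  red_seeker <- scripted_policy("approach_color", color = c(150, 0, 0))
  res <- dplyr::bind_rows(lapply(1:10, function(e) {
    run_probe_episode(red_seeker, pcfg, agent_group = "red", seed = e)
  }))
  decided <- res[res$chosen != "none", ]
  expect_gt(nrow(decided), 7L)
  expect_true(all(decided$chosen_group == "red"))

  res_noop <- run_probe_episode(scripted_policy("noop"), pcfg,
                                agent_group = "red", seed = 1)
  expect_equal(res_noop$chosen, "none")
  expect_equal(res_noop$steps_taken, 400L)
})

test_that("probe episodes are reproducible under a fixed seed", {
  pcfg <- micro_probe_config(max_steps = 300L)
  pol <- scripted_policy("random_walk")
  expect_identical(run_probe_episode(pol, pcfg, "red", seed = 7),
                   run_probe_episode(pol, pcfg, "red", seed = 7))
  snap <- snapshot_policy(init_policy(policy_spec_micro(), seed = 1), step = 0)
  expect_identical(run_probe_episode(snap, pcfg, "blue", seed = 9),
                   run_probe_episode(snap, pcfg, "blue", seed = 9))
})

test_that("probes never mutate policy parameters", {
  pcfg <- micro_probe_config(max_steps = 200L)
  snap <- snapshot_policy(init_policy(policy_spec_micro(), seed = 2), step = 0)
  before <- snap$params
  invisible(run_probe_episode(snap, pcfg, "red", seed = 3))
  expect_identical(snap$params, before)
})

test_that("group-bias evaluation bins, counts and averages per agent", {
  # two red agents always seeking red, two blue agents always seeking blue:
  # ratio must be 1.0 in every bin; an indifferent random walker sits near 0.5
  snaps <- tibble::tibble(
    agent_id = c("r1", "r2", "b1", "b2"),
    group = c("red", "red", "blue", "blue"),
    training_step = c(0, 0, 0, 0),
    policy = list(scripted_policy("approach_color", color = c(150, 0, 0)),
                  scripted_policy("approach_color", color = c(150, 0, 0)),
                  scripted_policy("approach_color", color = c(0, 0, 150)),
                  scripted_policy("approach_color", color = c(0, 0, 150))))
  pcfg <- probe_config(max_steps = 400L, episodes = 6L)
  tab <- evaluate_group_bias(snaps, pcfg, bin_width = 1, seed = 5)
  expect_s3_class(tab, "gs_bias_table")
  expect_true(all(tab$ratio[tab$n_decided > 0] == 1))
  gb <- group_bias_table(tab)
  expect_equal(gb$bias, 0.5, tolerance = 1e-9)
})

test_that("undecided episodes are excluded from ratios and counted separately", {
  snaps <- tibble::tibble(agent_id = "r1", group = "red", training_step = 0,
                          policy = list(scripted_policy("noop")))
  pcfg <- probe_config(max_steps = 50L, episodes = 3L)
  tab <- evaluate_group_bias(snaps, pcfg, bin_width = 1, seed = 6)
  expect_equal(tab$n_decided, 0L)
  expect_equal(tab$n_undecided, 3L)
  expect_true(is.na(tab$ratio))
})

test_that("known choice bias is recovered within binomial error", {
  # synthetic choosers with P(own color) = 0.5 + b feed the full probe +
  # binning pipeline; the estimated group bias must recover b
  pcfg <- probe_config(max_steps = 500L, episodes = 50L)
  for (b in c(0, 0.3)) {
    snaps <- tibble::tibble(
      agent_id = c("r1", "r2", "b1", "b2"),
      group = c("red", "red", "blue", "blue"),
      training_step = 0,
      policy = list(
        make_biased_chooser(0.5 + b, c(150, 0, 0), c(0, 0, 150)),
        make_biased_chooser(0.5 + b, c(150, 0, 0), c(0, 0, 150)),
        make_biased_chooser(0.5 + b, c(0, 0, 150), c(150, 0, 0)),
        make_biased_chooser(0.5 + b, c(0, 0, 150), c(150, 0, 0))))
    tab <- evaluate_group_bias(snaps, pcfg, bin_width = 1,
                               seed = 100 + round(100 * b))
    n <- sum(tab$n_decided)
    expect_gt(n, 150)
    est <- group_bias_table(tab)$bias
    p <- 0.5 + b
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(est - b), 3 * se + 1e-9)
  }
})

test_that("individuation probes score marked-sprite avoidance per side", {
  marked <- list(red = c(255, 255, 0), blue = c(255, 255, 0))
  snaps <- tibble::tibble(
    agent_id = c("r2", "b2"), group = c("red", "blue"), training_step = 0,
    policy = list(scripted_policy("avoid_pixel"), scripted_policy("avoid_pixel")))
  pcfg <- probe_config(max_steps = 400L, episodes = 5L)
  tab <- evaluate_individuation(snaps, pcfg, marked, bin_width = 1, seed = 8)
  expect_setequal(unique(tab$target_side), c("ingroup", "outgroup"))
  ok <- tab$n_decided > 0
  expect_true(all(tab$score[ok] == 1))
  expect_equal(individuation_gap(tab$score[tab$target_side == "ingroup" & ok][1],
                                 tab$score[tab$target_side == "outgroup" & ok][1]),
               0)
})
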