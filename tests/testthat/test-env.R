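test_that("reset places agents on distinct cells with zeroed state", {
  cfg <- env_config(make_layout("default"))
  st <- reset_episode(cfg, roster_n(4, 4), seed = 1)
  as <- agent_states(st)
  expect_equal(nrow(as), 8L)
  expect_equal(anyDuplicated(paste(as$row, as$col)), 0L)
  expect_true(all(as$inv1 == 0 & as$inv2 == 0 & as$inv3 == 0))
  expect_true(all(!as$ready))
  expect_true(all(as$freeze_timer == 0L & as$removal_timer == 0L))
  expect_true(st$episode_length >= 1000L && st$episode_length <= 5000L)
  expect_false(any(cfg$layout$wall[cbind(as$row, as$col)]))
})

test_that("two resets with the same seed give identical states", {
  cfg <- env_config(make_layout("default"))
  s1 <- reset_episode(cfg, roster_n(4, 4), seed = 99)
  s2 <- reset_episode(cfg, roster_n(4, 4), seed = 99)
  expect_identical(s1, s2)
})

test_that("wall layout spawns each color strictly on its own side", {
  cfg <- env_config(make_layout("wall"))
  mid <- (cfg$layout$ncol + 1L) %/% 2L
  for (seed in 1:5) {
    st <- reset_episode(cfg, roster_n(4, 4), seed = seed)
    as <- agent_states(st)
    expect_true(all(as$col[as$group == "red"] < mid))
    expect_true(all(as$col[as$group == "blue"] > mid))
  }
})

test_that("reset rejects rosters larger than the spawn capacity", {
  cfg <- env_config(make_layout("probe"))
  big <- roster_n(15, 15)
  expect_error(reset_episode(cfg, big, seed = 1), "spawn points")
})

test_that("walking over a resource collects it, sets ready, clears the cell", {
  st <- face_off_state(orient = c(2L, 4L), inv = list(c(0, 0, 0), c(0, 0, 0)),
                       ready = c(FALSE, FALSE),
                       pos = list(c(8L, 8L), c(14L, 14L)))
  st$resources[8L, 9L] <- 2L  # green resource one cell east of agent a
  out <- env_step(st, c(ACTIONS[["FORWARD"]], ACTIONS[["NOOP"]]))
  as <- agent_states(out$state)
  expect_equal(c(as$inv1[1], as$inv2[1], as$inv3[1]), c(0, 1, 0))
  expect_true(as$ready[1])
  expect_equal(out$state$resources[8L, 9L], 0L)
})

test_that("frozen agents' actions are ignored and timers tick down", {
  st <- face_off_state()
  st$agents$freeze[1] <- 3L
  out <- env_step(st, c(ACTIONS[["FORWARD"]], ACTIONS[["NOOP"]]))
  as <- agent_states(out$state)
  expect_equal(c(as$row[1], as$col[1]), c(8L, 8L))
  expect_equal(as$freeze_timer[1], 2L)
})

test_that("null dynamics: all NOOP on a bare board yields no rewards or events", {
  st <- face_off_state()
  out <- env_step(st, c(ACTIONS[["NOOP"]], ACTIONS[["NOOP"]]))
  expect_equal(unname(out$rewards), c(0, 0))
  expect_equal(nrow(out$events), 0L)
})

test_that("movement into walls or occupied cells is a no-op", {
  st <- face_off_state(pos = list(c(2L, 2L), c(2L, 3L)), orient = c(1L, 1L))
  out <- env_step(st, c(ACTIONS[["FORWARD"]], ACTIONS[["NOOP"]]))  # into border wall
  expect_equal(agent_states(out$state)$row[1], 2L)
  st2 <- face_off_state(pos = list(c(5L, 2L), c(4L, 2L)), orient = c(1L, 1L))
  out2 <- env_step(st2, c(ACTIONS[["FORWARD"]], ACTIONS[["NOOP"]]))  # into agent b
  expect_equal(agent_states(out2$state)$row[1], 5L)
})

test_that("interaction reward equals the inventory dot product over a grid of pairs", {
  pairs <- list(
    list(c(2, 0, 1), c(1, 0, 3), 5),
    list(c(1, 0, 0), c(0, 1, 0), 0),     # orthogonal inventories
    list(c(1, 1, 1), c(1, 1, 1), 3),
    list(c(4, 2, 0), c(3, 5, 1), 22),
    list(c(0, 0, 0), c(2, 2, 2), 0),
    list(c(7, 1, 2), c(0, 0, 9), 18))
  for (p in pairs) {
    st <- face_off_state(inv = list(p[[1]], p[[2]]))
    res <- resolve_interaction(st, "a")
    expect_false(is.null(res$event))
    expect_equal(res$event$reward, p[[3]])
    expect_equal(unname(res$rewards["a"]), unname(res$rewards["b"]))
    # freeze applied even at zero reward
    expect_equal(res$state$agents$freeze, c(16L, 16L))
  }
})

test_that("beam respects range, walls, and readiness requirements", {
  # out of range (beam range 3, target 4 cells away)
  st <- face_off_state(pos = list(c(8L, 8L), c(8L, 12L)))
  expect_null(resolve_interaction(st, "a")$event)
  # in range
  st <- face_off_state(pos = list(c(8L, 8L), c(8L, 11L)))
  expect_false(is.null(resolve_interaction(st, "a")$event))
  # wall between: wall layout center column blocks the beam
  cfgw <- env_config(make_layout("wall"), restock_prob = 0)
  mid <- (cfgw$layout$ncol + 1L) %/% 2L
  st <- face_off_state(cfg = cfgw, pos = list(c(8L, mid - 1L), c(8L, mid + 1L)))
  expect_null(resolve_interaction(st, "a")$event)
  # target not ready -> no event
  st <- face_off_state(ready = c(TRUE, FALSE))
  expect_null(resolve_interaction(st, "a")$event)
  # initiator not ready -> no event by default, event when the flag is off
  st <- face_off_state(ready = c(FALSE, TRUE))
  expect_null(resolve_interaction(st, "a")$event)
  cfg2 <- env_config(make_layout("default"), require_initiator_ready = FALSE,
                     restock_prob = 0)
  st2 <- face_off_state(cfg = cfg2, ready = c(FALSE, TRUE))
  expect_false(is.null(resolve_interaction(st2, "a")$event))
})

test_that("elevated personal freeze applies to both interaction partners", {
  st <- face_off_state(roster = roster_two(pfreeze = c(16L, 64L)))
  res <- resolve_interaction(st, "a")
  expect_equal(res$state$agents$freeze, c(64L, 64L))
})

test_that("an interacting pair is frozen exactly 16 steps then absent exactly 50", {
  st <- face_off_state()
  out <- env_step(st, c(ACTIONS[["INTERACT"]], ACTIONS[["NOOP"]]))
  expect_equal(nrow(out$events), 1L)
  tr <- track_agent(out$state, "a", 70L)
  # frozen in place for steps 1..15 after the interaction step (16 counting it)
  expect_true(all(tr$log$present[1:15] & tr$log$frozen[1:15]))
  expect_equal(out$state$agents$freeze[1], 16L)  # frozen at the event step itself
  # absent for exactly 50 steps
  expect_true(all(!tr$log$present[16:65]))
  # present again afterwards, inventory and ready reset
  expect_true(tr$log$present[66])
  expect_false(tr$log$frozen[66])
  expect_equal(sum(tr$state$agents$inv[, 1]), 0)
  expect_false(tr$state$agents$ready[1])
})

test_that("inventory conservation: collected totals never exceed spawned resources", {
  cfg <- env_config(make_layout("default"), restock_prob = 0)
  st <- reset_episode(cfg, roster_n(4, 4), seed = 5)
  spawned <- tabulate(st$resources[st$resources > 0L], nbins = 3L)
  set.seed(7)
  for (t in 1:200) {
    out <- env_step(st, sample(7L, 8L, replace = TRUE))  # movement only
    st <- out$state
    collected <- rowSums(st$agents$inv)
    remaining <- tabulate(st$resources[st$resources > 0L], nbins = 3L)
    expect_true(all(collected + remaining == spawned))
  }
})

test_that("episode lengths are uniform on [1000, 5000]", {
  cfg <- env_config(make_layout("default"))
  set.seed(123)
  lens <- replicate(400, reset_episode(cfg, roster_n(2, 2))$episode_length)
  expect_true(all(lens >= 1000L & lens <= 5000L))
  # frequency test against the uniform distribution over the range
  thirds <- cut(lens, breaks = c(999, 2333, 3666, 5000))
  p <- stats::chisq.test(table(thirds), p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.001)
})

test_that("action vector length mismatch is a contract violation", {
  st <- face_off_state()
  expect_error(env_step(st, ACTIONS[["NOOP"]]), "one action per agent")
})
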