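# Oracles for the learning machinery: explicit-summation returns, surrogate
# finite-difference gradient checks, and a one-step bandit convergence run.

test_that("discounted returns match the stated examples and explicit summation", {
  expect_equal(discounted_returns(c(1, 0, 0), 0.99, 0), c(1, 0, 0))
  expect_equal(discounted_returns(c(0, 0, 1), 0.99, 0), c(0.9801, 0.99, 1))
  expect_equal(discounted_returns(c(0, 0), 0.99, 2), c(0.99^2 * 2, 0.99 * 2))
  set.seed(11)
  max_dev <- 0
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    r <- rnorm(n)
    g <- runif(1, 0.5, 0.999)
    v <- rnorm(1)
    max_dev <- max(max_dev, abs(discounted_returns(r, g, v) -
                                  brute_force_returns(r, g, v)))
  }
  expect_lt(max_dev, 1e-10)
})

test_that("actor-critic gradients match finite differences (feedforward, features)", {
  check_gradients(policy_spec_micro(), function() runif(FEATURE_DIM))
})

test_that("actor-critic gradients match finite differences (GRU core)", {
  spec <- policy_spec("features", core = "gru", core_units = 8L,
                      trunk = c(10L, 10L), head_units = 8L)
  check_gradients(spec, function() runif(FEATURE_DIM), n_steps = 4L)
})

test_that("actor-critic gradients match finite differences (conv + LSTM, tiny pixels)", {
  spec <- policy_spec("pixels",
                      conv = list(list(channels = 4L, kernel = 4L, stride = 4L),
                                  list(channels = 6L, kernel = 2L, stride = 1L)),
                      obs_shape = c(16L, 16L, 3L),
                      trunk = c(8L, 8L), core = "lstm", core_units = 6L,
                      head_units = 8L)
  check_gradients(spec, function() array(runif(16 * 16 * 3, 0, 255),
                                         dim = c(16L, 16L, 3L)),
                  n_steps = 3L, n_checks = 3L)
})

test_that("zero advantages leave only value and entropy gradients", {
  spec <- policy_spec_micro()
  pol <- init_policy(spec, seed = 3)
  # rewards chosen so returns exactly equal the (near-zero) values is hard;
  # instead check the decomposition: with rewards == values and gamma-chain
  # broken by one-step segments, adv = 0 gives pg term exactly 0
  obs <- runif(FEATURE_DIM)
  o <- policy_forward(pol, obs, c(0, 0, 0))
  seg <- make_segment(list(obs), matrix(0, 1, 3), actions = 1L,
                      rewards = o$value, bootstrap_value = 0)
  cfg <- training_config("micro", gamma = 0.99)
  # make the return equal the value so the advantage vanishes
  seg$rewards <- o$value
  out <- actor_critic_loss(pol, seg, cfg)
  expect_equal(out$pg_loss, 0, tolerance = 1e-12)
  expect_equal(out$vf_loss, 0, tolerance = 1e-12)
  expect_gt(out$entropy, 2.07)  # ~ln 8 at init
})

test_that("repeated updates on a one-step bandit converge on the rewarded action", {
  spec <- policy_spec("features", feature_dim = 4L, core = "none",
                      trunk = c(8L, 8L), head_units = 8L)
  pol <- init_policy(spec, seed = 7)
  cfg <- training_config("micro", lr = 0.02, entropy_weight = 0.003)
  obs <- c(1, 0, 1, 0)
  probs_of <- function(p) {
    l <- policy_forward(p, obs, c(0, 0, 0))$logits
    e <- exp(l - max(l)); e / sum(e)
  }
  p0 <- probs_of(pol)[3]
  set.seed(8)
  traj <- numeric(0)
  for (it in 1:300) {
    segs <- lapply(1:8, function(j) {
      a <- sample.int(8, 1, prob = probs_of(pol))
      make_segment(list(obs), matrix(0, 1, 3), actions = a,
                   rewards = as.numeric(a == 3L), bootstrap_value = 0)
    })
    upd <- actor_critic_update(pol, segs, cfg)
    pol <- upd$policy
    traj <- c(traj, probs_of(pol)[3])
  }
  expect_gt(tail(traj, 1), 0.95)
  # probability rises essentially monotonically in expectation
  expect_gt(mean(tail(traj, 50)), mean(head(traj, 50)))
  expect_gt(p0, 0.1); expect_lt(p0, 0.2)  # near-uniform start
})

test_that("a large entropy weight keeps the policy near uniform", {
  spec <- policy_spec("features", feature_dim = 4L, core = "none",
                      trunk = c(8L, 8L), head_units = 8L)
  pol <- init_policy(spec, seed = 9)
  cfg <- training_config("micro", lr = 0.02, entropy_weight = 5)
  obs <- c(1, 0, 1, 0)
  set.seed(10)
  for (it in 1:100) {
    a <- sample.int(8, 1)
    seg <- make_segment(list(obs), matrix(0, 1, 3), actions = a,
                        rewards = as.numeric(a == 3L), bootstrap_value = 0)
    pol <- actor_critic_update(pol, seg, cfg)$policy
  }
  l <- policy_forward(pol, obs, c(0, 0, 0))$logits
  p <- exp(l - max(l)); p <- p / sum(p)
  expect_gt(-sum(p * log(p)), log(8) - 0.05)
})

test_that("policy forward is deterministic and near-uniform at initialization", {
  pol <- init_policy(policy_spec_micro(), seed = 12)
  obs <- runif(FEATURE_DIM)
  o1 <- policy_forward(pol, obs, c(1, 2, 0))
  o2 <- policy_forward(pol, obs, c(1, 2, 0))
  expect_identical(o1, o2)
  p <- exp(o1$logits - max(o1$logits)); p <- p / sum(p)
  expect_gt(-sum(p * log(p)), log(8) - 0.01)
  expect_true(all(is.finite(o1$logits)))
})

test_that("observation locality: world changes outside the window leave outputs unchanged", {
  cfg <- env_config(make_layout("default", width = 25, height = 25),
                    restock_prob = 0)
  st <- face_off_state(cfg = cfg, pos = list(c(13L, 10L), c(13L, 13L)),
                       orient = c(2L, 4L))
  st2 <- st
  st2$resources[25L, 25L] <- 1L   # far outside the 11x11 window
  pol <- init_policy(policy_spec_micro(), seed = 13)
  f1 <- feature_observation(st, "a")
  f2 <- feature_observation(st2, "a")
  expect_identical(f1, f2)
  expect_identical(policy_forward(pol, f1, c(0, 0, 0)),
                   policy_forward(pol, f2, c(0, 0, 0)))
  expect_identical(render_observation(st, "a"), render_observation(st2, "a"))
})

test_that("snapshots are immutable, reproducible and step-tagged", {
  pol <- init_policy(policy_spec_micro(), seed = 14)
  snap <- snapshot_policy(pol, step = 5e6)
  expect_equal(snap$step, 5e6)
  # training the live policy must not change the snapshot
  obs <- runif(FEATURE_DIM)
  seg <- make_segment(list(obs), matrix(0, 1, 3), actions = 2L, rewards = 1)
  upd <- actor_critic_update(pol, seg, training_config("micro"))
  expect_false(identical(upd$policy$params, snap$params))
  expect_identical(snap$params, pol$params)
  # frozen policies refuse updates
  expect_error(actor_critic_update(snap, seg, training_config("micro")),
               "frozen")
  # identical replay
  o1 <- policy_forward(snap, obs, c(0, 0, 0))
  o2 <- policy_forward(snap, obs, c(0, 0, 0))
  expect_identical(o1, o2)
})

test_that("importance-weighted targets reduce to plain returns on-policy", {
  set.seed(15)
  r <- rnorm(6); v <- rnorm(6)
  vt <- groupsim:::vtrace_targets(v, r, 0.9, 0.5, rho = rep(1, 6))
  expect_equal(vt$vs, brute_force_returns(r, 0.9, 0.5), tolerance = 1e-12)
})
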