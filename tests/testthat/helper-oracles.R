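# Shared independent oracles: explicit-summation discounted returns and the
# finite-difference gradient checker (surrogate objective computed through
# the public forward pass only).

brute_force_returns <- function(rewards, gamma, v) {
  n <- length(rewards)
  vapply(seq_len(n), function(t) {
    sum(gamma^(0:(n - t)) * rewards[t:n]) + gamma^(n - t + 1) * v
  }, 0)
}


# Surrogate loss computed through the public forward pass only: policy-gradient
# term with advantages frozen at the reference parameters, value regression and
# entropy. Its gradient at the reference point equals the actor-critic gradient.
surrogate_loss <- function(policy, seg, cfg, adv_fixed, targets_fixed) {
  n <- length(seg$actions)
  state <- seg$state0
  if (is.null(state)) state <- initial_core_state(policy)
  pa <- values <- ent <- numeric(n)
  for (t in seq_len(n)) {
    out <- policy_forward(policy, seg$obs[[t]], seg$inv[t, ], state)
    p <- exp(out$logits - max(out$logits)); p <- p / sum(p)
    lp <- log(pmax(p, 1e-12))
    pa[t] <- lp[seg$actions[t]]
    ent[t] <- -sum(p * lp)
    values[t] <- out$value
    state <- out$state
  }
  -mean(pa * adv_fixed) + cfg$value_weight * 0.5 * mean((values - targets_fixed)^2) -
    cfg$entropy_weight * mean(ent)
}

check_gradients <- function(spec, obs_maker, n_steps = 3L, n_checks = 4L,
                            seed = 21) {
  set.seed(seed)
  pol <- init_policy(spec, seed = seed)
  # jitter all parameters (including the zero-initialized biases) so no ReLU
  # pre-activation sits exactly on its kink, where central differences and
  # the analytic subgradient legitimately disagree
  pol$params <- lapply(pol$params, function(m) m + rnorm(length(m), sd = 0.05))
  obs <- lapply(seq_len(n_steps), function(t) obs_maker())
  seg <- make_segment(obs, matrix(runif(3 * n_steps), n_steps, 3),
                      actions = sample(8, n_steps, replace = TRUE),
                      rewards = rnorm(n_steps), bootstrap_value = rnorm(1))
  cfg <- training_config("micro")
  out <- actor_critic_loss(pol, seg, cfg)
  # recover the frozen advantages/targets the analytic gradient used
  targets <- discounted_returns(seg$rewards, cfg$gamma, seg$bootstrap_value)
  st <- initial_core_state(pol); values <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    o <- policy_forward(pol, seg$obs[[t]], seg$inv[t, ], st)
    values[t] <- o$value; st <- o$state
  }
  adv <- targets - values
  h <- 1e-5
  for (nm in names(pol$params)) {
    sz <- length(pol$params[[nm]])
    for (k in sample(sz, min(n_checks, sz))) {
      pp <- pol; pp$params[[nm]][k] <- pp$params[[nm]][k] + h
      pm <- pol; pm$params[[nm]][k] <- pm$params[[nm]][k] - h
      fd <- (surrogate_loss(pp, seg, cfg, adv, targets) -
               surrogate_loss(pm, seg, cfg, adv, targets)) / (2 * h)
      an <- out$grads[[nm]][k]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = paste("analytic grad", nm, "entry", k),
                   expected.label = "finite difference")
    }
  }
}

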