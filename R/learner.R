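## Actor-critic training: each agent is an independent learner maximizing its
## own discounted return. Updates are synchronous advantage actor-critic with
## an optional truncated-importance-weighting (V-trace style) correction for
## off-policy segments, RMSprop optimization, and explicit loss diagnostics.

#' Training configuration
#'
#' Reference values: discount 0.99, learning rate 4e-4, entropy weight 3e-3,
#' RMSprop (epsilon 1e-5, momentum 0, decay 0.99), unroll length 100, batch
#' 252 sequences fed from 1,000 parallel environments. The `desk` and `micro`
#' presets shrink batch/rollout sizes for single-CPU use and record themselves
#' as such — a shrunk preset never reports itself as reference-scale.
#'
#' @param preset `"paper"`, `"desk"` or `"micro"`.
#' @param gamma discount factor in (0,1).
#' @param lr RMSprop learning rate.
#' @param entropy_weight weight of the policy-entropy bonus.
#' @param value_weight weight of the value-regression loss.
#' @param rmsprop_eps,rmsprop_decay,momentum RMSprop constants.
#' @param unroll truncation length of trajectory segments.
#' @param batch_size sequences per update.
#' @param n_envs parallel rollout workers.
#' @param vtrace apply the truncated importance-weighted off-policy correction
#'   (needs behavior logits in the batch); plain on-policy advantage
#'   actor-critic otherwise.
#' @return a `gs_training_config` list.
#' @export
training_config <- function(preset = c("desk", "paper", "micro"),
                            gamma = 0.99, lr = 4e-4, entropy_weight = 0.003,
                            value_weight = 0.5, rmsprop_eps = 1e-5,
                            rmsprop_decay = 0.99, momentum = 0,
                            unroll = NULL, batch_size = NULL, n_envs = NULL,
                            vtrace = FALSE) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    paper = list(unroll = 100L, batch_size = 252L, n_envs = 1000L),
    desk  = list(unroll = 100L, batch_size = 32L, n_envs = 8L),
    micro = list(unroll = 100L, batch_size = 8L, n_envs = 1L))
  stopifnot(gamma > 0, gamma < 1, lr > 0)
  structure(list(preset = preset, gamma = gamma, lr = lr,
                 entropy_weight = entropy_weight, value_weight = value_weight,
                 rmsprop_eps = rmsprop_eps, rmsprop_decay = rmsprop_decay,
                 momentum = momentum,
                 unroll = unroll %||% defaults$unroll,
                 batch_size = batch_size %||% defaults$batch_size,
                 n_envs = n_envs %||% defaults$n_envs,
                 vtrace = isTRUE(vtrace)),
            class = "gs_training_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discounted returns with bootstrapping
#'
#' Computes `G_t = r_t + gamma * G_{t+1}` with `G_{T+1}` seeded by
#' `bootstrap_value`, i.e. `G_t = sum_k gamma^k r_{t+k} + gamma^(T-t+1) * v`.
#'
#' @param rewards numeric reward sequence.
#' @param gamma discount in (0,1).
#' @param bootstrap_value value estimate beyond the truncation (0 if terminal).
#' @return numeric vector of returns, same length as `rewards`.
#' @export
#' @examples
#' discounted_returns(c(1, 0, 0), 0.99, 0)
discounted_returns <- function(rewards, gamma, bootstrap_value = 0) {
  stopifnot(gamma > 0, gamma < 1)
  n <- length(rewards)
  g <- numeric(n)
  acc <- bootstrap_value
  for (t in rev(seq_len(n))) {
    acc <- rewards[t] + gamma * acc
    g[t] <- acc
  }
  g
}

## Truncated importance-weighted value targets and advantages
## (rho and c both clipped at 1).
vtrace_targets <- function(values, rewards, gamma, bootstrap_value, rho) {
  n <- length(rewards)
  rho <- pmin(rho, 1)
  v_next <- c(values[-1L], bootstrap_value)
  delta <- rho * (rewards + gamma * v_next - values)
  vs <- numeric(n)
  acc <- 0
  for (t in rev(seq_len(n))) {
    acc <- delta[t] + gamma * rho[t] * acc
    vs[t] <- values[t] + acc
  }
  vs_next <- c(vs[-1L], bootstrap_value)
  adv <- rho * (rewards + gamma * vs_next - values)
  list(vs = vs, adv = adv)
}

#' Build a trajectory segment
#'
#' @param obs list of observations (one per step), or a T x d matrix of
#'   feature observations.
#' @param inv T x 3 matrix of inventories.
#' @param actions integer action codes.
#' @param rewards numeric rewards, aligned with `actions`.
#' @param bootstrap_value value estimate for the state after the segment.
#' @param state0 recurrent core state at the segment start.
#' @param behavior_logits optional T x 8 matrix of behavior-policy logits (for
#'   the off-policy correction).
#' @return a `gs_segment` list.
#' @export
make_segment <- function(obs, inv, actions, rewards, bootstrap_value = 0,
                         state0 = NULL, behavior_logits = NULL) {
  n_obs <- if (is.matrix(obs)) nrow(obs) else length(obs)
  stopifnot(n_obs == length(actions), length(actions) == length(rewards))
  structure(list(obs = obs, inv = inv, actions = as.integer(actions),
                 rewards = rewards, bootstrap_value = bootstrap_value,
                 state0 = state0, behavior_logits = behavior_logits),
            class = "gs_segment")
}

zero_like <- function(params) lapply(params, function(p) p * 0)

## Loss and explicit gradients over one segment (mean over steps).
segment_loss_grads <- function(policy, seg, config) {
  if (policy$spec$core == "none" && policy$spec$input == "features") {
    return(segment_loss_grads_ff(policy, seg, config))
  }
  n <- length(seg$actions)
  state <- seg$state0 %||% initial_core_state(policy)
  caches <- vector("list", n)
  logits <- matrix(0, n, policy$spec$n_actions)
  values <- numeric(n)
  for (t in seq_len(n)) {
    out <- forward_step(policy, seg$obs[[t]], seg$inv[t, ], state, keep_cache = TRUE)
    caches[[t]] <- out$cache
    logits[t, ] <- out$logits
    values[t] <- out$value
    state <- out$state
  }
  probs <- t(apply(logits, 1L, softmax))
  logp <- log(pmax(probs, 1e-12))
  pa <- logp[cbind(seq_len(n), seg$actions)]
  ent <- -rowSums(probs * logp)

  if (config$vtrace && !is.null(seg$behavior_logits)) {
    mu <- t(apply(seg$behavior_logits, 1L, softmax))
    rho <- exp(pa - log(pmax(mu[cbind(seq_len(n), seg$actions)], 1e-12)))
    vt <- vtrace_targets(values, seg$rewards, config$gamma, seg$bootstrap_value, rho)
    targets <- vt$vs
    adv <- vt$adv
  } else {
    targets <- discounted_returns(seg$rewards, config$gamma, seg$bootstrap_value)
    adv <- targets - values
  }

  pg_loss <- -mean(pa * adv)
  vf_loss <- 0.5 * mean((values - targets)^2)
  ent_mean <- mean(ent)
  total <- pg_loss + config$value_weight * vf_loss - config$entropy_weight * ent_mean

  grads <- zero_like(policy$params)
  dstate <- initial_core_state(policy)
  if (!is.null(dstate)) dstate <- lapply(dstate, function(v) v * 0)
  for (t in rev(seq_len(n))) {
    onehot <- numeric(policy$spec$n_actions); onehot[seg$actions[t]] <- 1
    dlog <- (adv[t] * (probs[t, ] - onehot) +
               config$entropy_weight * probs[t, ] * (logp[t, ] + ent[t])) / n
    dval <- config$value_weight * (values[t] - targets[t]) / n
    bk <- backward_step(policy, caches[[t]], dlog, dval, dstate)
    for (nm in names(bk$grads)) grads[[nm]] <- grads[[nm]] + bk$grads[[nm]]
    dstate <- bk$dstate
  }
  list(loss = total, pg_loss = pg_loss, vf_loss = vf_loss, entropy = ent_mean,
       grads = grads, mean_return = mean(targets))
}

## Whole-segment matrix-algebra path for the feedforward feature policy:
## identical mathematics to the per-step path, one GEMM per layer per segment.
segment_loss_grads_ff <- function(policy, seg, config) {
  p <- policy$params
  n <- length(seg$actions)
  X <- if (is.matrix(seg$obs)) {
    cbind(seg$obs, seg$inv)
  } else {
    cbind(do.call(rbind, lapply(seg$obs, as.numeric)), seg$inv)
  }
  if (!config$vtrace || is.null(seg$behavior_logits)) {
    ## compiled kernel for the on-policy case
    out <- cpp_ff_segment_grads(p, X, seg$actions, seg$rewards,
                                seg$bootstrap_value, config$gamma,
                                config$entropy_weight, config$value_weight)
    out$grads <- out$grads[names(p)]
    return(out)
  }
  addb <- function(Z, b) Z + rep(b, each = nrow(Z))
  Z1 <- addb(X %*% p$trunk1_W, p$trunk1_b); M1 <- Z1 > 0; A1 <- Z1 * M1
  Z2 <- addb(A1 %*% p$trunk2_W, p$trunk2_b); M2 <- Z2 > 0; A2 <- Z2 * M2
  ZP <- addb(A2 %*% p$pol1_W, p$pol1_b); MP <- ZP > 0; AP <- ZP * MP
  logits <- addb(AP %*% p$pol2_W, p$pol2_b)
  ZV <- addb(A2 %*% p$val1_W, p$val1_b); MV <- ZV > 0; AV <- ZV * MV
  values <- c(AV %*% p$val2_W) + p$val2_b

  mx <- logits[cbind(seq_len(n), max.col(logits, ties.method = "first"))]
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  logp <- log(pmax(probs, 1e-12))
  idx <- cbind(seq_len(n), seg$actions)
  pa <- logp[idx]
  ent <- -rowSums(probs * logp)

  if (config$vtrace && !is.null(seg$behavior_logits)) {
    mu <- t(apply(seg$behavior_logits, 1L, softmax))
    rho <- exp(pa - log(pmax(mu[idx], 1e-12)))
    vt <- vtrace_targets(values, seg$rewards, config$gamma, seg$bootstrap_value, rho)
    targets <- vt$vs
    adv <- vt$adv
  } else {
    targets <- discounted_returns(seg$rewards, config$gamma, seg$bootstrap_value)
    adv <- targets - values
  }

  pg_loss <- -mean(pa * adv)
  vf_loss <- 0.5 * mean((values - targets)^2)
  ent_mean <- mean(ent)
  total <- pg_loss + config$value_weight * vf_loss - config$entropy_weight * ent_mean

  onehot <- matrix(0, n, ncol(logits)); onehot[idx] <- 1
  dlog <- (adv * (probs - onehot) +
             config$entropy_weight * probs * (logp + ent)) / n
  dval <- config$value_weight * (values - targets) / n

  g <- list()
  g$pol2_W <- crossprod(AP, dlog); g$pol2_b <- colSums(dlog)
  dZP <- (dlog %*% t(p$pol2_W)) * MP
  g$pol1_W <- crossprod(A2, dZP); g$pol1_b <- colSums(dZP)
  dA2 <- dZP %*% t(p$pol1_W)
  g$val2_W <- matrix(colSums(AV * dval), ncol = 1L); g$val2_b <- sum(dval)
  dZV <- outer(dval, p$val2_W[, 1L]) * MV
  g$val1_W <- crossprod(A2, dZV); g$val1_b <- colSums(dZV)
  dA2 <- dA2 + dZV %*% t(p$val1_W)
  dZ2 <- dA2 * M2
  g$trunk2_W <- crossprod(A1, dZ2); g$trunk2_b <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(p$trunk2_W)) * M1
  g$trunk1_W <- crossprod(X, dZ1); g$trunk1_b <- colSums(dZ1)

  list(loss = total, pg_loss = pg_loss, vf_loss = vf_loss, entropy = ent_mean,
       grads = g[names(policy$params)], mean_return = mean(targets))
}

#' Actor-critic loss and gradients for a batch
#'
#' Loss = policy-gradient term with advantage (return minus value) +
#' value-regression term + entropy bonus (weight 0.003 by default); gradients
#' are computed by explicit backpropagation (validated against finite
#' differences in the test suite). Exposed separately from
#' [actor_critic_update()] so gradients can be inspected and checked.
#'
#' @param policy a `gs_policy`.
#' @param batch a `gs_segment` or list of segments.
#' @param config a [training_config()].
#' @return list `loss`, `pg_loss`, `vf_loss`, `entropy`, `grads`, `mean_return`.
#' @export
actor_critic_loss <- function(policy, batch, config) {
  if (inherits(batch, "gs_segment")) batch <- list(batch)
  outs <- lapply(batch, function(seg) segment_loss_grads(policy, seg, config))
  k <- length(outs)
  if (k == 1L) return(outs[[1L]])
  grads <- zero_like(policy$params)
  for (o in outs) for (nm in names(grads)) {
    grads[[nm]] <- grads[[nm]] + o$grads[[nm]] / k
  }
  list(loss = mean(vapply(outs, `[[`, 0, "loss")),
       pg_loss = mean(vapply(outs, `[[`, 0, "pg_loss")),
       vf_loss = mean(vapply(outs, `[[`, 0, "vf_loss")),
       entropy = mean(vapply(outs, `[[`, 0, "entropy")),
       mean_return = mean(vapply(outs, `[[`, 0, "mean_return")),
       grads = grads)
}

#' One actor-critic update
#'
#' Computes the batch loss/gradients and applies one RMSprop step with the
#' configured constants. The optimizer's second-moment state rides along on
#' the policy object. Updates touch only this agent's parameters.
#'
#' @param policy a `gs_policy`.
#' @param batch a `gs_segment` or list of segments.
#' @param config a [training_config()].
#' @return list `policy` (updated), `diagnostics` (loss components).
#' @export
actor_critic_update <- function(policy, batch, config) {
  if (inherits(policy, "gs_frozen_policy")) {
    abort("frozen snapshots do not learn")
  }
  out <- actor_critic_loss(policy, batch, config)
  if (!is.finite(out$loss)) {
    abort(paste0("non-finite loss; components: pg=", out$pg_loss,
                 " vf=", out$vf_loss, " ent=", out$entropy))
  }
  if (is.null(policy$opt)) policy$opt <- zero_like(policy$params)
  d <- config$rmsprop_decay
  for (nm in names(policy$params)) {
    gr <- out$grads[[nm]]
    policy$opt[[nm]] <- d * policy$opt[[nm]] + (1 - d) * gr^2
    policy$params[[nm]] <- policy$params[[nm]] -
      config$lr * gr / sqrt(policy$opt[[nm]] + config$rmsprop_eps)
  }
  list(policy = policy,
       diagnostics = out[c("loss", "pg_loss", "vf_loss", "entropy", "mean_return")])
}
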