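## Per-agent neural policies. The reference architecture is the pixel policy:
## two conv stages (16 channels, kernel/stride 8 to match the 8x8 sprites;
## then 32 channels, 4x4 kernel, stride 1), inventory concatenated to the
## flattened encoder output, a 2-layer ReLU trunk (64+64), a recurrent core
## (LSTM-256), and 256-unit policy / value heads with linear outputs (8 logits
## and a scalar value). Desk presets shrink the trunk/core; the micro preset
## swaps pixels for the compact symbolic observation and drops the core.
## Forward and backward passes are written explicitly so updates need no
## external autodiff; gradients are validated against finite differences in
## the test suite.

#' Describe a policy architecture
#'
#' @param input `"pixels"` (88x88x3 egocentric window) or `"features"`
#'   (compact symbolic vector, see [feature_observation()]).
#' @param conv list of conv stages `list(channels, kernel, stride)` (pixels only).
#' @param obs_shape pixel observation shape.
#' @param feature_dim symbolic observation length.
#' @param trunk integer sizes of the two fully connected ReLU layers.
#' @param core `"lstm"`, `"gru"` or `"none"`.
#' @param core_units recurrent state size.
#' @param head_units hidden size of the policy and value heads.
#' @param n_actions number of discrete actions (8).
#' @return a `gs_policy_spec` list.
#' @export
policy_spec <- function(input = c("features", "pixels"),
                        conv = list(list(channels = 16L, kernel = 8L, stride = 8L),
                                    list(channels = 32L, kernel = 4L, stride = 1L)),
                        obs_shape = c(88L, 88L, 3L),
                        feature_dim = FEATURE_DIM,
                        trunk = c(64L, 64L),
                        core = c("lstm", "gru", "none"),
                        core_units = 256L,
                        head_units = 256L,
                        n_actions = 8L) {
  input <- match.arg(input)
  core <- match.arg(core)
  structure(list(input = input, conv = conv, obs_shape = as.integer(obs_shape),
                 feature_dim = as.integer(feature_dim), trunk = as.integer(trunk),
                 core = core, core_units = as.integer(core_units),
                 head_units = as.integer(head_units),
                 n_actions = as.integer(n_actions)),
            class = "gs_policy_spec")
}

#' Reference-scale pixel policy spec (conv encoder + LSTM-256)
#' @export
policy_spec_paper <- function() {
  policy_spec("pixels", core = "lstm", core_units = 256L,
              trunk = c(64L, 64L), head_units = 256L)
}

#' Desk-scale pixel policy spec (smaller trunk, GRU-64)
#' @export
policy_spec_desk <- function() {
  policy_spec("pixels", core = "gru", core_units = 64L,
              trunk = c(32L, 32L), head_units = 64L)
}

#' Micro policy spec (symbolic observation, feedforward)
#' @export
policy_spec_micro <- function() {
  policy_spec("features", core = "none", trunk = c(32L, 32L), head_units = 32L)
}

conv_out_dim <- function(spec) {
  h <- spec$obs_shape[1L]; w <- spec$obs_shape[2L]; c <- spec$obs_shape[3L]
  for (l in spec$conv) {
    h <- (h - l$kernel) %/% l$stride + 1L
    w <- (w - l$kernel) %/% l$stride + 1L
    c <- l$channels
  }
  c(h = h, w = w, c = c)
}

## scaled-uniform init; small-scale output layers so initial policies are
## near-uniform (entropy ~ ln 8)
runif_mat <- function(nr, nc, scale = sqrt(6 / (nr + nc))) {
  matrix(runif(nr * nc, -scale, scale), nr, nc)
}

orth_mat <- function(nr, nc) {
  q <- qr.Q(qr(matrix(rnorm(nr * nc), nr, nc)))
  q[seq_len(nr), seq_len(nc), drop = FALSE]
}

#' Initialize policy parameters
#'
#' Orthogonal initialization for the recurrent core's recurrent weights,
#' scaled-uniform elsewhere; near-zero final layers so the initial action
#' distribution is close to uniform. Parameters are private to one agent.
#'
#' @param spec a [policy_spec()].
#' @param seed optional integer seed.
#' @return a `gs_policy` list with elements `spec` and `params`.
#' @export
init_policy <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list()
  if (spec$input == "pixels") {
    cin <- spec$obs_shape[3L]
    for (li in seq_along(spec$conv)) {
      l <- spec$conv[[li]]
      p[[paste0("conv", li, "_W")]] <- runif_mat(l$kernel^2 * cin, l$channels)
      p[[paste0("conv", li, "_b")]] <- numeric(l$channels)
      cin <- l$channels
    }
    enc_dim <- prod(conv_out_dim(spec))
  } else {
    enc_dim <- spec$feature_dim
  }
  d <- enc_dim + 3L   # inventory concatenated to encoder output
  p$trunk1_W <- runif_mat(d, spec$trunk[1L]); p$trunk1_b <- numeric(spec$trunk[1L])
  p$trunk2_W <- runif_mat(spec$trunk[1L], spec$trunk[2L]); p$trunk2_b <- numeric(spec$trunk[2L])
  tout <- spec$trunk[2L]
  if (spec$core != "none") {
    ng <- if (spec$core == "lstm") 4L else 3L
    h <- spec$core_units
    p$core_W <- runif_mat(tout, ng * h)
    p$core_U <- do.call(cbind, replicate(ng, orth_mat(h, h), simplify = FALSE))
    p$core_b <- numeric(ng * h)
    if (spec$core == "lstm") p$core_b[(h + 1L):(2L * h)] <- 1  # forget-gate bias
    cout <- h
  } else {
    cout <- tout
  }
  p$pol1_W <- runif_mat(cout, spec$head_units); p$pol1_b <- numeric(spec$head_units)
  p$pol2_W <- 0.01 * runif_mat(spec$head_units, spec$n_actions)
  p$pol2_b <- numeric(spec$n_actions)
  p$val1_W <- runif_mat(cout, spec$head_units); p$val1_b <- numeric(spec$head_units)
  p$val2_W <- 0.01 * runif_mat(spec$head_units, 1L); p$val2_b <- 0
  structure(list(spec = spec, params = p), class = "gs_policy")
}

#' Zero recurrent state for a policy
#' @param policy a `gs_policy`.
#' @return list `h` (and `c` for LSTM), or `NULL` for feedforward policies.
#' @export
initial_core_state <- function(policy) {
  spec <- policy$spec
  if (spec$core == "none") return(NULL)
  s <- list(h = numeric(spec$core_units))
  if (spec$core == "lstm") s$c <- numeric(spec$core_units)
  s
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

## ---- im2col machinery (index matrices cached per geometry) ----------------

.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, C, k, stride) {
  key <- paste(H, W, C, k, stride, sep = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  r0 <- rep(seq.int(0L, by = stride, length.out = Ho), times = Wo)
  c0 <- rep(seq.int(0L, by = stride, length.out = Wo), each = Ho)
  base <- r0 + c0 * H + 1L                      # linear index of patch corner
  offs <- integer(k * k * C); t <- 0L
  for (ci in seq_len(C)) for (kw in seq_len(k)) for (kh in seq_len(k)) {
    t <- t + 1L
    offs[t] <- (kh - 1L) + (kw - 1L) * H + (ci - 1L) * H * W
  }
  idx <- outer(base, offs, "+")
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  .im2col_cache[[key]] <- out
  out
}

## ---- forward / backward ----------------------------------------------------

dense_fwd <- function(x, W, b) c(x %*% W) + b

## One policy step with optional cache for backprop. obs: pixel array or
## feature vector; inv: length-3 inventory; hstate: core state or NULL.
forward_step <- function(policy, obs, inv, hstate, keep_cache = FALSE) {
  spec <- policy$spec; p <- policy$params
  if (!keep_cache && spec$core == "none" && spec$input == "features") {
    out <- cpp_ff_forward(p$trunk1_W, p$trunk1_b, p$trunk2_W, p$trunk2_b,
                          p$pol1_W, p$pol1_b, p$pol2_W, p$pol2_b,
                          p$val1_W, p$val1_b, p$val2_W, p$val2_b,
                          c(as.numeric(obs), as.numeric(inv)))
    return(list(logits = as.numeric(out$logits), value = out$value,
                state = NULL, cache = NULL))
  }
  cache <- if (keep_cache) list() else NULL
  if (spec$input == "pixels") {
    x <- obs / 255
    H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
    acts <- vector("list", length(spec$conv))
    for (li in seq_along(spec$conv)) {
      l <- spec$conv[[li]]
      ii <- im2col_idx(H, W, C, l$kernel, l$stride)
      P <- matrix(x[ii$idx], nrow(ii$idx), ncol(ii$idx))
      Z <- sweep(P %*% p[[paste0("conv", li, "_W")]], 2L,
                 p[[paste0("conv", li, "_b")]], "+")
      A <- Z * (Z > 0)
      if (keep_cache) acts[[li]] <- list(P = P, mask = Z > 0, H = H, W = W, C = C)
      x <- array(A, dim = c(ii$Ho, ii$Wo, l$channels))
      H <- ii$Ho; W <- ii$Wo; C <- l$channels
    }
    enc <- as.numeric(x)
    if (keep_cache) cache$conv <- acts
  } else {
    enc <- as.numeric(obs)
  }
  x0 <- c(enc, as.numeric(inv))
  z1 <- dense_fwd(x0, p$trunk1_W, p$trunk1_b); a1 <- z1 * (z1 > 0)
  z2 <- dense_fwd(a1, p$trunk2_W, p$trunk2_b); a2 <- z2 * (z2 > 0)

  if (spec$core == "gru") {
    h <- hstate$h; nh <- spec$core_units
    g <- dense_fwd(a2, p$core_W, p$core_b) + c(h %*% p$core_U)
    ## gate order: z, r, n; candidate uses r*h through U's third block
    zi <- 1:nh; ri <- (nh + 1L):(2L * nh); ni <- (2L * nh + 1L):(3L * nh)
    zg <- sigmoid(g[zi]); rg <- sigmoid(g[ri])
    gn_x <- c(a2 %*% p$core_W[, ni, drop = FALSE]) + p$core_b[ni]
    gn_h <- c(h %*% p$core_U[, ni, drop = FALSE])
    ng_ <- tanh(gn_x + rg * gn_h)
    hn <- (1 - zg) * h + zg * ng_
    new_state <- list(h = hn)
    core_out <- hn
    if (keep_cache) cache$core <- list(h = h, zg = zg, rg = rg, ng = ng_,
                                       gn_h = gn_h, a2 = a2)
  } else if (spec$core == "lstm") {
    h <- hstate$h; cc <- hstate$c; nh <- spec$core_units
    g <- dense_fwd(a2, p$core_W, p$core_b) + c(h %*% p$core_U)
    ii_ <- 1:nh; fi <- (nh + 1L):(2L * nh)
    gi <- (2L * nh + 1L):(3L * nh); oi <- (3L * nh + 1L):(4L * nh)
    ig <- sigmoid(g[ii_]); fg <- sigmoid(g[fi]); gg <- tanh(g[gi]); og <- sigmoid(g[oi])
    cn <- fg * cc + ig * gg
    tn <- tanh(cn)
    hn <- og * tn
    new_state <- list(h = hn, c = cn)
    core_out <- hn
    if (keep_cache) cache$core <- list(h = h, c = cc, ig = ig, fg = fg, gg = gg,
                                       og = og, cn = cn, tn = tn, a2 = a2)
  } else {
    new_state <- NULL
    core_out <- a2
  }

  zp <- dense_fwd(core_out, p$pol1_W, p$pol1_b); ap <- zp * (zp > 0)
  logits <- dense_fwd(ap, p$pol2_W, p$pol2_b)
  zv <- dense_fwd(core_out, p$val1_W, p$val1_b); av <- zv * (zv > 0)
  value <- dense_fwd(av, p$val2_W, p$val2_b)[1L]

  if (keep_cache) {
    cache$x0 <- x0; cache$a1 <- a1; cache$m1 <- z1 > 0
    cache$a2 <- a2; cache$m2 <- z2 > 0
    cache$core_out <- core_out
    cache$ap <- ap; cache$mp <- zp > 0
    cache$av <- av; cache$mv <- zv > 0
  }
  list(logits = logits, value = value, state = new_state, cache = cache)
}

#' Evaluate the policy network for one step
#'
#' Deterministic map from (observation, inventory, recurrent state) to action
#' logits, a scalar value estimate and the next recurrent state.
#'
#' @param policy a `gs_policy` (or frozen snapshot).
#' @param observation pixel array (pixels input) or feature vector.
#' @param inventory length-3 inventory vector.
#' @param recurrent_state from [initial_core_state()] or a previous call.
#' @return list `logits` (length 8), `value` (scalar), `state`.
#' @export
policy_forward <- function(policy, observation, inventory,
                           recurrent_state = initial_core_state(policy)) {
  spec <- policy$spec
  if (spec$input == "pixels") {
    stopifnot(identical(dim(observation), as.integer(spec$obs_shape)))
  } else {
    stopifnot(length(observation) == spec$feature_dim)
  }
  stopifnot(length(inventory) == 3L)
  out <- forward_step(policy, observation, inventory, recurrent_state)
  out[c("logits", "value", "state")]
}

## Backward through one cached step. dlogits (8), dvalue (scalar),
## dstate_next: list(h[, c]) gradient flowing from step t+1 (or zeros).
## Returns list(grads = named list, dstate = gradient w.r.t. incoming state).
backward_step <- function(policy, cache, dlogits, dvalue, dstate_next) {
  spec <- policy$spec; p <- policy$params
  g <- list()
  ## policy head
  dap <- c(dlogits %*% t(p$pol2_W))
  g$pol2_W <- outer(cache$ap, dlogits); g$pol2_b <- dlogits
  dzp <- dap * cache$mp
  g$pol1_W <- outer(cache$core_out, dzp); g$pol1_b <- dzp
  dcore <- c(dzp %*% t(p$pol1_W))
  ## value head
  dav <- dvalue * p$val2_W[, 1L]
  g$val2_W <- matrix(cache$av * dvalue, ncol = 1L); g$val2_b <- dvalue
  dzv <- dav * cache$mv
  g$val1_W <- outer(cache$core_out, dzv); g$val1_b <- dzv
  dcore <- dcore + c(dzv %*% t(p$val1_W))

  if (spec$core == "gru") {
    cs <- cache$core; nh <- spec$core_units
    dh_next <- dcore + dstate_next$h
    dz <- dh_next * (cs$ng - cs$h) * cs$zg * (1 - cs$zg)
    dn <- dh_next * cs$zg * (1 - cs$ng^2)
    dr <- dn * cs$gn_h * cs$rg * (1 - cs$rg)
    dh_prev <- dh_next * (1 - cs$zg)
    zi <- 1:nh; ri <- (nh + 1L):(2L * nh); ni <- (2L * nh + 1L):(3L * nh)
    dg <- numeric(3L * nh); dg[zi] <- dz; dg[ri] <- dr; dg[ni] <- dn
    ## x path: all three blocks see a2 directly
    g$core_W <- outer(cs$a2, dg)
    g$core_b <- dg
    ## h path: z and r blocks see h; n block sees r*h
    dU <- matrix(0, nh, 3L * nh)
    dU[, zi] <- outer(cs$h, dz); dU[, ri] <- outer(cs$h, dr)
    dU[, ni] <- outer(cs$h, dn * cs$rg)
    g$core_U <- dU
    dh_prev <- dh_prev +
      c(dz %*% t(p$core_U[, zi, drop = FALSE])) +
      c(dr %*% t(p$core_U[, ri, drop = FALSE])) +
      c((dn * cs$rg) %*% t(p$core_U[, ni, drop = FALSE]))
    da2 <- c(dg %*% t(p$core_W))
    dstate_prev <- list(h = dh_prev)
  } else if (spec$core == "lstm") {
    cs <- cache$core; nh <- spec$core_units
    dh_next <- dcore + dstate_next$h
    dc_next <- dstate_next$c
    do_ <- dh_next * cs$tn * cs$og * (1 - cs$og)
    dcn <- dh_next * cs$og * (1 - cs$tn^2) + dc_next
    di <- dcn * cs$gg * cs$ig * (1 - cs$ig)
    df <- dcn * cs$c * cs$fg * (1 - cs$fg)
    dg_ <- dcn * cs$ig * (1 - cs$gg^2)
    dc_prev <- dcn * cs$fg
    dgate <- c(di, df, dg_, do_)
    g$core_W <- outer(cs$a2, dgate)
    g$core_U <- outer(cs$h, dgate)
    g$core_b <- dgate
    dh_prev <- c(dgate %*% t(p$core_U))
    da2 <- c(dgate %*% t(p$core_W))
    dstate_prev <- list(h = dh_prev, c = dc_prev)
  } else {
    da2 <- dcore
    dstate_prev <- NULL
  }

  dz2 <- da2 * cache$m2
  g$trunk2_W <- outer(cache$a1, dz2); g$trunk2_b <- dz2
  da1 <- c(dz2 %*% t(p$trunk2_W))
  dz1 <- da1 * cache$m1
  g$trunk1_W <- outer(cache$x0, dz1); g$trunk1_b <- dz1

  if (spec$input == "pixels") {
    enc_dim <- prod(conv_out_dim(spec))
    dx0 <- c(dz1 %*% t(p$trunk1_W))
    dA <- dx0[seq_len(enc_dim)]
    for (li in rev(seq_along(spec$conv))) {
      l <- spec$conv[[li]]
      cc <- cache$conv[[li]]
      npos <- nrow(cc$P)
      dZ <- matrix(dA, npos, l$channels) * cc$mask
      g[[paste0("conv", li, "_W")]] <- crossprod(cc$P, dZ)
      g[[paste0("conv", li, "_b")]] <- colSums(dZ)
      if (li > 1L) {
        dP <- dZ %*% t(p[[paste0("conv", li, "_W")]])
        ii <- im2col_idx(cc$H, cc$W, cc$C, l$kernel, l$stride)
        dxin <- numeric(cc$H * cc$W * cc$C)
        for (j in seq_len(ncol(ii$idx))) {
          tgt <- ii$idx[, j]
          dxin[tgt] <- dxin[tgt] + dP[, j]
        }
        dA <- dxin
      }
    }
  }
  list(grads = g, dstate = dstate_prev)
}

#' Take a frozen, evaluable snapshot of a policy
#'
#' Snapshots deep-copy the parameters (R value semantics), never learn, and
#' are tagged with the training step at which they were taken so probe results
#' can be binned by training time.
#'
#' @param policy a `gs_policy`.
#' @param step training step count of the snapshot.
#' @return a `gs_frozen_policy`.
#' @export
snapshot_policy <- function(policy, step = 0L) {
  structure(list(spec = policy$spec, params = policy$params,
                 step = as.numeric(step)),
            class = c("gs_frozen_policy", "gs_policy"))
}

#' Act with a policy in the live environment
#'
#' Generic over neural policies (which consume the rendered or symbolic
#' observation) and scripted fixture policies (which read the state directly).
#'
#' @param policy a `gs_policy`, `gs_frozen_policy` or `gs_scripted_policy`.
#' @param state a `gs_state`.
#' @param agent_id the acting agent.
#' @param core_state recurrent state carried between steps (neural policies).
#' @param greedy take the argmax action instead of sampling.
#' @return list `action` (integer code), `core_state`, `logits` (or `NULL`).
#' @export
policy_act <- function(policy, state, agent_id, core_state = NULL, greedy = FALSE) {
  UseMethod("policy_act")
}

#' @export
policy_act.gs_policy <- function(policy, state, agent_id, core_state = NULL,
                                 greedy = FALSE) {
  obs <- if (policy$spec$input == "pixels") {
    render_observation(state, agent_id)
  } else {
    feature_observation(state, agent_id)
  }
  if (is.null(obs)) {
    return(list(action = ACTIONS[["NOOP"]], core_state = core_state, logits = NULL))
  }
  i <- match(agent_id, state$agents$id)
  inv <- state$agents$inv[, i]
  if (is.null(core_state)) core_state <- initial_core_state(policy)
  out <- forward_step(policy, obs, inv, core_state)
  pr <- softmax(out$logits)
  action <- if (greedy) which.max(pr) else sample.int(length(pr), 1L, prob = pr)
  list(action = action, core_state = out$state, logits = out$logits)
}
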