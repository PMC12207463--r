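## Scripted (non-learning) policies: deterministic-under-seed behavioral
## fixtures so every environment, probe and metric operation is testable
## without training. Scripted policies read the simulation state directly
## (perfect information), which is what makes them usable as adversarial
## oracles, e.g. for the wall-impermeability property.

#' Create a scripted policy
#'
#' Kinds:
#' * `noop`: always NOOP.
#' * `random_walk`: uniform over all 8 actions (including the beam).
#' * `approach_nearest_ready`: collect a resource if not ready, then approach
#'   the nearest ready agent and fire the beam when aligned within range.
#' * `approach_color`: as above, but only targets agents of body color `color`.
#' * `avoid_pixel`: as above, but prefers ready agents without an
#'   individuation pixel (used as the "avoid the marked sprite" oracle).
#'
#' @param kind policy kind, see above.
#' @param color RGB triple for `approach_color`.
#' @param jitter probability of a random move instead of the steering action
#'   (breaks deadlocks between scripted agents).
#' @return a `gs_scripted_policy`.
#' @export
scripted_policy <- function(kind = c("random_walk", "noop",
                                     "approach_nearest_ready",
                                     "approach_color", "avoid_pixel"),
                            color = NULL, jitter = 0.1) {
  kind <- match.arg(kind)
  if (kind == "approach_color") stopifnot(length(color) == 3L)
  structure(list(kind = kind, color = color, jitter = jitter),
            class = "gs_scripted_policy")
}

## egocentric (forward, right) offsets of a world cell relative to agent i
ego_offset <- function(state, i, row, col) {
  fwd <- FWD_D[state$agents$orient[i], ]
  rgt <- RGT_D[state$agents$orient[i], ]
  dr <- row - state$agents$row[i]; dc <- col - state$agents$col[i]
  c(f = dr * fwd[1L] + dc * fwd[2L], r = dr * rgt[1L] + dc * rgt[2L])
}

nearest_of <- function(state, i, rows, cols) {
  if (!length(rows)) return(NULL)
  d <- abs(rows - state$agents$row[i]) + abs(cols - state$agents$col[i])
  k <- which.min(d)
  c(rows[k], cols[k])
}

steer_towards <- function(state, i, target, interact = FALSE) {
  fr <- ego_offset(state, i, target[1L], target[2L])
  f <- fr[1L]; r <- fr[2L]
  if (interact && r == 0 && f >= 1 && f <= state$config$beam_range) {
    return(ACTIONS[["INTERACT"]])
  }
  if (f >= 1) {
    if (abs(r) >= 1) {
      if (r > 0) ACTIONS[["STRAFE_RIGHT"]] else ACTIONS[["STRAFE_LEFT"]]
    } else {
      ACTIONS[["FORWARD"]]
    }
  } else if (f == 0 && r != 0) {
    if (r > 0) ACTIONS[["TURN_RIGHT"]] else ACTIONS[["TURN_LEFT"]]
  } else {
    ACTIONS[["TURN_RIGHT"]]
  }
}

#' @export
policy_act.gs_scripted_policy <- function(policy, state, agent_id,
                                          core_state = NULL, greedy = FALSE) {
  i <- match(agent_id, state$agents$id)
  stopifnot(!is.na(i))
  a <- state$agents
  act <- ACTIONS[["NOOP"]]
  if (policy$kind == "noop" || is.na(a$row[i])) {
    return(list(action = act, core_state = core_state, logits = NULL))
  }
  if (policy$kind == "random_walk") {
    return(list(action = sample.int(8L, 1L), core_state = core_state, logits = NULL))
  }
  if (runif(1) < policy$jitter) {
    return(list(action = sample(c(2L, 3L, 4L, 5L, 6L, 7L), 1L),
                core_state = core_state, logits = NULL))
  }
  needs_resource <- state$config$require_initiator_ready && !a$ready[i]
  if (needs_resource) {
    res <- which(state$resources > 0L, arr.ind = TRUE)
    tgt <- nearest_of(state, i, res[, 1L], res[, 2L])
    if (is.null(tgt)) {
      act <- sample(c(2L, 4L, 5L, 6L, 7L), 1L)
    } else {
      act <- steer_towards(state, i, tgt, interact = FALSE)
    }
  } else {
    cand <- setdiff(which(!is.na(a$row) & a$ready & a$freeze == 0L), i)
    if (policy$kind == "approach_color") {
      same <- vapply(cand, function(j) all(a$color[, j] == policy$color), TRUE)
      cand <- cand[same]
    } else if (policy$kind == "avoid_pixel") {
      unmarked <- cand[vapply(cand, function(j) is.null(a$pixel[[j]]), TRUE)]
      if (length(unmarked)) cand <- unmarked
    }
    if (length(cand)) {
      k <- nearest_of(state, i, a$row[cand], a$col[cand])
      act <- steer_towards(state, i, k, interact = TRUE)
      if (act == ACTIONS[["INTERACT"]]) {
        ## only fire if the first agent in the beam path is the intended target
        hit <- beam_target(state, i)
        if (hit == 0L || a$row[hit] != k[1L] || a$col[hit] != k[2L]) {
          act <- sample(c(4L, 5L, 6L, 7L), 1L)
        }
      }
    } else {
      act <- sample(c(2L, 4L, 5L, 6L, 7L), 1L)
    }
  }
  list(action = act, core_state = core_state, logits = NULL)
}
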