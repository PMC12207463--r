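## The dual-choice behavioral probe: a frozen policy is placed in a small
## resource-stocked room with exactly two immobile, always-ready target
## sprites at randomized positions. The episode ends when the evaluated agent
## interacts with one of them (or after max_steps). Choice frequencies over
## many episodes measure group bias and individuation; probes never mutate
## policy parameters.

#' Configure the dual-choice probe
#'
#' @param targets list of two target sprite specs `A` and `B`, each
#'   `list(group =, color =, pixel = NULL)`; targets never act and are always
#'   ready.
#' @param max_steps episode cap (1000 in the reference setting; an undecided
#'   episode records `chosen = "none"` at exactly this count).
#' @param episodes episodes per snapshot evaluation.
#' @param env a [env_config()] for the probe room; defaults to the small open
#'   probe arena with all resource colors and fast restocking so the evaluated
#'   agent can become ready quickly.
#' @return a `gs_probe_config` list.
#' @export
probe_config <- function(targets = NULL, max_steps = 1000L, episodes = 10L,
                         env = NULL) {
  if (is.null(env)) {
    env <- env_config(make_layout("probe"), restock_prob = 0.05)
  }
  structure(list(targets = targets, max_steps = as.integer(max_steps),
                 episodes = as.integer(episodes), env = env),
            class = "gs_probe_config")
}

## Build the probe state: evaluated agent on a spawn point, both targets
## relocated to random free interior cells, made ready (inventory (1,1,1)) and
## flagged scripted so the dynamics never move them. probe_reset() builds a
## full state; probe_fast_reset() re-randomizes an existing template (the only
## per-episode stochastic elements: resource fill, evaluated agent placement
## and orientation, target positions), which keeps large probe sweeps cheap.
probe_reset <- function(pcfg, agent_group, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tg <- pcfg$targets
  stopifnot(length(tg) == 2L)
  cfg <- pcfg$env
  ## target body colors may not be among the configured groups (e.g. both
  ## targets share one color in the individuation probe); register them
  labels <- names(cfg$groups)
  roster <- tibble::tibble(
    agent_id = c("evaluated", "target_A", "target_B"),
    group = c(agent_group,
              if (tg[[1]]$group %in% labels) tg[[1]]$group else labels[1L],
              if (tg[[2]]$group %in% labels) tg[[2]]$group else labels[1L]),
    pixel = list(NULL, tg[[1]]$pixel, tg[[2]]$pixel)
  )
  st <- reset_episode(cfg, roster)
  a <- st$agents
  for (k in 2:3) {
    a$color[, k] <- tg[[k - 1L]]$color
    a$ready[k] <- TRUE
    a$inv[, k] <- 1
    a$scripted[k] <- TRUE
  }
  st$agents <- a
  ## relocate the two targets to random free interior cells
  lay <- cfg$layout
  free <- which(!lay$wall & st$occ == 0L & st$resources == 0L)
  pick <- sample(free, 2L)
  for (k in 2:3) {
    a <- st$agents
    st$occ[a$row[k], a$col[k]] <- 0L
    rc <- arrayInd(pick[k - 1L], dim(lay$wall))
    a$row[k] <- rc[1L]; a$col[k] <- rc[2L]
    st$occ[rc[1L], rc[2L]] <- k
    st$agents <- a
  }
  st
}

probe_fast_reset <- function(template, pcfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- template
  lay <- st$config$layout
  st$occ[] <- 0L
  st$resources[] <- 0L
  if (st$config$initial_stock) {
    cols <- st$config$resource_colors
    st$resources[lay$resource_points] <-
      cols[sample.int(length(cols), nrow(lay$resource_points), replace = TRUE)]
  }
  a <- st$agents
  sp <- lay$spawn_points
  k <- sample.int(nrow(sp), 1L)
  a$row[1L] <- sp[k, 1L]; a$col[1L] <- sp[k, 2L]
  a$orient[1L] <- sample.int(4L, 1L)
  a$inv[, 1L] <- 0
  a$ready[1L] <- FALSE
  a$freeze[] <- 0L; a$removal[] <- 0L; a$removal_pending[] <- FALSE
  st$occ[a$row[1L], a$col[1L]] <- 1L
  free <- which(!lay$wall & st$occ == 0L & st$resources == 0L)
  pick <- sample(free, 2L)
  for (kk in 2:3) {
    rc <- arrayInd(pick[kk - 1L], dim(lay$wall))
    a$row[kk] <- rc[1L]; a$col[kk] <- rc[2L]
    st$occ[rc[1L], rc[2L]] <- kk
  }
  st$agents <- a
  st$step_index <- 0L
  st$episode_length <- pcfg$max_steps
  st
}

## One probe episode against a prebuilt template; returns list(chosen, steps)
## without tibble overhead. `chosen` is "A", "B" or "none".
probe_episode_fast <- function(policy, pcfg, template, seed = NULL) {
  st <- probe_fast_reset(template, pcfg, seed)
  if (inherits(policy, "gs_policy") &&
      policy$spec$input == "features" && policy$spec$core == "none") {
    a <- st$agents; cfg <- st$config
    out <- cpp_rollout(pcfg$max_steps,
                       list(policy$params, NULL, NULL),
                       cfg$layout$wall, st$occ, st$resources,
                       cfg$layout$resource_points, cfg$layout$spawn_points,
                       cfg$layout$spawn_slot,
                       a$row, a$col, a$orient, a$inv, a$ready, a$freeze,
                       a$removal, a$removal_pending, a$scripted, a$slot,
                       a$pfreeze, cfg$resource_colors, cfg$removal_steps,
                       cfg$beam_range, cfg$restock_prob, cfg$reward_scale,
                       cfg$require_initiator_ready,
                       record = FALSE, stop_agent = 1L)
    if (out$chosen == 0L) return(list(chosen = "none", steps = pcfg$max_steps))
    return(list(chosen = c("A", "B")[out$chosen - 1L], steps = out$steps))
  }
  core <- NULL
  for (t in seq_len(pcfg$max_steps)) {
    act <- policy_act(policy, st, "evaluated", core)
    core <- act$core_state
    out <- env_step(st, c(act$action, ACTIONS[["NOOP"]], ACTIONS[["NOOP"]]))
    st <- out$state
    if (nrow(out$events)) {
      ev <- out$events[out$events$initiator_id == "evaluated", , drop = FALSE]
      if (nrow(ev)) {
        return(list(chosen = sub("target_", "", ev$target_id[1L]), steps = t))
      }
    }
  }
  list(chosen = "none", steps = pcfg$max_steps)
}

#' Run one dual-choice probe episode
#'
#' Simulates the probe room with full game dynamics: the evaluated agent can
#' move, collect resources (to become ready) and fire its beam; the two
#' targets are immobile and always ready. The episode ends when the evaluated
#' agent's beam connects with a target, or after `max_steps` steps
#' (`chosen = "none"`). No learning occurs.
#'
#' @param policy a frozen or scripted policy.
#' @param pcfg a [probe_config()] with `targets` set.
#' @param agent_group group label of the evaluated agent (for its own sprite).
#' @param seed optional integer seed (same seed + same snapshot gives an
#'   identical result).
#' @return one-row tibble: `chosen` ("A", "B" or "none"), `chosen_group`,
#'   `steps_taken`.
#' @export
run_probe_episode <- function(policy, pcfg, agent_group = "red", seed = NULL) {
  template <- probe_reset(pcfg, agent_group)
  res <- probe_episode_fast(policy, pcfg, template, seed)
  chosen_group <- if (res$chosen == "none") NA_character_ else {
    pcfg$targets[[res$chosen]]$group
  }
  tibble::tibble(chosen = res$chosen, chosen_group = chosen_group,
                 steps_taken = res$steps)
}

default_bias_targets <- function(envcfg) {
  labels <- names(envcfg$groups)
  list(A = list(group = labels[1L], color = envcfg$groups[[1L]], pixel = NULL),
       B = list(group = labels[2L], color = envcfg$groups[[2L]], pixel = NULL))
}

#' Evaluate group bias of policy snapshots via dual-choice probes
#'
#' For each snapshot, runs probe episodes against one generic (pixel-free)
#' sprite per group color, bins results by training step, and computes per
#' (agent, bin) the fraction of decided episodes choosing the same-color
#' target. Undecided episodes are excluded from the ratio and counted
#' separately; a bin with zero decided episodes is flagged with `ratio = NA`.
#'
#' @param snapshots tibble with columns `agent_id`, `group`, `training_step`
#'   and `policy` (list column of frozen/scripted policies).
#' @param pcfg a [probe_config()]; its `targets` are replaced by the two
#'   generic group sprites.
#' @param bin_width bin width in training steps (the reference analysis bins
#'   every 30 million steps, 6 evaluation points per bin).
#' @param seed master seed; every episode draws a derived substream seed.
#' @return a `gs_bias_table` tibble: `agent_id`, `group`, `bin`, `ratio`,
#'   `n_decided`, `n_undecided`.
#' @export
evaluate_group_bias <- function(snapshots, pcfg, bin_width = 1L, seed = 1L) {
  stopifnot(all(c("agent_id", "group", "training_step", "policy") %in% names(snapshots)))
  pcfg$targets <- default_bias_targets(pcfg$env)
  tgroup <- c(A = pcfg$targets$A$group, B = pcfg$targets$B$group)
  rows <- purrr::pmap(snapshots[c("agent_id", "group", "training_step", "policy")],
    function(agent_id, group, training_step, policy) {
      template <- probe_reset(pcfg, group)
      chosen <- character(pcfg$episodes)
      steps <- integer(pcfg$episodes)
      for (e in seq_len(pcfg$episodes)) {
        s <- substream_seed(seed, paste0("probe_", agent_id, "_", training_step), e)
        r <- probe_episode_fast(policy, pcfg, template, seed = s)
        chosen[e] <- r$chosen; steps[e] <- r$steps
      }
      tibble::tibble(chosen = chosen,
                     chosen_group = ifelse(chosen == "none", NA_character_,
                                           unname(tgroup[chosen])),
                     steps_taken = steps,
                     agent_id = agent_id, group = group,
                     training_step = training_step)
    })
  log <- dplyr::bind_rows(rows)
  out <- log |>
    dplyr::mutate(bin = floor(.data$training_step / bin_width)) |>
    dplyr::group_by(.data$agent_id, .data$group, .data$bin) |>
    dplyr::summarise(
      n_decided = sum(.data$chosen != "none"),
      n_undecided = sum(.data$chosen == "none"),
      ratio = mean(.data$chosen_group[.data$chosen != "none"] == .data$group[1L]),
      .groups = "drop")
  out$ratio[out$n_decided == 0] <- NA_real_
  class(out) <- c("gs_bias_table", class(out))
  attr(out, "probe_log") <- log
  out
}

#' Group-level bias summary from a per-agent bias table
#'
#' Averages the per-agent in-group choice ratios within each (group, bin) —
#' the average of the averages obtained for each probed agent — and derives
#' the group-bias value (mean in-group ratio across both groups minus 0.5).
#'
#' @param bias_table output of [evaluate_group_bias()].
#' @return tibble with one row per bin: per-group mean ratios and `bias`.
#' @export
group_bias_table <- function(bias_table) {
  per_group <- bias_table |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     n_agents = dplyr::n(), .groups = "drop")
  per_group |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      bias = mean(.data$mean_ratio) - 0.5,
      n_groups = dplyr::n(), .groups = "drop")
}

#' Evaluate individuation (marked-sprite avoidance) of snapshots
#'
#' Both targets share one body color; exactly one bears the designated
#' less-desirable agent's individuation pixel. The discrimination score is the
#' fraction of decided episodes choosing the generic (pixel-free) target —
#' 1 means always picking the more desirable partner. Scores are computed
#' separately with the targets drawn from the probed agent's own group and
#' from the other group.
#'
#' @param snapshots as in [evaluate_group_bias()].
#' @param pcfg a [probe_config()].
#' @param marked_pixels named list mapping group label to the less-desirable
#'   member's pixel RGB.
#' @param bin_width bin width in training steps.
#' @param seed master seed.
#' @return tibble: `agent_id`, `group`, `target_side` ("ingroup"/"outgroup"),
#'   `bin`, `score`, `n_decided`, `n_undecided`.
#' @export
evaluate_individuation <- function(snapshots, pcfg, marked_pixels,
                                   bin_width = 1L, seed = 1L) {
  labels <- names(pcfg$env$groups)
  rows <- purrr::pmap(snapshots[c("agent_id", "group", "training_step", "policy")],
    function(agent_id, group, training_step, policy) {
      purrr::map(c("ingroup", "outgroup"), function(side) {
        tgroup <- if (side == "ingroup") group else setdiff(labels, group)
        col <- pcfg$env$groups[[tgroup]]
        p2 <- pcfg
        p2$targets <- list(
          A = list(group = tgroup, color = col, pixel = NULL),
          B = list(group = tgroup, color = col, pixel = marked_pixels[[tgroup]]))
        template <- probe_reset(p2, group)
        chosen <- character(p2$episodes)
        steps <- integer(p2$episodes)
        for (e in seq_len(p2$episodes)) {
          s <- substream_seed(seed, paste0("ind_", agent_id, "_", side, "_",
                                           training_step), e)
          r <- probe_episode_fast(policy, p2, template, seed = s)
          chosen[e] <- r$chosen; steps[e] <- r$steps
        }
        tibble::tibble(chosen = chosen, steps_taken = steps,
                       agent_id = agent_id, group = group, target_side = side,
                       training_step = training_step)
      }) |> dplyr::bind_rows()
    })
  log <- dplyr::bind_rows(rows)
  out <- log |>
    dplyr::mutate(bin = floor(.data$training_step / bin_width)) |>
    dplyr::group_by(.data$agent_id, .data$group, .data$target_side, .data$bin) |>
    dplyr::summarise(
      n_decided = sum(.data$chosen != "none"),
      n_undecided = sum(.data$chosen == "none"),
      score = mean(.data$chosen[.data$chosen != "none"] == "A"),
      .groups = "drop")
  out$score[out$n_decided == 0] <- NA_real_
  attr(out, "probe_log") <- log
  out
}
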