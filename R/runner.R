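## Experiment orchestration: named configurations for every experiment
## condition, seeding through named substreams, the synchronous training loop,
## logging, and figure-ready tidy tables.

COLOR_PAIRS <- list(
  default = list(c(150, 0, 0), c(0, 0, 150)),
  purple1 = list(c(150, 0, 50), c(50, 0, 150)),
  purple2 = list(c(150, 0, 100), c(100, 0, 150))
)

#' Build an experiment configuration
#'
#' A config plus a master seed fully determines a run. The scale preset sets
#' the learner architecture and rollout sizes; the game rules (beam range,
#' freeze/removal, reward rule, sampling logic) are identical across presets —
#' presets shrink budgets, not rules.
#'
#' @param name experiment name (free text, archived in the manifest).
#' @param layout `"default"`, `"wall"` or `"eight_cell"`.
#' @param mixed_ratio majority:minority ratio of the mixed server
#'   (`c(8,0)` ... `c(4,4)`).
#' @param color_pair `"default"` (red/blue), `"purple1"` or `"purple2"`
#'   (increasingly similar), or a list of two RGB triples.
#' @param individuation enable per-member individuation pixels and one
#'   less-desirable member per group.
#' @param pixel_variant `"bright"` or `"dark"` individuation pixel.
#' @param elevated_freeze freeze duration of the less-desirable member.
#' @param resource_colors integer subset of 1:3 (length 1 = single-resource
#'   control).
#' @param preset `"micro"`, `"desk"` or `"paper"` learner/scale preset.
#' @param n_episodes training episodes.
#' @param episode_length length-2 range of steps per episode.
#' @param probe_every probe cadence in environment steps.
#' @param probe_episodes probe episodes per evaluated snapshot.
#' @param probe_max_steps step cap of one probe episode.
#' @param n_probed agents probed per group (6 in the reference setting, 4 in
#'   individuation mode).
#' @param restock_prob per-point resource restock probability.
#' @param arena interior arena size for the default layout.
#' @param policy_kind `"learned"`, or a scripted kind (see [scripted_policy()])
#'   for fixture runs without training.
#' @param learner named list of [training_config()] overrides (e.g. `lr`,
#'   `entropy_weight`, `unroll`, `vtrace`).
#' @param replication replication index (archived).
#' @param seed default master seed.
#' @return a `gs_experiment_config` list.
#' @export
experiment_config <- function(name = "ratio_sweep/6v2",
                              layout = "default",
                              mixed_ratio = c(6L, 2L),
                              color_pair = "default",
                              individuation = FALSE,
                              pixel_variant = c("bright", "dark"),
                              elevated_freeze = 64L,
                              resource_colors = 1:3,
                              preset = c("micro", "desk", "paper"),
                              n_episodes = 30L,
                              episode_length = c(60L, 100L),
                              probe_every = 500L,
                              probe_episodes = 4L,
                              probe_max_steps = 300L,
                              n_probed = if (individuation) 4L else 6L,
                              restock_prob = 0.05,
                              arena = 11L,
                              policy_kind = "learned",
                              learner = list(),
                              replication = 1L,
                              seed = 1L) {
  preset <- match.arg(preset)
  pixel_variant <- match.arg(pixel_variant)
  if (is.character(color_pair)) color_pair <- COLOR_PAIRS[[color_pair]]
  stopifnot(length(color_pair) == 2L)
  structure(list(name = name, layout = layout, mixed_ratio = as.integer(mixed_ratio),
                 color_pair = color_pair, individuation = individuation,
                 pixel_variant = pixel_variant,
                 elevated_freeze = as.integer(elevated_freeze),
                 resource_colors = as.integer(resource_colors), preset = preset,
                 n_episodes = as.integer(n_episodes),
                 episode_length = as.integer(episode_length),
                 probe_every = as.integer(probe_every),
                 probe_episodes = as.integer(probe_episodes),
                 probe_max_steps = as.integer(probe_max_steps),
                 n_probed = as.integer(n_probed),
                 restock_prob = restock_prob, arena = as.integer(arena),
                 policy_kind = policy_kind, learner = learner,
                 replication = as.integer(replication), seed = as.integer(seed)),
            class = "gs_experiment_config")
}

#' Load an experiment configuration from a YAML file
#'
#' @param path YAML file with `experiment_config()` fields.
#' @return a `gs_experiment_config`.
#' @export
load_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(experiment_config, vals)
}

#' Validate an experiment configuration
#'
#' @param config a `gs_experiment_config`.
#' @return invisibly `TRUE`; aborts with a message on an invalid config.
#' @export
validate_experiment_config <- function(config) {
  stopifnot(inherits(config, "gs_experiment_config"))
  if (!config$layout %in% c("default", "wall", "eight_cell")) {
    abort("unknown layout")
  }
  if (sum(config$mixed_ratio) != 8L || config$mixed_ratio[2L] > config$mixed_ratio[1L]) {
    abort("mixed ratio must be a majority:minority split of 8")
  }
  if (!all(config$resource_colors %in% 1:3)) abort("resource colors must be in 1:3")
  invisible(TRUE)
}

env_config_for <- function(config) {
  lay <- if (config$layout == "default") {
    make_layout("default", width = config$arena, height = config$arena)
  } else {
    make_layout(config$layout)
  }
  groups <- setNames(config$color_pair, c("red", "blue"))
  env_config(lay, groups = groups,
             episode_length = config$episode_length,
             resource_colors = config$resource_colors,
             restock_prob = config$restock_prob)
}

policy_spec_for <- function(preset) {
  switch(preset, micro = policy_spec_micro(), desk = policy_spec_desk(),
         paper = policy_spec_paper())
}

training_config_for <- function(preset, overrides = list()) {
  ## micro shrinks the nets and raises lr/entropy so tiny budgets still move;
  ## paper/desk keep the reference optimization constants
  base <- if (preset == "micro") {
    ## micro deviations from the reference constants (see methods vignette):
    ## higher lr for tiny nets/batches, gamma 0.9 to concentrate credit on
    ## the approach-and-fire segment at short horizons
    list(preset = "micro", lr = 0.02, entropy_weight = 0.005, gamma = 0.9,
         unroll = 500L)
  } else {
    list(preset = preset)
  }
  do.call(training_config, modifyList(base, overrides))
}

#' Run one experiment end to end
#'
#' Samples episodes from the two servers, steps the environment with the
#' per-agent policies (independent actor-critic learners, or a scripted
#' fixture policy), logs every interaction event, snapshots the probed agents
#' at the probe cadence, then runs the dual-choice probes and computes the
#' binned bias tables (and individuation scores when enabled).
#'
#' @param config a [experiment_config()].
#' @param seed master seed (defaults to the config's seed); all substreams
#'   derive from it.
#' @param outdir optional run directory; when given, event logs (JSONL),
#'   probe/bias tables (CSV), the training curve (CSV) and a manifest (JSON)
#'   are written there.
#' @return a `gs_run` list: `config`, `manifest`, `events`, `episodes`,
#'   `bias`, `bias_by_bin`, `individuation` (or `NULL`), `curve`, `summed_bias`.
#' @export
run_experiment <- function(config, seed = config$seed, outdir = NULL) {
  validate_experiment_config(config)
  envcfg <- env_config_for(config)
  pops <- population_config(
    labels = c("red", "blue"), colors = config$color_pair,
    individuation = config$individuation,
    pixel_base = if (config$pixel_variant == "bright") c(255, 255, 0) else c(80, 80, 0),
    elevated_freeze = config$elevated_freeze)
  schedule <- make_schedule(pops, mixed_ratio = config$mixed_ratio)
  tcfg <- training_config_for(config$preset, config$learner)
  spec <- policy_spec_for(config$preset)

  learned <- identical(config$policy_kind, "learned")
  policies <- if (learned) {
    setNames(lapply(seq_len(nrow(pops)), function(k) {
      init_policy(spec, seed = substream_seed(seed, "init", k))
    }), pops$agent_id)
  } else {
    scripted <- scripted_policy(config$policy_kind)
    setNames(rep(list(scripted), nrow(pops)), pops$agent_id)
  }

  probed_ids <- pops |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_head(n = config$n_probed) |>
    dplyr::pull(.data$agent_id)

  events_log <- list()
  snapshots <- list()
  cum_steps <- 0
  next_probe <- 0
  n_eps <- config$n_episodes
  ep_server <- character(n_eps); ep_majority <- character(n_eps)
  ep_roster <- vector("list", n_eps)
  ep_len <- integer(n_eps); ep_nev <- integer(n_eps)
  curve_reward <- rep(NA_real_, n_eps); curve_loss <- rep(NA_real_, n_eps)
  curve_steps <- rep(NA_real_, n_eps)

  for (ep in seq_len(config$n_episodes)) {
    set.seed(substream_seed(seed, "scheduler", ep))
    asg <- next_episode_assignment(schedule)
    roster <- asg$roster
    set.seed(substream_seed(seed, "episode", ep))
    state <- reset_episode(envcfg, roster)
    n <- nrow(roster)
    ids <- roster$agent_id

    fast <- learned && spec$input == "features" && spec$core == "none"
    if (fast) {
      a <- state$agents
      out <- cpp_rollout(state$episode_length,
                         lapply(ids, function(id) policies[[id]]$params),
                         envcfg$layout$wall, state$occ, state$resources,
                         envcfg$layout$resource_points, envcfg$layout$spawn_points,
                         envcfg$layout$spawn_slot,
                         a$row, a$col, a$orient, a$inv, a$ready, a$freeze,
                         a$removal, a$removal_pending, a$scripted, a$slot,
                         a$pfreeze, envcfg$resource_colors, envcfg$removal_steps,
                         envcfg$beam_range, envcfg$restock_prob,
                         envcfg$reward_scale, envcfg$require_initiator_ready,
                         record = TRUE, stop_agent = 0L)
      state$step_index <- out$steps
      ep_reward <- setNames(out$total_reward, ids)
      ev <- out$events
      ep_ev <- if (length(ev$step_index)) {
        tibble::tibble(
          step_index = ev$step_index,
          initiator_id = ids[ev$initiator], target_id = ids[ev$target],
          initiator_group = roster$group[ev$initiator],
          target_group = roster$group[ev$target],
          inventory_initiator = lapply(seq_along(ev$step_index),
                                       function(e) ev$inv_initiator[e, ]),
          inventory_target = lapply(seq_along(ev$step_index),
                                    function(e) ev$inv_target[e, ]),
          reward = ev$reward)
      } else empty_events()
      if (nrow(ep_ev)) {
        ep_ev$episode_id <- ep
        ep_ev$server <- asg$server_kind
        ep_ev$majority_group <- asg$majority_group
        events_log <- c(events_log, list(ep_ev))
      }
      ep_server[ep] <- asg$server_kind; ep_majority[ep] <- asg$majority_group
      ep_roster[[ep]] <- tibble::as_tibble(roster[c("agent_id", "group")])
      ep_len[ep] <- state$episode_length; ep_nev[ep] <- nrow(ep_ev)
      diags <- numeric(0)
      for (k in seq_len(n)) {
        tr <- out$trajectories[[k]]
        if (is.null(tr) || length(tr$actions) < 2L) next
        Tn <- length(tr$actions)
        chunks <- split(seq_len(Tn), ceiling(seq_len(Tn) / tcfg$unroll))
        segs <- lapply(seq_along(chunks), function(ci) {
          idx <- chunks[[ci]]
          boot <- if (ci < length(chunks)) tr$values[chunks[[ci + 1L]][1L]] else 0
          make_segment(tr$obs[idx, , drop = FALSE],
                       tr$inv[idx, , drop = FALSE],
                       tr$actions[idx], tr$rewards[idx], bootstrap_value = boot)
        })
        upd <- actor_critic_update(policies[[ids[k]]], segs, tcfg)
        policies[[ids[k]]] <- upd$policy
        diags <- c(diags, upd$diagnostics$loss)
      }
      curve_steps[ep] <- cum_steps
      curve_reward[ep] <- mean(ep_reward)
      curve_loss[ep] <- if (length(diags)) mean(diags) else NA_real_
      cum_steps <- cum_steps + state$step_index
      if (cum_steps >= next_probe) {
        for (id in probed_ids) {
          snapshots <- c(snapshots, list(tibble::tibble(
            agent_id = id, group = pops$group[pops$agent_id == id],
            training_step = cum_steps,
            policy = list(snapshot_policy(policies[[id]], step = cum_steps)))))
        }
        next_probe <- next_probe + config$probe_every
      }
      next
    }

    traj <- if (learned) {
      setNames(lapply(ids, function(i) list(obs = list(), inv = list(),
                                            action = integer(), reward = numeric(),
                                            value = numeric(), logits = list())), ids)
    } else NULL
    cores <- setNames(vector("list", n), ids)
    ep_events <- list()
    ep_reward <- setNames(numeric(n), ids)

    while (!is_terminal(state)) {
      actions <- rep(ACTIONS[["NOOP"]], n)
      recorded <- rep(FALSE, n)
      for (k in seq_len(n)) {
        a <- state$agents
        if (is.na(a$row[k]) || a$freeze[k] > 0L) next
        if (learned) {
          pol <- policies[[ids[k]]]
          obs <- if (spec$input == "pixels") render_observation(state, ids[k]) else feature_observation(state, ids[k])
          cs <- cores[[ids[k]]] %||% initial_core_state(pol)
          out <- forward_step(pol, obs, a$inv[, k], cs)
          pr <- softmax(out$logits)
          actions[k] <- sample.int(length(pr), 1L, prob = pr)
          cores[[ids[k]]] <- out$state
          tr <- traj[[ids[k]]]
          tr$obs[[length(tr$obs) + 1L]] <- obs
          tr$inv[[length(tr$inv) + 1L]] <- a$inv[, k]
          tr$action <- c(tr$action, actions[k])
          tr$value <- c(tr$value, out$value)
          tr$reward <- c(tr$reward, 0)
          traj[[ids[k]]] <- tr
          recorded[k] <- TRUE
        } else {
          actions[k] <- policy_act(policies[[ids[k]]], state, ids[k])$action
        }
      }
      out <- env_step(state, actions)
      state <- out$state
      ep_reward <- ep_reward + out$rewards[ids]
      if (learned) {
        for (k in which(recorded)) {
          tr <- traj[[ids[k]]]
          tr$reward[length(tr$reward)] <- out$rewards[[ids[k]]]
          traj[[ids[k]]] <- tr
        }
      }
      if (nrow(out$events)) ep_events <- c(ep_events, list(out$events))
    }

    ep_ev <- if (length(ep_events)) dplyr::bind_rows(ep_events) else empty_events()
    if (nrow(ep_ev)) {
      ep_ev$episode_id <- ep
      ep_ev$server <- asg$server_kind
      ep_ev$majority_group <- asg$majority_group
      events_log <- c(events_log, list(ep_ev))
    }
    ep_server[ep] <- asg$server_kind; ep_majority[ep] <- asg$majority_group
    ep_roster[[ep]] <- tibble::as_tibble(roster[c("agent_id", "group")])
    ep_len[ep] <- state$episode_length; ep_nev[ep] <- nrow(ep_ev)

    if (learned) {
      diags <- numeric(0)
      for (id in ids) {
        tr <- traj[[id]]
        Tn <- length(tr$action)
        if (Tn < 2L) next
        chunks <- split(seq_len(Tn), ceiling(seq_len(Tn) / tcfg$unroll))
        segs <- lapply(seq_along(chunks), function(ci) {
          idx <- chunks[[ci]]
          boot <- if (ci < length(chunks)) tr$value[chunks[[ci + 1L]][1L]] else 0
          make_segment(tr$obs[idx],
                       do.call(rbind, tr$inv[idx]),
                       tr$action[idx], tr$reward[idx], bootstrap_value = boot)
        })
        upd <- actor_critic_update(policies[[id]], segs, tcfg)
        policies[[id]] <- upd$policy
        diags <- c(diags, upd$diagnostics$loss)
      }
      curve_steps[ep] <- cum_steps
      curve_reward[ep] <- mean(ep_reward)
      curve_loss[ep] <- if (length(diags)) mean(diags) else NA_real_
    }

    cum_steps <- cum_steps + state$step_index
    if (learned && cum_steps >= next_probe) {
      for (id in probed_ids) {
        snapshots <- c(snapshots, list(tibble::tibble(
          agent_id = id, group = pops$group[pops$agent_id == id],
          training_step = cum_steps,
          policy = list(snapshot_policy(policies[[id]], step = cum_steps)))))
      }
      next_probe <- next_probe + config$probe_every
    }
  }

  events <- if (length(events_log)) dplyr::bind_rows(events_log) else empty_events()
  episodes <- tibble::tibble(episode_id = seq_len(n_eps), server = ep_server,
                             majority_group = ep_majority, roster = ep_roster,
                             length = ep_len, n_events = ep_nev)
  curve <- if (learned) {
    tibble::tibble(episode_id = seq_len(n_eps), steps = curve_steps,
                   mean_reward = curve_reward, mean_loss = curve_loss)
  } else NULL

  ## probes on the frozen snapshots
  bias <- bias_by_bin <- individuation <- NULL
  if (learned && length(snapshots)) {
    snap_tbl <- dplyr::bind_rows(snapshots)
    pcfg <- probe_config(max_steps = config$probe_max_steps,
                         episodes = config$probe_episodes,
                         env = env_config(make_layout("probe"),
                                          groups = setNames(config$color_pair, c("red", "blue")),
                                          resource_colors = config$resource_colors,
                                          restock_prob = 0.05))
    bin_width <- 6L * config$probe_every
    bias <- evaluate_group_bias(snap_tbl, pcfg, bin_width = bin_width,
                                seed = substream_seed(seed, "probe"))
    bias_by_bin <- group_bias_table(bias)
    if (config$individuation) {
      marked <- pops |> dplyr::filter(.data$less_desirable)
      marked_pixels <- setNames(marked$pixel, marked$group)
      individuation <- evaluate_individuation(
        snap_tbl, pcfg, marked_pixels, bin_width = bin_width,
        seed = substream_seed(seed, "probe_ind"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("groupsim")),
    seed = seed, preset = config$preset, name = config$name,
    replication = config$replication,
    config_hash = substream_seed(1L, paste(deparse(config), collapse = "")),
    probed_agents = probed_ids, total_steps = cum_steps)

  run <- structure(list(config = config, manifest = manifest, events = events,
                        episodes = episodes, curve = curve, bias = bias,
                        bias_by_bin = bias_by_bin, individuation = individuation,
                        final_policies = if (learned) {
                          lapply(policies, snapshot_policy, step = cum_steps)
                        } else NULL,
                        summed_bias = if (!is.null(bias_by_bin) && nrow(bias_by_bin))
                          summed_bias(bias_by_bin$bias) else NA_real_),
                   class = "gs_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

write_jsonl <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, digits = NA), con)
  }
}

#' Write a run's logs to a directory
#'
#' @param run a `gs_run`.
#' @param outdir directory (created if needed).
#' @return invisibly, `outdir`.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ev <- run$events
  if (nrow(ev)) {
    ev$inventory_initiator <- vapply(ev$inventory_initiator, paste, "", collapse = ",")
    ev$inventory_target <- vapply(ev$inventory_target, paste, "", collapse = ",")
    write_jsonl(ev, file.path(outdir, "events.jsonl"))
  }
  if (!is.null(run$bias)) {
    utils::write.csv(run$bias, file.path(outdir, "bias_by_agent.csv"), row.names = FALSE)
    utils::write.csv(run$bias_by_bin, file.path(outdir, "bias_by_bin.csv"), row.names = FALSE)
  }
  if (!is.null(run$curve)) {
    utils::write.csv(run$curve, file.path(outdir, "training_curve.csv"), row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Figure-ready tidy tables from a set of completed runs
#'
#' Reassembles the quantities plotted in the study's figure panels:
#' * `fig2a`: chance-normalized interaction-category frequencies per run.
#' * `fig2b`: per (run, group, bin) in-group choice ratios.
#' * `fig2c`: per (condition, bin) group bias (the ratio sweep).
#' * `fig2d`: per condition summed bias.
#' * `fig3a`: summed bias by color-pair RGB distance and condition.
#' * `fig3b`/`fig3c`: as `fig2c` for the wall / eight-cell layouts.
#' * `fig4a`: individuation scores by side and bin; `fig4b`: gaps;
#'   `fig4c`: per-run (gap, summed bias) pairs with their correlation.
#'
#' @param runs list of `gs_run` objects.
#' @param figure_id one of the panel ids above.
#' @return a tibble; missing conditions are reported in the
#'   `missing_conditions` attribute.
#' @export
reproduce_figure_table <- function(runs, figure_id = "fig2c") {
  if (!length(runs)) {
    out <- tibble::tibble()
    attr(out, "missing_conditions") <- "all (empty run set)"
    return(out)
  }
  cond <- function(rn) paste(rn$config$mixed_ratio, collapse = ":")
  rgb_dist <- function(rn) {
    sqrt(sum((rn$config$color_pair[[1]] - rn$config$color_pair[[2]])^2))
  }
  if (figure_id == "fig2a") {
    out <- purrr::imap(runs, function(rn, ri) {
      ## training-environment analysis: mixed-server episodes with both
      ## groups present (the in-group server cannot produce mixed events)
      two_group <- vapply(rn$episodes$roster,
                          function(r) length(unique(r$group)) == 2L, TRUE)
      keep <- rn$episodes$episode_id[two_group]
      evs <- rn$events[rn$events$episode_id %in% keep, ]
      per_ep <- purrr::map(split(evs, evs$episode_id), function(e) {
        ros <- rn$episodes$roster[[e$episode_id[1L]]]
        attr(ros, "majority_group") <- e$majority_group[1L]
        categorize_interactions(e, ros)
      })
      dplyr::bind_rows(per_ep) |>
        dplyr::group_by(.data$category) |>
        dplyr::summarise(count = sum(.data$count), m = .data$m[1L], n = .data$n[1L],
                         .groups = "drop") |>
        chance_normalize() |>
        dplyr::mutate(run = ri, condition = cond(rn))
    })
    return(dplyr::bind_rows(out))
  }
  if (figure_id == "fig2b") {
    out <- purrr::imap(runs, function(rn, ri) {
      rn$bias |>
        dplyr::filter(!is.na(.data$ratio)) |>
        dplyr::group_by(.data$group, .data$bin) |>
        dplyr::summarise(mean_ratio = mean(.data$ratio), .groups = "drop") |>
        dplyr::mutate(run = ri, condition = cond(rn))
    })
    return(dplyr::bind_rows(out))
  }
  if (figure_id %in% c("fig2c", "fig3b", "fig3c")) {
    out <- purrr::imap(runs, function(rn, ri) {
      rn$bias_by_bin |>
        dplyr::mutate(run = ri, condition = cond(rn), layout = rn$config$layout)
    })
    out <- dplyr::bind_rows(out)
    want <- if (figure_id == "fig2c") c("8:0", "7:1", "6:2", "5:3", "4:4") else character()
    attr(out, "missing_conditions") <- setdiff(want, unique(out$condition))
    return(out)
  }
  if (figure_id %in% c("fig2d", "fig3a")) {
    out <- purrr::imap(runs, function(rn, ri) {
      tibble::tibble(run = ri, condition = cond(rn),
                     rgb_distance = rgb_dist(rn),
                     summed_bias = rn$summed_bias)
    })
    return(dplyr::bind_rows(out))
  }
  if (figure_id == "fig4a") {
    out <- purrr::imap(runs, function(rn, ri) {
      if (is.null(rn$individuation)) return(NULL)
      rn$individuation |>
        dplyr::filter(!is.na(.data$score)) |>
        dplyr::group_by(.data$target_side, .data$bin) |>
        dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
        dplyr::mutate(run = ri, freeze_time = rn$config$elevated_freeze,
                      pixel_variant = rn$config$pixel_variant)
    })
    return(dplyr::bind_rows(out))
  }
  if (figure_id %in% c("fig4b", "fig4c")) {
    out <- purrr::imap(runs, function(rn, ri) {
      if (is.null(rn$individuation)) return(NULL)
      sc <- rn$individuation |>
        dplyr::filter(!is.na(.data$score)) |>
        dplyr::group_by(.data$target_side) |>
        dplyr::summarise(score = mean(.data$score), .groups = "drop")
      gap <- individuation_gap(sc$score[sc$target_side == "ingroup"],
                               sc$score[sc$target_side == "outgroup"])
      tibble::tibble(run = ri, freeze_time = rn$config$elevated_freeze,
                     pixel_variant = rn$config$pixel_variant,
                     individuation_gap = gap, summed_bias = rn$summed_bias)
    })
    out <- dplyr::bind_rows(out)
    if (figure_id == "fig4c" && nrow(out) >= 3L) {
      attr(out, "pearson_r") <- pearson_r(out$individuation_gap, out$summed_bias)
    }
    return(out)
  }
  abort(paste0("unknown figure id: ", figure_id))
}
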