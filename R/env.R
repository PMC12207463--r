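## The partially observable Markov game: grid dynamics, resource collection,
## interaction-beam resolution, freeze/removal/respawn, episode termination.
##
## Agent state is stored struct-of-arrays (parallel vectors) for speed; use
## agent_states() for a tidy view.

#' The eight discrete actions
#'
#' Movement in all directions (forward/backward/strafe), turning, a no-op and
#' the interaction beam. `INTERACT` is the only non-movement action.
#' @export
ACTIONS <- c(NOOP = 1L, FORWARD = 2L, BACKWARD = 3L, STRAFE_LEFT = 4L,
             STRAFE_RIGHT = 5L, TURN_LEFT = 6L, TURN_RIGHT = 7L, INTERACT = 8L)

## heading deltas: rows = orientation (1 N, 2 E, 3 S, 4 W); forward and right
## unit vectors as (drow, dcol)
FWD_D <- matrix(c(-1L, 0L, 0L, 1L, 1L, 0L, 0L, -1L), 4L, 2L, byrow = TRUE)
RGT_D <- matrix(c(0L, 1L, 1L, 0L, 0L, -1L, -1L, 0L), 4L, 2L, byrow = TRUE)

#' Reset an episode
#'
#' Places the roster's agents on distinct spawn points (respecting per-slot
#' color restrictions in the wall and eight-cell layouts), zeroes inventories
#' and timers, clears ready flags, optionally stocks every resource point, and
#' draws the episode length uniformly from the configured range.
#'
#' @param config a [env_config()].
#' @param roster a data frame with columns `agent_id`, `group`, and optionally
#'   `personal_freeze` (default 16) and `pixel` (list column of RGB triples or
#'   `NULL`s for the individuation experiments).
#' @param seed optional integer; when given, seeds the RNG before placement so
#'   two resets with the same seed are identical.
#' @return a `gs_state` list; see [agent_states()] for the tidy agent view.
#' @export
#' @examples
#' cfg <- env_config(make_layout("default"))
#' ros <- tibble::tibble(agent_id = paste0("r", 1:8), group = "red")
#' st <- reset_episode(cfg, ros, seed = 1)
reset_episode <- function(config, roster, seed = NULL) {
  stopifnot(inherits(config, "gs_env_config"), is.data.frame(roster))
  if (!is.null(seed)) set.seed(seed)
  lay <- config$layout
  n <- nrow(roster)
  if (nrow(lay$spawn_points) < n) {
    abort("configuration error: fewer spawn points than agents")
  }
  slot <- group_slot(config, roster$group)
  pfreeze <- if ("personal_freeze" %in% names(roster)) {
    as.integer(roster$personal_freeze)
  } else rep(config$freeze_default, n)
  stopifnot(all(pfreeze >= 1L))
  pixel <- if ("pixel" %in% names(roster)) roster$pixel else rep(list(NULL), n)

  ## spawn placement, honoring slot restrictions
  pos <- matrix(NA_integer_, n, 2L)
  if (all(is.na(lay$spawn_slot))) {
    idx <- sample.int(nrow(lay$spawn_points), n)
    pos[] <- lay$spawn_points[idx, ]
  } else {
    for (s in 1:2) {
      who <- which(slot == s)
      if (!length(who)) next
      avail <- which(lay$spawn_slot == s)
      if (length(avail) < length(who)) {
        abort("configuration error: roster/layout color mismatch (not enough restricted spawn points)")
      }
      idx <- avail[sample.int(length(avail), length(who))]
      pos[who, ] <- lay$spawn_points[idx, , drop = FALSE]
    }
  }

  resources <- matrix(0L, lay$nrow, lay$ncol)
  if (config$initial_stock) {
    cols <- config$resource_colors
    resources[lay$resource_points] <-
      cols[sample.int(length(cols), nrow(lay$resource_points), replace = TRUE)]
  }

  occ <- matrix(0L, lay$nrow, lay$ncol)
  occ[pos] <- seq_len(n)

  colors <- vapply(roster$group, function(g) config$groups[[g]], numeric(3))

  structure(list(
    config = config,
    resources = resources,
    occ = occ,
    agents = list(
      id = as.character(roster$agent_id),
      group = as.character(roster$group),
      slot = slot,
      color = colors,                      # 3 x n
      pixel = pixel,                       # list of NULL / RGB
      row = pos[, 1L], col = pos[, 2L],
      orient = sample(4L, n, replace = TRUE),
      inv = matrix(0, 3L, n),
      ready = rep(FALSE, n),
      freeze = rep(0L, n),
      removal = rep(0L, n),
      removal_pending = rep(FALSE, n),
      pfreeze = pfreeze,
      scripted = rep(FALSE, n)             # probe targets: never act, stay ready
    ),
    step_index = 0L,
    episode_length = sample(seq.int(config$episode_length[1L],
                                    config$episode_length[2L]), 1L)
  ), class = "gs_state")
}

#' Tidy view of the agents in a state
#'
#' @param state a `gs_state`.
#' @return a tibble with one row per agent (position `NA` while removed).
#' @export
agent_states <- function(state) {
  a <- state$agents
  tibble::tibble(
    agent_id = a$id, group = a$group,
    row = a$row, col = a$col, orientation = a$orient,
    inv1 = a$inv[1, ], inv2 = a$inv[2, ], inv3 = a$inv[3, ],
    ready = a$ready, freeze_timer = a$freeze, removal_timer = a$removal,
    personal_freeze = a$pfreeze
  )
}

#' Is the episode over?
#' @param state a `gs_state`.
#' @return logical.
#' @export
is_terminal <- function(state) state$step_index >= state$episode_length

active_agents <- function(state) !is.na(state$agents$row)

.event_cache <- new.env(parent = emptyenv())

empty_events <- function() {
  ev <- .event_cache$empty
  if (is.null(ev)) {
    ev <- tibble::tibble(step_index = integer(), initiator_id = character(),
                         target_id = character(), initiator_group = character(),
                         target_group = character(), inventory_initiator = list(),
                         inventory_target = list(), reward = numeric())
    .event_cache$empty <- ev
  }
  ev
}

## Trace the interaction beam: first agent on the straight line along the
## initiator's heading within beam_range cells, stopped by walls.
beam_target <- function(state, i) {
  a <- state$agents
  lay <- state$config$layout
  d <- FWD_D[a$orient[i], ]
  r <- a$row[i]; cc <- a$col[i]
  for (k in seq_len(state$config$beam_range)) {
    r <- r + d[1L]; cc <- cc + d[2L]
    if (r < 1L || r > lay$nrow || cc < 1L || cc > lay$ncol) return(0L)
    if (lay$wall[r, cc]) return(0L)
    j <- state$occ[r, cc]
    if (j > 0L) return(j)
  }
  0L
}

#' Resolve one interaction beam
#'
#' Traces the initiator's beam along its heading (up to the configured range,
#' blocked by walls). If it connects with a ready agent (and, by default, the
#' initiator is itself ready), both participants receive reward equal to the
#' dot product of their inventories (times `reward_scale`), both are frozen
#' for the maximum of their personal freeze durations, and removal for
#' `removal_steps` is scheduled once the freeze elapses. Otherwise the beam is
#' a no-op and no event is returned.
#'
#' @param state a `gs_state`.
#' @param initiator_id agent id submitting `INTERACT`.
#' @return list with elements `state` (updated), `event` (one-row tibble or
#'   `NULL`) and `rewards` (named numeric, both participants, or `NULL`).
#' @export
resolve_interaction <- function(state, initiator_id) {
  i <- match(initiator_id, state$agents$id)
  stopifnot(!is.na(i))
  a <- state$agents
  cfg <- state$config
  res <- cpp_resolve_interaction(cfg$layout$wall, state$occ, a$row, a$col,
                                 a$orient, a$inv, a$ready, a$freeze,
                                 a$removal_pending, a$pfreeze,
                                 cfg$beam_range, cfg$reward_scale,
                                 cfg$require_initiator_ready, i)
  if (res$target == 0L) return(list(state = state, event = NULL, rewards = NULL))
  j <- res$target
  a$freeze <- res$freeze
  a$removal_pending <- res$removal_pending
  state$agents <- a
  event <- tibble::tibble(
    step_index = state$step_index + 1L,
    initiator_id = a$id[i], target_id = a$id[j],
    initiator_group = a$group[i], target_group = a$group[j],
    inventory_initiator = list(a$inv[, i]),
    inventory_target = list(a$inv[, j]),
    reward = res$reward
  )
  rewards <- setNames(c(res$reward, res$reward), c(a$id[i], a$id[j]))
  list(state = state, event = event, rewards = rewards)
}

#' Advance the game by one joint step
#'
#' Applies one action per agent. Frozen and removed agents' actions are
#' ignored and their timers decremented: a freeze expiring converts into
#' removal for `removal_steps`, and a removal expiring respawns the agent at a
#' free (slot-eligible) spawn point with inventory and ready flag reset.
#' Movements are resolved in randomized agent order (a move into a wall or
#' occupied cell is a no-op); walking over a resource collects it into the
#' matching inventory component, sets the ready flag and clears the cell.
#' Interaction beams are then resolved (randomized order), empty resource
#' points restock stochastically, and the step counter advances; the episode
#' is terminal when it reaches the drawn episode length.
#'
#' @param state a `gs_state` (not terminal).
#' @param actions integer vector, one action code per agent (see [ACTIONS]).
#' @return list `state`, `rewards` (numeric per agent), `events` (tibble of
#'   interaction events this step).
#' @export
env_step <- function(state, actions) {
  a <- state$agents
  n <- length(a$id)
  if (length(actions) != n) {
    abort("contract violation: need one action per agent")
  }
  if (is_terminal(state)) abort("episode is terminal")
  actions <- as.integer(actions)
  rewards <- setNames(numeric(n), a$id)
  lay <- state$config$layout

  order_ <- sample.int(n)

  ## pass A: timers, movement and resource pickup (compiled inner loop)
  upd <- cpp_step_phase_a(order_, actions, lay$wall, state$occ, state$resources,
                          a$row, a$col, a$orient, a$inv, a$ready, a$freeze,
                          a$removal, a$removal_pending, a$scripted, a$slot,
                          lay$spawn_points, lay$spawn_slot,
                          state$config$removal_steps)
  state$occ <- upd$occ
  state$resources <- upd$resources
  for (nm in c("row", "col", "orient", "inv", "ready", "freeze", "removal",
               "removal_pending")) {
    a[[nm]] <- upd[[nm]]
  }
  state$agents <- a

  ## pass B: interaction beams
  events <- NULL
  for (i in order_) {
    if (actions[i] != ACTIONS[["INTERACT"]]) next
    a <- state$agents
    if (is.na(a$row[i]) || a$freeze[i] > 0L || a$scripted[i]) next
    res <- resolve_interaction(state, a$id[i])
    state <- res$state
    if (!is.null(res$event)) {
      events <- c(events, list(res$event))
      rewards[names(res$rewards)] <- rewards[names(res$rewards)] + res$rewards
    }
  }

  ## restock empty resource points
  pts <- lay$resource_points
  empty <- which(state$resources[pts] == 0L)
  if (length(empty)) {
    hit <- empty[runif(length(empty)) < state$config$restock_prob]
    if (length(hit)) {
      cols <- state$config$resource_colors
      state$resources[pts[hit, , drop = FALSE]] <-
        cols[sample.int(length(cols), length(hit), replace = TRUE)]
    }
  }

  state$step_index <- state$step_index + 1L
  events <- if (is.null(events)) empty_events() else dplyr::bind_rows(events)
  list(state = state, rewards = rewards, events = events)
}
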