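# Shared fixtures: tiny rosters, scripted episodes, and a hand-steered episode
# driver used to measure freeze/removal timing exactly.

roster_two <- function(pfreeze = c(16L, 16L)) {
  tibble::tibble(agent_id = c("a", "b"), group = c("red", "blue"),
                 personal_freeze = pfreeze)
}

roster_n <- function(n_red, n_blue) {
  tibble::tibble(
    agent_id = c(paste0("r", seq_len(n_red)), paste0("b", seq_len(n_blue))),
    group = rep(c("red", "blue"), c(n_red, n_blue)))
}

make_roster <- function(df, majority_group) {
  attr(df, "majority_group") <- majority_group
  class(df) <- c("gs_roster", class(df))
  df
}

# Deterministic face-off state: two agents placed on given cells/orientations
# with given inventories; no resources on the board unless kept.
face_off_state <- function(cfg = env_config(make_layout("default"), restock_prob = 0),
                           roster = roster_two(),
                           pos = list(c(8L, 8L), c(8L, 10L)),
                           orient = c(2L, 4L),
                           inv = list(c(1, 0, 0), c(1, 0, 0)),
                           ready = c(TRUE, TRUE),
                           keep_resources = FALSE) {
  st <- reset_episode(cfg, roster, seed = 42)
  if (!keep_resources) st$resources[] <- 0L
  a <- st$agents
  st$occ[] <- 0L
  for (k in seq_along(pos)) {
    a$row[k] <- pos[[k]][1L]; a$col[k] <- pos[[k]][2L]
    a$orient[k] <- orient[k]
    a$inv[, k] <- inv[[k]]
    a$ready[k] <- ready[k]
    st$occ[pos[[k]][1L], pos[[k]][2L]] <- k
  }
  st$agents <- a
  st
}

# Step a state N times with all agents submitting a fixed action, recording the
# per-step presence/freeze status of one agent.
track_agent <- function(st, agent_id, n_steps, action = ACTIONS[["NOOP"]]) {
  idx <- match(agent_id, st$agents$id)
  n <- length(st$agents$id)
  out <- data.frame(step = seq_len(n_steps), present = NA, frozen = NA)
  for (t in seq_len(n_steps)) {
    res <- env_step(st, rep(action, n))
    st <- res$state
    out$present[t] <- !is.na(st$agents$row[idx])
    out$frozen[t] <- st$agents$freeze[idx] > 0L
  }
  list(state = st, log = out)
}

micro_probe_config <- function(max_steps = 1000L) {
  probe_config(
    targets = list(A = list(group = "red", color = c(150, 0, 0), pixel = NULL),
                   B = list(group = "blue", color = c(0, 0, 150), pixel = NULL)),
    max_steps = max_steps)
}
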