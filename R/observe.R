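## Egocentric observation rendering: the O(s, i) of the Markov game.
##
## Each agent sees an 11x11 sprite window (5 sprites to each side, 9 forward,
## 1 back), rotated so its heading points up; with 8x8-pixel sprites this is an
## 88x88 RGB buffer. A compact symbolic view (feature observation) is provided
## for fast desk-scale learners and tests.

OBS_SPRITES <- 11L
SELF_WROW <- 10L   # self position inside the window (row 10 of 11, col 6 of 11)
SELF_WCOL <- 6L

#' Render an agent's egocentric pixel observation
#'
#' Pure function of (state, agent id): covers 5 sprites left/right, 9 forward
#' and 1 back of the agent's cell in heading-relative coordinates. Out-of-map
#' cells render as void tiles; other agents render with their avatar sprite
#' including the headband iff ready and their individuation pixel if they
#' carry one; the agent renders itself at its window position.
#'
#' @param state a `gs_state`.
#' @param agent_id agent to observe for.
#' @return an 88x88x3 numeric array of RGB values in 0-255, or `NULL` if the
#'   agent is currently removed (no-observation signal).
#' @export
render_observation <- function(state, agent_id) {
  i <- match(agent_id, state$agents$id)
  stopifnot(!is.na(i))
  a <- state$agents
  if (is.na(a$row[i])) return(NULL)
  cfg <- state$config
  lay <- cfg$layout
  sheet <- sprite_sheet(cfg$palette)
  fwd <- FWD_D[a$orient[i], ]
  rgt <- RGT_D[a$orient[i], ]
  px <- SPRITE_PX
  obs <- array(0, dim = c(OBS_SPRITES * px, OBS_SPRITES * px, 3L))
  for (wr in seq_len(OBS_SPRITES)) {
    f <- SELF_WROW - wr
    for (wc in seq_len(OBS_SPRITES)) {
      rl <- wc - SELF_WCOL
      r <- a$row[i] + f * fwd[1L] + rl * rgt[1L]
      cc <- a$col[i] + f * fwd[2L] + rl * rgt[2L]
      tile <- if (r < 1L || r > lay$nrow || cc < 1L || cc > lay$ncol) {
        sheet$void
      } else if (lay$wall[r, cc]) {
        sheet$wall
      } else {
        j <- state$occ[r, cc]
        if (j > 0L) {
          compose_avatar_sprite(a$color[, j], ready = a$ready[j],
                                individuation_pixel = a$pixel[[j]],
                                palette = cfg$palette)
        } else if (state$resources[r, cc] > 0L) {
          sheet$resources[[state$resources[r, cc]]]
        } else {
          sheet$background
        }
      }
      obs[((wr - 1L) * px + 1L):(wr * px), ((wc - 1L) * px + 1L):(wc * px), ] <- tile
    }
  }
  obs
}

#' Dimension of the compact symbolic observation
#' @export
FEATURE_DIM <- 18L

#' Compact symbolic observation (debug / desk-scale mode)
#'
#' An 18-vector summarising the same egocentric window as the pixel renderer:
#' own ready flag; own inventory (clipped at 5, scaled); (presence, forward/9,
#' right/5) triples for the nearest visible resource, the nearest visible ready
#' agent of population slot 1, of slot 2, and the nearest visible non-ready
#' agent; and two beam-alignment indicators (a ready agent of slot 1 / slot 2
#' stands straight ahead within beam range — the alignment a conv encoder
#' reads off the pixel raster directly). "Visible" means within the 11x11
#' window (forward offset -1..9, lateral -5..5); wall occlusion is not
#' modelled in this view. Slots are keyed by global population order, not by
#' the observer's own group, so nothing about group identity is built in —
#' both channels are represented identically.
#'
#' @param state a `gs_state`.
#' @param agent_id agent to observe for.
#' @return numeric vector of length [FEATURE_DIM], or `NULL` if removed.
#' @export
feature_observation <- function(state, agent_id) {
  i <- match(agent_id, state$agents$id)
  stopifnot(!is.na(i))
  a <- state$agents
  if (is.na(a$row[i])) return(NULL)
  as.numeric(cpp_features_all(i, state$config$layout$resource_points,
                              state$resources, a$row, a$col, a$orient,
                              a$inv, a$ready, a$slot,
                              state$config$beam_range))
}
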