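## Arena layouts. Coordinates are (row, col), 1-indexed, row 1 at the top.
## Every layout is an interior of non-wall cells surrounded by a one-cell wall
## border; layouts differ in internal walls and in whether agent spawn points
## are restricted to one population slot (1 or 2, NA = unrestricted).

#' Build an arena layout
#'
#' Three training layouts plus the small probe room:
#' * `default`: open arena (15x15 interior), unrestricted spawn points.
#' * `wall`: the arena bisected by a full-height wall; population slot 1 spawns
#'   only on the left half, slot 2 only on the right, so the two groups can see
#'   but never reach each other.
#' * `eight_cell`: the arena partitioned into 8 sealed rooms; 7 rooms have one
#'   slot-1 and one slot-2 spawn point, the eighth has two of each, so most
#'   co-located pairs are cross-group.
#' * `probe`: a small open room (7x9 interior) used by the dual-choice probe.
#'
#' @param kind one of `"default"`, `"wall"`, `"eight_cell"`, `"probe"`.
#' @param width,height interior size in cells for the open layouts (the wall
#'   and eight-cell layouts use the default 15x15 geometry).
#' @return a `gs_layout` list: `kind`, `wall` (logical matrix), `resource_points`
#'   and `spawn_points` (2-column matrices of row/col), `spawn_slot` (integer,
#'   NA = any population).
#' @export
#' @examples
#' lay <- make_layout("default")
#' sum(!lay$wall)  # interior cells
make_layout <- function(kind = c("default", "wall", "eight_cell", "probe"),
                        width = 15L, height = 15L) {
  kind <- match.arg(kind)
  if (kind == "probe") { width <- 9L; height <- 7L }
  if (kind %in% c("wall", "eight_cell")) { width <- 15L; height <- 15L }
  nr <- as.integer(height) + 2L
  nc <- as.integer(width) + 2L
  wall <- matrix(FALSE, nr, nc)
  wall[c(1L, nr), ] <- TRUE
  wall[, c(1L, nc)] <- TRUE

  lattice <- function(rows, cols) as.matrix(expand.grid(row = rows, col = cols))

  if (kind == "default" || kind == "probe") {
    res_rows <- seq(3L, nr - 1L, by = 3L)
    res_cols <- seq(3L, nc - 1L, by = 3L)
    resource_points <- lattice(res_rows, res_cols)
    sp_step <- if (min(nr, nc) >= 14L) 4L else 2L   # small arenas need a denser spawn lattice
    sp_rows <- seq(2L, nr - 1L, by = sp_step)
    sp_cols <- seq(2L, nc - 1L, by = sp_step)
    spawn_points <- lattice(sp_rows, sp_cols)
    keep <- !(paste(spawn_points[, 1], spawn_points[, 2]) %in%
                paste(resource_points[, 1], resource_points[, 2]))
    spawn_points <- spawn_points[keep, , drop = FALSE]
    spawn_slot <- rep(NA_integer_, nrow(spawn_points))
  } else if (kind == "wall") {
    mid <- (nc + 1L) %/% 2L
    wall[, mid] <- TRUE
    res_rows <- seq(3L, nr - 1L, by = 3L)
    resource_points <- rbind(
      lattice(res_rows, c(3L, 6L)),
      lattice(res_rows, c(mid + 3L, mid + 6L))
    )
    left <- lattice(c(2L, 6L, 10L, 14L), c(2L, 5L))
    right <- lattice(c(2L, 6L, 10L, 14L), c(mid + 4L, mid + 7L))
    spawn_points <- rbind(left, right)
    spawn_slot <- rep(c(1L, 2L), times = c(nrow(left), nrow(right)))
  } else { # eight_cell
    vwalls <- c(5L, 9L, 13L)
    wall[, vwalls] <- TRUE
    wall[9L, ] <- TRUE
    room_rows <- list(2:8, 10:16)
    room_cols <- list(2:4, 6:8, 10:12, 14:16)
    resource_points <- NULL
    spawn_points <- NULL
    spawn_slot <- integer(0)
    room_id <- 0L
    for (rr in room_rows) for (cc in room_cols) {
      room_id <- room_id + 1L
      rmid <- rr[4L]; cmid <- cc[2L]
      resource_points <- rbind(resource_points,
                               cbind(row = c(rr[2L], rr[6L]), col = cmid))
      if (room_id < 8L) {
        pts <- cbind(row = c(rr[1L], rr[7L]), col = cmid)
        spawn_points <- rbind(spawn_points, pts)
        spawn_slot <- c(spawn_slot, 1L, 2L)
      } else {
        pts <- cbind(row = c(rr[1L], rr[1L], rr[7L], rr[7L]),
                     col = c(cc[1L], cc[3L], cc[1L], cc[3L]))
        spawn_points <- rbind(spawn_points, pts)
        spawn_slot <- c(spawn_slot, 1L, 2L, 1L, 2L)
      }
    }
  }
  ok <- !wall[cbind(resource_points[, 1], resource_points[, 2])]
  resource_points <- resource_points[ok, , drop = FALSE]
  stopifnot(all(!wall[cbind(spawn_points[, 1], spawn_points[, 2])]))

  structure(list(kind = kind, nrow = nr, ncol = nc, wall = wall,
                 resource_points = resource_points,
                 spawn_points = spawn_points, spawn_slot = spawn_slot),
            class = "gs_layout")
}

#' Environment configuration
#'
#' Bundles the layout with the game-rule parameters. Defaults are the
#' reference conditions: beam range 3 cells, post-interaction freeze of 16
#' steps, removal for 50 steps, episode length drawn uniformly on
#' \[1000, 5000\], three resource colors, Bernoulli restocking at p = 0.005
#' per empty resource point per step, reward = 1 x dot(inventories), and both
#' participants required to be ready for an interaction to fire.
#'
#' @param layout a `gs_layout` from [make_layout()] or a layout kind string.
#' @param groups named list mapping the two group labels to body-color RGB
#'   triples; order defines population slots 1 and 2 in restricted layouts.
#' @param beam_range beam reach in cells (straight line, blocked by walls).
#' @param freeze_default default per-agent freeze duration after interacting.
#' @param removal_steps steps an agent is absent after its freeze elapses.
#' @param episode_length length-2 integer range; drawn uniformly at reset.
#' @param resource_colors integer subset of 1:3; the single-resource control
#'   passes one color.
#' @param restock_prob per-step restock probability for an empty resource point.
#' @param initial_stock fill every resource point at reset.
#' @param reward_scale proportionality constant of the dot-product reward.
#' @param require_initiator_ready must the beam's initiator also be ready.
#' @param palette sprite palette, see [default_palette()].
#' @return a `gs_env_config` list.
#' @export
env_config <- function(layout = make_layout("default"),
                       groups = list(red = c(150, 0, 0), blue = c(0, 0, 150)),
                       beam_range = 3L,
                       freeze_default = 16L,
                       removal_steps = 50L,
                       episode_length = c(1000L, 5000L),
                       resource_colors = 1:3,
                       restock_prob = 0.005,
                       initial_stock = TRUE,
                       reward_scale = 1,
                       require_initiator_ready = TRUE,
                       palette = default_palette()) {
  if (is.character(layout)) layout <- make_layout(layout)
  stopifnot(inherits(layout, "gs_layout"), length(groups) == 2L,
            length(episode_length) == 2L, episode_length[1] <= episode_length[2],
            all(resource_colors %in% 1:3), beam_range >= 1L)
  structure(list(layout = layout, groups = groups,
                 beam_range = as.integer(beam_range),
                 freeze_default = as.integer(freeze_default),
                 removal_steps = as.integer(removal_steps),
                 episode_length = as.integer(episode_length),
                 resource_colors = as.integer(resource_colors),
                 restock_prob = restock_prob,
                 initial_stock = isTRUE(initial_stock),
                 reward_scale = reward_scale,
                 require_initiator_ready = isTRUE(require_initiator_ready),
                 palette = palette),
            class = "gs_env_config")
}

group_slot <- function(config, group) {
  slot <- match(group, names(config$groups))
  if (anyNA(slot)) {
    abort(paste0("unknown group label(s): ",
                 paste(unique(group[is.na(slot)]), collapse = ", ")))
  }
  slot
}
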