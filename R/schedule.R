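## Two-population bookkeeping and the in-group / mixed server episode sampler.

#' Configure the two populations
#'
#' @param labels length-2 character, group labels (order defines population
#'   slots 1 and 2 for spawn-restricted layouts).
#' @param colors list of two RGB triples, body colors per group.
#' @param size members per population (default 8).
#' @param individuation turn on per-member individuation pixels: every member
#'   gets a unique pixel coordinate... rendered as one fixed-coordinate pixel
#'   whose RGB is unique per member (derived from the base pixel color), and
#'   exactly one member per group is designated "less desirable" with an
#'   elevated personal freeze duration.
#' @param pixel_base RGB triple of the individuation pixel (bright
#'   `c(255,255,0)` by default; the harder variant uses dark `c(80,80,0)`).
#' @param elevated_freeze personal freeze duration of the less desirable member
#'   (all others keep the 16-step default).
#' @param freeze_default default freeze duration.
#' @return a `gs_populations` tibble: one row per member with `agent_id`,
#'   `group`, `slot`, `personal_freeze`, `pixel` (list column),
#'   `less_desirable`.
#' @export
population_config <- function(labels = c("red", "blue"),
                              colors = list(c(150, 0, 0), c(0, 0, 150)),
                              size = 8L,
                              individuation = FALSE,
                              pixel_base = c(255, 255, 0),
                              elevated_freeze = 64L,
                              freeze_default = 16L) {
  stopifnot(length(labels) == 2L, length(colors) == 2L, size >= 1L)
  members <- tidyr::expand_grid(slot = 1:2, member = seq_len(size))
  pop <- tibble::tibble(
    agent_id = paste0(labels[members$slot], members$member),
    group = labels[members$slot],
    slot = members$slot,
    member = members$member,
    personal_freeze = as.integer(freeze_default),
    less_desirable = FALSE,
    pixel = rep(list(NULL), nrow(members))
  )
  if (individuation) {
    ## one unique pixel per member: scale the base color so members differ;
    ## member 1 of each group is the designated less-desirable agent
    shades <- seq(0.4, 1, length.out = size)
    pop$pixel <- purrr::map2(pop$member, pop$slot,
                             function(m, s) round(pixel_base * shades[m]))
    pop$less_desirable <- pop$member == 1L
    pop$personal_freeze[pop$less_desirable] <- as.integer(elevated_freeze)
  }
  attr(pop, "labels") <- labels
  attr(pop, "colors") <- setNames(colors, labels)
  class(pop) <- c("gs_populations", class(pop))
  pop
}

#' Configure an episode-sampling server
#'
#' @param kind `"ingroup"` (all 8 from one population) or `"mixed"`.
#' @param ratio length-2 integer majority:minority split for the mixed server
#'   (8:0, 7:1, 6:2, 5:3 or 4:4); entries must sum to the roster size. A mixed
#'   server at 8:0 behaves identically to the in-group server.
#' @param roster_size agents per episode (default 8).
#' @return a `gs_server` list.
#' @export
server_config <- function(kind = c("ingroup", "mixed"), ratio = c(6L, 2L),
                          roster_size = 8L) {
  kind <- match.arg(kind)
  ratio <- as.integer(ratio)
  if (kind == "mixed") {
    stopifnot(length(ratio) == 2L, sum(ratio) == roster_size,
              ratio[1L] >= ratio[2L], ratio[2L] >= 0L)
  }
  structure(list(kind = kind, ratio = ratio, roster_size = as.integer(roster_size)),
            class = "gs_server")
}

#' Sample an episode roster from the populations
#'
#' In-group server: all `roster_size` members of one uniformly chosen
#' population. Mixed server m:n: m members without replacement from a
#' uniformly chosen majority population and n from the other.
#'
#' @param server a [server_config()].
#' @param populations a [population_config()] tibble.
#' @return a `gs_roster` tibble (rows = sampled members, in sampling order)
#'   with attribute `majority_group`.
#' @export
sample_roster <- function(server, populations) {
  labels <- attr(populations, "labels")
  maj <- labels[sample.int(2L, 1L)]
  min_ <- setdiff(labels, maj)
  take <- function(group, k) {
    rows <- which(populations$group == group)
    if (k > length(rows)) abort("configuration error: ratio exceeds population size")
    populations[rows[sample.int(length(rows), k)], , drop = FALSE]
  }
  if (server$kind == "ingroup" || server$ratio[2L] == 0L) {
    roster <- take(maj, server$roster_size)
  } else {
    roster <- dplyr::bind_rows(take(maj, server$ratio[1L]),
                               take(min_, server$ratio[2L]))
  }
  attr(roster, "majority_group") <- maj
  class(roster) <- c("gs_roster", setdiff(class(roster), "gs_populations"))
  roster
}

#' Draw the next episode assignment (server + roster)
#'
#' Chooses the in-group or the mixed server by a fair coin flip — which makes
#' each agent's long-run expected share of in-group-server episodes 1/2 — and
#' samples the roster from the chosen server.
#'
#' @param schedule a `gs_schedule` from [make_schedule()].
#' @return list `server_kind`, `roster`, `majority_group`.
#' @export
next_episode_assignment <- function(schedule) {
  server <- if (runif(1) < 0.5) schedule$ingroup else schedule$mixed
  roster <- sample_roster(server, schedule$populations)
  list(server_kind = server$kind, roster = roster,
       majority_group = attr(roster, "majority_group"))
}

#' Bundle populations with the two servers
#'
#' @param populations a [population_config()].
#' @param mixed_ratio length-2 majority:minority ratio of the mixed server.
#' @param roster_size agents per episode.
#' @return a `gs_schedule` list with elements `populations`, `ingroup`, `mixed`.
#' @export
make_schedule <- function(populations, mixed_ratio = c(6L, 2L), roster_size = 8L) {
  structure(list(
    populations = populations,
    ingroup = server_config("ingroup", roster_size = roster_size),
    mixed = server_config("mixed", ratio = mixed_ratio, roster_size = roster_size)
  ), class = "gs_schedule")
}
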