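## The bespoke bias statistics: interaction categorization with chance
## normalization, group-bias and summed-bias measures, the individuation gap,
## and the gap-bias correlation. All functions are data-frame-first and return
## tibbles (or scalars for the reductions).

#' Categorize interaction events by group composition
#'
#' Assigns each event of one episode to exactly one category:
#' `majority_on_majority` (both participants from the episode's majority
#' group), `minority_on_minority`, or `mixed` (one participant from each
#' group, regardless of which group currently holds the majority).
#'
#' @param events tibble of interaction events (`initiator_id`, `target_id`).
#' @param roster the episode's `gs_roster` (defines the majority group).
#' @return tibble: `category`, `count`, plus `m` (majority size) and `n`
#'   (minority size) carried as columns.
#' @export
categorize_interactions <- function(events, roster) {
  maj <- attr(roster, "majority_group")
  stopifnot(!is.null(maj))
  ids <- roster$agent_id
  bad <- setdiff(unique(c(events$initiator_id, events$target_id)), ids)
  if (length(bad)) {
    abort(paste0("data error: event participant(s) not in roster: ",
                 paste(bad, collapse = ", ")))
  }
  grp <- setNames(roster$group, roster$agent_id)
  gi <- grp[events$initiator_id]
  gt <- grp[events$target_id]
  cat_ <- dplyr::case_when(
    gi == maj & gt == maj ~ "majority_on_majority",
    gi != maj & gt != maj ~ "minority_on_minority",
    TRUE ~ "mixed"
  )
  m <- sum(roster$group == maj)
  n <- nrow(roster) - m
  tibble::tibble(
    category = c("majority_on_majority", "minority_on_minority", "mixed"),
    count = c(sum(cat_ == "majority_on_majority"),
              sum(cat_ == "minority_on_minority"),
              sum(cat_ == "mixed")),
    m = m, n = n)
}

#' Chance weights for the interaction categories
#'
#' With majority size m and minority size n, the chance expectation uses
#' ordered within-group pair counts and the unordered cross count:
#' `w_majmaj = m(m-1)/D`, `w_minmin = n(n-1)/D`, `w_mixed = mn/D` with
#' `D = m(m-1) + n(n-1) + mn`. At 6:2 this gives exactly 30/44, 2/44 and
#' 12/44. The mixed within/cross counting convention is deliberate — it is the
#' convention under which those printed fractions are exact — and the weights
#' always sum to 1.
#'
#' @param m,n majority and minority sizes.
#' @return named numeric: `majority_on_majority`, `minority_on_minority`,
#'   `mixed`.
#' @export
chance_weights <- function(m, n) {
  d <- m * (m - 1) + n * (n - 1) + m * n
  if (d == 0) abort("degenerate roster: no possible pairs")
  c(majority_on_majority = m * (m - 1) / d,
    minority_on_minority = n * (n - 1) / d,
    mixed = m * n / d)
}

#' Chance-normalize interaction category counts
#'
#' Converts counts to within-episode percentages and divides each by its
#' chance weight (see [chance_weights()]), so 1.0 means a frequency not
#' deviating from the chance expectation given the group sizes.
#'
#' @param counts output of [categorize_interactions()] (columns `category`,
#'   `count`, `m`, `n`).
#' @return the input tibble with `percentage`, `chance_weight` and
#'   `normalized` columns added.
#' @export
chance_normalize <- function(counts) {
  stopifnot(all(c("category", "count", "m", "n") %in% names(counts)))
  total <- sum(counts$count)
  if (total == 0) abort("zero total events: normalized frequencies undefined")
  w <- chance_weights(counts$m[1L], counts$n[1L])
  counts |>
    dplyr::mutate(percentage = .data$count / total,
                  chance_weight = unname(w[.data$category]),
                  normalized = .data$percentage / .data$chance_weight)
}

#' Group bias from the two in-group choice ratios
#'
#' `bias = (ratio_red + ratio_blue)/2 - 0.5`: 0 at chance, 0.5 when both
#' groups always choose their own color, symmetric under swapping group
#' labels, range \[-0.5, 0.5\].
#'
#' @param ratio_red_group,ratio_blue_group in-group choice fractions in
#'   \[0, 1\] (vectors allowed; `NA` propagates).
#' @return numeric bias value(s).
#' @export
#' @examples
#' group_bias(0.7, 0.6)  # 0.15
group_bias <- function(ratio_red_group, ratio_blue_group) {
  stopifnot(all(ratio_red_group >= 0 & ratio_red_group <= 1, na.rm = TRUE),
            all(ratio_blue_group >= 0 & ratio_blue_group <= 1, na.rm = TRUE))
  (ratio_red_group + ratio_blue_group) / 2 - 0.5
}

#' Summed bias over a complete bin series
#'
#' @param bias_by_bin numeric vector of per-bin bias values; missing bins are
#'   an error (no silent interpolation).
#' @return scalar sum.
#' @export
summed_bias <- function(bias_by_bin) {
  if (anyNA(bias_by_bin)) abort("missing bins in bias series")
  sum(bias_by_bin)
}

#' Individuation gap
#'
#' Difference between the in-group and out-group discrimination scores
#' (ability to avoid the less desirable agent): positive when individuation is
#' better within the agent's own group.
#'
#' @param in_group_score,out_group_score discrimination scores in \[0, 1\].
#' @return numeric gap.
#' @export
individuation_gap <- function(in_group_score, out_group_score) {
  stopifnot(all(in_group_score >= 0 & in_group_score <= 1, na.rm = TRUE),
            all(out_group_score >= 0 & out_group_score <= 1, na.rm = TRUE))
  in_group_score - out_group_score
}

#' Pearson product-moment correlation (with precondition checks)
#'
#' Thin wrapper around the standard product-moment correlation used for the
#' individuation-gap vs. group-bias relationship across runs.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Within-minus-between group-bias statistic for full-environment evaluation
#'
#' For 4:4 evaluation episodes: observed within-group interaction count minus
#' the chance-expected within-group count (chance weights at m = n = 4),
#' scaled per episode. 0 at chance proportions, positive when within-group
#' interactions dominate.
#'
#' @param events tibble of interaction events with an `episode_id` column (or
#'   a single episode's events).
#' @param roster the evaluation `gs_roster` (must be 4:4).
#' @return scalar statistic (per-episode average).
#' @export
full_env_bias <- function(events, roster) {
  grp <- setNames(roster$group, roster$agent_id)
  sizes <- table(roster$group)
  stopifnot(length(sizes) == 2L)
  m <- as.integer(sizes[1L]); n <- as.integer(sizes[2L])
  w <- chance_weights(m, n)
  w_within <- w[["majority_on_majority"]] + w[["minority_on_minority"]]
  n_ep <- if ("episode_id" %in% names(events)) {
    max(1L, length(unique(events$episode_id)))
  } else 1L
  within <- sum(grp[events$initiator_id] == grp[events$target_id])
  (within - w_within * nrow(events)) / n_ep
}
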