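## Broom-style tidiers for result objects.

#' @describeIn tidy One row per (group, bin) with the in-group choice ratio
#'   and the derived group-bias value for a completed run.
#' @export
tidy.gs_run <- function(x, ...) {
  if (is.null(x$bias)) {
    return(tibble::tibble(group = character(), bin = integer(),
                          mean_ratio = numeric(), bias = numeric()))
  }
  per_group <- x$bias |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio), .groups = "drop")
  bias <- x$bias_by_bin
  dplyr::left_join(per_group, bias, by = "bin")
}

#' @describeIn tidy One-row run summary: total steps, events, mean reward of
#'   the final quarter of training, summed bias.
#' @export
glance.gs_run <- function(x, ...) {
  final_reward <- if (!is.null(x$curve) && nrow(x$curve)) {
    tail_n <- max(1L, nrow(x$curve) %/% 4L)
    mean(utils::tail(x$curve$mean_reward, tail_n))
  } else NA_real_
  tibble::tibble(
    name = x$config$name,
    condition = paste(x$config$mixed_ratio, collapse = ":"),
    layout = x$config$layout,
    preset = x$config$preset,
    total_steps = x$manifest$total_steps,
    n_events = nrow(x$events),
    final_mean_reward = final_reward,
    summed_bias = x$summed_bias)
}

#' @describeIn tidy Pass-through tidier for binned bias tables (drops the
#'   probe-log attribute, returns a plain tibble).
#' @export
tidy.gs_bias_table <- function(x, ...) {
  class(x) <- setdiff(class(x), "gs_bias_table")
  attr(x, "probe_log") <- NULL
  x
}
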