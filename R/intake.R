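#' Marginal Value Theorem intake rates and RIAIR
#'
#' For every collected target in a trial, computes the instantaneous
#' intake rate (value of the pick divided by the time since the previous
#' pick, with trial onset as the zeroth event), the average intake rate
#' (cumulative value divided by elapsed time), and their ratio, the
#' RIAIR. Under the Marginal Value Theorem an optimal forager stays while
#' the RIAIR exceeds 1 and leaves as soon as it drops below 1; sustained
#' values below 1 indicate overharvesting.
#'
#' In `"items"` mode (default) each target contributes 1 and the series
#' depends only on pick times; `"points"` mode uses the logged score
#' deltas (by default +2 per target, -1 per distractor) and includes
#' distractor selections in the cumulative value.
#'
#' @param trial A `forage_trial`.
#' @param value_mode `"items"` or `"points"`.
#' @param include_travel Add the between-patch travel cost to the elapsed
#'   time in the average rate (default `FALSE`: the average is over the
#'   trial's own clock).
#' @param travel_cost_sec Travel cost in seconds (used only when
#'   `include_travel = TRUE`).
#' @return Tibble with one row per collected target: trial keys, `n`,
#'   `t_sec`, `inst_rate`, `avg_rate`, `riair`.
#' @export
riair_series <- function(trial, value_mode = c("items", "points"),
                         include_travel = FALSE, travel_cost_sec = 2) {
  value_mode <- match.arg(value_mode)
  picks <- target_picks(trial)
  if (nrow(picks) == 0) {
    return(tibble::tibble(
      participant_id = character(), condition = character(),
      trial_id = character(), age_group = character(), n = integer(),
      t_sec = double(), inst_rate = double(), avg_rate = double(),
      riair = double()
    ))
  }
  t <- picks$t_sec
  if (any(diff(c(0, t)) <= 0)) {
    abort(paste0("pick times must be strictly increasing in trial ",
                 trial$trial_id),
          class = "patchleave_validation_error")
  }
  if (value_mode == "items") {
    v <- rep(1, length(t))
    cum <- cumsum(v)
  } else {
    v <- picks$points
    # cumulative points include distractor penalties up to each target pick
    all_ev <- trial$events
    cum <- vapply(t, function(ti) sum(all_ev$points[all_ev$t_sec <= ti]),
                  numeric(1))
  }
  offset <- if (include_travel) travel_cost_sec else 0
  inst <- v / diff(c(0, t))
  avg <- cum / (t + offset)
  tibble::tibble(
    participant_id = trial$participant_id, condition = trial$condition,
    trial_id = trial$trial_id, age_group = trial$age_group,
    n = seq_along(t), t_sec = t, inst_rate = inst, avg_rate = avg,
    riair = inst / avg
  )
}
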