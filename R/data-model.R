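#' Event-log column schema
#'
#' The on-disk interchange format for foraging event logs is a UTF-8 CSV
#' with one row per event. Events are item selections (`target`,
#' `distractor`) and the final `leave` event that closes a patch visit.
#' Timestamps are seconds since trial onset; coordinates are screen pixels
#' with the origin at the top-left corner and y increasing downward, the
#' usual touchscreen logging convention. The 2-s travel cost between
#' patches is session metadata, never part of a trial's clock.
#'
#' @format A character vector of mandatory column names.
#' @export
event_log_columns <- c(
  "session_id", "participant_id", "age_group", "condition", "trial_id",
  "set_size", "event_index", "event_type", "t_sec", "x_px", "y_px", "points"
)

event_log_coltypes <- readr::cols(
  session_id = readr::col_character(),
  participant_id = readr::col_character(),
  age_group = readr::col_character(),
  condition = readr::col_character(),
  trial_id = readr::col_character(),
  set_size = readr::col_integer(),
  event_index = readr::col_integer(),
  event_type = readr::col_character(),
  t_sec = readr::col_double(),
  x_px = readr::col_double(),
  y_px = readr::col_double(),
  points = readr::col_integer()
)

#' Read a foraging event log
#'
#' Reads the CSV event-log dialect described in [event_log_columns],
#' validates it, and returns a tidy `forage_log` tibble with events sorted
#' by time within each trial. Trials are keyed by
#' (`participant_id`, `condition`, `trial_id`).
#'
#' @param path Path to a CSV file.
#' @return A `forage_log` tibble (one row per event).
#' @details Validation errors name the offending trial and, where
#'   applicable, the source line numbers. Timestamps must be strictly
#'   increasing within a trial: ties are rejected because pick order would
#'   be ambiguous.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("event log not found: ", path), class = "patchleave_io_error")
  }
  df <- readr::read_csv(path, col_types = event_log_coltypes,
                        progress = FALSE)
  validate_event_log(df)
}

#' Write a foraging event log
#'
#' @param log A `forage_log` tibble (see [read_event_log]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  readr::write_csv(log[, event_log_columns], path, progress = FALSE)
  invisible(path)
}

#' Validate an event-log data frame
#'
#' Checks the mandatory columns, event types, and within-trial time
#' ordering, and returns the log sorted by trial and time with class
#' `forage_log`.
#'
#' @param df A data frame with the columns of [event_log_columns].
#' @return A validated, sorted `forage_log` tibble.
#' @export
validate_event_log <- function(df) {
  missing <- setdiff(event_log_columns, names(df))
  if (length(missing) > 0) {
    abort(paste0("event log is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "patchleave_format_error")
  }
  bad_type <- !df$event_type %in% c("target", "distractor", "leave")
  if (any(bad_type)) {
    abort(paste0("unknown event_type at data row(s) ",
                 paste(head(which(bad_type), 5L), collapse = ", ")),
          class = "patchleave_format_error")
  }
  if (any(!is.finite(df$t_sec)) || any(df$t_sec < 0)) {
    abort("t_sec must be finite and non-negative",
          class = "patchleave_validation_error")
  }
  df <- dplyr::arrange(tibble::as_tibble(df),
                       .data$participant_id, .data$condition, .data$trial_id,
                       .data$t_sec, .data$event_index)
  dup <- df |>
    dplyr::filter(.data$event_type != "leave") |>
    dplyr::group_by(.data$participant_id, .data$condition, .data$trial_id) |>
    dplyr::summarise(dup = anyDuplicated(.data$t_sec) > 0, .groups = "drop") |>
    dplyr::filter(.data$dup)
  if (nrow(dup) > 0) {
    abort(paste0("non-monotone (duplicated) timestamps within trial(s): ",
                 paste(dup$trial_id, collapse = ", ")),
          class = "patchleave_validation_error")
  }
  structure(df, class = c("forage_log", class(df)))
}

#' Split an event log into trial objects
#'
#' @param log A validated `forage_log` tibble.
#' @return A list of `forage_trial` objects, one per
#'   (`participant_id`, `condition`, `trial_id`) group, each holding the
#'   trial metadata, its pick events, and the leave time.
#' @export
as_trials <- function(log) {
  keys <- dplyr::distinct(log, .data$participant_id, .data$condition,
                          .data$trial_id)
  groups <- dplyr::group_split(
    dplyr::group_by(log, .data$participant_id, .data$condition,
                    .data$trial_id),
    .keep = TRUE
  )
  trials <- lapply(groups, function(g) {
    leave_rows <- g[g$event_type == "leave", , drop = FALSE]
    picks <- g[g$event_type != "leave", , drop = FALSE]
    leave_time <- if (nrow(leave_rows) > 0) max(leave_rows$t_sec) else NA_real_
    if (nrow(picks) > 0 && is.finite(leave_time) &&
        leave_time < max(picks$t_sec)) {
      abort(paste0("leave_time precedes last pick in trial ", g$trial_id[1]),
            class = "patchleave_validation_error")
    }
    new_trial(
      trial_id = g$trial_id[1], participant_id = g$participant_id[1],
      session_id = g$session_id[1], condition = g$condition[1],
      age_group = g$age_group[1], set_size = g$set_size[1],
      events = picks, leave_time = leave_time
    )
  })
  names(trials) <- paste(keys$participant_id, keys$condition, keys$trial_id,
                         sep = "/")
  trials
}

#' Construct a single trial object
#'
#' @param trial_id,participant_id,session_id,condition,age_group Trial
#'   metadata labels.
#' @param set_size Number of items initially on the display.
#' @param events Tibble of pick events (`event_type` target/distractor,
#'   `t_sec`, `x_px`, `y_px`, `points`), in time order.
#' @param leave_time Seconds since trial onset at which the patch was
#'   abandoned (`NA` if not recorded).
#' @param depleted `TRUE` if every target was collected, `NA` if unknown.
#' @return A `forage_trial` object.
#' @export
new_trial <- function(trial_id, participant_id = "p1", session_id = "s1",
                      condition = "static", age_group = "adult",
                      set_size = NA_integer_, events, leave_time = NA_real_,
                      depleted = NA) {
  structure(
    list(trial_id = trial_id, participant_id = participant_id,
         session_id = session_id, condition = condition,
         age_group = age_group, set_size = set_size,
         events = tibble::as_tibble(events), leave_time = leave_time,
         depleted = depleted),
    class = "forage_trial"
  )
}

#' @export
print.forage_trial <- function(x, ...) {
  cat("<forage_trial> ", x$trial_id, " (", x$condition, ", ",
      x$participant_id, "): ", sum(x$events$event_type == "target"),
      " targets collected, leave at ",
      format(x$leave_time, digits = 4), " s\n", sep = "")
  invisible(x)
}

#' Target picks of a trial
#'
#' Organization indicators and intake rates are defined over collected
#' targets only; distractor selections are excluded (they enter only the
#' optional points-based intake rates).
#'
#' @param trial A `forage_trial`.
#' @return Tibble of target pick events in collection order.
#' @export
target_picks <- function(trial) {
  trial$events[trial$events$event_type == "target", , drop = FALSE]
}

#' Convert a trial into labeled stay/leave decision records
#'
#' Every collected target from the `min_picks`-th onward is one decision:
#' the pick immediately preceding the departure (i.e. the last target
#' collected) is a *leave* decision, every earlier one a *stay* decision.
#' Trials with fewer than `min_picks` collected targets contribute no
#' decisions, because the trial-so-far organization indicators are
#' undefined below three picks.
#'
#' @param trial A `forage_trial`.
#' @param min_picks First decision ordinal (default 3; lower values are
#'   rejected).
#' @return Tibble with one row per decision: trial keys, `n` (targets
#'   collected so far), `t_sec` of the pick, and `label`
#'   (`"stay"`/`"leave"`).
#' @export
extract_decisions <- function(trial, min_picks = 3L) {
  if (min_picks < 3L) {
    abort("min_picks must be >= 3: organization indicators are undefined below 3 picks",
          class = "patchleave_config_error")
  }
  picks <- target_picks(trial)
  n_total <- nrow(picks)
  if (n_total < min_picks) {
    return(tibble::tibble(
      participant_id = character(), condition = character(),
      trial_id = character(), age_group = character(),
      n = integer(), t_sec = double(), label = character()
    ))
  }
  n <- seq.int(min_picks, n_total)
  tibble::tibble(
    participant_id = trial$participant_id, condition = trial$condition,
    trial_id = trial$trial_id, age_group = trial$age_group,
    n = as.integer(n), t_sec = picks$t_sec[n],
    label = ifelse(n == n_total, "leave", "stay")
  )
}
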