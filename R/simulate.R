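#' Arena configuration for the foraging simulator
#'
#' Describes one display (patch): its pixel dimensions, the number of
#' items, the proportion of targets, and the item motion model. Moving
#' items travel at constant speed, redraw their direction at intervals
#' drawn uniformly from `dir_change_interval`, and reflect off the
#' display edges. Defaults mirror a touchscreen foraging task on a
#' 1400 x 1500 px screen with static (0), slow (44 px/s) or fast
#' (88 px/s) item motion and 20-30% targets.
#'
#' @param width,height Display size, pixels.
#' @param set_size Number of items on the display.
#' @param target_proportion Proportion of items that are targets;
#'   `NULL` (default) draws it uniformly in `[0.20, 0.30]` per trial.
#' @param speed Item speed, px/s (0 = static).
#' @param dir_change_interval Bounds (s) of the uniform interval between
#'   direction changes.
#' @return An `arena_config` list.
#' @export
arena_config <- function(width = 1400, height = 1500, set_size = 80L,
                         target_proportion = NULL, speed = 0,
                         dir_change_interval = c(0.5, 2.0)) {
  if (!is.null(target_proportion) &&
      (target_proportion < 0.05 || target_proportion > 0.95)) {
    abort("target_proportion out of range", class = "patchleave_config_error")
  }
  if (speed < 0) abort("speed must be >= 0", class = "patchleave_config_error")
  structure(list(width = width, height = height, set_size = as.integer(set_size),
                 target_proportion = target_proportion, speed = speed,
                 dir_change_interval = dir_change_interval),
            class = "arena_config")
}

#' Leaving rules for simulated foragers
#'
#' @description
#' * `rule_mvt(theta)`: leave at the first pick (at or after the
#'   minimum pick count) whose RIAIR falls below `theta`; `theta = 1` is
#'   the strict Marginal Value Theorem forager.
#' * `rule_giving_up_time(g)`: leave when the prospective time to the
#'   next capture exceeds `g` seconds.
#' * `rule_fixed_count(k)`: leave after `k` collected targets.
#' * `rule_random(p)`: after each eligible pick, leave with
#'   probability `p`.
#'
#' @param theta RIAIR threshold (> 0).
#' @return A leaving-rule list understood by [simulate_trial].
#' @export
rule_mvt <- function(theta = 1) {
  stopifnot(theta > 0)
  list(rule = "mvt", theta = theta)
}

#' @rdname rule_mvt
#' @param g Giving-up time, seconds (> 0).
#' @export
rule_giving_up_time <- function(g) {
  stopifnot(g > 0)
  list(rule = "giving_up_time", g = g)
}

#' @rdname rule_mvt
#' @param k Number of targets to collect (>= 1).
#' @export
rule_fixed_count <- function(k) {
  stopifnot(k >= 1)
  list(rule = "fixed_count", k = as.integer(k))
}

#' @rdname rule_mvt
#' @param p Per-pick leaving probability in `[0, 1]`.
#' @export
rule_random <- function(p) {
  stopifnot(p >= 0, p <= 1)
  list(rule = "random", p = p)
}

#' Agent configuration for the foraging simulator
#'
#' Describes how a simulated forager collects targets and when it quits.
#' Collection strategies: `"nearest_neighbor"` picks the closest
#' remaining target (at the item positions current at decision time),
#' `"scanner"` follows a reading-like order (top rows first, left to
#' right, with positional noise), `"random"` picks uniformly. The
#' `disorder` parameter mixes in uniform-random picks with the given
#' probability, so `disorder = 1` makes every strategy random. Pick time
#' is `(base_latency + distance / movement_speed)` scaled by
#' multiplicative lognormal noise - a simple Fitts-like model that makes
#' intake slow down as targets deplete and distances grow.
#'
#' @param strategy `"nearest_neighbor"`, `"scanner"` or `"random"`.
#' @param disorder Probability in `[0, 1]` of a uniform-random pick.
#' @param base_latency Fixed per-pick latency, s.
#' @param movement_speed Effective hand speed, px/s.
#' @param noise_sd SD of the lognormal pick-time noise (log scale).
#' @param leave_rule A rule from [rule_mvt] and friends.
#' @param min_picks Minimum picks before the leaving rule may fire.
#' @param error_rate Probability of a distractor selection before each
#'   target pick (default 0; distractors are excluded from the core
#'   pipeline).
#' @param scan_noise_px Positional noise of the scanner's reading order.
#' @param leave_latency Delay between the last pick and the recorded
#'   leave event, s.
#' @return An `agent_config` list.
#' @export
agent_config <- function(strategy = c("nearest_neighbor", "scanner", "random"),
                         disorder = 0, base_latency = 0.3,
                         movement_speed = 1000, noise_sd = 0.2,
                         leave_rule = rule_mvt(1), min_picks = 4L,
                         error_rate = 0, scan_noise_px = 30,
                         leave_latency = 0.3) {
  strategy <- match.arg(strategy)
  if (disorder < 0 || disorder > 1) {
    abort("disorder must be in [0, 1]", class = "patchleave_config_error")
  }
  structure(list(strategy = strategy, disorder = disorder,
                 base_latency = base_latency,
                 movement_speed = movement_speed, noise_sd = noise_sd,
                 leave_rule = leave_rule, min_picks = as.integer(min_picks),
                 error_rate = error_rate, scan_noise_px = scan_noise_px,
                 leave_latency = leave_latency),
            class = "agent_config")
}

# Advance reflecting items by dt under constant velocity with direction
# redraws at each item's scheduled change times. `items` is a data frame
# with x, y, vx, vy, next_change. Exact reflection via modular folding.
.advance_items <- function(items, t_from, t_to, arena) {
  if (arena$speed == 0 || t_to <= t_from) return(items)
  fold <- function(p, v, L) {
    q <- p %% (2 * L)
    flip <- q > L
    list(p = ifelse(flip, 2 * L - q, q), v = ifelse(flip, -v, v))
  }
  move <- function(it, dt) {
    fx <- fold(it$x + it$vx * dt, it$vx, arena$width)
    fy <- fold(it$y + it$vy * dt, it$vy, arena$height)
    it$x <- fx$p; it$vx <- fx$v
    it$y <- fy$p; it$vy <- fy$v
    it
  }
  for (i in seq_len(nrow(items))) {
    t <- t_from
    it <- items[i, ]
    while (it$next_change <= t_to) {
      it <- move(it, it$next_change - t)
      t <- it$next_change
      ang <- runif(1, 0, 2 * pi)
      it$vx <- arena$speed * cos(ang)
      it$vy <- arena$speed * sin(ang)
      it$next_change <- t + runif(1, arena$dir_change_interval[1],
                                  arena$dir_change_interval[2])
    }
    items[i, ] <- move(it, t_to - t)
  }
  items
}

#' Simulate one foraging trial
#'
#' Places items uniformly at random, moves them per the arena's motion
#' model, and lets the agent collect targets until its leaving rule
#' fires (or the patch depletes, which is flagged). Recorded coordinates
#' are the item positions at the collection instants, as required for
#' organization indicators on moving displays.
#'
#' @param arena An [arena_config].
#' @param agent An [agent_config].
#' @param seed Optional RNG seed for this trial.
#' @param trial_id,participant_id,session_id,condition,age_group Metadata
#'   labels attached to the trial.
#' @return List with `trial` (a `forage_trial`) and `ground_truth`
#'   (configs, seed, per-pick leaving-rule evaluations).
#' @export
simulate_trial <- function(arena, agent, seed = NULL, trial_id = "t1",
                           participant_id = "sim1", session_id = "sim",
                           condition = "sim", age_group = "agent") {
  if (!is.null(seed)) set.seed(seed)
  n_items <- arena$set_size
  prop <- arena$target_proportion %||% runif(1, 0.20, 0.30)
  n_targets <- max(1L, round(prop * n_items))
  need_distractors <- agent$error_rate > 0
  n_sim <- if (need_distractors) n_items else n_targets
  ang <- runif(n_sim, 0, 2 * pi)
  items <- data.frame(
    x = runif(n_sim, 0, arena$width), y = runif(n_sim, 0, arena$height),
    vx = arena$speed * cos(ang), vy = arena$speed * sin(ang),
    next_change = runif(n_sim, arena$dir_change_interval[1],
                        arena$dir_change_interval[2])
  )
  is_target <- seq_len(n_sim) <= n_targets
  scan_rank <- rep(NA_real_, n_sim)
  if (agent$strategy == "scanner") {
    band <- 150
    ny <- items$y + rnorm(n_sim, 0, agent$scan_noise_px)
    nx <- items$x + rnorm(n_sim, 0, agent$scan_noise_px)
    scan_rank <- floor(ny / band) * (arena$width + 1) + nx
  }
  cur <- c(arena$width / 2, arena$height / 2)
  t <- 0
  remaining <- which(is_target)
  rule <- agent$leave_rule
  events <- list()
  evals <- list()
  n_picked <- 0L
  cum_items <- 0
  depleted <- FALSE
  leave_time <- NA_real_
  repeat {
    if (length(remaining) == 0) {
      depleted <- TRUE
      leave_time <- t + agent$leave_latency
      break
    }
    # choose the next target
    d <- sqrt((items$x[remaining] - cur[1])^2 +
                (items$y[remaining] - cur[2])^2)
    pick_random <- agent$strategy == "random" || runif(1) < agent$disorder
    idx <- if (pick_random) {
      remaining[sample.int(length(remaining), 1)]
    } else if (agent$strategy == "scanner") {
      remaining[which.min(scan_rank[remaining])]
    } else {
      remaining[which.min(d)]
    }
    dist <- sqrt((items$x[idx] - cur[1])^2 + (items$y[idx] - cur[2])^2)
    dt <- (agent$base_latency + dist / agent$movement_speed) *
      rlnorm(1, 0, agent$noise_sd)
    if (rule$rule == "giving_up_time" && dt > rule$g) {
      leave_time <- t + rule$g
      break
    }
    items <- .advance_items(items, t, t + dt, arena)
    t <- t + dt
    n_picked <- n_picked + 1L
    cum_items <- cum_items + 1
    cur <- c(items$x[idx], items$y[idx])
    remaining <- setdiff(remaining, idx)
    events[[n_picked]] <- list(t = t, x = items$x[idx], y = items$y[idx])
    inst <- 1 / dt
    avg <- cum_items / t
    riair <- inst / avg
    fired <- FALSE
    if (n_picked >= agent$min_picks) {
      fired <- switch(rule$rule,
                      mvt = riair < rule$theta,
                      fixed_count = n_picked >= rule$k,
                      random = runif(1) < rule$p,
                      giving_up_time = FALSE)
    } else if (rule$rule == "fixed_count") {
      fired <- n_picked >= rule$k
    }
    evals[[n_picked]] <- tibble::tibble(n = n_picked, riair = riair,
                                        dt = dt, fired = fired)
    if (fired) {
      leave_time <- t + agent$leave_latency
      break
    }
  }
  ev <- if (n_picked > 0) {
    tibble::tibble(
      event_index = seq_len(n_picked),
      event_type = "target",
      t_sec = vapply(events, `[[`, numeric(1), "t"),
      x_px = vapply(events, `[[`, numeric(1), "x"),
      y_px = vapply(events, `[[`, numeric(1), "y"),
      points = 2L
    )
  } else {
    tibble::tibble(event_index = integer(), event_type = character(),
                   t_sec = double(), x_px = double(), y_px = double(),
                   points = integer())
  }
  trial <- new_trial(trial_id = trial_id, participant_id = participant_id,
                     session_id = session_id, condition = condition,
                     age_group = age_group, set_size = n_items,
                     events = ev, leave_time = leave_time,
                     depleted = depleted)
  list(trial = trial,
       ground_truth = list(arena = arena, agent = agent, seed = seed,
                           n_targets = n_targets, depleted = depleted,
                           rule_evals = dplyr::bind_rows(evals)))
}

#' Simulate a foraging session
#'
#' Runs a design of (arena, agent, trial count) blocks and concatenates
#' the resulting trials into one event log in the standard CSV schema,
#' with leave events included and the 2-s travel cost recorded as
#' metadata (attribute `travel_cost_sec`), never on any trial's clock.
#'
#' @param design A list of blocks, each a list with elements `arena`,
#'   `agent`, `n_trials`, and optional `condition`, `participant_id`,
#'   `age_group`.
#' @param seed RNG seed; identical seed and design give a byte-identical
#'   log.
#' @param session_id Session label.
#' @param travel_cost_sec Between-patch travel cost, seconds (metadata).
#' @return List with `log` (a validated `forage_log`) and `ground_truth`
#'   (one entry per trial).
#' @export
simulate_session <- function(design, seed = 1L, session_id = "sim",
                             travel_cost_sec = 2) {
  if (length(design) == 0) {
    abort("design must be nonempty", class = "patchleave_config_error")
  }
  set.seed(seed)
  rows <- list()
  gt <- list()
  k <- 0L
  for (b in seq_along(design)) {
    blk <- design[[b]]
    cond <- blk$condition %||% paste0("block", b)
    pid <- blk$participant_id %||% paste0("sim", b)
    age <- blk$age_group %||% "agent"
    for (i in seq_len(blk$n_trials)) {
      k <- k + 1L
      tid <- sprintf("%s_%03d", cond, i)
      sim <- simulate_trial(blk$arena, blk$agent, seed = NULL,
                            trial_id = tid, participant_id = pid,
                            session_id = session_id, condition = cond,
                            age_group = age)
      tr <- sim$trial
      ev <- tr$events
      ev_rows <- tibble::tibble(
        session_id = session_id, participant_id = pid, age_group = age,
        condition = cond, trial_id = tid, set_size = tr$set_size,
        event_index = c(ev$event_index, nrow(ev) + 1L),
        event_type = c(ev$event_type, "leave"),
        t_sec = c(ev$t_sec, tr$leave_time),
        x_px = c(ev$x_px, NA_real_), y_px = c(ev$y_px, NA_real_),
        points = c(ev$points, 0L)
      )
      rows[[k]] <- ev_rows
      gt[[paste(pid, cond, tid, sep = "/")]] <- sim$ground_truth
    }
  }
  log <- validate_event_log(dplyr::bind_rows(rows))
  attr(log, "travel_cost_sec") <- travel_cost_sec
  list(log = log, ground_truth = gt)
}
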