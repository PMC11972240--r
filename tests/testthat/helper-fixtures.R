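# Programmatic fixtures: trials, logs, and brute-force oracles.

# A trial with given pick coordinates and times (targets only).
make_trial <- function(x, y, t = seq_along(x), trial_id = "t1",
                       participant_id = "p1", condition = "static",
                       age_group = "adult", leave_time = max(t) + 0.5) {
  new_trial(
    trial_id = trial_id, participant_id = participant_id,
    condition = condition, age_group = age_group,
    set_size = length(x) * 4L,
    events = tibble::tibble(
      event_index = seq_along(x), event_type = "target",
      t_sec = t, x_px = x, y_px = y, points = 2L
    ),
    leave_time = leave_time
  )
}

# Event-log rows for one trial (including the closing leave event).
make_log_rows <- function(x, y, t = seq_along(x), trial_id = "t1",
                          participant_id = "p1", condition = "static",
                          age_group = "adult", session_id = "s1",
                          leave_time = max(t) + 0.5) {
  n <- length(x)
  tibble::tibble(
    session_id = session_id, participant_id = participant_id,
    age_group = age_group, condition = condition, trial_id = trial_id,
    set_size = n * 4L,
    event_index = c(seq_len(n), n + 1L),
    event_type = c(rep("target", n), "leave"),
    t_sec = c(t, leave_time),
    x_px = c(x, NA), y_px = c(y, NA),
    points = c(rep(2L, n), 0L)
  )
}

# All permutations of a vector (oracle helper; n <= 8).
all_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], all_perms(v[-i]))
  }))
}

# Brute-force shortest open Hamiltonian path length.
brute_force_path <- function(x, y) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  perms <- all_perms(seq_len(n))
  min(apply(perms, 1, function(o) sum(d[cbind(o[-n], o[-1])])))
}

# Brute-force Mann-Whitney AUC by pair counting (leave above stay).
brute_force_auc <- function(values, is_leave) {
  lv <- values[is_leave]
  sv <- values[!is_leave]
  tot <- 0
  for (a in lv) for (b in sv) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(lv) * length(sv))
}
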