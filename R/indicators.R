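#' Best-r: strongest scanner-pattern correlation
#'
#' Correlates the order of target collection (1, 2, ..., n) with each
#' screen coordinate and returns the larger of the two absolute Pearson
#' correlations. Values near 1 indicate a reading-like (left-right) or
#' columnwise (top-down) sweep; disorganized collection gives moderate
#' values.
#'
#' A coordinate with zero variance (all picks on one vertical or
#' horizontal line) has an undefined correlation; it contributes 0 rather
#' than propagating `NA`, and the result carries a `degenerate` attribute
#' when both coordinates are constant.
#'
#' @param x,y Pick coordinates (pixels) in collection order, length >= 3.
#' @return Best-r in `[0, 1]`.
#' @export
best_r <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) {
    abort("best_r requires >= 3 picks with matching x and y",
          class = "patchleave_domain_error")
  }
  ord <- seq_len(n)
  rx <- if (sd(x) > 0) cor(ord, x) else 0
  ry <- if (sd(y) > 0) cor(ord, y) else 0
  out <- max(abs(rx), abs(ry))
  if (sd(x) == 0 && sd(y) == 0) attr(out, "degenerate") <- TRUE
  out
}

#' Mean inter-target distance
#'
#' Arithmetic mean of the Euclidean distances between consecutively
#' collected targets, in pixels.
#'
#' @inheritParams best_r
#' @return Mean ITD (>= 0), pixels.
#' @export
mean_itd <- function(x, y) {
  n <- length(x)
  if (n < 2 || length(y) != n) {
    abort("mean_itd requires >= 2 picks", class = "patchleave_domain_error")
  }
  mean(sqrt(diff(x)^2 + diff(y)^2))
}

#' Shortest open Hamiltonian path through a point set
#'
#' Length of the optimal scan path: the shortest open path visiting every
#' collection location exactly once, with both endpoints free. This is the
#' path-variant of the Traveling Salesman Problem. `method = "exact"` uses
#' Held-Karp dynamic programming over subsets (feasible up to
#' `exact_cap` points); `"heuristic"` uses best-of-all-starts nearest
#' neighbor refined by 2-opt, whose result can never fall below the exact
#' optimum; `"auto"` (default) switches between them at `exact_cap`.
#'
#' @inheritParams best_r
#' @param method One of `"auto"`, `"exact"`, `"heuristic"`.
#' @param exact_cap Largest n solved exactly (default 13).
#' @return Path length in pixels.
#' @export
optimal_path_length <- function(x, y, method = c("auto", "exact", "heuristic"),
                                exact_cap = 13L) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 2 || length(y) != n) {
    abort("optimal_path_length requires >= 2 points",
          class = "patchleave_domain_error")
  }
  if (method == "auto") method <- if (n <= exact_cap) "exact" else "heuristic"
  if (method == "exact") {
    if (n > exact_cap) {
      abort(paste0("exact path solver capped at n = ", exact_cap,
                   " (got ", n, "); use method = 'heuristic'"),
            class = "patchleave_capacity_error")
    }
    .tsp_exact_cpp(as.numeric(x), as.numeric(y))
  } else {
    .tsp_heuristic_cpp(as.numeric(x), as.numeric(y))
  }
}

#' Percentage above the optimal path (PAO)
#'
#' How much longer the actual collection path is than the shortest
#' possible path through the same locations:
#' `PAO = (actual / optimal - 1) * 100`. A perfectly efficient collection
#' order gives 0; a meandering path gives large positive values.
#'
#' When every pick is at the same location the optimal length is 0 and the
#' ratio is undefined: the function returns `NA` with attribute
#' `degenerate = TRUE`, and such instances are excluded downstream.
#'
#' @inheritParams optimal_path_length
#' @param anchor_first If `TRUE`, constrain the optimal path to start at
#'   the first collected target rather than leaving both endpoints free.
#' @return PAO in percent (>= 0), or flagged `NA` when degenerate.
#' @export
pao <- function(x, y, method = c("auto", "exact", "heuristic"),
                exact_cap = 13L, anchor_first = FALSE) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3 || length(y) != n) {
    abort("pao requires >= 3 picks", class = "patchleave_domain_error")
  }
  actual <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (anchor_first) {
    # anchor by duplicating the start point far enough that every optimal
    # path must use it as an endpoint: solve with a dummy node glued to
    # pick 1 at distance 0 is equivalent to free-endpoint on the rest;
    # instead solve exactly by fixing the first index via enumeration of
    # the free solver on the reflected problem.
    opt <- .anchored_path_length(x, y, method, exact_cap)
  } else {
    opt <- optimal_path_length(x, y, method = method, exact_cap = exact_cap)
  }
  if (opt <= 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (actual / opt - 1) * 100
}

# Shortest open path constrained to start at point 1. Held-Karp already
# computes, per end vertex, the best path over the full set; anchoring is
# done by brute force over permutations for tiny n and by running the
# heuristic with the first point pinned otherwise.
.anchored_path_length <- function(x, y, method, exact_cap) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  if (n <= 9) {
    perms <- .permutations(seq_len(n - 1L))
    best <- Inf
    for (i in seq_len(nrow(perms))) {
      ord <- c(1L, perms[i, ] + 1L)
      len <- sum(d[cbind(ord[-n], ord[-1])])
      if (len < best) best <- len
    }
    return(best)
  }
  # pinned nearest-neighbor + 2-opt that never moves index 1
  ord <- 1L
  left <- setdiff(seq_len(n), 1L)
  while (length(left) > 0) {
    nxt <- left[which.min(d[ord[length(ord)], left])]
    ord <- c(ord, nxt)
    left <- setdiff(left, nxt)
  }
  len <- function(o) sum(d[cbind(o[-n], o[-1])])
  best <- len(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 2:(n - 1)) {
      for (j in (i + 1):n) {
        cand <- c(ord[seq_len(i - 1)], rev(ord[i:j]),
                  if (j < n) ord[(j + 1):n])
        cl <- len(cand)
        if (cl < best - 1e-12) {
          ord <- cand; best <- cl; improved <- TRUE
        }
      }
    }
  }
  best
}

.permutations <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- .permutations(v[-i])
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}

#' Intersection rate of the scan path
#'
#' Counts pairs of non-consecutive scan-path segments that intersect
#' (proper crossing, endpoint touching, or collinear overlap each count
#' once per pair) and divides by the number of segments (`n - 1`).
#' Organized searches avoid revisiting inspected regions, so their paths
#' self-intersect rarely.
#'
#' @inheritParams best_r
#' @param per_target Divide by the number of picks `n` instead of the
#'   number of segments `n - 1` (the "intersections/target" unit seen in
#'   some reports). Default `FALSE`.
#' @return Intersections per segment (or per target), >= 0.
#' @export
intersection_rate <- function(x, y, per_target = FALSE) {
  n <- length(x)
  if (n < 3 || length(y) != n) {
    abort("intersection_rate requires >= 3 picks",
          class = "patchleave_domain_error")
  }
  n_seg <- n - 1L
  count <- 0L
  for (i in seq_len(n_seg - 2L)) {
    for (j in seq.int(i + 2L, n_seg)) {
      if (segments_intersect(x[i], y[i], x[i + 1], y[i + 1],
                             x[j], y[j], x[j + 1], y[j + 1])) {
        count <- count + 1L
      }
    }
  }
  count / if (per_target) n else n_seg
}

# Robust segment intersection: orientation tests plus collinear overlap.
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  orient <- function(px, py, qx, qy, rx, ry) {
    v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
    scale <- max(abs(c(qx - px, ry - py, qy - py, rx - px)), 1)
    if (abs(v) <= 1e-9 * scale * scale) 0 else sign(v)
  }
  o1 <- orient(ax, ay, bx, by, cx, cy)
  o2 <- orient(ax, ay, bx, by, dx, dy)
  o3 <- orient(cx, cy, dx, dy, ax, ay)
  o4 <- orient(cx, cy, dx, dy, bx, by)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(px, py, qx, qy, rx, ry) {
    # r collinear with pq: is r within the bounding box?
    min(px, qx) - 1e-9 <= rx && rx <= max(px, qx) + 1e-9 &&
      min(py, qy) - 1e-9 <= ry && ry <= max(py, qy) + 1e-9
  }
  (o1 == 0 && on_seg(ax, ay, bx, by, cx, cy)) ||
    (o2 == 0 && on_seg(ax, ay, bx, by, dx, dy)) ||
    (o3 == 0 && on_seg(cx, cy, dx, dy, ax, ay)) ||
    (o4 == 0 && on_seg(cx, cy, dx, dy, bx, by))
}

#' Trial-so-far indicator series
#'
#' Recomputes all four organization indicators on the first `n` collected
#' targets for every `n = 3 .. N`, attaching each row to the decision made
#' at the `n`-th pick. Element `n` depends only on the first `n` picks
#' (prefix property), so appending a pick never changes earlier rows. The
#' optimal path is re-solved from scratch at each prefix.
#'
#' Indicator failures (degenerate geometry) are flagged per row rather
#' than raised.
#'
#' @param trial A `forage_trial` (coordinates must be those recorded at
#'   the collection instants, which matters for moving displays).
#' @param method,exact_cap Passed to [optimal_path_length].
#' @param per_target Passed to [intersection_rate].
#' @param anchor_first Passed to [pao].
#' @return Tibble with one row per `n`: trial keys, `n`, `best_r`,
#'   `mean_itd_px`, `pao_pct`, `intersection_rate`, `flag_degenerate`.
#' @export
indicator_series <- function(trial, method = "auto", exact_cap = 13L,
                             per_target = FALSE, anchor_first = FALSE) {
  picks <- target_picks(trial)
  n_total <- nrow(picks)
  if (n_total < 3) {
    return(tibble::tibble(
      participant_id = character(), condition = character(),
      trial_id = character(), age_group = character(), n = integer(),
      best_r = double(), mean_itd_px = double(), pao_pct = double(),
      intersection_rate = double(), flag_degenerate = logical()
    ))
  }
  rows <- lapply(3:n_total, function(n) {
    xs <- picks$x_px[seq_len(n)]
    ys <- picks$y_px[seq_len(n)]
    br <- best_r(xs, ys)
    pa <- pao(xs, ys, method = method, exact_cap = exact_cap,
              anchor_first = anchor_first)
    tibble::tibble(
      n = as.integer(n),
      best_r = as.numeric(br),
      mean_itd_px = mean_itd(xs, ys),
      pao_pct = as.numeric(pa),
      intersection_rate = intersection_rate(xs, ys, per_target = per_target),
      flag_degenerate = isTRUE(attr(br, "degenerate")) ||
        isTRUE(attr(pa, "degenerate"))
    )
  })
  out <- dplyr::bind_rows(rows)
  tibble::add_column(
    out,
    participant_id = trial$participant_id, condition = trial$condition,
    trial_id = trial$trial_id, age_group = trial$age_group,
    .before = 1
  )
}
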