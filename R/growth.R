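#' Log-phase generation time in a fixed OD600 window
#'
#' For each replicate, regresses `ln(OD600)` on time over the points with
#' `od_lo <= OD <= od_hi` (default 0.1-0.3, the published window, before any
#' diauxic halt) and converts the slope `b` to a generation time
#' `g = ln(2) / b`. Replicates are then summarized as mean +/- sd per strain
#' and medium. OD values are used as recorded (no path-length correction).
#'
#' @param curve Growth tibble: `time_h`, `od`, `replicate`, and optionally
#'   `strain`, `medium` label columns.
#' @param od_lo,od_hi OD600 window bounds (defaults 0.1 and 0.3).
#' @param min_points Minimum window points per replicate (default 3).
#' @return A `generation_time` tibble: `strain`, `medium`, `g_mean`, `g_sd`,
#'   `n_replicates`, `od_lo`, `od_hi`; the per-replicate fits are in the
#'   `"per_replicate"` attribute (`replicate`, `g`, `slope`,
#'   `n_points_used`).
#' @examples
#' gc <- simulate_growth_curves(growth_truth(od_max = Inf, noise_cv = 0),
#'                              seq(0, 8, 0.5), seed = 1)
#' generation_time(gc)
#' @export
generation_time <- function(curve, od_lo = 0.1, od_hi = 0.3, min_points = 3L) {
  curve <- as_tibble(curve)
  assert_that(all(c("time_h", "od", "replicate") %in% names(curve)),
              "growth curve needs columns time_h, od, replicate")
  assert_that(all(curve$od > 0), "OD600 values must be positive")
  assert_that(od_lo > 0 && od_hi > od_lo, "need 0 < od_lo < od_hi")
  if (!"strain" %in% names(curve)) curve$strain <- "strain"
  if (!"medium" %in% names(curve)) curve$medium <- "medium"

  per_rep <- curve |>
    group_by(.data$strain, .data$medium, .data$replicate) |>
    dplyr::group_modify(function(g, key) {
      win <- filter(g, .data$od >= od_lo, .data$od <= od_hi)
      assert_that(nrow(win) >= min_points,
                  sprintf("replicate %s (%s, %s): only %d point(s) in OD window [%g, %g]",
                          key$replicate, key$strain, key$medium, nrow(win),
                          od_lo, od_hi))
      b <- unname(coef(lm(log(od) ~ time_h, data = win))[2])
      assert_that(b > 0,
                  sprintf("replicate %s (%s, %s): non-positive growth rate in window",
                          key$replicate, key$strain, key$medium))
      tibble(g = log(2) / b, slope = b, n_points_used = nrow(win))
    }) |>
    ungroup()

  out <- per_rep |>
    group_by(.data$strain, .data$medium) |>
    summarise(g_mean = mean(.data$g),
              g_sd = if (n() > 1) sd(.data$g) else 0,
              n_replicates = n(), .groups = "drop") |>
    mutate(od_lo = od_lo, od_hi = od_hi)
  attr(out, "per_replicate") <- per_rep
  class(out) <- c("generation_time", class(out))
  out
}

# smoothed specific growth rate mu(t): rolling-median (window 3) on ln OD,
# then central differences (one-sided at the ends)
specific_growth_rate <- function(time_h, od) {
  l <- runmed(log(od), k = 3, endrule = "keep")
  n <- length(l)
  mu <- numeric(n)
  mu[1] <- (l[2] - l[1]) / (time_h[2] - time_h[1])
  mu[n] <- (l[n] - l[n - 1]) / (time_h[n] - time_h[n - 1])
  idx <- 2:(n - 1)
  mu[idx] <- (l[idx + 1] - l[idx - 1]) / (time_h[idx + 1] - time_h[idx - 1])
  mu
}

#' Detect the end of the first growth phase (diauxic shift)
#'
#' A diauxic culture grows, pauses while switching carbon sources, then
#' resumes. The end of the first phase is operationalized as the earliest
#' time, after the culture passes `od_threshold`, at which the smoothed
#' specific growth rate falls below `min_rate_fraction` of its running
#' maximum for at least `min_pause_points` consecutive points. Each replicate
#' is aligned on its own phase end over a +/- `window_h` hour window so
#' curves entering the shift at different times can be overlaid.
#'
#' @param curve Growth tibble (`time_h`, `od`, `replicate`, optional labels);
#'   >= 7 points per replicate.
#' @param min_rate_fraction Rate-collapse threshold relative to the running
#'   maximum rate (default 0.25).
#' @param min_pause_points Consecutive sub-threshold points required
#'   (default 2).
#' @param od_threshold Detection armed only after OD exceeds this (default
#'   0.1, the bottom of the generation-time window).
#' @param window_h Alignment half-window in hours (default 3).
#' @return A `diauxic_alignment` list: `summary` (`strain`, `medium`,
#'   `replicate`, `detected`, `t_end1`) and `aligned` (`replicate`,
#'   `relative_time`, `time_h`, `od` over `[-window_h, window_h]` where data
#'   exist; empty for undetected replicates).
#' @export
detect_first_phase_end <- function(curve, min_rate_fraction = 0.25,
                                   min_pause_points = 2L, od_threshold = 0.1,
                                   window_h = 3) {
  curve <- as_tibble(curve)
  assert_that(all(c("time_h", "od", "replicate") %in% names(curve)),
              "growth curve needs columns time_h, od, replicate")
  if (!"strain" %in% names(curve)) curve$strain <- "strain"
  if (!"medium" %in% names(curve)) curve$medium <- "medium"

  pieces <- curve |>
    group_by(.data$strain, .data$medium, .data$replicate) |>
    dplyr::group_map(function(g, key) {
      g <- arrange(g, .data$time_h)
      assert_that(nrow(g) >= 7,
                  sprintf("replicate %s: need >= 7 points to smooth, got %d",
                          key$replicate, nrow(g)))
      mu <- specific_growth_rate(g$time_h, g$od)
      run_max <- cummax(mu)
      armed <- g$od > od_threshold
      below <- armed & mu < min_rate_fraction * run_max & run_max > 0
      # earliest start of a run of >= min_pause_points sub-threshold points
      t_end1 <- NA_real_
      r <- rle(below)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      hit <- which(r$values & r$lengths >= min_pause_points)
      if (length(hit) > 0) t_end1 <- g$time_h[starts[hit[1]]]
      detected <- !is.na(t_end1)
      aligned <- if (detected) {
        g |>
          filter(.data$time_h >= t_end1 - window_h,
                 .data$time_h <= t_end1 + window_h) |>
          mutate(relative_time = .data$time_h - t_end1) |>
          select("relative_time", "time_h", "od")
      } else {
        tibble(relative_time = numeric(), time_h = numeric(), od = numeric())
      }
      list(summary = bind_cols(key, tibble(detected = detected,
                                           t_end1 = t_end1)),
           aligned = bind_cols(key[rep(1, nrow(aligned)), , drop = FALSE],
                               aligned))
    })
  summary <- bind_rows(purrr::map(pieces, "summary"))
  aligned <- bind_rows(purrr::map(pieces, "aligned"))
  structure(list(summary = summary, aligned = aligned,
                 params = list(min_rate_fraction = min_rate_fraction,
                               min_pause_points = min_pause_points,
                               od_threshold = od_threshold,
                               window_h = window_h)),
            class = "diauxic_alignment")
}

#' @export
print.diauxic_alignment <- function(x, ...) {
  cat("Diauxic-shift detection (rate fraction ",
      x$params$min_rate_fraction, ", +/-", x$params$window_h, " h window)\n",
      sep = "")
  print(x$summary)
  invisible(x)
}
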