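#' Relative response factors against an internal standard
#'
#' GC-MS response factors vary with instrument gain and injection volume, so
#' each peak is expressed relative to the ribitol internal standard spiked
#' into the same sample: `rrf = peak RF / ribitol RF`. The internal standard's
#' own RRF is 1 in every sample by construction, and RRFs are invariant to
#' rescaling all of a sample's response factors.
#'
#' @param peaks Peak table tibble: `sample_id`, `strain`, `condition`,
#'   `replicate`, `compound`, `response_factor` (> 0 for the standard).
#' @param internal_standard Internal-standard compound name (default
#'   `"ribitol"`).
#' @return An `rrf_table` tibble: the input rows with an `rrf` column; the
#'   internal-standard name is carried in the `"internal_standard"` attribute.
#' @examples
#' peaks <- tibble::tibble(
#'   sample_id = "s1", strain = "wt", condition = "succinate", replicate = 1,
#'   compound = c("malate", "ribitol"), response_factor = c(6, 3))
#' compute_rrf(peaks)
#' @export
compute_rrf <- function(peaks, internal_standard = "ribitol") {
  peaks <- as_tibble(peaks)
  assert_that(all(c("sample_id", "compound", "response_factor") %in% names(peaks)),
              "peak table needs columns sample_id, compound, response_factor")
  is_rows <- filter(peaks, .data$compound == internal_standard)
  per_sample <- count(is_rows, .data$sample_id)
  missing <- setdiff(unique(peaks$sample_id), per_sample$sample_id)
  assert_that(length(missing) == 0,
              paste0("internal standard '", internal_standard,
                     "' missing in sample(s): ",
                     paste(missing, collapse = ", ")))
  assert_that(all(per_sample$n == 1),
              paste0("internal standard must appear exactly once per sample; ",
                     "violated in: ",
                     paste(per_sample$sample_id[per_sample$n != 1],
                           collapse = ", ")))
  bad <- is_rows$sample_id[!(is.finite(is_rows$response_factor) &
                               is_rows$response_factor > 0)]
  assert_that(length(bad) == 0,
              paste("non-positive internal-standard signal in sample(s):",
                    paste(bad, collapse = ", ")))
  out <- peaks |>
    left_join(select(is_rows, "sample_id", is_rf = "response_factor"),
              by = "sample_id") |>
    mutate(rrf = .data$response_factor / .data$is_rf) |>
    select(-"is_rf")
  attr(out, "internal_standard") <- internal_standard
  class(out) <- c("rrf_table", class(out))
  out
}

#' One-way ANOVA screen for strain effects on metabolite levels
#'
#' Screens each compound, within each growth condition, for differences in
#' mean RRF across strains by one-way fixed-effects ANOVA
#' (`F = MS_between / MS_within`, df = (k - 1, N - k)). A compound is flagged
#' significant when `p <= threshold` (raw p, no multiple-testing correction
#' by default, matching the published P <= 0.05 screen). The internal
#' standard itself is excluded.
#'
#' @param rrf An `rrf_table` from [compute_rrf()] (needs columns `compound`,
#'   `strain`, `condition`, `rrf`).
#' @param threshold Significance threshold on p (default 0.05).
#' @param adjust_p If `TRUE`, apply Benjamini-Hochberg across compounds within
#'   each condition and call significance on the adjusted p.
#' @return An `anova_screen` tibble: `condition`, `compound`, `n_groups`,
#'   `df_between`, `df_within`, `F`, `p`, `significant`.
#' @export
anova_screen <- function(rrf, threshold = 0.05, adjust_p = FALSE) {
  rrf <- as_tibble(rrf)
  assert_that(all(c("compound", "strain", "condition", "rrf") %in% names(rrf)),
              "rrf table needs columns compound, strain, condition, rrf")
  is_name <- attr(rrf, "internal_standard") %||% "ribitol"
  dat <- filter(rrf, .data$compound != is_name)
  res <- dat |>
    group_by(.data$condition, .data$compound) |>
    dplyr::group_modify(function(g, key) {
      sizes <- count(g, .data$strain)
      assert_that(nrow(sizes) >= 2,
                  paste0("need >= 2 strains for ", key$compound,
                         " in ", key$condition))
      assert_that(all(sizes$n >= 2),
                  paste0("strain group with < 2 replicates for ",
                         key$compound, " in ", key$condition))
      # aov warns on an exactly zero-residual fit; that case is handled below
      fit <- suppressWarnings(anova(aov(rrf ~ strain, data = g)))
      f_val <- fit[["F value"]][1]
      p_val <- fit[["Pr(>F)"]][1]
      if (is.nan(f_val)) { # zero variance everywhere: no evidence of effect
        f_val <- 0
        p_val <- 1
      }
      tibble(n_groups = nrow(sizes), df_between = fit$Df[1],
             df_within = fit$Df[2], F = f_val, p = p_val)
    }) |>
    ungroup()
  p_call <- if (adjust_p) {
    res <- res |>
      group_by(.data$condition) |>
      mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
      ungroup()
    res$p_adj
  } else {
    res$p
  }
  res <- mutate(res, significant = p_call <= threshold)
  class(res) <- c("anova_screen", class(res))
  res
}

#' Extracellular excretion time-course
#'
#' Summarizes RRFs over a sampling time-course (replicate mean and sd per
#' strain, compound and time) and reports, per strain and compound, the
#' terminal/initial mean-RRF ratio as an accumulation index (a derived
#' summary: 1 means no net accumulation).
#'
#' @param rrf An `rrf_table` with one row per sample and compound.
#' @param times Tibble `(sample_id, time_h)` mapping samples to sampling
#'   times.
#' @return A `timecourse` list with `series`
#'   (`strain`, `compound`, `time_h`, `mean_rrf`, `sd_rrf`, `n`) sorted by
#'   time, and `accumulation` (`strain`, `compound`, `index`).
#' @export
excretion_timecourse <- function(rrf, times) {
  rrf <- as_tibble(rrf)
  times <- as_tibble(times)
  assert_that(all(c("sample_id", "time_h") %in% names(times)),
              "times needs columns sample_id and time_h")
  is_name <- attr(rrf, "internal_standard") %||% "ribitol"
  dat <- rrf |>
    filter(.data$compound != is_name) |>
    inner_join(times, by = "sample_id")
  series <- dat |>
    group_by(.data$strain, .data$compound, .data$time_h) |>
    summarise(mean_rrf = mean(.data$rrf),
              sd_rrf = if (n() > 1) sd(.data$rrf) else 0,
              n = n(), .groups = "drop") |>
    arrange(.data$strain, .data$compound, .data$time_h)
  npts <- series |> count(.data$strain, .data$compound)
  assert_that(all(npts$n >= 2),
              "need >= 2 time points per strain and compound")
  accumulation <- series |>
    group_by(.data$strain, .data$compound) |>
    summarise(index = last(.data$mean_rrf) / first(.data$mean_rrf),
              .groups = "drop")
  structure(list(series = series, accumulation = accumulation),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("Excretion time-course:",
      dplyr::n_distinct(x$series$compound), "compound(s),",
      dplyr::n_distinct(x$series$strain), "strain(s),",
      dplyr::n_distinct(x$series$time_h), "time points\n")
  print(x$accumulation)
  invisible(x)
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of `signal = slope * concentration + intercept`
#' from calibration standards of known concentration, as used to quantify
#' L-malate enzymatically.
#'
#' @param standards Tibble or data frame with columns `concentration_uM` and
#'   `signal` (>= 2 distinct concentrations).
#' @return A `standard_curve` object (`slope`, `intercept`, `r_squared`,
#'   underlying `lm` fit); supports [tidy()], [glance()] and [quantify()].
#' @examples
#' sc <- fit_standard_curve(
#'   tibble::tibble(concentration_uM = c(0, 250, 500, 1000),
#'                  signal = c(0.01, 0.26, 0.50, 1.01)))
#' quantify(sc, 0.62)
#' @export
fit_standard_curve <- function(standards) {
  standards <- as_tibble(standards)
  assert_that(all(c("concentration_uM", "signal") %in% names(standards)),
              "standards needs columns concentration_uM and signal")
  assert_that(n_distinct(standards$concentration_uM) >= 2,
              "need >= 2 distinct concentrations to fit a line")
  fit <- lm(signal ~ concentration_uM, data = standards)
  # exact calibration lines trigger the "essentially perfect fit" warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, fit = fit, n = nrow(standards),
                 standards = standards),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: signal = %.6g x conc(uM) + %.6g  (r^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Concentrations from a standard curve
#'
#' Inverts the calibration line: `concentration = (signal - intercept) /
#' slope`. Signals below the blank give negative concentrations, which are
#' reported (flagged `below_blank`) rather than truncated so downstream
#' statistics stay unbiased.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param signal Numeric vector of measured signals.
#' @return Tibble `(signal, concentration_uM, below_blank)`.
#' @export
quantify <- function(curve, signal) {
  assert_that(inherits(curve, "standard_curve"),
              "curve must come from fit_standard_curve()")
  assert_that(curve$slope != 0, "standard-curve slope is zero; cannot invert")
  conc <- (signal - curve$intercept) / curve$slope
  tibble(signal = signal, concentration_uM = conc, below_blank = conc < 0)
}
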