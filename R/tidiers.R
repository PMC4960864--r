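#' Broom-style tidiers for fitted objects
#'
#' `tidy()` on a `standard_curve` returns the coefficient table of the
#' underlying least-squares fit; `glance()` returns a one-row model summary.
#' `tidy()` on an `experiment_clustering` returns the merge table (one row
#' per agglomeration with its height); `glance()` a one-row summary.
#'
#' @param x A `standard_curve` or `experiment_clustering` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = unname(s[, "Estimate"]),
         std_error = unname(s[, "Std. Error"]),
         statistic = unname(s[, "t value"]),
         p_value = unname(s[, "Pr(>|t|)"]))
}

#' @rdname tidiers
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         n = x$n)
}

#' @rdname tidiers
#' @export
tidy.experiment_clustering <- function(x, ...) {
  hc <- x$hclust
  merges <- as_tibble(hc$merge, .name_repair = ~ c("left", "right"))
  lab <- function(i) if_else(i < 0, hc$labels[pmax(-i, 1)],
                             paste0("node_", i))
  merges |>
    mutate(step = dplyr::row_number(), height = hc$height,
           left = lab(.data$left), right = lab(.data$right)) |>
    select("step", "left", "right", "height")
}

#' @rdname tidiers
#' @export
glance.experiment_clustering <- function(x, ...) {
  tibble(n_experiments = length(x$hclust$labels),
         max_height = max(x$hclust$height),
         distance = x$distance, linkage = x$linkage)
}

#' @rdname tidiers
#' @export
glance.generation_time <- function(x, ...) {
  as_tibble(x)
}
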