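#' Differential-expression configuration
#'
#' Thresholds and preprocessing knobs for the probe-to-feature pipeline. The
#' defaults reproduce the published calling rule: a feature is significant when
#' its fold change is at least 3 *and* the Student's t p-value is at most 0.05,
#' after requiring at least six non-redundant probes per feature.
#'
#' @param fold_threshold Minimum fold change (>= 1; default 3).
#' @param p_threshold Maximum p-value (in (0,1); default 0.05).
#' @param min_probes Minimum distinct probes per retained feature (default 6).
#' @param negative_floor Positive floor applied to background-corrected
#'   feature values so ratios stay defined (default 1 intensity unit).
#' @param background_stat Null-probe summary used as the per-array background:
#'   `"median"` (robust default) or `"mean"`.
#' @param adjust_p If `TRUE`, add a Benjamini-Hochberg adjusted p-value column
#'   and use it for the significance call. Off by default, matching the raw
#'   P <= 0.05 screen.
#' @return A `de_config` list.
#' @export
de_config <- function(fold_threshold = 3, p_threshold = 0.05, min_probes = 6L,
                      negative_floor = 1, background_stat = c("median", "mean"),
                      adjust_p = FALSE) {
  assert_that(fold_threshold >= 1, "fold_threshold must be >= 1")
  assert_that(p_threshold > 0 && p_threshold < 1, "p_threshold must be in (0, 1)")
  assert_that(min_probes >= 1, "min_probes must be >= 1")
  assert_that(negative_floor > 0, "negative_floor must be positive")
  structure(list(fold_threshold = fold_threshold, p_threshold = p_threshold,
                 min_probes = as.integer(min_probes),
                 negative_floor = negative_floor,
                 background_stat = match.arg(background_stat),
                 adjust_p = isTRUE(adjust_p)),
            class = "de_config")
}

validate_probe_table <- function(probes) {
  probes <- as_tibble(probes)
  assert_that(all(c("probe_id", "feature_id") %in% names(probes)),
              "probe table needs columns probe_id and feature_id")
  cols <- intensity_cols(probes)
  assert_that(length(cols) >= 1, "probe table needs at least one array column")
  vals <- as.matrix(probes[cols])
  assert_that(!anyNA(vals), "probe intensities contain missing values")
  probes
}

#' Quantile-normalize a probe-intensity table
#'
#' Forces every array to share one intensity distribution while preserving
#' within-array ranks: each value is replaced by the mean, across arrays, of
#' the values holding its rank (the row means of the column-sorted matrix).
#' Tied values within an array receive the mean of the reference values their
#' ranks span.
#'
#' @param probes Probe table: `probe_id`, `feature_id` (`NA` for null probes),
#'   one intensity column per array. No missing values allowed.
#' @return The probe table with every intensity column normalized.
#' @examples
#' p <- tibble::tibble(probe_id = paste0("p", 1:4), feature_id = "g1",
#'                     A = c(2, 4, 6, 8), B = c(1, 3, 5, 7))
#' quantile_normalize(p)
#' @export
quantile_normalize <- function(probes) {
  probes <- validate_probe_table(probes)
  cols <- intensity_cols(probes)
  m <- as.matrix(probes[cols])
  if (length(cols) > 1) {
    ref <- rowMeans(apply(m, 2, sort))
    cs <- cumsum(ref)
    for (j in seq_along(cols)) {
      rmin <- rank(m[, j], ties.method = "min")
      rmax <- rank(m[, j], ties.method = "max")
      m[, j] <- (cs[rmax] - c(0, cs)[rmin]) / (rmax - rmin + 1)
    }
    probes[cols] <- as_tibble(m)
  }
  probes
}

#' Features passing the non-redundant probe filter
#'
#' Retains features targeted by at least `min_probes` non-redundant probes,
#' where non-redundant means distinct `probe_id` (duplicate rows for one probe
#' count once). Null probes never count towards a feature.
#'
#' @param probes Probe table (see [quantile_normalize()]).
#' @param config A [de_config()]; only `min_probes` is used.
#' @return Character vector of retained feature ids (sorted).
#' @export
filter_features <- function(probes, config = de_config()) {
  probes <- as_tibble(probes)
  if (nrow(probes) == 0) return(character())
  probes |>
    filter(!is.na(.data$feature_id)) |>
    distinct(.data$feature_id, .data$probe_id) |>
    count(.data$feature_id) |>
    filter(.data$n >= config$min_probes) |>
    pull("feature_id") |>
    sort()
}

#' Per-array background from null probes
#'
#' Null probes match no genomic sequence, so their signal estimates the
#' per-array background. The default statistic is the median (robust to the
#' occasional bright null probe); the mean is available via
#' `de_config(background_stat = "mean")`.
#'
#' @inheritParams filter_features
#' @return Tibble `(array_id, background)`, one row per array.
#' @export
estimate_background <- function(probes, config = de_config()) {
  probes <- validate_probe_table(probes)
  nulls <- filter(probes, is.na(.data$feature_id))
  assert_that(nrow(nulls) > 0,
              "no null probes found (feature_id NA / NULL_PROBE rows are required)")
  stat <- if (config$background_stat == "median") median else mean
  nulls |>
    tidyr::pivot_longer(dplyr::all_of(intensity_cols(probes)),
                        names_to = "array_id", values_to = "intensity") |>
    group_by(.data$array_id) |>
    summarise(background = stat(.data$intensity), .groups = "drop")
}

#' Background-corrected feature expression
#'
#' The median of a feature's (normalized, filtered) probe intensities on each
#' array is the uncorrected expression; subtracting that array's estimated
#' background gives the corrected value. Values below `negative_floor` are
#' set to the floor and flagged, so downstream ratios remain defined.
#'
#' @param probes Quantile-normalized probe table.
#' @param background Per-array background from [estimate_background()].
#' @param design Array design table (see [array_design()]).
#' @param config A [de_config()].
#' @param features Features to summarize; defaults to
#'   `filter_features(probes, config)`.
#' @return A `feature_expr` tibble: `feature_id`, `array_id`, `experiment`,
#'   `replicate`, `value`, `floored`.
#' @export
feature_expression <- function(probes, background, design,
                               config = de_config(),
                               features = filter_features(probes, config)) {
  probes <- validate_probe_table(probes)
  design <- ensure_experiment(design)
  cols <- intensity_cols(probes)
  missing_arrays <- setdiff(cols, design$array_id)
  assert_that(length(missing_arrays) == 0,
              paste("arrays absent from design:",
                    paste(missing_arrays, collapse = ", ")))
  expr <- probes |>
    filter(.data$feature_id %in% features) |>
    tidyr::pivot_longer(dplyr::all_of(cols),
                        names_to = "array_id", values_to = "intensity") |>
    group_by(.data$feature_id, .data$array_id) |>
    summarise(median_intensity = median(.data$intensity), .groups = "drop") |>
    inner_join(background, by = "array_id") |>
    mutate(raw = .data$median_intensity - .data$background,
           floored = .data$raw < config$negative_floor,
           value = pmax(.data$raw, config$negative_floor)) |>
    inner_join(select(design, "array_id", "experiment", "replicate"),
               by = "array_id") |>
    select("feature_id", "array_id", "experiment", "replicate",
           "value", "floored") |>
    arrange(.data$feature_id, .data$array_id)
  class(expr) <- c("feature_expr", class(expr))
  expr
}

#' Replicate-averaged expression per experiment
#'
#' @param expr A `feature_expr` table from [feature_expression()].
#' @return Tibble `(feature_id, experiment, mean_value, n_replicates)`.
#' @export
experiment_means <- function(expr) {
  expr |>
    as_tibble() |>
    group_by(.data$feature_id, .data$experiment) |>
    summarise(mean_value = mean(.data$value), n_replicates = n(),
              .groups = "drop")
}

#' Pairwise differential expression between two experiments
#'
#' For each feature the ratio of the two experiments' replicate-averaged,
#' background-corrected expression values gives the fold change; a
#' pooled-variance two-sample Student's t-test on the replicate-level values
#' (df = n_a + n_b - 2) gives the p-value. A feature is significant when
#' `fold >= fold_threshold` and `p <= p_threshold`. Degenerate zero-variance
#' cases: equal means give t = 0, p = 1; unequal means with zero pooled
#' variance are flagged `degenerate` and reported with p = 0.
#'
#' @param expr A `feature_expr` table from [feature_expression()].
#' @param exp_a,exp_b Experiment labels to compare (ratio is a / b).
#' @param config A [de_config()].
#' @return A `de_result` tibble: `feature_id`, `mean_a`, `mean_b`, `ratio`,
#'   `fold`, `direction`, `t`, `df`, `p`, `significant`, `floored`,
#'   `degenerate` (plus `p_adj` when `adjust_p` is on).
#' @export
differential_expression <- function(expr, exp_a, exp_b, config = de_config()) {
  expr <- as_tibble(expr)
  assert_that(all(c(exp_a, exp_b) %in% expr$experiment),
              "both experiments must be present in the expression table")
  sub <- filter(expr, .data$experiment %in% c(exp_a, exp_b))
  counts <- sub |> count(.data$feature_id, .data$experiment)
  assert_that(all(counts$n >= 2),
              "each experiment needs >= 2 replicate values per feature (t-test undefined)")

  res <- sub |>
    group_by(.data$feature_id) |>
    summarise(
      mean_a = mean(.data$value[.data$experiment == exp_a]),
      mean_b = mean(.data$value[.data$experiment == exp_b]),
      var_a = stats::var(.data$value[.data$experiment == exp_a]),
      var_b = stats::var(.data$value[.data$experiment == exp_b]),
      n_a = sum(.data$experiment == exp_a),
      n_b = sum(.data$experiment == exp_b),
      floored = any(.data$floored),
      .groups = "drop"
    ) |>
    mutate(
      ratio = .data$mean_a / .data$mean_b,
      fold = pmax(.data$ratio, 1 / .data$ratio),
      direction = if_else(.data$ratio > 1, "up", "down"),
      df = .data$n_a + .data$n_b - 2L,
      sp2 = ((.data$n_a - 1) * .data$var_a + (.data$n_b - 1) * .data$var_b) /
        .data$df,
      se = sqrt(.data$sp2 * (1 / .data$n_a + 1 / .data$n_b)),
      t = (.data$mean_a - .data$mean_b) / .data$se,
      degenerate = .data$se == 0 & .data$mean_a != .data$mean_b,
      t = dplyr::case_when(
        .data$se > 0 ~ .data$t,
        .data$mean_a == .data$mean_b ~ 0,
        .default = Inf * sign(.data$mean_a - .data$mean_b)
      ),
      p = dplyr::case_when(
        .data$se > 0 ~ 2 * pt(-abs(.data$t), .data$df),
        .data$mean_a == .data$mean_b ~ 1,
        .default = 0
      )
    )
  p_call <- if (config$adjust_p) {
    res <- mutate(res, p_adj = stats::p.adjust(.data$p, method = "BH"))
    res$p_adj
  } else {
    res$p
  }
  res <- res |>
    mutate(significant = .data$fold >= config$fold_threshold &
             p_call <= config$p_threshold) |>
    select("feature_id", "mean_a", "mean_b", "ratio", "fold", "direction",
           "t", "df", "p", dplyr::any_of("p_adj"), "significant", "floored",
           "degenerate") |>
    arrange(.data$feature_id)
  attr(res, "comparison") <- c(a = exp_a, b = exp_b)
  class(res) <- c("de_result", class(res))
  res
}

#' Functional categories used in the published summary table
#'
#' @return Character vector of the fixed category vocabulary.
#' @export
table1_categories <- function() {
  c("Amino acid metabolism", "Cofactor and vitamin metabolism",
    "Fatty acid, ester, and phospholipid", "Carbohydrate metabolism",
    "Purine, pyrimidine, and nucleotide", "Regulatory function",
    "DNA replication and repair", "Transport system", "Energy metabolism",
    "Other categories", "Hypothetical protein")
}

#' Summarize significant calls by functional category
#'
#' Counts significantly up- and down-regulated features per functional
#' category, with a `Total` row equal to the column sums. Every significant
#' feature must be present in the category map unless a `default_category`
#' (normally `"Hypothetical protein"`) is configured for unknowns.
#'
#' @param de A `de_result` from [differential_expression()].
#' @param categories Tibble `(feature_id, category)`; category labels must
#'   come from `vocabulary`.
#' @param default_category Optional label assigned to significant features
#'   missing from `categories`; `NULL` (default) makes a missing feature an
#'   error.
#' @param vocabulary Allowed category labels (default [table1_categories()]).
#' @return Tibble `(category, n_up, n_down)` over the full vocabulary plus a
#'   `Total` row.
#' @export
summarize_by_category <- function(de, categories, default_category = NULL,
                                  vocabulary = table1_categories()) {
  categories <- as_tibble(categories)
  assert_that(all(c("feature_id", "category") %in% names(categories)),
              "categories needs columns feature_id and category")
  bad <- setdiff(unique(categories$category), vocabulary)
  assert_that(length(bad) == 0,
              paste("categories outside the vocabulary:",
                    paste(bad, collapse = ", ")))
  assert_that(!anyDuplicated(categories$feature_id),
              "each feature must map to exactly one category")
  sig <- filter(as_tibble(de), .data$significant)
  missing <- setdiff(sig$feature_id, categories$feature_id)
  if (length(missing) > 0) {
    assert_that(!is.null(default_category),
                paste("significant features missing from the category map:",
                      paste(utils::head(missing, 5), collapse = ", ")))
    assert_that(default_category %in% vocabulary,
                "default_category must be in the vocabulary")
    categories <- bind_rows(categories,
                            tibble(feature_id = missing,
                                   category = default_category))
  }
  tallies <- sig |>
    inner_join(categories, by = "feature_id") |>
    count(.data$category, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("up", "down")) {
    if (!col %in% names(tallies)) tallies[[col]] <- 0L
  }
  out <- tibble(category = vocabulary) |>
    left_join(tallies, by = "category") |>
    mutate(n_up = dplyr::coalesce(.data$up, 0L),
           n_down = dplyr::coalesce(.data$down, 0L)) |>
    select("category", "n_up", "n_down")
  bind_rows(out, tibble(category = "Total", n_up = sum(out$n_up),
                        n_down = sum(out$n_down)))
}

#' Hierarchical clustering of experiment transcriptomes
#'
#' Clusters the experiments' replicate-averaged expression profiles by
#' average-linkage agglomeration on `1 - Pearson correlation` of
#' log2-transformed corrected expression. Experiments are ordered
#' lexicographically before clustering so ties break deterministically.
#'
#' @param expr A `feature_expr` table from [feature_expression()].
#' @param log_base Base of the log transform applied before correlation
#'   (default 2).
#' @return An `experiment_clustering` object wrapping the `hclust` tree;
#'   see [as_newick()] for serialization.
#' @export
cluster_experiments <- function(expr, log_base = 2) {
  means <- experiment_means(expr)
  wide <- tidyr::pivot_wider(means, id_cols = "feature_id",
                             names_from = "experiment",
                             values_from = "mean_value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  assert_that(ncol(m) >= 2, "need at least two experiments to cluster")
  assert_that(!anyNA(m), "every experiment needs a value for every feature")
  m <- log(m, base = log_base)
  sds <- apply(m, 2, sd)
  assert_that(all(sds > 0),
              paste("constant expression profile (zero variance) in:",
                    paste(colnames(m)[sds == 0], collapse = ", ")))
  m <- m[, order(colnames(m)), drop = FALSE]
  d <- as.dist(1 - cor(m))
  hc <- hclust(d, method = "average")
  structure(list(hclust = hc, distance = "1 - Pearson (log2)",
                 linkage = "average"),
            class = "experiment_clustering")
}

#' Newick serialization of an experiment dendrogram
#'
#' @param clustering An `experiment_clustering` from [cluster_experiments()].
#' @param file Optional path; when given the tree is written there.
#' @return The newick string, invisibly when `file` is given.
#' @export
as_newick <- function(clustering, file = NULL) {
  assert_that(inherits(clustering, "experiment_clustering"),
              "clustering must come from cluster_experiments()")
  phy <- ape::as.phylo(clustering$hclust)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' @export
print.experiment_clustering <- function(x, ...) {
  cat("Experiment clustering (", x$distance, ", ", x$linkage, " linkage)\n",
      sep = "")
  cat("  ", length(x$hclust$labels), " experiments: ",
      paste(x$hclust$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}
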