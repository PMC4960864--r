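#' Percent of initial substrate represented by an excreted metabolite
#'
#' `100 * excreted_uM / (1000 * initial_mM)`: e.g. 613 uM malate excreted
#' into medium that started with 5 mM succinate is 12.26 %, the "~12 %"
#' back-of-envelope that situates the excretion flux.
#'
#' @param excreted_uM Excreted concentration, uM (>= 0).
#' @param initial_mM Initial substrate concentration, mM (> 0).
#' @return Percentage (numeric).
#' @examples
#' fraction_of_substrate(613, 5)
#' @export
fraction_of_substrate <- function(excreted_uM, initial_mM) {
  assert_that(all(initial_mM > 0), "initial_mM must be positive")
  assert_that(all(excreted_uM >= 0), "excreted_uM must be >= 0")
  100 * excreted_uM / (1000 * initial_mM)
}

#' Run the full analysis pipeline from files
#'
#' Orchestrates normalize -> filter -> background -> expression -> DE ->
#' category summary -> clustering on the microarray inputs, plus the
#' metabolomics (RRF, ANOVA screen, optional time-course and standard-curve
#' quantification) and growth (generation time, diauxic detection) stages
#' when their inputs are provided. All stage outputs are written under
#' `config$output_dir` and a machine-readable JSON report is returned and
#' written alongside them. Counts in the report are recounted from the
#' written files, and reruns with the same config are identical up to the
#' timestamp.
#'
#' @param config A named list (or path to a JSON file holding one) with
#'   elements: `probe_table`, `design_table` (paths); `comparisons`, a list
#'   of `list(a = , b = )` experiment pairs; optional `categories` (path to a
#'   `feature_id  category` TSV), `default_category`; optional `peak_table`,
#'   `sample_times` (path to `sample_id,time_h` CSV), `standards`,
#'   `malate_signal`, `initial_substrate_mM`; optional `growth_curves` +
#'   `plate_map`; optional `de` (list of [de_config()] arguments),
#'   `anova_threshold`, `od_window`; `output_dir`.
#' @return The report, an object of class `run_report` (a named list),
#'   invisibly written to `output_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  assert_that(!is.null(config[["output_dir"]]), "config$output_dir is required")
  dir.create(config[["output_dir"]], showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config[["output_dir"]], f)
  cfg <- do.call(de_config, config[["de"]] %||% list())
  report <- list(package_version = as.character(packageVersion("dmeomics")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 parameters = list(
                   fold_threshold = cfg$fold_threshold,
                   p_threshold = cfg$p_threshold,
                   min_probes = cfg$min_probes,
                   anova_threshold = config[["anova_threshold"]] %||% 0.05),
                 stages = list())

  # -- microarray stage ------------------------------------------------
  if (!is.null(config[["probe_table"]])) {
    assert_that(file.exists(config[["probe_table"]]), "probe_table file not found")
    assert_that(file.exists(config[["design_table"]]),
                "design_table file not found")
    probes <- read_probe_table(config[["probe_table"]])
    design <- read_design_table(config[["design_table"]])
    norm <- quantile_normalize(probes)
    feats <- filter_features(norm, cfg)
    bg <- estimate_background(norm, cfg)
    expr <- feature_expression(norm, bg, design, cfg, features = feats)
    write_probe_table(norm, out("normalized_probes.tsv"))
    readr::write_tsv(bg, out("background.tsv"))

    n_features_total <- n_distinct(probes$feature_id[!is.na(probes$feature_id)])
    report$stages$microarray <- list(
      n_probes = nrow(probes),
      n_null_probes = sum(is.na(probes$feature_id)),
      n_arrays = length(intensity_cols(probes)),
      n_features_before_filter = n_features_total,
      n_features_after_filter = length(feats))

    categories <- NULL
    if (!is.null(config[["categories"]])) {
      categories <- readr::read_tsv(config[["categories"]], col_types = "cc")
    }
    comparisons <- config[["comparisons"]] %||% list()
    de_reports <- list()
    for (cmp in comparisons) {
      tag <- paste0(cmp[["a"]], "_vs_", cmp[["b"]])
      de <- differential_expression(expr, cmp[["a"]], cmp[["b"]], cfg)
      de_path <- out(paste0("de_", tag, ".tsv"))
      write_de_table(de, de_path)
      # recount significant calls from the written file, not from memory
      written <- readr::read_tsv(de_path, show_col_types = FALSE)
      cmp_report <- list(
        a = cmp[["a"]], b = cmp[["b"]],
        n_features = nrow(written),
        n_significant_up = sum(written$significant & written$direction == "up"),
        n_significant_down = sum(written$significant &
                                   written$direction == "down"))
      if (!is.null(categories)) {
        summary <- summarize_by_category(
          de, categories, default_category = config[["default_category"]])
        readr::write_tsv(summary, out(paste0("categories_", tag, ".tsv")))
        total_up <- summary$n_up[summary$category == "Total"]
        pct <- summary |>
          filter(.data$category != "Total") |>
          mutate(pct_up = if (total_up > 0) 100 * .data$n_up / total_up else 0,
                 pct_up_rounded = round(.data$pct_up)) |>
          select("category", "n_up", "n_down", "pct_up", "pct_up_rounded")
        cmp_report$category_summary <- pct
      }
      de_reports[[tag]] <- cmp_report
    }
    report$stages$differential_expression <- de_reports

    if (length(unique(expr$experiment)) >= 2) {
      cl <- cluster_experiments(expr)
      as_newick(cl, out("experiment_dendrogram.nwk"))
      report$stages$clustering <- list(
        n_experiments = length(cl$hclust$labels),
        newick = as_newick(cl))
    }
  }

  # -- metabolomics stage ----------------------------------------------
  if (!is.null(config[["peak_table"]])) {
    peaks <- read_peak_table(config[["peak_table"]])
    rrf <- compute_rrf(peaks)
    readr::write_tsv(as_tibble(rrf), out("rrf.tsv"))
    screen <- anova_screen(rrf, threshold = config[["anova_threshold"]] %||% 0.05)
    readr::write_tsv(as_tibble(screen), out("anova.tsv"))
    written <- readr::read_tsv(out("anova.tsv"), show_col_types = FALSE)
    report$stages$metabolomics <- list(
      n_samples = n_distinct(peaks$sample_id),
      n_compounds = nrow(written),
      n_significant = sum(written$significant))
    if (!is.null(config[["sample_times"]])) {
      times <- readr::read_csv(config[["sample_times"]],
                               col_types = readr::cols(
                                 sample_id = readr::col_character(),
                                 time_h = readr::col_double()))
      tc <- excretion_timecourse(rrf, times)
      readr::write_tsv(tc$series, out("timecourse.tsv"))
      report$stages$metabolomics$accumulation <- tc$accumulation
    }
  }
  if (!is.null(config[["standards"]])) {
    curve <- fit_standard_curve(read_standards(config[["standards"]]))
    report$stages$malate_quantification <- list(
      slope = curve$slope, intercept = curve$intercept,
      r_squared = curve$r_squared)
    if (!is.null(config[["malate_signal"]])) {
      q <- quantify(curve, config[["malate_signal"]])
      report$stages$malate_quantification$concentration_uM <-
        q$concentration_uM
      if (!is.null(config[["initial_substrate_mM"]])) {
        pct <- fraction_of_substrate(q$concentration_uM,
                                     config[["initial_substrate_mM"]])
        report$stages$malate_quantification$fraction_of_substrate_pct <- pct
        report$stages$malate_quantification$fraction_of_substrate_pct_rounded <-
          round(pct)
      }
    }
  }

  # -- growth stage ----------------------------------------------------
  if (!is.null(config[["growth_curves"]])) {
    growth <- read_growth_curves(config[["growth_curves"]], config[["plate_map"]])
    od_window <- config[["od_window"]] %||% c(0.1, 0.3)
    gt <- generation_time(growth, od_lo = od_window[[1]],
                          od_hi = od_window[[2]])
    readr::write_tsv(as_tibble(gt), out("generation_times.tsv"))
    dx <- detect_first_phase_end(growth)
    readr::write_tsv(dx$summary, out("diauxie_summary.tsv"))
    readr::write_tsv(dx$aligned, out("diauxie_aligned.tsv"))
    written <- readr::read_tsv(out("generation_times.tsv"),
                               show_col_types = FALSE)
    report$stages$growth <- list(
      n_curves = nrow(written),
      generation_times = written,
      n_diauxic_detected = sum(dx$summary$detected),
      n_replicates_total = nrow(dx$summary))
  }

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (dmeomics", x$package_version, "),",
      x$timestamp, "\n")
  for (s in names(x$stages)) cat(" stage:", s, "\n")
  invisible(x)
}
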