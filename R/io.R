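#' Read and write the pipeline's plain-text table formats
#'
#' Probe tables are TSV with header `probe_id  feature_id  <array_id> ...`;
#' null probes carry the literal `NULL_PROBE` in `feature_id` on disk and are
#' represented as `NA` in memory. Design tables are TSV
#' (`array_id strain carbon replicate`). Peak tables and calibration
#' standards are CSV. Growth curves are a wide CSV (`time_h` plus one column
#' per well) accompanied by a plate-map CSV
#' (`well, strain, medium, replicate`).
#'
#' @param path File path.
#' @return `read_probe_table()` a probe tibble; `read_design_table()` a
#'   design tibble with the derived `experiment` column; `read_peak_table()`
#'   a peak tibble; `read_standards()` a standards tibble;
#'   `read_growth_curves()` a long growth tibble (`time_h`, `od`,
#'   `replicate`, `strain`, `medium`, `well`).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_probe_table <- function(path) {
  probes <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), feature_id = readr::col_character(),
    .default = readr::col_double()))
  mutate(probes,
         feature_id = if_else(.data$feature_id == "NULL_PROBE",
                              NA_character_, .data$feature_id))
}

#' @rdname pipeline_io
#' @param probes Probe tibble (see [quantile_normalize()]).
#' @export
write_probe_table <- function(probes, path) {
  probes |>
    mutate(feature_id = if_else(is.na(.data$feature_id), "NULL_PROBE",
                                .data$feature_id)) |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_design_table <- function(path) {
  design <- readr::read_tsv(path, col_types = readr::cols(
    array_id = readr::col_character(), strain = readr::col_character(),
    carbon = readr::col_character(), replicate = readr::col_integer()))
  ensure_experiment(design)
}

#' @rdname pipeline_io
#' @param design Design tibble (see [array_design()]).
#' @export
write_design_table <- function(design, path) {
  readr::write_tsv(select(design, "array_id", "strain", "carbon", "replicate"),
                   path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_peak_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), strain = readr::col_character(),
    condition = readr::col_character(), replicate = readr::col_integer(),
    compound = readr::col_character(),
    response_factor = readr::col_double()))
}

#' @rdname pipeline_io
#' @export
read_standards <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    concentration_uM = readr::col_double(), signal = readr::col_double()))
}

#' @rdname pipeline_io
#' @param plate_map Path to the plate-map CSV (`well, strain, medium,
#'   replicate`).
#' @export
read_growth_curves <- function(path, plate_map) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    time_h = readr::col_double(), .default = readr::col_double()))
  map <- readr::read_csv(plate_map, col_types = readr::cols(
    well = readr::col_character(), strain = readr::col_character(),
    medium = readr::col_character(), replicate = readr::col_integer()))
  wide |>
    tidyr::pivot_longer(-"time_h", names_to = "well", values_to = "od") |>
    inner_join(map, by = "well") |>
    arrange(.data$strain, .data$medium, .data$replicate, .data$time_h)
}

#' Write a differential-expression result table
#'
#' TSV with columns `feature_id, mean_a, mean_b, ratio, fold, direction, t,
#' df, p, significant, floored`; floats are written with 6 significant
#' digits.
#'
#' @param de A `de_result` tibble.
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  de |>
    as_tibble() |>
    mutate(across(c("mean_a", "mean_b", "ratio", "fold", "t", "p"),
                  ~ signif(.x, 6))) |>
    select("feature_id", "mean_a", "mean_b", "ratio", "fold", "direction",
           "t", "df", "p", "significant", "floored") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Write a complete synthetic fixture set
#'
#' Emits one coherent set of inputs for [run_pipeline()]: a probe table and
#' design (with spiked fold changes), a GC-MS peak table, growth curves with
#' plate map, an L-malate standard curve, and a `truth.json` recording the
#' generator's ground truth.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling all randomness.
#' @param n_features,n_spiked,spike_fold,noise_cv Probe-simulation knobs; by
#'   default 200 features of which 10 are spiked 5-fold in the `dme`
#'   succinate experiment, at measurement noise CV 0.15.
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_fixture_set <- function(dir, seed = 1L, n_features = 200L,
                                 n_spiked = 10L, spike_fold = 5,
                                 noise_cv = 0.15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- array_design(c("wt", "dme"), "succinate")
  feats <- sprintf("g%04d", seq_len(n_features))
  spiked <- feats[seq_len(n_spiked)]
  withr::with_seed(seed, {
    base_expr <- tibble(feature_id = feats,
                        expression = rlnorm(n_features, log(1000), 0.5))
  })
  truth <- probe_truth(
    base_expr, array_background = 100, n_null_probes = 300L,
    noise_cv = noise_cv,
    fold_spikes = tibble(feature_id = spiked, experiment = "dme_succinate",
                         fold = spike_fold))
  sim <- simulate_probe_data(design, truth, seed = seed)

  mtruth <- metabolite_truth(
    tidyr::expand_grid(compound = c("malate", "fumarate", "trehalose"),
                       strain = c("wt", "dme"), condition = "succinate") |>
      mutate(rrf = if_else(.data$strain == "dme" &
                             .data$compound != "trehalose", 2.0, 0.2)))
  peaks <- simulate_peak_table(mtruth, n_replicates = 3L, seed = seed + 1L)

  gtruth <- growth_truth("diauxic")
  growth <- purrr::imap(
    list(wt = 6, dme = 7),
    function(ps, s) {
      tr <- growth_truth("diauxic", pause_start = ps)
      simulate_growth_curves(tr, seq(0, 16, 0.25), n_replicates = 3L,
                             seed = seed + 2L, strain = s,
                             medium = "succinate_glucose")
    }) |> bind_rows()
  growth_wide <- growth |>
    mutate(well = paste0(.data$strain, "_w", .data$replicate)) |>
    tidyr::pivot_wider(id_cols = "time_h", names_from = "well",
                       values_from = "od")
  plate_map <- growth |>
    distinct(.data$strain, .data$medium, .data$replicate) |>
    mutate(well = paste0(.data$strain, "_w", .data$replicate)) |>
    select("well", "strain", "medium", "replicate")

  standards <- tibble(concentration_uM = c(0, 250, 500, 1000),
                      signal = c(0, 0.25, 0.5, 1.0))

  paths <- list(
    probe_table = file.path(dir, "probes.tsv"),
    design_table = file.path(dir, "design.tsv"),
    peak_table = file.path(dir, "peaks.csv"),
    growth_curves = file.path(dir, "growth.csv"),
    plate_map = file.path(dir, "plate_map.csv"),
    standards = file.path(dir, "standards.csv"),
    truth = file.path(dir, "truth.json"))
  write_probe_table(sim$probes, paths$probe_table)
  write_design_table(design, paths$design_table)
  readr::write_csv(peaks, paths$peak_table)
  readr::write_csv(growth_wide, paths$growth_curves)
  readr::write_csv(plate_map, paths$plate_map)
  readr::write_csv(standards, paths$standards)
  jsonlite::write_json(
    list(seed = seed,
         spiked_features = spiked, spike_fold = spike_fold,
         noise_cv = noise_cv,
         array_background = 100,
         feature_expression = sim$truth$feature_expression_resolved,
         true_rrf = mtruth$true_rrf,
         growth_pause_start = list(wt = 6, dme = 7)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
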