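#' Build a two-colour-free array design table
#'
#' Enumerates hybridized arrays for a strain-by-carbon-source experiment,
#' mirroring the layout of the mutant study this package re-implements:
#' every strain/carbon combination ("experiment") is hybridized on
#' `replicates` arrays (default 2, i.e. 6 experiments x 2 replicates = 12
#' arrays for 3 strains on 2 carbon sources).
#'
#' @param strains Character vector of strain labels (e.g. `c("wt", "dme")`).
#' @param carbons Character vector of carbon sources (e.g. `"succinate"`).
#' @param replicates Number of replicate arrays per experiment (>= 1).
#' @return A tibble with columns `array_id`, `strain`, `carbon`, `replicate`
#'   and the derived `experiment` label (`strain_carbon`).
#' @examples
#' array_design(c("wt", "dme"), "succinate")
#' @export
array_design <- function(strains, carbons, replicates = 2L) {
  assert_that(length(strains) >= 1 && length(carbons) >= 1,
              "need at least one strain and one carbon source")
  assert_that(replicates >= 1, "`replicates` must be >= 1")
  design <- tidyr::expand_grid(strain = strains, carbon = carbons,
                               replicate = seq_len(replicates)) |>
    mutate(
      experiment = paste(.data$strain, .data$carbon, sep = "_"),
      array_id = paste0(.data$experiment, "_r", .data$replicate)
    ) |>
    select("array_id", "strain", "carbon", "replicate", "experiment")
  assert_that(!anyDuplicated(design$array_id), "array ids must be unique")
  design
}

# attach the experiment label if a hand-built design table lacks it
ensure_experiment <- function(design) {
  assert_that(all(c("array_id", "strain", "carbon", "replicate") %in% names(design)),
              "design table needs columns array_id, strain, carbon, replicate")
  if (!"experiment" %in% names(design)) {
    design <- mutate(design,
                     experiment = paste(.data$strain, .data$carbon, sep = "_"))
  }
  as_tibble(design)
}

#' Ground truth for a simulated probe-intensity matrix
#'
#' Describes what the probe simulator should emit: true per-feature expression
#' (optionally per experiment), per-array additive background, probe counts,
#' noise level, and spiked fold changes. Expression and background must be
#' strictly positive; probe intensities are fluorescence-scale arbitrary units.
#'
#' @param feature_expression Either a tibble `(feature_id, expression)` giving
#'   one baseline per feature (recycled across experiments), or
#'   `(feature_id, experiment, expression)` for full control.
#' @param array_background A single positive background level applied to every
#'   array, or a tibble `(array_id, background)`.
#' @param probes_per_feature Probes targeting each feature (default 6, the
#'   minimum retained by the downstream non-redundant-probe filter).
#' @param n_null_probes Number of null probes (oligos matching no genomic
#'   sequence) used downstream for background estimation.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (default 0.15).
#' @param affinity_sdlog Log-sd of the per-probe lognormal affinity factor,
#'   drawn once per probe and reused on every array (default 0.25; 0 gives
#'   unit affinities).
#' @param fold_spikes Optional tibble `(feature_id, experiment, fold)` of true
#'   fold changes (>= 1) multiplied onto the baseline expression in the named
#'   experiment.
#' @return A `probe_truth` list, validated.
#' @export
probe_truth <- function(feature_expression, array_background,
                        probes_per_feature = 6L, n_null_probes = 300L,
                        noise_cv = 0.15, affinity_sdlog = 0.25,
                        fold_spikes = NULL) {
  feature_expression <- as_tibble(feature_expression)
  assert_that(all(c("feature_id", "expression") %in% names(feature_expression)),
              "feature_expression needs columns feature_id and expression")
  assert_that(all(is.finite(feature_expression$expression)) &&
                all(feature_expression$expression > 0),
              "feature expression must be strictly positive")
  if (is.data.frame(array_background)) {
    assert_that(all(c("array_id", "background") %in% names(array_background)),
                "array_background table needs columns array_id and background")
    assert_that(all(array_background$background > 0),
                "array background must be strictly positive")
  } else {
    assert_that(is.numeric(array_background) && length(array_background) == 1 &&
                  array_background > 0,
                "array background must be strictly positive")
  }
  assert_that(probes_per_feature >= 1, "probes_per_feature must be >= 1")
  assert_that(n_null_probes >= 0, "n_null_probes must be >= 0")
  assert_that(noise_cv >= 0, "noise_cv must be >= 0")
  assert_that(affinity_sdlog >= 0, "affinity_sdlog must be >= 0")
  if (!is.null(fold_spikes)) {
    fold_spikes <- as_tibble(fold_spikes)
    assert_that(all(c("feature_id", "experiment", "fold") %in% names(fold_spikes)),
                "fold_spikes needs columns feature_id, experiment, fold")
    assert_that(all(fold_spikes$fold >= 1), "spiked folds must be >= 1")
  }
  structure(
    list(feature_expression = feature_expression,
         array_background = array_background,
         probes_per_feature = as.integer(probes_per_feature),
         n_null_probes = as.integer(n_null_probes),
         noise_cv = noise_cv, affinity_sdlog = affinity_sdlog,
         fold_spikes = fold_spikes),
    class = "probe_truth"
  )
}

#' Simulate a probe-intensity matrix with recorded ground truth
#'
#' Generates the raw input of the microarray stage: for each feature,
#' `probes_per_feature` probes whose intensity is
#' `true expression x probe affinity x lognormal noise + array background`,
#' plus a population of null probes carrying `background x noise` only. Probe
#' affinities are drawn once per probe and shared across arrays, so quantile
#' normalization and per-feature medians behave as they do on real arrays.
#'
#' @param design Array design from [array_design()] (or a compatible tibble).
#' @param truth A [probe_truth()] object.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A list with `probes` (tibble: `probe_id`, `feature_id` — `NA` for
#'   null probes — and one intensity column per `array_id`) and `truth`, the
#'   input truth augmented with every drawn value (resolved per-experiment
#'   expression after spiking, per-array backgrounds, probe affinities).
#' @examples
#' d <- array_design(c("wt", "dme"), "succ")
#' tr <- probe_truth(tibble::tibble(feature_id = c("g1", "g2"),
#'                                  expression = c(500, 900)),
#'                   array_background = 100, n_null_probes = 20)
#' sim <- simulate_probe_data(d, tr, seed = 1)
#' dim(sim$probes)
#' @export
simulate_probe_data <- function(design, truth, seed) {
  assert_that(inherits(truth, "probe_truth"), "truth must come from probe_truth()")
  design <- ensure_experiment(design)
  experiments <- unique(design$experiment)

  fe <- truth$feature_expression
  if (!"experiment" %in% names(fe)) {
    fe <- tidyr::expand_grid(fe, experiment = experiments)
  }
  assert_that(all(experiments %in% fe$experiment),
              "feature_expression must cover every experiment in the design")
  if (!is.null(truth$fold_spikes)) {
    fe <- fe |>
      left_join(truth$fold_spikes, by = c("feature_id", "experiment")) |>
      mutate(expression = .data$expression * dplyr::coalesce(.data$fold, 1)) |>
      select(-"fold")
  }

  bg <- truth$array_background
  if (!is.data.frame(bg)) {
    bg <- tibble(array_id = design$array_id, background = bg)
  }
  assert_that(all(design$array_id %in% bg$array_id),
              "array_background must cover every array in the design")

  features <- unique(fe$feature_id)
  n_feat <- length(features)
  k <- truth$probes_per_feature

  withr::with_seed(seed, {
    affinities <- if (truth$affinity_sdlog == 0) {
      rep(1, n_feat * k)
    } else {
      rlnorm(n_feat * k, meanlog = -truth$affinity_sdlog^2 / 2,
             sdlog = truth$affinity_sdlog)
    }
    probe_tbl <- tibble(
      probe_id = paste0("p_", rep(features, each = k), "_", rep(seq_len(k), n_feat)),
      feature_id = rep(features, each = k),
      affinity = affinities
    )

    expr_mat <- fe |>
      tidyr::pivot_wider(names_from = "experiment", values_from = "expression")
    expr_lookup <- as.matrix(expr_mat[, -1, drop = FALSE])
    rownames(expr_lookup) <- expr_mat$feature_id

    intens <- matrix(0, nrow = n_feat * k + truth$n_null_probes,
                     ncol = nrow(design))
    colnames(intens) <- design$array_id
    bg_by_array <- setNames(bg$background, bg$array_id)
    for (j in seq_len(nrow(design))) {
      a <- design$array_id[j]
      mu <- expr_lookup[probe_tbl$feature_id, design$experiment[j]] *
        probe_tbl$affinity
      signal <- mu * rlnorm_cv(length(mu), truth$noise_cv) + bg_by_array[[a]]
      nulls <- bg_by_array[[a]] * rlnorm_cv(truth$n_null_probes, truth$noise_cv)
      intens[, j] <- c(signal, nulls)
    }
  })

  probes <- bind_rows(
    select(probe_tbl, "probe_id", "feature_id"),
    tibble(probe_id = sprintf("null_%04d", seq_len(truth$n_null_probes)),
           feature_id = NA_character_)
  ) |>
    bind_cols(as_tibble(intens))

  truth$feature_expression_resolved <- fe
  truth$array_background_resolved <- bg
  truth$probe_affinity <- select(probe_tbl, "probe_id", "feature_id", "affinity")
  list(probes = probes, truth = truth)
}

#' Ground truth for a simulated GC-MS peak table
#'
#' @param true_rrf Tibble `(compound, strain, condition, rrf)` of true relative
#'   response factors (>= 0, finite). The internal-standard name must not
#'   appear among the compounds.
#' @param replicate_cv Coefficient of variation of replicate-to-replicate
#'   multiplicative noise on compound response factors (default 0.1).
#' @param internal_standard_rf Response factor recorded for the internal
#'   standard in every sample (positive; default 1000).
#' @param internal_standard Internal-standard compound name (default
#'   `"ribitol"`).
#' @return A validated `metabolite_truth` list.
#' @export
metabolite_truth <- function(true_rrf, replicate_cv = 0.1,
                             internal_standard_rf = 1000,
                             internal_standard = "ribitol") {
  true_rrf <- as_tibble(true_rrf)
  assert_that(all(c("compound", "strain", "condition", "rrf") %in% names(true_rrf)),
              "true_rrf needs columns compound, strain, condition, rrf")
  assert_that(all(is.finite(true_rrf$rrf)) && all(true_rrf$rrf >= 0),
              "true RRFs must be finite and >= 0")
  assert_that(!internal_standard %in% true_rrf$compound,
              paste0("compound named like the internal standard ('",
                     internal_standard, "') is not allowed in true_rrf"))
  assert_that(replicate_cv >= 0, "replicate_cv must be >= 0")
  assert_that(internal_standard_rf > 0, "internal_standard_rf must be positive")
  structure(
    list(true_rrf = true_rrf, replicate_cv = replicate_cv,
         internal_standard_rf = internal_standard_rf,
         internal_standard = internal_standard),
    class = "metabolite_truth"
  )
}

#' Simulate a GC-MS peak table with a ribitol internal standard
#'
#' Each replicate culture yields one sample; every compound's response factor
#' is `true RRF x internal-standard RF x lognormal noise(replicate_cv)`, and
#' the internal-standard row is present in every sample at its nominal RF, so
#' [compute_rrf()] on noiseless output returns the true RRFs exactly.
#'
#' @param truth A [metabolite_truth()] object.
#' @param n_replicates Replicate cultures per strain/condition (default 3).
#' @param seed Integer seed.
#' @return A peak-table tibble: `sample_id`, `strain`, `condition`,
#'   `replicate`, `compound`, `response_factor`.
#' @export
simulate_peak_table <- function(truth, n_replicates = 3L, seed = 1L) {
  assert_that(inherits(truth, "metabolite_truth"),
              "truth must come from metabolite_truth()")
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  samples <- truth$true_rrf |>
    distinct(.data$strain, .data$condition) |>
    tidyr::expand_grid(replicate = seq_len(n_replicates)) |>
    mutate(sample_id = paste(.data$strain, .data$condition,
                             paste0("r", .data$replicate), sep = "_"))
  peaks <- samples |>
    inner_join(truth$true_rrf, by = c("strain", "condition"),
               relationship = "many-to-many")
  withr::with_seed(seed, {
    peaks <- peaks |>
      mutate(response_factor = .data$rrf * truth$internal_standard_rf *
               rlnorm_cv(n(), truth$replicate_cv))
  })
  is_rows <- samples |>
    mutate(compound = truth$internal_standard,
           response_factor = truth$internal_standard_rf)
  bind_rows(select(peaks, "sample_id", "strain", "condition", "replicate",
                   "compound", "response_factor"),
            select(is_rows, "sample_id", "strain", "condition", "replicate",
                   "compound", "response_factor")) |>
    arrange(.data$sample_id, .data$compound)
}

#' Ground truth for a simulated growth curve
#'
#' Monophasic curves follow logistic growth with rate `mu1` and carrying
#' capacity `od_max` (`od_max = Inf` gives pure exponential growth). Diauxic
#' curves grow exponentially at `mu1` until `pause_start`, hold flat for
#' `pause_duration` (the inter-phase pause), then resume at `mu2`, capped at
#' `od_max`.
#'
#' @param model `"monophasic"` or `"diauxic"`.
#' @param od0 Initial OD600 (> 0; default 0.05).
#' @param mu1 First-phase specific growth rate, 1/h (default `log(2)/2`, i.e.
#'   a 2 h doubling time).
#' @param pause_start,pause_duration Diauxic pause onset and length, h.
#' @param mu2 Second-phase rate, 1/h (diauxic only).
#' @param od_max Carrying capacity (> od0; may be `Inf`).
#' @param noise_cv Multiplicative noise CV per point per replicate
#'   (default 0.02).
#' @return A validated `growth_truth` list.
#' @export
growth_truth <- function(model = c("monophasic", "diauxic"), od0 = 0.05,
                         mu1 = log(2) / 2, pause_start = 6, pause_duration = 3,
                         mu2 = log(2) / 3, od_max = 1.5, noise_cv = 0.02) {
  model <- match.arg(model)
  assert_that(od0 > 0, "od0 must be positive")
  assert_that(mu1 > 0, "mu1 must be positive")
  assert_that(od_max > od0, "od_max must exceed od0")
  assert_that(noise_cv >= 0, "noise_cv must be >= 0")
  if (model == "diauxic") {
    assert_that(pause_start > 0 && pause_duration >= 0 && mu2 > 0,
                "diauxic model needs pause_start > 0 and mu2 > 0")
  }
  structure(list(model = model, od0 = od0, mu1 = mu1,
                 pause_start = pause_start, pause_duration = pause_duration,
                 mu2 = mu2, od_max = od_max, noise_cv = noise_cv),
            class = "growth_truth")
}

# deterministic OD600 trajectory for a growth_truth at times t
growth_model_od <- function(truth, t) {
  if (truth$model == "monophasic") {
    od <- if (is.infinite(truth$od_max)) {
      truth$od0 * exp(truth$mu1 * t)
    } else {
      K <- truth$od_max
      K / (1 + (K - truth$od0) / truth$od0 * exp(-truth$mu1 * t))
    }
  } else {
    t1 <- truth$pause_start
    t2 <- truth$pause_start + truth$pause_duration
    od_p <- truth$od0 * exp(truth$mu1 * t1)
    od <- ifelse(t < t1, truth$od0 * exp(truth$mu1 * t),
                 ifelse(t < t2, od_p, od_p * exp(truth$mu2 * (t - t2))))
    od <- pmin(od, truth$od_max)
  }
  od
}

#' Simulate replicate plate-reader growth curves
#'
#' @param truth A [growth_truth()] object.
#' @param t_grid Strictly increasing sampling times, h.
#' @param n_replicates Replicate wells (default 3, mirroring triplicate
#'   cultures).
#' @param seed Integer seed.
#' @param strain,medium Labels carried on the output.
#' @return A growth-curve tibble: `time_h`, `od`, `replicate`, `strain`,
#'   `medium`.
#' @examples
#' tr <- growth_truth("monophasic", od_max = Inf, noise_cv = 0)
#' gc <- simulate_growth_curves(tr, seq(0, 8, 0.5), seed = 1)
#' @export
simulate_growth_curves <- function(truth, t_grid, n_replicates = 3L, seed = 1L,
                                   strain = "wt", medium = "medium") {
  assert_that(inherits(truth, "growth_truth"), "truth must come from growth_truth()")
  assert_that(length(t_grid) > 0, "t_grid must not be empty")
  assert_that(all(diff(t_grid) > 0), "t_grid must be strictly increasing")
  base <- growth_model_od(truth, t_grid)
  withr::with_seed(seed, {
    curves <- purrr::map(seq_len(n_replicates), function(r) {
      tibble(time_h = t_grid,
             od = base * rlnorm_cv(length(t_grid), truth$noise_cv),
             replicate = r)
    }) |> bind_rows()
  })
  mutate(curves, strain = strain, medium = medium)
}
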