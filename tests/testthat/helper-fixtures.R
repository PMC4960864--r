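# small in-code fixtures shared across test files

# replicate-level corrected expression table for DE tests
make_feature_expr <- function(values_a, values_b, feature_id = "f1",
                              exp_a = "A", exp_b = "B", floored = FALSE) {
  expr <- tibble::tibble(
    feature_id = feature_id,
    array_id = c(paste0("a", seq_along(values_a)),
                 paste0("b", seq_along(values_b))),
    experiment = c(rep(exp_a, length(values_a)), rep(exp_b, length(values_b))),
    replicate = c(seq_along(values_a), seq_along(values_b)),
    value = c(values_a, values_b),
    floored = floored)
  class(expr) <- c("feature_expr", class(expr))
  expr
}

# probe table with two features and some null probes, constant intensities
make_probe_table <- function(arrays = c("a1", "a2"), n_null = 3) {
  vals <- tibble::tibble(
    probe_id = c(paste0("pf1_", 1:6), paste0("pf2_", 1:6),
                 paste0("null_", seq_len(n_null))),
    feature_id = c(rep("f1", 6), rep("f2", 6), rep(NA_character_, n_null)))
  for (a in arrays) vals[[a]] <- seq_len(nrow(vals)) * 10
  vals
}

# spike-in DE recovery experiment: n_null_features true-fold-1 features plus
# n_spiked features at spike_fold in experiment "dme_succ", full pipeline
# (quantile normalization included when noise is present)
run_spike_sim <- function(seed, noise_cv = 0.15, n_null_features = 1000,
                          n_spiked = 20, spike_fold = 5, normalize = TRUE) {
  design <- array_design(c("wt", "dme"), "succ")
  feats <- sprintf("g%04d", seq_len(n_null_features + n_spiked))
  spiked <- feats[seq_len(n_spiked)]
  base_expr <- withr::with_seed(seed * 1000L, {
    tibble::tibble(feature_id = feats,
                   expression = stats::rlnorm(length(feats), log(1000), 0.5))
  })
  truth <- probe_truth(
    base_expr, array_background = 100, n_null_probes = 300L,
    noise_cv = noise_cv,
    affinity_sdlog = if (noise_cv == 0) 0 else 0.25,
    fold_spikes = tibble::tibble(feature_id = spiked,
                                 experiment = "dme_succ",
                                 fold = spike_fold))
  sim <- simulate_probe_data(design, truth, seed = seed)
  probes <- if (normalize) quantile_normalize(sim$probes) else sim$probes
  cfg <- de_config()
  bg <- estimate_background(probes, cfg)
  expr <- feature_expression(probes, bg, design, cfg)
  de <- differential_expression(expr, "dme_succ", "wt_succ", cfg)
  list(de = de, spiked = spiked, truth = sim$truth, design = design,
       probes = probes)
}
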