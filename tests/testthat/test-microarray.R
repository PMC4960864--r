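test_that("quantile normalization matches the rank-average oracle", {
  p <- tibble::tibble(probe_id = paste0("p", 1:4), feature_id = "g1",
                      A = c(2, 4, 6, 8), B = c(1, 3, 5, 7))
  out <- quantile_normalize(p)
  expect_equal(out$A, c(1.5, 3.5, 5.5, 7.5))
  expect_equal(out$B, c(1.5, 3.5, 5.5, 7.5))
  # rank order within columns is preserved under shuffling
  ps <- p[c(3, 1, 4, 2), ]
  outs <- quantile_normalize(ps)
  expect_equal(outs$A, c(5.5, 1.5, 7.5, 3.5))
})

test_that("quantile normalization is idempotent and distribution-equalizing", {
  probes <- make_probe_table()
  probes$a1 <- probes$a1 * 3 + 17
  probes$a2 <- probes$a2^1.2
  once <- quantile_normalize(probes)
  expect_equal(sort(once$a1), sort(once$a2))
  twice <- quantile_normalize(once)
  expect_equal(twice, once)
  # identical columns and single columns pass through unchanged
  same <- make_probe_table()
  expect_equal(quantile_normalize(same), same)
  single <- same[c("probe_id", "feature_id", "a1")]
  expect_equal(quantile_normalize(single), single)
})

test_that("tied values receive the mean of the reference values they span", {
  p <- tibble::tibble(probe_id = paste0("p", 1:3), feature_id = "g",
                      A = c(5, 5, 5), B = c(1, 2, 3))
  out <- quantile_normalize(p)
  ref <- (sort(p$A) + sort(p$B)) / 2           # c(3, 3.5, 4)
  expect_equal(out$A, rep(mean(ref), 3))
  expect_equal(out$B, ref)
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  probes <- make_probe_table(arrays = c("a1", "a2", "a3"))
  set.seed(42)
  for (a in c("a1", "a2", "a3")) {
    probes[[a]] <- stats::rlnorm(nrow(probes), log(500), 0.6)
  }
  ours <- quantile_normalize(probes)
  theirs <- limma::normalizeQuantiles(as.matrix(probes[c("a1", "a2", "a3")]))
  expect_equal(as.matrix(ours[c("a1", "a2", "a3")]), theirs,
               ignore_attr = TRUE)
})

test_that("missing intensities are rejected", {
  probes <- make_probe_table()
  probes$a1[2] <- NA
  expect_error(quantile_normalize(probes), "missing")
})

test_that("feature filter counts distinct probes only", {
  probes <- make_probe_table()                 # f1, f2 with 6 probes each
  expect_equal(filter_features(probes), c("f1", "f2"))
  # dropping one probe of f2 leaves it below the threshold
  expect_equal(filter_features(probes[-7, ]), "f1")
  # a duplicated probe_id row does not rescue the count
  dup <- dplyr::bind_rows(probes[-7, ], probes[8, ])
  expect_equal(filter_features(dup), "f1")
  # but an extra distinct probe does
  extra <- probes[-7, ]
  extra <- dplyr::bind_rows(
    extra, dplyr::mutate(probes[8, ], probe_id = "pf2_new"))
  expect_equal(filter_features(extra), c("f1", "f2"))
  expect_equal(filter_features(probes[0, ]), character())
})

test_that("background is the per-array null-probe median", {
  probes <- make_probe_table(n_null = 5)
  probes$a1[13:17] <- c(1, 2, 3, 4, 100)       # outlier-robust median
  probes$a2[13:17] <- 7
  bg <- estimate_background(probes)
  expect_equal(bg$background[bg$array_id == "a1"], 3)
  expect_equal(bg$background[bg$array_id == "a2"], 7)
  # mean variant behind the config switch
  bg_mean <- estimate_background(probes, de_config(background_stat = "mean"))
  expect_equal(bg_mean$background[bg_mean$array_id == "a1"], 22)
  no_nulls <- dplyr::filter(probes, !is.na(feature_id))
  expect_error(estimate_background(no_nulls), "null probes")
})

test_that("feature expression is the background-corrected median, floored", {
  design <- tibble::tibble(array_id = c("a1", "a2"), strain = "wt",
                           carbon = "succ", replicate = 1:2)
  probes <- tibble::tibble(
    probe_id = c(paste0("p", 1:3), paste0("q", 1:4), "n1"),
    feature_id = c(rep("f1", 3), rep("f2", 4), NA),
    a1 = c(10, 20, 30, 10, 20, 30, 40, 5),
    a2 = c(3, 3, 3, 10, 20, 30, 40, 10))
  bg <- estimate_background(probes)
  expr <- feature_expression(probes, bg, design, de_config(),
                             features = c("f1", "f2"))
  val <- function(f, a) expr$value[expr$feature_id == f & expr$array_id == a]
  expect_equal(val("f1", "a1"), 15)            # odd count: 20 - 5
  expect_equal(val("f2", "a1"), 20)            # even count: 25 - 5
  expect_equal(val("f1", "a2"), 1)             # 3 - 10 floored at 1
  expect_true(expr$floored[expr$feature_id == "f1" & expr$array_id == "a2"])
  expect_equal(val("f2", "a2"), 15)
  # array missing from the design is an error
  expect_error(feature_expression(probes, bg, design[1, ], de_config(),
                                  features = "f1"),
               "design")
})

test_that("adding a constant to one array shifts background, not expression", {
  design <- array_design("wt", "succ")
  truth <- probe_truth(tibble::tibble(feature_id = sprintf("g%02d", 1:20),
                                      expression = 500),
                       array_background = 100, n_null_probes = 50,
                       noise_cv = 0.1)
  sim <- simulate_probe_data(design, truth, seed = 3)
  probes <- sim$probes
  shifted <- dplyr::mutate(probes, wt_succ_r1 = wt_succ_r1 + 250)
  bg0 <- estimate_background(probes)
  bg1 <- estimate_background(shifted)
  expect_equal(bg1$background[bg1$array_id == "wt_succ_r1"],
               bg0$background[bg0$array_id == "wt_succ_r1"] + 250)
  e0 <- feature_expression(probes, bg0, design)
  e1 <- feature_expression(shifted, bg1, design)
  expect_equal(e1$value, e0$value)
})

test_that("differential expression matches the closed-form t oracle", {
  expr <- make_feature_expr(c(10, 12), c(2, 4))
  de <- differential_expression(expr, "A", "B")
  expect_equal(de$ratio, 11 / 3, tolerance = 1e-12)
  expect_equal(de$t, 8 / sqrt(2), tolerance = 1e-12)
  expect_equal(de$df, 2)
  # analytic t CDF for df = 2: F(t) = 1/2 (1 + t / sqrt(t^2 + 2))
  t <- 8 / sqrt(2)
  p_analytic <- 2 * (1 - 0.5 * (1 + t / sqrt(t^2 + 2)))
  expect_equal(de$p, p_analytic, tolerance = 1e-12)
  expect_equal(round(de$p, 4), 0.0299)
  expect_true(de$significant)
})

test_that("significance requires both the fold and the p threshold", {
  # fold 2.9 with tiny p: fails the fold gate
  expr <- make_feature_expr(c(2.9, 2.9001), c(1, 1.0001))
  de <- differential_expression(expr, "A", "B")
  expect_lt(de$p, 0.01)
  expect_false(de$significant)
  # fold >= 3 but p too large: also not significant
  expr2 <- make_feature_expr(c(1, 9), c(0.5, 2))
  de2 <- differential_expression(expr2, "A", "B")
  expect_gte(de2$fold, 3)
  expect_gt(de2$p, 0.05)
  expect_false(de2$significant)
})

test_that("degenerate variance cases follow the documented convention", {
  same <- make_feature_expr(c(5, 5), c(5, 5))
  de <- differential_expression(same, "A", "B")
  expect_equal(de$ratio, 1)
  expect_equal(de$t, 0)
  expect_equal(de$p, 1)
  expect_false(de$significant)
  apart <- make_feature_expr(c(9, 9), c(3, 3))
  de2 <- differential_expression(apart, "A", "B")
  expect_true(de2$degenerate)
  expect_equal(de2$p, 0)
  expect_true(de2$significant)                  # fold 3 exactly, p 0
})

test_that("swapping experiments inverts the ratio and negates t", {
  expr <- make_feature_expr(c(10, 12), c(2, 4))
  ab <- differential_expression(expr, "A", "B")
  ba <- differential_expression(expr, "B", "A")
  expect_equal(ba$ratio, 1 / ab$ratio)
  expect_equal(ba$fold, ab$fold)
  expect_equal(ba$t, -ab$t)
  expect_equal(ba$p, ab$p)
  expect_equal(ba$direction, "down")
})

test_that("fewer than two replicates per experiment is an error", {
  expr <- make_feature_expr(10, c(2, 4))
  expect_error(differential_expression(expr, "A", "B"), "2 replicate")
})

test_that("category summary tallies significant calls with a Total row", {
  de <- tibble::tibble(
    feature_id = c("f1", "f2", "f3", "f4"),
    direction = c("up", "up", "up", "down"),
    significant = c(TRUE, TRUE, TRUE, FALSE))
  cats <- tibble::tibble(
    feature_id = c("f1", "f2", "f3", "f4"),
    category = c("Transport system", "Transport system",
                 "Hypothetical protein", "Energy metabolism"))
  out <- summarize_by_category(de, cats)
  expect_equal(out$n_up[out$category == "Transport system"], 2)
  expect_equal(out$n_up[out$category == "Hypothetical protein"], 1)
  expect_equal(out$n_up[out$category == "Total"], 3)
  expect_equal(out$n_down[out$category == "Total"], 0)
  tot <- dplyr::filter(out, category == "Total")
  body <- dplyr::filter(out, category != "Total")
  expect_equal(tot$n_up, sum(body$n_up))
  expect_equal(tot$n_down, sum(body$n_down))
  # empty significant set gives all zeros
  none <- summarize_by_category(dplyr::mutate(de, significant = FALSE), cats)
  expect_true(all(none$n_up == 0) && all(none$n_down == 0))
})

test_that("category summary validates its vocabulary and coverage", {
  de <- tibble::tibble(feature_id = "f1", direction = "up",
                       significant = TRUE)
  expect_error(summarize_by_category(
    de, tibble::tibble(feature_id = "f1", category = "Not a category")),
    "vocabulary")
  expect_error(summarize_by_category(
    de, tibble::tibble(feature_id = "other", category = "Transport system")),
    "missing")
  # unknowns allowed only with an explicit default
  out <- summarize_by_category(
    de, tibble::tibble(feature_id = "other", category = "Transport system"),
    default_category = "Hypothetical protein")
  expect_equal(out$n_up[out$category == "Hypothetical protein"], 1)
})

test_that("clustering joins the correlated pair first and serializes", {
  set.seed(5)
  base <- stats::rlnorm(60, log(500), 0.8)
  expr <- dplyr::bind_rows(
    tibble::tibble(feature_id = sprintf("g%02d", 1:60), experiment = "e1",
                   value = base),
    tibble::tibble(feature_id = sprintf("g%02d", 1:60), experiment = "e2",
                   value = base * stats::rlnorm(60, 0, 0.05)),
    tibble::tibble(feature_id = sprintf("g%02d", 1:60), experiment = "e3",
                   value = sample(base)))
  expr$array_id <- paste0(expr$experiment, "_a")
  expr$replicate <- 1L
  expr$floored <- FALSE
  cl <- cluster_experiments(expr)
  merged_first <- cl$hclust$labels[-cl$hclust$merge[1, ]]
  expect_setequal(merged_first, c("e1", "e2"))
  expect_true(all(diff(cl$hclust$height) >= 0))
  nwk <- as_newick(cl)
  expect_match(nwk, "^\\(")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("e1", "e2", "e3"))
  # identical profiles merge at height zero
  dup <- dplyr::bind_rows(expr, dplyr::mutate(
    dplyr::filter(expr, experiment == "e1"), experiment = "e0"))
  cl0 <- cluster_experiments(dup)
  expect_equal(min(cl0$hclust$height), 0, tolerance = 1e-12)
})

test_that("constant profiles and single experiments are rejected", {
  expr <- tibble::tibble(feature_id = c("g1", "g2"), experiment = "e1",
                         array_id = "a1", replicate = 1L,
                         value = c(5, 5), floored = FALSE)
  expect_error(cluster_experiments(expr), "two experiments")
  both <- dplyr::bind_rows(expr, dplyr::mutate(expr, experiment = "e2",
                                               value = c(1, 2)))
  expect_error(cluster_experiments(both), "zero variance")
})

test_that("carbon-source effect dominates the root split on synthetic data", {
  design <- array_design(c("wt", "dme"), c("glc", "succ"))
  feats <- sprintf("g%03d", 1:120)
  base <- withr::with_seed(9, stats::rlnorm(120, log(800), 0.7))
  carbon_eff <- withr::with_seed(10, stats::rlnorm(120, 0, 1.0))
  strain_eff <- withr::with_seed(11, stats::rlnorm(120, 0, 0.1))
  fe <- tidyr::expand_grid(feature_id = feats,
                           experiment = unique(design$experiment)) |>
    dplyr::mutate(
      expression = base[match(feature_id, feats)] *
        ifelse(grepl("succ", experiment),
               carbon_eff[match(feature_id, feats)], 1) *
        ifelse(grepl("dme", experiment),
               strain_eff[match(feature_id, feats)], 1))
  truth <- probe_truth(fe, array_background = 100, n_null_probes = 100,
                       noise_cv = 0.05)
  sim <- simulate_probe_data(design, truth, seed = 21)
  probes <- quantile_normalize(sim$probes)
  bg <- estimate_background(probes)
  expr <- feature_expression(probes, bg, design)
  cl <- cluster_experiments(expr)
  # the deepest split separates glucose from succinate experiments
  sides <- split(cl$hclust$labels, stats::cutree(cl$hclust, 2))
  expect_true(all(vapply(sides, function(s)
    all(grepl("glc", s)) || all(grepl("succ", s)), logical(1))))
  expect_equal(length(unlist(sides)), 4)
})
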