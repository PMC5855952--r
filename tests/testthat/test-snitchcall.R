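norm_prof <- function(values, positions = seq_along(values)) {
  tibble::tibble(position = positions, normalized_reactivity = values)
}

test_that("identical profiles give r = 1, eSDC = 0, nothing changed", {
  set.seed(41)
  v <- rgamma(101, 2, 1.5)
  p <- norm_prof(v)
  f <- compare_profiles(p, p, variant = 51, window_halfwidth = 50)
  expect_equal(f$pearson_r, 1)
  expect_equal(f$esdc, 0)
  expect_equal(f$n_changed, 0L)
  expect_equal(f$n_compared, 100L)  # variant position excluded
})

test_that("a mean-centred negation gives r = -1 and eSDC = 2 sqrt(n)", {
  set.seed(42)
  v <- rnorm(101)
  v <- v - mean(v)
  f <- compare_profiles(norm_prof(v), norm_prof(-v), variant = 51)
  expect_equal(f$pearson_r, -1)
  expect_equal(f$esdc, 2 * sqrt(f$n_compared))
})

test_that("features on the packaged fixture match direct formula recomputation", {
  fx <- read.delim(system.file("extdata", "compare_fixture_100.tsv",
                               package = "shapesorter"))
  vp <- 50L
  f <- compare_profiles(norm_prof(fx$ref, fx$position),
                        norm_prof(fx$alt, fx$position), vp,
                        window_halfwidth = 50, change_threshold = 0.5)
  keep <- fx$position != vp & abs(fx$position - vp) <= 50
  r_exp <- cor(fx$ref[keep], fx$alt[keep])
  delta <- fx$alt[keep] - fx$ref[keep]
  expect_equal(f$pearson_r, r_exp)
  expect_equal(f$spearman_rho, cor(fx$ref[keep], fx$alt[keep], method = "spearman"))
  expect_equal(f$esdc, (1 - r_exp) * sqrt(sum(keep)))
  expect_equal(f$max_abs_delta, max(abs(delta)))
  expect_equal(f$n_changed, sum(abs(delta) >= 0.5))
  expect_equal(f$signed_area_before, sum(delta[fx$position[keep] < vp]))
  expect_equal(f$signed_area_after, sum(delta[fx$position[keep] > vp]))
})

test_that("comparison requires at least 10 shared positions", {
  p <- norm_prof(c(rep(NA, 45), rgamma(8, 2), rep(NA, 48)))
  expect_error(compare_profiles(p, p, 51), class = "shapesorter_input_error")
})

test_that("eSDC follows its scale law: quadrupling n doubles eSDC at fixed r", {
  set.seed(43)
  a <- rnorm(25); b <- 0.6 * a + rnorm(25, 0, 0.5)
  a4 <- rep(a, 4); b4 <- rep(b, 4)
  f1 <- compare_profiles(norm_prof(c(a, NA), positions = 1:26),
                         norm_prof(c(b, NA), positions = 1:26), 26,
                         window_halfwidth = 26)
  f4 <- compare_profiles(norm_prof(c(a4, NA), positions = 1:101),
                         norm_prof(c(b4, NA), positions = 1:101), 101,
                         window_halfwidth = 101)
  expect_equal(f4$pearson_r, f1$pearson_r)
  expect_equal(f4$esdc, 2 * f1$esdc, tolerance = 1e-10)
})

test_that("classification calls the trivial cases correctly", {
  set.seed(44)
  v <- rgamma(101, 2, 1.5)
  self <- compare_profiles(norm_prof(v), norm_prof(v), 51)
  expect_equal(classify(self)$label, "nonchanger")

  planted <- v
  planted[60:74] <- planted[60:74] + 2
  f <- compare_profiles(norm_prof(v), norm_prof(planted), 51)
  expect_equal(classify(f)$label, "riboSNitch")

  expect_error(classify(f, model = NULL), class = "shapesorter_input_error")
})

test_that("pure replicate noise is called nonchanger in >= 90% of seeds", {
  calls <- vapply(1:100, function(s) {
    set.seed(s)
    f <- shapesorter:::simulate_comparison_features(
      changer = FALSE, effect_size = 0, block_width = 10, noise_sd = 0.1)
    classify(f)$label
  }, "")
  expect_gte(mean(calls == "nonchanger"), 0.9)
})

test_that("training refuses degenerate effect grids and is reproducible", {
  expect_error(train_on_synthetic(effect_sizes = c(0, 0)),
               class = "shapesorter_input_error")
  expect_error(train_on_synthetic(n_changers = 10),
               class = "shapesorter_input_error")

  m1 <- train_on_synthetic(n_changers = 50, n_nonchangers = 50, seed = 7)
  m2 <- train_on_synthetic(n_changers = 50, n_nonchangers = 50, seed = 7)
  expect_identical(serialize(m1$forest$forest, NULL),
                   serialize(m2$forest$forest, NULL))

  f <- tempfile(fileext = ".rds")
  write_snitch_model(m1, f)
  expect_identical(read_snitch_model(f)$type, "rf")
})

test_that("a trained model calls a self-comparison nonchanger", {
  m <- train_on_synthetic(n_changers = 50, n_nonchangers = 50, seed = 8)
  set.seed(45)
  v <- rgamma(101, 2, 1.5)
  f <- compare_profiles(norm_prof(v), norm_prof(v), 51)
  expect_equal(classify(f, m)$label, "nonchanger")
})

test_that("ratiometric split uses largest-remainder sizes on read pairs", {
  reads <- tibble::tibble(qname = rep(sprintf("p%04d", 1:1000), each = 2),
                          mate = rep(1:2, 1000), pos = 1L, cigar = "5M",
                          seq = "AAAAA", qual = "IIIII")
  sp <- ratiometric_split(reads, c(0.75, 0.25), seed = 9)
  expect_equal(length(unique(sp[[1]]$qname)), 750)
  expect_equal(length(unique(sp[[2]]$qname)), 250)
  expect_length(intersect(sp[[1]]$qname, sp[[2]]$qname), 0)
  expect_equal(sort(c(unique(sp[[1]]$qname), unique(sp[[2]]$qname))),
               sort(unique(reads$qname)))

  reads999 <- reads[reads$qname != "p1000", ]
  sp2 <- ratiometric_split(reads999, c(0.75, 0.25), seed = 10)
  expect_equal(length(unique(sp2[[1]]$qname)), 749)
  expect_equal(length(unique(sp2[[2]]$qname)), 250)

  expect_error(ratiometric_split(reads, c(1, 0)), class = "shapesorter_input_error")
  expect_error(ratiometric_split(reads[1:10, ], c(0.5, 0.5)),
               class = "shapesorter_input_error")
})

test_that("ratiometric subsets preserve per-position mutation rates", {
  scn <- e2e_scenario(depth = 3000, seed = 46)
  sp <- ratiometric_split(scn$treated$reads, c(0.75, 0.25), seed = 11)
  full <- count_mutations(scn$treated$reads, scn$reference)
  sub <- count_mutations(sp[[2]], scn$reference)
  keep <- full$effective_depth > 500 & sub$effective_depth > 100
  p_full <- full$mutation_events[keep] / full$effective_depth[keep]
  p_sub <- sub$mutation_events[keep] / sub$effective_depth[keep]
  se <- sqrt(pmax(p_full, 1e-4) * (1 - p_full) / sub$effective_depth[keep])
  expect_gte(mean(abs(p_sub - p_full) <= 3.5 * se), 0.95)
})

test_that("roc_auc matches the rank identity on edge cases and random data", {
  r <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "shapesorter_input_error")

  set.seed(47)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("roc curve starts at (0,0), ends at (1,1) and is monotone", {
  set.seed(48)
  r <- roc_auc(runif(50), runif(50) < 0.4)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(dplyr::last(r$curve$fpr), 1)
  expect_equal(dplyr::last(r$curve$tpr), 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_s3_class(glance(r), "tbl_df")
})

test_that("random scores give AUC near 0.5 (Mann-Whitney equivalence)", {
  set.seed(49)
  scores <- runif(2000)
  labels <- rep(c(TRUE, FALSE), 1000)
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.03)
})

test_that("evaluate_designs separates perfectly in the noiseless limit", {
  ev <- evaluate_designs(n_changers = 10, n_nonchangers = 10,
                         effect_size = 2, replicate_noise_sd = 0,
                         depth = 50000, seed = 12)
  expect_equal(ev$auc$auc[ev$auc$design == "within_sample"], 1.0)
  expect_equal(ev$auc$auc[ev$auc$design == "between_replicate"], 1.0)
  expect_error(evaluate_designs(n_changers = 1, n_nonchangers = 1),
               class = "shapesorter_input_error")
})

test_that("within-sample design beats between-replicate under replicate noise", {
  gaps <- vapply(1:5, function(s) {
    ev <- evaluate_designs(n_changers = 20, n_nonchangers = 20,
                           effect_size = 1.5, replicate_noise_sd = 0.3,
                           depth = 3000, seed = s)
    ev$auc$auc[ev$auc$design == "within_sample"] -
      ev$auc$auc[ev$auc$design == "between_replicate"]
  }, 0)
  expect_gt(mean(gaps), 0)
})

test_that("calibrated thresholds keep the null false-call rate at target", {
  set.seed(50)
  null_scores <- runif(500)
  thr <- calibrate_threshold(null_scores, fpr = 0.10)
  expect_lte(mean(null_scores >= thr), 0.10)
})
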