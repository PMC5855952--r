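#' Compare two aligned reactivity profiles around a variant
#'
#' Computes the feature vector used for riboSNitch classification over the
#' positions that are non-missing in both profiles, within
#' `window_halfwidth` nt of the variant, excluding the variant position
#' itself (sorting consumes its base identity). Features include the Pearson
#' and Spearman correlations, the structural disruption coefficient
#' eSDC = (1 - r) * sqrt(n), and local-change summaries of the reactivity
#' difference (alt - ref).
#'
#' @param profile_ref,profile_alt Profile tibbles carrying `position` and
#'   `normalized_reactivity`.
#' @param variant A [variant_spec()] or a single 1-based position.
#' @param window_halfwidth Half-width of the analysis window in nt
#'   (default 50, i.e. ~100 nt around the mutation).
#' @param change_threshold Absolute normalized-reactivity difference that
#'   counts a position as changed (default 0.5 normalized SHAPE units).
#' @return A one-row tibble of class `snitch_features`: `pearson_r`,
#'   `spearman_rho`, `esdc`, `n_compared`, `max_abs_delta`, `n_changed`,
#'   `longest_changed_run`, `signed_area_before`, `signed_area_after`.
#' @export
compare_profiles <- function(profile_ref, profile_alt, variant,
                             window_halfwidth = 50L, change_threshold = 0.5) {
  vp <- if (is.numeric(variant)) as.integer(variant[1]) else {
    as_variant_spec(variant)$position
  }
  merged <- dplyr::inner_join(
    select(profile_ref, "position", ref = "normalized_reactivity"),
    select(profile_alt, "position", alt = "normalized_reactivity"),
    by = "position"
  ) |>
    filter(abs(.data$position - vp) <= window_halfwidth,
           .data$position != vp,
           !is.na(.data$ref), !is.na(.data$alt)) |>
    arrange(.data$position)
  n <- nrow(merged)
  if (n < 10) {
    stop_input("insufficient overlap: only %d shared non-missing positions", n)
  }
  r <- suppressWarnings(cor(merged$ref, merged$alt, method = "pearson"))
  rho <- suppressWarnings(cor(merged$ref, merged$alt, method = "spearman"))
  delta <- merged$alt - merged$ref
  changed <- abs(delta) >= change_threshold
  # runs must be contiguous in transcript coordinates, not merely adjacent
  # among the compared positions
  full <- rep(FALSE, 2L * window_halfwidth + 1L)
  full[merged$position - vp + window_halfwidth + 1L] <- changed
  runs <- rle(full)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  out <- tibble(
    pearson_r = r,
    spearman_rho = rho,
    esdc = (1 - r) * sqrt(n),
    n_compared = n,
    max_abs_delta = max(abs(delta)),
    n_changed = sum(changed),
    longest_changed_run = as.integer(longest),
    signed_area_before = sum(delta[merged$position < vp]),
    signed_area_after = sum(delta[merged$position > vp])
  )
  class(out) <- c("snitch_features", class(out))
  out
}

FEATURE_COLS <- c("pearson_r", "spearman_rho", "esdc", "max_abs_delta",
                  "n_changed", "longest_changed_run",
                  "signed_area_before", "signed_area_after")

#' Threshold-rule riboSNitch model
#'
#' A transparent model scoring a comparison by its eSDC alone: the score is
#' `esdc / (esdc + esdc_threshold)`, which is monotone in the disruption and
#' crosses the 0.5 decision boundary exactly at `esdc_threshold`.
#'
#' @param esdc_threshold eSDC at which a comparison is called a riboSNitch.
#' @return A model object of class `snitch_model`.
#' @export
snitch_threshold_model <- function(esdc_threshold = 1.0) {
  if (esdc_threshold <= 0) stop_input("`esdc_threshold` must be > 0")
  structure(list(type = "threshold", esdc_threshold = esdc_threshold,
                 decision_threshold = 0.5, version = "1"),
            class = "snitch_model")
}

#' Score comparison features under a riboSNitch model
#'
#' @param model A `snitch_model` (threshold rule or trained random forest).
#' @param features A `snitch_features` tibble (one or more rows).
#' @return Numeric scores in `[0, 1]`, one per row.
#' @export
predict_score <- function(model, features) {
  if (is.null(model) || !inherits(model, "snitch_model")) {
    stop_input("`model` must be a snitch_model (see snitch_threshold_model / train_on_synthetic)")
  }
  if (model$type == "threshold") {
    e <- pmax(features$esdc, 0)
    e / (e + model$esdc_threshold)
  } else {
    x <- as.data.frame(features[, model$feature_cols, drop = FALSE])
    as.numeric(stats::predict(model$forest, newdata = x, type = "prob")[, "changer"])
  }
}

#' Call a riboSNitch from comparison features
#'
#' @param features `snitch_features` (one or more rows).
#' @param model A `snitch_model`; missing model is an error.
#' @param variant_id Optional identifier(s) carried into the output.
#' @return Tibble with `variant_id`, `score`, `label`
#'   (`"riboSNitch"`/`"nonchanger"`) and the decision threshold used.
#' @export
classify <- function(features, model = snitch_threshold_model(),
                     variant_id = NULL) {
  score <- predict_score(model, features)
  tibble(
    variant_id = variant_id %||% sprintf("comparison%d", seq_along(score)),
    score = score,
    label = ifelse(score >= model$decision_threshold, "riboSNitch", "nonchanger"),
    decision_threshold = model$decision_threshold
  )
}

# Generate one synthetic comparison (profile-level): a ground-truth profile,
# two replicate-noise realizations, and for changers an added reactivity
# block on the alt copy. Returns the feature row.
simulate_comparison_features <- function(changer, effect_size, block_width,
                                         noise_sd, profile_length = 200L,
                                         window_halfwidth = 50L) {
  gt <- make_profile(
    paste(sample(BASES, profile_length, replace = TRUE), collapse = ""),
    runif(profile_length) < 0.5
  )
  vp <- profile_length %/% 2L
  a <- perturb_replicate(gt, noise_sd)
  b <- perturb_replicate(gt, noise_sd)
  if (changer) {
    lo <- vp - window_halfwidth + 5L
    hi <- vp + window_halfwidth - 5L - block_width
    start <- sample(lo:hi, 1L)
    idx <- start:(start + block_width - 1L)
    b$reactivity[idx] <- b$reactivity[idx] + effect_size
  }
  compare_profiles(
    tibble(position = a$position, normalized_reactivity = a$reactivity),
    tibble(position = b$position, normalized_reactivity = b$reactivity),
    vp, window_halfwidth = window_halfwidth
  )
}

#' Train a riboSNitch classifier on synthetic comparisons
#'
#' Substitutes for an expert-labeled training set: changer comparisons are
#' simulated with a planted reactivity block (effect size and width drawn
#' from the grids) on top of replicate noise; nonchangers carry replicate
#' noise only. A random forest is fit on the comparison features.
#'
#' @param n_changers,n_nonchangers Training class sizes (each >= 50).
#' @param effect_sizes Grid of planted effect sizes (normalized SHAPE units);
#'   all-zero grids are refused (classes would be indistinguishable).
#' @param block_widths Grid of planted block widths (nt).
#' @param noise_sds Grid of replicate log-normal noise SDs.
#' @param profile_length Length of the simulated profiles.
#' @param n_trees Random-forest size.
#' @param seed RNG seed; the trained model is reproducible given the seed.
#' @param path Optional path; the model is serialized there with
#'   [write_snitch_model()].
#' @return A `snitch_model` of type `"rf"`.
#' @export
train_on_synthetic <- function(n_changers = 200L, n_nonchangers = 200L,
                               effect_sizes = c(1, 1.5, 2),
                               block_widths = c(10L, 15L, 20L),
                               noise_sds = c(0.1, 0.2, 0.3),
                               profile_length = 200L, n_trees = 300L,
                               seed = 1L, path = NULL) {
  if (n_changers < 50L || n_nonchangers < 50L) {
    stop_input("need at least 50 training comparisons per class")
  }
  if (max(effect_sizes) <= 0) {
    stop_input("degenerate effect-size grid (all zero): classes are indistinguishable; training refused")
  }
  with_seed(seed, {
    feats <- simulate_feature_set(n_changers, n_nonchangers, effect_sizes,
                                  block_widths, noise_sds, profile_length)
    x <- as.data.frame(feats[, FEATURE_COLS])
    y <- factor(feats$class, levels = c("nonchanger", "changer"))
    forest <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
    model <- structure(
      list(type = "rf", forest = forest, feature_cols = FEATURE_COLS,
           decision_threshold = 0.5, version = "1", seed = as.integer(seed)),
      class = "snitch_model"
    )
    if (!is.null(path)) write_snitch_model(model, path)
    model
  })
}

simulate_feature_set <- function(n_changers, n_nonchangers, effect_sizes,
                                 block_widths, noise_sds, profile_length) {
  one <- function(changer) {
    simulate_comparison_features(
      changer,
      effect_size = sample(effect_sizes, 1L),
      block_width = sample(block_widths, 1L),
      noise_sd = sample(noise_sds, 1L),
      profile_length = profile_length
    )
  }
  bind_rows(
    purrr::map_dfr(seq_len(n_changers), function(i) one(TRUE)) |>
      mutate(class = "changer"),
    purrr::map_dfr(seq_len(n_nonchangers), function(i) one(FALSE)) |>
      mutate(class = "nonchanger")
  )
}

#' Serialize / restore a trained riboSNitch model
#'
#' @param model A `snitch_model`.
#' @param path File path.
#' @return `read_snitch_model()` returns the model; `write_snitch_model()`
#'   returns `path` invisibly.
#' @export
write_snitch_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_snitch_model
#' @export
read_snitch_model <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  model <- readRDS(path)
  if (!inherits(model, "snitch_model")) stop_input("%s is not a snitch_model", path)
  model
}

#' Ratiometrically split a read set at the pair level
#'
#' Randomly partitions read pairs into disjoint subsets of the given
#' fractions (largest-remainder rounding), emulating the 75/25 within-sample
#' split used to build a no-difference null while matching the sequencing
#' depths of allele-sorted data.
#'
#' @param reads Read tibble.
#' @param fractions Numeric fractions summing to 1 (default `c(0.75, 0.25)`).
#' @param seed Optional RNG seed (local to this call).
#' @return A list of read tibbles, one per fraction; their union is the
#'   input and they are pairwise disjoint.
#' @export
ratiometric_split <- function(reads, fractions = c(0.75, 0.25), seed = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stop_input("`fractions` must sum to 1")
  pairs <- unique(reads$qname)
  n <- length(pairs)
  if (n < 20) stop_input("need at least 20 read pairs to split (have %d)", n)
  sizes <- largest_remainder(n, fractions)
  if (any(sizes == 0)) {
    stop_input("split would leave an empty subset (sizes: %s)",
               paste(sizes, collapse = ", "))
  }
  with_seed(seed, {
    shuffled <- sample(pairs)
    bounds <- cumsum(c(0L, sizes))
    lapply(seq_along(fractions), function(i) {
      qn <- shuffled[(bounds[i] + 1L):bounds[i + 1L]]
      reads |> filter(.data$qname %in% qn)
    })
  })
}

#' ROC curve and AUC for riboSNitch scores
#'
#' AUC is computed through the Mann-Whitney identity on ranks, counting ties
#' as 1/2; curve points are generated at each distinct score threshold
#' (descending; tied scores share a threshold point).
#'
#' @param scores Numeric scores (higher = more riboSNitch-like).
#' @param labels Truth labels: logical, 0/1, or `"changer"`/`"nonchanger"`.
#' @return An object of class `snitch_roc` with `curve` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
roc_auc <- function(scores, labels) {
  pos <- coerce_labels(labels)
  if (length(pos) != length(scores)) stop_input("scores and labels differ in length")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop_input("both classes must be present (have %d positive, %d negative)", n1, n0)
  }
  r <- rank(scores)  # average ranks: ties counted 1/2 in the U statistic
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t), 0) / n1
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t), 0) / n0
  curve <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(curve = curve, auc = auc, n_pos = n1, n_neg = n0),
            class = "snitch_roc")
}

coerce_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  if (is.character(labels) || is.factor(labels)) {
    l <- tolower(as.character(labels))
    return(l %in% c("changer", "ribosnitch", "true", "1", "positive"))
  }
  stop_input("cannot interpret `labels`")
}

#' Choose a decision threshold from null scores at a target false-call rate
#'
#' Returns the score threshold such that at most `fpr` of the supplied
#' null-comparison scores fall at or above it (midpoint between the relevant
#' order statistics).
#'
#' @param null_scores Scores of comparisons with no true difference.
#' @param fpr Target false-positive rate (default 0.10, the design anchor of
#'   the within-sample null).
#' @return A single numeric threshold.
#' @export
calibrate_threshold <- function(null_scores, fpr = 0.10) {
  s <- sort(null_scores, decreasing = TRUE)
  k <- floor(fpr * length(s))
  if (k == 0) return(s[1] + abs(s[1]) * 1e-6 + 1e-12)
  (s[k] + s[k + 1]) / 2
}

# Binomial measurement of a ground-truth reactivity profile at a given
# per-position depth: treated rate = clamp(bg + scale * r), untreated = bg.
measure_profile <- function(truth_reactivity, depth, background_rate,
                            mod_detection_scale) {
  L <- length(truth_reactivity)
  p <- pmin(pmax(background_rate + mod_detection_scale * truth_reactivity, 0), 1)
  kt <- rbinom(L, depth, p)
  ku <- rbinom(L, depth, background_rate)
  prof <- tibble(position = seq_len(L),
                 raw_reactivity = kt / depth - ku / depth,
                 mask = "ok")
  suppressWarnings(normalize_profile(prof))
}

#' Compare the within-sample and between-replicate riboSNitch designs
#'
#' Simulates a panel of variants (changers carry a planted reactivity block
#' on the alt allele) and scores each variant under both experimental
#' designs with the same model:
#' \describe{
#'   \item{between-replicate}{the two alleles are probed in separate tubes:
#'     each allele's ground truth receives independent lognormal replicate
#'     noise, and each tube is measured at the full per-position depth;}
#'   \item{within-sample}{both alleles share one tube (no replicate noise
#'     between them) and reads are allele-sorted, so the ref and alt
#'     profiles are measured at `(1 - allele_fraction_alt)` and
#'     `allele_fraction_alt` of the depth.}
#' }
#' Measurement noise is binomial per position in both designs. ROC/AUC over
#' the changer truth labels quantifies each design; the false-positive rate
#' at the model's decision threshold is also reported.
#'
#' @param n_changers,n_nonchangers Panel sizes (total >= 4).
#' @param effect_size Planted reactivity change (normalized SHAPE units).
#' @param effect_width Width of the planted block (nt).
#' @param replicate_noise_sd Between-tube lognormal noise SD.
#' @param depth Per-position read depth of one tube.
#' @param allele_fraction_alt Alt-allele fraction in the shared tube.
#' @param profile_length Transcript length simulated per variant.
#' @param background_rate,mod_detection_scale MaP chemistry parameters.
#' @param window_halfwidth Comparison window half-width (nt).
#' @param model `snitch_model` used to score both designs.
#' @param seed RNG seed (local).
#' @return List with `scores` (tibble: `variant`, `changer`, `design`,
#'   `score`, `label`), `roc` (named list of `snitch_roc` per design),
#'   `auc` (tibble), and `false_positive_rate` (tibble per design).
#' @export
evaluate_designs <- function(n_changers = 50L, n_nonchangers = 50L,
                             effect_size = 1.5, effect_width = 15L,
                             replicate_noise_sd = 0.3, depth = 3000L,
                             allele_fraction_alt = 0.75,
                             profile_length = 200L,
                             background_rate = 0.002,
                             mod_detection_scale = 0.03,
                             window_halfwidth = 50L,
                             model = snitch_threshold_model(),
                             seed = 1L) {
  n_var <- n_changers + n_nonchangers
  if (n_var < 4L) stop_input("need at least 4 variants for a useful ROC")
  if (depth <= 0) stop_input("`depth` must be positive")
  with_seed(seed, {
    changer <- c(rep(TRUE, n_changers), rep(FALSE, n_nonchangers))
    vp <- profile_length %/% 2L
    rows <- purrr::map_dfr(seq_len(n_var), function(i) {
      gt <- make_profile(
        paste(sample(BASES, profile_length, replace = TRUE), collapse = ""),
        runif(profile_length) < 0.5
      )
      gt_alt <- gt
      if (changer[i]) {
        lo <- vp - window_halfwidth + 5L
        hi <- vp + window_halfwidth - 5L - effect_width
        start <- sample(lo:hi, 1L)
        idx <- start:(start + effect_width - 1L)
        gt_alt$reactivity[idx] <- gt_alt$reactivity[idx] + effect_size
      }
      # between-replicate: separate tubes, full depth, independent noise
      tube_ref <- perturb_replicate(gt, replicate_noise_sd)
      tube_alt <- perturb_replicate(gt_alt, replicate_noise_sd)
      prof_between_ref <- measure_profile(tube_ref$reactivity, depth,
                                          background_rate, mod_detection_scale)
      prof_between_alt <- measure_profile(tube_alt$reactivity, depth,
                                          background_rate, mod_detection_scale)
      # within-sample: one tube, allele-sorted depths, shared conditions
      d_ref <- max(1L, as.integer(round(depth * (1 - allele_fraction_alt))))
      d_alt <- max(1L, as.integer(round(depth * allele_fraction_alt)))
      prof_within_ref <- measure_profile(gt$reactivity, d_ref,
                                         background_rate, mod_detection_scale)
      prof_within_alt <- measure_profile(gt_alt$reactivity, d_alt,
                                         background_rate, mod_detection_scale)
      feats_b <- compare_profiles(prof_between_ref, prof_between_alt, vp,
                                  window_halfwidth = window_halfwidth)
      feats_w <- compare_profiles(prof_within_ref, prof_within_alt, vp,
                                  window_halfwidth = window_halfwidth)
      tibble(variant = i, changer = changer[i],
             design = c("between_replicate", "within_sample"),
             score = c(predict_score(model, feats_b),
                       predict_score(model, feats_w)))
    })
    rows$label <- ifelse(rows$score >= model$decision_threshold,
                         "riboSNitch", "nonchanger")
    rocs <- lapply(split(rows, rows$design),
                   function(d) roc_auc(d$score, d$changer))
    auc <- tibble(design = names(rocs),
                  auc = unname(vapply(rocs, function(x) x$auc, 0)))
    fpr <- rows |>
      filter(!.data$changer) |>
      group_by(.data$design) |>
      summarise(false_positive_rate = mean(.data$label == "riboSNitch"),
                .groups = "drop")
    list(scores = rows, roc = rocs, auc = auc, false_positive_rate = fpr)
  })
}
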