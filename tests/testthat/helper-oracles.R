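# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals.

# Brute-force 2%/8% box normalizer: drop the top 2% (ceiling) of values,
# average the next 8% (ceiling), invert.
oracle_box_multiplier <- function(values) {
  v <- values[!is.na(values)]
  v <- v[order(v, decreasing = TRUE)]
  n <- length(v)
  drop_n <- ceiling(0.02 * n)
  band_n <- ceiling(0.08 * n)
  band <- v[seq(drop_n + 1, min(n, drop_n + band_n))]
  1 / mean(band)
}

# O(n^2) pairwise-concordance AUC with ties counted 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Naive centered sliding median with the >= 50%-usable rule and missing edges.
oracle_sliding_median <- function(v, w) {
  h <- (w - 1) / 2
  out <- rep(NA_real_, length(v))
  for (i in seq_along(v)) {
    if (i - h < 1 || i + h > length(v)) next
    win <- v[(i - h):(i + h)]
    if (sum(!is.na(win)) >= w / 2) out[i] <- median(win, na.rm = TRUE)
  }
  out
}

# Naive centered sliding Pearson correlation, pairwise complete, >= 5 pairs,
# NA when either window is constant.
oracle_window_cor <- function(a, b, w) {
  h <- (w - 1) / 2
  out <- rep(NA_real_, length(a))
  for (i in seq_along(a)) {
    if (i - h < 1 || i + h > length(a)) next
    ia <- a[(i - h):(i + h)]; ib <- b[(i - h):(i + h)]
    ok <- !is.na(ia) & !is.na(ib)
    if (sum(ok) < 5) next
    if (length(unique(ia[ok])) == 1 || length(unique(ib[ok])) == 1) next
    out[i] <- cor(ia[ok], ib[ok])
  }
  out
}

# Base-pair set of a dot-bracket string as "i-j" strings, by stack matching.
oracle_pair_set <- function(s) {
  chars <- strsplit(s, "")[[1]]
  stack <- integer(0)
  pairs <- character(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    if (chars[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs <- c(pairs, paste0(j, "-", i))
    }
  }
  pairs
}

oracle_bp_distance <- function(s1, s2) {
  p1 <- oracle_pair_set(s1)
  p2 <- oracle_pair_set(s2)
  length(setdiff(p1, p2)) + length(setdiff(p2, p1))
}

# Shared synthetic scenario builders -----------------------------------------

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# A compact end-to-end scenario: short transcript, short fragments whose
# mates jointly span most positions, so nearly every pair is sortable.
e2e_scenario <- function(depth = 4000, seed = 1, effect = 0, L = 120,
                         variant_pos = 60, allele_fraction_alt = 0.75) {
  set.seed(seed)
  gt <- make_profile(random_seq(L), random_dotbracket(L, seed = seed + 1),
                     seed = seed + 2)
  ref_seq <- attr(gt, "sequence")
  rb <- substr(ref_seq, variant_pos, variant_pos)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  v <- variant_spec(variant_pos, rb, ab, id = "var1")
  gt_alt <- gt
  if (effect != 0) {
    idx <- (variant_pos + 3):(variant_pos + 17)
    gt_alt$reactivity[idx] <- gt_alt$reactivity[idx] + effect
  }
  cfg <- function(s) sim_config(depth = depth, read_length = 50,
                                fragment_length_mean = 60,
                                fragment_length_sd = 4,
                                allele_fraction_alt = allele_fraction_alt,
                                seed = s)
  treated <- simulate_reads(gt, cfg(seed * 13 + 1), variant = v,
                            profile_alt = gt_alt, channel = "treated")
  untreated <- simulate_reads(gt, cfg(seed * 13 + 3), variant = v,
                              channel = "untreated")
  list(gt = gt, gt_alt = gt_alt, variant = v, reference = ref_seq,
       treated = treated, untreated = untreated)
}

# Perturbed copies of a hairpin / open-structure template, for planted
# two-group ensembles: remove `n_drop` randomly chosen pairs.
perturbed_structure <- function(template, n_drop = 1) {
  pairs <- oracle_pair_set(template)
  chars <- strsplit(template, "")[[1]]
  if (length(pairs) > 0 && n_drop > 0) {
    drop <- sample(pairs, min(n_drop, length(pairs)))
    for (p in drop) {
      ij <- as.integer(strsplit(p, "-")[[1]])
      chars[ij] <- "."
    }
  }
  paste(chars, collapse = "")
}

HAIRPIN_40 <- paste0(strrep("(", 12), strrep(".", 16), strrep(")", 12))
OPEN_40 <- strrep(".", 40)
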