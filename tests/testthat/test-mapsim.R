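test_that("make_profile respects the pairing structure", {
  p <- make_profile("ACGU", "....", seed = 1)
  expect_false(any(p$paired))
  expect_true(all(p$reactivity >= 0))
  expect_equal(p$nt, c("A", "C", "G", "U"))

  p2 <- make_profile("ACGUAC", "((..))", seed = 1)
  expect_equal(p2$paired, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))

  expect_error(make_profile("ACGU", "((.."), class = "shapesorter_input_error")
  expect_error(make_profile("ACGU", "..."), class = "shapesorter_input_error")
})

test_that("unpaired positions are more reactive than paired ones across seeds", {
  for (s in 1:10) {
    set.seed(s)
    struct <- random_dotbracket(200, pair_prob = 0.4, seed = s)
    p <- make_profile(random_seq(200), struct, seed = s + 100)
    expect_gt(mean(p$reactivity[!p$paired]), mean(p$reactivity[p$paired]))
  }
})

test_that("simulate_reads produces mutation-free reads when both rates are zero", {
  gt <- make_profile(random_seq(80), strrep(".", 80), seed = 1)
  cfg <- sim_config(depth = 200, read_length = 30, fragment_length_mean = 50,
                    fragment_length_sd = 5, mod_detection_scale = 0,
                    background_rate = 0, seed = 3)
  sim <- simulate_reads(gt, cfg, channel = "treated")
  ref <- attr(gt, "sequence")
  expect_true(all(mapply(function(s, p) {
    s == substr(ref, p, p + nchar(s) - 1L)
  }, sim$reads$seq, sim$reads$pos)))
})

test_that("allele_fraction_alt = 1 puts the alt base on every covering fragment", {
  gt <- make_profile(random_seq(80), strrep(".", 80), seed = 2)
  ref <- attr(gt, "sequence")
  v <- variant_spec(40, substr(ref, 40, 40),
                    setdiff(c("A", "C", "G", "T"), substr(ref, 40, 40))[1])
  cfg <- sim_config(depth = 300, read_length = 30, fragment_length_mean = 50,
                    fragment_length_sd = 5, mod_detection_scale = 0,
                    background_rate = 0, allele_fraction_alt = 1, seed = 4)
  sim <- simulate_reads(gt, cfg, variant = v, channel = "treated")
  expect_true(all(sim$truth$allele == "alt"))
  obs <- shapesorter:::read_base_at(sim$reads, 40)
  expect_true(all(obs$base[!is.na(obs$base)] == v$alt_base))
})

test_that("untreated-channel mutation rates follow the background binomial", {
  gt <- make_profile(random_seq(100), strrep(".", 100), seed = 5)
  cfg <- sim_config(depth = 20000, read_length = 50, paired_end = FALSE,
                    fragment_length_mean = 60, fragment_length_sd = 5,
                    background_rate = 0.002, seed = 6)
  sim <- simulate_reads(gt, cfg, channel = "untreated")
  counts <- count_mutations(sim$reads, attr(gt, "sequence"),
                            channel = "untreated")
  keep <- counts$effective_depth > 0
  rate <- counts$mutation_events[keep] / counts$effective_depth[keep]
  se <- sqrt(0.002 * 0.998 / counts$effective_depth[keep])
  within <- abs(rate - 0.002) <= 3 * se
  expect_gte(mean(within), 0.95)
})

test_that("treated-channel mutation rate is monotone in ground-truth reactivity", {
  # constant-reactivity blocks on a grid; empirical block rates must increase
  grid <- c(0, 0.5, 1, 1.5, 2, 3)
  reactivity <- rep(grid, each = 20)
  gt <- make_profile(random_seq(120), strrep(".", 120), seed = 7)
  gt$reactivity <- reactivity
  cfg <- sim_config(depth = 30000, read_length = 40, paired_end = FALSE,
                    fragment_length_mean = 50, fragment_length_sd = 3,
                    mod_detection_scale = 0.03, background_rate = 0.002,
                    seed = 8)
  sim <- simulate_reads(gt, cfg, channel = "treated")
  counts <- count_mutations(sim$reads, attr(gt, "sequence"))
  block <- rep(seq_along(grid), each = 20)
  block_rate <- tapply(counts$mutation_events, block, sum) /
    tapply(counts$effective_depth, block, sum)
  expect_true(all(diff(block_rate) > 0))
})

test_that("allele counts at the variant site are binomial across seeds", {
  gt <- make_profile(random_seq(60), strrep(".", 60), seed = 9)
  ref <- attr(gt, "sequence")
  v <- variant_spec(30, substr(ref, 30, 30),
                    setdiff(c("A", "C", "G", "T"), substr(ref, 30, 30))[1])
  n <- 200; f <- 0.75
  alt_counts <- vapply(1:100, function(s) {
    cfg <- sim_config(depth = n, read_length = 40, paired_end = FALSE,
                      fragment_length_mean = 50, fragment_length_sd = 3,
                      allele_fraction_alt = f, background_rate = 0, seed = s)
    sim <- simulate_reads(gt, cfg, variant = v, channel = "untreated")
    sum(sim$truth$allele == "alt")
  }, 0L)
  # Pearson goodness-of-fit of the 100 binomial draws against Binom(n, f)
  z2 <- sum((alt_counts - n * f)^2 / (n * f * (1 - f)))
  expect_gt(stats::pchisq(z2, df = 100, lower.tail = FALSE), 0.01)
})

test_that("identical seeds give byte-identical SAM output", {
  gt <- make_profile(random_seq(100), random_dotbracket(100, seed = 1), seed = 10)
  cfg <- sim_config(depth = 150, seed = 11, fragment_length_mean = 80)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  simulate_reads(gt, cfg, channel = "treated", sam_path = f1)
  simulate_reads(gt, cfg, channel = "treated", sam_path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("SAM output round-trips through Rsamtools", {
  gt <- make_profile(random_seq(100), random_dotbracket(100, seed = 2), seed = 12)
  cfg <- sim_config(depth = 100, seed = 13, fragment_length_mean = 80)
  f <- tempfile(fileext = ".sam")
  sim <- simulate_reads(gt, cfg, channel = "treated", sam_path = f)
  back <- read_alignments(f)
  expect_equal(as.data.frame(back[names(sim$reads)]),
               as.data.frame(sim$reads))
})

test_that("perturb_replicate applies multiplicative lognormal noise", {
  gt <- make_profile(random_seq(200), strrep(".", 200), seed = 14)
  expect_identical(perturb_replicate(gt, 0), gt)

  pert <- perturb_replicate(gt, 0.3, seed = 15)
  lr <- log(pert$reactivity / gt$reactivity)
  expect_gt(sd(lr), 0.2)
  expect_lt(sd(lr), 0.4)

  zero <- gt; zero$reactivity <- rep(0, 200)
  expect_equal(perturb_replicate(zero, 0.5, seed = 16)$reactivity, rep(0, 200))
  expect_error(perturb_replicate(gt, -0.1), class = "shapesorter_input_error")
})

test_that("simulation config rejects invalid parameters", {
  expect_error(sim_config(depth = 0), class = "shapesorter_input_error")
  expect_error(sim_config(background_rate = 1.5), class = "shapesorter_input_error")
  expect_error(sim_config(allele_fraction_alt = -0.1), class = "shapesorter_input_error")
  gt <- make_profile("ACGU", "....", seed = 1)
  expect_error(simulate_reads(gt, sim_config(read_length = 10)),
               class = "shapesorter_input_error")
})
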