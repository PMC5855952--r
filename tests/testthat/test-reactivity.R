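test_that("count_mutations counts mismatches and depth per position", {
  ref <- "AAAAA"
  reads <- tibble::tibble(
    qname = c("r1", "r2", "r3"), mate = 1L, pos = c(1L, 1L, 3L),
    cigar = "3M",
    seq = c("AAA", "ACA", "AAA"),
    qual = rep("III", 3)
  )
  counts <- count_mutations(reads, ref)
  expect_equal(counts$effective_depth, c(2L, 2L, 3L, 1L, 1L))
  expect_equal(counts$mutation_events, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(counts$nt, c("A", "A", "A", "A", "A"))
  # zero-coverage positions report zero depth and zero events
  expect_equal(counts$effective_depth[5], 1L)
  counts0 <- count_mutations(reads[0, ], ref)
  expect_true(all(counts0$effective_depth == 0L))
})

test_that("quality filtering removes calls from depth and events", {
  ref <- "AAA"
  reads <- tibble::tibble(qname = "r1", mate = 1L, pos = 1L, cigar = "3M",
                          seq = "ACA", qual = "I#I")  # middle call Q2
  counts <- count_mutations(reads, ref, min_base_quality = 20)
  expect_equal(counts$effective_depth, c(1L, 0L, 1L))
  expect_equal(counts$mutation_events, c(0L, 0L, 0L))
})

test_that("counting is order-independent", {
  scn <- e2e_scenario(depth = 300, seed = 31)
  shuffled <- scn$treated$reads[sample(nrow(scn$treated$reads)), ]
  expect_equal(count_mutations(scn$treated$reads, scn$reference),
               count_mutations(shuffled, scn$reference))
})

test_that("empirical mutation rates match the simulated probabilities", {
  gt <- make_profile(random_seq(150), random_dotbracket(150, seed = 1), seed = 32)
  cfg <- sim_config(depth = 20000, read_length = 50, paired_end = FALSE,
                    fragment_length_mean = 60, fragment_length_sd = 5,
                    mod_detection_scale = 0.03, background_rate = 0.002,
                    seed = 33)
  sim <- simulate_reads(gt, cfg, channel = "treated")
  counts <- count_mutations(sim$reads, attr(gt, "sequence"))
  p <- pmin(0.002 + 0.03 * gt$reactivity, 1)
  keep <- counts$effective_depth > 100
  rate <- counts$mutation_events[keep] / counts$effective_depth[keep]
  se <- sqrt(p[keep] * (1 - p[keep]) / counts$effective_depth[keep])
  expect_gte(mean(abs(rate - p[keep]) <= 3 * se), 0.95)
})

test_that("raw reactivity is the treated-minus-background rate with masking", {
  mk_counts <- function(events, depth, channel) {
    tibble::tibble(position = seq_along(events), nt = "A",
                   mutation_events = events, effective_depth = depth,
                   channel = channel)
  }
  tr <- mk_counts(c(50L, 10L, 5L), c(1000L, 1000L, 500L), "treated")
  un <- mk_counts(c(10L, 20L, 1L), c(1000L, 1000L, 1000L), "untreated")
  prof <- raw_reactivity(tr, un, min_depth = 1000)
  expect_equal(prof$raw_reactivity[1], 0.04)
  expect_equal(prof$raw_reactivity[2], -0.01)  # negative retained
  expect_true(is.na(prof$raw_reactivity[3]))   # treated depth below threshold
  expect_equal(prof$mask, c("ok", "ok", "low_depth"))
  expect_error(raw_reactivity(tr, un[1:2, ]), class = "shapesorter_input_error")
})

test_that("box 2%/8% normalization matches the brute-force oracle", {
  fixture <- read.delim(system.file("extdata", "norm_fixture_50.tsv",
                                    package = "shapesorter"))$value
  prof <- tibble::tibble(position = seq_along(fixture), nt = "A",
                         raw_reactivity = fixture, mask = "ok")
  norm <- normalize_profile(prof)
  mult <- attr(norm, "normalization_multiplier")
  expect_equal(mult, oracle_box_multiplier(fixture), tolerance = 1e-12)
  expect_equal(norm$normalized_reactivity, fixture * mult)
})

test_that("a constant profile of 2.0 normalizes to 1.0 with multiplier 0.5", {
  prof <- tibble::tibble(position = 1:100, nt = "A",
                         raw_reactivity = rep(2, 100), mask = "ok")
  norm <- normalize_profile(prof)
  expect_equal(attr(norm, "normalization_multiplier"), 0.5)
  expect_equal(norm$normalized_reactivity, rep(1, 100))
})

test_that("external-reference normalization of a profile against itself matches self-normalization", {
  set.seed(34)
  v <- rgamma(80, 2, 2)
  prof <- tibble::tibble(position = 1:80, nt = "A", raw_reactivity = v,
                         mask = "ok")
  self_norm <- normalize_profile(prof)
  ext_norm <- normalize_profile(prof, method = "external_reference",
                                reference_profile = prof)
  expect_equal(attr(ext_norm, "normalization_multiplier"),
               attr(self_norm, "normalization_multiplier"))
})

test_that("normalization is scale-equivariant", {
  set.seed(35)
  v <- rgamma(60, 2, 2) - 0.02
  prof <- tibble::tibble(position = 1:60, nt = "A", raw_reactivity = v,
                         mask = "ok")
  base <- normalize_profile(prof)
  for (i in 1:20) {
    c0 <- runif(1, 0.1, 10)
    scaled <- prof
    scaled$raw_reactivity <- v * c0
    norm <- normalize_profile(scaled)
    expect_equal(attr(norm, "normalization_multiplier"),
                 attr(base, "normalization_multiplier") / c0)
    expect_equal(norm$normalized_reactivity, base$normalized_reactivity)
  }
})

test_that("normalization refuses profiles with too few usable positions", {
  prof <- tibble::tibble(position = 1:10, nt = "A",
                         raw_reactivity = rgamma(10, 2), mask = "ok")
  expect_warning(out <- normalize_profile(prof), "usable positions")
  expect_true(all(is.na(out$normalized_reactivity)))
})

test_that("profile files round-trip with -999 missing encoding", {
  prof <- tibble::tibble(position = 1:25, nt = rep("A", 25),
                         raw_reactivity = c(rgamma(24, 2), NA),
                         mask = c(rep("ok", 24), "low_depth"))
  prof <- suppressWarnings(normalize_profile(prof))
  f <- tempfile(fileext = ".map")
  write_profile(prof, f, extended_path = paste0(f, ".tsv"))
  back <- read_profile(f)
  expect_equal(back$normalized_reactivity, prof$normalized_reactivity)
  expect_true(is.na(back$normalized_reactivity[25]))
  raw_line <- readLines(f)[25]
  expect_match(raw_line, "-999")

  expect_error(write_profile(prof[0, ], tempfile()),
               class = "shapesorter_input_error")
  bad <- tempfile()
  writeLines(c("1\t0.5\t0\tA", "2\tnot_a_number\t0\tA"), bad)
  expect_error(read_profile(bad), "line 2")
})

test_that("raw reactivity recovers ground truth at depth", {
  gt <- make_profile(random_seq(200), random_dotbracket(200, seed = 3), seed = 36)
  cfg <- function(s) sim_config(depth = 5000, read_length = 50,
                                fragment_length_mean = 150,
                                fragment_length_sd = 20, seed = s)
  tr <- simulate_reads(gt, cfg(37), channel = "treated")
  un <- simulate_reads(gt, cfg(38), channel = "untreated")
  prof <- raw_reactivity(
    count_mutations(tr$reads, attr(gt, "sequence"), channel = "treated"),
    count_mutations(un$reads, attr(gt, "sequence"), channel = "untreated"),
    min_depth = 1000
  )
  ok <- prof$mask == "ok"
  expect_gt(sum(ok), 100)
  expect_gt(cor(prof$raw_reactivity[ok], gt$reactivity[ok]), 0.9)
})
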