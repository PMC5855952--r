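#' Run the full per-variant allele-specific SHAPE workflow
#'
#' sort -> count -> background-correct -> normalize -> compare -> classify,
#' for one variant: reads from both channels are allele-sorted at the
#' variant site, each allele's treated/untreated mutation counts yield a
#' background-corrected reactivity profile, the variant site is masked,
#' profiles are normalized, and the ref/alt comparison is scored by the
#' model. Variants that cannot be called are skipped with an explicit
#' reason code instead of an error.
#'
#' @param reference Reference sequence string (or path to a FASTA file).
#' @param variant A [variant_spec()].
#' @param treated_reads,untreated_reads Read tibbles or SAM/BAM paths for
#'   the 1M7-treated and DMSO (background) channels.
#' @param min_depth Minimum per-position effective depth per channel.
#' @param min_base_quality Minimum base quality for sorting and counting.
#' @param window_halfwidth Comparison window half-width (nt).
#' @param change_threshold Changed-position threshold (normalized units).
#' @param model `snitch_model` used for the call.
#' @param normalize_method Passed to [normalize_profile()].
#' @return List with `report` (one-row tibble: identifiers, allele counts,
#'   estimated allele fraction, comparison features, score, `call`, and a
#'   `reason` code when skipped) and `profiles` (list of the per-allele
#'   normalized profiles, `NULL` when skipped).
#' @export
run_variant <- function(reference, variant, treated_reads, untreated_reads,
                        min_depth = 1000L, min_base_quality = 20L,
                        window_halfwidth = 50L, change_threshold = 0.5,
                        model = snitch_threshold_model(),
                        normalize_method = "box2_8") {
  reference <- read_reference(reference)
  variant <- as_variant_spec(variant)
  treated_reads <- as_reads(treated_reads)
  untreated_reads <- as_reads(untreated_reads)

  skip <- function(reason, sorted_t = NULL) {
    counts <- if (is.null(sorted_t)) {
      tibble(n_ref = 0L, n_alt = 0L, n_other = 0L, n_unassigned = 0L)
    } else {
      cn <- setNames(sorted_t$counts$n, sorted_t$counts$call)
      tibble(n_ref = cn[["ref"]], n_alt = cn[["alt"]],
             n_other = cn[["other"]], n_unassigned = cn[["unassigned"]])
    }
    list(report = bind_cols(
      tibble(variant_id = variant$id, position = variant$position),
      counts,
      tibble(fraction_alt = NA_real_, pearson_r = NA_real_, esdc = NA_real_,
             n_compared = NA_integer_, score = NA_real_,
             call = "skipped", reason = reason)
    ), profiles = NULL)
  }

  sorted_t <- sort_reads(treated_reads, variant, min_base_quality)
  sorted_u <- sort_reads(untreated_reads, variant, min_base_quality)
  n_inf <- sum(sorted_t$counts$n[sorted_t$counts$call %in% c("ref", "alt")])
  if (n_inf == 0) return(skip("no informative reads", sorted_t))

  profile_for <- function(allele) {
    tr <- count_mutations(sorted_t[[allele]], reference, min_base_quality,
                          channel = "treated")
    un <- count_mutations(sorted_u[[allele]], reference, min_base_quality,
                          channel = "untreated")
    raw_reactivity(tr, un, min_depth = min_depth) |>
      mask_variant_site(variant$position)
  }
  prof_ref <- profile_for("ref")
  prof_alt <- profile_for("alt")
  in_window <- function(p) {
    abs(p$position - variant$position) <= window_halfwidth &
      p$position != variant$position
  }
  shared <- sum(in_window(prof_ref) & prof_ref$mask == "ok" &
                  prof_alt$mask == "ok")
  if (shared < 10) return(skip("insufficient sorted depth", sorted_t))

  prof_ref <- suppressWarnings(normalize_profile(prof_ref, normalize_method))
  prof_alt <- suppressWarnings(normalize_profile(prof_alt, normalize_method))
  if (all(is.na(prof_ref$normalized_reactivity)) ||
      all(is.na(prof_alt$normalized_reactivity))) {
    return(skip("normalization failed", sorted_t))
  }
  feats <- compare_profiles(prof_ref, prof_alt, variant,
                            window_halfwidth = window_halfwidth,
                            change_threshold = change_threshold)
  call <- classify(feats, model, variant_id = variant$id)
  frac <- estimate_allele_fraction(sorted_t$counts)
  cn <- setNames(sorted_t$counts$n, sorted_t$counts$call)
  report <- bind_cols(
    tibble(variant_id = variant$id, position = variant$position,
           n_ref = cn[["ref"]], n_alt = cn[["alt"]], n_other = cn[["other"]],
           n_unassigned = cn[["unassigned"]],
           fraction_alt = frac$fraction_alt),
    tibble(pearson_r = feats$pearson_r, esdc = feats$esdc,
           n_compared = feats$n_compared, score = call$score,
           call = call$label, reason = NA_character_)
  )
  list(report = report, profiles = list(ref = prof_ref, alt = prof_alt))
}

read_reference <- function(reference) {
  if (file.exists(reference) && grepl("\\.(fa|fasta)$", reference,
                                      ignore.case = TRUE)) {
    lines <- readLines(reference)
    return(normalize_sequence(paste(lines[!startsWith(lines, ">")],
                                    collapse = "")))
  }
  normalize_sequence(reference)
}

as_reads <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(read_alignments(x))
  stop_input("reads must be a tibble or a SAM/BAM path")
}

#' Summarize a batch of per-variant reports
#'
#' @param rows A tibble of per-variant report rows (stacked
#'   [run_variant()] reports).
#' @param path Optional TSV output path for the full report.
#' @return List with `report` (the rows) and `summary`: counts of
#'   riboSNitches, nonchangers and skipped variants and the fraction
#'   changed, `changers / (changers + nonchangers)` (skipped excluded).
#'   All variants skipped sets a `no_callable_variants` flag.
#' @export
batch_report <- function(rows, path = NULL) {
  if (is.null(rows) || nrow(rows) == 0) stop_input("empty report")
  n_snitch <- sum(rows$call == "riboSNitch")
  n_non <- sum(rows$call == "nonchanger")
  n_skip <- sum(rows$call == "skipped")
  callable <- n_snitch + n_non
  summary <- tibble(
    n_ribosnitch = n_snitch, n_nonchanger = n_non, n_skipped = n_skip,
    fraction_changed = if (callable > 0) n_snitch / callable else NA_real_,
    no_callable_variants = callable == 0
  )
  if (summary$no_callable_variants) warn("no callable variants in batch")
  if (!is.null(path)) readr::write_tsv(rows, path)
  list(report = rows, summary = summary)
}

#' Relative expression from qRT-PCR cycle thresholds
#'
#' For matched doxycycline-induced vs untreated samples with a target (GFP)
#' and control (GAPDH) gene: triplicate CT values are cleaned (values more
#' than 1 cycle from the triplicate median are dropped, with a message) and
#' averaged, ΔCT = target - control is formed per condition, and relative
#' expression defaults to the exponential interpretation
#' `2^(-ΔCT_dox) / 2^(-ΔCT_untreated)`. `literal_formula = TRUE` instead
#' computes `(-ΔCT_dox)^2 / (-ΔCT_untreated)^2` exactly as sometimes
#' printed; the exponential form is the default because squaring a
#' negative-base ΔCT does not behave as an expression ratio.
#'
#' @param records Tibble with `sample`, `condition` (`"dox"`/`"untreated"`),
#'   `ct_target`, `ct_control`; replicate rows are averaged.
#' @param literal_formula Use the squared-ΔCT form.
#' @return Tibble with `sample`, `delta_ct_dox`, `delta_ct_untreated`,
#'   `relative_expression`.
#' @export
relative_expression <- function(records, literal_formula = FALSE) {
  needed <- c("sample", "condition", "ct_target", "ct_control")
  if (!all(needed %in% names(records))) {
    stop_input("records must have columns: %s", paste(needed, collapse = ", "))
  }
  if (any(!is.finite(records$ct_target)) || any(!is.finite(records$ct_control))) {
    stop_input("cycle values must be finite (is a control gene missing?)")
  }
  if (any(records$ct_target <= 0) || any(records$ct_control <= 0)) {
    stop_input("cycle values must be positive")
  }
  clean_mean <- function(x) {
    drop <- abs(x - median(x)) > 1
    if (any(drop)) {
      message(sprintf("dropping %d outlier CT value(s) (>1 cycle from median)",
                      sum(drop)))
    }
    mean(x[!drop])
  }
  dct <- records |>
    group_by(.data$sample, .data$condition) |>
    summarise(delta_ct = clean_mean(.data$ct_target) -
                clean_mean(.data$ct_control), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "delta_ct")
  if (!all(c("dox", "untreated") %in% names(dct)) ||
      anyNA(dct$dox) || anyNA(dct$untreated)) {
    stop_input("each sample needs matched dox and untreated records")
  }
  rel <- if (literal_formula) {
    (-dct$dox)^2 / (-dct$untreated)^2
  } else {
    2^(-dct$dox) / 2^(-dct$untreated)
  }
  tibble(sample = dct$sample, delta_ct_dox = dct$dox,
         delta_ct_untreated = dct$untreated, relative_expression = rel)
}
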