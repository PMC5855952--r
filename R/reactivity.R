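#' Count per-position mutation events and effective depth
#'
#' For every reference position, `effective_depth` counts aligned,
#' quality-passing base calls and `mutation_events` counts non-reference
#' substitutions among them, in the style of MaP mutation counting.
#' With `collapse_adjacent = TRUE`, mismatches within 3 nt of each other on
#' the same read are collapsed into a single event at the 3'-most position
#' (multi-nucleotide mutation handling; off by default).
#'
#' @param reads Read tibble ([simulate_reads()] / [read_alignments()]).
#' @param reference Reference sequence string (A/C/G/U/T).
#' @param min_base_quality Minimum Phred quality for a base call to count.
#' @param channel Label stored on the result (`"treated"` or `"untreated"`).
#' @param collapse_adjacent Collapse mismatches closer than 3 nt on a read
#'   into one event at the 3'-most position.
#' @return Tibble with `position`, `nt` (RNA alphabet), `mutation_events`,
#'   `effective_depth` and a `channel` column.
#' @export
count_mutations <- function(reads, reference, min_base_quality = 20L,
                            channel = "treated", collapse_adjacent = FALSE) {
  ref <- normalize_sequence(reference)
  L <- nchar(ref)
  ref_chars <- strsplit(ref, "")[[1]]
  depth <- integer(L)
  events <- integer(L)
  if (nrow(reads) > 0) {
    if (any(reads$pos + nchar(reads$seq) - 1L > L & grepl("^[0-9]+M$", reads$cigar))) {
      stop_input("read alignment extends past the reference (length %d)", L)
    }
    simple <- grepl("^[0-9]+M$", reads$cigar)
    if (!all(simple)) {
      stop_input("count_mutations currently requires pure-match (nM) CIGARs")
    }
    rl <- nchar(reads$seq)
    if (length(unique(rl)) == 1L) {
      # constant read length: fully vectorized matrix path
      w <- rl[1]
      posmat <- outer(reads$pos, 0:(w - 1L), `+`)
      base_mat <- matrix(unlist(strsplit(reads$seq, ""), use.names = FALSE),
                         ncol = w, byrow = TRUE)
      qual_mat <- matrix(phred_from_qual(paste(reads$qual, collapse = "")),
                         ncol = w, byrow = TRUE)
      ok <- qual_mat >= min_base_quality
      mm <- ok & base_mat != matrix(ref_chars[posmat], ncol = w)
      if (collapse_adjacent && any(mm)) mm <- collapse_mismatch_runs(mm)
      depth <- tabulate(posmat[ok], nbins = L)
      events <- tabulate(posmat[mm], nbins = L)
    } else {
      for (i in seq_len(nrow(reads))) {
        w <- rl[i]
        p <- reads$pos[i]:(reads$pos[i] + w - 1L)
        b <- strsplit(reads$seq[i], "")[[1]]
        q <- phred_from_qual(reads$qual[i])
        ok <- q >= min_base_quality
        mm <- ok & b != ref_chars[p]
        if (collapse_adjacent && any(mm)) {
          mm <- collapse_mismatch_runs(matrix(mm, nrow = 1))[1, ]
        }
        depth[p] <- depth[p] + as.integer(ok)
        events[p] <- events[p] + as.integer(mm)
      }
    }
  }
  tibble(position = seq_len(L), nt = strsplit(to_rna(ref), "")[[1]],
         mutation_events = events, effective_depth = depth,
         channel = channel)
}

# Collapse, per read (row), mismatches separated by < 3 nt into a single
# event retained at the 3'-most position of the run.
collapse_mismatch_runs <- function(mm) {
  t(apply(mm, 1L, function(row) {
    hits <- which(row)
    if (length(hits) < 2) return(row)
    keep <- logical(length(row))
    gap_new <- c(TRUE, diff(hits) >= 3L)
    run_id <- cumsum(gap_new)
    keep[tapply(hits, run_id, max)] <- TRUE
    keep
  }))
}

#' Background-corrected raw reactivity from two channels
#'
#' Raw reactivity at a position is the treated-channel mutation rate minus
#' the untreated (background) rate; positions where either channel is below
#' `min_depth` are masked as missing. Negative values are retained at this
#' stage.
#'
#' @param treated,untreated `MutationCounts` tibbles from [count_mutations()]
#'   over the same reference.
#' @param min_depth Minimum effective depth required in both channels.
#' @return A reactivity-profile tibble with `position`, `nt`,
#'   `rate_treated`, `rate_untreated`, `depth_treated`, `depth_untreated`,
#'   `raw_reactivity` and `mask` (`"ok"`, `"low_depth"` or `"variant_site"`).
#' @export
raw_reactivity <- function(treated, untreated, min_depth = 1000L) {
  if (nrow(treated) != nrow(untreated)) {
    stop_input("treated and untreated cover references of different length")
  }
  out <- tibble(
    position = treated$position,
    nt = treated$nt,
    rate_treated = ifelse(treated$effective_depth > 0,
                          treated$mutation_events / treated$effective_depth, NA_real_),
    rate_untreated = ifelse(untreated$effective_depth > 0,
                            untreated$mutation_events / untreated$effective_depth, NA_real_),
    depth_treated = treated$effective_depth,
    depth_untreated = untreated$effective_depth
  )
  ok <- out$depth_treated >= min_depth & out$depth_untreated >= min_depth
  out$mask <- ifelse(ok, "ok", "low_depth")
  out$raw_reactivity <- ifelse(ok, out$rate_treated - out$rate_untreated, NA_real_)
  out
}

#' Mask the variant site in a reactivity profile
#'
#' Allele sorting consumes the base identity at the variant position, so its
#' reactivity is not interpretable; this flags it `variant_site` and sets the
#' reactivity to missing.
#'
#' @param profile Reactivity-profile tibble.
#' @param position Variant position(s), 1-based.
#' @return The profile with the site(s) masked.
#' @export
mask_variant_site <- function(profile, position) {
  hit <- profile$position %in% position
  profile$mask[hit] <- "variant_site"
  profile$raw_reactivity[hit] <- NA_real_
  if ("normalized_reactivity" %in% names(profile)) {
    profile$normalized_reactivity[hit] <- NA_real_
  }
  profile
}

# The 2%/8% box normalizer: exclude the top 2% of non-missing values, the
# multiplier is 1 / mean of the next 8%.
box_multiplier <- function(values) {
  v <- sort(values[!is.na(values)], decreasing = TRUE)
  n <- length(v)
  n_excl <- ceiling(0.02 * n)
  n_band <- ceiling(0.08 * n)
  band <- v[(n_excl + 1):min(n, n_excl + n_band)]
  m <- mean(band)
  if (!is.finite(m) || m <= 0) {
    stop_input("normalization band mean is not positive; cannot normalize")
  }
  1 / m
}

#' Normalize a raw reactivity profile
#'
#' Scales raw reactivities by a single positive multiplier. The default
#' `box2_8` rule excludes the top 2% of non-missing values and sets the
#' multiplier to 1/mean of the next 8% (standard SHAPE box normalization).
#' `external_reference` computes the same statistic on a supplied reference
#' profile's raw reactivities and applies that multiplier, supporting
#' normalization against a common full-length transcript distribution.
#' Negative values are scaled, not clipped, unless `clip_negative = TRUE`.
#'
#' @param profile Profile tibble from [raw_reactivity()].
#' @param method `"box2_8"` or `"external_reference"`.
#' @param reference_profile Profile (or numeric vector of raw reactivities)
#'   supplying the normalization distribution for `external_reference`.
#' @param clip_negative Clip negative normalized values to zero.
#' @return The profile with a `normalized_reactivity` column; the multiplier
#'   is stored in `attr(, "normalization_multiplier")`.
#' @export
normalize_profile <- function(profile, method = c("box2_8", "external_reference"),
                              reference_profile = NULL, clip_negative = FALSE) {
  method <- match.arg(method)
  values <- profile$raw_reactivity
  source_values <- if (method == "external_reference") {
    if (is.null(reference_profile)) {
      stop_input("external_reference normalization needs `reference_profile`")
    }
    if (is.numeric(reference_profile)) reference_profile
    else reference_profile$raw_reactivity
  } else {
    values
  }
  n_usable <- sum(!is.na(source_values))
  if (n_usable < 20) {
    warn(sprintf(
      "only %d usable positions (< 20); returning unnormalized profile", n_usable))
    profile$normalized_reactivity <- NA_real_
    attr(profile, "normalization_multiplier") <- NA_real_
    return(profile)
  }
  mult <- box_multiplier(source_values)
  norm <- values * mult
  if (clip_negative) norm <- pmax(norm, 0)
  profile$normalized_reactivity <- norm
  attr(profile, "normalization_multiplier") <- mult
  profile
}

MAP_MISSING <- -999

#' Write / read a reactivity profile
#'
#' `write_profile()` writes a community-style `.map` TSV (1-based position,
#' reactivity, standard-error placeholder, nucleotide; missing encoded as
#' -999) and, optionally, an extended TSV with rates, depths and mask.
#' `read_profile()` reads the `.map` file back, decoding -999 as missing.
#'
#' @param profile Profile tibble (normalized if available, else raw).
#' @param path Output `.map` path.
#' @param extended_path Optional path for the extended profile TSV.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a tibble with `position`, `nt`, `normalized_reactivity`.
#' @export
write_profile <- function(profile, path, extended_path = NULL) {
  if (nrow(profile) == 0) stop_input("refusing to write an empty profile")
  value <- if ("normalized_reactivity" %in% names(profile)) {
    profile$normalized_reactivity
  } else {
    profile$raw_reactivity
  }
  map <- tibble(
    position = profile$position,
    reactivity = ifelse(is.na(value), MAP_MISSING, value),
    stderr = 0,
    nt = profile$nt
  )
  readr::write_tsv(map, path, col_names = FALSE)
  if (!is.null(extended_path)) {
    readr::write_tsv(profile, extended_path)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop_input("empty profile file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 4L)
  if (length(bad) > 0) {
    stop_input("malformed profile line %d in %s (expected 4 fields, got %d)",
               bad[1], path, n_fields[bad[1]])
  }
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  val <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos)) {
    stop_input("malformed position at line %d in %s", which(is.na(pos))[1], path)
  }
  if (anyNA(val)) {
    stop_input("malformed reactivity at line %d in %s", which(is.na(val))[1], path)
  }
  tibble(position = pos,
         nt = vapply(fields, `[[`, "", 4L),
         normalized_reactivity = ifelse(val == MAP_MISSING, NA_real_, val))
}
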