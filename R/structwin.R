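# Pull a per-position numeric vector out of a profile tibble or a plain
# numeric vector; NA marks missing positions.
profile_values <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x)) {
    for (col in c("normalized_reactivity", "raw_reactivity", "value", "reactivity")) {
      if (col %in% names(x)) return(as.numeric(x[[col]]))
    }
  }
  stop_input("cannot extract per-position values; supply a numeric vector or a profile tibble")
}

# Force an odd, centered window size; even sizes are rounded up with a note.
odd_window <- function(window_size, min_size) {
  w <- as.integer(window_size)
  if (w < min_size) stop_input("window_size must be >= %d", min_size)
  if (w %% 2L == 0L) {
    w <- w + 1L
    message(sprintf("even window rounded up to %d", w))
  }
  w
}

#' Sliding median reactivity track
#'
#' Median reactivity over a centered moving window, the track used to
#' delineate structured (low median SHAPE) and unstructured (high median
#' SHAPE) regions. Windows extending past either transcript end are missing
#' (no shrinking); a window with fewer than 50% usable positions is missing.
#'
#' @param profile Profile tibble or numeric vector of per-position values
#'   (NA = missing).
#' @param window_size Window width in nt; typically 40-50. Even widths are
#'   rounded up to the next odd value so the window stays centered.
#' @return A tibble with `position` and `value`; `attr(, "window_size")` and
#'   `attr(, "statistic")` record the track parameters.
#' @export
sliding_median <- function(profile, window_size = 41L) {
  v <- profile_values(profile)
  w <- odd_window(window_size, 3L)
  L <- length(v)
  if (w > L) stop_input("window (%d) larger than transcript (%d)", w, L)
  h <- (w - 1L) %/% 2L
  out <- rep(NA_real_, L)
  for (i in (h + 1L):(L - h)) {
    win <- v[(i - h):(i + h)]
    usable <- sum(!is.na(win))
    if (usable >= w / 2) out[i] <- median(win, na.rm = TRUE)
  }
  track <- tibble(position = seq_len(L), value = out)
  attr(track, "window_size") <- w
  attr(track, "statistic") <- "median"
  track
}

#' Multi-scale sliding-window correlation of two profiles
#'
#' Per-position Pearson correlation between two equal-length profiles over a
#' centered window, computed at each requested scale (e.g. 10-50 nt),
#' exposing where two conditions agree or disagree structurally. Pairwise
#' complete positions are used; a position is missing if fewer than 5
#' complete pairs remain or either window is constant, or if the window
#' extends past the transcript.
#'
#' @param profile_a,profile_b Profile tibbles or numeric vectors, equal length.
#' @param window_sizes Integer vector of window widths (each >= 5; even
#'   widths rounded up to odd).
#' @return A long tibble with `position`, `window_size`, `value` (Pearson r).
#' @export
multiscale_correlation <- function(profile_a, profile_b,
                                   window_sizes = seq(10L, 50L, by = 10L)) {
  a <- profile_values(profile_a)
  b <- profile_values(profile_b)
  if (length(a) != length(b)) {
    stop_input("profiles differ in length (%d vs %d)", length(a), length(b))
  }
  L <- length(a)
  purrr::map_dfr(window_sizes, function(ws) {
    w <- odd_window(ws, 5L)
    if (w > L) stop_input("window (%d) larger than transcript (%d)", w, L)
    h <- (w - 1L) %/% 2L
    out <- rep(NA_real_, L)
    for (i in (h + 1L):(L - h)) {
      ia <- a[(i - h):(i + h)]
      ib <- b[(i - h):(i + h)]
      ok <- !is.na(ia) & !is.na(ib)
      if (sum(ok) < 5L) next
      if (sd(ia[ok]) == 0 || sd(ib[ok]) == 0) next
      out[i] <- cor(ia[ok], ib[ok])
    }
    tibble(position = seq_len(L), window_size = w, value = out)
  })
}

#' Call similar / dissimilar regions from a correlation track
#'
#' Positions whose track value exceeds `mean + threshold_sd * SD` (over
#' defined positions) are similar; below `mean - threshold_sd * SD`,
#' dissimilar (default 0.75 SD). Adjacent qualifying positions are merged
#' into intervals.
#'
#' @param track Tibble with `position` and `value` (e.g. one scale of
#'   [multiscale_correlation()]), or a numeric vector.
#' @param threshold_sd Threshold in standard deviations from the mean.
#' @return Tibble of class `region_calls` with `start`, `end` (1-based,
#'   inclusive) and `class` (`"similar"`/`"dissimilar"`). Track mean and SD
#'   are stored as attributes.
#' @export
call_regions <- function(track, threshold_sd = 0.75) {
  v <- if (is.data.frame(track)) track$value else as.numeric(track)
  defined <- !is.na(v)
  if (length(unique(v[defined])) < 2) {
    warn("track has fewer than 2 distinct defined values; no regions called")
    out <- tibble(start = integer(), end = integer(), class = character())
  } else {
    m <- mean(v[defined])
    s <- sd(v[defined])
    hi <- defined & v > m + threshold_sd * s
    lo <- defined & v < m - threshold_sd * s
    out <- bind_rows(runs_to_intervals(hi, "similar"),
                     runs_to_intervals(lo, "dissimilar"))
    attr(out, "track_mean") <- m
    attr(out, "track_sd") <- s
  }
  attr(out, "threshold_sd") <- threshold_sd
  class(out) <- c("region_calls", class(out))
  out
}

runs_to_intervals <- function(flag, label) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep], class = label)
}

# Place `lengths` non-overlapping intervals uniformly at random on
# [1, transcript_length] (stars-and-bars over the free space).
place_regions_uniform <- function(lengths, transcript_length) {
  k <- length(lengths)
  lens <- lengths[sample.int(k)]  # random order
  free <- transcript_length - sum(lens)
  slots <- sort(sample.int(free + k, k))
  starts <- slots - seq_len(k) + 1L + c(0L, cumsum(lens))[seq_len(k)]
  tibble(start = as.integer(starts), end = as.integer(starts + lens - 1L))
}

# Count feature overlap with regions: positions falling inside, or intervals
# touching, any region.
overlap_count <- function(features, regions) {
  if (is.numeric(features)) {
    covered <- unlist(purrr::map2(regions$start, regions$end, seq.int),
                      use.names = FALSE)
    return(sum(features %in% covered))
  }
  sum(vapply(seq_len(nrow(features)), function(i) {
    any(features$start[i] <= regions$end & features$end[i] >= regions$start)
  }, logical(1)))
}

#' Bootstrap enrichment of annotation features within called regions
#'
#' Tests whether features (splice sites, protein-binding sites, conserved
#' nucleotides, ...) overlap the called regions more than expected by
#' re-placing intervals of the same lengths uniformly (non-overlapping) on
#' the transcript. The default p-value is `(1 + #{null >= observed}) /
#' (n_boot + 1)`; because overlap counts are small integers, ties with the
#' observed count make this conservative, and `p_method = "mid"` applies the
#' standard mid-p correction (ties weighted 1/2), which is calibrated under
#' a uniform null.
#'
#' @param regions Region tibble (`start`, `end`, 1-based inclusive), e.g.
#'   one class of [call_regions()].
#' @param features Integer vector of feature positions, or a tibble of
#'   feature intervals (`start`, `end`).
#' @param transcript_length Transcript length (nt).
#' @param n_boot Number of bootstrap replicates.
#' @param alternative `"enrichment"` (observed high), `"depletion"`, or
#'   `"two_sided"`.
#' @param p_method `"add_one"` (the formula above) or `"mid"`.
#' @param seed Optional RNG seed (local).
#' @return List of class `enrichment_test`: `observed`, `null` (numeric
#'   vector), `expected` (null mean), `p_value`, plus the call parameters.
#' @export
bootstrap_enrichment <- function(regions, features, transcript_length,
                                 n_boot = 1000L,
                                 alternative = c("enrichment", "depletion", "two_sided"),
                                 p_method = c("add_one", "mid"),
                                 seed = NULL) {
  alternative <- match.arg(alternative)
  p_method <- match.arg(p_method)
  if (nrow(regions) == 0) stop_input("no regions supplied")
  if (any(regions$start < 1L) || any(regions$end > transcript_length)) {
    stop_input("regions fall outside [1, transcript_length]")
  }
  lens <- regions$end - regions$start + 1L
  if (sum(lens) > transcript_length) {
    stop_input("regions are longer than the transcript")
  }
  observed <- overlap_count(features, regions)
  with_seed(seed, {
    null <- vapply(seq_len(n_boot), function(b) {
      overlap_count(features, place_regions_uniform(lens, transcript_length))
    }, 0)
    p_one <- function(extreme, ties) {
      switch(p_method,
             add_one = (1 + extreme + ties) / (n_boot + 1),
             mid = (0.5 + extreme + 0.5 * ties) / (n_boot + 1))
    }
    ties <- sum(null == observed)
    p_enr <- p_one(sum(null > observed), ties)
    p_dep <- p_one(sum(null < observed), ties)
    p <- switch(alternative,
                enrichment = p_enr,
                depletion = p_dep,
                two_sided = min(1, 2 * min(p_enr, p_dep)))
    structure(list(observed = observed, null = null, expected = mean(null),
                   p_value = p, alternative = alternative,
                   p_method = p_method, n_boot = n_boot),
              class = "enrichment_test")
  })
}

#' Mean conservation score by region class
#'
#' Averages a per-position score track (e.g. PhyloP: positive = conserved,
#' negative = accelerated) over similar regions, dissimilar regions and the
#' remainder of the transcript, and reports the similar-minus-dissimilar
#' difference.
#'
#' @param scores Numeric vector of per-position scores (NA allowed) or a
#'   tibble with `position` and `score`.
#' @param regions A [call_regions()] result.
#' @return A tibble with `class`, `mean_score`, `n_positions`; the
#'   similar-dissimilar difference is in `attr(, "difference")` (NA when a
#'   class has no scored positions).
#' @export
conservation_by_class <- function(scores, regions) {
  if (is.data.frame(scores)) {
    v <- rep(NA_real_, max(scores$position))
    v[scores$position] <- scores$score
  } else {
    v <- as.numeric(scores)
  }
  classes <- rep("neither", length(v))
  for (i in seq_len(nrow(regions))) {
    span <- regions$start[i]:regions$end[i]
    span <- span[span <= length(v)]
    classes[span] <- regions$class[i]
  }
  out <- tibble(class = classes, score = v) |>
    filter(!is.na(.data$score)) |>
    group_by(.data$class) |>
    summarise(mean_score = mean(.data$score),
              n_positions = dplyr::n(), .groups = "drop")
  for (cl in c("similar", "dissimilar")) {
    if (!cl %in% out$class && cl %in% regions$class) {
      warn(sprintf("no scored positions in %s regions; class mean undefined", cl))
    }
  }
  ms <- out$mean_score[out$class == "similar"]
  md <- out$mean_score[out$class == "dissimilar"]
  attr(out, "difference") <- if (length(ms) == 1 && length(md) == 1) ms - md else NA_real_
  out
}

#' Write / read interval and track files in BED conventions
#'
#' Interval I/O uses BED coordinates (0-based half-open); the package's
#' in-memory intervals are 1-based inclusive, and conversion happens here.
#' `write_bedgraph()`/`read_bedgraph()` handle per-position score tracks.
#'
#' @param regions Tibble with `start`, `end` (1-based inclusive) and
#'   optionally `class`.
#' @param path File path.
#' @param chrom Sequence name written in the first column.
#' @return Readers return tibbles in the package's 1-based convention.
#' @export
write_bed <- function(regions, path, chrom = "transcript") {
  name <- if ("class" %in% names(regions)) regions$class else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, regions$start - 1L,
                     regions$end, name), path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  out <- tibble(start = as.integer(raw[[2]]) + 1L, end = as.integer(raw[[3]]))
  if (ncol(raw) >= 4) out$class <- as.character(raw[[4]])
  out
}

#' @rdname write_bed
#' @param track Tibble with `position`, `value`.
#' @export
write_bedgraph <- function(track, path, chrom = "transcript") {
  keep <- !is.na(track$value)
  writeLines(sprintf("%s\t%d\t%d\t%g", chrom, track$position[keep] - 1L,
                     track$position[keep], track$value[keep]), path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         show_col_types = FALSE, progress = FALSE)
  tibble(position = as.integer(raw$start) + 1L, value = raw$value)
}
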