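#' Specify a single-nucleotide variant on a transcript
#'
#' @param position 1-based transcript coordinate of the variant.
#' @param ref_base,alt_base Reference and alternate bases (A/C/G/T; U is
#'   accepted and mapped to T). Must differ.
#' @param id Free-text label (e.g. a dbSNP or COSMIC identifier).
#' @return A one-row tibble of class `variant_spec`.
#' @examples
#' variant_spec(101, "G", "A", id = "rs0000001")
#' @export
variant_spec <- function(position, ref_base, alt_base, id = "variant") {
  ref_base <- normalize_sequence(ref_base)
  alt_base <- normalize_sequence(alt_base)
  if (nchar(ref_base) != 1L || nchar(alt_base) != 1L) {
    stop_input("ref_base and alt_base must be single nucleotides")
  }
  if (ref_base == alt_base) stop_input("ref_base and alt_base must differ")
  position <- as.integer(position)
  if (is.na(position) || position < 1L) {
    stop_input("`position` must be a positive 1-based coordinate")
  }
  out <- tibble(id = as.character(id), position = position,
                ref_base = ref_base, alt_base = alt_base)
  class(out) <- c("variant_spec", class(out))
  out
}

as_variant_spec <- function(x) {
  if (inherits(x, "variant_spec")) return(x)
  if (is.data.frame(x) && all(c("position", "ref_base", "alt_base") %in% names(x))) {
    return(variant_spec(x$position[1], x$ref_base[1], x$alt_base[1],
                        id = if ("id" %in% names(x)) x$id[1] else "variant"))
  }
  stop_input("cannot interpret `variant`; use variant_spec()")
}

# Base and quality observed at reference `position` for each read.
# Fast path for pure-match CIGARs; general CIGAR walk otherwise.
# Deletions spanning the site yield base "-" (a gap observation).
read_base_at <- function(reads, position) {
  n <- nrow(reads)
  base <- rep(NA_character_, n)
  qual <- rep(NA_integer_, n)
  simple <- grepl("^[0-9]+M$", reads$cigar)
  if (any(simple)) {
    len <- as.integer(sub("M$", "", reads$cigar[simple]))
    off <- position - reads$pos[simple] + 1L
    cov <- off >= 1L & off <= len
    i <- which(simple)[cov]
    o <- off[cov]
    base[i] <- substr(reads$seq[i], o, o)
    qual[i] <- phred_from_qual(substr(reads$qual[i], o, o))
  }
  for (i in which(!simple)) {
    ops <- cigar_ops(reads$cigar[i])
    rpos <- reads$pos[i]   # next reference position
    qpos <- 1L             # next query (seq) position
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]; ln <- ops$len[k]
      if (op %in% c("M", "=", "X")) {
        if (position >= rpos && position < rpos + ln) {
          q <- qpos + (position - rpos)
          base[i] <- substr(reads$seq[i], q, q)
          qual[i] <- phred_from_qual(substr(reads$qual[i], q, q))
          break
        }
        rpos <- rpos + ln; qpos <- qpos + ln
      } else if (op %in% c("D", "N")) {
        if (position >= rpos && position < rpos + ln) {
          base[i] <- "-"
          qual[i] <- 0L
          break
        }
        rpos <- rpos + ln
      } else if (op %in% c("I", "S")) {
        qpos <- qpos + ln
      } else if (op == "H") {
        # consumes neither
      } else {
        stop_input("unsupported CIGAR op '%s'", op)
      }
    }
  }
  tibble(base = base, qual = qual)
}

cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  tibble(len = lens, op = ops)
}

#' Assign read pairs to alleles by the base at the variant site
#'
#' For each read pair (grouped by `qname`), the base observed at the variant
#' position decides the call: `ref` or `alt` when one mate covers the site
#' (or both cover and agree), `other` when the covering base matches neither
#' allele, is a gap, is below `min_base_quality`, or the mates disagree, and
#' `unassigned` when no mate covers the site.
#'
#' @param reads Read tibble (see [simulate_reads()] / [read_alignments()]).
#' @param variant A [variant_spec()].
#' @param min_base_quality Minimum Phred base quality for allele evidence.
#' @return Tibble with one row per read pair: `qname`, `call`,
#'   `evidence_base`, `evidence_quality`.
#' @export
assign_alleles <- function(reads, variant, min_base_quality = 20L) {
  variant <- as_variant_spec(variant)
  if (nrow(reads) == 0) {
    return(tibble(qname = character(), call = character(),
                  evidence_base = character(), evidence_quality = integer()))
  }
  obs <- read_base_at(reads, variant$position)
  covering <- !is.na(obs$base)
  usable <- covering & obs$base != "-" & !is.na(obs$qual) &
    obs$qual >= min_base_quality
  is_ref <- usable & obs$base == variant$ref_base
  is_alt <- usable & obs$base == variant$alt_base
  qn <- factor(reads$qname)
  agg <- rowsum(cbind(cover = as.integer(covering),
                      usable = as.integer(usable),
                      ref = as.integer(is_ref),
                      alt = as.integer(is_alt)),
                group = qn, reorder = TRUE)
  # a pair is ref/alt only if every usable covering base agrees with that
  # allele; any disagreement (mate conflict or third base) falls to `other`
  call <- rep("other", nrow(agg))
  call[agg[, "cover"] == 0L] <- "unassigned"
  call[agg[, "usable"] > 0L & agg[, "ref"] == agg[, "usable"]] <- "ref"
  call[agg[, "usable"] > 0L & agg[, "alt"] == agg[, "usable"]] <- "alt"

  evidence_base <- rep(NA_character_, nrow(agg))
  evidence_quality <- rep(NA_integer_, nrow(agg))
  cov_rows <- which(covering)
  first_cov <- cov_rows[!duplicated(qn[cov_rows])]
  slot <- match(as.character(qn[first_cov]), rownames(agg))
  evidence_base[slot] <- obs$base[first_cov]
  evidence_quality[slot] <- obs$qual[first_cov]

  tibble(qname = rownames(agg), call = call,
         evidence_base = evidence_base, evidence_quality = evidence_quality)
}

#' Sort reads into per-allele read sets
#'
#' Applies [assign_alleles()] and splits the input into disjoint `ref` and
#' `alt` read sets; `other` and `unassigned` pairs are excluded from both.
#'
#' @inheritParams assign_alleles
#' @param ref_path,alt_path Optional SAM output paths for the two sets.
#' @param ref_name,ref_length Header fields used when writing SAM.
#' @return A list with `ref` and `alt` read tibbles, the per-pair
#'   `assignments`, and `counts` (tibble of `call`, `n` over all four calls).
#' @export
sort_reads <- function(reads, variant, min_base_quality = 20L,
                       ref_path = NULL, alt_path = NULL,
                       ref_name = "ref", ref_length = NULL) {
  assignments <- assign_alleles(reads, variant, min_base_quality)
  counts <- tibble(call = c("ref", "alt", "other", "unassigned")) |>
    left_join(count(assignments, .data$call), by = "call") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  pick <- function(which_call) {
    qn <- assignments$qname[assignments$call == which_call]
    reads |> filter(.data$qname %in% qn)
  }
  out <- list(ref = pick("ref"), alt = pick("alt"),
              assignments = assignments, counts = counts)
  paired <- any(reads$mate == 2L)
  if (!is.null(ref_path)) {
    write_sam(out$ref, ref_path, ref_name, ref_length %||% max(reads$pos + nchar(reads$seq)) - 1L,
              paired = paired)
  }
  if (!is.null(alt_path)) {
    write_sam(out$alt, alt_path, ref_name, ref_length %||% max(reads$pos + nchar(reads$seq)) - 1L,
              paired = paired)
  }
  out
}

#' Estimate the alternate-allele fraction from sorting counts
#'
#' Point estimate `alt / (ref + alt)` with a 95% Wilson score interval
#' (via `prop.test` without continuity correction). Useful as a QC readout
#' of mutagenesis efficiency / spike-in ratio.
#'
#' @param counts Either the `counts` tibble from [sort_reads()] or a named
#'   vector/list with `ref` and `alt`.
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble: `n_ref`, `n_alt`, `fraction_alt`, `conf_low`,
#'   `conf_high`.
#' @export
estimate_allele_fraction <- function(counts, conf_level = 0.95) {
  if (is.data.frame(counts)) {
    n_ref <- counts$n[counts$call == "ref"]
    n_alt <- counts$n[counts$call == "alt"]
  } else {
    n_ref <- counts[["ref"]]
    n_alt <- counts[["alt"]]
  }
  n <- n_ref + n_alt
  if (length(n) == 0 || n == 0) {
    stop_input("no informative (ref/alt) reads: allele fraction undefined")
  }
  ci <- stats::prop.test(n_alt, n, conf.level = conf_level,
                         correct = FALSE)$conf.int
  tibble(n_ref = as.integer(n_ref), n_alt = as.integer(n_alt),
         fraction_alt = n_alt / n,
         conf_low = ci[1], conf_high = ci[2])
}
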