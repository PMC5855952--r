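#' Simulation configuration for synthetic MaP read sets
#'
#' Bundles the parameters of the mutational-profiling read simulator.
#' `mod_detection_scale` maps ground-truth reactivity to a per-nucleotide
#' adduct-detection (mutation) probability in the treated channel;
#' `background_rate` is the combined background mutation / sequencing error
#' rate applied in both channels. `allele_fraction_alt` is the fraction of
#' fragments carrying the alternate allele when a variant is simulated,
#' defaulting to 0.75 (more reads on the mutant than on the spiked-in
#' wild type, matching the ratiometric 75/25 analysis design).
#'
#' @param depth Number of simulated fragments (read pairs if `paired_end`).
#' @param read_length Read length in nt.
#' @param paired_end Simulate mate pairs (2 x `read_length`)?
#' @param fragment_length_mean,fragment_length_sd Fragment length distribution
#'   (normal, rounded, clamped to `[read_length, reference length]`).
#' @param mod_detection_scale Treated-channel mutation probability per unit of
#'   ground-truth reactivity.
#' @param background_rate Background mutation probability per nucleotide.
#' @param allele_fraction_alt Fraction of fragments carrying the alt allele.
#' @param replicate_noise_sd Log-scale SD of multiplicative between-replicate
#'   reactivity noise (see [perturb_replicate()]).
#' @param seed Integer seed making the simulation deterministic.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(depth = 5000L, read_length = 50L, paired_end = TRUE,
                       fragment_length_mean = 150, fragment_length_sd = 30,
                       mod_detection_scale = 0.03, background_rate = 0.002,
                       allele_fraction_alt = 0.75, replicate_noise_sd = 0.3,
                       seed = 1L) {
  cfg <- list(
    depth = as.integer(depth), read_length = as.integer(read_length),
    paired_end = isTRUE(paired_end),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    mod_detection_scale = mod_detection_scale,
    background_rate = background_rate,
    allele_fraction_alt = allele_fraction_alt,
    replicate_noise_sd = replicate_noise_sd,
    seed = as.integer(seed)
  )
  if (cfg$depth <= 0L) stop_input("`depth` must be > 0")
  if (cfg$read_length <= 0L) stop_input("`read_length` must be > 0")
  for (p in c("background_rate", "allele_fraction_alt")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_input("`%s` must be in [0, 1]", p)
  }
  if (cfg$mod_detection_scale < 0) stop_input("`mod_detection_scale` must be >= 0")
  if (cfg$replicate_noise_sd < 0) stop_input("`replicate_noise_sd` must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Build a ground-truth SHAPE reactivity profile from a secondary structure
#'
#' Draws per-nucleotide reactivities from two gamma distributions: unpaired
#' positions from a high-reactivity distribution and paired positions from a
#' low-reactivity one, so that structured regions show low reactivity and
#' flexible regions high reactivity, as in SHAPE probing. Defaults give mean
#' reactivities of about 1.4 (unpaired) and 0.1 (paired) in normalized SHAPE
#' units.
#'
#' @param sequence Nucleotide string over A/C/G/U/T.
#' @param structure Either a dot-bracket string of the same length or a
#'   logical paired-mask vector (`TRUE` = paired).
#' @param unpaired_params,paired_params Lists with `shape` and `rate` of the
#'   gamma distributions for unpaired and paired positions.
#' @param seed Optional RNG seed (local to this call).
#' @return A tibble with columns `position` (1-based), `nt` (RNA alphabet),
#'   `paired` and `reactivity`, with the DNA-normalized sequence stored in
#'   `attr(, "sequence")`.
#' @examples
#' make_profile("GGGAAACCC", "(((...)))", seed = 1)
#' @export
make_profile <- function(sequence, structure,
                         unpaired_params = list(shape = 2.2, rate = 1.6),
                         paired_params = list(shape = 0.8, rate = 8),
                         seed = NULL) {
  seq_dna <- normalize_sequence(sequence)
  n <- nchar(seq_dna)
  if (is.character(structure)) {
    if (nchar(structure) != n) {
      stop_input("sequence length (%d) and structure length (%d) differ",
                 n, nchar(structure))
    }
    paired <- !is.na(dotbracket_pairs(structure))
  } else if (is.logical(structure)) {
    if (length(structure) != n) {
      stop_input("sequence length (%d) and paired-mask length (%d) differ",
                 n, length(structure))
    }
    paired <- structure
  } else {
    stop_input("`structure` must be a dot-bracket string or a logical mask")
  }
  with_seed(seed, {
    reactivity <- numeric(n)
    n_up <- sum(!paired)
    n_p <- sum(paired)
    if (n_up > 0) {
      reactivity[!paired] <- rgamma(n_up, shape = unpaired_params$shape,
                                    rate = unpaired_params$rate)
    }
    if (n_p > 0) {
      reactivity[paired] <- rgamma(n_p, shape = paired_params$shape,
                                   rate = paired_params$rate)
    }
    out <- tibble(
      position = seq_len(n),
      nt = strsplit(to_rna(seq_dna), "")[[1]],
      paired = paired,
      reactivity = reactivity
    )
    attr(out, "sequence") <- seq_dna
    out
  })
}

#' Apply between-replicate noise to a ground-truth profile
#'
#' Multiplies each reactivity by an independent lognormal factor with the
#' given log-scale SD, emulating the tube-to-tube variability that separates
#' replicate SHAPE experiments. An SD of zero returns the profile unchanged.
#'
#' @param profile A profile tibble from [make_profile()].
#' @param replicate_noise_sd Log-scale SD of the multiplicative noise (>= 0).
#' @param seed Optional RNG seed (local to this call).
#' @return The profile with perturbed `reactivity`.
#' @export
perturb_replicate <- function(profile, replicate_noise_sd, seed = NULL) {
  if (replicate_noise_sd < 0) stop_input("`replicate_noise_sd` must be >= 0")
  if (replicate_noise_sd == 0) return(profile)
  with_seed(seed, {
    profile$reactivity <- profile$reactivity *
      exp(rnorm(nrow(profile), 0, replicate_noise_sd))
    profile
  })
}

profile_sequence <- function(profile) {
  s <- attr(profile, "sequence")
  if (is.null(s)) s <- normalize_sequence(paste(profile$nt, collapse = ""))
  s
}

#' Simulate an allele-mixed MaP read set from a ground-truth profile
#'
#' Emulates SHAPE-MaP chemistry: in the treated channel each nucleotide of a
#' fragment mutates with probability
#' `clamp(background_rate + mod_detection_scale * reactivity, 0, 1)`; the
#' untreated channel uses `background_rate` alone. Mutations are substitutions
#' to a uniformly random non-template base. When a variant is supplied, each
#' fragment carries the alternate allele with probability
#' `allele_fraction_alt`; its true allele is recorded in the returned truth
#' table (and in the sidecar truth TSV), never in the SAM.
#'
#' @param profile Ground-truth profile from [make_profile()].
#' @param config A [sim_config()].
#' @param variant Optional [variant_spec()] placing a single-nucleotide
#'   variant on the reference.
#' @param profile_alt Optional ground-truth profile for fragments carrying
#'   the alt allele (defaults to `profile`); lets a riboSNitch scenario give
#'   the two alleles different reactivity landscapes within one tube.
#' @param channel `"treated"` (1M7) or `"untreated"` (DMSO background).
#' @param sam_path Optional path; when given, a SAM v1.6 file is written.
#' @param truth_path Optional path for the sidecar truth TSV
#'   (`qname`, `allele`).
#' @param fasta_path Optional path; writes the reference as FASTA.
#' @param ref_name Reference name used in SAM/FASTA headers.
#' @param base_quality Constant Phred quality assigned to all base calls.
#' @return A list with `reads` (tibble: `qname`, `mate`, `pos`, `cigar`,
#'   `seq`, `qual`) and `truth` (tibble: `qname`, `allele`).
#' @export
simulate_reads <- function(profile, config = sim_config(), variant = NULL,
                           channel = c("treated", "untreated"),
                           profile_alt = NULL,
                           sam_path = NULL, truth_path = NULL,
                           fasta_path = NULL, ref_name = "ref",
                           base_quality = 37L) {
  channel <- match.arg(channel)
  ref <- profile_sequence(profile)
  L <- nchar(ref)
  rl <- config$read_length
  if (rl > L) stop_input("read_length (%d) exceeds reference length (%d)", rl, L)
  if (config$fragment_length_mean > L) {
    stop_input("mean fragment length (%s) exceeds reference length (%d)",
               format(config$fragment_length_mean), L)
  }
  if (!is.null(variant)) {
    variant <- as_variant_spec(variant)
    if (variant$position < 1L || variant$position > L) {
      stop_input("variant position %d outside reference [1, %d]",
                 variant$position, L)
    }
    ref_at <- substr(ref, variant$position, variant$position)
    if (ref_at != variant$ref_base) {
      stop_input("variant ref_base %s does not match reference base %s at %d",
                 variant$ref_base, ref_at, variant$position)
    }
  }
  treated_p <- function(prof) {
    pmin(pmax(config$background_rate +
                config$mod_detection_scale * prof$reactivity, 0), 1)
  }
  p_mut <- if (channel == "treated") treated_p(profile) else {
    rep(config$background_rate, L)
  }
  p_mut_alt <- if (channel == "treated" && !is.null(profile_alt)) {
    if (nrow(profile_alt) != L) {
      stop_input("`profile_alt` length differs from `profile`")
    }
    treated_p(profile_alt)
  } else {
    p_mut
  }

  # channel offset keeps treated/untreated streams distinct at a shared seed
  seed_use <- config$seed + if (channel == "untreated") 1L else 0L
  with_seed(seed_use, {
    n <- config$depth
    flen <- as.integer(round(rnorm(n, config$fragment_length_mean,
                                   config$fragment_length_sd)))
    flen <- pmin(pmax(flen, rl), L)
    fstart <- 1L + as.integer(floor(runif(n) * (L - flen + 1L)))
    fend <- fstart + flen - 1L
    allele <- if (is.null(variant)) {
      rep("ref", n)
    } else {
      ifelse(runif(n) < config$allele_fraction_alt, "alt", "ref")
    }
    qname <- sprintf("frag%07d", seq_len(n))

    # per-mate (or single-end) windows, all exactly `rl` long
    if (config$paired_end) {
      starts <- c(fstart, fend - rl + 1L)
      mate <- rep(1:2, each = n)
      rid <- rep(seq_len(n), 2L)
    } else {
      starts <- fstart
      mate <- rep(1L, n)
      rid <- seq_len(n)
    }
    nreads <- length(starts)
    posmat <- outer(starts, 0:(rl - 1L), `+`)  # nreads x rl reference positions
    ref_chars <- strsplit(ref, "")[[1]]
    base_mat <- matrix(ref_chars[posmat], nrow = nreads)
    if (!is.null(variant)) {
      hit <- which(posmat == variant$position &
                     allele[rid] == "alt")
      base_mat[hit] <- variant$alt_base
    }
    pm <- matrix(p_mut[posmat], nrow = nreads)
    alt_rows <- which(allele[rid] == "alt")
    if (length(alt_rows) > 0 && !identical(p_mut_alt, p_mut)) {
      pm[alt_rows, ] <- p_mut_alt[posmat[alt_rows, , drop = FALSE]]
    }
    mut <- runif(nreads * rl) < pm
    if (any(mut)) {
      idx <- which(mut)
      cur <- base_mat[idx]
      pick <- 1L + as.integer(floor(runif(length(idx)) * 3))
      base_mat[idx] <- vapply(seq_along(idx),
                              function(k) OTHER_BASES[[cur[k]]][pick[k]],
                              character(1))
    }
    seqs <- do.call(paste0, lapply(seq_len(rl), function(j) base_mat[, j]))
    reads <- tibble(
      qname = qname[rid],
      mate = mate,
      pos = starts,
      cigar = paste0(rl, "M"),
      seq = seqs,
      qual = strrep(qual_char(as.integer(base_quality)), rl)
    ) |>
      arrange(.data$qname, .data$mate)
    truth <- tibble(qname = qname, allele = allele)
    if (!is.null(sam_path)) {
      write_sam(reads, sam_path, ref_name = ref_name, ref_length = L,
                paired = config$paired_end)
    }
    if (!is.null(truth_path)) {
      readr::write_tsv(truth, truth_path)
    }
    if (!is.null(fasta_path)) {
      writeLines(c(paste0(">", ref_name), ref), fasta_path)
    }
    list(reads = reads, truth = truth)
  })
}

#' Write an aligned read tibble as a SAM file
#'
#' Emits a SAM v1.6 file with a single `@SQ` reference line. Reads must carry
#' `qname`, `mate`, `pos`, `cigar`, `seq`, `qual` (the tibble produced by
#' [simulate_reads()] or [read_alignments()]).
#'
#' @param reads Read tibble.
#' @param path Output path.
#' @param ref_name,ref_length Reference name and length for the header.
#' @param paired Whether reads are mate pairs (sets SAM flags accordingly).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, ref_name, ref_length, paired = TRUE) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_length)))
  if (paired) {
    flags <- ifelse(reads$mate == 1L, 99L, 147L)
    # mate coordinates: join mate rows by qname
    mate_pos <- reads |>
      select("qname", "mate", "pos") |>
      mutate(mate = 3L - .data$mate)
    rd <- left_join(reads, mate_pos, by = c("qname", "mate"),
                    suffix = c("", "_mate"), relationship = "many-to-many")
    rl <- nchar(rd$seq)
    tlen <- ifelse(rd$mate == 1L,
                   rd$pos_mate + rl - rd$pos,
                   -(rd$pos + rl - rd$pos_mate))
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t=\t%d\t%d\t%s\t%s",
                    rd$qname, flags, ref_name, rd$pos, rd$cigar,
                    rd$pos_mate, tlen, rd$seq, rd$qual)
  } else {
    body <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
                    reads$qname, ref_name, reads$pos, reads$cigar,
                    reads$seq, reads$qual)
  }
  con <- file(path, open = "wb")  # fixed EOL across platforms
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read aligned reads from SAM/BAM into a tibble
#'
#' Uses Rsamtools: SAM input is first converted to BAM (`asBam`), then
#' scanned. Unmapped reads are dropped with a warning.
#'
#' @param path A `.sam` or `.bam` file.
#' @return Tibble with `qname`, `mate`, `pos`, `cigar`, `seq`, `qual`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "pos", "cigar", "seq", "qual")
    )
  )[[1]]
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  if (any(unmapped)) {
    warn(sprintf("dropping %d unmapped read(s)", sum(unmapped)))
  }
  keep <- !unmapped
  mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
  tibble(
    qname = res$qname[keep],
    mate = mate[keep],
    pos = res$pos[keep],
    cigar = res$cigar[keep],
    seq = as.character(res$seq)[keep],
    qual = as.character(res$qual)[keep]
  ) |>
    arrange(.data$qname, .data$mate)
}
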