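#' Parse dot-bracket structure samples
#'
#' Validates a set of dot-bracket strings (one structure per line): all
#' structures must parse (balanced, pseudoknot-free) and share one length.
#' Parse failures report the offending line number.
#'
#' @param lines Character vector of dot-bracket strings.
#' @param source Source label for the sample (e.g. `"ref"`, `"alt"`, a
#'   condition tag).
#' @return A tibble of class `structure_sample` with columns `structure` and
#'   `source`; the common length is in `attr(, "length")`.
#' @export
parse_dotbracket <- function(lines, source = "sample") {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_input("no structures supplied")
  for (i in seq_along(lines)) {
    tryCatch(dotbracket_pairs(lines[i]), error = function(e) {
      stop_input("line %d: %s", i, conditionMessage(e))
    })
  }
  lens <- nchar(lines)
  if (length(unique(lens)) > 1) {
    stop_input("structures have differing lengths (line %d has %d, line 1 has %d)",
               which(lens != lens[1])[1], lens[lens != lens[1]][1], lens[1])
  }
  out <- tibble(structure = lines, source = source)
  attr(out, "length") <- lens[1]
  class(out) <- c("structure_sample", class(out))
  out
}

#' @rdname parse_dotbracket
#' @param path File with one dot-bracket structure per line.
#' @export
read_dotbracket <- function(path, source = "sample") {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  parse_dotbracket(readLines(path), source = source)
}

# Base pairs of a structure encoded as sortable integer keys i*(L+1)+j, i<j.
pair_keys <- function(structure) {
  partner <- dotbracket_pairs(structure)
  L <- length(partner)
  i <- which(!is.na(partner) & partner > seq_along(partner))
  i * (L + 1) + partner[i]
}

#' Base-pair distance between two structures
#'
#' The size of the symmetric difference of the two base-pair sets: the
#' number of pairs present in exactly one structure. This is a metric on
#' structures of a common length.
#'
#' @param s1,s2 Dot-bracket strings of equal length.
#' @return A non-negative integer.
#' @examples
#' bp_distance("((..))", "......")  # 2
#' @export
bp_distance <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) {
    stop_input("structures differ in length (%d vs %d)", nchar(s1), nchar(s2))
  }
  k1 <- pair_keys(s1)
  k2 <- pair_keys(s2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Pairwise base-pair distance matrix
#'
#' @param structures Character vector of equal-length dot-bracket strings.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
bp_distance_matrix <- function(structures) {
  n <- length(structures)
  keys <- lapply(structures, pair_keys)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    ki <- keys[[i]]
    for (j in (i + 1L):n) {
      kj <- keys[[j]]
      dij <- length(setdiff(ki, kj)) + length(setdiff(kj, ki))
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

#' Classical MDS embedding of a structure distance matrix
#'
#' Projects a distance matrix to 2-D with classical multidimensional scaling
#' and reports how faithfully embedded distances preserve the input ranking
#' (Spearman rho).
#'
#' @param distances Symmetric distance matrix.
#' @return List with `coordinates` (tibble `id`, `dim1`, `dim2`) and
#'   `spearman_rho`.
#' @export
embed_2d <- function(distances) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances))) stop_input("distance matrix is not symmetric")
  n <- nrow(distances)
  if (all(distances == 0)) {
    # all structures identical: everything sits at the origin
    return(list(coordinates = tibble(id = seq_len(n), dim1 = 0, dim2 = 0),
                spearman_rho = NA_real_))
  }
  xy <- stats::cmdscale(distances, k = min(2L, n - 1L))
  if (!is.matrix(xy)) xy <- matrix(xy, nrow = n)
  if (ncol(xy) < 2L) {
    # degenerate geometries (collinear or all-identical points)
    xy <- cbind(xy, matrix(0, n, 2L - ncol(xy)))
  }
  emb <- as.matrix(stats::dist(xy))
  lower <- lower.tri(distances)
  rho <- if (sd(distances[lower]) == 0 || sd(emb[lower]) == 0) NA_real_ else {
    suppressWarnings(cor(distances[lower], emb[lower], method = "spearman"))
  }
  list(coordinates = tibble(id = seq_len(n), dim1 = xy[, 1], dim2 = xy[, 2]),
       spearman_rho = rho)
}

#' Cluster two allele ensembles in one shared conformational space
#'
#' Pools the structure samples of both sources, clusters the pooled
#' base-pair distance matrix with PAM k-medoids (the deterministic
#' BUILD/SWAP algorithm), extracts the medoid structure of each cluster, and
#' counts the per-source cluster populations, so the two alleles' ensembles
#' are directly comparable within the same space. `k = "auto"` maximizes the
#' mean silhouette width over k = 2..6; if every structure is identical, k
#' is forced to 1 with a warning.
#'
#' @param sample_ref,sample_alt [parse_dotbracket()] samples of a common
#'   sequence length (typically the ref and alt allele ensembles).
#' @param k Number of clusters, or `"auto"`.
#' @return An object of class `ensemble_map`: `clusters` (tibble `id`,
#'   `source`, `structure`, `cluster`), `medoids` (tibble `cluster`, `id`,
#'   `structure`), `populations` (tibble `source`, `cluster`, `fraction`),
#'   `embedding` (2-D coordinates), `distances`, `k`, `mean_silhouette`,
#'   `embedding_rho`. Supports [tidy()], [glance()], [autoplot()] and
#'   [ensemble_shift()].
#' @export
cluster_shared <- function(sample_ref, sample_alt = NULL, k = "auto") {
  pooled <- if (is.null(sample_alt)) sample_ref else {
    if (attr(sample_ref, "length") != attr(sample_alt, "length")) {
      stop_input("samples have different sequence lengths")
    }
    bind_rows(sample_ref, sample_alt)
  }
  n <- nrow(pooled)
  if (n < 2) stop_input("need at least 2 structures to cluster")
  d <- bp_distance_matrix(pooled$structure)
  all_same <- all(d == 0)
  sil <- NA_real_
  if (all_same) {
    warn("all structures identical; forcing a single cluster")
    k_use <- 1L
    labels <- rep(1L, n)
    medoid_idx <- 1L
  } else if (identical(k, "auto")) {
    ks <- 2:min(6L, n - 1L)
    fits <- lapply(ks, function(kk) cluster::pam(d, kk, diss = TRUE))
    widths <- vapply(fits, function(f) f$silinfo$avg.width, 0)
    best <- which.max(widths)
    k_use <- ks[best]
    sil <- widths[best]
    labels <- fits[[best]]$clustering
    medoid_idx <- fits[[best]]$id.med
  } else {
    k_use <- as.integer(k)
    if (n < 2L * k_use) stop_input("pooled sample (%d) smaller than 2k (%d)", n, 2L * k_use)
    fit <- cluster::pam(d, k_use, diss = TRUE)
    labels <- fit$clustering
    medoid_idx <- fit$id.med
    sil <- if (k_use > 1) fit$silinfo$avg.width else NA_real_
  }
  clusters <- tibble(id = seq_len(n), source = pooled$source,
                     structure = pooled$structure, cluster = as.integer(labels))
  populations <- clusters |>
    count(.data$source, .data$cluster) |>
    tidyr::complete(source = unique(clusters$source),
                    cluster = seq_len(k_use), fill = list(n = 0L)) |>
    group_by(.data$source) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("source", "cluster", "fraction")
  emb <- embed_2d(d)
  structure(
    list(clusters = clusters,
         medoids = tibble(cluster = seq_len(k_use), id = medoid_idx,
                          structure = pooled$structure[medoid_idx]),
         populations = populations,
         embedding = emb$coordinates,
         distances = d,
         k = k_use,
         mean_silhouette = sil,
         embedding_rho = emb$spearman_rho,
         source_levels = unique(pooled$source)),
    class = "ensemble_map"
  )
}

#' Quantify the ensemble shift between two sources
#'
#' Per-cluster population difference (alt minus ref) and the total-variation
#' distance `0.5 * sum(|delta|)` between the two sources' cluster
#' compositions: 0 for identical ensembles, 1 for fully disjoint ones. A
#' riboSNitch typically shifts population into clusters the reference allele
#' does not occupy.
#'
#' @param map An [cluster_shared()] result built from two sources.
#' @return List of class `ensemble_shift`: `deltas` (tibble `cluster`,
#'   `fraction_ref`, `fraction_alt`, `delta`) and `total_variation`.
#' @export
ensemble_shift <- function(map) {
  src <- map$source_levels
  if (length(src) < 2) stop_input("ensemble map was built from a single source")
  pop <- map$populations |>
    tidyr::pivot_wider(names_from = "source", values_from = "fraction")
  deltas <- tibble(
    cluster = pop$cluster,
    fraction_ref = pop[[src[1]]],
    fraction_alt = pop[[src[2]]],
    delta = pop[[src[2]]] - pop[[src[1]]]
  )
  structure(list(deltas = deltas,
                 total_variation = 0.5 * sum(abs(deltas$delta)),
                 source_ref = src[1], source_alt = src[2]),
            class = "ensemble_shift")
}
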