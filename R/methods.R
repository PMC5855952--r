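#' @export
print.snitch_model <- function(x, ...) {
  if (x$type == "threshold") {
    cat(sprintf("<snitch_model: threshold rule, eSDC threshold %.3g>\n",
                x$esdc_threshold))
  } else {
    cat(sprintf("<snitch_model: random forest (%d trees), features: %s>\n",
                x$forest$ntree, paste(x$feature_cols, collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.snitch_roc <- function(x, ...) {
  cat(sprintf("<snitch_roc: AUC %.3f over %d positives / %d negatives>\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.ensemble_map <- function(x, ...) {
  cat(sprintf("<ensemble_map: %d structures, k = %d cluster(s)%s>\n",
              nrow(x$clusters), x$k,
              if (is.na(x$mean_silhouette)) "" else
                sprintf(", mean silhouette %.3f", x$mean_silhouette)))
  invisible(x)
}

#' @export
print.ensemble_shift <- function(x, ...) {
  cat(sprintf("<ensemble_shift: total variation %.3f (%s -> %s)>\n",
              x$total_variation, x$source_ref, x$source_alt))
  invisible(x)
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf(
    "<enrichment_test: observed %d, expected %.2f, p = %.4g (%s, %d boots)>\n",
    x$observed, x$expected, x$p_value, x$alternative, x$n_boot))
  invisible(x)
}

#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-element table of a
#' result (ROC curve points, cluster memberships, per-cluster population
#' deltas), `glance()` a one-row summary.
#'
#' @param x A `snitch_roc`, `ensemble_map`, `ensemble_shift` or
#'   `enrichment_test` object.
#' @param ... Unused.
#' @return A tibble.
#' @name shapesorter-tidiers
NULL

#' @rdname shapesorter-tidiers
#' @export
tidy.snitch_roc <- function(x, ...) x$curve

#' @rdname shapesorter-tidiers
#' @export
glance.snitch_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname shapesorter-tidiers
#' @export
tidy.ensemble_map <- function(x, ...) {
  left_join(x$clusters, x$embedding, by = "id")
}

#' @rdname shapesorter-tidiers
#' @export
glance.ensemble_map <- function(x, ...) {
  tibble(n_structures = nrow(x$clusters), k = x$k,
         mean_silhouette = x$mean_silhouette,
         embedding_rho = x$embedding_rho)
}

#' @rdname shapesorter-tidiers
#' @export
tidy.ensemble_shift <- function(x, ...) x$deltas

#' @rdname shapesorter-tidiers
#' @export
glance.ensemble_shift <- function(x, ...) {
  tibble(total_variation = x$total_variation,
         source_ref = x$source_ref, source_alt = x$source_alt)
}

#' @rdname shapesorter-tidiers
#' @export
glance.enrichment_test <- function(x, ...) {
  tibble(observed = x$observed, expected = x$expected,
         p_value = x$p_value, alternative = x$alternative,
         n_boot = x$n_boot)
}

#' Plot a ROC curve
#'
#' @param object A `snitch_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snitch_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step(colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("AUC = %.2f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble map
#'
#' 2-D MDS embedding of the pooled structures, coloured by cluster with the
#' source (allele) as point shape; medoids are emphasized.
#'
#' @param object An `ensemble_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ensemble_map <- function(object, ...) {
  df <- tidy(object)
  med <- df[df$id %in% object$medoids$id, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = factor(.data$cluster),
                                   shape = .data$source)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = med, size = 4, shape = 8) +
    ggplot2::labs(colour = "cluster", shape = "source",
                  x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

#' Plot two allele reactivity profiles around a variant
#'
#' @param profile_ref,profile_alt Normalized profile tibbles.
#' @param variant A [variant_spec()] or position; drawn as a vertical line.
#' @param window_halfwidth Window shown around the variant.
#' @return A ggplot with one panel per allele.
#' @export
plot_profile_comparison <- function(profile_ref, profile_alt, variant,
                                    window_halfwidth = 50L) {
  vp <- if (is.numeric(variant)) as.integer(variant[1]) else {
    as_variant_spec(variant)$position
  }
  df <- bind_rows(
    mutate(profile_ref, allele = "ref"),
    mutate(profile_alt, allele = "alt")
  ) |>
    filter(abs(.data$position - vp) <= window_halfwidth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$normalized_reactivity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = vp, linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~allele, ncol = 1) +
    ggplot2::labs(x = "Position (nt)", y = "Normalized SHAPE reactivity") +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window track
#'
#' @param track A track tibble from [sliding_median()] or one scale of
#'   [multiscale_correlation()].
#' @return A ggplot.
#' @export
plot_window_track <- function(track) {
  stat <- attr(track, "statistic") %||% "value"
  ggplot2::ggplot(track[!is.na(track$value), ],
                  ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Position (nt)", y = stat) +
    ggplot2::theme_minimal()
}
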