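# ggplot2 views of the main result types.

#' Volcano-style view of an iBioID enrichment fit
#'
#' log2 enrichment ratio against -log10 p-value, coloured by the
#' significance call (p < alpha and ratio > 1). Infinite ratios (bait-only
#' proteins) are pinned at the plot edge.
#'
#' @param object An `ibioid_fit` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ibioid_fit <- function(object, ...) {
  res <- object$results
  res <- res[res$ratio_flag != "undefined", , drop = FALSE]
  finite_ratio <- res$ratio[is.finite(res$ratio) & res$ratio > 0]
  cap <- if (length(finite_ratio) > 0) max(log2(finite_ratio)) + 1 else 1
  res$log2_ratio <- ifelse(is.finite(res$ratio), log2(pmax(res$ratio, 2^-20)), cap)
  res$neg_log10_p <- -log10(pmax(res$p_value, 1e-300))
  ggplot(res, aes(x = .data$log2_ratio, y = .data$neg_log10_p, colour = .data$significant)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    labs(
      x = "log2(mean bait / mean control)",
      y = "-log10 p (pooled Student's t)",
      colour = "enriched",
      title = sprintf("iBioID enrichment (%s, alpha = %g)", object$mode, object$alpha)
    ) +
    theme_minimal()
}

#' Ranked gene-gene correlation plot
#'
#' Correlation with the reference gene by rank, with the analytic
#' significance threshold drawn as a horizontal line.
#'
#' @param ranked Tibble from [rank_genes()].
#' @param r_min Optional threshold from [significance_threshold()].
#' @return A ggplot object.
#' @export
plot_correlation_ranking <- function(ranked, r_min = NULL) {
  p <- ggplot(ranked, aes(x = .data$rank, y = .data$r)) +
    geom_point() +
    labs(
      x = "rank (descending r)",
      y = "Pearson r with reference gene",
      title = "Coexpression with the reference gene"
    ) +
    theme_minimal()
  if (!is.null(r_min)) p <- p + geom_hline(yintercept = r_min, linetype = "dashed")
  p
}

#' Group comparison of spine enrichment factors
#'
#' @param object An `ef_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ef_comparison <- function(object, ...) {
  pts <- bind_rows(
    tibble(group = object$per_group$group[1], ef = object$values[[1]]),
    tibble(group = object$per_group$group[2], ef = object$values[[2]])
  )
  ggplot(pts, aes(x = .data$group, y = .data$ef)) +
    geom_jitter(width = 0.08, alpha = 0.7) +
    geom_point(
      data = object$per_group,
      aes(x = .data$group, y = .data$mean_ef),
      shape = 95, size = 12
    ) +
    labs(
      x = NULL, y = "enrichment factor (spine / shaft)",
      title = sprintf("Ratio of group means: %.2f", object$ratio_of_means)
    ) +
    theme_minimal()
}

#' Raster view of one plane of a volume
#'
#' @param vol An [em_volume] or 3D array.
#' @param plane 1-based plane index.
#' @return A ggplot object.
#' @export
plot_volume_plane <- function(vol, plane = 1L) {
  a <- as_volume_array(vol)
  plane <- assert_count(plane, "plane", lower = 1)
  sl <- a[plane, , ]
  df <- tidyr::expand_grid(row = seq_len(nrow(sl)), col = seq_len(ncol(sl)))
  df$intensity <- as.vector(t(sl))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white") +
    labs(title = sprintf("plane %d", plane), x = "x", y = "y") +
    theme_minimal()
}
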