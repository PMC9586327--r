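# Spine-versus-shaft fluorescence enrichment: threshold-based spot
# detection, mean of the top-k brightest spots (k = 40 by default), pooled
# shaft-ROI mean, and the per-image enrichment factor
# EF_i = mu_spine_i / mu_shaft_i.

#' Detect bright fluorescence spots by thresholding
#'
#' Connected components (8-neighbourhood) of the supra-threshold pixel mask
#' with area at least `min_area`, each summarised by its mean intensity and
#' centroid, sorted by descending mean. If `mask` is given, analysis is
#' restricted to it (e.g. to exclude the dendritic shaft).
#'
#' @param img Numeric matrix of intensities.
#' @param threshold Intensity cut (inclusive); alternatively a percentile
#'   directive `c(percentile = p)` with `p` in (0, 100), evaluated on the
#'   analysed pixels.
#' @param min_area Minimum spot area in pixels (default 2).
#' @param mask Optional logical matrix restricting the analysis.
#' @return An object of class `spot_set`: a tibble with `spot_id`, `area`,
#'   `mean_intensity`, `centroid_row`, `centroid_col`, plus attributes
#'   `masks` (list of pixel-index vectors) and `image_dim`. An empty set is
#'   returned with a warning (not an error) when nothing survives the
#'   threshold.
#' @export
detect_spots <- function(img, threshold, min_area = 2L, mask = NULL) {
  if (!is.matrix(img) || !is.numeric(img) || any(!is.finite(img))) {
    stop_spinescope("`img` must be a finite numeric matrix.", "parameter")
  }
  min_area <- assert_count(min_area, "min_area", lower = 1)
  analysed <- if (is.null(mask)) {
    matrix(TRUE, nrow(img), ncol(img))
  } else {
    if (!is.logical(mask) || !all(dim(mask) == dim(img))) {
      stop_spinescope("`mask` must be a logical matrix matching `img`.", "parameter")
    }
    mask
  }
  if (!is.null(names(threshold)) && identical(names(threshold), "percentile")) {
    assert_number(threshold[["percentile"]], "threshold percentile", lower = 0, upper = 100)
    threshold <- quantile(img[analysed], threshold[["percentile"]] / 100, names = FALSE)
  } else {
    assert_number(threshold, "threshold")
  }
  supra <- img >= threshold & analysed
  lab <- label_components2(supra, connectivity = 8L)
  n_comp <- max(lab)
  rows <- list()
  masks <- list()
  if (n_comp > 0L) {
    for (i in seq_len(n_comp)) {
      px <- which(lab == i)
      if (length(px) < min_area) next
      ind <- arrayInd(px, dim(img))
      rows[[length(rows) + 1L]] <- tibble(
        area = length(px),
        mean_intensity = mean(img[px]),
        centroid_row = mean(ind[, 1]),
        centroid_col = mean(ind[, 2])
      )
      masks[[length(masks) + 1L]] <- px
    }
  }
  if (length(rows) == 0L) {
    warn("No spot survives the threshold; returning an empty spot set.")
    out <- tibble(
      spot_id = integer(0), area = integer(0), mean_intensity = numeric(0),
      centroid_row = numeric(0), centroid_col = numeric(0)
    )
    attr(out, "masks") <- list()
    attr(out, "image_dim") <- dim(img)
    class(out) <- c("spot_set", class(out))
    return(out)
  }
  out <- bind_rows(rows)
  ord <- order(-out$mean_intensity)
  out <- out[ord, , drop = FALSE]
  out <- tibble(spot_id = seq_len(nrow(out)), out)
  attr(out, "masks") <- masks[ord]
  attr(out, "image_dim") <- dim(img)
  class(out) <- c("spot_set", class(out))
  out
}

#' Mean intensity of the top-k brightest spots
#'
#' Averages the per-spot mean intensities of the `k` brightest spots
#' (k = 40 by default, one value per neuron/image). When fewer than `k`
#' spots were detected, all are used and a warning records the shortfall.
#'
#' @param spots A `spot_set` from [detect_spots()].
#' @param k Number of spots to average (default 40).
#' @return `mu_spine`, a single number, with attribute `k_used`.
#' @export
top_k_spot_mean <- function(spots, k = 40L) {
  k <- assert_count(k, "k", lower = 1)
  if (nrow(spots) == 0L) {
    stop_spinescope("Spot set is empty; cannot compute a spine mean.", "value")
  }
  k_used <- min(k, nrow(spots))
  if (k_used < k) {
    warn(sprintf("Only %d spots available; using all of them (k requested = %d).", k_used, k))
  }
  mu <- mean(sort(spots$mean_intensity, decreasing = TRUE)[seq_len(k_used)])
  attr(mu, "k_used") <- k_used
  mu
}

#' Pooled mean intensity of dendritic-shaft regions
#'
#' Computes the mean intensity of each shaft ROI and pools them with equal
#' region weighting (the documented convention; `weighting = "area"` pools
#' all pixels instead).
#'
#' @param img Numeric intensity matrix.
#' @param rois List of ROIs, each either a logical matrix matching `img` or
#'   a vector of pixel indices; all must be non-empty.
#' @param weighting `"equal"` (mean of region means, default) or `"area"`
#'   (pixel-weighted).
#' @return `mu_shaft`, a single number, with attribute `region_means`.
#' @export
shaft_mean <- function(img, rois, weighting = c("equal", "area")) {
  weighting <- match.arg(weighting)
  if (!is.list(rois) || length(rois) == 0L) {
    stop_spinescope("`rois` must be a non-empty list of regions.", "parameter")
  }
  px <- map(rois, function(r) {
    if (is.logical(r)) {
      if (!all(dim(r) == dim(img))) {
        stop_spinescope("ROI mask shape does not match the image.", "parameter")
      }
      r <- which(r)
    }
    if (length(r) == 0L) stop_spinescope("Empty shaft ROI.", "parameter")
    r
  })
  means <- map_dbl(px, function(p) mean(img[p]))
  mu <- if (weighting == "equal") mean(means) else mean(img[unlist(px)])
  attr(mu, "region_means") <- means
  mu
}

#' Spine/shaft enrichment factor
#'
#' `EF = mu_spine / mu_shaft`.
#'
#' @param mu_spine Mean of the selected top-k spot means.
#' @param mu_shaft Pooled shaft mean; must be strictly positive.
#' @return The enrichment factor, a single number.
#' @export
enrichment_factor <- function(mu_spine, mu_shaft) {
  assert_number(mu_spine, "mu_spine")
  if (!is.numeric(mu_shaft) || length(mu_shaft) != 1L || !is.finite(mu_shaft) || mu_shaft <= 0) {
    stop_spinescope("`mu_shaft` must be strictly positive.", "domain")
  }
  as.numeric(mu_spine) / as.numeric(mu_shaft)
}

#' Quantify spine enrichment for one image
#'
#' Convenience composition of [detect_spots()], [top_k_spot_mean()],
#' [shaft_mean()] and [enrichment_factor()].
#'
#' @param img Numeric intensity matrix.
#' @param threshold Spot threshold (see [detect_spots()]).
#' @param shaft_rois List of shaft ROIs (see [shaft_mean()]).
#' @param k Top-k spot count (default 40).
#' @param mask Optional analysis mask for spot detection.
#' @param image_id Identifier recorded in the output.
#' @return One-row tibble: `image_id`, `n_spots`, `k_used`, `mu_spine`,
#'   `mu_shaft`, `ef`.
#' @export
spine_enrichment <- function(img, threshold, shaft_rois, k = 40L,
                             mask = NULL, image_id = "img1") {
  spots <- detect_spots(img, threshold, mask = mask)
  mu_spine <- top_k_spot_mean(spots, k = k)
  mu_shaft <- shaft_mean(img, shaft_rois)
  tibble(
    image_id = image_id,
    n_spots = nrow(spots),
    k_used = attr(mu_spine, "k_used"),
    mu_spine = as.numeric(mu_spine),
    mu_shaft = as.numeric(mu_shaft),
    ef = enrichment_factor(mu_spine, mu_shaft)
  )
}

#' Compare enrichment factors between two groups of neurons
#'
#' @param ef_a,ef_b Numeric vectors of per-image enrichment factors, or
#'   tibbles from [spine_enrichment()] (their `ef` column is used).
#' @param labels Group labels (length 2).
#' @return An object of class `ef_comparison` with per-group mean and SEM
#'   (SEM is `NA` for a single record) and the ratio of group means.
#' @export
compare_groups <- function(ef_a, ef_b, labels = c("group_a", "group_b")) {
  if (is.data.frame(ef_a)) ef_a <- ef_a$ef
  if (is.data.frame(ef_b)) ef_b <- ef_b$ef
  if (length(ef_a) < 1L || length(ef_b) < 1L) {
    stop_spinescope("Each group needs at least one enrichment-factor record.", "parameter")
  }
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  per_group <- tibble(
    group = labels,
    n = c(length(ef_a), length(ef_b)),
    mean_ef = c(mean(ef_a), mean(ef_b)),
    sem_ef = c(sem(ef_a), sem(ef_b))
  )
  structure(
    list(
      per_group = per_group,
      ratio_of_means = mean(ef_a) / mean(ef_b),
      values = list(ef_a, ef_b)
    ),
    class = "ef_comparison"
  )
}

#' @export
print.ef_comparison <- function(x, ...) {
  g <- x$per_group
  cat(sprintf(
    "<ef_comparison> %s: %.3g +/- %.2g (n=%d) vs %s: %.3g +/- %.2g (n=%d); ratio of means %.3g\n",
    g$group[1], g$mean_ef[1], g$sem_ef[1], g$n[1],
    g$group[2], g$mean_ef[2], g$sem_ef[2], g$n[2],
    x$ratio_of_means
  ))
  invisible(x)
}

#' @rdname compare_groups
#' @param x An `ef_comparison`.
#' @param ... Unused.
#' @export
tidy.ef_comparison <- function(x, ...) x$per_group

#' @rdname compare_groups
#' @export
glance.ef_comparison <- function(x, ...) {
  g <- x$per_group
  tibble(
    mean_a = g$mean_ef[1], sem_a = g$sem_ef[1], n_a = g$n[1],
    mean_b = g$mean_ef[2], sem_b = g$sem_ef[2], n_b = g$n[2],
    ratio_of_means = x$ratio_of_means
  )
}
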