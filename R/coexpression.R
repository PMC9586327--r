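# Single-cell coexpression with a reference gene: per-gene Pearson
# correlation of raw read counts across cells, computed from sufficient
# statistics so sparse matrices are never densified, plus the analytic
# t-to-r significance threshold r = t / sqrt(n - 2 + t^2).

#' Pearson correlation of every gene with a reference gene
#'
#' Computes, for each gene, the Pearson correlation coefficient between its
#' per-cell read counts and those of the reference gene, on raw counts
#' (no normalization or log transform). The computation uses sufficient
#' statistics (sums, sums of squares, cross-products), so sparse matrices
#' stay sparse. Genes with zero variance get an undefined flag (`r = NA`).
#'
#' @param m Gene-by-cell count matrix: a `dgCMatrix`/`Matrix`, a base
#'   matrix, or a data frame with genes as rows (rownames = gene ids).
#' @param ref_gene Name of the reference gene; must be a row of `m` with
#'   nonzero variance.
#' @return Tibble: `gene`, `r`, `n_cells`, `defined` (logical).
#' @export
pearson_vs_reference <- function(m, ref_gene) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (is.null(rownames(m))) {
    stop_spinescope("`m` must have gene ids as rownames.", "schema")
  }
  if (!(ref_gene %in% rownames(m))) {
    stop_spinescope(sprintf("Reference gene '%s' not found in the matrix.", ref_gene), "reference")
  }
  n <- ncol(m)
  if (n < 3L) {
    stop_spinescope("At least 3 cells are required.", "parameter")
  }
  y <- as.numeric(m[ref_gene, ])
  sy <- sum(y)
  syy <- sum(y^2)
  var_y <- n * syy - sy^2
  if (var_y <= 0) {
    stop_spinescope("Reference gene has zero variance across cells.", "reference")
  }
  if (inherits(m, "Matrix")) {
    sx <- Matrix::rowSums(m)
    sxx <- Matrix::rowSums(m^2)
    sxy <- as.numeric(m %*% y)
  } else {
    sx <- rowSums(m)
    sxx <- rowSums(m^2)
    sxy <- as.numeric(m %*% y)
  }
  var_x <- n * sxx - sx^2
  r <- (n * sxy - sx * sy) / sqrt(pmax(var_x, 0) * var_y)
  r[var_x <= 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  r[var_x <= 0] <- NA_real_
  tibble(
    gene = rownames(m),
    r = unname(r),
    n_cells = n,
    defined = unname(var_x > 0)
  )
}

#' Analytic correlation-significance threshold (t-to-r inversion)
#'
#' The Pearson coefficient whose Student's t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` equals the requested `t`:
#' `r_min = t / sqrt(n - 2 + t^2)`. At droplet-atlas sample sizes
#' (hundreds of thousands of cells) this is on the order of 1e-3.
#'
#' @param n Number of cells (`>= 3`).
#' @param t t-statistic cut (default 0.99).
#' @return The threshold `r_min`, a single number in (0, 1).
#' @export
significance_threshold <- function(n, t = 0.99) {
  n <- assert_count(n, "n", lower = 3)
  assert_number(t, "t", lower = 1e-12)
  t / sqrt(n - 2 + t^2)
}

#' Rank genes by correlation with the reference
#'
#' Defined-`r` genes are sorted by descending `r`; exact ties are broken
#' lexicographically by gene id. The reference gene and undefined genes are
#' excluded from the ranking. When `r_min` (or `t`) is supplied, an
#' `above_threshold` column is added.
#'
#' @param results Tibble from [pearson_vs_reference()].
#' @param ref_gene Reference gene id to exclude (optional).
#' @param r_min Significance threshold from [significance_threshold()];
#'   alternatively give `t` to compute it from the data's `n_cells`.
#' @param t t-statistic cut used when `r_min` is missing.
#' @return The ranked tibble with columns `gene`, `r`, `n_cells`,
#'   `above_threshold` (if a threshold was given) and `rank`.
#' @export
rank_genes <- function(results, ref_gene = NULL, r_min = NULL, t = NULL) {
  out <- results[results$defined, , drop = FALSE]
  if (!is.null(ref_gene)) out <- out[out$gene != ref_gene, , drop = FALSE]
  out <- out[order(-out$r, out$gene), , drop = FALSE]
  if (is.null(r_min) && !is.null(t)) {
    r_min <- significance_threshold(out$n_cells[1], t = t)
  }
  if (!is.null(r_min)) out$above_threshold <- out$r > r_min
  out$rank <- seq_len(nrow(out))
  as_tibble(out)
}
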