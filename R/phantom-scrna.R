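# Sparse single-cell count-matrix simulator with controlled per-gene
# Pearson correlation to a reference gene. Counts are generated through a
# Gaussian copula with Poisson marginals: a shared standard-normal latent
# factor per cell is mixed into each gene's latent variable with weight
# rho, then discretized by the Poisson quantile function. Discretization
# attenuates the correlation, so the latent weight is calibrated
# deterministically (1D quadrature over the shared factor) such that the
# post-discretization Pearson correlation equals the requested target.

#' Specification of a simulated single-cell count matrix
#'
#' @param target_r Named numeric vector mapping each gene of interest to its
#'   desired Pearson correlation (on counts) with the reference gene; values
#'   in `[-1, 1]`.
#' @param n_cells Number of cells.
#' @param ref_gene_id Name of the reference gene (default `"Synpo"`).
#' @param mean_expression Mean counts per cell, either a single value for
#'   all genes or a named vector covering the reference and every target
#'   gene. Default 1 (sparse, droplet-scale expression).
#' @param seed Integer seed.
#' @return An object of class `scrna_sim_spec`.
#' @export
scrna_sim_spec <- function(target_r,
                           n_cells = 1e5,
                           ref_gene_id = "Synpo",
                           mean_expression = 1,
                           seed = 1L) {
  if (!is.numeric(target_r) || is.null(names(target_r)) || any(names(target_r) == "")) {
    stop_spinescope("`target_r` must be a named numeric vector (gene -> r).", "parameter")
  }
  if (any(abs(target_r) > 1)) {
    stop_spinescope("|target_r| must not exceed 1.", "validation")
  }
  if (ref_gene_id %in% names(target_r)) {
    stop_spinescope("`target_r` must not include the reference gene.", "parameter")
  }
  n_cells <- assert_count(n_cells, "n_cells", lower = 3)
  genes <- c(ref_gene_id, names(target_r))
  if (length(mean_expression) == 1L && is.null(names(mean_expression))) {
    mean_expression <- setNames(rep(mean_expression, length(genes)), genes)
  }
  missing_mu <- setdiff(genes, names(mean_expression))
  if (length(missing_mu) > 0L) {
    stop_spinescope(
      sprintf("`mean_expression` missing gene(s): %s.", paste(missing_mu, collapse = ", ")),
      "parameter"
    )
  }
  if (any(mean_expression[genes] <= 0)) {
    stop_spinescope("`mean_expression` must be strictly positive.", "parameter")
  }
  structure(
    list(
      target_r = target_r,
      n_cells = n_cells,
      ref_gene_id = ref_gene_id,
      mean_expression = mean_expression[genes],
      seed = as.integer(seed)
    ),
    class = "scrna_sim_spec"
  )
}

# Pearson correlation (on counts) induced by latent weight rho in the
# Gaussian copula with Poisson(lambda_ref), Poisson(lambda_g) marginals.
# Uses E[XY] = Int phi(z) f_ref(z) m_g(rho * z) dz where
# m_g(c) = sum_{b>=1} P(N(c, 1 - rho^2) > z_b), z_b = qnorm(ppois(b - 1, lambda_g)).
copula_count_pearson <- function(rho, lambda_ref, lambda_g, n_grid = 4001L) {
  if (abs(rho) >= 1 - 1e-12) {
    rho <- sign(rho) * (1 - 1e-12)
  }
  z <- seq(-9, 9, length.out = n_grid)
  dz <- z[2] - z[1]
  f_ref <- qpois(pmin(pnorm(z), 1 - 1e-16), lambda_ref)
  b_max <- max(2L, qpois(1 - 1e-12, lambda_g) + 1L)
  z_b <- qnorm(ppois(seq_len(b_max) - 1L, lambda_g)) # thresholds for N >= b
  z_b <- z_b[is.finite(z_b)]
  s <- sqrt(1 - rho^2)
  # m[j] = sum_b P(latent_g > z_b | shared = z_j)
  m <- colSums(pnorm((rho * matrix(z, nrow = length(z_b), ncol = n_grid, byrow = TRUE) -
                        z_b) / s))
  exy <- sum(stats::dnorm(z) * f_ref * m) * dz
  (exy - lambda_ref * lambda_g) / sqrt(lambda_ref * lambda_g)
}

# invert the attenuation map: latent rho achieving a target count-scale r
calibrate_latent_rho <- function(target, lambda_ref, lambda_g) {
  if (abs(target) < 1e-12) return(0)
  if (target >= 1 - 1e-12) {
    # r = 1 requires an exact copy, which needs identical marginals
    if (abs(lambda_g - lambda_ref) > 1e-12) {
      stop_spinescope(
        "target_r = 1 requires the gene's mean to equal the reference mean.",
        "validation"
      )
    }
    return(1)
  }
  r_max <- copula_count_pearson(1, lambda_ref, lambda_g)
  r_min <- copula_count_pearson(-1, lambda_ref, lambda_g)
  if (target > r_max + 1e-9 || target < r_min - 1e-9) {
    stop_spinescope(
      sprintf(
        "target_r = %.3f unattainable for Poisson marginals (attainable range [%.3f, %.3f]).",
        target, r_min, r_max
      ),
      "validation"
    )
  }
  if (target >= r_max) return(1)
  if (target <= r_min) return(-1)
  uniroot(
    function(rho) copula_count_pearson(rho, lambda_ref, lambda_g) - target,
    interval = c(-1, 1), tol = 1e-6
  )$root
}

#' Generate a sparse gene-by-cell count matrix with planted correlations
#'
#' See [scrna_sim_spec()] for the model. When a gene's target correlation
#' is (numerically) 1 and its mean equals the reference mean, the gene is
#' an exact copy of the reference counts.
#'
#' @param spec An [scrna_sim_spec()].
#' @return A [Matrix::sparseMatrix] (class `dgCMatrix`), genes x cells,
#'   with the reference gene as the first row; dimnames carry gene and cell
#'   ids. Attribute `"latent_rho"` records the calibrated latent weights.
#' @export
generate_scrna_matrix <- function(spec) {
  stopifnot(inherits(spec, "scrna_sim_spec"))
  genes <- names(spec$mean_expression)
  lambda <- spec$mean_expression
  ref <- spec$ref_gene_id
  rho <- vapply(
    names(spec$target_r),
    function(g) calibrate_latent_rho(spec$target_r[[g]], lambda[[ref]], lambda[[g]]),
    numeric(1)
  )
  n <- spec$n_cells
  counts <- withr::with_seed(spec$seed, {
    z0 <- rnorm(n)
    rows <- vector("list", length(genes))
    names(rows) <- genes
    rows[[ref]] <- qpois(pnorm(z0), lambda[[ref]])
    for (g in names(spec$target_r)) {
      w <- rho[[g]]
      zg <- if (abs(w) >= 1 - 1e-9) {
        sign(w) * z0
      } else {
        w * z0 + sqrt(1 - w^2) * rnorm(n)
      }
      rows[[g]] <- qpois(pnorm(zg), lambda[[g]])
    }
    do.call(rbind, rows)
  })
  dimnames(counts) <- list(genes, sprintf("cell%06d", seq_len(n)))
  out <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  attr(out, "latent_rho") <- rho
  out
}
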