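# Differential enrichment statistics for in vivo proximity biotinylation
# (iBioID): per-protein ratio of group mean counts, two-sample pooled
# Student's t test with a P < 0.1 enrichment rule, optional normalization
# by the two endogenously biotinylated carboxylases, and cross-experiment
# overlap of significant sets.

#' Protein-by-sample peptide/spectral-count table
#'
#' Container for a nonnegative count matrix with a bait/control group map.
#' A protein absent from a sample is a zero count.
#'
#' @param counts Numeric matrix, rows = proteins (rownames required),
#'   columns = samples (colnames required); all entries `>= 0`.
#' @param groups Data frame with columns `sample` and `group`
#'   (`"bait"`/`"control"`), covering every column of `counts`; each group
#'   needs at least two samples.
#' @param control_ids Identifiers of the internal-standard proteins
#'   (default the two endogenously biotinylated carboxylases).
#' @param experiment Free-text experiment identifier.
#' @return An object of class `peptide_count_table`.
#' @export
peptide_count_table <- function(counts, groups,
                                control_ids = c("Pcca", "Pc"),
                                experiment = "exp1") {
  if (!is.matrix(counts) || !is.numeric(counts) ||
      is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_spinescope("`counts` must be a numeric matrix with row and column names.", "schema")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)[1L, ]
    stop_spinescope(
      sprintf(
        "Counts must be finite and nonnegative; offending cell: protein '%s', sample '%s'.",
        rownames(counts)[bad[1]], colnames(counts)[bad[2]]
      ),
      "schema"
    )
  }
  groups <- as_tibble(groups)
  if (!all(c("sample", "group") %in% names(groups))) {
    stop_spinescope("`groups` needs columns `sample` and `group`.", "schema")
  }
  if (!setequal(groups$sample, colnames(counts))) {
    stop_spinescope("`groups$sample` must match the columns of `counts`.", "schema")
  }
  groups <- groups[match(colnames(counts), groups$sample), ]
  if (!all(groups$group %in% c("bait", "control"))) {
    stop_spinescope("Group labels must be 'bait' or 'control'.", "schema")
  }
  tab <- table(groups$group)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop_spinescope("Each group needs at least two samples.", "design")
  }
  structure(
    list(
      counts = counts,
      groups = groups,
      control_ids = as.character(control_ids),
      experiment = experiment,
      normalized = FALSE
    ),
    class = "peptide_count_table"
  )
}

#' @export
print.peptide_count_table <- function(x, ...) {
  cat(sprintf(
    "<peptide_count_table '%s'> %d proteins x %d samples (%d bait, %d control)%s\n",
    x$experiment, nrow(x$counts), ncol(x$counts),
    sum(x$groups$group == "bait"), sum(x$groups$group == "control"),
    if (x$normalized) ", endogenous-normalized" else ""
  ))
  invisible(x)
}

#' @rdname peptide_count_table
#' @param x A `peptide_count_table`.
#' @param ... Unused.
#' @export
tidy.peptide_count_table <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample", values_to = "count")
  left_join(long, x$groups, by = "sample")
}

is_control_row <- function(table) rownames(table$counts) %in% table$control_ids

#' Normalize counts to the endogenously biotinylated internal standards
#'
#' Divides every non-control protein's count in each sample by the summed
#' counts of the two internal-control proteins (the endogenously
#' biotinylated carboxylases) in that sample, removing per-sample variation
#' in biotinylated-material recovery. Control rows are retained and
#' flagged; the input table is untouched.
#'
#' @param table A [peptide_count_table].
#' @param control_ids Overrides the table's control protein ids.
#' @return A new [peptide_count_table] with `normalized = TRUE`.
#' @export
normalize_by_endogenous <- function(table, control_ids = NULL) {
  stopifnot(inherits(table, "peptide_count_table"))
  control_ids <- control_ids %||% table$control_ids
  missing_ctrl <- setdiff(control_ids, rownames(table$counts))
  if (length(missing_ctrl) > 0L) {
    stop_spinescope(
      sprintf("Control protein(s) absent from the table: %s.", paste(missing_ctrl, collapse = ", ")),
      "normalization"
    )
  }
  ctrl <- table$counts[control_ids, , drop = FALSE]
  factors <- colSums(ctrl)
  if (any(factors <= 0)) {
    bad <- colnames(table$counts)[factors <= 0]
    stop_spinescope(
      sprintf(
        "Zero summed control counts in sample(s): %s; cannot normalize.",
        paste(bad, collapse = ", ")
      ),
      "normalization"
    )
  }
  out <- table
  out$control_ids <- control_ids
  keep <- !(rownames(table$counts) %in% control_ids)
  out$counts[keep, ] <- sweep(table$counts[keep, , drop = FALSE], 2L, factors, `/`)
  out$normalized <- TRUE
  attr(out$counts, "normalization_factors") <- factors
  out
}

#' Per-protein enrichment ratio of group mean counts
#'
#' Means are taken over all samples of each group (absent protein = 0).
#' A positive bait mean over a zero control mean is flagged `"infinite"`;
#' 0/0 is flagged `"undefined"`.
#'
#' @param table A [peptide_count_table].
#' @return Tibble: `protein_id`, `mean_bait`, `mean_ctrl`, `ratio`,
#'   `ratio_flag` (`"finite"`, `"infinite"`, `"undefined"`).
#' @export
enrichment_ratio <- function(table) {
  stopifnot(inherits(table, "peptide_count_table"))
  bait <- table$counts[, table$groups$group == "bait", drop = FALSE]
  ctrl <- table$counts[, table$groups$group == "control", drop = FALSE]
  mean_bait <- rowMeans(bait)
  mean_ctrl <- rowMeans(ctrl)
  ratio <- mean_bait / mean_ctrl
  flag <- dplyr::case_when(
    mean_ctrl > 0 ~ "finite",
    mean_bait > 0 ~ "infinite",
    TRUE ~ "undefined"
  )
  ratio[flag == "undefined"] <- NA_real_
  tibble(
    protein_id = rownames(table$counts),
    mean_bait = unname(mean_bait),
    mean_ctrl = unname(mean_ctrl),
    ratio = unname(ratio),
    ratio_flag = unname(flag)
  )
}

# vectorised two-sample pooled-variance Student's t test
pooled_t_test <- function(x_mat, y_mat) {
  n1 <- ncol(x_mat)
  n2 <- ncol(y_mat)
  m1 <- rowMeans(x_mat)
  m2 <- rowMeans(y_mat)
  v1 <- apply(x_mat, 1L, var)
  v2 <- apply(y_mat, 1L, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * pt(-abs(t_stat), df)
  # degenerate zero-variance cases: equal means -> no evidence (p = 1);
  # different means with zero pooled variance -> p -> 0 sentinel
  degen <- se == 0
  t_stat[degen & m1 == m2] <- 0
  p[degen & m1 == m2] <- 1
  t_stat[degen & m1 != m2] <- sign(m1 - m2)[degen & m1 != m2] * Inf
  p[degen & m1 != m2] <- 0
  list(t_stat = t_stat, p_value = p, df = df)
}

#' Test per-protein enrichment between bait and control groups
#'
#' Two-sample Student's t test (pooled variance, two-sided) on the
#' per-sample counts of each protein, combined with the enrichment ratio.
#' A protein is significantly enriched when `p_value < alpha` AND
#' `ratio > 1` (the direction gate, so proteins enriched near the spatial
#' reference are never called). No multiple-testing correction is applied,
#' mirroring the stated P < 0.1 rule; a Benjamini-Hochberg column
#' (`p_adj_bh`) is reported for reference but not used for the call.
#'
#' @param table A [peptide_count_table].
#' @param alpha Significance level (default 0.1).
#' @param include_controls Keep the internal-standard rows in the output?
#'   Default `FALSE`.
#' @return Tibble: `protein_id`, `mean_bait`, `mean_ctrl`, `ratio`,
#'   `ratio_flag`, `t_stat`, `p_value`, `p_adj_bh`, `significant`.
#' @export
test_enrichment <- function(table, alpha = 0.1, include_controls = FALSE) {
  stopifnot(inherits(table, "peptide_count_table"))
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1)
  res <- enrichment_ratio(table)
  bait <- table$counts[, table$groups$group == "bait", drop = FALSE]
  ctrl <- table$counts[, table$groups$group == "control", drop = FALSE]
  tt <- pooled_t_test(bait, ctrl)
  res$t_stat <- unname(tt$t_stat)
  res$p_value <- unname(tt$p_value)
  res$p_adj_bh <- unname(stats::p.adjust(tt$p_value, method = "BH"))
  res$significant <- res$p_value < alpha &
    (res$ratio_flag == "infinite" | (!is.na(res$ratio) & res$ratio > 1))
  if (!include_controls) {
    res <- res[!(res$protein_id %in% table$control_ids), , drop = FALSE]
  }
  res
}

#' Run one iBioID enrichment experiment
#'
#' Composes (optional) internal-standard normalization, enrichment ratios
#' and the Student's t test, and returns the full result table ordered by
#' descending ratio together with the significant-protein set.
#'
#' @param table A [peptide_count_table].
#' @param mode `"raw"` (experiment-1 style) or `"endogenous_normalized"`
#'   (experiment-2 style, normalizing to the carboxylase internal
#'   standards).
#' @param alpha Significance level (default 0.1).
#' @return An object of class `ibioid_fit`: list with `results` (ordered
#'   tibble), `significant` (character vector), `mode`, `alpha`,
#'   `experiment`.
#' @export
run_experiment <- function(table, mode = c("raw", "endogenous_normalized"),
                           alpha = 0.1) {
  mode <- match.arg(mode)
  work <- if (mode == "endogenous_normalized") normalize_by_endogenous(table) else table
  res <- test_enrichment(work, alpha = alpha)
  # order: infinite ratios first, then descending finite ratio, undefined last
  res <- res[order(-(res$ratio_flag == "infinite"),
                   -ifelse(is.na(res$ratio) | is.infinite(res$ratio), 0, res$ratio)), ]
  structure(
    list(
      results = as_tibble(res),
      significant = res$protein_id[res$significant],
      mode = mode,
      alpha = alpha,
      experiment = table$experiment
    ),
    class = "ibioid_fit"
  )
}

#' @export
print.ibioid_fit <- function(x, ...) {
  cat(sprintf(
    "<ibioid_fit '%s'> mode = %s, alpha = %g: %d / %d proteins significantly enriched\n",
    x$experiment, x$mode, x$alpha, length(x$significant), nrow(x$results)
  ))
  invisible(x)
}

#' @rdname run_experiment
#' @param x An `ibioid_fit`.
#' @param ... Unused.
#' @export
tidy.ibioid_fit <- function(x, ...) x$results

#' @rdname run_experiment
#' @export
glance.ibioid_fit <- function(x, ...) {
  tibble(
    experiment = x$experiment,
    mode = x$mode,
    alpha = x$alpha,
    n_proteins = nrow(x$results),
    n_significant = length(x$significant)
  )
}

#' Directional overlap between two significant-protein sets
#'
#' @param set_a,set_b Character vectors of protein ids (or `ibioid_fit`
#'   objects, whose significant sets are used).
#' @return Tibble with one row: `n_a`, `n_b`, `n_common`,
#'   `frac_a_in_b` (`|A∩B|/|A|`), `frac_b_in_a` (`|A∩B|/|B|`); a fraction is
#'   `NA` when its denominator set is empty.
#' @export
cross_experiment_overlap <- function(set_a, set_b) {
  if (inherits(set_a, "ibioid_fit")) set_a <- set_a$significant
  if (inherits(set_b, "ibioid_fit")) set_b <- set_b$significant
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  common <- length(intersect(set_a, set_b))
  tibble(
    n_a = length(set_a),
    n_b = length(set_b),
    n_common = common,
    frac_a_in_b = if (length(set_a) > 0) common / length(set_a) else NA_real_,
    frac_b_in_a = if (length(set_b) > 0) common / length(set_b) else NA_real_
  )
}
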