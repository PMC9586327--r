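# iBioID differential enrichment: normalization, ratios, Student's t,
# composition and overlap.

make_table <- function(bait, ctrl, control_rows = NULL, control_ids = c("Pcca", "Pc")) {
  counts <- rbind(bait_ctrl = c(bait, ctrl))
  if (!is.null(control_rows)) counts <- rbind(counts, control_rows)
  colnames(counts) <- c(
    sprintf("bait_%d", seq_along(bait)),
    sprintf("ctrl_%d", seq_along(ctrl))
  )
  peptide_count_table(
    counts,
    groups = tibble::tibble(
      sample = colnames(counts),
      group = rep(c("bait", "control"), c(length(bait), length(ctrl)))
    ),
    control_ids = control_ids
  )
}

test_that("normalize_by_endogenous divides by control sums and is scale invariant", {
  counts <- rbind(
    p1 = c(5, 6, 2, 3),
    Pcca = c(6, 4, 5, 5),
    Pc = c(4, 6, 5, 5)
  )
  colnames(counts) <- c("bait_1", "bait_2", "ctrl_1", "ctrl_2")
  groups <- tibble::tibble(
    sample = colnames(counts), group = c("bait", "bait", "control", "control")
  )
  tab <- peptide_count_table(counts, groups)
  norm <- normalize_by_endogenous(tab)
  expect_equal(unname(norm$counts["p1", "bait_1"]), 0.5) # 5 / (6 + 4)
  expect_equal(unname(norm$counts["Pcca", ]), unname(counts["Pcca", ])) # controls retained

  # multiplying one whole sample (controls included) changes nothing
  counts2 <- counts
  counts2[, "bait_1"] <- counts2[, "bait_1"] * 3
  norm2 <- normalize_by_endogenous(peptide_count_table(counts2, groups))
  keep <- rownames(counts) == "p1"
  expect_equal(norm2$counts[keep, ], norm$counts[keep, ])

  # missing control protein names the problem
  tab_missing <- peptide_count_table(counts[c("p1", "Pcca"), ], groups)
  expect_error(normalize_by_endogenous(tab_missing), class = "spinescope_error_normalization")
  # zero control sum names the sample
  counts3 <- counts
  counts3[c("Pcca", "Pc"), "ctrl_2"] <- 0
  expect_error(
    normalize_by_endogenous(peptide_count_table(counts3, groups)),
    regexp = "ctrl_2"
  )
})

test_that("enrichment_ratio handles the stated edge conventions", {
  tab <- make_table(c(4, 4, 4, 4), c(2, 2, 2))
  r <- enrichment_ratio(tab)
  expect_equal(r$ratio[r$protein_id == "bait_ctrl"], 2)

  same <- make_table(c(3, 3), c(3, 3))
  expect_equal(enrichment_ratio(same)$ratio[1], 1)

  inf_tab <- make_table(c(5, 7, 6), c(0, 0, 0))
  ri <- enrichment_ratio(inf_tab)
  expect_equal(ri$ratio_flag[1], "infinite")
  expect_true(is.infinite(ri$ratio[1]))

  zero <- make_table(c(0, 0), c(0, 0))
  rz <- enrichment_ratio(zero)
  expect_equal(rz$ratio_flag[1], "undefined")
  expect_true(is.na(rz$ratio[1]))
})

test_that("test_enrichment matches t.test and applies degenerate conventions", {
  set.seed(3)
  bait <- c(12, 9, 15, 11)
  ctrl <- c(5, 8, 6)
  tab <- make_table(bait, ctrl)
  res <- test_enrichment(tab)
  ref <- t.test(bait, ctrl, var.equal = TRUE)
  expect_equal(res$t_stat[1], unname(ref$statistic))
  expect_equal(res$p_value[1], ref$p.value)

  # identical groups: t = 0, p = 1, not significant
  flat <- test_enrichment(make_table(c(4, 4, 4), c(4, 4, 4)))
  expect_equal(flat$t_stat[1], 0)
  expect_equal(flat$p_value[1], 1)
  expect_false(flat$significant[1])

  # zero variance in both groups, different means: p -> 0 sentinel, significant
  degen <- test_enrichment(make_table(c(10, 10, 10, 10), c(2, 2, 2)))
  expect_equal(degen$p_value[1], 0)
  expect_true(degen$significant[1])

  # direction gate: control-enriched protein is never called
  down <- test_enrichment(make_table(c(2, 2, 2, 2), c(10, 10, 10)))
  expect_false(down$significant[1])
  expect_equal(down$p_value[1], 0) # evidence is there, direction is wrong
})

test_that("results are invariant to row and column order and to common scaling", {
  ph <- generate_proteomics_table(
    proteomics_sim_spec(n_proteins = 60, frac_enriched = 0.2, seed = 21)
  )
  tab <- ph$table
  res <- test_enrichment(tab)

  perm_rows <- sample(nrow(tab$counts))
  perm_cols <- sample(ncol(tab$counts))
  tab2 <- peptide_count_table(
    tab$counts[perm_rows, perm_cols],
    groups = tab$groups[perm_cols, ],
    control_ids = tab$control_ids
  )
  res2 <- test_enrichment(tab2)
  res2 <- res2[match(res$protein_id, res2$protein_id), ]
  expect_equal(res2$t_stat, res$t_stat)
  expect_equal(res2$p_value, res$p_value)

  # common scaling of every sample leaves raw-mode t and ratio unchanged
  tab3 <- peptide_count_table(tab$counts * 7, tab$groups, tab$control_ids)
  res3 <- test_enrichment(tab3)
  expect_equal(res3$t_stat, res$t_stat)
  expect_equal(res3$ratio, res$ratio)
})

test_that("run_experiment composes, orders and exposes tidiers", {
  ph <- generate_proteomics_table(
    proteomics_sim_spec(n_proteins = 100, frac_enriched = 0.1, seed = 22)
  )
  fit <- run_experiment(ph$table, mode = "raw")
  finite <- fit$results$ratio[is.finite(fit$results$ratio)]
  expect_true(all(diff(finite) <= 0)) # descending ratio
  expect_identical(
    fit$significant,
    fit$results$protein_id[fit$results$significant]
  )
  # controls excluded from the tested output
  expect_false(any(ph$table$control_ids %in% fit$results$protein_id))

  # near-zero alpha with no planted signal: empty set
  ph0 <- generate_proteomics_table(
    proteomics_sim_spec(n_proteins = 200, frac_enriched = 0, seed = 23)
  )
  fit0 <- run_experiment(ph0$table, alpha = 1e-6)
  expect_length(fit0$significant, 0L)

  g <- glance(fit)
  expect_equal(g$n_significant, length(fit$significant))
  expect_equal(nrow(tidy(fit)), nrow(fit$results))
})

test_that("power is monotone in effect size on paired seeds", {
  recall_at <- function(lfc) {
    hits <- vapply(1:3, function(s) {
      ph <- generate_proteomics_table(
        proteomics_sim_spec(
          n_proteins = 400, frac_enriched = 0.1, log2_fc = lfc, seed = s
        )
      )
      fit <- run_experiment(ph$table)
      mean(ph$truth %in% fit$significant)
    }, numeric(1))
    mean(hits)
  }
  expect_lte(recall_at(0.5), recall_at(1.25) + 1e-9)
  expect_lte(recall_at(1.25), recall_at(2.5) + 1e-9)
})

test_that("cross_experiment_overlap enumerates correctly", {
  same <- cross_experiment_overlap(c("a", "b"), c("a", "b"))
  expect_equal(c(same$frac_a_in_b, same$frac_b_in_a), c(1, 1))

  disj <- cross_experiment_overlap(c("a"), c("b", "c"))
  expect_equal(c(disj$frac_a_in_b, disj$frac_b_in_a), c(0, 0))

  part <- cross_experiment_overlap(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(part$frac_a_in_b, 2 / 3)
  expect_equal(part$frac_b_in_a, 1 / 2)

  empt <- cross_experiment_overlap(character(0), c("x"))
  expect_true(is.na(empt$frac_a_in_b))
  expect_equal(empt$frac_b_in_a, 0)
})
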