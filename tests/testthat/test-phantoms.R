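# Synthetic-data generators: determinism, planted ground truth, and the
# stated degenerate cases.

test_that("EM phantom honours degenerate fractions and samplers", {
  ph0 <- generate_em_phantom(
    volume_phantom_spec(n_spines = 10, frac_sa = 0, noise_sigma = 0, seed = 3)
  )
  expect_equal(sum(ph0$spines$has_sa), 0L)

  ph3 <- generate_em_phantom(
    volume_phantom_spec(
      n_spines = 10, frac_sa = 1,
      cistern_count_sampler = c(`3` = 1), noise_sigma = 0, seed = 3
    )
  )
  expect_true(all(ph3$spines$cistern_count == 3L))
  expect_true(all(ph3$spines$has_sa))
})

test_that("EM phantom SA fraction falls in the binomial interval at n = 200", {
  spec <- volume_phantom_spec(
    shape = c(48, 170, 224), n_spines = 200, frac_sa = 0.5,
    noise_sigma = 0, seed = 11
  )
  ph <- generate_em_phantom(spec)
  expect_binomial_interval(sum(ph$spines$has_sa), 200, 0.5)
})

test_that("EM phantom is deterministic given the seed and errors on small volumes", {
  spec <- volume_phantom_spec(n_spines = 6, seed = 9)
  a <- generate_em_phantom(spec)
  b <- generate_em_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$spines, b$spines)

  expect_error(
    generate_em_phantom(volume_phantom_spec(shape = c(16, 40, 16), n_spines = 50)),
    class = "spinescope_error_sizing"
  )
  expect_error(
    generate_em_phantom(volume_phantom_spec(shape = c(16, 40, 16), n_spines = 50)),
    regexp = "limiting dimension"
  )
})

test_that("proteomics phantom: empty truth at frac 0, Poisson limit, efficiency plumbing", {
  ph <- generate_proteomics_table(
    proteomics_sim_spec(n_proteins = 50, frac_enriched = 0, log2_fc = 3, seed = 5)
  )
  expect_length(ph$truth, 0L)

  # dispersion -> 0 gives variance ~ mean (index of dispersion ~ 1)
  big <- generate_proteomics_table(
    proteomics_sim_spec(
      n_proteins = 1500, n_bait = 8, n_ctrl = 8, frac_enriched = 0,
      baseline_mean = 100, dispersion = 0, seed = 6
    )
  )
  counts <- big$table$counts[!spinescope:::is_control_row(big$table), ]
  iod <- apply(counts, 1, var) / rowMeans(counts)
  expect_equal(mean(iod), 1, tolerance = 0.05)

  # efficiency_range = [1,1]: normalized table is exactly raw / control sums
  tab <- generate_proteomics_table(
    proteomics_sim_spec(n_proteins = 40, efficiency_range = c(1, 1), seed = 7)
  )$table
  norm <- normalize_by_endogenous(tab)
  ctrl_sums <- colSums(tab$counts[tab$control_ids, ])
  keep <- !spinescope:::is_control_row(tab)
  expect_equal(
    norm$counts[keep, ],
    sweep(tab$counts[keep, ], 2, ctrl_sums, `/`)
  )
})

test_that("proteomics phantom control counts anticorrelate with yield relative to exogenous", {
  ph <- generate_proteomics_table(
    proteomics_sim_spec(
      n_proteins = 800, frac_enriched = 0, efficiency_range = c(0.2, 1),
      seed = 8
    )
  )
  eff <- ph$table$counts
  exo_mean <- colMeans(eff[!spinescope:::is_control_row(ph$table), ])
  ctrl_share <- colSums(eff[ph$table$control_ids, ]) / colSums(eff)
  # samples with lower exogenous signal carry a higher control share
  expect_lt(cor(exo_mean, ctrl_share), 0)
})

test_that("scrna generator hits planted correlations and validates input", {
  # exact copy at target 1 with equal means
  m1 <- generate_scrna_matrix(
    scrna_sim_spec(target_r = c(copy = 1), n_cells = 2000, seed = 4)
  )
  expect_identical(as.numeric(m1["copy", ]), as.numeric(m1["Synpo", ]))
  expect_equal(pearson_vs_reference(m1, "Synpo")$r[2], 1)

  # null gene at 50k cells: |r| below the 2/sqrt(n) sampling bound
  m0 <- generate_scrna_matrix(
    scrna_sim_spec(target_r = c(null = 0), n_cells = 50000, seed = 4)
  )
  r0 <- pearson_vs_reference(m0, "Synpo")$r[2]
  expect_lt(abs(r0), 0.02)

  expect_error(
    scrna_sim_spec(target_r = c(bad = 1.2), n_cells = 100),
    class = "spinescope_error_validation"
  )
  expect_error(
    generate_scrna_matrix(
      scrna_sim_spec(
        target_r = c(g = 0.99), n_cells = 100,
        mean_expression = c(Synpo = 0.05, g = 5)
      )
    ),
    class = "spinescope_error_validation"
  )
})

test_that("scrna generator is deterministic and sparse", {
  spec <- scrna_sim_spec(target_r = c(a = 0.3, b = -0.1), n_cells = 5000, seed = 12)
  m1 <- generate_scrna_matrix(spec)
  m2 <- generate_scrna_matrix(spec)
  expect_identical(as.matrix(m1), as.matrix(m2))
  expect_s4_class(m1, "dgCMatrix")
})

test_that("fluorescence phantom plants exact intensities and errors on impossible placement", {
  ph <- generate_fluor_image(
    fluor_sim_spec(n_spots = 5, target_ef = 1, noise_sigma = 0, seed = 2)
  )
  px <- ph$image[cbind(ph$spots$row, ph$spots$col)]
  expect_true(all(px == ph$spec$shaft_intensity)) # spot centre equals shaft exactly

  expect_error(
    generate_fluor_image(fluor_sim_spec(shape = c(64, 64), n_spots = 500, seed = 1)),
    class = "spinescope_error_placement"
  )
})

test_that("fluorescence phantom spots are recovered at planted positions", {
  ph <- generate_fluor_image(
    fluor_sim_spec(n_spots = 60, target_ef = 5.1, noise_sigma = 1, seed = 3)
  )
  spots <- detect_spots(ph$image, threshold = 300, mask = !ph$shaft_mask)
  expect_equal(nrow(spots), 60L)
  # every detected centroid within 1 px of a planted centre
  dmat <- outer(spots$centroid_row, ph$spots$row, `-`)^2 +
    outer(spots$centroid_col, ph$spots$col, `-`)^2
  expect_lt(max(apply(dmat, 1, min)), 1)
})
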