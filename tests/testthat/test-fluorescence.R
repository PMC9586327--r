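# Spine/shaft fluorescence enrichment: spot detection, top-k mean, shaft
# ROIs, the enrichment factor, and the group comparison.

test_that("detect_spots thresholds, filters by area and sorts by mean", {
  img <- matrix(1, 40, 40)
  # empty result with a warning, not an error
  expect_warning(s0 <- detect_spots(img, threshold = 10), "No spot")
  expect_equal(nrow(s0), 0L)

  # two disks with means 20 and 10 above threshold, ordered (20, 10)
  img2 <- matrix(0, 40, 40)
  img2[5:8, 5:8] <- 10
  img2[20:23, 20:23] <- 20
  s2 <- detect_spots(img2, threshold = 5)
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$mean_intensity, c(20, 10))

  # min_area prunes single-pixel blips
  img3 <- img2
  img3[35, 35] <- 50
  expect_equal(nrow(detect_spots(img3, threshold = 5, min_area = 2)), 2L)
  expect_equal(nrow(detect_spots(img3, threshold = 5, min_area = 1)), 3L)

  # percentile directive
  sp <- detect_spots(img2, threshold = c(percentile = 99))
  expect_gte(nrow(sp), 1L)
})

test_that("top_k_spot_mean selects and falls back as documented", {
  fake_spots <- function(means) {
    out <- tibble::tibble(
      spot_id = seq_along(means), area = 4L, mean_intensity = means,
      centroid_row = 1, centroid_col = 1
    )
    class(out) <- c("spot_set", class(out))
    out
  }
  # fewer than k: use all with a warning
  expect_warning(mu <- top_k_spot_mean(fake_spots(c(1, 2, 3)), k = 40), "Only 3")
  expect_equal(as.numeric(mu), 2)
  expect_equal(attr(mu, "k_used"), 3L)

  # 50 identical spots
  expect_equal(as.numeric(top_k_spot_mean(fake_spots(rep(7, 50)), k = 40)), 7)

  # 60 spots with known means: equals the sort oracle
  set.seed(8)
  means <- runif(60, 10, 100)
  mu60 <- top_k_spot_mean(fake_spots(means), k = 40)
  expect_equal(as.numeric(mu60), mean(sort(means, decreasing = TRUE)[1:40]))

  # monotone: raising a selected spot never lowers the mean
  means2 <- means
  means2[which.max(means)] <- means2[which.max(means)] + 5
  expect_gte(as.numeric(top_k_spot_mean(fake_spots(means2), 40)), as.numeric(mu60))

  expect_error(
    top_k_spot_mean(fake_spots(numeric(0))),
    class = "spinescope_error_value"
  )
})

test_that("shaft_mean pools region means with equal weighting", {
  img <- matrix(0, 30, 30)
  rois <- lapply(1:5, function(i) {
    m <- matrix(FALSE, 30, 30)
    m[i * 5, 1:4] <- TRUE
    m
  })
  for (i in 1:5) img[rois[[i]]] <- i # region means 1..5
  expect_equal(as.numeric(shaft_mean(img, rois)), 3)

  # uniform regions at 4
  img4 <- matrix(4, 30, 30)
  expect_equal(as.numeric(shaft_mean(img4, rois)), 4)

  # area weighting differs when region sizes differ
  rois2 <- rois
  rois2[[1]][1:2, 1:10] <- TRUE
  img[rois2[[1]]] <- 1
  expect_false(isTRUE(all.equal(
    as.numeric(shaft_mean(img, rois2, weighting = "area")),
    as.numeric(shaft_mean(img, rois2, weighting = "equal"))
  )))

  expect_error(shaft_mean(img, list()), class = "spinescope_error_parameter")
})

test_that("enrichment_factor enforces its domain and scale behaviour", {
  expect_equal(enrichment_factor(5, 5), 1)
  expect_error(enrichment_factor(5, 0), class = "spinescope_error_domain")

  # EF invariant under multiplicative gain; offset changes it predictably
  ph <- generate_fluor_image(fluor_sim_spec(target_ef = 3, noise_sigma = 0, seed = 5))
  rois <- sample_shaft_rois(ph$shaft_mask)
  thr <- 100 * (1 + 3) / 2
  ef1 <- spine_enrichment(ph$image, thr, rois, mask = !ph$shaft_mask)$ef
  ef_gain <- spine_enrichment(ph$image * 2.5, thr * 2.5, rois, mask = !ph$shaft_mask)$ef
  expect_equal(ef_gain, ef1, tolerance = 1e-12)
  off <- 50
  ef_off <- spine_enrichment(ph$image + off, thr + off, rois, mask = !ph$shaft_mask)$ef
  mu_sh <- 100
  expect_equal(ef_off, (ef1 * mu_sh + off) / (mu_sh + off), tolerance = 1e-6)
})

test_that("compare_groups summarises per-group EF and the ratio of means", {
  cmp <- compare_groups(c(5, 5.2, 4.8), c(2.4, 2.6, 2.2))
  expect_equal(cmp$ratio_of_means, 5 / 2.4)
  expect_equal(cmp$per_group$mean_ef, c(5, 2.4))

  same <- compare_groups(c(3, 3), c(3, 3))
  expect_equal(same$ratio_of_means, 1)

  single <- compare_groups(5, 4)
  expect_true(all(is.na(single$per_group$sem_ef)))

  g <- glance(cmp)
  expect_equal(g$ratio_of_means, 5 / 2.4)
  expect_error(compare_groups(numeric(0), 1), class = "spinescope_error_parameter")
})
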