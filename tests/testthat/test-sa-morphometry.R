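# Semiautomated SA detection: DoG filtering, thresholding, continuity
# tracking, refinement, cistern morphometry, contacts and the census.

test_that("dog_filter annihilates constants and is offset-invariant", {
  v <- array(5, c(10, 12, 9))
  expect_equal(max(abs(dog_filter(v, 1, 2)$voxels)), 0)

  set.seed(1)
  a <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  f1 <- dog_filter(a, 1, 2)$voxels
  f2 <- dog_filter(a + 17.5, 1, 2)$voxels
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("dog_filter has a Mexican-hat response to a point source", {
  v <- array(0, c(11, 11, 11))
  v[6, 6, 6] <- 1
  f <- dog_filter(v, 1, 2)$voxels
  expect_equal(which.max(f), which(v == 1)) # peak at the source
  expect_lt(f[6, 6, 2], 0) # negative annulus away from the centre
})

test_that("dog_filter matches a direct-convolution oracle on a dark sheet", {
  d <- c(13, 13, 13)
  v <- array(200, d)
  v[, 6:8, ] <- 60 # dark sheet, 3 voxels thick
  f <- dog_filter(v, 1, 3, invert = TRUE)$voxels
  o <- oracle_dog(-v, 1, 3)
  expect_equal(f, o, tolerance = 1e-10)
  # extremal response on the sheet mid-plane
  expect_equal(arrayInd(which.max(f), d)[, 2], 7)
})

test_that("threshold_mask uses the inclusive >= convention", {
  v <- array(c(0, 5, 10), c(3, 1, 1))
  m <- threshold_mask(v, 6)
  expect_equal(as.vector(m$mask), c(FALSE, FALSE, TRUE))
  expect_equal(as.vector(threshold_mask(v, 5)$mask), c(FALSE, TRUE, TRUE))
  expect_false(any(threshold_mask(v, 11)$mask))
})

test_that("track_structure recovers pillars and respects separation", {
  # 3-plane pillar: all planes joined
  m <- array(FALSE, c(5, 7, 7))
  m[2:4, 3:4, 3:4] <- TRUE
  seed <- single_voxel_seed(dim(m), which(m)[1])
  tr <- track_structure(voxel_mask(m), seed)
  expect_equal(sort(which(as_mask(tr)$mask)), sort(which(m)))

  # seed plane component with no qualifying neighbour stays single-plane
  m2 <- array(FALSE, c(5, 7, 7))
  m2[3, 2:3, 2:3] <- TRUE
  m2[2, 6, 6] <- TRUE # same volume, far away laterally
  region <- matrix(FALSE, 7, 7)
  region[2, 2] <- TRUE
  tr2 <- track_structure(voxel_mask(m2), seed_selection(3, region))
  expect_equal(tr2$plane_index, 3L)

  # two parallel pillars without overlap: tracking one never leaks
  m3 <- array(FALSE, c(6, 9, 9))
  m3[2:5, 2:3, 2:3] <- TRUE # pillar A
  m3[2:5, 7:8, 7:8] <- TRUE # pillar B
  regionA <- matrix(FALSE, 9, 9)
  regionA[2, 2] <- TRUE
  trA <- track_structure(voxel_mask(m3), seed_selection(3, regionA))
  got <- which(as_mask(trA)$mask, arr.ind = TRUE)
  expect_true(all(got[, 2] <= 3)) # no voxel of pillar B
  expect_equal(nrow(got), 4 * 4)
})

test_that("track_structure with min_overlap = 1 equals the 26-CC oracle", {
  set.seed(42)
  for (trial in 1:8) {
    dims <- c(18, 20, 19)
    mask <- random_blob_mask(dims)
    sv <- sample(which(mask), 1)
    tr <- track_structure(voxel_mask(mask), single_voxel_seed(dims, sv))
    expect_identical(sort(which(as_mask(tr)$mask)), oracle_cc26(mask, sv))
  }
})

test_that("min_overlap above 1 prunes weakly connected planes", {
  m <- array(FALSE, c(4, 6, 6))
  m[2, 2:4, 2:4] <- TRUE # 9-voxel slab
  m[3, 4, 4] <- TRUE # attached by a single corner voxel
  seed <- single_voxel_seed(dim(m), which(m)[1])
  tr1 <- track_structure(voxel_mask(m), seed, min_overlap = 1)
  expect_equal(sort(tr1$plane_index), c(2L, 3L))
  tr2 <- track_structure(voxel_mask(m), seed, min_overlap = 2)
  expect_equal(tr2$plane_index, 2L)
})

test_that("tracking errors are informative", {
  m <- array(FALSE, c(4, 6, 6))
  m[2, 2, 2] <- TRUE
  region <- matrix(FALSE, 6, 6)
  region[5, 5] <- TRUE
  expect_error(
    track_structure(voxel_mask(m), seed_selection(2, region)),
    class = "spinescope_error_seed"
  )
})

test_that("refine_object applies edits with removal precedence and is idempotent", {
  m <- array(FALSE, c(4, 6, 6))
  m[2:3, 2:4, 2:4] <- TRUE
  tr <- track_structure(voxel_mask(m), single_voxel_seed(dim(m), which(m)[1]))

  # identity edit
  same <- refine_object(tr)
  expect_equal(as_mask(same)$mask, as_mask(tr)$mask)

  add <- array(FALSE, dim(m))
  add[4, 5, 5] <- TRUE
  rem <- array(FALSE, dim(m))
  rem[4, 5, 5] <- TRUE # same voxel added and removed: removal wins
  r1 <- refine_object(tr, additions = add, removals = rem)
  expect_false(as_mask(r1)$mask[4, 5, 5])

  # idempotence for fixed edits
  rem2 <- array(FALSE, dim(m))
  rem2[3, , ] <- TRUE
  r2 <- refine_object(tr, additions = add, removals = rem2)
  r3 <- refine_object(r2, additions = add, removals = rem2)
  expect_equal(as_mask(r3)$mask, as_mask(r2)$mask)

  # removing everything is an error
  all_rem <- array(TRUE, dim(m))
  expect_error(refine_object(tr, removals = all_rem), class = "spinescope_error_refinement")
})

test_that("segment_cisterns measures flatness and orientation", {
  # one planar slab: flat, normal perpendicular to the slab
  m <- array(FALSE, c(12, 12, 12))
  m[3:10, 6, 3:10] <- TRUE
  cis <- segment_cisterns(voxel_mask(m, "ER"))
  expect_equal(nrow(cis), 1L)
  expect_lt(cis$flatness[1], 0.33)
  expect_true(cis$planar[1])
  expect_equal(abs(cis$normal[[1]][2]), 1, tolerance = 1e-9) # y axis

  # a ball is not flat: eigenvalues near-equal
  d <- c(13, 13, 13)
  ctr <- c(7, 7, 7)
  ball <- array(FALSE, d)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  ball[idx[rowSums(sweep(idx, 2, ctr)^2) <= 25, ]] <- TRUE
  cball <- segment_cisterns(voxel_mask(ball, "ER"))
  expect_gt(cball$flatness[1], 0.8)
  # direct eigenvalue oracle: scatter of the discretised ball coordinates
  coords <- which(ball, arr.ind = TRUE) * 8
  ev <- sort(eigen(cov(coords), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(sort(c(cball$eig1, cball$eig2, cball$eig3), decreasing = TRUE), ev)

  # three disjoint parallel slabs: pairwise-parallel normals
  m3 <- array(FALSE, c(14, 14, 14))
  for (y in c(3, 6, 9)) m3[3:10, y, 3:10] <- TRUE
  cis3 <- segment_cisterns(voxel_mask(m3, "ER"))
  expect_equal(nrow(cis3), 3L)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      ang <- spinescope:::normal_angle_deg(cis3$normal[[i]], cis3$normal[[j]])
      expect_lt(ang, 30)
    }
  }
})

test_that("classify_sa applies the >= 2 flat-parallel-apposed rule", {
  slab <- function(dims, ys) {
    m <- array(FALSE, dims)
    for (y in ys) m[3:10, y, 3:10] <- TRUE
    m
  }
  # single flat cistern: counted but not an SA
  one <- classify_sa(segment_cisterns(voxel_mask(slab(c(12, 12, 12), 6), "ER")))
  expect_false(one$is_sa)
  expect_equal(one$cistern_count, 1L)

  # three apposed parallel slabs (gap 2 voxels = 16 nm at 8 nm voxels)
  three <- classify_sa(segment_cisterns(voxel_mask(slab(c(14, 14, 14), c(3, 6, 9)), "ER")))
  expect_true(three$is_sa)
  expect_equal(three$cistern_count, 3L)

  # two flat slabs at 90 degrees: parallelism violated
  cross <- array(FALSE, c(14, 14, 14))
  cross[3:10, 4, 3:10] <- TRUE # normal along y
  cross[3:10, 7:12, 6] <- TRUE # normal along x
  xc <- classify_sa(segment_cisterns(voxel_mask(cross, "ER")))
  expect_false(xc$is_sa)

  # far-apart parallel slabs: apposition violated at a tight gap_max
  far <- classify_sa(
    segment_cisterns(voxel_mask(slab(c(14, 14, 14), c(3, 12)), "ER")),
    gap_max_nm = 30
  )
  expect_false(far$is_sa)

  # a 1-voxel-wide tubule is never a flat cistern
  tub <- array(FALSE, c(12, 12, 12))
  tub[3:10, 6, 6] <- TRUE
  tc <- classify_sa(segment_cisterns(voxel_mask(tub, "ER")))
  expect_equal(tc$cistern_count, 0L)
})

test_that("detect_contacts respects physical distance and monotonicity", {
  a <- array(FALSE, c(8, 8, 8))
  a[4, 4, 4] <- TRUE
  b <- array(FALSE, c(8, 8, 8))
  b[4, 4, 5] <- TRUE # face-adjacent: 8 nm at 8 nm voxels
  hit <- detect_contacts(voxel_mask(a), voxel_mask(b), contact_dist_nm = 8)
  expect_true(attr(hit, "contact"))
  expect_equal(hit$dist_nm, 8)

  # everything farther than the cut: empty
  b2 <- array(FALSE, c(8, 8, 8))
  b2[4, 4, 8] <- TRUE # 32 nm away
  miss <- detect_contacts(voxel_mask(a), voxel_mask(b2), contact_dist_nm = 30)
  expect_false(attr(miss, "contact"))
  expect_equal(nrow(miss), 0L)

  # anisotropy: same voxel offset, larger physical size along x
  aniso <- detect_contacts(
    voxel_mask(a, voxel_size_nm = c(8, 8, 40)),
    voxel_mask(b, voxel_size_nm = c(8, 8, 40)),
    contact_dist_nm = 30
  )
  expect_false(attr(aniso, "contact"))

  # shrinking the distance never adds contacts
  set.seed(7)
  sa <- array(FALSE, c(10, 10, 10))
  sa[5, 4:6, 4:6] <- TRUE
  other <- array(runif(1000) < 0.1, c(10, 10, 10))
  n_wide <- nrow(detect_contacts(voxel_mask(sa), voxel_mask(other), 40))
  n_narrow <- nrow(detect_contacts(voxel_mask(sa), voxel_mask(other), 20))
  expect_lte(n_narrow, n_wide)
})

test_that("spine_census counts PSD-positive spines only and enforces invariants", {
  spines <- tibble::tibble(
    has_psd = c(TRUE, TRUE, TRUE, FALSE),
    has_er = c(TRUE, TRUE, FALSE, TRUE),
    has_sa = c(TRUE, FALSE, FALSE, TRUE)
  )
  cen <- spine_census(spines)
  expect_equal(cen$n_psd, 3L)
  expect_equal(cen$frac_er, 2 / 3)
  expect_equal(cen$frac_sa, 1 / 3)
  expect_equal(cen$frac_sa_given_er, 1 / 2)

  # all ER-negative: SA fraction 0
  none <- tibble::tibble(has_psd = TRUE, has_er = c(FALSE, FALSE), has_sa = FALSE)
  expect_equal(spine_census(none)$frac_sa, 0)

  # single PSD+SA spine: all fractions 1
  one <- tibble::tibble(has_psd = TRUE, has_er = TRUE, has_sa = TRUE)
  expect_equal(spine_census(one)$frac_sa, 1)

  # invariant and empty-denominator errors
  expect_error(
    spine_census(tibble::tibble(has_psd = TRUE, has_er = FALSE, has_sa = TRUE)),
    class = "spinescope_error_invariant"
  )
  expect_error(
    spine_census(tibble::tibble(has_psd = FALSE, has_er = TRUE, has_sa = FALSE)),
    class = "spinescope_error_census"
  )
})
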