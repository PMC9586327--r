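# Volume-EM phantom generator. Builds a 3D intensity stack with spine-like
# compartments on a regular grid; each compartment gets a plasma-membrane
# shell, a PSD patch, and (depending on the planted fractions) a spine
# apparatus (stack of flat ER cisterns), plain ER, a PM contact extension
# and/or a nearby tubulovesicle. Membranes are rendered dark on a bright
# background (heavy-metal-stain convention) plus Gaussian noise.

default_cistern_pmf <- function() {
  # counts 2..8 with median 3, matching reported SA cistern statistics
  setNames(c(0.25, 0.30, 0.20, 0.12, 0.07, 0.04, 0.02), 2:8)
}

#' Specification of an EM phantom volume
#'
#' Describes the stated world for [generate_em_phantom()]: volume size,
#' voxel size, number of spines, the fraction carrying a spine apparatus
#' (SA), the distribution of cistern counts per SA, cistern geometry, and
#' the fractions of SAs with a plasma-membrane contact or a nearby
#' tubulovesicle.
#'
#' @param shape Volume dimensions `(planes, rows, cols)`, each at least 8.
#' @param voxel_size_nm Voxel edge lengths `(z, y, x)` in nm.
#' @param n_spines Number of spine compartments to plant.
#' @param frac_sa Fraction of spines given an SA (Bernoulli per spine).
#' @param cistern_count_sampler Either a named numeric probability vector
#'   over integer counts `>= 2` (default: counts 2..8, median 3) or a
#'   `function(n)` returning `n` integer counts `>= 2`.
#' @param cistern_thickness_vox,cistern_gap_vox Cistern thickness and
#'   inter-cistern gap in voxels (positive integers).
#' @param frac_pm_contact Fraction of SAs touching the plasma-membrane shell.
#' @param frac_tv_contact Fraction of SAs with a tubulovesicle within
#'   contact range.
#' @param noise_sigma Standard deviation of additive Gaussian intensity
#'   noise (intensity units; background is 200, membrane 60).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `volume_phantom_spec`.
#' @export
volume_phantom_spec <- function(shape = c(48, 136, 128),
                                voxel_size_nm = c(8, 8, 8),
                                n_spines = 24,
                                frac_sa = 0.5,
                                cistern_count_sampler = NULL,
                                cistern_thickness_vox = 1,
                                cistern_gap_vox = 2,
                                frac_pm_contact = 0.83,
                                frac_tv_contact = 0.41,
                                noise_sigma = 4,
                                seed = 1L) {
  shape <- vapply(seq_along(shape), function(i) {
    assert_count(shape[i], sprintf("shape[%d]", i), lower = 8)
  }, integer(1))
  if (length(shape) != 3L) {
    stop_spinescope("`shape` must have three entries (planes, rows, cols).", "parameter")
  }
  n_spines <- assert_count(n_spines, "n_spines", lower = 1)
  assert_fraction(frac_sa, "frac_sa")
  assert_fraction(frac_pm_contact, "frac_pm_contact")
  assert_fraction(frac_tv_contact, "frac_tv_contact")
  assert_number(noise_sigma, "noise_sigma", lower = 0)
  thickness <- assert_count(cistern_thickness_vox, "cistern_thickness_vox", lower = 1)
  gap <- assert_count(cistern_gap_vox, "cistern_gap_vox", lower = 1)
  if (is.null(cistern_count_sampler)) cistern_count_sampler <- default_cistern_pmf()
  if (is.numeric(cistern_count_sampler)) {
    counts <- suppressWarnings(as.integer(names(cistern_count_sampler)))
    if (anyNA(counts) || any(counts < 2L) || any(cistern_count_sampler < 0) ||
        sum(cistern_count_sampler) <= 0) {
      stop_spinescope(
        "`cistern_count_sampler` must be a probability vector named by integer counts >= 2.",
        "parameter"
      )
    }
  } else if (!is.function(cistern_count_sampler)) {
    stop_spinescope(
      "`cistern_count_sampler` must be a named probability vector or a function(n).",
      "parameter"
    )
  }
  structure(
    list(
      shape = shape,
      voxel_size_nm = rep(as.numeric(voxel_size_nm), length.out = 3L),
      n_spines = n_spines,
      frac_sa = frac_sa,
      cistern_count_sampler = cistern_count_sampler,
      cistern_thickness_vox = thickness,
      cistern_gap_vox = gap,
      frac_pm_contact = frac_pm_contact,
      frac_tv_contact = frac_tv_contact,
      noise_sigma = noise_sigma,
      seed = as.integer(seed)
    ),
    class = "volume_phantom_spec"
  )
}

draw_cistern_counts <- function(sampler, n) {
  if (n == 0L) return(integer(0))
  if (is.function(sampler)) {
    k <- as.integer(sampler(n))
  } else {
    vals <- as.integer(names(sampler))
    k <- vals[sample.int(length(vals), n, replace = TRUE, prob = sampler)]
  }
  if (any(k < 2L)) {
    stop_spinescope("cistern_count_sampler produced a count below 2.", "parameter")
  }
  k
}

max_cistern_count <- function(sampler) {
  if (is.function(sampler)) 8L else max(as.integer(names(sampler)))
}

#' Generate a volume-EM phantom with planted spine apparatuses
#'
#' Spine compartments are laid out on a regular grid of boxes; each box is
#' wrapped in a 1-voxel plasma-membrane shell with a PSD patch at the top
#' face. SA-positive spines receive a stack of flat cisterns (thickness and
#' gap from the spec, count from the cistern sampler) stacked along the row
#' axis; PM-contact SAs have one cistern extended to within one voxel of the
#' shell; tubulovesicle-contact SAs get a small vesicle blob within contact
#' range. SA-negative spines receive plain ER (a single cistern or a
#' tubule) with probability 1/2. Membranes are dark (intensity 60) on a
#' bright background (200) with additive Gaussian noise.
#'
#' @param spec A [volume_phantom_spec()].
#' @return A list of class `em_phantom` with elements `volume`
#'   ([em_volume]), `masks` (named list of [voxel_mask]: `PM`, `ER`, `PSD`,
#'   `tubulovesicle`), `spines` (ground-truth tibble: `spine_id`, box
#'   bounds, `has_psd`, `has_er`, `has_sa`, `cistern_count`, `pm_contact`,
#'   `tv_contact`), and `spec`.
#' @export
generate_em_phantom <- function(spec) {
  stopifnot(inherits(spec, "volume_phantom_spec"))
  t_vox <- spec$cistern_thickness_vox
  g_vox <- spec$cistern_gap_vox
  k_max <- max_cistern_count(spec$cistern_count_sampler)
  h_max <- k_max * t_vox + (k_max - 1L) * g_vox
  box <- c(16L, h_max + 12L, 16L)
  n_boxes <- spec$shape %/% box
  capacity <- prod(n_boxes)
  if (capacity < spec$n_spines) {
    limiting <- c("planes (z)", "rows (y)", "cols (x)")[which.min(n_boxes)]
    stop_spinescope(
      sprintf(
        "Volume too small: %d spine boxes of %d x %d x %d fit (need %d); limiting dimension: %s.",
        capacity, box[1], box[2], box[3], spec$n_spines, limiting
      ),
      "sizing"
    )
  }

  d <- spec$shape
  pm <- array(FALSE, d)
  er <- array(FALSE, d)
  psd <- array(FALSE, d)
  tv <- array(FALSE, d)

  withr::with_seed(spec$seed, {
    has_sa <- runif(spec$n_spines) < spec$frac_sa
    k_sa <- integer(spec$n_spines)
    k_sa[has_sa] <- draw_cistern_counts(spec$cistern_count_sampler, sum(has_sa))
    pm_contact <- has_sa & (runif(spec$n_spines) < spec$frac_pm_contact)
    tv_contact <- has_sa & (runif(spec$n_spines) < spec$frac_tv_contact)
    # SA-negative spines: plain ER half the time, split between one flat
    # cistern and a tubule
    er_type <- ifelse(
      has_sa, "sa",
      sample(c("slab", "tubule", "none"), spec$n_spines,
        replace = TRUE, prob = c(0.25, 0.25, 0.5)
      )
    )
    noise <- if (spec$noise_sigma > 0) {
      array(rnorm(prod(d), 0, spec$noise_sigma), d)
    } else {
      array(0, d)
    }
  })

  grid <- expand.grid(
    iz = seq_len(n_boxes[1]), iy = seq_len(n_boxes[2]), ix = seq_len(n_boxes[3])
  )
  spines <- vector("list", spec$n_spines)
  for (s in seq_len(spec$n_spines)) {
    z0 <- (grid$iz[s] - 1L) * box[1] + 1L
    y0 <- (grid$iy[s] - 1L) * box[2] + 1L
    x0 <- (grid$ix[s] - 1L) * box[3] + 1L
    z1 <- z0 + box[1] - 1L
    y1 <- y0 + box[2] - 1L
    x1 <- x0 + box[3] - 1L

    # plasma-membrane shell: all six faces of the box
    pm[c(z0, z1), y0:y1, x0:x1] <- TRUE
    pm[z0:z1, c(y0, y1), x0:x1] <- TRUE
    pm[z0:z1, y0:y1, c(x0, x1)] <- TRUE
    # PSD patch just inside the top (max-y) face
    psd[(z0 + 6L):(z0 + 9L), y1 - 1L, (x0 + 6L):(x0 + 9L)] <- TRUE

    lat_z <- (z0 + 5L):(z0 + 10L) # 6-voxel lateral extent, >= 5 voxels off shell
    lat_x <- (x0 + 5L):(x0 + 10L)
    cistern_count <- 0L
    has_er_s <- FALSE

    if (er_type[s] == "sa") {
      k <- k_sa[s]
      h <- k * t_vox + (k - 1L) * g_vox
      ys <- y0 + (box[2] - h) %/% 2L
      for (j in seq_len(k)) {
        yy <- (ys + (j - 1L) * (t_vox + g_vox)):(ys + (j - 1L) * (t_vox + g_vox) + t_vox - 1L)
        er[lat_z, yy, lat_x] <- TRUE
      }
      mid <- ceiling(k / 2)
      y_mid <- (ys + (mid - 1L) * (t_vox + g_vox)):(ys + (mid - 1L) * (t_vox + g_vox) + t_vox - 1L)
      if (pm_contact[s]) {
        # extend the middle cistern to one voxel short of the shell
        er[lat_z, y_mid, (x0 + 11L):(x1 - 1L)] <- TRUE
      }
      if (tv_contact[s]) {
        # 2x2x2 vesicle two voxels off the opposite edge of the middle cistern
        tv[(z0 + 7L):(z0 + 8L), y_mid[1]:(y_mid[1] + 1L), (x0 + 2L):(x0 + 3L)] <- TRUE
      }
      cistern_count <- k
      has_er_s <- TRUE
    } else if (er_type[s] == "slab") {
      ys <- y0 + box[2] %/% 2L
      er[lat_z, ys:(ys + t_vox - 1L), lat_x] <- TRUE
      cistern_count <- 1L
      has_er_s <- TRUE
    } else if (er_type[s] == "tubule") {
      er[z0 + 8L, y0 + box[2] %/% 2L, lat_x] <- TRUE
      cistern_count <- 0L
      has_er_s <- TRUE
    }

    spines[[s]] <- tibble(
      spine_id = s,
      z0 = z0, z1 = z1, y0 = y0, y1 = y1, x0 = x0, x1 = x1,
      has_psd = TRUE,
      has_er = has_er_s,
      has_sa = has_sa[s],
      cistern_count = cistern_count,
      pm_contact = pm_contact[s],
      tv_contact = tv_contact[s]
    )
  }

  intensity <- array(200, d)
  intensity[pm | er | psd | tv] <- 60
  intensity <- intensity + noise

  structure(
    list(
      volume = em_volume(intensity, spec$voxel_size_nm),
      masks = list(
        PM = voxel_mask(pm, "PM", spec$voxel_size_nm),
        ER = voxel_mask(er, "ER", spec$voxel_size_nm),
        PSD = voxel_mask(psd, "PSD", spec$voxel_size_nm),
        tubulovesicle = voxel_mask(tv, "tubulovesicle", spec$voxel_size_nm)
      ),
      spines = bind_rows(spines),
      spec = spec
    ),
    class = "em_phantom"
  )
}

#' Extract a role mask cropped to one spine's bounding box
#'
#' @param phantom An `em_phantom` from [generate_em_phantom()].
#' @param spine_id Spine identifier (row of `phantom$spines`).
#' @param role One of `"PM"`, `"ER"`, `"PSD"`, `"tubulovesicle"`.
#' @return A [voxel_mask] restricted to the spine's box.
#' @export
phantom_spine_mask <- function(phantom, spine_id, role = "ER") {
  stopifnot(inherits(phantom, "em_phantom"))
  role <- match.arg(role, c("PM", "ER", "PSD", "tubulovesicle"))
  row <- phantom$spines[phantom$spines$spine_id == spine_id, ]
  if (nrow(row) != 1L) {
    stop_spinescope(sprintf("Unknown spine_id %s.", spine_id), "parameter")
  }
  full <- phantom$masks[[role]]$mask
  sub <- full[row$z0:row$z1, row$y0:row$y1, row$x0:row$x1, drop = FALSE]
  voxel_mask(sub, role = role, voxel_size_nm = phantom$spec$voxel_size_nm)
}
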