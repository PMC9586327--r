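# Fluorescence-image phantom: a dendritic shaft band at a known intensity
# and non-overlapping circular spine spots at shaft_intensity * target_ef,
# plus additive Gaussian noise, with planted spot centres and the shaft
# mask as ground truth.

#' Specification of a simulated spine-fluorescence image
#'
#' @param shape Image dimensions `(rows, cols)`.
#' @param n_spots Number of spine spots to plant (`>= 1`; the downstream
#'   top-40 average wants at least 40).
#' @param target_ef Planted spine/shaft mean-intensity ratio (`> 0`).
#' @param shaft_intensity Mean intensity of the dendritic shaft band.
#' @param spot_radius Spot radius in pixels.
#' @param noise_sigma Additive Gaussian noise SD (intensity units).
#' @param seed Integer seed.
#' @return An object of class `fluor_sim_spec`.
#' @export
fluor_sim_spec <- function(shape = c(256, 256),
                           n_spots = 60,
                           target_ef = 5.1,
                           shaft_intensity = 100,
                           spot_radius = 3,
                           noise_sigma = 2,
                           seed = 1L) {
  shape <- vapply(seq_along(shape), function(i) {
    assert_count(shape[i], sprintf("shape[%d]", i), lower = 32)
  }, integer(1))
  if (length(shape) != 2L) {
    stop_spinescope("`shape` must have two entries (rows, cols).", "parameter")
  }
  n_spots <- assert_count(n_spots, "n_spots", lower = 1)
  assert_number(target_ef, "target_ef", lower = 1e-9)
  assert_number(shaft_intensity, "shaft_intensity", lower = 1e-9)
  spot_radius <- assert_count(spot_radius, "spot_radius", lower = 1)
  assert_number(noise_sigma, "noise_sigma", lower = 0)
  structure(
    list(
      shape = shape, n_spots = n_spots, target_ef = target_ef,
      shaft_intensity = shaft_intensity, spot_radius = spot_radius,
      noise_sigma = noise_sigma, seed = as.integer(seed)
    ),
    class = "fluor_sim_spec"
  )
}

#' Generate a fluorescence image with planted spine/shaft enrichment
#'
#' The dendritic shaft is a horizontal band through the image centre
#' rendered at `shaft_intensity`; spots are disks at
#' `shaft_intensity * target_ef` placed off the shaft without overlap
#' (bounded rejection sampling; a placement error is raised when the image
#' cannot host `n_spots` disjoint spots).
#'
#' @param spec A [fluor_sim_spec()].
#' @return A list of class `fluor_phantom`: `image` (numeric matrix),
#'   `shaft_mask` (logical matrix), `spots` (tibble of planted centres:
#'   `spot_id`, `row`, `col`, `radius`), `spec`.
#' @export
generate_fluor_image <- function(spec) {
  stopifnot(inherits(spec, "fluor_sim_spec"))
  d <- spec$shape
  r <- spec$spot_radius
  band_half <- 12L
  mid <- d[1] %/% 2L
  shaft <- matrix(FALSE, d[1], d[2])
  shaft[(mid - band_half):(mid + band_half), ] <- TRUE

  margin <- r + 2L
  allowed_rows <- setdiff(
    seq.int(margin + 1L, d[1] - margin),
    (mid - band_half - margin):(mid + band_half + margin)
  )
  if (length(allowed_rows) == 0L) {
    stop_spinescope("Image too small to place spots off the shaft band.", "placement")
  }

  withr::with_seed(spec$seed, {
    centres <- matrix(NA_real_, 0L, 2L)
    tries <- 0L
    max_tries <- 400L * spec$n_spots
    while (nrow(centres) < spec$n_spots) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop_spinescope(
          sprintf(
            "Could not place %d non-overlapping spots after %d tries (placed %d).",
            spec$n_spots, max_tries, nrow(centres)
          ),
          "placement"
        )
      }
      cand <- c(sample(allowed_rows, 1L), sample.int(d[2] - 2L * margin, 1L) + margin)
      if (nrow(centres) > 0L) {
        d2 <- (centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2
        if (min(d2) < (2L * r + 2L)^2) next
      }
      centres <- rbind(centres, cand)
    }
    noise <- if (spec$noise_sigma > 0) {
      matrix(rnorm(prod(d), 0, spec$noise_sigma), d[1], d[2])
    } else {
      matrix(0, d[1], d[2])
    }
  })

  img <- matrix(0, d[1], d[2])
  img[shaft] <- spec$shaft_intensity
  # rasterise disks
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  for (i in seq_len(nrow(centres))) {
    rows <- centres[i, 1] + off$dr
    cols <- centres[i, 2] + off$dc
    img[cbind(rows, cols)] <- spec$shaft_intensity * spec$target_ef
  }
  img <- img + noise

  structure(
    list(
      image = img,
      shaft_mask = shaft,
      spots = tibble(
        spot_id = seq_len(nrow(centres)),
        row = centres[, 1], col = centres[, 2], radius = r
      ),
      spec = spec
    ),
    class = "fluor_phantom"
  )
}

#' Deterministically sample rectangular shaft ROIs from a shaft mask
#'
#' Splits the shaft band into `n` equal horizontal segments and takes a
#' centred rectangle from each — a stand-in for the manual selection of
#' shaft regions on real images.
#'
#' @param shaft_mask Logical matrix marking the dendritic shaft.
#' @param n Number of ROIs (default 5).
#' @param width ROI width in pixels (default 16).
#' @return A list of `n` logical ROI masks.
#' @export
sample_shaft_rois <- function(shaft_mask, n = 5L, width = 16L) {
  n <- assert_count(n, "n", lower = 1)
  width <- assert_count(width, "width", lower = 1)
  idx <- which(shaft_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_spinescope("Shaft mask is empty.", "parameter")
  rows <- range(idx[, 1])
  cols <- range(idx[, 2])
  # shrink rows slightly so ROIs sit inside the band
  row_span <- max(rows[1] + 2L, rows[1]):min(rows[2] - 2L, rows[2])
  breaks <- floor(seq(cols[1], cols[2] + 1L, length.out = n + 1L))
  map(seq_len(n), function(i) {
    seg_mid <- (breaks[i] + breaks[i + 1L] - 1L) %/% 2L
    half <- width %/% 2L
    cc <- max(cols[1], seg_mid - half):min(cols[2], seg_mid + half)
    roi <- matrix(FALSE, nrow(shaft_mask), ncol(shaft_mask))
    roi[row_span, cc] <- TRUE
    roi & shaft_mask
  })
}
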