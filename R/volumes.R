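# 3D EM volume and mask containers, plus the semiautomated tracking tools:
# difference-of-Gaussians filtering, thresholding, seeded plane-by-plane
# continuity tracking, and manual refinement of tracked objects.

MASK_ROLES <- c("ER", "PM", "PSD", "tubulovesicle", "SA-candidate")

#' 3D electron-microscopy intensity volume
#'
#' A light container for a grayscale image stack, indexed
#' `(plane, row, col)`, together with the physical voxel edge lengths in
#' nanometres. All distances downstream (cistern gaps, membrane contacts)
#' are computed in nm via `voxel_size_nm`, so anisotropic voxels are handled
#' correctly.
#'
#' @param voxels Numeric 3D array `(plane, row, col)`.
#' @param voxel_size_nm Positive length-3 numeric, physical size of a voxel
#'   along `(z, y, x)` in nm.
#' @return An object of class `em_volume`.
#' @export
em_volume <- function(voxels, voxel_size_nm = c(8, 8, 8)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_spinescope("`voxels` must be a 3D array (plane, row, col).", "parameter")
  }
  voxel_size_nm <- rep(as.numeric(voxel_size_nm), length.out = 3L)
  if (any(!is.finite(voxel_size_nm)) || any(voxel_size_nm <= 0)) {
    stop_spinescope("`voxel_size_nm` must be strictly positive.", "parameter")
  }
  structure(
    list(voxels = voxels, voxel_size_nm = voxel_size_nm),
    class = "em_volume"
  )
}

#' @export
print.em_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<em_volume> %d planes x %d rows x %d cols, voxel %.3g x %.3g x %.3g nm\n",
    d[1], d[2], d[3], x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3]
  ))
  invisible(x)
}

#' @export
dim.em_volume <- function(x) dim(x$voxels)

as_volume_array <- function(x) {
  if (inherits(x, "em_volume")) x$voxels else x
}

#' Binary voxel mask with a role tag
#'
#' @param mask Logical 3D array, same shape as its parent volume.
#' @param role One of `"ER"`, `"PM"`, `"PSD"`, `"tubulovesicle"`,
#'   `"SA-candidate"`.
#' @param voxel_size_nm Physical voxel size `(z, y, x)` in nm.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(mask, role = "SA-candidate", voxel_size_nm = c(8, 8, 8)) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    stop_spinescope("`mask` must be a logical 3D array.", "parameter")
  }
  if (!is.character(role) || length(role) != 1L || !(role %in% MASK_ROLES)) {
    stop_spinescope(
      sprintf("`role` must be one of: %s.", paste(MASK_ROLES, collapse = ", ")),
      "parameter"
    )
  }
  voxel_size_nm <- rep(as.numeric(voxel_size_nm), length.out = 3L)
  structure(
    list(mask = mask, role = role, voxel_size_nm = voxel_size_nm),
    class = "voxel_mask"
  )
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<voxel_mask role=%s> %d x %d x %d, %d voxels set\n",
    x$role, d[1], d[2], d[3], sum(x$mask)
  ))
  invisible(x)
}

as_mask_array <- function(x) {
  if (inherits(x, "voxel_mask")) x$mask else x
}

#' Manual seed for continuity tracking
#'
#' Records the single plane and the 2D region a user selected to start
#' tracking a structure through the stack.
#'
#' @param plane 1-based plane index.
#' @param region Logical matrix (rows x cols of the volume) marking the
#'   selected segment; must be non-empty.
#' @return An object of class `seed_selection`.
#' @export
seed_selection <- function(plane, region) {
  plane <- assert_count(plane, "plane", lower = 1)
  if (!is.matrix(region) || !is.logical(region) || !any(region)) {
    stop_spinescope("`region` must be a non-empty logical matrix.", "seed")
  }
  structure(list(plane = plane, region = region), class = "seed_selection")
}

# ---- DoG filtering ----------------------------------------------------------

#' Difference-of-Gaussians band-pass filter for image stacks
#'
#' Computes `G(sigma_small) * vol - G(sigma_large) * vol` with separable
#' Gaussian convolution and edge replication at the stack boundary. The DoG
#' annihilates constant intensity and responds maximally at edges and thin
#' membranes whose width matches the sigma band. In heavy-metal-stained EM
#' membranes are dark; set `invert = TRUE` to flip the contrast first so
#' membranes come out as positive ridges (the convention assumed by the
#' spine-apparatus tracking pipeline).
#'
#' @param vol An [em_volume] or numeric 3D array.
#' @param sigma_small,sigma_large Gaussian standard deviations in voxels,
#'   `0 < sigma_small < sigma_large`.
#' @param invert If `TRUE`, negate intensities before filtering (dark
#'   structures become positive responses). Default `FALSE`.
#' @return An [em_volume] with the filtered intensities.
#' @export
dog_filter <- function(vol, sigma_small, sigma_large, invert = FALSE) {
  assert_number(sigma_small, "sigma_small", lower = 1e-9)
  assert_number(sigma_large, "sigma_large", lower = 1e-9)
  if (sigma_small >= sigma_large) {
    stop_spinescope("`sigma_small` must be strictly less than `sigma_large`.", "parameter")
  }
  a <- as_volume_array(vol)
  if (isTRUE(invert)) a <- -a
  filtered <- gaussian_blur3(a, sigma_small) - gaussian_blur3(a, sigma_large)
  vsz <- if (inherits(vol, "em_volume")) vol$voxel_size_nm else c(8, 8, 8)
  em_volume(filtered, vsz)
}

#' Threshold a filtered volume into a binary mask
#'
#' Voxels with intensity greater than or equal to `threshold` are selected
#' (inclusive convention).
#'
#' @param filtered An [em_volume] or numeric 3D array.
#' @param threshold Intensity cut.
#' @param role Role tag for the resulting mask (see [voxel_mask]).
#' @return A [voxel_mask].
#' @export
threshold_mask <- function(filtered, threshold, role = "SA-candidate") {
  assert_number(threshold, "threshold")
  a <- as_volume_array(filtered)
  vsz <- if (inherits(filtered, "em_volume")) filtered$voxel_size_nm else c(8, 8, 8)
  voxel_mask(a >= threshold, role = role, voxel_size_nm = vsz)
}

# ---- continuity tracking ----------------------------------------------------

#' Track a seeded structure plane by plane through a binary mask
#'
#' Starting from the 2D connected components of the mask that intersect the
#' manually selected seed region, the structure is propagated to adjacent
#' planes: a 2D component of the mask in a neighbouring plane is accepted when
#' at least `min_overlap` of its voxels lie within the tracked selection of
#' the current plane (grown by one voxel laterally when
#' `overlap_connectivity = 26`, so diagonal continuity counts, matching 3D
#' 26-neighbourhood connectivity). Propagation runs in both directions and
#' revisits planes until no further component qualifies, so branched and
#' re-entrant structures are followed completely. With `min_overlap = 1` and
#' 26-neighbour overlap the result is exactly the 3D connected component of
#' the mask containing the seed.
#'
#' @param mask A [voxel_mask] (e.g. from [threshold_mask()]).
#' @param seed A [seed_selection].
#' @param min_overlap Minimum number of overlapping voxels required to accept
#'   a component in the adjacent plane (default 1).
#' @param overlap_connectivity 26 (default; overlap includes diagonal
#'   neighbours) or 6 (strictly vertical overlap).
#' @return A `tracked_object`: per-plane 2D masks over a contiguous plane
#'   interval plus provenance (seed plane, parameters).
#' @export
track_structure <- function(mask, seed, min_overlap = 1L, overlap_connectivity = 26L) {
  m <- as_mask_array(mask)
  min_overlap <- assert_count(min_overlap, "min_overlap", lower = 1)
  if (!inherits(seed, "seed_selection")) {
    stop_spinescope("`seed` must be a seed_selection.", "parameter")
  }
  d <- dim(m)
  if (seed$plane > d[1]) {
    stop_spinescope("Seed plane lies outside the volume.", "seed")
  }
  if (!all(dim(seed$region) == d[2:3])) {
    stop_spinescope("Seed region shape does not match the volume planes.", "seed")
  }
  use26 <- identical(as.integer(overlap_connectivity), 26L)

  plane_labels <- vector("list", d[1])
  get_labels <- function(p) {
    if (is.null(plane_labels[[p]])) {
      plane_labels[[p]] <<- label_components2(m[p, , ], connectivity = 8L)
    }
    plane_labels[[p]]
  }

  sel <- vector("list", d[1]) # selected 2D mask per plane (NULL = empty)
  lab0 <- get_labels(seed$plane)
  seed_ids <- setdiff(unique(lab0[seed$region]), 0L)
  if (length(seed_ids) == 0L) {
    stop_spinescope("Seed region does not intersect the mask in the seed plane.", "seed")
  }
  sel[[seed$plane]] <- matrix(lab0 %in% seed_ids, d[2], d[3])

  queue <- seed$plane
  while (length(queue) > 0L) {
    p <- queue[[1L]]
    queue <- queue[-1L]
    src <- sel[[p]]
    src_grown <- if (use26) dilate2(src, 8L) else src
    for (q in c(p - 1L, p + 1L)) {
      if (q < 1L || q > d[1]) next
      lab <- get_labels(q)
      if (all(lab == 0L)) next
      current <- sel[[q]]
      # overlap of every component in plane q with the (grown) selection
      hit <- lab[src_grown & lab > 0L]
      if (length(hit) == 0L) next
      counts <- tabulate(hit)
      accept <- which(counts >= min_overlap)
      if (length(accept) == 0L) next
      newsel <- matrix(lab %in% accept, d[2], d[3])
      if (!is.null(current)) newsel <- newsel | current
      if (is.null(current) || sum(newsel) > sum(current)) {
        sel[[q]] <- newsel
        queue <- c(queue, q)
      }
    }
  }

  planes_used <- which(!vapply(sel, is.null, logical(1)))
  vsz <- if (inherits(mask, "voxel_mask")) mask$voxel_size_nm else c(8, 8, 8)
  structure(
    list(
      planes = sel[planes_used],
      plane_index = planes_used,
      dim = d,
      voxel_size_nm = vsz,
      provenance = list(
        seed_plane = seed$plane,
        min_overlap = min_overlap,
        overlap_connectivity = if (use26) 26L else 6L,
        edits = list()
      )
    ),
    class = "tracked_object"
  )
}

#' @export
print.tracked_object <- function(x, ...) {
  cat(sprintf(
    "<tracked_object> planes %d..%d, %d voxels (seed plane %d, min_overlap %d)\n",
    min(x$plane_index), max(x$plane_index),
    sum(vapply(x$planes, sum, numeric(1))),
    x$provenance$seed_plane, x$provenance$min_overlap
  ))
  invisible(x)
}

#' Convert a tracked object to a full 3D voxel mask
#'
#' @param obj A `tracked_object`.
#' @param role Role tag for the resulting mask.
#' @return A [voxel_mask].
#' @export
as_mask <- function(obj, role = "SA-candidate") {
  stopifnot(inherits(obj, "tracked_object"))
  out <- array(FALSE, obj$dim)
  for (i in seq_along(obj$plane_index)) {
    out[obj$plane_index[i], , ] <- obj$planes[[i]]
  }
  voxel_mask(out, role = role, voxel_size_nm = obj$voxel_size_nm)
}

#' Manually refine a tracked object
#'
#' Applies user edits: the voxel set becomes
#' `(object UNION additions) MINUS removals`; removals win when a voxel is in
#' both. The edit is recorded in the object's provenance.
#'
#' @param obj A `tracked_object`.
#' @param additions,removals [voxel_mask] objects or logical 3D arrays
#'   (or `NULL` for no edit).
#' @return The refined `tracked_object`.
#' @export
refine_object <- function(obj, additions = NULL, removals = NULL) {
  stopifnot(inherits(obj, "tracked_object"))
  vox <- as_mask(obj)$mask
  n_add <- 0L
  n_rem <- 0L
  if (!is.null(additions)) {
    add <- as_mask_array(additions)
    if (!all(dim(add) == obj$dim)) {
      stop_spinescope("`additions` shape does not match the tracked volume.", "parameter")
    }
    n_add <- sum(add & !vox)
    vox <- vox | add
  }
  if (!is.null(removals)) {
    rem <- as_mask_array(removals)
    if (!all(dim(rem) == obj$dim)) {
      stop_spinescope("`removals` shape does not match the tracked volume.", "parameter")
    }
    n_rem <- sum(rem & vox)
    vox <- vox & !rem
  }
  if (!any(vox)) {
    stop_spinescope("Refinement removed every voxel of the object.", "refinement")
  }
  planes_used <- which(apply(vox, 1L, any))
  out <- obj
  out$planes <- lapply(planes_used, function(p) vox[p, , ])
  out$plane_index <- planes_used
  out$provenance$edits <- c(
    obj$provenance$edits,
    list(list(added = n_add, removed = n_rem))
  )
  out
}
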