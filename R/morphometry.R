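# Cistern morphometry and classification of the spine apparatus (SA):
# an SA is a stack of >= 2 closely apposed, parallel, flat ER cisterns
# inside a dendritic spine. Flatness/parallelism/apposition are quantified
# from principal-axis decomposition of each 3D connected component of the
# ER mask, with all distances in nm.

#' Segment ER cisterns and describe their shape
#'
#' Splits an ER mask into 3D connected components (26-neighbourhood) and
#' computes, per component, the eigenvalues of the voxel-coordinate scatter
#' in physical units (nm^2), a flatness score (smallest / middle
#' eigenvalue), and the unit normal (eigenvector of the smallest
#' eigenvalue). A component counts as a flat sheet when it is extended in
#' two directions (middle principal SD at least `min_planar_sd_nm`) and thin
#' in the third; rods and single voxels are never flat because their middle
#' eigenvalue is degenerate.
#'
#' @param er_mask A [voxel_mask] (role `"ER"`) or logical 3D array.
#' @param voxel_size_nm Voxel edge lengths `(z, y, x)` in nm; taken from the
#'   mask when it is a [voxel_mask].
#' @param min_planar_sd_nm Minimum middle principal standard deviation (nm)
#'   for a component to qualify as a sheet. Default: mean voxel edge.
#' @return A tibble with one row per component: `cistern_id`, `n_voxels`,
#'   `eig1`, `eig2`, `eig3` (nm^2, descending), `flatness`, `normal`
#'   (list-column of unit 3-vectors), `centroid_nm` (list-column), and
#'   `coords_nm` (list-column of voxel coordinates, used for gap and contact
#'   computations).
#' @export
segment_cisterns <- function(er_mask, voxel_size_nm = NULL,
                             min_planar_sd_nm = NULL) {
  m <- as_mask_array(er_mask)
  if (!any(m)) {
    stop_spinescope("ER mask is empty.", "parameter")
  }
  if (is.null(voxel_size_nm)) {
    voxel_size_nm <- if (inherits(er_mask, "voxel_mask")) {
      er_mask$voxel_size_nm
    } else {
      c(8, 8, 8)
    }
  }
  if (is.null(min_planar_sd_nm)) min_planar_sd_nm <- mean(voxel_size_nm)

  lab <- label_components3(m, connectivity = 26L)
  ids <- seq_len(max(lab))
  rows <- map(ids, function(i) {
    coords <- mask_coords_nm(lab == i, voxel_size_nm)
    n <- nrow(coords)
    if (n >= 2L) {
      ev <- eigen(cov(coords), symmetric = TRUE)
      vals <- pmax(ev$values, 0)
      normal <- ev$vectors[, 3L]
    } else {
      vals <- c(0, 0, 0)
      normal <- c(NA_real_, NA_real_, NA_real_)
    }
    planar <- sqrt(vals[2L]) >= min_planar_sd_nm
    flatness <- if (vals[2L] > 0) vals[3L] / vals[2L] else NA_real_
    tibble(
      cistern_id = i,
      n_voxels = n,
      eig1 = vals[1L], eig2 = vals[2L], eig3 = vals[3L],
      flatness = flatness,
      planar = planar,
      normal = list(normal),
      centroid_nm = list(colMeans(coords)),
      coords_nm = list(coords)
    )
  })
  out <- bind_rows(rows)
  attr(out, "voxel_size_nm") <- voxel_size_nm
  out
}

# angle (degrees, in [0, 90]) between two unit normals
normal_angle_deg <- function(a, b) {
  if (anyNA(a) || anyNA(b)) return(NA_real_)
  cosang <- min(1, abs(sum(a * b)))
  acos(cosang) * 180 / pi
}

# largest connected group under the pairwise qualification relation: in a
# stack of cisterns apposition holds between neighbours, not between the
# two ends, so a stack is a chain in the qualification graph
largest_qualifying_group <- function(adj) {
  n <- nrow(adj)
  unvisited <- rep(TRUE, n)
  best <- integer(0)
  for (v in seq_len(n)) {
    if (!unvisited[v]) next
    comp <- v
    frontier <- v
    unvisited[v] <- FALSE
    while (length(frontier) > 0L) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & unvisited)
      comp <- c(comp, nb)
      unvisited[nb] <- FALSE
      frontier <- nb
    }
    if (length(comp) > length(best)) best <- comp
  }
  best
}

#' Classify a set of cisterns as a spine apparatus
#'
#' Applies the SA definition: at least two flat cisterns that are pairwise
#' parallel (normal angle within `parallel_tol_deg`) and closely apposed
#' (surface-to-surface gap within `gap_max_nm`). `cistern_count` is the size
#' of the largest qualifying group of flat sheets — the largest connected
#' group under the pairwise (parallel AND apposed) relation, because in a
#' stack apposition holds between neighbouring cisterns, not between the two
#' ends. A single flat cistern yields `cistern_count = 1` but
#' `is_sa = FALSE`.
#'
#' The gap between two components is approximated as the minimum
#' centre-to-centre voxel distance minus one mean voxel edge (surface
#' correction), never below zero.
#'
#' @param cisterns Tibble from [segment_cisterns()].
#' @param gap_max_nm Maximum apposition gap in nm (default 80).
#' @param parallel_tol_deg Maximum angle between cistern normals in degrees
#'   (default 30).
#' @param flatness_max Maximum smallest/middle eigenvalue ratio for a flat
#'   sheet (default 0.33).
#' @return A one-row tibble: `is_sa`, `cistern_count`, `n_components`,
#'   `sa_cistern_ids` (list-column).
#' @export
classify_sa <- function(cisterns, gap_max_nm = 80, parallel_tol_deg = 30,
                        flatness_max = 0.33) {
  assert_number(gap_max_nm, "gap_max_nm", lower = 0)
  assert_number(parallel_tol_deg, "parallel_tol_deg", lower = 0, upper = 90)
  assert_number(flatness_max, "flatness_max", lower = 0)
  vsz <- attr(cisterns, "voxel_size_nm") %||% c(8, 8, 8)
  surface_corr <- mean(vsz)

  flat <- cisterns$planar & !is.na(cisterns$flatness) &
    cisterns$flatness <= flatness_max
  flat_idx <- which(flat)
  k <- length(flat_idx)
  if (k == 0L) {
    return(tibble(
      is_sa = FALSE, cistern_count = 0L,
      n_components = nrow(cisterns), sa_cistern_ids = list(integer(0))
    ))
  }
  if (k == 1L) {
    return(tibble(
      is_sa = FALSE, cistern_count = 1L,
      n_components = nrow(cisterns),
      sa_cistern_ids = list(cisterns$cistern_id[flat_idx])
    ))
  }
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- flat_idx[i]
      b <- flat_idx[j]
      ang <- normal_angle_deg(cisterns$normal[[a]], cisterns$normal[[b]])
      if (is.na(ang) || ang > parallel_tol_deg) next
      gap <- max(0, min_cross_dist(cisterns$coords_nm[[a]], cisterns$coords_nm[[b]]) - surface_corr)
      if (gap <= gap_max_nm) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  grp <- largest_qualifying_group(adj)
  count <- max(1L, length(grp))
  tibble(
    is_sa = count >= 2L,
    cistern_count = as.integer(count),
    n_components = nrow(cisterns),
    sa_cistern_ids = list(cisterns$cistern_id[flat_idx[grp]])
  )
}

#' Detect close membrane appositions (contact sites)
#'
#' Finds voxels of `other` whose Euclidean distance (in nm, respecting
#' anisotropic voxels) to the SA mask is at most `contact_dist_nm`.
#' Distances are centre-to-centre. Shrinking `contact_dist_nm` never adds
#' contacts.
#'
#' @param sa_mask,other [voxel_mask] objects or logical 3D arrays of equal
#'   shape.
#' @param contact_dist_nm Maximum contact distance in nm (default 30,
#'   conventional for ER-plasma membrane contact sites).
#' @param voxel_size_nm Voxel size, taken from `sa_mask` when available.
#' @return A tibble of contact voxels of `other` (`z`, `y`, `x` 1-based
#'   indices, `dist_nm`); zero rows means no contact. The logical attribute
#'   `"contact"` flags non-emptiness.
#' @export
detect_contacts <- function(sa_mask, other, contact_dist_nm = 30,
                            voxel_size_nm = NULL) {
  assert_number(contact_dist_nm, "contact_dist_nm", lower = 1e-9)
  a <- as_mask_array(sa_mask)
  b <- as_mask_array(other)
  if (!all(dim(a) == dim(b))) {
    stop_spinescope("Masks must have the same shape.", "parameter")
  }
  if (is.null(voxel_size_nm)) {
    voxel_size_nm <- if (inherits(sa_mask, "voxel_mask")) {
      sa_mask$voxel_size_nm
    } else {
      c(8, 8, 8)
    }
  }
  empty <- tibble(
    z = integer(0), y = integer(0), x = integer(0), dist_nm = numeric(0)
  )
  if (!any(a) || !any(b)) {
    attr(empty, "contact") <- FALSE
    return(empty)
  }
  # restrict candidates to the SA bounding box expanded by the contact reach
  sa_idx <- which(a, arr.ind = TRUE)
  pad <- ceiling(contact_dist_nm / voxel_size_nm)
  lo <- pmax(apply(sa_idx, 2L, min) - pad, 1L)
  hi <- pmin(apply(sa_idx, 2L, max) + pad, dim(a))
  cand <- which(b, arr.ind = TRUE)
  keep <- cand[, 1] >= lo[1] & cand[, 1] <= hi[1] &
    cand[, 2] >= lo[2] & cand[, 2] <= hi[2] &
    cand[, 3] >= lo[3] & cand[, 3] <= hi[3]
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    attr(empty, "contact") <- FALSE
    return(empty)
  }
  sa_nm <- sweep(sa_idx, 2L, voxel_size_nm, `*`)
  cand_nm <- sweep(cand, 2L, voxel_size_nm, `*`)
  sa2 <- rowSums(sa_nm^2)
  dmin <- numeric(nrow(cand))
  chunk <- 2000L
  for (start in seq(1L, nrow(cand), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(cand))
    cc <- cand_nm[idx, , drop = FALSE]
    d2 <- outer(sa2, rowSums(cc^2), `+`) - 2 * tcrossprod(sa_nm, cc)
    dmin[idx] <- sqrt(pmax(apply(d2, 2L, min), 0))
  }
  hit <- dmin <= contact_dist_nm
  out <- tibble(
    z = as.integer(cand[hit, 1]),
    y = as.integer(cand[hit, 2]),
    x = as.integer(cand[hit, 3]),
    dist_nm = dmin[hit]
  )
  attr(out, "contact") <- nrow(out) > 0L
  out
}

#' PSD-first spine census
#'
#' Summarises per-spine records under the bias-minimising protocol: spines
#' are identified by their postsynaptic density (PSD) first, and only
#' PSD-positive spines enter the denominator; the presence of ER and of the
#' spine apparatus is then tallied.
#'
#' @param spines Data frame with logical columns `has_psd`, `has_er`,
#'   `has_sa` (one row per spine), e.g. the ground-truth table of
#'   [generate_em_phantom()].
#' @param protocol Census protocol; only `"psd_first"` is implemented.
#' @return A one-row tibble: `n_spines`, `n_psd`, `frac_er`, `frac_sa`,
#'   `frac_sa_given_er` (all fractions over PSD-positive spines).
#' @export
spine_census <- function(spines, protocol = "psd_first") {
  protocol <- match.arg(protocol, "psd_first")
  need <- c("has_psd", "has_er", "has_sa")
  missing_cols <- setdiff(need, names(spines))
  if (length(missing_cols) > 0L) {
    stop_spinescope(
      sprintf("`spines` is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  if (any(spines$has_sa & !spines$has_er)) {
    stop_spinescope(
      "Invariant violated: a spine with an SA must also have ER.",
      "invariant"
    )
  }
  psd <- spines[spines$has_psd, , drop = FALSE]
  if (nrow(psd) == 0L) {
    stop_spinescope("No PSD-positive spines: census denominator is empty.", "census")
  }
  n_er <- sum(psd$has_er)
  tibble(
    n_spines = nrow(spines),
    n_psd = nrow(psd),
    frac_er = n_er / nrow(psd),
    frac_sa = sum(psd$has_sa) / nrow(psd),
    frac_sa_given_er = if (n_er > 0) sum(psd$has_sa) / n_er else NA_real_
  )
}
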