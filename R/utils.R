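# Internal helpers: validation, array morphology, Gaussian smoothing.
# Masks are plain logical arrays; all loops are shift-and-combine over whole
# arrays so volumes up to ~64^3 stay fast in pure R.

stop_spinescope <- function(message, class) {
  abort(message, class = c(paste0("spinescope_error_", class), "spinescope_error"))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_spinescope(
      sprintf("`%s` must be a single finite number in [%s, %s].", name, lower, upper),
      "parameter"
    )
  }
  invisible(x)
}

assert_fraction <- function(x, name) assert_number(x, name, 0, 1)

assert_count <- function(x, name, lower = 0) {
  assert_number(x, name, lower)
  if (x != round(x)) {
    stop_spinescope(sprintf("`%s` must be an integer.", name), "parameter")
  }
  invisible(as.integer(x))
}

# ---- shifts -----------------------------------------------------------------

# zero-filled shift of a 3D logical array by s = c(dz, dy, dx)
shift3 <- function(a, s) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- vector("list", 3L)
  for (k in 1:3) {
    if (s[k] >= 0) {
      keep <- d[k] - s[k]
      if (keep <= 0) return(out)
      idx_dst[[k]] <- seq_len(keep) + s[k]
      idx_src[[k]] <- seq_len(keep)
    } else {
      keep <- d[k] + s[k]
      if (keep <= 0) return(out)
      idx_dst[[k]] <- seq_len(keep)
      idx_src[[k]] <- seq_len(keep) - s[k]
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

shift2 <- function(a, s) {
  d <- dim(a)
  out <- matrix(FALSE, d[1], d[2])
  idx_src <- idx_dst <- vector("list", 2L)
  for (k in 1:2) {
    if (s[k] >= 0) {
      keep <- d[k] - s[k]
      if (keep <= 0) return(out)
      idx_dst[[k]] <- seq_len(keep) + s[k]
      idx_src[[k]] <- seq_len(keep)
    } else {
      keep <- d[k] + s[k]
      if (keep <= 0) return(out)
      idx_dst[[k]] <- seq_len(keep)
      idx_src[[k]] <- seq_len(keep) - s[k]
    }
  }
  out[idx_dst[[1]], idx_dst[[2]]] <- a[idx_src[[1]], idx_src[[2]]]
  out
}

neighbourhood3 <- function(connectivity = 26L) {
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1L, ]
  } else if (connectivity == 18L) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) <= 2L, ]
  } else if (connectivity != 26L) {
    stop_spinescope("3D connectivity must be 6, 18 or 26.", "parameter")
  }
  as.matrix(offs)
}

neighbourhood2 <- function(connectivity = 8L) {
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  if (connectivity == 4L) {
    offs <- offs[abs(offs$dr) + abs(offs$dc) == 1L, ]
  } else if (connectivity != 8L) {
    stop_spinescope("2D connectivity must be 4 or 8.", "parameter")
  }
  as.matrix(offs)
}

dilate3 <- function(a, connectivity = 26L) {
  offs <- neighbourhood3(connectivity)
  out <- a
  for (i in seq_len(nrow(offs))) out <- out | shift3(a, offs[i, ])
  out
}

dilate2 <- function(a, connectivity = 8L) {
  offs <- neighbourhood2(connectivity)
  out <- a
  for (i in seq_len(nrow(offs))) out <- out | shift2(a, offs[i, ])
  out
}

# geodesic flood fill: grow `seed` inside `mask` until stable
flood_fill3 <- function(mask, seed, connectivity = 26L) {
  sel <- seed & mask
  n_prev <- sum(sel)
  repeat {
    sel <- dilate3(sel, connectivity) & mask
    n_now <- sum(sel)
    if (n_now == n_prev) return(sel)
    n_prev <- n_now
  }
}

flood_fill2 <- function(mask, seed, connectivity = 8L) {
  sel <- seed & mask
  n_prev <- sum(sel)
  repeat {
    sel <- dilate2(sel, connectivity) & mask
    n_now <- sum(sel)
    if (n_now == n_prev) return(sel)
    n_prev <- n_now
  }
}

# label connected components; returns integer array (0 = background)
label_components3 <- function(mask, connectivity = 26L) {
  lab <- array(0L, dim(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    first <- which(remaining)[1L]
    seed <- array(FALSE, dim(mask))
    seed[first] <- TRUE
    comp <- flood_fill3(remaining, seed, connectivity)
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

label_components2 <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    first <- which(remaining)[1L]
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[first] <- TRUE
    comp <- flood_fill2(remaining, seed, connectivity)
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

# ---- Gaussian smoothing -----------------------------------------------------

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-(x^2) / (2 * sigma^2))
  k / sum(k)
}

# shift a numeric 3D array along one axis with edge replication
shift_replicate3 <- function(a, off, axis) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) - off, 1L), n)
  switch(axis,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE]
  )
}

blur_axis3 <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  out <- array(0, dim(a))
  for (i in seq_along(k)) {
    out <- out + k[i] * shift_replicate3(a, i - r - 1L, axis)
  }
  out
}

# separable Gaussian blur with edge replication; sigma scalar or length-3
gaussian_blur3 <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  for (axis in 1:3) a <- blur_axis3(a, sigma[axis], axis)
  a
}

# ---- geometry ---------------------------------------------------------------

# physical coordinates (nm) of TRUE voxels, rows = voxels, cols = (z, y, x)
mask_coords_nm <- function(mask, voxel_size_nm) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx, 2L, voxel_size_nm, `*`)
}

# minimum pairwise Euclidean distance between two coordinate sets (chunked)
min_cross_dist <- function(a, b, chunk = 2000L) {
  a2 <- rowSums(a^2)
  best <- Inf
  for (start in seq(1L, nrow(b), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(b))
    bb <- b[idx, , drop = FALSE]
    d2 <- outer(a2, rowSums(bb^2), `+`) - 2 * tcrossprod(a, bb)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

seq_range <- function(from, to) seq.int(from, to)
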