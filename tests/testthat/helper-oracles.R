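# Independent oracles used across the suite.

# Brute-force 3D 26-connected component containing a seed voxel, built on
# igraph over the explicit voxel adjacency graph (independent of the
# package's plane-propagation tracking path).
oracle_cc26 <- function(mask, seed_lin) {
  vox <- which(mask)
  d <- dim(mask)
  pos <- arrayInd(vox, d)
  id <- seq_along(vox)
  names(id) <- vox
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  # half-space of offsets: each undirected edge built once
  offs <- offs[offs[, 1] > 0 |
    (offs[, 1] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 3] > 0))), ]
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    np <- sweep(pos, 2, offs[i, ], `+`)
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] &
      np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    lin <- (np[ok, 3] - 1) * d[1] * d[2] + (np[ok, 2] - 1) * d[1] + np[ok, 1]
    hit <- lin %in% vox
    edges[[i]] <- cbind(id[as.character(vox[ok][hit])], id[as.character(lin[hit])])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  sort(vox[comp == comp[id[as.character(seed_lin)]]])
}

# Direct (non-separable) Gaussian-difference convolution with replicate
# padding, evaluated voxel by voxel on small volumes.
oracle_dog <- function(a, sigma_small, sigma_large) {
  d <- dim(a)
  kern3 <- function(sigma) {
    r <- max(1L, as.integer(ceiling(4 * sigma)))
    x <- (-r):r
    k1 <- exp(-(x^2) / (2 * sigma^2))
    k1 <- k1 / sum(k1)
    list(k = outer(outer(k1, k1), k1), r = r)
  }
  ks <- kern3(sigma_small)
  kl <- kern3(sigma_large)
  r <- max(ks$r, kl$r)
  # replicate-pad once at the larger radius
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  pad <- a[
    clampi(seq.int(1L - r, d[1] + r), d[1]),
    clampi(seq.int(1L - r, d[2] + r), d[2]),
    clampi(seq.int(1L - r, d[3] + r), d[3])
  ]
  embed_k <- function(kk, rr) {
    out <- array(0, c(2L * r + 1L, 2L * r + 1L, 2L * r + 1L))
    idx <- (r - rr + 1L):(r + rr + 1L)
    out[idx, idx, idx] <- kk
    out
  }
  kdiff <- embed_k(ks$k, ks$r) - embed_k(kl$k, kl$r)
  out <- array(0, d)
  for (z in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      for (x in seq_len(d[3])) {
        out[z, y, x] <- sum(pad[z:(z + 2L * r), y:(y + 2L * r), x:(x + 2L * r)] * kdiff)
      }
    }
  }
  out
}

# random blob mask from thresholded smoothed noise (for tracking tests)
random_blob_mask <- function(dims, fg_quantile = 0.72, smooth_sigma = 1.5) {
  noise <- array(rnorm(prod(dims)), dims)
  sm <- spinescope:::gaussian_blur3(noise, smooth_sigma)
  sm >= quantile(sm, fg_quantile)
}

single_voxel_seed <- function(dims, lin) {
  si <- arrayInd(lin, dims)
  region <- matrix(FALSE, dims[2], dims[3])
  region[si[2], si[3]] <- TRUE
  seed_selection(si[1], region)
}

expect_binomial_interval <- function(observed_count, n, p, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- qbinom(a, n, p)
  hi <- qbinom(1 - a, n, p)
  expect_gte(observed_count, lo)
  expect_lte(observed_count, hi)
}
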