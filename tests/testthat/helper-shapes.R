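# geometric fixtures, all generated in code

lin_idx <- function(zyx, shape) {
  as.integer(zyx[, 1] + shape[1] * (zyx[, 2] + shape[2] * zyx[, 3]) + 1)
}

grid_coords <- function(shape) {
  as.matrix(expand.grid(z = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                        x = 0:(shape[3] - 1)))
}

ball_coords <- function(center, r, shape) {
  g <- grid_coords(shape)
  g[sqrt(rowSums((g - rep(center, each = nrow(g)))^2)) <= r, , drop = FALSE]
}

shell_coords <- function(center, r_out, r_in, shape) {
  g <- grid_coords(shape)
  d <- sqrt(rowSums((g - rep(center, each = nrow(g)))^2))
  g[d <= r_out & d >= r_in, , drop = FALSE]
}

tube_coords <- function(p, q, r, shape) {
  g <- grid_coords(shape)
  v <- q - p
  rel <- g - rep(p, each = nrow(g))
  t <- pmin(pmax(c(rel %*% v) / sum(v^2), 0), 1)
  g[rowSums((rel - outer(t, v))^2) <= r^2, , drop = FALSE]
}

make_instance <- function(coords, shape, seed_ids = 1L,
                          voxel_size = c(1, 1, 1)) {
  structure(list(id = 1L, idx = mask_from_coords(coords, shape)$idx,
                 seed_ids = seed_ids, is_cluster = length(seed_ids) >= 2,
                 shape = as.integer(shape), voxel_size = voxel_size),
            class = "cell_instance")
}

make_seed_set <- function(centroids, radii, shape, surfaces = NULL,
                          voxel_size = c(1, 1, 1)) {
  centroids <- matrix(centroids, ncol = 3, byrow = FALSE)
  if (is.null(dim(centroids))) centroids <- matrix(centroids, 1)
  instances <- lapply(seq_len(nrow(centroids)), function(i)
    list(id = i, voxels = integer(0),
         surface = if (is.null(surfaces)) integer(0) else
           as.integer(surfaces[[i]]),
         centroid = centroids[i, ], radius = radii[i], voxel_count = 1L))
  structure(list(instances = instances, shape = as.integer(shape),
                 voxel_size = voxel_size), class = "seed_set")
}

# random mask as a set of indices (possibly disconnected)
random_mask_idx <- function(seed, shape, n) {
  set.seed(seed)
  sort(sample(prod(shape), n))
}

# random connected blobby mask: union of gaussian blobs, thresholded,
# largest 26-component kept (via the R flood-fill oracle)
random_connected_mask <- function(seed, shape = c(24, 24, 24),
                                  fg_target = 0.06) {
  set.seed(seed)
  g <- grid_coords(shape)
  field <- numeric(nrow(g))
  k <- 6
  centers <- matrix(runif(3 * k, 2, rep(shape - 3, each = k)), k, 3)
  sig <- runif(k, 2, 5)
  for (i in seq_len(k))
    field <- field + exp(-rowSums((g - rep(centers[i, ],
                                           each = nrow(g)))^2) /
                           (2 * sig[i]^2))
  thr <- stats::quantile(field, 1 - fg_target)
  idx <- lin_idx(g[field > thr, , drop = FALSE], shape)
  lab <- flood_components(idx, shape, 26)
  big <- which.max(tabulate(lab))
  sparse_mask(idx[lab == big], shape)
}
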