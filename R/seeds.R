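#' Equivalent-sphere radius of a voxel region
#'
#' Radius of the sphere whose volume equals `voxel_count` times the volume
#' of one voxel.
#'
#' @param voxel_count number of voxels (>= 1).
#' @param voxel_size µm per voxel (z, y, x).
#' @return Radius in µm.
#' @export
seed_radius <- function(voxel_count, voxel_size = c(1, 1, 1)) {
  if (any(voxel_count < 1)) stop("voxel_count must be >= 1")
  (3 * voxel_count * prod(voxel_size) / (4 * pi))^(1 / 3)
}

new_seed_set <- function(instances, shape, voxel_size) {
  structure(list(instances = instances, shape = shape,
                 voxel_size = voxel_size), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed_set: %d instance(s)\n", length(x$instances)))
  for (s in x$instances)
    cat(sprintf("  #%d centroid (%.1f, %.1f, %.1f) um, r %.2f um, %d voxels\n",
                s$id, s$centroid[1], s$centroid[2], s$centroid[3],
                s$radius, s$voxel_count))
  invisible(x)
}

#' Detect and instance-label somas on a foreground mask
#'
#' Soma (seed) segmentation for surface-labeled signal: the foreground mask
#' is reduced to its surface shell, closed with a ball of `close_radius`
#' voxels (fills hollow cell bodies), opened with `open_radius` (removes
#' thin branches), and split into 26-connected instances.  Components
#' smaller than `min_voxels` are dropped; the default cutoff is the voxel
#' count of a ball of radius `open_radius`, since nothing smaller can be a
#' genuine survivor of the opening.  Pass `min_voxels = 0` to keep every
#' component (reproducing high-recall / low-precision seed output that is
#' filtered downstream).
#'
#' Each instance records its filled voxel region, the µm centroid, the
#' equivalent-sphere radius, and the subset of original mask voxels inside
#' the region, which later seeds the reachability sweep at distance zero.
#'
#' @param mask a `sparse_mask` (the thresholded foreground).
#' @param close_radius,open_radius ball radii in voxels (>= 1).  Defaults
#'   suit somas of roughly 5-7 µm radius with ~2-voxel shells and branches
#'   up to ~2 µm radius at micrometer sampling: closing must bridge the
#'   shell cavity, opening must erase the widest branch.
#' @param min_voxels minimum instance size; `NULL` for the default cutoff.
#' @return A `seed_set`; empty mask gives an empty seed set.
#' @export
segment_seeds <- function(mask, close_radius = 5, open_radius = 4,
                          min_voxels = NULL) {
  close_radius <- morph_radius_check(close_radius)
  open_radius <- morph_radius_check(open_radius)
  if (close_radius < 1L || open_radius < 1L)
    stop("close_radius and open_radius must be >= 1")
  min_voxels <- min_voxels %||% nrow(ball_offsets(open_radius))
  if (!length(mask$idx))
    return(new_seed_set(list(), mask$shape, mask$voxel_size))
  surf <- extract_surface(mask)
  closed <- mask_close(surf, close_radius)
  opened <- mask_open(closed, open_radius)
  cc <- connected_components(opened, 26)
  instances <- list()
  vs <- mask$voxel_size
  id <- 0L
  for (lab in seq_len(cc$n_labels)) {
    region <- cc$idx[cc$label == lab]
    if (length(region) < min_voxels) next
    id <- id + 1L
    zyx <- idx_to_zyx(region, mask$shape)
    centroid <- colMeans(zyx) * vs
    surface_idx <- intersect(region, mask$idx)
    if (!length(surface_idx))
      surface_idx <- mask_surface_cpp(region, mask$shape)
    instances[[id]] <- list(
      id = id, voxels = region, surface = as.integer(surface_idx),
      centroid = unname(centroid),
      radius = seed_radius(length(region), vs),
      voxel_count = length(region))
  }
  new_seed_set(instances, mask$shape, vs)
}

#' Seed set as a data frame / CSV
#'
#' Columns: `id, z_um, y_um, x_um, radius_um, voxel_count` (centroids in µm,
#' 0-based voxel-center convention).
#'
#' @param x a `seed_set`.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.seed_set <- function(x, ...) {
  if (!length(x$instances))
    return(data.frame(id = integer(0), z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), radius_um = numeric(0),
                      voxel_count = integer(0)))
  do.call(rbind, lapply(x$instances, function(s)
    data.frame(id = s$id, z_um = s$centroid[1], y_um = s$centroid[2],
               x_um = s$centroid[3], radius_um = s$radius,
               voxel_count = s$voxel_count)))
}

#' @rdname as.data.frame.seed_set
#' @param seeds a `seed_set` or compatible data frame.
#' @param path CSV file path.
#' @export
write_seeds_csv <- function(seeds, path) {
  df <- if (inherits(seeds, "seed_set")) as.data.frame(seeds) else seeds
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname as.data.frame.seed_set
#' @export
read_seeds_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "z_um", "y_um", "x_um", "radius_um", "voxel_count")
  if (!all(need %in% names(df)))
    stop("seed CSV must have columns: ", paste(need, collapse = ", "))
  df
}
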