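#' Seeded reachability by eikonal fast sweeping
#'
#' Solves `|grad u| = 1` on the active voxels of the mask with `u = 0` on
#' the seed surface voxels, i.e. geodesic arrival distance (µm) from the
#' soma surfaces through the foreground.  First-order upwind updates (with
#' per-axis physical spacing) are applied in the 8 axis-ordering
#' Gauss-Seidel sweeps until the largest update falls below `tolerance`;
#' a 26-neighbor graph relaxation is folded into the local update so that
#' single-voxel-wide diagonal paths stay reachable and arrival values never
#' exceed the 26-neighbor Dijkstra distance.  Voxels in components that
#' contain no seed are never updated and are reported as unreached.
#'
#' @param mask a `sparse_mask` (the foreground `W_s`).
#' @param seeds a `seed_set` from [segment_seeds()]; seed surface voxels not
#'   present in the mask are dropped with a warning.
#' @param tolerance convergence tolerance in µm (> 0).
#' @param max_rounds cap on 8-sweep rounds.
#' @return A `reach_field`: sorted `idx` of reached voxels, parallel `dist`
#'   values (µm, 0 exactly on seed voxels), plus `shape`, `voxel_size`,
#'   `seed_ids` and `n_mask` (active count of the swept mask).
#' @export
fastsweep <- function(mask, seeds, tolerance = 1e-3, max_rounds = 100) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (!length(seeds$instances)) {
    warning("empty seed set: nothing is reachable")
    return(structure(list(idx = integer(0), dist = numeric(0),
                          shape = mask$shape, voxel_size = mask$voxel_size,
                          seed_ids = integer(0), n_mask = length(mask$idx)),
                     class = "reach_field"))
  }
  if (!identical(as.integer(mask$shape),
                 as.integer(seeds$shape)))
    stop("mask and seeds have different domain shapes")
  seed_idx <- unlist(lapply(seeds$instances, `[[`, "surface"))
  inmask <- seed_idx %in% mask$idx
  if (any(!inmask)) {
    warning(sum(!inmask), " seed surface voxel(s) outside the mask; dropped")
    seed_idx <- seed_idx[inmask]
  }
  if (!length(mask$idx) || !length(seed_idx))
    return(structure(list(idx = integer(0), dist = numeric(0),
                          shape = mask$shape, voxel_size = mask$voxel_size,
                          seed_ids = integer(0), n_mask = length(mask$idx)),
                     class = "reach_field"))
  d <- fastsweep_cpp(mask$idx, as.integer(seed_idx), mask$shape,
                     mask$voxel_size, tolerance, as.integer(max_rounds))
  keep <- is.finite(d)
  structure(list(idx = mask$idx[keep], dist = d[keep], shape = mask$shape,
                 voxel_size = mask$voxel_size,
                 seed_ids = vapply(seeds$instances, `[[`, integer(1), "id"),
                 n_mask = length(mask$idx)),
            class = "reach_field")
}

#' Drop voxels not reached from any seed
#'
#' A linear scan keeping exactly the voxels with a finite arrival value;
#' the result is the causally sparse working set `W_c`.
#'
#' @param mask the `sparse_mask` the field was computed on.
#' @param field a `reach_field` from [fastsweep()].
#' @return A `sparse_mask` that is a subset of `mask`.
#' @export
prune_unreached <- function(mask, field) {
  if (!identical(as.integer(mask$shape), as.integer(field$shape)))
    stop("field was not computed on this mask's domain")
  sparse_mask(field$idx, mask$shape, mask$voxel_size)
}

#' Split the reachable set into cell instances
#'
#' 26-connected components of the reached mask, annotated with the seed
#' instances whose surface voxels they contain.  By construction every
#' component contains at least one seed (anything else would have been
#' pruned as unreached); a component with none raises an internal error.
#' Components containing two or more seeds are flagged as clusters
#' (colliding / touching neurons).
#'
#' @param reached a `sparse_mask` from [prune_unreached()].
#' @param seeds the `seed_set` used for sweeping.
#' @return A list of `cell_instance` objects: `id`, `idx` (voxels),
#'   `seed_ids`, `is_cluster`, `shape`, `voxel_size`.
#' @export
split_cells <- function(reached, seeds) {
  cc <- connected_components(reached, 26)
  cells <- vector("list", cc$n_labels)
  for (lab in seq_len(cc$n_labels)) {
    region <- cc$idx[cc$label == lab]
    sid <- vapply(seeds$instances, function(s)
      if (any(s$surface %in% region)) s$id else NA_integer_, integer(1))
    sid <- sid[!is.na(sid)]
    if (!length(sid))
      stop("internal invariant violated: reachable component ", lab,
           " contains no seed")
    cells[[lab]] <- structure(
      list(id = lab, idx = region, seed_ids = sid,
           is_cluster = length(sid) >= 2L,
           shape = reached$shape, voxel_size = reached$voxel_size),
      class = "cell_instance")
  }
  cells
}

#' Optionally close branch gaps before sweeping
#'
#' Morphological closing of the foreground mitigates path breaks in thin
#' branches at the cost of possible path collisions between nearby
#' branches.  Radius 0 is a no-op.
#'
#' @param mask a `sparse_mask`.
#' @param radius ball radius in voxels (>= 0).
#' @return A `sparse_mask`.
#' @export
close_branches <- function(mask, radius) {
  radius <- morph_radius_check(radius)
  if (radius == 0L) return(mask)
  mask_close(mask, radius)
}
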