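#' Synthetic neuron phantom specification
#'
#' Parameters of the synthetic-data generator.  Phantoms emulate the signal
#' properties of surface-labeled lightsheet data: somas drawn as spherical
#' *shells* (label only on the cell surface, interior dark), thin solid
#' tubular branches, multiplicative vertical stripe shadows, a smooth
#' multiplicative bleaching field, anisotropic axial blur (axial sigma
#' 2.5x lateral by default) and additive Gaussian (optionally Poisson)
#' noise.  Every draw is fully reproducible from `seed`.
#'
#' @param shape volume extents (nz, ny, nx) in voxels.
#' @param voxel_size µm per voxel (z, y, x).
#' @param n_neurons number of neurons.
#' @param soma_radius soma radius range (µm).
#' @param shell_thickness soma shell thickness (voxels).
#' @param branch_radius branch tube radius range (µm).
#' @param depth maximum branching depth (generations of splits).
#' @param branch_prob probability that a segment end splits into two.
#' @param segment_length per-segment length range (µm).
#' @param node_spacing spacing of ground-truth nodes along segments (µm).
#' @param stripe_amplitude relative amplitude of the sinusoidal stripe
#'   modulation (0 disables).
#' @param stripe_period stripe period in voxels along x (37 by default:
#'   deliberately non-commensurate with dyadic wavelet scales).
#' @param bleach_range multiplicative bleach field range, dimmest to 1.
#' @param psf a [psf_model()], or `NULL` for no blur.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param poisson also apply Poisson resampling of intensities.
#' @param fg_intensity,bg_intensity foreground / background levels (8-bit
#'   scale).
#' @param seed RNG seed; all outputs are deterministic functions of it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(256, 256, 256), voxel_size = c(1, 1, 1),
                         n_neurons = 3, soma_radius = c(5, 7),
                         shell_thickness = 2, branch_radius = c(1, 2),
                         depth = 3, branch_prob = 0.6,
                         segment_length = c(25, 45), node_spacing = 4,
                         stripe_amplitude = 0.3, stripe_period = 37,
                         bleach_range = c(0.3, 1), psf = psf_model(1, 2.5),
                         noise_sigma = 4, poisson = FALSE,
                         fg_intensity = 200, bg_intensity = 10, seed = 1) {
  spec <- list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
               n_neurons = as.integer(n_neurons), soma_radius = soma_radius,
               shell_thickness = shell_thickness,
               branch_radius = branch_radius, depth = as.integer(depth),
               branch_prob = branch_prob, segment_length = segment_length,
               node_spacing = node_spacing,
               stripe_amplitude = stripe_amplitude,
               stripe_period = stripe_period, bleach_range = bleach_range,
               psf = psf, noise_sigma = noise_sigma, poisson = isTRUE(poisson),
               fg_intensity = fg_intensity, bg_intensity = bg_intensity,
               seed = as.integer(seed))
  if (any(spec$shape < 1) || any(spec$voxel_size <= 0))
    stop("bad shape or voxel size")
  if (any(soma_radius <= 0) || any(branch_radius <= 0) ||
      any(segment_length <= 0) || node_spacing <= 0)
    stop("all geometric ranges must be positive")
  if (min(spec$shape * spec$voxel_size) < 4 * max(soma_radius))
    stop("volume too small to contain the requested somas")
  structure(spec, class = "phantom_spec")
}

tree_rng_seed <- function(spec, neuron_index)
  ((spec$seed %% 1000000L) * 1009L + neuron_index * 7919L) %% 2147483647L

# deterministic low-discrepancy soma center, µm (z, y, x)
soma_center <- function(spec, i) {
  ext <- spec$shape * spec$voxel_size
  margin <- pmin(0.22 * ext, max(spec$soma_radius) + 0.15 * ext)
  u <- (i * c(0.5545497, 0.3085170, 0.1141610)) %% 1
  margin + u * (ext - 2 * margin)
}

norm3 <- function(v) v / sqrt(sum(v^2))

#' Generate a ground-truth skeleton tree
#'
#' Random recursive branching from a soma root: the root emits two primary
#' segments (one when `branch_prob` is 0); each segment is a gently
#' wandering run of nodes spaced `node_spacing` µm with length drawn from
#' `segment_length`; segment ends split into two children with probability
#' `branch_prob` until `depth` generations.  Branch radii are drawn from
#' `branch_radius` and never increase downstream.  Growth is clipped to
#' stay inside the volume; a degenerate draw is retried up to 50 times.
#' Fully reproducible from `(seed, neuron_index)`.
#'
#' @param spec a [phantom_spec()].
#' @param neuron_index which neuron (1-based).
#' @return A standardized `skeleton_tree` with attributes `soma_radius`
#'   (µm) and `center` (µm, z/y/x).
#' @export
generate_tree <- function(spec, neuron_index = 1) {
  with_seed(tree_rng_seed(spec, neuron_index), {
    ext <- spec$shape * spec$voxel_size
    lo <- pmax(2, 0.02 * ext)
    hi <- ext - lo
    center <- soma_center(spec, neuron_index)
    for (attempt in 1:50) {
      soma_r <- runif(1, spec$soma_radius[1], spec$soma_radius[2])
      nodes <- data.frame(id = 1L, type = 1L,
                          x = center[3], y = center[2], z = center[1],
                          radius = soma_r, parent = -1L)
      nid <- 1L
      add_node <- function(pos, radius, parent) {
        nid <<- nid + 1L
        nodes[nid, ] <<- list(nid, 3L, pos[3], pos[2], pos[1], radius, parent)
        nid
      }
      grow_segment <- function(start_pos, dir, level, parent_id, radius) {
        len <- runif(1, spec$segment_length[1], spec$segment_length[2])
        steps <- max(2L, round(len / spec$node_spacing))
        pos <- start_pos
        last <- parent_id
        for (s in seq_len(steps)) {
          dir <- norm3(dir + 0.12 * rnorm(3))
          nxt <- pos + spec$node_spacing * c(dir[1], dir[2], dir[3])
          if (any(nxt < lo) || any(nxt > hi)) {
            dir <- norm3(dir - 1.5 * dir * (nxt < lo | nxt > hi))
            nxt <- pos + spec$node_spacing * dir
            if (any(nxt < lo) || any(nxt > hi)) break
          }
          pos <- nxt
          last <- add_node(pos, radius, last)
        }
        if (last == parent_id) return(invisible(NULL))  # nothing grew
        if (level < spec$depth && runif(1) < spec$branch_prob) {
          for (b in 1:2) {
            cdir <- norm3(dir + 0.9 * rnorm(3))
            crad <- min(radius, runif(1, spec$branch_radius[1],
                                      spec$branch_radius[2]))
            grow_segment(pos, cdir, level + 1L, last, crad)
          }
        }
        invisible(NULL)
      }
      n_primary <- if (spec$branch_prob > 0) 2L else 1L
      d0 <- norm3(rnorm(3))
      for (p in seq_len(n_primary)) {
        dir <- if (p == 1L) d0 else norm3(-d0 + 0.6 * rnorm(3))
        rad <- runif(1, spec$branch_radius[1], spec$branch_radius[2])
        # neurites emerge from the soma surface, not the center
        grow_segment(center + soma_r * dir, dir, 1L, 1L, rad)
      }
      if (nrow(nodes) >= 3L) {
        tree <- standardize(as_skeleton_tree(nodes),
                            min_radius = min(spec$voxel_size) / 2)
        attr(tree, "soma_radius") <- soma_r
        attr(tree, "center") <- center
        return(tree)
      }
    }
    stop("failed to grow neuron ", neuron_index, " within the volume bounds")
  })
}

# draw a solid tube (capsule) between two µm points into a dense array
add_capsule <- function(data, shape, voxel_size, p, q, r_um, value) {
  lo <- pmax(floor(pmin(p, q) / voxel_size - r_um / min(voxel_size) - 1), 0)
  hi <- pmin(ceiling(pmax(p, q) / voxel_size + r_um / min(voxel_size) + 1),
             shape - 1)
  if (any(hi < lo)) return(data)
  g <- as.matrix(expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2],
                             x = lo[3]:hi[3]))
  pts <- g * rep(voxel_size, each = nrow(g))
  v <- q - p
  vv <- sum(v^2)
  rel <- pts - rep(p, each = nrow(g))
  t <- if (vv > 0) pmin(pmax(c(rel %*% v) / vv, 0), 1) else 0
  d2 <- rowSums((rel - outer(t, v))^2)
  sel <- d2 <= r_um^2
  if (any(sel)) data[zyx_to_idx(g[sel, , drop = FALSE], shape)] <- value
  data
}

add_shell <- function(data, shape, voxel_size, center, r_um, thick_um, value) {
  lo <- pmax(floor((center - r_um) / voxel_size) - 1, 0)
  hi <- pmin(ceiling((center + r_um) / voxel_size) + 1, shape - 1)
  g <- as.matrix(expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2],
                             x = lo[3]:hi[3]))
  pts <- g * rep(voxel_size, each = nrow(g))
  d <- sqrt(rowSums((pts - rep(center, each = nrow(g)))^2))
  sel <- d <= r_um & d > r_um - thick_um
  if (any(sel)) data[zyx_to_idx(g[sel, , drop = FALSE], shape)] <- value
  data
}

#' Rasterize ground-truth trees into a clean volume
#'
#' Somas are rendered as spherical shells (surface labeling: interior stays
#' at background), branches as solid tubes with the node radius.  In any
#' tree with branches, the tubes emanate from the root, so every
#' ground-truth node position lands on foreground.
#'
#' @param trees list of `skeleton_tree`s from [generate_tree()].
#' @param spec the [phantom_spec()].
#' @return A clean [dense_volume()] at `bg_intensity` / `fg_intensity`.
#' @export
rasterize <- function(trees, spec) {
  shape <- spec$shape
  vs <- spec$voxel_size
  data <- array(spec$bg_intensity, shape)
  thick_um <- spec$shell_thickness * min(vs)
  for (tree in trees) {
    pr <- tree_parent_row(tree)
    for (v in seq_len(nrow(tree))) {
      p <- pr[v]
      if (is.na(p)) next
      data <- add_capsule(data, shape, vs,
                          c(tree$z[p], tree$y[p], tree$x[p]),
                          c(tree$z[v], tree$y[v], tree$x[v]),
                          tree$radius[v], spec$fg_intensity)
    }
    root <- which(tree$parent == -1L)
    soma_r <- attr(tree, "soma_radius") %||% tree$radius[root]
    data <- add_shell(data, shape, vs,
                      c(tree$z[root], tree$y[root], tree$x[root]),
                      soma_r, thick_um, spec$fg_intensity)
  }
  dense_volume(data, vs)
}

#' Foreground fraction of a clean phantom volume
#' @param clean the clean volume from [rasterize()].
#' @param spec the [phantom_spec()].
#' @return Fraction of voxels at foreground intensity.
#' @export
phantom_fg_fraction <- function(clean, spec)
  mean(clean$data > (spec$fg_intensity + spec$bg_intensity) / 2)

#' Corrupt a clean phantom into a raw-like volume
#'
#' Applies, in order: multiplicative sinusoidal stripes along x (constant
#' along y within each stripe line), a smooth multiplicative bleach field
#' (linear ramp across x times a broad Gaussian in y), convolution with
#' the PSF, additive Gaussian noise and optional Poisson resampling, and
#' clamping to the 8-bit range.  Deterministic given `spec$seed`.
#'
#' @param clean a clean [dense_volume()] from [rasterize()].
#' @param spec the [phantom_spec()].
#' @return A raw-like [dense_volume()].
#' @export
corrupt <- function(clean, spec) {
  d <- dim(clean$data)
  out <- clean$data
  if (spec$stripe_amplitude > 0) {
    mx <- 1 + spec$stripe_amplitude *
      sin(2 * pi * (0:(d[3] - 1)) / spec$stripe_period)
    out <- out * rep(mx, each = d[1] * d[2])
  }
  if (spec$bleach_range[1] < spec$bleach_range[2]) {
    ramp <- seq(1, spec$bleach_range[1] / spec$bleach_range[2],
                length.out = d[3])
    gy <- exp(-((0:(d[2] - 1)) - (d[2] - 1) / 2)^2 / (2 * d[2]^2))
    field <- outer(gy / max(gy), ramp)           # (y, x)
    field <- field / max(field) * spec$bleach_range[2]
    out <- out * rep(field, each = d[1])         # broadcast over z
  }
  if (!is.null(spec$psf)) {
    psf <- make_psf(spec$psf, clean$voxel_size)
    out <- psf_convolve(out, psf)
  }
  with_seed(spec$seed + 104729L, {
    if (spec$noise_sigma > 0)
      out <- out + rnorm(length(out), 0, spec$noise_sigma)
    if (spec$poisson)
      out <- array(rpois(length(out), pmax(out, 0)), d)
  })
  dense_volume(array(pmin(pmax(out, 0), 255), d), clean$voxel_size)
}

#' Generate a complete phantom dataset
#'
#' Ground-truth trees, the clean and corrupted volumes, and the gold seed
#' list; optionally written to disk as a 32-bit TIFF stack, `gold/*.swc`,
#' `seeds.csv` and `spec.json` (all parameters echoed).
#'
#' @param spec a [phantom_spec()].
#' @param out_dir optional output directory.
#' @return List with `trees`, `clean`, `raw`, `gold_seeds` (data frame),
#'   `fg_fraction` and `spec`.
#' @export
generate_phantom <- function(spec, out_dir = NULL) {
  trees <- lapply(seq_len(spec$n_neurons), function(i) generate_tree(spec, i))
  clean <- rasterize(trees, spec)
  raw <- corrupt(clean, spec)
  gold_seeds <- do.call(rbind, lapply(trees, function(t) {
    root <- which(t$parent == -1L)
    data.frame(z_um = t$z[root], y_um = t$y[root], x_um = t$x[root],
               radius_um = attr(t, "soma_radius") %||% t$radius[root])
  }))
  gold_seeds <- cbind(id = seq_len(nrow(gold_seeds)), gold_seeds)
  out <- list(trees = trees, clean = clean, raw = raw,
              gold_seeds = gold_seeds,
              fg_fraction = phantom_fg_fraction(clean, spec), spec = spec)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "gold"), recursive = TRUE,
               showWarnings = FALSE)
    write_tiff_volume(raw, file.path(out_dir, "raw.tif"), bits = 32)
    for (i in seq_along(trees))
      write_swc(trees[[i]], file.path(out_dir, "gold",
                                      sprintf("neuron%03d.swc", i)))
    gs <- gold_seeds
    gs$voxel_count <- NA_integer_
    utils::write.csv(gs, file.path(out_dir, "seeds.csv"), row.names = FALSE,
                     quote = FALSE)
    sp <- spec
    sp$psf <- if (!is.null(sp$psf)) unclass(sp$psf)
    jsonlite::write_json(unclass(sp), file.path(out_dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
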