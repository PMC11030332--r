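#' Pipeline configuration
#'
#' Bundles every stage toggle and parameter of the end-to-end run:
#' enhancement (destripe, debleach, deconvolve), optional z-downsampling,
#' conversion to a sparse mask at a target foreground percentage, seed
#' segmentation, reachability-based cell segmentation, skeletonization and
#' an optional benchmark against gold SWC trees.
#'
#' @param input a [dense_volume()], or a path to a TIFF stack / slice
#'   directory.
#' @param out_dir output directory for stage artifacts and manifests.
#' @param voxel_size µm per voxel (z, y, x); used when `input` is a path.
#' @param destripe,debleach,deconvolve stage toggles.
#' @param destripe_params a [destripe_params()].
#' @param lowpass_sigma debleach low-pass sigma (µm), `NULL` for default.
#' @param psf a [psf_model()] for deconvolution.
#' @param rl_iterations Richardson-Lucy iterations.
#' @param z_factor z block-averaging factor applied after deconvolution
#'   (1 = off); 3 suits the ~2.5x axial blur regime.
#' @param fg_percent target foreground fraction for thresholding.
#' @param close_radius,open_radius,min_voxels seed segmentation parameters
#'   (see [segment_seeds()]).
#' @param branch_close_radius closing radius applied to the mask before
#'   sweeping (0 = off); mitigates path breaks at the cost of path
#'   collisions.  At micrometer sampling radius 1 bridges single-voxel
#'   breaks without fusing neurons whose branches pass within a few µm;
#'   raise it only for heavily broken masks.
#' @param tolerance fast-sweeping convergence tolerance (µm).
#' @param coarsen_steps,max_ball,min_radius skeletonization parameters.
#' @param bench_gold optional directory containing gold `*.swc` (and
#'   optionally `seeds.csv`) to score against.
#' @param match a [match_params()].
#' @param resume skip stages whose manifest matches the configured
#'   parameters and inputs.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input, out_dir, voxel_size = c(1, 1, 1),
                            destripe = TRUE,
                            destripe_params = somatrace::destripe_params(),
                            debleach = TRUE, lowpass_sigma = NULL,
                            deconvolve = TRUE, psf = psf_model(1, 2.5),
                            rl_iterations = 10, z_factor = 1,
                            fg_percent = 0.008, close_radius = 5,
                            open_radius = 4, min_voxels = NULL,
                            branch_close_radius = 1, tolerance = 1e-3,
                            coarsen_steps = 2, max_ball = 4000,
                            min_radius = NULL, bench_gold = NULL,
                            match = match_params(), resume = FALSE) {
  structure(list(input = input, out_dir = out_dir,
                 voxel_size = as.numeric(voxel_size),
                 destripe = isTRUE(destripe),
                 destripe_params = destripe_params,
                 debleach = isTRUE(debleach), lowpass_sigma = lowpass_sigma,
                 deconvolve = isTRUE(deconvolve), psf = psf,
                 rl_iterations = rl_iterations, z_factor = z_factor,
                 fg_percent = fg_percent, close_radius = close_radius,
                 open_radius = open_radius, min_voxels = min_voxels,
                 branch_close_radius = branch_close_radius,
                 tolerance = tolerance, coarsen_steps = coarsen_steps,
                 max_ball = max_ball, min_radius = min_radius,
                 bench_gold = bench_gold, match = match,
                 resume = isTRUE(resume)),
            class = "pipeline_config")
}

config_fingerprint <- function(config, stage, extra = NULL) {
  drop <- c("input", "out_dir", "resume", "bench_gold")
  cf <- unclass(config)[setdiff(names(config), drop)]
  cf$psf <- if (!is.null(cf$psf)) unclass(cf$psf)
  cf$destripe_params <- unclass(cf$destripe_params)
  cf$match <- unclass(cf$match)
  jsonlite::toJSON(list(stage = stage, config = cf, extra = extra),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

write_manifest <- function(dir, stage, fingerprint, inputs, outputs, info) {
  man <- list(stage = stage, fingerprint = as.character(fingerprint),
              input_md5 = as.list(inputs), outputs = as.list(outputs),
              info = info)
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", stage,
                                                  ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

manifest_matches <- function(dir, stage, fingerprint, inputs) {
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  if (!file.exists(path)) return(FALSE)
  man <- tryCatch(jsonlite::read_json(path), error = function(e) NULL)
  if (is.null(man)) return(FALSE)
  if (!identical(man$fingerprint, as.character(fingerprint))) return(FALSE)
  if (!identical(lapply(man$input_md5, as.character),
                 lapply(as.list(inputs), as.character))) return(FALSE)
  all(file.exists(file.path(dir, unlist(man$outputs))))
}

file_md5 <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.character(h), basename(paths))
}

#' Run the full reconstruction pipeline
#'
#' Stage order: enhance (destripe, debleach, deconvolve), optional
#' z-downsample, threshold + sparse conversion, seed segmentation, branch
#' closing + fast sweeping + pruning + instance split, skeletonization,
#' and (if `bench_gold` is set) TreeBench scoring.  Each stage writes its
#' artifact plus a JSON manifest holding the parameter fingerprint, input
#' hashes and element counts; with `resume = TRUE`, stages whose manifest
#' matches are reloaded instead of recomputed.  The run itself uses no
#' randomness, so identical inputs and configuration give byte-identical
#' SWC outputs.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_result` list: `out_dir`, `threshold`, working-set
#'   counts (`n_W`, `n_Ws`, `n_Wc`), `seeds`, `cells` summary, `swc_paths`
#'   and (when benchmarked) `scores`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$out_dir

  vol <- if (inherits(config$input, "dense_volume")) config$input
         else read_tiff_volume(config$input, config$voxel_size)
  n_W <- prod(dim(vol$data))

  # -- enhance ---------------------------------------------------------------
  enh_path <- file.path(out, "enhanced.tif")
  fp <- config_fingerprint(config, "enhance", extra = dim(vol$data))
  if (config$resume && manifest_matches(out, "enhance", fp, character(0))) {
    enh <- read_tiff_volume(enh_path, vol$voxel_size)
    if (config$z_factor > 1)
      enh$voxel_size <- vol$voxel_size * c(config$z_factor, 1, 1)
  } else {
    enh <- vol
    if (config$destripe) enh <- destripe_volume(enh, config$destripe_params)
    if (config$debleach) enh <- debleach(enh, config$lowpass_sigma)
    if (config$deconvolve && !is.null(config$psf)) {
      psf <- make_psf(config$psf, enh$voxel_size)
      enh <- deconvolve(enh, psf, config$rl_iterations)
    }
    if (config$z_factor > 1) enh <- z_downsample(enh, config$z_factor)
    write_tiff_volume(enh, enh_path, bits = 32)
    write_manifest(out, "enhance", fp, character(0), "enhanced.tif",
                   list(shape = dim(enh$data)))
  }

  # -- convert ---------------------------------------------------------------
  mask_path <- file.path(out, "mask.smk")
  fp <- config_fingerprint(config, "convert")
  ins <- file_md5(enh_path)
  if (config$resume && manifest_matches(out, "convert", fp, ins)) {
    mask <- read_mask(mask_path)
    threshold <- jsonlite::read_json(file.path(out,
                                               "manifest_convert.json"))$info$threshold
  } else {
    threshold <- select_threshold(enh, config$fg_percent)
    mask <- dense_to_sparse(enh, threshold)
    write_mask(mask, mask_path)
    write_manifest(out, "convert", fp, ins, "mask.smk",
                   list(threshold = threshold, n_Ws = length(mask$idx)))
  }

  # -- seeds -----------------------------------------------------------------
  seeds <- segment_seeds(mask, config$close_radius, config$open_radius,
                         config$min_voxels)
  write_seeds_csv(seeds, file.path(out, "seeds.csv"))
  fp <- config_fingerprint(config, "seeds")
  write_manifest(out, "seeds", fp, file_md5(mask_path), "seeds.csv",
                 list(n_seeds = length(seeds$instances)))

  # -- cells -----------------------------------------------------------------
  # W_s is the foreground the sweep actually runs on (after the optional
  # branch closing), so the containment W_c subset of W_s holds by
  # construction
  swept_mask <- close_branches(mask, config$branch_close_radius)
  field <- fastsweep(swept_mask, seeds, config$tolerance)
  reached <- prune_unreached(swept_mask, field)
  cells <- split_cells(reached, seeds)
  comp_df <- do.call(rbind, c(list(data.frame(cell_id = integer(0),
                                              n_voxels = integer(0),
                                              n_seeds = integer(0),
                                              is_cluster = logical(0),
                                              seed_ids = character(0))),
    lapply(cells, function(cl)
      data.frame(cell_id = cl$id, n_voxels = length(cl$idx),
                 n_seeds = length(cl$seed_ids), is_cluster = cl$is_cluster,
                 seed_ids = paste(cl$seed_ids, collapse = ";")))))
  utils::write.csv(comp_df, file.path(out, "components.csv"),
                   row.names = FALSE, quote = FALSE)
  for (cl in cells)
    write_mask(sparse_mask(cl$idx, reached$shape, reached$voxel_size),
               file.path(out, sprintf("cell%03d.smk", cl$id)))
  fp <- config_fingerprint(config, "cells")
  write_manifest(out, "cells", fp, file_md5(mask_path), "components.csv",
                 list(n_Wc = length(reached$idx), n_cells = length(cells)))

  # -- skeletonize -----------------------------------------------------------
  swc_paths <- character(0)
  for (cl in cells) {
    trees <- skeletonize_instance(cl, seeds,
                                  coarsen_steps = config$coarsen_steps,
                                  max_ball = config$max_ball,
                                  min_radius = config$min_radius)
    for (nm in names(trees)) {
      sid <- as.integer(sub("seed", "", nm))
      p <- file.path(out, sprintf("cell%03d_seed%03d.swc", cl$id, sid))
      write_swc(trees[[nm]], p)
      swc_paths <- c(swc_paths, p)
    }
  }
  fp <- config_fingerprint(config, "skeletonize")
  write_manifest(out, "skeletonize", fp, file_md5(mask_path),
                 basename(swc_paths), list(n_trees = length(swc_paths)))

  result <- list(out_dir = out, threshold = threshold, n_W = n_W,
                 n_Ws = length(swept_mask$idx), n_Wc = length(reached$idx),
                 seeds = seeds, cells = comp_df, swc_paths = swc_paths,
                 shape = dim(enh$data), voxel_size = enh$voxel_size)

  # -- bench -----------------------------------------------------------------
  if (!is.null(config$bench_gold)) {
    gold_files <- sort(list.files(config$bench_gold, pattern = "\\.swc$",
                                  full.names = TRUE))
    if (!length(gold_files)) stop("no gold SWC files in ", config$bench_gold)
    result$scores <- bench_trees(gold_files, swc_paths, config$match)
    utils::write.csv(result$scores, file.path(out, "scores.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  class(result) <- "pipeline_result"
  result
}

#' Score reconstructed trees against a gold set
#'
#' Each gold tree is paired with the test tree whose root is nearest its
#' own root, then scored with [decomposed_scores()].  The returned table
#' has one row per gold tree plus a `cohort` summary row carrying the mean
#' of each score and the [cohort_yield()] of the topology column.
#'
#' @param gold_files,test_files character vectors of SWC paths.
#' @param params a [match_params()].
#' @return A data frame of per-tree and cohort scores.
#' @export
bench_trees <- function(gold_files, test_files, params = match_params()) {
  golds <- lapply(gold_files, read_swc)
  tests <- lapply(test_files, read_swc)
  rows <- list()
  for (i in seq_along(golds)) {
    g <- golds[[i]]
    groot <- which(g$parent == -1L)
    sc <- if (length(tests)) {
      d <- vapply(tests, function(t) {
        r <- which(t$parent == -1L)
        sqrt((t$x[r] - g$x[groot])^2 + (t$y[r] - g$y[groot])^2 +
             (t$z[r] - g$z[groot])^2)
      }, numeric(1))
      decomposed_scores(g, tests[[which.min(d)]], params)
    } else {
      decomposed_scores(g, g[0, ], params)
    }
    rows[[i]] <- cbind(data.frame(tree = basename(gold_files[i])), sc)
  }
  df <- do.call(rbind, rows)
  topo <- df$topology[!is.na(df$topology)]
  summary <- data.frame(tree = "cohort",
                        topology = mean(topo),
                        recall = mean(df$recall, na.rm = TRUE),
                        branch = mean(df$branch, na.rm = TRUE),
                        leaf = mean(df$leaf, na.rm = TRUE),
                        direction = mean(df$direction, na.rm = TRUE),
                        precision = mean(df$precision, na.rm = TRUE))
  summary$yield <- if (length(topo) >= 2) cohort_yield(topo) else NA_real_
  df$yield <- NA_real_
  rbind(df, summary)
}

#' Working-set element counts of a pipeline run
#'
#' Reports `|W|` (dense voxel count), `|W_s|` (foreground after
#' conversion), `|W_c|` (reachable after pruning) and their ratios; the
#' containment `|W_c| <= |W_s| <= |W|` holds by construction.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @return List with `W`, `Ws`, `Wc`, `Ws_over_Wc`, `W_over_Wc`.
#' @export
working_set_report <- function(result) {
  list(W = result$n_W, Ws = result$n_Ws, Wc = result$n_Wc,
       Ws_over_Wc = if (result$n_Wc > 0) result$n_Ws / result$n_Wc else NA,
       W_over_Wc = if (result$n_Wc > 0) result$n_W / result$n_Wc else NA)
}
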