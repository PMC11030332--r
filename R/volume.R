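#' Dense image volume
#'
#' Container for the dense working set `W`: a 3D grid of non-negative
#' intensities with a physical voxel size.  Data are stored as an array with
#' `dim = c(nz, ny, nx)` and the voxel size as `c(z, y, x)` in micrometers.
#'
#' @param data 3D numeric array (z, y, x order) of non-negative intensities,
#'   or a matrix (treated as a single z slice).
#' @param voxel_size numeric length-3, µm per voxel along (z, y, x).
#' @return An object of class `dense_volume` with elements `data` and
#'   `voxel_size`.
#' @examples
#' v <- dense_volume(array(0, c(4, 4, 4)), voxel_size = c(1, 1, 1))
#' dim(v$data)
#' @export
dense_volume <- function(data, voxel_size = c(1, 1, 1)) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all shape components must be >= 1")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 positive values (z, y, x) in um")
  if (anyNA(data) || any(data < 0))
    stop("volume intensities must be finite and non-negative")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "dense_volume")
}

#' @export
print.dense_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dense_volume %d x %d x %d (z y x), voxel %s um, range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 3), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

as_dense_volume <- function(x, voxel_size = c(1, 1, 1)) {
  if (inherits(x, "dense_volume")) x else dense_volume(x, voxel_size)
}

#' Read a 3D volume from a TIFF stack or a per-slice TIFF series
#'
#' A single multi-page TIFF is read as a z stack; a directory is read as a
#' filename-sorted series of single-slice TIFFs.  8/16-bit integer samples
#' are read at their native integer scale; 32-bit float samples as-is.
#'
#' @param path a TIFF file or a directory of TIFF slices.
#' @param voxel_size µm per voxel along (z, y, x).
#' @return A [dense_volume()].
#' @export
read_tiff_volume <- function(path, voxel_size = c(1, 1, 1)) {
  read1 <- function(f) {
    info <- tiff::readTIFF(f, all = TRUE, info = TRUE, payload = FALSE)
    bits <- if (is.data.frame(info) && "bits.per.sample" %in% names(info))
      info$bits.per.sample[1] else 8
    # integer samples at native scale; float samples as-is, times any
    # sidecar scale written by write_tiff_volume()
    s <- tiff::readTIFF(f, as.is = bits < 32, all = TRUE)
    if (!is.list(s)) s <- list(s)
    scale_file <- paste0(f, ".scale")
    if (bits >= 32 && file.exists(scale_file)) {
      sc <- as.numeric(readLines(scale_file, n = 1))
      s <- lapply(s, function(m) m * sc)
    }
    lapply(s, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]  # first channel of multi-channel
      m
    })
  }
  slices <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF slices found in ", path)
    unlist(lapply(files, read1), recursive = FALSE)
  } else {
    read1(path)
  }
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]])
  arr <- array(0, c(length(slices), ny, nx))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
  dense_volume(arr, voxel_size)
}

#' Write a volume as a multi-page TIFF stack
#'
#' @param vol a [dense_volume()].
#' @param path output file.
#' @param bits 8, 16 (integer, values clamped to the dtype range) or 32
#'   (float).  Float volumes with intensities above 1 are normalized on
#'   write and the scale stored in a `<path>.scale` sidecar, which
#'   [read_tiff_volume()] applies transparently on read.
#' @return `path`, invisibly.
#' @export
write_tiff_volume <- function(vol, path, bits = 32) {
  vol <- as_dense_volume(vol)
  d <- dim(vol$data)
  slices <- lapply(seq_len(d[1]), function(z) vol$data[z, , ])
  if (bits %in% c(8, 16)) {
    top <- 2^bits - 1
    slices <- lapply(slices, function(m) pmin(pmax(round(m), 0), top) / top)
  } else {
    mx <- max(vol$data)
    scale_file <- paste0(path, ".scale")
    if (mx > 1) {
      slices <- lapply(slices, function(m) m / mx)
      writeLines(shortest_dec(mx), scale_file)
    } else if (file.exists(scale_file)) {
      unlink(scale_file)
    }
  }
  tiff::writeTIFF(slices, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Downsample a volume along z by block averaging
#'
#' Groups of `factor` consecutive z slices are averaged (trailing slices
#' that do not fill a block are dropped) and the z voxel size is multiplied
#' by `factor`.  Used to restore near-isotropic sampling when the axial
#' point-spread function dominates.
#'
#' @param vol a [dense_volume()].
#' @param factor integer >= 1.
#' @return A [dense_volume()] with `floor(nz / factor)` slices.
#' @export
z_downsample <- function(vol, factor) {
  vol <- as_dense_volume(vol)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  d <- dim(vol$data)
  if (factor > d[1]) stop("factor exceeds the z extent (", d[1], ")")
  if (factor == 1L) return(vol)
  zp <- d[1] %/% factor
  a <- array(vol$data[seq_len(zp * factor), , ], c(factor, zp, d[2], d[3]))
  out <- colMeans(a, dims = 1)
  dense_volume(out, vol$voxel_size * c(factor, 1, 1))
}
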