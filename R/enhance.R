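#' Destriping parameters
#'
#' Configures wavelet-Fourier stripe removal.  Stripe artifacts are
#' multiplicative shadow lines that are (nearly) constant along one image
#' axis; in slice coordinates used here they run along dim 1 (y), i.e. each
#' column x carries a common attenuation factor.
#'
#' @param sigma Gaussian notch width in cycles per band extent; the notch
#'   `1 - exp(-k^2 / (2 sigma^2))` attenuates the lowest stripe-axis
#'   frequencies of the detail coefficients.
#' @param levels wavelet decomposition depth; `NULL` (default) uses
#'   `min(5, floor(log2(min(dim))))`, further capped so every level keeps
#'   even band sizes of at least twice the filter length.
#' @param wavelet `"db1"`/`"haar"`, `"db2"` or `"db3"` (default).
#' @param bidirectional also notch-filter the orthogonal detail band, for
#'   stripes along both axes.
#' @return A `destripe_params` object.
#' @export
destripe_params <- function(sigma = 1, levels = NULL, wavelet = "db3",
                            bidirectional = FALSE) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.null(levels) && levels < 1) stop("levels must be >= 1")
  dwt_filters(wavelet)  # validates the family
  structure(list(sigma = sigma, levels = levels, wavelet = wavelet,
                 bidirectional = isTRUE(bidirectional)),
            class = "destripe_params")
}

notch_gain <- function(n, sigma) {
  k <- 0:(n - 1)
  kk <- pmin(k, n - k)
  1 - exp(-kk^2 / (2 * sigma^2))
}

# FFT along dim 1, multiply by the notch, inverse FFT
notch_rows <- function(band, sigma) {
  n <- nrow(band)
  if (n < 2L) return(band)
  g <- notch_gain(n, sigma)
  Re(stats::mvfft(stats::mvfft(band) * g, inverse = TRUE)) / n
}

#' Remove stripe artifacts from a 2D slice
#'
#' Multi-level wavelet decomposition isolates stripe energy in the detail
#' band that is high-pass across the stripes and low-pass along them; a 1D
#' Fourier transform along the stripe axis of that band concentrates the
#' stripes near zero frequency, where a Gaussian notch suppresses them.
#' The slice is then recomposed and clamped to be non-negative.  The
#' approximation band is never touched, so constant images pass through
#' unchanged.
#'
#' @param image 2D numeric matrix (y, x), finite and non-negative.
#' @param params a [destripe_params()].
#' @return A matrix of the same shape.
#' @export
destripe_slice <- function(image, params = destripe_params()) {
  if (!is.matrix(image)) stop("destripe_slice expects a 2D matrix")
  if (anyNA(image) || any(!is.finite(image)))
    stop("image must be finite")
  levels <- params$levels %||% max(1L, min(5L, floor(log2(min(dim(image))))))
  dec <- dwt2(image, wavelet = params$wavelet, levels = levels)
  for (l in seq_along(dec$bands)) {
    dec$bands[[l]]$hx <- notch_rows(dec$bands[[l]]$hx, params$sigma)
    if (params$bidirectional)
      dec$bands[[l]]$hy <- t(notch_rows(t(dec$bands[[l]]$hy), params$sigma))
  }
  out <- idwt2(dec)
  pmax(out, 0)
}

#' Remove stripe artifacts from every z slice of a volume
#'
#' @param volume a [dense_volume()].
#' @param params a [destripe_params()].
#' @return A [dense_volume()] of the same shape and voxel size.
#' @export
destripe_volume <- function(volume, params = destripe_params()) {
  volume <- as_dense_volume(volume)
  out <- volume$data
  for (z in seq_len(dim(out)[1]))
    out[z, , ] <- destripe_slice(out[z, , ], params)
  dense_volume(out, volume$voxel_size)
}

#' Correct smooth bleaching / illumination fields
#'
#' Estimates the smooth brightness field with a 3D Gaussian low-pass filter
#' and divides the volume by it (flat-field correction), flooring the
#' divisor at `1e-3` of its maximum.  The result is rescaled so its mean
#' intensity equals the input mean; a constant volume therefore passes
#' through unchanged.
#'
#' @param volume a [dense_volume()].
#' @param lowpass_sigma Gaussian sigma in µm; default is 1/8 of the smaller
#'   lateral (y/x) physical extent.
#' @return A [dense_volume()] of the same shape and voxel size.
#' @export
debleach <- function(volume, lowpass_sigma = NULL) {
  volume <- as_dense_volume(volume)
  d <- dim(volume$data)
  vs <- volume$voxel_size
  if (all(volume$data == 0)) stop("cannot debleach an all-zero volume")
  sigma <- lowpass_sigma %||% (min(d[2] * vs[2], d[3] * vs[3]) / 8)
  if (sigma <= 0) stop("lowpass_sigma must be > 0")
  kz <- gauss_kernel(sigma / vs[1])
  ky <- gauss_kernel(sigma / vs[2])
  kx <- gauss_kernel(sigma / vs[3])
  low <- conv_sep3_cpp(as.numeric(volume$data), d, kz, ky, kx)
  floorv <- 1e-3 * max(low)
  out <- as.numeric(volume$data) / pmax(low, floorv)
  out <- out * (mean(volume$data) / mean(out))
  dense_volume(array(out, d), vs)
}

#' Ellipsoidal point-spread-function model
#'
#' Lightsheet optics blur a point source into an axially elongated
#' ellipsoid; axial blur typically exceeds lateral blur by about 2.5x.
#'
#' @param sigma_xy lateral Gaussian sigma, µm.
#' @param sigma_z axial Gaussian sigma, µm; must be >= `sigma_xy`.
#' @param kernel_truncate kernel support, in multiples of sigma.
#' @return A `psf_model` object.
#' @export
psf_model <- function(sigma_xy = 1, sigma_z = 2.5 * sigma_xy,
                      kernel_truncate = 3) {
  if (!(sigma_xy > 0) || sigma_z < sigma_xy)
    stop("need sigma_z >= sigma_xy > 0")
  if (kernel_truncate <= 0) stop("kernel_truncate must be > 0")
  structure(list(sigma_xy = sigma_xy, sigma_z = sigma_z,
                 kernel_truncate = kernel_truncate), class = "psf_model")
}

#' Sample a PSF model on the voxel grid
#'
#' Builds a separable anisotropic Gaussian kernel, truncated at
#' `kernel_truncate` sigmas and normalized to sum 1.
#'
#' @param model a [psf_model()].
#' @param voxel_size µm per voxel (z, y, x).
#' @return A `psf_kernel` object carrying the per-axis factors (`kz`, `ky`,
#'   `kx`) and the dense 3D `array`.
#' @export
make_psf <- function(model, voxel_size = c(1, 1, 1)) {
  kz <- gauss_kernel(model$sigma_z / voxel_size[1], model$kernel_truncate)
  ky <- gauss_kernel(model$sigma_xy / voxel_size[2], model$kernel_truncate)
  kx <- gauss_kernel(model$sigma_xy / voxel_size[3], model$kernel_truncate)
  arr <- outer(outer(kz, ky), kx)
  structure(list(kz = kz, ky = ky, kx = kx, array = arr,
                 voxel_size = voxel_size), class = "psf_kernel")
}

psf_convolve <- function(data, psf) {
  d <- dim(data)
  if (inherits(psf, "psf_kernel")) {
    if (length(psf$kz) > d[1] || length(psf$ky) > d[2] || length(psf$kx) > d[3])
      stop("PSF kernel is larger than the volume")
    array(conv_sep3_cpp(as.numeric(data), d, psf$kz, psf$ky, psf$kx), d)
  } else {
    kd <- dim(psf)
    if (any(kd > d)) stop("PSF kernel is larger than the volume")
    array(conv3_direct_cpp(as.numeric(data), d, as.numeric(psf), kd), d)
  }
}

#' Richardson-Lucy deconvolution
#'
#' Multiplicative update scheme: `e <- e * K^T(v / K(e))`, with mirror
#' boundary handling.  Updates preserve non-negativity and approximately
#' conserve total intensity for interior signal.  Symmetric (Gaussian)
#' kernels are their own adjoint, which is the case for [make_psf()]
#' output.
#'
#' @param volume a [dense_volume()].
#' @param psf a `psf_kernel` from [make_psf()] (fast separable path) or a
#'   plain non-negative 3D kernel array normalized to sum 1.
#' @param iterations number of multiplicative updates (>= 1).
#' @return A [dense_volume()] of the same shape and voxel size.
#' @export
deconvolve <- function(volume, psf, iterations = 10) {
  volume <- as_dense_volume(volume)
  if (iterations < 1) stop("iterations must be >= 1")
  karr <- if (inherits(psf, "psf_kernel")) psf$array else psf
  if (any(karr < 0)) stop("PSF must be non-negative")
  if (abs(sum(karr) - 1) > 1e-4) stop("PSF must be normalized to sum 1")
  flipped <- if (inherits(psf, "psf_kernel")) psf else {
    kd <- dim(psf)
    array(rev(as.numeric(psf)), kd)  # adjoint kernel for the correction pass
  }
  eps <- 1e-12
  est <- volume$data
  for (i in seq_len(iterations)) {
    blur <- psf_convolve(est, psf)
    ratio <- volume$data / pmax(blur, eps)
    est <- est * psf_convolve(ratio, flipped)
  }
  dense_volume(pmax(est, 0), volume$voxel_size)
}
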