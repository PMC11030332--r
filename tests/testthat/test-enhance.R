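# destriping, debleaching, PSF and deconvolution behavior

test_that("wavelet decomposition reconstructs perfectly and constants pass through", {
  set.seed(42)
  for (nn in c(16, 96, 128)) {
    x <- matrix(runif(nn * nn), nn, nn)
    dec <- somatrace:::dwt2(x, "db3", 8)
    expect_lt(max(abs(somatrace:::idwt2(dec) - x)), 1e-9)
  }
  cimg <- matrix(7, 64, 64)
  expect_lt(max(abs(destripe_slice(cimg) - 7)), 1e-8)
  # volume wrappers: constant volume unchanged, single slice equivalence
  v <- dense_volume(array(3, c(2, 32, 32)))
  expect_lt(max(abs(destripe_volume(v)$data - 3)), 1e-8)
  set.seed(1)
  img <- matrix(runif(64 * 64, 10, 50), 64, 64)
  one <- dense_volume(array(img, c(1, 64, 64)))
  expect_equal(destripe_volume(one)$data[1, , ], destripe_slice(img))
})

test_that("destriping removes most stripe-band excess and spares granular texture", {
  ny <- 128; nx <- 128
  bg <- outer(seq(20, 60, length.out = ny), seq(1, 1.4, length.out = nx))
  stripe <- 1 + 0.3 * sin(2 * pi * (0:(nx - 1)) / 37)
  img <- bg * rep(stripe, each = ny)
  band_energy <- function(im) {
    p <- colMeans(im)
    f <- abs(stats::fft(p - mean(p)))^2
    k <- round(nx / 37)
    sum(f[c(k, k + 1, nx - k + 1, nx - k) + 1])
  }
  ds <- destripe_slice(img)
  reduction <- (band_energy(img) - band_energy(ds)) /
    (band_energy(img) - band_energy(bg))
  expect_gte(reduction, 0.90)
  # granular stripe-free texture: RMS change below 2% of image RMS
  set.seed(7)
  tex <- 40 + outer(seq(0, 20, length.out = ny), rep(1, nx)) +
    matrix(rnorm(ny * nx, 0, 8), ny)
  tex <- pmax(tex, 0)
  rel <- sqrt(mean((destripe_slice(tex) - tex)^2)) / sqrt(mean(tex^2))
  expect_lt(rel, 0.02)
  # non-negativity and shape preservation
  expect_true(all(ds >= 0))
  expect_identical(dim(ds), dim(img))
  # parameter validation
  expect_error(destripe_params(sigma = 0), "sigma")
  expect_error(destripe_slice(array(1, c(2, 2, 2))), "2D")
})

test_that("destriping a striped volume improves gzip compressibility", {
  set.seed(4)
  img <- 40 + matrix(rnorm(96 * 96, 0, 5), 96)
  img <- img * rep(1 + 0.3 * sin(2 * pi * (0:95) / 37), each = 96)
  vol <- dense_volume(array(rep(img, 3), c(96, 96, 3)))
  bytes <- function(v) length(memCompress(writeBin(as.numeric(round(v$data)),
                                                   raw()), "gzip"))
  expect_lte(bytes(destripe_volume(vol)), bytes(vol))
})

test_that("debleaching reverses smooth multiplicative fields", {
  # constant volume is a fixed point (ratio 1, mean restored)
  v <- dense_volume(array(5, c(16, 16, 16)))
  expect_lt(max(abs(debleach(v)$data - 5)), 1e-10)
  expect_error(debleach(dense_volume(array(0, c(4, 4, 4)))), "all-zero")
  # smooth zero-edge-slope field alone flattens out
  nx <- 128
  field <- 0.65 + 0.35 * cos(pi * (0:(nx - 1)) / (nx - 1))
  gr <- dense_volume(array(rep(field, each = 128 * 128),
                           c(128, 128, 128)) * 100)
  cv <- function(x) stats::sd(x) / mean(x)
  dg <- debleach(gr, lowpass_sigma = 8)
  expect_lt(cv(as.numeric(dg$data)) / cv(as.numeric(gr$data)), 0.05)
  # shape/voxel-size preservation and mean rescale
  expect_identical(dim(dg$data), dim(gr$data))
  expect_equal(mean(dg$data), mean(gr$data))
})

test_that("PSF kernels are normalized, symmetric, and 2.5x anisotropic", {
  p <- make_psf(psf_model(2, 5), c(1, 1, 1))
  expect_lt(abs(sum(p$array) - 1), 1e-6)
  iso <- make_psf(psf_model(1.5, 1.5), c(1, 1, 1))
  mz <- apply(iso$array, 1, sum); mx <- apply(iso$array, 3, sum)
  expect_equal(mz, mx, tolerance = 1e-12)
  # interpolated FWHM ratio matches the 2.5x axial elongation
  fwhm <- function(k) {
    k <- k / max(k)
    x <- seq_along(k)
    above <- which(k >= 0.5)
    lo <- min(above); hi <- max(above)
    f1 <- if (lo > 1) lo - (k[lo] - 0.5) / (k[lo] - k[lo - 1]) else lo
    f2 <- if (hi < length(k)) hi + (k[hi] - 0.5) / (k[hi] - k[hi + 1]) else hi
    f2 - f1
  }
  p <- make_psf(psf_model(2, 5), c(1, 1, 1))
  ratio <- fwhm(apply(p$array, 1, sum)) / fwhm(apply(p$array, 3, sum))
  expect_equal(ratio, 2.5, tolerance = 0.05)
  expect_error(psf_model(2, 1), "sigma_z")
})

test_that("Richardson-Lucy relocates a blurred delta and stays non-negative", {
  psf <- make_psf(psf_model(1.2, 3), c(1, 1, 1))
  delta <- array(0, c(41, 41, 41)); delta[21, 21, 21] <- 100
  blurred <- dense_volume(somatrace:::psf_convolve(delta, psf))
  dec <- deconvolve(blurred, psf, 20)
  expect_identical(which.max(dec$data), which.max(delta))
  expect_true(all(dec$data >= 0))
  # flux conservation for interior signal
  expect_equal(sum(dec$data), sum(blurred$data), tolerance = 0.01)
  # axial sharpening of a blurred two-point phantom
  two <- array(0, c(41, 21, 21))
  two[17, 11, 11] <- 50; two[25, 11, 11] <- 50
  btwo <- dense_volume(somatrace:::psf_convolve(two, psf))
  dtwo <- deconvolve(btwo, psf, 15)
  width <- function(p) sum(p / max(p) >= 0.5)
  expect_lte(width(dtwo$data[, 11, 11]), width(btwo$data[, 11, 11]))
  # negative kernels rejected; non-negative for any iteration count
  expect_error(deconvolve(blurred, array(-1, c(3, 3, 3))), "non-negative")
  expect_true(all(deconvolve(blurred, psf, 1)$data >= 0))
})
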