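# Periodized orthogonal Daubechies wavelet transform (1D/2D, multi-level).
# Only what stripe removal needs: separable analysis into (low-low,
# high-x, high-y, high-high) bands with perfect reconstruction.

dwt_filters <- function(wavelet) {
  h <- switch(wavelet,
    haar = ,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(0.482962913144690, 0.836516303737469,
            0.224143868041857, -0.129409522550921),
    db3 = c(0.332670552950957, 0.806891509313339, 0.459877502119331,
            -0.135011020010391, -0.085441273882241, 0.035226291882101),
    stop("unknown wavelet family: ", wavelet)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror highpass
  list(h = h, g = g, len = L)
}

# one analysis step along dim 1 (rows), periodic boundary; nrow(x) even
dwt_step_rows <- function(x, f) {
  n <- nrow(x)
  n2 <- n %/% 2L
  base <- 2L * (seq_len(n2) - 1L)
  a <- matrix(0, n2, ncol(x))
  d <- a
  for (k in seq_len(f$len) - 1L) {
    rows <- ((base + k) %% n) + 1L
    xs <- x[rows, , drop = FALSE]
    a <- a + f$h[k + 1L] * xs
    d <- d + f$g[k + 1L] * xs
  }
  list(a = a, d = d)
}

idwt_step_rows <- function(a, d, f) {
  n2 <- nrow(a)
  n <- 2L * n2
  base <- 2L * (seq_len(n2) - 1L)
  x <- matrix(0, n, ncol(a))
  for (k in seq_len(f$len) - 1L) {
    rows <- ((base + k) %% n) + 1L
    x[rows, ] <- x[rows, ] + f$h[k + 1L] * a + f$g[k + 1L] * d
  }
  x
}

dwt_step_cols <- function(x, f) {
  s <- dwt_step_rows(t(x), f)
  list(a = t(s$a), d = t(s$d))
}

idwt_step_cols <- function(a, d, f) t(idwt_step_rows(t(a), t(d), f))

# Multi-level 2D decomposition.  Per level: hx = low along y (dim 1), high
# along x (dim 2) -- the band that carries stripes running along y; hy the
# transpose band; hh the diagonal band.  Decomposition stops early when a
# band dimension becomes odd or shorter than twice the filter length.
dwt2 <- function(x, wavelet = "db3", levels = 5L) {
  f <- dwt_filters(wavelet)
  out <- list(wavelet = wavelet, bands = list(), approx = NULL)
  cur <- x
  for (l in seq_len(levels)) {
    d <- dim(cur)
    if (any(d %% 2L != 0L) || any(d < f$len + 2L)) break
    sy <- dwt_step_rows(cur, f)
    lo <- dwt_step_cols(sy$a, f)   # from low-y: (ll, hx)
    hi <- dwt_step_cols(sy$d, f)   # from high-y: (hy, hh)
    out$bands[[l]] <- list(hx = lo$d, hy = hi$a, hh = hi$d)
    cur <- lo$a
  }
  out$approx <- cur
  out
}

idwt2 <- function(dec) {
  f <- dwt_filters(dec$wavelet)
  cur <- dec$approx
  for (l in rev(seq_along(dec$bands))) {
    b <- dec$bands[[l]]
    ay <- idwt_step_cols(cur, b$hx, f)
    dy <- idwt_step_cols(b$hy, b$hh, f)
    cur <- idwt_step_rows(ay, dy, f)
  }
  cur
}
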