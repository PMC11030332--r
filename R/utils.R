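# small shared helpers (internal)

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# 0-based (z, y, x) coordinates of 1-based linear indices for dim shape
idx_to_zyx <- function(idx, shape) {
  i0 <- idx - 1L
  z <- i0 %% shape[1]
  r <- i0 %/% shape[1]
  y <- r %% shape[2]
  x <- r %/% shape[2]
  cbind(z = z, y = y, x = x)
}

# inverse of idx_to_zyx: 0-based coords -> 1-based linear indices
zyx_to_idx <- function(zyx, shape) {
  as.integer(zyx[, 1] + shape[1] * (zyx[, 2] + shape[2] * zyx[, 3]) + 1)
}

# shortest decimal representation that round-trips to the same double
shortest_dec <- function(x) {
  vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%d", as.integer(v)))
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

# normalized 1D Gaussian kernel, sigma in samples, truncated at `trunc` sigma
gauss_kernel <- function(sigma, trunc = 3) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(trunc * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
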