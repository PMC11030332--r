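# brute-force / independent oracles, deliberately written without reusing
# the package's computational kernels

oracle_offsets <- function(radius) {
  r <- -radius:radius
  g <- as.matrix(expand.grid(r, r, r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

# Minkowski sum on an explicit (optionally padded) grid
oracle_dilate <- function(coords, radius, shape) {
  off <- oracle_offsets(radius)
  n <- nrow(coords); k <- nrow(off)
  all <- coords[rep(seq_len(n), each = k), , drop = FALSE] +
    off[rep(seq_len(k), n), , drop = FALSE]
  ok <- all[, 1] >= 0 & all[, 2] >= 0 & all[, 3] >= 0 &
    all[, 1] < shape[1] & all[, 2] < shape[2] & all[, 3] < shape[3]
  unique(all[ok, , drop = FALSE])
}

oracle_erode <- function(coords, radius, shape) {
  if (!nrow(coords)) return(coords)
  off <- oracle_offsets(radius)
  act <- array(FALSE, shape)
  act[lin_idx(coords, shape)] <- TRUE
  keep <- vapply(seq_len(nrow(coords)), function(i) {
    p <- coords[rep(i, nrow(off)), , drop = FALSE] + off
    if (any(p < 0) || any(p[, 1] >= shape[1]) || any(p[, 2] >= shape[2]) ||
        any(p[, 3] >= shape[3])) return(FALSE)
    all(act[lin_idx(p, shape)])
  }, logical(1))
  coords[keep, , drop = FALSE]
}

oracle_open <- function(coords, radius, shape)
  oracle_dilate(oracle_erode(coords, radius, shape), radius, shape)

# closing on a radius-padded grid (unbounded-domain semantics), clipped back
oracle_close <- function(coords, radius, shape) {
  pshape <- shape + 2 * radius
  pc <- coords + radius
  out <- oracle_erode(oracle_dilate(pc, radius, pshape), radius, pshape) -
    radius
  ok <- out[, 1] >= 0 & out[, 2] >= 0 & out[, 3] >= 0 &
    out[, 1] < shape[1] & out[, 2] < shape[2] & out[, 3] < shape[3]
  out[ok, , drop = FALSE]
}

coords_key <- function(coords, shape) sort(lin_idx(coords, shape))

neighbor_table <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  m <- rowSums(abs(g))
  if (connectivity == 6) g[m == 1, , drop = FALSE]
  else if (connectivity == 18) g[m <= 2, , drop = FALSE]
  else g
}

# BFS flood fill; labels numbered by smallest linear index first
flood_components <- function(idx, shape, connectivity = 26) {
  idx <- sort(idx)
  pos <- integer(prod(shape))
  pos[idx] <- seq_along(idx)
  nb <- neighbor_table(connectivity)
  zyx <- cbind((idx - 1) %% shape[1],
               ((idx - 1) %/% shape[1]) %% shape[2],
               (idx - 1) %/% (shape[1] * shape[2]))
  lab <- integer(length(idx))
  cur <- 0L
  for (i in seq_along(idx)) {
    if (lab[i]) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p <- zyx[rep(v, nrow(nb)), , drop = FALSE] + nb
      ok <- p[, 1] >= 0 & p[, 2] >= 0 & p[, 3] >= 0 &
        p[, 1] < shape[1] & p[, 2] < shape[2] & p[, 3] < shape[3]
      w <- pos[lin_idx(p[ok, , drop = FALSE], shape)]
      w <- w[w > 0]
      w <- w[lab[w] == 0]
      lab[w] <- cur
      queue <- c(queue, w)
    }
  }
  lab
}

# Jacobi fixed point of the local arrival update (order-independent):
# eikonal upwind over the axes plus 26-neighbor graph relaxation
jacobi_eikonal <- function(mask_idx, seed_idx, shape, spacing = c(1, 1, 1),
                           tol = 1e-9, max_iter = 5000) {
  mask_idx <- sort(mask_idx)
  n <- length(mask_idx)
  pos <- integer(prod(shape))
  pos[mask_idx] <- seq_len(n)
  zyx <- cbind((mask_idx - 1) %% shape[1],
               ((mask_idx - 1) %/% shape[1]) %% shape[2],
               (mask_idx - 1) %/% (shape[1] * shape[2]))
  nb <- neighbor_table(26)
  d26 <- sqrt(colSums((t(nb) * spacing)^2))
  nbr <- matrix(NA_integer_, n, nrow(nb))
  for (j in seq_len(nrow(nb))) {
    p <- zyx + nb[rep(j, n), , drop = FALSE]
    ok <- p[, 1] >= 0 & p[, 2] >= 0 & p[, 3] >= 0 &
      p[, 1] < shape[1] & p[, 2] < shape[2] & p[, 3] < shape[3]
    w <- rep(NA_integer_, n)
    w[ok] <- pos[lin_idx(p[ok, , drop = FALSE], shape)]
    w[!is.na(w) & w == 0] <- NA_integer_
    nbr[, j] <- w
  }
  # face-neighbor column pairs per axis (dz, dy, dx single steps)
  axis_cols <- lapply(1:3, function(ax) {
    which(abs(nb[, ax]) == 1 & rowSums(abs(nb)) == 1)
  })
  dist <- rep(Inf, n)
  dist[pos[seed_idx]] <- 0
  seedmask <- dist == 0
  getcol <- function(j, d) {
    v <- rep(Inf, n)
    ok <- !is.na(nbr[, j])
    v[ok] <- d[nbr[ok, j]]
    v
  }
  for (it in seq_len(max_iter)) {
    a <- sapply(1:3, function(ax) {
      cols <- axis_cols[[ax]]
      pmin(getcol(cols[1], dist), getcol(cols[2], dist))
    })
    h <- matrix(rep(spacing, each = n), n, 3)
    # 3-element sort network on (a, h) pairs
    for (pair in list(c(1, 2), c(2, 3), c(1, 2))) {
      i1 <- pair[1]; i2 <- pair[2]
      s <- a[, i1] > a[, i2]
      s[is.na(s)] <- FALSE
      if (any(s)) {
        ta <- a[s, i1]; a[s, i1] <- a[s, i2]; a[s, i2] <- ta
        th <- h[s, i1]; h[s, i1] <- h[s, i2]; h[s, i2] <- th
      }
    }
    u <- a[, 1] + h[, 1]
    for (k in 2:3) {
      need <- is.finite(a[, k]) & u > a[, k]
      if (!any(need)) next
      A <- rowSums(1 / h[, 1:k, drop = FALSE]^2)
      B <- rowSums(a[, 1:k, drop = FALSE] / h[, 1:k, drop = FALSE]^2)
      C <- rowSums(a[, 1:k, drop = FALSE]^2 / h[, 1:k, drop = FALSE]^2) - 1
      disc <- B^2 - A * C
      cand <- (B + sqrt(pmax(disc, 0))) / A
      upd <- need & disc >= 0 & cand < u
      u[upd] <- cand[upd]
    }
    relax <- do.call(pmin, c(lapply(seq_len(ncol(nbr)), function(j)
      getcol(j, dist) + d26[j]), list(u)))
    new <- pmin(dist, relax)
    new[seedmask] <- 0
    delta <- suppressWarnings(max(abs(new - dist)[is.finite(dist) |
                                                    is.finite(new)], na.rm = TRUE))
    dist <- new
    if (!is.finite(delta) && it > 3) next
    if (is.finite(delta) && delta < tol && it > 3) break
  }
  dist
}

# independent upper bound: 26-neighbor Dijkstra via igraph
dijkstra_bound <- function(mask_idx, seed_idx, shape, spacing = c(1, 1, 1)) {
  mask_idx <- sort(mask_idx)
  n <- length(mask_idx)
  pos <- integer(prod(shape))
  pos[mask_idx] <- seq_len(n)
  zyx <- cbind((mask_idx - 1) %% shape[1],
               ((mask_idx - 1) %/% shape[1]) %% shape[2],
               (mask_idx - 1) %/% (shape[1] * shape[2]))
  nb <- neighbor_table(26)
  half <- nb[nb[, 3] > 0 | (nb[, 3] == 0 & nb[, 2] > 0) |
               (nb[, 3] == 0 & nb[, 2] == 0 & nb[, 1] > 0), , drop = FALSE]
  ef <- NULL; et <- NULL; ew <- NULL
  for (j in seq_len(nrow(half))) {
    p <- zyx + half[rep(j, n), , drop = FALSE]
    ok <- p[, 1] >= 0 & p[, 2] >= 0 & p[, 3] >= 0 &
      p[, 1] < shape[1] & p[, 2] < shape[2] & p[, 3] < shape[3]
    w <- pos[lin_idx(p[ok, , drop = FALSE], shape)]
    keep <- w > 0
    ef <- c(ef, which(ok)[keep])
    et <- c(et, w[keep])
    ew <- c(ew, rep(sqrt(sum((half[j, ] * spacing)^2)), sum(keep)))
  }
  g <- igraph::make_graph(rbind(ef, et), n = n, directed = FALSE)
  dm <- igraph::distances(g, v = pos[seed_idx], weights = ew)
  apply(dm, 2, min)
}

# independent lower bound: straight-line distance to the nearest seed voxel
euclid_bound <- function(mask_idx, seed_idx, shape, spacing = c(1, 1, 1)) {
  zyx <- function(i) cbind((i - 1) %% shape[1],
                           ((i - 1) %/% shape[1]) %% shape[2],
                           (i - 1) %/% (shape[1] * shape[2]))
  m <- zyx(sort(mask_idx)) * rep(spacing, each = length(mask_idx))
  s <- zyx(seed_idx) * rep(spacing, each = length(seed_idx))
  apply(sqrt(outer(m[, 1], s[, 1], "-")^2 + outer(m[, 2], s[, 2], "-")^2 +
               outer(m[, 3], s[, 3], "-")^2), 1, min)
}
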