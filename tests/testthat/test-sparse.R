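# sparse mask construction, thresholding, morphology, components, I/O

test_that("select_threshold hits the closest achievable foreground fraction", {
  v <- dense_volume(array(0:999, c(10, 10, 10)))
  expect_equal(select_threshold(v, 0.10), 899)
  expect_error(select_threshold(dense_volume(array(1, c(4, 4, 4))), 0.1),
               "constant")
  expect_error(select_threshold(v, 1.2), "fg_percent")
  # heavy ties: compare with exhaustive scan over unique intensities
  set.seed(3)
  vals <- sample(c(0, 1, 2, 5, 9), 512, replace = TRUE,
                 prob = c(.5, .2, .15, .1, .05))
  vv <- dense_volume(array(vals, c(8, 8, 8)))
  for (fg in c(0.01, 0.05, 0.2, 0.4)) {
    t <- select_threshold(vv, fg)
    uq <- sort(unique(vals))
    fr <- vapply(uq, function(u) mean(vals > u), numeric(1))
    best <- min(abs(fr - fg))
    expect_equal(abs(mean(vals > t) - fg), best)
    # ties break toward the smaller foreground fraction
    cand <- uq[abs(fr - fg) == best]
    expect_equal(t, max(cand))
  }
})

test_that("dense_to_sparse matches a brute-force scan and edge cases", {
  set.seed(11)
  a <- array(runif(16^3), c(16, 16, 16))
  v <- dense_volume(a)
  m <- dense_to_sparse(v, 0.7)
  expect_identical(m$idx, which(a > 0.7))
  expect_length(dense_to_sparse(v, max(a))$idx, 0)
  expect_length(dense_to_sparse(v, -1)$idx, 16^3)
  # densify round trip
  expect_identical(which(mask_densify(m)), m$idx)
})

test_that("ball morphology matches the brute-force oracle", {
  shape <- c(16, 16, 16)
  m1 <- mask_from_coords(cbind(5, 5, 5), c(11, 11, 11))
  expect_length(mask_dilate(m1, 1)$idx, 7)
  set.seed(21)
  for (rep in 1:5) {
    coords <- unique(cbind(sample(0:15, 60, TRUE), sample(0:15, 60, TRUE),
                           sample(0:15, 60, TRUE)))
    m <- mask_from_coords(coords, shape)
    for (r in 1:2) {
      expect_identical(mask_dilate(m, r)$idx,
                       coords_key(oracle_dilate(coords, r, shape), shape))
      expect_identical(mask_erode(m, r)$idx,
                       coords_key(oracle_erode(coords, r, shape), shape))
    }
  }
})

test_that("closing fills shell cavities and opening removes tubes", {
  shape <- c(24, 24, 24)
  ctr <- c(11, 11, 11)
  shell <- shell_coords(ctr, 6, 4, shape)
  closed <- mask_close(mask_from_coords(shell, shape), 4)
  expect_identical(closed$idx,
                   coords_key(oracle_close(shell, 4, shape), shape))
  # the cavity (entire inner ball) is filled
  ball <- ball_coords(ctr, 6, shape)
  expect_true(all(lin_idx(ball, shape) %in% closed$idx))
  # ball with a thin tube: opening keeps the ball, removes the tube
  shape2 <- c(24, 24, 40)
  bt <- rbind(ball_coords(c(11, 11, 8), 6, shape2),
              tube_coords(c(11, 11, 8), c(11, 11, 38), 1.3, shape2))
  op <- mask_open(mask_from_coords(bt, shape2), 3)
  expect_identical(op$idx, coords_key(oracle_open(bt, 3, shape2), shape2))
  expect_lte(max(mask_coords(op)[, 3]), 15)   # tube gone, ball extent kept
  expect_gte(length(op$idx), 0.8 * nrow(ball_coords(c(11, 11, 8), 6, shape2)))
})

test_that("morphology algebra: idempotence, extensivity, anti-extensivity", {
  set.seed(5)
  for (rep in 1:5) {
    m <- sparse_mask(sample(16^3, 250), c(16, 16, 16))
    for (r in 1:2) {
      cl <- mask_close(m, r); op <- mask_open(m, r)
      expect_true(all(op$idx %in% m$idx))
      expect_true(all(m$idx %in% cl$idx))
      expect_identical(mask_close(cl, r)$idx, cl$idx)
      expect_identical(mask_open(op, r)$idx, op$idx)
    }
  }
  # radius 0 are no-ops; unit-step variant is also idempotent in radius 1
  m <- sparse_mask(sample(16^3, 100), c(16, 16, 16))
  expect_identical(mask_close(m, 0)$idx, m$idx)
  expect_identical(mask_open(m, 0)$idx, m$idx)
  expect_identical(mask_close(m, 1, unit_steps = TRUE)$idx,
                   mask_close(m, 1)$idx)
})

test_that("surface extraction matches the 6-neighbor boundary rule", {
  cube <- mask_from_coords(as.matrix(expand.grid(4:6, 4:6, 4:6)),
                           c(11, 11, 11))
  expect_length(extract_surface(cube)$idx, 26)
  single <- mask_from_coords(cbind(3, 3, 3), c(8, 8, 8))
  expect_identical(extract_surface(single)$idx, single$idx)
  set.seed(9)
  m <- sparse_mask(sample(12^3, 400), c(12, 12, 12))
  zyx <- mask_coords(m)
  act <- array(FALSE, m$shape); act[m$idx] <- TRUE
  faces <- neighbor_table(6)
  issurf <- vapply(seq_len(nrow(zyx)), function(i) {
    p <- zyx[rep(i, 6), ] + faces
    out <- p[, 1] < 0 | p[, 2] < 0 | p[, 3] < 0 | p[, 1] >= 12 |
      p[, 2] >= 12 | p[, 3] >= 12
    any(out) || !all(act[lin_idx(p[!out, , drop = FALSE], m$shape)])
  }, logical(1))
  expect_identical(extract_surface(m)$idx, m$idx[issurf])
})

test_that("connected components agree with a flood-fill oracle", {
  shape <- c(10, 10, 10)
  two <- mask_from_coords(rbind(as.matrix(expand.grid(1:2, 1:2, 1:2)),
                                as.matrix(expand.grid(6:7, 6:7, 6:7))), shape)
  expect_equal(connected_components(two, 26)$n_labels, 2)
  corner <- mask_from_coords(rbind(c(1, 1, 1), c(2, 2, 2)), c(5, 5, 5))
  expect_equal(connected_components(corner, 26)$n_labels, 1)
  expect_equal(connected_components(corner, 6)$n_labels, 2)
  set.seed(13)
  for (conn in c(6, 18, 26)) {
    m <- sparse_mask(sample(12^3, 350), c(12, 12, 12))
    cc <- connected_components(m, conn)
    oracle <- flood_components(m$idx, m$shape, conn)
    expect_identical(cc$label, oracle)
    # partition property
    expect_identical(sort(unique(cc$label)), seq_len(cc$n_labels))
  }
})

test_that("mask serialization and TIFF export round-trip", {
  set.seed(17)
  m <- sparse_mask(sample(20^3, 500), c(20, 20, 20), c(2, 1, 1))
  f <- tempfile(fileext = ".smk")
  write_mask(m, f)
  m2 <- read_mask(f)
  expect_identical(m2$idx, m$idx)
  expect_identical(m2$shape, m$shape)
  expect_equal(m2$voxel_size, m$voxel_size)
  ft <- tempfile(fileext = ".tif")
  mask_to_tiff(m, ft)
  v <- read_tiff_volume(ft)
  expect_identical(which(v$data > 0), m$idx)
})
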