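# seeded eikonal fast sweeping, pruning, instance splitting

test_that("arrival distance on a straight 1-voxel path equals arc length", {
  shape <- c(1, 1, 10)
  seg <- mask_from_coords(cbind(0, 0, 0:9), shape)
  seeds <- make_seed_set(c(0, 0, 0), 1, shape, surfaces = list(seg$idx[1]))
  f <- fastsweep(seg, seeds)
  expect_equal(unname(f$dist[order(f$idx)]), 0:9, tolerance = 1e-9)
  # anisotropic spacing scales the answer
  seg2 <- sparse_mask(seg$idx, shape, voxel_size = c(1, 1, 2.5))
  f2 <- fastsweep(seg2, make_seed_set(c(0, 0, 0), 1, shape,
                                      surfaces = list(seg$idx[1])))
  expect_equal(max(f2$dist), 9 * 2.5, tolerance = 1e-9)
})

test_that("voxels in unseeded components stay unreached and are pruned", {
  shape <- c(8, 8, 20)
  a <- mask_from_coords(tube_coords(c(3, 3, 1), c(3, 3, 8), 1.2, shape), shape)
  b <- mask_from_coords(tube_coords(c(3, 3, 13), c(3, 3, 18), 1.2, shape),
                        shape)
  both <- sparse_mask(c(a$idx, b$idx), shape)
  seeds <- make_seed_set(c(3, 3, 1), 1, shape, surfaces = list(a$idx[1]))
  f <- fastsweep(both, seeds)
  expect_true(all(f$idx %in% a$idx))
  pruned <- prune_unreached(both, f)
  # the pruned mask is exactly the seeded 26-component (flood-fill oracle)
  lab <- flood_components(both$idx, shape, 26)
  seedlab <- lab[match(a$idx[1], sort(both$idx))]
  expect_identical(pruned$idx, sort(both$idx)[lab == seedlab])
  expect_lte(length(pruned$idx), length(both$idx))
})

test_that("converged sweeps agree with the order-independent fixed point", {
  for (sd in c(101, 102)) {
    m <- random_connected_mask(sd, c(20, 20, 20))
    set.seed(sd)
    seed_idx <- sample(m$idx, 2)
    seeds <- make_seed_set(c(1, 1, 1), 1, m$shape,
                           surfaces = list(seed_idx))
    f <- fastsweep(m, seeds, tolerance = 1e-3)
    oracle <- jacobi_eikonal(m$idx, seed_idx, m$shape)
    expect_lt(max(abs(f$dist - oracle[is.finite(oracle)])), 1e-3)
    expect_identical(f$idx, sort(m$idx)[is.finite(oracle)])
  }
})

test_that("split_cells annotates seeds and flags bridged clusters", {
  shape <- c(12, 12, 40)
  t1 <- tube_coords(c(5, 5, 2), c(5, 5, 14), 1.3, shape)
  t2 <- tube_coords(c(5, 5, 24), c(5, 5, 37), 1.3, shape)
  m <- mask_from_coords(rbind(t1, t2), shape)
  s1 <- lin_idx(t1[1, , drop = FALSE], shape)
  s2 <- lin_idx(t2[nrow(t2), , drop = FALSE], shape)
  seeds <- make_seed_set(rbind(c(5, 5, 2), c(5, 5, 37)), c(1, 1), shape,
                         surfaces = list(s1, s2))
  reached <- prune_unreached(m, fastsweep(m, seeds))
  cells <- split_cells(reached, seeds)
  expect_length(cells, 2)
  expect_false(any(vapply(cells, `[[`, logical(1), "is_cluster")))
  # bridge the tubes: one cluster instance with both seeds
  bridged <- mask_from_coords(rbind(t1, t2,
                                    tube_coords(c(5, 5, 14), c(5, 5, 24),
                                                1.3, shape)), shape)
  reached2 <- prune_unreached(bridged, fastsweep(bridged, seeds))
  cells2 <- split_cells(reached2, seeds)
  expect_length(cells2, 1)
  expect_true(cells2[[1]]$is_cluster)
  expect_setequal(cells2[[1]]$seed_ids, c(1, 2))
})

test_that("close_branches bridges gaps and merges close parallel tubes", {
  # square-section tube with a one-voxel gap: radius-1 closing bridges it
  shape <- c(9, 9, 21)
  sq <- as.matrix(expand.grid(3:5, 3:5))
  mk <- function(xs) do.call(rbind, lapply(xs, function(x) cbind(sq, x)))
  m <- mask_from_coords(rbind(mk(1:9), mk(11:19)), shape)
  expect_identical(close_branches(m, 0)$idx, m$idx)
  expect_equal(connected_components(m, 26)$n_labels, 2)
  bridged <- close_branches(m, 1)
  expect_equal(connected_components(bridged, 26)$n_labels, 1)
  # downstream sweep now reaches across the bridged gap
  seeds <- make_seed_set(c(4, 4, 1), 1, shape,
                         surfaces = list(lin_idx(cbind(4, 4, 1), shape)))
  f <- fastsweep(bridged, seeds)
  expect_true(lin_idx(cbind(4, 4, 19), shape) %in% f$idx)
  # parallel tubes with 2-voxel surface separation stay separate until the
  # closing ball spans the gap, then merge: the path-collision trade-off
  shape2 <- c(16, 16, 20)
  par2 <- rbind(tube_coords(c(7, 5, 2), c(7, 5, 18), 2, shape2),
                tube_coords(c(7, 11, 2), c(7, 11, 18), 2, shape2))
  mp <- mask_from_coords(par2, shape2)
  expect_equal(connected_components(mp, 26)$n_labels, 2)
  expect_equal(connected_components(close_branches(mp, 1), 26)$n_labels, 2)
  expect_equal(connected_components(close_branches(mp, 3), 26)$n_labels, 1)
})

test_that("empty seeds or out-of-mask seed voxels degrade with warnings", {
  shape <- c(6, 6, 6)
  m <- sparse_mask(1:20, shape)
  empty_seeds <- make_seed_set(matrix(numeric(0), 0, 3), numeric(0), shape)
  expect_warning(f <- fastsweep(m, empty_seeds), "empty seed")
  expect_length(f$idx, 0)
  # a seed surface voxel outside the mask is dropped with a warning
  seeds <- make_seed_set(c(0, 0, 0), 1, shape, surfaces = list(c(1L, 200L)))
  expect_warning(f2 <- fastsweep(m, seeds), "outside the mask")
  expect_true(1L %in% f2$idx)
})
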