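# surface graphs, coarsening, local separators, tree building, standardize

test_that("surface graphs match a pairwise adjacency oracle", {
  shape <- c(11, 11, 11)
  cube <- make_instance(as.matrix(expand.grid(4:6, 4:6, 4:6)), shape)
  g <- surface_to_graph(cube)
  expect_equal(g$n, 26)
  expect_equal(somatrace:::graph_n_components(g), 1L)
  single <- make_instance(cbind(5, 5, 5), shape)
  gs <- surface_to_graph(single)
  expect_equal(gs$n, 1)
  expect_equal(nrow(gs$edges), 0)
  # random instance: edge set equals brute-force 26-adjacency of surface
  set.seed(31)
  m <- random_connected_mask(31, c(14, 14, 14))
  inst <- make_instance(mask_coords(m), m$shape)
  gr <- surface_to_graph(inst)
  surf <- extract_surface(sparse_mask(inst$idx, inst$shape))
  zyx <- mask_coords(surf)
  expect_equal(gr$n, nrow(zyx))
  want <- NULL
  for (i in seq_len(nrow(zyx) - 1)) {
    d <- abs(zyx[(i + 1):nrow(zyx), , drop = FALSE] -
               rep(zyx[i, ], each = nrow(zyx) - i))
    j <- which(apply(d, 1, max) == 1)
    if (length(j)) want <- rbind(want, cbind(i, i + j))
  }
  got <- unique(t(apply(gr$edges, 1, sort)))
  expect_equal(nrow(got), nrow(want))
  expect_true(all(paste(want[, 1], want[, 2]) %in% paste(got[, 1], got[, 2])))
})

test_that("light-edge coarsening preserves components and halves a path", {
  # path of 8 unit-spaced vertices contracts to 4 under id tie-breaks
  path8 <- structure(list(pos = cbind(0, 0, 0:7), edges = cbind(1:7, 2:8),
                          weight = rep(1, 8), n = 8L,
                          voxel_size = c(1, 1, 1)), class = "surface_graph")
  c1 <- coarsen(path8, 1)
  expect_equal(c1$n, 4)
  expect_equal(somatrace:::graph_n_components(c1), 1L)
  expect_equal(sum(c1$weight), 8)
  # steps = 0 is the identity
  expect_identical(coarsen(path8, 0), path8)
  # components invariant on a random two-component graph
  m <- random_connected_mask(41, c(12, 12, 12))
  inst <- make_instance(mask_coords(m), m$shape)
  g <- surface_to_graph(inst)
  comps0 <- somatrace:::graph_n_components(g)
  g2 <- coarsen(g, 2)
  expect_equal(somatrace:::graph_n_components(g2), comps0)
  expect_gte(g2$n, ceiling(g$n / 4))
})

test_that("local separators split paths and hubs but not complete graphs", {
  mkgraph <- function(edges, n) structure(
    list(pos = cbind(seq_len(n), 0, 0), edges = edges, weight = rep(1, n),
         n = as.integer(n), voxel_size = c(1, 1, 1)),
    class = "surface_graph")
  path7 <- mkgraph(cbind(1:6, 2:7), 7)
  s <- find_local_separator(path7, 4)
  expect_equal(s$vertices, 4L)
  # removal disconnects: verified exhaustively on the path
  expect_equal(length(unique(flood_components(c(1:3, 5:7), c(7, 1, 1), 6))), 2)
  star <- mkgraph(cbind(1, 2:5), 5)
  s2 <- find_local_separator(star, 1)
  expect_equal(s2$vertices, 1L)
  k4 <- mkgraph(t(utils::combn(4, 2)), 4)
  expect_null(find_local_separator(k4, 1))
})

test_that("greedy packing keeps small disjoint separators first", {
  sep <- function(v, q = length(v), cen = c(0, 0, mean(v)))
    structure(list(vertices = as.integer(v), centroid = cen, radius = 1,
                   quality = q), class = "separator")
  a <- sep(1:3); b <- sep(2:6); c <- sep(10:13)
  kept <- pack_separators(list(b, a, c))
  expect_equal(lapply(kept, `[[`, "vertices"), list(1:3, 10:13))
  expect_length(pack_separators(list()), 0)
  disj <- list(sep(1:2), sep(4:5), sep(7:8))
  expect_length(pack_separators(disj), 3)
})

test_that("canonical phantoms skeletonize to the expected topology", {
  shape <- c(24, 24, 80)
  seeds <- function(cen, r = 3) make_seed_set(cen, r, shape)
  nch <- function(tr) tabulate(match(tr$parent, tr$id), nbins = nrow(tr))
  # straight cylinder: a path tree, nodes on-axis, radius near truth
  cyl <- tube_coords(c(11, 11, 5), c(11, 11, 64), 3, shape)
  tr <- skeletonize_instance(make_instance(cyl, shape),
                             seeds(c(11, 11, 5)))[[1]]
  k <- nch(tr)
  expect_equal(sum(k >= 2 & tr$parent != -1), 0)
  expect_equal(sum(k == 0), 1)
  mid <- tr$parent != -1 & tr$x < 55          # away from root and cap
  expect_lt(max(sqrt((tr$y[mid] - 11)^2 + (tr$z[mid] - 11)^2)), 1.5)
  expect_equal(mean(tr$radius[mid]), 3, tolerance = 0.3)
  # every node near the instance envelope
  expect_true(all(tr$x > 0 & tr$x < 80))
  # sphere-only instance: single-node tree
  sph <- ball_coords(c(11, 11, 40), 6, shape)
  tr2 <- skeletonize_instance(make_instance(sph, shape),
                              seeds(c(11, 11, 40), 6))[[1]]
  expect_equal(nrow(tr2), 1)
  expect_equal(tr2$parent, -1L)
  # Y phantom: exactly one branch node, two non-root leaves
  yco <- rbind(tube_coords(c(11, 11, 5), c(11, 11, 40), 2.5, shape),
               tube_coords(c(11, 11, 40), c(4, 18, 70), 2.5, shape),
               tube_coords(c(11, 11, 40), c(18, 4, 70), 2.5, shape))
  tr3 <- skeletonize_instance(make_instance(yco, shape),
                              seeds(c(11, 11, 5)))[[1]]
  k3 <- nch(tr3)
  expect_equal(sum(k3 >= 2 & tr3$parent != -1), 1)
  expect_equal(sum(k3 == 0), 2)
})

test_that("standardize reorders, merges duplicates, and is idempotent", {
  # child listed before its parent
  t1 <- data.frame(id = c(5, 1, 9), type = c(3, 1, 3),
                   x = c(1, 0, 2), y = 0, z = 0, radius = 1,
                   parent = c(1, -1, 5))
  s1 <- standardize(t1)
  expect_identical(s1$id, 1:3)
  expect_true(all(match(s1$parent[-1], s1$id) < s1$id[-1]))
  expect_identical(standardize(s1), s1)
  # coincident nodes merge keeping the max radius
  t2 <- data.frame(id = 1:3, type = c(1, 3, 3), x = c(0, 1, 1), y = 0, z = 0,
                   radius = c(1, 1, 2), parent = c(-1, 1, 2))
  s2 <- standardize(t2)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$radius[2], 2)
  # radius floor
  t3 <- data.frame(id = 1:2, type = c(1, 3), x = c(0, 1), y = 0, z = 0,
                   radius = c(1, 0.01), parent = c(-1, 1))
  expect_equal(standardize(t3, min_radius = 0.5)$radius[2], 0.5)
  # cycles are an error; multiple roots split into a list
  t4 <- data.frame(id = 1:2, type = 3, x = 0:1, y = 0, z = 0, radius = 1,
                   parent = c(2, 1))
  expect_error(standardize(t4), "root|cycl")
  t5 <- data.frame(id = 1:4, type = c(1, 3, 1, 3), x = c(0, 1, 9, 10),
                   y = 0, z = 0, radius = 1, parent = c(-1, 1, -1, 3))
  s5 <- standardize(t5)
  expect_false(inherits(s5, "data.frame"))
  expect_length(s5, 2)
  expect_equal(vapply(s5, nrow, integer(1)), c(2L, 2L))
})

test_that("pipeline skeletons always satisfy the SWC tree invariants", {
  m <- random_connected_mask(55, c(20, 20, 20), fg_target = 0.1)
  inst <- make_instance(mask_coords(m), m$shape)
  cen <- colMeans(mask_coords(m))
  trees <- skeletonize_instance(inst, make_seed_set(cen, 3, m$shape))
  for (tr in trees) {
    expect_s3_class(tr, "skeleton_tree")
    expect_equal(sum(tr$parent == -1), 1)
    expect_identical(tr$id, seq_len(nrow(tr)))
    expect_true(all(tr$radius > 0))
    nonroot <- tr$parent != -1
    expect_true(all(match(tr$parent[nonroot], tr$id) < tr$id[nonroot]))
  }
})
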