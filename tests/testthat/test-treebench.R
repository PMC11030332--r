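# DIADEM-style matching and the decomposed accuracy suite

# small hand-built tree: root with two symmetric subtrees
sym_tree <- function() {
  as_tree(data.frame(id = 1:7, type = c(1, 3, 3, 3, 3, 3, 3),
                     x = c(0, -5, 5, -8, -2, 8, 2),
                     y = c(0, 5, 5, 10, 10, 10, 10),
                     z = 0, radius = 1,
                     parent = c(-1, 1, 1, 2, 2, 3, 3)))
}
as_tree <- function(df) somatrace:::as_skeleton_tree(df)

test_that("identical trees match perfectly; far translations match nothing", {
  spec <- phantom_spec(shape = c(96, 96, 96), n_neurons = 1, depth = 2,
                       branch_prob = 1, seed = 5)
  tr <- generate_tree(spec, 1)
  m <- match_nodes(tr, tr)
  expect_equal(nrow(m$pairs), nrow(tr))
  expect_length(m$unmatched_gold, 0)
  expect_equal(diadem_score(tr, tr), 1.0)
  sc <- decomposed_scores(tr, tr)
  expect_equal(unlist(sc[c("topology", "recall", "branch", "leaf",
                           "direction", "precision")]),
               c(topology = 1, recall = 1, branch = 1, leaf = 1,
                 direction = 1, precision = 1))
  shifted <- tr
  shifted$x <- shifted$x + 3 * match_params()$dist_threshold
  expect_equal(nrow(match_nodes(tr, shifted)$pairs), 0)
  expect_error(match_nodes(tr[0, ], tr), "empty gold")
})

test_that("a displaced node fails the ancestor criterion", {
  # gold path A-B-C; test's B displaced onto a side branch hanging off A
  gold <- as_tree(data.frame(id = 1:3, type = c(1, 3, 3), x = c(0, 10, 20),
                             y = 0, z = 0, radius = 1, parent = c(-1, 1, 2)))
  test <- as_tree(data.frame(id = 1:4, type = c(1, 3, 3, 3),
                             x = c(0, 10, 20, 10.5),
                             y = c(0, 30, 30, 2), z = 0, radius = 1,
                             parent = c(-1, 1, 2, 1)))
  # t4 sits near gold B but its path (direct to root) disagrees with
  # gold's B->A path by more than the tolerance?  here path agrees, so it
  # matches; push it off the path to break the path-length criterion
  test2 <- test
  test2$y[4] <- 7.9   # dt ~ 12.9 vs dg 10: |diff| 2.9 > 0.2 * max(10, 8)
  m <- match_nodes(gold, test2)
  expect_false(2 %in% m$pairs$gold_row)
})

test_that("DIADEM weights critical nodes by subtree terminal count", {
  gold <- sym_tree()
  expect_equal(diadem_score(gold, gold), 1.0)
  # missing one entire symmetric subtree halves the score
  half <- gold[c(1, 2, 4, 5), ]
  expect_equal(diadem_score(gold, half), 0.5)
  # empty-of-matches test tree scores 0
  far <- gold
  far$x <- far$x + 1000
  expect_equal(diadem_score(gold, far), 0)
  # removing a leaf subtree reduces the score by its exact weight share
  cw <- somatrace:::critical_weights(gold)
  total <- sum(cw$weight)
  noleaf <- gold[gold$id != 7, ]
  # node 7 is a terminal (weight 1) and its loss also demotes nothing else
  expect_equal(diadem_score(gold, noleaf), (total - 1) / total)
  expect_error(diadem_score(gold[1, ], gold[1, ]), "critical")
})

test_that("decomposed scores react to leaf deletion and direction flips", {
  spec <- phantom_spec(shape = c(96, 96, 96), n_neurons = 1, depth = 2,
                       branch_prob = 1, seed = 9)
  tr <- generate_tree(spec, 1)
  leaves <- which(somatrace:::tree_n_children(tr) == 0)
  drop <- leaves[1:2]
  pruned <- somatrace:::as_skeleton_tree(tr[-drop, ])
  sc <- decomposed_scores(tr, pruned)
  expect_equal(sc$leaf, (length(leaves) - 2) / length(leaves))
  expect_equal(sc$recall, (nrow(tr) - 2) / nrow(tr))
  # monotone degradation: deleting test nodes never raises recall
  sc_full <- decomposed_scores(tr, tr)
  expect_lte(sc$recall, sc_full$recall)
  expect_lte(sc$leaf, sc_full$leaf)
  # direction: flip one of four matched branch nodes' parent orientation.
  # gold is a comb: a chain of four branch nodes each carrying two leaves;
  # in the test copy the last branch node is reached via a short overshoot
  # so its parent-pointing vector reverses while path lengths stay close.
  comb <- function() {
    nodes <- data.frame(id = 1, type = 1, x = 0, y = 0, z = 0, radius = 1,
                        parent = -1)
    nid <- 1
    prev <- 1
    for (i in 1:4) {
      nid <- nid + 1
      nodes <- rbind(nodes, data.frame(id = nid, type = 3, x = 10 * i,
                                       y = 0, z = 0, radius = 1,
                                       parent = prev))
      ci <- nid
      for (s in c(-3, 3)) {
        nid <- nid + 1
        nodes <- rbind(nodes, data.frame(id = nid, type = 3, x = 10 * i,
                                         y = s, z = 0, radius = 1,
                                         parent = ci))
      }
      prev <- ci
    }
    as_tree(nodes)
  }
  gold <- comb()
  test <- gold
  # insert an overshoot node past the last branch node and reroute it
  over <- data.frame(id = 14, type = 3, x = 42, y = 0, z = 0, radius = 1,
                     parent = 8)           # node 8 is the third branch node
  test <- as_tree(rbind(test, over))
  test$parent[test$id == 11] <- 14         # last branch node hangs off it
  p <- match_params(dist_threshold = 8, path_tolerance = 0.5)
  scd <- decomposed_scores(gold, test, p)
  expect_equal(scd$branch, 1)
  expect_equal(scd$direction, 0.75)
})

test_that("spurious test nodes lower precision but not recall", {
  gold <- sym_tree()
  noisy <- rbind(gold, data.frame(id = 8:10, type = 3,
                                  x = c(40, 41, 42), y = 40, z = 0,
                                  radius = 1, parent = c(1, 8, 9)))
  noisy <- somatrace:::as_skeleton_tree(noisy)
  sc <- decomposed_scores(gold, noisy)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 7 / 10)
  expect_lte(sc$precision, decomposed_scores(gold, gold)$precision)
})

test_that("cohort yield counts scores within two sample deviations", {
  expect_equal(cohort_yield(c(1, 1, 1, 1)), 1)
  expect_equal(cohort_yield(c(1, 1, 1, 0)), 1)   # sd .5, all within 2 sd
  x <- c(rep(1, 9), 0)
  expect_equal(cohort_yield(x),
               mean(abs(x - mean(x)) <= 2 * stats::sd(x)))
  expect_error(cohort_yield(1), "at least 2")
})

test_that("seed scoring applies the one-radius tolerance one-to-one", {
  gold <- data.frame(id = 1:3, z_um = c(10, 40, 70), y_um = 20, x_um = 20,
                     radius_um = 5)
  hit <- data.frame(z_um = c(10, 40, 70), y_um = 20, x_um = 20)
  s <- score_seeds(hit, gold)
  expect_equal(c(s$recall, s$precision, s$f1), c(1, 1, 1))
  # 3 true + 3 far spurious: recall 1, precision 0.5
  sp <- rbind(hit, data.frame(z_um = c(110, 120, 130), y_um = 90, x_um = 90))
  s2 <- score_seeds(sp, gold)
  expect_equal(c(s2$recall, s2$precision), c(1, 0.5))
  # offsets at 0.9 vs 1.1 gold radii: only the former counts
  jit <- data.frame(z_um = c(10 + 4.5, 40 + 5.5, 70), y_um = 20, x_um = 20)
  s3 <- score_seeds(jit, gold)
  expect_equal(s3$tp, 2L)
  # empty detections: recall 0, precision not applicable
  s4 <- score_seeds(hit[0, ], gold)
  expect_equal(s4$recall, 0)
  expect_true(is.na(s4$precision))
  expect_error(score_seeds(hit, gold[0, ]), "non-empty")
})
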