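#' Matching parameters for skeleton comparison
#'
#' @param dist_threshold node matching radius in µm; 8 µm is the diameter
#'   of the largest branch points on typical gold-standard datasets.
#' @param path_tolerance relative tolerance on path-length agreement
#'   between a node and its nearest matched ancestor, in (0, 1).
#' @return A `match_params` object.
#' @export
match_params <- function(dist_threshold = 8, path_tolerance = 0.2) {
  if (!(dist_threshold > 0)) stop("dist_threshold must be > 0")
  if (!(path_tolerance > 0 && path_tolerance < 1))
    stop("path_tolerance must be in (0, 1)")
  structure(list(dist_threshold = dist_threshold,
                 path_tolerance = path_tolerance), class = "match_params")
}

# path length (µm) from row v up to ancestor row a (NA if a not an ancestor)
path_len_to <- function(tree, pr, elen, v, a) {
  d <- 0
  while (!is.na(v)) {
    if (v == a) return(d)
    d <- d + elen[v]
    v <- pr[v]
  }
  NA_real_
}

#' Match gold-standard nodes to test nodes (three-step criterion)
#'
#' For each gold node, candidate test nodes are those within
#' `dist_threshold` µm.  A candidate is confirmed iff (a) the gold node is
#' the root, or (b) some already-matched gold ancestor (climbing from the
#' nearest upward) has a match that is an ancestor of the candidate, and
#' the path length from node to that ancestor agrees between the two
#' trees within `path_tolerance` (relative to the gold path length, with
#' the distance threshold as a lower bound on the denominator).  Gold
#' nodes are processed root-first (by depth) and conflicts resolved
#' greedily by smallest Euclidean distance; the result is one-to-one.
#'
#' @param gold,test standardized `skeleton_tree`s.
#' @param params a [match_params()].
#' @return A `node_match`: data frame `pairs` (`gold_row`, `test_row`,
#'   `dist`), plus `unmatched_gold`, `unmatched_test` (row indices).
#' @export
match_nodes <- function(gold, test, params = match_params()) {
  gold <- as_skeleton_tree(gold)
  if (!nrow(gold)) stop("empty gold tree")
  test <- as_skeleton_tree(test)
  ng <- nrow(gold); nt <- nrow(test)
  match_of <- rep(NA_integer_, ng)   # gold row -> test row
  if (nt > 0) {
    gp <- tree_parent_row(gold); ge <- tree_edge_len(gold)
    tp <- tree_parent_row(test); te <- tree_edge_len(test)
    gdepth <- tree_depth(gold)
    used <- logical(nt)
    dmat <- outer(gold$x, test$x, "-")^2 + outer(gold$y, test$y, "-")^2 +
      outer(gold$z, test$z, "-")^2
    dmat <- sqrt(dmat)
    is_anc <- function(a, v) {  # is test row a an ancestor of test row v?
      v <- tp[v]
      while (!is.na(v)) {
        if (v == a) return(TRUE)
        v <- tp[v]
      }
      FALSE
    }
    for (g in order(gdepth)) {
      cand <- which(dmat[g, ] <= params$dist_threshold & !used)
      if (!length(cand)) next
      cand <- cand[order(dmat[g, cand])]
      for (t in cand) {
        if (gold$parent[g] == -1L) {
          match_of[g] <- t; used[t] <- TRUE; break
        }
        # climb the matched gold ancestors until one confirms the pair
        ok <- FALSE
        a <- gp[g]
        while (!is.na(a)) {
          if (!is.na(match_of[a])) {
            at <- match_of[a]
            if (is_anc(at, t)) {
              dg <- path_len_to(gold, gp, ge, g, a)
              dt <- path_len_to(test, tp, te, t, at)
              if (abs(dg - dt) <=
                  params$path_tolerance * max(dg, params$dist_threshold)) {
                ok <- TRUE
                break
              }
            }
          }
          a <- gp[a]
        }
        if (ok) {
          match_of[g] <- t; used[t] <- TRUE; break
        }
      }
    }
  }
  matched <- which(!is.na(match_of))
  pairs <- data.frame(gold_row = matched, test_row = match_of[matched],
                      dist = if (length(matched) && nt)
                        sqrt((gold$x[matched] - test$x[match_of[matched]])^2 +
                             (gold$y[matched] - test$y[match_of[matched]])^2 +
                             (gold$z[matched] - test$z[match_of[matched]])^2)
                      else numeric(0))
  structure(list(pairs = pairs,
                 unmatched_gold = setdiff(seq_len(ng), matched),
                 unmatched_test = setdiff(seq_len(nt), pairs$test_row)),
            class = "node_match")
}

# critical nodes (non-root branch + terminal rows) and their weights
# (number of terminals in the subtree; terminals weigh 1)
critical_weights <- function(tree) {
  pr <- tree_parent_row(tree)
  nterm <- as.numeric(tree_n_children(tree) == 0L)
  # accumulate terminal counts up the tree (children before parents holds
  # for standardized trees; otherwise iterate to fixed point)
  for (v in rev(seq_len(nrow(tree)))) {
    p <- pr[v]
    if (!is.na(p)) nterm[p] <- nterm[p] + nterm[v]
  }
  rows <- sort(unique(c(tree_branch_rows(tree), tree_terminal_rows(tree))))
  rows <- rows[tree$parent[rows] != -1L]  # the root is never critical
  list(rows = rows, weight = nterm[rows])
}

#' DIADEM-style topological similarity score
#'
#' Fraction of gold critical-node weight recovered by the test skeleton:
#' critical nodes are the gold branch and terminal nodes, each weighted by
#' the number of terminals in its subtree (terminals weigh 1, the root is
#' excluded), and a critical node counts iff matched under the three-step
#' criterion of [match_nodes()].  Identical trees score exactly 1.
#'
#' @inheritParams match_nodes
#' @return A fraction in `[0, 1]`.
#' @export
diadem_score <- function(gold, test, params = match_params()) {
  gold <- as_skeleton_tree(gold)
  cw <- critical_weights(gold)
  if (!length(cw$rows)) stop("gold tree has no critical (branch/leaf) nodes")
  m <- match_nodes(gold, test, params)
  matched <- cw$rows %in% m$pairs$gold_row
  sum(cw$weight[matched]) / sum(cw$weight)
}

#' Decomposed topological accuracy scores
#'
#' Per-category accuracy around the same matching: `topology` (the DIADEM
#' aggregate), `recall` (matched gold nodes / gold nodes), `branch` and
#' `leaf` (likewise over gold branch and terminal nodes), `direction`
#' (among matched gold branch nodes, fraction whose test match's
#' parent-pointing unit vector has positive dot product with the gold
#' one), and `precision` (matched test nodes / test nodes).  A category
#' with no members is reported as `NA` (not applicable), never `NaN`.
#'
#' @inheritParams match_nodes
#' @return A `tree_score`: one-row data frame with columns `topology`,
#'   `recall`, `branch`, `leaf`, `direction`, `precision`.
#' @export
decomposed_scores <- function(gold, test, params = match_params()) {
  gold <- as_skeleton_tree(gold)
  test <- as_skeleton_tree(test)
  m <- match_nodes(gold, test, params)
  matched_gold <- m$pairs$gold_row
  frac <- function(rows) {
    if (!length(rows)) return(NA_real_)
    mean(rows %in% matched_gold)
  }
  brows <- tree_branch_rows(gold)
  dir_score <- NA_real_
  mb <- intersect(brows, matched_gold)
  if (length(mb)) {
    gp <- tree_parent_row(gold)
    tp <- tree_parent_row(test)
    ok <- vapply(mb, function(g) {
      t <- m$pairs$test_row[m$pairs$gold_row == g]
      pgt <- tp[t]
      if (is.na(pgt)) return(NA)  # matched to the test root: no direction
      vg <- c(gold$x[gp[g]] - gold$x[g], gold$y[gp[g]] - gold$y[g],
              gold$z[gp[g]] - gold$z[g])
      vt <- c(test$x[pgt] - test$x[t], test$y[pgt] - test$y[t],
              test$z[pgt] - test$z[t])
      sum(vg * vt) > 0
    }, logical(1))
    dir_score <- if (all(is.na(ok))) NA_real_ else mean(ok, na.rm = TRUE)
  }
  score <- data.frame(
    topology = tryCatch(diadem_score(gold, test, params),
                        error = function(e) NA_real_),
    recall = frac(seq_len(nrow(gold))),
    branch = frac(brows),
    leaf = frac(tree_terminal_rows(gold)),
    direction = dir_score,
    precision = if (nrow(test) == 0) NA_real_
                else nrow(m$pairs) / nrow(test))
  class(score) <- c("tree_score", "data.frame")
  score
}

#' Cohort yield of topology scores
#'
#' Fraction of reconstructions whose topology score lies within 2 sample
#' standard deviations of the cohort mean.
#'
#' @param scores numeric vector of topology fractions (length >= 2).
#' @return A fraction in `[0, 1]`.
#' @export
cohort_yield <- function(scores) {
  if (length(scores) < 2) stop("cohort_yield needs at least 2 scores")
  mean(abs(scores - mean(scores)) <= 2 * stats::sd(scores))
}

#' Score detected seeds against gold somas
#'
#' One-to-one greedy nearest matching: a detection matches a gold soma iff
#' their center distance is at most the gold soma's radius (the "1 radius
#' width" tolerance).  Recall is TP / gold count, precision TP / detected
#' count (`NA` when nothing was detected), F1 their harmonic mean.
#'
#' @param detected a `seed_set` or a data frame with columns
#'   `z_um`, `y_um`, `x_um`.
#' @param gold data frame with columns `z_um`, `y_um`, `x_um`, `radius_um`.
#' @return List with `recall`, `precision`, `f1`, `tp`.
#' @export
score_seeds <- function(detected, gold) {
  if (!nrow(gold)) stop("gold soma list must be non-empty")
  det <- if (inherits(detected, "seed_set")) as.data.frame(detected)
         else detected
  nd <- nrow(det)
  if (nd == 0)
    return(list(recall = 0, precision = NA_real_, f1 = NA_real_, tp = 0L))
  dmat <- outer(gold$z_um, det$z_um, "-")^2 +
    outer(gold$y_um, det$y_um, "-")^2 + outer(gold$x_um, det$x_um, "-")^2
  dmat <- sqrt(dmat)
  ord <- order(dmat)
  gused <- logical(nrow(gold)); dused <- logical(nd)
  tp <- 0L
  for (k in ord) {
    gi <- (k - 1) %% nrow(gold) + 1
    di <- (k - 1) %/% nrow(gold) + 1
    if (gused[gi] || dused[di]) next
    if (dmat[gi, di] > gold$radius_um[gi]) next  # outside this soma's radius
    gused[gi] <- TRUE; dused[di] <- TRUE
    tp <- tp + 1L
  }
  recall <- tp / nrow(gold)
  precision <- tp / nd
  f1 <- if (recall + precision > 0) 2 * recall * precision /
    (recall + precision) else 0
  list(recall = recall, precision = precision, f1 = f1, tp = tp)
}
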