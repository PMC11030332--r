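#' Surface adjacency graph of a cell instance
#'
#' Vertices are the instance's surface voxels (active voxels with an
#' inactive 6-neighbor), positioned at voxel centers in µm; edges join
#' 26-adjacent surface voxels.  This graph realization of the surface mesh
#' is all the separator skeletonizer needs.
#'
#' @param instance a `cell_instance` (or a `sparse_mask`).
#' @return A `surface_graph`: `pos` (n x 3 µm, z/y/x columns), `edges`
#'   (m x 2, 1-based), per-vertex `weight` (merged-voxel count, initially
#'   1), `n`, and `voxel_size`.
#' @export
surface_to_graph <- function(instance) {
  if (!length(instance$idx)) stop("cannot build a graph from an empty instance")
  surf <- mask_surface_cpp(instance$idx, instance$shape)
  pos <- idx_to_zyx(surf, instance$shape) *
    rep(instance$voxel_size, each = length(surf))
  edges <- surface_edges_cpp(surf, instance$shape)
  structure(list(pos = unname(pos), edges = edges,
                 weight = rep(1, length(surf)), n = length(surf),
                 voxel_size = instance$voxel_size),
            class = "surface_graph")
}

#' @export
print.surface_graph <- function(x, ...) {
  cat(sprintf("surface_graph: %d vertices, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

# CSR adjacency (0-based) for the C++ search kernels
graph_csr <- function(graph) {
  n <- graph$n
  e <- graph$edges
  u <- c(e[, 1], e[, 2]) - 1L
  v <- c(e[, 2], e[, 1]) - 1L
  ord <- order(u, v)
  u <- u[ord]; v <- v[ord]
  deg <- tabulate(u + 1L, nbins = n)
  list(xadj = c(0L, cumsum(deg)), adjncy = v)
}

graph_n_components <- function(graph) {
  csr <- graph_csr(graph)
  comp <- graph_components_cpp(csr$xadj, csr$adjncy, rep(TRUE, graph$n))
  if (graph$n) max(comp) else 0L
}

#' Coarsen a surface graph by light-edge matching
#'
#' Each step computes a maximal matching that prefers the shortest edges
#' (ties broken by vertex id), contracts every matched pair to its
#' weight-averaged midpoint, merges vertex weights, and deduplicates edges.
#' Contraction can never split or join components, so the component count
#' is invariant (asserted per step); one step removes at most half the
#' vertices.
#'
#' @param graph a `surface_graph`.
#' @param steps number of matching/contraction passes (>= 0).
#' @return A coarsened `surface_graph`.
#' @export
coarsen <- function(graph, steps = 2) {
  if (steps < 0) stop("steps must be >= 0")
  if (steps == 0) return(graph)
  comps0 <- graph_n_components(graph)
  for (s in seq_len(steps)) {
    if (nrow(graph$edges) == 0) break
    r <- coarsen_step_cpp(graph$pos, graph$weight, graph$edges)
    graph <- structure(list(pos = r$pos, edges = r$edges, weight = r$weight,
                            n = nrow(r$pos), voxel_size = graph$voxel_size),
                       class = "surface_graph")
    stopifnot(graph_n_components(graph) == comps0)
  }
  graph
}

make_separator <- function(graph, vertices) {
  w <- graph$weight[vertices]
  centroid <- colSums(graph$pos[vertices, , drop = FALSE] * w) / sum(w)
  rad <- mean(sqrt(rowSums(
    (graph$pos[vertices, , drop = FALSE] -
       rep(centroid, each = length(vertices)))^2)))
  structure(list(vertices = as.integer(vertices), centroid = unname(centroid),
                 radius = rad, quality = length(vertices)),
            class = "separator")
}

#' Find a local separator by ball growth
#'
#' Grows a breadth-ordered ball from `seed_vertex`; before each expansion
#' the front (unvisited neighbors of the ball) is tested for connectivity.
#' When the front splits into two or more induced components the ball is a
#' separator, which is then greedily minimized: vertices are dropped,
#' outermost first, while the subgraph induced on the set's neighbors still
#' splits into at least two components.  Returns `NULL` when the front
#' never splits before the component is exhausted (closed surfaces such as
#' spheres, or complete graphs) or before the ball exceeds `max_ball`.
#'
#' @param graph a `surface_graph`.
#' @param seed_vertex 1-based vertex index.
#' @param max_ball growth cap (vertices).
#' @return A `separator` (`vertices`, µm `centroid`, `radius` = mean
#'   vertex-to-centroid distance, `quality` = cardinality) or `NULL`.
#' @export
find_local_separator <- function(graph, seed_vertex, max_ball = 4000) {
  if (seed_vertex < 1 || seed_vertex > graph$n) stop("seed_vertex not in graph")
  csr <- graph_csr(graph)
  r <- separator_search_cpp(csr$xadj, csr$adjncy, as.integer(seed_vertex),
                            as.integer(max_ball), TRUE)
  if (!r$found) return(NULL)
  make_separator(graph, r$vertices)
}

#' Sweep a graph for packed local separators
#'
#' Vertices are visited in deterministic ascending order, skipping vertices
#' already covered by an accepted separator; each found separator is kept
#' iff vertex-disjoint from all previously kept ones (greedy packing in
#' discovery order).  A connected component on which no front ever splits
#' (e.g. an isolated closed sphere) contributes one whole-component
#' separator so that every component yields at least one skeleton node.
#'
#' @param graph a `surface_graph`.
#' @param max_ball growth cap per search.
#' @return List of `separator` objects (pairwise vertex-disjoint).
#' @export
find_separators <- function(graph, max_ball = 4000) {
  csr <- graph_csr(graph)
  r <- local_separators_cpp(csr$xadj, csr$adjncy, as.integer(max_ball))
  seps <- lapply(seq_len(r$n_sep), function(i)
    make_separator(graph, which(r$sep_id == i)))
  comp <- graph_components_cpp(csr$xadj, csr$adjncy, rep(TRUE, graph$n))
  has_sep <- unique(comp[r$sep_id > 0])
  for (cid in setdiff(unique(comp), has_sep))
    seps[[length(seps) + 1L]] <- make_separator(graph, which(comp == cid))
  seps
}

#' Greedy weighted packing of separator candidates
#'
#' Candidates are ordered by ascending cardinality (thin separators are the
#' better waist estimates), ties broken by centroid lexicographic order,
#' and kept iff vertex-disjoint from everything already kept.
#'
#' @param candidates list of `separator` objects from the same graph.
#' @return The kept, pairwise-disjoint subset, in packing order.
#' @export
pack_separators <- function(candidates) {
  if (!length(candidates)) return(list())
  qual <- vapply(candidates, `[[`, numeric(1), "quality")
  cen <- t(vapply(candidates, `[[`, numeric(3), "centroid"))
  ord <- order(qual, cen[, 1], cen[, 2], cen[, 3])
  used <- integer(0)
  kept <- list()
  for (i in ord) {
    v <- candidates[[i]]$vertices
    if (any(v %in% used)) next
    used <- c(used, v)
    kept[[length(kept) + 1L]] <- candidates[[i]]
  }
  kept
}

# Quotient the surface graph by the packed separators.  Every separator
# becomes a skeleton node.  Connected regions of uncovered vertices are
# classified by how many distinct separators they touch: a region
# touching exactly two acts as an edge between them (the ordinary band
# between successive waists); regions touching one (terminal caps) or
# three and more (junction hubs) become skeleton nodes of their own,
# which is what preserves branch points and leaf tips.  Directly
# adjacent separators are connected as well.
skeleton_quotient <- function(graph, seps) {
  n <- graph$n
  assign <- integer(n)
  for (i in seq_along(seps)) assign[seps[[i]]$vertices] <- i
  csr <- graph_csr(graph)
  region <- graph_components_cpp(csr$xadj, csr$adjncy, assign == 0L)
  nsep <- length(seps)
  nreg <- if (any(region > 0)) max(region) else 0L
  e <- graph$edges
  su <- assign[e[, 1]]; sv <- assign[e[, 2]]
  ru <- region[e[, 1]]; rv <- region[e[, 2]]
  # sep-sep contacts
  ss <- cbind(pmin(su, sv), pmax(su, sv))[su > 0 & sv > 0 & su != sv, ,
                                          drop = FALSE]
  # sep-region contacts
  sr <- rbind(cbind(su, rv)[su > 0 & rv > 0, , drop = FALSE],
              cbind(sv, ru)[sv > 0 & ru > 0, , drop = FALSE])
  sr <- unique(sr)
  nodes <- seps
  pairs <- ss
  for (r in seq_len(nreg)) {
    touch <- sort(unique(sr[sr[, 2] == r, 1]))
    if (length(touch) == 2L) {
      pairs <- rbind(pairs, touch)
    } else {
      nodes[[length(nodes) + 1L]] <- make_separator(graph,
                                                    which(region == r))
      rid <- length(nodes)
      if (length(touch))
        pairs <- rbind(pairs, cbind(touch, rid))
    }
  }
  pairs <- unique(pairs)
  dimnames(pairs) <- NULL
  list(nodes = nodes, edges = pairs, n_sep = nsep)
}

#' Build rooted skeleton trees from packed separators
#'
#' The surface graph is quotiented by the packed separators: each
#' separator becomes a skeleton node (µm centroid, mean vertex-to-centroid
#' radius), and each connected region of uncovered vertices becomes one as
#' well, which is what preserves junction regions as branch points and
#' terminal caps as leaf tips.  Nodes connect when the corresponding
#' vertex sets share a surface edge, i.e. when two separators are joined
#' by a path crossing no third separator.  Each tree is rooted at a type-1
#' node at the seed centroid carrying the seed's equivalent-sphere radius;
#' quotient nodes lying within the soma radius are absorbed into that root
#' (the soma surface is one cell body, not a chain of branch waists).
#' Remaining nodes join the seed with the shortest geodesic path in a
#' multi-source shortest-path search, and parent links follow that
#' forest, giving every node a single unidirectional path back to its
#' seed.  Non-root nodes get SWC type 3 (dendrite).
#'
#' @param graph the (coarsened) `surface_graph` the separators live on.
#' @param packed list of pairwise-disjoint `separator` objects.
#' @param seeds a `seed_set`; only instances whose ids appear in
#'   `seed_ids` (default: all) are used as roots.
#' @param seed_ids seed instance ids contained in this cell.
#' @return Named list of `skeleton_tree` data frames (one per seed), names
#'   `seed<ID>`.
#' @export
build_trees <- function(graph, packed, seeds,
                        seed_ids = vapply(seeds$instances, `[[`, integer(1),
                                          "id")) {
  if (!length(packed)) stop("no separators to build trees from")
  use <- Filter(function(s) s$id %in% seed_ids, seeds$instances)
  if (!length(use)) stop("no seeds mapped into this instance")
  q <- skeleton_quotient(graph, packed)
  nq <- length(q$nodes)
  cen <- t(vapply(q$nodes, `[[`, numeric(3), "centroid"))
  rad <- vapply(q$nodes, `[[`, numeric(1), "radius")
  nseed <- length(use)
  # soma absorption: quotient nodes inside a seed's soma radius collapse
  # into that seed's root (the soma surface is one body, not branch waists)
  scen <- t(vapply(use, `[[`, numeric(3), "centroid"))
  sdist <- sqrt(pmax(outer(rowSums(cen^2), rep(1, nseed)) -
                2 * cen %*% t(scen) + outer(rep(1, nq), rowSums(scen^2)), 0))
  owner_seed <- apply(sdist, 1, which.min)
  inside <- sdist[cbind(seq_len(nq), owner_seed)] <=
    1.05 * vapply(use, `[[`, numeric(1), "radius")[owner_seed]
  for (i in seq_len(nseed))
    if (min(sdist[, i]) > max(4 * use[[i]]$radius, 20))
      stop("no separator near seed ", use[[i]]$id, " (nearest node ",
           sprintf("%.1f", min(sdist[, i])), " um away)")
  # contracted node set: one root per seed, then the unabsorbed nodes
  map <- integer(nq)
  map[inside] <- owner_seed[inside]
  free <- which(!inside)
  map[free] <- nseed + seq_along(free)
  ncon <- nseed + length(free)
  cpos <- rbind(scen, cen[free, , drop = FALSE])
  crad <- c(vapply(use, `[[`, numeric(1), "radius"), rad[free])
  ed <- unique(cbind(pmin(map[q$edges[, 1]], map[q$edges[, 2]]),
                     pmax(map[q$edges[, 1]], map[q$edges[, 2]])))
  ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
  # a seed whose soma absorbed nothing still needs a connection
  for (i in seq_len(nseed))
    if (!any(ed == i) && ncon > nseed) {
      d2 <- rowSums((cpos[(nseed + 1):ncon, , drop = FALSE] -
                       rep(scen[i, ], each = ncon - nseed))^2)
      ed <- rbind(ed, c(i, nseed + which.min(d2)))
    }
  adj <- vector("list", ncon)
  wts <- vector("list", ncon)
  if (nrow(ed))
    for (k in seq_len(nrow(ed))) {
      a <- ed[k, 1]; b <- ed[k, 2]
      w <- sqrt(sum((cpos[a, ] - cpos[b, ])^2))
      adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], w)
      adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], w)
    }
  # multi-source Dijkstra: each node joins the seed with the shortest
  # geodesic path; parent links follow the shortest-path forest
  dist <- rep(Inf, ncon)
  owner <- integer(ncon)
  parent <- integer(ncon)
  done <- logical(ncon)
  dist[seq_len(nseed)] <- 0
  owner[seq_len(nseed)] <- seq_len(nseed)
  order_out <- integer(0)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    v <- cand[which.min(dist[cand])]
    done[v] <- TRUE
    order_out <- c(order_out, v)
    nb <- adj[[v]]
    if (length(nb))
      for (j in seq_along(nb)) {
        u <- nb[j]
        nd <- dist[v] + wts[[v]][j]
        if (nd < dist[u] - 1e-12) {
          dist[u] <- nd
          owner[u] <- owner[v]
          parent[u] <- v
        }
      }
  }
  if (any(!done))
    warning(sum(!done), " skeleton node(s) unreachable from any root; dropped")
  trees <- list()
  for (i in seq_len(nseed)) {
    s <- use[[i]]
    nodes <- order_out[owner[order_out] == i & order_out != i]
    newid <- integer(ncon)
    newid[i] <- 1L
    newid[nodes] <- seq_along(nodes) + 1L
    pv <- parent[nodes]
    df <- data.frame(
      id = c(1L, seq_along(nodes) + 1L),
      type = c(1L, rep(3L, length(nodes))),
      x = c(cpos[i, 3], cpos[nodes, 3]),
      y = c(cpos[i, 2], cpos[nodes, 2]),
      z = c(cpos[i, 1], cpos[nodes, 1]),
      radius = c(crad[i], crad[nodes]),
      parent = c(-1L, newid[pmax(pv, 1L)]))
    trees[[paste0("seed", s$id)]] <- as_skeleton_tree(df)
  }
  trees
}

#' Skeletonize one cell instance into standardized SWC trees
#'
#' Full skeletonization pass: surface graph, `coarsen_steps` rounds of
#' light-edge matching, local-separator sweep with greedy packing, tree
#' construction rooted at each contained seed, and standardization.
#'
#' @param instance a `cell_instance` from [split_cells()].
#' @param seeds the `seed_set`.
#' @param coarsen_steps surface coarsening passes (2 is suited to ~1 µm
#'   voxels; 4 for sub-µm sampling).
#' @param max_ball separator growth cap.
#' @param min_radius node radius floor in µm; default half the smallest
#'   voxel dimension.
#' @return Named list of standardized `skeleton_tree`s.
#' @export
skeletonize_instance <- function(instance, seeds, coarsen_steps = 2,
                                 max_ball = 4000, min_radius = NULL) {
  min_radius <- min_radius %||% (min(instance$voxel_size) / 2)
  g <- surface_to_graph(instance)
  g <- coarsen(g, coarsen_steps)
  seps <- find_separators(g, max_ball)
  trees <- build_trees(g, seps, seeds, seed_ids = instance$seed_ids)
  lapply(trees, standardize, min_radius = min_radius)
}

as_skeleton_tree <- function(df) {
  stopifnot(all(c("id", "type", "x", "y", "z", "radius", "parent") %in%
                  names(df)))
  df <- df[, c("id", "type", "x", "y", "z", "radius", "parent")]
  df$id <- as.integer(df$id)
  df$type <- as.integer(df$type)
  df$parent <- as.integer(df$parent)
  rownames(df) <- NULL
  class(df) <- c("skeleton_tree", "data.frame")
  df
}

#' Standardize a skeleton tree
#'
#' Community-standard SWC hygiene: node ids are re-indexed 1..N in
#' parent-before-child (breadth-first) order; coincident nodes are merged
#' keeping the largest radius; zero-length parent-child segments are
#' collapsed; radii are floored at `min_radius`; the root keeps type 1 and
#' parent -1.  The operation is idempotent.  Cyclic parent links raise an
#' error; a tree with several roots is split and a list of standardized
#' trees is returned.
#'
#' @param tree a `skeleton_tree` (or SWC-shaped data frame).
#' @param min_radius radius floor in µm.
#' @return A standardized `skeleton_tree`, or a list of them when the
#'   input had multiple roots.
#' @export
standardize <- function(tree, min_radius = 0.5) {
  tree <- as_skeleton_tree(tree)
  if (!nrow(tree)) stop("empty tree")
  if (anyDuplicated(tree$id)) stop("duplicate node ids")
  rootpos <- which(tree$parent == -1L)
  if (!length(rootpos)) stop("tree has no root (parent -1)")
  if (length(rootpos) > 1L) {
    comp <- tree_component(tree, rootpos)
    return(lapply(seq_along(rootpos), function(i)
      standardize(tree[comp == i, , drop = FALSE], min_radius)))
  }
  id2row <- match(tree$parent, tree$id)
  if (any(is.na(id2row) & tree$parent != -1L))
    stop("parent id not present in tree")
  n <- nrow(tree)
  # cycle check + children lists
  children <- vector("list", n)
  for (r in seq_len(n)) {
    p <- id2row[r]
    if (!is.na(p)) children[[p]] <- c(children[[p]], r)
  }
  order_bfs <- integer(0)
  queue <- rootpos
  seen <- logical(n)
  seen[rootpos] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_bfs <- c(order_bfs, v)
    for (u in children[[v]]) {
      if (seen[u]) stop("cyclic parent links")
      seen[u] <- TRUE
      queue <- c(queue, u)
    }
  }
  if (length(order_bfs) < n) stop("cyclic parent links")
  # merge coincident nodes: representative = earliest in BFS order
  key <- paste(tree$x, tree$y, tree$z)
  rep_row <- integer(n)
  first_of <- new.env(parent = emptyenv())
  for (v in order_bfs) {
    k <- key[v]
    f <- get0(k, envir = first_of)
    if (is.null(f)) {
      assign(k, v, envir = first_of)
      rep_row[v] <- v
    } else {
      rep_row[v] <- f
    }
  }
  radius <- tree$radius
  for (v in seq_len(n))
    if (rep_row[v] != v)
      radius[rep_row[v]] <- max(radius[rep_row[v]], radius[v])
  keep <- order_bfs[rep_row[order_bfs] == order_bfs]
  newid <- integer(n)
  newid[keep] <- seq_along(keep)
  out <- data.frame(
    id = seq_along(keep),
    type = ifelse(keep == rootpos, 1L, tree$type[keep]),
    x = tree$x[keep], y = tree$y[keep], z = tree$z[keep],
    radius = pmax(radius[keep], min_radius),
    parent = vapply(keep, function(v) {
      if (v == rootpos) return(-1L)
      p <- id2row[v]
      p <- if (is.na(p)) NA_integer_ else rep_row[p]
      # collapse chains of merged/coincident ancestors
      while (!is.na(p) && key[p] == key[v]) {
        pp <- id2row[p]
        p <- if (is.na(pp)) NA_integer_ else rep_row[pp]
      }
      if (is.na(p)) -1L else newid[p]
    }, integer(1)))
  out <- as_skeleton_tree(out)
  # a collapse may have produced a second "-1" parent; reattach to root
  extra <- which(out$parent == -1L & out$id != 1L)
  if (length(extra)) out$parent[extra] <- 1L
  out
}

# component id (by root) for multi-root trees
tree_component <- function(tree, rootpos) {
  id2row <- match(tree$parent, tree$id)
  comp <- integer(nrow(tree))
  comp[rootpos] <- seq_along(rootpos)
  repeat {
    todo <- which(comp == 0L)
    if (!length(todo)) break
    progressed <- FALSE
    for (v in todo) {
      p <- id2row[v]
      if (!is.na(p) && comp[p] != 0L) {
        comp[v] <- comp[p]
        progressed <- TRUE
      }
    }
    if (!progressed) stop("nodes not attached to any root")
  }
  comp
}
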