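#' Read and write SWC skeleton files
#'
#' The SWC dialect used throughout: whitespace-separated columns
#' `id type x y z radius parent`, `#` comment lines, coordinates and radii
#' in µm, ids starting at 1, root parent -1.  Numbers are written with the
#' shortest decimal representation that round-trips to the same double, so
#' write-then-read is an identity on standardized trees and outputs are
#' byte-stable across runs.
#'
#' @param path SWC file path.
#' @param reorder if `TRUE` (default) a file listing children before
#'   parents is reordered via [standardize()]; if `FALSE` that is an error.
#' @return [read_swc()]: a `skeleton_tree`; [write_swc()]: `path`.
#' @export
read_swc <- function(path, reorder = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- trimws(lines[keep])
  if (!length(lines)) stop("no nodes in SWC file: ", path)
  fields <- strsplit(lines, "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC line ", which(keep)[bad[1]], " in ", path)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m))
    stop("non-numeric field in SWC file ", path)
  tree <- as_skeleton_tree(data.frame(
    id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4], z = m[, 5],
    radius = m[, 6], parent = m[, 7]))
  forward <- tree$parent != -1 &
    match(tree$parent, tree$id) > seq_len(nrow(tree))
  if (any(forward, na.rm = TRUE)) {
    if (!reorder)
      stop("forward parent reference in ", path,
           " (line ", which(forward)[1], " of node list)")
    tree <- standardize(tree, min_radius = 0)
  }
  tree
}

#' @rdname read_swc
#' @param tree a `skeleton_tree`.
#' @param comment optional character vector of header comment lines
#'   (written prefixed with `"# "`).
#' @export
write_swc <- function(tree, path, comment = NULL) {
  tree <- as_skeleton_tree(tree)
  con <- file(path, "wb")  # binary mode: fixed newlines, byte-stable
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste("#", comment), con, sep = "\n")
  lines <- paste(tree$id, tree$type, shortest_dec(tree$x),
                 shortest_dec(tree$y), shortest_dec(tree$z),
                 shortest_dec(tree$radius), tree$parent)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# --- small tree utilities shared by treebench / phantom ---------------------

tree_parent_row <- function(tree) match(tree$parent, tree$id)

tree_n_children <- function(tree) {
  pr <- tree_parent_row(tree)
  tabulate(pr[!is.na(pr)], nbins = nrow(tree))
}

# rows of branch nodes (non-root, >= 2 children) and terminals (0 children)
tree_branch_rows <- function(tree) {
  which(tree_n_children(tree) >= 2L & tree$parent != -1L)
}

tree_terminal_rows <- function(tree) which(tree_n_children(tree) == 0L)

# µm length of the parent edge of each node (0 for the root)
tree_edge_len <- function(tree) {
  pr <- tree_parent_row(tree)
  len <- numeric(nrow(tree))
  ok <- !is.na(pr)
  len[ok] <- sqrt((tree$x[ok] - tree$x[pr[ok]])^2 +
                  (tree$y[ok] - tree$y[pr[ok]])^2 +
                  (tree$z[ok] - tree$z[pr[ok]])^2)
  len
}

# depth (edge count from root) per node
tree_depth <- function(tree) {
  pr <- tree_parent_row(tree)
  depth <- rep(NA_integer_, nrow(tree))
  depth[tree$parent == -1L] <- 0L
  repeat {
    todo <- which(is.na(depth) & !is.na(pr) & !is.na(depth[pr]))
    if (!length(todo)) break
    depth[todo] <- depth[pr[todo]] + 1L
  }
  depth
}
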