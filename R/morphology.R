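#' Neuron morphology from SWC points
#'
#' A `morphology` is a validated table of SWC points (id, structure type, x, y,
#' z, radius, parent) forming a tree rooted at the soma. Types follow the SWC
#' convention: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite.
#'
#' @param points data.frame with columns `id, type, x, y, z, r, parent`
#'   (radii in um, parent -1 for the root).
#' @return an object of class `morphology`.
#' @export
morphology <- function(points) {
  required <- c("id", "type", "x", "y", "z", "r", "parent")
  if (!all(required %in% names(points))) {
    stop("morphology points need columns: ", paste(required, collapse = ", "))
  }
  points <- points[, required]
  n <- nrow(points)
  if (n < 1L) stop("empty morphology")
  if (anyDuplicated(points$id)) stop("duplicate SWC ids")
  roots <- which(points$parent == -1L)
  if (length(roots) != 1L) stop("morphology must have exactly one root, found ", length(roots))
  if (points$type[roots] != 1L) stop("root point must be soma (type 1)")
  idx <- match(points$parent, points$id)
  orphan <- which(points$parent != -1L & is.na(idx))
  if (length(orphan)) {
    stop("structure error: parent id ", points$parent[orphan[1]],
         " of point ", points$id[orphan[1]], " does not exist")
  }
  if (any(points$r <= 0)) stop("all radii must be positive")
  # renumber to 1..n in parent-before-child order (BFS from root)
  parent_idx <- idx
  parent_idx[roots] <- 0L
  order_bfs <- integer(n)
  children <- split(seq_len(n), factor(parent_idx, levels = 0:n))
  queue <- roots
  k <- 0L
  while (length(queue)) {
    p <- queue[1L]; queue <- queue[-1L]
    k <- k + 1L
    order_bfs[k] <- p
    queue <- c(queue, children[[as.character(p)]])
  }
  if (k != n) stop("structure error: morphology contains a cycle or disconnected points")
  points <- points[order_bfs, ]
  newpos <- match(seq_len(n), order_bfs) # old row -> new row
  pidx <- parent_idx[order_bfs]
  points$parent_idx <- ifelse(pidx == 0L, 0L, newpos[pmax(pidx, 1L)])
  points$id <- seq_len(n)
  rownames(points) <- NULL
  # edge lengths to parent; zero-length edges are not allowed outside the soma
  len <- .point_edge_lengths(points)
  if (any(len[points$parent_idx > 0L & points$type != 1L] <= 0)) {
    stop("all edge lengths must be positive")
  }
  structure(list(points = points), class = "morphology")
}

.point_edge_lengths <- function(pts) {
  len <- numeric(nrow(pts))
  has_par <- pts$parent_idx > 0L
  p <- pts$parent_idx[has_par]
  len[has_par] <- sqrt((pts$x[has_par] - pts$x[p])^2 +
                       (pts$y[has_par] - pts$y[p])^2 +
                       (pts$z[has_par] - pts$z[p])^2)
  len
}

#' Read an SWC morphology file
#'
#' Reads the 7-column SWC dialect (`id type x y z radius parent`). Comment
#' lines starting with `#` are ignored. Malformed lines are reported with
#' their line number.
#'
#' @param path path to an SWC file
#' @return a [morphology()] object
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("SWC file contains no data lines: ", path)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad)) {
    stop("malformed SWC line ", rows[bad[1]], " in ", path,
         ": expected 7 whitespace-separated fields")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  nf <- which(!stats::complete.cases(m))
  if (length(nf)) stop("malformed SWC line ", rows[nf[1]], " in ", path, ": non-numeric field")
  morphology(data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                        x = m[, 3], y = m[, 4], z = m[, 5], r = m[, 6],
                        parent = as.integer(m[, 7])))
}

#' Write a morphology to an SWC file
#'
#' @param morph a [morphology()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "morphology"))
  pts <- morph$points
  parent <- ifelse(pts$parent_idx == 0L, -1L, pts$parent_idx)
  df <- data.frame(pts$id, pts$type, pts$x, pts$y, pts$z, pts$r, parent)
  write.table(format(df, digits = 9, trim = TRUE, scientific = FALSE),
              file = path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Decompose a morphology into unbranched sections. Returns a list of sections,
# each a list(type, point_rows, parent_point), where point_rows are the rows of
# the section's own points (excluding the start/attachment point) and
# parent_point is the row the section emanates from (a soma point or a branch
# point of another section).
.swc_sections <- function(morph) {
  pts <- morph$points
  n <- nrow(pts)
  is_soma <- pts$type == 1L
  nonsoma <- which(!is_soma)
  if (!length(nonsoma)) return(list())
  nchild <- tabulate(pts$parent_idx[nonsoma], nbins = n)
  starts <- nonsoma[is_soma[pts$parent_idx[nonsoma]] | nchild[pts$parent_idx[nonsoma]] >= 2L]
  children <- split(nonsoma, factor(pts$parent_idx[nonsoma], levels = seq_len(n)))
  sections <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    rows <- integer(0)
    p <- starts[si]
    repeat {
      rows <- c(rows, p)
      ch <- children[[p]]
      if (length(ch) != 1L) break
      p <- ch
    }
    sections[[si]] <- list(type = pts$type[starts[si]],
                           point_rows = rows,
                           parent_point = pts$parent_idx[starts[si]])
  }
  sections
}

#' @export
print.morphology <- function(x, ...) {
  pts <- x$points
  cat("morphology:", nrow(pts), "points;",
      sum(pts$type == 1L), "soma,",
      sum(pts$type == 2L), "axon,",
      sum(pts$type == 3L), "basal,",
      sum(pts$type == 4L), "apical points\n")
  invisible(x)
}
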