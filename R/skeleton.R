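#' Center-line skeletons
#'
#' A `skeleton` is an ordered 3D polyline in micrometres with an optional
#' per-node radius, as produced by skeletonising a segmented structure and
#' exporting it in SWC format. The object keeps the full SWC node table (so a
#' file round-trips) plus the unbranched *profiling path* used by all
#' arc-length operations: for branched skeletons this is the longest
#' root-to-leaf chain by arc length.
#'
#' @param xyz numeric matrix (n x 3) of node coordinates in micrometres, in
#'   path order.
#' @param radius optional numeric vector of node radii (micrometres).
#' @return An object of class `skeleton`.
#' @examples
#' sk <- skeleton(cbind(c(0, 3), c(0, 4), c(0, 0)))
#' path_length(sk)  # 5
#' @export
skeleton <- function(xyz, radius = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  if (n < 1L) stop("skeleton needs at least one node")
  nodes <- data.frame(
    id = seq_len(n), type = rep(0L, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = if (is.null(radius)) rep(1, n) else as.numeric(radius),
    parent = c(-1L, seq_len(n - 1L))
  )
  new_skeleton(nodes, path = seq_len(n), unit_scale = c(1, 1, 1))
}

new_skeleton <- function(nodes, path, unit_scale) {
  xyz <- as.matrix(nodes[path, c("x", "y", "z")])
  rownames(xyz) <- NULL
  seg <- NULL
  if (nrow(xyz) >= 2L) {
    d <- diff(xyz)
    len <- sqrt(rowSums(d^2))
    if (any(len <= 0)) stop("consecutive path nodes must be distinct points")
    seg <- list(a = xyz[-nrow(xyz), , drop = FALSE], d = d, len = len,
                cum = c(0, cumsum(len)))
  }
  structure(
    list(nodes = nodes, path = path, path_xyz = xyz, seg = seg,
         unit_scale = unit_scale),
    class = "skeleton"
  )
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d nodes, profiling path %d nodes, length %.4f um\n",
              nrow(x$nodes), length(x$path), path_length(x)))
  invisible(x)
}

#' Read an SWC skeleton file
#'
#' Reads the 7-column SWC dialect (`id type x y z radius parent`, `#`
#' comments). Coordinates are multiplied per axis by `unit_scale` at load time
#' (e.g. `c(0.005, 0.005, 0.040)` to convert 5 nm pixels with a 40 nm Z-step
#' to micrometres); the radius column is scaled by the mean of the x/y
#' factors. The profiling path is the longest root-to-leaf chain by arc
#' length; side branches are retained in the node table but ignored by
#' arc-length operations.
#'
#' @param path path to an SWC file.
#' @param unit_scale numeric length-3 vector of micrometres per input unit.
#' @return A [skeleton] object.
#' @export
read_swc <- function(path, unit_scale = c(1, 1, 1)) {
  stopifnot(length(unit_scale) == 3, all(is.finite(unit_scale)))
  lines <- readLines(path)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) != 7L)
      stop(sprintf("SWC parse error at line %d: expected 7 fields, got %d",
                   i, length(tok)))
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v)))
      stop(sprintf("SWC parse error at line %d: non-numeric field", i))
    rows[[i]] <- v
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("SWC file contains no nodes")
  m <- do.call(rbind, rows)
  nodes <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3] * unit_scale[1], y = m[, 4] * unit_scale[2],
    z = m[, 5] * unit_scale[3],
    radius = m[, 6] * mean(unit_scale[1:2]),
    parent = as.integer(m[, 7])
  )
  if (anyDuplicated(nodes$id)) stop("SWC structure error: duplicate node ids")
  idx <- match(nodes$parent, nodes$id)          # NA for roots (-1)
  root <- nodes$parent < 0 | is.na(idx)
  idx[root] <- 0L
  if (any(!root & idx >= seq_len(nrow(nodes))))
    stop("SWC structure error: a parent must precede its child")
  path <- extract_path(nodes, idx)
  new_skeleton(nodes, path, unit_scale)
}

# longest root-to-leaf chain by arc length; pidx is the row index of each
# node's parent (0 for roots), guaranteed topologically sorted
extract_path <- function(nodes, pidx) {
  n <- nrow(nodes)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  dist <- numeric(n)
  for (i in seq_len(n)) {
    p <- pidx[i]
    if (p > 0L) dist[i] <- dist[p] + sqrt(sum((xyz[i, ] - xyz[p, ])^2))
  }
  has_child <- rep(FALSE, n)
  has_child[pidx[pidx > 0L]] <- TRUE
  leaves <- which(!has_child)
  leaf <- leaves[which.max(dist[leaves])]
  path <- integer(0)
  i <- leaf
  while (i > 0L) {
    path <- c(i, path)
    i <- pidx[i]
  }
  path
}

#' Write a skeleton to an SWC file
#'
#' Writes the full node table (micrometre coordinates) as 7-column SWC.
#' Reading the result back with identity `unit_scale` reproduces the
#' coordinates.
#'
#' @param skel a [skeleton].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path) {
  stopifnot(inherits(skel, "skeleton"))
  nd <- skel$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by cpmorph (coordinates in micrometres)", con)
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent),
             con)
  invisible(path)
}

#' Arc length of the profiling path
#'
#' Sum of Euclidean 3D segment lengths along the profiling path (the
#' Pythagorean length). A single-node path has length 0.
#'
#' @param skel a [skeleton].
#' @return length in micrometres.
#' @export
path_length <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  if (is.null(skel$seg)) return(0)
  skel$seg$cum[length(skel$seg$cum)]
}

#' Orthogonally project a point onto a skeleton path
#'
#' Projects `p` onto every segment of the profiling path (clamped to segment
#' endpoints) and returns the globally nearest location. Ties between
#' equidistant segments resolve to the lowest segment index. With
#' `extend_base = TRUE` the first segment is extended infinitely backward
#' along its own direction, so projections can land behind the path start;
#' positions are then signed arc lengths, with `t_norm = -1` one full path
#' length behind the start.
#'
#' @param skel a [skeleton] with a path of at least 2 nodes.
#' @param p numeric length-3 point (micrometres).
#' @param extend_base extrapolate the first segment backward (basal
#'   extrapolation)?
#' @return list with `t_norm` (normalised arc-length position, in `[0, 1]`
#'   unless extrapolated), `s_um` (signed arc length from the path start),
#'   `distance_um`, and `segment_index`.
#' @export
project_point <- function(skel, p, extend_base = FALSE) {
  stopifnot(inherits(skel, "skeleton"))
  if (is.null(skel$seg)) stop("geometry error: path needs at least 2 nodes")
  p <- as.numeric(p)
  stopifnot(length(p) == 3)
  seg <- skel$seg
  L <- seg$cum[length(seg$cum)]
  m <- length(seg$len)
  best <- list(d2 = Inf, s = NA_real_, i = NA_integer_)
  for (i in seq_len(m)) {
    w <- p - seg$a[i, ]
    t <- sum(w * seg$d[i, ]) / seg$len[i]^2
    lo <- if (extend_base && i == 1L) -Inf else 0
    t <- min(max(t, lo), 1)
    d2 <- sum((w - t * seg$d[i, ])^2)
    # strict improvement only, so the lowest segment index wins exact ties
    if (d2 < best$d2) {
      best <- list(d2 = d2, s = seg$cum[i] + t * seg$len[i], i = i)
    }
  }
  list(t_norm = best$s / L, s_um = best$s,
       distance_um = sqrt(best$d2), segment_index = best$i)
}

# vectorised projection of an n x 3 point matrix; returns list(s, d2).
# Ties resolve to the lowest segment index because only strict improvements
# replace the incumbent.
project_points <- function(skel, pts, extend_base = FALSE) {
  stopifnot(inherits(skel, "skeleton"))
  if (is.null(skel$seg)) stop("geometry error: path needs at least 2 nodes")
  pts <- as.matrix(pts)
  seg <- skel$seg
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_s <- rep(NA_real_, n)
  best_i <- rep(NA_integer_, n)
  for (i in seq_along(seg$len)) {
    w1 <- pts[, 1] - seg$a[i, 1]
    w2 <- pts[, 2] - seg$a[i, 2]
    w3 <- pts[, 3] - seg$a[i, 3]
    t <- (w1 * seg$d[i, 1] + w2 * seg$d[i, 2] + w3 * seg$d[i, 3]) / seg$len[i]^2
    lo <- if (extend_base && i == 1L) -Inf else 0
    t <- pmin(pmax(t, lo), 1)
    d2 <- (w1 - t * seg$d[i, 1])^2 + (w2 - t * seg$d[i, 2])^2 +
      (w3 - t * seg$d[i, 3])^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_s[upd] <- seg$cum[i] + t[upd] * seg$len[i]
      best_i[upd] <- i
    }
  }
  list(s = best_s, d2 = best_d2, segment = best_i)
}

# split a skeleton's path at node index k (1-based along the path), returning
# the two sub-skeletons; used by additivity checks
split_path <- function(skel, k) {
  xyz <- skel$path_xyz
  stopifnot(k >= 1, k <= nrow(xyz))
  list(skeleton(xyz[seq_len(k), , drop = FALSE]),
       if (k < nrow(xyz)) skeleton(xyz[k:nrow(xyz), , drop = FALSE])
       else skeleton(xyz[k, , drop = FALSE]))
}
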