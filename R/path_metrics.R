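#' Net displacement
#'
#' Bee-line distance between a DAR's start and end points, the "openness"
#' measure: near zero for closed routines that return to the same roost,
#' large for one-way excursions.
#'
#' @param start,end numeric `c(x, y)` in meters, or `NULL`/`NA` when missing.
#' @return Distance in km, or `NA` when either endpoint is missing.
#' @export
net_displacement <- function(start, end) {
  if (is.null(start) || is.null(end) || anyNA(start) || anyNA(end))
    return(NA_real_)
  sqrt(sum((as.numeric(end)[1:2] - as.numeric(start)[1:2])^2)) / 1000
}

#' Maximum displacement from the start point
#'
#' @param points a two-column (x, y) matrix or data frame in meters.
#' @param start numeric `c(x, y)`, or `NULL`/`NA` when missing.
#' @return Maximum Euclidean distance from `start` to any point, in km;
#'   `NA` when the start point is missing.
#' @export
max_displacement <- function(points, start) {
  if (is.null(start) || anyNA(start)) return(NA_real_)
  p <- as_point_matrix(points)
  if (nrow(p) == 0L) stop("empty point set")
  sqrt(max((p[, 1] - start[1])^2 + (p[, 2] - start[2])^2)) / 1000
}

#' Maximum diameter of a point set
#'
#' The greatest distance between any two trajectory points; the segment
#' joining them is the diameter line. For small sets the pairwise scan is
#' exhaustive; above `cutoff` points the diameter is found on the convex
#' hull (the maximizing pair are always hull vertices), which gives the
#' identical result faster. Ties are broken by the lexicographically
#' smallest index pair.
#'
#' @param points a two-column (x, y) matrix or data frame in meters.
#' @param cutoff point count above which the convex-hull route is used
#'   (default 500).
#' @return A list with `km` (diameter in km) and `pair` (indices into
#'   `points` of the two achieving points; `c(1, 1)` for a single point).
#' @export
max_diameter <- function(points, cutoff = 500) {
  p <- as_point_matrix(points)
  n <- nrow(p)
  if (n == 0L) stop("empty point set")
  if (n == 1L) return(list(km = 0, pair = c(1L, 1L)))
  if (n <= cutoff) {
    cand <- seq_len(n)
  } else {
    cand <- sort(grDevices::chull(p[, 1], p[, 2]))
    if (length(cand) < 2L) cand <- c(1L, 2L)  # all points coincident
  }
  q <- p[cand, , drop = FALSE]
  m <- length(cand)
  d2max <- -1
  pair <- c(1L, 1L)
  for (i in seq_len(m - 1L)) {
    d2 <- (q[(i + 1L):m, 1] - q[i, 1])^2 + (q[(i + 1L):m, 2] - q[i, 2])^2
    j <- which.max(d2)          # first maximum: smallest j for this i
    if (d2[j] > d2max) {
      d2max <- d2[j]
      pair <- c(cand[i], cand[i + j])
    }
  }
  list(km = sqrt(d2max) / 1000, pair = pair)
}

#' Maximum width about the diameter line
#'
#' Signed perpendicular offsets of all points to the infinite line through
#' the diameter pair; the width is the largest offset on one side plus the
#' largest on the other (a side with no points contributes zero). Captures
#' the elongation of a routine: transverse, commute-like routines have width
#' far below their diameter.
#'
#' @param points a two-column (x, y) matrix or data frame in meters.
#' @param diameter_pair indices of the two diameter points (from
#'   [max_diameter()]).
#' @return Width in km (0 for collinear or degenerate sets).
#' @export
max_width <- function(points, diameter_pair) {
  p <- as_point_matrix(points)
  a <- p[diameter_pair[1], ]
  b <- p[diameter_pair[2], ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) return(0)
  # signed offset = cross((b-a), (p-a)) / |b-a|
  off <- (ab[1] * (p[, 2] - a[2]) - ab[2] * (p[, 1] - a[1])) / len
  pos <- max(c(off[off > 0], 0))
  neg <- max(c(-off[off < 0], 0))
  (pos + neg) / 1000
}

#' Compute the four whole-path metrics for one DAR
#'
#' The start point (and end point, when present) is added to the point set
#' before computing displacement and diameter, so the invariant chain
#' net displacement <= max displacement <= max diameter, and
#' max width <= max diameter, holds by construction. `complete` is FALSE
#' when either endpoint is missing (such rows are dropped before
#' clustering).
#'
#' @param dar a DAR object from [build_dars()], or any list with `points`
#'   (data frame with x, y), `start_point`, `end_point`, `dar_id`.
#' @return A one-row data frame: `dar_id`, `net_displacement`,
#'   `max_displacement`, `max_diameter`, `max_width` (all km), `diam_i`,
#'   `diam_j` (diameter pair indices into the augmented point set),
#'   `complete`.
#' @export
compute_metrics <- function(dar) {
  pts <- as_point_matrix(dar$points)
  if (nrow(pts) == 0L) stop("DAR has no points: ", dar$dar_id)
  aug <- pts
  if (!is.null(dar$start_point)) aug <- rbind(unname(dar$start_point[1:2]), aug)
  if (!is.null(dar$end_point)) aug <- rbind(aug, unname(dar$end_point[1:2]))
  nd <- net_displacement(dar$start_point, dar$end_point)
  md <- max_displacement(aug, dar$start_point)
  dia <- max_diameter(aug)
  w <- max_width(aug, dia$pair)
  data.frame(dar_id = dar$dar_id,
             net_displacement = nd,
             max_displacement = md,
             max_diameter = dia$km,
             max_width = w,
             diam_i = dia$pair[1], diam_j = dia$pair[2],
             complete = !is.na(nd) && !is.na(md),
             stringsAsFactors = FALSE)
}

#' Metrics table for a set of DARs
#'
#' @param dars list of DAR objects (e.g. `build_dars(...)$dars`).
#' @return A data frame with one row per DAR (see [compute_metrics()]).
#' @export
compute_metrics_table <- function(dars) {
  do.call(rbind, lapply(dars, compute_metrics))
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    m <- cbind(points$x, points$y)
  } else {
    m <- as.matrix(points)
    m <- m[, 1:2, drop = FALSE]
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}
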