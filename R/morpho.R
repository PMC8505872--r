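# Polygon shape descriptors equivalent to the ImageJ measurements used for
# leaf-cell morphometrics: area, perimeter, circularity, solidity,
# moment-ellipse aspect ratio, and the minimum bounding rectangle.

as_polygon <- function(contour) {
  if (is.data.frame(contour)) {
    stopifnot(all(c("x", "y") %in% names(contour)))
    if ("vertex_index" %in% names(contour)) {
      contour <- contour[order(contour$vertex_index), ]
    }
    contour <- cbind(contour$x, contour$y)
  }
  xy <- as.matrix(contour)
  if (ncol(xy) != 2 || nrow(xy) < 3) {
    stop("a contour needs at least three (x, y) vertices")
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3) stop("degenerate contour")
  unname(xy)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' All non-adjacent edge pairs are checked for proper crossings (vectorized
#' orientation test).
#'
#' @param contour Two-column matrix or data frame of ordered vertices.
#' @return Logical.
#' @export
is_simple_polygon <- function(contour) {
  xy <- as_polygon(contour)
  n <- nrow(xy)
  nxt <- c(2:n, 1)
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1 & !(i == 1 & j == n)
  }), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  !any(segments_intersect(xy[i, , drop = FALSE], xy[nxt[i], , drop = FALSE],
                          xy[j, , drop = FALSE], xy[nxt[j], , drop = FALSE]))
}

#' Polygon area and perimeter
#'
#' Shoelace area (absolute value, orientation invariant) and closed-path
#' perimeter.
#'
#' @param contour Two-column matrix or data frame (`x`, `y`) of ordered
#'   vertices; the polygon closes implicitly.
#' @param check Verify the polygon is simple (error on self-intersection).
#' @return Named numeric vector `c(area = , perimeter = )`.
#' @export
area_perimeter <- function(contour, check = FALSE) {
  xy <- as_polygon(contour)
  if (check && !is_simple_polygon(xy)) stop("self-intersecting contour")
  n <- nrow(xy)
  nxt <- c(2:n, 1)
  cross <- xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2]
  area <- abs(sum(cross)) / 2
  per <- sum(sqrt(rowSums((xy[nxt, ] - xy)^2)))
  c(area = area, perimeter = per)
}

#' Circularity
#'
#' `4 * pi * area / perimeter^2`, clipped at 1 (discrete polygons can
#' slightly exceed 1 numerically; the ImageJ convention caps it).
#'
#' @inheritParams area_perimeter
#' @return Circularity in `(0, 1]`.
#' @export
circularity <- function(contour, check = FALSE) {
  ap <- area_perimeter(contour, check = check)
  if (ap["perimeter"] <= 0 || ap["area"] <= 0) stop("degenerate polygon")
  unname(min(1, 4 * pi * ap["area"] / ap["perimeter"]^2))
}

#' Solidity
#'
#' Polygon area divided by convex-hull area; 1 for convex shapes, lower for
#' lobed (jigsaw-like) cells.
#'
#' @inheritParams area_perimeter
#' @return Solidity in `(0, 1]`.
#' @export
solidity <- function(contour, check = FALSE) {
  xy <- as_polygon(contour)
  if (check && !is_simple_polygon(xy)) stop("self-intersecting contour")
  a <- area_perimeter(xy)["area"]
  if (a <= 0) stop("degenerate polygon")
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  unname(min(1, a / area_perimeter(hull)["area"]))
}

# Exact second-order central moments of the polygon interior (Green's
# theorem), normalized by area. Independent of vertex density.
polygon_moments <- function(xy) {
  n <- nrow(xy)
  nxt <- c(2:n, 1)
  x0 <- xy[, 1]; y0 <- xy[, 2]
  x1 <- xy[nxt, 1]; y1 <- xy[nxt, 2]
  cr <- x0 * y1 - x1 * y0
  a <- sum(cr) / 2
  if (a == 0) stop("degenerate polygon (zero signed area)")
  cx <- sum((x0 + x1) * cr) / (6 * a)
  cy <- sum((y0 + y1) * cr) / (6 * a)
  mxx <- sum((x0^2 + x0 * x1 + x1^2) * cr) / 12
  myy <- sum((y0^2 + y0 * y1 + y1^2) * cr) / 12
  mxy <- sum((x0 * y1 + 2 * x0 * y0 + 2 * x1 * y1 + x1 * y0) * cr) / 24
  list(area = abs(a),
       u20 = mxx / a - cx^2,
       u02 = myy / a - cy^2,
       u11 = mxy / a - cx * cy)
}

#' Aspect ratio of the best-fit (moment) ellipse
#'
#' Ratio of major to minor axis of the ellipse sharing the polygon's
#' second-order central moments, computed analytically over the polygon
#' interior; always >= 1 and rotation invariant.
#'
#' @inheritParams area_perimeter
#' @return Aspect ratio (>= 1).
#' @export
ellipse_aspect_ratio <- function(contour, check = FALSE) {
  xy <- as_polygon(contour)
  if (check && !is_simple_polygon(xy)) stop("self-intersecting contour")
  m <- polygon_moments(xy)
  tr <- (m$u20 + m$u02) / 2
  dlt <- sqrt(((m$u20 - m$u02) / 2)^2 + m$u11^2)
  l1 <- tr + dlt
  l2 <- tr - dlt
  if (l2 <= 0) stop("degenerate polygon: zero minor axis")
  sqrt(l1 / l2)
}

#' Minimum bounding rectangle
#'
#' Smallest-area enclosing rectangle of the polygon, found by rotating
#' calipers over the convex hull (the optimum has a side collinear with a
#' hull edge). Side lengths define the cell length (longer) and width.
#'
#' @inheritParams area_perimeter
#' @return Named vector `c(length = , width = )`.
#' @export
min_bounding_rectangle <- function(contour, check = FALSE) {
  xy <- as_polygon(contour)
  if (check && !is_simple_polygon(xy)) stop("self-intersecting contour")
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  if (nrow(hull) < 3) stop("degenerate polygon")
  n <- nrow(hull)
  nxt <- c(2:n, 1)
  edges <- hull[nxt, ] - hull
  angles <- unique(atan2(edges[, 2], edges[, 1]) %% (pi / 2))
  best <- c(Inf, NA, NA)
  for (th in angles) {
    rot <- rotate_xy(hull, -th)
    dx <- diff(range(rot[, 1]))
    dy <- diff(range(rot[, 2]))
    if (dx * dy < best[1]) best <- c(dx * dy, dx, dy)
  }
  sides <- sort(best[2:3], decreasing = TRUE)
  c(length = sides[1], width = sides[2])
}

#' Shape descriptors for a population of contours
#'
#' Computes the full descriptor panel per cell: area, perimeter,
#' circularity, solidity, moment-ellipse aspect ratio, and the minimum
#' bounding rectangle's length and width.
#'
#' @param contours Tibble with columns `cell_id`, `group` (optional),
#'   `vertex_index`, `x`, `y`, as produced by
#'   [generate_cell_population()] or [read_contours()].
#' @param check Verify polygons are simple.
#' @return Tibble with one row per cell.
#' @export
shape_descriptors <- function(contours, check = FALSE) {
  stopifnot(all(c("cell_id", "x", "y") %in% names(contours)))
  ids <- unique(contours$cell_id)
  rows <- lapply(ids, function(id) {
    sub <- contours[contours$cell_id == id, , drop = FALSE]
    xy <- as_polygon(sub)
    if (check && !is_simple_polygon(xy)) {
      stop("self-intersecting contour: ", id)
    }
    ap <- area_perimeter(xy)
    mbr <- min_bounding_rectangle(xy)
    tibble::tibble(
      cell_id = id,
      group = if ("group" %in% names(sub)) sub$group[1] else NA_character_,
      area = ap[["area"]], perimeter = ap[["perimeter"]],
      circularity = circularity(xy), solidity = solidity(xy),
      aspect_ratio = ellipse_aspect_ratio(xy),
      length = mbr[["length"]], width = mbr[["width"]]
    )
  })
  do.call(rbind, rows)
}
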