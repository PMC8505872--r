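# Synthetic cell contours: closed polygons emulating the three leaf-cell
# classes measured in the study -- jigsaw-lobed pavement cells, round
# palisade cells, and cells elongated along the proximal-distal axis.

#' Parameterize a synthetic cell contour
#'
#' Shape classes: `"circle"` (radius `size`); `"ellipse"` (semi-minor axis
#' `size`, semi-major `size * aspect`); `"lobed"` (radial profile
#' `r(theta) = size * (1 + lobe_amplitude * sin(lobe_count * theta))`, the
#' jigsaw pavement-cell model); `"rectangle"` (width `size`, length
#' `size * aspect`, vertices spread along the boundary).
#'
#' @param class One of `"circle"`, `"ellipse"`, `"lobed"`, `"rectangle"`.
#' @param size Characteristic size (length units).
#' @param aspect Elongation (>= 1; ignored for circle/lobed).
#' @param lobe_amplitude Relative lobe depth, in `[0, 0.5)`.
#' @param lobe_count Integer number of lobes.
#' @param rotation Rotation angle in radians.
#' @param n_vertices Number of polygon vertices (>= 16).
#' @return A `contour_spec` object.
#' @export
contour_spec <- function(class = c("circle", "ellipse", "lobed", "rectangle"),
                         size = 1, aspect = 1, lobe_amplitude = 0,
                         lobe_count = 8L, rotation = 0, n_vertices = 128L) {
  class <- match.arg(class)
  if (size <= 0) stop("size must be positive")
  if (aspect < 1) stop("aspect must be >= 1")
  if (lobe_amplitude < 0 || lobe_amplitude >= 0.5) {
    stop("lobe_amplitude must lie in [0, 0.5)")
  }
  if (n_vertices < 16) stop("n_vertices must be >= 16")
  structure(list(class = class, size = size, aspect = aspect,
                 lobe_amplitude = lobe_amplitude,
                 lobe_count = as.integer(lobe_count),
                 rotation = rotation, n_vertices = as.integer(n_vertices)),
            class = "contour_spec")
}

rotate_xy <- function(xy, theta) {
  r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy %*% t(r)
}

# Noiseless vertex coordinates for a spec, plus its analytic descriptors.
contour_vertices <- function(spec) {
  n <- spec$n_vertices
  s <- spec$size
  xy <- switch(spec$class,
    circle = {
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      cbind(s * cos(th), s * sin(th))
    },
    lobed = {
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      r <- s * (1 + spec$lobe_amplitude * sin(spec$lobe_count * th))
      cbind(r * cos(th), r * sin(th))
    },
    ellipse = {
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      cbind(s * spec$aspect * cos(th), s * sin(th))
    },
    rectangle = {
      l <- s * spec$aspect
      w <- s
      per <- 2 * (l + w)
      # corners are always vertices, so area/perimeter match the analytics
      d <- seq(0, per, length.out = n - 2)[-(n - 2)]
      d <- sort(unique(c(d, c(0, l, l + w, 2 * l + w))))
      t(vapply(d, function(p) {
        if (p < l) c(p, 0)
        else if (p < l + w) c(l, p - l)
        else if (p < 2 * l + w) c(2 * l + w - p, w)
        else c(0, per - p)
      }, numeric(2)))
    })
  rotate_xy(xy, spec$rotation)
}

# Analytic descriptors of the noiseless shape (oracle values for tests).
analytic_descriptors <- function(spec) {
  s <- spec$size
  switch(spec$class,
    circle = tibble::tibble(area = pi * s^2, perimeter = 2 * pi * s,
                            circularity = 1, solidity = 1, aspect_ratio = 1,
                            length = 2 * s, width = 2 * s),
    lobed = tibble::tibble(
      area = pi * s^2 * (1 + spec$lobe_amplitude^2 / 2),
      perimeter = NA_real_, circularity = NA_real_, solidity = NA_real_,
      aspect_ratio = NA_real_,
      length = NA_real_, width = NA_real_),
    ellipse = {
      a <- s * spec$aspect
      b <- s
      tibble::tibble(area = pi * a * b, perimeter = NA_real_,
                     circularity = NA_real_, solidity = 1,
                     aspect_ratio = spec$aspect,
                     length = 2 * a, width = 2 * b)
    },
    rectangle = {
      l <- s * spec$aspect
      w <- s
      tibble::tibble(area = l * w, perimeter = 2 * (l + w),
                     circularity = 4 * pi * l * w / (2 * (l + w))^2,
                     solidity = 1, aspect_ratio = spec$aspect,
                     length = l, width = w)
    })
}

#' Generate a population of cell contours
#'
#' Draws `n` simple closed polygons from a [contour_spec()], optionally
#' perturbed by multiplicative radial jitter (relative, Gaussian) around the
#' shape centroid. The analytic descriptors of the noiseless shape are
#' attached as attribute `"analytic"` for oracle use.
#'
#' @param spec A [contour_spec()].
#' @param n Number of cells.
#' @param jitter Relative radial noise SD (0 for noiseless shapes).
#' @param seed Integer seed.
#' @param group Group label stored with each cell (condition/treatment).
#' @param cell_prefix Prefix for cell identifiers.
#' @return A tibble with columns `cell_id`, `group`, `vertex_index`, `x`,
#'   `y` (vertices in order; the polygon closes implicitly).
#' @export
generate_cell_population <- function(spec, n, jitter = 0, seed = 1,
                                     group = spec$class,
                                     cell_prefix = "cell") {
  stopifnot(inherits(spec, "contour_spec"), n >= 1, jitter >= 0)
  base <- contour_vertices(spec)
  m <- nrow(base)
  with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      xy <- base
      if (jitter > 0) {
        for (try in 1:20) {
          f <- 1 + stats::rnorm(m, 0, jitter)
          cand <- base * f   # radial scaling about the origin (centroid)
          if (is_simple_polygon(cand)) break
          cand <- NULL
        }
        if (is.null(cand)) {
          stop("jitter produced self-intersecting contours; reduce it")
        }
        xy <- cand
      }
      tibble::tibble(cell_id = sprintf("%s_%s_%03d", cell_prefix, group, i),
                     group = group, vertex_index = seq_len(m),
                     x = xy[, 1], y = xy[, 2])
    })
    out <- do.call(rbind, out)
    attr(out, "analytic") <- analytic_descriptors(spec)
    attr(out, "spec") <- spec
    out
  })
}

#' Default synthetic cell populations
#'
#' The qualitative contrast measured in the study: aerial pavement cells are
#' jigsaw-lobed, aerial palisade cells are round, and both cell types of
#' submerged leaves are strongly elongated along the proximal-distal axis.
#'
#' @param n Cells per population (the study traced 30 per leaf).
#' @param seed Integer seed.
#' @return A single tibble of contours with `group` labels
#'   `aerial_pavement`, `aerial_palisade`, `submerged_elongated`.
#' @export
default_cell_populations <- function(n = 30, seed = 1) {
  pops <- list(
    generate_cell_population(
      contour_spec("lobed", size = 20, lobe_amplitude = 0.3, lobe_count = 8,
                   n_vertices = 128),
      n, jitter = 0.03, seed = seed, group = "aerial_pavement"),
    generate_cell_population(
      contour_spec("circle", size = 18, n_vertices = 128),
      n, jitter = 0.03, seed = seed + 1L, group = "aerial_palisade"),
    generate_cell_population(
      contour_spec("ellipse", size = 9, aspect = 5, rotation = pi / 2,
                   n_vertices = 128),
      n, jitter = 0.03, seed = seed + 2L, group = "submerged_elongated")
  )
  out <- do.call(rbind, pops)
  attr(out, "analytic") <- NULL
  attr(out, "spec") <- NULL
  out
}
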