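#' Cell contour
#'
#' A closed, ordered polygon of contour vertices for one segmented cell,
#' in micrometres.  Segmentation itself is upstream; contours are inputs.
#'
#' @param cell_id Label.
#' @param vertices Two-column matrix (or data.frame) of `x`, `y` vertex
#'   positions, ordered along the outline, without a repeated closing
#'   vertex.
#' @return An object of class `cell_contour`.
#' @export
cell_contour <- function(cell_id, vertices) {
  vertices <- as.matrix(vertices)
  ko_check(is.numeric(vertices) && ncol(vertices) == 2 &&
             all(is.finite(vertices)),
           "vertices must be a finite two-column matrix")
  # a duplicated closing vertex is tolerated and dropped
  n <- nrow(vertices)
  if (n >= 2 && all(vertices[1, ] == vertices[n, ])) {
    vertices <- vertices[-n, , drop = FALSE]
  }
  ko_check(nrow(vertices) >= 20, "a contour needs at least 20 vertices")
  structure(list(cell_id = as.character(cell_id), vertices = vertices),
            class = "cell_contour")
}

#' Major axis of a cell by total regression
#'
#' Total-least-squares line through the vertex centroid: the direction is
#' the leading eigenvector of the vertex covariance matrix, which
#' minimizes summed perpendicular distances.  The sign is normalized to
#' non-negative x (ties toward non-negative y).  For nearly isotropic
#' contours (eigenvalue ratio below `1.05`) the axis is ill defined: a
#' warning of class `kickout_degenerate_axis` is issued and the direction
#' of the longest vertex-to-vertex chord is used instead.
#'
#' @param contour A [cell_contour()].
#' @return List of class `cell_axis`: `direction` (unit vector),
#'   `centroid`, `degenerate` flag.
#' @export
principal_axis <- function(contour) {
  ko_check(inherits(contour, "cell_contour"),
           "contour must be a cell_contour")
  v <- contour$vertices
  centroid <- colMeans(v)
  cc <- sweep(v, 2, centroid)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  degenerate <- ev$values[1] / max(ev$values[2], .Machine$double.eps) < 1.05
  if (degenerate) {
    warning(warningCondition(
      "contour is nearly isotropic; falling back to the longest chord",
      class = "kickout_degenerate_axis"))
    d <- as.matrix(dist(v))
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    dir <- v[ij[2], ] - v[ij[1], ]
    dir <- dir / sqrt(sum(dir^2))
  } else {
    dir <- ev$vectors[, 1]
  }
  if (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)) dir <- -dir
  structure(list(direction = as.numeric(dir),
                 centroid = as.numeric(centroid),
                 degenerate = degenerate),
            class = "cell_axis")
}

# axial coordinate and perpendicular distance of each vertex
axis_coords <- function(contour, axis) {
  cc <- sweep(contour$vertices, 2, axis$centroid)
  s <- cc %*% axis$direction
  perp <- c(-axis$direction[2], axis$direction[1])
  d <- abs(cc %*% perp)
  list(s = as.numeric(s), d = as.numeric(d))
}

#' Cell width from a contour
#'
#' Width is twice the mean perpendicular distance between the contour and
#' the major axis, excluding the poles, so that a capsule's width equals
#' its diameter.  Pole exclusion: a first-pass width `w0` is estimated
#' from all vertices, then vertices whose axial coordinate lies within
#' `w0 / 2` of either axial extreme are dropped and the width recomputed
#' once (a single refinement pass).  Vertices are the averaging unit.
#'
#' @param contour A [cell_contour()].
#' @param axis Optional [principal_axis()] result (computed if missing).
#' @return Width in micrometres, with attributes `n_vertices_used`,
#'   `half_width` (the single-sided mean distance) and `w0`.
#' @export
cell_width <- function(contour, axis = NULL) {
  if (is.null(axis)) axis <- principal_axis(contour)
  ko_check(inherits(axis, "cell_axis"), "axis must be a cell_axis")
  co <- axis_coords(contour, axis)
  w0 <- 2 * mean(co$d)
  margin <- w0 / 2
  keep <- co$s >= (min(co$s) + margin) & co$s <= (max(co$s) - margin)
  if (sum(keep) < 10) {
    ko_stop("fewer than 10 vertices remain after pole exclusion",
            "kickout_too_short_cell")
  }
  half <- mean(co$d[keep])
  structure(2 * half, n_vertices_used = sum(keep), half_width = half,
            w0 = w0)
}

#' Cell length from a contour
#'
#' Extent of the contour along the major axis: maximum minus minimum
#' axial vertex coordinate.
#'
#' @param contour A [cell_contour()].
#' @param axis Optional [principal_axis()] result (computed if missing).
#' @return Length in micrometres.
#' @export
cell_length <- function(contour, axis = NULL) {
  if (is.null(axis)) axis <- principal_axis(contour)
  ko_check(inherits(axis, "cell_axis"), "axis must be a cell_axis")
  co <- axis_coords(contour, axis)
  max(co$s) - min(co$s)
}

#' Measure width and length for a table of contours
#'
#' @param contours Either a list of [cell_contour()] objects or a
#'   data.frame with columns `cell_id`, `vertex_index`, `x`, `y`.
#' @return data.frame: `cell_id`, `width`, `length`, `n_vertices_used`.
#' @export
measure_cells <- function(contours) {
  if (is.data.frame(contours)) {
    ko_check(all(c("cell_id", "vertex_index", "x", "y") %in%
                   names(contours)),
             "contour table needs cell_id, vertex_index, x, y")
    contours <- lapply(split(contours, contours$cell_id), function(d) {
      d <- d[order(d$vertex_index), ]
      cell_contour(d$cell_id[1], cbind(d$x, d$y))
    })
  }
  rows <- lapply(contours, function(ct) {
    ax <- principal_axis(ct)
    w <- cell_width(ct, ax)
    data.frame(cell_id = ct$cell_id, width = as.numeric(w),
               length = cell_length(ct, ax),
               n_vertices_used = attr(w, "n_vertices_used"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize contours to the long table format
#'
#' @param contours List of [cell_contour()] objects.
#' @return data.frame with `cell_id`, `vertex_index`, `x`, `y`.
#' @export
contours_to_table <- function(contours) {
  if (inherits(contours, "cell_contour")) contours <- list(contours)
  do.call(rbind, lapply(contours, function(ct) {
    data.frame(cell_id = ct$cell_id,
               vertex_index = seq_len(nrow(ct$vertices)),
               x = ct$vertices[, 1], y = ct$vertices[, 2])
  }))
}
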