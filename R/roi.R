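#' Regions of interest
#'
#' An ROI is a simple (non-self-intersecting) closed polygon in nm, used to
#' delimit a cell for per-cell statistics such as nanocluster density. Area
#' is reported in square micrometres.
#'
#' @param vertices numeric matrix (or data.frame) with two columns, x and y
#'   in nm; the polygon is implicitly closed.
#' @return object of class `roi` with elements `vertices` and `area_um2`.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3)
    qp_param_error("an ROI needs a two-column matrix of >= 3 vertices")
  if (!all(is.finite(v))) qp_param_error("ROI vertices must be finite")
  if (.polygon_self_intersects(v))
    qp_param_error("ROI polygon must be simple (non-self-intersecting)")
  area <- abs(.shoelace(v)) / 1e6   # nm^2 -> um^2
  if (area <= 0) qp_param_error("ROI area must be > 0")
  structure(list(vertices = v, area_um2 = area), class = "roi")
}

#' Rectangular ROI helper
#' @param width,height extents in nm.
#' @param x0,y0 top-left corner in nm.
#' @return an [roi_polygon()].
#' @export
roi_rect <- function(width, height, x0 = 0, y0 = 0) {
  roi_polygon(rbind(c(x0, y0), c(x0 + width, y0),
                    c(x0 + width, y0 + height), c(x0, y0 + height)))
}

.shoelace <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      # skip edges sharing a vertex
      if (j == i || nxt[j] == i || nxt[i] == j) next
      if (.segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Test points against an ROI
#'
#' Even-odd (ray casting) point-in-polygon test; points exactly on an edge
#' count as inside.
#'
#' @param x,y numeric vectors in nm.
#' @param roi an [roi_polygon()].
#' @return logical vector.
#' @export
points_in_roi <- function(x, y, roi) {
  v <- roi$vertices
  n <- nrow(v)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read / write an ROI as a JSON polygon
#'
#' The on-disk form is `{"units": "nm", "vertices": [[x, y], ...]}`.
#'
#' @param roi an [roi_polygon()].
#' @param path JSON file path.
#' @return `read_roi`: an `roi`; `write_roi`: `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  jsonlite::write_json(
    list(units = "nm",
         vertices = unname(apply(roi$vertices, 1, as.numeric, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) qp_stop("qp_io_error", "file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_polygon(obj$vertices)
}
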