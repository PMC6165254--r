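#' Lesion contours
#'
#' A lesion contour is the ordered polygon a reader draws around the mass on
#' the B-mode panel (or directly on the elastogram). Coordinates are 0-based
#' pixel coordinates with `x` the column and `y` the row; pixel centers sit at
#' integer coordinates.
#'
#' @param x,y Numeric vectors of vertex coordinates (>= 3 vertices), in
#'   drawing order.
#' @param frame Which panel the coordinates refer to: `"b_mode"` or
#'   `"elastogram"`.
#' @param id Lesion identifier used in reports and error messages.
#' @return An object of class `lesion_contour`.
#' @export
lesion_contour <- function(x, y, frame = c("b_mode", "elastogram"),
                           id = "lesion") {
  frame <- match.arg(frame)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "elastocad_invalid_input")
  }
  if (length(x) < 3L) {
    abort(sprintf("Contour '%s' has fewer than 3 vertices.", id),
          class = "elastocad_invalid_input")
  }
  if (anyNA(x) || anyNA(y)) {
    abort(sprintf("Contour '%s' has missing coordinates.", id),
          class = "elastocad_invalid_input")
  }
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  # drop an explicitly repeated closing vertex
  n <- nrow(v)
  if (n > 3L && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (.polygon_self_intersects(v)) {
    abort(sprintf("Contour '%s' is self-intersecting.", id),
          class = "elastocad_invalid_input")
  }
  structure(list(id = id, vertices = v, frame = frame),
            class = "lesion_contour")
}

#' @export
print.lesion_contour <- function(x, ...) {
  cat(sprintf("<lesion_contour> '%s': %d vertices on the %s panel\n",
              x$id, nrow(x$vertices), x$frame))
  invisible(x)
}

# proper-intersection test between non-adjacent edges (simple polygon check)
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):n) {
      if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
      a <- v[i, ]; b <- v[nxt[i], ]; c <- v[j, ]; d <- v[nxt[j], ]
      o1 <- orient(a[1], a[2], b[1], b[2], c[1], c[2])
      o2 <- orient(a[1], a[2], b[1], b[2], d[1], d[2])
      o3 <- orient(c[1], c[2], d[1], d[2], a[1], a[2])
      o4 <- orient(c[1], c[2], d[1], d[2], b[1], b[2])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rasterize a contour to a binary lesion mask
#'
#' A pixel belongs to the mask iff its center satisfies the even-odd rule for
#' the polygon, evaluated with the standard half-open ray convention (so a
#' square with corners at 0 and s covers exactly s^2 pixel centers, and
#' abutting polygons never double-count a pixel). The rule is
#' orientation-independent, so reversing the vertex order gives an identical
#' mask, and it is equivariant under integer translations.
#'
#' @param contour A [lesion_contour].
#' @param shape Raster dimensions `c(rows, cols)` of the target image.
#' @return A logical matrix of class `lesion_mask` with attribute `area_px`.
#' @export
polygon_to_mask <- function(contour, shape) {
  stopifnot(inherits(contour, "lesion_contour"))
  shape <- as.integer(shape)
  v <- contour$vertices
  if (min(v[, 1]) < 0 || min(v[, 2]) < 0 ||
      max(v[, 1]) > shape[2] - 1L || max(v[, 2]) > shape[1] - 1L) {
    abort(sprintf("Contour '%s' extends outside a %d x %d raster.",
                  contour$id, shape[1], shape[2]),
          class = "elastocad_invalid_input")
  }
  cols <- seq.int(max(0L, floor(min(v[, 1]))), min(shape[2] - 1L, ceiling(max(v[, 1]))))
  rows <- seq.int(max(0L, floor(min(v[, 2]))), min(shape[1] - 1L, ceiling(max(v[, 2]))))
  px <- rep(cols, each = length(rows))   # x = column coordinate
  py <- rep(rows, times = length(cols))  # y = row coordinate
  inside <- .points_in_polygon(px, py, v)
  mask <- matrix(FALSE, shape[1], shape[2])
  mask[cbind(py + 1L, px + 1L)] <- inside
  area <- sum(mask)
  if (area < 1L) {
    abort(sprintf("Contour '%s' rasterizes to an empty mask (degenerate polygon).",
                  contour$id),
          class = "elastocad_degenerate")
  }
  structure(mask, class = c("lesion_mask", "matrix"), area_px = area)
}

# even-odd rule via half-open ray casting, vectorized over points
.points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[j, 1]; y1 <- v[j, 2]; x2 <- v[i, 1]; y2 <- v[i, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

#' Area of a lesion mask in pixels
#'
#' @param mask A `lesion_mask` or logical matrix.
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) {
  a <- attr(mask, "area_px")
  if (!is.null(a)) return(a)
  sum(mask)
}

#' Side-by-side panel layout
#'
#' Composite exports place the elastogram and the B-mode image side by side
#' at the same scale; transferring a contour between panels is a pure
#' translation.
#'
#' @param elastogram_offset `c(dx, dy)` translation taking B-mode panel
#'   coordinates to elastogram panel coordinates.
#' @param panel_size `c(width, height)` of the elastogram panel in pixels.
#' @return An object of class `panel_layout`.
#' @export
panel_layout <- function(elastogram_offset, panel_size) {
  stopifnot(length(elastogram_offset) == 2L, length(panel_size) == 2L)
  structure(list(elastogram_offset = as.numeric(elastogram_offset),
                 panel_size = as.numeric(panel_size)),
            class = "panel_layout")
}

#' Transfer a B-mode contour onto the elastogram panel
#'
#' @param contour A [lesion_contour] with `frame = "b_mode"`.
#' @param layout A [panel_layout].
#' @return The translated [lesion_contour] with `frame = "elastogram"`.
#' @export
transfer_contour <- function(contour, layout) {
  stopifnot(inherits(contour, "lesion_contour"), inherits(layout, "panel_layout"))
  if (contour$frame != "b_mode") {
    abort("Contour is already in the elastogram frame.",
          class = "elastocad_invalid_input")
  }
  v <- contour$vertices
  v[, 1] <- v[, 1] + layout$elastogram_offset[1]
  v[, 2] <- v[, 2] + layout$elastogram_offset[2]
  w <- layout$panel_size[1]; h <- layout$panel_size[2]
  if (min(v[, 1]) < 0 || min(v[, 2]) < 0 || max(v[, 1]) > w - 1 || max(v[, 2]) > h - 1) {
    abort(sprintf(
      "Contour '%s' falls outside the %g x %g elastogram panel after translation.",
      contour$id, w, h), class = "elastocad_invalid_input")
  }
  lesion_contour(v[, 1], v[, 2], frame = "elastogram", id = contour$id)
}

#' Read and write contour tables
#'
#' Contours travel as CSV with columns `lesion_id, vertex_index, x, y, frame`,
#' one row per vertex in drawing order.
#'
#' @param path CSV file path.
#' @return `read_contours()` returns a named list of [lesion_contour]s;
#'   `write_contours()` returns `path` invisibly.
#' @export
read_contours <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("lesion_id", "vertex_index", "x", "y", "frame")
  if (!all(need %in% names(df))) {
    abort(paste0("Contour CSV must have columns: ", paste(need, collapse = ", ")),
          class = "elastocad_io_error")
  }
  if (nrow(df) == 0L) {
    abort("Contour file contains no vertices.", class = "elastocad_invalid_input")
  }
  df <- df[order(df$lesion_id, df$vertex_index), ]
  sp <- split(df, df$lesion_id)
  lapply(sp, function(d) {
    lesion_contour(d$x, d$y, frame = d$frame[1], id = as.character(d$lesion_id[1]))
  })
}

#' @param contours A [lesion_contour] or list of them.
#' @rdname read_contours
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "lesion_contour")) contours <- list(contours)
  rows <- purrr::map_dfr(contours, function(ct) {
    tibble(lesion_id = ct$id,
           vertex_index = seq_len(nrow(ct$vertices)),
           x = ct$vertices[, 1], y = ct$vertices[, 2],
           frame = ct$frame)
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' Export a binary mask as a single-channel PNG (0/255)
#'
#' @param mask A logical matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}
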