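#' Frame specification
#'
#' Describes a pixel coordinate frame (camera or projector). Coordinates are
#' 0-based with x rightward (column) and y downward (row); the centre of pixel
#' (i, j) is at integer coordinates (x = i, y = j). Sub-pixel positions are
#' real-valued everywhere; rounding happens only at rasterisation.
#'
#' @param width,height frame size in pixels (>= 1).
#' @param name frame label, conventionally `"camera"` or `"projector"`.
#' @return A `frame_spec` object.
#' @examples
#' camera_frame()   # 1920 x 1088, the high-quality camera sensor at 10x
#' projector_frame()
#' @export
frame_spec <- function(width, height, name = "frame") {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(length(width) == 1L, length(height) == 1L,
            is.finite(width), is.finite(height), width >= 1L, height >= 1L)
  structure(list(width = width, height = height, name = as.character(name)),
            class = "frame_spec")
}

#' @rdname frame_spec
#' @export
camera_frame <- function(width = 1920, height = 1088) {
  frame_spec(width, height, "camera")
}

#' @rdname frame_spec
#' @param width,height projector frame size; the default 640 x 360 is a
#'   configurable stand-in, never assumed by any algorithm.
#' @export
projector_frame <- function(width = 640, height = 360) {
  frame_spec(width, height, "projector")
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf("<frame_spec '%s' %d x %d px>\n", x$name, x$width, x$height))
  invisible(x)
}

#' Affine coordinate map
#'
#' The 2 x 3 affine transform between pixel frames: (x, y) maps to
#' (a11 x + a12 y + a13, a21 x + a22 y + a23). This is the product of
#' calibration: the six-parameter map relating camera and projector pixel
#' coordinates.
#'
#' @param matrix numeric 2 x 3 coefficient matrix.
#' @param source,target frame labels the map converts between.
#' @return An `affine_map` object.
#' @export
affine_map <- function(matrix, source = "camera", target = "projector") {
  matrix <- base::matrix(as.numeric(matrix), 2L, 3L)
  stopifnot(all(is.finite(matrix)))
  structure(list(matrix = matrix, source = source, target = target),
            class = "affine_map")
}

#' @rdname affine_map
#' @export
identity_map <- function(source = "camera", target = "projector") {
  affine_map(cbind(diag(2), c(0, 0)), source, target)
}

#' Build an affine map from scale / rotation / translation
#'
#' Convenience constructor: rotation (degrees, about the origin) composed with
#' anisotropic scale then translation.
#'
#' @param scale length-1 or length-2 scale factor.
#' @param rotation_deg rotation angle in degrees, positive = x-toward-y.
#' @param translation length-2 offset (tx, ty), in target-frame pixels.
#' @inheritParams affine_map
#' @export
affine_from_srt <- function(scale = 1, rotation_deg = 0, translation = c(0, 0),
                            source = "projector", target = "camera") {
  s <- rep_len(as.numeric(scale), 2L)
  th <- rotation_deg * pi / 180
  R <- base::matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  A <- R %*% diag(s)
  affine_map(cbind(A, as.numeric(translation)), source, target)
}

#' @export
print.affine_map <- function(x, ...) {
  cat(sprintf("<affine_map %s -> %s>\n", x$source, x$target))
  print(round(x$matrix, 6))
  invisible(x)
}

map_det <- function(map) {
  m <- map$matrix
  m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
}

#' Polyline in a named pixel frame
#'
#' An ordered list of real-valued (x, y) vertices, e.g. a wound-edge contour.
#'
#' @param xy numeric matrix (or two-column object) of vertices, columns x, y.
#' @param frame name of the frame the coordinates live in.
#' @return A numeric matrix with columns `x`, `y`, class `polyline`, and a
#'   `frame` attribute.
#' @export
polyline <- function(xy, frame = "camera") {
  xy <- base::matrix(as.numeric(as.matrix(xy)), ncol = 2L,
                     dimnames = list(NULL, c("x", "y")))
  stopifnot(all(is.finite(xy)))
  structure(xy, class = c("polyline", "matrix"), frame = frame)
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline, %d vertices, frame '%s'>\n", nrow(x),
              attr(x, "frame") %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Arc length of a polyline
#' @param line a `polyline` or two-column matrix of vertices.
#' @return total polygonal arc length in pixels.
#' @export
polyline_length <- function(line) {
  if (nrow(line) < 2L) return(0)
  sum(sqrt(rowSums(diff(unclass(line))^2)))
}

#' Apply an affine map to points
#'
#' @param map an `affine_map`.
#' @param points a `polyline` or n x 2 matrix of (x, y) coordinates.
#' @return points of the same shape, in the map's target frame.
#' @export
apply_map <- function(map, points) {
  stopifnot(inherits(map, "affine_map"))
  pts <- base::matrix(as.numeric(as.matrix(points)), ncol = 2L)
  if (nrow(pts) == 0L) return(polyline(pts[, , drop = FALSE], map$target))
  m <- map$matrix
  out <- cbind(m[1, 1] * pts[, 1] + m[1, 2] * pts[, 2] + m[1, 3],
               m[2, 1] * pts[, 1] + m[2, 2] * pts[, 2] + m[2, 3])
  polyline(out, map$target)
}

#' Invert an affine map
#'
#' @param map an `affine_map` with non-degenerate linear part.
#' @return the inverse `affine_map` (source and target swapped).
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "affine_map"))
  d <- map_det(map)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("degenerate transform: linear part is not invertible (|det| < 1e-12)")
  A <- map$matrix[, 1:2]
  t <- map$matrix[, 3]
  Ainv <- base::matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2L, 2L) / d
  affine_map(cbind(Ainv, -Ainv %*% t), source = map$target, target = map$source)
}

#' Compose two affine maps
#'
#' `compose_map(m2, m1)` is the map applying `m1` first, then `m2`.
#' @param m2,m1 `affine_map` objects with compatible frames.
#' @export
compose_map <- function(m2, m1) {
  A2 <- m2$matrix[, 1:2]; A1 <- m1$matrix[, 1:2]
  affine_map(cbind(A2 %*% A1, A2 %*% m1$matrix[, 3] + m2$matrix[, 3]),
             source = m1$source, target = m2$target)
}

#' Rasterise a polyline into a binary image
#'
#' Stamps the polyline into a frame-sized 0/1 image: a pixel is on iff the
#' Euclidean distance from its centre to the polyline is at most
#' `thickness / 2`. Segments are clipped to the frame; an empty polyline gives
#' an all-off image.
#'
#' @param line a `polyline` (or n x 2 matrix); single-vertex lines stamp a dot.
#' @param frame the `frame_spec` to draw into.
#' @param thickness stroke thickness in pixels (>= 1).
#' @return numeric `height x width` matrix of 0/1 values (row = y, col = x).
#' @export
rasterize_polyline <- function(line, frame, thickness = 1) {
  stopifnot(inherits(frame, "frame_spec"), thickness >= 1)
  img <- base::matrix(0, frame$height, frame$width)
  pts <- base::matrix(as.numeric(as.matrix(line)), ncol = 2L)
  if (nrow(pts) == 0L) return(img)
  r <- thickness / 2
  segs <- if (nrow(pts) == 1L) list(c(1L, 1L)) else
    lapply(seq_len(nrow(pts) - 1L), function(i) c(i, i + 1L))
  for (s in segs) {
    p1 <- pts[s[1], ]; p2 <- pts[s[2], ]
    x0 <- max(0L, floor(min(p1[1], p2[1]) - r))
    x1 <- min(frame$width - 1L, ceiling(max(p1[1], p2[1]) + r))
    y0 <- max(0L, floor(min(p1[2], p2[2]) - r))
    y1 <- min(frame$height - 1L, ceiling(max(p1[2], p2[2]) + r))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
    d <- dist_point_segment(gx, gy, p1, p2)
    on <- d <= r
    if (any(on)) img[cbind(gy[on] + 1L, gx[on] + 1L)] <- 1
  }
  img
}

# distance from points (px, py) to segment p1-p2 (all 0-based real coords)
dist_point_segment <- function(px, py, p1, p2) {
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - p1[1])^2 + (py - p1[2])^2))
  t <- pmin(1, pmax(0, ((px - p1[1]) * dx + (py - p1[2]) * dy) / L2))
  sqrt((px - (p1[1] + t * dx))^2 + (py - (p1[2] + t * dy))^2)
}

#' Serialise / deserialise an affine map as JSON
#'
#' The JSON layout is `{"matrix": [[a11,a12,a13],[a21,a22,a23]],
#' "source": "camera", "target": "projector"}`.
#'
#' @param map an `affine_map`.
#' @param path file to write / read.
#' @export
write_affine_json <- function(map, path) {
  stopifnot(inherits(map, "affine_map"))
  obj <- list(matrix = lapply(1:2, function(i) map$matrix[i, ]),
              source = map$source, target = map$target)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$matrix
  if (is.list(m)) m <- do.call(rbind, m)
  affine_map(base::matrix(as.numeric(t(t(m))), 2L, 3L),
             source = obj$source %||% "camera",
             target = obj$target %||% "projector")
}

#' Read / write 8-bit grayscale images
#'
#' Images are numeric `height x width` matrices with values in \[0, 255\];
#' element `[y + 1, x + 1]` is the pixel at 0-based coordinates (x, y).
#' PNG and TIFF are supported by file extension.
#'
#' @param path image file path (.png, .tif, .tiff).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image extension: ", ext))
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                       c(1, 2), mean)
  a * 255
}

#' @rdname read_image
#' @param img numeric matrix in \[0, 255\].
#' @export
write_image <- function(img, path) {
  a <- pmin(pmax(img / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(a, path),
         tif = , tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
         stop("unsupported image extension: ", ext))
  invisible(path)
}
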