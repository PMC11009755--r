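#' Segmentation settings for monolayer detection
#'
#' @param contrast_method `"stretch"` (percentile contrast stretch, default)
#'   or `"clahe"` (adaptive histogram equalisation).
#' @param stretch_percentiles lower/upper percentiles for the stretch.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold intensity cutoff in \[0, 255\] for `"fixed"`.
#' @param polarity `"auto"` picks the larger-area class as the monolayer;
#'   `"dark"` / `"bright"` force the monolayer to be the darker or brighter
#'   class.
#' @param min_object_px connected components smaller than this are removed.
#' @param closing_radius radius (px) of the morphological closing brush.
#' @param edge_margin_px contour vertices within this distance of the image
#'   border are discarded before picking the wound edge.
#' @export
segmentation_settings <- function(contrast_method = c("stretch", "clahe"),
                                  stretch_percentiles = c(2, 98),
                                  threshold_method = c("otsu", "fixed"),
                                  fixed_threshold = 128,
                                  polarity = c("auto", "dark", "bright"),
                                  min_object_px = 64,
                                  closing_radius = 3,
                                  edge_margin_px = 3) {
  contrast_method <- match.arg(contrast_method)
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  stopifnot(fixed_threshold >= 0, fixed_threshold <= 255,
            min_object_px >= 0, closing_radius >= 0, edge_margin_px >= 0)
  structure(list(contrast_method = contrast_method,
                 stretch_percentiles = stretch_percentiles,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 polarity = polarity, min_object_px = min_object_px,
                 closing_radius = closing_radius,
                 edge_margin_px = edge_margin_px),
            class = "segmentation_settings")
}

#' Segment the cell monolayer in a brightfield image
#'
#' Contrast enhancement, thresholding, morphological closing, and small-object
#' removal. The monolayer is returned as the foreground (1) class; polarity is
#' chosen automatically as the larger-area class by default (in a scratch
#' assay the confluent monolayer surrounds the wound band).
#'
#' @param image 8-bit grayscale camera image (matrix in \[0, 255\]).
#' @param settings a [segmentation_settings()] object.
#' @return binary matrix, 1 = monolayer.
#' @export
segment_monolayer <- function(image, settings = segmentation_settings()) {
  img <- as.matrix(image)
  if (settings$contrast_method == "stretch") {
    q <- stats::quantile(img, settings$stretch_percentiles / 100, names = FALSE)
    if (q[2] > q[1]) img <- (img - q[1]) / (q[2] - q[1]) * 255
    img <- pmin(pmax(img, 0), 255)
  } else {
    e <- EBImage::clahe(EBImage::Image(img / 255), nx = 8)
    img <- base::matrix(EBImage::imageData(e), nrow(img), ncol(img)) * 255
  }
  thr <- if (settings$threshold_method == "otsu")
    EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1)) * 255
  else settings$fixed_threshold
  dark <- img < thr
  frac_dark <- mean(dark)
  if (frac_dark < 1e-4 || frac_dark > 1 - 1e-4)
    stop("degenerate segmentation: thresholding produced a single class")
  fg <- switch(settings$polarity,
               dark = dark,
               bright = !dark,
               auto = if (frac_dark >= 0.5) dark else !dark)
  mask <- base::matrix(as.numeric(fg), nrow(img), ncol(img))
  if (settings$closing_radius > 0) {
    k <- EBImage::makeBrush(2 * floor(settings$closing_radius) + 1, "disc")
    mask <- EBImage::closing(mask, k)
    mask <- EBImage::opening(mask, k)   # also despeckle the wound interior
  }
  if (settings$min_object_px > 0) {
    lab <- base::matrix(as.numeric(EBImage::bwlabel(mask)),
                        nrow(mask), ncol(mask))
    if (max(lab) > 0) {
      counts <- tabulate(lab[lab > 0])
      small <- which(counts < settings$min_object_px)
      if (length(small)) mask[lab %in% small] <- 0
    }
  }
  if (sum(mask) == 0 || sum(mask) == length(mask))
    stop("degenerate segmentation: mask is a single class after cleanup")
  mask
}

#' Extract the leading wound edge from a segmentation mask
#'
#' Traces the sub-pixel iso-contours of the mask at level 0.5, discards
#' vertices within `edge_margin_px` of the image border (frame-border
#' artefacts are never a wound edge), splits contours at the discarded gaps,
#' and returns the longest remaining continuous chain — the leading wound
#' edge — as an ordered polyline. With `both_fronts = TRUE` the two longest
#' chains are returned for symmetric-illumination experiments.
#'
#' @param mask binary monolayer mask.
#' @param edge_margin_px border exclusion width, px.
#' @param smooth_window odd moving-average window (vertices) applied before
#'   simplification; 0 disables.
#' @param simplify_tol Douglas-Peucker simplification tolerance, px.
#' @param both_fronts return a list of the two longest chains.
#' @return a `polyline` (or list of two) in the camera frame.
#' @export
extract_wound_edge <- function(mask, edge_margin_px = 3, smooth_window = 5,
                               simplify_tol = 0.5, both_fronts = FALSE) {
  mask <- as.matrix(mask)
  h <- nrow(mask); w <- ncol(mask)
  cl <- withCallingHandlers(
    grDevices::contourLines(x = 0:(w - 1), y = 0:(h - 1),
                            z = t(mask), levels = 0.5),
    warning = function(w) {
      if (grepl("all z values are equal", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(cl) == 0) stop("no edge found: mask has no internal boundary")
  chains <- list()
  for (cc in cl) {
    keep <- cc$x >= edge_margin_px & cc$x <= (w - 1) - edge_margin_px &
      cc$y >= edge_margin_px & cc$y <= (h - 1) - edge_margin_px
    if (!any(keep)) next
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      idx <- starts[r]:ends[r]
      if (length(idx) >= 2)
        chains[[length(chains) + 1L]] <- cbind(cc$x[idx], cc$y[idx])
    }
  }
  if (length(chains) == 0)
    stop("no edge found: all contours lie within the border margin")
  lens <- vapply(chains, function(ch) polyline_length(ch), numeric(1))
  ord <- order(lens, decreasing = TRUE)
  finish <- function(ch) {
    if (smooth_window >= 3 && nrow(ch) > smooth_window)
      ch <- smooth_polyline(ch, smooth_window)
    if (simplify_tol > 0) ch <- simplify_polyline(ch, simplify_tol)
    polyline(ch, frame = "camera")
  }
  if (both_fronts) {
    lapply(chains[ord[seq_len(min(2, length(ord)))]], finish)
  } else {
    finish(chains[[ord[1]]])
  }
}

# centred moving average, endpoints kept
smooth_polyline <- function(ch, window) {
  k <- rep(1 / window, window)
  pad <- floor(window / 2)
  sm <- function(v) {
    vv <- c(rep(v[1], pad), v, rep(v[length(v)], pad))
    as.numeric(stats::filter(vv, k))[(pad + 1):(pad + length(v))]
  }
  cbind(sm(ch[, 1]), sm(ch[, 2]))
}

# Douglas-Peucker simplification (iterative, stack-based)
simplify_polyline <- function(ch, tol) {
  n <- nrow(ch)
  if (n <= 2) return(ch)
  keep <- logical(n); keep[c(1, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- dist_point_segment(ch[mid, 1], ch[mid, 2], ch[i, ], ch[j, ])
    k <- which.max(d)
    if (d[k] > tol) {
      k <- mid[k]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  ch[keep, , drop = FALSE]
}

#' Convert a camera-frame edge to a projector light pattern
#'
#' Maps the edge vertices through the calibration (camera -> projector) and
#' rasterises them with the requested stroke thickness, clipped to the
#' projector frame.
#'
#' @param edge a `polyline` in the camera frame.
#' @param calib camera->projector `affine_map`.
#' @param projector projector `frame_spec`.
#' @param thickness_pp stroke thickness in projector px (>= 1).
#' @return binary projector-frame matrix.
#' @export
edge_to_pattern <- function(edge, calib, projector = projector_frame(),
                            thickness_pp = 5) {
  stopifnot(thickness_pp >= 1)
  if (is.null(edge) || nrow(edge) == 0)
    return(base::matrix(0, projector$height, projector$width))
  mapped <- apply_map(calib, edge)
  inside <- mapped[, 1] >= 0 & mapped[, 1] <= projector$width - 1 &
    mapped[, 2] >= 0 & mapped[, 2] <= projector$height - 1
  if (!any(inside))
    warning("mapped edge lies entirely outside the projector frame")
  rasterize_polyline(mapped, projector, thickness_pp)
}

#' Full wound-targeting pipeline
#'
#' Composes [segment_monolayer()], [extract_wound_edge()] and
#' [edge_to_pattern()]: from a brightfield camera image to the projector
#' pattern tracing the leading wound edge. Stage failures are reported with
#' the stage name.
#'
#' @param image 8-bit grayscale camera image.
#' @param calib camera->projector `affine_map`.
#' @param settings a [segmentation_settings()].
#' @param projector projector `frame_spec`.
#' @param thickness_pp pattern stroke thickness, projector px.
#' @return A `targeting_result`: list with `mask`, `edge` (camera-frame
#'   polyline), `pattern` (projector binary image) and `edge_length_px`.
#' @export
target_wound <- function(image, calib, settings = segmentation_settings(),
                         projector = projector_frame(), thickness_pp = 5) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  mask <- stage("segment_monolayer", segment_monolayer(image, settings))
  edge <- stage("extract_wound_edge",
                extract_wound_edge(mask, settings$edge_margin_px))
  pattern <- stage("edge_to_pattern",
                   edge_to_pattern(edge, calib, projector, thickness_pp))
  structure(list(mask = mask, edge = edge, pattern = pattern,
                 edge_length_px = polyline_length(edge)),
            class = "targeting_result")
}

#' @export
print.targeting_result <- function(x, ...) {
  cat(sprintf("<targeting_result: edge %d vertices, %.1f px; pattern %d on-pixels>\n",
              nrow(x$edge), x$edge_length_px, sum(x$pattern > 0)))
  invisible(x)
}

#' Mean distance from points to a polyline
#'
#' Evaluation helper: the mean over `points` of the Euclidean distance to the
#' nearest segment of `line`. Used to score detected edges and back-mapped
#' patterns against the simulator's ground truth.
#'
#' @param points n x 2 matrix of (x, y).
#' @param line a `polyline` or two-column matrix.
#' @param summary `"mean"`, `"max"`, or `"none"` (per-point distances).
#' @export
distance_to_polyline <- function(points, line, summary = c("mean", "max", "none")) {
  summary <- match.arg(summary)
  P <- base::matrix(as.numeric(as.matrix(points)), ncol = 2L)
  L <- base::matrix(as.numeric(as.matrix(line)), ncol = 2L)
  if (nrow(L) < 2) stop("line needs at least 2 vertices")
  d <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(L) - 1L)) {
    d <- pmin(d, dist_point_segment(P[, 1], P[, 2], L[i, ], L[i + 1L, ]))
  }
  switch(summary, mean = mean(d), max = max(d), none = d)
}
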