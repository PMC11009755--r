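#' Calibration hyper-parameters
#'
#' Collects the user-tunable and derived quantities of the scan-zone
#' calibration:
#' \itemize{
#'   \item `brightness` — projector drive level used for scan patterns, \[0, 255\].
#'   \item `threshold` — camera intensity cutoff for the illuminable region.
#'   \item `b` — border variable in \[0, 1\]: 0 places scan zones directly on
#'     the border of the illuminable region, 1 packs them mutually adjacent at
#'     its centre; 1/3 is an effective compromise in practice.
#'   \item `l_p` — scan-line breadth in projector px (lower = more accurate,
#'     slower; 10 is usually sufficient).
#'   \item `G_p`, `G_c` — projected and superimposed reference grid spacings.
#'   \item `g_p`, `g_c` — user-observed square sizes of the two grids, in
#'     common relative units, from which the magnification is estimated.
#'   \item `M`, `l_c`, `s_c` — derived: magnification, camera-frame scan-line
#'     breadth (`l_c = M l_p`) and scan-zone breadth (`s_c ~ 2 l_c`).
#' }
#'
#' @param brightness,threshold intensities in \[0, 255\].
#' @param b border variable in \[0, 1\].
#' @param l_p scan-line breadth, projector px >= 1.
#' @param G_p,G_c grid spacings (projector px / camera px).
#' @param g_p,g_c observed grid-square sizes (relative units), or `NA` to have
#'   [calibrate()] measure them on the bench.
#' @param M magnification, or `NA` to derive it from the grid observations.
#' @param n_zones number of scan zones (3 or 4; 4 gives least-squares
#'   redundancy over the minimum).
#' @param use_centroid use the intensity-weighted centroid peak locator
#'   (sub-band accuracy); `FALSE` selects plain argmax of band intensity.
#' @param contrast_floor_mads zone peak must exceed this multiple of the
#'   dark-frame noise MAD or the zone is dropped.
#' @param residual_warn RMS reprojection residual (projector px) above which
#'   [calibrate()] warns.
#' @return A `calibration_params` object.
#' @export
calibration_params <- function(brightness = 200, threshold = 60, b = 1 / 3,
                               l_p = 10, G_p = 32, G_c = 32,
                               g_p = NA, g_c = NA, M = NA,
                               n_zones = 4, use_centroid = TRUE,
                               contrast_floor_mads = 5, residual_warn = 3) {
  stopifnot(brightness > 0, brightness <= 255,
            threshold >= 0, threshold <= 255,
            b >= 0, b <= 1, l_p >= 1, G_p > 0, G_c > 0,
            n_zones %in% c(3, 4))
  structure(list(brightness = brightness, threshold = threshold, b = b,
                 l_p = l_p, G_p = G_p, G_c = G_c, g_p = g_p, g_c = g_c,
                 M = M, n_zones = as.integer(n_zones),
                 use_centroid = isTRUE(use_centroid),
                 contrast_floor_mads = contrast_floor_mads,
                 residual_warn = residual_warn),
            class = "calibration_params")
}

#' Detect the illuminable region of the camera frame
#'
#' Step 1 of the calibration: capture with every projector pixel on, subtract
#' a dark-frame capture, threshold the difference, and keep the largest
#' connected component (this rejects stray light artefacts near the border).
#'
#' @param bench a bench backend.
#' @param brightness projector drive level for the all-on pattern.
#' @param threshold difference-intensity cutoff in \[0, 255\].
#' @param scene optional scene on the stage during calibration.
#' @return An `illuminable_region`: list with `mask` (binary camera matrix),
#'   `bbox` (`c(x_min, y_min, x_max, y_max)`, 0-based), and `area` (px^2).
#' @export
detect_illuminable_region <- function(bench, brightness = 200, threshold = 60,
                                      scene = NULL) {
  stopifnot(brightness > 0, threshold >= 0, threshold <= 255)
  all_on <- base::matrix(brightness, bench$projector$height,
                         bench$projector$width)
  lit <- bench_capture(bench, all_on, scene)
  dark <- bench_capture(bench, NULL, scene)
  diff <- lit - dark
  mask <- diff >= threshold
  if (!any(mask))
    stop(sprintf(paste0("no illuminable region at this threshold ",
                        "(max observed difference %.1f < threshold %.1f)"),
                 max(diff), threshold))
  lab <- EBImage::bwlabel(base::matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- base::matrix(as.numeric(lab), nrow(mask), ncol(mask))
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  mask <- base::matrix(as.numeric(lab == keep), nrow(mask), ncol(mask))
  idx <- which(mask > 0, arr.ind = TRUE)
  bbox <- c(x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
            x_max = max(idx[, 2]) - 1, y_max = max(idx[, 1]) - 1)
  structure(list(mask = mask, bbox = bbox, area = sum(mask),
                 dark_frame = dark),
            class = "illuminable_region")
}

#' @export
print.illuminable_region <- function(x, ...) {
  cat(sprintf("<illuminable_region area %d px^2, bbox [%g, %g] x [%g, %g]>\n",
              as.integer(x$area), x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

#' Estimate the projector-to-camera magnification from grid observations
#'
#' Solves `g_c / G_c ~ M g_p / G_p` for M: the user projects a grid with
#' spacing `G_p`, superimposes a reference grid with spacing `G_c` on the
#' camera view, and reports the observed square sizes `g_p` and `g_c` in any
#' common relative units.
#'
#' @param G_p projected grid spacing, projector px.
#' @param g_p observed projected-grid square size, relative units.
#' @param G_c reference grid spacing, camera px.
#' @param g_c observed reference-grid square size, same relative units.
#' @return the magnification estimate M.
#' @export
estimate_magnification <- function(G_p, g_p, G_c, g_c) {
  vals <- c(G_p = G_p, g_p = g_p, G_c = G_c, g_c = g_c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all grid quantities must be positive and finite")
  (g_c * G_p) / (G_c * g_p)
}

#' Scan-zone breadth from the scan-line breadth and magnification
#'
#' At least two observed scan lines must be able to intersect a zone, so the
#' camera-frame zone breadth is twice the camera-frame scan-line breadth:
#' `s_c ~ 2 l_c = 2 M l_p`. The result is rounded up to the next odd integer
#' (>= 1) so a zone has a well-defined centre pixel.
#'
#' @param l_p scan-line breadth, projector px (>= 1).
#' @param M magnification (> 0).
#' @return scan-zone breadth `s_c`, camera px (odd integer).
#' @export
scan_zone_breadth <- function(l_p, M) {
  stopifnot(l_p >= 1, M > 0)
  s <- 2 * M * l_p
  s <- ceiling(s)
  if (s %% 2 == 0) s <- s + 1
  max(1, s)
}

#' Scan-zone breadth directly from grid observations
#'
#' The combined form `s_c ~ 2 l_p g_c G_p / (G_c g_p)`, algebraically equal to
#' composing [estimate_magnification()] with [scan_zone_breadth()] before the
#' odd rounding.
#'
#' @inheritParams estimate_magnification
#' @inheritParams scan_zone_breadth
#' @param round_odd apply the odd-integer rounding (default `TRUE`); `FALSE`
#'   returns the raw real value.
#' @export
scan_zone_breadth_from_grids <- function(l_p, G_p, g_p, G_c, g_c,
                                         round_odd = TRUE) {
  vals <- c(G_p, g_p, G_c, g_c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all grid quantities must be positive and finite")
  s <- 2 * l_p * g_c * G_p / (G_c * g_p)
  if (!round_odd) return(s)
  s <- ceiling(s)
  if (s %% 2 == 0) s <- s + 1
  max(1, s)
}

#' Place scan zones inside the illuminable region
#'
#' Zone centres sit on the diagonals of the region's bounding box, at a
#' per-axis offset from the centre of `(1 - b) * h + b * s_c / 2` where `h` is
#' the bbox half-extent: at `b = 0` the centres lie directly on the border; at
#' `b = 1` the zones are mutually adjacent around the centre. Zones whose
#' square does not intersect the mask are nudged inward along their corner
#' diagonal until they do.
#'
#' @param region an `illuminable_region`.
#' @param b border variable in \[0, 1\].
#' @param s_c zone breadth, camera px.
#' @param n_zones 3 or 4 zones (4 = one per bbox corner).
#' @return list of scan zones, each `list(centre = c(x, y), breadth = s_c,
#'   pixels = <camera matrix indices of zone-square pixels on the mask>,
#'   cam_point = <centroid of those pixels>)`. Intensities are measured, and
#'   the camera-side correspondence point taken, over the zone square's
#'   intersection with the illuminable mask, so border zones (b near 0, or a
#'   rotated footprint) stay photometrically consistent.
#' @export
place_scan_zones <- function(region, b = 1 / 3, s_c, n_zones = 4) {
  stopifnot(b >= 0, b <= 1, n_zones %in% c(3, 4), s_c >= 1)
  bb <- region$bbox
  cx <- (bb[["x_min"]] + bb[["x_max"]]) / 2
  cy <- (bb[["y_min"]] + bb[["y_max"]]) / 2
  hx <- (bb[["x_max"]] - bb[["x_min"]]) / 2
  hy <- (bb[["y_max"]] - bb[["y_min"]]) / 2
  off_x <- (1 - b) * hx + b * (s_c / 2)
  off_y <- (1 - b) * hy + b * (s_c / 2)
  dirs <- list(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))[seq_len(n_zones)]
  zones <- lapply(dirs, function(d) {
    centre <- c(cx + d[1] * off_x, cy + d[2] * off_y)
    # nudge inward along the corner diagonal until the square meets the mask
    step <- 0
    max_step <- max(off_x, off_y)
    px <- zone_mask_pixels(centre, s_c, region$mask)
    while (length(px$idx) == 0 && step < max_step) {
      step <- step + max(1, s_c / 4)
      centre <- c(cx + d[1] * max(0, off_x - step),
                  cy + d[2] * max(0, off_y - step))
      px <- zone_mask_pixels(centre, s_c, region$mask)
    }
    if (length(px$idx) == 0)
      stop("region too small to host the requested scan zones")
    list(centre = centre, breadth = s_c, pixels = px$idx,
         cam_point = px$centroid)
  })
  # mutual-overlap check: region must host the zones distinctly
  if (n_zones >= 3) {
    cs <- do.call(rbind, lapply(zones, `[[`, "cam_point"))
    if (any(duplicated(round(cs, 6))))
      stop("region too small to host the requested scan zones")
  }
  zones
}

# indices (into the camera matrix) and centroid of zone-square pixels on mask
zone_mask_pixels <- function(centre, s_c, mask) {
  half <- floor(s_c / 2)
  x0 <- max(0, round(centre[1]) - half); x1 <- min(ncol(mask) - 1, round(centre[1]) + half)
  y0 <- max(0, round(centre[2]) - half); y1 <- min(nrow(mask) - 1, round(centre[2]) + half)
  if (x0 > x1 || y0 > y1) return(list(idx = integer(0), centroid = centre))
  xs <- x0:x1; ys <- y0:y1
  sub <- mask[ys + 1L, xs + 1L, drop = FALSE] > 0
  if (!any(sub)) return(list(idx = integer(0), centroid = centre))
  on <- which(sub, arr.ind = TRUE)
  gx <- xs[on[, 2]]; gy <- ys[on[, 1]]
  idx <- (gx) * nrow(mask) + gy + 1L     # column-major index into [h, w]
  list(idx = as.integer(idx), centroid = c(mean(gx), mean(gy)))
}

# mean intensity over the zone's mask pixels (img is a camera-frame matrix)
zone_mean <- function(img, zone) {
  if (length(zone$pixels) == 0) return(0)
  mean(img[zone$pixels])
}

#' Sweep scan bands across one projector axis
#'
#' Steps 2-3 of the calibration: sequentially illuminate adjacent bands of
#' `l_p` projector columns (or rows) and record, for every scan zone, the mean
#' camera intensity inside the zone square minus its dark-frame mean.
#' Bands are adjacent and non-overlapping with stride `l_p`; the final
#' partial band is clipped at the frame edge.
#'
#' @param bench a bench backend.
#' @param axis `"columns"` or `"rows"`.
#' @param l_p band breadth in projector px.
#' @param zones scan zones from [place_scan_zones()].
#' @param brightness projector drive level.
#' @param dark_frame optional pre-captured dark frame (re-captured if `NULL`).
#' @param scene optional scene on the stage.
#' @return A `scan_profile`: list with `axis`, `band_breadth`, and
#'   `intensities` (matrix, bands x zones).
#' @export
run_axis_scan <- function(bench, axis = c("columns", "rows"), l_p, zones,
                          brightness = 200, dark_frame = NULL, scene = NULL) {
  axis <- match.arg(axis)
  stopifnot(l_p >= 1, length(zones) >= 1)
  pw <- bench$projector$width; ph <- bench$projector$height
  extent <- if (axis == "columns") pw else ph
  n_bands <- ceiling(extent / l_p)
  if (is.null(dark_frame)) dark_frame <- bench_capture(bench, NULL, scene)
  dark_means <- vapply(zones, function(z) zone_mean(dark_frame, z), numeric(1))
  intens <- base::matrix(0, n_bands, length(zones))
  for (k in seq_len(n_bands) - 1L) {
    lo <- k * l_p
    hi <- min(extent, (k + 1L) * l_p) - 1L
    pattern <- base::matrix(0, ph, pw)
    if (axis == "columns") pattern[, (lo:hi) + 1L] <- brightness
    else pattern[(lo:hi) + 1L, ] <- brightness
    img <- tryCatch(bench_capture(bench, pattern, scene),
                    error = function(e)
                      stop(sprintf("capture failed at band %d: %s", k,
                                   conditionMessage(e))))
    intens[k + 1L, ] <- vapply(zones, function(z) zone_mean(img, z),
                               numeric(1)) - dark_means
  }
  structure(list(axis = axis, band_breadth = l_p, intensities = intens,
                 dark_frame = dark_frame),
            class = "scan_profile")
}

#' Estimate scan-zone positions in the projector frame
#'
#' Step 4: per zone and axis, locate the bands with the highest measured
#' intensities. Default locator is the intensity-weighted centroid of band
#' centres over all bands above `centroid_floor_frac` of the zone's peak
#' (sub-band accuracy: an affine map sends region centroids to region
#' centroids, so the full photometric centroid is an almost unbiased reader
#' of the zone's projector position, while cutting the profile at a high
#' fraction of the peak biases it by up to half a band).
#' `use_centroid = FALSE` uses the bare band argmax (ties broken toward the
#' lower band index). With pixel centres at integer coordinates, 0-based band
#' k (projector pixels `k l_p` to `(k+1) l_p - 1`) has photometric centre
#' `(k + 0.5) l_p - 0.5`.
#'
#' Zones whose peak is below `contrast_floor` are dropped with a warning; if
#' fewer than 3 zones survive, calibration cannot proceed.
#'
#' @param col_profile,row_profile `scan_profile`s from [run_axis_scan()].
#' @param l_p band breadth used for the scans.
#' @param use_centroid centroid (default) or argmax locator.
#' @param contrast_floor minimum acceptable zone peak intensity.
#' @param centroid_floor_frac bands below this fraction of the zone's peak are
#'   excluded from the centroid (suppresses noise-only bands).
#' @return list with `points` (n x 2 matrix of projector (x, y)), and `kept`
#'   (indices of surviving zones).
#' @export
estimate_zone_positions <- function(col_profile, row_profile, l_p,
                                    use_centroid = TRUE, contrast_floor = 0,
                                    centroid_floor_frac = 0.05) {
  stopifnot(inherits(col_profile, "scan_profile"),
            inherits(row_profile, "scan_profile"),
            col_profile$axis == "columns", row_profile$axis == "rows")
  n_zones <- ncol(col_profile$intensities)
  locate <- function(prof) {
    i <- pmax(prof, 0)
    peak <- max(i)
    # band k spans pixels [k l_p, (k+1) l_p - 1]; with pixel centres at
    # integer coordinates its photometric centre is (k + 0.5) l_p - 0.5
    if (!use_centroid) return((which.max(i) - 1 + 0.5) * l_p - 0.5)
    # contiguous support around the peak
    k0 <- which.max(i)
    l <- k0; while (l > 1 && i[l - 1] > centroid_floor_frac * peak) l <- l - 1
    r <- k0; while (r < length(i) && i[r + 1] > centroid_floor_frac * peak) r <- r + 1
    sel <- l:r
    centres <- (sel - 1 + 0.5) * l_p - 0.5
    if (length(sel) >= 3) {
      # partial edge bands: under near-uniform coverage their light occupies a
      # strip of width lambda at the inner side, so their photometric centre
      # sits lambda/2 inside the inner band edge, not at the band centre
      plateau <- max(i[sel])
      lam_l <- min(1, i[l] / plateau) * l_p
      lam_r <- min(1, i[r] / plateau) * l_p
      centres[1] <- l * l_p - lam_l / 2 - 0.5        # right edge of band l-1
      centres[length(sel)] <- (r - 1) * l_p + lam_r / 2 - 0.5
    }
    sum(centres * i[sel]) / sum(i[sel])
  }
  pts <- base::matrix(NA_real_, n_zones, 2L)
  kept <- logical(n_zones)
  for (z in seq_len(n_zones)) {
    pc <- max(col_profile$intensities[, z])
    pr <- max(row_profile$intensities[, z])
    if (min(pc, pr) < contrast_floor) {
      warning(sprintf("zone %d dropped: peak contrast %.2f below floor %.2f",
                      z, min(pc, pr), contrast_floor))
      next
    }
    kept[z] <- TRUE
    pts[z, ] <- c(locate(col_profile$intensities[, z]),
                  locate(row_profile$intensities[, z]))
  }
  if (sum(kept) < min(3L, n_zones))
    stop("fewer than 3 scan zones with usable contrast; calibration failed")
  list(points = pts[kept, , drop = FALSE], kept = which(kept))
}

#' Fit the camera-to-projector affine map from point correspondences
#'
#' Step 5: least-squares solution of the six-parameter affine transform from
#' camera points to projector points, with the RMS reprojection residual in
#' projector px. Exact (residual < 1e-9) when the pairs are affine-consistent.
#'
#' @param camera_points,projector_points n x 2 matrices of corresponding
#'   (x, y) coordinates, n >= 3, camera points not collinear.
#' @return A `calibration_result`: list with `map` (camera->projector
#'   `affine_map`), `residual`, and `correspondences`.
#' @export
fit_affine <- function(camera_points, projector_points) {
  P <- base::matrix(as.numeric(as.matrix(camera_points)), ncol = 2L)
  Q <- base::matrix(as.numeric(as.matrix(projector_points)), ncol = 2L)
  if (nrow(P) < 3L || nrow(P) != nrow(Q))
    stop("degenerate correspondence set: need >= 3 matched pairs")
  X <- cbind(P, 1)
  if (qr(X)$rank < 3L)
    stop("degenerate correspondence set: camera points are collinear")
  beta <- qr.solve(X, Q)            # 3 x 2: columns are (x', y') coefficients
  m <- rbind(c(beta[1, 1], beta[2, 1], beta[3, 1]),
             c(beta[1, 2], beta[2, 2], beta[3, 2]))
  map <- affine_map(m, source = "camera", target = "projector")
  pred <- X %*% beta
  residual <- sqrt(mean(rowSums((pred - Q)^2)))
  structure(list(map = map, residual = residual,
                 correspondences = list(camera = P, projector = Q)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result: %d correspondences, RMS residual %.4g projector px>\n",
              nrow(x$correspondences$camera), x$residual))
  print(x$map)
  invisible(x)
}

#' Measure the projected-grid square size on the bench
#'
#' Renders a projected line grid of spacing `G_p`, dark-subtracts, and reads
#' the observed spacing of the grid lines in the camera image from the
#' median peak separation of the column/row intensity profiles. The result is
#' returned as grid observations ready for [estimate_magnification()]: the
#' projected-square size expressed in units of reference-grid squares
#' (`g_c = observed_px / G_c`, `g_p = 1`).
#'
#' @param bench a bench backend.
#' @param G_p projected grid spacing, projector px.
#' @param G_c reference grid spacing, camera px.
#' @param brightness projector drive level.
#' @param scene optional scene on the stage.
#' @return list with `g_p`, `g_c`, `observed_px` (projected spacing in camera
#'   px) and `M` (the resulting magnification estimate).
#' @export
measure_grid_observations <- function(bench, G_p = 32, G_c = 32,
                                      brightness = 200, scene = NULL) {
  pw <- bench$projector$width; ph <- bench$projector$height
  grid <- base::matrix(0, ph, pw)
  grid[, seq(1, pw, by = G_p)] <- brightness
  grid[seq(1, ph, by = G_p), ] <- brightness
  dark <- bench_capture(bench, NULL, scene)
  img <- bench_capture(bench, grid, scene) - dark
  # restrict to the lit footprint so the envelope does not mask the grid
  all_on <- bench_capture(bench, base::matrix(brightness, ph, pw), scene) - dark
  lit <- all_on > 0.5 * max(all_on)
  idx <- which(lit, arr.ind = TRUE)
  rows <- min(idx[, 1]):max(idx[, 1])
  cols <- min(idx[, 2]):max(idx[, 2])
  prof <- colMeans(pmax(img[rows, cols, drop = FALSE], 0))
  # detrend: remove the footprint envelope, keep the grid modulation
  win <- max(9, 2 * floor(length(prof) / 8) + 1)
  if (length(prof) > win) {
    k <- rep(1 / win, win)
    pad <- floor(win / 2)
    base_line <- as.numeric(stats::filter(
      c(rep(prof[1], pad), prof, rep(prof[length(prof)], pad)), k))
    prof <- prof - base_line[(pad + 1):(pad + length(prof))]
  }
  spacing <- profile_peak_spacing(prof)
  if (!is.finite(spacing))
    stop("could not resolve grid lines in the camera image; adjust G_p")
  M <- estimate_magnification(G_p = G_p, g_p = 1, G_c = G_c,
                              g_c = spacing / G_c)
  list(g_p = 1, g_c = spacing / G_c, observed_px = spacing, M = M)
}

# period of a line-grid intensity profile: autocorrelation peak, with a
# run-centre fallback for very short profiles
profile_peak_spacing <- function(prof) {
  p <- prof - mean(prof)
  n <- length(p)
  if (n >= 16 && stats::sd(p) > 0) {
    ac <- stats::acf(p, lag.max = floor(n / 2), plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    lags <- seq_along(ac) - 1
    # first local maximum (above a noise floor) after the zero-lag peak
    is_max <- c(FALSE, ac[2:(length(ac) - 1)] >= ac[1:(length(ac) - 2)] &
                  ac[2:(length(ac) - 1)] >= ac[3:length(ac)], FALSE)
    cand <- which(is_max & lags >= 3 & ac > 0.15 * ac[1])
    if (length(cand) > 0) {
      i <- cand[1]
      # parabolic refinement around the peak lag
      if (i > 1 && i < length(ac)) {
        y0 <- ac[i - 1]; y1 <- ac[i]; y2 <- ac[i + 1]
        den <- y0 - 2 * y1 + y2
        d <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
        return(lags[i] + max(-0.5, min(0.5, d)))
      }
      return(lags[i])
    }
  }
  thr <- min(prof) + 0.5 * (max(prof) - min(prof))
  on <- prof >= thr
  if (!any(on)) return(NA_real_)
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  centres <- (starts[runs$values] + ends[runs$values]) / 2
  if (length(centres) < 2) return(NA_real_)
  stats::median(diff(centres))
}

#' Run the full scan-zone calibration
#'
#' Orchestrates the five calibration steps with hyper-parameter auto-tuning:
#' detect the illuminable region (all-on vs dark threshold), estimate the
#' magnification from grid observations (`g_c/G_c ~ M g_p/G_p`),
#' derive the scan-zone breadth (`s_c ~ 2 M l_p`), place the zones with the
#' border variable `b`, sweep column and row bands, locate each zone's
#' projector position from the intensity peaks, and fit the camera->projector
#' affine map by least squares.
#'
#' In interactive sessions (`interactive = TRUE`) the user is prompted for
#' brightness, threshold and the grid observations, with textual feedback
#' after each stage; in batch mode every value comes from `params` (grid
#' observations are measured on the bench when not supplied).
#'
#' @param bench a bench backend.
#' @param params a [calibration_params()] object.
#' @param scene optional scene on the stage during calibration.
#' @param interactive prompt for parameters instead of using `params`.
#' @param out optional path: serialise the resulting map as calibration JSON.
#' @return A `calibration_result` with `params_used` and `region` attached.
#' @export
calibrate <- function(bench, params = calibration_params(), scene = NULL,
                      interactive = FALSE, out = NULL) {
  ask_num <- function(prompt, default) {
    ans <- readline(sprintf("%s [%g]: ", prompt, default))
    if (!nzchar(ans)) default else as.numeric(ans)
  }
  if (interactive) {
    params$brightness <- ask_num("projector brightness (0-255)", params$brightness)
    params$threshold <- ask_num("illuminable-region threshold (0-255)", params$threshold)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  region <- stage("detect_illuminable_region",
                  detect_illuminable_region(bench, params$brightness,
                                            params$threshold, scene))
  if (interactive) {
    message(sprintf("Illuminable region: %d px^2, bbox [%g, %g] x [%g, %g]",
                    as.integer(region$area), region$bbox[1], region$bbox[3],
                    region$bbox[2], region$bbox[4]))
    message("Projecting a grid of spacing G_p; compare with the reference grid.")
    params$G_p <- ask_num("projected grid spacing G_p (projector px)", params$G_p)
    params$g_p <- ask_num("observed projected-grid square size g_p", 1)
    params$g_c <- ask_num("observed reference-grid square size g_c", 1)
  }
  if (is.na(params$M)) {
    if (is.na(params$g_p) || is.na(params$g_c)) {
      obs <- stage("estimate_magnification",
                   measure_grid_observations(bench, params$G_p, params$G_c,
                                             params$brightness, scene))
      params$g_p <- obs$g_p; params$g_c <- obs$g_c
    }
    params$M <- stage("estimate_magnification",
                      estimate_magnification(params$G_p, params$g_p,
                                             params$G_c, params$g_c))
  }
  s_c <- stage("scan_zone_breadth", scan_zone_breadth(params$l_p, params$M))
  zones <- stage("place_scan_zones",
                 place_scan_zones(region, params$b, s_c, params$n_zones))
  cols <- stage("run_axis_scan",
                run_axis_scan(bench, "columns", params$l_p, zones,
                              params$brightness, region$dark_frame, scene))
  rows <- stage("run_axis_scan",
                run_axis_scan(bench, "rows", params$l_p, zones,
                              params$brightness, region$dark_frame, scene))
  floor_val <- params$contrast_floor_mads *
    max(stats::mad(region$dark_frame), 1e-6)
  est <- stage("estimate_zone_positions",
               estimate_zone_positions(cols, rows, params$l_p,
                                       params$use_centroid, floor_val))
  cam_pts <- do.call(rbind, lapply(zones[est$kept], `[[`, "cam_point"))
  result <- stage("fit_affine", fit_affine(cam_pts, est$points))
  if (result$residual > params$residual_warn)
    warning(sprintf("calibration residual %.2f projector px exceeds %.2f",
                    result$residual, params$residual_warn))
  params$l_c <- params$M * params$l_p
  params$s_c <- s_c
  result$params_used <- params
  result$region <- region
  if (!is.null(out)) write_affine_json(result$map, out)
  result
}
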