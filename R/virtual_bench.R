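#' Virtual optical bench
#'
#' Simulates the projector -> sample -> camera light path so that calibration,
#' wound targeting and the closed loop can run without hardware. The bench
#' holds the ground-truth projector-to-camera affine map, the two frame
#' specifications, and simple optical degradations (vignetting, Gaussian blur,
#' additive Gaussian read noise).
#'
#' If `ground_truth_map` is `NULL` a centred pure-scale map is constructed so
#' that the warped projector rectangle occupies `illum_coverage` of the camera
#' frame area. The illuminable footprint is always the image of the projector
#' rectangle under the ground-truth map, clipped to the camera frame.
#'
#' @param camera,projector `frame_spec` objects.
#' @param ground_truth_map projector->camera `affine_map`, or `NULL` to derive
#'   one from `illum_coverage`.
#' @param blur_sigma optical blur (camera px, >= 0).
#' @param noise_sigma additive Gaussian noise sd (intensity units, >= 0).
#' @param vignette_strength radial falloff in \[0, 1\] (0 = none).
#' @param illum_coverage fraction of the camera frame reachable by light; used
#'   only when `ground_truth_map` is `NULL`.
#' @param background_level dark-scene camera intensity in \[0, 255\].
#' @param rng_seed integer seed making every render deterministic.
#' @param fault_captures integer vector of capture ordinals at which the
#'   camera returns a blank (uniform background) frame — fault injection for
#'   testing fail-safe behaviour downstream.
#' @return A `virtual_bench` object.
#' @export
virtual_bench <- function(camera = camera_frame(),
                          projector = projector_frame(),
                          ground_truth_map = NULL,
                          blur_sigma = 0, noise_sigma = 0,
                          vignette_strength = 0, illum_coverage = 1,
                          background_level = 20, rng_seed = 1L,
                          fault_captures = integer(0)) {
  stopifnot(inherits(camera, "frame_spec"), inherits(projector, "frame_spec"),
            blur_sigma >= 0, noise_sigma >= 0,
            vignette_strength >= 0, vignette_strength <= 1,
            illum_coverage > 0, illum_coverage <= 1,
            background_level >= 0, background_level <= 255)
  if (is.null(ground_truth_map)) {
    # centred pure scale: warped projector rect area = coverage * camera area
    s <- sqrt(illum_coverage * camera$width * camera$height /
                (projector$width * projector$height))
    tx <- (camera$width - s * projector$width) / 2
    ty <- (camera$height - s * projector$height) / 2
    ground_truth_map <- affine_from_srt(scale = s, translation = c(tx, ty),
                                        source = "projector", target = "camera")
  }
  stopifnot(inherits(ground_truth_map, "affine_map"))
  invert_map(ground_truth_map)  # must be invertible
  state <- new.env()
  state$n_captures <- 0L
  structure(list(camera = camera, projector = projector,
                 state = state, fault_captures = as.integer(fault_captures),
                 ground_truth_map = ground_truth_map,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 vignette_strength = vignette_strength,
                 illum_coverage = illum_coverage,
                 background_level = background_level,
                 rng_seed = as.integer(rng_seed)),
            class = c("virtual_bench", "bench"))
}

#' @export
print.virtual_bench <- function(x, ...) {
  cat(sprintf("<virtual_bench cam %dx%d, proj %dx%d, blur %.2g, noise %.2g>\n",
              x$camera$width, x$camera$height, x$projector$width,
              x$projector$height, x$blur_sigma, x$noise_sigma))
  invisible(x)
}

#' Capture an image from a bench backend
#'
#' Generic over bench backends: the virtual bench renders; a folder bench
#' writes the pattern and reads back a matching capture file.
#'
#' @param bench a bench object.
#' @param pattern projector-frame image in \[0, 255\], or `NULL` for all-off.
#' @param scene optional `scene_state` placed on the stage.
#' @return camera-frame image matrix in \[0, 255\].
#' @export
bench_capture <- function(bench, pattern = NULL, scene = NULL) {
  UseMethod("bench_capture")
}

#' @export
bench_capture.virtual_bench <- function(bench, pattern = NULL, scene = NULL) {
  bench$state$n_captures <- bench$state$n_captures + 1L
  if (bench$state$n_captures %in% bench$fault_captures)
    return(base::matrix(bench$background_level,
                        bench$camera$height, bench$camera$width))
  render_camera_view(bench, pattern, scene)
}

# local RNG scope: run expr with a fixed seed, restore global RNG state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# cheap deterministic content hash -> integer in [0, 2^20)
content_hash <- function(x) {
  if (is.null(x)) return(0L)
  v <- as.numeric(x)
  h <- (sum(v) + sum(v * seq_along(v) %% 97)) %% 1048576
  as.integer(floor(h))
}

#' Illuminable footprint of the projector in the camera frame
#'
#' The binary mask of camera pixels inside the image of the projector
#' rectangle under the ground-truth map.
#'
#' @param bench a `virtual_bench`.
#' @return binary camera-frame matrix.
#' @export
bench_footprint <- function(bench) {
  uv <- camera_to_projector_grid(bench)
  inside <- uv$u >= -0.5 & uv$u <= bench$projector$width - 0.5 &
    uv$v >= -0.5 & uv$v <= bench$projector$height - 0.5
  base::matrix(as.numeric(inside), bench$camera$height, bench$camera$width)
}

# inverse-map every camera pixel centre to projector coords (vectorised)
camera_to_projector_grid <- function(bench) {
  w <- bench$camera$width; h <- bench$camera$height
  inv <- invert_map(bench$ground_truth_map)
  m <- inv$matrix
  x <- rep(0:(w - 1), each = h)   # column-major over [h, w] matrix
  y <- rep(0:(h - 1), times = w)
  list(u = base::matrix(m[1, 1] * x + m[1, 2] * y + m[1, 3], h, w),
       v = base::matrix(m[2, 1] * x + m[2, 2] * y + m[2, 3], h, w))
}

#' Render the camera view of the bench
#'
#' Pipeline: (scene brightfield base) + (pattern warped through the
#' ground-truth map, masked to the illuminable footprint), then vignette,
#' Gaussian blur, additive Gaussian noise, and clipping to \[0, 255\].
#' With no pattern and no scene the result is the background level plus noise.
#' Rendering is deterministic given the bench seed, the pattern and the scene.
#'
#' @inheritParams bench_capture
#' @return camera-frame image matrix in \[0, 255\].
#' @export
render_camera_view <- function(bench, pattern = NULL, scene = NULL) {
  h <- bench$camera$height; w <- bench$camera$width
  img <- if (is.null(scene)) base::matrix(bench$background_level, h, w)
         else scene_brightfield(scene, bench)
  if (!is.null(pattern)) {
    pattern <- as.matrix(pattern)
    if (nrow(pattern) != bench$projector$height ||
        ncol(pattern) != bench$projector$width)
      stop(sprintf("pattern size %dx%d does not match projector frame %dx%d",
                   ncol(pattern), nrow(pattern),
                   bench$projector$width, bench$projector$height))
    uv <- camera_to_projector_grid(bench)
    ui <- round(uv$u); vi <- round(uv$v)
    inside <- ui >= 0 & ui < bench$projector$width &
      vi >= 0 & vi < bench$projector$height
    contrib <- base::matrix(0, h, w)
    idx <- which(inside)
    contrib[idx] <- pattern[cbind(vi[idx] + 1L, ui[idx] + 1L)]
    img <- img + contrib
  }
  if (bench$vignette_strength > 0) {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    x <- rep(0:(w - 1), each = h); y <- rep(0:(h - 1), times = w)
    r2 <- ((x - cx)^2 + (y - cy)^2) / (cx^2 + cy^2)
    img <- img * (1 - bench$vignette_strength * base::matrix(r2, h, w))
  }
  if (bench$blur_sigma > 0)
    img <- gaussian_blur(img, bench$blur_sigma)
  if (bench$noise_sigma > 0) {
    seed <- (bench$rng_seed + content_hash(pattern) * 7L +
               content_hash(if (is.null(scene)) NULL else scene$time_h) * 131L +
               if (is.null(scene)) 0L else content_hash(scene$x_left)) %% .Machine$integer.max
    img <- img + with_seed(seed, base::matrix(
      stats::rnorm(h * w, 0, bench$noise_sigma), h, w))
  }
  pmin(pmax(img, 0), 255)
}

gaussian_blur <- function(img, sigma) {
  out <- EBImage::gblur(EBImage::Image(img), sigma = sigma)
  base::matrix(EBImage::imageData(out), nrow(img), ncol(img))
}

#' Synthetic scratch-assay scene
#'
#' Models a confluent epithelial monolayer with a vertical scratch wound: two
#' opposing fronts stored as per-row sub-pixel positions `x_left(y)` and
#' `x_right(y)` (monolayer occupies `x <= x_left` and `x >= x_right`).
#' Representing the fronts as single-valued height functions keeps them
#' connected by construction and makes the ground-truth edge exact.
#'
#' Defaults emulate a 10x brightfield scratch assay at 1.25 um/px: a 0.5 mm
#' wound (400 px) in the full camera frame, monolayer darker than the open
#' wound, and a migration front advancing at `heal_rate_v` um/h.
#'
#' @param frame camera `frame_spec` the scene fills.
#' @param wound_width_um wound breadth in micrometres (> 0).
#' @param um_per_px pixel pitch (default 1.25 um/px at 10x).
#' @param heal_rate_v front advance speed, um/h.
#' @param light_gain_g dimensionless light response: illuminated front pixels
#'   advance at `v * (1 + g)`.
#' @param edge_roughness front roughness amplitude, px (0 = straight fronts).
#' @param front_profile `"noise"` for correlated random roughness, `"sine"`
#'   for a sinusoidal front (period `front_period_px`).
#' @param front_period_px wavelength of the sine profile, px.
#' @param monolayer_level,wound_level mean brightfield intensities (the
#'   monolayer images darker than the open scratch by default).
#' @param texture_amp,texture_corr_px amplitude and correlation length of the
#'   static cell texture overlay.
#' @param light_reach_px how far (px, in x) from a front an illumination
#'   on-pixel still counts as hitting that front.
#' @param seed integer; the scene is deterministic given the seed.
#' @return A `scene_state` object.
#' @export
make_scratch_scene <- function(frame = camera_frame(),
                               wound_width_um = 500, um_per_px = 1.25,
                               heal_rate_v = 8, light_gain_g = 0,
                               edge_roughness = 5,
                               front_profile = c("noise", "sine"),
                               front_period_px = 120,
                               monolayer_level = 140, wound_level = 200,
                               texture_amp = 10, texture_corr_px = 6,
                               light_reach_px = 4, seed = 1L) {
  front_profile <- match.arg(front_profile)
  stopifnot(wound_width_um > 0, um_per_px > 0, heal_rate_v >= 0,
            light_gain_g >= 0, edge_roughness >= 0)
  width_px <- wound_width_um / um_per_px
  if (width_px >= frame$width)
    stop("wound width exceeds the frame extent along the wound axis")
  h <- frame$height
  y <- 0:(h - 1)
  rough <- function(phase) {
    if (edge_roughness == 0) return(rep(0, h))
    if (front_profile == "sine")
      return(edge_roughness * sin(2 * pi * y / front_period_px + phase))
    r <- stats::rnorm(h)
    k <- stats::dnorm(seq(-3, 3, length.out = 25))
    r <- stats::filter(c(rev(r[1:12]), r, rev(r[(h - 11):h])), k / sum(k))
    r <- as.numeric(r)[13:(h + 12)]
    edge_roughness * r / max(stats::sd(r), 1e-9)
  }
  cx <- (frame$width - 1) / 2
  fronts <- with_seed(as.integer(seed), {
    list(left = cx - width_px / 2 + rough(0),
         right = cx + width_px / 2 + rough(pi / 2))
  })
  structure(list(frame = frame,
                 x_left = fronts$left, x_right = fronts$right,
                 heal_rate_v = heal_rate_v, um_per_px = um_per_px,
                 light_gain_g = light_gain_g,
                 edge_roughness = edge_roughness,
                 monolayer_level = monolayer_level, wound_level = wound_level,
                 texture_amp = texture_amp, texture_corr_px = texture_corr_px,
                 light_reach_px = light_reach_px,
                 time_h = 0, rng_seed = as.integer(seed)),
            class = "scene_state")
}

#' @export
print.scene_state <- function(x, ...) {
  cat(sprintf(
    "<scene_state %dx%d, t = %.2f h, wound width ~ %.1f px, v = %g um/h, g = %g>\n",
    x$frame$width, x$frame$height, x$time_h,
    mean(pmax(0, x$x_right - x$x_left)), x$heal_rate_v, x$light_gain_g))
  invisible(x)
}

#' Monolayer occupancy mask of a scene
#'
#' @param scene a `scene_state`.
#' @return binary camera-frame matrix, 1 = cell monolayer.
#' @export
scene_occupancy <- function(scene) {
  h <- scene$frame$height; w <- scene$frame$width
  x <- base::matrix(rep(0:(w - 1), each = h), h, w)
  xl <- base::matrix(scene$x_left, h, w)
  xr <- base::matrix(scene$x_right, h, w)
  occ <- (x <= xl) | (x >= xr)
  closed <- scene$x_left >= scene$x_right
  if (any(closed)) occ[closed, ] <- TRUE
  base::matrix(as.numeric(occ), h, w)
}

#' Wound area of a scene
#' @param scene a `scene_state`.
#' @return open wound area in px^2 (sub-pixel, from the front positions).
#' @export
wound_area <- function(scene) {
  sum(pmax(0, scene$x_right - scene$x_left))
}

# brightfield base image for a scene (static textured monolayer, bright wound)
scene_brightfield <- function(scene, bench) {
  occ <- scene_occupancy(scene)
  h <- nrow(occ); w <- ncol(occ)
  img <- scene$wound_level + (scene$monolayer_level - scene$wound_level) * occ
  if (scene$texture_amp > 0) {
    tex <- with_seed(scene$rng_seed + 7919L, {
      n <- base::matrix(stats::rnorm(h * w), h, w)
      n <- gaussian_blur(n, scene$texture_corr_px / 2)
      n / max(stats::sd(n), 1e-9)
    })
    img <- img + scene$texture_amp * tex * occ
  }
  img
}

#' Advance the scratch scene in time
#'
#' Each front row advances into the wound by `v * dt` (converted to px via the
#' pixel pitch); rows whose front lies under an on-pixel of `illumination`
#' (within `light_reach_px`) advance by `v * (1 + g) * dt` instead — the
#' light-accelerated migration channel. A closed wound is a fixed point.
#'
#' @param scene a `scene_state`.
#' @param dt time step in hours (> 0).
#' @param illumination camera-frame binary mask of light actually reaching the
#'   sample, or `NULL` for dark.
#' @return the advanced `scene_state`.
#' @export
step_scene <- function(scene, dt, illumination = NULL) {
  stopifnot(dt > 0)
  v_px <- scene$heal_rate_v * dt / scene$um_per_px
  h <- scene$frame$height; w <- scene$frame$width
  lit_rows <- function(xf) {
    if (is.null(illumination) || scene$light_gain_g == 0)
      return(rep(FALSE, h))
    illum <- as.matrix(illumination)
    reach <- scene$light_reach_px
    vapply(seq_len(h), function(i) {
      if (scene$x_left[i] >= scene$x_right[i]) return(FALSE)
      xs <- round(xf[i]) + (-reach):reach
      xs <- xs[xs >= 0 & xs < w]
      length(xs) > 0 && any(illum[i, xs + 1L] > 0)
    }, logical(1))
  }
  adv_l <- v_px * (1 + scene$light_gain_g * lit_rows(scene$x_left))
  adv_r <- v_px * (1 + scene$light_gain_g * lit_rows(scene$x_right))
  closed <- scene$x_left >= scene$x_right
  new_l <- scene$x_left + adv_l
  new_r <- scene$x_right - adv_r
  cross <- !closed & new_l > new_r
  if (any(cross)) {  # fronts meet within the step; stop at the meeting point
    tot <- adv_l[cross] + adv_r[cross]
    meet <- (scene$x_left[cross] * adv_r[cross] +
               scene$x_right[cross] * adv_l[cross]) / tot
    new_l[cross] <- meet
    new_r[cross] <- meet
  }
  new_l[closed] <- scene$x_left[closed]
  new_r[closed] <- scene$x_right[closed]
  scene$x_left <- new_l
  scene$x_right <- new_r
  scene$time_h <- scene$time_h + dt
  scene
}

#' Exact ground-truth wound edge
#'
#' The sub-pixel front polyline, ordered top to bottom. This is the evaluation
#' oracle for the detector; the detection pipeline never reads it.
#'
#' @param scene a `scene_state`.
#' @param which_front `"left"` or `"right"` front of the wound band.
#' @return a `polyline` in the camera frame.
#' @export
ground_truth_edge <- function(scene, which_front = c("left", "right")) {
  which_front <- match.arg(which_front)
  open_rows <- scene$x_left < scene$x_right
  if (!any(open_rows)) stop("no wound: the scratch has closed")
  xf <- if (which_front == "left") scene$x_left else scene$x_right
  y <- 0:(scene$frame$height - 1)
  polyline(cbind(xf[open_rows], y[open_rows]), frame = "camera")
}

#' Folder bench backend
#'
#' For offline use with real hardware: each requested pattern is written as a
#' numbered PNG under `dir/patterns/` and the correspondingly numbered capture
#' is read back from `dir/captures/`. Capturing fails if the capture file is
#' missing, which lets an external acquisition step be interleaved.
#'
#' @param dir working directory for the exchange.
#' @param camera,projector `frame_spec`s describing the hardware.
#' @export
folder_bench <- function(dir, camera = camera_frame(),
                         projector = projector_frame()) {
  dir.create(file.path(dir, "patterns"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "captures"), recursive = TRUE, showWarnings = FALSE)
  env <- new.env()
  env$counter <- 0L
  structure(list(dir = dir, camera = camera, projector = projector,
                 state = env),
            class = c("folder_bench", "bench"))
}

#' @export
bench_capture.folder_bench <- function(bench, pattern = NULL, scene = NULL) {
  bench$state$counter <- bench$state$counter + 1L
  n <- bench$state$counter
  if (is.null(pattern))
    pattern <- base::matrix(0, bench$projector$height, bench$projector$width)
  write_image(pattern, file.path(bench$dir, "patterns",
                                 sprintf("pattern_%04d.png", n)))
  cap <- file.path(bench$dir, "captures", sprintf("capture_%04d.png", n))
  if (!file.exists(cap))
    stop("folder bench: missing capture file ", cap)
  read_image(cap)
}
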