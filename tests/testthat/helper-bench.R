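# Shared fixtures: small-frame benches and independent oracles.
# Simulation scale used throughout the suite: 480 x 270 camera, 160 x 90
# projector, scan-line breadth 4 (same fraction of the projector extent as
# breadth 10 on a 640-px projector).

test_camera <- function() frame_spec(480, 270, "camera")
test_projector <- function() frame_spec(160, 90, "projector")
test_lp <- 4

# bench with a randomly drawn ground truth: |rotation| <= 10 deg,
# scale in [0.5, 2], translation <= 25% of the camera frame
random_bench <- function(seed, noise_sigma = NULL, blur_sigma = NULL) {
  cam <- test_camera(); proj <- test_projector()
  with_seed_local(seed, {
    sc <- stats::runif(1, 0.5, 2)
    rot <- stats::runif(1, -10, 10)
    tx <- stats::runif(1, 0, max(1, cam$width - sc * proj$width))
    ty <- stats::runif(1, 0, max(1, cam$height - sc * proj$height))
    tx <- min(tx, 0.25 * cam$width); ty <- min(ty, 0.25 * cam$height)
    ns <- if (is.null(noise_sigma)) stats::runif(1, 0, 4) else noise_sigma
    bs <- if (is.null(blur_sigma)) stats::runif(1, 0, 2) else blur_sigma
    gt <- affine_from_srt(scale = sc, rotation_deg = rot,
                          translation = c(tx, ty),
                          source = "projector", target = "camera")
    virtual_bench(cam, proj, gt, blur_sigma = bs, noise_sigma = ns,
                  background_level = 20, rng_seed = seed)
  })
}

# bench whose footprint covers the whole camera frame (the well-configured
# instrument: every camera pixel is illuminable)
full_coverage_bench <- function(seed = 1, rotation_deg = 3,
                                noise_sigma = 2, blur_sigma = 1) {
  cam <- test_camera(); proj <- test_projector()
  gt <- affine_from_srt(scale = 3.4, rotation_deg = rotation_deg,
                        translation = c(-25, -20),
                        source = "projector", target = "camera")
  virtual_bench(cam, proj, gt, blur_sigma = blur_sigma,
                noise_sigma = noise_sigma, background_level = 20,
                rng_seed = seed)
}

with_seed_local <- function(seed, expr) {
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

# mean reprojection error of a recovered camera->projector map against the
# bench ground truth, over a camera-frame grid (projector px)
frame_reprojection_error <- function(map, bench, n = c(20, 10)) {
  inv_gt <- invert_map(bench$ground_truth_map)
  grid <- as.matrix(expand.grid(
    x = seq(0, bench$camera$width - 1, length.out = n[1]),
    y = seq(0, bench$camera$height - 1, length.out = n[2])))
  mean(sqrt(rowSums((as.matrix(apply_map(map, grid)) -
                       as.matrix(apply_map(inv_gt, grid)))^2)))
}

# independent brute-force scan oracle: illuminate single projector columns
# (or rows) one at a time and return, per zone, the argmax position. Zone
# means are computed directly from the zone square here, not via the
# package's scan machinery.
brute_force_axis_argmax <- function(bench, zones, axis = "columns",
                                    brightness = 200) {
  pw <- bench$projector$width; ph <- bench$projector$height
  extent <- if (axis == "columns") pw else ph
  dark <- bench_capture(bench, NULL)
  square_mean <- function(img, centre, breadth) {
    half <- floor(breadth / 2)
    xs <- max(0, round(centre[1]) - half):min(ncol(img) - 1, round(centre[1]) + half)
    ys <- max(0, round(centre[2]) - half):min(nrow(img) - 1, round(centre[2]) + half)
    mean(img[ys + 1, xs + 1])
  }
  intens <- matrix(0, extent, length(zones))
  for (k in seq_len(extent) - 1L) {
    pat <- matrix(0, ph, pw)
    if (axis == "columns") pat[, k + 1L] <- brightness else pat[k + 1L, ] <- brightness
    img <- bench_capture(bench, pat)
    intens[k + 1L, ] <- vapply(zones, function(z)
      square_mean(img, z$centre, z$breadth), numeric(1)) -
      vapply(zones, function(z) square_mean(dark, z$centre, z$breadth),
             numeric(1))
  }
  apply(intens, 2, which.max) - 1L   # 0-based argmax column/row
}

# shoelace area of the quad formed by mapping the projector corners
footprint_quad_area <- function(bench) {
  pw <- bench$projector$width; ph <- bench$projector$height
  corners <- rbind(c(-0.5, -0.5), c(pw - 0.5, -0.5),
                   c(pw - 0.5, ph - 0.5), c(-0.5, ph - 0.5))
  q <- as.matrix(apply_map(bench$ground_truth_map, corners))
  n <- nrow(q)
  abs(sum(q[, 1] * q[c(2:n, 1), 2] - q[c(2:n, 1), 1] * q[, 2])) / 2
}

# synthetic illuminable region with a rectangular mask, for placement tests
rect_region <- function(x0, y0, x1, y1, frame = test_camera()) {
  mask <- matrix(0, frame$height, frame$width)
  mask[(y0:y1) + 1, (x0:x1) + 1] <- 1
  structure(list(mask = mask,
                 bbox = c(x_min = x0, y_min = y0, x_max = x1, y_max = y1),
                 area = sum(mask),
                 dark_frame = matrix(0, frame$height, frame$width)),
            class = "illuminable_region")
}
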