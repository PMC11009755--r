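test_that("magnification estimation follows the grid-ratio relation", {
  expect_equal(estimate_magnification(G_p = 10, g_p = 3, G_c = 10, g_c = 3), 1)
  expect_equal(estimate_magnification(G_p = 10, g_p = 2, G_c = 10, g_c = 4), 2)
  expect_error(estimate_magnification(10, 0, 10, 4), "positive")
  expect_error(estimate_magnification(-1, 2, 10, 4), "positive")
})

test_that("scan-zone breadth derives from l_p and M with odd rounding", {
  expect_equal(scan_zone_breadth(l_p = 10, M = 1), 21)
  expect_equal(scan_zone_breadth(l_p = 1, M = 0.5), 1)
  # combined grid form agrees with the two-step path (M = 2 here)
  expect_equal(scan_zone_breadth_from_grids(10, G_p = 32, g_p = 1,
                                            G_c = 16, g_c = 1),
               scan_zone_breadth(10, estimate_magnification(32, 1, 16, 1)))
  expect_equal(scan_zone_breadth_from_grids(10, 32, 1, 16, 1), 41)
})

test_that("combined breadth equation equals the composed equations exactly", {
  set.seed(42)
  for (i in 1:1000) {
    l_p <- stats::runif(1, 1, 50)
    G_p <- stats::runif(1, 1e-3, 1e3); g_p <- stats::runif(1, 1e-3, 1e3)
    G_c <- stats::runif(1, 1e-3, 1e3); g_c <- stats::runif(1, 1e-3, 1e3)
    direct <- scan_zone_breadth_from_grids(l_p, G_p, g_p, G_c, g_c,
                                           round_odd = FALSE)
    composed <- 2 * estimate_magnification(G_p, g_p, G_c, g_c) * l_p
    expect_lt(abs(direct - composed) / composed, 1e-12)
  }
})

test_that("grid magnification is measured to within 10% on a scaling bench", {
  cam <- test_camera(); proj <- test_projector()
  gt <- affine_from_srt(scale = 3, translation = c(0, 0),
                        source = "projector", target = "camera")
  bench <- virtual_bench(cam, proj, gt, blur_sigma = 1, noise_sigma = 2,
                         background_level = 20, rng_seed = 8)
  obs <- measure_grid_observations(bench, G_p = 16, G_c = 16)
  expect_equal(obs$M, 3, tolerance = 0.1)
})

test_that("zone placement respects the border variable limits", {
  region <- rect_region(0, 0, 100, 100, frame_spec(480, 270))
  centres <- function(zs) do.call(rbind, lapply(zs, `[[`, "centre"))
  z0 <- centres(place_scan_zones(region, b = 0, s_c = 10))
  expect_equal(z0, rbind(c(0, 0), c(100, 0), c(0, 100), c(100, 100)),
               ignore_attr = TRUE)
  z1 <- centres(place_scan_zones(region, b = 1, s_c = 10))
  expect_equal(z1, rbind(c(45, 45), c(55, 45), c(45, 55), c(55, 55)),
               ignore_attr = TRUE)
  z3 <- centres(place_scan_zones(region, b = 1 / 3, s_c = 10))
  expect_equal(z3, rbind(c(15, 15), c(85, 15), c(15, 85), c(85, 85)),
               ignore_attr = TRUE)
})

test_that("zone distance from the border is monotone in b", {
  region <- rect_region(10, 20, 210, 170, frame_spec(480, 270))
  dist_border <- function(b) {
    z <- place_scan_zones(region, b = b, s_c = 11)[[1]]$centre
    min(abs(z - c(10, 20)))
  }
  ds <- vapply(seq(0, 1, by = 0.1), dist_border, numeric(1))
  expect_true(all(diff(ds) >= 0))
  expect_equal(ds[1], 0)
})

test_that("illuminable region detection thresholds the lit-minus-dark image", {
  cam <- frame_spec(240, 180, "camera"); proj <- frame_spec(120, 180, "projector")
  # projector lights exactly the left half of the camera frame
  gt <- identity_map(source = "projector", target = "camera")
  bench <- virtual_bench(cam, proj, gt, background_level = 0, rng_seed = 1)
  reg <- detect_illuminable_region(bench, brightness = 200, threshold = 100)
  expect_equal(unname(reg$bbox), c(0, 0, 119, 179))
  expect_equal(reg$area, 120 * 180)
  expect_true(all(reg$mask[, 1:120] == 1) && all(reg$mask[, 121:240] == 0))
  # threshold above the maximum observed difference names the shortfall
  expect_error(detect_illuminable_region(bench, 100, 250),
               "no illuminable region.*max observed difference")
})

test_that("detected footprint area matches the warped projector rectangle", {
  bench <- virtual_bench(test_camera(), test_projector(),
                         illum_coverage = 0.6, blur_sigma = 1,
                         noise_sigma = 2, background_level = 20, rng_seed = 12)
  reg <- detect_illuminable_region(bench, 200, 60)
  expect_equal(reg$area, footprint_quad_area(bench), tolerance = 0.05)
})

test_that("axis scans peak at the band that covers the zone", {
  cam <- frame_spec(240, 180, "camera"); proj <- frame_spec(240, 180, "projector")
  gt <- identity_map(source = "projector", target = "camera")
  bench <- virtual_bench(cam, proj, gt, background_level = 0, rng_seed = 1)
  reg <- detect_illuminable_region(bench, 200, 100)
  zones <- list(list(centre = c(105, 90), breadth = 11,
                     pixels = procam:::zone_mask_pixels(c(105, 90), 11,
                                                        reg$mask)$idx))
  prof <- run_axis_scan(bench, "columns", l_p = 10, zones, 200,
                        reg$dark_frame)
  expect_equal(which.max(prof$intensities[, 1]) - 1, 10)  # cols 100-109
  # a zone far outside the footprint sees a flat profile
  bench2 <- virtual_bench(test_camera(), test_projector(),
                          illum_coverage = 0.4, background_level = 10,
                          rng_seed = 2)
  reg2 <- detect_illuminable_region(bench2, 200, 60)
  outside <- list(list(centre = c(5, 5), breadth = 11,
                       pixels = procam:::zone_mask_pixels(
                         c(5, 5), 11, matrix(1, 270, 480))$idx))
  prof2 <- run_axis_scan(bench2, "columns", l_p = test_lp, outside, 200)
  expect_lt(max(prof2$intensities), 1)
})

test_that("banded scan argmax agrees with a per-column brute-force scan", {
  bench <- random_bench(31, noise_sigma = 0, blur_sigma = 0)
  reg <- detect_illuminable_region(bench, 200, 60)
  s_c <- scan_zone_breadth(test_lp, 1.2)
  zones <- place_scan_zones(reg, 1 / 3, s_c)
  for (axis in c("columns", "rows")) {
    prof <- run_axis_scan(bench, axis, test_lp, zones, 200, reg$dark_frame)
    band_argmax <- apply(prof$intensities, 2, which.max) - 1L
    col_argmax <- brute_force_axis_argmax(bench, zones, axis)
    expect_true(all(abs(band_argmax - col_argmax %/% test_lp) <= 1))
  }
})

test_that("zone position estimation localises intensity peaks", {
  mk <- function(axis, v) structure(
    list(axis = axis, band_breadth = 10, intensities = cbind(v)),
    class = "scan_profile")
  # band 3 covers pixels 30..39, whose centre of mass is 34.5
  onehot <- numeric(8); onehot[4] <- 50          # 0-based band 3
  est <- estimate_zone_positions(mk("columns", onehot), mk("rows", onehot),
                                 l_p = 10)
  expect_equal(unname(est$points[1, ]), c(34.5, 34.5))
  twin <- numeric(8); twin[4:5] <- 50            # equal peaks, bands 3 and 4
  est <- estimate_zone_positions(mk("columns", twin), mk("rows", twin), 10)
  expect_equal(unname(est$points[1, ]), c(39.5, 39.5))
  # argmax mode breaks the tie toward the lower band
  est <- estimate_zone_positions(mk("columns", twin), mk("rows", twin), 10,
                                 use_centroid = FALSE)
  expect_equal(unname(est$points[1, ]), c(34.5, 34.5))
  # low-contrast zones are dropped; < 3 remaining zones is an error
  good <- cbind(onehot, onehot, onehot, onehot)
  bad <- good; bad[, 2] <- bad[, 2] / 100
  mkm <- function(axis, m) structure(
    list(axis = axis, band_breadth = 10, intensities = m),
    class = "scan_profile")
  expect_warning(
    est <- estimate_zone_positions(mkm("columns", bad), mkm("rows", bad), 10,
                                   contrast_floor = 5),
    "dropped")
  expect_equal(est$kept, c(1, 3, 4))
  worse <- good; worse[, 2:3] <- worse[, 2:3] / 100
  expect_error(
    suppressWarnings(
      estimate_zone_positions(mkm("columns", worse), mkm("rows", worse), 10,
                              contrast_floor = 5)),
    "fewer than 3")
})

test_that("estimated zone positions land near the ground-truth mapping", {
  bench <- random_bench(17, noise_sigma = 1, blur_sigma = 1)
  reg <- detect_illuminable_region(bench, 200, 60)
  s_c <- scan_zone_breadth(test_lp, 1.2)
  zones <- place_scan_zones(reg, 1 / 3, s_c)
  cols <- run_axis_scan(bench, "columns", test_lp, zones, 200, reg$dark_frame)
  rows <- run_axis_scan(bench, "rows", test_lp, zones, 200, reg$dark_frame)
  est <- estimate_zone_positions(cols, rows, test_lp)
  inv_gt <- invert_map(bench$ground_truth_map)
  truth <- as.matrix(apply_map(inv_gt, do.call(rbind, lapply(
    zones[est$kept], `[[`, "cam_point"))))
  expect_lt(max(abs(est$points - truth)), test_lp / 2)
})

test_that("affine fitting is exact on consistent pairs and rejects degeneracy", {
  P <- rbind(c(0, 0), c(100, 0), c(0, 80), c(100, 80))
  r <- fit_affine(P, P)
  expect_equal(r$map$matrix, cbind(diag(2), c(0, 0)), tolerance = 1e-12)
  expect_lt(r$residual, 1e-9)
  r <- fit_affine(P[1:3, ], sweep(P[1:3, ], 2, c(-5, -7)))
  expect_equal(r$map$matrix, cbind(diag(2), c(5, 7)), tolerance = 1e-9)
  set.seed(5)
  m <- affine_from_srt(scale = c(0.4, 0.6), rotation_deg = 12,
                       translation = c(30, -10))
  Q <- as.matrix(apply_map(m, P))
  r <- fit_affine(P, Q)
  expect_equal(r$map$matrix, m$matrix, tolerance = 1e-6)
  # independent normal-equations oracle
  X <- cbind(P, 1)
  beta <- solve(t(X) %*% X, t(X) %*% Q)
  expect_equal(r$map$matrix, t(beta)[, c(1, 2, 3)], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(fit_affine(P[1:2, ], Q[1:2, ]), "degenerate")
  collinear <- rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))
  expect_error(fit_affine(collinear, collinear), "collinear")
})

test_that("calibration recovers the identity map on a clean bench", {
  cam <- frame_spec(240, 180, "camera"); proj <- frame_spec(240, 180, "projector")
  gt <- identity_map(source = "projector", target = "camera")
  bench <- virtual_bench(cam, proj, gt, background_level = 5, rng_seed = 3)
  res <- calibrate(bench, calibration_params(l_p = test_lp, G_p = 16, G_c = 16))
  expect_lt(frame_reprojection_error(res$map, bench), 0.1)
})

test_that("calibration recovers a warped map under blur and noise", {
  cam <- test_camera(); proj <- test_projector()
  gt <- affine_from_srt(scale = 1.3, rotation_deg = 5, translation = c(60, 40),
                        source = "projector", target = "camera")
  bench <- virtual_bench(cam, proj, gt, blur_sigma = 1, noise_sigma = 2,
                         background_level = 20, rng_seed = 42)
  res <- calibrate(bench, calibration_params(l_p = test_lp, G_p = 16, G_c = 16))
  expect_lt(frame_reprojection_error(res$map, bench), 2)
  expect_equal(res$params_used$M, 1.3, tolerance = 0.1)
  expect_equal(res$params_used$s_c,
               scan_zone_breadth(test_lp, res$params_used$M))
})

test_that("calibration errors carry the failing stage name", {
  bench <- full_coverage_bench(3)
  expect_error(calibrate(bench, calibration_params(threshold = 255)),
               "\\[detect_illuminable_region\\]")
})

test_that("calibration serialises its map to the calibration JSON", {
  bench <- full_coverage_bench(2)
  f <- withr::local_tempfile(fileext = ".json")
  res <- calibrate(bench, calibration_params(l_p = test_lp, G_p = 16, G_c = 16),
                   out = f)
  m <- read_affine_json(f)
  expect_equal(m$matrix, res$map$matrix, tolerance = 1e-9)
  expect_equal(m$source, "camera")
  expect_equal(m$target, "projector")
})

test_that("recovery error stays low across random benches and grows with noise", {
  errs <- vapply(1:6, function(i) {
    bench <- random_bench(100 + i)
    res <- calibrate(bench,
                     calibration_params(l_p = test_lp, G_p = 16, G_c = 16))
    frame_reprojection_error(res$map, bench)
  }, numeric(1))
  expect_lt(stats::median(errs), 2)
  med_err_at_noise <- function(sigma) {
    stats::median(vapply(1:4, function(i) {
      bench <- random_bench(200 + i, noise_sigma = sigma, blur_sigma = 1)
      res <- calibrate(bench,
                       calibration_params(l_p = test_lp, G_p = 16, G_c = 16))
      frame_reprojection_error(res$map, bench)
    }, numeric(1)))
  }
  expect_lte(med_err_at_noise(0), med_err_at_noise(4) + 1e-9)
})
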