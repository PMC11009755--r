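test_that("scratch scenes honour wound geometry and units", {
  cam <- test_camera()
  # 150 um at 1.25 um/px -> 120 px nominal band
  sc <- make_scratch_scene(cam, wound_width_um = 150, edge_roughness = 5,
                           seed = 2)
  expect_equal(mean(sc$x_right - sc$x_left), 120, tolerance = 0.05)
  # roughness 0: exact straight fronts
  sc0 <- make_scratch_scene(cam, wound_width_um = 150, edge_roughness = 0,
                            seed = 2)
  expect_equal(stats::sd(sc0$x_left), 0)
  expect_equal(sc0$x_right - sc0$x_left, rep(120, cam$height))
  # determinism
  sc2 <- make_scratch_scene(cam, wound_width_um = 150, edge_roughness = 5,
                            seed = 2)
  expect_identical(scene_occupancy(sc), scene_occupancy(sc2))
  # invalid geometry
  expect_error(make_scratch_scene(cam, wound_width_um = 0), "positive|> 0|width")
  expect_error(make_scratch_scene(cam, wound_width_um = 1000), "exceeds")
})

test_that("rendering follows the bench optical pipeline", {
  cam <- frame_spec(120, 100, "camera"); proj <- frame_spec(120, 100, "projector")
  gt <- identity_map(source = "projector", target = "camera")
  clean <- virtual_bench(cam, proj, gt, background_level = 30, rng_seed = 1)
  # all-off, no scene, no noise: uniform background
  img <- render_camera_view(clean, NULL, NULL)
  expect_true(all(img == 30))
  # identity ground truth: single on-pixel lands exactly at (50, 60)
  pat <- matrix(0, 100, 120); pat[61, 51] <- 200
  img <- render_camera_view(clean, pat, NULL)
  expect_equal(img[61, 51], 230)
  expect_true(all(img[-61, ] == 30) && all(img[61, -51] == 30))
  # pure translation (+20, +10): rendered spot centroid shifts accordingly
  gt2 <- affine_from_srt(translation = c(20, 10), source = "projector",
                         target = "camera")
  b2 <- virtual_bench(cam, proj, gt2, background_level = 0, rng_seed = 1)
  img <- render_camera_view(b2, pat, NULL)
  on <- which(img > 100, arr.ind = TRUE)
  centroid <- c(mean(on[, 2]) - 1, mean(on[, 1]) - 1)
  expect_lt(max(abs(centroid - c(70, 70))), 0.5)
  # frame mismatch rejected
  expect_error(render_camera_view(clean, matrix(0, 10, 10)), "match")
})

test_that("rendering is deterministic and monotone in added light", {
  bench <- full_coverage_bench(seed = 5, noise_sigma = 3, blur_sigma = 1)
  pat <- matrix(0, 90, 160); pat[30:40, 50:70] <- 180
  expect_identical(render_camera_view(bench, pat),
                   render_camera_view(bench, pat))
  # energy monotonicity, checked pre-noise
  quiet <- full_coverage_bench(seed = 5, noise_sigma = 0, blur_sigma = 1)
  img1 <- render_camera_view(quiet, pat)
  pat2 <- pat; pat2[60:70, 100:120] <- 200
  img2 <- render_camera_view(quiet, pat2)
  expect_true(all(img2 - img1 >= -1e-9))
})

test_that("render of a rasterised line commutes with the ground-truth map", {
  cam <- frame_spec(120, 100, "camera"); proj <- frame_spec(120, 100, "projector")
  gt <- identity_map(source = "projector", target = "camera")
  bench <- virtual_bench(cam, proj, gt, background_level = 0, rng_seed = 1)
  line <- polyline(cbind(seq(20, 100, length.out = 30),
                         50 + 20 * sin(seq(0, 2 * pi, length.out = 30))))
  pat <- rasterize_polyline(line, proj, 1) * 200
  img <- render_camera_view(bench, pat)
  on <- which(img > 100, arr.ind = TRUE)
  d <- distance_to_polyline(cbind(on[, 2] - 1, on[, 1] - 1),
                            as.matrix(apply_map(gt, line)), "max")
  expect_lt(d, 1)
})

test_that("scene dynamics: fronts advance by v dt and respond to light", {
  cam <- test_camera()
  sc <- make_scratch_scene(cam, wound_width_um = 500, heal_rate_v = 0,
                           edge_roughness = 3, seed = 4)
  s2 <- step_scene(sc, 2)
  expect_equal(s2$x_left, sc$x_left)   # v = 0: unchanged
  expect_equal(s2$x_right, sc$x_right)

  # straight 400 px wound, v dt = 10 px in the dark: width 380 after the step
  sc <- make_scratch_scene(cam, wound_width_um = 500, heal_rate_v = 12.5,
                           edge_roughness = 0, seed = 4)
  s2 <- step_scene(sc, 1)   # 12.5 um/h / 1.25 um/px * 1 h = 10 px per front
  expect_equal(unique(s2$x_right - s2$x_left), 380)

  # g = 1, one front illuminated: that front advances twice as far
  sc <- make_scratch_scene(cam, wound_width_um = 500, heal_rate_v = 12.5,
                           light_gain_g = 1, edge_roughness = 0, seed = 4)
  illum <- matrix(0, cam$height, cam$width)
  illum[, seq_len(round(mean(sc$x_left)) + 3)] <- 1   # covers left front only
  s2 <- step_scene(sc, 1, illum)
  expect_equal(mean(s2$x_left - sc$x_left), 20)
  expect_equal(mean(sc$x_right - s2$x_right), 10)
})

test_that("wound area is non-increasing and closure is a fixed point", {
  cam <- test_camera()
  sc <- make_scratch_scene(cam, wound_width_um = 100, heal_rate_v = 20,
                           edge_roughness = 6, seed = 9)
  areas <- wound_area(sc)
  for (i in 1:8) {
    sc <- step_scene(sc, 1)
    areas <- c(areas, wound_area(sc))
  }
  expect_true(all(diff(areas) <= 0))
  expect_true(any(diff(areas) < 0))
  expect_equal(areas[length(areas)], 0)   # 80 px wound, 16 px/h both fronts
  closed <- step_scene(sc, 1)
  expect_equal(closed$x_left, sc$x_left)
  expect_error(ground_truth_edge(sc), "no wound")
})

test_that("ground-truth edges are exact and track front motion", {
  cam <- test_camera()
  sc <- make_scratch_scene(cam, wound_width_um = 200, heal_rate_v = 12.5,
                           edge_roughness = 0, seed = 1)
  e <- ground_truth_edge(sc, "left")
  cx <- (cam$width - 1) / 2
  expect_equal(unique(e[, 1]), cx - 80)
  expect_equal(e[, 2], 0:(cam$height - 1))   # ordered top to bottom
  s2 <- step_scene(sc, 1)                    # 10 px advance
  e2 <- ground_truth_edge(s2, "left")
  expect_equal(e2[, 1] - e[, 1], rep(10, nrow(e)))
})

test_that("footprint area matches the corner-mapped quad", {
  bench <- virtual_bench(test_camera(), test_projector(),
                         illum_coverage = 0.6, rng_seed = 3)
  fp <- bench_footprint(bench)
  expect_equal(sum(fp) / (480 * 270), 0.6, tolerance = 0.02)
  expect_equal(sum(fp), footprint_quad_area(bench), tolerance = 0.02)
})

test_that("folder bench writes patterns and reads captures back", {
  dir <- withr::local_tempdir()
  cam <- frame_spec(40, 30, "camera"); proj <- frame_spec(20, 15, "projector")
  fb <- folder_bench(dir, cam, proj)
  pat <- matrix(0, 15, 20); pat[5, 5] <- 255
  expect_error(bench_capture(fb, pat), "missing capture")
  expect_true(file.exists(file.path(dir, "patterns", "pattern_0001.png")))
  # supply the capture an external rig would have produced
  write_image(matrix(128, 30, 40), file.path(dir, "captures", "capture_0002.png"))
  img <- bench_capture(fb, pat)
  expect_equal(dim(img), c(30, 40))
  expect_equal(img[1, 1], 128, tolerance = 0.51)
})
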