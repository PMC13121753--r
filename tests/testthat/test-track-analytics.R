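frame150 <- tissue_frame(half_width_um = 150)

test_that("registration subtracts the reference and round-trips", {
  m <- cbind(c(0, 30, 60), c(10, 10, 10), c(0, 0, 0), c(2, 2, 2))
  tr <- tt(m)
  ref0 <- data.frame(time_min = c(0, 60), x_um = 0, y_um = 0, z_um = 0)
  expect_equal(as.data.frame(register_to_reference(tr, ref0)),
               as.data.frame(tr))

  # drifting reference: a stationary cell appears to move backwards
  refd <- data.frame(time_min = c(0, 30, 60), x_um = c(0, 5, 10),
                     y_um = 0, z_um = 0)
  reg <- register_to_reference(tr, refd)
  expect_equal(reg$x_um, c(10, 5, 0))

  # adding random drift then registering it away reproduces the input
  set.seed(33)
  g <- gen_tracks(track_gen_params(n_tracks = 10, seed = 14))
  drift <- data.frame(time_min = sort(unique(g$tracks$time_min)))
  drift$x_um <- cumsum(rnorm(nrow(drift)))
  drift$y_um <- cumsum(rnorm(nrow(drift)))
  drift$z_um <- cumsum(rnorm(nrow(drift)))
  shifted <- g$tracks
  i <- match(shifted$time_min, drift$time_min)
  shifted$x_um <- shifted$x_um + drift$x_um[i]
  shifted$y_um <- shifted$y_um + drift$y_um[i]
  shifted$z_um <- shifted$z_um + drift$z_um[i]
  back <- register_to_reference(shifted, drift)
  expect_equal(back$x_um, g$tracks$x_um)
  expect_equal(back$z_um, g$tracks$z_um)

  expect_error(register_to_reference(tr,
                                     data.frame(time_min = c(10, 60),
                                                x_um = 0, y_um = 0, z_um = 0)),
               "outside reference span")
})

test_that("origin subtraction zeroes the start, keeps steps, and is idempotent", {
  tr <- tt(cbind(c(0, 10, 20), c(10, 12, 15), c(-4, -4, -2), c(2, 3, 7)))
  z <- zero_origin(tr)
  expect_equal(unlist(z[1, c("x_um", "y_um", "z_um")]), c(x_um = 0, y_um = 0, z_um = 0))
  expect_equal(diff(z$x_um), diff(tr$x_um))
  expect_equal(diff(z$z_um), diff(tr$z_um))
  expect_equal(as.data.frame(zero_origin(z)), as.data.frame(z))

  set.seed(4)
  g <- gen_tracks(track_gen_params(n_tracks = 25, seed = 4))
  z2 <- zero_origin(g$tracks)
  for (id in unique(z2$track_id)[1:5]) {
    a <- g$tracks[g$tracks$track_id == id, ]
    b <- z2[z2$track_id == id, ]
    expect_equal(cbind(diff(b$x_um), diff(b$y_um), diff(b$z_um)),
                 cbind(diff(a$x_um), diff(a$y_um), diff(a$z_um)))
  }
})

test_that("displacement components follow the sign conventions", {
  tr <- tt(cbind(c(0, 60), c(50, 30), c(0, 0), c(0, 0)),       # inward
           cbind(c(0, 60), c(-50, -60), c(0, 0), c(0, 0)),     # outward
           cbind(c(0, 60), c(10, 10), c(0, 0), c(0, 6.3)))     # ventral
  rec <- displacement_components(tr, frame150)
  expect_equal(rec$toward_midline_um, c(20, -10, 0))
  expect_equal(rec$ventral_um, c(0, 0, 6.3))
  expect_equal(rec$net_um[1], 20)
})

test_that("region classification matches both schemes", {
  expect_equal(as.character(classify_region(c(40, 120, -40, -120), frame150)),
               c("medial", "lateral", "medial", "lateral"))
  expect_equal(as.character(classify_region(75, frame150)), "intermediate")
  fb <- tissue_frame(half_width_um = 150, region_scheme = "fixed_band",
                     fixed_band_um = 100)
  expect_equal(as.character(classify_region(c(70, 100, 120, 45), fb)),
               c("medial", "medial", "lateral", "medial"))
  expect_warning(classify_region(200, frame150), "clamped")
})

test_that("displacement profile bins conserve counts and capture the gradient", {
  g <- gen_tracks(track_gen_params(n_tracks = 300, diffusion_sigma_um = 0,
                                   v_ing_um_min = 0, seed = 17))
  rec <- displacement_components(g$tracks, g$frame)
  prof <- displacement_profile(rec, g$frame, "toward_midline")
  expect_equal(sum(prof$n), nrow(rec))
  nz <- prof$mean_um[prof$n > 0]
  expect_true(all(diff(nz) >= -1e-9))   # monotone in the noise-free case

  # identical displacement everywhere: every non-empty bin mean = v, sem 0
  tr <- tt(cbind(c(0, 60), c(90, 80), c(0, 0), c(0, 0)),
           cbind(c(0, 60), c(140, 130), c(0, 0), c(0, 0)),
           cbind(c(0, 60), c(30, 20), c(0, 0), c(0, 0)))
  rec2 <- displacement_components(tr, frame150)
  prof2 <- displacement_profile(rec2, frame150, "toward_midline")
  expect_true(all(prof2$mean_um[prof2$n > 0] == 10))
  expect_true(all(prof2$n %in% c(0L, 1L)))
})

test_that("polar histogram reproduces the hand-binned example", {
  tr <- tt(cbind(c(0, 60), c(0, 2 * cos(10 * pi / 180)),
                 c(0, 2 * sin(10 * pi / 180)), c(0, 0)),
           cbind(c(0, 60), c(0, 4 * cos(15 * pi / 180)),
                 c(0, 4 * sin(15 * pi / 180)), c(0, 0)),
           cbind(c(0, 60), c(0, 6 * cos(350 * pi / 180)),
                 c(0, 6 * sin(350 * pi / 180)), c(0, 0)))
  h <- polar_histogram(tr, "XY")
  b1 <- h[h$bin_lo_deg == 0, ]
  expect_equal(b1$count, 2L)
  expect_equal(b1$mean_magnitude_um, 3)
  expect_equal(b1$weight, 6)
  b18 <- h[h$bin_lo_deg == 340, ]
  expect_equal(b18$count, 1L)
  expect_equal(b18$weight, 6)
  expect_equal(sum(h$count), 3L)
})

test_that("polar histogram equals the brute-force loop on random tracks", {
  set.seed(55)
  for (rep in 1:3) {
    g <- gen_tracks(track_gen_params(n_tracks = 120, seed = 100 + rep))
    for (plane in c("XY", "XZ")) {
      h <- polar_histogram(g$tracks, plane)
      o <- brute_polar_hist(as.data.frame(g$tracks), 20,
                            ycol = if (plane == "XY") "y_um" else "z_um")
      expect_equal(h$count, o$count)
      expect_equal(h$mean_magnitude_um, o$mean_magnitude, tolerance = 1e-12)
      expect_equal(h$weight, o$weight, tolerance = 1e-12)
    }
  }
})

test_that("rotating all net vectors by one bin width rotates the histogram", {
  set.seed(9)
  n <- 40
  ang <- runif(n, 0, 360); mag <- runif(n, 1, 5)
  build <- function(angles) {
    df <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(embryo_id = "e", track_id = sprintf("t%02d", i),
                 time_min = c(0, 10),
                 x_um = c(0, mag[i] * cos(angles[i] * pi / 180)),
                 y_um = c(0, mag[i] * sin(angles[i] * pi / 180)),
                 z_um = 0)))
    track_table(df)
  }
  h0 <- polar_histogram(build(ang), "XY")
  h1 <- polar_histogram(build((ang + 20) %% 360), "XY")
  expect_equal(h1$count, h0$count[c(18, 1:17)])
  expect_equal(h1$weight, h0$weight[c(18, 1:17)], tolerance = 1e-9)
})

test_that("mirror symmetry: reflecting ML leaves convergence analytics unchanged", {
  g <- gen_tracks(track_gen_params(n_tracks = 200, seed = 31))
  mir <- g$tracks
  mir$x_um <- -mir$x_um
  rec <- displacement_components(g$tracks, g$frame)
  recm <- displacement_components(mir, g$frame)
  expect_equal(recm$toward_midline_um, rec$toward_midline_um)
  expect_equal(as.character(recm$region), as.character(rec$region))
  expect_equal(displacement_profile(recm, g$frame, "toward_midline"),
               displacement_profile(rec, g$frame, "toward_midline"))
  # polar histograms mirror bin-for-bin: angle theta -> 180 - theta
  h <- polar_histogram(g$tracks, "XY")
  hm <- polar_histogram(mir, "XY")
  nb <- nrow(h)
  mirror_map <- ((180 - (h$bin_lo_deg + 10)) %% 360) %/% 20 + 1
  expect_equal(hm$count[mirror_map], h$count)
  expect_equal(hm$weight[mirror_map], h$weight, tolerance = 1e-9)
})

test_that("position histograms bin midline distance over common breaks", {
  f <- tissue_frame(half_width_um = 100)
  ph <- position_histogram(c(10, 95, -70), c(10, 95, -70), 20, f)
  a <- ph[ph$timepoint == "initial", ]
  b <- ph[ph$timepoint == "final", ]
  expect_equal(a$count, b$count)
  expect_equal(sum(a$count), 3L)
  ph2 <- position_histogram(c(90, 80), c(10, 20), 50, f)
  final <- ph2[ph2$timepoint == "final", ]
  expect_equal(sum(final$count[final$bin_lo_um >= 50]), 0L)
})

test_that("tissue dimensions derive width and length from landmarks", {
  node <- data.frame(time_min = c(0, 30), ap_um = c(0, 0))
  borders <- data.frame(time_min = c(0, 30), left_ml_um = c(-100, -90),
                        right_ml_um = c(100, 90))
  streak <- data.frame(time_min = c(0, 30), ap_um = c(-300, -310))
  td <- tissue_dimensions(node, borders, streak)
  expect_equal(td$width_um, c(200, 180))
  expect_equal(td$length_um, c(300, 310))
  expect_warning(
    tissue_dimensions(node, borders[1, , drop = FALSE], streak),
    "skipped 1")
})

test_that("half-width defaults to the 95th percentile of start distances", {
  g <- gen_tracks(track_gen_params(n_tracks = 400, seed = 77))
  hw <- estimate_half_width(g$tracks)
  x0 <- g$truth$per_track$x0_um
  expect_equal(hw, unname(quantile(abs(x0), 0.95)), tolerance = 1e-6)
})
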