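test_that("zero drift and zero noise give stationary tracks", {
  g <- gen_tracks(track_gen_params(n_tracks = 20, v_conv_um_min = 0,
                                   v_ing_um_min = 0, diffusion_sigma_um = 0,
                                   seed = 3))
  for (col in c("x_um", "y_um", "z_um"))
    expect_equal(tapply(g$tracks[[col]],
                        g$tracks$track_id, function(v) max(v) - min(v)),
                 tapply(g$tracks[[col]], g$tracks$track_id, function(v) 0),
                 tolerance = 1e-12)
})

test_that("noise-free linear convergence integrates exactly", {
  # a cell at d = 1 with v_conv = 0.1 um/min over 180 min moves 18 um inward
  p <- track_gen_params(n_tracks = 400, duration_min = 180, dt_min = 10,
                        v_conv_um_min = 0.1, v_ing_um_min = 0,
                        diffusion_sigma_um = 0, seed = 8)
  g <- gen_tracks(p)
  rec <- displacement_components(g$tracks, g$frame)
  tr <- g$truth$per_track
  expect_equal(rec$toward_midline_um,
               0.1 * 180 * tr$d0_norm[match(rec$track_id, tr$track_id)],
               tolerance = 1e-9)
  edge <- which.max(tr$d0_norm)
  expect_equal(rec$toward_midline_um[match(tr$track_id[edge], rec$track_id)],
               18 * tr$d0_norm[edge], tolerance = 1e-9)
})

test_that("with noise the sample mean convergence tracks the drift integral", {
  g <- gen_tracks(track_gen_params(n_tracks = 500, seed = 21))
  rec <- displacement_components(g$tracks, g$frame)
  tr <- g$truth$per_track
  pred <- mean(tr$conv_drift_um)
  obs <- rec$toward_midline_um
  expect_lt(abs(mean(obs) - pred), 3 * sem(obs))
})

test_that("generators are bit-identical under a fixed seed and vary across seeds", {
  a <- gen_tracks(track_gen_params(n_tracks = 30, seed = 5))
  b <- gen_tracks(track_gen_params(n_tracks = 30, seed = 5))
  c <- gen_tracks(track_gen_params(n_tracks = 30, seed = 6))
  expect_identical(a$tracks$x_um, b$tracks$x_um)
  expect_false(identical(a$tracks$x_um, c$tracks$x_um))

  e1 <- gen_epithelium(epithelium_gen_params(n_cells = 25, seed = 9,
                                             noise_sd = 10))
  e2 <- gen_epithelium(epithelium_gen_params(n_cells = 25, seed = 9,
                                             noise_sd = 10))
  e3 <- gen_epithelium(epithelium_gen_params(n_cells = 25, seed = 10,
                                             noise_sd = 10))
  expect_identical(e1$pair$channels$junction, e2$pair$channels$junction)
  expect_false(identical(e1$pair$channels$nuclear, e3$pair$channels$nuclear))
})

test_that("symmetric epithelium paints ML and AP junctions equally", {
  e <- gen_epithelium(epithelium_gen_params(n_cells = 64,
                                            ml_polarity_factor = 1, seed = 2))
  cls <- e$truth$junctions$class
  expect_equal(mean(e$junctions$mean_intensity[cls == "ML"]),
               mean(e$junctions$mean_intensity[cls == "AP"]))
})

test_that("polarized epithelium at zero noise paints an exact factor", {
  e <- gen_epithelium(epithelium_gen_params(n_cells = 64,
                                            ml_polarity_factor = 2, seed = 2))
  cls <- e$truth$junctions$class
  ml <- e$junctions$mean_intensity[cls == "ML"]
  ap <- e$junctions$mean_intensity[cls == "AP"]
  expect_equal(mean(ml) / mean(ap), 2, tolerance = 1e-12)
  expect_true(all(ml == 2000) && all(ap == 1000))
})

test_that("ground-truth labels match the generated data keys", {
  e <- gen_epithelium(epithelium_gen_params(n_cells = 36, seed = 4,
                                            positive_fraction = 0.5,
                                            cortical_fraction = 0.25))
  expect_setequal(e$truth$cells$label,
                  setdiff(unique(as.vector(e$pair$label_image)), 0L))
  expect_setequal(e$truth$junctions$junction_id, e$junctions$junction_id)
  expect_setequal(setdiff(unique(as.vector(e$truth$nuclear_labels)), 0L),
                  e$truth$cells$label)
  g <- gen_epithelium(epithelium_gen_params(n_cells = 36, seed = 4,
                                            positive_fraction = 0))
  expect_equal(sum(g$truth$cells$positive), 0L)
})

test_that("constriction generator honours its closed-form timing", {
  # rate 0 and no noise: constant plateau, nobody ingresses
  g0 <- gen_constriction_set(n_cells = 10, ingressing_fraction = 0,
                             noise_sd = 0, seed = 3)
  expect_true(all(tapply(g0$series$area_um2, g0$series$cell_id,
                         function(v) max(v) - min(v)) == 0))
  expect_true(all(is.na(g0$truth$per_cell$true_ingression_min)))

  # linear decay 100 -> 0 over 60 min after the plateau: the normalized
  # area crosses 0.1 at 54 min into constriction, so the first sampled
  # time below threshold is plateau + 55 (sampling every 5 min)
  g1 <- gen_constriction_set(n_cells = 4, pre_phase_min = 60,
                             constriction_rate = 1 / 60,
                             ingressing_fraction = 1, total_min = 150,
                             dt_min = 5, noise_sd = 0, seed = 3)
  expect_equal(unique(g1$truth$per_cell$true_ingression_min), 60 + 55)
})

test_that("noisy ingression times are recovered within one frame for >= 90% of cells", {
  g <- gen_constriction_set(n_cells = 50, pre_phase_min = 60,
                            constriction_rate = 1 / 60,
                            ingressing_fraction = 1, total_min = 150,
                            dt_min = 5, noise_sd = 2, seed = 12)
  aligned <- normalize_align_all(g$series)
  est <- vapply(split(aligned, aligned$cell_id), detect_ingression,
                numeric(1), threshold = 0.1, full_span_min = 150)
  truth <- g$truth$per_cell
  err <- abs(est[truth$cell_id] - truth$true_ingression_min)
  expect_gte(mean(err <= 5, na.rm = TRUE), 0.9)
})

test_that("depth sections realize the requested third mixture", {
  d1 <- gen_depth_sections(100, weights = c(1, 0, 0), seed = 2)
  expect_true(all(d1$depths$relative_depth_pct < 100 / 3 + 0.1))
  d3 <- gen_depth_sections(100, weights = c(0, 0, 1), seed = 2)
  expect_true(all(d3$depths$relative_depth_pct > 200 / 3 - 0.1))
  du <- gen_depth_sections(3000, weights = c(1, 1, 1) / 3, seed = 4)
  occ <- depth_third_fractions(du$depths$relative_depth_pct)
  expect_true(all(abs(occ - 1 / 3) < 0.03))
  expect_error(gen_depth_sections(10, weights = c(-0.1, 0.6, 0.5)),
               "non-negative")
})
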