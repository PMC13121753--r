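test_that("extract_cells measures a square cell exactly", {
  lab <- matrix(0L, 30, 30)
  lab[11:20, 6:15] <- 1L
  p <- make_pair(lab)
  cells <- extract_cells(p)
  expect_length(cells, 1L)
  cl <- cells[["1"]]
  expect_equal(cl$area_um2, 100)
  expect_equal(unname(cl$centroid_um), c(10.5, 15.5))  # (x = col, y = row)

  lab[3:8, 22:27] <- 2L
  expect_length(extract_cells(make_pair(lab)), 2L)
})

test_that("tiny labels are skipped and areas sum to the foreground", {
  set.seed(12)
  for (rep in 1:3) {
    e <- gen_epithelium(epithelium_gen_params(n_cells = 36, seed = rep))
    cells <- extract_cells(e$pair)
    total <- sum(vapply(cells, `[[`, numeric(1), "area_um2"))
    expect_equal(total,
                 sum(e$pair$label_image > 0L) * e$pair$pixel_size_um^2)
  }
  lab <- matrix(0L, 10, 10); lab[1:2, 1] <- 1L; lab[5:8, 5:8] <- 2L
  expect_warning(cells <- extract_cells(make_pair(lab)), "< 4 pixels")
  expect_named(cells, "2")
})

test_that("per-cell means match brute-force pixel accumulation", {
  # uniform channel: every mean equals the constant
  lab <- matrix(0L, 20, 20); lab[2:8, 2:8] <- 1L; lab[12:18, 12:18] <- 2L
  p <- image_pair(lab, list(u = matrix(7, 20, 20)))
  expect_equal(unname(cell_mean_intensity(p, "u")), c(7, 7))

  # one cell painted, others zero
  ch <- matrix(0, 20, 20); ch[lab == 2L] <- 10
  p2 <- image_pair(lab, list(s = ch))
  expect_equal(cell_mean_intensity(p2, "s"), c("1" = 0, "2" = 10))

  set.seed(66)
  for (rep in 1:3) {
    e <- gen_epithelium(epithelium_gen_params(n_cells = 16, seed = 40 + rep,
                                              noise_sd = 50))
    m <- cell_mean_intensity(e$pair, "junction")
    o <- brute_label_means(e$pair$label_image, e$pair$channels$junction)
    expect_equal(m[names(o)], o, tolerance = 1e-12)
  }
})

test_that("reference normalization is elementwise and homogeneous", {
  t <- c(a = 50, b = 30); r <- c(a = 25, b = 30)
  expect_equal(normalize_by_reference(t, r), c(a = 2, b = 1),
               ignore_attr = TRUE)
  expect_equal(unname(normalize_by_reference(t, r * 2)),
               unname(normalize_by_reference(t, r)) / 2, ignore_attr = TRUE)
  r2 <- c(a = 25, b = 0)
  expect_warning(out <- normalize_by_reference(t, r2), "non-positive")
  expect_equal(names(out), "a")
  expect_equal(attr(out, "excluded"), "b")
})

test_that("cortex mask approaches the full cell and the empty set in the limits", {
  r <- 20; n <- 2 * r + 11
  X <- matrix(rep(1:n, each = n), n, n); Y <- t(X)
  lab <- matrix(0L, n, n); c0 <- (n + 1) / 2
  lab[(X - c0)^2 + (Y - c0)^2 <= r^2] <- 1L
  p <- make_pair(lab)
  cl <- extract_cells(p)[["1"]]
  hi <- cortex_mask(cl, p, 0.999)
  lo <- cortex_mask(cl, p, 0.02)
  expect_gt(length(hi$pixels) / cl$n_pixels, 0.97)
  expect_lt(length(lo$pixels) / cl$n_pixels, 0.01)
})

test_that("cortex mask equals the point-in-scaled-polygon oracle on convex cells", {
  set.seed(23)
  for (rep in 1:25) {
    poly <- random_convex_polygon(n_pts = 10, radius = runif(1, 6, 12))
    cp <- cell_from_polygon(poly, 32)
    if (is.null(cp) || cp$cell$n_pixels < 20) next
    frac <- runif(1, 0.5, 0.9)
    got <- sort(cortex_mask(cp$cell, cp$pair, frac)$pixels)
    want <- sort(oracle_cortex_pixels(cp$cell, cp$pair, frac))
    expect_equal(got, want)
  }
})

test_that("cortical intensity separates patch-bearing cells by the painted offset", {
  lab <- matrix(0L, 24, 24); lab[5:20, 5:20] <- 1L
  ch <- matrix(5, 24, 24)
  p <- image_pair(lab, list(c = ch))
  cl <- extract_cells(p)[["1"]]
  cm <- cortex_mask(cl, p, 0.8)
  expect_equal(cortical_mean_intensity(p, "c", cm), 5)

  ch2 <- ch; ch2[11:14, 11:14] <- 105   # interior patch inside the cortex
  p2 <- image_pair(lab, list(c = ch2))
  expect_gt(cortical_mean_intensity(p2, "c", cortex_mask(cl, p2, 0.8)),
            mean(ch2[lab == 1L]))

  e <- gen_epithelium(epithelium_gen_params(n_cells = 49, seed = 13,
                                            cortical_fraction = 0.4,
                                            cortical_offset = 2000,
                                            noise_sd = 50))
  cells <- extract_cells(e$pair)
  cort <- vapply(cells, function(cl)
    cortical_mean_intensity(e$pair, "cortical",
                            cortex_mask(cl, e$pair, 0.8)), numeric(1))
  truth <- e$truth$cells
  flag <- truth$cortical[match(as.integer(names(cort)), truth$label)]
  gap <- min(cort[flag]) - max(cort[!flag])
  expect_gt(gap, 0)
})
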