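test_that("background statistics exclude nuclei and use the population SD", {
  ch <- matrix(100, 20, 20)
  nuc <- matrix(0L, 20, 20); nuc[8:12, 8:12] <- 1L
  p <- image_pair(matrix(1L, 20, 20), list(n = ch))
  bg <- background_stats(p, "n", nuc)
  expect_equal(bg$mean, 100)
  expect_equal(bg$sd, 0)
  expect_equal(bg$n, 400 - 25)

  ch2 <- matrix(rep(c(90, 110), length.out = 400), 20, 20)
  p2 <- image_pair(matrix(1L, 20, 20), list(n = ch2))
  bg2 <- background_stats(p2, "n", matrix(0L, 20, 20))
  expect_equal(bg2$mean, 100)
  expect_equal(bg2$sd, 10)

  nuc_all <- matrix(1L, 20, 20); nuc_all[1, seq(2, 20, 2)] <- 0L
  expect_error(background_stats(p, "n", nuc_all), "background pixels")
})

test_that("background statistics match brute-force masked accumulation", {
  set.seed(14)
  for (rep in 1:3) {
    ch <- matrix(runif(30 * 30, 0, 1000), 30, 30)
    nuc <- matrix(0L, 30, 30)
    nuc[sample(900, 150)] <- sample(1:9, 150, replace = TRUE)
    p <- image_pair(matrix(1L, 30, 30), list(n = ch))
    bg <- background_stats(p, "n", nuc)
    o <- brute_background(ch, nuc)
    expect_equal(bg$mean, o$mean, tolerance = 1e-12)
    expect_equal(bg$sd, o$sd, tolerance = 1e-12)
    expect_equal(bg$n, o$n)
  }
})

test_that("positivity uses a strict mean + k SD threshold", {
  bg <- list(mean = 100, sd = 10)
  expect_true(classify_positive(125, bg, 2))
  expect_false(classify_positive(120, bg, 2))   # exactly at threshold
  expect_false(classify_positive(119.999, bg, 2))
  bg0 <- list(mean = 100, sd = 0)
  expect_true(classify_positive(100.001, bg0, 2))
  expect_false(classify_positive(100, bg0, 2))
})

test_that("positivity is monotone in intensity and anti-monotone in k", {
  set.seed(5)
  bg <- list(mean = 500, sd = 50)
  means <- runif(200, 300, 800)
  p2 <- classify_positive(means, bg, 2)
  p3 <- classify_positive(means, bg, 3)
  expect_true(all(which(p3) %in% which(p2)))    # k = 3 subset of k = 2
  ord <- order(means)
  expect_true(all(diff(p2[ord]) >= 0))          # monotone in intensity
})

test_that("positive fractions per region honour restriction markers", {
  pos <- c(rep(TRUE, 3), rep(FALSE, 5))
  reg <- rep("jz", 8)
  pf <- positive_fraction_by_region(pos, reg)
  expect_equal(pf$percent, 37.5)

  marked <- c(FALSE, FALSE, FALSE, rep(TRUE, 5))  # excludes all positives
  pf2 <- positive_fraction_by_region(pos, reg, restrict_to = marked)
  expect_equal(pf2$percent, 0)
  expect_equal(pf2$n, 5L)
})

test_that("relative depth follows D/(D+V) and its antisymmetry", {
  expect_equal(relative_depth(0, 10), 0)
  expect_equal(relative_depth(10, 10), 50)
  expect_equal(relative_depth(75, 25), 75)
  set.seed(2)
  d <- runif(200, 0, 80); v <- runif(200, 1e-3, 80)
  expect_equal(relative_depth(d, v) + relative_depth(v, d),
               rep(100, 200))
  expect_error(relative_depth(0, 0), "D \\+ V")
})

test_that("depth histogram bins every 10% and ratios against a reference", {
  dh <- depth_histogram(c(5, 15, 95))
  expect_equal(dh$count, c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(sum(dh$count), 3L)
  expect_equal(dh$bin_hi_pct[10], 100)
  # depth 100 lands in the final (closed) bin
  expect_equal(depth_histogram(100)$count[10], 1L)

  set.seed(6)
  x <- runif(400, 0, 100)
  dh2 <- depth_histogram(x, reference_pct = x)
  expect_true(all(dh2$freq_ratio[dh2$ref_count > 0] == 1))
})

test_that("third occupancy sums to one and recovers generator weights", {
  expect_equal(depth_third_fractions(rep(90, 5)),
               c(dorsal = 0, middle = 0, ventral = 1))
  grid <- seq(0.05, 99.95, length.out = 3000)
  expect_equal(unname(depth_third_fractions(grid)), rep(1 / 3, 3),
               tolerance = 0.01)

  g <- gen_depth_sections(2000, weights = c(0.6, 0.3, 0.1), seed = 9)
  occ <- depth_third_fractions(g$depths$relative_depth_pct)
  for (i in 1:3) {
    se <- sqrt(0.6 * 0.4 / 2000)
    expect_lt(abs(occ[i] - c(0.6, 0.3, 0.1)[i]),
              3 * sqrt(c(.6, .3, .1)[i] * (1 - c(.6, .3, .1)[i]) / 2000))
  }
})

test_that("synthetic nuclear fields classify with near-perfect accuracy", {
  e <- gen_epithelium(epithelium_gen_params(n_cells = 100, seed = 3,
                                            positive_fraction = 0.4,
                                            positive_offset_sd = 5))
  nuc <- e$truth$nuclear_labels
  bg <- background_stats(e$pair, "nuclear", nuc)
  means <- cell_mean_intensity(image_pair(nuc, e$pair$channels,
                                          e$pair$pixel_size_um), "nuclear")
  pos <- classify_positive(means, bg, 2)
  truth <- e$truth$cells$positive[match(as.integer(names(means)),
                                        e$truth$cells$label)]
  expect_gte(sum(pos & truth) / sum(truth), 0.99)
  expect_gte(sum(!pos & !truth) / sum(!truth), 0.99)
})
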