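test_that("Otsu threshold separates a perfectly bimodal frame", {
  img <- matrix(c(rep(20, 500), rep(40, 500)), 25)
  thr <- otsu_threshold(img)
  expect_gt(thr, 20); expect_lt(thr, 40)
  mask <- segment_thermal(img)
  expect_equal(sum(mask), 500L)
  expect_true(all(img[mask] == 20))
  expect_error(otsu_threshold(matrix(30, 10, 10)), "degenerate",
               class = "ct_error_degenerate")
})

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(c(rnorm(600, 25, 1), rnorm(400, 45, 1)), 40)
    expect_equal(otsu_threshold(img), oracle_otsu(as.numeric(img)))
  }
})

test_that("Otsu threshold shifts with an affine temperature offset (within a bin)", {
  set.seed(22)
  img <- matrix(c(rnorm(500, 25, 1), rnorm(500, 45, 1)), 40)
  t0 <- otsu_threshold(img)
  bin_w <- diff(range(img)) / 256
  expect_lt(abs(otsu_threshold(img + 5) - (t0 + 5)), bin_w + 1e-12)
})

test_that("Otsu agrees with the EBImage reference on a rescaled frame", {
  set.seed(23)
  img <- matrix(c(rnorm(700, 24, 1.2), rnorm(500, 42, 1.5)), 40)
  rng <- range(img)
  scaled <- (img - rng[1]) / diff(rng)
  thr_eb <- EBImage::otsu(scaled, range = c(0, 1), levels = 256) * diff(rng) + rng[1]
  ## conventions may pick different ends of an empty valley, but the
  ## resulting plant/soil partition must be identical
  expect_equal(img < otsu_threshold(img), img < thr_eb)
})

test_that("connected components report exact centroid and circumcircle", {
  m <- matrix(FALSE, 10, 10); m[4:6, 4:6] <- TRUE     # 3x3 square
  comps <- find_components(m)
  expect_equal(nrow(comps), 1L)
  expect_equal(comps$n_px, 9L)
  expect_equal(c(comps$x_px, comps$y_px), c(4, 4))     # 0-based centre
  expect_equal(comps$r_px, sqrt(2))                    # half-diagonal of span
})

test_that("diagonal pixels connect under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(nrow(find_components(m, 8L)), 1L)
  expect_equal(nrow(find_components(m, 4L)), 2L)
  expect_equal(nrow(find_components(matrix(FALSE, 5, 5))), 0L)
})

test_that("component circumcircles match the exhaustive circle oracle", {
  set.seed(31)
  img <- matrix(FALSE, 30, 30)
  for (b in 1:3) {                      # random blobs
    cx <- sample(5:25, 1); cy <- sample(5:25, 1)
    px <- cbind(pmin(pmax(cy + sample(-2:2, 12, TRUE), 1), 30),
                pmin(pmax(cx + sample(-2:2, 12, TRUE), 1), 30))
    img[px] <- TRUE
  }
  comps <- find_components(img)
  for (i in seq_len(nrow(comps))) {
    px <- comps$pixels[[i]]
    want <- oracle_min_circle(px[, "col"] - 1, px[, "row"] - 1)
    expect_equal(comps$r_px[i], want$radius, tolerance = 1e-7)
  }
})

test_that("the most central component is selected, ties to the larger", {
  one <- tibble::tibble(component = 1L, n_px = 5L, x_px = 10, y_px = 10,
                        r_px = 2, cx_px = 10, cy_px = 10, pixels = list(NULL))
  expect_equal(select_plant_component(one, 640, 480), 1L)
  two <- dplyr::bind_rows(one,
    tibble::tibble(component = 2L, n_px = 50L, x_px = 320, y_px = 240,
                   r_px = 9, cx_px = 320, cy_px = 240, pixels = list(NULL)))
  expect_equal(select_plant_component(two, 640, 480), 2L)
  expect_error(select_plant_component(two[0, ], 640, 480),
               class = "ct_error_no_plant")

  set.seed(33)
  comps <- tibble::tibble(component = 1:50, n_px = sample(10:100, 50, TRUE),
                          x_px = runif(50, 0, 639), y_px = runif(50, 0, 479),
                          r_px = runif(50, 1, 20), cx_px = 0, cy_px = 0,
                          pixels = vector("list", 50))
  d <- sqrt((comps$x_px - 639 / 2)^2 + (comps$y_px - 479 / 2)^2)
  expect_equal(select_plant_component(comps, 640, 480), which.min(d))
})

test_that("disjoint-circumcircle components are removed, intersecting ones kept", {
  mk <- function(cx, cy, r, i) tibble::tibble(
    component = i, n_px = 10L, x_px = cx, y_px = cy, r_px = r,
    cx_px = cx, cy_px = cy, pixels = list(cbind(row = 1L, col = 1L)))
  tgt_only <- validate_components(mk(320, 240, 50, 1L), 1L)
  expect_equal(tgt_only$kept, TRUE)

  comps <- dplyr::bind_rows(mk(320, 240, 50, 1L), mk(600, 240, 20, 2L))
  v <- validate_components(comps, 1L)     # 50+20 = 70 <= 280: disjoint
  expect_equal(v$kept, c(TRUE, FALSE))

  comps <- dplyr::bind_rows(mk(320, 240, 50, 1L), mk(390, 240, 30, 2L))
  v <- validate_components(comps, 1L)     # 80 > 70: circles intersect
  expect_equal(v$kept, c(TRUE, TRUE))
})

test_that("the separate/kept decision is invariant to uniform scaling", {
  set.seed(35)
  for (rep in 1:20) {
    comps <- tibble::tibble(
      component = 1:6, n_px = 10L,
      x_px = runif(6, 0, 600), y_px = runif(6, 0, 400),
      r_px = runif(6, 5, 60), pixels = vector("list", 6))
    comps$cx_px <- comps$x_px; comps$cy_px <- comps$y_px
    v1 <- validate_components(comps, 1L)$kept
    s <- runif(1, 0.1, 10)
    scaled <- dplyr::mutate(comps, x_px = x_px * s, y_px = y_px * s,
                            cx_px = cx_px * s, cy_px = cy_px * s, r_px = r_px * s)
    expect_equal(validate_components(scaled, 1L)$kept, v1)
  }
})

test_that("mean canopy temperature and Tc-Ta are exact", {
  img <- matrix(28, 4, 4)
  expect_equal(mean_canopy_temperature(img, matrix(TRUE, 4, 4)), 28)
  img[1, 1] <- 20; img[1, 2] <- 30
  m <- matrix(FALSE, 4, 4); m[1, 1:2] <- TRUE
  expect_equal(mean_canopy_temperature(img, m), 25)
  expect_error(mean_canopy_temperature(img, matrix(FALSE, 4, 4)),
               class = "ct_error_empty_mask")

  set.seed(36)
  img <- matrix(rnorm(400, 30), 20)
  m <- matrix(runif(400) < 0.3, 20)
  expect_equal(mean_canopy_temperature(img, m), sum(img[m]) / sum(m))

  expect_equal(canopy_air_delta(30, 30), 0)
  expect_equal(canopy_air_delta(28, 31), -3)
  tc <- rnorm(100, 30); ta <- rnorm(100, 33)
  expect_equal(canopy_air_delta(tc, ta), tc - ta)
})

test_that("drift compensation removes the shared ambient drift", {
  base <- tidyr::expand_grid(condition = seq(0, 1.5, 0.1), frame = 1:20)
  ## constant thermocouple: nothing to compensate
  s1 <- dplyr::mutate(base, ti_raw = 30 + condition, tc = 25)
  expect_equal(compensate_series(s1)$ti_comp, s1$ti_raw)
  ## camera tracks thermocouple exactly: collapses to the reference
  s2 <- dplyr::mutate(base, tc = 25 + sin(frame), ti_raw = tc)
  expect_equal(compensate_series(s2)$ti_comp, rep(mean(s2$tc), nrow(s2)))
  ## synthetic drift d[i] added to both: compensation recovers the
  ## drift-free signal up to the constant reference offset
  set.seed(40)
  d <- rnorm(20, 0, 0.5)
  s3 <- dplyr::mutate(base, sig = 30 + condition, drift = d[frame],
                      ti_raw = sig + drift, tc = 25 + drift)
  cs <- compensate_series(s3)
  expect_equal(cs$ti_comp, s3$sig + (mean(s3$tc) - 25), tolerance = 1e-12)
  ## first-frame reference option: same cancellation, offset d[1]
  cs1 <- compensate_series(s3, reference = "first_frame")
  expect_equal(cs1$ti_comp, s3$sig + d[1], tolerance = 1e-12)
  expect_error(compensate_series(dplyr::select(s3, -tc)),
               class = "ct_error_misaligned")
})

test_that("paired shading differences summarise to mean and sample SD", {
  expect_equal(paired_difference_summary(c(30, 31), c(30, 31))$mean_diff_c, 0)
  p <- paired_difference_summary(c(30.1, 29.9), c(30, 30))
  expect_equal(p$mean_diff_c, 0)
  expect_equal(p$sd_diff_c, sd(c(0.1, -0.1)))
  expect_error(paired_difference_summary(1, 1), class = "ct_error_too_few")

  set.seed(44)
  shaded <- rnorm(90, 30, 1)
  unshaded <- shaded + rnorm(90, 0, 0.2)
  s <- paired_difference_summary(shaded, unshaded)
  expect_lt(abs(s$mean_diff_c), 3 * s$sd_diff_c / sqrt(90))
  expect_lt(s$sd_diff_c, 0.5)       # no shading effect at the stated noise
})
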