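test_that("the default field echoes the single-plant-layout design", {
  cfg <- sim_config(seed = 1)
  sim <- generate_field(cfg)
  expect_equal(nrow(sim$plants), 132L)
  expect_equal(length(unique(sim$plants$genotype)), 23L)
  expect_equal(sort(unique(sim$truth$dap)), c(51, 65, 72, 87, 94))
  d <- as.matrix(dist(cbind(sim$plants$x_m, sim$plants$y_m)))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(1.52, 132))
  ## exactly one barbadense genotype, as in the trial design
  gg <- unique(sim$plants[c("genotype", "group")])
  expect_equal(sum(gg$group == "barbadense"), 1L)
})

test_that("generation is deterministic and variance components behave", {
  cfg <- sim_config(seed = 5)
  s1 <- generate_field(cfg); s2 <- generate_field(cfg)
  expect_identical(s1, s2)
  ## V_E = 0: plants of a genotype share identical traits on each date
  cfg0 <- sim_config(seed = 5, v_e = 0)
  s0 <- generate_field(cfg0)
  spread <- dplyr::summarise(
    dplyr::group_by(s0$truth, .data$genotype, .data$dap),
    sd = sd(.data$h_m), .groups = "drop")
  expect_true(all(spread$sd < 1e-12, na.rm = TRUE))
  ## height is monotone non-decreasing through canopy development
  wide <- tidyr::pivot_wider(s0$truth[c("plant_id", "dap", "h_m")],
                             names_from = "dap", values_from = "h_m")
  expect_true(all(wide$`65` >= wide$`51` & wide$`72` >= wide$`65` &
                    wide$`87` >= wide$`72`))
})

test_that("between/within mean squares match the analytic ANOVA expectation", {
  ## balanced small design so E[MS_G] = r V_G + V_E, E[MS_E] = V_E exactly
  gl <- tibble::tibble(genotype = sprintf("G%02d", 1:10),
                       group = "hirsutum")
  v_g <- 4; v_e <- 1; r <- 6
  ms <- t(vapply(1:80, function(s) {
    cfg <- sim_config(rows = 10, cols = 6, pitch_m = 1.52, genotypes = gl,
                      dap = 87L, v_g = v_g, v_e = v_e, seed = 1000 + s,
                      mean_semiaxes = function(dap) c(a = 10, b = 10, c = 10))
    an <- oneway_anova(generate_field(cfg)$truth, "h_m", "genotype")
    c(an$ms_genotype, an$ms_error)
  }, c(0, 0)))
  expect_lt(abs(mean(ms[, 1]) - (r * v_g + v_e)) / (r * v_g + v_e), 0.15)
  expect_lt(abs(mean(ms[, 2]) - v_e) / v_e, 0.1)
})

test_that("the environment log is 1 Hz with a recoverable diurnal signal", {
  cfg <- sim_config(seed = 2, window_s = 3600L)
  env <- generate_env_log(cfg, dates = 1L)
  expect_equal(nrow(env), 3600L)
  expect_equal(diff(env$timestamp), rep(1, 3599))
  ## zero noise: the sinusoid is exact
  cfg0 <- sim_config(seed = 2, window_s = 3600L, env_noise_sd_c = 0)
  env0 <- generate_env_log(cfg0, dates = 1L)
  el <- env0$timestamp - env0$timestamp[1]
  expect_equal(env0$t_air_c,
               33 + 1.5 * sin(2 * pi * el / (2 * 3600)), tolerance = 1e-12)
  ## every frame timestamp falls within 0.5 s of a log entry
  sim <- generate_field(cfg)
  ts <- sim$truth$timestamp[sim$truth$dap == sim$truth$dap[1]]
  gaps <- vapply(ts, function(t) min(abs(env$timestamp - t)), 0)
  expect_true(all(gaps <= 0.5))
})

test_that("an empty plot renders flat ground and segments to an empty cloud", {
  cfg <- sim_config(seed = 3, depth_noise_mm = 0, thermal_noise_sd_c = 0)
  sim <- generate_field(cfg)
  row <- sim$truth[1, ]
  row$a_m <- row$b_m <- row$c_m <- row$h_m <- 0
  sc <- render_scene(row, cfg)
  expect_true(all(sc$depth == 2400))
  cloud <- reconstruct_point_cloud(sc$depth, sc$color, cfg$depth_camera)
  seg <- segment_canopy(cloud)
  expect_equal(nrow(seg), 0L)
  expect_true(attr(seg, "empty_plant"))
})

test_that("a noiseless render recovers height within depth quantisation", {
  cfg <- sim_config(seed = 4, depth_noise_mm = 0, gps_sd_m = 0,
                    thermal_noise_sd_c = 0)
  sim <- generate_field(cfg)
  row <- sim$truth[5, ]
  row$a_m <- 0.45; row$b_m <- 0.4; row$c_m <- row$h_m <- 1.0
  sc <- render_scene(row, cfg)
  ex <- extract_scene_traits(sc, cfg)
  ## apex sampling: within one depth quantisation step + pixel footprint
  expect_lt(abs(ex$h_m - 1.0), 0.005)
  ## the nearest surface point is the apex: depth = (2.4 - 1.0) m in mm
  expect_lte(abs(min(sc$depth) - 1400), 1)
})

test_that("neighbour fragments are detected and removed by the circumcircle filter", {
  cfg <- sim_config(seed = 6, gps_sd_m = 0)
  sim <- generate_field(cfg)
  row <- sim$truth[sim$truth$dap == 87, ][3, ]
  sc <- render_scene(row, cfg, neighbors = TRUE)
  mask0 <- segment_thermal(sc$thermal)
  comps <- find_components(mask0)
  expect_gte(nrow(comps), 2L)            # target + at least one fragment
  tgt <- select_plant_component(comps, ncol(sc$thermal), nrow(sc$thermal))
  ## the selected component is the most central (brute-force check)
  d <- sqrt((comps$x_px - (ncol(sc$thermal) - 1) / 2)^2 +
              (comps$y_px - (nrow(sc$thermal) - 1) / 2)^2)
  expect_equal(order(d, -comps$n_px)[1], tgt)
  v <- validate_components(comps, tgt)
  expect_gte(sum(v$separate), 1L)        # fragments removed
  ## removed fragments sit at the frame margins
  expect_true(all(v$y_px[v$separate] < 25 | v$y_px[v$separate] > 95))
  ex <- extract_scene_traits(sc, cfg)
  expect_lt(abs(ex$t_canopy_c - row$t_canopy_c), 0.5)
})

test_that("renders are deterministic and FOV overflow is flagged", {
  cfg <- sim_config(seed = 8)
  sim <- generate_field(cfg)
  row <- sim$truth[10, ]
  s1 <- render_scene(row, cfg); s2 <- render_scene(row, cfg)
  expect_identical(s1, s2)
  big <- row
  big$a_m <- 2.5; big$b_m <- 0.4; big$c_m <- big$h_m <- 1
  expect_true(render_scene(big, cfg)$warn_fov)
  expect_false(s1$warn_fov)
  tall <- row; tall$c_m <- 3
  expect_error(render_scene(tall, cfg), class = "ct_error_camera_low")
})

test_that("raster files round-trip through the TIFF/PNG writers", {
  d <- withr::local_tempdir()
  set.seed(77)
  depth <- matrix(sample(0:4000, 64 * 48, TRUE), 48)
  write_depth_tiff(depth, file.path(d, "d.tif"))
  expect_equal(read_depth_tiff(file.path(d, "d.tif")), depth, ignore_attr = TRUE)
  thermal <- matrix(runif(64 * 48, 15, 60), 48)
  write_thermal_tiff(thermal, file.path(d, "t.tif"))
  expect_equal(read_thermal_tiff(file.path(d, "t.tif")), thermal,
               tolerance = 1e-5, ignore_attr = TRUE)
  color <- array(sample(0:255, 48 * 64 * 3, TRUE), c(48, 64, 3))
  write_color_png(color, file.path(d, "c.png"))
  expect_equal(read_color_png(file.path(d, "c.png")), color,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a simulated directory is complete and re-readable end to end", {
  cfg <- sim_config(seed = 15)
  d <- withr::local_tempdir()
  simulate_field_data(cfg, d, plant_ids = c("P001", "P002"), dates = c(1L, 4L))
  pm <- read_plant_map(file.path(d, "plant_map.csv"))
  expect_equal(nrow(pm), 132L)
  idx <- read_image_index(file.path(d, "image_index.csv"))
  expect_equal(nrow(idx), 2L * 2L * 3L)   # plants x dates x sensors
  expect_true(all(file.exists(file.path(d, idx$path))))
  env <- read_env_log(file.path(d, "env_log.csv"))
  ## run the pipeline from files for one plant/date
  frames <- idx[grepl("P001_d87", idx$frame_id), ]
  depth <- read_depth_tiff(file.path(d, frames$path[frames$sensor == "depth"]))
  color <- read_color_png(file.path(d, frames$path[frames$sensor == "color"]))
  thermal <- read_thermal_tiff(file.path(d, frames$path[frames$sensor == "thermal"]))
  ta <- air_temperature_at(env, frames$timestamp[1])$t_air_c
  ex <- extract_scene_traits(list(depth = depth, color = color,
                                  thermal = thermal), cfg, t_air_c = ta)
  truth <- readr::read_csv(file.path(d, "truth.csv"), show_col_types = FALSE)
  row <- truth[truth$plant_id == "P001" & truth$dap == 87, ]
  expect_lt(abs(ex$h_m - row$h_m), 0.035)
  expect_lt(abs(ex$t_canopy_c - row$t_canopy_c), 0.5)
})
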