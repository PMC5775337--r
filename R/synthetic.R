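## Synthetic single-plant-layout field: plant map, per-date ground-truth
## traits, and rendered depth/color/thermal frames with GPS and environment
## logs, so every pipeline stage is testable without field data.
##
## The canopy model is an upper half-ellipsoid surface with semi-axes
## (a, b, c): every true trait is closed-form (H = c, WAR = 2a, WIR = 2b,
## PLA = pi a b, CV = (2/3) pi a b c), giving analytic oracles for trait
## extraction.

#' Configuration for the synthetic field generator
#'
#' Defaults emulate the study conditions of a small single-plant-layout
#' trial: a 12 x 11 grid at 1.52 m pitch (132 plants), 23 genotypes in three
#' species groups with a single-genotype outgroup, five measurement dates at
#' DAP 51/65/72/87/94, nadir cameras 2.4 m above ground, midday canopies
#' about 8 deg C cooler than soil, and genotype/plant variance components on
#' the canopy semi-axes with V_G/(V_G + V_E) = 0.6.
#'
#' @param rows,cols Grid dimensions (rows x cols plants).
#' @param pitch_m In-row and across-row plot pitch (m).
#' @param genotypes Tibble with columns `genotype`, `group`; default 12
#'   hirsutum + 1 barbadense ("PimaS6") + 10 exotic.
#' @param dap Measurement dates as days after planting, strictly increasing.
#' @param mean_semiaxes Function `dap -> c(a, b, c)` of mean canopy
#'   semi-axes (m): a across-row, b in-row, c vertical (= mean height).
#'   The default is a saturating growth curve that plateaus after DAP 87.
#' @param v_g,v_e Genotype and residual variance components applied to each
#'   semi-axis (m^2). Defaults 0.006 and 0.004 (ratio 0.6).
#' @param soil_temp_c Soil surface temperature (deg C).
#' @param canopy_offset_c Canopy cooling below soil (deg C, default 8).
#' @param canopy_temp_sd_c Between-plant SD of canopy temperature (deg C).
#' @param thermal_noise_sd_c Per-pixel thermal noise SD (deg C, default 0.3).
#' @param depth_noise_mm Per-pixel depth noise SD in mm (default 2).
#' @param air_temp_base_c,air_temp_amp_c Midday air-temperature sinusoid.
#' @param env_noise_sd_c Noise SD of the 1 Hz environment log (deg C).
#' @param window_s Collection window per date, seconds (default 3 h,
#'   1200-1500 h).
#' @param gps_sd_m SD of the frame-centre offset from the plant position.
#' @param depth_camera,thermal_camera [camera_intrinsics()] for the two
#'   imagers (defaults: 128 x 106 depth raster with 70 x 60 deg FOV;
#'   160 x 120 thermal raster with 80 x 64.4 deg FOV; both at 2.4 m).
#' @param depth_dim,thermal_dim `c(h, w)` raster sizes.
#' @param neighbor_fragments Render fragments of the in-row neighbours at
#'   thermal frame margins (exercises circumcircle removal).
#' @param yield_intercept_g,yield_slope_g_per_m2,yield_noise_sd_g Latent
#'   fiber-yield model: `yield = intercept + slope * PLA(dap 87) + noise`.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(rows = 12L, cols = 11L, pitch_m = 1.52,
                       genotypes = default_genotypes(),
                       dap = c(51L, 65L, 72L, 87L, 94L),
                       mean_semiaxes = default_mean_semiaxes,
                       v_g = 0.006, v_e = 0.004,
                       soil_temp_c = 38, canopy_offset_c = 8,
                       canopy_temp_sd_c = 0.3, thermal_noise_sd_c = 0.3,
                       depth_noise_mm = 2,
                       air_temp_base_c = 33, air_temp_amp_c = 1.5,
                       env_noise_sd_c = 0.1, window_s = 3L * 3600L,
                       gps_sd_m = 0.05,
                       depth_dim = c(106L, 128L), thermal_dim = c(120L, 160L),
                       depth_camera = NULL, thermal_camera = NULL,
                       neighbor_fragments = TRUE,
                       yield_intercept_g = 20, yield_slope_g_per_m2 = 40,
                       yield_noise_sd_g = 8,
                       seed = 1L) {
  stopifnot(rows >= 1L, cols >= 1L, pitch_m > 0, v_g >= 0, v_e >= 0,
            all(diff(dap) > 0),
            all(c("genotype", "group") %in% names(genotypes)))
  if (anyDuplicated(genotypes$genotype)) {
    ct_abort("duplicate genotype names in config", "ct_error_duplicate_id")
  }
  if (!all(genotypes$group %in% plant_groups)) {
    ct_abort("genotype groups must be hirsutum/barbadense/exotic",
             "ct_error_bad_group")
  }
  if (is.null(depth_camera)) {
    depth_camera <- camera_intrinsics(
      fx = (depth_dim[2L] / 2) / tan(35 * pi / 180),
      fy = (depth_dim[1L] / 2) / tan(30 * pi / 180),
      cx = (depth_dim[2L] - 1) / 2, cy = (depth_dim[1L] - 1) / 2,
      depth_scale = 0.001, camera_height = 2.4)
  }
  if (is.null(thermal_camera)) {
    thermal_camera <- camera_intrinsics(
      fx = (thermal_dim[2L] / 2) / tan(40 * pi / 180),
      fy = (thermal_dim[1L] / 2) / tan(32.2 * pi / 180),
      cx = (thermal_dim[2L] - 1) / 2, cy = (thermal_dim[1L] - 1) / 2,
      depth_scale = 0.001, camera_height = 2.4)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_genotypes <- function() {
  tibble(
    genotype = c(sprintf("H%02d", 1:12), "PimaS6", sprintf("X%02d", 1:10)),
    group = c(rep("hirsutum", 12L), "barbadense", rep("exotic", 10L))
  )
}

## mean canopy semi-axes (m) as a saturating function of DAP: growth through
## the canopy-development stage, near-plateau after DAP 87
default_mean_semiaxes <- function(dap) {
  f <- 1 / (1 + exp(-(dap - 58) / 11))      # logistic development fraction
  c(a = 0.50 * f, b = 0.48 * f, c = 1.10 * f)
}

## air-temperature sinusoid over one collection window (noiseless mean)
env_mean_temp <- function(config, elapsed_s) {
  config$air_temp_base_c +
    config$air_temp_amp_c * sin(2 * pi * elapsed_s / (2 * config$window_s))
}

## collection-window start time (s) for date index k (1-based)
window_start <- function(config, k) (k - 1L) * 86400 + 12 * 3600

#' Generate a synthetic field: plant map and per-date ground truth
#'
#' Plants are laid out on the grid; genotypes are assigned cyclically then
#' shuffled. Each genotype draws a shared effect `g ~ N(0, V_G)` and each
#' plant a residual `e ~ N(0, V_E)` per canopy semi-axis, constant across
#' dates so growth is monotone; `semi-axis(date) = mean(date) + g + e`,
#' truncated at 0. Latent fiber yield is linear in projected leaf area at
#' DAP 87 plus Gaussian noise. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `plants` (a plant-map tibble: `plant_id`, `genotype`,
#'   `group`, `x_m`, `y_m`, `yield_g`) and `truth` (one row per plant per
#'   date: semi-axes, the five morphological traits, canopy and air
#'   temperature, acquisition timestamp).
#' @export
generate_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$rows * config$cols
    gl <- config$genotypes
    geno <- sample(rep(gl$genotype, length.out = n))
    grid <- expand.grid(row = seq_len(config$rows), col = seq_len(config$cols))
    plants <- tibble(
      plant_id = sprintf("P%03d", seq_len(n)),
      genotype = geno,
      group = gl$group[match(geno, gl$genotype)],
      x_m = (grid$col - 1L) * config$pitch_m,
      y_m = (grid$row - 1L) * config$pitch_m
    )
    ## per-genotype and per-plant effects on each semi-axis, plus temperature
    g_eff <- matrix(stats::rnorm(nrow(gl) * 3L, 0, sqrt(config$v_g)),
                    nrow(gl), 3L, dimnames = list(gl$genotype, NULL))
    e_eff <- matrix(stats::rnorm(n * 3L, 0, sqrt(config$v_e)), n, 3L)
    t_eff <- stats::rnorm(n, 0, config$canopy_temp_sd_c)

    truth <- purrr::map_dfr(seq_along(config$dap), function(k) {
      d <- config$dap[k]
      mu <- config$mean_semiaxes(d)
      ax <- sweep(g_eff[plants$genotype, , drop = FALSE] + e_eff, 2L, mu, `+`)
      ax <- pmax(ax, 0)
      dimnames(ax) <- NULL
      ts <- window_start(config, k) + 600 + seq_len(n) * 2
      t_air <- env_mean_temp(config, ts - window_start(config, k))
      tibble(
        plant_id = plants$plant_id, genotype = plants$genotype,
        group = plants$group, dap = d,
        x_m = plants$x_m, y_m = plants$y_m,
        a_m = ax[, 1L], b_m = ax[, 2L], c_m = ax[, 3L],
        h_m = ax[, 3L], war_m = 2 * ax[, 1L], wir_m = 2 * ax[, 2L],
        pla_m2 = pi * ax[, 1L] * ax[, 2L],
        cv_m3 = 2 / 3 * pi * ax[, 1L] * ax[, 2L] * ax[, 3L],
        t_canopy_c = config$soil_temp_c - config$canopy_offset_c + t_eff,
        t_air_c = t_air,
        tc_minus_ta_c = config$soil_temp_c - config$canopy_offset_c + t_eff - t_air,
        timestamp = ts
      )
    })
    pla87 <- truth$pla_m2[truth$dap == config$dap[which.min(abs(config$dap - 87))]]
    plants$yield_g <- pmax(config$yield_intercept_g +
                             config$yield_slope_g_per_m2 * pla87 +
                             stats::rnorm(n, 0, config$yield_noise_sd_g), 0)
    list(plants = plants, truth = truth)
  })
}

#' Generate the 1 Hz environment log
#'
#' One record per second over each date's collection window (1200-1500 h):
#' a slow sinusoid plus Gaussian noise for air temperature, near-constant
#' relative humidity and pressure.
#'
#' @param config A [sim_config()].
#' @param dates Indices into `config$dap` (default all).
#' @return An env-log tibble: `timestamp`, `t_air_c`, `rh_pct`, `p_hpa`.
#' @export
generate_env_log <- function(config, dates = seq_along(config$dap)) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    purrr::map_dfr(dates, function(k) {
      el <- seq_len(config$window_s) - 1L
      tibble(
        timestamp = window_start(config, k) + el,
        t_air_c = env_mean_temp(config, el) +
          stats::rnorm(config$window_s, 0, config$env_noise_sd_c),
        rh_pct = 55 + stats::rnorm(config$window_s, 0, 0.5),
        p_hpa = 1003 + stats::rnorm(config$window_s, 0, 0.2)
      )
    })
  })
}

## smallest positive z-depth at which the pixel ray (ar*t, br*t, Hc - t)
## meets the upper half-ellipsoid ((x-dx)/A)^2 + ((y-dy)/B)^2 + (z/C)^2 = 1;
## NA where the ray misses. ar, br may be matrices.
ray_ellipsoid_depth <- function(ar, br, hc, dx, dy, A, B, C) {
  if (A <= 0 || B <= 0 || C <= 0) return(array(NA_real_, dim(ar)))
  al <- ar^2 / A^2 + br^2 / B^2 + 1 / C^2
  be <- -2 * (ar * dx / A^2 + br * dy / B^2 + hc / C^2)
  ga <- dx^2 / A^2 + dy^2 / B^2 + hc^2 / C^2 - 1
  disc <- be^2 - 4 * al * ga
  t <- (-be - sqrt(pmax(disc, 0))) / (2 * al)
  t[disc < 0 | t <= 0 | (hc - t) < 0] <- NA_real_
  t
}

## pixel ray-slope matrices for a raster under given intrinsics
ray_slopes <- function(dim, intr) {
  u <- matrix(seq_len(dim[2L]) - 1, dim[1L], dim[2L], byrow = TRUE)
  v <- matrix(seq_len(dim[1L]) - 1, dim[1L], dim[2L])
  list(ar = (u - intr$cx) / intr$fx, br = (v - intr$cy) / intr$fy)
}

#' Render the depth/color/thermal frames for one plant
#'
#' The plant's half-ellipsoid canopy is ray-cast through the pinhole model
#' of each camera, nadir above the plant position plus a small GPS offset.
#' The depth raster stores z-depth in mm (ground at
#' `camera_height / depth_scale`); the color raster paints canopy pixels
#' green (ExG well above 0.15) and soil brown (ExG about 0); the thermal
#' raster sets soil at `soil_temp_c` and canopy `canopy_offset_c` cooler,
#' plus per-pixel Gaussian noise, optionally with fragments of the two
#' in-row neighbours at the frame margins.
#'
#' @param truth_row One row of the `truth` table from [generate_field()].
#' @param config The [sim_config()].
#' @param neighbors Override `config$neighbor_fragments`.
#' @return A list: `depth` (integer matrix, mm), `color` (h x w x 3, 0-255),
#'   `thermal` (deg C matrix), `records` (image-index tibble rows for the
#'   three frames), `warn_fov` (TRUE when the canopy exceeds the field of
#'   view).
#' @export
render_scene <- function(truth_row, config, neighbors = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(truth_row) == 1L)
  neighbors <- neighbors %||% config$neighbor_fragments
  dc <- config$depth_camera; tc <- config$thermal_camera
  if (dc$camera_height <= truth_row$c_m) {
    ct_abort("camera height must exceed plant height", "ct_error_camera_low")
  }
  seed <- (config$seed * 1009L +
             sum(utf8ToInt(truth_row$plant_id)) * 131L +
             as.integer(truth_row$dap)) %% .Machine$integer.max
  withr::with_seed(seed, {
    off <- stats::rnorm(2L, 0, config$gps_sd_m)  # frame centre - plant position
    dx <- -off[1L]; dy <- -off[2L]               # plant in camera frame
    A <- truth_row$a_m; B <- truth_row$b_m; C <- truth_row$c_m

    ## field-of-view check at the depth camera
    half_x <- dc$camera_height * max(abs(c(-dc$cx, config$depth_dim[2L] - 1 - dc$cx))) / dc$fx
    half_y <- dc$camera_height * max(abs(c(-dc$cy, config$depth_dim[1L] - 1 - dc$cy))) / dc$fy
    warn_fov <- (abs(dx) + A > half_x) || (abs(dy) + B > half_y)

    ## depth + color (target plant only: one plot per frame)
    rs <- ray_slopes(config$depth_dim, dc)
    t_hit <- ray_ellipsoid_depth(rs$ar, rs$br, dc$camera_height, dx, dy, A, B, C)
    depth_m <- ifelse(is.na(t_hit), dc$camera_height, t_hit)
    if (config$depth_noise_mm > 0) {
      depth_m <- depth_m + stats::rnorm(length(depth_m), 0,
                                        config$depth_noise_mm / 1000)
    }
    depth <- matrix(pmax(round(depth_m / dc$depth_scale), 1), config$depth_dim[1L])
    canopy <- !is.na(t_hit)
    color <- array(0, c(config$depth_dim, 3L))
    color[, , 1L] <- ifelse(canopy, 60, 120)
    color[, , 2L] <- ifelse(canopy, 180, 90)
    color[, , 3L] <- ifelse(canopy, 60, 60)

    ## thermal (target plus optional neighbour fragments)
    rst <- ray_slopes(config$thermal_dim, tc)
    mask_t <- !is.na(ray_ellipsoid_depth(rst$ar, rst$br, tc$camera_height,
                                         dx, dy, A, B, C))
    if (neighbors) {
      for (s in c(-1, 1)) {
        mask_t <- mask_t | !is.na(ray_ellipsoid_depth(
          rst$ar, rst$br, tc$camera_height, dx, dy + s * config$pitch_m,
          A, B, C))
      }
    }
    thermal <- matrix(config$soil_temp_c, config$thermal_dim[1L],
                      config$thermal_dim[2L])
    thermal[mask_t] <- truth_row$t_canopy_c
    thermal <- thermal + stats::rnorm(length(thermal), 0,
                                      config$thermal_noise_sd_c)

    ## acquisition position in the field frame (plant position + GPS offset)
    px <- truth_row$x_m + off[1L]
    py <- truth_row$y_m + off[2L]
    records <- tibble(
      frame_id = sprintf("%s_d%02d_%s", truth_row$plant_id, truth_row$dap,
                         c("depth", "color", "thermal")),
      sensor = c("depth", "color", "thermal"),
      x_m = px, y_m = py, timestamp = truth_row$timestamp,
      path = sprintf("frames/%s_d%02d_%s.%s", truth_row$plant_id,
                     truth_row$dap, c("depth", "color", "thermal"),
                     c("tif", "png", "tif"))
    )
    list(depth = depth, color = color, thermal = thermal, records = records,
         warn_fov = warn_fov)
  })
}

#' Run the trait-extraction pipeline on one rendered scene
#'
#' Reconstruct, segment by excess green, compute morphological traits, and
#' extract mean canopy temperature with circumcircle neighbour filtering.
#'
#' @param scene A list from [render_scene()] (or with the same elements read
#'   from disk).
#' @param config The [sim_config()] (for camera intrinsics).
#' @param t_air_c Concurrent air temperature (deg C), or `NA` to skip the
#'   canopy-air delta.
#' @return A one-row tibble of extracted traits: `h_m`, `wir_m`, `war_m`,
#'   `pla_m2`, `cv_m3`, `t_canopy_c`, `tc_minus_ta_c`, plus bookkeeping
#'   columns from the component filter.
#' @export
extract_scene_traits <- function(scene, config, t_air_c = NA_real_) {
  cloud <- reconstruct_point_cloud(scene$depth, scene$color,
                                   config$depth_camera)
  plant <- segment_canopy(cloud)
  morph <- morphological_traits(plant)
  therm <- extract_canopy_temperature(scene$thermal)
  dplyr::bind_cols(
    morph[c("h_m", "wir_m", "war_m", "pla_m2", "cv_m3", "n_points")],
    therm[c("t_canopy_c", "threshold_c", "n_components", "n_removed")],
    tibble(tc_minus_ta_c = if (is.na(t_air_c)) NA_real_ else
      canopy_air_delta(therm$t_canopy_c, t_air_c))
  )
}

#' Write a complete synthetic data set to a directory
#'
#' Writes `plant_map.csv`, `image_index.csv`, `env_log.csv`, `truth.csv` and
#' a `frames/` directory of depth/color/thermal rasters for the selected
#' plants and dates. File formats match the readers
#' ([read_plant_map()] etc. and the raster IO in [write_depth_tiff()]).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param plant_ids Plants to render (default: all; rendering all 132 plants
#'   on all dates writes ~2000 small rasters).
#' @param dates Indices into `config$dap` (default all).
#' @return The directory path, invisibly.
#' @export
simulate_field_data <- function(config, dir, plant_ids = NULL,
                                dates = seq_along(config$dap)) {
  sim <- generate_field(config)
  env <- generate_env_log(config, dates)
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  plant_ids <- plant_ids %||% sim$plants$plant_id
  sel <- sim$truth[sim$truth$plant_id %in% plant_ids &
                     sim$truth$dap %in% config$dap[dates], ]
  recs <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    sc <- render_scene(sel[i, ], config)
    write_depth_tiff(sc$depth, file.path(dir, sc$records$path[1L]))
    write_color_png(sc$color, file.path(dir, sc$records$path[2L]))
    write_thermal_tiff(sc$thermal, file.path(dir, sc$records$path[3L]))
    sc$records
  })
  readr::write_csv(sim$plants, file.path(dir, "plant_map.csv"))
  readr::write_csv(recs, file.path(dir, "image_index.csv"))
  readr::write_csv(env, file.path(dir, "env_log.csv"))
  readr::write_csv(sel, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Build a per-plant, per-date trait table from rendered scenes
#'
#' Renders (in memory) and processes the selected plants and dates through
#' the full extraction pipeline, attaching genotype, group, yield and the
#' concurrent air temperature; the result feeds [correlate_with_yield()],
#' [heritability_pipeline()] and [growth_rate()].
#'
#' @param config A [sim_config()].
#' @param sim Output of [generate_field()] (regenerated when `NULL`).
#' @param plant_ids,dates Subset selectors as in [simulate_field_data()].
#' @return A trait-table tibble, one row per plant per date.
#' @export
pipeline_trait_table <- function(config, sim = NULL, plant_ids = NULL,
                                 dates = seq_along(config$dap)) {
  sim <- sim %||% generate_field(config)
  plant_ids <- plant_ids %||% sim$plants$plant_id
  sel <- sim$truth[sim$truth$plant_id %in% plant_ids &
                     sim$truth$dap %in% config$dap[dates], ]
  purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    row <- sel[i, ]
    sc <- render_scene(row, config)
    ex <- extract_scene_traits(sc, config, t_air_c = row$t_air_c)
    dplyr::bind_cols(
      tibble(plant_id = row$plant_id, genotype = row$genotype,
             group = row$group, dap = row$dap,
             yield_g = sim$plants$yield_g[match(row$plant_id,
                                                sim$plants$plant_id)]),
      ex)
  })
}
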