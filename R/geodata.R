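## Field/plot data model: plant map, image index, environment log, and
## assignment of each acquired frame to the plant it images.

plant_groups <- c("hirsutum", "barbadense", "exotic")

#' Read a plant map CSV
#'
#' One row per surveyed plant. Required columns: `plant_id`, `genotype`,
#' `group` (one of `"hirsutum"`, `"barbadense"`, `"exotic"`), `x_m`, `y_m`
#' (planar field coordinates in metres, x across-row, y in-row) and `yield_g`
#' (fiber yield in grams; may be blank). Positions are the surveyed main-stem
#' positions of individual plants.
#'
#' @param path Path to a comma-separated, UTF-8, "." decimal CSV with header.
#' @return A tibble with columns `plant_id`, `genotype`, `group` (factor),
#'   `x_m`, `y_m`, `yield_g`.
#' @export
read_plant_map <- function(path) {
  req <- c("plant_id", "genotype", "group", "x_m", "y_m", "yield_g")
  df <- read_checked_csv(path, req,
    col_types = readr::cols(
      plant_id = readr::col_character(), genotype = readr::col_character(),
      group = readr::col_character(), x_m = readr::col_double(),
      y_m = readr::col_double(), yield_g = readr::col_double()
    ))
  dup <- unique(df$plant_id[duplicated(df$plant_id)])
  if (length(dup)) {
    ct_abort(paste0("Duplicate plant_id in plant map: ",
                    paste(dup, collapse = ", ")), "ct_error_duplicate_id")
  }
  bad <- setdiff(unique(df$group), plant_groups)
  if (length(bad)) {
    ct_abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", "),
                    " (expected ", paste(plant_groups, collapse = "/"), ")"),
             "ct_error_bad_group")
  }
  assert_finite(df$x_m, "x_m"); assert_finite(df$y_m, "y_m")
  dplyr::mutate(df, group = factor(.data$group, levels = plant_groups))
}

#' Read an image index CSV
#'
#' One row per acquired frame with its geo-referenced acquisition position
#' (the GPS record represents the image centre). Required columns:
#' `frame_id`, `sensor` (one of depth/color/thermal/hyperspectral), `x_m`,
#' `y_m`, `timestamp` (seconds), `path`.
#'
#' @param path CSV path.
#' @return A tibble with those columns.
#' @export
read_image_index <- function(path) {
  req <- c("frame_id", "sensor", "x_m", "y_m", "timestamp", "path")
  df <- read_checked_csv(path, req,
    col_types = readr::cols(
      frame_id = readr::col_character(), sensor = readr::col_character(),
      x_m = readr::col_double(), y_m = readr::col_double(),
      timestamp = readr::col_double(), path = readr::col_character()
    ))
  bad <- setdiff(unique(df$sensor), c("depth", "color", "thermal", "hyperspectral"))
  if (length(bad)) {
    ct_abort(paste0("Unknown sensor label(s): ", paste(bad, collapse = ", ")),
             "ct_error_bad_sensor")
  }
  assert_finite(df$x_m, "x_m"); assert_finite(df$y_m, "y_m")
  df
}

#' Read an environment log CSV
#'
#' The auxiliary 1 Hz log of ambient conditions. Required columns:
#' `timestamp` (seconds, strictly increasing), `t_air_c`, `rh_pct`, `p_hpa`.
#'
#' @param path CSV path.
#' @return A tibble with those columns.
#' @export
read_env_log <- function(path) {
  req <- c("timestamp", "t_air_c", "rh_pct", "p_hpa")
  df <- read_checked_csv(path, req,
    col_types = readr::cols(.default = readr::col_double()))
  if (nrow(df) > 1L && any(diff(df$timestamp) <= 0)) {
    ct_abort("Environment log timestamps must be strictly increasing.",
             "ct_error_env_order")
  }
  df
}

## shared CSV reader: required header, parse problems reported with line numbers
read_checked_csv <- function(path, required, col_types) {
  if (!file.exists(path)) {
    ct_abort(paste0("File not found: ", path), "ct_error_missing_file")
  }
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE,
                        show_col_types = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    ct_abort(paste0("Missing required column(s) in ", basename(path), ": ",
                    paste(missing, collapse = ", ")), "ct_error_missing_column")
  }
  probs <- readr::problems(df)
  if (nrow(probs)) {
    msg <- paste(sprintf("line %d: %s", probs$row + 1L, probs$expected),
                 collapse = "; ")
    ct_abort(paste0("Parse error(s) in ", basename(path), ": ", msg),
             "ct_error_parse")
  }
  df[required]
}

#' Project longitude/latitude records to local field coordinates
#'
#' Equirectangular projection about the field centroid (or a supplied
#' origin). At field scale (tens of metres) the distortion is sub-centimetre,
#' so planar Euclidean distances on the result are accurate for frame
#' assignment.
#'
#' @param lon,lat Numeric vectors (degrees).
#' @param origin Optional `c(lon, lat)` origin; defaults to the centroid.
#' @return A tibble with `x_m` (easting) and `y_m` (northing) in metres.
#' @export
lonlat_to_local <- function(lon, lat, origin = NULL) {
  stopifnot(length(lon) == length(lat))
  assert_finite(lon, "lon"); assert_finite(lat, "lat")
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  r_earth <- 6371008.8
  tibble(
    x_m = (lon - origin[1L]) * pi / 180 * r_earth * cos(origin[2L] * pi / 180),
    y_m = (lat - origin[2L]) * pi / 180 * r_earth
  )
}

#' Assign the closest frame of each sensor to each plant
#'
#' For every plant and every sensor, the frame whose acquisition position has
#' the minimum Euclidean distance to the plant's surveyed position is
#' selected. Ties are broken by earliest timestamp, then lexicographic
#' `frame_id`. A sensor requested but absent from the image index yields a
#' row with `NA` frame and `absent = TRUE` rather than an error.
#'
#' @param plants Tibble from [read_plant_map()] (needs `plant_id`, `x_m`, `y_m`).
#' @param images Tibble from [read_image_index()].
#' @param sensors Character vector of sensors to assign; defaults to the
#'   sensors present in `images`.
#' @return A tibble with one row per plant x sensor: `plant_id`, `sensor`,
#'   `frame_id`, `distance_m`, `absent`.
#' @export
assign_images <- function(plants, images,
                          sensors = sort(unique(images$sensor))) {
  stopifnot(all(c("plant_id", "x_m", "y_m") %in% names(plants)),
            all(c("frame_id", "sensor", "x_m", "y_m", "timestamp") %in% names(images)))
  grid <- tidyr::expand_grid(plant_id = plants$plant_id, sensor = sensors)
  px <- setNames(plants$x_m, plants$plant_id)
  py <- setNames(plants$y_m, plants$plant_id)
  pick <- function(pid, sen) {
    cand <- images[images$sensor == sen, ]
    if (nrow(cand) == 0L) {
      return(tibble(frame_id = NA_character_, distance_m = NA_real_, absent = TRUE))
    }
    d <- sqrt((cand$x_m - px[[pid]])^2 + (cand$y_m - py[[pid]])^2)
    ord <- order(d, cand$timestamp, cand$frame_id)
    tibble(frame_id = cand$frame_id[ord[1L]], distance_m = d[ord[1L]],
           absent = FALSE)
  }
  dplyr::bind_cols(grid, purrr::map2_dfr(grid$plant_id, grid$sensor, pick))
}

#' Air temperature at given timestamps (nearest log record)
#'
#' Looks up the environment-log record nearest in time to each query. The log
#' is nominally 1 Hz, so nearest-neighbour lookup is used rather than
#' interpolation. Queries falling outside the logged range by more than
#' `max_gap_s` are flagged as extrapolated.
#'
#' @param env Tibble from [read_env_log()].
#' @param timestamp Numeric vector of query times (seconds).
#' @param max_gap_s Extrapolation tolerance in seconds (default 60).
#' @return A tibble with `timestamp`, `t_air_c`, `extrapolated`.
#' @export
air_temperature_at <- function(env, timestamp, max_gap_s = 60) {
  if (is.null(env) || nrow(env) == 0L) {
    ct_abort("Environment log is empty.", "ct_error_empty_env")
  }
  assert_finite(timestamp, "timestamp")
  ## nearest record via findInterval on the sorted log
  ts <- env$timestamp
  i <- findInterval(timestamp, ts, all.inside = TRUE)
  lo_d <- abs(timestamp - ts[i])
  hi_d <- abs(ts[pmin(i + 1L, length(ts))] - timestamp)
  nearest <- ifelse(hi_d < lo_d, pmin(i + 1L, length(ts)), i)
  tibble(
    timestamp = timestamp,
    t_air_c = env$t_air_c[nearest],
    extrapolated = timestamp < ts[1L] - max_gap_s | timestamp > ts[length(ts)] + max_gap_s
  )
}
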