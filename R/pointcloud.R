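## Colored point-cloud reconstruction from depth/color pairs and the five
## canopy-level morphological traits.

#' Camera intrinsics for a nadir-mounted depth/color pair
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels (0-based, inside the raster).
#' @param depth_scale Metres per depth raster unit (default 0.001, i.e. the
#'   raster stores millimetres).
#' @param camera_height Camera height above the ground plane in metres.
#' @return A list of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, depth_scale = 0.001,
                              camera_height = 2.4) {
  stopifnot(fx > 0, fy > 0, depth_scale > 0, camera_height > 0,
            cx >= 0, cy >= 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 depth_scale = depth_scale, camera_height = camera_height),
            class = "camera_intrinsics")
}

#' Reconstruct a colored point cloud from a depth/color frame pair
#'
#' Inverse pinhole projection of each depth pixel, with the camera nadir at
#' `camera_height` above a flat ground plane at z = 0. For a pixel (u, v)
#' (0-based) with raw depth d > 0:
#' x = (u - cx) d s / fx, y = (v - cy) d s / fy, z = camera_height - d s,
#' where s is `depth_scale`. Zero-depth pixels (no return) are dropped; the
#' color of a point is copied from the same pixel of the co-registered color
#' frame. x is across-row, y in-row, z up.
#'
#' @param depth Numeric matrix (rows = v, cols = u) of raw depth units.
#' @param color Either `NULL` or an array `dim(h, w, 3)` of RGB in 0..255
#'   (or 0..1, auto-scaled), co-registered with `depth`.
#' @param intr A [camera_intrinsics()] object.
#' @return A tibble with columns `x`, `y`, `z`, `r`, `g`, `b`. Attribute
#'   `empty = TRUE` when no pixel had a depth return.
#' @export
reconstruct_point_cloud <- function(depth, color, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"), is.matrix(depth))
  h <- nrow(depth); w <- ncol(depth)
  if (!is.null(color)) {
    if (length(dim(color)) != 3L || dim(color)[3L] < 3L ||
        dim(color)[1L] != h || dim(color)[2L] != w) {
      ct_abort("`color` must be an (h, w, 3) array co-registered with `depth`.",
               "ct_error_shape")
    }
    if (max(color, na.rm = TRUE) <= 1) color <- color * 255
  }
  keep <- which(depth > 0)
  if (length(keep) == 0L) {
    out <- tibble(x = double(), y = double(), z = double(),
                  r = double(), g = double(), b = double())
    attr(out, "empty") <- TRUE
    return(out)
  }
  v <- (keep - 1L) %% h          # 0-based row index
  u <- (keep - 1L) %/% h         # 0-based col index
  d_m <- depth[keep] * intr$depth_scale
  out <- tibble(
    x = (u - intr$cx) * d_m / intr$fx,
    y = (v - intr$cy) * d_m / intr$fy,
    z = intr$camera_height - d_m,
    r = if (is.null(color)) 0 else color[cbind(v + 1L, u + 1L, 1L)],
    g = if (is.null(color)) 0 else color[cbind(v + 1L, u + 1L, 2L)],
    b = if (is.null(color)) 0 else color[cbind(v + 1L, u + 1L, 3L)]
  )
  attr(out, "empty") <- FALSE
  out
}

#' Excess green (ExG) vegetation index
#'
#' ExG = 2g' - r' - b' on chromaticity-normalised channels
#' (r' = r/(r+g+b) etc.), the classic soil/vegetation discriminator. Black
#' pixels (r + g + b = 0) score 0 and are treated as background.
#'
#' @param r,g,b Non-negative channel vectors (any common scale).
#' @return Numeric vector in \[-1, 2\].
#' @export
#' @examples
#' excess_green(0, 255, 0)   # 2: pure green
#' excess_green(85, 85, 85)  # 0: achromatic
excess_green <- function(r, g, b) {
  stopifnot(all(r >= 0), all(g >= 0), all(b >= 0))
  s <- r + g + b
  out <- ifelse(s > 0, (2 * g - r - b) / s, 0)
  as.numeric(out)
}

#' Segment canopy points by the excess-green index
#'
#' Retains exactly the points with ExG strictly above `threshold` (default
#' 0.15), preserving order. An empty result marks an absent or dead plant
#' (attribute `empty_plant`), not a failure.
#'
#' @param cloud Point-cloud tibble with `r`, `g`, `b` columns.
#' @param threshold ExG cut-off (default 0.15).
#' @return The filtered tibble, with attribute `empty_plant`.
#' @export
segment_canopy <- function(cloud, threshold = 0.15) {
  stopifnot(all(c("r", "g", "b") %in% names(cloud)))
  out <- cloud[excess_green(cloud$r, cloud$g, cloud$b) > threshold, ]
  attr(out, "empty_plant") <- nrow(out) == 0L
  out
}

#' Optional statistical outlier filter for point clouds
#'
#' Removes points whose mean distance to their `k` nearest neighbours exceeds
#' the cloud mean by more than `sd_mult` standard deviations. Off by default
#' in the trait pipeline; exposed for noisy depth frames.
#'
#' @param cloud Point-cloud tibble with `x`, `y`, `z`.
#' @param k Number of neighbours (default 8).
#' @param sd_mult Cut-off in standard deviations (default 2).
#' @return Filtered tibble.
#' @export
filter_outliers <- function(cloud, k = 8L, sd_mult = 2) {
  n <- nrow(cloud)
  if (n <= k + 1L) return(cloud)
  d <- as.matrix(stats::dist(cbind(cloud$x, cloud$y, cloud$z)))
  mean_knn <- apply(d, 1L, function(row) mean(sort(row)[2:(k + 1L)]))
  cloud[mean_knn <= mean(mean_knn) + sd_mult * sd(mean_knn), ]
}

#' Canopy-level morphological traits of a segmented plant cloud
#'
#' Computes, with the ground plane at z = 0:
#' * `h_m` — plant height, the z of the highest plant point;
#' * `war_m` — width across-row, the maximum extent along x;
#' * `wir_m` — width in-row, the maximum extent along y;
#' * `pla_m2` — projected leaf area, the area covered by the canopy boundary
#'   in the (x, y) projection: by default the 2D convex-hull area
#'   ([convex_hull_area()]); `pla_mode = "grid"` instead counts occupied
#'   cells of size `grid_cell_m` (better for strongly concave canopies);
#' * `cv_m3` — canopy volume, the 3D convex-hull volume
#'   ([convex_hull_volume()]).
#'
#' Degenerate inputs are handled, not rejected: fewer than 4 non-coplanar
#' points give `cv_m3 = 0`, fewer than 3 non-collinear points give
#' `pla_m2 = 0`, both with `degenerate = TRUE`.
#'
#' @param cloud Segmented point-cloud tibble with `x`, `y`, `z` (metres).
#' @param pla_mode `"hull"` (default) or `"grid"`.
#' @param grid_cell_m Occupancy-grid cell size in metres (default 0.005).
#' @return A one-row tibble: `h_m`, `wir_m`, `war_m`, `pla_m2`, `cv_m3`,
#'   `n_points`, `degenerate`.
#' @export
morphological_traits <- function(cloud, pla_mode = c("hull", "grid"),
                                 grid_cell_m = 0.005) {
  pla_mode <- match.arg(pla_mode)
  stopifnot(all(c("x", "y", "z") %in% names(cloud)))
  n <- nrow(cloud)
  if (n == 0L) {
    return(tibble(h_m = 0, wir_m = 0, war_m = 0, pla_m2 = 0, cv_m3 = 0,
                  n_points = 0L, degenerate = TRUE))
  }
  assert_finite(cloud$x, "x"); assert_finite(cloud$y, "y")
  assert_finite(cloud$z, "z")
  pla <- if (pla_mode == "hull") {
    convex_hull_area(cloud$x, cloud$y)
  } else {
    nrow(unique(cbind(floor(cloud$x / grid_cell_m),
                      floor(cloud$y / grid_cell_m)))) * grid_cell_m^2
  }
  cv <- convex_hull_volume(cbind(cloud$x, cloud$y, cloud$z))
  tibble(
    h_m = max(cloud$z),
    wir_m = diff(range(cloud$y)),
    war_m = diff(range(cloud$x)),
    pla_m2 = pla,
    cv_m3 = as.numeric(cv),
    n_points = n,
    degenerate = isTRUE(attr(cv, "degenerate")) || pla == 0
  )
}

#' Daily growth rate of a trait between two measurement days
#'
#' `(trait_t2 - trait_t1) / (dap2 - dap1)` in trait units per day; may be
#' negative. Vectorised.
#'
#' @param trait_t1,trait_t2 Trait values at the two days.
#' @param dap1,dap2 Days after planting; requires `dap2 > dap1`.
#' @return Numeric vector of per-day rates.
#' @export
#' @examples
#' growth_rate(0.5, 1.2, 51, 65) # 0.05 m/day
growth_rate <- function(trait_t1, trait_t2, dap1, dap2) {
  if (any(dap2 <= dap1)) {
    ct_abort("`dap2` must be strictly greater than `dap1`.", "ct_error_dap_order")
  }
  (trait_t2 - trait_t1) / (dap2 - dap1)
}

#' Write a colored point cloud as ASCII PLY
#'
#' @param cloud Point-cloud tibble with `x`, `y`, `z`, `r`, `g`, `b`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(cloud)),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "end_header"
  ), con)
  if (nrow(cloud)) {
    writeLines(sprintf("%.6f %.6f %.6f %d %d %d", cloud$x, cloud$y, cloud$z,
                       as.integer(round(cloud$r)), as.integer(round(cloud$g)),
                       as.integer(round(cloud$b))), con)
  }
  invisible(path)
}
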