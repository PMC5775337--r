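## Mean canopy temperature from thermal frames: Otsu thresholding,
## 8-connected components with circumcircles, central-component selection,
## disjoint-circumcircle neighbour removal, and the calibration-time
## drift compensation and shading comparison.

#' Otsu threshold of a thermal frame
#'
#' Bins the frame into `n_bins` equal-width bins over its min-max range and
#' returns the bin boundary maximising the between-class variance
#' w0 w1 (mu0 - mu1)^2. At midday a transpiring canopy is cooler than bare
#' soil, so the plant class is the pixels *below* the threshold (set
#' `plant_is = "hot"` for the opposite polarity when masking).
#'
#' @param img Numeric matrix of temperatures (deg C), finite, with at least
#'   two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (deg C), a bin boundary strictly inside the value
#'   range. Ties take the lowest boundary.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  x <- as.numeric(img)
  assert_finite(x, "img")
  rng <- range(x)
  if (diff(rng) == 0) {
    ct_abort("degenerate histogram: image is constant", "ct_error_degenerate")
  }
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  ## bin j covers [breaks[j], breaks[j+1]); top bin closed
  bin <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * mids)
  n <- w0[n_bins]; mtot <- m0[n_bins]
  ## candidate thresholds: interior boundaries breaks[j+1], j = 1..n_bins-1
  j <- seq_len(n_bins - 1L)
  p0 <- w0[j] / n
  mu0 <- ifelse(w0[j] > 0, m0[j] / w0[j], 0)
  mu1 <- ifelse(n - w0[j] > 0, (mtot - m0[j]) / (n - w0[j]), 0)
  sb <- p0 * (1 - p0) * (mu0 - mu1)^2
  sb[w0[j] == 0 | w0[j] == n] <- -Inf
  breaks[which.max(sb) + 1L]
}

#' Binary plant mask of a thermal frame
#'
#' Applies [otsu_threshold()] and keeps the cold class (`img < threshold`)
#' by default, the canopy being cooler than soil.
#'
#' @param img Numeric temperature matrix.
#' @param plant_is `"cold"` (default) or `"hot"`.
#' @param n_bins Histogram bins for Otsu.
#' @return A logical matrix, with the threshold as attribute `threshold`.
#' @export
segment_thermal <- function(img, plant_is = c("cold", "hot"), n_bins = 256L) {
  plant_is <- match.arg(plant_is)
  thr <- otsu_threshold(img, n_bins)
  mask <- if (plant_is == "cold") img < thr else img >= thr
  attr(mask, "threshold") <- thr
  mask
}

## 8- (or 4-) connected labelling by iterative flood fill
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8L) {
    cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L), c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  }
  current <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- (px - 1L) %% h + 1L
      c0 <- (px - 1L) %/% h + 1L
      rr <- r0 + nb[, 1L]; cc <- c0 + nb[, 2L]
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      idx <- (cc[ok] - 1L) * h + rr[ok]
      idx <- idx[mask[idx] & lab[idx] == 0L]
      if (length(idx)) {
        lab[idx] <- current
        queue <- c(queue, idx)
      }
    }
  }
  lab
}

#' Connected components of a binary mask with centroids and circumcircles
#'
#' Labels the mask (8-connected by default), then reports per component the
#' pixel count, area-weighted centroid and the exact minimum enclosing
#' circle of the pixel centres ([min_enclosing_circle()]). Coordinates are
#' 0-based pixel positions, `x` along columns and `y` along rows.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return A tibble with one row per component: `component`, `n_px`,
#'   `x_px`, `y_px` (centroid), `r_px` (circumcircle radius), `cx_px`,
#'   `cy_px` (circumcircle centre), and a list-column `pixels` of (row, col)
#'   1-based index matrices. Empty mask gives zero rows.
#' @export
find_components <- function(mask, connectivity = 8L) {
  mask <- mask != 0
  lab <- label_components(mask, connectivity)
  k <- max(lab)
  if (k == 0L) {
    return(tibble(component = integer(), n_px = integer(), x_px = double(),
                  y_px = double(), r_px = double(), cx_px = double(),
                  cy_px = double(), pixels = list()))
  }
  h <- nrow(mask)
  purrr::map_dfr(seq_len(k), function(i) {
    idx <- which(lab == i)
    row <- (idx - 1L) %% h + 1L
    col <- (idx - 1L) %/% h + 1L
    x <- col - 1; y <- row - 1   # 0-based pixel-centre coordinates
    mec <- min_enclosing_circle(x, y)
    tibble(component = i, n_px = length(idx),
           x_px = mean(x), y_px = mean(y),
           r_px = mec$radius, cx_px = mec$center[1L], cy_px = mec$center[2L],
           pixels = list(cbind(row = row, col = col)))
  })
}

#' Select the most central connected component as the target plant
#'
#' The component whose centroid is closest to the image centre
#' `((width - 1)/2, (height - 1)/2)` is taken as the plant imaged by the
#' frame. Ties go to the larger component, then the lower index.
#'
#' @param components Tibble from [find_components()].
#' @param width,height Frame dimensions in pixels.
#' @return The row index (into `components`) of the target component.
#' @export
select_plant_component <- function(components, width, height) {
  if (nrow(components) == 0L) {
    ct_abort("no plant detected: empty component list", "ct_error_no_plant")
  }
  d <- sqrt((components$x_px - (width - 1) / 2)^2 +
              (components$y_px - (height - 1) / 2)^2)
  order(d, -components$n_px, components$component)[1L]
}

#' Remove neighbouring-plant components by the disjoint-circumcircle test
#'
#' A component i is classified as a separate plant (or weed) when its
#' circumcircle is disjoint from the target's:
#' `(r_i + r_c) <= sqrt((x_i - x_c)^2 + (y_i - y_c)^2)`.
#' Such components are removed; the final plant mask is the union of the
#' target and every component whose circumcircle intersects the target's.
#'
#' @param components Tibble from [find_components()].
#' @param target Row index of the target component
#'   (from [select_plant_component()]).
#' @return `components` with logical columns `separate` and `kept` added
#'   (the raw flags are retained so either reading of the convention is
#'   recoverable). The target row always has `kept = TRUE`.
#' @export
validate_components <- function(components, target) {
  stopifnot(target >= 1L, target <= nrow(components))
  xc <- components$cx_px[target]; yc <- components$cy_px[target]
  rc <- components$r_px[target]
  d <- sqrt((components$cx_px - xc)^2 + (components$cy_px - yc)^2)
  separate <- (components$r_px + rc) <= d
  separate[target] <- FALSE
  dplyr::mutate(components, separate = separate, kept = !separate)
}

#' Rasterise kept components back into a logical mask
#'
#' @param components Tibble from [validate_components()] (uses `kept`), or
#'   from [find_components()] (all components used).
#' @param dim `c(height, width)` of the frame.
#' @return Logical matrix.
#' @export
components_mask <- function(components, dim) {
  mask <- matrix(FALSE, dim[1L], dim[2L])
  keep <- if ("kept" %in% names(components)) which(components$kept)
          else seq_len(nrow(components))
  for (i in keep) {
    px <- components$pixels[[i]]
    mask[px] <- TRUE
  }
  mask
}

#' Mean canopy temperature over a mask
#'
#' @param img Numeric temperature matrix (deg C).
#' @param mask Logical matrix of the same shape.
#' @return Arithmetic mean of `img` over the mask pixels.
#' @export
mean_canopy_temperature <- function(img, mask) {
  stopifnot(all(dim(img) == dim(mask)))
  if (!any(mask)) ct_abort("empty mask", "ct_error_empty_mask")
  mean(img[mask != 0])
}

#' Canopy minus air temperature
#'
#' The water-stress indicator Tc - Ta. Vectorised.
#'
#' @param t_canopy,t_air Temperatures in deg C.
#' @return `t_canopy - t_air`.
#' @export
canopy_air_delta <- function(t_canopy, t_air) {
  assert_finite(t_canopy, "t_canopy"); assert_finite(t_air, "t_air")
  t_canopy - t_air
}

#' Full canopy-temperature extraction from one thermal frame
#'
#' Otsu segmentation (cold class), 8-connected components with
#' circumcircles, central-component selection, disjoint-circumcircle
#' neighbour removal, then the mean of the original frame over the final
#' mask.
#'
#' @param img Numeric temperature matrix (deg C).
#' @param plant_is Plant polarity for [segment_thermal()].
#' @param connectivity Component connectivity (default 8).
#' @return A one-row tibble: `t_canopy_c`, `threshold_c`, `n_components`,
#'   `n_removed`, `mask_px`; the final mask as attribute `mask`.
#' @export
extract_canopy_temperature <- function(img, plant_is = "cold",
                                       connectivity = 8L) {
  mask0 <- segment_thermal(img, plant_is)
  comps <- find_components(mask0, connectivity)
  tgt <- select_plant_component(comps, ncol(img), nrow(img))
  comps <- validate_components(comps, tgt)
  final <- components_mask(comps, dim(img))
  out <- tibble(
    t_canopy_c = mean_canopy_temperature(img, final),
    threshold_c = attr(mask0, "threshold"),
    n_components = nrow(comps),
    n_removed = sum(comps$separate),
    mask_px = sum(final)
  )
  attr(out, "mask") <- final
  out
}

#' Drift-compensate a paired camera/thermocouple measurement series
#'
#' During repeatability trials the reference blackbody's true temperature
#' drifts with ambient conditions; the thermocouple tracks that drift. The
#' camera reading is compensated to a common reference as
#' `ti_comp = ti_raw + (tc_ref - tc)`, removing the ambient drift so that
#' condition-wise means become comparable. `tc_ref` is the grand mean of the
#' thermocouple series by default, or the first frame's thermocouple
#' reading.
#'
#' @param series A tibble with columns `condition` (e.g. blackbody height),
#'   `frame`, `ti_raw` (camera, deg C) and `tc` (thermocouple, deg C).
#' @param reference `"grand_mean"` (default) or `"first_frame"`.
#' @return `series` with a `ti_comp` column added.
#' @export
compensate_series <- function(series, reference = c("grand_mean", "first_frame")) {
  reference <- match.arg(reference)
  req <- c("condition", "frame", "ti_raw", "tc")
  if (!all(req %in% names(series))) {
    ct_abort(paste0("`series` must have columns ",
                    paste(req, collapse = ", ")), "ct_error_misaligned")
  }
  if (anyNA(series$ti_raw) || anyNA(series$tc)) {
    ct_abort("camera and thermocouple series must be index-aligned (no NA)",
             "ct_error_misaligned")
  }
  tc_ref <- switch(reference,
    grand_mean = mean(series$tc),
    first_frame = series$tc[order(series$frame)][1L]
  )
  dplyr::mutate(series, ti_comp = .data$ti_raw + (tc_ref - .data$tc))
}

#' Summary of paired shaded/unshaded temperature differences
#'
#' Mean and sample standard deviation (n - 1) of `t_shaded - t_unshaded`
#' over paired frames of the same plant, used to verify the absence of a
#' shading effect on canopy-temperature measurement.
#'
#' @param t_shaded,t_unshaded Paired temperature vectors (deg C), length >= 2.
#' @return A one-row tibble: `mean_diff_c`, `sd_diff_c`, `n`.
#' @export
paired_difference_summary <- function(t_shaded, t_unshaded) {
  stopifnot(length(t_shaded) == length(t_unshaded))
  if (length(t_shaded) < 2L) {
    ct_abort("need at least 2 pairs", "ct_error_too_few")
  }
  d <- t_shaded - t_unshaded
  tibble(mean_diff_c = mean(d), sd_diff_c = sd(d), n = length(d))
}
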