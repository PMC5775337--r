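## Independent brute-force oracles used to validate the package's geometry
## and segmentation primitives. These deliberately use different algorithms
## from the implementation.

## gift-wrapping (Jarvis march) 2D convex hull; returns polygon vertex order
oracle_giftwrap_hull <- function(x, y) {
  n <- length(x)
  start <- which.min(x + 1e-12 * y)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    best <- cand[1L]
    for (q in cand[-1L]) {
      cr <- (x[best] - x[p]) * (y[q] - y[p]) - (y[best] - y[p]) * (x[q] - x[p])
      if (cr < 0 ||
          (cr == 0 && (x[q] - x[p])^2 + (y[q] - y[p])^2 >
             (x[best] - x[p])^2 + (y[best] - y[p])^2)) {
        best <- q
      }
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("giftwrap failed to terminate")
  }
  hull
}

oracle_shoelace_area <- function(x, y) {
  h <- oracle_giftwrap_hull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

## 3D hull volume by exhaustive facet enumeration (O(n^4)); assumes points
## in general position (no 4 coplanar hull points). Small n only.
oracle_hull_volume <- function(pts) {
  n <- nrow(pts)
  o <- colMeans(pts)
  vol <- 0
  scale <- max(apply(pts, 2, function(v) diff(range(v))))
  tol <- 1e-9 * scale^3
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    u <- pts[j, ] - pts[i, ]; v <- pts[k, ] - pts[i, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    s <- (pts - matrix(pts[i, ], n, 3, byrow = TRUE)) %*% nrm
    if (all(s <= tol) || all(s >= -tol)) {
      if (sum(nrm * (o - pts[i, ])) > 0) nrm <- -nrm   # outward
      vol <- vol + sum((pts[i, ] - o) * nrm) / 6
    }
  }
  vol
}

## scipy.spatial.ConvexHull as a fully independent large-n oracle
oracle_scipy_hull <- function(pts) {
  csv <- tempfile(fileext = ".csv")
  utils::write.table(pts, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from scipy.spatial import ConvexHull",
    "p = np.loadtxt(sys.argv[1], delimiter=',')",
    "h = ConvexHull(p)",
    "print(repr(h.volume)); print(repr(h.area))"
  ), py)
  out <- system2("python", c(py, csv), stdout = TRUE)
  list(volume = as.numeric(out[1]), area = as.numeric(out[2]))
}

## minimum enclosing circle by exhaustive search over all pairs and triples
oracle_min_circle <- function(x, y) {
  n <- length(x)
  best <- NULL
  covers <- function(cx, cy, r) all(sqrt((x - cx)^2 + (y - cy)^2) <= r + 1e-9)
  consider <- function(cx, cy, r) {
    if (covers(cx, cy, r) && (is.null(best) || r < best$radius)) {
      best <<- list(center = unname(c(cx, cy)), radius = unname(r))
    }
  }
  for (i in 1:n) for (j in i:n) {
    consider((x[i] + x[j]) / 2, (y[i] + y[j]) / 2,
             sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) / 2)
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    d <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) + x[k] * (y[i] - y[j]))
    if (abs(d) < 1e-12) next
    ux <- ((x[i]^2 + y[i]^2) * (y[j] - y[k]) + (x[j]^2 + y[j]^2) * (y[k] - y[i]) +
             (x[k]^2 + y[k]^2) * (y[i] - y[j])) / d
    uy <- ((x[i]^2 + y[i]^2) * (x[k] - x[j]) + (x[j]^2 + y[j]^2) * (x[i] - x[k]) +
             (x[k]^2 + y[k]^2) * (x[j] - x[i])) / d
    consider(ux, uy, sqrt((x[i] - ux)^2 + (y[i] - uy)^2))
  }
  best
}

## Otsu threshold by direct evaluation: for every candidate bin boundary,
## split the raw values and compute the weighted between-class variance from
## the two subsamples (no histogram-moment recursion)
oracle_otsu <- function(x, n_bins = 256L) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  xb <- mids[bin]                      # binned values, as the histogram sees them
  best_sb <- -Inf; best_thr <- NA
  for (j in 1:(n_bins - 1)) {
    thr <- breaks[j + 1]
    lo <- xb[bin <= j]; hi <- xb[bin > j]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(xb)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best_sb + 1e-15) { best_sb <- sb; best_thr <- thr }
  }
  best_thr
}

## random points in the upper half of an ellipsoid (rejection sampling)
half_ellipsoid_points <- function(n, a = 1, b = 0.8, c = 0.6) {
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    cand <- cbind(stats::runif(2 * n, -a, a), stats::runif(2 * n, -b, b),
                  stats::runif(2 * n, 0, c))
    keep <- (cand[, 1] / a)^2 + (cand[, 2] / b)^2 + (cand[, 3] / c)^2 <= 1
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts[seq_len(n), ]
}
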