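#' Area of the 2D convex hull of a point set
#'
#' Computes the area enclosed by the convex hull of the points `(x, y)` using
#' [grDevices::chull()] for the hull and the shoelace formula for the area.
#' This is the default definition of projected leaf area: the area covered by
#' the canopy boundary in the ground-plane projection.
#'
#' @param x,y Numeric vectors of planar coordinates (same length).
#' @return A single non-negative number. Fewer than 3 distinct, non-collinear
#'   points give area 0.
#' @export
#' @examples
#' convex_hull_area(c(0, 1, 1, 0), c(0, 0, 1, 1)) # unit square -> 1
convex_hull_area <- function(x, y) {
  stopifnot(length(x) == length(y))
  assert_finite(x, "x"); assert_finite(y, "y")
  if (length(x) < 3L) return(0)
  idx <- grDevices::chull(x, y)
  if (length(idx) < 3L) return(0)
  hx <- x[idx]; hy <- y[idx]
  abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
}

#' Volume of the 3D convex hull of a point set
#'
#' Incremental convex-hull construction: an initial non-degenerate tetrahedron
#' is grown point by point; for each point outside the current hull the
#' visible facets are replaced by a cone of new facets over the horizon edges.
#' The volume is the sum of signed tetrahedra from an interior point over the
#' outward-oriented facets. Used for canopy volume.
#'
#' @param pts A numeric matrix with 3 columns (x, y, z) or a data frame with
#'   columns `x`, `y`, `z`.
#' @return A single non-negative number, with attribute `degenerate = TRUE`
#'   and value 0 when fewer than 4 points are supplied or all points are
#'   coplanar (within tolerance).
#' @export
#' @examples
#' cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
#' convex_hull_volume(cube) # 1
convex_hull_volume <- function(pts) {
  if (is.data.frame(pts)) pts <- cbind(pts$x, pts$y, pts$z)
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L)
  storage.mode(pts) <- "double"
  assert_finite(pts, "pts")
  degenerate <- function() structure(0, degenerate = TRUE)
  n <- nrow(pts)
  if (n < 4L) return(degenerate())

  scale <- max(apply(pts, 2L, function(v) diff(range(v))), 0)
  if (scale == 0) return(degenerate())
  eps <- 1e-12 * scale

  ## initial simplex: two extreme points, then farthest from line, then plane
  i1 <- which.min(pts[, 1L])
  d1 <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < eps^2) return(degenerate())
  ab <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2L, pts[i1, ])
  cr <- cbind(rel[, 2L] * ab[3L] - rel[, 3L] * ab[2L],
              rel[, 3L] * ab[1L] - rel[, 1L] * ab[3L],
              rel[, 1L] * ab[2L] - rel[, 2L] * ab[1L])
  dline <- rowSums(cr^2)
  i3 <- which.max(dline)
  if (dline[i3] < (eps * sqrt(sum(ab^2)))^2) return(degenerate())
  nrm <- c(
    (pts[i2, 2L] - pts[i1, 2L]) * (pts[i3, 3L] - pts[i1, 3L]) -
      (pts[i2, 3L] - pts[i1, 3L]) * (pts[i3, 2L] - pts[i1, 2L]),
    (pts[i2, 3L] - pts[i1, 3L]) * (pts[i3, 1L] - pts[i1, 1L]) -
      (pts[i2, 1L] - pts[i1, 1L]) * (pts[i3, 3L] - pts[i1, 3L]),
    (pts[i2, 1L] - pts[i1, 1L]) * (pts[i3, 2L] - pts[i1, 2L]) -
      (pts[i2, 2L] - pts[i1, 2L]) * (pts[i3, 1L] - pts[i1, 1L])
  )
  nrm <- nrm / sqrt(sum(nrm^2))
  dplane <- abs(rel %*% nrm)
  i4 <- which.max(dplane)
  if (dplane[i4] < eps) return(degenerate())

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))

  face_geom <- function(faces) {
    a <- pts[faces[, 1L], , drop = FALSE]
    b <- pts[faces[, 2L], , drop = FALSE]
    cc <- pts[faces[, 3L], , drop = FALSE]
    u <- b - a; v <- cc - a
    nr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    off <- rowSums(nr * a)
    ## orient outward: interior strictly below every facet plane
    flip <- (nr %*% interior - off) > 0
    faces[flip, c(2L, 3L)] <- faces[flip, c(3L, 2L)]
    nr[flip, ] <- -nr[flip, ]
    off[flip] <- -off[flip]
    list(faces = faces, normal = nr, offset = off)
  }
  g <- face_geom(faces)

  todo <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in todo) {
    above <- g$normal %*% pts[p, ] - g$offset
    vis <- which(above > eps * sqrt(rowSums(g$normal^2)))
    if (length(vis) == 0L) next
    ## horizon = directed edges of visible facets whose twin is not visible
    vf <- g$faces[vis, , drop = FALSE]
    edges <- rbind(vf[, c(1L, 2L)], vf[, c(2L, 3L)], vf[, c(3L, 1L)])
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    new_faces <- cbind(horizon, p)
    faces2 <- rbind(g$faces[-vis, , drop = FALSE], new_faces)
    g <- face_geom(faces2)
  }

  a <- pts[g$faces[, 1L], , drop = FALSE]
  vol <- sum((a - matrix(interior, nrow(g$faces), 3L, byrow = TRUE)) *
               g$normal) / 6
  structure(max(vol, 0), degenerate = FALSE)
}

## exact circle through two points (diameter) / three points (circumcircle)
circle2 <- function(p, q) {
  list(center = unname((p + q) / 2), radius = unname(sqrt(sum((p - q)^2)) / 2))
}

circle3 <- function(p, q, r) {
  ax <- p[1L]; ay <- p[2L]; bx <- q[1L]; by <- q[2L]; cx <- r[1L]; cy <- r[2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14 * max(abs(c(ax, ay, bx, by, cx, cy)), 1)) {
    ## collinear: smallest 2-point circle covering all three
    cand <- list(circle2(p, q), circle2(p, r), circle2(q, r))
    ok <- vapply(cand, function(cc) {
      all(vapply(list(p, q, r), function(z)
        sqrt(sum((z - cc$center)^2)) <= cc$radius * (1 + 1e-12), TRUE))
    }, TRUE)
    return(cand[ok][[which.min(vapply(cand[ok], `[[`, 0, "radius"))]])
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

#' Exact minimum enclosing circle of planar points
#'
#' Smallest circle containing every input point, computed by an incremental
#' Welzl-style construction restricted to the convex-hull points (the minimum
#' enclosing circle is determined by at most three hull points). Used for the
#' circumcircle of a connected component in thermal plant masking.
#'
#' @param x,y Numeric coordinate vectors of equal length (at least 1 point).
#' @return A list with `center` (length-2 numeric) and `radius`.
#' @export
#' @examples
#' min_enclosing_circle(c(0, 2, 1), c(0, 0, 5))
min_enclosing_circle <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  assert_finite(x, "x"); assert_finite(y, "y")
  pts <- unname(unique(cbind(x, y)))
  if (nrow(pts) == 1L) return(list(center = pts[1L, ], radius = 0))
  if (nrow(pts) > 3L) {
    h <- grDevices::chull(pts[, 1L], pts[, 2L])
    if (length(h) >= 2L) pts <- pts[h, , drop = FALSE]
  }
  scale <- max(diff(range(pts[, 1L])), diff(range(pts[, 2L])))
  tol <- 1 + 1e-10
  inside <- function(cc, p) sqrt(sum((p - cc$center)^2)) <= cc$radius * tol + 1e-12 * scale
  n <- nrow(pts)
  cc <- circle2(pts[1L, ], pts[2L, ])
  if (n >= 3L) for (i in 3:n) {
    if (inside(cc, pts[i, ])) next
    cc <- circle2(pts[1L, ], pts[i, ])
    for (j in 2:(i - 1L)) {
      if (inside(cc, pts[j, ])) next
      cc <- circle2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1L)) {
        if (inside(cc, pts[k, ])) next
        cc <- circle3(pts[i, ], pts[j, ], pts[k, ])
      }
    }
  }
  cc
}
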