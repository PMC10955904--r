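# Piecewise-linear interpolation of expert scores over a 2-D feature plane.
# The point set is Delaunay-triangulated (Bowyer-Watson) and scores are
# interpolated barycentrically within each triangle; grid nodes outside the
# convex hull are NA.

# Internal: Delaunay triangulation by incremental insertion with a
# super-triangle. Returns an integer matrix, one row per triangle.
delaunay_triangulation <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("triangulation requires at least 3 points")
  # scale into a unit box for numerical robustness
  rngx <- range(x); rngy <- range(y)
  span <- max(rngx[2] - rngx[1], rngy[2] - rngy[1])
  if (span == 0) stop("all points coincide")
  px <- (x - rngx[1]) / span
  py <- (y - rngy[1]) / span
  # super-triangle comfortably enclosing the unit box
  px <- c(px, -10, 10, 0.5)
  py <- c(py, -10, -10, 20)
  sup <- n + 1:3
  tris <- matrix(sup, nrow = 1)
  circum <- function(t) {
    ax <- px[t[1]]; ay <- py[t[1]]
    bx <- px[t[2]]; by <- py[t[2]]
    cx <- px[t[3]]; cy <- py[t[3]]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) return(c(NA, NA, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- list(circum(tris[1, ]))
  for (i in seq_len(n)) {
    bad <- vapply(seq_len(nrow(tris)), function(j) {
      c0 <- cc[[j]]
      (px[i] - c0[1])^2 + (py[i] - c0[2])^2 <= c0[3] + 1e-12
    }, logical(1))
    if (!any(bad)) next   # duplicate point exactly on hull; skip
    edges <- NULL
    for (j in which(bad)) {
      t <- tris[j, ]
      edges <- rbind(edges,
                     sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))
    }
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad]
    for (e in seq_len(nrow(boundary))) {
      t <- c(boundary[e, ], i)
      c0 <- circum(t)
      if (!is.finite(c0[3])) next   # degenerate sliver with a collinear edge
      tris <- rbind(tris, t)
      cc <- c(cc, list(c0))
    }
  }
  keep <- apply(tris, 1, function(t) !any(t %in% sup))
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0) {
    stop("points are collinear: no triangulation exists")
  }
  dimnames(tris) <- NULL
  tris
}

# Internal: barycentric coordinates of (qx, qy) in triangle (indices t).
barycentric <- function(qx, qy, x, y, t) {
  x1 <- x[t[1]]; y1 <- y[t[1]]
  x2 <- x[t[2]]; y2 <- y[t[2]]
  x3 <- x[t[3]]; y3 <- y[t[3]]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  if (abs(det) < 1e-300) return(c(NA, NA, NA))
  l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det
  l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det
  c(l1, l2, 1 - l1 - l2)
}

#' Linearly interpolated score surface over a 2-D feature plane
#'
#' Triangulates the trial coordinates (Delaunay) and linearly interpolates
#' the expert scores inside each triangle, reproducing contour plots of
#' evaluation score over e.g. the `(v_L, v_U)` plane or a PC score plane.
#' Values outside the convex hull of the points are undefined (`NA`).
#'
#' @param x,y Numeric coordinates of the scored trials (at least 3
#'   non-collinear points).
#' @param scores Numeric score per point.
#' @param grid_n Grid resolution per axis (default 50).
#' @return An object of class `score_surface`: grid vectors `x`, `y`, matrix
#'   `z` (`grid_n` rows = x, columns = y), the `triangles` index matrix and
#'   the inputs. Use `interpolate_score(surface, qx, qy)` for point queries.
#' @examples
#' s <- score_surface(c(0, 1, 0.5), c(0, 0, 1), scores = c(0, 0, 3))
#' interpolate_score(s, 0.5, 1 / 3)  # barycenter of the triangle -> 1
#' @export
score_surface <- function(x, y, scores, grid_n = 50) {
  x <- as.numeric(x); y <- as.numeric(y); scores <- as.numeric(scores)
  if (length(x) != length(y) || length(x) != length(scores)) {
    stop("x, y and scores must have equal length")
  }
  if (length(x) < 3) stop("at least 3 points are required")
  if (any(!is.finite(c(x, y, scores)))) stop("inputs must be finite")
  tris <- delaunay_triangulation(x, y)
  gx <- seq(min(x), max(x), length.out = grid_n)
  gy <- seq(min(y), max(y), length.out = grid_n)
  surf <- structure(list(x = gx, y = gy, z = NULL, triangles = tris,
                         px = x, py = y, scores = scores),
                    class = "score_surface")
  z <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    z[i, ] <- interpolate_score(surf, rep(gx[i], grid_n), gy)
  }
  surf$z <- z
  surf
}

#' Query a score surface at arbitrary points
#'
#' @param surface A `score_surface`.
#' @param qx,qy Query coordinates (equal-length vectors).
#' @return Interpolated scores; `NA` outside the convex hull.
#' @export
interpolate_score <- function(surface, qx, qy) {
  stopifnot(inherits(surface, "score_surface"))
  out <- rep(NA_real_, length(qx))
  tol <- 1e-9
  for (q in seq_along(qx)) {
    for (r in seq_len(nrow(surface$triangles))) {
      t <- surface$triangles[r, ]
      lam <- barycentric(qx[q], qy[q], surface$px, surface$py, t)
      if (anyNA(lam)) next
      if (all(lam >= -tol)) {
        out[q] <- sum(lam * surface$scores[t])
        break
      }
    }
  }
  out
}

#' @export
print.score_surface <- function(x, ...) {
  cat(sprintf("<score_surface: %d points, %d triangles, %dx%d grid>\n",
              length(x$px), nrow(x$triangles), length(x$x), length(x$y)))
  invisible(x)
}
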