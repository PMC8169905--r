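# Shared fixtures and independent oracles.

# Geometric (orthogonal-distance) circle fit by direct minimization:
# independent check for the algebraic Taubin fit.
geomCircleFit <- function(points) {
  x <- points[, 1L]; y <- points[, 2L]
  # initialize from the circumcircle of three spread points (a centroid
  # start is far off for shallow arcs)
  n <- length(x)
  i3 <- c(1L, (n + 1L) %/% 2L, n)
  ax <- x[i3[1L]]; ay <- y[i3[1L]]
  bx <- x[i3[2L]]; by <- y[i3[2L]]
  cx <- x[i3[3L]]; cy <- y[i3[3L]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  cx0 <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
            (cx^2 + cy^2) * (ay - by)) / d
  cy0 <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
            (cx^2 + cy^2) * (bx - ax)) / d
  r0 <- mean(sqrt((x - cx0)^2 + (y - cy0)^2))
  obj <- function(p) {
    d <- sqrt((x - p[1L])^2 + (y - p[2L])^2)
    sum((d - p[3L])^2)
  }
  fit <- optim(c(cx0, cy0, r0), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  list(center = fit$par[1:2], radius = fit$par[3L])
}

# A straight stroke of given width between two points, rasterized on a
# blank canvas (used for crossing/branching fixtures).
strokeMask <- function(nr, nc, p0, p1, width = 5) {
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  v <- c(p1[1L] - p0[1L], p1[2L] - p0[2L])
  len2 <- sum(v^2)
  t <- pmin(pmax(((ii - p0[1L]) * v[1L] + (jj - p0[2L]) * v[2L]) / len2,
                 0), 1)
  di <- ii - (p0[1L] + t * v[1L])
  dj <- jj - (p0[2L] + t * v[2L])
  sqrt(di^2 + dj^2) <= width / 2
}

# Small-canvas defaults used throughout the unit tests; arcs in the study
# range fit these comfortably.
testCanvasArc <- c(2600L, 1950L)
testCanvasEllipse <- c(700L, 700L)
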