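# Independent oracles used across the suite. These deliberately do not
# share code with the package: the ellipse perimeter is checked against
# adaptive quadrature of the exact arc length, average widths against a
# fine-grid integral, and convex hulls against a Jarvis-march
# implementation written here from scratch.

# exact ellipse circumference by arc-length quadrature (full axes in)
ellipse_perimeter_quadrature <- function(major, minor) {
  a <- major / 2
  b <- minor / 2
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

# limit of the sectioned average width as sections shrink to zero:
# mean of w(x) over the passable set {x : w(x) > threshold}
average_width_integral <- function(width_at, axis_length, threshold = 5,
                                   n_grid = 2e5) {
  x <- seq(0, axis_length, length.out = n_grid)
  w <- vapply(x, width_at, numeric(1))
  w <- w[w > threshold]
  if (!length(w)) 0 else mean(w)
}

# Jarvis march (gift wrapping) convex hull perimeter
hull_perimeter_jarvis <- function(x, y) {
  pts <- cbind(x, y)
  n <- nrow(pts)
  cross3 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- which.min(x)
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p) next
      cc <- cross3(pts[p, ], pts[q, ], pts[r, ])
      further <- sum((pts[r, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2)
      if (cc < 0 || (cc == 0 && further)) q <- r
    }
    p <- q
    if (p == start) break
    if (length(hull) > n) stop("jarvis march failed to close")
  }
  hx <- x[hull]
  hy <- y[hull]
  j <- c(seq_along(hull)[-1], 1)
  sum(sqrt((hx[j] - hx)^2 + (hy[j] - hy)^2))
}

rect_hole <- function(id, fa, length, width,
                      params = an_gambiae_params()) {
  hole(id, fa, hole_shape("rectangle", length = length, width = width),
       params = params)
}

circ_hole <- function(id, fa, diameter, params = an_gambiae_params()) {
  hole(id, fa, hole_shape("circle", diameter = diameter), params = params)
}

# the 14-hole mixed-damage net built directly in code (independent of the
# packaged JSON fixture)
mixed_damage_net <- function(params = an_gambiae_params()) {
  c(
    lapply(1:3, function(i) rect_hole(paste0("low", i), "FA2_LOW", 300, 70,
                                      params)),
    lapply(1:3, function(i) rect_hole(paste0("high", i), "FA2_HIGH", 300, 70,
                                      params)),
    lapply(1:5, function(i) rect_hole(paste0("fa3_", i), "FA3", 300, 70,
                                      params)),
    lapply(1:3, function(i) rect_hole(paste0("roof", i), "FA1", 30, 30,
                                      params))
  )
}
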