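#' Hole metrics: the triple the entry-risk model consumes
#'
#' @param perimeter Effective perimeter (mm) used by the encounter model.
#' @param area Opening area (mm^2).
#' @param avg_width Average passable width (mm); 0 means the hole is
#'   impassable.
#' @param raw_perimeter Actual boundary length (mm); differs from
#'   `perimeter` only for irregular outlines where the convex-hull
#'   perimeter is substituted to avoid overestimating encounter
#'   opportunity.
#' @param hull_perimeter Convex-hull perimeter (mm) where computed.
#' @return Object of class `hole_metrics`.
#' @export
hole_metrics <- function(perimeter, area, avg_width,
                         raw_perimeter = perimeter,
                         hull_perimeter = NA_real_) {
  stopifnot(is.numeric(perimeter), is.numeric(area), is.numeric(avg_width))
  if (perimeter < 0 || area < 0 || avg_width < 0) {
    stop("hole metrics must be non-negative", call. = FALSE)
  }
  structure(
    list(perimeter = as.numeric(perimeter), area = as.numeric(area),
         avg_width = as.numeric(avg_width),
         raw_perimeter = as.numeric(raw_perimeter),
         hull_perimeter = as.numeric(hull_perimeter)),
    class = "hole_metrics"
  )
}

#' @export
print.hole_metrics <- function(x, ...) {
  cat(sprintf("Hole metrics: perimeter %.1f mm, area %.0f mm^2, average width %.1f mm%s\n",
              x$perimeter, x$area, x$avg_width,
              if (x$avg_width == 0) " (impassable)" else ""))
  if (!is.na(x$hull_perimeter) && x$hull_perimeter < x$raw_perimeter) {
    cat(sprintf("  (convex-hull effective perimeter %.1f mm replaces raw boundary %.1f mm)\n",
                x$hull_perimeter, x$raw_perimeter))
  }
  invisible(x)
}

check_positive <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("invalid shape: dimension(s) must be positive and finite: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(vals)
}

#' Width profile of a hole along its longest axis
#'
#' Describes the transverse width of a hole as a function of position
#' along its longest axis, for use with the sectioned average-width
#' procedure of [average_width()].
#'
#' @param axis_length Length (mm) of the measurement axis.
#' @param width_at Function mapping a position in `[0, axis_length]` (mm)
#'   to the transverse width (mm) at that position.
#' @param section_length Default section length (mm) for averaging.
#' @return Object of class `width_profile`.
#' @export
width_profile <- function(axis_length, width_at, section_length = 10) {
  check_positive(axis_length = axis_length, section_length = section_length)
  stopifnot(is.function(width_at))
  structure(list(axis_length = axis_length, width_at = width_at,
                 section_length = section_length),
            class = "width_profile")
}

#' Average passable width by midpoint sectioning
#'
#' The field procedure for irregular and tapering holes: partition the
#' hole's longest axis into consecutive sections (1 cm by default, with a
#' final partial section kept), measure the transverse width at each
#' section midpoint, and average the widths of the sections that are wider
#' than the impassability threshold. Sections at or below the threshold
#' are excluded because mosquitoes essentially never pass gaps of half a
#' centimetre or less; if no section qualifies the hole is impassable and
#' the average width is 0.
#'
#' The threshold comparison uses the unrounded midpoint width and is
#' strict (`> threshold`); rounding to the nearest millimetre is a
#' display-time operation only.
#'
#' @param profile A [width_profile()].
#' @param threshold Impassability threshold (mm), default 5.
#' @param section_length Section length (mm); defaults to the profile's.
#' @return Average passable width in mm (0 if impassable).
#' @export
#' @examples
#' # tapering triangular hole, apex at 0: width grows linearly to 80 mm
#' p <- width_profile(210, function(x) 80 * x / 210)
#' average_width(p)  # ~41.9, rounds to 42
average_width <- function(profile, threshold = 5, section_length = NULL) {
  stopifnot(inherits(profile, "width_profile"), threshold >= 0)
  sl <- section_length %||% profile$section_length
  check_positive(section_length = sl)
  n <- ceiling(profile$axis_length / sl - 1e-9)
  if (n < 1) return(0)
  starts <- (seq_len(n) - 1) * sl
  ends <- pmin(starts + sl, profile$axis_length)
  mids <- (starts + ends) / 2
  w <- vapply(mids, profile$width_at, numeric(1))
  if (any(w < 0)) stop("width profile returned a negative width", call. = FALSE)
  w <- w[w > threshold]
  if (!length(w)) 0 else mean(w)
}

ellipse_width_profile <- function(major, minor, section_length = 10) {
  width_profile(major, function(x) {
    minor * sqrt(max(0, 1 - ((2 * x - major) / major)^2))
  }, section_length)
}

#' Metrics for a rectangular hole
#'
#' @param length,width Side lengths in mm, `width <= length`.
#' @param impassable_width Impassability threshold (mm).
#' @return A [hole_metrics()] object.
#' @export
#' @examples
#' rectangle_metrics(300, 70)
rectangle_metrics <- function(length, width, impassable_width = 5) {
  check_positive(length = length, width = width)
  if (width > length) {
    stop("invalid shape: rectangle width must not exceed length", call. = FALSE)
  }
  hole_metrics(
    perimeter = 2 * (length + width),
    area = length * width,
    avg_width = if (width > impassable_width) width else 0
  )
}

#' Metrics for a circular hole
#'
#' The diameter serves as the hole's width.
#'
#' @param diameter Diameter in mm.
#' @inheritParams rectangle_metrics
#' @return A [hole_metrics()] object.
#' @export
#' @examples
#' circle_metrics(25)
circle_metrics <- function(diameter, impassable_width = 5) {
  check_positive(diameter = diameter)
  hole_metrics(
    perimeter = pi * diameter,
    area = pi * diameter^2 / 4,
    avg_width = if (diameter > impassable_width) diameter else 0
  )
}

#' Metrics for an elliptical hole
#'
#' Area is `pi * a * b` and perimeter `2 * pi * sqrt((a^2 + b^2) / 2)`
#' with `a`, `b` the semi-axes; the perimeter approximation is accurate to
#' within about 5\% while the major axis is at most three times the minor
#' axis. For much narrower ellipses the closed form overestimates; with
#' `narrow_fallback = TRUE` the perimeter of an ellipse with
#' `major > 3 * minor` is instead estimated as twice the major axis (the
#' default keeps the closed form for continuity). Average width comes from
#' the sectioned-midpoint procedure along the major axis.
#'
#' @param major_axis,minor_axis Full axis lengths in mm,
#'   `minor_axis <= major_axis`.
#' @param section_length Section length (mm) for the average width.
#' @param narrow_fallback Use the doubled-length perimeter estimate for
#'   very narrow ellipses (aspect ratio > 3).
#' @inheritParams rectangle_metrics
#' @return A [hole_metrics()] object.
#' @export
#' @examples
#' ellipse_metrics(120, 50)  # perimeter ~289 mm, area ~4712 mm^2
#' ellipse_metrics(120, 8)   # average width ~7 mm
#' ellipse_metrics(120, 5)   # impassable: average width 0
ellipse_metrics <- function(major_axis, minor_axis, impassable_width = 5,
                            section_length = 10, narrow_fallback = FALSE) {
  check_positive(major_axis = major_axis, minor_axis = minor_axis)
  if (minor_axis > major_axis) {
    stop("invalid shape: ellipse minor axis must not exceed major axis",
         call. = FALSE)
  }
  a <- major_axis / 2
  b <- minor_axis / 2
  perim <- 2 * pi * sqrt((a^2 + b^2) / 2)
  if (narrow_fallback && major_axis > 3 * minor_axis) perim <- 2 * major_axis
  hole_metrics(
    perimeter = perim,
    area = pi * a * b,
    avg_width = average_width(
      ellipse_width_profile(major_axis, minor_axis, section_length),
      threshold = impassable_width
    )
  )
}

#' Metrics for an isosceles triangular hole
#'
#' The triangle has the given `base` and a perpendicular `length` from
#' base to apex. Its width profile is linear, `w(x) = base * x / length`
#' with `x` measured from the apex, so the average width is taken over
#' 1 cm midpoint sections of that taper.
#'
#' @param base Base of the triangle (mm).
#' @param length Perpendicular height, apex to base (mm).
#' @inheritParams ellipse_metrics
#' @return A [hole_metrics()] object.
#' @export
#' @examples
#' triangle_metrics(80, 210)  # average width ~42 mm
triangle_metrics <- function(base, length, impassable_width = 5,
                             section_length = 10) {
  check_positive(base = base, length = length)
  slant <- sqrt(length^2 + (base / 2)^2)
  hole_metrics(
    perimeter = base + 2 * slant,
    area = base * length / 2,
    avg_width = average_width(
      width_profile(length, function(x) base * x / length, section_length),
      threshold = impassable_width
    )
  )
}

#' Polygon outline of an irregular hole
#'
#' @param x,y Vertex coordinates in mm, in boundary order (the closing
#'   edge back to the first vertex is implicit). Alternatively `x` may be
#'   a two-column matrix.
#' @return Object of class `polygon_outline`.
#' @export
polygon_outline <- function(x, y = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    stopifnot(ncol(x) == 2)
    y <- x[, 2]
    x <- x[, 1]
  }
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  if (length(x) >= 2 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]  # drop duplicated closing vertex
    y <- y[-length(y)]
  }
  if (length(x) < 3) {
    stop("invalid shape: polygon needs at least 3 vertices", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("invalid shape: non-finite polygon vertex", call. = FALSE)
  }
  out <- structure(list(x = as.numeric(x), y = as.numeric(y)),
                   class = "polygon_outline")
  if (polygon_self_intersects(out)) {
    stop("invalid shape: polygon outline is self-intersecting", call. = FALSE)
  }
  if (abs(shoelace_area(out$x, out$y)) < 1e-9) {
    stop("invalid shape: polygon has (near-)zero area", call. = FALSE)
  }
  out
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# orientation test and proper-intersection check for segment pairs
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(outline) {
  x <- outline$x; y <- outline$y
  n <- length(x)
  nxt <- c(seq_len(n)[-1], 1)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      # skip adjacent edges (shared vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_cross(c(x[i], y[i]), c(x[nxt[i]], y[nxt[i]]),
                         c(x[j], y[j]), c(x[nxt[j]], y[nxt[j]]))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

boundary_length <- function(x, y) {
  n <- length(x)
  j <- c(seq_len(n)[-1], 1)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

#' Perimeter of the convex hull of a polygon outline
#'
#' The convex hull bounds the hole and its perimeter never exceeds the raw
#' boundary length of a (simple) outline; it is the "effective perimeter"
#' used for complex hole shapes whose true boundary would overstate
#' encounter opportunity.
#'
#' @param outline A [polygon_outline()], a two-column matrix, or a bare
#'   point set as `list(x =, y =)`. Unordered point clouds are accepted:
#'   the hull does not depend on boundary order.
#' @return Hull perimeter in mm.
#' @export
convex_hull_perimeter <- function(outline) {
  if (inherits(outline, "polygon_outline") ||
      (is.list(outline) && !is.null(outline$x))) {
    x <- outline$x
    y <- outline$y
  } else {
    outline <- as.matrix(outline)
    stopifnot(ncol(outline) == 2)
    x <- outline[, 1]
    y <- outline[, 2]
  }
  if (length(x) < 3) {
    stop("invalid shape: need at least 3 vertices", call. = FALSE)
  }
  h <- chull(x, y)
  if (length(h) < 3) {
    stop("invalid shape: vertices are collinear", call. = FALSE)
  }
  boundary_length(x[h], y[h])
}

# width of the polygon cross-section at abscissa x0: total measure of the
# intersection of the vertical line x = x0 with the polygon interior,
# by even-odd edge crossings (half-open convention per edge)
polygon_section_width <- function(x, y, x0) {
  n <- length(x)
  j <- c(seq_len(n)[-1], 1)
  ys <- numeric(0)
  for (i in seq_len(n)) {
    x1 <- x[i]; x2 <- x[j[i]]
    if (x1 == x2) next
    lo <- min(x1, x2); hi <- max(x1, x2)
    if (x0 >= lo && x0 < hi) {
      t <- (x0 - x1) / (x2 - x1)
      ys <- c(ys, y[i] + t * (y[j[i]] - y[i]))
    }
  }
  if (length(ys) < 2) return(0)
  ys <- sort(ys)
  if (length(ys) %% 2 == 1) ys <- ys[-length(ys)]  # numeric vertex grazing
  sum(ys[seq(2, length(ys), by = 2)] - ys[seq(1, length(ys), by = 2)])
}

# rotate outline so its longest vertex-to-vertex extent lies along +x
polygon_principal_axis <- function(outline) {
  x <- outline$x; y <- outline$y
  n <- length(x)
  best <- c(1, 2); bestd <- -1
  for (i in seq_len(n - 1)) {
    d2 <- (x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2
    k <- which.max(d2)
    if (d2[k] > bestd) {
      bestd <- d2[k]
      best <- c(i, i + k)
    }
  }
  theta <- atan2(y[best[2]] - y[best[1]], x[best[2]] - x[best[1]])
  xr <- x * cos(-theta) - y * sin(-theta)
  yr <- x * sin(-theta) + y * cos(-theta)
  list(x = xr - min(xr), y = yr, axis_length = max(xr) - min(xr))
}

#' Width profile of a polygon outline along its longest axis
#'
#' The measurement axis is the direction of the outline's maximal
#' vertex-to-vertex extent; widths are the total cross-section of the
#' polygon measured perpendicular to that axis.
#'
#' @param outline A [polygon_outline()].
#' @param section_length Section length (mm).
#' @return A [width_profile()].
#' @export
polygon_width_profile <- function(outline, section_length = 10) {
  if (!inherits(outline, "polygon_outline")) outline <- polygon_outline(outline)
  r <- polygon_principal_axis(outline)
  width_profile(r$axis_length,
                function(p) polygon_section_width(r$x, r$y, p),
                section_length)
}

#' Metrics for an irregular hole given its polygon outline
#'
#' Area comes from the shoelace formula. The effective perimeter is the
#' smaller of the raw boundary length and the convex-hull perimeter, an
#' anti-overestimation device for deeply indented outlines; both values
#' are retained in the result. Average width uses midpoint sectioning
#' along the outline's longest-extent axis.
#'
#' @param outline A [polygon_outline()], or vertex coordinates it accepts.
#' @inheritParams ellipse_metrics
#' @return A [hole_metrics()] object.
#' @export
#' @examples
#' sq <- polygon_outline(c(0, 100, 100, 0), c(0, 0, 100, 100))
#' polygon_metrics(sq)  # perimeter 400, area 10000, width 100
polygon_metrics <- function(outline, impassable_width = 5,
                            section_length = 10) {
  if (!inherits(outline, "polygon_outline")) outline <- polygon_outline(outline)
  raw <- boundary_length(outline$x, outline$y)
  hull <- convex_hull_perimeter(outline)
  hole_metrics(
    perimeter = min(raw, hull),
    area = abs(shoelace_area(outline$x, outline$y)),
    avg_width = average_width(
      polygon_width_profile(outline, section_length),
      threshold = impassable_width
    ),
    raw_perimeter = raw,
    hull_perimeter = hull
  )
}
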