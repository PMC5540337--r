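#' Describe a hole's shape
#'
#' A tagged description of hole geometry, convertible to [hole_metrics()]
#' with [shape_metrics()]. Supported variants and their dimension fields
#' (all mm):
#' \describe{
#'   \item{rectangle}{`length`, `width` (`width <= length`)}
#'   \item{circle}{`diameter`}
#'   \item{ellipse}{`major_axis`, `minor_axis`}
#'   \item{triangle}{isosceles; `base`, `length` (apex-to-base height)}
#'   \item{polygon}{`outline`, a [polygon_outline()]}
#'   \item{measured}{pre-measured `perimeter` (mm), `area` (mm^2),
#'     `avg_width` (mm) for holes measured in the field}
#' }
#'
#' @param type Variant tag.
#' @param ... Dimension fields for the variant.
#' @return Object of class `hole_shape`.
#' @export
#' @examples
#' hole_shape("rectangle", length = 300, width = 70)
#' hole_shape("measured", perimeter = 276, area = 1378, avg_width = 12)
hole_shape <- function(type = c("rectangle", "circle", "ellipse", "triangle",
                                "polygon", "measured"),
                       ...) {
  type <- match.arg(type)
  fields <- list(...)
  required <- switch(type,
    rectangle = c("length", "width"),
    circle = "diameter",
    ellipse = c("major_axis", "minor_axis"),
    triangle = c("base", "length"),
    polygon = "outline",
    measured = c("perimeter", "area", "avg_width")
  )
  missing <- setdiff(required, names(fields))
  if (length(missing)) {
    stop("invalid shape: ", type, " needs field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fields <- fields[required]
  if (type == "polygon" && !inherits(fields$outline, "polygon_outline")) {
    fields$outline <- polygon_outline(fields$outline)
  }
  structure(c(list(type = type), fields), class = "hole_shape")
}

#' Compute hole metrics from a shape description
#'
#' @param shape A [hole_shape()].
#' @param params A [species_params()] object supplying the impassability
#'   threshold and section length.
#' @return A [hole_metrics()] object. Pre-measured holes pass their values
#'   through, except that an average width at or below the impassability
#'   threshold is set to 0.
#' @export
shape_metrics <- function(shape, params = an_gambiae_params()) {
  stopifnot(inherits(shape, "hole_shape"))
  thr <- params$impassable_width
  sl <- params$section_length
  switch(shape$type,
    rectangle = rectangle_metrics(shape$length, shape$width, thr),
    circle = circle_metrics(shape$diameter, thr),
    ellipse = ellipse_metrics(shape$major_axis, shape$minor_axis, thr, sl),
    triangle = triangle_metrics(shape$base, shape$length, thr, sl),
    polygon = polygon_metrics(shape$outline, thr, sl),
    measured = {
      check_positive(perimeter = shape$perimeter, area = shape$area)
      if (shape$avg_width < 0) {
        stop("invalid shape: negative measured width", call. = FALSE)
      }
      hole_metrics(shape$perimeter, shape$area,
                   if (shape$avg_width > thr) shape$avg_width else 0)
    }
  )
}

#' Longest extent of a hole shape
#'
#' The single "diameter" a sizing template would assign to the hole: its
#' longest straight-line extent. Used when scoring non-round holes on the
#' pHI scale, mirroring template-based field practice. For pre-measured
#' holes with no recorded outline the extent is approximated by half the
#' perimeter (exact in the elongated-slit limit).
#'
#' @param shape A [hole_shape()].
#' @return Longest extent in mm.
#' @export
shape_longest_extent <- function(shape) {
  stopifnot(inherits(shape, "hole_shape"))
  switch(shape$type,
    rectangle = sqrt(shape$length^2 + shape$width^2),
    circle = shape$diameter,
    ellipse = shape$major_axis,
    triangle = max(shape$base, sqrt(shape$length^2 + (shape$base / 2)^2)),
    polygon = polygon_principal_axis(shape$outline)$axis_length,
    measured = shape$perimeter / 2
  )
}

# largest length-or-width style dimension, for the 300 mm entry cap
shape_max_dimension <- function(shape) {
  switch(shape$type,
    rectangle = shape$length,
    circle = shape$diameter,
    ellipse = shape$major_axis,
    triangle = max(shape$base, shape$length),
    polygon = polygon_principal_axis(shape$outline)$axis_length,
    measured = NA_real_
  )
}

#' @export
print.hole_shape <- function(x, ...) {
  dims <- x[setdiff(names(x), c("type", "outline"))]
  cat("Hole shape:", x$type,
      if (length(dims)) paste0("(", paste(sprintf("%s=%g", names(dims),
                                                  unlist(dims)),
                                          collapse = ", "), ")"),
      if (x$type == "polygon") sprintf("(%d vertices)", length(x$outline$x)),
      "\n")
  invisible(x)
}
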