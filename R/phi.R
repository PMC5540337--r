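#' WHOPES pHI hole size classes
#'
#' The proportionate hole index assigns each hole over half a centimetre
#' in diameter to one of four size classes -- smaller than a thumb
#' (0.5--2 cm), thumb to fist (2--10 cm), fist to head (10--25 cm), larger
#' than a head (over 25 cm) -- and weights the class counts by
#' area-derived factors. The thresholds and classes are standard WHOPES
#' practice; the default weights (1, 23, 196, 578) come from WHO guidance
#' and are configuration values here, replaceable per programme.
#'
#' Boundary diameters are assigned to the higher class (a 2 cm hole is
#' thumb-to-fist).
#'
#' @param weights Numeric vector of four per-class weights.
#' @return Data frame with columns `class`, `min_cm`, `max_cm`, `weight`.
#' @export
phi_size_classes <- function(weights = c(1, 23, 196, 578)) {
  stopifnot(length(weights) == 4, all(weights >= 0))
  data.frame(
    class = c("smaller_than_thumb", "thumb_to_fist", "fist_to_head",
              "larger_than_head"),
    min_cm = c(0.5, 2, 10, 25),
    max_cm = c(2, 10, 25, Inf),
    weight = weights,
    stringsAsFactors = FALSE
  )
}

#' Assign a hole diameter to a pHI size class
#'
#' @param diameter_cm Hole diameter(s) in cm, as a sizing template would
#'   record them.
#' @param classes Size-class table from [phi_size_classes()].
#' @return Character vector of class names, `NA` for excluded holes
#'   (diameter under 0.5 cm).
#' @export
#' @examples
#' classify_hole_size(c(0.4, 1, 2, 12.5, 30))
classify_hole_size <- function(diameter_cm, classes = phi_size_classes()) {
  if (any(diameter_cm < 0)) stop("diameter must be >= 0", call. = FALSE)
  out <- rep(NA_character_, length(diameter_cm))
  for (i in seq_len(nrow(classes))) {
    hit <- diameter_cm >= classes$min_cm[i] & diameter_cm < classes$max_cm[i]
    out[hit] <- classes$class[i]
  }
  # upper boundary of the top class is open-ended; >= handles Inf already
  out
}

#' Proportionate hole index of a net
#'
#' Sums class counts times class weights and categorises the result:
#' below 64 the net is in good condition, 64--642 acceptable (both count
#' as serviceable), above 642 too torn for continued use.
#'
#' Non-round holes are assigned the diameter a sizing template would give
#' them -- their longest extent (see [shape_longest_extent()]) -- which is
#' exactly the circularity assumption the entry-risk model avoids; the
#' two scores are designed to be compared side by side.
#'
#' @param holes List of [hole()] objects, or a numeric vector of template
#'   diameters in cm.
#' @param classes Size-class table from [phi_size_classes()].
#' @return Object of class `phi_result` with `counts`, `index` and
#'   `category`.
#' @export
#' @examples
#' phi_score(c(1, 3, 12, 30))
phi_score <- function(holes, classes = phi_size_classes()) {
  if (is.null(classes$weight)) stop("size classes need weights", call. = FALSE)
  diam_cm <- if (is.numeric(holes)) {
    holes
  } else {
    vapply(holes, function(h) {
      if (is.null(h$shape)) {
        stop("hole ", h$id, " has no shape; pHI needs a template diameter",
             call. = FALSE)
      }
      shape_longest_extent(h$shape) / 10
    }, numeric(1))
  }
  cls <- classify_hole_size(diam_cm, classes)
  counts <- vapply(classes$class, function(k) sum(cls == k, na.rm = TRUE),
                   integer(1))
  index <- sum(counts * classes$weight)
  category <- if (index < 64) "good"
              else if (index <= 642) "acceptable"
              else "too_torn"
  structure(list(counts = counts, excluded = sum(is.na(cls)),
                 index = index, category = category, classes = classes),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat("Proportionate hole index (pHI):", x$index, "->", x$category, "\n")
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-20s x%d (weight %g)\n",
                names(x$counts)[i], x$counts[i], x$classes$weight[i]))
  }
  if (x$excluded) {
    cat("  excluded (under 0.5 cm):", x$excluded, "\n")
  }
  invisible(x)
}
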