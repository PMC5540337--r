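#' Generate a synthetic hole inventory
#'
#' Deterministic (seeded) generator of random hole inventories for
#' testing and simulation. Hole widths are log-uniform between
#' `width_range[1]` and `width_range[2]` mm, so sub-threshold (impassable)
#' holes and large gashes both occur; a fraction of rectangles is drawn
#' longer than the 300 mm entry cap to exercise the splitting rule.
#' Functional areas and shape variants are sampled from the supplied
#' mixes.
#'
#' @param n Number of holes.
#' @param seed Integer seed; identical seeds give identical inventories.
#' @param fa_weights Named sampling weights over [FA_LEVELS].
#' @param shape_mix Named sampling weights over the shape variants.
#' @param width_range Width range in mm (log-uniform).
#' @param long_hole_prob Probability that a rectangle's length exceeds
#'   the 300 mm cap (drawn up to 900 mm).
#' @return List of inventory records (JSON style, see
#'   `?"inventory-format"`), suitable for [holes_from_records()] or
#'   [write_inventory()].
#' @export
#' @examples
#' inv <- generate_inventory(10, seed = 1)
#' length(holes_from_records(inv))
generate_inventory <- function(n = 20, seed = 1,
                               fa_weights = c(FA1 = 0.15, FA2_LOW = 0.35,
                                              FA2_HIGH = 0.20, FA3 = 0.30),
                               shape_mix = c(rectangle = 0.40, circle = 0.20,
                                             ellipse = 0.15, triangle = 0.10,
                                             polygon = 0.10, measured = 0.05),
                               width_range = c(1, 300),
                               long_hole_prob = 0.10) {
  stopifnot(n >= 0, all(fa_weights >= 0), all(shape_mix >= 0),
            width_range[1] > 0, width_range[2] >= width_range[1])
  set.seed(seed)
  fas <- sample(names(fa_weights), n, replace = TRUE, prob = fa_weights)
  shapes <- sample(names(shape_mix), n, replace = TRUE, prob = shape_mix)
  rlogu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    w <- rlogu(width_range[1], width_range[2])
    rec <- list(id = sprintf("gen%03d", i), fa = fas[i], shape = shapes[i])
    rec <- switch(shapes[i],
      rectangle = {
        len <- if (runif(1) < long_hole_prob) runif(1, 300, 900)
               else runif(1, w, 300)
        c(rec, list(length_mm = max(len, w), width_mm = min(len, w)))
      },
      circle = c(rec, list(diameter_mm = min(w, 300))),
      ellipse = {
        minor <- min(w, 300)
        c(rec, list(major_mm = runif(1, minor, 300), minor_mm = minor))
      },
      triangle = c(rec, list(base_mm = min(w, 300),
                             length_mm = runif(1, 10, 300))),
      polygon = {
        out <- generate_polygon_hole(
          seed = NULL,  # continue the current RNG stream
          target_area = pi * min(w, 100)^2 / 4,
          elongation = rlogu(1, 2)
        )
        c(rec, list(vertices = lapply(seq_along(out$x),
                                      function(k) c(out$x[k], out$y[k]))))
      },
      measured = {
        m <- rectangle_metrics(max(w, 300 * runif(1)), min(w, 300))
        rec$shape <- "measured"
        c(rec, list(perimeter_mm = m$perimeter, area_mm2 = m$area,
                    avg_width_mm = if (m$avg_width > 0) m$avg_width else w))
      }
    )
    records[[i]] <- rec
  }
  records
}

#' Generate a random simple polygon outline
#'
#' Builds a star-shaped (hence simple by construction) polygon around its
#' centroid: vertices at sorted angles with smoothly perturbed radii,
#' stretched along x by the elongation factor and rescaled so the
#' shoelace area matches `target_area` exactly. Useful for exercising the
#' convex-hull, sectioning and width-profile machinery on irregular
#' outlines.
#'
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @param target_area Target area in mm^2.
#' @param elongation Axis ratio of the underlying ellipse (1 = isotropic).
#' @param n_vertices Number of vertices.
#' @param roughness Relative amplitude of the radial perturbation.
#' @return A [polygon_outline()].
#' @export
#' @examples
#' out <- generate_polygon_hole(seed = 7, target_area = 2000, elongation = 3)
#' polygon_metrics(out)
generate_polygon_hole <- function(seed = NULL, target_area,
                                  elongation = 1, n_vertices = 24,
                                  roughness = 0.15) {
  stopifnot(target_area > 0, elongation >= 1, n_vertices >= 3,
            roughness >= 0, roughness < 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- sort(runif(n_vertices, 0, 2 * pi))
  bump <- runif(n_vertices, -1, 1)
  # circular 3-point smoothing keeps radii positive and outlines tame
  smooth <- (bump + bump[c(n_vertices, 1:(n_vertices - 1))] +
             bump[c(2:n_vertices, 1)]) / 3
  r <- 1 + roughness * smooth
  x <- r * cos(theta) * sqrt(elongation)
  y <- r * sin(theta) / sqrt(elongation)
  a0 <- abs(shoelace_area(x, y))
  s <- sqrt(target_area / a0)
  polygon_outline(x * s, y * s)
}

#' Simulate passage-trial observations from the model
#'
#' Generates synthetic encounter/passage count rows whose true passage
#' probabilities follow the packaged log-width model, with binomial
#' sampling noise. Used to verify that [fit_passage_model()] recovers the
#' coefficients it should.
#'
#' @param widths Hole widths (mm), one row per width.
#' @param location `"roof"` or `"side"`.
#' @param encounters Encounters per row (recycled).
#' @param params A [species_params()] object supplying the true
#'   coefficients.
#' @param seed Integer seed, or `NULL`.
#' @param exact If TRUE, passage counts are the exact expectations
#'   (rounded binomial-free limit of infinitely many encounters).
#' @return A [passage_observations()] data frame.
#' @export
simulate_passage_observations <- function(widths,
                                          location = c("side", "roof"),
                                          encounters = 100,
                                          params = an_gambiae_params(),
                                          seed = NULL, exact = FALSE) {
  location <- match.arg(location)
  if (!is.null(seed)) set.seed(seed)
  n <- length(widths)
  enc <- rep_len(encounters, n)
  p <- passage_probability(widths, location, params)
  pass <- if (exact) p * enc else rbinom(n, enc, p)
  passage_observations(data.frame(
    width_mm = widths, length_mm = NA_real_, location = location,
    shape = "rectangle", encounters = enc, passages = pass,
    stringsAsFactors = FALSE
  ))
}
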