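#' A hole on a net, located and measured
#'
#' Binds an identifier, a functional-area location and geometry into the
#' unit the risk model scores. Metrics are derived from `shape` when not
#' supplied directly.
#'
#' @param id Hole identifier (coerced to character).
#' @param fa Functional area (see [FA_LEVELS]); `"roof"` is accepted and
#'   mapped to FA1.
#' @param shape A [hole_shape()], or `NULL` if `metrics` are supplied.
#' @param metrics A [hole_metrics()], or `NULL` to derive from `shape`.
#' @param params Species parameters used when deriving metrics.
#' @return Object of class `net_hole`.
#' @export
#' @examples
#' hole("h1", "FA2_LOW", hole_shape("rectangle", length = 300, width = 70))
hole <- function(id, fa, shape = NULL, metrics = NULL,
                 params = an_gambiae_params()) {
  if (identical(tolower(fa), "roof")) fa <- "FA1"
  fa <- check_fa(fa)
  if (is.null(metrics)) {
    if (is.null(shape)) {
      stop("hole needs a shape or pre-computed metrics", call. = FALSE)
    }
    metrics <- shape_metrics(shape, params)
  }
  stopifnot(inherits(metrics, "hole_metrics"))
  structure(list(id = as.character(id), fa = fa, shape = shape,
                 metrics = metrics),
            class = "net_hole")
}

#' @export
print.net_hole <- function(x, ...) {
  cat(sprintf("Hole %s in %s: P %.1f mm, A %.0f mm^2, w %.1f mm\n",
              x$id, x$fa, x$metrics$perimeter, x$metrics$area,
              x$metrics$avg_width))
  invisible(x)
}

#' Hourly appearance rate for a functional area
#'
#' Expected appearances per hour of one attacking mosquito within a
#' 30 cm x 30 cm sampling area of the given functional area.
#'
#' @param fa Functional-area code.
#' @param params A [species_params()] object.
#' @return Appearances per mosquito-hour (vectorised over `fa`).
#' @export
#' @examples
#' appearance_rate("FA1")  # 72.3
appearance_rate <- function(fa, params = an_gambiae_params()) {
  fa <- check_fa(fa)
  unname(params$appearances_per_mosquito_hour[fa])
}

#' Per-appearance probability of encountering a hole
#'
#' Linear in the hole's perimeter (mm) plus area (mm^2) -- the perimeter
#' term capturing bouncing flight along the net surface, the area term
#' visiting flight onto the net plane -- clamped to `[0, 1]`.
#'
#' @param metrics A [hole_metrics()] object, or a perimeter in mm.
#' @param area Area in mm^2 (when `metrics` is a bare perimeter).
#' @param params A [species_params()] object.
#' @return Encounter probability per appearance.
#' @export
#' @examples
#' encounter_probability(1200, 90000)  # 30 cm square hole: ~0.82
encounter_probability <- function(metrics, area = NULL,
                                  params = an_gambiae_params()) {
  if (inherits(metrics, "hole_metrics")) {
    p <- metrics$perimeter
    a <- metrics$area
  } else {
    p <- metrics
    a <- area
    if (is.null(a)) stop("supply area with a bare perimeter", call. = FALSE)
  }
  if (any(p < 0) || any(a < 0)) {
    stop("perimeter and area must be non-negative", call. = FALSE)
  }
  pmin(pmax(params$encounter_coefficient * (p + a), 0), 1)
}

#' Per-encounter probability of passing through a hole
#'
#' Log-linear in the hole's average width: `slope * ln(width) + intercept`
#' with orientation-specific coefficients (roof holes are more passable
#' than side holes of the same width), clamped to `[0, 1]`. Widths at or
#' below the impassability threshold have probability 0 -- consistent
#' with the fits themselves, whose x-intercepts sit at about 5 mm.
#'
#' @param avg_width Average passable width in mm (vectorised).
#' @param orientation `"roof"` or `"side"`.
#' @param params A [species_params()] object.
#' @return Passage probability per encounter.
#' @export
#' @examples
#' passage_probability(30, "roof")  # 0.34*ln(30) - 0.55 = 0.606
#' passage_probability(5, "side")   # impassable: 0
passage_probability <- function(avg_width, orientation = c("roof", "side"),
                                params = an_gambiae_params()) {
  orientation <- match.arg(orientation)
  if (any(avg_width < 0)) stop("avg_width must be >= 0", call. = FALSE)
  cf <- if (orientation == "roof") params$passage_roof else params$passage_side
  p <- ifelse(avg_width <= params$impassable_width, 0,
              cf[["slope"]] * log(avg_width) + cf[["intercept"]])
  pmin(pmax(p, 0), 1)
}

#' Hourly entry rate through one hole
#'
#' The core model: entries/h = appearance rate of the hole's functional
#' area x per-appearance encounter probability x per-encounter passage
#' probability, under the one-mosquito-constantly-present convention.
#'
#' @param hole A [hole()].
#' @param params A [species_params()] object.
#' @return Object of class `hole_risk`: a list with `appearances_per_hour`,
#'   `encounter_prob`, `encounters_per_hour`, `passage_prob` and
#'   `entries_per_hour`.
#' @export
#' @examples
#' h <- hole("roof1", "FA1", hole_shape("rectangle", length = 30, width = 30))
#' hole_entry_rate(h)$entries_per_hour  # ~0.402
hole_entry_rate <- function(hole, params = an_gambiae_params()) {
  stopifnot(inherits(hole, "net_hole"))
  if (is.null(hole$metrics)) stop("hole has no metrics", call. = FALSE)
  app <- appearance_rate(hole$fa, params)
  enc <- encounter_probability(hole$metrics, params = params)
  pas <- passage_probability(hole$metrics$avg_width,
                             fa_orientation(hole$fa), params)
  structure(list(
    id = hole$id, fa = hole$fa,
    appearances_per_hour = app,
    encounter_prob = enc,
    encounters_per_hour = app * enc,
    passage_prob = pas,
    entries_per_hour = app * enc * pas
  ), class = "hole_risk")
}

#' Assess a whole net
#'
#' Scores every hole, sums entry rates by functional area and over the
#' net, and reports each area's share of the total plus the roof/side
#' split. Rates are per hour for one constantly present mosquito; use
#' [scale_risk()] for other exposures.
#'
#' @param holes List of [hole()] objects (possibly empty).
#' @param params A [species_params()] object.
#' @return Object of class `net_assessment` with elements `holes` (per-hole
#'   data frame), `by_fa` (per-area subtotals and shares),
#'   `total_entries_per_hour`, `share_roof`, `share_side`, `n_mosquitoes`,
#'   `hours` and `params`.
#' @export
#' @examples
#' net <- list(
#'   hole("r1", "FA1", hole_shape("rectangle", length = 30, width = 30)),
#'   hole("s1", "FA2_LOW", hole_shape("rectangle", length = 300, width = 70))
#' )
#' assess_net(net)
assess_net <- function(holes, params = an_gambiae_params()) {
  stopifnot(is.list(holes))
  risks <- lapply(holes, hole_entry_rate, params = params)
  per_hole <- data.frame(
    id = vapply(risks, `[[`, character(1), "id"),
    fa = vapply(risks, `[[`, character(1), "fa"),
    perimeter_mm = vapply(holes, function(h) h$metrics$perimeter, numeric(1)),
    area_mm2 = vapply(holes, function(h) h$metrics$area, numeric(1)),
    avg_width_mm = vapply(holes, function(h) h$metrics$avg_width, numeric(1)),
    appearances_per_hour = vapply(risks, `[[`, numeric(1),
                                  "appearances_per_hour"),
    encounter_prob = vapply(risks, `[[`, numeric(1), "encounter_prob"),
    passage_prob = vapply(risks, `[[`, numeric(1), "passage_prob"),
    entries_per_hour = vapply(risks, `[[`, numeric(1), "entries_per_hour"),
    stringsAsFactors = FALSE
  )
  fa_tot <- vapply(FA_LEVELS, function(f) {
    sum(per_hole$entries_per_hour[per_hole$fa == f])
  }, numeric(1))
  total <- sum(fa_tot)
  by_fa <- data.frame(
    fa = FA_LEVELS,
    n_holes = vapply(FA_LEVELS, function(f) sum(per_hole$fa == f), integer(1)),
    entries_per_hour = unname(fa_tot),
    share = if (total > 0) unname(fa_tot) / total else rep(NA_real_, 4),
    stringsAsFactors = FALSE
  )
  roof <- fa_tot[["FA1"]]
  structure(list(
    holes = per_hole,
    by_fa = by_fa,
    total_entries_per_hour = total,
    share_roof = if (total > 0) roof / total else NA_real_,
    share_side = if (total > 0) (total - roof) / total else NA_real_,
    n_mosquitoes = 1,
    hours = 1,
    total_entries = total,
    params = params
  ), class = "net_assessment")
}

#' Scale an assessment to a different exposure
#'
#' The one-mosquito, one-hour convention scales linearly: total expected
#' entries for `n_mosquitoes` attacking over `hours` is the hourly rate
#' times both factors. Per-hole and per-area *rates* are left as is; the
#' scaled expectation is stored in `total_entries`.
#'
#' @param assessment A [assess_net()] result.
#' @param n_mosquitoes Number of mosquitoes attacking the net.
#' @param hours Exposure duration in hours.
#' @return The assessment with `n_mosquitoes`, `hours` and
#'   `total_entries` updated.
#' @export
#' @examples
#' a <- assess_net(list(hole("r1", "FA1",
#'                           hole_shape("circle", diameter = 25))))
#' scale_risk(a, n_mosquitoes = 2, hours = 3)$total_entries
scale_risk <- function(assessment, n_mosquitoes = 1, hours = 1) {
  stopifnot(inherits(assessment, "net_assessment"))
  if (n_mosquitoes < 0 || hours < 0) {
    stop("n_mosquitoes and hours must be >= 0", call. = FALSE)
  }
  assessment$n_mosquitoes <- n_mosquitoes
  assessment$hours <- hours
  assessment$total_entries <-
    assessment$total_entries_per_hour * n_mosquitoes * hours
  assessment
}

#' Split an over-long hole into model-entry-sized pieces
#'
#' All model rates are calibrated on 30 cm x 30 cm sampling units, so no
#' single entry may have length or width above `max_dim` (300 mm by
#' default). A rectangular hole longer than that is divided into
#' `ceiling(length / max_dim)` equal-length rectangles of the same width,
#' each scored with its own full perimeter and area (total area is
#' preserved; the shared cut edges are intentionally counted in both
#' pieces, matching the hole-per-line treatment of the original tool).
#' Non-rectangular shapes exceeding the cap cannot be split automatically
#' and must be apportioned by hand.
#'
#' @param hole A [hole()].
#' @param max_dim Maximum entry dimension in mm.
#' @param params Species parameters (used to re-derive piece metrics).
#' @return List of [hole()] objects (length 1 if no split was needed).
#' @export
#' @examples
#' h <- hole("long", "FA3", hole_shape("rectangle", length = 400, width = 50))
#' length(split_long_hole(h))  # 2
split_long_hole <- function(hole, max_dim = params$max_entry_dimension,
                            params = an_gambiae_params()) {
  stopifnot(inherits(hole, "net_hole"))
  shape <- hole$shape
  if (is.null(shape) || is.na(shape_max_dimension(shape)) ||
      shape_max_dimension(shape) <= max_dim) {
    return(list(hole))
  }
  if (shape$type != "rectangle") {
    stop("hole ", hole$id, " exceeds ", max_dim,
         " mm and is not rectangular; apportion it manually into ",
         "sub-holes of at most ", max_dim, " mm", call. = FALSE)
  }
  if (shape$width > max_dim) {
    stop("hole ", hole$id, " is wider than ", max_dim,
         " mm; apportion it manually", call. = FALSE)
  }
  k <- ceiling(shape$length / max_dim)
  piece <- shape$length / k
  lapply(seq_len(k), function(i) {
    hole(paste0(hole$id, ".", i), hole$fa,
         hole_shape("rectangle",
                    length = max(piece, shape$width),
                    width = min(piece, shape$width)),
         params = params)
  })
}

#' Normalize a list of holes for assessment
#'
#' Applies the entry-size rule: every hole whose longest dimension exceeds
#' the model cap is split (rectangles) or rejected with instructions
#' (other shapes).
#'
#' @param holes List of [hole()] objects.
#' @param params A [species_params()] object.
#' @return Flat list of holes, all within the entry cap.
#' @export
normalize_holes <- function(holes, params = an_gambiae_params()) {
  out <- lapply(holes, split_long_hole,
                max_dim = params$max_entry_dimension, params = params)
  out <- unlist(out, recursive = FALSE)
  if (is.null(out)) list() else out
}

circle_entry_rate <- function(diameter, fa, params) {
  h <- hole("equiv", fa, hole_shape("circle", diameter = diameter),
            params = params)
  hole_entry_rate(h, params)$entries_per_hour
}

#' Diameter of a round hole with a given entry risk
#'
#' Solves for the diameter of a circular hole in functional area `fa`
#' whose hourly entry rate equals `target_rate`. The rate is strictly
#' increasing in diameter above the impassability threshold (the
#' encounter term keeps growing even once passage probability clamps at
#' 1), so the root is unique; it is found by bisection to 0.01 mm.
#'
#' @param target_rate Entries per hour to match (> 0).
#' @param fa Functional area of the sought hole.
#' @param params A [species_params()] object.
#' @param upper Search bound on the diameter (mm). Diameters above the
#'   300 mm entry cap are allowed here: the solver answers a "what single
#'   round opening would be as risky" question, not an inventory entry.
#' @return Diameter in mm.
#' @export
#' @examples
#' ref <- hole_entry_rate(hole("r", "FA1",
#'                             hole_shape("circle", diameter = 25)))
#' equivalent_diameter(ref$entries_per_hour, "FA2_LOW") / 10  # ~6.3 cm
equivalent_diameter <- function(target_rate, fa,
                                params = an_gambiae_params(),
                                upper = 1000) {
  fa <- check_fa(fa)
  if (target_rate <= 0) stop("target_rate must be > 0", call. = FALSE)
  lo <- params$impassable_width * (1 + 1e-9)
  f <- function(d) circle_entry_rate(d, fa, params) - target_rate
  if (f(upper) < 0) {
    stop("no round hole up to ", upper, " mm in ", fa,
         " reaches an entry rate of ", signif(target_rate, 4),
         "/h", call. = FALSE)
  }
  uniroot(f, c(lo, upper), tol = 1e-3)$root
}

#' Apportion a side rectangle across functional-area bands
#'
#' Holes spanning more than one functional area must be entered as per-FA
#' components. This helper cuts a rectangle on the net side at the 300 mm
#' and 600 mm height boundaries, given the height of its bottom edge. The
#' rectangle's `height_extent` is its vertical dimension and `horizontal`
#' its dimension along the net; each fragment becomes its own full
#' rectangle.
#'
#' @param id Base identifier for the fragments.
#' @param horizontal Horizontal dimension (mm).
#' @param height_extent Vertical dimension (mm).
#' @param bottom_height_mm Height of the bottom edge above the net hem (mm).
#' @param params A [species_params()] object.
#' @return List of [hole()] objects, one per band intersected.
#' @export
#' @examples
#' # a 100 mm tall hole sitting across the 300 mm boundary
#' frags <- apportion_side_rectangle("h", 200, 100, 250)
#' vapply(frags, function(h) h$fa, character(1))
apportion_side_rectangle <- function(id, horizontal, height_extent,
                                     bottom_height_mm,
                                     params = an_gambiae_params()) {
  check_positive(horizontal = horizontal, height_extent = height_extent)
  if (bottom_height_mm < 0) stop("bottom_height_mm must be >= 0", call. = FALSE)
  cuts <- c(300, 600)
  lo <- bottom_height_mm
  hi <- bottom_height_mm + height_extent
  edges <- sort(unique(c(lo, cuts[cuts > lo & cuts < hi], hi)))
  out <- vector("list", length(edges) - 1)
  for (i in seq_along(out)) {
    seg <- edges[i + 1] - edges[i]
    out[[i]] <- hole(
      if (length(out) == 1) id else paste0(id, ".", i),
      fa_from_height(edges[i]),
      hole_shape("rectangle",
                 length = max(horizontal, seg),
                 width = min(horizontal, seg)),
      params = params
    )
  }
  out
}
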