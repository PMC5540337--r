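#' Packaged damage scenarios
#'
#' Three illustrative analyses ship with the package:
#' \describe{
#'   \item{`mixed_damage`}{A net damaged the way used nets typically are:
#'     three 300 x 70 mm rectangular slits in each of FA2-low and
#'     FA2-high, five in FA3, and three 30 x 30 mm squares on the roof.
#'     Total risk is about 6.3 mosquitoes/hour, roughly 81\% of it from
#'     the side holes -- yet the three small roof holes alone, barely 1\%
#'     of the hole area, would still admit about 1.2 mosquitoes/hour.
#'     Returns the `net_assessment`.}
#'   \item{`equal_risk`}{Solves for the diameters of single round holes
#'     in FA2-low, FA2-high and FA3 that match the risk of a 2.5 cm round
#'     roof hole (about 6.3, 13.9 and 30.6 cm respectively). Returns a
#'     list with the reference rate, the solved diameters, and the
#'     assessment of the four-hole net.}
#'   \item{`size_class_extremes`}{Models roof entry risk for round and
#'     square holes at the minimum, mid-range and maximum diameter of
#'     each pHI size class, quantifying how much risk variation each
#'     class hides (the smallest class alone spans about a 70-fold
#'     range). The class minimum of 5 mm is impassable, so 6 mm is used
#'     as the smallest passable diameter. Returns a data frame.}
#' }
#'
#' @param name Scenario name.
#' @param params A [species_params()] object.
#' @return See the scenario descriptions.
#' @export
#' @examples
#' scenario("mixed_damage")$total_entries_per_hour  # ~6.3
scenario <- function(name = c("mixed_damage", "equal_risk",
                              "size_class_extremes"),
                     params = an_gambiae_params()) {
  name <- match.arg(name)
  switch(name,
    mixed_damage = assess_net(mixed_damage_holes(params), params),
    equal_risk = equal_risk_scenario(params),
    size_class_extremes = size_class_extremes_scenario(params)
  )
}

mixed_damage_holes <- function(params = an_gambiae_params()) {
  path <- system.file("extdata", "mixed_damage.json", package = "netentry")
  read_inventory(path, params = params)
}

equal_risk_scenario <- function(params = an_gambiae_params(),
                                reference_diameter = 25,
                                reference_fa = "FA1") {
  ref <- hole("ref", reference_fa,
              hole_shape("circle", diameter = reference_diameter),
              params = params)
  target <- hole_entry_rate(ref, params)$entries_per_hour
  others <- setdiff(FA_LEVELS, check_fa(reference_fa))
  diam <- vapply(others, function(fa) {
    equivalent_diameter(target, fa, params)
  }, numeric(1))
  all_fa <- c(check_fa(reference_fa), others)
  all_d <- c(reference_diameter, unname(diam))
  holes <- mapply(function(fa, d) {
    hole(paste0("round_", fa), fa, hole_shape("circle", diameter = d),
         params = params)
  }, all_fa, all_d, SIMPLIFY = FALSE)
  list(
    reference = list(fa = check_fa(reference_fa),
                     diameter_mm = reference_diameter,
                     entries_per_hour = target),
    diameters = data.frame(fa = all_fa, diameter_mm = all_d,
                           diameter_cm = all_d / 10,
                           stringsAsFactors = FALSE),
    assessment = assess_net(holes, params)
  )
}

size_class_extremes_scenario <- function(params = an_gambiae_params()) {
  classes <- phi_size_classes()
  pts <- data.frame(
    class = rep(classes$class, each = 3),
    point = rep(c("minimum", "mid_range", "maximum"), 4),
    diameter_mm = c(5, 12.5, 20,
                    20, 60, 100,
                    100, 175, 250,
                    250, 300, NA),
    stringsAsFactors = FALSE
  )
  # 5 mm is impassable by construction; the smallest scoreable hole in the
  # bottom class is taken as 6 mm
  pts$diameter_used_mm <- ifelse(pts$diameter_mm == 5, 6, pts$diameter_mm)
  roof_rate <- function(shape) {
    if (is.null(shape)) return(NA_real_)
    hole_entry_rate(hole("x", "FA1", shape, params = params),
                    params)$entries_per_hour
  }
  pts$risk_round <- vapply(pts$diameter_used_mm, function(d) {
    if (is.na(d)) NA_real_
    else roof_rate(hole_shape("circle", diameter = d))
  }, numeric(1))
  pts$risk_square <- vapply(pts$diameter_used_mm, function(d) {
    if (is.na(d)) NA_real_
    else roof_rate(hole_shape("rectangle", length = d, width = d))
  }, numeric(1))
  pts
}
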