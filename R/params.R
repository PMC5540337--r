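#' Functional areas of a bed net
#'
#' Zones of the net under characteristically different levels of
#' host-seeking mosquito pressure: `FA1` is the roof, `FA2_LOW` the bottom
#' 0--30 cm of the sides, `FA2_HIGH` the 30--60 cm band, and `FA3` the
#' upper two-thirds of the sides. All roof holes are scored as FA1
#' regardless of position, a deliberately cautious convention since
#' sleepers move and nets are often shared.
#'
#' @format Character vector of the four functional-area codes, in
#'   decreasing order of mosquito pressure.
#' @export
FA_LEVELS <- c("FA1", "FA2_LOW", "FA2_HIGH", "FA3")

#' Orientation (roof or side) of a functional area
#'
#' @param fa Functional-area code(s), see [FA_LEVELS].
#' @return `"roof"` for FA1, `"side"` otherwise (vectorised).
#' @export
#' @examples
#' fa_orientation(c("FA1", "FA3"))
fa_orientation <- function(fa) {
  fa <- check_fa(fa)
  ifelse(fa == "FA1", "roof", "side")
}

check_fa <- function(fa) {
  fa <- toupper(gsub("[- ]", "_", as.character(fa)))
  bad <- !fa %in% FA_LEVELS
  if (any(bad)) {
    stop("unknown functional area: ", paste(unique(fa[bad]), collapse = ", "),
         " (expected one of ", paste(FA_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  }
  fa
}

#' Map a side-hole height band to its functional area
#'
#' Side holes are assigned by the height of their bottom edge above the
#' net's lower hem: below 300 mm is FA2-low, 300--600 mm FA2-high, above
#' 600 mm FA3. Roof holes are always FA1 and should not be passed here.
#'
#' @param bottom_height_mm Height (mm) of the hole's bottom edge above the
#'   bottom of the net.
#' @return Functional-area code (vectorised).
#' @export
#' @examples
#' fa_from_height(c(0, 250, 300, 599, 600, 1000))
fa_from_height <- function(bottom_height_mm) {
  if (any(bottom_height_mm < 0)) {
    stop("bottom_height_mm must be >= 0", call. = FALSE)
  }
  ifelse(bottom_height_mm < 300, "FA2_LOW",
         ifelse(bottom_height_mm < 600, "FA2_HIGH", "FA3"))
}

#' Species parameters for the entry-risk model
#'
#' All constants of the appearance-encounter-passage model, bundled so the
#' tool can be recalibrated for other vector species or net types without
#' touching the model code. The defaults are the laboratory *Anopheles
#' gambiae* values:
#'
#' \describe{
#'   \item{appearances_per_mosquito_hour}{Hourly appearances of one
#'     attacking mosquito within a 30 cm x 30 cm sampling area, by
#'     functional area: FA1 72.3, FA2-low 9.5, FA2-high 1.5, FA3 0.3
#'     (measured rates for 200 caged mosquitoes, divided by 200).}
#'   \item{encounter_coefficient}{Per-appearance hole encounter probability
#'     per unit of (perimeter in mm + area in mm^2): 9e-6.}
#'   \item{passage_roof, passage_side}{Slope and intercept of the
#'     per-encounter passage probability on ln(average width in mm):
#'     0.34 ln(w) - 0.55 for roof holes, 0.30 ln(w) - 0.52 for side holes.
#'     Roof holes are roughly 20\% more passable at any width, consistent
#'     with a gravity assist and the rising host-odour plume.}
#'   \item{impassable_width}{Widths at or below this (5 mm) carry zero
#'     passage probability; note exp(-intercept/slope) of the passage fits
#'     lands at about this width for both orientations.}
#'   \item{section_length}{Section length (mm) for the average-width
#'     measurement procedure; 10 mm (one centimetre) by default.}
#'   \item{max_entry_dimension}{Largest hole length or width (300 mm) that
#'     a single model entry can carry, because all rates are calibrated on
#'     30 cm x 30 cm sampling units; longer holes must be split
#'     (see [split_long_hole()]).}
#' }
#'
#' @param ... Named overrides for any of the fields above.
#' @return An object of class `species_params`.
#' @seealso [read_species_params()] to load overrides from YAML/JSON.
#' @export
#' @examples
#' p <- an_gambiae_params()
#' p$appearances_per_mosquito_hour
#' slow <- an_gambiae_params(encounter_coefficient = 5e-6)
an_gambiae_params <- function(...) {
  p <- list(
    species = "Anopheles gambiae",
    appearances_per_mosquito_hour = c(
      FA1 = 72.3, FA2_LOW = 9.5, FA2_HIGH = 1.5, FA3 = 0.3
    ),
    encounter_coefficient = 9e-6,
    passage_roof = c(slope = 0.34, intercept = -0.55),
    passage_side = c(slope = 0.30, intercept = -0.52),
    impassable_width = 5,
    section_length = 10,
    max_entry_dimension = 300
  )
  species_params(modifyList(p, list(...)))
}

#' Construct and validate a species-parameters object
#'
#' @param x Named list with the fields documented in [an_gambiae_params()].
#' @return Validated object of class `species_params`.
#' @export
species_params <- function(x) {
  required <- c("appearances_per_mosquito_hour", "encounter_coefficient",
                "passage_roof", "passage_side", "impassable_width",
                "section_length", "max_entry_dimension")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("species parameters missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  app <- unlist(x$appearances_per_mosquito_hour)
  if (!all(FA_LEVELS %in% names(app))) {
    stop("appearances_per_mosquito_hour must name all of ",
         paste(FA_LEVELS, collapse = ", "), call. = FALSE)
  }
  x$appearances_per_mosquito_hour <- app[FA_LEVELS]
  for (side in c("passage_roof", "passage_side")) {
    v <- unlist(x[[side]])
    if (!all(c("slope", "intercept") %in% names(v))) {
      stop(side, " must have named elements slope and intercept",
           call. = FALSE)
    }
    if (v[["slope"]] <= 0) stop(side, " slope must be > 0", call. = FALSE)
    x[[side]] <- v[c("slope", "intercept")]
  }
  if (any(x$appearances_per_mosquito_hour < 0)) {
    stop("appearance rates must be >= 0", call. = FALSE)
  }
  stopifnot(x$encounter_coefficient >= 0, x$impassable_width >= 0,
            x$section_length > 0, x$max_entry_dimension > 0)
  structure(x, class = "species_params")
}

#' Load species parameters from a YAML or JSON config file
#'
#' Fields present in the file override the *An. gambiae* defaults; absent
#' fields keep their default values. Field names are those of
#' [an_gambiae_params()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param base Parameters to override; defaults to [an_gambiae_params()].
#' @return A `species_params` object.
#' @export
read_species_params <- function(path, base = an_gambiae_params()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file type: .", ext, call. = FALSE)
  )
  if (!is.list(raw)) stop("parameter file must contain a mapping", call. = FALSE)
  for (fld in c("appearances_per_mosquito_hour", "passage_roof", "passage_side")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  }
  species_params(modifyList(unclass(base), raw))
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters:", x$species %||% "(unnamed)", "\n")
  cat("  appearances/mosquito-hour: ",
      paste(sprintf("%s=%g", names(x$appearances_per_mosquito_hour),
                    x$appearances_per_mosquito_hour), collapse = ", "), "\n")
  cat(sprintf("  encounter: p = %g x (perimeter + area)\n",
              x$encounter_coefficient))
  cat(sprintf("  passage  : roof %g ln(w) %+g ; side %g ln(w) %+g\n",
              x$passage_roof[["slope"]], x$passage_roof[["intercept"]],
              x$passage_side[["slope"]], x$passage_side[["intercept"]]))
  cat(sprintf("  impassable width <= %g mm; sections %g mm; max entry %g mm\n",
              x$impassable_width, x$section_length, x$max_entry_dimension))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
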