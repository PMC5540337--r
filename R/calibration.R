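#' Validate a table of passage observations
#'
#' Each row summarises one hole size/location trial: how many times
#' mosquitoes encountered the hole and how many of those encounters ended
#' in passage. Columns:
#' `width_mm` (width, diameter, or average width as appropriate for the
#' shape), `length_mm` (NA where not applicable), `location`
#' (`"roof"`/`"side"`), `shape` (`"rectangle"`, `"circle"`,
#' `"triangle"`), `encounters`, `passages`.
#'
#' @param obs Data frame with the columns above.
#' @return The validated data frame (invisibly classed
#'   `passage_observations`).
#' @export
passage_observations <- function(obs) {
  need <- c("width_mm", "location", "shape", "encounters", "passages")
  missing <- setdiff(need, names(obs))
  if (length(missing)) {
    stop("observation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"length_mm" %in% names(obs)) obs$length_mm <- NA_real_
  obs$location <- tolower(obs$location)
  if (!all(obs$location %in% c("roof", "side"))) {
    stop("location must be 'roof' or 'side'", call. = FALSE)
  }
  if (!all(obs$shape %in% c("rectangle", "circle", "triangle"))) {
    stop("shape must be rectangle, circle or triangle", call. = FALSE)
  }
  if (any(obs$width_mm <= 0)) stop("width_mm must be > 0", call. = FALSE)
  if (any(obs$encounters <= 0)) {
    stop("every row needs encounters > 0", call. = FALSE)
  }
  if (any(obs$passages < 0 | obs$passages > obs$encounters)) {
    stop("passages must lie in [0, encounters]", call. = FALSE)
  }
  class(obs) <- c("passage_observations", "data.frame")
  obs
}

#' Read a passage-observation CSV
#'
#' Expects the header
#' `width_mm,length_mm,location,shape,encounters,passages`. A hand-checked
#' example dataset of *An. gambiae* trials through holes in fibreglass
#' netting ships with the package:
#' `system.file("extdata", "passage_trials.csv", package = "netentry")`
#' (transcribed from a typeset summary table; independent verification
#' against the original is advised before quantitative reuse).
#'
#' @param path CSV file path.
#' @return A `passage_observations` data frame.
#' @export
read_passage_observations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  passage_observations(read.csv(path, stringsAsFactors = FALSE))
}

passage_predictor_values <- function(obs, predictor) {
  w <- obs$width_mm
  l <- obs$length_mm
  switch(predictor,
    width = w,
    ln_width = log(w),
    length = l,
    perimeter = ifelse(obs$shape == "circle", pi * w,
                ifelse(obs$shape == "rectangle", 2 * (w + l),
                       # isosceles triangle: width_mm is the average width,
                       # perimeter needs base+slants; only length is known
                       NA_real_)),
    area = ifelse(obs$shape == "circle", pi * w^2 / 4,
           ifelse(obs$shape == "rectangle", w * l, NA_real_)),
    stop("unknown predictor: ", predictor, call. = FALSE)
  )
}

#' Refit the passage model from observation counts
#'
#' Ordinary least squares of the per-row passage proportion
#' (`passages / encounters`) on the chosen predictor, for holes at one
#' location (roof or side). The default predictor `ln_width` reproduces
#' the structure of the packaged model, whose side and roof coefficients
#' were obtained the same way; fitting is unweighted by default, with
#' `weighted = TRUE` weighting rows by their encounter counts (rows can
#' differ more than tenfold in encounters, so the choice matters).
#'
#' @param obs A [passage_observations()] data frame.
#' @param location `"roof"` or `"side"`.
#' @param predictor One of `"ln_width"`, `"width"`, `"perimeter"`,
#'   `"area"`, `"length"`.
#' @param weighted Weight rows by encounter counts.
#' @return Object of class `calibration_fit` with `slope`, `intercept`,
#'   `r_squared`, `n_rows`, and the underlying `lm` fit.
#' @export
#' @examples
#' obs <- passage_observations(data.frame(
#'   width_mm = c(8, 15, 30, 60), length_mm = NA, location = "side",
#'   shape = "circle", encounters = 100,
#'   passages = c(10, 29, 50, 71)
#' ))
#' fit_passage_model(obs, "side")
fit_passage_model <- function(obs, location = c("side", "roof"),
                              predictor = c("ln_width", "width", "perimeter",
                                            "area", "length"),
                              weighted = FALSE) {
  obs <- passage_observations(as.data.frame(obs))
  location <- match.arg(location)
  predictor <- match.arg(predictor)
  obs <- obs[obs$location == location, , drop = FALSE]
  x <- passage_predictor_values(obs, predictor)
  keep <- is.finite(x)
  if (sum(keep) < nrow(obs)) {
    warning(nrow(obs) - sum(keep), " row(s) dropped: predictor '",
            predictor, "' undefined for their shape/fields", call. = FALSE)
  }
  obs <- obs[keep, , drop = FALSE]
  x <- x[keep]
  if (length(unique(x)) < 2) {
    stop("degenerate design: need at least 2 distinct predictor values",
         call. = FALSE)
  }
  y <- obs$passages / obs$encounters
  fit <- if (weighted) {
    dat <- data.frame(x = x, y = y, n = obs$encounters)
    lm(y ~ x, data = dat, weights = n)
  } else {
    lm(y ~ x, data = data.frame(x = x, y = y))
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    predictor = predictor, location = location,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, n_rows = length(x), weighted = weighted, model = fit
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Passage fit (%s, %s%s, n=%d): p = %.4f %s %+.4f,  R^2 = %.4f\n",
              x$location, x$predictor,
              if (x$weighted) ", encounter-weighted" else "",
              x$n_rows,
              x$slope,
              if (x$predictor == "ln_width") "* ln(width)"
              else paste0("* ", x$predictor),
              x$intercept, x$r_squared))
  invisible(x)
}

#' Fit and rank all candidate passage predictors
#'
#' Fits every applicable predictor for the location and ranks the fits by
#' R-squared. When the data really were generated by the log-width
#' mechanism, `ln_width` comes out on top as encounter counts grow.
#'
#' @inheritParams fit_passage_model
#' @param predictors Predictors to compare.
#' @return Data frame of fits sorted by decreasing `r_squared`, with the
#'   `calibration_fit` objects in an attribute `fits`.
#' @export
compare_predictors <- function(obs, location = c("side", "roof"),
                               predictors = c("ln_width", "width",
                                              "perimeter", "area", "length"),
                               weighted = FALSE) {
  location <- match.arg(location)
  fits <- list()
  for (p in predictors) {
    f <- tryCatch(
      suppressWarnings(
        fit_passage_model(obs, location, p, weighted = weighted)
      ),
      error = function(e) NULL
    )
    if (!is.null(f)) fits[[p]] <- f
  }
  if (!length(fits)) stop("no predictor could be fitted", call. = FALSE)
  tab <- data.frame(
    predictor = vapply(fits, `[[`, character(1), "predictor"),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    n_rows = vapply(fits, `[[`, integer(1), "n_rows"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$r_squared), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Turn a calibration fit into species parameters
#'
#' Installs refitted `ln_width` passage coefficients for one orientation
#' into a parameter set, leaving everything else untouched.
#'
#' @param params A [species_params()] object to update.
#' @param fit A `calibration_fit` with `predictor == "ln_width"`.
#' @return Updated `species_params`.
#' @export
apply_calibration <- function(params, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$predictor != "ln_width") {
    stop("only ln_width fits can be installed as passage coefficients",
         call. = FALSE)
  }
  field <- if (fit$location == "roof") "passage_roof" else "passage_side"
  params[[field]] <- c(slope = fit$slope, intercept = fit$intercept)
  species_params(unclass(params))
}
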