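#' @keywords internal
#' @name inventory-format
#' @title Hole inventory file format
#' @description
#' An inventory is a list of hole records, as a JSON array (canonical) or
#' a CSV table. Each record has:
#' \itemize{
#'   \item `id` -- optional identifier (generated when absent);
#'   \item a location: either `fa` (`FA1`, `FA2_LOW`, `FA2_HIGH`, `FA3`)
#'     or `surface` (`roof`/`side`), side records needing
#'     `bottom_height_mm` to resolve the height band;
#'   \item a `shape` tag (`rectangle`, `circle`, `ellipse`, `triangle`,
#'     `polygon`, `measured`) with its dimension fields in mm:
#'     `length_mm`, `width_mm`, `diameter_mm`, `major_mm`, `minor_mm`,
#'     `base_mm`, `vertices` (JSON only), or `perimeter_mm`, `area_mm2`,
#'     `avg_width_mm` for pre-measured holes. Any dimension may instead
#'     be given in centimetres with a `_cm` suffix.
#' }
#' CSV files use the header
#' `id,fa,surface,bottom_height_mm,shape,length_mm,width_mm,diameter_mm,major_mm,minor_mm,base_mm,perimeter_mm,area_mm2,avg_width_mm`
#' with unused fields blank; polygons are JSON-only.
NULL

inventory_csv_columns <- c(
  "id", "fa", "surface", "bottom_height_mm", "shape",
  "length_mm", "width_mm", "diameter_mm", "major_mm", "minor_mm", "base_mm",
  "perimeter_mm", "area_mm2", "avg_width_mm"
)

# fetch a dimension from a record, honouring _mm / _cm suffixes
record_dim <- function(rec, stem, where, required = TRUE) {
  mm <- rec[[paste0(stem, "_mm")]]
  cm <- rec[[paste0(stem, "_cm")]]
  val <- if (!is.null(mm) && length(mm) && !is.na(mm)) {
    as.numeric(mm)
  } else if (!is.null(cm) && length(cm) && !is.na(cm)) {
    10 * as.numeric(cm)
  } else if (stem == "area") {
    # area carries squared units: area_mm2 / area_cm2
    mm2 <- rec[["area_mm2"]]
    cm2 <- rec[["area_cm2"]]
    if (!is.null(mm2) && length(mm2) && !is.na(mm2)) as.numeric(mm2)
    else if (!is.null(cm2) && length(cm2) && !is.na(cm2)) 100 * as.numeric(cm2)
    else NULL
  } else {
    NULL
  }
  if (is.null(val) && required) {
    stop(where, ": missing field ", stem, "_mm", call. = FALSE)
  }
  val
}

record_to_shape <- function(rec, where) {
  type <- rec$shape
  if (is.null(type) || is.na(type) || !nzchar(type)) {
    stop(where, ": missing shape tag", call. = FALSE)
  }
  measured_fields <- !is.null(record_dim(rec, "perimeter", where, FALSE)) ||
    !is.null(record_dim(rec, "area", where, FALSE))
  if (type != "measured" && measured_fields) {
    stop(where, ": give either a shape with dimensions or measured ",
         "metrics, not both", call. = FALSE)
  }
  tryCatch(
    switch(type,
      rectangle = hole_shape("rectangle",
                             length = record_dim(rec, "length", where),
                             width = record_dim(rec, "width", where)),
      circle = hole_shape("circle",
                          diameter = record_dim(rec, "diameter", where)),
      ellipse = hole_shape("ellipse",
                           major_axis = record_dim(rec, "major", where),
                           minor_axis = record_dim(rec, "minor", where)),
      triangle = hole_shape("triangle",
                            base = record_dim(rec, "base", where),
                            length = record_dim(rec, "length", where)),
      polygon = {
        v <- rec$vertices
        if (is.null(v)) stop(where, ": polygon needs vertices", call. = FALSE)
        if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
        hole_shape("polygon", outline = polygon_outline(v))
      },
      measured = hole_shape("measured",
                            perimeter = record_dim(rec, "perimeter", where),
                            area = record_dim(rec, "area", where),
                            avg_width = record_dim(rec, "avg_width", where)),
      stop(where, ": unknown shape '", type, "'", call. = FALSE)
    ),
    error = function(e) {
      msg <- conditionMessage(e)
      if (startsWith(msg, where)) stop(e)
      stop(where, ": ", msg, call. = FALSE)
    }
  )
}

record_fa <- function(rec, where) {
  fa <- rec$fa
  if (!is.null(fa) && length(fa) && !is.na(fa) && nzchar(fa)) {
    if (identical(tolower(fa), "roof")) return("FA1")
    return(tryCatch(check_fa(fa),
                    error = function(e) stop(where, ": ",
                                             conditionMessage(e),
                                             call. = FALSE)))
  }
  surface <- rec$surface
  if (is.null(surface) || is.na(surface) || !nzchar(surface)) {
    stop(where, ": record needs either fa or surface", call. = FALSE)
  }
  surface <- tolower(surface)
  if (surface == "roof") return("FA1")
  if (surface != "side") {
    stop(where, ": surface must be 'roof' or 'side'", call. = FALSE)
  }
  h <- record_dim(rec, "bottom_height", where, required = FALSE)
  if (is.null(h)) {
    stop(where, ": side records need bottom_height_mm", call. = FALSE)
  }
  fa_from_height(h)
}

#' Build holes from inventory records
#'
#' @param records List of records (JSON style) or a data frame in the CSV
#'   layout; see `?"inventory-format"`.
#' @param params A [species_params()] object.
#' @param normalize Split entries exceeding the 300 mm cap.
#' @return List of [hole()] objects.
#' @export
holes_from_records <- function(records, params = an_gambiae_params(),
                               normalize = TRUE) {
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i) {
      as.list(records[i, , drop = FALSE])
    })
  }
  holes <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    id <- rec$id
    if (is.null(id) || is.na(id) || !nzchar(as.character(id))) {
      id <- paste0("hole", i)
    }
    where <- sprintf("record %d (%s)", i, id)
    holes[[i]] <- tryCatch(
      hole(id, record_fa(rec, where),
           shape = record_to_shape(rec, where), params = params),
      error = function(e) {
        msg <- conditionMessage(e)
        if (startsWith(msg, where)) stop(e)
        stop(where, ": ", msg, call. = FALSE)
      }
    )
  }
  if (normalize) holes <- normalize_holes(holes, params)
  holes
}

#' Read a hole inventory file
#'
#' Reads and validates a JSON or CSV inventory (see
#' `?"inventory-format"`), computes metrics for every hole, resolves
#' side height bands to functional areas, and splits entries longer than
#' the 300 mm model cap. Validation failures name the offending record.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @param params A [species_params()] object.
#' @param normalize Split over-long entries (default TRUE).
#' @return List of [hole()] objects.
#' @export
#' @examples
#' inv <- system.file("extdata", "mixed_damage.json", package = "netentry")
#' length(read_inventory(inv))  # 14 holes
read_inventory <- function(path, format = c("auto", "json", "csv"),
                           params = an_gambiae_params(), normalize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", csv = "csv",
                     stop("cannot infer inventory format from '", path,
                          "'; pass format=", call. = FALSE))
  }
  records <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    df
  }
  holes_from_records(records, params = params, normalize = normalize)
}

#' Write inventory records to JSON or CSV
#'
#' @param records Data frame in the CSV column layout (as produced by
#'   [generate_inventory()]).
#' @param path Destination; `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(records, path) {
  stopifnot(is.data.frame(records))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    recs <- lapply(seq_len(nrow(records)), function(i) {
      r <- as.list(records[i, , drop = FALSE])
      r[!vapply(r, function(v) is.na(v) || identical(v, ""), logical(1))]
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    write.csv(records, path, row.names = FALSE, na = "")
  } else {
    stop("unsupported inventory extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

# small deterministic content hash (FNV-1a, 32-bit) for report provenance
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    lowb <- h %% 256
    h <- h - lowb + bitwXor(as.integer(lowb), b)
    # exact 32-bit modular multiply by the FNV prime 16777619
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

param_hash <- function(params) {
  txt <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  h <- fnv1a32(as.character(txt))  # double-valued 32-bit hash
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write an assessment report
#'
#' Serialises a [assess_net()] result to JSON at full precision, with the
#' package version and a parameter digest for provenance. The JSON holds
#' exactly the numbers the printed rendering rounds for display.
#'
#' @param assessment A `net_assessment`.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(assessment, path) {
  stopifnot(inherits(assessment, "net_assessment"))
  payload <- list(
    tool = "netentry",
    version = as.character(utils::packageVersion("netentry")),
    params = unclass(assessment$params),
    param_hash = param_hash(assessment$params),
    n_mosquitoes = assessment$n_mosquitoes,
    hours = assessment$hours,
    total_entries_per_hour = assessment$total_entries_per_hour,
    total_entries = assessment$total_entries,
    share_roof = assessment$share_roof,
    share_side = assessment$share_side,
    by_fa = assessment$by_fa,
    holes = assessment$holes
  )
  # 17 significant digits: doubles survive the JSON round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Read an assessment report back
#'
#' @param path A report written by [write_report()].
#' @return Named list mirroring the report fields, with `holes` and
#'   `by_fa` as data frames.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.net_assessment <- function(x, ...) {
  cat("Bed net entry risk assessment (",
      x$params$species %||% "custom parameters", ")\n", sep = "")
  cat(sprintf("  holes assessed: %d\n", nrow(x$holes)))
  if (nrow(x$holes)) {
    for (i in seq_len(nrow(x$holes))) {
      r <- x$holes[i, ]
      cat(sprintf("   %-10s %-8s P %7.1f  A %8.0f  w %5.1f  -> %6.2f /h\n",
                  r$id, r$fa, r$perimeter_mm, r$area_mm2, r$avg_width_mm,
                  r$entries_per_hour))
    }
  }
  cat("  by functional area:\n")
  for (i in seq_len(nrow(x$by_fa))) {
    r <- x$by_fa[i, ]
    cat(sprintf("   %-8s %2d hole(s)  %6.2f /h%s\n", r$fa, r$n_holes,
                r$entries_per_hour,
                if (!is.na(r$share)) sprintf("  (%.0f%%)", 100 * r$share)
                else ""))
  }
  cat(sprintf("  total entry risk: %.2f mosquitoes/hour",
              x$total_entries_per_hour))
  if (!is.na(x$share_side)) {
    cat(sprintf("  (roof %.0f%%, sides %.0f%%)",
                100 * x$share_roof, 100 * x$share_side))
  }
  cat("\n")
  if (x$n_mosquitoes != 1 || x$hours != 1) {
    cat(sprintf("  scaled: %g mosquito(es) x %g h -> %.2f expected entries\n",
                x$n_mosquitoes, x$hours, x$total_entries))
  }
  invisible(x)
}
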