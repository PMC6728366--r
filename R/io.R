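# Readers and writers for the package's table, profile, image and result
# formats. Tables are TSV by default with comma auto-detection; images are
# single-plane TIFF; results serialize to JSON with a schema version and a
# config echo.

NM_SCHEMA_VERSION <- "1.0"

detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

read_delim_quiet <- function(path) {
  readr::read_delim(path, delim = detect_delim(path),
                    show_col_types = FALSE, progress = FALSE)
}

#' Read a cell-record table
#'
#' Expects columns `cell_id`, `x`, `y`, `axial_angle_deg` (plus optional
#' `dir_angle_deg`, `cell_class`). Annotations exported from image viewers
#' live in a y-down frame; with `frame = "image_y_down"` (default) y is
#' negated on ingestion so the package's anticlockwise-positive convention
#' holds. Angles are wrapped on ingestion.
#'
#' @param path Delimited-text file (TSV or CSV, auto-detected).
#' @param frame `"image_y_down"` or `"math_y_up"`.
#' @return A tibble of cell records.
#' @export
read_cells <- function(path, frame = c("image_y_down", "math_y_up")) {
  frame <- match.arg(frame)
  tab <- read_delim_quiet(path)
  required <- c("cell_id", "x", "y", "axial_angle_deg")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c("x", "y", "axial_angle_deg", "dir_angle_deg"),
                        names(tab))) {
    v <- tab[[col]]
    if (is.logical(v) && all(is.na(v))) {
      # an all-missing optional column parses as logical NA
      tab[[col]] <- as.numeric(v)
    } else if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric value in column '", col, "' at data line ",
           if (length(bad)) bad[1] else "?", call. = FALSE)
    }
  }
  bad <- which(!is.finite(tab$x) | !is.finite(tab$y) |
                 !is.finite(tab$axial_angle_deg))
  if (length(bad) > 0) {
    stop("malformed row(s) at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (frame == "image_y_down") tab$y <- -tab$y
  tab$axial_angle_deg <- wrap_axial(tab$axial_angle_deg)
  if ("dir_angle_deg" %in% names(tab)) {
    ok <- is.finite(tab$dir_angle_deg)
    tab$dir_angle_deg[ok] <- wrap_directional(tab$dir_angle_deg[ok])
  }
  if (!"cell_class" %in% names(tab)) tab$cell_class <- "hair"
  tab
}

#' Write a cell-record table as TSV
#'
#' @param cells Tibble of cell records.
#' @param path Output path.
#' @export
write_cells <- function(cells, path) {
  readr::write_tsv(cells, path)
  invisible(path)
}

#' Read a division-event table
#'
#' Expects columns `d1x`, `d1y`, `d2x`, `d2y`, `cx`, `cy` (optional `d1z`,
#' `d2z`, `cz` for 3D positions, and `timepoint`).
#'
#' @param path Delimited-text file.
#' @return A tibble of division events.
#' @export
read_divisions <- function(path) {
  tab <- read_delim_quiet(path)
  required <- c("d1x", "d1y", "d2x", "d2y", "cx", "cy")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Read a two-column angular profile table
#'
#' @param path Delimited-text file with columns `angle_deg`, `intensity`
#'   (optional `sem`).
#' @return An [angular_profile()].
#' @export
read_profile <- function(path) {
  tab <- read_delim_quiet(path)
  if (!all(c("angle_deg", "intensity") %in% names(tab))) {
    stop("profile file needs columns angle_deg, intensity", call. = FALSE)
  }
  ord <- order(tab$angle_deg)
  angular_profile(tab$angle_deg[ord], tab$intensity[ord],
                  sem = if ("sem" %in% names(tab)) tab$sem[ord])
}

#' Write an angular profile as TSV
#'
#' @param profile An [angular_profile()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path)
  invisible(path)
}

#' Write a label image as unsigned 16-bit single-plane TIFF
#'
#' @param img Integer matrix of labels (0..65535).
#' @param path Output path.
#' @export
write_label_tiff <- function(img, path) {
  stopifnot(all(img >= 0), all(img <= 65535))
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a label image from TIFF
#'
#' @param path TIFF path (8- or 16-bit single plane).
#' @return Integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "integer"
  img
}

#' Write an intensity image as 32-bit float single-plane TIFF
#'
#' @param img Numeric matrix.
#' @param path Output path.
#' @export
write_intensity_tiff <- function(img, path) {
  rng <- range(img)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32, compression = "none")
  invisible(path)
}

# Strip classes so jsonlite serializes plain structures.
as_plain <- function(x) {
  if (is.list(x)) {
    x <- lapply(unclass(x), as_plain)
  } else if (!is.null(attributes(x))) {
    if (is.matrix(x)) return(unclass(x))
    attributes(x) <- attributes(x)["names"]
  }
  x
}

#' Write an analysis result as JSON
#'
#' Serializes any of the package's result objects with a schema version and
#' an echo of the configuration that produced it, at full numeric
#' precision, so a written result round-trips losslessly.
#'
#' @param result A result object (e.g. from [concentricity_test()]).
#' @param path Output path.
#' @param config Optional configuration list to echo.
#' @param timestamp Include a timestamp field (default `FALSE` so reruns
#'   are byte-identical).
#' @export
write_result <- function(result, path, config = NULL, timestamp = FALSE) {
  payload <- list(
    schema_version = NM_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("neuromast")),
    result_class = class(result)[1],
    config = as_plain(config),
    result = as_plain(result)
  )
  if (timestamp) payload$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a result JSON written by [write_result()]
#'
#' @param path JSON path.
#' @return A list with `schema_version`, `result_class`, `config`, `result`.
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
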