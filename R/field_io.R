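# Field image and results I/O ------------------------------------------------
#
# Fields are stored as multi-page 16-bit TIFF files (one page per channel;
# z-stacks interleave channel-major as channel, slice) with a JSON sidecar
# holding channel names, pixel size and identifiers. Camera counts are
# integers well below 2^16, so the round trip is lossless.

TIFF_MAX <- 65535

#' Write a field image to TIFF (+ JSON sidecar)
#'
#' @param field a [field_image()].
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  pages <- list(); page_meta <- list()
  for (ch in names(field$channels)) {
    x <- field$channels[[ch]]
    if (length(dim(x)) == 3L) {
      for (z in seq_len(dim(x)[3])) {
        pages[[length(pages) + 1L]] <- x[, , z]
        page_meta[[length(page_meta) + 1L]] <- list(channel = ch, z = z)
      }
    } else {
      pages[[length(pages) + 1L]] <- x
      page_meta[[length(page_meta) + 1L]] <- list(channel = ch, z = 1L)
    }
  }
  mx <- max(vapply(pages, max, numeric(1)), 1)
  if (mx > TIFF_MAX)
    stop("I/O error: intensities exceed 16-bit range")
  pages <- lapply(pages, function(p) round(p) / TIFF_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pages = page_meta, pixel_size_um = field$pixel_size_um,
               plate = field$plate, well = field$well, field = field$field,
               channel_order = names(field$channels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a field image from TIFF
#'
#' Channel names are resolved from the JSON sidecar when present, else from
#' `channels` in page order.
#'
#' @param path TIFF path written by [write_field()] (or any multi-page
#'   TIFF).
#' @param channels fallback channel names when no sidecar exists.
#' @param require character vector of channels that must be present.
#' @param pixel_size_um fallback pixel size when no sidecar exists.
#' @return a [field_image()].
#' @export
read_field <- function(path, channels = c("er", "nucleus", "membrane"),
                       require = c("er", "nucleus"),
                       pixel_size_um = ERSCREEN_PIXEL_SIZE_UM) {
  stopifnot(file.exists(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) round(p * TIFF_MAX))
  side <- paste0(path, ".json")
  plate <- NA_character_; well <- NA_character_; fieldno <- NA_integer_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pm <- meta$pages
    chs <- unique(pm$channel)
    chan <- setNames(vector("list", length(chs)), chs)
    for (ch in chs) {
      zpages <- pages[pm$channel == ch]
      chan[[ch]] <- if (length(zpages) == 1L) zpages[[1]] else
        array(unlist(zpages), dim = c(dim(zpages[[1]]), length(zpages)))
    }
    pixel_size_um <- meta$pixel_size_um
    as_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
    plate <- as_chr(meta$plate); well <- as_chr(meta$well)
    fieldno <- suppressWarnings(as.integer(meta$field))
    if (!length(fieldno)) fieldno <- NA_integer_
  } else {
    n <- min(length(pages), length(channels))
    chan <- setNames(pages[seq_len(n)], channels[seq_len(n)])
  }
  missing <- setdiff(require, names(chan))
  if (length(missing))
    stop("I/O error: required channel(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  field_image(chan, pixel_size_um = pixel_size_um, plate = plate,
              well = well, field = fieldno)
}

#' Write / read tidy result tables
#'
#' Plain UTF-8 comma-separated files with a header row and full-precision
#' floats.
#'
#' @param table a data.frame.
#' @param path CSV path.
#' @export
write_results <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
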