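# Serialization: track sets as CSV + JSON metadata sidecar, movies as
# 16-bit multi-page TIFF, foci fields as TIFF pages + truth CSV,
# signatures as JSON and flat CSV.

#' Write a track set as CSV with a JSON metadata sidecar
#'
#' @param ts A `trackset`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trackset <- function(ts, path) {
  stopifnot(inherits(ts, "trackset"))
  utils::write.csv(ts$tracks, path, row.names = FALSE)
  jsonlite::write_json(ts$metadata, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a track set written by [write_trackset()]
#'
#' @param path CSV path.
#' @return A `trackset`.
#' @export
read_trackset <- function(path) {
  tracks <- tibble::as_tibble(utils::read.csv(path))
  meta_path <- paste0(path, ".meta.json")
  metadata <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  trackset(tracks, metadata)
}

movie_scale <- 65535

#' Write a movie stack as a 16-bit multi-page TIFF
#'
#' One file per channel; counts are stored as 16-bit values (clipped at
#' 65535). The row order is flipped so files follow the usual top-left
#' image convention while internal arrays keep the lower-left origin.
#'
#' @param movie A `[height, width, frames]` array.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(length(dim(movie)) == 3L)
  pages <- lapply(seq_len(dim(movie)[3]), function(f) {
    img <- pmin(pmax(movie[, , f], 0), movie_scale) / movie_scale
    img[rev(seq_len(nrow(img))), , drop = FALSE]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a movie stack written by [write_movie_tiff()]
#'
#' @param path TIFF path.
#' @return A `[height, width, frames]` numeric array in camera counts.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                            length(pages)))
  for (f in seq_along(pages)) {
    img <- pages[[f]] * movie_scale
    stack[, , f] <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  }
  stack
}

#' Write a foci field (mask + channels + truth counts)
#'
#' The labelled nucleus mask and each channel go into one multi-page TIFF
#' (mask first); the ground-truth counts go into a CSV next to it.
#'
#' @param field A `foci_field`.
#' @param prefix Path prefix; writes `<prefix>.tif` and
#'   `<prefix>_truth.csv`.
#' @return `prefix`, invisibly.
#' @export
write_foci_field <- function(field, prefix) {
  stopifnot(inherits(field, "foci_field"))
  pages <- c(list(field$nucleus_mask / movie_scale),
             lapply(field$channels,
                    function(m) pmin(pmax(m, 0), movie_scale) / movie_scale))
  pages <- lapply(pages, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 16L)
  utils::write.csv(field$truth_counts, paste0(prefix, "_truth.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' Write a phenotypic signature as JSON and flat CSV
#'
#' @param signature A `phenotypic_signature`.
#' @param prefix Path prefix; writes `<prefix>.json` and `<prefix>.csv`.
#' @return `prefix`, invisibly.
#' @export
write_signature <- function(signature, prefix) {
  stopifnot(inherits(signature, "phenotypic_signature"))
  flat <- dplyr::mutate(signature$labels,
                        label = names(signature$values),
                        z = unname(signature$values),
                        line = signature$line, day = signature$day)
  utils::write.csv(flat, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(line = signature$line, day = signature$day,
         baseline_id = signature$baseline_id,
         labels = names(signature$values),
         values = unname(signature$values)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}

#' Read a phenotypic signature written by [write_signature()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `phenotypic_signature`.
#' @export
read_signature <- function(prefix) {
  j <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  values <- as.numeric(j$values)
  names(values) <- j$labels
  parts <- do.call(rbind, strsplit(j$labels, ".", fixed = TRUE))
  labels <- tibble::tibble(channel = parts[, 1], site = parts[, 2],
                           parameter = apply(parts[, -(1:2), drop = FALSE],
                                             1, paste, collapse = "."))
  structure(list(values = values, labels = labels, line = j$line,
                 day = j$day, baseline_id = j$baseline_id),
            class = "phenotypic_signature")
}
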