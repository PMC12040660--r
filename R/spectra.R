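#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Metadata columns of a spectra tibble; all other columns are wavenumber
# channels named by their position on the Raman-shift axis (cm^-1).
.meta_cols <- c("spectrum_id", "subject_id", "group")

.group_levels <- c("Target", "Control")

#' Construct a spectra tibble
#'
#' The package's central container is an ordinary tibble: one row per
#' recorded spectrum, three metadata columns (`spectrum_id`, `subject_id`,
#' `group`) followed by one numeric column per wavenumber channel, named by
#' the channel's Raman shift in cm^-1 (e.g. `"632"`). Because it is a plain
#' tibble it pipes through dplyr verbs; the helpers below recover the
#' numeric view when linear algebra is needed.
#'
#' @param axis numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @param intensities numeric matrix, rows = spectra, columns = channels
#'   (arbitrary units); `ncol` must equal `length(axis)`.
#' @param meta data frame with columns `spectrum_id`, `subject_id`, `group`
#'   and one row per spectrum. `group` values must be `"Target"` or
#'   `"Control"`.
#' @return a tibble of class `sers_spectra`.
#' @export
spectra_tbl <- function(axis, intensities, meta) {
  intensities <- as.matrix(intensities)
  axis <- as.numeric(axis)
  if (length(axis) != ncol(intensities)) {
    abort("length(axis) must equal ncol(intensities)")
  }
  if (is.unsorted(axis, strictly = TRUE)) {
    abort("axis must be strictly increasing")
  }
  meta <- as_tibble(meta)
  if (!all(.meta_cols %in% names(meta))) {
    abort(paste("meta must have columns:", paste(.meta_cols, collapse = ", ")))
  }
  if (nrow(meta) != nrow(intensities)) {
    abort("meta and intensities disagree on the number of spectra")
  }
  if (!all(as.character(meta$group) %in% .group_levels)) {
    abort("group labels must be 'Target' or 'Control'")
  }
  colnames(intensities) <- format_axis(axis)
  out <- dplyr::bind_cols(meta[.meta_cols], as_tibble(intensities))
  out$group <- factor(as.character(out$group), levels = .group_levels)
  validate_spectra(out)
  class(out) <- c("sers_spectra", class(out))
  out
}

format_axis <- function(axis) {
  # shortest decimal representation that round-trips a double
  vapply(axis, function(v) format(v, digits = 15, scientific = FALSE), "")
}

#' Recover the wavenumber axis of a spectra tibble
#' @param x a spectra tibble (see [spectra_tbl()]).
#' @return numeric vector of wavenumbers (cm^-1).
#' @export
spectra_axis <- function(x) {
  as.numeric(setdiff(names(x), .meta_cols))
}

#' Extract the intensity matrix of a spectra tibble
#' @inheritParams spectra_axis
#' @return numeric matrix, rows = spectra (named by `spectrum_id`),
#'   columns = channels.
#' @export
spectra_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), .meta_cols)])
  rownames(m) <- x$spectrum_id
  m
}

#' Extract the metadata columns of a spectra tibble
#' @inheritParams spectra_axis
#' @return tibble with columns `spectrum_id`, `subject_id`, `group`.
#' @export
spectra_meta <- function(x) {
  as_tibble(x[, .meta_cols])
}

validate_spectra <- function(x) {
  chan <- setdiff(names(x), .meta_cols)
  if (length(chan) == 0L) abort("spectra tibble has no channel columns")
  ax <- suppressWarnings(as.numeric(chan))
  if (anyNA(ax)) abort("channel column names must be numeric wavenumbers")
  if (nrow(x) > 0L) {
    map <- unique(tibble(subject_id = x$subject_id, group = as.character(x$group)))
    if (anyDuplicated(map$subject_id)) {
      abort("every subject must map to exactly one group")
    }
    if (anyDuplicated(x$spectrum_id)) abort("spectrum_id values must be unique")
  }
  invisible(x)
}

# rebuild a spectra tibble from a transformed matrix, keeping metadata
rebuild_spectra <- function(template, intensities) {
  spectra_tbl(spectra_axis(template), intensities, spectra_meta(template))
}

#' Write a spectra tibble to delimited text
#'
#' Writes two CSV files: `<prefix>_spectra.csv` (first column `spectrum_id`,
#' remaining columns one per wavenumber, header row = wavenumbers) and
#' `<prefix>_meta.csv` (`spectrum_id`, `subject_id`, `group`). Numeric
#' values are written with shortest round-trip precision, so
#' [read_spectra()] recovers the data losslessly.
#'
#' @param x spectra tibble.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_spectra <- function(x, prefix) {
  validate_spectra(x)
  f_spec <- paste0(prefix, "_spectra.csv")
  f_meta <- paste0(prefix, "_meta.csv")
  num <- as.data.frame(spectra_matrix(x), check.names = FALSE)
  # %.17g round-trips any double exactly through decimal text
  num[] <- lapply(num, function(col) sprintf("%.17g", col))
  wide <- dplyr::bind_cols(x["spectrum_id"], as_tibble(num))
  readr::write_csv(wide, f_spec)
  readr::write_csv(spectra_meta(x), f_meta)
  invisible(c(spectra = f_spec, meta = f_meta))
}

#' Read a spectra tibble written by [write_spectra()]
#' @param prefix path prefix used when writing.
#' @return a spectra tibble.
#' @export
read_spectra <- function(prefix) {
  wide <- readr::read_csv(paste0(prefix, "_spectra.csv"),
    show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  # base-R numeric conversion is correctly rounded, so %.17g text restores
  # every double bit-exactly
  wide[-1] <- lapply(wide[-1], as.numeric)
  meta <- readr::read_csv(paste0(prefix, "_meta.csv"),
    show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  meta <- meta[match(wide$spectrum_id, meta$spectrum_id), ]
  axis <- as.numeric(setdiff(names(wide), "spectrum_id"))
  spectra_tbl(axis, as.matrix(wide[, -1]), meta)
}
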