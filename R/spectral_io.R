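# Plain-text I/O for spectra. Wide CSV: one row per sample with columns
# plant_id, condition, chlorophyll, campaign, then one column per
# wavelength named by integer nm (e.g. "w400").

#' Write / read spectra as wide CSV
#'
#' The wide dialect stores one sample per row: `plant_id`, `condition`,
#' `chlorophyll`, `campaign`, then one reflectance column per wavelength
#' (`w400`, `w401`, ...). Round-trips are lossless to well below 1e-9.
#'
#' @param ds A `spectral_dataset`.
#' @param path File path.
#' @return `write_spectra_csv` returns `path` invisibly;
#'   `read_spectra_csv` returns a `spectral_dataset`.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  refl <- as.data.frame(ds$reflectance)
  names(refl) <- paste0("w", ds$wavelengths)
  df <- cbind(ds$meta, refl)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wcols <- grep("^w[0-9.]+$", names(df), value = TRUE)
  if (!length(wcols)) stop("no wavelength columns (w<nm>) found in ", path)
  w <- as.numeric(sub("^w", "", wcols))
  ord <- order(w)
  spectral_dataset(
    wavelengths = w[ord],
    reflectance = as.matrix(df[, wcols[ord], drop = FALSE]),
    condition = df$condition,
    chlorophyll = if ("chlorophyll" %in% names(df)) df$chlorophyll else NULL,
    plant_id = df$plant_id,
    campaign = if ("campaign" %in% names(df)) df$campaign[1] else NA_character_
  )
}

#' Read spectra from long CSV
#'
#' Long dialect: columns `plant_id`, `condition`, `chlorophyll`,
#' `wavelength`, `reflectance`, one row per (sample, band). All samples
#' must share one wavelength grid.
#'
#' @param path File path.
#' @return A `spectral_dataset`.
#' @export
read_spectra_long <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "wavelength", "reflectance")
  if (!all(need %in% names(df)))
    stop("long CSV needs columns: ", paste(need, collapse = ", "))
  ids <- unique(df$plant_id)
  w <- sort(unique(df$wavelength))
  refl <- matrix(NA_real_, length(ids), length(w))
  meta_cond <- character(length(ids)); meta_chl <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$plant_id == ids[i], ]
    if (!identical(sort(sub$wavelength), w))
      stop("sample ", ids[i], " is not on the shared wavelength grid")
    refl[i, ] <- sub$reflectance[order(sub$wavelength)]
    meta_cond[i] <- if ("condition" %in% names(sub)) sub$condition[1] else RESERVED_SOURCE
    if ("chlorophyll" %in% names(sub)) meta_chl[i] <- sub$chlorophyll[1]
  }
  spectral_dataset(w, refl, condition = meta_cond, chlorophyll = meta_chl,
                   plant_id = as.character(ids))
}
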