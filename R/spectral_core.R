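# Spectral data model and the preprocessing transforms used ahead of
# feature selection: crop -> Savitzky-Golay smoothing -> one of
# {continuum removal, standard normal variate, first derivative}.

#' Construct a spectral dataset
#'
#' A `spectral_dataset` holds reflectance spectra on one shared wavelength
#' grid together with per-sample metadata: shading condition, chlorophyll
#' content and plant identifier.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param reflectance Numeric matrix, one row per sample, columns aligned to
#'   `wavelengths`; all values finite.
#' @param condition Character/factor vector of shading labels, one of
#'   `"S1".."S4"` or `"RESERVED_SOURCE"`; recycled if length 1.
#' @param chlorophyll Optional numeric vector of chlorophyll contents in
#'   ug/cm^2 (nonnegative; `NA` allowed).
#' @param plant_id Character vector of per-plant identifiers, unique within
#'   a campaign. Defaults to `sample_1..n`.
#' @param campaign Optional campaign tag.
#' @param transforms Character vector recording the transform history.
#' @return An object of class `spectral_dataset` with elements
#'   `wavelengths`, `reflectance`, `meta` (data frame) and `transforms`.
#' @export
#' @examples
#' ds <- spectral_dataset(400:900, matrix(runif(2 * 501), 2), condition = "S1")
#' n_bands(ds)
spectral_dataset <- function(wavelengths, reflectance,
                             condition = RESERVED_SOURCE,
                             chlorophyll = NULL, plant_id = NULL,
                             campaign = NA_character_,
                             transforms = character()) {
  wavelengths <- as.numeric(wavelengths)
  if (is.vector(reflectance)) reflectance <- matrix(reflectance, nrow = 1)
  reflectance <- as.matrix(reflectance)
  n <- nrow(reflectance)
  if (length(wavelengths) < 2) stop("need at least 2 wavelengths")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (ncol(reflectance) != length(wavelengths))
    stop("reflectance columns must align with wavelengths")
  if (!all(is.finite(reflectance))) stop("reflectance must be finite")
  condition <- as.character(condition)
  if (length(condition) == 1) condition <- rep(condition, n)
  if (length(condition) != n) stop("condition length must match sample count")
  bad <- setdiff(unique(condition), all_condition_levels())
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  if (is.null(chlorophyll)) chlorophyll <- rep(NA_real_, n)
  chlorophyll <- as.numeric(chlorophyll)
  if (length(chlorophyll) == 1) chlorophyll <- rep(chlorophyll, n)
  if (length(chlorophyll) != n) stop("chlorophyll length must match sample count")
  if (any(!is.na(chlorophyll) & chlorophyll < 0)) stop("chlorophyll must be nonnegative")
  if (is.null(plant_id)) plant_id <- paste0("sample_", seq_len(n))
  plant_id <- as.character(plant_id)
  if (length(plant_id) != n) stop("plant_id length must match sample count")
  if (anyDuplicated(paste(campaign[1], plant_id)))
    stop("plant_id values must be unique within a campaign")
  structure(
    list(
      wavelengths = wavelengths,
      reflectance = unname(reflectance),
      meta = data.frame(plant_id = plant_id, condition = condition,
                        chlorophyll = chlorophyll,
                        campaign = rep(campaign[1], n),
                        stringsAsFactors = FALSE),
      transforms = transforms
    ),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples x %d bands (%g-%g nm)\n",
    nrow(x$reflectance), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths)))
  tab <- table(x$meta$condition)
  cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(x$transforms))
    cat("  transforms:", paste(x$transforms, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of samples / bands in a spectral dataset
#' @param ds A `spectral_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$reflectance)

#' @rdname n_samples
#' @export
n_bands <- function(ds) length(ds$wavelengths)

replace_reflectance <- function(ds, refl, transform = NULL,
                                wavelengths = ds$wavelengths) {
  ds$reflectance <- unname(as.matrix(refl))
  ds$wavelengths <- wavelengths
  if (!is.null(transform)) ds$transforms <- c(ds$transforms, transform)
  stopifnot(ncol(ds$reflectance) == length(ds$wavelengths))
  ds
}

#' Named spectral regions
#'
#' The three wavelength windows used throughout: the full working range
#' (400-900 nm), the green reflectance peak of healthy vegetation
#' (500-600 nm) and the red edge (680-760 nm), whose inflection point
#' shifts with chlorophyll content.
#'
#' @param name One of `"full"`, `"green_peak"`, `"red_edge"`, or custom
#'   bounds via `lo`/`hi`.
#' @param lo,hi Optional custom bounds in nm (must satisfy
#'   `400 <= lo < hi <= 900`).
#' @return A list with `name`, `lo`, `hi` of class `spectral_region`.
#' @export
#' @examples
#' spectral_region("red_edge")
spectral_region <- function(name = c("full", "green_peak", "red_edge"),
                            lo = NULL, hi = NULL) {
  if (is.null(lo) || is.null(hi)) {
    name <- match.arg(name)
    bounds <- switch(name, full = c(400, 900), green_peak = c(500, 600),
                     red_edge = c(680, 760))
    lo <- bounds[1]; hi <- bounds[2]
  } else {
    name <- as.character(name)[1]
  }
  if (!(lo < hi)) stop("region requires lo < hi")
  if (lo < 400 || hi > 900) stop("region bounds must lie within 400-900 nm")
  structure(list(name = name, lo = lo, hi = hi), class = "spectral_region")
}

#' Crop a dataset to a wavelength region
#'
#' Restricts the wavelength grid to the closed interval `[lo, hi]` of a
#' region. Edge bands outside 400-900 nm carry poor signal-to-noise, so
#' the full working region is 400-900 nm.
#'
#' @param ds A `spectral_dataset`.
#' @param region A `spectral_region` (default the full 400-900 nm window).
#' @return The cropped `spectral_dataset`; sample metadata preserved.
#' @export
#' @examples
#' ds <- spectral_dataset(325:1100, matrix(runif(776), 1))
#' n_bands(crop_bands(ds, spectral_region("full")))  # 501
crop_bands <- function(ds, region = spectral_region("full")) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(region, "spectral_region"))
  keep <- ds$wavelengths >= region$lo & ds$wavelengths <= region$hi
  if (!any(keep)) stop("region [", region$lo, ",", region$hi,
                       "] does not overlap the wavelength grid")
  replace_reflectance(ds, ds$reflectance[, keep, drop = FALSE],
                      transform = paste0("crop[", region$lo, ",", region$hi, "]"),
                      wavelengths = ds$wavelengths[keep])
}

#' Slice a (possibly transformed) dataset to a named region
#'
#' Identical band selection to [crop_bands()]; provided as a separate verb
#' because slicing is applied after transforms when building per-region
#' diagnostics.
#'
#' @inheritParams crop_bands
#' @return The sliced `spectral_dataset`.
#' @export
slice_region <- function(ds, region) crop_bands(ds, region)

sg_matrix <- function(n_bands, window, polyorder) {
  # full n x n smoothing operator: interior rows apply the central SG
  # kernel, the first/last half-window rows use the boundary rows of the
  # sgolay projection matrix (polynomial fit over the edge window).
  F <- signal::sgolay(p = polyorder, n = window)
  F <- unclass(F)
  k <- (window - 1) %/% 2
  S <- matrix(0, n_bands, n_bands)
  for (i in seq_len(k)) S[i, 1:window] <- F[i, ]
  centre <- F[k + 1, ]
  for (i in (k + 1):(n_bands - k)) S[i, (i - k):(i + k)] <- centre
  for (j in seq_len(k)) S[n_bands - k + j, (n_bands - window + 1):n_bands] <- F[k + 1 + j, ]
  S
}

#' Savitzky-Golay smoothing
#'
#' Replaces each spectrum by its local least-squares polynomial fit,
#' improving signal-to-noise while preserving band shapes (window 11,
#' quadratic by default — mild smoothing that keeps the red-edge slope).
#'
#' @param ds A `spectral_dataset`.
#' @param window Odd integer window length (bands), `polyorder < window <=
#'   n_bands`.
#' @param polyorder Polynomial order of the local fit.
#' @return The smoothed `spectral_dataset`.
#' @export
sg_smooth <- function(ds, window = 11L, polyorder = 2L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (window > n_bands(ds)) stop("window exceeds the number of bands")
  S <- sg_matrix(n_bands(ds), window, polyorder)
  replace_reflectance(ds, tcrossprod(ds$reflectance, S),
                      transform = sprintf("SG(w=%d,p=%d)", window, polyorder))
}

upper_hull_idx <- function(x, y) {
  # Upper convex hull over points ordered by x; endpoints always kept.
  # grDevices::chull (C code) prunes to the full hull first, then a short
  # monotone-chain pass keeps the upper chain only.
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  cand <- sort(unique(c(1L, n, grDevices::chull(x, y))))
  cx <- x[cand]; cy <- y[cand]
  keep <- integer(0)
  for (i in seq_along(cand)) {
    while (length(keep) >= 2) {
      a <- keep[length(keep) - 1]; b <- keep[length(keep)]
      # pop b if it lies on or below the chord a -> i (non-right turn)
      cr <- (cx[b] - cx[a]) * (cy[i] - cy[a]) - (cy[b] - cy[a]) * (cx[i] - cx[a])
      if (cr >= 0) keep <- keep[-length(keep)] else break
    }
    keep <- c(keep, i)
  }
  cand[keep]
}

#' Continuum removal
#'
#' Divides each spectrum by the linear interpolation of its upper convex
#' hull over (wavelength, reflectance), isolating absorption features.
#' Outputs lie in (0, 1] and equal 1 exactly at hull vertices (both grid
#' endpoints are always hull vertices).
#'
#' @param ds A `spectral_dataset` with strictly positive reflectance.
#' @return The continuum-removed `spectral_dataset`.
#' @export
continuum_removal <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (any(ds$reflectance <= 0))
    stop("continuum removal requires strictly positive reflectance")
  w <- ds$wavelengths
  out <- ds$reflectance
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    h <- upper_hull_idx(w, r)
    cont <- approx(w[h], r[h], xout = w)$y
    out[i, ] <- r / cont
  }
  replace_reflectance(ds, pmin(out, 1), transform = "CR")
}

#' Standard normal variate transform
#'
#' Standardises each spectrum to mean 0 and (sample, n-1) standard
#' deviation 1, removing multiplicative scatter and additive baseline
#' effects — in particular any affine brightness change.
#'
#' @param ds A `spectral_dataset`; every spectrum must be nonconstant.
#' @return The SNV-transformed `spectral_dataset`.
#' @export
snv_transform <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  mu <- rowMeans(ds$reflectance)
  centred <- ds$reflectance - mu
  sds <- sqrt(rowSums(centred^2) / (ncol(centred) - 1))
  if (any(sds == 0)) stop("SNV undefined for constant spectra")
  replace_reflectance(ds, centred / sds, transform = "SNV")
}

#' First derivative transform
#'
#' Numerical first derivative with respect to wavelength (units nm^-1):
#' central differences at interior bands, one-sided differences at the two
#' ends, so the band count is preserved. Requires a uniform grid.
#'
#' @param ds A `spectral_dataset` with >= 3 bands on a uniform grid.
#' @return The derivative `spectral_dataset`.
#' @export
first_derivative <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  w <- ds$wavelengths
  p <- length(w)
  if (p < 3) stop("first derivative needs at least 3 bands")
  steps <- diff(w)
  if (max(steps) - min(steps) > 1e-8) stop("first derivative requires a uniform grid")
  d <- steps[1]
  R <- ds$reflectance
  out <- matrix(0, nrow(R), p)
  out[, 2:(p - 1)] <- (R[, 3:p, drop = FALSE] - R[, 1:(p - 2), drop = FALSE]) / (2 * d)
  out[, 1] <- (R[, 2] - R[, 1]) / d
  out[, p] <- (R[, p] - R[, p - 1]) / d
  replace_reflectance(ds, out, transform = "FD")
}

#' Run the standard preprocessing pipeline
#'
#' crop to 400-900 nm, Savitzky-Golay smooth, then branch into the three
#' parallel transforms: continuum removal (CR), standard normal variate
#' (SNV) and first derivative (FD).
#'
#' @param ds A `spectral_dataset`.
#' @param window,polyorder Savitzky-Golay parameters.
#' @return A named list with elements `base` (cropped + smoothed), `CR`,
#'   `SNV`, `FD`.
#' @export
preprocess_branches <- function(ds, window = 11L, polyorder = 2L) {
  base <- sg_smooth(crop_bands(ds, spectral_region("full")), window, polyorder)
  # smoothing can graze zero on dark spectra; continuum removal needs > 0
  cr_base <- base
  cr_base$reflectance <- pmax(cr_base$reflectance, 1e-6)
  list(base = base,
       CR = continuum_removal(cr_base),
       SNV = snv_transform(base),
       FD = first_derivative(base))
}
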