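# Simulated source domain: Latin-hypercube sampling of a parameter space,
# a self-contained surrogate forward model mapping (chlorophyll,
# structure) to canopy reflectance, lookup-table construction, and the
# SPAD-to-chlorophyll calibration.

#' Forward-model parameter space
#'
#' Named `[lo, hi]` bounds for the surrogate forward model: `cab` (leaf
#' chlorophyll a+b, ug/cm^2), `s0` (visible albedo floor), `s1` (NIR
#' plateau amplitude), `w_re` (red-edge logistic width, nm) and
#' `noise_sd` (iid spectral noise sd). The `cab` range covers the
#' synthetic campaign's chlorophyll range.
#'
#' @param cab,s0,s1,w_re,noise_sd Length-2 numeric bounds `c(lo, hi)`.
#' @return An object of class `parameter_space` (named list of bounds).
#' @export
parameter_space <- function(cab = c(15, 55), s0 = c(0.02, 0.06),
                            s1 = c(0.30, 0.60), w_re = c(15, 25),
                            noise_sd = c(0, 0.005)) {
  space <- list(cab = cab, s0 = s0, s1 = s1, w_re = w_re, noise_sd = noise_sd)
  for (nm in names(space)) {
    b <- as.numeric(space[[nm]])
    if (length(b) != 2 || !(b[1] < b[2]))
      stop("parameter ", nm, " needs bounds c(lo, hi) with lo < hi")
    space[[nm]] <- b
  }
  structure(space, class = "parameter_space")
}

#' Latin hypercube sample of a parameter space
#'
#' Stratified sampling: for every parameter, exactly one draw falls in
#' each of the `n` equal-width strata of its range (uniform jitter within
#' the stratum), with stratum order randomised independently per
#' parameter (via \pkg{lhs}).
#'
#' @param space A `parameter_space`.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; same seed, same matrix.
#' @return Numeric matrix `n x n_params` with parameter names as columns.
#' @export
sample_lhs <- function(space, n, seed = 1L) {
  stopifnot(inherits(space, "parameter_space"))
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  u <- lhs::randomLHS(as.integer(n), length(space))
  out <- sapply(seq_along(space), function(j) {
    b <- space[[j]]
    b[1] + u[, j] * (b[2] - b[1])
  })
  out <- matrix(out, nrow = n)
  colnames(out) <- names(space)
  out
}

# fixed surrogate constants: absorption coefficients (cm^2/ug) and
# Gaussian absorption-band widths (nm) for the blue and red chlorophyll
# absorption features; red-edge centre drifts upward with cab.
SURROGATE_CONST <- list(k_b = 0.020, k_r = 0.025, sigma_b = 25, sigma_r = 30,
                        blue_centre = 450, red_centre = 670,
                        redge_base = 700, redge_slope = 0.2)

#' Surrogate forward model: parameters to reflectance
#'
#' A compact chlorophyll-to-reflectance model keeping the two structures
#' an inversion exploits: the red absorption deepens with `cab`, and the
#' red-edge inflection point moves to longer wavelengths with `cab`.
#' Reflectance on the 400-900 nm grid:
#' \deqn{R(\lambda) = [s_0 + s_1\,\sigma((\lambda-\lambda_{re})/w_{re})]
#'   \exp\{-cab\,[k_b g(\lambda;450,\sigma_b) + k_r g(\lambda;670,\sigma_r)]\}
#'   + \epsilon(\lambda)}
#' with logistic \eqn{\sigma}, unit-height Gaussians `g`,
#' \eqn{\lambda_{re} = 700 + 0.2\,cab} nm, \eqn{k_b = 0.020},
#' \eqn{k_r = 0.025} cm^2/ug, and iid Gaussian noise; output clipped to
#' (0, 1). Any callable with the same `params -> spectrum` contract (e.g.
#' a PROSAIL binding) can replace it wherever a forward model is accepted.
#'
#' @param params Named numeric vector/list with `cab`, `s0`, `s1`, `w_re`,
#'   `noise_sd` (see [parameter_space()]); values must lie within `space`.
#' @param wavelengths Wavelength grid (nm), default `400:900`.
#' @param space Bounds to validate against (default [parameter_space()]).
#' @param k_r_scale Multiplier on the red absorption coefficient; the
#'   synthetic campaign uses it to realise a condition-dependent
#'   spectrum-chlorophyll mapping shift.
#' @return A `spectral_sample`-style list, here returned as a one-row
#'   `spectral_dataset` with `chlorophyll = cab` and condition
#'   `RESERVED_SOURCE`.
#' @export
surrogate_forward <- function(params, wavelengths = 400:900,
                              space = parameter_space(), k_r_scale = 1) {
  p <- as.list(params)
  for (nm in names(space)) {
    if (is.null(p[[nm]])) stop("missing parameter: ", nm)
    b <- space[[nm]]
    if (p[[nm]] < b[1] - 1e-12 || p[[nm]] > b[2] + 1e-12)
      stop("parameter ", nm, " = ", p[[nm]], " outside bounds [", b[1], ", ", b[2], "]")
  }
  refl <- surrogate_reflectance(wavelengths, p$cab, p$s0, p$s1, p$w_re,
                                p$noise_sd, k_r_scale)
  spectral_dataset(wavelengths, matrix(refl, 1), condition = RESERVED_SOURCE,
                   chlorophyll = p$cab, plant_id = "surrogate_1")
}

# vectorised core: cab, s0, s1, w_re, noise_sd may be vectors (one row per
# sample); returns n x length(wavelengths) matrix.
surrogate_reflectance <- function(wavelengths, cab, s0, s1, w_re,
                                  noise_sd = 0, k_r_scale = 1) {
  K <- SURROGATE_CONST
  w <- as.numeric(wavelengths)
  n <- max(length(cab), 1)
  g_b <- exp(-(w - K$blue_centre)^2 / (2 * K$sigma_b^2))
  g_r <- exp(-(w - K$red_centre)^2 / (2 * K$sigma_r^2))
  lam_re <- K$redge_base + K$redge_slope * cab
  # rows are samples: column-major recycling applies lam_re / w_re per row
  sig <- plogis((matrix(w, n, length(w), byrow = TRUE) - lam_re) / w_re)
  base <- s0 + s1 * sig
  absorb <- exp(-cab %o% (K$k_b * g_b) - (k_r_scale * cab) %o% (K$k_r * g_r))
  R <- base * absorb
  if (any(noise_sd > 0)) {
    R <- R + matrix(rnorm(n * length(w), 0, rep(noise_sd, length.out = n)),
                    n, length(w))
  }
  pmin(pmax(R, 1e-6), 1 - 1e-6)
}

#' Build a lookup table of simulated (spectrum, chlorophyll) pairs
#'
#' Latin-hypercube samples the parameter space and runs the forward model
#' for each row, producing the source domain for domain-adaptive
#' inversion: a `spectral_dataset` on the 400-900 nm grid whose rows carry
#' the sampled `cab` as chlorophyll and the `RESERVED_SOURCE` condition.
#'
#' @param space A `parameter_space`.
#' @param n Number of table rows (>= 2).
#' @param seed Integer seed.
#' @param forward Forward model; either the default vectorised surrogate
#'   or any function `(params_row, wavelengths) -> numeric spectrum`.
#' @return An object of class `lookup_table`: list with `spectra`
#'   (`spectral_dataset`), `chlorophyll` and the sampled `parameters`
#'   matrix.
#' @export
build_lut <- function(space = parameter_space(), n = 5000L, seed = 1L,
                      forward = NULL) {
  if (n < 2) stop("lookup table needs n >= 2")
  pars <- sample_lhs(space, n, seed = derive_seed(seed, "lhs"))
  w <- 400:900
  set.seed(derive_seed(seed, "forward-noise"))
  if (is.null(forward)) {
    R <- surrogate_reflectance(w, pars[, "cab"], pars[, "s0"], pars[, "s1"],
                               pars[, "w_re"], pars[, "noise_sd"])
  } else {
    R <- t(apply(pars, 1, function(row) forward(row, w)))
  }
  ds <- spectral_dataset(w, R, condition = RESERVED_SOURCE,
                         chlorophyll = pars[, "cab"],
                         plant_id = sprintf("src_%05d", seq_len(n)))
  structure(list(spectra = ds, chlorophyll = pars[, "cab"], parameters = pars),
            class = "lookup_table")
}

#' SPAD to absolute chlorophyll conversion
#'
#' Nonlinear calibration from relative SPAD meter readings to absolute
#' chlorophyll density (ug/cm^2), derived for tropical tree species:
#' \deqn{CHL = 117.1 \cdot SPAD / (148.84 - SPAD)}
#' Strictly increasing on its domain `0 <= SPAD < 148.84`.
#'
#' @param spad Numeric SPAD value(s).
#' @return Chlorophyll content in ug/cm^2.
#' @export
#' @examples
#' spad_to_chl(50)  # 59.237
spad_to_chl <- function(spad) {
  if (any(spad < 0) || any(spad >= 148.84))
    stop("SPAD must lie in [0, 148.84)")
  117.1 * spad / (148.84 - spad)
}
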