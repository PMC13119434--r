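# Synthetic shaded field campaign: four shading conditions with both a
# marginal spectral shift (brightness, diffuse offset, tilt, noise) and a
# conditional mapping shift (condition-dependent red absorption
# sensitivity), emulating a measured target domain.

#' Per-condition shift configuration
#'
#' Defaults encode the study conditions the generator emulates: mean
#' chlorophyll increases from full sun (S1) to heavy shade (S4) —
#' 28.463, 31.238, 34.226, 36.681 ug/cm^2 — while incident brightness
#' decreases, the diffuse-light offset and spectral tilt grow, the noise
#' level rises, and the red-absorption sensitivity of the
#' spectrum-chlorophyll mapping weakens (multiplier `gamma` on the red
#' absorption coefficient: the conditional mapping shift).
#'
#' @param chl_mean Per-condition mean chlorophyll (strictly increasing).
#' @param chl_sd Per-condition chlorophyll sd (scalar recycled).
#' @param brightness Multiplicative brightness `a_c` (strictly decreasing).
#' @param diffuse Additive diffuse offset `b_c`.
#' @param tilt Wavelength tilt `t_c` of the diffuse term.
#' @param noise_sd Additive spectral noise sd per condition.
#' @param gamma Red-absorption multiplier `gamma_c` (mapping shift).
#' @return An object of class `condition_shift_config`.
#' @export
condition_shift_config <- function(chl_mean = c(28.463, 31.238, 34.226, 36.681),
                                   chl_sd = 4.0,
                                   brightness = c(1.00, 0.85, 0.65, 0.45),
                                   diffuse = c(0.000, 0.005, 0.010, 0.015),
                                   tilt = c(0, 0.05, 0.10, 0.15),
                                   noise_sd = c(0.002, 0.003, 0.004, 0.006),
                                   gamma = c(1.00, 0.95, 0.90, 0.85)) {
  chl_sd <- rep(chl_sd, length.out = 4)
  cfg <- list(chl_mean = chl_mean, chl_sd = chl_sd, brightness = brightness,
              diffuse = diffuse, tilt = tilt, noise_sd = noise_sd, gamma = gamma)
  for (nm in names(cfg)) {
    if (length(cfg[[nm]]) != 4) stop(nm, " must have one value per condition S1..S4")
  }
  if (any(diff(chl_mean) <= 0)) stop("chl_mean must be strictly increasing S1 -> S4")
  if (any(diff(brightness) >= 0)) stop("brightness must be strictly decreasing S1 -> S4")
  if (any(chl_sd < 0) || any(cfg$noise_sd < 0)) stop("sds must be nonnegative")
  for (nm in names(cfg)) names(cfg[[nm]]) <- CONDITION_LEVELS
  structure(cfg, class = "condition_shift_config")
}

#' Read a condition-shift configuration from YAML
#'
#' @param path YAML file whose keys match [condition_shift_config()]
#'   arguments.
#' @return A `condition_shift_config`.
#' @export
read_condition_config <- function(path) {
  do.call(condition_shift_config, yaml::read_yaml(path))
}

#' Apply a condition's illumination transform to spectra
#'
#' The shading-dependent illumination operator on the 400-900 nm grid:
#' \deqn{R'(\lambda) = a_c R(\lambda) + b_c (1 + t_c (\lambda - 650)/250)
#'   + \eta(\lambda)}
#' with iid Gaussian noise `eta` of sd `nu_c`, clipped to (0, 1). The
#' returned dataset carries condition label `condition`.
#'
#' @param ds A `spectral_dataset` on the 400-900 nm grid.
#' @param condition One of `"S1".."S4"`.
#' @param config A `condition_shift_config`.
#' @param seed Integer seed for the noise draw.
#' @return The transformed `spectral_dataset`.
#' @export
apply_illumination <- function(ds, condition, config = condition_shift_config(),
                               seed = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"),
            inherits(config, "condition_shift_config"))
  if (!(condition %in% CONDITION_LEVELS))
    stop("unknown condition label: ", condition)
  w <- ds$wavelengths
  if (min(w) < 400 || max(w) > 900)
    stop("illumination transform is defined on the 400-900 nm grid")
  a <- config$brightness[[condition]]
  b <- config$diffuse[[condition]]
  tl <- config$tilt[[condition]]
  nu <- config$noise_sd[[condition]]
  base <- b * (1 + tl * (w - 650) / 250)
  R <- a * ds$reflectance + matrix(base, n_samples(ds), length(w), byrow = TRUE)
  if (nu > 0) {
    set.seed(seed)
    R <- R + matrix(rnorm(length(R), 0, nu), nrow(R), ncol(R))
  }
  out <- replace_reflectance(ds, pmin(pmax(R, 1e-6), 1 - 1e-6),
                             transform = paste0("illum[", condition, "]"))
  out$meta$condition <- condition
  out
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * n, mean, sd)
    out <- c(out, draw[draw > lo & draw < hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic shaded field campaign
#'
#' For each condition S1..S4: draw chlorophyll from a truncated normal
#' (bounds 5-80 ug/cm^2) around the condition's mean, draw structural
#' parameters by Latin hypercube, run the surrogate forward model with
#' the condition's red-absorption multiplier `gamma_c` (the conditional
#' mapping shift), then apply the condition's illumination transform (the
#' marginal shift). Plant ids are unique across the campaign; the default
#' size, 79 plants per condition, gives a campaign of 316 plants.
#'
#' @param config A `condition_shift_config`.
#' @param n_per_condition Plants per condition (>= 2), default 79.
#' @param space A `parameter_space` for the structural draws.
#' @param seed Integer master seed.
#' @return A `spectral_dataset` of `4 * n_per_condition` samples on the
#'   400-900 nm grid.
#' @export
generate_campaign <- function(config = condition_shift_config(),
                              n_per_condition = 79L,
                              space = parameter_space(), seed = 1L) {
  stopifnot(inherits(config, "condition_shift_config"))
  if (n_per_condition < 2) stop("n_per_condition must be >= 2")
  n <- as.integer(n_per_condition)
  w <- 400:900
  parts <- list()
  for (ci in seq_along(CONDITION_LEVELS)) {
    cond <- CONDITION_LEVELS[ci]
    set.seed(derive_seed(seed, paste0("chl/", cond)))
    chl <- rtruncnorm(n, config$chl_mean[[cond]], config$chl_sd[[cond]], 5, 80)
    pars <- sample_lhs(space, n, seed = derive_seed(seed, paste0("lhs/", cond)))
    # structural params from LHS; forward-model noise off - all
    # measurement noise enters through the illumination operator
    R <- surrogate_reflectance(w, chl, pars[, "s0"], pars[, "s1"],
                               pars[, "w_re"], noise_sd = 0,
                               k_r_scale = config$gamma[[cond]])
    ds <- spectral_dataset(w, R, condition = cond, chlorophyll = chl,
                           plant_id = sprintf("%s_%03d", cond, seq_len(n)))
    parts[[ci]] <- apply_illumination(ds, cond, config,
                                      seed = derive_seed(seed, paste0("illum/", cond)))
  }
  bind_spectral(parts)
}

#' Row-bind spectral datasets sharing one grid
#' @param ds_list List of `spectral_dataset`s on identical grids.
#' @return A combined `spectral_dataset`.
#' @export
bind_spectral <- function(ds_list) {
  w <- ds_list[[1]]$wavelengths
  for (d in ds_list) {
    if (!isTRUE(all.equal(d$wavelengths, w))) stop("datasets must share one grid")
  }
  spectral_dataset(
    w, do.call(rbind, lapply(ds_list, `[[`, "reflectance")),
    condition = unlist(lapply(ds_list, function(d) d$meta$condition)),
    chlorophyll = unlist(lapply(ds_list, function(d) d$meta$chlorophyll)),
    plant_id = unlist(lapply(ds_list, function(d) d$meta$plant_id)),
    campaign = ds_list[[1]]$meta$campaign[1]
  )
}

#' Subset a spectral dataset by row index or plant id
#' @param ds A `spectral_dataset`.
#' @param idx Integer indices or character plant ids.
#' @return The subset `spectral_dataset`.
#' @export
subset_spectral <- function(ds, idx) {
  if (is.character(idx)) idx <- match(idx, ds$meta$plant_id)
  if (anyNA(idx)) stop("unknown plant id(s)")
  spectral_dataset(ds$wavelengths, ds$reflectance[idx, , drop = FALSE],
                   condition = ds$meta$condition[idx],
                   chlorophyll = ds$meta$chlorophyll[idx],
                   plant_id = ds$meta$plant_id[idx],
                   campaign = ds$meta$campaign[1],
                   transforms = ds$transforms)
}
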