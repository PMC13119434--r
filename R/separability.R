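# Separability diagnostics: how strongly the shading condition structures
# the (transformed, region-sliced) spectra. Band-wise Fisher discriminant
# ratio profiles and PERMANOVA on Euclidean distances.

#' Band-wise Fisher discriminant ratio profile
#'
#' For every band, the ratio of weighted between-class scatter to weighted
#' within-class scatter across condition groups:
#' \deqn{FDR = \sum_g n_g (\mu_g - \bar\mu)^2 / \sum_g n_g s_g^2}
#' with group sample variances \eqn{s_g^2} (n-1 denominator) and the grand
#' mean \eqn{\bar\mu}. Zero within-class scatter at a band yields `Inf`
#' with a warning.
#'
#' @param ds A `spectral_dataset`.
#' @param labels Condition label per sample (default: the dataset's
#'   condition column). At least 2 groups with >= 2 samples each.
#' @return An object of class `fdr_profile`: list with `wavelengths`,
#'   `fdr` and `group_sizes`.
#' @export
band_fdr <- function(ds, labels = ds$meta$condition) {
  stopifnot(inherits(ds, "spectral_dataset"))
  labels <- as.character(labels)
  if (length(labels) != n_samples(ds)) stop("labels length must match samples")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("band_fdr needs at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  R <- ds$reflectance
  grand <- colMeans(R)
  between <- numeric(ncol(R)); within <- numeric(ncol(R))
  for (g in names(sizes)) {
    Rg <- R[labels == g, , drop = FALSE]
    ng <- nrow(Rg)
    mg <- colMeans(Rg)
    between <- between + ng * (mg - grand)^2
    within <- within + ng * colSums((Rg - rep(mg, each = ng))^2) / (ng - 1)
  }
  fdr <- ifelse(within == 0 & between > 0, Inf, between / pmax(within, .Machine$double.xmin))
  fdr[within == 0 & between == 0] <- 0
  if (any(is.infinite(fdr)))
    warning("zero within-class scatter at ", sum(is.infinite(fdr)), " band(s); FDR reported as Inf")
  structure(list(wavelengths = ds$wavelengths, fdr = as.numeric(fdr),
                 group_sizes = as.integer(sizes)),
            class = "fdr_profile")
}

#' PERMANOVA on spectra
#'
#' Permutational multivariate analysis of variance over Euclidean
#' distances between the (transformed, region-sliced) spectra. Sums of
#' squares follow the pairwise-distance identities
#' \eqn{SS_{tot} = \frac{1}{n}\sum_{i<j} d_{ij}^2} and
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2};
#' the pseudo-F statistic is
#' \eqn{(SS_{between}/(a-1)) / (SS_{within}/(n-a))} for `a` groups.
#' The permutation p-value uses the `(1 + c)/(B + 1)` convention, so its
#' attainable minimum with 999 permutations is exactly 0.001. The effect
#' size is `r2_perm = SS_between / SS_total` and is invariant to a global
#' rescaling of the spectra (pseudo-F is scale-dependent only through the
#' distances, which cancel in the ratio as well; r2 invariance is the
#' asserted property).
#'
#' @param ds A `spectral_dataset` (or a numeric matrix of row vectors).
#' @param labels Group label per sample; at least 2 groups.
#' @param n_perm Number of label permutations (>= 1), default 999.
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `permanova_result`: `pseudo_f`, `p_perm`,
#'   `r2_perm`, `n_perm`, `seed`, plus the sums of squares.
#' @export
permanova <- function(ds, labels = NULL, n_perm = 999L, seed = 1L) {
  X <- if (inherits(ds, "spectral_dataset")) ds$reflectance else as.matrix(ds)
  if (is.null(labels)) {
    if (!inherits(ds, "spectral_dataset")) stop("labels required for matrix input")
    labels <- ds$meta$condition
  }
  labels <- as.character(labels)
  n <- nrow(X)
  if (length(labels) != n) stop("labels length must match samples")
  groups <- unique(labels)
  a <- length(groups)
  if (a < 2) stop("permanova needs at least 2 groups")
  if (n_perm < 1) stop("n_perm must be >= 1")
  D2 <- as.matrix(dist(X))^2
  if (all(D2 == 0)) stop("all pairwise distances are zero; pseudo-F undefined")
  ss_total <- sum(D2) / (2 * n)

  ss_within_for <- function(lab) {
    s <- 0
    for (g in groups) {
      idx <- which(lab == g)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  pseudo_f_for <- function(ssw) ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))

  ssw_obs <- ss_within_for(labels)
  if (ssw_obs == 0) stop("zero within-group distances; pseudo-F undefined")
  f_obs <- pseudo_f_for(ssw_obs)

  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    f_b <- pseudo_f_for(ss_within_for(sample(labels)))
    if (f_b >= f_obs) count <- count + 1L
  }
  structure(list(
    pseudo_f = f_obs,
    p_perm = (1 + count) / (n_perm + 1),
    r2_perm = (ss_total - ssw_obs) / ss_total,
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    ss_total = ss_total, ss_within = ssw_obs,
    ss_between = ss_total - ssw_obs,
    df_between = a - 1L, df_within = n - a
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, p_perm = %.4g, R2_perm = %.3f (%d permutations)\n",
              x$pseudo_f, x$p_perm, x$r2_perm, x$n_perm))
  invisible(x)
}

#' Separability table across transforms and regions
#'
#' Runs PERMANOVA for each preprocessing branch (CR, SNV, FD) restricted
#' to each named region (green peak, red edge), producing one row per
#' (transform, region) with pseudo-F, p and R2.
#'
#' @param ds A raw `spectral_dataset` on (at least) the 400-900 nm grid.
#' @param regions List of `spectral_region` objects.
#' @param n_perm Permutations per test.
#' @param seed Master seed; each cell derives its own stream.
#' @return A data frame with columns `transform`, `region`, `pseudo_f`,
#'   `p_perm`, `r2_perm`.
#' @export
separability_table <- function(ds, regions = list(spectral_region("green_peak"),
                                                  spectral_region("red_edge")),
                               n_perm = 999L, seed = 1L) {
  br <- preprocess_branches(ds)
  rows <- list()
  for (tr in c("CR", "SNV", "FD")) {
    for (rg in regions) {
      res <- permanova(slice_region(br[[tr]], rg),
                       n_perm = n_perm,
                       seed = derive_seed(seed, paste0("permanova/", tr, "/", rg$name)))
      rows[[length(rows) + 1]] <- data.frame(
        transform = tr, region = rg$name, pseudo_f = res$pseudo_f,
        p_perm = res$p_perm, r2_perm = res$r2_perm)
    }
  }
  do.call(rbind, rows)
}
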