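# Loss components of the domain-adaptive model: CORAL, target-conditioned
# CORAL, heteroscedastic negative log-likelihood, and condition-level
# uncertainty weighting. Each has an internal *_grad companion returning
# analytic gradients for the training loop (verified against finite
# differences in the tests).

centred <- function(Z) sweep(Z, 2, colMeans(Z))

batch_cov <- function(Z) {
  # 1/(n-1) covariance, the original CORAL convention
  n <- nrow(Z)
  crossprod(centred(Z)) / (n - 1)
}

#' CORAL loss between two feature batches
#'
#' Correlation alignment: the squared Frobenius distance between the two
#' batch covariance matrices, scaled by the feature dimension,
#' \deqn{L = \|C_s - C_t\|_F^2 / (4 d^2)}
#' with `1/(n-1)` covariances. Symmetric in its arguments and invariant
#' to adding a constant vector to either batch.
#'
#' @param Zs,Zt Numeric matrices (rows = samples, shared column dimension
#'   `d`), each with >= 2 rows.
#' @return Nonnegative scalar loss.
#' @export
coral_loss <- function(Zs, Zt) {
  Zs <- as.matrix(Zs); Zt <- as.matrix(Zt)
  if (nrow(Zs) < 2 || nrow(Zt) < 2) stop("CORAL needs >= 2 rows per batch")
  if (ncol(Zs) != ncol(Zt)) stop("batches must share the feature dimension")
  d <- ncol(Zs)
  D <- batch_cov(Zs) - batch_cov(Zt)
  sum(D^2) / (4 * d^2)
}

coral_grad <- function(Zs, Zt) {
  d <- ncol(Zs)
  D <- batch_cov(Zs) - batch_cov(Zt)
  list(value = sum(D^2) / (4 * d^2),
       d_Zs = centred(Zs) %*% D / (d^2 * (nrow(Zs) - 1)),
       d_Zt = -centred(Zt) %*% D / (d^2 * (nrow(Zt) - 1)))
}

#' Target-conditioned CORAL loss
#'
#' Aligns the global source-batch covariance to each target condition's
#' covariance separately and averages over the conditions actually
#' aligned:
#' \deqn{L = \frac{1}{|C|} \sum_{c \in C} \|C_s - C_t^c\|_F^2 / (4 d^2)}
#' Conditions with fewer than 2 rows in the batch are skipped; if no
#' condition has >= 2 rows, alignment is skipped with a warning and the
#' loss is 0. With a single target condition this reduces exactly to
#' [coral_loss()].
#'
#' @param Zs Source feature batch (>= 2 rows).
#' @param Zt Target feature batch.
#' @param target_conditions Condition label per target row.
#' @return Nonnegative scalar loss.
#' @export
tc_coral_loss <- function(Zs, Zt, target_conditions) {
  tc_coral_grad(Zs, Zt, target_conditions, want_grad = FALSE)$value
}

tc_coral_grad <- function(Zs, Zt, target_conditions, want_grad = TRUE) {
  Zs <- as.matrix(Zs); Zt <- as.matrix(Zt)
  if (nrow(Zs) < 2) stop("CORAL needs >= 2 source rows")
  if (ncol(Zs) != ncol(Zt)) stop("batches must share the feature dimension")
  target_conditions <- as.character(target_conditions)
  if (length(target_conditions) != nrow(Zt))
    stop("one condition label per target row required")
  d <- ncol(Zs)
  conds <- unique(target_conditions)
  conds <- conds[vapply(conds, function(c) sum(target_conditions == c) >= 2, logical(1))]
  if (!length(conds)) {
    warning("no target condition has >= 2 rows; alignment skipped")
    return(list(value = 0,
                d_Zs = matrix(0, nrow(Zs), d), d_Zt = matrix(0, nrow(Zt), d)))
  }
  Cs <- batch_cov(Zs)
  Zsc <- centred(Zs)
  val <- 0
  d_Zs <- matrix(0, nrow(Zs), d)
  d_Zt <- matrix(0, nrow(Zt), d)
  for (cc in conds) {
    idx <- which(target_conditions == cc)
    Ztc <- Zt[idx, , drop = FALSE]
    D <- Cs - batch_cov(Ztc)
    val <- val + sum(D^2) / (4 * d^2)
    if (want_grad) {
      d_Zs <- d_Zs + Zsc %*% D / (d^2 * (nrow(Zs) - 1))
      d_Zt[idx, ] <- d_Zt[idx, ] - centred(Ztc) %*% D / (d^2 * (length(idx) - 1))
    }
  }
  list(value = val / length(conds),
       d_Zs = d_Zs / length(conds), d_Zt = d_Zt / length(conds))
}

#' Heteroscedastic negative log-likelihood
#'
#' Per-sample loss \eqn{l_i = e^{-\log\sigma_i^2}(y_i-\mu_i)^2 +
#' \log\sigma_i^2}, averaged over the batch:
#' \deqn{L = \frac{1}{N}\sum_i e^{-\log\sigma_i^2}(y_i-\mu_i)^2 +
#'   \log\sigma_i^2}
#' With `log_var = 0` this equals the mean squared error. The loss can be
#' negative through the log term; its minimum over `log_var` at fixed
#' residual `r` is attained at `log_var = log r^2` with value
#' `1 + log r^2`.
#'
#' @param mu Predicted means.
#' @param log_var Predicted log-variances (same length).
#' @param y Observed values.
#' @param reduce If `FALSE`, return the per-sample losses `l_i`.
#' @return Scalar mean loss (or per-sample vector).
#' @export
het_nll <- function(mu, log_var, y, reduce = TRUE) {
  if (length(mu) != length(y) || length(log_var) != length(y))
    stop("mu, log_var and y must have equal length")
  if (!all(is.finite(mu)) || !all(is.finite(log_var)) || !all(is.finite(y)))
    stop("non-finite inputs to het_nll")
  l <- exp(-log_var) * (y - mu)^2 + log_var
  if (reduce) mean(l) else l
}

het_nll_grad <- function(mu, log_var, y) {
  r <- y - mu
  e <- exp(-log_var)
  list(per_sample = e * r^2 + log_var,
       d_mu = -2 * e * r,      # gradient of l_i w.r.t. mu_i
       d_log_var = 1 - e * r^2)
}

#' Condition-level uncertainty-weighted loss
#'
#' Aggregates per-sample losses by condition with one learnable
#' log-precision per target condition:
#' \deqn{L_t = \sum_{c} e^{-\log v_c}\,\mathrm{mean}_{i \in c}(l_i) +
#'   \log v_c}
#' summed over the conditions present in the batch. Its minimum over
#' `log_v` for a condition with mean loss `m` is at `log v = log m` with
#' contribution `1 + log m`; the gradient w.r.t. `log v_c` is
#' `1 - exp(-log v_c) * mean_c(l)`.
#'
#' @param losses Per-sample losses `l_i`.
#' @param conditions Condition label per sample.
#' @param log_v Named numeric vector of per-condition log-weights; every
#'   condition present must have an entry.
#' @return Scalar loss (may be negative through the log terms).
#' @export
condition_weighted_loss <- function(losses, conditions, log_v) {
  condition_weighted_grad(losses, conditions, log_v)$value
}

condition_weighted_grad <- function(losses, conditions, log_v) {
  conditions <- as.character(conditions)
  if (length(losses) != length(conditions))
    stop("one condition per loss required")
  present <- unique(conditions)
  missing <- setdiff(present, names(log_v))
  if (length(missing))
    stop("no weight entry for condition(s): ", paste(missing, collapse = ", "))
  val <- 0
  d_l <- numeric(length(losses))
  d_log_v <- setNames(numeric(length(log_v)), names(log_v))
  for (cc in present) {
    idx <- which(conditions == cc)
    m <- mean(losses[idx])
    w <- exp(-log_v[[cc]])
    val <- val + w * m + log_v[[cc]]
    d_l[idx] <- w / length(idx)
    d_log_v[cc] <- 1 - w * m
  }
  list(value = val, d_losses = d_l, d_log_v = d_log_v)
}

#' Total training loss of a model variant
#'
#' Combines the task loss and the alignment term according to the
#' variant's switches: ResDNN uses plain MSE; GAI adds global CORAL; CA
#' and CA-IE add target-conditioned CORAL; CAI-DAI replaces the task loss
#' by condition-weighted heteroscedastic losses and adds
#' target-conditioned CORAL. The alignment term enters with weight
#' `align_weight`.
#'
#' @param config A [variant_config()].
#' @param mu,y Predictions and targets for the task batch.
#' @param log_var Predicted log-variances (CAI-DAI only).
#' @param conditions Target-batch condition labels (conditional variants).
#' @param Zs,Zt Source/target latent batches (alignment variants).
#' @param log_v Named per-condition log-weights (CAI-DAI only).
#' @return Scalar loss.
#' @export
total_loss <- function(config, mu, y, log_var = NULL, conditions = NULL,
                       Zs = NULL, Zt = NULL, log_v = NULL) {
  stopifnot(inherits(config, "variant_config"))
  task <- if (config$het) {
    if (is.null(log_var) || is.null(log_v) || is.null(conditions))
      stop("CAI-DAI needs log_var, conditions and log_v")
    condition_weighted_loss(het_nll(mu, log_var, y, reduce = FALSE),
                            conditions, log_v)
  } else {
    mean((y - mu)^2)
  }
  align <- 0
  if (config$align != "none" && config$align_weight != 0) {
    if (is.null(Zs) || is.null(Zt))
      stop("alignment variants need Zs and Zt batches")
    align <- if (config$align == "global") {
      coral_loss(Zs, Zt)
    } else {
      if (is.null(conditions)) stop("conditional alignment needs target conditions")
      tc_coral_loss(Zs, Zt, conditions)
    }
  }
  task + config$align_weight * align
}
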