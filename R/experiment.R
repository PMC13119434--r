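# Experimental protocol: target-domain splitting, source pretraining,
# target adaptation, evaluation metrics, the full pipeline for one
# (variant, ratio, seed) cell and the ablation grid.

#' Stratified fine-tune / test split of the target campaign
#'
#' Splits plants within every shading level at the requested ratio
#' (stratified random sampling), keeping the two subsets mutually
#' exclusive at the plant level and every condition represented in both.
#'
#' @param ds The target `spectral_dataset`.
#' @param ratio Fine-tune:test ratio as a string (`"3:7"`, `"4:6"`,
#'   `"5:5"`, `"6:4"`, `"7:3"`) or a numeric fine-tune fraction.
#' @param seed Integer seed.
#' @return An object of class `split_plan`: `ratio`, `fine_tune` and
#'   `test` plant-id vectors, `seed`.
#' @export
split_target <- function(ds, ratio = "3:7", seed = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  frac <- if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":")[[1]])
    parts[1] / sum(parts)
  } else {
    as.numeric(ratio)
  }
  if (!(frac > 0 && frac < 1)) stop("ratio must give a fraction in (0,1)")
  set.seed(seed)
  ft <- character(); te <- character()
  for (cc in unique(ds$meta$condition)) {
    ids <- ds$meta$plant_id[ds$meta$condition == cc]
    if (length(ids) < 2) stop("condition ", cc, " has fewer than 2 plants")
    n_ft <- min(max(round(frac * length(ids)), 1L), length(ids) - 1L)
    pick <- sample(ids, n_ft)
    ft <- c(ft, pick)
    te <- c(te, setdiff(ids, pick))
  }
  structure(list(ratio = if (is.character(ratio)) ratio else sprintf("%.2f", frac),
                 fine_tune = ft, test = te, seed = as.integer(seed)),
            class = "split_plan")
}

mse_grad <- function(mu, y) {
  n <- length(y)
  list(value = mean((y - mu)^2), d_mu = -2 * (y - mu) / n)
}

#' Pretrain a variant on the simulated source domain
#'
#' Splits the lookup-table feature set 8:2 into training and validation,
#' trains the backbone on the training part (task loss only: MSE, or the
#' heteroscedastic likelihood for CAI-DAI), and early-stops on validation
#' MAE. Source rows use the `RESERVED_SOURCE` embedding entry.
#'
#' @param tbl A `feature_table` built from the lookup table (selected
#'   feature columns, chlorophyll target).
#' @param config A [variant_config()].
#' @param seed Integer seed (initialisation, split and batch order).
#' @return A fitted `chl_da_model` (stage `"pretrained"`) whose `log`
#'   records per-epoch training loss and validation MAE.
#' @export
pretrain_source <- function(tbl, config, seed = 1L) {
  stopifnot(inherits(tbl, "feature_table"), inherits(config, "variant_config"))
  n <- nrow(tbl$values)
  if (n < 10) stop("lookup table too small to pretrain on")
  set.seed(derive_seed(seed, "pretrain-split"))
  val_idx <- sample(n, max(1, round(0.2 * n)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  scaler_x <- scale_fit(tbl$values[tr_idx, , drop = FALSE])
  y_tr_raw <- tbl$target[tr_idx]
  scaler_y <- list(mean = mean(y_tr_raw), sd = sd(y_tr_raw))
  Xtr <- scale_apply(tbl$values[tr_idx, , drop = FALSE], scaler_x)
  Xval <- scale_apply(tbl$values[val_idx, , drop = FALSE], scaler_x)
  ytr <- (y_tr_raw - scaler_y$mean) / scaler_y$sd
  yval_raw <- tbl$target[val_idx]
  src_idx_tr <- rep(cond_to_idx(RESERVED_SOURCE), length(tr_idx))
  src_idx_val <- rep(cond_to_idx(RESERVED_SOURCE), length(val_idx))

  params <- nn_init(ncol(Xtr), config, derive_seed(seed, "init"))
  state <- adam_init(params)
  set.seed(derive_seed(seed, "pretrain-order"))
  best <- list(params = params, val_mae = Inf, epoch = 0L)
  wait <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(), val_mae = numeric())
  for (epoch in seq_len(config$pretrain_epochs)) {
    ord <- sample(length(tr_idx))
    batch_starts <- seq(1, length(ord), by = config$batch_size)
    ep_loss <- 0
    for (s in batch_starts) {
      bi <- ord[s:min(s + config$batch_size - 1, length(ord))]
      if (length(bi) < 2) next
      fw <- nn_forward(params, Xtr[bi, , drop = FALSE], src_idx_tr[bi],
                       config, training = TRUE)
      if (config$het) {
        hg <- het_nll_grad(fw$mu, fw$log_var, ytr[bi])
        nb <- length(bi)
        grads <- nn_backward(params, fw$cache, config,
                             g_mu = hg$d_mu / nb, g_lv = hg$d_log_var / nb)
        loss <- mean(hg$per_sample)
      } else {
        mg <- mse_grad(fw$mu, ytr[bi])
        grads <- nn_backward(params, fw$cache, config, g_mu = mg$d_mu)
        loss <- mg$value
      }
      if (!is.finite(loss)) stop("pretraining diverged (non-finite loss) at epoch ", epoch)
      upd <- adam_step(params, grads, state, config$lr_pretrain)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + loss * length(bi)
    }
    fwv <- nn_forward(params, Xval, src_idx_val, config, training = FALSE)
    val_mae <- mean(abs(fwv$mu * scaler_y$sd + scaler_y$mean - yval_raw))
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = ep_loss / length(tr_idx),
                                 val_mae = val_mae))
    if (val_mae < best$val_mae - config$min_delta) {
      best <- list(params = params, val_mae = val_mae, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  new_chl_da_model(config, best$params, tbl$feature_id, scaler_x, scaler_y,
                   log = log, seed = as.integer(seed), stage = "pretrained")
}

stratified_batch <- function(conditions, batch_size) {
  conds <- unique(conditions)
  per <- max(2L, batch_size %/% length(conds))
  unlist(lapply(conds, function(cc) {
    idx <- which(conditions == cc)
    sample(idx, min(per, length(idx)))
  }))
}

#' Adapt a pretrained model to the target campaign
#'
#' Fine-tunes all layers on the target fine-tuning subset with the
#' variant's total loss. For alignment variants, source batches keep
#' streaming during adaptation so the source covariance is available each
#' step; target batches are condition-stratified at the configured batch
#' size. CAI-DAI additionally learns one log-weight per target condition
#' (condition-level uncertainty weighting).
#'
#' @param model A pretrained `chl_da_model`.
#' @param target_tbl `feature_table` of the fine-tuning subset (columns
#'   must match the model's selected features).
#' @param target_conditions Condition label per fine-tuning row.
#' @param source_tbl `feature_table` of the source domain (for the
#'   alignment stream); required for alignment variants.
#' @param seed Integer seed.
#' @param epochs Override of `config$adapt_epochs`.
#' @return The adapted `chl_da_model` (stage `"adapted"`).
#' @export
adapt <- function(model, target_tbl, target_conditions, source_tbl = NULL,
                  seed = 1L, epochs = NULL) {
  stopifnot(inherits(model, "chl_da_model"), inherits(target_tbl, "feature_table"))
  config <- model$config
  if (!identical(target_tbl$feature_id, model$feature_ids))
    stop("feature mismatch between model and target table")
  n_ft <- nrow(target_tbl$values)
  if (n_ft < 1) stop("empty fine-tuning set")
  if (config$align != "none" && is.null(source_tbl))
    stop("variant ", config$variant, " needs a source stream for alignment")
  if (!is.null(source_tbl) && !identical(source_tbl$feature_id, model$feature_ids))
    stop("feature mismatch between model and source table")
  epochs <- as.integer(epochs %||% config$adapt_epochs)
  target_conditions <- as.character(target_conditions)
  if (length(target_conditions) != n_ft)
    stop("one condition per fine-tuning row required")

  Xt <- scale_apply(target_tbl$values, model$scaler_x)
  yt <- (target_tbl$target - model$scaler_y$mean) / model$scaler_y$sd
  cidx_t <- cond_to_idx(target_conditions)
  if (!is.null(source_tbl)) {
    Xs <- scale_apply(source_tbl$values, model$scaler_x)
    cidx_s <- rep(cond_to_idx(RESERVED_SOURCE), nrow(Xs))
  }
  params <- model$params
  if (config$cond_weight) {
    # one learnable log-weight per target condition present
    params$log_v <- setNames(numeric(length(unique(target_conditions))),
                             sort(unique(target_conditions)))
  }
  state <- adam_init(params)
  set.seed(derive_seed(seed, "adapt"))
  steps_per_epoch <- max(1L, round(n_ft / config$batch_size))
  for (epoch in seq_len(epochs)) {
    for (step in seq_len(steps_per_epoch)) {
      bi <- stratified_batch(target_conditions, config$batch_size)
      fw_t <- nn_forward(params, Xt[bi, , drop = FALSE], cidx_t[bi],
                         config, training = TRUE)
      nb <- length(bi)
      grads_extra <- NULL
      if (config$het) {
        hg <- het_nll_grad(fw_t$mu, fw_t$log_var, yt[bi])
        cw <- condition_weighted_grad(hg$per_sample, target_conditions[bi],
                                      params$log_v)
        g_mu <- cw$d_losses * hg$d_mu
        g_lv <- cw$d_losses * hg$d_log_var
        task <- cw$value
        grads_extra <- list(log_v = pmin(pmax(cw$d_log_v, -1e3), 1e3))
      } else {
        mg <- mse_grad(fw_t$mu, yt[bi])
        g_mu <- mg$d_mu; g_lv <- NULL
        task <- mg$value
      }
      g_zt <- NULL
      align_grads <- NULL
      if (config$align != "none" && config$align_weight != 0) {
        if (config$align_scope == "domain") {
          # large stratified draws approximate the domain covariances
          ai <- stratified_batch(target_conditions, config$align_rows)
          fw_ta <- nn_forward(params, Xt[ai, , drop = FALSE], cidx_t[ai],
                              config, training = TRUE)
          sb <- sample(nrow(Xs), min(config$align_rows, nrow(Xs)))
          fw_s <- nn_forward(params, Xs[sb, , drop = FALSE], cidx_s[sb],
                             config, training = TRUE)
          ag <- if (config$align == "global") {
            coral_grad(fw_s$z, fw_ta$z)
          } else {
            withCallingHandlers(
              tc_coral_grad(fw_s$z, fw_ta$z, target_conditions[ai]),
              warning = function(w) invokeRestart("muffleWarning"))
          }
          align_grads <- nn_backward(params, fw_ta$cache, config,
                                     g_z = config$align_weight * ag$d_Zt)
        } else {
          sb <- sample(nrow(Xs), min(config$batch_size, nrow(Xs)))
          fw_s <- nn_forward(params, Xs[sb, , drop = FALSE], cidx_s[sb],
                             config, training = TRUE)
          ag <- if (config$align == "global") {
            coral_grad(fw_s$z, fw_t$z)
          } else {
            withCallingHandlers(
              tc_coral_grad(fw_s$z, fw_t$z, target_conditions[bi]),
              warning = function(w) invokeRestart("muffleWarning"))
          }
          g_zt <- config$align_weight * ag$d_Zt
        }
        task <- task + config$align_weight * ag$value
      }
      if (!is.finite(task)) stop("adaptation diverged (non-finite loss) at epoch ", epoch)
      grads <- nn_backward(params, fw_t$cache, config, g_mu = g_mu,
                           g_lv = g_lv, g_z = g_zt)
      if (!is.null(align_grads)) {
        for (nm in names(align_grads)) grads[[nm]] <- grads[[nm]] + align_grads[[nm]]
      }
      if (config$align != "none" && config$align_weight != 0) {
        grads_s <- nn_backward(params, fw_s$cache, config,
                               g_z = config$align_weight * ag$d_Zs)
        for (nm in names(grads_s)) grads[[nm]] <- grads[[nm]] + grads_s[[nm]]
      }
      if (!is.null(grads_extra)) grads <- c(grads, grads_extra)
      upd <- adam_step(params, grads, state, config$lr_adapt)
      params <- upd$params; state <- upd$state
      if (config$cond_weight)
        params$log_v <- pmin(pmax(params$log_v, -10), 10)
    }
  }
  log_v <- params$log_v
  params$log_v <- NULL
  new_chl_da_model(config, params, model$feature_ids, model$scaler_x,
                   model$scaler_y, log = model$log, seed = as.integer(seed),
                   stage = "adapted", log_v = log_v)
}

#' Evaluate a model on a held-out test subset
#'
#' Computes the overall metrics — coefficient of determination
#' `r2 = 1 - SS_res/SS_tot` (may be negative), `nrmse = 100 * RMSE /
#' mean(y)` (percent) and MAE (ug/cm^2) — plus per-condition MAE and the
#' mean and coefficient of variation (sd/mean, n-1 sd) of the
#' per-condition MAE values.
#'
#' @param model A fitted `chl_da_model`.
#' @param test_tbl `feature_table` of the test subset.
#' @param conditions Condition label per test row.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_model <- function(model, test_tbl, conditions) {
  stopifnot(inherits(test_tbl, "feature_table"))
  if (nrow(test_tbl$values) < 1) stop("empty test subset")
  conditions <- as.character(conditions)
  mu <- predict(model, test_tbl$values, conditions = conditions)$mu
  rep <- regression_metrics(test_tbl$target, mu, conditions)
  rep$variant <- model$config$variant
  rep
}

#' Regression metrics with per-condition breakdown
#'
#' @param y Observed chlorophyll values (nonconstant).
#' @param mu Predicted values.
#' @param conditions Condition label per sample.
#' @return An `evaluation_report` (see [evaluate_model()]).
#' @export
regression_metrics <- function(y, mu, conditions) {
  if (length(mu) != length(y) || length(conditions) != length(y))
    stop("y, mu and conditions must have equal length")
  if (sd(y) == 0) stop("constant test target; r2 undefined")
  conditions <- as.character(conditions)
  per_cond <- vapply(sort(unique(conditions)), function(cc) {
    mean(abs(y[conditions == cc] - mu[conditions == cc]))
  }, numeric(1))
  structure(list(
    r2 = 1 - sum((y - mu)^2) / sum((y - mean(y))^2),
    nrmse = 100 * sqrt(mean((y - mu)^2)) / mean(y),
    mae = mean(abs(y - mu)),
    per_condition_mae = per_cond,
    mae_mean = mean(per_cond),
    mae_cv = if (length(per_cond) > 1 && mean(per_cond) > 0)
      sd(per_cond) / mean(per_cond) else 0,
    variant = NA_character_,
    n_test = length(y)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: R2 = %.3f, nRMSE = %.1f%%, MAE = %.3f ug/cm2\n",
              x$variant, x$r2, x$nrmse, x$mae))
  cat("  per-condition MAE:",
      paste(names(x$per_condition_mae),
            sprintf("%.3f", x$per_condition_mae), sep = "=", collapse = ", "),
      sprintf("(mean %.3f, CV %.3f)\n", x$mae_mean, x$mae_cv))
  invisible(x)
}
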