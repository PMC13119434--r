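# Model-variant configuration and the user-facing model object: a
# residual-network regressor with optional condition embedding,
# alignment loss and heteroscedastic head, covering the five ablation
# variants.

#' Configure a model variant
#'
#' The five ablation variants and their switches:
#' \itemize{
#'   \item `ResDNN` — residual network, no adaptation mechanism.
#'   \item `GAI` — adds global CORAL alignment.
#'   \item `CA` — target-conditioned CORAL alignment.
#'   \item `CA-IE` — conditional alignment plus the condition
#'     (illumination) embedding.
#'   \item `CAI-DAI` — the full framework: embedding, conditional
#'     alignment, heteroscedastic head and condition-level uncertainty
#'     weighting.
#' }
#' Architecture constants: 32-d condition embedding, 256-d latent
#' features, dropout 0.2, batch size 64.
#'
#' @param variant One of `"ResDNN"`, `"GAI"`, `"CA"`, `"CA-IE"`,
#'   `"CAI-DAI"`.
#' @param embed_dim Condition-embedding width.
#' @param feature_dim Latent feature width.
#' @param dropout Dropout rate in the extractor.
#' @param batch_size Training batch size.
#' @param align_weight Weight of the alignment loss (constant through
#'   training).
#' @param align_scope How the alignment covariances are estimated:
#'   `"domain"` (default) computes them from large stratified draws of
#'   the fine-tuning set and the source stream (up to `align_rows` rows
#'   each, per step) — closer to the population covariances the
#'   alignment losses are defined on; `"batch"` estimates both from the
#'   current 64-row minibatches (noisier, cheaper).
#' @param align_rows Total row cap of each alignment draw under
#'   `"domain"` scope.
#' @param n_blocks Residual blocks in the extractor.
#' @param lr_pretrain,lr_adapt Adam learning rates for source
#'   pretraining and target adaptation.
#' @param pretrain_epochs Maximum pretraining epochs (early stopping on
#'   validation error, see `patience`).
#' @param patience Early-stopping patience in epochs.
#' @param adapt_epochs Fine-tuning epochs on the target fine-tune subset.
#' @param min_delta Minimum validation-MAE improvement (ug/cm^2) that
#'   resets the patience counter.
#' @return An object of class `variant_config` with derived switches
#'   `use_embedding`, `align` (`"none"`/`"global"`/`"conditional"`),
#'   `het` and `cond_weight`.
#' @export
variant_config <- function(variant = c("ResDNN", "GAI", "CA", "CA-IE", "CAI-DAI"),
                           embed_dim = 32L, feature_dim = 256L, dropout = 0.2,
                           batch_size = 64L, align_weight = 1.0, n_blocks = 3L,
                           lr_pretrain = 1e-3, lr_adapt = 3e-4,
                           pretrain_epochs = 500L, patience = 20L,
                           adapt_epochs = 150L, min_delta = 1e-3,
                           align_scope = c("domain", "batch"),
                           align_rows = 128L) {
  variant <- match.arg(variant)
  align_scope <- match.arg(align_scope)
  structure(list(
    variant = variant,
    embed_dim = as.integer(embed_dim), feature_dim = as.integer(feature_dim),
    dropout = dropout, batch_size = as.integer(batch_size),
    align_weight = align_weight, n_blocks = as.integer(n_blocks),
    align_scope = align_scope, align_rows = as.integer(align_rows),
    lr_pretrain = lr_pretrain, lr_adapt = lr_adapt,
    pretrain_epochs = as.integer(pretrain_epochs),
    patience = as.integer(patience), adapt_epochs = as.integer(adapt_epochs),
    min_delta = min_delta,
    use_embedding = variant %in% c("CA-IE", "CAI-DAI"),
    align = switch(variant, ResDNN = "none", GAI = "global", "conditional"),
    het = variant == "CAI-DAI",
    cond_weight = variant == "CAI-DAI"
  ), class = "variant_config")
}

cond_to_idx <- function(conditions) {
  idx <- match(as.character(conditions), all_condition_levels())
  if (anyNA(idx))
    stop("unknown condition label(s): ",
         paste(unique(conditions[is.na(idx)]), collapse = ", "))
  idx
}

#' Condition embedding vector
#'
#' Deterministic lookup of a shading level's learned embedding row.
#'
#' @param model A fitted model (from [pretrain_source()] / [adapt()]).
#' @param condition A condition label (`"S1".."S4"` or
#'   `"RESERVED_SOURCE"`).
#' @return Numeric vector of length `embed_dim`.
#' @export
embed_condition <- function(model, condition) {
  stopifnot(inherits(model, "chl_da_model"))
  if (!model$config$use_embedding)
    stop("variant ", model$config$variant, " has the condition embedding disabled")
  model$params$E[cond_to_idx(condition), ]
}

#' Extract latent features
#'
#' Runs the residual extractor in evaluation mode (dropout off) and
#' returns the latent representation `z` for each row.
#'
#' @param model A fitted model.
#' @param X Feature matrix matching the model's selected-feature list
#'   (columns in the fitted order).
#' @param conditions Condition label per row (used by embedding
#'   variants).
#' @return Numeric matrix `n x feature_dim`.
#' @export
extract_features <- function(model, X, conditions = RESERVED_SOURCE) {
  stopifnot(inherits(model, "chl_da_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$feature_ids))
    stop("feature dimension mismatch: model expects ",
         length(model$feature_ids), " features")
  Xs <- scale_apply(X, model$scaler_x)
  cidx <- cond_to_idx(rep(as.character(conditions), length.out = nrow(X)))
  nn_forward(model$params, Xs, cidx, model$config, training = FALSE)$z
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, sd)
  sd_[sd_ == 0] <- 1
  list(mean = mu, sd = sd_)
}
scale_apply <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, `/`)
}

new_chl_da_model <- function(config, params, feature_ids, scaler_x, scaler_y,
                             log = NULL, seed = NA_integer_,
                             stage = "pretrained", log_v = NULL) {
  structure(list(config = config, params = params, feature_ids = feature_ids,
                 scaler_x = scaler_x, scaler_y = scaler_y, log = log,
                 seed = seed, stage = stage, log_v = log_v),
            class = "chl_da_model")
}

#' @export
print.chl_da_model <- function(x, ...) {
  cat(sprintf("<chl_da_model> variant %s (%s), %d features, %d-d latent\n",
              x$config$variant, x$stage, length(x$feature_ids),
              x$config$feature_dim))
  invisible(x)
}

#' Predict chlorophyll content
#'
#' @param object A fitted `chl_da_model`.
#' @param newdata Feature matrix or `feature_table` whose columns match
#'   the model's selected features.
#' @param conditions Condition label per row.
#' @param ... Unused.
#' @return A data frame with `mu` (predicted chlorophyll, ug/cm^2) and,
#'   for the heteroscedastic variant, `sd` (predictive standard
#'   deviation, ug/cm^2).
#' @export
predict.chl_da_model <- function(object, newdata, conditions = RESERVED_SOURCE,
                                 ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  if (!is.null(colnames(X))) {
    if (!all(object$feature_ids %in% colnames(X)))
      stop("feature mismatch: newdata is missing model features: ",
           paste(head(setdiff(object$feature_ids, colnames(X))), collapse = ", "))
    X <- X[, object$feature_ids, drop = FALSE]
  } else if (ncol(X) != length(object$feature_ids)) {
    stop("feature dimension mismatch")
  }
  Xs <- scale_apply(X, object$scaler_x)
  cidx <- cond_to_idx(rep(as.character(conditions), length.out = nrow(X)))
  fw <- nn_forward(object$params, Xs, cidx, object$config, training = FALSE)
  mu <- fw$mu * object$scaler_y$sd + object$scaler_y$mean
  out <- data.frame(mu = mu)
  if (object$config$het) out$sd <- exp(fw$log_var / 2) * object$scaler_y$sd
  out
}

#' Save / load a fitted model
#'
#' The binary checkpoint (RDS) stores the parameter matrices; a JSON
#' sidecar (`<path>.json`) records the variant configuration and the
#' selected-feature id list. [load_model()] restores both and
#' [predict.chl_da_model()] refuses feature-mismatched inputs.
#'
#' @param model A `chl_da_model`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "chl_da_model"))
  saveRDS(model, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(config = unclass(model$config), feature_ids = model$feature_ids,
         stage = model$stage, seed = model$seed),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "chl_da_model"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(as.character(side$feature_ids), model$feature_ids))
      stop("sidecar feature list does not match the checkpoint")
  }
  model
}
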