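# End-to-end pipeline for one experiment cell: preprocess both domains,
# select features on the target fine-tuning subset only (never on test
# rows), pretrain on the simulated source, adapt, evaluate; plus the full
# ablation grid.

#' Build the three branch feature tables of a dataset
#'
#' Preprocesses (crop, Savitzky-Golay, CR/SNV/FD) and turns each branch
#' into a `feature_table` with branch-prefixed ids.
#'
#' @param ds A raw `spectral_dataset` with chlorophyll metadata.
#' @param band_step Keep every `band_step`-th band (default 5 nm: thins
#'   near-duplicate neighbouring bands).
#' @return Named list of `feature_table`s (`CR`, `SNV`, `FD`).
#' @export
build_branch_tables <- function(ds, band_step = 5L) {
  br <- preprocess_branches(ds)
  list(CR = branch_feature_table(br$CR, "CR", band_step),
       SNV = branch_feature_table(br$SNV, "SNV", band_step),
       FD = branch_feature_table(br$FD, "FD", band_step))
}

merge_branch_features <- function(branches, ids) {
  vals <- do.call(cbind, lapply(branches, `[[`, "values"))
  colnames(vals) <- unlist(lapply(branches, `[[`, "feature_id"))
  feature_table(vals[, ids, drop = FALSE], ids, branches[[1]]$target)
}

#' Run one experiment cell: variant x ratio x seed
#'
#' The full protocol: split the campaign (stratified by shading level),
#' select features on the fine-tuning subset only, extract the same
#' features from the lookup table, pretrain the variant on the source
#' domain, adapt on the fine-tuning subset, and evaluate on the held-out
#' test subset.
#'
#' @param campaign Target `spectral_dataset` (e.g. from
#'   [generate_campaign()]).
#' @param lut A `lookup_table` (source domain).
#' @param variant Variant name or a [variant_config()].
#' @param ratio Fine-tune:test ratio (string or fraction).
#' @param seed Master seed; component seeds are derived from it.
#' @param band_step,threshold Feature construction/screen parameters.
#' @param selection Optional precomputed `selection_result` for this
#'   (ratio, seed) split (shared across variants in the ablation grid).
#' @param pretrained Optional pretrained model to reuse.
#' @param adapt_epochs,pretrain_epochs Optional overrides.
#' @param target_branches,lut_branches Optional precomputed
#'   [build_branch_tables()] results (reused across cells; preprocessing
#'   is deterministic, so caching does not change results).
#' @return List with `report` (`evaluation_report`), `model`,
#'   `selection`, `plan`.
#' @export
run_variant <- function(campaign, lut, variant = "CAI-DAI", ratio = "3:7",
                        seed = 42L, band_step = 5L, threshold = 0.3,
                        selection = NULL, pretrained = NULL,
                        adapt_epochs = NULL, pretrain_epochs = NULL,
                        target_branches = NULL, lut_branches = NULL) {
  config <- if (inherits(variant, "variant_config")) variant else variant_config(variant)
  if (!is.null(pretrain_epochs)) config$pretrain_epochs <- as.integer(pretrain_epochs)
  plan <- split_target(campaign, ratio, derive_seed(seed, "split"))
  ft_rows <- match(plan$fine_tune, campaign$meta$plant_id)
  te_rows <- match(plan$test, campaign$meta$plant_id)

  if (is.null(target_branches))
    target_branches <- build_branch_tables(campaign, band_step)
  if (is.null(lut_branches))
    lut_branches <- build_branch_tables(lut$spectra, band_step)
  if (is.null(selection)) {
    ft_branches <- lapply(target_branches, subset_samples, rows = ft_rows)
    selection <- two_stage_select(ft_branches, threshold = threshold,
                                  seed = derive_seed(seed, "select"))
  }
  ids <- selection$kept_final
  if (!length(ids))
    stop("feature selection confirmed no features; lower the threshold or alpha")

  target_full <- merge_branch_features(target_branches, ids)
  lut_tbl <- merge_branch_features(lut_branches, ids)

  model <- pretrained %||%
    pretrain_source(lut_tbl, config, derive_seed(seed, "pretrain"))
  if (!identical(model$feature_ids, ids))
    stop("pretrained model feature list does not match the selection")
  if (!identical(pretrain_signature(model$config), pretrain_signature(config)))
    stop("pretrained checkpoint is incompatible with variant ", config$variant)
  model$config <- config  # adaptation switches belong to the requested variant

  adapted <- adapt(model, subset_samples(target_full, ft_rows),
                   campaign$meta$condition[ft_rows],
                   source_tbl = lut_tbl,
                   seed = derive_seed(seed, "adapt"),
                   epochs = adapt_epochs)
  report <- evaluate_model(adapted, subset_samples(target_full, te_rows),
                           campaign$meta$condition[te_rows])
  list(report = report, model = adapted, pretrained = model,
       selection = selection, plan = plan, lut_tbl = lut_tbl,
       target_tbl = target_full, ft_rows = ft_rows, te_rows = te_rows)
}

pretrain_signature <- function(config) {
  # variants whose pretraining is identical share a checkpoint: only the
  # embedding switch and the task loss matter before adaptation
  paste(config$use_embedding, config$het, sep = "/")
}

#' Run the ablation grid
#'
#' Full factorial run over variants x ratios x seeds, reusing the feature
#' selection within each (ratio, seed) split and the source pretraining
#' across variants that pretrain identically. Failed cells are recorded
#' (`NA` metrics) and the run continues.
#'
#' @param campaign,lut As in [run_variant()].
#' @param ratios Character vector of ratios.
#' @param variants Character vector of variant names (nonempty).
#' @param seeds Integer vector of master seeds.
#' @param ... Passed to [run_variant()] (e.g. `adapt_epochs`,
#'   `pretrain_epochs`, `band_step`).
#' @return A data frame: one row per cell with `variant`, `ratio`,
#'   `seed`, `r2`, `nrmse`, `mae`, per-condition MAE columns
#'   (`mae_S1..S4`), `mae_cond_mean`, `mae_cond_cv`, and `error` for
#'   failed cells.
#' @export
ablate <- function(campaign, lut,
                   ratios = c("3:7", "4:6", "5:5", "6:4", "7:3"),
                   variants = c("ResDNN", "GAI", "CA", "CA-IE", "CAI-DAI"),
                   seeds = 42L, band_step = 5L, ...) {
  if (!length(variants)) stop("empty variant grid")
  if (!length(ratios)) stop("empty ratio grid")
  target_branches <- build_branch_tables(campaign, band_step)
  lut_branches <- build_branch_tables(lut$spectra, band_step)
  rows <- list()
  for (seed in seeds) {
    for (ratio in ratios) {
      sel <- NULL
      pre_cache <- list()
      for (variant in variants) {
        cfg <- variant_config(variant)
        res <- tryCatch({
          out <- run_variant(campaign, lut, cfg, ratio, seed,
                             band_step = band_step, selection = sel,
                             pretrained = pre_cache[[pretrain_signature(cfg)]],
                             target_branches = target_branches,
                             lut_branches = lut_branches, ...)
          sel <- out$selection
          pre_cache[[pretrain_signature(cfg)]] <- out$pretrained
          out$report
        }, error = function(e) e)
        if (inherits(res, "error")) {
          message("cell failed (", variant, ", ", ratio, ", seed ", seed, "): ",
                  conditionMessage(res))
          rows[[length(rows) + 1]] <- data.frame(
            variant = variant, ratio = ratio, seed = seed, r2 = NA_real_,
            nrmse = NA_real_, mae = NA_real_, mae_S1 = NA_real_,
            mae_S2 = NA_real_, mae_S3 = NA_real_, mae_S4 = NA_real_,
            mae_cond_mean = NA_real_, mae_cond_cv = NA_real_,
            error = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          pc <- res$per_condition_mae
          rows[[length(rows) + 1]] <- data.frame(
            variant = variant, ratio = ratio, seed = seed, r2 = res$r2,
            nrmse = res$nrmse, mae = res$mae,
            mae_S1 = pc[["S1"]] %||% NA_real_, mae_S2 = pc[["S2"]] %||% NA_real_,
            mae_S3 = pc[["S3"]] %||% NA_real_, mae_S4 = pc[["S4"]] %||% NA_real_,
            mae_cond_mean = res$mae_mean, mae_cond_cv = res$mae_cv,
            error = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarise an ablation table in the two coefficient-of-variation views
#'
#' Reports, per variant: the CV of MAE across ratios within each shading
#' level, and the CV across shading levels at each ratio (both views of
#' cross-condition stability, clearly labelled).
#'
#' @param tab An [ablate()] result.
#' @return A data frame with columns `variant`, `view`, `within`, `cv`.
#' @export
summarise_ablation <- function(tab) {
  tab <- tab[is.na(tab$error), , drop = FALSE]
  out <- list()
  cv <- function(x) if (length(x) > 1 && mean(x) != 0) sd(x) / mean(x) else 0
  for (v in unique(tab$variant)) {
    sub <- tab[tab$variant == v, ]
    for (lev in c("S1", "S2", "S3", "S4")) {
      out[[length(out) + 1]] <- data.frame(
        variant = v, view = "across_ratios", within = lev,
        cv = cv(sub[[paste0("mae_", lev)]]))
    }
    for (r in unique(sub$ratio)) {
      pc <- unlist(sub[sub$ratio == r, c("mae_S1", "mae_S2", "mae_S3", "mae_S4")])
      out[[length(out) + 1]] <- data.frame(
        variant = v, view = "across_levels", within = r, cv = cv(pc))
    }
  }
  do.call(rbind, out)
}
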