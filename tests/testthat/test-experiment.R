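# Shared small fixtures: a modest lookup table and campaign with
# hand-picked features (selection mechanics are tested elsewhere).
local_lut <- build_lut(parameter_space(noise_sd = c(0, 1e-9)), n = 400, seed = 3)
local_camp <- tiny_campaign
pick_ids <- function(branches) {
  ids <- unlist(lapply(branches, `[[`, "feature_id"))
  ids[grepl("_(5[0-9]0|6[0-9]0|7[0-9]0)$", ids)]  # every 10 nm in 500-790
}
lut_branches <- build_branch_tables(local_lut$spectra, band_step = 10)
camp_branches <- build_branch_tables(local_camp, band_step = 10)
ids <- pick_ids(lut_branches)
lut_tbl <- chladapt:::merge_branch_features(lut_branches, ids)
camp_tbl <- chladapt:::merge_branch_features(camp_branches, ids)

test_that("stratified split respects ratio, disjointness and conditions", {
  camp <- generate_campaign(n_per_condition = 80, seed = 1)
  plan <- split_target(camp, "3:7", seed = 2)
  expect_s3_class(plan, "split_plan")
  ft_cond <- camp$meta$condition[match(plan$fine_tune, camp$meta$plant_id)]
  te_cond <- camp$meta$condition[match(plan$test, camp$meta$plant_id)]
  for (cc in paste0("S", 1:4)) {
    expect_lte(abs(sum(ft_cond == cc) - 24), 1)
    expect_lte(abs(sum(te_cond == cc) - 56), 1)
  }
  expect_length(intersect(plan$fine_tune, plan$test), 0)
  expect_setequal(c(plan$fine_tune, plan$test), camp$meta$plant_id)
  expect_false(anyDuplicated(c(plan$fine_tune, plan$test)) > 0)
  expect_identical(split_target(camp, "3:7", seed = 2)$fine_tune, plan$fine_tune)

  small <- subset_spectral(camp, c(1, 81, 161, 241))  # one plant per condition
  expect_error(split_target(small, "3:7", 1), "fewer than 2")
})

test_that("evaluation metrics match hand-computed arithmetic", {
  y <- c(30, 32, 28, 35, 40, 25)
  mu <- c(31, 31, 27, 36, 38, 26)
  conds <- c("S1", "S1", "S2", "S2", "S3", "S3")
  rep <- regression_metrics(y, mu, conds)
  expect_equal(rep$mae, mean(c(1, 1, 1, 1, 2, 1)))
  expect_equal(rep$r2, 1 - sum((y - mu)^2) / sum((y - mean(y))^2))
  expect_equal(rep$nrmse, 100 * sqrt(mean((y - mu)^2)) / mean(y))
  expect_equal(unname(rep$per_condition_mae), c(1, 1, 1.5))
  expect_equal(rep$mae_mean, mean(c(1, 1, 1.5)))
  expect_equal(rep$mae_cv, sd(c(1, 1, 1.5)) / mean(c(1, 1, 1.5)))

  perfect <- regression_metrics(y, y, conds)
  expect_equal(perfect$r2, 1); expect_equal(perfect$nrmse, 0)
  expect_equal(perfect$mae, 0); expect_equal(perfect$mae_cv, 0)
  expect_equal(regression_metrics(y, rep(mean(y), 6), conds)$r2, 0)
  expect_error(regression_metrics(rep(1, 3), 1:3, rep("S1", 3)), "constant")
})

test_that("pretraining learns the source mapping and is deterministic", {
  cfg <- variant_config("ResDNN", feature_dim = 64, n_blocks = 2,
                        pretrain_epochs = 60, patience = 10)
  m1 <- pretrain_source(lut_tbl, cfg, seed = 5)
  expect_s3_class(m1, "chl_da_model")
  expect_lt(min(m1$log$val_mae), 1)  # noise-free table is invertible
  m2 <- pretrain_source(lut_tbl, cfg, seed = 5)
  expect_identical(m1$log$val_mae, m2$log$val_mae)
  expect_identical(m1$params, m2$params)
  expect_error(pretrain_source(feature_table(matrix(1:4, 2), c("a", "b"), 1:2),
                               cfg, 1), "too small")
})

test_that("adaptation contracts: feature match, empty sets, source stream", {
  cfg <- fast_config("CA")
  m <- pretrain_source(lut_tbl, cfg, seed = 6)
  wrong <- feature_table(camp_tbl$values[, 1:3], camp_tbl$feature_id[1:3],
                         camp_tbl$target)
  expect_error(adapt(m, wrong, local_camp$meta$condition), "feature mismatch")
  expect_error(adapt(m, camp_tbl, local_camp$meta$condition), "source stream")
  # ResDNN adapts without any source stream (plain fine-tuning)
  mr <- pretrain_source(lut_tbl, fast_config("ResDNN"), seed = 6)
  ad <- adapt(mr, camp_tbl, local_camp$meta$condition, seed = 1, epochs = 3)
  expect_equal(ad$stage, "adapted")
})

test_that("condition embeddings exist only for embedding variants and differentiate", {
  cfg <- fast_config("CAI-DAI", adapt_epochs = 15L)
  m <- pretrain_source(lut_tbl, cfg, seed = 8)
  e1 <- embed_condition(m, "RESERVED_SOURCE")
  expect_length(e1, 32)
  expect_identical(e1, embed_condition(m, "RESERVED_SOURCE"))
  expect_error(embed_condition(m, "S9"), "unknown condition")

  ad <- adapt(m, camp_tbl, local_camp$meta$condition, source_tbl = lut_tbl,
              seed = 2)
  embs <- sapply(paste0("S", 1:4), function(cc) embed_condition(ad, cc))
  for (i in 1:3) expect_gt(sum(abs(embs[, i] - embs[, i + 1])), 0)
  # adaptation learned per-condition weights
  expect_length(ad$log_v, 4)

  mr <- pretrain_source(lut_tbl, fast_config("ResDNN"), seed = 8)
  expect_error(embed_condition(mr, "S1"), "disabled")
})

test_that("latent extraction returns a feature_dim block per batch", {
  cfg <- variant_config("CAI-DAI", pretrain_epochs = 1L, patience = 1L)
  lut64 <- chladapt:::subset_samples(lut_tbl, 1:80)
  m <- pretrain_source(lut64, cfg, seed = 2)
  Z <- extract_features(m, lut_tbl$values[101:164, ], "RESERVED_SOURCE")
  expect_equal(dim(Z), c(64, 256))
  expect_true(all(is.finite(Z)))
  expect_error(extract_features(m, camp_tbl$values[, 1:4]), "mismatch")
})

test_that("checkpoints round-trip and refuse mismatched feature sidecars", {
  cfg <- fast_config("CAI-DAI")
  m <- pretrain_source(lut_tbl, cfg, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_identical(back$feature_ids, m$feature_ids)
  pr1 <- predict(m, camp_tbl$values[1:5, ], local_camp$meta$condition[1:5])
  pr2 <- predict(back, camp_tbl$values[1:5, ], local_camp$meta$condition[1:5])
  expect_equal(pr1, pr2)
  expect_true(all(c("mu", "sd") %in% names(pr1)))

  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  side$feature_ids <- side$feature_ids[-1]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(load_model(path), "does not match")
  expect_error(predict(m, camp_tbl$values[, -1]), "mismatch")
})

test_that("test rows never influence the fitted model (mutation check)", {
  run_once <- function(camp) {
    run_variant(camp, local_lut, fast_config("CA-IE"), "5:5", seed = 11,
                band_step = 25, threshold = 0.2,
                adapt_epochs = 4, pretrain_epochs = 6)
  }
  out1 <- suppressWarnings(run_once(local_camp))
  mutated <- local_camp
  te_rows <- match(out1$plan$test, mutated$meta$plant_id)
  set.seed(99)
  mutated$reflectance[te_rows, ] <-
    pmin(pmax(mutated$reflectance[te_rows, ] +
                matrix(rnorm(length(te_rows) * 501, 0, 0.01),
                       length(te_rows)), 1e-6), 1 - 1e-6)
  out2 <- suppressWarnings(run_once(mutated))
  expect_identical(out1$plan$fine_tune, out2$plan$fine_tune)
  expect_identical(out1$selection$kept_final, out2$selection$kept_final)
  expect_identical(out1$model$params, out2$model$params)
})

test_that("the ablation grid runs, records cells and tolerates failures", {
  tab <- suppressWarnings(
    ablate(local_camp, local_lut, ratios = c("3:7", "7:3"),
           variants = c("ResDNN", "CAI-DAI"), seeds = 11L,
           band_step = 25, threshold = 0.2,
           adapt_epochs = 4, pretrain_epochs = 6))
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$variant), c("ResDNN", "CAI-DAI"))
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$mae[!is.na(tab$mae)] >= 0))
  summ <- summarise_ablation(tab)
  expect_setequal(unique(summ$view), c("across_ratios", "across_levels"))
  expect_error(ablate(local_camp, local_lut, variants = character(0)),
               "empty variant grid")
})

test_that("the full pipeline is deterministic under one master seed", {
  run_once <- function() {
    suppressWarnings(
      run_variant(local_camp, local_lut, fast_config("CAI-DAI"), "5:5",
                  seed = 21, band_step = 25, threshold = 0.2,
                  adapt_epochs = 3, pretrain_epochs = 4))
  }
  r1 <- run_once(); r2 <- run_once()
  expect_identical(r1$report$mae, r2$report$mae)
  expect_identical(r1$model$params, r2$model$params)
})
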