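# Two-stage feature selection: a Pearson correlation screen per
# preprocessing branch, then a Boruta shadow-feature wrapper (random
# forest importance vs column-shuffled shadows) on the merged survivors.

#' Construct a feature table
#'
#' A samples x features matrix with unique feature ids and the chlorophyll
#' target; no missing values allowed.
#'
#' @param values Numeric matrix (samples x features).
#' @param feature_id Character vector of unique ids, one per column.
#' @param target Numeric chlorophyll target, one per row (ug/cm^2).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, feature_id = colnames(values), target) {
  values <- as.matrix(values)
  if (is.null(feature_id)) feature_id <- paste0("f", seq_len(ncol(values)))
  if (length(feature_id) != ncol(values)) stop("one feature_id per column required")
  if (anyDuplicated(feature_id)) stop("feature_id values must be unique")
  if (length(target) != nrow(values)) stop("one target value per row required")
  if (anyNA(values) || anyNA(target)) stop("feature table must have no missing values")
  colnames(values) <- feature_id
  structure(list(values = values, feature_id = as.character(feature_id),
                 target = as.numeric(target)),
            class = "feature_table")
}

#' Build a feature table from one preprocessing branch
#'
#' Each retained band becomes a feature named `<branch>_<nm>` (e.g.
#' `CR_712`). A band step > 1 thins the grid to reduce redundancy among
#' neighbouring, highly collinear bands.
#'
#' @param ds A transformed `spectral_dataset` whose metadata carries
#'   chlorophyll values.
#' @param branch Branch prefix, e.g. `"CR"`, `"SNV"`, `"FD"`.
#' @param band_step Keep every `band_step`-th band (default 1).
#' @return A `feature_table`.
#' @export
branch_feature_table <- function(ds, branch, band_step = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  keep <- seq(1, n_bands(ds), by = band_step)
  feature_table(ds$reflectance[, keep, drop = FALSE],
                paste0(branch, "_", ds$wavelengths[keep]),
                ds$meta$chlorophyll)
}

subset_features <- function(tbl, ids) {
  feature_table(tbl$values[, ids, drop = FALSE], ids, tbl$target)
}

subset_samples <- function(tbl, rows) {
  feature_table(tbl$values[rows, , drop = FALSE], tbl$feature_id, tbl$target[rows])
}

#' Pearson correlation screen
#'
#' Stage 1 of the two-stage selection: keep features whose absolute
#' Pearson correlation with the chlorophyll target reaches the threshold.
#' A liberal default (|r| >= 0.3) performs bulk dimension reduction before
#' the Boruta wrapper. Constant features get r = 0 (with a warning) and
#' are screened out.
#'
#' @param tbl A `feature_table` with >= 3 samples and nonconstant target.
#' @param threshold Absolute-correlation cutoff in `[0, 1]`.
#' @return A `selection_result` with `kept_stage1` (data frame of
#'   `feature_id`, `r`) and empty Boruta fields.
#' @export
pearson_screen <- function(tbl, threshold = 0.3) {
  stopifnot(inherits(tbl, "feature_table"))
  if (nrow(tbl$values) < 3) stop("need at least 3 samples")
  if (sd(tbl$target) == 0) stop("target is constant")
  sds <- apply(tbl$values, 2, sd)
  r <- rep(0, ncol(tbl$values))
  if (any(sds == 0)) warning(sum(sds == 0), " constant feature(s); r set to 0")
  ok <- sds > 0
  r[ok] <- as.numeric(cor(tbl$values[, ok, drop = FALSE], tbl$target))
  kept <- which(abs(r) >= threshold & ok)
  structure(list(
    kept_stage1 = data.frame(feature_id = tbl$feature_id[kept], r = r[kept],
                             stringsAsFactors = FALSE),
    kept_final = character(), rejected = character(), tentative = character(),
    n_iterations = 0L, seed = NA_integer_, threshold = threshold
  ), class = "selection_result")
}

#' Boruta all-relevant feature selection
#'
#' Iterative shadow-feature wrapper: each round appends a column-shuffled
#' shadow copy of every undecided feature, fits a random-forest regressor
#' (via \pkg{ranger}), and scores a "hit" for features whose importance
#' exceeds the maximum shadow importance. After each round a two-sided
#' binomial test at level `alpha`, Bonferroni-corrected across the
#' undecided features, confirms (significantly more hits than chance) or
#' rejects (significantly fewer) features; iteration stops when all are
#' decided or `max_iter` is reached. Features still undecided at
#' termination are reported `tentative` and treated as not selected.
#'
#' @param tbl A nonempty `feature_table`.
#' @param max_iter Maximum rounds (>= 1).
#' @param alpha Test level per round (default 0.01).
#' @param n_trees Trees per random forest (default 100).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @return A `selection_result`; `kept_final`, `rejected` and `tentative`
#'   partition the input features.
#' @export
boruta_select <- function(tbl, max_iter = 50L, alpha = 0.01, n_trees = 100L,
                          seed = 1L) {
  stopifnot(inherits(tbl, "feature_table"))
  if (max_iter < 1) stop("max_iter must be >= 1")
  p <- ncol(tbl$values)
  if (p < 1) stop("feature table is empty")
  set.seed(seed)
  status <- rep("undecided", p)  # undecided / confirmed / rejected
  hits <- integer(p)
  rounds <- integer(p)  # rounds each feature has participated in
  n <- nrow(tbl$values)
  iter <- 0L
  while (any(status == "undecided") && iter < max_iter) {
    iter <- iter + 1L
    active <- which(status != "rejected")  # confirmed stay in to stabilise importances
    X <- tbl$values[, active, drop = FALSE]
    shadow <- apply(X, 2, sample)
    colnames(shadow) <- paste0(".shadow_", seq_len(ncol(shadow)))
    dat <- data.frame(X, shadow, check.names = FALSE)
    fit <- ranger::ranger(
      x = dat, y = tbl$target, num.trees = n_trees,
      importance = "impurity", seed = derive_seed(seed, paste0("rf", iter)),
      num.threads = 1
    )
    imp <- fit$variable.importance
    shadow_max <- max(imp[grepl("^\\.shadow_", names(imp))])
    feat_imp <- imp[seq_along(active)]
    und <- which(status == "undecided")
    hit_now <- tbl$feature_id[active][feat_imp > shadow_max]
    hits[und] <- hits[und] + (tbl$feature_id[und] %in% hit_now)
    rounds[und] <- rounds[und] + 1L
    # two-sided binomial decision, Bonferroni across currently undecided
    m <- length(und)
    thr <- alpha / m
    p_hi <- pbinom(hits[und] - 1, rounds[und], 0.5, lower.tail = FALSE)
    p_lo <- pbinom(hits[und], rounds[und], 0.5)
    status[und[p_hi < thr]] <- "confirmed"
    status[und[p_lo < thr]] <- "rejected"
  }
  structure(list(
    kept_stage1 = data.frame(feature_id = tbl$feature_id,
                             r = rep(NA_real_, p), stringsAsFactors = FALSE),
    kept_final = tbl$feature_id[status == "confirmed"],
    rejected = tbl$feature_id[status == "rejected"],
    tentative = tbl$feature_id[status == "undecided"],
    n_iterations = iter, seed = as.integer(seed), hits = setNames(hits, tbl$feature_id)
  ), class = "selection_result")
}

#' Two-stage feature selection across preprocessing branches
#'
#' Screens each branch's feature table by Pearson correlation, merges the
#' survivors (ids keep their branch prefixes, so a band retained in two
#' branches stays two distinct features), and runs Boruta once on the
#' merged table.
#'
#' @param branches Named list of `feature_table`s (e.g. CR, SNV, FD),
#'   sharing samples and target.
#' @param threshold Pearson screen cutoff.
#' @param max_iter,alpha,n_trees,seed Passed to [boruta_select()].
#' @return A `selection_result` whose `kept_stage1` carries per-branch r
#'   values and whose Boruta verdict sets partition the stage-1 survivors.
#' @export
two_stage_select <- function(branches, threshold = 0.3, max_iter = 50L,
                             alpha = 0.01, n_trees = 100L, seed = 1L) {
  stopifnot(is.list(branches), length(branches) >= 1)
  tgt <- branches[[1]]$target
  for (b in branches) {
    if (!inherits(b, "feature_table")) stop("branches must be feature_tables")
    if (!isTRUE(all.equal(b$target, tgt))) stop("branches must share samples and target")
  }
  screened <- lapply(branches, pearson_screen, threshold = threshold)
  stage1 <- do.call(rbind, lapply(screened, function(s) s$kept_stage1))
  if (nrow(stage1) == 0)
    stop("no feature passed the correlation screen; lower the threshold")
  merged_vals <- do.call(cbind, Map(function(b, s) {
    b$values[, s$kept_stage1$feature_id, drop = FALSE]
  }, branches, screened))
  merged <- feature_table(merged_vals, stage1$feature_id, tgt)
  bres <- boruta_select(merged, max_iter = max_iter, alpha = alpha,
                        n_trees = n_trees, seed = seed)
  structure(list(
    kept_stage1 = stage1,
    kept_final = bres$kept_final,
    rejected = bres$rejected,
    tentative = bres$tentative,
    n_iterations = bres$n_iterations,
    seed = as.integer(seed), threshold = threshold
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> stage1: %d kept", nrow(x$kept_stage1)))
  cat(sprintf("; boruta: %d confirmed, %d rejected, %d tentative (%d rounds)\n",
              length(x$kept_final), length(x$rejected), length(x$tentative),
              x$n_iterations))
  invisible(x)
}
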