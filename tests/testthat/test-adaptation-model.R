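toy_batches <- function(seed = 1, n = 3, d = 2) {
  set.seed(seed)
  list(Zs = matrix(rnorm(n * d), n, d), Zt = matrix(rnorm(n * d), n, d))
}

# independent covariance oracle written out elementwise
hand_cov <- function(Z) {
  n <- nrow(Z); d <- ncol(Z)
  C <- matrix(0, d, d)
  for (a in 1:d) for (b in 1:d) {
    ma <- sum(Z[, a]) / n; mb <- sum(Z[, b]) / n
    C[a, b] <- sum((Z[, a] - ma) * (Z[, b] - mb)) / (n - 1)
  }
  C
}

test_that("variant switches follow the ablation ladder", {
  expect_false(variant_config("ResDNN")$use_embedding)
  expect_false(variant_config("GAI")$use_embedding)
  expect_false(variant_config("CA")$use_embedding)
  expect_true(variant_config("CA-IE")$use_embedding)
  expect_equal(variant_config("GAI")$align, "global")
  expect_equal(variant_config("CA")$align, "conditional")
  expect_equal(variant_config("ResDNN")$align, "none")
  caidai <- variant_config("CAI-DAI")
  expect_true(caidai$het && caidai$cond_weight && caidai$use_embedding)
  expect_false(variant_config("CA-IE")$het)
  expect_equal(caidai$embed_dim, 32L)
  expect_equal(caidai$feature_dim, 256L)
  expect_equal(caidai$dropout, 0.2)
  expect_equal(caidai$batch_size, 64L)
})

test_that("CORAL matches hand-computed covariance arithmetic on toy batches", {
  b <- toy_batches(5)
  d <- 2
  expected <- sum((hand_cov(b$Zs) - hand_cov(b$Zt))^2) / (4 * d^2)
  expect_equal(coral_loss(b$Zs, b$Zt), expected, tolerance = 1e-10)
  # symmetry, zero at equality, translation invariance
  expect_equal(coral_loss(b$Zs, b$Zt), coral_loss(b$Zt, b$Zs))
  expect_equal(coral_loss(b$Zs, b$Zs), 0)
  shift <- sweep(b$Zt, 2, c(3, -7), `+`)
  expect_equal(coral_loss(b$Zs, shift), coral_loss(b$Zs, b$Zt), tolerance = 1e-12)
  expect_error(coral_loss(b$Zs[1, , drop = FALSE], b$Zt), ">= 2 rows")
})

test_that("target-conditioned CORAL reduces to CORAL and averages per condition", {
  b <- toy_batches(6, n = 6)
  expect_equal(tc_coral_loss(b$Zs, b$Zt, rep("S2", 6)),
               coral_loss(b$Zs, b$Zt), tolerance = 1e-12)

  conds <- rep(c("S1", "S3"), each = 3)
  d <- 2
  hand <- mean(c(
    sum((hand_cov(b$Zs) - hand_cov(b$Zt[1:3, ]))^2) / (4 * d^2),
    sum((hand_cov(b$Zs) - hand_cov(b$Zt[4:6, ]))^2) / (4 * d^2)))
  expect_equal(tc_coral_loss(b$Zs, b$Zt, conds), hand, tolerance = 1e-10)

  # two conditions with identical covariances equal the single-condition loss
  Zt2 <- rbind(b$Zt[1:3, ], sweep(b$Zt[1:3, ], 2, c(1, 2), `+`))
  expect_equal(tc_coral_loss(b$Zs, Zt2, conds),
               coral_loss(b$Zs, b$Zt[1:3, ]), tolerance = 1e-12)

  # singleton conditions are skipped; none usable -> warning and zero
  expect_warning(v <- tc_coral_loss(b$Zs, b$Zt[1:2, ], c("S1", "S2")), "skipped")
  expect_equal(v, 0)
})

test_that("heteroscedastic likelihood: MSE reduction and stationary point", {
  set.seed(7)
  mu <- rnorm(10); y <- rnorm(10)
  expect_equal(het_nll(mu, rep(0, 10), y), mean((y - mu)^2))
  expect_equal(het_nll(y, rep(0, 10), y), 0)

  # fixed residual r: minimum over log_var at log r^2 with value 1 + log r^2
  r <- 0.7
  opt <- optimize(function(s) het_nll(0, s, r), c(-10, 10))
  expect_equal(opt$minimum, log(r^2), tolerance = 1e-4)
  expect_equal(opt$objective, 1 + log(r^2), tolerance = 1e-8)
  expect_equal(het_nll(0, log(r^2), r), 1 + log(r^2), tolerance = 1e-12)

  expect_error(het_nll(c(1, NaN), c(0, 0), c(0, 0)), "non-finite")
})

test_that("condition weighting: sums, stationary point and analytic gradient", {
  l <- c(1, 3, 2, 6)
  conds <- c("S1", "S1", "S2", "S2")
  lv <- c(S1 = 0, S2 = 0)
  expect_equal(condition_weighted_loss(l, conds, lv), 2 + 4)

  # one condition with mean loss m: optimum log v = log m, value 1 + log m
  m <- mean(l)
  opt <- optimize(function(v) condition_weighted_loss(l, rep("S1", 4), c(S1 = v)),
                  c(-10, 10))
  expect_equal(opt$minimum, log(m), tolerance = 1e-4)
  expect_equal(opt$objective, 1 + log(m), tolerance = 1e-8)

  # gradient vs central finite differences
  lv2 <- c(S1 = 0.4, S2 = -0.3)
  g <- chladapt:::condition_weighted_grad(l, conds, lv2)
  eps <- 1e-6
  for (cc in names(lv2)) {
    up <- lv2; up[cc] <- up[cc] + eps
    dn <- lv2; dn[cc] <- dn[cc] - eps
    fd <- (condition_weighted_loss(l, conds, up) -
             condition_weighted_loss(l, conds, dn)) / (2 * eps)
    expect_equal(g$d_log_v[[cc]], fd, tolerance = 1e-4)
    expect_equal(g$d_log_v[[cc]],
                 1 - exp(-lv2[[cc]]) * mean(l[conds == cc]), tolerance = 1e-12)
  }
  expect_error(condition_weighted_loss(l, conds, c(S1 = 0)), "no weight entry")
})

test_that("every loss gradient passes finite-difference verification", {
  eps <- 1e-5
  b <- toy_batches(9, n = 5, d = 3)
  conds <- c("S1", "S1", "S2", "S2", "S2")
  g <- chladapt:::tc_coral_grad(b$Zs, b$Zt, conds)
  gc <- chladapt:::coral_grad(b$Zs, b$Zt)
  for (i in seq_len(5)) for (j in seq_len(3)) {
    pert <- function(Z, delta) { Z[i, j] <- Z[i, j] + delta; Z }
    fd_t <- (tc_coral_loss(b$Zs, pert(b$Zt, eps), conds) -
               tc_coral_loss(b$Zs, pert(b$Zt, -eps), conds)) / (2 * eps)
    fd_s <- (tc_coral_loss(pert(b$Zs, eps), b$Zt, conds) -
               tc_coral_loss(pert(b$Zs, -eps), b$Zt, conds)) / (2 * eps)
    expect_equal(g$d_Zt[i, j], fd_t, tolerance = 1e-4)
    expect_equal(g$d_Zs[i, j], fd_s, tolerance = 1e-4)
    fd_c <- (coral_loss(pert(b$Zs, eps), b$Zt) -
               coral_loss(pert(b$Zs, -eps), b$Zt)) / (2 * eps)
    expect_equal(gc$d_Zs[i, j], fd_c, tolerance = 1e-4)
  }
  set.seed(2)
  mu <- rnorm(6); lv <- rnorm(6, 0, 0.5); y <- rnorm(6)
  hg <- chladapt:::het_nll_grad(mu, lv, y)
  for (i in 1:6) {
    mup <- mu; mup[i] <- mup[i] + eps; mum <- mu; mum[i] <- mum[i] - eps
    expect_equal(hg$d_mu[i],
                 (sum(chladapt:::het_nll_grad(mup, lv, y)$per_sample) -
                    sum(chladapt:::het_nll_grad(mum, lv, y)$per_sample)) / (2 * eps),
                 tolerance = 1e-4)
    lvp <- lv; lvp[i] <- lvp[i] + eps; lvm <- lv; lvm[i] <- lvm[i] - eps
    expect_equal(hg$d_log_var[i],
                 (sum(chladapt:::het_nll_grad(mu, lvp, y)$per_sample) -
                    sum(chladapt:::het_nll_grad(mu, lvm, y)$per_sample)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("backpropagation through the residual extractor is exact", {
  cfg <- variant_config("CAI-DAI", embed_dim = 4, feature_dim = 8,
                        n_blocks = 2, dropout = 0)
  set.seed(9)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rnorm(10)
  cidx <- rep(c(1L, 2L), 5)
  params <- chladapt:::nn_init(5, cfg, 11)
  lossfun <- function(p) {
    fw <- chladapt:::nn_forward(p, X, cidx, cfg, training = FALSE)
    het_nll(fw$mu, fw$log_var, y)
  }
  fw <- chladapt:::nn_forward(params, X, cidx, cfg, training = FALSE)
  hg <- chladapt:::het_nll_grad(fw$mu, fw$log_var, y)
  grads <- chladapt:::nn_backward(params, fw$cache, cfg,
                                  g_mu = hg$d_mu / 10, g_lv = hg$d_log_var / 10)
  eps <- 1e-5
  for (nm in names(grads)) {
    p <- params[[nm]]
    for (i in seq_len(min(length(p), 5))) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(unname(grads[[nm]][i]), fd, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("total loss honours the variant switches and algebraic reductions", {
  b <- toy_batches(4, n = 4)
  conds <- rep("S1", 4)
  mu <- c(1, 2, 3, 4); y <- c(1.5, 2, 2.5, 4.5)
  mse <- mean((y - mu)^2)

  cfg0 <- variant_config("GAI", align_weight = 0)
  expect_equal(total_loss(cfg0, mu, y, Zs = b$Zs, Zt = b$Zt), mse)

  expect_equal(total_loss(variant_config("ResDNN"), mu, y), mse)
  expect_equal(total_loss(variant_config("GAI"), mu, y, Zs = b$Zs, Zt = b$Zt),
               mse + coral_loss(b$Zs, b$Zt))
  expect_equal(total_loss(variant_config("CA"), mu, y, conditions = conds,
                          Zs = b$Zs, Zt = b$Zt),
               mse + tc_coral_loss(b$Zs, b$Zt, conds))
  # CAI-DAI with zero log-variance, zero weights and one condition
  # collapses to the global-alignment form
  expect_equal(total_loss(variant_config("CAI-DAI"), mu, y,
                          log_var = rep(0, 4), conditions = conds,
                          Zs = b$Zs, Zt = b$Zt, log_v = c(S1 = 0)),
               mse + coral_loss(b$Zs, b$Zt), tolerance = 1e-12)
  expect_error(total_loss(variant_config("GAI"), mu, y), "Zs and Zt")
  expect_error(total_loss(variant_config("CAI-DAI"), mu, y), "log_v")
})

test_that("residual blocks with zeroed branches are identity skips", {
  cfg <- variant_config("ResDNN", feature_dim = 16, n_blocks = 3, dropout = 0)
  params <- chladapt:::nn_init(4, cfg, 2)
  for (k in 1:3) {
    params[[paste0("W2_", k)]][] <- 0
    params[[paste0("b2_", k)]][] <- 0
  }
  X <- matrix(rnorm(8 * 4), 8, 4)
  fw <- chladapt:::nn_forward(params, X, rep(5L, 8), cfg, training = FALSE)
  proj <- pmax(sweep(X %*% params$W0, 2, params$b0, `+`), 0)
  expect_equal(fw$z, proj, tolerance = 1e-12)
})

test_that("dropout is stochastic in training mode and off in eval mode", {
  cfg <- variant_config("ResDNN", feature_dim = 16, n_blocks = 1, dropout = 0.5)
  params <- chladapt:::nn_init(3, cfg, 4)
  X <- matrix(rnorm(6 * 3), 6, 3)
  set.seed(1); a <- chladapt:::nn_forward(params, X, rep(5L, 6), cfg, training = TRUE)$z
  set.seed(2); b <- chladapt:::nn_forward(params, X, rep(5L, 6), cfg, training = TRUE)$z
  expect_false(isTRUE(all.equal(a, b)))
  c1 <- chladapt:::nn_forward(params, X, rep(5L, 6), cfg, training = FALSE)$z
  c2 <- chladapt:::nn_forward(params, X, rep(5L, 6), cfg, training = FALSE)$z
  expect_identical(c1, c2)
})
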