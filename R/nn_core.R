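# Residual multilayer-perceptron backbone with an optional condition
# embedding, a mean head and a log-variance head. Forward pass, exact
# backpropagation and Adam are implemented directly on base-R matrices
# (BLAS-backed); gradients are verified against finite differences in the
# test suite.
#
# Architecture: [x, e(c)] -> affine -> ReLU -> dropout -> K residual
# blocks, each z + dropout(ReLU(ReLU(z W1 + b1) W2 + b2)) -> linear heads.

relu <- function(x) pmax(x, 0)

nn_init <- function(d_in, config, seed) {
  set.seed(seed)
  H <- config$feature_dim
  he <- function(fan_in, fan_out) {
    matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
  }
  params <- list()
  if (config$use_embedding) {
    params$E <- matrix(rnorm(length(all_condition_levels()) * config$embed_dim,
                             0, 0.1),
                       length(all_condition_levels()), config$embed_dim)
    d_in <- d_in + config$embed_dim
  }
  params$W0 <- he(d_in, H); params$b0 <- numeric(H)
  for (k in seq_len(config$n_blocks)) {
    params[[paste0("W1_", k)]] <- he(H, H)
    params[[paste0("b1_", k)]] <- numeric(H)
    # residual branches start near zero so blocks begin as identities
    params[[paste0("W2_", k)]] <- he(H, H) * 0.1
    params[[paste0("b2_", k)]] <- numeric(H)
  }
  params$wmu <- matrix(rnorm(H, 0, sqrt(1 / H)), H, 1); params$bmu <- 0
  params$wlv <- matrix(rnorm(H, 0, sqrt(1 / H)) * 0.1, H, 1); params$blv <- 0
  params
}

# cond_idx: integer index into the embedding rows (per sample)
nn_forward <- function(params, X, cond_idx, config, training = FALSE) {
  n <- nrow(X)
  p_drop <- if (training) config$dropout else 0
  drop_mask <- function() {
    if (p_drop > 0) {
      matrix((runif(n * config$feature_dim) >= p_drop) / (1 - p_drop),
             n, config$feature_dim)
    } else NULL
  }
  xin <- if (config$use_embedding) {
    cbind(X, params$E[cond_idx, , drop = FALSE])
  } else X
  cache <- list(xin = xin, cond_idx = cond_idx, n = n)
  a0 <- sweep(xin %*% params$W0, 2, params$b0, `+`)
  z <- relu(a0)
  m0 <- drop_mask()
  if (!is.null(m0)) z <- z * m0
  cache$a0 <- a0; cache$m0 <- m0
  for (k in seq_len(config$n_blocks)) {
    a1 <- sweep(z %*% params[[paste0("W1_", k)]], 2, params[[paste0("b1_", k)]], `+`)
    h1 <- relu(a1)
    a2 <- sweep(h1 %*% params[[paste0("W2_", k)]], 2, params[[paste0("b2_", k)]], `+`)
    h2 <- relu(a2)
    mk <- drop_mask()
    h2d <- if (!is.null(mk)) h2 * mk else h2
    cache[[paste0("zin_", k)]] <- z
    cache[[paste0("a1_", k)]] <- a1
    cache[[paste0("h1_", k)]] <- h1
    cache[[paste0("a2_", k)]] <- a2
    cache[[paste0("m_", k)]] <- mk
    z <- z + h2d
  }
  cache$z <- z
  mu_raw <- drop(z %*% params$wmu) + params$bmu
  lv_raw <- drop(z %*% params$wlv) + params$blv
  log_var <- pmin(pmax(lv_raw, -10), 10)
  cache$lv_clamped <- lv_raw < -10 | lv_raw > 10
  list(mu = mu_raw, log_var = log_var, z = z, cache = cache)
}

# g_mu, g_lv: dL/dmu, dL/dlog_var per sample (vectors); g_z: dL/dz matrix
# (from alignment terms) or NULL. Returns gradient list matching params.
nn_backward <- function(params, cache, config, g_mu = NULL, g_lv = NULL,
                        g_z = NULL) {
  n <- cache$n
  H <- config$feature_dim
  z <- cache$z
  grads <- list()
  gz <- if (is.null(g_z)) matrix(0, n, H) else g_z
  if (!is.null(g_mu)) {
    grads$wmu <- crossprod(z, g_mu)
    grads$bmu <- sum(g_mu)
    gz <- gz + g_mu %o% drop(params$wmu)
  } else {
    grads$wmu <- matrix(0, H, 1); grads$bmu <- 0
  }
  if (!is.null(g_lv)) {
    g_lv_eff <- ifelse(cache$lv_clamped, 0, g_lv)
    grads$wlv <- crossprod(z, g_lv_eff)
    grads$blv <- sum(g_lv_eff)
    gz <- gz + g_lv_eff %o% drop(params$wlv)
  } else {
    grads$wlv <- matrix(0, H, 1); grads$blv <- 0
  }
  for (k in rev(seq_len(config$n_blocks))) {
    mk <- cache[[paste0("m_", k)]]
    g_h2 <- if (!is.null(mk)) gz * mk else gz
    g_a2 <- g_h2 * (cache[[paste0("a2_", k)]] > 0)
    grads[[paste0("W2_", k)]] <- crossprod(cache[[paste0("h1_", k)]], g_a2)
    grads[[paste0("b2_", k)]] <- colSums(g_a2)
    g_h1 <- tcrossprod(g_a2, params[[paste0("W2_", k)]])
    g_a1 <- g_h1 * (cache[[paste0("a1_", k)]] > 0)
    grads[[paste0("W1_", k)]] <- crossprod(cache[[paste0("zin_", k)]], g_a1)
    grads[[paste0("b1_", k)]] <- colSums(g_a1)
    gz <- gz + tcrossprod(g_a1, params[[paste0("W1_", k)]])
  }
  if (!is.null(cache$m0)) gz <- gz * cache$m0
  g_a0 <- gz * (cache$a0 > 0)
  grads$W0 <- crossprod(cache$xin, g_a0)
  grads$b0 <- colSums(g_a0)
  if (config$use_embedding) {
    g_xin <- tcrossprod(g_a0, params$W0)
    g_emb <- g_xin[, (ncol(cache$xin) - config$embed_dim + 1):ncol(cache$xin),
                   drop = FALSE]
    gE <- matrix(0, nrow(params$E), config$embed_dim)
    agg <- rowsum(g_emb, cache$cond_idx)
    gE[as.integer(rownames(agg)), ] <- agg
    grads$E <- gE
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (is.null(params[[nm]])) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
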