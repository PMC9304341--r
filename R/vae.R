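#' Configuration for the sample-conditioned V-plot VAE
#'
#' The model treats each region-by-sample V-plot `x` as a draw from a
#' multinomial distribution over grid cells whose probabilities are decoded
#' from a K-dimensional Gaussian latent variable `z` plus the sample
#' indicator `s`. Conditioning both encoder and decoder on `s` lets the
#' sample indicator absorb nuisance variation such as sample-specific
#' fragment-size profiles, leaving `z` as a batch-corrected representation
#' of the V-plot.
#'
#' @param K Latent dimensionality (default 5).
#' @param grid The [vplot_grid()] the model operates on.
#' @param hidden Hidden-layer width of encoder and decoder (default 64).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param warmup_steps Linear warmup length in steps (default 50).
#' @param total_steps Total optimization steps; the learning rate follows a
#'   cosine decay to 0 after warmup (default 2000).
#' @param batch_size Minibatch size (default 64).
#' @param seed Integer seed; all training randomness flows from it.
#' @return A `vae_config` list.
#' @export
vae_config <- function(K = 5L, grid = vplot_grid(), hidden = 64L,
                       learning_rate = 0.01, warmup_steps = 50L,
                       total_steps = 2000L, batch_size = 64L, seed = 1L) {
  stopifnot(K >= 1, learning_rate > 0, warmup_steps < total_steps,
            batch_size >= 1, hidden >= 1)
  structure(list(K = as.integer(K), grid = grid, hidden = as.integer(hidden),
                 learning_rate = learning_rate,
                 warmup_steps = as.integer(warmup_steps),
                 total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "vae_config")
}

# cosine schedule with linear warmup
lr_at_step <- function(config, step) {
  if (step <= config$warmup_steps)
    return(config$learning_rate * step / config$warmup_steps)
  frac <- (step - config$warmup_steps) /
    (config$total_steps - config$warmup_steps)
  config$learning_rate * 0.5 * (1 + cos(pi * min(frac, 1)))
}

relu <- function(x) pmax(x, 0)

# stack V-plots and sample ids into training matrices
vplot_matrix <- function(vplots, sample_ids, sample_levels = NULL) {
  n <- length(vplots)
  stopifnot(length(sample_ids) == n, n >= 1)
  D <- vplots[[1]]$grid$n_size * vplots[[1]]$grid$n_pos
  X <- matrix(0, n, D)
  for (i in seq_len(n)) X[i, ] <- as.numeric(vplots[[i]]$counts)
  if (is.null(sample_levels)) sample_levels <- sort(unique(sample_ids))
  si <- match(sample_ids, sample_levels)
  if (anyNA(si)) stop("unknown sample id: ",
                      sample_ids[which(is.na(si))[1]], call. = FALSE)
  S <- matrix(0, n, length(sample_levels))
  S[cbind(seq_len(n), si)] <- 1
  list(X = X, S = S, totals = rowSums(X), sample_levels = sample_levels)
}

init_weights <- function(Din, H, K, Dc, D) {
  g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  list(W1 = g(Din, H), b1 = numeric(H),
       Wm = g(H, K), bm = numeric(K),
       Wv = g(H, K), bv = numeric(K),
       W2 = g(Dc, H), b2 = numeric(H),
       W3 = g(H, D), b3 = numeric(D))
}

encode_forward <- function(w, X, S, totals) {
  Xn <- X / pmax(totals, 1)                 # density input, scale-free
  A <- cbind(Xn, S)
  H1 <- relu(sweep(A %*% w$W1, 2, w$b1, `+`))
  MU <- sweep(H1 %*% w$Wm, 2, w$bm, `+`)
  LV <- sweep(H1 %*% w$Wv, 2, w$bv, `+`)
  LV <- pmin(pmax(LV, -10), 10)
  list(A = A, H1 = H1, MU = MU, LV = LV)
}

decode_forward <- function(w, Z, S) {
  Zc <- cbind(Z, S)
  H2 <- relu(sweep(Zc %*% w$W2, 2, w$b2, `+`))
  LOGITS <- sweep(H2 %*% w$W3, 2, w$b3, `+`)
  mx <- apply(LOGITS, 1, max)
  LOGP <- LOGITS - mx - log(rowSums(exp(LOGITS - mx)))
  list(Zc = Zc, H2 = H2, LOGP = LOGP)
}

#' Closed-form KL divergence from a diagonal Gaussian to the standard normal
#'
#' `KL(N(mu, diag(sd^2)) || N(0, I)) = sum_k (sd_k^2 + mu_k^2 - 1
#'   - 2 log sd_k) / 2`.
#'
#' @param mean,sd Numeric vectors (or matrices with one row per posterior).
#' @return Numeric vector of KL divergences (nats).
#' @export
kl_standard_normal <- function(mean, sd) {
  if (is.null(dim(mean))) mean <- matrix(mean, 1)
  if (is.null(dim(sd))) sd <- matrix(sd, 1)
  rowSums((sd^2 + mean^2 - 1 - 2 * log(sd)) / 2)
}

#' Train the sample-conditioned V-plot VAE
#'
#' Maximizes the evidence lower bound
#' `E_q(z|x,s) log p(x|z,s) - KL(q(z|x,s) || p(z))` with a multinomial
#' likelihood over grid cells, one reparameterized Monte Carlo draw per step,
#' and Adam with a linear-warmup cosine learning-rate schedule. A standard
#' multivariate normal prior is placed on `z`.
#'
#' @param vplots List of `vplot` objects (all regions x all samples).
#' @param sample_ids Character vector, one per V-plot.
#' @param config A [vae_config()].
#' @param verbose Print the running ELBO every 200 steps.
#' @return A `vplot_vae` model: weights, config, `sample_levels`, and an
#'   `elbo_trace` of the minibatch ELBO (nats/region, up to the multinomial
#'   normalization constant).
#' @export
train_vae <- function(vplots, sample_ids, config = vae_config(),
                      verbose = FALSE) {
  stopifnot(length(vplots) >= 2)
  dat <- vplot_matrix(vplots, sample_ids)
  n <- nrow(dat$X); D <- ncol(dat$X); Sn <- ncol(dat$S)
  K <- config$K; H <- config$hidden
  if (!same_grid(vplots[[1]]$grid, config$grid))
    stop("V-plot grid does not match model grid", call. = FALSE)
  set.seed(config$seed)
  w <- init_weights(D + Sn, H, K, K + Sn, D)
  m <- lapply(w, function(p) p * 0)          # Adam first moments
  v <- lapply(w, function(p) p * 0)          # Adam second moments
  b1_ <- 0.9; b2_ <- 0.999; eps_ <- 1e-8
  trace <- numeric(0)
  for (step in seq_len(config$total_steps)) {
    idx <- sample.int(n, min(config$batch_size, n))
    X <- dat$X[idx, , drop = FALSE]
    S <- dat$S[idx, , drop = FALSE]
    totals <- dat$totals[idx]
    nb <- length(idx)

    enc <- encode_forward(w, X, S, totals)
    SD <- exp(0.5 * enc$LV)
    EPS <- matrix(stats::rnorm(nb * K), nb, K)
    Z <- enc$MU + EPS * SD
    dec <- decode_forward(w, Z, S)
    P <- exp(dec$LOGP)

    recon <- rowSums(X * dec$LOGP)
    kl <- kl_standard_normal(enc$MU, SD)
    loss <- mean(-recon + kl)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at step ", step, call. = FALSE)
    trace <- c(trace, -loss)

    # backprop (all gradients of the mean loss over the minibatch)
    dLOGITS <- (P * totals - X) / nb
    dW3 <- crossprod(dec$H2, dLOGITS); db3 <- colSums(dLOGITS)
    dH2 <- (dLOGITS %*% t(w$W3)) * (dec$H2 > 0)
    dW2 <- crossprod(dec$Zc, dH2); db2 <- colSums(dH2)
    dZc <- dH2 %*% t(w$W2)
    dZ <- dZc[, seq_len(K), drop = FALSE]
    dMU <- dZ + enc$MU / nb
    dLV <- dZ * EPS * 0.5 * SD + 0.5 * (SD^2 - 1) / nb
    dH1 <- (dMU %*% t(w$Wm) + dLV %*% t(w$Wv)) * (enc$H1 > 0)
    dWm <- crossprod(enc$H1, dMU); dbm <- colSums(dMU)
    dWv <- crossprod(enc$H1, dLV); dbv <- colSums(dLV)
    dW1 <- crossprod(enc$A, dH1); db1 <- colSums(dH1)
    grads <- list(W1 = dW1, b1 = db1, Wm = dWm, bm = dbm, Wv = dWv, bv = dbv,
                  W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)

    lr <- lr_at_step(config, step)
    for (nm in names(w)) {
      m[[nm]] <- b1_ * m[[nm]] + (1 - b1_) * grads[[nm]]
      v[[nm]] <- b2_ * v[[nm]] + (1 - b2_) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - b1_^step)
      vhat <- v[[nm]] / (1 - b2_^step)
      w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps_)
    }
    if (verbose && step %% 200 == 0)
      message(sprintf("step %d  lr %.4g  elbo %.2f", step, lr,
                      mean(utils::tail(trace, 50))))
  }
  structure(list(weights = w, config = config,
                 sample_levels = dat$sample_levels, elbo_trace = trace),
            class = "vplot_vae")
}

#' Encode V-plots into latent posteriors
#'
#' Deterministic given the model state: returns the mean and standard
#' deviation of the diagonal-Gaussian variational posterior `q(z | x, s)`
#' for each V-plot.
#'
#' @param model A trained `vplot_vae`.
#' @param vplots List of `vplot` objects (or a single `vplot`).
#' @param sample_ids Character vector of sample ids (levels known to the
#'   model).
#' @return List with matrices `mean` and `sd` (regions x K).
#' @export
encode_vplots <- function(model, vplots, sample_ids) {
  if (inherits(vplots, "vplot")) vplots <- list(vplots)
  for (v in vplots)
    if (!same_grid(v$grid, model$config$grid))
      stop("V-plot grid does not match model grid", call. = FALSE)
  dat <- vplot_matrix(vplots, sample_ids, model$sample_levels)
  enc <- encode_forward(model$weights, dat$X, dat$S, dat$totals)
  list(mean = enc$MU, sd = exp(0.5 * enc$LV))
}

#' Evidence lower bound of one V-plot
#'
#' Reconstruction term estimated with `n_mc` reparameterized Monte Carlo
#' draws from the encoder posterior; the KL term is the closed form of
#' [kl_standard_normal()]. The multinomial normalization constant
#' (`log total! - sum log x!`) is included, so the value is a true lower
#' bound on `log p(x | s)`.
#'
#' @param model A `vplot_vae`.
#' @param vplot A `vplot`.
#' @param sample_id Sample id.
#' @param n_mc Number of Monte Carlo draws (default 1).
#' @return List with `elbo`, `reconstruction`, `kl`.
#' @export
elbo <- function(model, vplot, sample_id, n_mc = 1L) {
  stopifnot(n_mc >= 1)
  dat <- vplot_matrix(list(vplot), sample_id, model$sample_levels)
  enc <- encode_forward(model$weights, dat$X, dat$S, dat$totals)
  SD <- exp(0.5 * enc$LV)
  K <- model$config$K
  recs <- numeric(n_mc)
  x <- dat$X[1, ]
  lconst <- lgamma(sum(x) + 1) - sum(lgamma(x + 1))
  for (i in seq_len(n_mc)) {
    Z <- enc$MU + matrix(stats::rnorm(K), 1, K) * SD
    dec <- decode_forward(model$weights, Z, dat$S)
    recs[i] <- sum(x * dec$LOGP[1, ]) + lconst
  }
  kl <- kl_standard_normal(enc$MU, SD)
  list(elbo = mean(recs) - kl, reconstruction = mean(recs), kl = kl)
}

#' Save / load a trained V-plot VAE
#'
#' The model (weights, config, sample levels) is serialized to a single
#' file; reloading yields bit-identical encodings.
#'
#' @param model A `vplot_vae`.
#' @param path File path.
#' @return `load_vae` returns the model.
#' @export
save_vae <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "vplot_vae"))
    stop("file does not contain a vplot_vae model", call. = FALSE)
  model
}
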