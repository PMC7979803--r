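## Variational autoencoder: a dense three-layer model (input ->
## encoder hidden -> latent (mu, log sigma^2) -> decoder hidden ->
## output) trained with the reparameterization trick and an Adam
## optimizer. A pool of independently seeded fits provides the
## candidate latent spaces from which the per-drug regression stage
## picks its best compression.

#' Configuration for a variational autoencoder
#'
#' Defaults follow the published operating point for cell-line panels:
#' latent size 100, learning rate 0.0005, batch size 100, 100 epochs,
#' sigmoid activation. Desk-scale analyses shrink these.
#'
#' @param latent_size Latent dimension.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size (capped at the number of samples).
#' @param epochs Training epochs.
#' @param hidden_size Width of the single hidden layer on each side.
#' @param activation Hidden activation, `"sigmoid"` or `"relu"`.
#' @param seed Integer seed controlling initialization, shuffling and
#'   the reparameterization noise.
#' @return A `vaen_vae_config` list.
#' @export
vae_config <- function(latent_size = 100L, learning_rate = 5e-4,
                       batch_size = 100L, epochs = 100L, hidden_size = 500L,
                       activation = c("sigmoid", "relu"), seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(latent_size >= 1L, hidden_size >= 1L, batch_size >= 1L,
            epochs >= 1L, learning_rate > 0)
  if (latent_size >= hidden_size)
    stopf("latent_size (%d) must be smaller than hidden_size (%d)",
          latent_size, hidden_size)
  structure(list(latent_size = as.integer(latent_size),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 hidden_size = as.integer(hidden_size),
                 activation = activation,
                 seed = as.integer(seed)),
            class = "vaen_vae_config")
}

#' VAE training objective: reconstruction MSE plus Gaussian KL
#'
#' The loss for one sample is the mean squared error between input and
#' reconstruction (averaged over genes) plus the KL divergence of the
#' encoded Gaussian q(z|x) = N(mu, diag(exp(logvar))) from the standard
#' normal prior, summed over latent dimensions:
#' KL = -0.5 * sum_j (1 + logvar_j - mu_j^2 - exp(logvar_j)).
#'
#' @param x Input vector.
#' @param x_hat Reconstruction, same length as `x`.
#' @param mu Latent means.
#' @param logvar Latent log-variances.
#' @return Scalar loss.
#' @export
vae_loss <- function(x, x_hat, mu, logvar) {
  if (length(x) != length(x_hat)) stopf("x and x_hat must have equal length")
  if (any(!is.finite(c(x, x_hat, mu, logvar)))) stopf("non-finite inputs to vae_loss")
  mse <- mean((x - x_hat)^2)
  kl <- -0.5 * sum(1 + logvar - mu^2 - exp(logvar))
  mse + kl
}

act_fun <- function(a, activation) {
  if (activation == "sigmoid") 1 / (1 + exp(-a)) else pmax(a, 0)
}
act_grad <- function(h, activation) {
  if (activation == "sigmoid") h * (1 - h) else (h > 0) * 1
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

## Forward pass on a samples-in-rows matrix X (n x d). Returns all
## intermediates needed for backprop. eps is the reparameterization
## draw (n x k) or NULL for the deterministic (mu) path.
vae_forward <- function(w, X, eps = NULL, activation, out_activation) {
  H  <- act_fun(sweep(X %*% w$W1, 2L, w$b1, "+"), activation)
  mu <- sweep(H %*% w$Wmu, 2L, w$bmu, "+")
  lv <- pmin(pmax(sweep(H %*% w$Wlv, 2L, w$blv, "+"), -10), 10)  # numeric guard
  z  <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
  Hd <- act_fun(sweep(z %*% w$W2, 2L, w$b2, "+"), activation)
  pre_out <- sweep(Hd %*% w$W3, 2L, w$b3, "+")
  out <- if (out_activation == "sigmoid") 1 / (1 + exp(-pre_out)) else pre_out
  list(H = H, mu = mu, lv = lv, z = z, Hd = Hd, out = out)
}

## One backprop pass; returns gradients of the batch-mean training
## loss: recon_weight * MSE (per gene) + KL summed over latent dims.
## recon_weight defaults to the gene count, i.e. reconstruction error
## summed over genes -- without this weighting the summed KL overwhelms
## the averaged reconstruction term and the posterior collapses
## (latent means shrink to the prior and carry no information).
vae_backward <- function(w, X, fw, eps, activation, out_activation,
                         recon_weight) {
  n <- nrow(X); d <- ncol(X)
  d_out <- 2 * recon_weight * (fw$out - X) / d / n
  d_pre <- if (out_activation == "sigmoid") d_out * fw$out * (1 - fw$out) else d_out
  gW3 <- crossprod(fw$Hd, d_pre); gb3 <- colSums(d_pre)
  d_Hd <- tcrossprod(d_pre, w$W3) * act_grad(fw$Hd, activation)
  gW2 <- crossprod(fw$z, d_Hd); gb2 <- colSums(d_Hd)
  d_z <- tcrossprod(d_Hd, w$W2)
  ## KL gradients (batch mean) plus the path through z
  d_mu <- d_z + fw$mu / n
  d_lv <- d_z * 0.5 * exp(0.5 * fw$lv) * eps + 0.5 * (exp(fw$lv) - 1) / n
  gWmu <- crossprod(fw$H, d_mu); gbmu <- colSums(d_mu)
  gWlv <- crossprod(fw$H, d_lv); gblv <- colSums(d_lv)
  d_H <- (tcrossprod(d_mu, w$Wmu) + tcrossprod(d_lv, w$Wlv)) *
    act_grad(fw$H, activation)
  gW1 <- crossprod(X, d_H); gb1 <- colSums(d_H)
  list(W1 = gW1, b1 = gb1, Wmu = gWmu, bmu = gbmu, Wlv = gWlv, blv = gblv,
       W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train a variational autoencoder on a normalized expression matrix
#'
#' The output layer uses a sigmoid when the input normalization is
#' `rank` or `z01` (values in (0, 1]) and a linear output for `zs`.
#' The training objective is the reconstruction error summed over genes
#' plus the Gaussian KL summed over latent dimensions (batch-averaged);
#' summing the reconstruction term keeps it commensurate with the KL so
#' the latent code stays informative ([vae_loss()] reports the
#' per-gene-mean diagnostic form). All randomness (weight
#' initialization, epoch shuffling, reparameterization noise) flows
#' from `config$seed`, so the loss trace and the weights are
#' reproducible on a fixed platform.
#'
#' @param expr Normalized genes x samples matrix (see
#'   [normalize_expression()]).
#' @param config A [vae_config()].
#' @return A `vaen_vae` object: weights, config, training gene list,
#'   normalization scheme, and the per-epoch loss trace.
#' @export
train_vae <- function(expr, config = vae_config()) {
  validate_expression(expr)
  norm <- attr(expr, "normalization")
  if (is.null(norm) || identical(norm, "raw"))
    stopf("train_vae expects a normalized matrix; call normalize_expression() first")
  out_activation <- if (norm %in% c("rank", "z01")) "sigmoid" else "linear"
  X <- t(expr)                       # samples in rows
  n <- nrow(X); d <- ncol(X)
  k <- config$latent_size; h <- config$hidden_size
  if (h >= d) warnf("hidden_size (%d) >= number of genes (%d)", h, d)
  bs <- min(config$batch_size, n)

  with_seed(config$seed, {
    w <- list(W1 = glorot(d, h), b1 = numeric(h),
              Wmu = glorot(h, k), bmu = numeric(k),
              Wlv = glorot(h, k) * 0.01, blv = numeric(k),
              W2 = glorot(k, h), b2 = numeric(h),
              W3 = glorot(h, d), b3 = numeric(d))
    m1 <- lapply(w, function(p) p * 0)
    m2 <- m1
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
    t_step <- 0L
    trace <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      batch_losses <- numeric(length(starts))
      for (b in seq_along(starts)) {
        idx <- ord[starts[b]:min(starts[b] + bs - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(idx) * k), length(idx), k)
        fw <- vae_forward(w, Xb, eps, config$activation, out_activation)
        mse <- mean(rowMeans((Xb - fw$out)^2))
        kl <- mean(-0.5 * rowSums(1 + fw$lv - fw$mu^2 - exp(fw$lv)))
        loss <- d * mse + kl
        if (!is.finite(loss))
          stopf("non-finite loss at epoch %d, batch %d; try a smaller learning rate",
                epoch, b)
        batch_losses[b] <- loss
        g <- vae_backward(w, Xb, fw, eps, config$activation, out_activation,
                          recon_weight = d)
        t_step <- t_step + 1L
        for (p in names(w)) {
          m1[[p]] <- beta1 * m1[[p]] + (1 - beta1) * g[[p]]
          m2[[p]] <- beta2 * m2[[p]] + (1 - beta2) * g[[p]]^2
          mhat <- m1[[p]] / (1 - beta1^t_step)
          vhat <- m2[[p]] / (1 - beta2^t_step)
          w[[p]] <- w[[p]] - config$learning_rate * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      trace[epoch] <- mean(batch_losses)
    }

    structure(list(config = config, weights = w, loss_trace = trace,
                   genes = rownames(expr), normalization = norm,
                   out_activation = out_activation),
              class = "vaen_vae")
  })
}

#' @export
print.vaen_vae <- function(x, ...) {
  cat(sprintf("VAE: %d genes -> %d hidden -> %d latent (%s), %d epochs, seed %d\n",
              length(x$genes), x$config$hidden_size, x$config$latent_size,
              x$config$activation, x$config$epochs, x$config$seed))
  cat(sprintf("final training loss %.5f (normalization: %s)\n",
              utils::tail(x$loss_trace, 1L), x$normalization))
  invisible(x)
}

#' Encode samples into the latent space
#'
#' Prediction-time encoding is deterministic: the latent mean vector mu
#' is returned with no reparameterization sampling, so the same sample
#' always maps to the same latent vector. The new cohort must carry
#' exactly the training gene set (any order) under the same
#' normalization scheme.
#'
#' @param model A `vaen_vae`.
#' @param expr Normalized genes x samples matrix.
#' @return Latent matrix, latent_size x n_samples, colnames = sample ids.
#' @export
encode <- function(model, expr) {
  stopifnot(inherits(model, "vaen_vae"))
  validate_expression(expr)
  norm <- attr(expr, "normalization")
  if (!identical(norm, model$normalization))
    stopf("normalization mismatch: model trained on '%s', input is '%s'",
          model$normalization, norm %||% "raw")
  missing_g <- setdiff(model$genes, rownames(expr))
  extra_g <- setdiff(rownames(expr), model$genes)
  if (length(missing_g) || length(extra_g))
    stopf("gene set mismatch: %d missing (e.g. %s), %d extra (e.g. %s)",
          length(missing_g), paste(utils::head(missing_g, 3L), collapse = ","),
          length(extra_g), paste(utils::head(extra_g, 3L), collapse = ","))
  X <- t(expr[model$genes, , drop = FALSE])
  fw <- vae_forward(model$weights, X, eps = NULL,
                    activation = model$config$activation,
                    out_activation = model$out_activation)
  lat <- t(fw$mu)
  rownames(lat) <- paste0("L", seq_len(nrow(lat)))
  colnames(lat) <- colnames(expr)
  lat
}

#' Reconstruct samples through the autoencoder (deterministic path)
#' @param model A `vaen_vae`.
#' @param expr Normalized genes x samples matrix.
#' @return Reconstructed genes x samples matrix.
#' @export
reconstruct <- function(model, expr) {
  stopifnot(inherits(model, "vaen_vae"))
  X <- t(expr[model$genes, , drop = FALSE])
  fw <- vae_forward(model$weights, X, eps = NULL,
                    activation = model$config$activation,
                    out_activation = model$out_activation)
  out <- t(fw$out)
  dimnames(out) <- list(model$genes, colnames(expr))
  out
}

#' Train a pool of independently seeded autoencoders
#'
#' The same input is compressed `n_models` times, model `i` trained
#' with seed `config$seed + i`, so any single pool member can be
#' reconstructed in isolation. The per-drug regression stage later
#' selects among these stochastic compressions by holdout R-squared.
#'
#' @param expr Normalized genes x samples matrix.
#' @param config Base [vae_config()]; member seeds are offsets of
#'   `config$seed`.
#' @param n_models Pool size (the published pipeline uses 100).
#' @return List of `n_models` elements, each
#'   `list(model = vaen_vae, latent = latent matrix, index = i)`.
#' @export
build_pool <- function(expr, config = vae_config(), n_models = 100L) {
  stopifnot(n_models >= 1L)
  lapply(seq_len(n_models), function(i) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + i)
    model <- tryCatch(train_vae(expr, cfg), error = function(e)
      stopf("pool member %d failed: %s", i, conditionMessage(e)))
    list(model = model, latent = encode(model, expr), index = i)
  })
}

#' Save / load a trained VAE as a JSON manifest
#'
#' Weights are serialized as plain JSON arrays alongside the config,
#' gene list, normalization scheme and loss trace; loading restores
#' bit-identical predictions.
#'
#' @param model A `vaen_vae`.
#' @param path Output path (JSON).
#' @return `path` (save) or the restored `vaen_vae` (load).
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "vaen_vae"))
  obj <- list(config = unclass(model$config),
              weights = lapply(model$weights, function(p)
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = NULL, data = as.numeric(p))),
              loss_trace = model$loss_trace, genes = model$genes,
              normalization = model$normalization,
              out_activation = model$out_activation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(obj$weights, function(p) {
    if (length(p$dim) == 2L) matrix(as.numeric(p$data), p$dim[[1L]], p$dim[[2L]])
    else as.numeric(p$data)
  })
  cfg <- do.call(vae_config, obj$config[c("latent_size", "learning_rate",
                                          "batch_size", "epochs", "hidden_size",
                                          "activation", "seed")])
  structure(list(config = cfg, weights = weights, loss_trace = obj$loss_trace,
                 genes = obj$genes, normalization = obj$normalization,
                 out_activation = obj$out_activation),
            class = "vaen_vae")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
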