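## Per-drug Elastic Net models on autoencoder latent spaces.
## For each drug, an Elastic Net (alpha fixed at 0.5, lambda by
## fivefold cross-validation) is fitted on every latent matrix in the
## pool; the latent features it selects are re-evaluated by ordinary
## least squares under tenfold cross-validation, and the pool member
## with the highest mean holdout R-squared wins. Imputation for a new
## cohort is encode-then-linear-predict and is fully deterministic.

#' Fit an Elastic Net for one drug on a latent matrix
#'
#' Minimizes `||y - Xb - b0||^2 / (2n) + lambda * (alpha*|b|_1 +
#' (1-alpha)*|b|_2^2 / 2)` with features standardized internally and
#' coefficients returned on the original scale. Lambda is chosen on a
#' standard path by cross-validation; by default the CV-error
#' minimizer, optionally the one-standard-error rule.
#'
#' @param latent Latent matrix, features x samples (as returned by
#'   [encode()]); transposed internally.
#' @param response Named numeric vector of drug response for (a subset
#'   of) the latent samples; higher = more sensitive. Samples with
#'   missing response are dropped.
#' @param alpha Elastic Net mixing parameter (default 0.5).
#' @param cv_folds Folds for lambda selection (default 5).
#' @param seed Seed for the CV fold assignment.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param thresh Convergence threshold of the coordinate-descent solver.
#' @return A `vaen_drug_model` (without holdout statistics; see
#'   [holdout_r2()] and [train_vaen()]).
#' @export
fit_elastic_net <- function(latent, response, alpha = 0.5, cv_folds = 5L,
                            seed = 1L, lambda_rule = c("min", "1se"),
                            thresh = 1e-14) {
  lambda_rule <- match.arg(lambda_rule)
  X <- t(latent)
  common <- intersect(rownames(X), names(response))
  y <- response[common]
  keep <- !is.na(y)
  y <- y[keep]
  X <- X[common[keep], , drop = FALSE]
  n <- length(y)
  if (n < cv_folds) stopf("only %d non-missing responses for %d folds", n, cv_folds)
  if (stats::sd(y) == 0) stopf("degenerate response: all values equal")
  foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  one_feature <- ncol(X) == 1L      # solver requires >= 2 columns; pad
  Xfit <- if (one_feature) cbind(X, .pad = 0) else X
  cv <- glmnet::cv.glmnet(Xfit, y, alpha = alpha, foldid = foldid,
                          standardize = TRUE, family = "gaussian",
                          thresh = thresh)
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.numeric(stats::coef(cv, s = lam))
  intercept <- cf[1L]
  beta <- cf[-1L]
  if (one_feature) beta <- beta[1L]
  names(beta) <- colnames(X)
  sel <- which(beta != 0)
  fitted <- as.numeric(X %*% beta + intercept)
  structure(list(drug_id = NA_character_, vae_model_index = NA_integer_,
                 scope = NA_character_, feature_space = "latent",
                 selected = sel, coefficients = beta, intercept = intercept,
                 alpha = alpha, lambda = lam, lambda_rule = lambda_rule,
                 cv_seed = seed, n_train = n,
                 in_sample_pcc = safe_cor(fitted, y),
                 holdout_r2 = NA_real_,
                 train_sample_ids = common[keep]),
            class = "vaen_drug_model")
}

#' @export
print.vaen_drug_model <- function(x, ...) {
  cat(sprintf("drug model%s: %d/%d features selected, lambda %.4g, n = %d\n",
              if (is.na(x$drug_id)) "" else paste0(" [", x$drug_id, "]"),
              length(x$selected), length(x$coefficients), x$lambda, x$n_train))
  cat(sprintf("in-sample PCC %.3f, holdout R2 %s, scope %s, pool index %s\n",
              x$in_sample_pcc,
              if (is.na(x$holdout_r2)) "NA" else sprintf("%.3f", x$holdout_r2),
              x$scope, x$vae_model_index))
  invisible(x)
}

#' Mean holdout R-squared of an OLS refit on selected features
#'
#' The Elastic-Net-selected latent features are re-fitted by standard
#' multivariate linear regression under k-fold cross-validation; each
#' fold's R-squared (1 - SS_res/SS_tot) is computed on the holdout
#' fold, and the mean over folds is returned. This is the
#' model-selection criterion across the autoencoder pool. A model that
#' selected no features returns `-Inf` so it can never win selection.
#'
#' @param latent Features x samples latent matrix.
#' @param response Named response vector (non-missing subset used).
#' @param selected_indices Integer indices of latent features.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment.
#' @return Mean holdout R-squared (scalar).
#' @export
holdout_r2 <- function(latent, response, selected_indices, folds = 10L, seed = 1L) {
  if (length(selected_indices) == 0L) return(-Inf)
  X <- t(latent)
  common <- intersect(rownames(X), names(response))
  y <- response[common]
  keep <- !is.na(y)
  y <- as.numeric(y[keep])
  X <- X[common[keep], selected_indices, drop = FALSE]
  n <- length(y)
  if (n < folds) stopf("only %d samples for %d folds", n, folds)
  foldid <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  r2 <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- foldid != f
    yte <- y[!tr]
    if (stats::sd(yte) == 0) {
      warnf("holdout fold %d has zero response variance; fold skipped", f)
      next
    }
    fit <- stats::lm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0           # rank-deficient training design
    pred <- as.numeric(cbind(1, X[!tr, , drop = FALSE]) %*% cf)
    r2[f] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
  }
  mean(r2, na.rm = TRUE)
}

#' Select the pool member with the highest holdout R-squared
#'
#' Ties are broken in favor of the lowest pool index.
#'
#' @param pool_results Nonempty list of `vaen_drug_model`s for one drug.
#' @return The winning `vaen_drug_model`.
#' @export
select_best <- function(pool_results) {
  if (!length(pool_results)) stopf("empty pool")
  r2 <- vapply(pool_results, function(m) m$holdout_r2, numeric(1))
  idx <- vapply(pool_results, function(m) m$vae_model_index %||% NA_integer_,
                integer(1))
  ord <- order(-r2, idx)
  pool_results[[ord[1L]]]
}

#' Mean pairwise correlation of top-model predictions
#'
#' Stability diagnostic: the top pool members for a drug (by holdout
#' R-squared) each impute response on a target cohort; the mean of all
#' pairwise Pearson correlations among those imputed vectors measures
#' how robust the prediction is to the stochastic choice of
#' compression.
#'
#' @param top_models List (>= 2) of `vaen_drug_model`s.
#' @param pool The autoencoder pool these models index into.
#' @param target_expr Normalized expression matrix to impute on.
#' @return Mean pairwise PCC.
#' @export
stability_check <- function(top_models, pool, target_expr) {
  if (length(top_models) < 2L) stopf("need >= 2 models for a stability check")
  preds <- vapply(top_models, function(m) {
    impute_response(m, pool[[m$vae_model_index]]$model, target_expr)
  }, numeric(ncol(target_expr)))
  cc <- stats::cor(preds)
  mean(cc[upper.tri(cc)])
}

#' Train the full per-drug model set over an autoencoder pool
#'
#' For every drug: fit an Elastic Net on each pool member's latent
#' matrix, score the selected features by [holdout_r2()] with a fixed
#' fold assignment per drug (so pool members are compared on identical
#' folds), and keep the best pool member. Scope `"S"` (solid-tumor)
#' drops samples of the hematopoietic lineage before fitting; scope
#' `"A"` uses all samples.
#'
#' @param pool Pool from [build_pool()].
#' @param responses Samples x drugs response matrix (rownames = sample
#'   ids); higher = more sensitive (negate GDSC LN_IC50 at load time).
#' @param meta Metadata data.frame (needed for scope `"S"`).
#' @param scope `"A"` (all samples) or `"S"` (solid only).
#' @param hematopoietic_label Lineage label identifying hematopoietic
#'   samples (scope `"S"`).
#' @param alpha,cv_folds,holdout_folds,lambda_rule Passed through to
#'   [fit_elastic_net()] / [holdout_r2()].
#' @param min_samples Drugs with fewer non-missing responses are
#'   skipped with a warning (default 30).
#' @param seed Base seed; per-drug fold seeds are derived from it.
#' @return Named list of `vaen_drug_model`s, one per trained drug.
#' @export
train_vaen <- function(pool, responses, meta = NULL, scope = c("A", "S"),
                       hematopoietic_label = "haematopoietic_and_lymphoid_tissue",
                       alpha = 0.5, cv_folds = 5L, holdout_folds = 10L,
                       lambda_rule = "min", min_samples = 30L, seed = 1L) {
  scope <- match.arg(scope)
  keep_samples <- rownames(responses)
  if (scope == "S") {
    if (is.null(meta)) stopf("scope 'S' requires sample metadata")
    heme <- meta$sample_id[meta$lineage == hematopoietic_label]
    keep_samples <- setdiff(keep_samples, heme)
  }
  drugs <- colnames(responses)
  out <- list()
  for (di in seq_along(drugs)) {
    drug <- drugs[di]
    y <- responses[keep_samples, drug]
    names(y) <- keep_samples
    y <- y[!is.na(y)]
    if (length(y) < min_samples) {
      warnf("drug '%s' skipped: %d responses < min_samples = %d",
            drug, length(y), min_samples)
      next
    }
    drug_seed <- child_seed(seed, di)
    fits <- lapply(pool, function(member) {
      m <- fit_elastic_net(member$latent, y, alpha = alpha, cv_folds = cv_folds,
                           seed = drug_seed, lambda_rule = lambda_rule,
                           thresh = 1e-9)
      m$drug_id <- drug
      m$vae_model_index <- member$index
      m$scope <- scope
      m$holdout_r2 <- holdout_r2(member$latent, y, m$selected,
                                 folds = holdout_folds, seed = drug_seed)
      m
    })
    out[[drug]] <- select_best(fits)
    attr(out[[drug]], "pool_holdout_r2") <-
      vapply(fits, function(m) m$holdout_r2, numeric(1))
  }
  out
}

#' Choose between the all-sample and the solid-only model for a drug
#'
#' The solid-only (S) model replaces the all-sample (A) model only when
#' it improves both metrics: strictly higher in-sample PCC and strictly
#' higher mean holdout R-squared. Otherwise the A-model is kept.
#'
#' @param a,s `vaen_drug_model`s for the same drug with scopes A and S.
#' @return The chosen model.
#' @export
choose_scope <- function(a, s) {
  stopifnot(identical(a$drug_id, s$drug_id) || (is.na(a$drug_id) && is.na(s$drug_id)))
  if (isTRUE(s$in_sample_pcc > a$in_sample_pcc) &&
      isTRUE(s$holdout_r2 > a$holdout_r2)) s else a
}

#' Impute drug response for a cohort
#'
#' Encodes the cohort with the autoencoder the drug model was selected
#' from, then applies the linear model: y-hat = X beta + intercept.
#' Deterministic, and invariant to the gene order and sample order of
#' the new cohort.
#'
#' @param model A `vaen_drug_model`.
#' @param vae The `vaen_vae` the model indexes (its pool member).
#' @param expr_new Normalized expression matrix (same scheme and gene
#'   set as training).
#' @return Named numeric vector of imputed response (higher = more
#'   sensitive).
#' @export
impute_response <- function(model, vae, expr_new) {
  lat <- encode(vae, expr_new)
  as.numeric(t(lat) %*% model$coefficients + model$intercept) |>
    stats::setNames(colnames(expr_new))
}

## Linear predictor on a precomputed latent matrix (internal).
predict_on_latent <- function(model, latent) {
  as.numeric(t(latent) %*% model$coefficients + model$intercept) |>
    stats::setNames(colnames(latent))
}

#' Cross-panel consistency of observed and predicted response
#'
#' For a drug screened by two panels, compares the Pearson correlation
#' of the observed responses on the shared samples against the
#' correlation of the two panels' model predictions on the same
#' samples. Because the expression-regulated component of response is
#' panel-invariant while measurement noise is not, predictions can be
#' more concordant across panels than the measurements themselves.
#'
#' @param pred_a,pred_b Named predicted-response vectors.
#' @param obs_a,obs_b Named observed-response vectors.
#' @return List: `pcc_observed`, `pcc_predicted`, `n_shared`.
#' @export
cross_panel_evaluate <- function(pred_a, pred_b, obs_a, obs_b) {
  shared <- Reduce(intersect, list(names(pred_a), names(pred_b),
                                   names(obs_a), names(obs_b)))
  if (length(shared) < 3L) stopf("only %d shared samples (< 3)", length(shared))
  list(pcc_observed = safe_cor(obs_a[shared], obs_b[shared]),
       pcc_predicted = safe_cor(pred_a[shared], pred_b[shared]),
       n_shared = length(shared))
}

#' Count and percentage of correlations above a threshold
#'
#' @param pccs Numeric vector of per-drug (or per cancer-drug pair)
#'   correlations.
#' @param threshold Values strictly greater count as above.
#' @return List: `count_above`, `percent` (rounded to 2 decimals).
#' @export
summarize_cross_panel <- function(pccs, threshold = 0.5) {
  if (!length(pccs)) stopf("empty correlation list")
  k <- sum(pccs > threshold)
  list(count_above = k, percent = round(100 * k / length(pccs), 2L))
}

#' Baseline: Elastic Net directly on gene expression
#'
#' Same Elastic Net settings as the latent-space models, but the
#' feature space is the full gene-by-sample matrix (no compression).
#' Prone to overfitting relative to the compressed models.
#'
#' @param expr Genes x samples expression matrix (the raw log-scale
#'   values, matching how the gene-level comparator is defined).
#' @inheritParams train_vaen
#' @return Named list of `vaen_drug_model`s with
#'   `feature_space = "gene"`.
#' @export
baseline_gene_en <- function(expr, responses, alpha = 0.5, cv_folds = 5L,
                             holdout_folds = 10L, min_samples = 30L, seed = 1L) {
  feats <- expr
  rownames(feats) <- rownames(expr)
  fit_feature_en(feats, responses, "gene", alpha, cv_folds, holdout_folds,
                 min_samples, seed, extra = list(genes = rownames(expr)))
}

#' Baseline: Elastic Net on principal components
#'
#' Linear compression comparator: centered PCA scores of the samples
#' feed the same Elastic Net machinery.
#'
#' @param n_components Number of leading components to retain.
#' @inheritParams baseline_gene_en
#' @return Named list of `vaen_drug_model`s with
#'   `feature_space = "pca"`; each carries the rotation and centers
#'   needed to project new cohorts.
#' @export
baseline_pca_en <- function(expr, responses, n_components, alpha = 0.5,
                            cv_folds = 5L, holdout_folds = 10L,
                            min_samples = 30L, seed = 1L) {
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  feats <- t(pc$x[, seq_len(k), drop = FALSE])
  fit_feature_en(feats, responses, "pca", alpha, cv_folds, holdout_folds,
                 min_samples, seed,
                 extra = list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                              center = pc$center, genes = rownames(expr)))
}

fit_feature_en <- function(feats, responses, space, alpha, cv_folds,
                           holdout_folds, min_samples, seed, extra) {
  drugs <- colnames(responses)
  out <- list()
  for (di in seq_along(drugs)) {
    drug <- drugs[di]
    y <- responses[, drug]
    names(y) <- rownames(responses)
    y <- y[!is.na(y)]
    if (length(y) < min_samples) {
      warnf("drug '%s' skipped: %d responses < min_samples = %d",
            drug, length(y), min_samples)
      next
    }
    drug_seed <- child_seed(seed, di)
    ## wide feature spaces: a looser solver tolerance keeps the lambda
    ## path tractable without affecting model selection
    m <- fit_elastic_net(feats, y, alpha = alpha, cv_folds = cv_folds,
                         seed = drug_seed, thresh = 1e-9)
    m$drug_id <- drug
    m$feature_space <- space
    m$holdout_r2 <- holdout_r2(feats, y, m$selected,
                               folds = holdout_folds, seed = drug_seed)
    m[names(extra)] <- extra
    out[[drug]] <- m
  }
  out
}

#' Impute with a baseline (gene or PCA) model
#'
#' @param model A baseline `vaen_drug_model`.
#' @param expr_new Genes x samples matrix on the training scale.
#' @return Named numeric vector of imputed response.
#' @export
impute_baseline <- function(model, expr_new) {
  miss <- setdiff(model$genes, rownames(expr_new))
  if (length(miss)) stopf("new cohort lacks %d training genes (e.g. %s)",
                          length(miss), paste(utils::head(miss, 3L), collapse = ","))
  X <- t(expr_new[model$genes, , drop = FALSE])
  feats <- switch(model$feature_space,
    gene = X,
    pca  = sweep(X, 2L, model$center) %*% model$rotation,
    stopf("unknown feature space '%s'", model$feature_space))
  as.numeric(feats %*% model$coefficients + model$intercept) |>
    stats::setNames(colnames(expr_new))
}

#' Write a drug-model manifest (JSON)
#'
#' Records, per drug: the winning pool index, scope, lambda, selected
#' features, holdout R-squared and in-sample PCC, plus the CV seeds --
#' enough to reproduce or audit the selection.
#'
#' @param models Named list of `vaen_drug_model`s.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_manifest <- function(models, path) {
  obj <- lapply(models, function(m) list(
    drug_id = m$drug_id, vae_model_index = m$vae_model_index, scope = m$scope,
    feature_space = m$feature_space, selected = as.integer(m$selected),
    coefficients = as.numeric(m$coefficients), intercept = m$intercept,
    alpha = m$alpha, lambda = m$lambda, lambda_rule = m$lambda_rule,
    cv_seed = m$cv_seed, n_train = m$n_train,
    in_sample_pcc = m$in_sample_pcc, holdout_r2 = m$holdout_r2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
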