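## Independent oracles used across the suite. These deliberately avoid
## the package's own code paths (and glmnet/fisher.test/wilcox.test)
## so that agreement is evidence, not tautology.

## Elastic Net by plain cyclic coordinate descent, replicating the
## standardization conventions of the package's solver (features
## standardized with 1/n variance, response internally standardized,
## coefficients returned on the original scale).
oracle_elastic_net <- function(X, y, lambda, alpha, tol = 1e-15,
                               maxit = 200000L) {
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  n <- nrow(X)
  xbar <- colMeans(X)
  s <- sqrt(colMeans(X^2) - xbar^2)
  Xs <- sweep(sweep(X, 2L, xbar), 2L, s, "/")
  ybar <- mean(y)
  sy <- sqrt(mean(y^2) - ybar^2)
  ys <- (y - ybar) / sy
  lam <- lambda / sy
  p <- ncol(X)
  g <- numeric(p)
  r <- ys
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      zj <- sum(Xs[, j] * r) / n + g[j]
      gj <- soft(zj, lam * alpha) / (1 + lam * (1 - alpha))
      if (gj != g[j]) {
        r <- r - Xs[, j] * (gj - g[j])
        delta <- max(delta, abs(gj - g[j]))
      }
      g[j] <- gj
    }
    if (delta < tol) break
  }
  beta <- g * sy / s
  c(intercept = ybar - sum(beta * xbar), beta)
}

## Two-sided Fisher exact P by direct enumeration of the
## hypergeometric distribution: sum of the probabilities of all tables
## (with the observed margins) no more probable than the observed one.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row-1 total
  k <- sum(tab[, 1])   # col-1 total
  N <- sum(tab)
  lo <- max(0L, k - (N - m))
  hi <- min(k, m)
  supp <- lo:hi
  logp <- lchoose(m, supp) + lchoose(N - m, k - supp) - lchoose(N, k)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[supp == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

## Exact two-sided Wilcoxon rank-sum P for small untied samples, by
## full enumeration of group assignments. Mirrors the convention
## p = min(1, 2 * one-sided tail including the observed value).
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))  # untied case only
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  total <- ncol(combos)
  if (u_obs > nx * ny / 2) {
    p <- sum(u_all >= u_obs) / total
  } else {
    p <- sum(u_all <= u_obs) / total
  }
  min(1, 2 * p)
}

## Benjamini-Hochberg step-up by the textbook formula (sorted
## cumulative minimum), independent of p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

## Numerical gradient of the VAE batch loss with respect to one weight
## entry, by central differences (used to check backprop).
numeric_grad <- function(loss_fun, w, param, i, j = NULL, h = 1e-5) {
  wp <- w; wm <- w
  if (is.null(j)) {
    wp[[param]][i] <- wp[[param]][i] + h
    wm[[param]][i] <- wm[[param]][i] - h
  } else {
    wp[[param]][i, j] <- wp[[param]][i, j] + h
    wm[[param]][i, j] <- wm[[param]][i, j] - h
  }
  (loss_fun(wp) - loss_fun(wm)) / (2 * h)
}

## Small deterministic expression fixture: 6 genes x 5 samples.
tiny_expr <- function() {
  set.seed(42)
  m <- matrix(abs(rnorm(30, 5, 2)), 6, 5,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  attr(m, "normalization") <- "raw"
  m
}

## Evaluate code under a temporary seed (test-side twin of the
## package's internal seeding, used to reproduce fold assignments).
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
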