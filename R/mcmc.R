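## Generic posterior-sampling utilities: Laplace approximation,
## independence Metropolis-Hastings, and Pareto-smoothed importance
## sampling leave-one-out cross-validation.

## mode + curvature of a log-posterior
laplace_approx <- function(logpost, init, ...) {
  obj <- function(x) -logpost(x, ...)
  opt <- stats::optim(init, obj, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  H <- opt$hessian
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-8 * max(ev$values))
  cov <- ev$vectors %*% diag(1 / ev$values, length(init)) %*% t(ev$vectors)
  list(mode = opt$par, cov = cov, chol = chol(cov), value = -opt$value)
}

## independence MH with a fixed Gaussian proposal; returns draws and the
## acceptance rate.  Near-Gaussian posteriors (e.g. multinomial logit at
## moderate n) mix almost like i.i.d. sampling under this scheme.
mh_independence <- function(logpost, proposal, n_iter, warmup = 100, ...) {
  p <- length(proposal$mode)
  Lc <- proposal$chol
  prop_logd <- function(x) {
    z <- backsolve(Lc, x - proposal$mode, transpose = TRUE)
    -0.5 * sum(z^2)
  }
  draws <- matrix(NA_real_, n_iter, p)
  x <- proposal$mode
  lp_x <- logpost(x, ...); ld_x <- prop_logd(x)
  acc <- 0L
  total <- warmup + n_iter
  for (s in seq_len(total)) {
    cand <- proposal$mode + as.vector(crossprod(Lc, stats::rnorm(p)))
    lp_c <- logpost(cand, ...)
    ld_c <- prop_logd(cand)
    if (is.finite(lp_c) &&
        log(stats::runif(1)) < (lp_c - lp_x) - (ld_c - ld_x)) {
      x <- cand; lp_x <- lp_c; ld_x <- ld_c
      acc <- acc + 1L
    }
    if (s > warmup) draws[s - warmup, ] <- x
  }
  list(draws = draws, accept_rate = acc / total)
}

## generalized-Pareto fit (profile posterior-mean method of Zhang &
## Stephens 2009), for tail smoothing of importance ratios
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) /
    (prior_bs * x[floor(n / 4 + 0.5)])
  ## profile likelihood over theta, in the Zhang-Stephens shape
  ## convention (their k is minus the usual xi)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  Ls <- n * (log(bs / ks) + ks - 1)
  Ls[!is.finite(Ls)] <- -Inf
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(Ls - Ls[j])), numeric(1))
  w[!is.finite(w)] <- 0
  b <- sum(bs * w) / sum(w)
  kstar <- -mean(log1p(-b * x))
  list(k = -kstar, sigma = kstar / b)
}

## Pareto-smoothed importance weights from log ratios (one observation)
psis_smooth <- function(logr) {
  S <- length(logr)
  logr <- logr - max(logr)
  M <- ceiling(pmin(0.2 * S, 3 * sqrt(S)))
  ord <- order(logr)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- logr[ord[S - M]]
  exceed <- exp(logr[tail_ids]) - exp(cutoff)
  fit <- gpd_fit(exceed[exceed > 0])
  k <- fit$k
  if (is.finite(k) && k < 0.7 && is.finite(fit$sigma) && fit$sigma > 0) {
    ## replace tail by expected order statistics of the fitted gPd;
    ## tail_ids are already ordered by increasing log ratio
    pp <- (seq_len(M) - 0.5) / M
    qgpd <- if (abs(k) < 1e-12) -fit$sigma * log1p(-pp) else
      fit$sigma * (exp(-k * log1p(-pp)) - 1) / k
    logr[tail_ids] <- log(exp(cutoff) + qgpd)
    logr[logr > 0] <- 0
  }
  list(logw = logr, k = k)
}

#' PSIS-LOO expected log predictive density
#'
#' Computes the leave-one-out expected log pointwise predictive density of
#' a Bayesian model from its pointwise log-likelihood matrix by
#' Pareto-smoothed importance sampling, with the tail shape diagnostic
#' `k` per observation.
#'
#' @param loglik matrix of pointwise log-likelihood values, rows =
#'   posterior draws, columns = observations.
#' @return list of class `"psis_loo"` with `elpd`, `se`, `pointwise`,
#'   `pareto_k`, and `unreliable` (TRUE when more than half of the
#'   `pareto_k` exceed 0.7).
#' @export
psis_loo <- function(loglik) {
  n <- ncol(loglik)
  pointwise <- numeric(n)
  ks <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$logw - max(sm$logw)
    w <- exp(lw)
    pointwise[i] <- log(sum(w * exp(ll - max(ll)))) + max(ll) - log(sum(w))
    ks[i] <- sm$k
  }
  structure(list(elpd = sum(pointwise), se = stats::sd(pointwise) * sqrt(n),
                 pointwise = pointwise, pareto_k = ks,
                 unreliable = mean(ks > 0.7) > 0.5),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO elpd: %.2f (SE %.2f); %d of %d Pareto-k > 0.7%s\n",
              x$elpd, x$se, sum(x$pareto_k > 0.7), length(x$pareto_k),
              if (x$unreliable) " [unreliable]" else ""))
  invisible(x)
}
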