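#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## simplex check with a floating-point tolerance suited to posterior draws
is_simplex <- function(p, tol = 1e-8) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) && abs(sum(p) - 1) <= tol
}

assert_simplex <- function(p, name = deparse(substitute(p)), tol = 1e-8) {
  if (!is_simplex(p, tol)) {
    stop(sprintf("'%s' must be a probability vector (nonnegative, summing to 1); got [%s]",
                 name, paste(signif(p, 4), collapse = ", ")), call. = FALSE)
  }
  invisible(p)
}

## Gauss-Legendre nodes/weights on [a, b], cached by order
gl_rule <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
    }
    cache[[key]]
  }
})

## nodes/weights for integrating over [a, b]
gl_nodes <- function(n, a, b) {
  r <- gl_rule(n)
  list(x = (b - a) / 2 * r$x + (a + b) / 2, w = (b - a) / 2 * r$w)
}

## split-chain potential scale reduction (Gelman-Rubin), draws: iter x chain
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, stats::var)
  if (all(vars < 1e-300)) return(1)
  B <- half * stats::var(means)
  Wv <- mean(vars)
  if (Wv <= 0) return(NA_real_)
  sqrt(((half - 1) / half * Wv + B / half) / Wv)
}

## effective sample size via initial positive sequence of autocovariances
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  acov <- function(v) {
    v <- v - mean(v)
    stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE,
               demean = FALSE, type = "covariance")$acf[, 1, 1]
  }
  ac <- rowMeans(sapply(seq_len(m), function(j) acov(x[, j])))
  if (ac[1] <= 0) return(n * m)
  rho <- ac / ac[1]
  s <- 0; k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n * m / (1 + 2 * s))
}

## posterior summary for a draws matrix (rows draws, cols parameters)
summarize_draws <- function(draws, probs = c(0.025, 0.5, 0.975)) {
  qs <- t(apply(draws, 2, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(
    parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(probs)) out[[sprintf("q%g", 100 * probs[i])]] <- qs[, i]
  rownames(out) <- NULL
  out
}

## equal-tailed credible interval
cred_int <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE)
}
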