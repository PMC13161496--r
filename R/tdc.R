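## Bayesian multinomial-logit model for the ordinal treatment-dependent
## confounder: log P(L=k | A, W) / P(L=0 | A, W) = phi0_k + phi1_k A +
## phi2_k' W (reference level 0), optionally with treatment-by-covariate
## interaction terms.

## columns of the linear predictor design for a given variant
tdc_design <- function(A, Wd, variant) {
  X <- cbind(intercept = 1, A = A, Wd)
  inter <- NULL
  if (identical(variant, "all_interactions")) {
    inter <- Wd * A
    colnames(inter) <- paste0("A:", colnames(Wd))
  } else if (startsWith(variant, "one:")) {
    cov <- sub("^one:", "", variant)
    cols <- grep(paste0("^", cov), colnames(Wd), value = TRUE)
    if (!length(cols)) {
      stop("unknown covariate in variant: ", cov, call. = FALSE)
    }
    inter <- Wd[, cols, drop = FALSE] * A
    colnames(inter) <- paste0("A:", cols)
  } else if (!identical(variant, "main")) {
    stop("unknown variant: ", variant, call. = FALSE)
  }
  cbind(X, inter)
}

## log-likelihood per subject for coefficient matrix (2 x p)
tdc_loglik <- function(coef2, X, L) {
  eta1 <- as.vector(X %*% coef2[1, ])
  eta2 <- as.vector(X %*% coef2[2, ])
  denom <- log1p(exp(eta1) + exp(eta2))
  ifelse(L == 0, 0, ifelse(L == 1, eta1, eta2)) - denom
}

#' Fit the Bayesian multinomial model for the confounder
#'
#' Posterior sampling of the multinomial-logit coefficients with
#' independent N(0, 5) priors, using an independence
#' Metropolis-Hastings sampler with a Laplace-approximation proposal
#' (the posterior is log-concave, so the proposal is nearly exact and the
#' chains mix almost like i.i.d. draws). Split-chain R-hat is reported
#' for every coefficient; the fit is flagged when any exceeds the
#' threshold.
#'
#' @param data a `tdc_data` object.
#' @param variant `"main"` (main effects of treatment and covariates),
#'   `"all_interactions"` (adds every treatment-by-covariate interaction),
#'   or `"one:<covariate>"` (adds the interaction with one covariate, e.g.
#'   `"one:smoking"`).
#' @param chains,warmup,sampling MCMC protocol (total draws = chains x
#'   sampling).
#' @param prior_sd prior standard deviation of all coefficients.
#' @param rhat_threshold convergence flag threshold.
#' @param seed RNG seed.
#' @return object of class `"tdc_fit"`: coefficient draws (`draws`, one
#'   row per draw, columns `L<k>:<term>`), design metadata, `rhat`,
#'   `accept_rate`, `converged`.
#' @export
fit_tdc <- function(data, variant = "main", chains = 4, warmup = 200,
                    sampling = 1000, prior_sd = 5, rhat_threshold = 1.01,
                    seed = 1) {
  stopifnot(inherits(data, "tdc_data"))
  s <- data$subjects
  if (length(unique(s$L)) < 2) {
    stop("the confounder takes a single observed level; the multinomial ",
         "model is not estimable", call. = FALSE)
  }
  Wd <- encode_w(s)
  X <- tdc_design(s$A, Wd, variant)
  p <- ncol(X)
  par_names <- c(paste0("L1:", colnames(X)), paste0("L2:", colnames(X)))
  logpost <- function(theta) {
    coef2 <- matrix(theta, 2, p, byrow = TRUE)
    sum(tdc_loglik(coef2, X, s$L)) - sum(theta^2) / (2 * prior_sd^2)
  }
  set.seed(seed)
  lap <- laplace_approx(logpost, rep(0, 2 * p))
  chain_draws <- vector("list", chains)
  acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    res <- mh_independence(logpost, lap, n_iter = sampling, warmup = warmup)
    chain_draws[[ch]] <- res$draws
    acc[ch] <- res$accept_rate
  }
  draws <- do.call(rbind, chain_draws)
  colnames(draws) <- par_names
  rhat <- vapply(seq_len(2 * p), function(j) {
    split_rhat(sapply(chain_draws, function(d) d[, j]))
  }, numeric(1))
  names(rhat) <- par_names
  converged <- all(is.na(rhat) | rhat <= rhat_threshold)
  if (!converged) {
    warning("fit_tdc: split R-hat above threshold for some coefficients; ",
            "result flagged as non-converged", call. = FALSE)
  }
  structure(list(draws = draws, variant = variant, p = p,
                 terms = colnames(X), data = data,
                 prior_sd = prior_sd, rhat = rhat,
                 accept_rate = mean(acc), converged = converged,
                 chains = chains, sampling = sampling, seed = seed),
            class = "tdc_fit")
}

#' @export
print.tdc_fit <- function(x, ...) {
  cat(sprintf("Bayesian multinomial confounder model (variant: %s)\n",
              x$variant))
  cat(sprintf("  %d draws (%d chains), acceptance %.2f, max R-hat %.3f%s\n",
              nrow(x$draws), x$chains, x$accept_rate,
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.tdc_fit <- function(object, ...) {
  out <- summarize_draws(object$draws)
  out$rhat <- object$rhat[out$parameter]
  out
}

#' @export
coef.tdc_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' Category probabilities of the confounder for one stratum and arm
#'
#' Applies the inverse multinomial-logit (softmax over linear predictors
#' `(0, eta1, eta2)`) for a coefficient draw.
#'
#' @param coef_draw numeric vector of coefficients in the draw layout of
#'   [fit_tdc()] (`L1:` terms then `L2:` terms), or a 2 x p matrix.
#' @param stratum one-row data.frame (or list) with the baseline
#'   covariates `age_cat, sex, smoking, base_score`.
#' @param arm 0 (control) or 1 (intervention).
#' @param variant design variant matching the fit.
#' @return probability 3-vector `(P(L=0), P(L=1), P(L=2))`.
#' @export
marginal_probs <- function(coef_draw, stratum, arm, variant = "main") {
  Wd <- encode_w(as.data.frame(stratum))
  x <- tdc_design(arm, Wd, variant)[1, ]
  coef2 <- if (is.matrix(coef_draw)) coef_draw else
    matrix(coef_draw, 2, length(coef_draw) / 2, byrow = TRUE)
  eta <- c(0, sum(coef2[1, ] * x), sum(coef2[2, ] * x))
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Per-stratum counterfactual marginals for every posterior draw
#'
#' Evaluates the model-implied marginal category probabilities of the
#' confounder under both arms in every stratum, for each posterior draw:
#' `phi1..phi3` are the treated-arm probabilities and `phi4..phi6` the
#' control-arm probabilities.
#'
#' @param fit a `tdc_fit`.
#' @param strata a `stratum_table` (or data.frame of covariate
#'   combinations).
#' @param draw_ids optional subset of draw indices.
#' @return data.frame with columns `draw`, `stratum`, `phi1..phi6`.
#' @export
stratum_marginals <- function(fit, strata, draw_ids = NULL) {
  stopifnot(inherits(fit, "tdc_fit"))
  draw_ids <- draw_ids %||% seq_len(nrow(fit$draws))
  Wd <- encode_w(strata)
  X1 <- tdc_design(rep(1, nrow(Wd)), Wd, fit$variant)
  X0 <- tdc_design(rep(0, nrow(Wd)), Wd, fit$variant)
  p <- fit$p
  res <- vector("list", length(draw_ids))
  softmax3 <- function(e1, e2) {
    m <- pmax(0, e1, e2)
    d <- exp(-m) + exp(e1 - m) + exp(e2 - m)
    cbind(exp(-m) / d, exp(e1 - m) / d, exp(e2 - m) / d)
  }
  for (j in seq_along(draw_ids)) {
    th <- fit$draws[draw_ids[j], ]
    c1 <- th[seq_len(p)]; c2 <- th[p + seq_len(p)]
    pa <- softmax3(as.vector(X1 %*% c1), as.vector(X1 %*% c2))
    pc <- softmax3(as.vector(X0 %*% c1), as.vector(X0 %*% c2))
    res[[j]] <- data.frame(draw = draw_ids[j], stratum = seq_len(nrow(Wd)),
                           phi1 = pa[, 1], phi2 = pa[, 2], phi3 = pa[, 3],
                           phi4 = pc[, 1], phi5 = pc[, 2], phi6 = pc[, 3])
  }
  do.call(rbind, res)
}

#' Compare confounder-model variants by PSIS-LOO
#'
#' Computes the PSIS-LOO expected log predictive density for each fitted
#' variant (on the same data) and all pairwise differences with standard
#' errors. Following a parsimony rule, the preferred model is the most
#' parsimonious one unless a richer variant wins by more than
#' `se_rule` standard errors of the difference.
#'
#' @param ... two or more `tdc_fit` objects (named arguments name the
#'   models).
#' @param n_draws number of posterior draws used for the pointwise
#'   log-likelihood (thinned evenly).
#' @param se_rule multiple of the difference SE a richer model must exceed
#'   to be preferred.
#' @return list of class `"tdc_comparison"`: per-model `loo` objects,
#'   `elpd` table, pairwise `differences`, and `preferred`.
#' @export
compare_tdc_models <- function(..., n_draws = 500, se_rule = 2) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "tdc_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "tdc_fit")))
  nm <- names(fits) %||% vapply(fits, function(f) f$variant, character(1))
  nm[nm == ""] <- vapply(fits[nm == ""], function(f) f$variant, character(1))
  loos <- list(); pw <- list()
  for (j in seq_along(fits)) {
    f <- fits[[j]]
    s <- f$data$subjects
    X <- tdc_design(s$A, encode_w(s), f$variant)
    ids <- unique(round(seq(1, nrow(f$draws), length.out = min(n_draws, nrow(f$draws)))))
    ll <- t(vapply(ids, function(d) {
      tdc_loglik(matrix(f$draws[d, ], 2, f$p, byrow = TRUE), X, s$L)
    }, numeric(nrow(s))))
    loos[[j]] <- psis_loo(ll)
    pw[[j]] <- loos[[j]]$pointwise
  }
  names(loos) <- nm
  elpd <- data.frame(model = nm,
                     elpd = vapply(loos, `[[`, numeric(1), "elpd"),
                     se = vapply(loos, `[[`, numeric(1), "se"),
                     npar = vapply(fits, function(f) 2 * f$p, numeric(1)))
  diffs <- NULL
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i >= j) next
    d <- pw[[i]] - pw[[j]]
    diffs <- rbind(diffs, data.frame(
      model1 = nm[i], model2 = nm[j],
      elpd_diff = sum(d), se_diff = stats::sd(d) * sqrt(length(d))))
  }
  ## parsimony rule: order by parameter count; richer model must beat every
  ## simpler one by > se_rule SEs
  ord <- order(elpd$npar)
  preferred <- nm[ord[1]]
  for (j in ord[-1]) {
    better <- TRUE
    for (i in ord[seq_len(which(ord == j) - 1)]) {
      row <- diffs[(diffs$model1 == nm[i] & diffs$model2 == nm[j]) |
                     (diffs$model1 == nm[j] & diffs$model2 == nm[i]), ]
      gain <- if (row$model1[1] == nm[j]) row$elpd_diff[1] else -row$elpd_diff[1]
      if (!(gain > se_rule * row$se_diff[1])) better <- FALSE
    }
    if (better) preferred <- nm[j]
  }
  structure(list(loo = loos, elpd = elpd, differences = diffs,
                 preferred = preferred, se_rule = se_rule),
            class = "tdc_comparison")
}

#' @export
print.tdc_comparison <- function(x, ...) {
  cat("Confounder-model comparison (PSIS-LOO)\n")
  print(x$elpd, row.names = FALSE)
  cat(sprintf("preferred (parsimony unless > %g SE gain): %s\n",
              x$se_rule, x$preferred))
  invisible(x)
}
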