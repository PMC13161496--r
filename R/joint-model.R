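## Joint longitudinal-survival model: latent mediator trajectory (natural
## cubic spline mixed model), proportional hazards with piecewise-constant
## arm-specific baseline hazards, a functional of the trajectory in the
## linear predictor, and a shared random intercept acting as frailty.

## one-hot encoding (reference level dropped) of the baseline covariates
encode_w <- function(subjects) {
  cbind(age_cat1 = as.numeric(subjects$age_cat == 1),
        age_cat2 = as.numeric(subjects$age_cat == 2),
        sex1 = as.numeric(subjects$sex == 1),
        smoking1 = as.numeric(subjects$smoking == 1),
        smoking2 = as.numeric(subjects$smoking == 2),
        base_score1 = as.numeric(subjects$base_score == 1),
        base_score2 = as.numeric(subjects$base_score == 2))
}

## treatment/confounder design X = (A, I(L=1), I(L=2), A I(L=1), A I(L=2))
encode_x <- function(A, L) {
  cbind(A = A, L1 = as.numeric(L == 1), L2 = as.numeric(L == 2),
        AL1 = A * (L == 1), AL2 = A * (L == 2))
}

#' Construct joint-model parameters
#'
#' Bundles and validates the population parameters of the joint model.
#'
#' @param beta0 trajectory intercept (analysis scale).
#' @param beta1 length-5 coefficients on `(A, I(L=1), I(L=2), A I(L=1),
#'   A I(L=2))`.
#' @param beta2 length-7 coefficients on the one-hot baseline covariates.
#' @param alpha length-4 population spline coefficients.
#' @param psi 4 x 5 matrix of spline-by-X interaction coefficients.
#' @param sigma residual SD of the mediator measurements.
#' @param Sigma 4 x 4 covariance of the random effects `(R0, R1, R2, R3)`.
#' @param h0 2 x P matrix of baseline hazard rates (row 1 control, row 2
#'   intervention; one column per piece).
#' @param gamma1 length-2 confounder main effects `(I(L=1), I(L=2))` on the
#'   log hazard.
#' @param gamma2 length-2 confounder-by-treatment interactions.
#' @param gamma3 length-7 baseline-covariate effects on the log hazard.
#' @param zeta length-4 coefficients on `g(M, t) * (1, I(L=1), I(L=2), A)`.
#' @param xi frailty loading of the shared random intercept `R0`.
#' @return list of class `"joint_params"`.
#' @export
joint_params <- function(beta0, beta1, beta2, alpha, psi, sigma, Sigma,
                         h0, gamma1, gamma2, gamma3, zeta, xi) {
  psi <- as.matrix(psi)
  Sigma <- as.matrix(Sigma)
  h0 <- rbind(h0)
  stopifnot(length(beta1) == 5, length(beta2) == 7,
            length(alpha) == nrow(psi), ncol(psi) == 5,
            sigma > 0, nrow(Sigma) == 4, ncol(Sigma) == 4,
            isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-8)),
            all(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values > 0),
            nrow(h0) == 2, all(h0 >= 0),
            length(gamma1) == 2, length(gamma2) == 2, length(gamma3) == 7,
            length(zeta) == 4, length(xi) == 1)
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, alpha = alpha,
                 psi = psi, sigma = sigma, Sigma = Sigma, h0 = h0,
                 gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 zeta = zeta, xi = xi),
            class = "joint_params")
}

#' Latent mediator trajectory for one covariate configuration
#'
#' Builds the trajectory implied by the model for a subject with design
#' `X`, covariates `W` and random effects `re`:
#' `M(t) = (beta0 + R0) + beta1'X + beta2'W + sum_k (alpha_k + psi_k'X)
#' B_k(t) + sum_k R_k B^r_k(t)`, with both bases anchored to 0 at `t = 0`.
#'
#' @param params a `joint_params` object.
#' @param X length-5 design vector, see [encode_x()] via `L` and `A`.
#' @param W length-7 one-hot covariate vector.
#' @param re length-4 random-effect vector `(R0, R1, R2, R3)`.
#' @param config an `analysis_config` (knot locations).
#' @return list of class `"trajectory"` with the baseline value `M0`, the
#'   population and random-effect spline coefficients, and the knots.
#' @export
trajectory <- function(params, X, W, re, config = analysis_config()) {
  structure(list(
    M0 = params$beta0 + re[1] + sum(params$beta1 * X) + sum(params$beta2 * W),
    cpop = params$alpha + as.vector(params$psi %*% X),
    cre = re[-1],
    pop_boundary_knots = config$pop_boundary_knots,
    pop_inner_knots = config$pop_inner_knots,
    re_boundary_knots = config$re_boundary_knots,
    re_inner_knots = config$re_inner_knots
  ), class = "trajectory")
}

#' Evaluate a mediator trajectory
#'
#' @param traj a `trajectory` object.
#' @param t numeric vector of times (years).
#' @return numeric vector `M(t)` on the analysis scale.
#' @export
trajectory_value <- function(traj, t) {
  B <- natural_cubic_basis(t, traj$pop_boundary_knots, traj$pop_inner_knots)
  Br <- natural_cubic_basis(t, traj$re_boundary_knots, traj$re_inner_knots)
  as.vector(traj$M0 + B %*% traj$cpop + Br %*% traj$cre)
}

#' Functional of the mediator trajectory entering the hazard
#'
#' `kind = "legacy"`: the cumulative change of the trajectory over the
#' first `window` years, `int_0^window (M(v) - M(0)) dv`, constant in `t`.
#' `kind = "current_change"`: the change since baseline at `t`,
#' `M(t) - M(0)`. The legacy integral uses Gauss-Legendre quadrature per
#' inter-knot segment, exact for the cubic segments.
#'
#' @param traj a `trajectory` object.
#' @param t evaluation time(s); ignored for `"legacy"`.
#' @param kind `"legacy"` or `"current_change"`.
#' @param window upper limit of the legacy integral (years).
#' @return numeric vector (length 1 for `"legacy"`).
#' @export
g_functional <- function(traj, t, kind = c("legacy", "current_change"),
                         window = 3) {
  kind <- match.arg(kind)
  if (kind == "legacy") {
    IB <- basis_integral(window, traj$pop_boundary_knots, traj$pop_inner_knots)
    IBr <- basis_integral(window, traj$re_boundary_knots, traj$re_inner_knots)
    sum(IB * traj$cpop) + sum(IBr * traj$cre)
  } else {
    trajectory_value(traj, t) - traj$M0
  }
}

## log-linear part of the hazard excluding the g(M,t) term, plus the
## multiplier of g (zeta'G with G = (1, I(L=1), I(L=2), A))
surv_linpred <- function(params, A, L, W, r0) {
  Lind <- c(L == 1, L == 2)
  list(
    lp0 = sum(params$gamma1 * Lind) + sum(params$gamma2 * Lind * A) +
      sum(params$gamma3 * W) + params$xi * r0,
    zg = sum(params$zeta * c(1, Lind, A))
  )
}

piece_index <- function(t, cuts) {
  pmin(pmax(findInterval(t, cuts, rightmost.closed = TRUE), 1L),
       length(cuts) - 1L)
}

#' Hazard rate at given times
#'
#' `h(t) = h0[arm](t) * exp(gamma1'Lind + gamma2'Lind A + gamma3'W +
#' g(M, t) zeta'G + xi R0)` with piecewise-constant arm-specific baseline.
#'
#' @param params a `joint_params` object.
#' @param A treatment arm (0/1).
#' @param L confounder level (0..2).
#' @param W length-7 one-hot covariate vector.
#' @param g_value value(s) of the trajectory functional at `t`.
#' @param r0 shared random intercept.
#' @param t numeric vector of times within the follow-up range.
#' @param config an `analysis_config`.
#' @return numeric vector of hazard rates.
#' @export
hazard <- function(params, A, L, W, g_value, r0, t,
                   config = analysis_config()) {
  if (any(params$h0 < 0)) stop("baseline hazard rates must be nonnegative")
  cuts <- hazard_cuts(config)
  lp <- surv_linpred(params, A, L, W, r0)
  params$h0[A + 1, piece_index(t, cuts)] * exp(lp$lp0 + g_value * lp$zg)
}

#' Cumulative hazard
#'
#' For the legacy functional the within-piece hazard is constant in time
#' and the cumulative hazard is a closed-form sum over pieces; for the
#' current-change functional (or when `force_quadrature = TRUE`) each piece
#' is integrated by Gauss-Legendre quadrature with `config$quad_nodes`
#' nodes.
#'
#' @inheritParams hazard
#' @param traj the subject's `trajectory` object.
#' @param t upper limit of integration.
#' @param force_quadrature evaluate the legacy kind by quadrature as well
#'   (dual-path check).
#' @return cumulative hazard `H(t)`, a nonnegative scalar.
#' @export
cumulative_hazard <- function(params, A, L, W, traj, r0, t,
                              config = analysis_config(),
                              force_quadrature = FALSE) {
  stopifnot(t >= 0)
  cuts <- hazard_cuts(config)
  lp <- surv_linpred(params, A, L, W, r0)
  h0 <- params$h0[A + 1, ]
  if (config$g_kind == "legacy" && !force_quadrature) {
    g <- g_functional(traj, 0, "legacy", config$legacy_window)
    expo <- pmax(0, pmin(t, cuts[-1]) - cuts[-length(cuts)])
    return(sum(h0 * expo) * exp(lp$lp0 + g * lp$zg))
  }
  H <- 0
  for (p in seq_len(length(cuts) - 1)) {
    a <- cuts[p]; b <- min(cuts[p + 1], t)
    if (b <= a) break
    q <- gl_nodes(config$quad_nodes, a, b)
    gq <- if (config$g_kind == "legacy") {
      rep(g_functional(traj, 0, "legacy", config$legacy_window), length(q$x))
    } else {
      g_functional(traj, q$x, "current_change")
    }
    H <- H + h0[p] * sum(q$w * exp(lp$lp0 + gq * lp$zg))
  }
  H
}

#' Restricted mean survival time for one covariate configuration
#'
#' `RMST = int_0^tmax exp(-H(v)) dv`, the expected event-free time within
#' the restriction window. For the legacy functional the survival curve is
#' piecewise exponential and the integral is closed form; otherwise the
#' outer integral uses per-piece Gauss-Legendre quadrature.
#'
#' @inheritParams cumulative_hazard
#' @param t_max restriction time (years).
#' @return a value in `[0, t_max]`.
#' @export
rmst <- function(params, A, L, W, traj, r0, t_max = NULL,
                 config = analysis_config()) {
  t_max <- t_max %||% config$t_max
  stopifnot(t_max > 0)
  cuts <- hazard_cuts(config)
  lp <- surv_linpred(params, A, L, W, r0)
  h0 <- params$h0[A + 1, ]
  if (config$g_kind == "legacy") {
    g <- g_functional(traj, 0, "legacy", config$legacy_window)
    rate <- h0 * exp(lp$lp0 + g * lp$zg)
    out <- 0; Hcum <- 0
    for (p in seq_len(length(cuts) - 1)) {
      a <- cuts[p]; b <- min(cuts[p + 1], t_max)
      if (b <= a) break
      dt <- b - a
      out <- out + exp(-Hcum) *
        (if (rate[p] > 1e-12) (1 - exp(-rate[p] * dt)) / rate[p] else
           dt * (1 - rate[p] * dt / 2))
      Hcum <- Hcum + rate[p] * dt
    }
    return(out)
  }
  ## current-change kind: outer quadrature with accumulated piece starts
  out <- 0; Hstart <- 0
  for (p in seq_len(length(cuts) - 1)) {
    a <- cuts[p]; b <- min(cuts[p + 1], t_max)
    if (b <= a) break
    q <- gl_nodes(config$quad_nodes, a, b)
    Hv <- vapply(q$x, function(v) {
      qq <- gl_nodes(config$quad_nodes, a, v)
      gq <- g_functional(traj, qq$x, "current_change")
      Hstart + h0[p] * sum(qq$w * exp(lp$lp0 + gq * lp$zg))
    }, numeric(1))
    out <- out + sum(q$w * exp(-Hv))
    qq <- gl_nodes(config$quad_nodes, a, b)
    gq <- g_functional(traj, qq$x, "current_change")
    Hstart <- Hstart + h0[p] * sum(qq$w * exp(lp$lp0 + gq * lp$zg))
  }
  out
}

#' Per-subject log-likelihood components of the joint model
#'
#' Returns the three factors of the joint likelihood for each subject: the
#' Gaussian measurement density of the visits around the latent trajectory
#' (`loglik_m`), the survival density
#' `d log h(T_exit) - H(T_exit)` (`loglik_s`), and the multivariate normal
#' density of the random effects (`loglik_r`). The survival factor depends
#' on the data only through the exit time and event indicator; given the
#' random effects it never reads the observed mediator measurements.
#'
#' @param data a `tdc_data` object (mediator already on the analysis
#'   scale).
#' @param params a `joint_params` object.
#' @param re n x 4 matrix of random effects, rows in the order of
#'   `data$subjects`.
#' @param config an `analysis_config`.
#' @return data.frame with columns `id`, `loglik_m`, `loglik_s`,
#'   `loglik_r`.
#' @export
log_likelihood <- function(data, params, re, config = analysis_config()) {
  if (params$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  ev <- eigen(params$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite", call. = FALSE)
  s <- data$subjects
  n <- nrow(s)
  Wm <- encode_w(s)
  lm_ <- ls_ <- numeric(n)
  Sinv <- solve(params$Sigma)
  ldet <- determinant(params$Sigma, logarithm = TRUE)$modulus
  lr_ <- -0.5 * (4 * log(2 * pi) + as.numeric(ldet) +
                   rowSums((re %*% Sinv) * re))
  for (i in seq_len(n)) {
    X <- encode_x(s$A[i], s$L[i])[1, ]
    traj <- trajectory(params, X, Wm[i, ], re[i, ], config)
    vi <- data$visits[data$visits$id == s$id[i], , drop = FALSE]
    if (nrow(vi)) {
      mu <- trajectory_value(traj, vi$t)
      lm_[i] <- sum(stats::dnorm(vi$m, mu, params$sigma, log = TRUE))
    }
    H <- cumulative_hazard(params, s$A[i], s$L[i], Wm[i, ], traj, re[i, 1],
                           s$T_exit[i], config)
    ls_[i] <- -H
    if (s$d[i] == 1) {
      g_exit <- if (config$g_kind == "legacy") {
        g_functional(traj, 0, "legacy", config$legacy_window)
      } else {
        g_functional(traj, s$T_exit[i], "current_change")
      }
      ls_[i] <- ls_[i] + log(hazard(params, s$A[i], s$L[i], Wm[i, ], g_exit,
                                    re[i, 1], s$T_exit[i], config))
    }
  }
  data.frame(id = s$id, loglik_m = lm_, loglik_s = ls_, loglik_r = lr_)
}
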