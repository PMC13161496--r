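cfg <- analysis_config()

test_that("the anchored natural basis is zero at baseline and linear beyond the boundaries", {
  B <- natural_cubic_basis(c(0, 0.5, 3, 9.9, 14))
  expect_equal(B[1, ], rep(0, 4), ignore_attr = TRUE)
  ## second differences vanish at and beyond the boundary knots
  h <- 1e-4
  for (t0 in c(0, 10, 12)) {
    sd2 <- (natural_cubic_basis(t0 + h) - 2 * natural_cubic_basis(t0) +
              natural_cubic_basis(t0 - h)) / h^2
    expect_lt(max(abs(sd2)), 1e-3)
  }
  expect_error(natural_cubic_basis(1, inner_knots = c(5, 3, 1)), "increasing")
})

test_that("the basis spans the textbook truncated-power natural spline space", {
  knots <- c(0, 1, 3, 5, 10)
  K <- length(knots)
  dk <- function(t, j) {
    (pmax(t - knots[j], 0)^3 - pmax(t - knots[K], 0)^3) / (knots[K] - knots[j])
  }
  tg <- seq(0, 12, by = 0.1)
  ## Hastie-Tibshirani-Friedman natural spline basis (minus intercept),
  ## anchored at zero like the package basis
  ref <- cbind(tg, sapply(seq_len(K - 2), function(j) {
    dk(tg, j) - dk(tg, K - 1)
  }))
  ref <- sweep(ref, 2, ref[1, ])
  B <- natural_cubic_basis(tg)
  ## each package basis column is a linear combination of the reference
  for (k in 1:4) {
    fit <- stats::lm.fit(ref, B[, k])
    expect_lt(max(abs(fit$residuals)), 1e-8)
  }
  ## and vice versa
  for (k in seq_len(ncol(ref))) {
    fit <- stats::lm.fit(B, ref[, k])
    expect_lt(max(abs(fit$residuals)), 1e-8)
  }
})

test_that("trajectories evaluate exactly as their term-by-term definition", {
  p <- default_true_params()
  set.seed(2)
  X <- tdcmediate:::encode_x(1, 2)[1, ]
  W <- as.numeric(tdcmediate:::encode_w(data.frame(age_cat = 1, sex = 1,
                                                   smoking = 0,
                                                   base_score = 2)))
  re <- c(0.3, -0.1, 0.2, 0.05)
  traj <- trajectory(p, X, W, re, cfg)
  tt <- seq(0, 14, length.out = 50)
  got <- trajectory_value(traj, tt)
  B <- natural_cubic_basis(tt); Br <- natural_cubic_basis(tt, c(0, 10), c(1, 5))
  manual <- (p$beta0 + re[1]) + sum(p$beta1 * X) + sum(p$beta2 * W) +
    as.vector(B %*% (p$alpha + p$psi %*% X)) + as.vector(Br %*% re[2:4])
  expect_equal(got, manual, tolerance = 1e-12)
  expect_equal(got[1], p$beta0 + re[1] + sum(p$beta1 * X) + sum(p$beta2 * W),
               tolerance = 1e-12)

  flat <- trajectory(joint_params(1, rep(0, 5), rep(0, 7), rep(0, 4),
                                  matrix(0, 4, 5), 0.1, diag(4) * 0.01,
                                  p$h0, c(0, 0), c(0, 0), rep(0, 7),
                                  rep(0, 4), 0),
                     X, W, c(0.5, 0, 0, 0), cfg)
  expect_equal(trajectory_value(flat, tt), rep(1.5, 50), tolerance = 1e-12)
})

test_that("trajectory functionals: flat is zero, linear has closed form, quadrature refines", {
  p <- default_true_params()
  X <- tdcmediate:::encode_x(0, 0)[1, ]
  W <- rep(0, 7)
  flat <- trajectory(p, X, W, c(0, 0, 0, 0), cfg)
  flat$cpop[] <- 0
  expect_equal(g_functional(flat, 0, "legacy"), 0)
  expect_equal(g_functional(flat, c(1, 7), "current_change"), c(0, 0))

  ## linear trajectory M(t) = M(0) + b t built inside the spline space
  b_slope <- 0.8
  tg <- seq(0, 12, by = 0.05)
  cl <- stats::lm.fit(natural_cubic_basis(tg), b_slope * tg)$coefficients
  lin <- flat; lin$cpop <- cl
  expect_equal(g_functional(lin, 0, "legacy"), 4.5 * b_slope,
               tolerance = 1e-6)
  expect_equal(g_functional(lin, 2, "current_change"), 2 * b_slope,
               tolerance = 1e-6)

  ## generic spline trajectory: per-segment quadrature matches a fine grid
  set.seed(3)
  gen <- flat; gen$cpop <- stats::rnorm(4); gen$cre <- stats::rnorm(3)
  fine <- seq(0, 3, length.out = 100001)
  fv <- trajectory_value(gen, fine) - gen$M0
  h_f <- fine[2] - fine[1]
  trapz <- h_f * (sum(fv) - (fv[1] + fv[length(fv)]) / 2)
  expect_equal(g_functional(gen, 0, "legacy"), trapz, tolerance = 1e-8)
})

test_that("hazard follows the log-linear form with frailty scaling", {
  p <- small_params()
  W <- rep(0, 7)
  null <- joint_params(0, rep(0, 5), rep(0, 7), rep(0, 4), matrix(0, 4, 5),
                       0.1, diag(4) * 0.01,
                       rbind(rep(0.05, 6), rep(0.05, 6)),
                       c(0, 0), c(0, 0), rep(0, 7), rep(0, 4), 0)
  expect_equal(hazard(null, 0, 0, W, 0, 0, 1, cfg), 0.05)
  null$xi <- 1
  expect_equal(hazard(null, 0, 0, W, 0, log(2), 1, cfg), 0.10,
               tolerance = 1e-12)

  set.seed(4)
  W2 <- as.numeric(tdcmediate:::encode_w(data.frame(age_cat = 2, sex = 0,
                                                    smoking = 1,
                                                    base_score = 1)))
  tt <- seq(0.2, 14.5, length.out = 20)
  g <- -0.3; r0 <- 0.25
  got <- hazard(p, 1, 2, W2, g, r0, tt, cfg)
  cuts <- tdcmediate:::hazard_cuts(cfg)
  manual <- p$h0[2, findInterval(tt, cuts, rightmost.closed = TRUE)] *
    exp(p$gamma1[2] + p$gamma2[2] + sum(p$gamma3 * W2) +
          g * (p$zeta[1] + p$zeta[3] + p$zeta[4]) + p$xi * r0)
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("cumulative hazard: closed form equals quadrature, monotone in t", {
  p <- small_params()
  X <- tdcmediate:::encode_x(1, 1)[1, ]
  W <- rep(0, 7); W[3] <- 1
  set.seed(6)
  re <- c(0.2, 0.1, -0.1, 0.05)
  traj <- trajectory(p, X, W, re, cfg)
  for (t in c(0.5, 3, 7.2, 15)) {
    Hc <- cumulative_hazard(p, 1, 1, W, traj, re[1], t, cfg)
    Hq <- cumulative_hazard(p, 1, 1, W, traj, re[1], t, cfg,
                            force_quadrature = TRUE)
    expect_equal(Hc, Hq, tolerance = 1e-8)
  }
  tt <- seq(0, 15, length.out = 40)
  Hs <- vapply(tt, function(t) {
    cumulative_hazard(p, 1, 1, W, traj, re[1], t, cfg)
  }, numeric(1))
  expect_true(all(diff(Hs) >= -1e-12))

  ## constant hazard sanity
  null <- joint_params(0, rep(0, 5), rep(0, 7), rep(0, 4), matrix(0, 4, 5),
                       0.1, diag(4) * 0.01,
                       rbind(rep(0.07, 6), rep(0.07, 6)),
                       c(0, 0), c(0, 0), rep(0, 7), rep(0, 4), 0)
  expect_equal(cumulative_hazard(null, 0, 0, rep(0, 7), traj, 0, 11, cfg),
               0.07 * 11, tolerance = 1e-10)
})

test_that("RMST: forced value under zero hazard, exponential closed form, fine-grid agreement", {
  zero <- joint_params(0, rep(0, 5), rep(0, 7), rep(0, 4), matrix(0, 4, 5),
                       0.1, diag(4) * 0.01, matrix(0, 2, 6),
                       c(0, 0), c(0, 0), rep(0, 7), rep(0, 4), 0)
  X <- tdcmediate:::encode_x(0, 0)[1, ]
  traj <- trajectory(zero, X, rep(0, 7), rep(0, 4), cfg)
  expect_equal(rmst(zero, 0, 0, rep(0, 7), traj, 0, 15, cfg), 15)

  cst <- zero; cst$h0 <- matrix(0.1, 2, 6)
  expect_equal(rmst(cst, 0, 0, rep(0, 7), traj, 0, 15, cfg),
               (1 - exp(-1.5)) / 0.1, tolerance = 1e-8)

  ## current-change kind with trajectory feedback vs fine Riemann grid
  cfg_c <- analysis_config(g_kind = "current_change")
  p <- small_params()
  set.seed(8)
  re <- c(0.1, 0.15, -0.2, 0.1)
  W <- rep(0, 7); W[1] <- 1
  trj <- trajectory(p, tdcmediate:::encode_x(1, 2)[1, ], W, re, cfg_c)
  got <- rmst(p, 1, 2, W, trj, re[1], 15, cfg_c)
  grid <- seq(0, 15, length.out = 100001)
  hz <- hazard(p, 1, 2, W, g_functional(trj, grid, "current_change"),
               re[1], grid, cfg_c)
  Hg <- cumsum(c(0, (hz[-1] + hz[-length(hz)]) / 2 * diff(grid)))
  Sg <- exp(-Hg)
  riemann <- sum((Sg[-1] + Sg[-length(Sg)]) / 2 * diff(grid))
  expect_equal(got, riemann, tolerance = 1e-6)
})

test_that("log-likelihood components match direct density computations", {
  cfg2 <- analysis_config()
  sim <- generate_dataset(generator_config(n = 12, seed = 10), cfg2)
  p <- generator_config(n = 1)$params
  set.seed(11)
  re <- matrix(stats::rnorm(12 * 4, 0, 0.2), 12, 4)
  ll <- log_likelihood(sim$data, p, re, cfg2)
  expect_equal(nrow(ll), 12)

  ## manual recomputation for one subject
  i <- 5
  s <- sim$data$subjects[i, ]
  W <- as.numeric(tdcmediate:::encode_w(s))
  X <- tdcmediate:::encode_x(s$A, s$L)[1, ]
  traj <- trajectory(p, X, W, re[i, ], cfg2)
  vi <- sim$data$visits[sim$data$visits$id == s$id, ]
  lm_man <- sum(stats::dnorm(vi$m, trajectory_value(traj, vi$t), p$sigma,
                             log = TRUE))
  H <- cumulative_hazard(p, s$A, s$L, W, traj, re[i, 1], s$T_exit, cfg2)
  g <- g_functional(traj, 0, "legacy")
  ls_man <- -H + s$d * log(hazard(p, s$A, s$L, W, g, re[i, 1], s$T_exit, cfg2))
  lr_man <- mvtnorm_logd <- {
    Sinv <- solve(p$Sigma)
    -0.5 * (4 * log(2 * pi) +
              as.numeric(determinant(p$Sigma, TRUE)$modulus) +
              as.numeric(re[i, ] %*% Sinv %*% re[i, ]))
  }
  expect_equal(ll$loglik_m[i], lm_man, tolerance = 1e-10)
  expect_equal(ll$loglik_s[i], ls_man, tolerance = 1e-10)
  expect_equal(ll$loglik_r[i], lr_man, tolerance = 1e-10)

  ## event with constant hazard: log lambda - lambda * T
  cst <- joint_params(0, rep(0, 5), rep(0, 7), rep(0, 4), matrix(0, 4, 5),
                      0.1, diag(4) * 0.01, matrix(0.2, 2, 6),
                      c(0, 0), c(0, 0), rep(0, 7), rep(0, 4), 0)
  d1 <- sim$data
  d1$subjects <- d1$subjects[d1$subjects$d == 1, ][1, , drop = FALSE]
  d1$visits <- d1$visits[d1$visits$id == d1$subjects$id, ]
  ll1 <- log_likelihood(d1, cst, matrix(0, 1, 4), cfg2)
  expect_equal(ll1$loglik_s, log(0.2) - 0.2 * d1$subjects$T_exit,
               tolerance = 1e-10)

  ## given the random effects, the survival factor ignores the raw visits
  d2 <- sim$data
  d2$visits$m <- d2$visits$m + 5
  ll2 <- log_likelihood(d2, p, re, cfg2)
  expect_equal(ll2$loglik_s, ll$loglik_s, tolerance = 1e-14)
  expect_false(isTRUE(all.equal(ll2$loglik_m, ll$loglik_m)))
})
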