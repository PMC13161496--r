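cfg <- analysis_config()

test_that("expected outcome delegates to the survival model and is forced under zero hazard", {
  zero <- joint_params(0, rep(0, 5), rep(0, 7), rep(0, 4), matrix(0, 4, 5),
                       0.1, diag(4) * 0.01, matrix(0, 2, 6),
                       c(0, 0), c(0, 0), rep(0, 7), rep(0, 4), 0)
  mref <- reference_trajectory(cfg)
  expect_equal(expected_outcome(zero, 1, mref, 2, rep(0, 7), 0, cfg), 15)

  p <- small_params()
  X <- tdcmediate:::encode_x(1, 1)[1, ]
  W <- rep(0, 7)
  traj <- trajectory(p, X, W, c(0.2, 0.1, 0, -0.1), cfg)
  expect_equal(expected_outcome(p, 1, traj, 1, W, 0.2, cfg),
               rmst(p, 1, 1, W, traj, 0.2, cfg$t_max, cfg), tolerance = 1e-14)

  ## protective ordering: higher confounder level cannot raise the hazard
  ## when its log-hazard coefficients are negative and ordered
  e_l <- vapply(0:2, function(l) {
    expected_outcome(p, 0, mref, l, W, 0, cfg)
  }, numeric(1))
  expect_true(all(diff(e_l) >= 0))
})

test_that("beta terms vanish at the reference and reassemble the expected outcome", {
  p <- small_params()
  W <- as.numeric(tdcmediate:::encode_w(data.frame(age_cat = 2, sex = 1,
                                                   smoking = 0,
                                                   base_score = 1)))
  mref <- reference_trajectory(cfg)
  b0 <- beta_terms(p, 1, mref, 0, W, 0.3, cfg)
  expect_equal(b0$beta_m, 0, tolerance = 1e-12)
  expect_equal(b0$beta_l, 0, tolerance = 1e-12)
  expect_equal(b0$beta_ml, 0, tolerance = 1e-12)

  ## hazard free of the confounder level: interaction and level terms zero
  pfree <- small_params(zeta = c(0.4, 0, 0, 0.1), gamma1 = c(0, 0),
                        gamma2 = c(0, 0))
  traj <- trajectory(pfree, tdcmediate:::encode_x(0, 2)[1, ], W,
                     c(0.1, 0.2, -0.1, 0), cfg)
  bf <- beta_terms(pfree, 1, traj, 2, W, 0.1, cfg)
  expect_equal(bf$beta_l, 0, tolerance = 1e-12)
  expect_equal(bf$beta_ml, 0, tolerance = 1e-12)

  ## generic reassembly
  set.seed(33)
  bt <- beta_terms(p, 0, traj, 2, W, -0.2, cfg)
  expect_equal(bt$beta_m + bt$beta_l + bt$beta_ml + bt$beta_bar,
               expected_outcome(p, 0, traj, 2, W, -0.2, cfg),
               tolerance = 1e-10)
})

make_fixture_fits <- function(params_list, n = 150, seed = 40) {
  sim <- generate_dataset(generator_config(n = n, seed = seed), cfg)
  list(jf = fake_joint_fit(params_list, cfg, sim$data),
       tf = fake_tdc_fit(default_tdc_truth(), sim$data,
                         ndraw = length(params_list)),
       data = sim$data)
}

test_that("components match an independent slow evaluation on a small problem", {
  p <- small_params()
  fx <- make_fixture_fits(list(p), n = 60, seed = 41)
  strata <- build_strata(fx$data)[1:2, ]
  strata$weight <- c(0.6, 0.4)
  ec <- effect_components(fx$jf, fx$tf, cfg, rho = 0.4, draw_ids = 1,
                          n_re_atoms = 3, strata = strata, seed = 7)
  ## reproduce the atoms exactly as effect_components draws them
  set.seed(7 + 1)
  RE <- matrix(stats::rnorm(4 * 3), 3, 4) %*% chol(p$Sigma)
  pa <- t(sapply(1:2, function(s) {
    marginal_probs(fx$tf$draws[1, ], strata[s, 1:4], 1)
  }))
  pc <- t(sapply(1:2, function(s) {
    marginal_probs(fx$tf$draws[1, ], strata[s, 1:4], 0)
  }))
  joints <- lapply(1:2, function(s) counterfactual_joint(pa[s, ], pc[s, ], 0.4))
  slow <- slow_components(p, pa, pc, joints, strata, RE, cfg)
  expect_equal(ec$de_r, slow$de_r, tolerance = 1e-8)
  expect_equal(ec$ie_r, slow$ie_r, tolerance = 1e-8)
  expect_equal(ec$dde, slow$dde, tolerance = 1e-8)
  expect_equal(ec$die, slow$die, tolerance = 1e-8)
  expect_equal(ec$delta, slow$delta, tolerance = 1e-8)
})

test_that("current-change assembly agrees with the scalar quadrature path", {
  cfg_c <- analysis_config(g_kind = "current_change")
  p <- small_params()
  sim <- generate_dataset(generator_config(n = 50, seed = 49), cfg_c)
  jf <- fake_joint_fit(list(p), cfg_c, sim$data)
  tf <- fake_tdc_fit(default_tdc_truth(), sim$data)
  strata <- build_strata(sim$data)[1:2, ]
  strata$weight <- c(0.5, 0.5)
  ec <- effect_components(jf, tf, cfg_c, rho = 0.5, draw_ids = 1,
                          n_re_atoms = 2, strata = strata, seed = 11)
  set.seed(11 + 1)
  RE <- matrix(stats::rnorm(4 * 2), 2, 4) %*% chol(p$Sigma)
  pa <- t(sapply(1:2, function(s) {
    marginal_probs(tf$draws[1, ], strata[s, 1:4], 1)
  }))
  pc <- t(sapply(1:2, function(s) {
    marginal_probs(tf$draws[1, ], strata[s, 1:4], 0)
  }))
  joints <- lapply(1:2, function(s) counterfactual_joint(pa[s, ], pc[s, ], 0.5))
  slow <- slow_components(p, pa, pc, joints, strata, RE, cfg_c)
  ## grid-trapezoid assembly vs nested-quadrature scalar path: agreement
  ## to the grid resolution (absolute, in years)
  expect_lt(abs(ec$de_r - slow$de_r), 2e-3)
  expect_lt(abs(ec$ie_r - slow$ie_r), 2e-3)
  expect_lt(abs(ec$delta - slow$delta), 2e-3)
})

test_that("null model gives identically zero components", {
  null <- joint_params(0, rep(0, 5), rep(0, 7), rep(0, 4), matrix(0, 4, 5),
                       0.1, diag(4) * 0.04, matrix(0.05, 2, 6),
                       c(0, 0), c(0, 0), rep(0, 7), rep(0, 4), 0)
  fx <- make_fixture_fits(list(null), n = 80, seed = 42)
  ec <- effect_components(fx$jf, fx$tf, cfg, rho = 0.5, draw_ids = 1,
                          n_re_atoms = 5, seed = 2)
  for (q in c("de_r", "ie_r", "dde", "die", "delta", "de", "ie", "te")) {
    expect_lt(abs(ec[[q]]), 1e-10)
  }
})

test_that("an L-free hazard forces the interaction components to zero", {
  pfree <- small_params(zeta = c(0.5, 0, 0, 0.12), gamma1 = c(0, 0),
                        gamma2 = c(0, 0))
  fx <- make_fixture_fits(list(pfree), n = 80, seed = 43)
  ec <- effect_components(fx$jf, fx$tf, cfg, rho = 0.3, draw_ids = 1,
                          n_re_atoms = 4, seed = 3)
  expect_lt(abs(ec$dde), 1e-10)
  expect_lt(abs(ec$die), 1e-10)
  expect_lt(abs(ec$delta), 1e-10)
  expect_equal(ec$de, ec$de_r, tolerance = 1e-12)
  expect_equal(ec$ie, ec$ie_r, tolerance = 1e-12)
})

test_that("assembly algebra: DE+IE=TE, TE invariant to rho, delta affine in rho", {
  set.seed(44)
  plist <- lapply(1:4, function(j) {
    p <- small_params(zeta = c(0.4, 0.1, 0.15, 0.1) + stats::rnorm(4, 0, 0.05),
                      xi = 0.3 + stats::rnorm(1, 0, 0.05))
    p
  })
  fx <- make_fixture_fits(plist, n = 100, seed = 45)
  ec0 <- effect_components(fx$jf, fx$tf, cfg, rho = 0, draw_ids = 1:4,
                           n_re_atoms = 4, seed = 5)
  ec5 <- effect_components(fx$jf, fx$tf, cfg, rho = 0.5, draw_ids = 1:4,
                           n_re_atoms = 4, seed = 5)
  ec1 <- effect_components(fx$jf, fx$tf, cfg, rho = 1, draw_ids = 1:4,
                           n_re_atoms = 4, seed = 5)
  me <- mediational_effects(ec5)
  expect_equal(me$de + me$ie, me$te, tolerance = 1e-12)
  ## the sensitivity term cancels from the total effect
  expect_equal(mediational_effects(ec0)$te, mediational_effects(ec1)$te,
               tolerance = 1e-10)
  ## identifiable interaction part is rho-invariant
  expect_equal(ec0$die - ec0$dde, ec1$die - ec1$dde, tolerance = 1e-10)
  ## delta is affine in rho: three-point collinearity
  expect_equal(ec5$delta, (ec0$delta + ec1$delta) / 2, tolerance = 1e-10)
  ## shifting delta moves DE and IE in opposite directions
  ecs <- ec5
  ecs$delta <- ecs$delta + 0.1
  mes <- mediational_effects(ecs)
  expect_equal(mes$de, me$de + 0.1, tolerance = 1e-12)
  expect_equal(mes$ie, me$ie - 0.1, tolerance = 1e-12)
})

test_that("per-stratum sensitivity extremes match brute force over endpoint assignments", {
  p <- small_params()
  fx <- make_fixture_fits(list(p), n = 60, seed = 46)
  strata <- build_strata(fx$data)[1:3, ]
  strata$weight <- c(0.5, 0.3, 0.2)
  ec0 <- effect_components(fx$jf, fx$tf, cfg, rho = 0, draw_ids = 1,
                           n_re_atoms = 3, strata = strata, seed = 8)
  ec1 <- effect_components(fx$jf, fx$tf, cfg, rho = 1, draw_ids = 1,
                           n_re_atoms = 3, strata = strata, seed = 8)
  ex <- rho_extremes(ec0, ec1)
  d0 <- attr(ec0, "delta_strat"); d1 <- attr(ec1, "delta_strat")
  deltas <- sapply(0:(2^3 - 1), function(mask) {
    pick <- as.logical(bitwAnd(2^(0:2), mask))
    sum(ifelse(pick, d1[1, ], d0[1, ]))
  })
  expect_equal(ex$de_min, ec0$de_r - ec0$dde + min(deltas), tolerance = 1e-10)
  expect_equal(ex$de_max, ec0$de_r - ec0$dde + max(deltas), tolerance = 1e-10)
  expect_equal(ex$ie_min, ec0$ie_r + ec0$die - max(deltas), tolerance = 1e-10)
  expect_equal(ex$ie_max, ec0$ie_r + ec0$die - min(deltas), tolerance = 1e-10)
  expect_lte(ex$de_min, ex$de_max)
  ## degenerate case: equal deltas at both endpoints
  ex_same <- rho_extremes(ec0, ec0)
  expect_equal(ex_same$de_min, ex_same$de_max, tolerance = 1e-12)
})

test_that("Kaplan-Meier total effect: identical arms, step areas, product-limit oracle", {
  s <- data.frame(id = sprintf("x%02d", 1:40),
                  A = rep(c(0, 1), each = 20),
                  age_cat = 0, sex = 0, smoking = 0, base_score = 0,
                  L = 0, T_exit = rep(c(2, 5, 9, 15), 10),
                  d = rep(c(1, 0), 20))
  s$T_exit <- rep(s$T_exit[1:20], 2)
  s$d <- rep(s$d[1:20], 2)
  dd <- tdcmediate:::new_tdc_data(s, data.frame(id = character(0),
                                                t = numeric(0),
                                                m = numeric(0)))
  expect_equal(km_te(dd, n_boot = 0)$te, 0, tolerance = 1e-12)

  ## no events in one arm, all events at t = 5 in the other
  s2 <- s
  s2$d[s2$A == 1] <- 0; s2$T_exit[s2$A == 1] <- 15
  s2$d[s2$A == 0] <- 1; s2$T_exit[s2$A == 0] <- 5
  dd2 <- tdcmediate:::new_tdc_data(s2, dd$visits)
  expect_equal(km_te(dd2, n_boot = 0)$te, 10, tolerance = 1e-12)

  ## random censored data against a hand-coded product-limit estimator
  set.seed(47)
  tt <- round(stats::rexp(60, 0.15), 3)
  ce <- stats::runif(60, 0, 20)
  s3 <- data.frame(id = sprintf("y%02d", 1:60), A = rep(c(0, 1), 30),
                   age_cat = 0, sex = 0, smoking = 0, base_score = 0, L = 0,
                   T_exit = pmin(tt, ce, 15), d = as.integer(tt <= pmin(ce, 15)))
  dd3 <- tdcmediate:::new_tdc_data(s3, dd$visits)
  hand_area <- function(time, event, tmax) {
    ut <- sort(unique(time[event == 1]))
    Spr <- 1; area <- 0; last <- 0
    for (u in ut) {
      if (u > tmax) break
      area <- area + Spr * (u - last)
      nrisk <- sum(time >= u)
      dev <- sum(time == u & event == 1)
      Spr <- Spr * (1 - dev / nrisk)
      last <- u
    }
    area + Spr * (tmax - last)
  }
  got <- km_te(dd3, n_boot = 0)
  expect_equal(got$area_treated,
               hand_area(s3$T_exit[s3$A == 1], s3$d[s3$A == 1], 15),
               tolerance = 1e-10)
  expect_equal(got$area_control,
               hand_area(s3$T_exit[s3$A == 0], s3$d[s3$A == 0], 15),
               tolerance = 1e-10)

  s4 <- s3[s3$A == 1, ]
  dd4 <- tdcmediate:::new_tdc_data(s4, dd$visits)
  expect_error(km_te(dd4), "both arms")
})

test_that("restricted summaries discard negative-effect draws and bound the proportion mediated", {
  eff <- data.frame(de = c(0.5, -0.2, 1.0, 0.3, -0.1),
                    ie = c(0.5, 0.8, 0.2, 0.4, 0.6))
  eff$te <- eff$de + eff$ie
  rs <- restricted_summary(eff)
  expect_equal(rs$discarded_fraction, 0.4)
  keep <- eff[eff$de >= 0 & eff$ie >= 0, ]
  expect_equal(rs$restricted$mean[rs$restricted$quantity == "DE"],
               mean(keep$de), tolerance = 1e-12)
  pm <- keep$ie / keep$te
  expect_equal(unname(rs$prop_mediated["mean"]), mean(pm), tolerance = 1e-12)
  expect_true(all(pm >= 0 & pm <= 1))

  allpos <- data.frame(de = c(0.1, 0.2), ie = c(0.3, 0.1))
  allpos$te <- allpos$de + allpos$ie
  rs2 <- restricted_summary(allpos)
  expect_equal(rs2$discarded_fraction, 0)
  expect_equal(rs2$restricted, rs2$full)

  allneg <- data.frame(de = c(-1, -2), ie = c(0.3, 0.1))
  allneg$te <- allneg$de + allneg$ie
  rs3 <- restricted_summary(allneg)
  expect_null(rs3$restricted)
  expect_match(rs3$note, "discarded")
})

test_that("switching the reference level leaves assembled effects unchanged", {
  ## DE and IE are contrasts; the four-term decomposition depends on the
  ## reference but its assembly does not
  p <- small_params()
  W <- rep(0, 7)
  mref <- reference_trajectory(cfg)
  set.seed(48)
  re <- c(0.2, 0.1, -0.05, 0.08)
  m00 <- trajectory(p, tdcmediate:::encode_x(0, 0)[1, ], W, re, cfg)
  m11 <- trajectory(p, tdcmediate:::encode_x(1, 1)[1, ], W, re, cfg)
  for (lref in 0:2) {
    bt <- beta_terms(p, 1, m11, 1, W, re[1], cfg, l_ref = lref, m_ref = m00)
    expect_equal(bt$beta_m + bt$beta_l + bt$beta_ml + bt$beta_bar,
                 expected_outcome(p, 1, m11, 1, W, re[1], cfg),
                 tolerance = 1e-10)
  }
})
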