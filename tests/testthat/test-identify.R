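test_that("p11 bounds match the margin constraints, including infeasible and forced cases", {
  b <- p11_bounds(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5))
  expect_equal(c(b$p_min, b$p_max), c(0.3, 0.3))
  expect_true(b$feasible)

  b2 <- p11_bounds(c(0.6, 0.2, 0.2), c(0.1, 0.2, 0.7))
  expect_false(b2$feasible)
  expect_equal(c(b2$p_min, b2$p_max), c(0.7, 0.2))

  b3 <- p11_bounds(c(0.1, 0.4, 0.5), c(0.3, 0.4, 0.3))
  expect_equal(c(b3$p_min, b3$p_max), c(0.2, 0.4))
  g <- grid_p11_oracle(c(0.1, 0.4, 0.5), c(0.3, 0.4, 0.3), npts = 100001)
  expect_equal(b3$p_min, g$p_min, tolerance = 1e-4)
  expect_equal(b3$p_max, g$p_max, tolerance = 1e-4)

  expect_error(p11_bounds(c(0.5, 0.6, 0.2), c(1, 0, 0)), "probability")
})

test_that("monotone coupling reproduces both margins with structural zeros", {
  set.seed(42)
  for (rep in 1:200) {
    pa <- rand_simplex(); pc <- rand_simplex()
    f <- monotonicity_feasible(pa, pc)
    expect_equal(f$feasible, grid_p11_oracle(pa, pc, npts = 2001)$feasible)
    if (!f$feasible) next
    rho <- stats::runif(1)
    J <- counterfactual_joint(pa, pc, rho)
    expect_equal(unname(colSums(J)), pa, tolerance = 1e-12)
    expect_equal(unname(rowSums(J)), pc, tolerance = 1e-12)
    expect_true(all(J[lower.tri(J)] == 0))
    expect_true(all(J >= 0))
  }
})

test_that("worked coupling examples: forced diagonal, maximal shift, midpoint", {
  J <- counterfactual_joint(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5), 0.7)
  expect_equal(unname(J), diag(c(0.2, 0.3, 0.5)), tolerance = 1e-12,
               ignore_attr = TRUE)

  J2 <- counterfactual_joint(c(0, 0, 1), c(1, 0, 0), 0.3)
  expect_equal(unname(J2[1, 3]), 1)
  expect_equal(sum(abs(J2)) - J2[1, 3], 0)

  J3 <- counterfactual_joint(c(0.1, 0.4, 0.5), c(0.3, 0.4, 0.3), 0.5)
  expect_equal(unname(c(J3[1, 1], J3[1, 2], J3[1, 3], J3[2, 2], J3[2, 3],
                        J3[3, 3])),
               c(0.1, 0.1, 0.1, 0.3, 0.1, 0.3), tolerance = 1e-12)
  expect_error(counterfactual_joint(c(0.6, 0.2, 0.2), c(0.1, 0.2, 0.7), 0.5),
               "infeasible")
})

test_that("step monotonicity is fully determined and detects improper cases", {
  s <- step_monotone_joint(c(0.1, 0.4, 0.5), c(0.3, 0.4, 0.3))
  expect_true(s$valid)
  expect_equal(unname(c(s$joint[1, 1], s$joint[1, 2], s$joint[1, 3],
                        s$joint[2, 2], s$joint[2, 3], s$joint[3, 3])),
               c(0.1, 0.2, 0, 0.2, 0.2, 0.3), tolerance = 1e-12)
  expect_equal(unname(rowSums(s$joint)), c(0.3, 0.4, 0.3), tolerance = 1e-12)
  expect_equal(unname(colSums(s$joint)), c(0.1, 0.4, 0.5), tolerance = 1e-12)

  s2 <- step_monotone_joint(c(0.1, 0.2, 0.7), c(0.5, 0.3, 0.2))
  expect_false(s2$valid)
  expect_equal(s2$violation, -0.2, tolerance = 1e-12)

  s3 <- step_monotone_joint(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5))
  expect_equal(unname(s3$joint), diag(c(0.2, 0.3, 0.5)), tolerance = 1e-12)
})

test_that("K-level coupling: binary case unique, K=3 matches, K=4 margins hold", {
  k2 <- k_level_monotone_joint(c(0.3, 0.7), c(0.6, 0.4))
  expect_equal(unname(k2), rbind(c(0.3, 0.3), c(0, 0.4)), tolerance = 1e-9)

  for (rho in c(0, 0.3, 1)) {
    pa <- c(0.1, 0.4, 0.5); pc <- c(0.3, 0.4, 0.3)
    expect_equal(unname(k_level_monotone_joint(pa, pc, rho)),
                 unname(counterfactual_joint(pa, pc, rho)), tolerance = 1e-7,
                 ignore_attr = TRUE)
  }

  set.seed(11)
  done <- 0
  while (done < 30) {
    pc4 <- rand_simplex(4)
    ## treated margin stochastically larger: shift mass upward
    pa4 <- rev(sort(pc4 + stats::runif(4, 0, 0.2)))
    pa4 <- (pa4 / sum(pa4))[c(4, 3, 2, 1)]
    sens <- stats::runif(3)
    J <- tryCatch(k_level_monotone_joint(pa4, pc4, sens),
                  error = function(e) NULL)
    if (is.null(J)) next
    done <- done + 1
    expect_equal(unname(colSums(J)), pa4, tolerance = 1e-7)
    expect_equal(unname(rowSums(J)), pc4, tolerance = 1e-7)
    expect_true(all(J[lower.tri(J)] == 0))
  }
})

test_that("partial-identification bounds equal transportation-polytope vertex extremes", {
  pa <- c(0.1, 0.4, 0.5); pc <- c(0.3, 0.4, 0.3)
  cw <- matrix(2.5, 3, 3)
  bc <- partial_id_bounds(pa, pc, cw)
  expect_equal(c(bc$min, bc$max), c(2.5, 2.5), tolerance = 1e-9)
  b0 <- partial_id_bounds(pa, pc, matrix(0, 3, 3))
  expect_equal(c(b0$min, b0$max), c(0, 0), tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:25) {
    pa <- rand_simplex(); pc <- rand_simplex()
    w <- matrix(stats::rnorm(9), 3, 3)
    lp <- partial_id_bounds(pa, pc, w)
    bf <- tp_vertex_extremes(pa, pc, w)
    expect_equal(lp$min, bf$min, tolerance = 1e-7)
    expect_equal(lp$max, bf$max, tolerance = 1e-7)
    expect_equal(sum(lp$argmin * w), lp$min, tolerance = 1e-7)
    expect_equal(sum(lp$argmax * w), lp$max, tolerance = 1e-7)
  }
})

test_that("linear functionals are affine in rho with endpoint extremes inside partial-id range", {
  set.seed(9)
  for (rep in 1:50) {
    pa <- rand_simplex(); pc <- rand_simplex()
    if (!monotonicity_feasible(pa, pc)$feasible) next
    w <- matrix(stats::rnorm(9), 3, 3)
    f <- vapply(c(0, 0.5, 1), function(r) {
      sum(counterfactual_joint(pa, pc, r) * w)
    }, numeric(1))
    expect_equal(f[2], (f[1] + f[3]) / 2, tolerance = 1e-10)
    pidb <- partial_id_bounds(pa, pc, w)
    expect_gte(min(f) - pidb$min, -1e-8)
    expect_lte(max(f) - pidb$max, 1e-8)
  }
})

test_that("empty middle category collapses to the fully identified binary case", {
  pa <- c(0.25, 0, 0.75); pc <- c(0.6, 0, 0.4)
  b <- p11_bounds(pa, pc)
  expect_equal(b$p_min, b$p_max, tolerance = 1e-12)
  J <- counterfactual_joint(pa, pc, 0.5)
  k2 <- k_level_monotone_joint(c(0.25, 0.75), c(0.6, 0.4))
  expect_equal(unname(J[c(1, 3), c(1, 3)]), unname(k2), tolerance = 1e-9)
  expect_equal(sum(J[2, ]) + sum(J[, 2]), 0)
})

test_that("feasibility diagnostics aggregate over strata and draws", {
  marg <- data.frame(
    draw = c(1, 1, 2, 2),
    stratum = c(1, 2, 1, 2),
    phi1 = c(0.1, 0.6, 0.1, 0.2), phi2 = c(0.4, 0.2, 0.4, 0.3),
    phi3 = c(0.5, 0.2, 0.5, 0.5),
    phi4 = c(0.3, 0.1, 0.3, 0.2), phi5 = c(0.4, 0.2, 0.4, 0.3),
    phi6 = c(0.3, 0.7, 0.3, 0.5))
  rep_ <- check_monotonicity(marg)
  expect_equal(rep_$prop_draws_infeasible, 0.5)
  expect_equal(unname(rep_$stratum_failure_prop["2"]), 0.5)
  expect_true(all(rep_$table$p_min[rep_$table$feasible] <=
                    rep_$table$p_max[rep_$table$feasible] + 1e-9))
})
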