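## Assembly of the causal estimands: the four-term decomposition of the
## expected restricted time, the identifiable parts DE(r), IE(r), dDE,
## dIE, the sensitivity term delta built from the counterfactual coupling,
## the assembled DE/IE/TE posterior, the nonparametric Kaplan-Meier total
## effect, and positivity-restricted summaries.

#' Expected restricted event-free time for one configuration
#'
#' The model-implied expected outcome `E(T | a, m, l, w, r0)`: the RMST of
#' the hazard evaluated at treatment `a`, mediator trajectory `m`,
#' confounder level `l`, covariates `w` and shared random intercept `r0`.
#' Delegates to [rmst()].
#'
#' @param params a `joint_params` draw.
#' @param a treatment arm (0/1).
#' @param m a `trajectory` object (the mediator trajectory held fixed).
#' @param l confounder level.
#' @param w length-7 one-hot covariate vector.
#' @param r0 shared random intercept.
#' @param config an `analysis_config`.
#' @return expected event-free years in `[0, t_max]`.
#' @export
expected_outcome <- function(params, a, m, l, w, r0,
                             config = analysis_config()) {
  rmst(params, a, l, w, m, r0, config$t_max, config)
}

#' Reference trajectory with zero change from baseline
#'
#' The default reference mediator trajectory: flat at the profile's
#' baseline value, so that the trajectory functional vanishes
#' (`g(m_ref, t) = 0` for both functional kinds).
#'
#' @param config an `analysis_config`.
#' @return a `trajectory` object.
#' @export
reference_trajectory <- function(config = analysis_config()) {
  structure(list(M0 = 0, cpop = rep(0, length(config$pop_inner_knots) + 1),
                 cre = rep(0, length(config$re_inner_knots) + 1),
                 pop_boundary_knots = config$pop_boundary_knots,
                 pop_inner_knots = config$pop_inner_knots,
                 re_boundary_knots = config$re_boundary_knots,
                 re_inner_knots = config$re_inner_knots),
            class = "trajectory")
}

#' Four-term decomposition of the expected outcome
#'
#' Decomposes `E(T | a, m, l, w, r0)` against a reference trajectory and
#' reference confounder level into the mediator main effect `beta_m`, the
#' confounder main effect `beta_l`, the mediator-by-confounder additive
#' interaction `beta_ml`, and the reference level `beta_bar`; they satisfy
#' `beta_m + beta_l + beta_ml + beta_bar = E(T | a, m, l, w, r0)`.
#'
#' @inheritParams expected_outcome
#' @param l_ref reference confounder level (default 0).
#' @param m_ref reference trajectory (default [reference_trajectory()]).
#' @return named list `beta_m`, `beta_l`, `beta_ml`, `beta_bar`.
#' @export
beta_terms <- function(params, a, m, l, w, r0, config = analysis_config(),
                       l_ref = 0, m_ref = reference_trajectory(config)) {
  E <- function(mm, ll) expected_outcome(params, a, mm, ll, w, r0, config)
  e_ml <- E(m, l); e_rl <- E(m_ref, l)
  e_mr <- E(m, l_ref); e_rr <- E(m_ref, l_ref)
  list(beta_m = e_mr - e_rr,
       beta_l = e_rl - e_rr,
       beta_ml = e_ml - e_rl - e_mr + e_rr,
       beta_bar = e_rr)
}

## vectorised RMST for the legacy functional: `loglin` is the log-linear
## part of the hazard (including g * zeta'G), `arm` the arm per scenario
rmst_legacy_vec <- function(loglin, arm, h0, cuts) {
  P <- ncol(h0)
  dt <- diff(cuts)
  rates <- h0[arm + 1, , drop = FALSE] * exp(loglin)
  Hinc <- sweep(rates, 2, dt, "*")
  out <- 0; Hcum <- 0
  for (p in seq_len(P)) {
    r <- rates[, p]
    term <- ifelse(r > 1e-12, (1 - exp(-r * dt[p])) / pmax(r, 1e-300),
                   dt[p] * (1 - r * dt[p] / 2))
    out <- out + exp(-Hcum) * term
    Hcum <- Hcum + Hinc[, p]
  }
  out
}

## vectorised RMST for the current-change functional on a uniform grid:
## `static` additive log-hazard per scenario, `dM` scenarios x grid matrix
## of trajectory changes, `zg` per scenario
rmst_current_vec <- function(static, zg, dM, arm, h0, cuts, grid) {
  pg <- piece_index(grid, cuts)
  h0g <- h0[, pg, drop = FALSE]
  h <- h0g[arm + 1, , drop = FALSE] * exp(static + zg * dM)
  dt <- grid[2] - grid[1]
  G <- length(grid)
  Hmid <- (h[, -G, drop = FALSE] + h[, -1, drop = FALSE]) / 2 * dt
  H <- cbind(0, t(apply(Hmid, 1, cumsum)))
  S <- exp(-H)
  as.vector((S[, -G, drop = FALSE] + S[, -1, drop = FALSE]) %*%
              rep(dt / 2, G - 1))
}

#' Per-draw components of the mediational effects
#'
#' For each posterior draw of the joint model (paired with a draw of the
#' confounder model), evaluates the identifiable components `DE(r)`,
#' `IE(r)`, `dDE`, `dIE` and the sensitivity term `delta` by exact
#' summation over the baseline strata and confounder levels and Monte
#' Carlo integration over the random effects, with the random-effect atoms
#' shared across every scenario within a draw. Draws whose marginals are
#' infeasible for monotonicity in at least one stratum are excluded (and
#' counted) or clipped, per `config$infeasible`.
#'
#' @param fit a `joint_fit`.
#' @param tdc a `tdc_fit` on the same data.
#' @param config an `analysis_config`; `rho` gives the sensitivity value
#'   when `rho_policy = "fixed"`.
#' @param rho overrides `config$rho`.
#' @param draw_ids joint-model draw indices to evaluate (default: all,
#'   thinned to at most `max_draws`).
#' @param max_draws cap on the number of evaluated draws.
#' @param n_re_atoms random-effect atoms per draw (default from config).
#' @param strata optional `stratum_table` (default: built from the fit's
#'   data).
#' @param seed seed for the random-effect atoms.
#' @return data.frame of class `"effect_components"` with one row per
#'   draw: `de_r, ie_r, dde, die, delta, de, ie, te, excluded`; attribute
#'   `"delta_strat"` holds the weighted per-stratum delta contributions
#'   (draws x strata), attribute `"rho"` the value used.
#' @export
effect_components <- function(fit, tdc, config = NULL, rho = NULL,
                              draw_ids = NULL, max_draws = 500,
                              n_re_atoms = NULL, strata = NULL, seed = 1) {
  stopifnot(inherits(fit, "joint_fit"), inherits(tdc, "tdc_fit"))
  config <- config %||% fit$config
  rho <- rho %||% config$rho
  n_re_atoms <- n_re_atoms %||% config$n_re_atoms
  strata <- strata %||% build_strata(fit$data)
  ndraw_all <- nrow(fit$draws)
  draw_ids <- draw_ids %||%
    unique(round(seq(1, ndraw_all, length.out = min(max_draws, ndraw_all))))
  ns <- nrow(strata)
  Wd <- encode_w(strata)
  wgt <- strata$weight
  legacy <- config$g_kind == "legacy"
  cuts <- hazard_cuts(config)
  natoms <- n_re_atoms
  ## scenario grid: stratum x atom x arm x mediator-world x level, with
  ## world 1 = reference trajectory, worlds 2..7 = (arm_m, l_m)
  worlds_am <- c(NA, 0, 0, 0, 1, 1, 1)
  worlds_lm <- c(NA, 0, 1, 2, 0, 1, 2)
  IB <- basis_integral(config$legacy_window, config$pop_boundary_knots,
                       config$pop_inner_knots)
  IBr <- basis_integral(config$legacy_window, config$re_boundary_knots,
                        config$re_inner_knots)
  grid <- if (!legacy) seq(0, config$t_max, length.out = 241) else NULL
  Bg <- if (!legacy) natural_cubic_basis(grid, config$pop_boundary_knots,
                                         config$pop_inner_knots) else NULL
  Brg <- if (!legacy) natural_cubic_basis(grid, config$re_boundary_knots,
                                          config$re_inner_knots) else NULL
  ntd <- nrow(tdc$draws)
  out <- data.frame(draw = draw_ids, de_r = NA_real_, ie_r = NA_real_,
                    dde = NA_real_, die = NA_real_, delta = NA_real_,
                    excluded = FALSE)
  delta_strat <- matrix(NA_real_, length(draw_ids), ns)
  X_world <- encode_x(worlds_am[-1], worlds_lm[-1])   # 6 x 5
  for (jj in seq_along(draw_ids)) {
    j <- draw_ids[jj]
    params <- draw_params(fit, j)
    th_tdc <- tdc$draws[((j - 1) %% ntd) + 1, ]
    ## stratum-level confounder probabilities under both arms
    pa <- t(vapply(seq_len(ns), function(s) {
      marginal_probs(th_tdc, strata[s, W_COLS], 1, tdc$variant)
    }, numeric(3)))
    pc <- t(vapply(seq_len(ns), function(s) {
      marginal_probs(th_tdc, strata[s, W_COLS], 0, tdc$variant)
    }, numeric(3)))
    feas <- vapply(seq_len(ns), function(s) {
      monotonicity_feasible(pa[s, ], pc[s, ])$feasible
    }, logical(1))
    if (any(!feas) && config$infeasible == "exclude") {
      out$excluded[jj] <- TRUE
      next
    }
    joints <- lapply(seq_len(ns), function(s) {
      if (feas[s]) return(counterfactual_joint(pa[s, ], pc[s, ], rho))
      ## clip: midpoint free probability, negatives zeroed, renormalised
      b <- p11_bounds(pa[s, ], pc[s, ])
      p11 <- (b$p_min + b$p_max) / 2
      p <- matrix(0, 3, 3)
      p[1, 1] <- pa[s, 1]; p[2, 2] <- p11; p[3, 3] <- pc[s, 3]
      p[1, 2] <- pa[s, 2] - p11; p[2, 3] <- pc[s, 2] - p11
      p[1, 3] <- p11 - (1 - pa[s, 3] - pc[s, 1])
      p[p < 0] <- 0
      p / sum(p)
    })
    ## random-effect atoms, shared across every scenario of this draw
    set.seed(seed + j)
    RE <- matrix(stats::rnorm(4 * natoms), natoms, 4) %*% chol(params$Sigma)
    ## log-linear hazard pieces
    eta_w <- as.vector(Wd %*% params$gamma3)                     # ns
    eta_al <- outer(0:1, 0:2, Vectorize(function(a, l) {
      sum(params$gamma1 * c(l == 1, l == 2)) +
        a * sum(params$gamma2 * c(l == 1, l == 2))
    }))                                                          # 2 x 3
    zg_al <- outer(0:1, 0:2, Vectorize(function(a, l) {
      sum(params$zeta * c(1, l == 1, l == 2, a))
    }))                                                          # 2 x 3
    gg <- expand.grid(s = seq_len(ns), at = seq_len(natoms), a = 0:1,
                      mw = 1:7, l = 0:2)
    loglin_static <- eta_w[gg$s] + eta_al[cbind(gg$a + 1, gg$l + 1)] +
      params$xi * RE[gg$at, 1]
    zg_v <- zg_al[cbind(gg$a + 1, gg$l + 1)]
    if (legacy) {
      gpop_w <- c(0, as.vector((X_world %*% t(params$psi)) %*% IB) +
                    sum(params$alpha * IB))                      # 7
      gre_at <- as.vector(RE[, 2:4, drop = FALSE] %*% IBr)       # natoms
      g_v <- gpop_w[gg$mw] + (gg$mw > 1) * gre_at[gg$at]
      Evec <- rmst_legacy_vec(loglin_static + g_v * zg_v, gg$a,
                              params$h0, cuts)
    } else {
      ## trajectory change on the grid per world (7 x G) and atom (natoms
      ## x G): world w change = Bg %*% (alpha + psi' X_w), reference = 0
      cpop_w <- matrix(0, 7, length(grid))
      for (w_ in 2:7) {
        cpop_w[w_, ] <- as.vector(Bg %*% (params$alpha +
                                            as.vector(params$psi %*% X_world[w_ - 1, ])))
      }
      cre_at <- RE[, 2:4, drop = FALSE] %*% t(Brg)               # natoms x G
      dM <- cpop_w[gg$mw, , drop = FALSE] +
        (gg$mw > 1) * cre_at[gg$at, , drop = FALSE]
      Evec <- rmst_current_vec(loglin_static, zg_v, dM, gg$a,
                               params$h0, cuts, grid)
    }
    Earr <- array(Evec, c(ns, natoms, 2, 7, 3))
    ## beta terms (l_ref = 0 is level index 1; reference world index 1);
    ## the subtracted lower-dimensional slices recycle along the dropped
    ## trailing dimension(s), i.e. are broadcast across worlds/levels
    bbar <- Earr[, , , 1, 1]                                     # ns x at x 2
    bm <- Earr[, , , , 1] - array(rep(bbar, 7), c(ns, natoms, 2, 7))
    bl <- Earr[, , , 1, ] - array(rep(bbar, 3), c(ns, natoms, 2, 3))
    bml <- Earr
    for (l_ in 1:3) {
      bml[, , , , l_] <- bml[, , , , l_] -
        array(rep(Earr[, , , 1, l_], 7), c(ns, natoms, 2, 7))
    }
    for (w_ in 1:7) {
      bml[, , , w_, ] <- bml[, , , w_, ] -
        array(rep(Earr[, , , w_, 1], 3), c(ns, natoms, 2, 3))
    }
    bml <- bml + array(rep(bbar, 21), c(ns, natoms, 2, 7, 3))
    ## per-stratum sums over levels, then atom means, then stratum weights
    pa_arr <- pa; pc_arr <- pc
    m_at <- function(x) apply(x, 1, mean)                        # ns vector
    ## DE(r)
    t1 <- matrix(0, ns, natoms)
    for (lp in 0:2) {
      t1 <- t1 + pc_arr[, lp + 1] * (bm[, , 2, 2 + lp] - bm[, , 1, 2 + lp])
    }
    t2 <- matrix(0, ns, natoms)
    for (l_ in 0:2) {
      t2 <- t2 + pa_arr[, l_ + 1] * bl[, , 2, l_ + 1] -
        pc_arr[, l_ + 1] * bl[, , 1, l_ + 1]
    }
    t3 <- bbar[, , 2] - bbar[, , 1]
    de_r_s <- m_at(t1 + t2 + t3)
    ## IE(r)
    t4 <- matrix(0, ns, natoms)
    for (l_ in 0:2) {
      t4 <- t4 + pa_arr[, l_ + 1] * bm[, , 2, 5 + l_] -
        pc_arr[, l_ + 1] * bm[, , 2, 2 + l_]
    }
    ie_r_s <- m_at(t4)
    ## interaction components
    t5 <- matrix(0, ns, natoms)
    for (lp in 0:2) {
      t5 <- t5 + pc_arr[, lp + 1] * bml[, , 1, 2 + lp, lp + 1]
    }
    dde_s <- m_at(t5)
    t6 <- matrix(0, ns, natoms)
    for (l_ in 0:2) {
      t6 <- t6 + pa_arr[, l_ + 1] * bml[, , 2, 5 + l_, l_ + 1]
    }
    die_s <- m_at(t6)
    t7 <- matrix(0, ns, natoms)
    for (l_ in 0:2) for (lp in 0:2) {
      Jv <- vapply(joints, function(J) J[lp + 1, l_ + 1], numeric(1))
      t7 <- t7 + Jv * bml[, , 2, 2 + lp, l_ + 1]
    }
    delta_s <- m_at(t7)
    out$de_r[jj] <- sum(wgt * de_r_s)
    out$ie_r[jj] <- sum(wgt * ie_r_s)
    out$dde[jj] <- sum(wgt * dde_s)
    out$die[jj] <- sum(wgt * die_s)
    out$delta[jj] <- sum(wgt * delta_s)
    delta_strat[jj, ] <- wgt * delta_s
  }
  out$de <- out$de_r - out$dde + out$delta
  out$ie <- out$ie_r + out$die - out$delta
  out$te <- out$de + out$ie
  attr(out, "delta_strat") <- delta_strat
  attr(out, "rho") <- rho
  attr(out, "n_excluded") <- sum(out$excluded)
  class(out) <- c("effect_components", "data.frame")
  out
}

#' Assemble DE, IE and TE draws from their components
#'
#' `DE = DE(r) - dDE + delta`, `IE = IE(r) + dIE - delta`,
#' `TE = DE + IE`; the sensitivity term cancels from the total effect.
#'
#' @param components an `effect_components` data.frame.
#' @return data.frame with columns `draw`, `de`, `ie`, `te` (excluded
#'   draws dropped).
#' @export
mediational_effects <- function(components) {
  cc <- components[!components$excluded, , drop = FALSE]
  data.frame(draw = cc$draw,
             de = cc$de_r - cc$dde + cc$delta,
             ie = cc$ie_r + cc$die - cc$delta,
             te = (cc$de_r - cc$dde + cc$delta) +
               (cc$ie_r + cc$die - cc$delta))
}

#' Stratum-wise sensitivity extremes of the mediational effects
#'
#' Given components evaluated at the two endpoints of the sensitivity
#' interval (`rho = 0` and `rho = 1`), chooses the endpoint separately in
#' each stratum to minimise or maximise each mediational effect. Because
#' `delta` enters `DE` positively and `IE` negatively, the reported
#' minimum of `DE` pairs the per-stratum minimal `delta` contributions,
#' and the minimum of `IE` the maximal ones; the total effect is
#' unaffected.
#'
#' @param comp0,comp1 `effect_components` at `rho = 0` and `rho = 1`
#'   (same draws).
#' @return data.frame per draw: `de_min, de_max, ie_min, ie_max, te`.
#' @export
rho_extremes <- function(comp0, comp1) {
  stopifnot(identical(comp0$draw, comp1$draw))
  d0 <- attr(comp0, "delta_strat"); d1 <- attr(comp1, "delta_strat")
  keep <- !comp0$excluded & !comp1$excluded
  dmin <- rowSums(pmin(d0, d1))
  dmax <- rowSums(pmax(d0, d1))
  data.frame(
    draw = comp0$draw,
    de_min = comp0$de_r - comp0$dde + dmin,
    de_max = comp0$de_r - comp0$dde + dmax,
    ie_min = comp0$ie_r + comp0$die - dmax,
    ie_max = comp0$ie_r + comp0$die - dmin,
    te = comp0$de_r - comp0$dde + comp0$ie_r + comp0$die
  )[keep, , drop = FALSE]
}

#' Nonparametric total effect from areas under Kaplan-Meier curves
#'
#' Estimates the total effect on the restricted event-free time as the
#' difference between the areas under the two arms' Kaplan-Meier curves
#' on `[0, t_max]`, with a percentile bootstrap confidence interval over
#' subjects.
#'
#' @param data a `tdc_data`.
#' @param t_max restriction time.
#' @param n_boot bootstrap replicates (0 skips the interval).
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return list with `te`, `area_treated`, `area_control`, `ci`.
#' @export
km_te <- function(data, t_max = 15, n_boot = 500, level = 0.95, seed = 1) {
  stopifnot(inherits(data, "tdc_data"))
  s <- data$subjects
  if (!all(c(0, 1) %in% s$A)) stop("both arms must be present", call. = FALSE)
  km_area <- function(time, event) {
    f <- survival::survfit(survival::Surv(time, event) ~ 1)
    tt <- c(0, f$time[f$time <= t_max], t_max)
    ss <- c(1, f$surv[f$time <= t_max])
    sum(ss * diff(tt))
  }
  a1 <- km_area(s$T_exit[s$A == 1], s$d[s$A == 1])
  a0 <- km_area(s$T_exit[s$A == 0], s$d[s$A == 0])
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    i1 <- which(s$A == 1); i0 <- which(s$A == 0)
    reps <- vapply(seq_len(n_boot), function(b) {
      j1 <- sample(i1, length(i1), replace = TRUE)
      j0 <- sample(i0, length(i0), replace = TRUE)
      km_area(s$T_exit[j1], s$d[j1]) - km_area(s$T_exit[j0], s$d[j0])
    }, numeric(1))
    ci <- cred_int(reps, level)
  }
  list(te = a1 - a0, area_treated = a1, area_control = a0, ci = ci)
}

#' Posterior summary with positivity restriction and proportion mediated
#'
#' Summarises the DE/IE/TE posterior draws (mean and equal-tailed 95%
#' interval), and additionally over the restricted posterior that
#' discards draws with a negative direct or indirect effect, under which
#' the proportion mediated `IE/TE` is a well-defined quantity in `[0, 1]`.
#'
#' @param effects data.frame with columns `de`, `ie`, `te` (one row per
#'   draw), e.g. from [mediational_effects()].
#' @param level credible level.
#' @return list of class `"effect_summary"`: `full` and `restricted`
#'   summary tables, `prop_mediated` (mean and interval, restricted set),
#'   `discarded_fraction`.
#' @export
restricted_summary <- function(effects, level = 0.95) {
  stopifnot(nrow(effects) >= 1)
  smry <- function(df) {
    do.call(rbind, lapply(c("de", "ie", "te"), function(q) {
      ci <- cred_int(df[[q]], level)
      data.frame(quantity = toupper(q), mean = mean(df[[q]]),
                 lower = ci[1], upper = ci[2])
    }))
  }
  keep <- effects$de >= 0 & effects$ie >= 0
  out <- list(full = smry(effects), level = level,
              discarded_fraction = mean(!keep))
  if (any(keep)) {
    res <- effects[keep, , drop = FALSE]
    pm <- res$ie / res$te
    out$restricted <- smry(res)
    out$prop_mediated <- c(mean = mean(pm), cred_int(pm, level))
  } else {
    out$restricted <- NULL
    out$note <- "all draws discarded by the positivity restriction"
  }
  class(out) <- "effect_summary"
  out
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("Posterior mediational effects (full posterior)\n")
  print(x$full, row.names = FALSE, digits = 3)
  if (!is.null(x$restricted)) {
    cat(sprintf("\nRestricted to DE >= 0 and IE >= 0 (discarded %.0f%%)\n",
                100 * x$discarded_fraction))
    print(x$restricted, row.names = FALSE, digits = 3)
    cat(sprintf("proportion mediated: %.2f (%.2f, %.2f)\n",
                x$prop_mediated[1], x$prop_mediated[2], x$prop_mediated[3]))
  } else if (!is.null(x$note)) cat("\n", x$note, "\n", sep = "")
  invisible(x)
}
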