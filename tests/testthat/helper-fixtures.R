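## fixtures and independent oracles, all built in code

tiny_subjects <- function() {
  data.frame(id = c("a1", "a2"), A = c(1, 0),
             age_cat = c(0, 2), sex = c(0, 1), smoking = c(1, 0),
             base_score = c(2, 0), L = c(2, 0),
             T_exit = c(12.5, 6.25), d = c(0, 1))
}

tiny_visits <- function() {
  data.frame(id = rep(c("a1", "a2"), each = 3),
             t = c(0, 1.1, 2.9, 0, 0.9, 2.2),
             m = c(1.2, 1.05, 0.9, 0.4, 0.5, 0.45))
}

write_tiny_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sp <- file.path(dir, "subjects.csv")
  lp <- file.path(dir, "longitudinal.csv")
  utils::write.csv(tiny_subjects(), sp, row.names = FALSE, quote = FALSE)
  utils::write.csv(tiny_visits(), lp, row.names = FALSE, quote = FALSE)
  list(subjects = sp, longitudinal = lp, dir = dir)
}

rand_simplex <- function(k = 3) {
  x <- stats::rexp(k)
  x / sum(x)
}

## independent grid oracle for the monotone coupling: scan the free
## probability on a grid, build every entry from the margin equations and
## keep values giving an all-nonnegative matrix with correct margins
grid_p11_oracle <- function(phi_a, phi_astar, npts = 2001, tol = 1e-9) {
  grid <- seq(0, 1, length.out = npts)
  ok <- logical(npts)
  for (i in seq_len(npts)) {
    p11 <- grid[i]
    p00 <- phi_a[1]
    p22 <- phi_astar[3]
    p01 <- phi_a[2] - p11
    p12 <- phi_astar[2] - p11
    p02 <- phi_a[3] - p12 - p22          # column-2 margin
    row0 <- p00 + p01 + p02              # must equal phi_astar[1]
    ok[i] <- all(c(p00, p01, p02, p11, p12, p22) >= -tol) &&
      abs(row0 - phi_astar[1]) < 1e-9
  }
  if (!any(ok)) return(list(feasible = FALSE, p_min = NA, p_max = NA))
  list(feasible = TRUE, p_min = min(grid[ok]), p_max = max(grid[ok]))
}

## brute-force vertex enumeration of the 3x3 transportation polytope:
## basic solutions have at most 5 support cells
tp_vertex_extremes <- function(phi_a, phi_astar, weight) {
  combs <- utils::combn(9, 5)
  ## margin constraint matrix over the 9 cells (rows l', cols l,
  ## column-major cell order), dropping one redundant constraint
  rows <- (seq_len(9) - 1) %% 3 + 1
  cols <- (seq_len(9) - 1) %/% 3 + 1
  A <- matrix(0, 5, 9)
  b <- numeric(5)
  for (r in 1:3) { A[r, rows == r] <- 1; b[r] <- phi_astar[r] }
  for (cc in 1:2) { A[3 + cc, cols == cc] <- 1; b[3 + cc] <- phi_a[cc] }
  best_min <- Inf; best_max <- -Inf
  for (j in seq_len(ncol(combs))) {
    S <- combs[, j]
    As <- A[, S, drop = FALSE]
    if (abs(det(As)) < 1e-12) next
    x <- solve(As, b)
    if (any(x < -1e-9)) next
    p <- numeric(9); p[S] <- x
    v <- sum(p * weight[cbind(rows, cols)])
    best_min <- min(best_min, v); best_max <- max(best_max, v)
  }
  list(min = best_min, max = best_max)
}

## pack a joint_params object into the draw layout of fit_joint
pack_joint_draw <- function(params) {
  P <- ncol(params$h0); KB <- length(params$alpha)
  sds <- sqrt(diag(params$Sigma))
  C <- stats::cov2cor(params$Sigma)
  row <- c(params$beta0, params$beta1, params$beta2, params$alpha,
           as.vector(t(params$psi)), params$sigma, sds,
           C[cbind(c(2, 3, 4, 3, 4, 4), c(1, 1, 1, 2, 2, 3))],
           as.vector(t(params$h0)), params$gamma1, params$gamma2,
           params$gamma3, params$zeta, params$xi)
  names(row) <- c(
    "beta0", paste0("beta1[", 1:5, "]"), paste0("beta2[", 1:7, "]"),
    paste0("alpha[", seq_len(KB), "]"),
    paste0("psi[", rep(seq_len(KB), each = 5), ",", rep(1:5, KB), "]"),
    "sigma", paste0("sd_R[", 1:4, "]"),
    paste0("cor_R[", c("2,1", "3,1", "4,1", "3,2", "4,2", "4,3"), "]"),
    paste0("h0[", rep(0:1, each = P), ",", rep(seq_len(P), 2), "]"),
    paste0("gamma1[", 1:2, "]"), paste0("gamma2[", 1:2, "]"),
    paste0("gamma3[", 1:7, "]"), paste0("zeta[", 1:4, "]"), "xi")
  row
}

fake_joint_fit <- function(params_list, config, data) {
  if (inherits(params_list, "joint_params")) params_list <- list(params_list)
  draws <- do.call(rbind, lapply(params_list, pack_joint_draw))
  structure(list(draws = draws, config = config, data = data,
                 n_pieces = ncol(params_list[[1]]$h0),
                 n_basis = length(params_list[[1]]$alpha),
                 rhat = rep(1, ncol(draws)), converged = TRUE),
            class = "joint_fit")
}

fake_tdc_fit <- function(tdc, data, ndraw = 1) {
  row <- c(tdc$phi0[1], tdc$phi1[1], tdc$phi2[1, ],
           tdc$phi0[2], tdc$phi1[2], tdc$phi2[2, ])
  wn <- c("age_cat1", "age_cat2", "sex1", "smoking1", "smoking2",
          "base_score1", "base_score2")
  names(row) <- c(paste0("L1:", c("intercept", "A", wn)),
                  paste0("L2:", c("intercept", "A", wn)))
  structure(list(draws = matrix(rep(row, ndraw), ndraw, byrow = TRUE,
                                dimnames = list(NULL, names(row))),
                 variant = "main", p = 9, data = data,
                 rhat = rep(1, 18), converged = TRUE),
            class = "tdc_fit")
}

## small parameter set with nontrivial interactions for algebra tests
small_params <- function(zeta = c(0.4, 0.1, 0.15, 0.1), xi = 0.3,
                         gamma1 = c(-0.2, -0.35), gamma2 = c(-0.1, -0.15)) {
  p <- default_true_params()
  joint_params(beta0 = p$beta0, beta1 = p$beta1, beta2 = p$beta2,
               alpha = p$alpha, psi = p$psi, sigma = p$sigma,
               Sigma = p$Sigma, h0 = p$h0, gamma1 = gamma1,
               gamma2 = gamma2, gamma3 = p$gamma3, zeta = zeta, xi = xi)
}

## independent slow evaluation of the effect components through the
## exported scalar functions, for tiny problems
slow_components <- function(params, pa, pc, joints, strata_w, RE_atoms,
                            config) {
  ns <- nrow(strata_w)
  nat <- nrow(RE_atoms)
  Wd <- tdcmediate:::encode_w(strata_w)
  traj_of <- function(am, lm, r, w) {
    X <- tdcmediate:::encode_x(am, lm)[1, ]
    trajectory(params, X, w, r, config)
  }
  mref <- reference_trajectory(config)
  E <- function(a, m, l, w, r0) expected_outcome(params, a, m, l, w, r0, config)
  de_r <- ie_r <- dde <- die <- delta <- 0
  for (s in seq_len(ns)) for (at in seq_len(nat)) {
    w <- Wd[s, ]; r <- RE_atoms[at, ]; r0 <- r[1]
    wt <- strata_w$weight[s] / nat
    bm <- function(a, m) E(a, m, 0, w, r0) - E(a, mref, 0, w, r0)
    bl <- function(a, l) E(a, mref, l, w, r0) - E(a, mref, 0, w, r0)
    bml <- function(a, m, l) {
      E(a, m, l, w, r0) - E(a, mref, l, w, r0) -
        E(a, m, 0, w, r0) + E(a, mref, 0, w, r0)
    }
    for (lp in 0:2) {
      m0 <- traj_of(0, lp, r, w)
      de_r <- de_r + wt * pc[s, lp + 1] * (bm(1, m0) - bm(0, m0))
      dde <- dde + wt * pc[s, lp + 1] * bml(0, m0, lp)
    }
    for (l_ in 0:2) {
      de_r <- de_r + wt * (bl(1, l_) * pa[s, l_ + 1] - bl(0, l_) * pc[s, l_ + 1])
      m1 <- traj_of(1, l_, r, w)
      ie_r <- ie_r + wt * pa[s, l_ + 1] * bm(1, m1)
      die <- die + wt * pa[s, l_ + 1] * bml(1, m1, l_)
    }
    for (lp in 0:2) {
      m0 <- traj_of(0, lp, r, w)
      ie_r <- ie_r - wt * pc[s, lp + 1] * bm(1, m0)
      for (l_ in 0:2) {
        delta <- delta + wt * joints[[s]][lp + 1, l_ + 1] * bml(1, m0, l_)
      }
    }
    de_r <- de_r + wt * (E(1, mref, 0, w, r0) - E(0, mref, 0, w, r0))
  }
  list(de_r = de_r, ie_r = ie_r, dde = dde, die = die, delta = delta,
       de = de_r - dde + delta, ie = ie_r + die - delta)
}
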