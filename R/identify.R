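## Identification of the joint distribution of the counterfactual confounder
## pair (L_{a*}, L_a) within a baseline stratum.
##
## Orientation used throughout: the joint probability matrix `p` has rows
## indexed by the control-world level l' (L_{a*}) and columns by the
## treated-world level l (L_a).  Monotonicity (treatment can only raise the
## confounder) therefore means p[l', l] = 0 whenever l < l', i.e. the matrix
## is upper triangular.

#' Bounds for the free joint probability under monotonicity
#'
#' For a trichotomous treatment-dependent confounder with treated-arm
#' marginals `phi_a` = (P(L_a=0), P(L_a=1), P(L_a=2)) and control-arm
#' marginals `phi_astar` = (P(L_a*=0), P(L_a*=1), P(L_a*=2)), monotonicity
#' leaves a single free parameter, the probability `p11` that both
#' counterfactual levels equal 1. Its admissible interval is
#' `[max(0, 1 - phi_a[3] - phi_astar[1]), min(phi_a[2], phi_astar[2])]`.
#'
#' @param phi_a numeric(3), marginal distribution of the confounder under
#'   treatment; must be a probability vector.
#' @param phi_astar numeric(3), marginal distribution under control.
#' @param tol numerical tolerance for the feasibility comparison.
#' @return list with elements `p_min`, `p_max` and logical `feasible`
#'   (`p_min <= p_max + tol`).
#' @export
#' @examples
#' p11_bounds(c(0.1, 0.4, 0.5), c(0.3, 0.4, 0.3))
p11_bounds <- function(phi_a, phi_astar, tol = 1e-9) {
  assert_simplex(phi_a)
  assert_simplex(phi_astar)
  p_min <- max(0, 1 - phi_a[3] - phi_astar[1])
  p_max <- min(phi_a[2], phi_astar[2])
  list(p_min = p_min, p_max = p_max, feasible = p_min <= p_max + tol)
}

#' Is a monotone counterfactual coupling feasible for given marginals?
#'
#' Checks whether an upper-triangular (monotone) joint probability matrix
#' with the given marginals exists. For three levels this is equivalent to
#' the interval of [p11_bounds()] being non-empty.
#'
#' @inheritParams p11_bounds
#' @return list with logical `feasible` and `margin = p_max - p_min`
#'   (negative when infeasible).
#' @export
monotonicity_feasible <- function(phi_a, phi_astar, tol = 1e-9) {
  b <- p11_bounds(phi_a, phi_astar, tol = tol)
  list(feasible = b$feasible, margin = b$p_max - b$p_min)
}

#' Monotone joint distribution of the counterfactual confounder pair
#'
#' Constructs the upper-triangular joint probability matrix of
#' (L_a*, L_a) from the two marginal triples and the sensitivity parameter
#' `rho` in `[0, 1]`, which places the free probability `p11` inside its
#' admissible interval: `p11 = p_min + rho * (p_max - p_min)`.
#'
#' @inheritParams p11_bounds
#' @param rho sensitivity parameter in `[0, 1]`.
#' @return 3x3 matrix; rows = control-world level (0..2), columns =
#'   treated-world level (0..2). Attribute `"rho"` records the value used.
#' @export
#' @examples
#' counterfactual_joint(c(0.1, 0.4, 0.5), c(0.3, 0.4, 0.3), rho = 0.5)
counterfactual_joint <- function(phi_a, phi_astar, rho, tol = 1e-9) {
  stopifnot(length(rho) == 1, is.finite(rho), rho >= 0, rho <= 1)
  b <- p11_bounds(phi_a, phi_astar, tol = tol)
  if (!b$feasible) {
    stop(sprintf(paste0("monotone coupling infeasible for these marginals: ",
                        "p_min = %.6g > p_max = %.6g"), b$p_min, b$p_max),
         call. = FALSE)
  }
  p11 <- b$p_min + rho * (b$p_max - b$p_min)
  p <- matrix(0, 3, 3, dimnames = list(astar = 0:2, a = 0:2))
  p[1, 1] <- phi_a[1]                      # p00
  p[2, 2] <- p11
  p[3, 3] <- phi_astar[3]                  # p22
  p[1, 2] <- phi_a[2] - p11                # p01
  p[2, 3] <- phi_astar[2] - p11            # p12
  p[1, 3] <- p11 - (1 - phi_a[3] - phi_astar[1])  # p02
  p[p < 0 & p > -tol] <- 0
  attr(p, "rho") <- rho
  p
}

#' Joint distribution under step monotonicity
#'
#' Step monotonicity restricts the treatment to either leave the confounder
#' unchanged or raise it by exactly one level, forcing `p02 = 0` and hence
#' `p11 = 1 - phi_a[3] - phi_astar[1]`. The joint is then fully determined
#' by the marginals; it may however fail to be a probability matrix, in
#' which case the marginals are inconsistent with step monotonicity.
#'
#' @inheritParams p11_bounds
#' @return list with `valid` (logical), `joint` (the 3x3 matrix, possibly
#'   containing a negative entry when invalid), and `violation` (smallest
#'   entry, negative when invalid).
#' @export
step_monotone_joint <- function(phi_a, phi_astar, tol = 1e-9) {
  assert_simplex(phi_a)
  assert_simplex(phi_astar)
  p11 <- 1 - phi_a[3] - phi_astar[1]
  p <- matrix(0, 3, 3, dimnames = list(astar = 0:2, a = 0:2))
  p[1, 1] <- phi_a[1]
  p[2, 2] <- p11
  p[3, 3] <- phi_astar[3]
  p[1, 2] <- phi_a[2] - p11
  p[2, 3] <- phi_astar[2] - p11
  worst <- min(p[upper.tri(p, diag = TRUE)])
  valid <- worst >= -tol
  if (valid) p[p < 0] <- 0
  list(valid = valid, joint = p, violation = worst)
}

## Linear program over upper-triangular (monotone) or unrestricted KxK
## probability matrices with fixed margins; minimises or maximises a linear
## objective in the free cells.  Cells listed in `fixed` (list of
## list(row, col, value)) are constrained to their values.
lp_transport <- function(phi_a, phi_astar, weight, maximise = FALSE,
                         monotone = FALSE, fixed = list()) {
  K <- length(phi_a)
  idx <- which(if (monotone) upper.tri(matrix(0, K, K), diag = TRUE)
               else matrix(TRUE, K, K))
  nv <- length(idx)
  rows <- (idx - 1L) %% K + 1L
  cols <- (idx - 1L) %/% K + 1L
  ## margin equalities; drop the last column constraint (redundant)
  A <- matrix(0, 2 * K - 1, nv)
  b <- numeric(2 * K - 1)
  for (r in seq_len(K)) { A[r, rows == r] <- 1; b[r] <- phi_astar[r] }
  for (cc in seq_len(K - 1)) { A[K + cc, cols == cc] <- 1; b[K + cc] <- phi_a[cc] }
  for (f in fixed) {
    A <- rbind(A, as.numeric(rows == f$row & cols == f$col))
    b <- c(b, f$value)
  }
  obj <- weight[cbind(rows, cols)]
  sol <- boot::simplex(a = obj, A3 = A, b3 = b, maxi = maximise, eps = 1e-10)
  if (sol$solved != 1) return(NULL)
  p <- matrix(0, K, K)
  p[cbind(rows, cols)] <- sol$soln
  list(value = unname(sol$value), matrix = p)
}

#' Monotone counterfactual coupling for an arbitrary number of levels
#'
#' Generalises [counterfactual_joint()] to a K-level ordinal confounder.
#' Beyond the margin constraints, the upper-triangular coupling has
#' `(K-1)(K-2)/2` free dimensions, exposed as a sensitivity vector with
#' entries in `[0, 1]`. The free cells are the interior cells (rows
#' `2..K-1`, columns within `row..K-1` in 1-based indexing); they are fixed
#' sequentially, each scaled into its currently admissible interval by the
#' corresponding sensitivity entry, starting at the (1,1)-level analogue and
#' moving outward row by row. `K = 2` is fully determined; `K = 3` with
#' `sens = rho` reproduces [counterfactual_joint()].
#'
#' @param phi_a,phi_astar probability vectors of length K (treated and
#'   control marginals).
#' @param sens numeric vector of length `(K-1)(K-2)/2` with entries in
#'   `[0,1]`; ignored entries may be omitted when the length is 0.
#' @param tol tolerance for feasibility and cleanup of negative round-off.
#' @return K x K upper-triangular probability matrix (rows: control world).
#' @export
k_level_monotone_joint <- function(phi_a, phi_astar, sens = numeric(0),
                                   tol = 1e-9) {
  assert_simplex(phi_a)
  assert_simplex(phi_astar)
  K <- length(phi_a)
  stopifnot(K >= 2, length(phi_astar) == K)
  nfree <- (K - 1) * (K - 2) / 2
  if (length(sens) != nfree) {
    stop(sprintf("'sens' must have length %d for K = %d", nfree, K),
         call. = FALSE)
  }
  stopifnot(all(sens >= 0 & sens <= 1))
  ## free cells: (r, c) with 2 <= r <= K-1, r <= c <= K-1
  free <- NULL
  for (r in seq_len(K)[-c(1, K)]) for (cc in r:(K - 1)) {
    free <- rbind(free, c(r, cc))
  }
  fixed <- list()
  zero_w <- matrix(0, K, K)
  cell_w <- function(r, cc) { w <- zero_w; w[r, cc] <- 1; w }
  if (nfree > 0) {
    for (j in seq_len(nfree)) {
      r <- free[j, 1]; cc <- free[j, 2]
      w <- cell_w(r, cc)
      lo <- lp_transport(phi_a, phi_astar, w, maximise = FALSE,
                         monotone = TRUE, fixed = fixed)
      hi <- lp_transport(phi_a, phi_astar, w, maximise = TRUE,
                         monotone = TRUE, fixed = fixed)
      if (is.null(lo) || is.null(hi)) {
        stop("monotone coupling infeasible for these marginals", call. = FALSE)
      }
      val <- lo$value + sens[j] * (hi$value - lo$value)
      fixed[[length(fixed) + 1L]] <- list(row = r, col = cc, value = val)
    }
  }
  ## with all free cells pinned, the coupling is determined by the margins
  p <- matrix(0, K, K, dimnames = list(astar = 0:(K - 1), a = 0:(K - 1)))
  for (f in fixed) p[f$row, f$col] <- f$value
  p[1, 1] <- phi_a[1]
  if (K > 2) {
    for (cc in 2:(K - 1)) p[1, cc] <- phi_a[cc] - sum(p[2:cc, cc])
  }
  p[K, K] <- phi_astar[K]
  for (r in seq_len(K - 1)) {
    p[r, K] <- phi_astar[r] - sum(p[r, seq_len(K - 1)])
  }
  colK <- sum(p[, K])
  if (abs(colK - phi_a[K]) > 1e-6 || min(p) < -max(tol, 1e-7)) {
    stop("monotone coupling infeasible for these marginals", call. = FALSE)
  }
  p[p < 0] <- 0
  p
}

#' Partial-identification bounds for a linear functional of the coupling
#'
#' Without any monotonicity assumption, the joint distribution of
#' (L_a*, L_a) is only constrained to the transportation polytope with row
#' margins `phi_astar` and column margins `phi_a`. For a linear functional
#' `sum(p * weight)` this returns its exact extremes over the polytope by
#' linear programming, along with the optimising couplings.
#'
#' @inheritParams k_level_monotone_joint
#' @param weight K x K numeric matrix of weights, `weight[l'+1, l+1]`
#'   multiplying `P(L_a* = l', L_a = l)`.
#' @return list with `min`, `max`, `argmin`, `argmax`.
#' @export
partial_id_bounds <- function(phi_a, phi_astar, weight) {
  assert_simplex(phi_a)
  assert_simplex(phi_astar)
  K <- length(phi_a)
  stopifnot(is.matrix(weight), all(dim(weight) == K), all(is.finite(weight)))
  lo <- lp_transport(phi_a, phi_astar, weight, maximise = FALSE)
  hi <- lp_transport(phi_a, phi_astar, weight, maximise = TRUE)
  if (is.null(lo) || is.null(hi)) {
    stop("transportation LP unexpectedly infeasible", call. = FALSE)
  }
  list(min = lo$value, max = hi$value, argmin = lo$matrix, argmax = hi$matrix)
}

#' Monotonicity diagnostics across strata and posterior draws
#'
#' Applies the feasibility checks to the per-stratum marginal probabilities
#' implied by each posterior draw of a fitted confounder model, mirroring
#' the reporting of the proportion of draws violating the necessary
#' monotonicity condition in at least one stratum.
#'
#' @param marginals data.frame with columns `draw`, `stratum`, and
#'   `phi1..phi6` (treated-arm triple then control-arm triple), as produced
#'   by [stratum_marginals()].
#' @param tol feasibility tolerance.
#' @return list of class `"feasibility_report"`: `table` (per stratum x draw
#'   flags and bounds), `prop_draws_infeasible` (proportion of draws with at
#'   least one infeasible stratum), `prop_draws_step_invalid` (same for step
#'   monotonicity), and per-stratum failure proportions.
#' @export
check_monotonicity <- function(marginals, tol = 1e-9) {
  stopifnot(all(c("draw", "stratum", paste0("phi", 1:6)) %in% names(marginals)))
  n <- nrow(marginals)
  p_min <- pmax(0, 1 - marginals$phi3 - marginals$phi4)
  p_max <- pmin(marginals$phi2, marginals$phi5)
  feasible <- p_min <= p_max + tol
  ## step monotonicity: p11 = 1 - phi3 - phi4 must give nonnegative entries
  p11s <- 1 - marginals$phi3 - marginals$phi4
  step_valid <- (p11s >= -tol) &
    (marginals$phi2 - p11s >= -tol) & (marginals$phi5 - p11s >= -tol)
  tab <- data.frame(
    stratum = marginals$stratum, draw = marginals$draw,
    feasible = feasible, p_min = p_min, p_max = p_max,
    step_valid = step_valid
  )
  by_draw_bad <- tapply(!feasible, marginals$draw, any)
  by_draw_step_bad <- tapply(!step_valid, marginals$draw, any)
  out <- list(
    table = tab,
    prop_draws_infeasible = mean(by_draw_bad),
    prop_draws_step_invalid = mean(by_draw_step_bad),
    stratum_failure_prop = tapply(!feasible, marginals$stratum, mean),
    stratum_step_failure_prop = tapply(!step_valid, marginals$stratum, mean),
    n = n
  )
  class(out) <- "feasibility_report"
  out
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("Monotonicity feasibility report\n")
  cat(sprintf("  stratum x draw combinations checked: %d\n", x$n))
  cat(sprintf("  draws with >=1 infeasible stratum:   %.1f%%\n",
              100 * x$prop_draws_infeasible))
  cat(sprintf("  draws with >=1 step-invalid stratum: %.1f%%\n",
              100 * x$prop_draws_step_invalid))
  invisible(x)
}
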