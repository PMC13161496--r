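#' Natural cubic spline basis anchored at time zero
#'
#' Evaluates a natural cubic spline basis (linear beyond the boundary knots,
#' zero second derivative at the boundaries) at times `t`, normalised so
#' that every basis function equals 0 at `t = 0`. The intercept of a
#' trajectory is therefore carried separately and remains interpretable as
#' the value at baseline. Beyond the upper boundary knot the basis
#' extrapolates linearly, so trajectories remain defined for exit times
#' exceeding the last knot.
#'
#' @param t numeric vector of times (years since baseline), `t >= 0`.
#' @param boundary_knots length-2 increasing vector, default `c(0, 10)`.
#' @param inner_knots strictly increasing interior knots, default
#'   `c(1, 3, 5)`.
#' @return matrix with `length(t)` rows and `length(inner_knots) + 1`
#'   columns.
#' @export
#' @examples
#' B <- natural_cubic_basis(c(0, 1, 5, 12))
#' stopifnot(all(B[1, ] == 0))
natural_cubic_basis <- function(t, boundary_knots = c(0, 10),
                                inner_knots = c(1, 3, 5)) {
  knots <- c(boundary_knots[1], inner_knots, boundary_knots[2])
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing and inner knots must lie ",
         "strictly inside the boundary knots", call. = FALSE)
  }
  B <- splines::ns(c(0, t), knots = inner_knots,
                   Boundary.knots = boundary_knots)
  B <- unclass(B)
  sweep(B[-1, , drop = FALSE], 2, B[1, ], "-")
}

## definite integral of each (anchored) basis column over [0, upper],
## by Gauss-Legendre quadrature per inter-knot segment (exact for cubics)
basis_integral <- function(upper, boundary_knots = c(0, 10),
                           inner_knots = c(1, 3, 5), n_nodes = 7) {
  brk <- sort(unique(c(0, inner_knots, boundary_knots, upper)))
  brk <- brk[brk <= upper + 1e-12]
  if (max(brk) < upper) brk <- c(brk, upper)
  total <- 0
  for (s in seq_len(length(brk) - 1)) {
    q <- gl_nodes(n_nodes, brk[s], brk[s + 1])
    B <- natural_cubic_basis(q$x, boundary_knots, inner_knots)
    total <- total + colSums(B * q$w)
  }
  total
}
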