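#' Analysis configuration
#'
#' Collects every tunable setting of the pipeline in one validated list:
#' the restriction time, confounder coding, the functional linking the
#' mediator trajectory to the hazard, spline knots, baseline-hazard
#' breakpoints, the mediator analysis scale, MCMC settings, the sensitivity
#' (`rho`) policy and Monte Carlo integration sizes.
#'
#' @param t_max restriction time in years; the outcome is the expected
#'   event-free time within `[0, t_max]`.
#' @param K number of ordinal confounder levels (levels `0..K-1`).
#' @param g_kind functional of the trajectory entering the hazard:
#'   `"legacy"` (cumulative change over the first `legacy_window` years,
#'   constant in t) or `"current_change"` (change since baseline at t).
#' @param legacy_window upper limit (years) of the legacy integral.
#' @param pop_boundary_knots,pop_inner_knots knots of the population spline
#'   basis.
#' @param re_boundary_knots,re_inner_knots knots of the random-effect basis.
#' @param hazard_breaks interior breakpoints (years) of the
#'   piecewise-constant baseline hazards; pieces span `0` to `t_max`.
#' @param m_center,m_scale mediator analysis scale: analysis value =
#'   (raw - m_center) / m_scale. Defaults suit BMI in kg/m2.
#' @param chains,warmup,sampling MCMC protocol for [fit_joint()].
#' @param seed base RNG seed recorded with fits.
#' @param rho_policy one of `"fixed"`, `"min"`, `"max"`; with `"fixed"`,
#'   `rho` gives the common sensitivity value.
#' @param rho sensitivity parameter in `[0,1]` used when
#'   `rho_policy = "fixed"`.
#' @param n_re_atoms Monte Carlo atoms for the random-effects integral in
#'   the effect assembly.
#' @param quad_nodes Gauss-Legendre nodes per baseline-hazard piece.
#' @param infeasible one of `"exclude"` (drop posterior draws whose
#'   marginals violate monotonicity in some stratum and report the
#'   proportion) or `"clip"` (clip `p11` to the nearest feasible value).
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(t_max = 15, K = 3,
                            g_kind = c("legacy", "current_change"),
                            legacy_window = 3,
                            pop_boundary_knots = c(0, 10),
                            pop_inner_knots = c(1, 3, 5),
                            re_boundary_knots = c(0, 10),
                            re_inner_knots = c(1, 5),
                            hazard_breaks = c(2, 4, 6, 9, 12),
                            m_center = 25, m_scale = 5,
                            chains = 4, warmup = 2000, sampling = 2000,
                            seed = 1,
                            rho_policy = c("fixed", "min", "max"),
                            rho = 0.5,
                            n_re_atoms = 100,
                            quad_nodes = 15,
                            infeasible = c("exclude", "clip")) {
  g_kind <- match.arg(g_kind)
  rho_policy <- match.arg(rho_policy)
  infeasible <- match.arg(infeasible)
  stopifnot(t_max > 0, K >= 2, legacy_window > 0,
            all(diff(pop_inner_knots) > 0), all(diff(re_inner_knots) > 0),
            all(hazard_breaks > 0), all(hazard_breaks < t_max),
            all(diff(hazard_breaks) > 0),
            m_scale > 0, chains >= 1, warmup >= 10, sampling >= 10,
            rho >= 0, rho <= 1, n_re_atoms >= 1, quad_nodes >= 2)
  structure(list(
    t_max = t_max, K = K, g_kind = g_kind, legacy_window = legacy_window,
    pop_boundary_knots = pop_boundary_knots,
    pop_inner_knots = pop_inner_knots,
    re_boundary_knots = re_boundary_knots,
    re_inner_knots = re_inner_knots,
    hazard_breaks = hazard_breaks,
    m_center = m_center, m_scale = m_scale,
    chains = chains, warmup = warmup, sampling = sampling, seed = seed,
    rho_policy = rho_policy, rho = rho,
    n_re_atoms = n_re_atoms, quad_nodes = quad_nodes,
    infeasible = infeasible
  ), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; absent keys fall back
#' to the defaults.
#'
#' @param path path to a YAML file.
#' @return an `analysis_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

## full piece boundaries 0, breaks..., t_max
hazard_cuts <- function(config) c(0, config$hazard_breaks, config$t_max)

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  restriction time: %g years, %d confounder levels\n",
              x$t_max, x$K))
  cat(sprintf("  trajectory functional: %s\n", x$g_kind))
  cat(sprintf("  baseline-hazard pieces: %s\n",
              paste(hazard_cuts(x), collapse = ", ")))
  cat(sprintf("  MCMC: %d chains x (%d warmup + %d sampling)\n",
              x$chains, x$warmup, x$sampling))
  cat(sprintf("  rho policy: %s%s\n", x$rho_policy,
              if (x$rho_policy == "fixed") sprintf(" (rho = %g)", x$rho) else ""))
  invisible(x)
}
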