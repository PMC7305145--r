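#' Right-hand side of the MMM model
#'
#' Evaluates the time derivatives of biomass and the lumped substrate pools.
#' Written for clarity rather than speed; [simulate_growth()] integrates a
#' compiled version of the same equations.
#'
#' @param biomass Biomass concentration \eqn{\phi P} (OD600-equivalent, >= 0).
#' @param substrates Numeric vector of pool concentrations \eqn{\phi S_i}, mM.
#' @param params An [mmm_params()] object.
#' @return Named numeric vector `c(dP, dS1, ..., dSn)` in units per hour.
#' @details Substrate consumption feeds biomass one-to-one, so with
#'   `death_rate = 0` the sum `biomass + sum(substrates)` is conserved.
#'   Substrate derivatives are never positive.
#' @examples
#' p <- mmm_params(beta = c(2, 1, 1, 1), k = rep(1, 4), death_rate = 0)
#' mmm_derivatives(1, c(1, 0, 0, 0), p)
#' @export
mmm_derivatives <- function(biomass, substrates, params) {
  stopifnot(inherits(params, "mmm_params"))
  if (length(substrates) != params$n_pools)
    stop("`substrates` must have one entry per pool")
  check_state(biomass, substrates)
  S <- pmax(substrates, 0)
  uptake <- params$beta * S^2 / (params$k + S) * biomass
  dP <- sum(uptake) - params$death_rate * biomass
  out <- c(dP, -uptake)
  names(out) <- c("biomass", paste0("S", seq_len(params$n_pools)))
  out
}

#' Cybernetic control variables u and v
#'
#' Given the per-pool growth rates `r`, computes the resource-allocation
#' fractions \eqn{u_i = r_i / \sum_j r_j} (matched-allocation: enzyme
#' synthesis capacity goes to substrates in proportion to their current
#' return) and the activity fractions \eqn{v_i = r_i / \max_j r_j}
#' (proportional activation: priority to the substrate(s) supporting the
#' highest growth rate). When every rate is zero both laws are 0/0; the
#' convention here is `u = v = 0`, so enzyme synthesis falls back to the
#' constitutive term only.
#'
#' @param r Numeric vector of non-negative growth rates, 1/h.
#' @return List with components `u` and `v`, same length as `r`.
#' @examples
#' cybernetic_controls(c(2, 1, 1, 0))  # u sums to 1, max(v) is 1
#' @export
cybernetic_controls <- function(r) {
  if (any(!is.finite(r))) stop("rates must be finite")
  if (any(r < 0)) stop("rates must be non-negative")
  rsum <- sum(r)
  if (rsum <= 0) return(list(u = numeric(length(r)), v = numeric(length(r))))
  list(u = r / rsum, v = r / max(r))
}

#' Right-hand side of the cybernetic model
#'
#' Evaluates the time derivatives of biomass, substrate pools and enzyme
#' levels, including the control variables of [cybernetic_controls()].
#' [simulate_growth()] integrates a compiled version of the same equations.
#'
#' @inheritParams mmm_derivatives
#' @param enzymes Numeric vector of dimensionless enzyme levels
#'   \eqn{\phi E_i}, one per pool.
#' @param params A [cybernetic_params()] object.
#' @return Named numeric vector `c(dP, dS1..n, dE1..n)` per hour, with
#'   attribute `controls` holding the evaluated `r`, `r_e`, `u`, `v`.
#' @examples
#' p <- cybernetic_params(v_max = c(2, 1, 1, 1), k_s = rep(1, 4),
#'                        v_e = rep(1, 4), k_e = rep(1, 4),
#'                        alpha = 0.05, beta_const = 0.05, death_rate = 0.01)
#' cybernetic_derivatives(1, c(1, 0, 0, 0), c(0.5, 0.01, 0.01, 0.01), p)
#' @export
cybernetic_derivatives <- function(biomass, substrates, enzymes, params) {
  stopifnot(inherits(params, "cybernetic_params"))
  n <- params$n_pools
  if (length(substrates) != n || length(enzymes) != n)
    stop("`substrates` and `enzymes` must have one entry per pool")
  check_state(biomass, substrates, enzymes)
  S <- pmax(substrates, 0)
  E <- pmax(enzymes, 0)
  r <- params$v_max * E * S / (params$k_s + S)
  r_e <- params$v_e * S / (params$k_e + S)
  ctrl <- cybernetic_controls(r)
  growth <- sum(ctrl$v * r)
  dS <- -r * ctrl$v * biomass
  dP <- growth * biomass - params$death_rate * biomass
  dilution <- switch(params$dilution_mode,
    standard = growth * E,
    as_printed = rep(growth * biomass, n)
  )
  dE <- ctrl$u * r_e - dilution - params$alpha * E + params$beta_const
  out <- c(dP, dS, dE)
  names(out) <- c("biomass", paste0("S", seq_len(n)), paste0("E", seq_len(n)))
  attr(out, "controls") <- c(ctrl, list(r = r, r_e = r_e))
  out
}
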