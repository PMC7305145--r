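#' Integrate a growth model over a time grid
#'
#' Numerically integrates the MMM or cybernetic model with an adaptive
#' explicit Runge-Kutta 4(5) scheme (deSolve's `ode45`) over the requested
#' time grid, using the package's compiled right-hand sides.
#'
#' Small negative excursions of substrate or enzyme levels are tolerated and
#' repaired: the right-hand sides clamp states at zero before computing rates,
#' and returned values in `[-clip_tol, 0)` are clipped to 0. Values below
#' `-clip_tol` abort with an error reporting the last valid time, since they
#' indicate a genuinely failing integration rather than roundoff.
#'
#' @param params An [mmm_params()] or [cybernetic_params()] object; selects
#'   the model.
#' @param biomass0 Initial biomass, OD600-equivalent.
#' @param substrates0 Initial pool concentrations, mM (one per pool).
#' @param enzymes0 Initial enzyme levels (cybernetic only); default 0.01 for
#'   every pool. Fixed by convention, not a fitted quantity.
#' @param times Strictly increasing numeric vector of output times, hours.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param method deSolve integration method (default `"ode45"`).
#' @param clip_tol Negative-state clipping tolerance (default `1e-9`).
#' @return A `growth_trajectory`: list with `times`, `biomass`, `substrates`
#'   (matrix, one column per pool), `enzymes` (matrix or `NULL`), `model`
#'   (`"mmm"` or `"cybernetic"`) and `params`.
#' @examples
#' p <- mmm_params(beta = c(3, 1.5, 0.6, 0.2), k = rep(0.5, 4), death_rate = 0)
#' tr <- simulate_growth(p, biomass0 = 0.1,
#'                       substrates0 = c(0.6, 0.8, 1.8, 0.6),
#'                       times = seq(0, 10, 0.5))
#' head(as.data.frame(tr))
#' @export
simulate_growth <- function(params, biomass0, substrates0, enzymes0 = NULL,
                            times, rtol = 1e-8, atol = 1e-10,
                            method = "ode45", clip_tol = 1e-9) {
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("`times` must be strictly increasing with at least 2 points")
  n <- params$n_pools
  if (length(substrates0) != n)
    stop("`substrates0` must have one entry per pool")
  is_cyb <- inherits(params, "cybernetic_params")
  if (!is_cyb && !inherits(params, "mmm_params"))
    stop("`params` must be an mmm_params or cybernetic_params object")
  if (is_cyb) {
    if (is.null(enzymes0)) enzymes0 <- rep(0.01, n)
    if (length(enzymes0) != n)
      stop("`enzymes0` must have one entry per pool")
    check_state(biomass0, substrates0, enzymes0)
    y0 <- c(biomass0, substrates0, enzymes0)
    parms <- pad_parms(c(n, params$v_max, params$k_s, params$v_e, params$k_e,
                         params$alpha, shared_beta(params), params$death_rate,
                         as.numeric(params$dilution_mode == "as_printed")),
                       4L * 16L + 5L)
    funcs <- c(func = "cybgrowth_cyb_derivs", initfunc = "cybgrowth_cyb_init")
  } else {
    check_state(biomass0, substrates0)
    y0 <- c(biomass0, substrates0)
    parms <- pad_parms(c(n, params$beta, params$k, params$death_rate),
                       2L * 16L + 2L)
    funcs <- c(func = "cybgrowth_mmm_derivs", initfunc = "cybgrowth_mmm_init")
  }

  out <- try(deSolve::ode(
    y = y0, times = times, parms = parms, method = method,
    func = funcs[["func"]], initfunc = funcs[["initfunc"]],
    dllname = "cybgrowth", rtol = rtol, atol = atol
  ), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("integration failed: ", attr(out, "condition")$message)
  out <- unclass(out)
  if (nrow(out) < length(times) || any(!is.finite(out[, -1]))) {
    last_ok <- out[max(which(apply(is.finite(out), 1, all))), 1]
    stop("integration failed (non-finite state); last valid time: ", last_ok)
  }
  y <- out[, -1, drop = FALSE]
  below <- y < -clip_tol
  if (any(below)) {
    i_bad <- min(which(apply(below, 1, any)))
    stop("integration produced states below -clip_tol; last valid time: ",
         if (i_bad > 1) out[i_bad - 1, 1] else "none")
  }
  y[y < 0] <- 0

  structure(
    list(
      times = times,
      biomass = y[, 1],
      substrates = y[, 2:(n + 1), drop = FALSE],
      enzymes = if (is_cyb) y[, (n + 2):(2 * n + 1), drop = FALSE] else NULL,
      model = if (is_cyb) "cybernetic" else "mmm",
      params = params
    ),
    class = "growth_trajectory"
  )
}

shared_beta <- function(params) {
  # compiled RHS uses one constitutive rate; per-pool vectors take the R path
  if (length(params$beta_const) > 1L)
    stop("per-pool `beta_const` is supported by cybernetic_derivatives() ",
         "but not by the compiled integrator; use a shared scalar")
  params$beta_const
}

pad_parms <- function(x, len) {
  c(x, numeric(len - length(x)))
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d time points over [%g, %g] h, %d pools\n",
              x$model, length(x$times), min(x$times), max(x$times),
              ncol(x$substrates)))
  cat(sprintf("  biomass %0.4g -> %0.4g; residual substrate %0.4g mM\n",
              x$biomass[1], x$biomass[length(x$biomass)],
              sum(x$substrates[nrow(x$substrates), ])))
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x A `growth_trajectory`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return Data frame with columns `time_h`, `species_id`, `value`, `model`.
#'   Species are `biomass`, `C1..Cn` (substrate pools) and, for the
#'   cybernetic model, `E1..En`.
#' @export
as.data.frame.growth_trajectory <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  n <- ncol(x$substrates)
  blocks <- list(
    data.frame(time_h = x$times, species_id = "biomass", value = x$biomass)
  )
  for (i in seq_len(n))
    blocks[[length(blocks) + 1L]] <- data.frame(
      time_h = x$times, species_id = paste0("C", i),
      value = x$substrates[, i])
  if (!is.null(x$enzymes))
    for (i in seq_len(n))
      blocks[[length(blocks) + 1L]] <- data.frame(
        time_h = x$times, species_id = paste0("E", i),
        value = x$enzymes[, i])
  out <- do.call(rbind, blocks)
  out$model <- x$model
  rownames(out) <- NULL
  out
}
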