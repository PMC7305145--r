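#' Options controlling the hybrid simplex/annealing fit
#'
#' The fit minimizes a weighted sum of squared deviations with a hybrid of the
#' Nelder-Mead simplex and simulated annealing: simplex moves are taken on
#' thermally perturbed objective values (a positive log-distributed random
#' term proportional to the temperature is added to stored vertex objectives
#' and subtracted from trial points), the temperature is lowered geometrically,
#' and a zero-temperature simplex polish finishes each restart. At zero
#' temperature the algorithm is plain bounded Nelder-Mead.
#'
#' @param seed Integer; restart `r` re-seeds the generator with `seed + r`, so
#'   results are reproducible bit-for-bit.
#' @param restarts Number of independent starts (first from the centre of the
#'   search box in log space, the rest random); best result wins.
#' @param initial_temperature `"auto"` (standard deviation of the objective
#'   over 20 seeded random parameter draws) or a positive number.
#' @param cooling_factor Geometric cooling ratio in (0, 1).
#' @param iterations_per_temperature Simplex steps at each temperature.
#' @param temperature_floor_ratio Annealing stops when the temperature falls
#'   below this fraction of the initial temperature.
#' @param lower,upper Parameter bounds: positive scalars applied to every
#'   parameter, or vectors with one entry per free parameter. The search runs
#'   in log space, so bounds must be strictly positive.
#' @param convergence_tolerance Relative objective spread of the simplex at
#'   which the zero-temperature polish stops.
#' @param polish_iterations Cap on zero-temperature simplex steps.
#' @param species_weights Optional named vector of per-species weights in the
#'   objective; default weights each species by `1 / max(observed)^2` so that
#'   biomass (OD of order 1) and substrates (mM of order 1) contribute
#'   comparably.
#' @return A list of class `fit_options`.
#' @seealso [fit_model()], [anneal_simplex()]
#' @export
fit_options <- function(seed = 1L, restarts = 3L,
                        initial_temperature = "auto",
                        cooling_factor = 0.9,
                        iterations_per_temperature = 50L,
                        temperature_floor_ratio = 1e-3,
                        lower = 1e-3, upper = 1e2,
                        convergence_tolerance = 1e-10,
                        polish_iterations = 2000L,
                        species_weights = NULL) {
  if (cooling_factor <= 0 || cooling_factor >= 1)
    stop("`cooling_factor` must be in (0, 1)")
  if (any(lower <= 0) || any(upper <= lower))
    stop("bounds must satisfy 0 < lower < upper")
  if (!identical(initial_temperature, "auto") &&
      (!is.numeric(initial_temperature) || initial_temperature < 0))
    stop("`initial_temperature` must be \"auto\" or a non-negative number")
  if (!is.null(species_weights) && any(species_weights < 0))
    stop("`species_weights` must be non-negative")
  structure(list(
    seed = as.integer(seed), restarts = as.integer(restarts),
    initial_temperature = initial_temperature,
    cooling_factor = cooling_factor,
    iterations_per_temperature = as.integer(iterations_per_temperature),
    temperature_floor_ratio = temperature_floor_ratio,
    lower = lower, upper = upper,
    convergence_tolerance = convergence_tolerance,
    polish_iterations = as.integer(polish_iterations),
    species_weights = species_weights
  ), class = "fit_options")
}

#' Weighted sum-of-squares objective between model and observations
#'
#' Simulates the model implied by `params` from the observed initial state on
#' the observed time grid and returns
#' \eqn{\sum_s w_s \sum_t (sim_s(t) - obs_s(t))^2}. Default weights are
#' \eqn{w_s = 1/\max_t obs_s(t)^2} per species. A failed integration yields
#' `+Inf`, so the optimizer simply rejects that move.
#'
#' @param params [mmm_params()] or [cybernetic_params()].
#' @param observed Tidy data frame with columns `time_h`, `species_id`,
#'   `value`; species `biomass` plus the pools `C1..Cn`, every species on one
#'   common time grid (interpolate first, see [interpolate_replicates()]).
#' @param species_weights Optional named per-species weights.
#' @param enzymes0 Initial enzyme levels for the cybernetic model.
#' @return Non-negative scalar (or `+Inf` on integration failure).
#' @export
sse_objective <- function(params, observed, species_weights = NULL,
                          enzymes0 = NULL) {
  obs <- observed_wide(observed)
  w <- resolve_weights(obs, species_weights)
  sim <- try(predict_species(params, obs$times, obs$initial, enzymes0),
             silent = TRUE)
  if (inherits(sim, "try-error")) return(Inf)
  sum(vapply(colnames(obs$Y), function(s)
    w[[s]] * sum((sim[, s] - obs$Y[, s])^2), numeric(1)))
}

#' Fit a growth model to observed series
#'
#' Estimates all free parameters (see [count_free_parameters()]) by
#' minimizing [sse_objective()] with [anneal_simplex()] in log-parameter
#' space. Deterministic given `options$seed`.
#'
#' @inheritParams sse_objective
#' @param model `"mmm"` or `"cybernetic"`.
#' @param options A [fit_options()] object.
#' @param dilution_mode Enzyme dilution form for the cybernetic model.
#' @return An object of class `growth_fit`: `params` (fitted parameter
#'   object), `sse` (unweighted per-species and total SSE), `objective`
#'   (weighted objective at the optimum), `n_points`, `n_params`,
#'   `objective_trace` (best-so-far per evaluation), `seed`, `model`,
#'   `weights`, `enzymes0`.
#' @examples
#' \donttest{
#' exp <- generate_experiment(seed = 42)
#' obs <- interpolate_replicates(lump_observed(exp$data), n_out = 49)
#' fit <- fit_model(obs, "mmm", fit_options(seed = 1, restarts = 1,
#'                                          iterations_per_temperature = 10))
#' fit$sse$total
#' }
#' @export
fit_model <- function(observed, model = c("mmm", "cybernetic"),
                      options = fit_options(), dilution_mode = "standard",
                      enzymes0 = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(options, "fit_options"))
  obs <- observed_wide(observed)
  n <- ncol(obs$Y) - 1L
  if (model == "cybernetic" && is.null(enzymes0)) enzymes0 <- rep(0.01, n)
  w <- resolve_weights(obs, options$species_weights)
  p <- count_free_parameters(model, n)

  lo <- log(rep_len(options$lower, p))
  hi <- log(rep_len(options$upper, p))
  objective <- function(theta) {
    pr <- try(theta_to_params(theta, model, n, dilution_mode), silent = TRUE)
    if (inherits(pr, "try-error")) return(Inf)
    sim <- try(predict_species(pr, obs$times, obs$initial, enzymes0),
               silent = TRUE)
    if (inherits(sim, "try-error")) return(Inf)
    val <- sum(vapply(colnames(obs$Y), function(s)
      w[[s]] * sum((sim[, s] - obs$Y[, s])^2), numeric(1)))
    if (!is.finite(val)) Inf else val
  }

  t0 <- options$initial_temperature
  if (identical(t0, "auto")) {
    set.seed(options$seed)
    draws <- replicate(20, objective(stats::runif(p, lo, hi)))
    draws <- draws[is.finite(draws)]
    t0 <- if (length(draws) >= 2) stats::sd(draws) else 1
    if (!is.finite(t0) || t0 <= 0) t0 <- 1
  }

  best <- NULL
  traces <- list()
  for (r in seq_len(options$restarts)) {
    set.seed(options$seed + r)
    x0 <- if (r == 1L) (lo + hi) / 2 else stats::runif(p, lo, hi)
    res <- anneal_simplex(
      objective, x0, lower = lo, upper = hi,
      initial_temperature = t0,
      cooling_factor = options$cooling_factor,
      iterations_per_temperature = options$iterations_per_temperature,
      temperature_floor_ratio = options$temperature_floor_ratio,
      convergence_tolerance = options$convergence_tolerance,
      polish_iterations = options$polish_iterations
    )
    traces[[r]] <- res$trace
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value))
    stop("fitting failed: no restart produced a finite objective ",
         "(all candidate parameter sets failed to integrate)")

  params <- theta_to_params(best$par, model, n, dilution_mode)
  sim <- predict_species(params, obs$times, obs$initial, enzymes0)
  sse_species <- vapply(colnames(obs$Y), function(s)
    sum((sim[, s] - obs$Y[, s])^2), numeric(1))
  structure(list(
    params = params,
    model = model,
    objective = best$value,
    sse = list(per_species = sse_species, total = sum(sse_species)),
    n_points = list(per_species = nrow(obs$Y),
                    total = nrow(obs$Y) * ncol(obs$Y)),
    n_params = p,
    objective_trace = best$trace,
    restart_traces = traces,
    evaluations = best$evaluations,
    seed = options$seed,
    weights = w,
    enzymes0 = enzymes0,
    observed_times = obs$times,
    initial = obs$initial
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("%s model fit: %d free parameters, objective %.4g (SSE %.4g)\n",
              x$model, x$n_params, x$objective, x$sse$total))
  cat(sprintf("  %d objective evaluations, seed %d\n",
              x$evaluations, x$seed))
  invisible(x)
}

#' Predicted species trajectories from a fit
#'
#' @param object A `growth_fit`.
#' @param times Time grid (default: the grid the model was fitted on).
#' @param ... Unused.
#' @return Matrix with one row per time and columns `biomass`, `C1..Cn`.
#' @export
predict.growth_fit <- function(object, times = object$observed_times, ...) {
  predict_species(object$params, times, object$initial, object$enzymes0)
}

#' Hybrid simplex / simulated-annealing minimizer
#'
#' Nelder-Mead with thermal noise: at temperature `T`, each stored vertex
#' objective is perceived as `y - T*log(runif(1))` (always worse) and each
#' trial point as `y + T*log(runif(1))` (always better), so uphill moves are
#' accepted with Metropolis-like probability; at `T = 0` this is exactly the
#' deterministic simplex. Box constraints are enforced by clamping trial
#' points. The true best point ever evaluated is tracked and returned.
#'
#' @param fn Objective function of a numeric vector; may return `Inf`.
#' @param x0 Starting point.
#' @param lower,upper Bounds (vectors or scalars, may be infinite).
#' @param initial_temperature Starting temperature (0 for plain simplex).
#' @param cooling_factor Geometric cooling ratio.
#' @param iterations_per_temperature Simplex steps per temperature level.
#' @param temperature_floor_ratio Stop annealing below this fraction of the
#'   initial temperature.
#' @param convergence_tolerance Relative spread of vertex objectives at which
#'   the zero-temperature polish stops.
#' @param polish_iterations Cap on polish steps.
#' @param initial_step Edge length of the starting simplex (default 10% of
#'   the box, or 0.1).
#' @return List: `par`, `value`, `trace` (best-so-far objective after each
#'   evaluation), `evaluations`.
#' @examples
#' # deterministic simplex on a quadratic bowl
#' anneal_simplex(function(x) sum((x - 3)^2), c(0, 0),
#'                initial_temperature = 0)$par
#' @export
anneal_simplex <- function(fn, x0, lower = -Inf, upper = Inf,
                           initial_temperature = 1,
                           cooling_factor = 0.9,
                           iterations_per_temperature = 50L,
                           temperature_floor_ratio = 1e-3,
                           convergence_tolerance = 1e-10,
                           polish_iterations = 2000L,
                           initial_step = NULL) {
  d <- length(x0)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  clamp <- function(x) pmin(pmax(x, lower), upper)
  if (is.null(initial_step)) {
    span <- upper - lower
    initial_step <- ifelse(is.finite(span), 0.1 * span, 0.1)
  }
  initial_step <- rep_len(initial_step, d)

  n_eval <- 0L
  best_x <- NULL; best_y <- Inf
  trace <- numeric(0)
  eval_fn <- function(x) {
    y <- fn(x)
    n_eval <<- n_eval + 1L
    if (y < best_y) { best_y <<- y; best_x <<- x }
    trace[n_eval] <<- best_y
    y
  }

  X <- matrix(rep(clamp(x0), d + 1L), nrow = d + 1L, byrow = TRUE)
  for (i in seq_len(d)) {
    X[i + 1L, i] <- X[i + 1L, i] + initial_step[i]
    X[i + 1L, ] <- clamp(X[i + 1L, ])
  }
  y <- apply(X, 1, eval_fn)

  step <- function(temp) {
    # perceived objectives: stored vertices penalized, trials favoured
    yp <- y + if (temp > 0) -temp * log(stats::runif(d + 1L)) else 0
    ord <- order(yp)
    X <<- X[ord, , drop = FALSE]; y <<- y[ord]; yp <- yp[ord]
    lo_p <- yp[1L]; hi_p <- yp[d + 1L]; next_hi_p <- yp[d]
    centroid <- colMeans(X[seq_len(d), , drop = FALSE])
    perceive <- function(val)
      val + if (temp > 0) temp * log(stats::runif(1L)) else 0

    xr <- clamp(centroid + (centroid - X[d + 1L, ]))
    yr <- eval_fn(xr); yr_p <- perceive(yr)
    if (yr_p < lo_p) {
      xe <- clamp(centroid + 2 * (centroid - X[d + 1L, ]))
      ye <- eval_fn(xe); ye_p <- perceive(ye)
      if (ye_p < yr_p) { X[d + 1L, ] <<- xe; y[d + 1L] <<- ye }
      else { X[d + 1L, ] <<- xr; y[d + 1L] <<- yr }
    } else if (yr_p < next_hi_p) {
      X[d + 1L, ] <<- xr; y[d + 1L] <<- yr
    } else {
      xc <- clamp(centroid + 0.5 * (X[d + 1L, ] - centroid))
      yc <- eval_fn(xc); yc_p <- perceive(yc)
      if (yc_p < hi_p) { X[d + 1L, ] <<- xc; y[d + 1L] <<- yc }
      else {
        for (i in 2:(d + 1L)) {
          X[i, ] <<- clamp(X[1L, ] + 0.5 * (X[i, ] - X[1L, ]))
          y[i] <<- eval_fn(X[i, ])
        }
      }
    }
  }

  temp <- initial_temperature
  if (temp > 0) {
    floor_t <- temp * temperature_floor_ratio
    while (temp >= floor_t) {
      for (it in seq_len(iterations_per_temperature)) step(temp)
      temp <- temp * cooling_factor
    }
    # polish from a fresh, well-conditioned simplex around the best point
    # seen during annealing (the annealed simplex is typically collapsed)
    if (!is.null(best_x)) {
      X <- matrix(rep(best_x, d + 1L), nrow = d + 1L, byrow = TRUE)
      for (i in seq_len(d)) {
        X[i + 1L, i] <- X[i + 1L, i] +
          min(initial_step[i], 0.1 * max(abs(best_x[i]), 1))
        X[i + 1L, ] <- clamp(X[i + 1L, ])
      }
      y <- apply(X, 1, eval_fn)
    }
  }
  for (it in seq_len(polish_iterations)) {
    fin <- y[is.finite(y)]
    if (length(fin) == d + 1L &&
        (max(fin) - min(fin)) <= convergence_tolerance *
          (abs(min(fin)) + convergence_tolerance))
      break
    step(0)
  }

  list(par = best_x, value = best_y, trace = trace, evaluations = n_eval)
}

## ---- internal helpers -----------------------------------------------------

# validate the tidy observed frame and pivot to a times x species matrix;
# species order: biomass, then pools C1..Cn
observed_wide <- function(observed) {
  if (inherits(observed, "growth_fit_obs")) return(observed)
  stopifnot(all(c("time_h", "species_id", "value") %in% names(observed)))
  species <- unique(observed$species_id)
  pools <- sort(species[grepl("^C[0-9]+$", species)])
  if (!"biomass" %in% species || length(pools) == 0L)
    stop("observed data must contain species `biomass` and pools `C1..Cn`")
  cols <- c("biomass", pools)
  sp_split <- split(observed, observed$species_id)
  times <- sort(sp_split[[cols[1]]]$time_h)
  Y <- vapply(cols, function(s) {
    df <- sp_split[[s]][order(sp_split[[s]]$time_h), ]
    if (length(df$time_h) != length(times) ||
        max(abs(df$time_h - times)) > 1e-8)
      stop("all species must share one common time grid")
    df$value
  }, numeric(length(times)))
  structure(list(times = times, Y = Y,
                 initial = Y[1, , drop = TRUE]),
            class = "growth_fit_obs")
}

resolve_weights <- function(obs, species_weights) {
  cols <- colnames(obs$Y)
  if (is.null(species_weights)) {
    w <- vapply(cols, function(s) {
      m <- max(obs$Y[, s])
      if (m <= 0) 0 else 1 / m^2
    }, numeric(1))
  } else {
    if (is.null(names(species_weights)) || !all(cols %in% names(species_weights)))
      stop("`species_weights` must be named with every observed species")
    w <- species_weights[cols]
  }
  as.list(w)
}

theta_to_params <- function(theta, model, n, dilution_mode = "standard") {
  x <- exp(theta)
  if (model == "mmm") {
    mmm_params(beta = x[1:n], k = x[(n + 1):(2 * n)],
               death_rate = x[2 * n + 1])
  } else {
    cybernetic_params(
      v_max = x[1:n], k_s = x[(n + 1):(2 * n)],
      v_e = x[(2 * n + 1):(3 * n)], k_e = x[(3 * n + 1):(4 * n)],
      alpha = x[4 * n + 1], beta_const = x[4 * n + 2],
      death_rate = x[4 * n + 3], dilution_mode = dilution_mode
    )
  }
}

params_to_theta <- function(params) {
  if (inherits(params, "mmm_params"))
    log(c(params$beta, params$k, params$death_rate))
  else
    log(c(params$v_max, params$k_s, params$v_e, params$k_e,
          params$alpha, params$beta_const, params$death_rate))
}

# simulate and return only the observable species (biomass + pools)
predict_species <- function(params, times, initial, enzymes0 = NULL) {
  n <- params$n_pools
  tr <- simulate_growth(params, biomass0 = initial[["biomass"]],
                        substrates0 = as.numeric(initial[-1]),
                        enzymes0 = enzymes0, times = times)
  out <- cbind(biomass = tr$biomass, tr$substrates)
  colnames(out) <- c("biomass", paste0("C", seq_len(n)))
  out
}
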