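# Shared fixtures and the independent fixed-step Euler oracle.
# The oracle integrates with the pure-R derivative functions, a route fully
# separate from the compiled adaptive integrator it is used to check.

euler_simulate <- function(params, biomass0, substrates0, enzymes0 = NULL,
                           times, h = 1e-4) {
  is_cyb <- inherits(params, "cybernetic_params")
  n <- params$n_pools
  if (is_cyb && is.null(enzymes0)) enzymes0 <- rep(0.01, n)
  y <- c(biomass0, substrates0, if (is_cyb) enzymes0)
  t <- times[1]
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y))
  out[1, ] <- y
  for (i in seq_along(times)[-1]) {
    while (t < times[i] - 1e-12) {
      step <- min(h, times[i] - t)
      dy <- if (is_cyb)
        cybernetic_derivatives(y[1], y[2:(n + 1)], y[(n + 2):(2 * n + 1)],
                               params)
      else
        mmm_derivatives(y[1], y[2:(n + 1)], params)
      y <- pmax(y + step * as.numeric(dy), 0)
      t <- t + step
    }
    out[i, ] <- y
  }
  out
}

# small random parameter draws used by property-style tests
random_mmm_params <- function() {
  mmm_params(beta = stats::runif(4, 0.1, 2), k = stats::runif(4, 0.05, 1),
             death_rate = stats::runif(1, 0, 0.1))
}

random_cybernetic_params <- function() {
  cybernetic_params(
    v_max = stats::runif(4, 0.2, 3), k_s = stats::runif(4, 0.05, 0.5),
    v_e = stats::runif(4, 0.1, 1.5), k_e = stats::runif(4, 0.05, 0.5),
    alpha = stats::runif(1, 0.05, 1), beta_const = stats::runif(1, 1e-3, 0.05),
    death_rate = stats::runif(1, 0, 0.1)
  )
}

default_s0 <- c(0.6, 0.8, 1.8, 0.6)

# fast fit settings for structural (non-recovery) fitting tests
quick_opts <- function(seed = 1L)
  fit_options(seed = seed, restarts = 1L, initial_temperature = 0,
              polish_iterations = 200L)

# build a growth_fit object around known parameters without optimizing,
# for tests that exercise comparison/reporting logic only
fit_stub <- function(params, observed, model = NULL) {
  obs <- cybgrowth:::observed_wide(observed)
  if (is.null(model))
    model <- if (inherits(params, "mmm_params")) "mmm" else "cybernetic"
  enz0 <- if (model == "cybernetic") rep(0.01, params$n_pools) else NULL
  pred <- cybgrowth:::predict_species(params, obs$times, obs$initial, enz0)
  sse_sp <- vapply(colnames(obs$Y), function(s)
    sum((pred[, s] - obs$Y[, s])^2), numeric(1))
  structure(list(
    params = params, model = model,
    objective = sum(sse_sp), sse = list(per_species = sse_sp,
                                        total = sum(sse_sp)),
    n_points = list(per_species = nrow(obs$Y),
                    total = nrow(obs$Y) * ncol(obs$Y)),
    n_params = count_free_parameters(model, params$n_pools),
    objective_trace = numeric(0), evaluations = 0L, seed = 0L,
    weights = cybgrowth:::resolve_weights(obs, NULL),
    enzymes0 = enz0, observed_times = obs$times, initial = obs$initial
  ), class = "growth_fit")
}
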