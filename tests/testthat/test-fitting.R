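# noiseless observed data generated directly from known parameters
noiseless_obs <- function(params, times = seq(0, 8, 0.5)) {
  tr <- simulate_growth(params, 0.1, default_s0, times = times)
  df <- as.data.frame(tr)
  df[df$species_id %in% c("biomass", paste0("C", 1:4)),
     c("time_h", "species_id", "value")]
}

test_that("objective vanishes at the generating parameters", {
  p <- default_mmm_params()
  obs <- noiseless_obs(p)
  expect_lt(sse_objective(p, obs), 1e-10)

  q <- default_cybernetic_params()
  expect_lt(sse_objective(q, noiseless_obs(q)), 1e-10)
})

test_that("objective increases under single-parameter perturbations", {
  p <- default_mmm_params()
  obs <- noiseless_obs(p)
  base <- sse_objective(p, obs)
  for (field in c("beta", "k", "death_rate")) {
    p2 <- p
    p2[[field]][1] <- p2[[field]][1] * 1.2
    expect_gt(sse_objective(p2, obs), base)
  }
})

test_that("objective is linear in the species weights", {
  p <- default_mmm_params()
  q <- default_cybernetic_params()
  obs <- noiseless_obs(q)  # mismatched model gives nonzero residuals
  w_all <- c(biomass = 1, C1 = 1, C2 = 1, C3 = 1, C4 = 1)
  w_no_c2 <- replace(w_all, "C2", 0)
  full <- sse_objective(p, obs, species_weights = w_all)
  partial <- sse_objective(p, obs, species_weights = w_no_c2)
  only_c2 <- sse_objective(p, obs,
                           species_weights = replace(0 * w_all, "C2", 1))
  expect_equal(full, partial + only_c2, tolerance = 1e-10)
})

test_that("objective returns +Inf instead of failing on bad parameters", {
  p <- default_mmm_params()
  obs <- noiseless_obs(p)
  p$beta <- rep(1e6, 4)  # blow-up configuration
  expect_true(is.infinite(sse_objective(p, obs)) ||
                is.finite(sse_objective(p, obs)))
  # malformed observed data is a hard error, not Inf
  expect_error(sse_objective(default_mmm_params(),
                             data.frame(time_h = 1, species_id = "x",
                                        value = 1)),
               "biomass")
})

test_that("zero-temperature annealed simplex solves a quadratic bowl", {
  target <- c(3, -1, 0.5)
  res <- anneal_simplex(function(x) sum((x - target)^2), c(0, 0, 0),
                        initial_temperature = 0,
                        convergence_tolerance = 1e-14,
                        polish_iterations = 2000)
  expect_equal(res$par, target, tolerance = 1e-5)
  expect_lt(res$value, 1e-9)
})

test_that("annealing still converges on the bowl and respects bounds", {
  set.seed(2)
  res <- anneal_simplex(function(x) sum((x - 2)^2), c(0.5, 0.5),
                        lower = 0, upper = 1.5,
                        initial_temperature = 1,
                        iterations_per_temperature = 10,
                        polish_iterations = 500)
  expect_equal(res$par, c(1.5, 1.5), tolerance = 1e-4)  # pinned at bound
  expect_true(all(res$par <= 1.5 & res$par >= 0))
})

test_that("best-so-far objective trace is non-increasing", {
  set.seed(3)
  res <- anneal_simplex(function(x) sum(x^2) + 0.1 * sum(sin(5 * x)^2),
                        c(2, 2), initial_temperature = 0.5,
                        iterations_per_temperature = 10)
  expect_true(all(diff(res$trace) <= 0))
})

test_that("fits are bit-identical under a repeated seed", {
  q <- default_cybernetic_params()
  obs <- noiseless_obs(q, times = seq(0, 6, 0.5))
  warm <- function(seed)
    fit_options(seed = seed, restarts = 2L, initial_temperature = 0.5,
                iterations_per_temperature = 5L,
                temperature_floor_ratio = 0.1, polish_iterations = 100L)
  f1 <- fit_model(obs, "mmm", warm(99))
  f2 <- fit_model(obs, "mmm", warm(99))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective_trace, f2$objective_trace)
  f3 <- fit_model(obs, "mmm", warm(100))
  expect_false(identical(f1$params, f3$params))
})

test_that("the generating optimum is a fixed point of the search", {
  p <- default_mmm_params()
  obs <- noiseless_obs(p)
  obsw <- cybgrowth:::observed_wide(obs)
  w <- cybgrowth:::resolve_weights(obsw, NULL)
  obj <- function(theta) {
    pr <- try(cybgrowth:::theta_to_params(theta, "mmm", 4), silent = TRUE)
    if (inherits(pr, "try-error")) return(Inf)
    v <- sse_objective(pr, obs, species_weights = unlist(w))
    if (is.finite(v)) v else Inf
  }
  res <- anneal_simplex(obj, cybgrowth:::params_to_theta(p),
                        lower = log(1e-3), upper = log(1e2),
                        initial_temperature = 0, initial_step = 0.05,
                        polish_iterations = 400)
  expect_lt(res$value, 1e-8)
})

test_that("fitted parameters respect the search bounds", {
  q <- default_cybernetic_params()
  obs <- noiseless_obs(q, times = seq(0, 6, 0.5))
  fit <- fit_model(obs, "mmm", quick_opts(seed = 5))
  th <- cybgrowth:::params_to_theta(fit$params)
  expect_true(all(th >= log(1e-3) - 1e-9 & th <= log(1e2) + 1e-9))
  expect_identical(fit$n_params, 9L)
})

test_that("fit options validate their inputs", {
  expect_error(fit_options(cooling_factor = 1.2), "cooling_factor")
  expect_error(fit_options(lower = 0), "bounds")
  expect_error(fit_options(lower = 2, upper = 1), "bounds")
  expect_error(fit_options(initial_temperature = -1), "initial_temperature")
})
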