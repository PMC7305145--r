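#' Pearson correlation between observed and predicted series
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3), neither
#'   constant.
#' @return Pearson product-moment correlation.
#' @export
pearson_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length")
  if (length(observed) < 3L) stop("at least 3 points are required")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("correlation is undefined for a constant series")
  stats::cor(observed, predicted)
}

#' Akaike information criterion from a sum of squared errors
#'
#' Computes `AIC = N * log(SSE / N) + 2 * p` with the natural logarithm,
#' the least-squares form appropriate when fits are compared on the same
#' training set of size `N` with `p` free parameters.
#'
#' @param sse Sum of squared errors (> 0; `sse = 0` returns `-Inf` with a
#'   warning, a perfect fit has unbounded support).
#' @param n Number of training cases.
#' @param p Number of free parameters.
#' @return AIC value (lower is better).
#' @examples
#' aic(49, 49, 9)   # 49 * log(1) + 18 = 18
#' @export
aic <- function(sse, n, p) {
  if (n <= 0 || p < 0) stop("`n` must be positive and `p` non-negative")
  if (sse < 0) stop("`sse` must be non-negative")
  if (sse == 0) {
    warning("SSE is exactly 0; AIC is -Inf")
    return(-Inf)
  }
  n * log(sse / n) + 2 * p
}

#' Compare two fitted growth models per species
#'
#' Simulates both fitted models on the common observed grid and reports, per
#' species (biomass and each pool), the Pearson correlation `r`, `R^2 = r^2`
#' and the AIC of each model, plus which model wins each species by higher
#' `r` and, separately, by lower AIC. A difference below `tie_tol` counts as
#' a tie and is credited to neither model.
#'
#' @param fit_a,fit_b `growth_fit` objects fitted to the same observed data.
#' @param observed The tidy observed data both models were fitted on.
#' @param tie_tol Absolute difference under which a comparison is a tie.
#' @return A `selection_report`: data frame `table` (one row per species with
#'   both models' metrics), `winner_by_r` and `winner_by_aic` (named counts
#'   `a`/`b`/`tie` summing to the number of species), and the models' tags.
#' @examples
#' \donttest{
#' exp <- generate_experiment(seed = 42)
#' obs <- interpolate_replicates(lump_observed(exp$data), n_out = 49)
#' opts <- fit_options(seed = 1, restarts = 1, iterations_per_temperature = 5)
#' compare_models(fit_model(obs, "mmm", opts),
#'                fit_model(obs, "cybernetic", opts), obs)
#' }
#' @export
compare_models <- function(fit_a, fit_b, observed, tie_tol = 1e-9) {
  stopifnot(inherits(fit_a, "growth_fit"), inherits(fit_b, "growth_fit"))
  obs <- observed_wide(observed)
  if (length(fit_a$observed_times) != length(obs$times) ||
      max(abs(fit_a$observed_times - obs$times)) > 1e-8 ||
      length(fit_b$observed_times) != length(obs$times) ||
      max(abs(fit_b$observed_times - obs$times)) > 1e-8)
    stop("both fits and `observed` must share one common time grid")

  pred_a <- predict(fit_a, obs$times)
  pred_b <- predict(fit_b, obs$times)
  species <- colnames(obs$Y)
  n <- nrow(obs$Y)

  row_for <- function(s) {
    r_a <- pearson_fit(obs$Y[, s], pred_a[, s])
    r_b <- pearson_fit(obs$Y[, s], pred_b[, s])
    sse_a <- sum((pred_a[, s] - obs$Y[, s])^2)
    sse_b <- sum((pred_b[, s] - obs$Y[, s])^2)
    a_aic <- aic(sse_a, n, fit_a$n_params)
    b_aic <- aic(sse_b, n, fit_b$n_params)
    data.frame(
      species_id = s,
      pearson_a = r_a, pearson_b = r_b,
      r2_a = r_a^2, r2_b = r_b^2,
      aic_a = a_aic, aic_b = b_aic,
      winner_r = pick_winner(r_b - r_a, tie_tol),
      winner_aic = pick_winner(a_aic - b_aic, tie_tol)
    )
  }
  tab <- do.call(rbind, lapply(species, row_for))
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    model_a = fit_a$model, model_b = fit_b$model,
    winner_by_r = count_winners(tab$winner_r),
    winner_by_aic = count_winners(tab$winner_aic),
    n_per_species = n
  ), class = "selection_report")
}

# positive delta favours model b
pick_winner <- function(delta, tie_tol) {
  if (abs(delta) < tie_tol) "tie" else if (delta > 0) "b" else "a"
}

count_winners <- function(w) {
  c(a = sum(w == "a"), b = sum(w == "b"), tie = sum(w == "tie"))
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Model comparison: a = %s, b = %s (%d species, N = %d each)\n",
              x$model_a, x$model_b, nrow(x$table), x$n_per_species))
  print(x$table, digits = 4)
  cat("wins by Pearson r:  ", format_wins(x$winner_by_r), "\n")
  cat("wins by AIC:        ", format_wins(x$winner_by_aic), "\n")
  invisible(x)
}

format_wins <- function(w)
  sprintf("a %d, b %d, ties %d", w[["a"]], w[["b"]], w[["tie"]])

#' Wide metric-by-species table of a model comparison
#'
#' Renders a [compare_models()] report with one row per metric and model and
#' one column per species (pool clusters first, biomass last).
#'
#' @param report A `selection_report`.
#' @return Data frame with columns `metric`, `model`, then one per species.
#' @export
selection_table <- function(report) {
  stopifnot(inherits(report, "selection_report"))
  tab <- report$table
  species <- tab$species_id
  ord <- c(setdiff(species, "biomass"), "biomass")
  rows <- list(
    c(metric = "pearson", model = report$model_a),
    c(metric = "pearson", model = report$model_b),
    c(metric = "aic", model = report$model_a),
    c(metric = "aic", model = report$model_b)
  )
  vals <- rbind(tab$pearson_a, tab$pearson_b, tab$aic_a, tab$aic_b)
  colnames(vals) <- species
  out <- data.frame(do.call(rbind, rows), vals[, ord, drop = FALSE],
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
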