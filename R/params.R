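#' Parameters of the Michaelis-Menten-Monod (MMM) growth model
#'
#' The MMM model describes batch growth of a bacterial population \eqn{\phi P}
#' on `n` lumped substrate pools \eqn{\phi S_i} with saturating uptake
#' kinetics and a first-order death term:
#' \deqn{d\phi P/dt = \sum_i \beta_i \phi S_i^2 / (k_i + \phi S_i) \cdot \phi P - d\,\phi P}
#' \deqn{d\phi S_i/dt = -\beta_i \phi S_i^2 / (k_i + \phi S_i) \cdot \phi P}
#' Biomass gain equals substrate consumption (no explicit yield factor); the
#' unit conversion between OD and mM is absorbed into \eqn{\beta_i}.
#'
#' @param beta Numeric vector of maximum rate constants for cell production,
#'   one per pool (effective 1/h per mM).
#' @param k Numeric vector of Michaelis-Menten constants, mM, one per pool.
#' @param death_rate Death rate `d`, 1/h.
#' @return An object of class `mmm_params`.
#' @seealso [cybernetic_params()], [simulate_growth()], [mmm_derivatives()]
#' @examples
#' mmm_params(beta = c(3, 1.5, 0.6, 0.2), k = rep(0.5, 4), death_rate = 0.02)
#' @export
mmm_params <- function(beta, k, death_rate) {
  beta <- as.numeric(beta)
  k <- as.numeric(k)
  death_rate <- as.numeric(death_rate)
  if (length(beta) != length(k))
    stop("`beta` and `k` must have the same length (one entry per pool)")
  if (length(death_rate) != 1L)
    stop("`death_rate` must be a single value")
  check_positive_finite(c(beta = beta, k = k))
  check_nonnegative_finite(c(death_rate = death_rate))
  structure(
    list(beta = beta, k = k, death_rate = death_rate,
         n_pools = length(beta)),
    class = "mmm_params"
  )
}

#' Parameters of the cybernetic growth model
#'
#' The cybernetic model adds, for each substrate pool, a key assimilatory
#' enzyme \eqn{\phi E_i} whose synthesis and activity are modulated by
#' optimality-derived control variables (see [cybernetic_controls()]):
#' resources for enzyme synthesis are allocated in proportion to the returns
#' (`u`), and enzyme activity is throttled relative to the best currently
#' available substrate (`v`). Per-pool rates are
#' \deqn{r_i = V_{max,i}\,\phi E_i\,\phi S_i/(K_{S,i} + \phi S_i), \qquad
#'       r_{E,i} = V_{E,i}\,\phi S_i/(K_{E,i} + \phi S_i).}
#'
#' The enzyme balance contains synthesis (`u_i r_{E,i}`), dilution by growth,
#' first-order decay (`alpha`) and constitutive synthesis (`beta_const`).
#' The dilution term has two forms:
#' \describe{
#'   \item{`"standard"`}{\eqn{-(\sum_j v_j r_j)\,\phi E_i}, the canonical
#'     dilution of an intensive enzyme level by biomass growth. Keeps
#'     \eqn{\phi E_i \ge 0} whenever `beta_const > 0`. The default.}
#'   \item{`"as_printed"`}{\eqn{-(\sum_j v_j r_j)\,\phi P}, an alternative
#'     form in which dilution scales with biomass rather than with the enzyme
#'     level itself; it is dimensionally inconsistent with an intensive enzyme
#'     variable and can drive enzyme levels negative. Provided for comparison.}
#' }
#'
#' @param v_max Maximum biomass production rate constants, 1/h, one per pool.
#' @param k_s Substrate affinity constants for growth, mM, one per pool.
#' @param v_e Maximum enzyme synthesis rate constants, 1/h, one per pool.
#' @param k_e Substrate affinity constants for enzyme synthesis, mM, one per
#'   pool.
#' @param alpha Enzyme decay constant, 1/h (scalar).
#' @param beta_const Constitutive enzyme production rate, 1/h. A scalar shared
#'   across pools (the default configuration, giving 19 free parameters for 4
#'   pools) or a vector with one entry per pool.
#' @param death_rate Death rate `d`, 1/h.
#' @param dilution_mode `"standard"` or `"as_printed"`, see Details.
#' @return An object of class `cybernetic_params`.
#' @seealso [mmm_params()], [simulate_growth()], [count_free_parameters()]
#' @examples
#' cybernetic_params(
#'   v_max = c(6, 4, 2.5, 1.2), k_s = rep(0.1, 4),
#'   v_e = c(1.5, 1, 0.8, 0.4), k_e = rep(0.1, 4),
#'   alpha = 0.05, beta_const = 0.02, death_rate = 0.02
#' )
#' @export
cybernetic_params <- function(v_max, k_s, v_e, k_e, alpha, beta_const,
                              death_rate,
                              dilution_mode = c("standard", "as_printed")) {
  dilution_mode <- match.arg(dilution_mode)
  v_max <- as.numeric(v_max); k_s <- as.numeric(k_s)
  v_e <- as.numeric(v_e); k_e <- as.numeric(k_e)
  n <- length(v_max)
  if (length(k_s) != n || length(v_e) != n || length(k_e) != n)
    stop("`v_max`, `k_s`, `v_e` and `k_e` must all have one entry per pool")
  if (!length(beta_const) %in% c(1L, n))
    stop("`beta_const` must be a scalar (shared) or one entry per pool")
  if (length(alpha) != 1L || length(death_rate) != 1L)
    stop("`alpha` and `death_rate` must be single values")
  check_positive_finite(c(v_max = v_max, k_s = k_s, v_e = v_e, k_e = k_e))
  check_nonnegative_finite(c(alpha = alpha, beta_const = beta_const,
                             death_rate = death_rate))
  structure(
    list(v_max = v_max, k_s = k_s, v_e = v_e, k_e = k_e,
         alpha = as.numeric(alpha), beta_const = as.numeric(beta_const),
         death_rate = as.numeric(death_rate), dilution_mode = dilution_mode,
         n_pools = n),
    class = "cybernetic_params"
  )
}

#' @export
print.mmm_params <- function(x, ...) {
  cat("MMM growth model parameters (", x$n_pools, " pools)\n", sep = "")
  cat("  beta:", format(x$beta, digits = 4), "\n")
  cat("  k:   ", format(x$k, digits = 4), "\n")
  cat("  d:   ", format(x$death_rate, digits = 4), "\n")
  invisible(x)
}

#' @export
print.cybernetic_params <- function(x, ...) {
  cat("Cybernetic growth model parameters (", x$n_pools, " pools, dilution ",
      x$dilution_mode, ")\n", sep = "")
  cat("  v_max:", format(x$v_max, digits = 4), "\n")
  cat("  k_s:  ", format(x$k_s, digits = 4), "\n")
  cat("  v_e:  ", format(x$v_e, digits = 4), "\n")
  cat("  k_e:  ", format(x$k_e, digits = 4), "\n")
  cat("  alpha:", format(x$alpha, digits = 4),
      " beta:", format(x$beta_const, digits = 4),
      " d:", format(x$death_rate, digits = 4), "\n")
  invisible(x)
}

#' Number of independently fitted scalar parameters of a model configuration
#'
#' For the default 4-pool configurations this gives 9 for the MMM model
#' (4 beta + 4 k + d) and 19 for the cybernetic model (4 V_max + 4 K_S +
#' 4 V_E + 4 K_E + alpha + one shared constitutive rate + d). Initial enzyme
#' levels are fixed, not fitted, and are not counted.
#'
#' @param model `"mmm"` or `"cybernetic"`.
#' @param n_pools Number of substrate pools (default 4).
#' @param beta_sharing For the cybernetic model, whether the constitutive
#'   enzyme production rate is `"shared"` across pools (default) or
#'   `"per_pool"`.
#' @return Integer count of free parameters.
#' @examples
#' count_free_parameters("mmm")         # 9
#' count_free_parameters("cybernetic")  # 19
#' @export
count_free_parameters <- function(model = c("mmm", "cybernetic"),
                                  n_pools = 4L,
                                  beta_sharing = c("shared", "per_pool")) {
  model <- match.arg(model)
  beta_sharing <- match.arg(beta_sharing)
  n <- as.integer(n_pools)
  if (n < 1L) stop("`n_pools` must be at least 1")
  if (model == "mmm") {
    2L * n + 1L
  } else {
    4L * n + 1L + (if (beta_sharing == "shared") 1L else n) + 1L
  }
}

# shared validators; rate/affinity constants must be strictly positive,
# decay-type constants may be zero (the conserving limit d = 0 is a valid
# and diagnostically useful configuration)
check_positive_finite <- function(x) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("parameters must be strictly positive and finite; offending: ",
         paste(unique(sub("[0-9]+$", "", names(x)[bad])), collapse = ", "))
  invisible(x)
}

check_nonnegative_finite <- function(x) {
  bad <- !is.finite(x) | x < 0
  if (any(bad))
    stop("parameters must be non-negative and finite; offending: ",
         paste(unique(sub("[0-9]+$", "", names(x)[bad])), collapse = ", "))
  invisible(x)
}

check_state <- function(biomass, substrates, enzymes = NULL) {
  vals <- c(biomass, substrates, enzymes)
  if (any(!is.finite(vals)))
    stop("state must be finite")
  if (any(vals < 0))
    stop("state components must be non-negative")
  invisible(TRUE)
}
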