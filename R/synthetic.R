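#' Default grouping of the 19 amino acids into kinetic groups
#'
#' The defined medium holds 19 amino acids at 0.2 mM each (cysteine is
#' excluded as it cannot be quantified reliably). They fall into four
#' co-utilized groups, ordered by when they are depleted: group 1
#' (Gln, Glu, Arg) first, then group 2 (Asn, Asp, Leu, Pro), then the large
#' group 3 of nine (Ala, Gly, Ile, Lys, Phe, Ser, Thr, Tyr, Val), with
#' group 4 (His, Met, Trp) consumed last and slowest.
#'
#' @return Named integer vector mapping amino-acid code to group index.
#' @export
aa_groups <- function() {
  c(Gln = 1L, Glu = 1L, Arg = 1L,
    Asn = 2L, Asp = 2L, Leu = 2L, Pro = 2L,
    Ala = 3L, Gly = 3L, Ile = 3L, Lys = 3L, Phe = 3L,
    Ser = 3L, Thr = 3L, Tyr = 3L, Val = 3L,
    His = 4L, Met = 4L, Trp = 4L)
}

#' Lumping scheme: amino acids to substrate pools
#'
#' Bridges per-amino-acid observables and the pooled model state: each amino
#' acid belongs to exactly one pool, with a within-pool share (default equal)
#' describing its fraction of the pooled concentration.
#'
#' @param group_of Named integer vector, amino acid -> group index
#'   (default [aa_groups()]).
#' @param shares Optional named numeric vector of within-group shares; must
#'   sum to 1 within each group. Default equal shares.
#' @return A `lumping_scheme` with `group_of`, `shares`, `n_groups`,
#'   `group_sizes`.
#' @export
lumping_scheme <- function(group_of = aa_groups(), shares = NULL) {
  if (is.null(names(group_of))) stop("`group_of` must be named")
  groups <- sort(unique(group_of))
  if (!identical(as.integer(groups), seq_along(groups)))
    stop("group indices must be 1..k")
  sizes <- as.integer(table(factor(group_of, levels = groups)))
  if (is.null(shares)) {
    shares <- 1 / sizes[group_of]
    names(shares) <- names(group_of)
  } else {
    if (!all(names(group_of) %in% names(shares)))
      stop("`shares` must be named for every amino acid")
    shares <- shares[names(group_of)]
    for (g in groups) {
      tot <- sum(shares[group_of == g])
      if (abs(tot - 1) > 1e-12)
        stop("shares within group ", g, " must sum to 1 (got ", tot, ")")
    }
  }
  structure(list(group_of = group_of, shares = shares,
                 n_groups = length(groups), group_sizes = sizes),
            class = "lumping_scheme")
}

#' Measurement and heterogeneity noise settings for the generator
#'
#' @param measurement_sd Measurement noise SD as a fraction of each species'
#'   initial concentration (amino acids: 0.2 mM; biomass: the starting OD).
#'   The default 0.05 gives an absolute SD of 0.01 mM per amino acid and
#'   0.005 OD units, typical of NMR quantification and OD600 reads.
#' @param within_group_jitter_sd SD of the log-normal per-amino-acid rate
#'   jitter that differentiates members of one pool. Default 0.1.
#' @param replicates Number of replicate cultures. Default 2.
#' @param seed Integer seed; `NULL` defers to the seed given at generation
#'   time.
#' @return A `noise_model` list.
#' @export
noise_model <- function(measurement_sd = 0.05, within_group_jitter_sd = 0.1,
                        replicates = 2L, seed = NULL) {
  if (measurement_sd < 0 || within_group_jitter_sd < 0)
    stop("noise SDs must be non-negative")
  if (replicates < 1L) stop("`replicates` must be at least 1")
  structure(list(measurement_sd = measurement_sd,
                 within_group_jitter_sd = within_group_jitter_sd,
                 replicates = as.integer(replicates),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

#' Default cybernetic parameters of the synthetic experiment
#'
#' Invented generating values (they are not fitted estimates from any real
#' dataset): rate and affinity constants are ordered so that pool 1 supports
#' the fastest growth and pool 4 the slowest, which yields sequential
#' depletion in the order 1, 2, 3, 4 with visible growth lags at the
#' switches, and a slow final phase on pool 4.
#'
#' @return A [cybernetic_params()] object.
#' @export
default_cybernetic_params <- function() {
  cybernetic_params(
    v_max = c(2.4, 1.2, 0.7, 0.05),
    k_s = c(0.05, 0.05, 0.1, 0.1),
    v_e = c(1.3, 0.7, 0.55, 0.08),
    k_e = c(0.05, 0.05, 0.05, 0.05),
    alpha = 0.9, beta_const = 0.001, death_rate = 0.01
  )
}

#' Default MMM parameters of the synthetic experiment
#'
#' Invented generating values for the unregulated Monod-type model, ordered
#' so the four pools are consumed at decreasing speed (simultaneously, as
#' this model has no regulatory switching).
#'
#' @return An [mmm_params()] object.
#' @export
default_mmm_params <- function() {
  mmm_params(
    beta = c(0.7, 0.55, 0.35, 0.22),
    k = c(0.04, 0.05, 0.1, 0.05),
    death_rate = 0.05
  )
}

#' Generate a synthetic multi-amino-acid depletion experiment
#'
#' Simulates the lumped model, disaggregates the pooled substrate curves
#' into per-amino-acid profiles (see [disaggregate()]), and adds
#' truncated-at-zero Gaussian measurement noise per replicate. Defaults
#' emulate a defined-medium experiment: 19 amino acids at `conc_per_aa =
#' 0.2` mM each (pool totals 0.6, 0.8, 1.8, 0.6 mM), starting OD600 0.1,
#' sampled every 0.5 h for 10 h, two replicates, 5% measurement noise.
#'
#' @param params Generating model parameters
#'   ([default_cybernetic_params()] or an [mmm_params()] object).
#' @param scheme A [lumping_scheme()].
#' @param noise A [noise_model()].
#' @param times Sampling grid, hours.
#' @param biomass0 Initial OD600.
#' @param conc_per_aa Initial concentration of every amino acid, mM.
#' @param seed Integer seed (used unless `noise$seed` is set).
#' @return An `aa_experiment`: `data` (tidy data frame `time_h`,
#'   `species_id`, `replicate_id`, `value`, holding every amino acid plus
#'   `biomass`) and `truth` (generating params, scheme, noise, noiseless
#'   lumped trajectory, noiseless per-amino-acid matrix, pool depletion
#'   times, switch times, seed).
#' @examples
#' exp <- generate_experiment(seed = 42)
#' head(exp$data)
#' exp$truth$switch_times
#' @export
generate_experiment <- function(params = default_cybernetic_params(),
                                scheme = lumping_scheme(),
                                noise = noise_model(),
                                times = seq(0, 10, 0.5),
                                biomass0 = 0.1, conc_per_aa = 0.2,
                                seed = 42L) {
  if (!is.null(noise$seed)) seed <- noise$seed
  n <- scheme$n_groups
  if (params$n_pools != n)
    stop("`params` and `scheme` disagree on the number of pools")
  S0 <- conc_per_aa * scheme$group_sizes
  traj <- simulate_growth(params, biomass0 = biomass0, substrates0 = S0,
                          times = times)

  set.seed(seed)
  aa_true <- disaggregate(traj, scheme,
                          jitter_sd = noise$within_group_jitter_sd)

  # per-species measurement noise SD: fraction of the initial concentration
  sd_aa <- noise$measurement_sd * conc_per_aa
  sd_od <- noise$measurement_sd * biomass0
  reps <- lapply(seq_len(noise$replicates), function(r) {
    noisy_aa <- pmax(aa_true + stats::rnorm(length(aa_true), sd = sd_aa), 0)
    noisy_od <- pmax(traj$biomass +
                       stats::rnorm(length(traj$biomass), sd = sd_od), 0)
    rbind(
      data.frame(time_h = rep(times, each = nrow(aa_true)),
                 species_id = rep(rownames(aa_true), length(times)),
                 replicate_id = r,
                 value = as.vector(noisy_aa)),
      data.frame(time_h = times, species_id = "biomass",
                 replicate_id = r, value = noisy_od)
    )
  })
  data <- do.call(rbind, reps)
  rownames(data) <- NULL

  dep <- depletion_times(times, t(traj$substrates))
  names(dep) <- paste0("C", seq_len(n))
  structure(list(
    data = data,
    truth = list(
      params = params, scheme = scheme, noise = noise, seed = seed,
      times = times, biomass0 = biomass0, conc_per_aa = conc_per_aa,
      trajectory = traj,
      aa_profiles = aa_true,
      pool_depletion = dep,
      switch_times = switch_times_from_depletion(dep, traj),
      noise_sd = c(aa = sd_aa, biomass = sd_od)
    )
  ), class = "aa_experiment")
}

# ground-truth substrate-switch events: a pool depleting while at least one
# other pool is still present (> threshold) and is itself consumed by more
# than the threshold during the remaining horizon
switch_times_from_depletion <- function(dep, traj, threshold = 0.01) {
  finite <- sort(dep[is.finite(dep)])
  if (length(finite) == 0L) return(numeric(0))
  S <- traj$substrates
  t_end <- nrow(S)
  keep <- vapply(finite, function(t_dep) {
    i <- which.min(abs(traj$times - t_dep))
    any(S[i, ] > threshold & (S[i, ] - S[t_end, ]) > threshold)
  }, logical(1))
  unname(finite[keep])
}

#' Disaggregate a pooled trajectory into per-amino-acid profiles
#'
#' Each amino acid receives its within-pool share of the pooled
#' concentration, modulated by a smooth per-amino-acid log-normal jitter
#' profile (random intercept and slope in log space, scaled by `jitter_sd`)
#' and renormalized so the amino acids of a pool sum exactly to the pooled
#' concentration at every time point. Zero jitter gives the exact
#' proportional split. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param traj A `growth_trajectory` from [simulate_growth()].
#' @param scheme A [lumping_scheme()].
#' @param jitter_sd Log-scale SD of the within-pool heterogeneity.
#' @return Matrix with one row per amino acid (rownames from the scheme) and
#'   one column per time point, mM.
#' @export
disaggregate <- function(traj, scheme, jitter_sd = 0.1) {
  stopifnot(inherits(traj, "growth_trajectory"),
            inherits(scheme, "lumping_scheme"))
  times <- traj$times
  tt <- if (diff(range(times)) > 0)
    (times - times[1]) / diff(range(times)) else times * 0
  n_aa <- length(scheme$group_of)
  out <- matrix(0, nrow = n_aa, ncol = length(times),
                dimnames = list(names(scheme$group_of), NULL))
  for (g in seq_len(scheme$n_groups)) {
    members <- names(scheme$group_of)[scheme$group_of == g]
    w <- scheme$shares[members]
    if (jitter_sd > 0) {
      z0 <- stats::rnorm(length(members))
      z1 <- stats::rnorm(length(members))
      logm <- jitter_sd * (outer(z0, rep(1, length(times))) + outer(z1, tt))
      wt <- w * exp(logm)
    } else {
      wt <- outer(w, rep(1, length(times)))
    }
    wt <- sweep(wt, 2, colSums(wt), "/")
    out[members, ] <- sweep(wt, 2, traj$substrates[, g], "*")
  }
  out
}

#' Generate a synthetic expression matrix with known co-expression structure
#'
#' Builds gene sets whose log2 expression profiles share a latent temporal
#' signal with prescribed pairwise correlation `rho`: for gene g in a set,
#' `z_g = mu + sd * (sqrt(rho) * L + sqrt(1 - rho) * eps_g)` per time point,
#' and TPM = `2^z - 1` (so `log2(TPM + 1)` recovers `z` exactly, floored at
#' 0).
#'
#' @param design Data frame with columns `size` (genes per set) and `rho`
#'   (within-set correlation in `[0, 1)`), one row per regulon.
#' @param n_timepoints Number of time points (>= 3).
#' @param mean_log2,sd_log2 Location and scale of log2 expression.
#' @param seed Integer seed.
#' @return List: `tpm` (genes x time points matrix), `regulons` (named list
#'   of gene ids per set), `design`.
#' @examples
#' sim <- generate_expression(data.frame(size = c(4, 4), rho = c(0.9, 0)),
#'                            n_timepoints = 5, seed = 1)
#' coherence_table(sim$tpm, sim$regulons)
#' @export
generate_expression <- function(design, n_timepoints = 5L,
                                mean_log2 = 5, sd_log2 = 1.5, seed = 1L) {
  design <- as.data.frame(design)
  stopifnot(all(c("size", "rho") %in% names(design)))
  if (any(design$rho < 0 | design$rho >= 1))
    stop("`rho` must lie in [0, 1)")
  if (n_timepoints < 3L) stop("at least 3 time points are required")
  set.seed(seed)
  mats <- list(); regs <- list()
  gene_counter <- 0L
  for (i in seq_len(nrow(design))) {
    size <- design$size[i]; rho <- design$rho[i]
    latent <- stats::rnorm(n_timepoints)
    z <- t(vapply(seq_len(size), function(g)
      mean_log2 + sd_log2 * (sqrt(rho) * latent +
                               sqrt(1 - rho) * stats::rnorm(n_timepoints)),
      numeric(n_timepoints)))
    ids <- paste0("g", gene_counter + seq_len(size))
    gene_counter <- gene_counter + size
    rownames(z) <- ids
    mats[[i]] <- z
    regs[[paste0("set", i)]] <- ids
  }
  z <- do.call(rbind, mats)
  tpm <- pmax(2^z - 1, 0)
  colnames(tpm) <- paste0("t", seq_len(n_timepoints))
  list(tpm = tpm, regulons = regs, design = design)
}

#' Pool tidy per-amino-acid data into lumped substrate series
#'
#' Sums the amino acids of each group into the pooled species `C1..Ck`
#' (per time point and replicate) and passes `biomass` through, producing
#' the observed format [fit_model()] expects.
#'
#' @param data Tidy data frame `time_h`, `species_id`, `replicate_id`,
#'   `value` holding amino-acid and `biomass` series.
#' @param scheme A [lumping_scheme()].
#' @return Tidy data frame with species `biomass`, `C1..Ck`.
#' @export
lump_observed <- function(data, scheme = lumping_scheme()) {
  stopifnot(all(c("time_h", "species_id", "replicate_id", "value") %in%
                  names(data)))
  aa <- data[data$species_id %in% names(scheme$group_of), ]
  od <- data[data$species_id == "biomass", ]
  if (nrow(aa) == 0L) stop("no amino-acid species found in `data`")
  aa$pool <- paste0("C", scheme$group_of[aa$species_id])
  pooled <- stats::aggregate(value ~ time_h + pool + replicate_id, aa, sum)
  names(pooled)[names(pooled) == "pool"] <- "species_id"
  out <- rbind(pooled[, c("time_h", "species_id", "replicate_id", "value")],
               od[, c("time_h", "species_id", "replicate_id", "value")])
  out <- out[order(out$species_id, out$replicate_id, out$time_h), ]
  rownames(out) <- NULL
  out
}
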