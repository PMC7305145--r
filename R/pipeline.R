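#' Pipeline configuration
#'
#' Collects every choice the end-to-end analysis depends on. Unknown
#' arguments are rejected so that typos cannot silently fall back to
#' defaults.
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param model Generating model for synthetic data, `"cybernetic"` or
#'   `"mmm"`.
#' @param data_csv Optional path to an observed tidy CSV (`time_h`,
#'   `species_id`, `replicate_id`, `value`); when given, no synthetic data
#'   are generated and clustering runs on the amino-acid species found there.
#' @param n_out Interpolation grid size used for fitting and AIC (default
#'   49).
#' @param k_range Candidate cluster counts for the amino-acid clustering.
#' @param depletion_threshold Negligibility threshold, mM.
#' @param fit Named list of overrides passed to [fit_options()].
#' @param noise Named list of overrides passed to [noise_model()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42L, model = c("cybernetic", "mmm"),
                            data_csv = NULL, n_out = 49L, k_range = 2:8,
                            depletion_threshold = 0.01,
                            fit = list(), noise = list()) {
  model <- match.arg(model)
  stopifnot(is.list(fit), is.list(noise))
  bad <- setdiff(names(fit), names(formals(fit_options)))
  if (length(bad)) stop("unknown fit option(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(noise), names(formals(noise_model)))
  if (length(bad)) stop("unknown noise option(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), model = model, data_csv = data_csv,
                 n_out = as.integer(n_out), k_range = k_range,
                 depletion_threshold = depletion_threshold,
                 fit = fit, noise = noise),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the amino-acid depletion experiment, interpolates and
#' pools it, fits both growth models, compares them per species, clusters the
#' per-amino-acid profiles, and writes every artifact plus a machine-readable
#' run manifest to `out_dir`. Fully reproducible from the config alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list; artifacts written: `data.csv`
#'   (tidy input data), `observed.csv` (interpolated pooled series),
#'   `fit_mmm.json`, `fit_cybernetic.json`, `report.csv` (metric x model by
#'   species), `clusters.json`, `manifest.json`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 42, fit = list(restarts = 1,
#'                                              iterations_per_temperature = 5))
#' manifest <- run_pipeline(cfg, tempfile("run"))
#' manifest$winner_by_r
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- lumping_scheme()

  if (is.null(config$data_csv)) {
    gen_params <- switch(config$model,
                         cybernetic = default_cybernetic_params(),
                         mmm = default_mmm_params())
    noise <- do.call(noise_model, config$noise)
    exper <- generate_experiment(gen_params, scheme, noise,
                                 seed = config$seed)
    data <- exper$data
  } else {
    exper <- NULL
    data <- read_tidy_series(config$data_csv)
  }
  write_tidy_series(data, file.path(out_dir, "data.csv"))

  observed <- interpolate_replicates(lump_observed(data, scheme),
                                     n_out = config$n_out)
  write_tidy_series(observed, file.path(out_dir, "observed.csv"))

  fit_opts <- do.call(fit_options,
                      c(list(seed = config$seed), config$fit))
  fits <- list(
    mmm = fit_model(observed, "mmm", fit_opts),
    cybernetic = fit_model(observed, "cybernetic", fit_opts)
  )
  for (m in names(fits))
    jsonlite::write_json(fit_to_list(fits[[m]]),
                         file.path(out_dir, paste0("fit_", m, ".json")),
                         auto_unbox = TRUE, digits = NA)

  report <- compare_models(fits$mmm, fits$cybernetic, observed)
  utils::write.csv(selection_table(report),
                   file.path(out_dir, "report.csv"), row.names = FALSE)

  aa_mat <- aa_profile_matrix(data, names(scheme$group_of))
  clusters <- cluster_profiles(aa_mat$profiles, k_range = config$k_range)
  dep <- depletion_times(aa_mat$times, aa_mat$profiles,
                         threshold = config$depletion_threshold)
  clusters <- order_clusters(clusters, dep)
  jsonlite::write_json(
    list(k = clusters$k,
         labels = as.list(clusters$labels),
         silhouette = as.list(clusters$silhouette),
         depletion_times = as.list(ifelse(is.finite(dep), dep, NA_real_))),
    file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)

  files <- c("data.csv", "observed.csv", "fit_mmm.json",
             "fit_cybernetic.json", "report.csv", "clusters.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("cybgrowth")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config)[c("seed", "model", "n_out",
                               "depletion_threshold")],
    n_species_fit = nrow(report$table),
    winner_by_r = as.list(report$winner_by_r),
    winner_by_aic = as.list(report$winner_by_aic),
    k_clusters = clusters$k,
    file_md5 = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$file_md5) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

fit_to_list <- function(fit) {
  p <- fit$params
  list(model = fit$model,
       params = unclass(p)[setdiff(names(unclass(p)), "n_pools")],
       objective = fit$objective,
       sse = fit$sse,
       n_points = fit$n_points,
       n_params = fit$n_params,
       evaluations = fit$evaluations,
       seed = fit$seed)
}

# replicate-average the tidy AA series onto their common sampling grid and
# pivot to an AA x time matrix
aa_profile_matrix <- function(data, aa_names) {
  aa <- data[data$species_id %in% aa_names, ]
  if (nrow(aa) == 0L) stop("no amino-acid species found")
  avg <- stats::aggregate(value ~ time_h + species_id, aa, mean)
  times <- sort(unique(avg$time_h))
  prof <- t(vapply(split(avg, avg$species_id), function(df)
    df$value[order(df$time_h)], numeric(length(times))))
  list(times = times, profiles = prof)
}

#' Read / write tidy series CSV
#'
#' The shared on-disk schema of the pipeline: columns `time_h`,
#' `species_id`, optional `replicate_id`, `value`.
#'
#' @param path CSV file path.
#' @return `read_tidy_series`: the validated data frame.
#' @export
read_tidy_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "species_id", "value")
  if (!all(need %in% names(df)))
    stop("tidy series CSV must have columns: ", paste(need, collapse = ", "))
  if (!"replicate_id" %in% names(df)) df$replicate_id <- 1L
  df
}

#' @rdname read_tidy_series
#' @param data Tidy data frame to write.
#' @export
write_tidy_series <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
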