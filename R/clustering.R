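#' Normalize depletion profiles to fraction remaining
#'
#' Divides each amino acid's concentration profile by its value at the first
#' time point, putting all profiles on a common fraction-remaining scale
#' before clustering.
#'
#' @param profiles Numeric matrix, one row per amino acid (rownames are the
#'   amino acid labels), one column per time point, concentrations in mM.
#' @return Matrix of the same shape with every row starting at 1.
#' @export
normalize_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  init <- profiles[, 1]
  if (any(init <= 0))
    stop("every profile must have a positive initial concentration")
  sweep(profiles, 1, init, "/")
}

#' Cluster amino-acid depletion profiles into co-utilized groups
#'
#' Average-linkage hierarchical clustering on the Euclidean distance between
#' normalized profiles; the number of clusters is chosen by the maximum mean
#' silhouette width over `k_range`. The method is deterministic, so the
#' number of groups is a genuine property of the data rather than an input.
#'
#' @param profiles Matrix as in [normalize_profiles()] (raw concentrations;
#'   set `normalize = FALSE` if rows are already fractions remaining).
#' @param k_range Candidate cluster counts, a subset of `2:(nrow - 1)`.
#' @param normalize Normalize rows to fraction remaining first (default).
#' @return An `aa_clusters` object: `labels` (named integer vector), `k`,
#'   `silhouette` (named mean silhouette width per candidate k), `hclust`
#'   (the dendrogram), `cluster_order` (identity permutation until
#'   [order_clusters()] is applied).
#' @examples
#' m <- rbind(fast = c(1, 0.2, 0, 0), slow1 = c(1, 0.9, 0.5, 0.1),
#'            slow2 = c(1, 0.85, 0.55, 0.12), slow3 = c(1, 0.95, 0.6, 0.1))
#' cluster_profiles(m, k_range = 2:3, normalize = FALSE)$k
#' @export
cluster_profiles <- function(profiles, k_range = 2:8, normalize = TRUE) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2L) stop("at least 2 amino acids are required")
  if (normalize) profiles <- normalize_profiles(profiles)
  d <- stats::dist(profiles, method = "euclidean")
  if (max(d) == 0) {
    warning("all profiles are identical; returning a single cluster")
    labels <- stats::setNames(rep(1L, n), rownames(profiles))
    return(structure(list(labels = labels, k = 1L,
                          silhouette = stats::setNames(numeric(0), character(0)),
                          hclust = NULL,
                          cluster_order = 1L),
                     class = "aa_clusters"))
  }
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0L) stop("`k_range` must contain values in [2, n-1]")
  hc <- stats::hclust(d, method = "average")
  sil <- vapply(k_range, function(k) {
    labs <- stats::cutree(hc, k = k)
    if (length(unique(labs)) < 2L) return(NA_real_)
    mean(cluster::silhouette(labs, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  k <- k_range[which.max(sil)]
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, k = k, silhouette = sil, hclust = hc,
                 cluster_order = seq_len(k)),
            class = "aa_clusters")
}

#' @export
print.aa_clusters <- function(x, ...) {
  cat(sprintf("amino-acid clustering: k = %d (silhouette-selected)\n", x$k))
  for (g in x$cluster_order) {
    members <- names(x$labels)[x$labels == g]
    cat(sprintf("  cluster %d (%d): %s\n", g, length(members),
                paste(members, collapse = ", ")))
  }
  invisible(x)
}

#' First time each profile drops below a negligibility threshold
#'
#' Linear interpolation between samples locates the first crossing; profiles
#' that never reach the threshold get `Inf`.
#'
#' @param times Numeric vector of sampling times, hours.
#' @param profiles Matrix, one row per amino acid, concentrations in mM.
#' @param threshold Negligibility level, mM (default 0.01).
#' @return Named numeric vector of depletion times, hours.
#' @examples
#' depletion_times(seq(0, 5, 1), rbind(lin = 0.2 * (1 - seq(0, 5, 1) / 5)))
#' @export
depletion_times <- function(times, profiles, threshold = 0.01) {
  if (threshold <= 0) stop("`threshold` must be positive")
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != length(times))
    stop("`profiles` must have one column per time point")
  apply(profiles, 1, function(y) {
    below <- y < threshold
    if (!any(below)) return(Inf)
    i <- which(below)[1]
    if (i == 1L) return(times[1])
    # linear crossing between samples i-1 and i
    t0 <- times[i - 1]; t1 <- times[i]
    y0 <- y[i - 1]; y1 <- y[i]
    t0 + (y0 - threshold) / (y0 - y1) * (t1 - t0)
  })
}

#' Order clusters by mean depletion time
#'
#' Relabels clusters `1..k` so that cluster 1 is depleted first (lowest mean
#' depletion time of its members); ties are broken by cluster size,
#' descending.
#'
#' @param assignment An `aa_clusters` object.
#' @param dep_times Named depletion times from [depletion_times()], covering
#'   every clustered amino acid.
#' @return The assignment with `labels` relabelled in depletion order,
#'   `cluster_order` the permutation applied, and `mean_depletion` per new
#'   label.
#' @export
order_clusters <- function(assignment, dep_times) {
  stopifnot(inherits(assignment, "aa_clusters"))
  if (assignment$k == 1L) return(assignment)
  if (!all(names(assignment$labels) %in% names(dep_times)))
    stop("`dep_times` must cover every clustered amino acid")
  dep <- dep_times[names(assignment$labels)]
  means <- vapply(seq_len(assignment$k), function(g)
    mean(dep[assignment$labels == g]), numeric(1))
  sizes <- tabulate(assignment$labels, assignment$k)
  perm <- order(means, -sizes)  # perm[new] = old
  new_of_old <- order(perm)
  out <- assignment
  out$labels <- stats::setNames(new_of_old[assignment$labels],
                                names(assignment$labels))
  out$cluster_order <- seq_len(assignment$k)
  out$mean_depletion <- means[perm]
  out
}
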