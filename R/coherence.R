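#' Co-expression coherence of a regulon
#'
#' Measures how coherently the genes of a regulon move together over a time
#' course: the mean over unordered gene pairs of the Fisher's-Z-transformed
#' Pearson correlation `atanh(r)` of their `log2(TPM + 1)` profiles across
#' time points. Averaging on the z scale stabilizes the variance and lets
#' tightly co-regulated sets score well above 1 (raw mean correlations are
#' bounded by 1). Correlations are clipped to `|r| <= 1 - 1e-6` so identical
#' profiles score `atanh(1 - 1e-6)` (about 7.25) rather than infinity.
#'
#' @param expr Numeric matrix of expression values (TPM), genes in rows
#'   (rownames are gene ids), time points in columns. Average replicates
#'   first, e.g. with [collapse_replicates()].
#' @param genes Character vector of regulon gene ids (>= 2 present in
#'   `expr`).
#' @param log_transform Apply `log2(x + 1)` first (default; set `FALSE` if
#'   `expr` is already on a log scale).
#' @return Scalar coherence score.
#' @examples
#' expr <- rbind(g1 = c(1, 4, 9, 2, 7), g2 = c(2, 8, 18, 4, 14),
#'               g3 = c(9, 1, 3, 8, 2))
#' coherence_score(expr, c("g1", "g2", "g3"))
#' @export
coherence_score <- function(expr, genes, log_transform = TRUE) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("at least 3 time points are required")
  genes <- unique(genes)
  present <- genes[genes %in% rownames(expr)]
  if (length(present) < 2L)
    stop("fewer than 2 regulon genes are present in the matrix")
  m <- expr[present, , drop = FALSE]
  if (log_transform) m <- log2(m + 1)
  constant <- apply(m, 1, stats::sd) == 0
  if (any(constant)) {
    warning("excluding constant gene(s): ",
            paste(rownames(m)[constant], collapse = ", "))
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < 2L)
    stop("fewer than 2 usable (non-constant) regulon genes")
  r <- stats::cor(t(m))
  z <- atanh(pmin(pmax(r[upper.tri(r)], -1 + 1e-6), 1 - 1e-6))
  mean(z)
}

#' Coherence scores for a set of regulons
#'
#' @inheritParams coherence_score
#' @param regulons Named list of gene-id vectors, one per regulon.
#' @return Data frame with columns `regulon`, `n_genes` (usable genes),
#'   `score`, sorted by descending score; regulons that cannot be scored get
#'   `NA` with the failure reason in `note`.
#' @export
coherence_table <- function(expr, regulons, log_transform = TRUE) {
  stopifnot(is.list(regulons), !is.null(names(regulons)))
  rows <- lapply(names(regulons), function(nm) {
    genes <- regulons[[nm]]
    score <- tryCatch(
      coherence_score(expr, genes, log_transform),
      error = function(e) structure(NA_real_, note = conditionMessage(e))
    )
    data.frame(regulon = nm,
               n_genes = sum(unique(genes) %in% rownames(expr)),
               score = as.numeric(score),
               note = if (is.na(score)) attr(score, "note") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$regulon, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average expression replicates by time point
#'
#' @param expr Genes x samples matrix.
#' @param timepoints Vector, one entry per column of `expr`, labelling the
#'   time point each sample belongs to.
#' @return Genes x time points matrix of per-time-point means, columns in
#'   order of first appearance.
#' @export
collapse_replicates <- function(expr, timepoints) {
  expr <- as.matrix(expr)
  if (ncol(expr) != length(timepoints))
    stop("`timepoints` must label every column of `expr`")
  levels <- unique(timepoints)
  out <- vapply(levels, function(tp)
    rowMeans(expr[, timepoints == tp, drop = FALSE]),
    numeric(nrow(expr)))
  colnames(out) <- as.character(levels)
  out
}
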