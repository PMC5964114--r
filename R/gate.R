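#' Gate reliably expressed genes per condition
#'
#' A gene is reliably expressed in a condition (genotype x timepoint) when
#' the per-sample mixture posterior meets the threshold in *every* sample of
#' that condition. Two modes mirror the two thresholds in use:
#' `strict` requires the posterior probability of the non-expressed
#' component to be below `threshold` (default 0.01) in each sample;
#' `permissive` requires the posterior probability of the expressed
#' component to exceed `threshold` (default 0.1) in each sample.
#'
#' @param fits Named list of `MixtureFit` objects, one per sample in
#'   `sheet$sample`; posteriors must share one gene universe (rownames).
#' @param sheet Sample sheet `data.frame` with a `condition` column (see
#'   [read_sample_sheet()]).
#' @param mode `"strict"` or `"permissive"`.
#' @param threshold Posterior threshold; defaults 0.01 (strict) / 0.1
#'   (permissive).
#' @return A `GateResult`: list with `expressed` (genes x conditions logical
#'   matrix), `expressed_any` (logical vector, the OR over conditions),
#'   `mode` and `threshold`.
#' @export
gate_reliably_expressed <- function(fits, sheet,
                                    mode = c("strict", "permissive"),
                                    threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "strict") 0.01 else 0.1
  missing <- setdiff(sheet$sample, names(fits))
  if (length(missing) > 0L) {
    stop("no mixture fit for sample(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  genes <- rownames(fits[[sheet$sample[1L]]]$posterior)
  if (is.null(genes)) stop("mixture posteriors must carry gene names", call. = FALSE)
  conditions <- unique(sheet$condition)
  pass <- matrix(NA, length(genes), length(conditions),
    dimnames = list(genes, conditions)
  )
  for (cond in conditions) {
    samples <- sheet$sample[sheet$condition == cond]
    if (length(samples) == 0L) stop("condition with zero samples: ", cond, call. = FALSE)
    ok <- rep(TRUE, length(genes))
    for (s in samples) {
      post <- fits[[s]]$posterior[genes, , drop = FALSE]
      ok <- ok & if (mode == "strict") {
        post[, "non_expressed"] < threshold
      } else {
        post[, "expressed"] > threshold
      }
    }
    pass[, cond] <- ok
  }
  structure(
    list(
      expressed = pass,
      expressed_any = apply(pass, 1L, any),
      mode = mode, threshold = threshold
    ),
    class = "GateResult"
  )
}

#' Fit per-sample mixtures and gate in one call
#'
#' Convenience wrapper: applies `log2(count + 1)`, fits one mixture per
#' sample column and gates with [gate_reliably_expressed()].
#'
#' @param counts Integer matrix (genes x samples).
#' @param sheet Sample sheet covering the columns of `counts`.
#' @inheritParams gate_reliably_expressed
#' @return A `GateResult` (with the per-sample fits attached as
#'   attribute `"fits"`).
#' @export
gate_counts <- function(counts, sheet, mode = c("strict", "permissive"),
                        threshold = NULL) {
  mode <- match.arg(mode)
  fits <- lapply(stats::setNames(sheet$sample, sheet$sample), function(s) {
    fit_two_component_mixture(log2(counts[, s] + 1))
  })
  out <- gate_reliably_expressed(fits, sheet, mode = mode, threshold = threshold)
  attr(out, "fits") <- fits
  out
}

#' Quantile normalise the columns of a count matrix
#'
#' Thin wrapper over `limma::normalizeQuantiles` (ties receive the mean of
#' their target quantile values), so every column ends with the identical
#' sorted value vector — the row-wise mean of the sorted columns.
#'
#' @param mat Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape, columns quantile normalised.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2L) stop("need >= 2 columns to quantile normalise", call. = FALSE)
  out <- limma::normalizeQuantiles(as.matrix(mat), ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Cluster samples by Spearman-correlation distance
#'
#' Distance between samples is 1 - Spearman rank correlation, so clustering
#' is invariant to monotone per-sample transforms; linkage is complete.
#' Samples are processed in lexicographic id order, which fixes the leaf
#' order deterministically.
#'
#' @param mat Numeric matrix (genes x samples), typically quantile-normalised
#'   expression restricted to gated genes.
#' @param gate Optional `GateResult`; rows are restricted to
#'   `expressed_any` genes.
#' @param k Optional number of flat clusters to cut.
#' @return List with `hclust` (the dendrogram), `dist` and, when `k` is
#'   given, `labels` (named cluster assignment).
#' @export
cluster_samples <- function(mat, gate = NULL, k = NULL) {
  if (!is.null(gate)) {
    keep <- names(gate$expressed_any)[gate$expressed_any]
    mat <- mat[intersect(rownames(mat), keep), , drop = FALSE]
  }
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(
      "constant sample vector(s): ",
      paste(colnames(mat)[sds == 0], collapse = ", "),
      "; Spearman correlation undefined",
      call. = FALSE
    )
  }
  d <- stats::as.dist(1 - stats::cor(mat, method = "spearman"))
  hc <- stats::hclust(d, method = "complete")
  out <- list(hclust = hc, dist = d)
  if (!is.null(k)) out$labels <- stats::cutree(hc, k = k)
  out
}
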