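#' Decompose an expression matrix into transcriptional programmes by SVD
#'
#' Takes a (typically log2 quantile-normalised, gated) genes x samples
#' matrix, optionally centres each gene, and computes the exact singular
#' value decomposition. The right singular vectors are the programme
#' profiles over samples; the variance fraction of component k is
#' d_k^2 / sum(d_i^2). Each right singular vector's sign is fixed by making
#' its largest-magnitude entry positive (SVD signs are otherwise arbitrary).
#'
#' @param mat Numeric genes x samples matrix, no missing values, >= 2
#'   samples.
#' @param center Centre each gene (row) before decomposition (default TRUE).
#'   A constant row becomes all-zero; the count of such rows is logged.
#' @param scale Also z-score each gene row (default FALSE; rows with zero
#'   variance are left on the centred scale).
#' @return A `ProgrammeDecomposition`: list with `u` (gene-space vectors),
#'   `d` (singular values, non-increasing), `v` (sample-space programme
#'   profiles), `var_frac`, and `x` (the matrix actually decomposed).
#' @export
decompose_programmes <- function(mat, center = TRUE, scale = FALSE) {
  if (anyNA(mat)) stop("expression matrix has missing values", call. = FALSE)
  if (ncol(mat) < 2L) stop("need >= 2 samples", call. = FALSE)
  x <- as.matrix(mat)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  if (center) {
    n_const <- sum(apply(x, 1L, function(r) max(r) == min(r)))
    if (n_const > 0L) irpaq_log(n_const, " constant row(s) become zero after centering")
    x <- x - rowMeans(x)
  }
  if (scale) {
    sds <- sqrt(rowMeans((x - rowMeans(x))^2))
    sds[sds == 0] <- 1
    x <- (x - rowMeans(x)) / sds
  }
  sv <- svd(x)
  # sign convention: largest-magnitude entry of each right vector positive
  for (k in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, k]))
    if (sv$v[i, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  rownames(sv$u) <- rownames(x)
  rownames(sv$v) <- colnames(x)
  structure(
    list(
      u = sv$u, d = sv$d, v = sv$v,
      var_frac = sv$d^2 / sum(sv$d^2),
      x = x
    ),
    class = "ProgrammeDecomposition"
  )
}

#' @export
print.ProgrammeDecomposition <- function(x, ...) {
  cat(
    "ProgrammeDecomposition:", nrow(x$u), "genes x", nrow(x$v), "samples;",
    "top variance fractions:",
    paste(sprintf("%.1f%%", 100 * utils::head(x$var_frac, 3L)), collapse = ", "),
    "\n"
  )
  invisible(x)
}

#' Score genes against a programme and select associated gene sets
#'
#' Each gene profile is scored against the k-th right singular vector by
#' Pearson correlation and by projection (inner product). Both scores are
#' standardised across genes and clustered with seeded K-means
#' (`n_clusters`, default 5: positive / weakly positive / neutral / weakly
#' negative / negative); the cluster
#' with the highest mean standardised (correlation + projection) is the
#' positively associated set, the lowest the negatively associated set.
#' Genes with constant profiles (correlation undefined) are excluded from
#' selection, with a logged count.
#'
#' @param dec A `ProgrammeDecomposition`.
#' @param component Programme index k (<= number of components).
#' @param n_clusters K-means cluster count (default 5).
#' @return A `ProgrammeGeneSets`: list with `scores` (`data.frame` of gene,
#'   correlation, projection), `positive` and `negative` (disjoint character
#'   vectors of gene ids), and `excluded` (count of constant-profile genes).
#' @export
score_and_select_programme_genes <- function(dec, component = 1L, n_clusters = 5L) {
  stopifnot(inherits(dec, "ProgrammeDecomposition"))
  if (component > length(dec$d)) {
    stop("component ", component, " exceeds the ", length(dec$d), " available",
      call. = FALSE
    )
  }
  vk <- dec$v[, component]
  x <- dec$x
  proj <- drop(x %*% vk)
  sds <- apply(x, 1L, stats::sd)
  ok <- sds > 0
  if (sum(!ok) > 0L) {
    irpaq_log(sum(!ok), " constant-profile gene(s) excluded from programme scoring")
  }
  corr <- rep(NA_real_, nrow(x))
  corr[ok] <- drop(stats::cor(t(x[ok, , drop = FALSE]), vk))
  genes <- rownames(x)
  scores <- data.frame(
    gene = genes, correlation = corr, projection = proj,
    stringsAsFactors = FALSE
  )
  usable <- which(ok)
  if (length(usable) < n_clusters) {
    stop("fewer scorable genes (", length(usable), ") than clusters", call. = FALSE)
  }
  z <- cbind(scale(corr[usable]), scale(proj[usable]))
  km <- with_seed(
    child_seed(2711, component),
    stats::kmeans(z, centers = n_clusters, nstart = 10L, iter.max = 100L)
  )
  mean_score <- tapply(rowSums(z), km$cluster, mean)
  pos_cl <- as.integer(names(which.max(mean_score)))
  neg_cl <- as.integer(names(which.min(mean_score)))
  structure(
    list(
      scores = scores,
      positive = genes[usable][km$cluster == pos_cl],
      negative = genes[usable][km$cluster == neg_cl],
      excluded = sum(!ok),
      component = component
    ),
    class = "ProgrammeGeneSets"
  )
}
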