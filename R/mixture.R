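#' Fit a two-component Gaussian mixture to log2 counts
#'
#' Models the characteristically bimodal histogram of per-sample log2 gene
#' counts as a mixture of a low-mean "non-expressed" and a high-mean
#' "expressed" Gaussian component, fitted by EM with free variances. The fit
#' is initialised by k-means on the sorted values; the best of five seeded
#' restarts is returned, so the result is deterministic and invariant to the
#' order of the input values.
#'
#' @param x Numeric vector of log2(count + 1) values for one sample
#'   (pseudocount already applied); length >= 100. Names, if present, are
#'   carried to the posterior rows.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param restarts Number of seeded k-means restarts (default 5).
#' @param sd_floor Lower bound on component standard deviations
#'   (default 0.5 log2 units). Low counts are discrete, so an unconstrained
#'   component collapses onto the point mass at log2(0 + 1) = 0 with
#'   unbounded likelihood, turning the gate into a "count >= 1" rule; the
#'   floor forces the low component to describe a mode of low counts
#'   rather than the exact-zero atom. It is far below the width of any
#'   genuine expression mode and does not bind on continuous data. Set to
#'   0 to disable, in which case a collapsing fit is retried and, if all
#'   restarts collapse, an error is raised.
#' @return A `MixtureFit`: list with `means`, `sds`, `weights` (component 1
#'   is the smaller-mean, non-expressed component), `loglik`, `posterior`
#'   (n x 2 matrix, columns `non_expressed` and `expressed`, rows summing to
#'   1), `converged` and `iterations`.
#' @export
fit_two_component_mixture <- function(x, max_iter = 500L, tol = 1e-8,
                                      restarts = 5L, sd_floor = 0.5) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (anyNA(x)) stop("'x' has missing values", call. = FALSE)
  if (length(x) < 100L) {
    stop("need >= 100 values to fit the mixture (got ", length(x), ")",
      call. = FALSE
    )
  }
  if (length(unique(x)) < 2L) {
    stop("mixture fit degenerate: fewer than 2 distinct values", call. = FALSE)
  }
  xs <- sort(unname(x))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(child_seed(1903, r), mixture_init(xs, jitter = r > 1L))
    fit <- tryCatch(
      em_two_gaussians(xs, init, max_iter = max_iter, tol = tol, sd_floor = sd_floor),
      degenerate = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) {
    stop("mixture fit degenerate in all restarts (component sd < 1e-6)",
      call. = FALSE
    )
  }
  # order components by mean: 1 = non-expressed, 2 = expressed
  ord <- order(best$means)
  post <- posterior_two_gaussians(x, best$means[ord], best$sds[ord], best$weights[ord])
  colnames(post) <- c("non_expressed", "expressed")
  rownames(post) <- names(x)
  structure(
    list(
      means = best$means[ord], sds = best$sds[ord], weights = best$weights[ord],
      loglik = best$loglik, posterior = post,
      converged = best$converged, iterations = best$iterations
    ),
    class = "MixtureFit"
  )
}

mixture_init <- function(xs, jitter = FALSE) {
  x0 <- if (jitter) xs + stats::rnorm(length(xs), 0, stats::sd(xs) / 20) else xs
  km <- stats::kmeans(x0, centers = 2L, nstart = 1L)
  mu <- as.numeric(km$centers)
  sds <- weights <- numeric(2L)
  for (k in 1:2) {
    xi <- xs[km$cluster == k]
    sds[k] <- if (length(xi) > 1L) stats::sd(xi) else stats::sd(xs) / 4
    weights[k] <- length(xi) / length(xs)
  }
  sds[sds < 1e-3 | is.na(sds)] <- stats::sd(xs) / 4
  list(means = mu, sds = sds, weights = weights)
}

em_two_gaussians <- function(x, init, max_iter, tol, sd_floor = 0) {
  mu <- init$means
  sds <- init$sds
  w <- init$weights
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    la <- log(w[1]) + stats::dnorm(x, mu[1], sds[1], log = TRUE)
    lb <- log(w[2]) + stats::dnorm(x, mu[2], sds[2], log = TRUE)
    m <- pmax(la, lb)
    lse <- m + log(exp(la - m) + exp(lb - m))
    ll <- sum(lse)
    r1 <- exp(la - lse)
    r2 <- 1 - r1
    n1 <- sum(r1)
    n2 <- sum(r2)
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sds <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1, sum(r2 * (x - mu[2])^2) / n2))
    sds <- pmax(sds, sd_floor)
    w <- c(n1, n2) / length(x)
    if (any(sds < 1e-6) || anyNA(sds)) {
      cond <- simpleCondition("degenerate component sd")
      class(cond) <- c("degenerate", "condition")
      stop(cond)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(means = mu, sds = sds, weights = w, loglik = ll, converged = converged, iterations = it)
}

posterior_two_gaussians <- function(x, mu, sds, w) {
  la <- log(w[1]) + stats::dnorm(x, mu[1], sds[1], log = TRUE)
  lb <- log(w[2]) + stats::dnorm(x, mu[2], sds[2], log = TRUE)
  m <- pmax(la, lb)
  lse <- m + log(exp(la - m) + exp(lb - m))
  cbind(exp(la - lse), exp(lb - lse))
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf(
    "MixtureFit: non-expressed N(%.3f, %.3f^2) w=%.3f | expressed N(%.3f, %.3f^2) w=%.3f | logLik %.2f (%s, %d iter)\n",
    x$means[1], x$sds[1], x$weights[1],
    x$means[2], x$sds[2], x$weights[2],
    x$loglik, if (x$converged) "converged" else "max iter", x$iterations
  ))
  invisible(x)
}
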