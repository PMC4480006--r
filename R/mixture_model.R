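# Two-component Gaussian mixture on log10 expression; HE/LE classification.
#
# Bulk RNA-seq log-expression from tissues is bimodal: a low-expressed (LE)
# component enriched in transcriptional noise and a high-expressed (HE)
# component carrying the functional transcriptome. The mixture is fitted by
# expectation-maximization and genes are called HE when their posterior
# probability of HE membership reaches a threshold (default 0.25).

#' Select the mixture fit set
#'
#' Genes with at least one fragment count in at least one replicate, mapped
#' to log10 of their replicate-mean FPKM.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param expr the matching \code{\link{expression_matrix}}.
#' @return List with \code{gene_ids} and \code{log_expr} (log10 mean FPKM).
#' @export
select_fit_set <- function(counts, expr) {
  stopifnot(inherits(counts, "count_matrix"), inherits(expr, "expression_matrix"))
  if (!identical(counts$gene_ids, expr$gene_ids)) {
    stop("count and expression matrices must share gene ids in the same order")
  }
  keep <- rowSums(counts$counts) >= 1L
  if (!any(keep)) stop("no expressed genes: every gene has zero counts")
  list(gene_ids = counts$gene_ids[keep],
       log_expr = log10(expr$mean_fpkm[keep]))
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Univariate two-component Gaussian mixture fitted by
#' expectation-maximization. Initialization is deterministic: the sample is
#' split at its median and component moments are taken from each half.
#' Components are ordered so that the HE component has the larger mean.
#' Convergence is declared when the relative change in log-likelihood falls
#' below \code{tol}. A variance floor (sd >= 1e-6) guards against
#' degenerate spikes.
#'
#' @param values numeric vector of log-expression values (>= 10 finite
#'   values with nonzero variance).
#' @param seed integer recorded in the fit (the fit itself is deterministic
#'   given the data).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return Object of class \code{mixture_fit}: weights (lambda_LE,
#'   lambda_HE), means, sds, per-gene posterior probability of HE
#'   membership, log-likelihood trace, convergence flag and iteration
#'   count.
#' @export
fit_em <- function(values, seed = 1L, tol = 1e-8, max_iter = 1000L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 10L) stop("mixture fit needs at least 10 finite values")
  if (stats::sd(values) == 0) stop("zero-variance input: mixture is undefined")

  # deterministic median-split initialization
  med <- stats::median(values)
  lo <- values[values <= med]; hi <- values[values > med]
  if (length(hi) == 0L) { lo <- values[values < med]; hi <- values[values >= med] }
  mu <- c(mean(lo), mean(hi))
  sigma <- pmax(c(stats::sd(lo), stats::sd(hi)), 1e-6)
  sigma[is.na(sigma)] <- stats::sd(values)
  lambda <- c(length(lo), length(hi)) / n

  loglik <- function(lambda, mu, sigma) {
    sum(log(lambda[1L] * stats::dnorm(values, mu[1L], sigma[1L]) +
            lambda[2L] * stats::dnorm(values, mu[2L], sigma[2L])))
  }
  ll <- loglik(lambda, mu, sigma)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step: responsibilities of component 2
    d1 <- lambda[1L] * stats::dnorm(values, mu[1L], sigma[1L])
    d2 <- lambda[2L] * stats::dnorm(values, mu[2L], sigma[2L])
    gam <- d2 / (d1 + d2)
    # M step
    w2 <- sum(gam); w1 <- n - w2
    lambda <- c(w1, w2) / n
    mu <- c(sum((1 - gam) * values) / w1, sum(gam * values) / w2)
    sigma <- c(sqrt(sum((1 - gam) * (values - mu[1L])^2) / w1),
               sqrt(sum(gam * (values - mu[2L])^2) / w2))
    sigma <- pmax(sigma, 1e-6)
    ll_new <- loglik(lambda, mu, sigma)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")

  # order components so HE has the larger mean
  ord <- order(mu)
  d_le <- lambda[ord[1L]] * stats::dnorm(values, mu[ord[1L]], sigma[ord[1L]])
  d_he <- lambda[ord[2L]] * stats::dnorm(values, mu[ord[2L]], sigma[ord[2L]])
  posterior_he <- d_he / (d_le + d_he)

  structure(list(
    weights = c(LE = lambda[ord[1L]], HE = lambda[ord[2L]]),
    means   = c(LE = mu[ord[1L]], HE = mu[ord[2L]]),
    sds     = c(LE = sigma[ord[1L]], HE = sigma[ord[2L]]),
    posteriors = posterior_he,
    loglik_trace = trace,
    converged = converged,
    n_iter = iter,
    seed = as.integer(seed)
  ), class = "mixture_fit")
}

#' Classify genes as high- or low-expressed
#'
#' A gene is called HE when its posterior probability of belonging to the
#' high-expressed mixture component is at least \code{threshold}
#' (inclusive).
#'
#' @param fit a \code{mixture_fit} from \code{\link{fit_em}}.
#' @param threshold posterior probability cutoff in [0, 1]; default 0.25.
#' @return Character vector of "HE"/"LE" calls, one per fitted value.
#' @export
classify_he <- function(fit, threshold = 0.25) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a probability in [0, 1]")
  }
  ifelse(fit$posteriors >= threshold, "HE", "LE")
}

#' Cumulative expression share of the top-k genes
#'
#' Percentage of the total replicate-mean FPKM held by the k most abundant
#' genes. Ties in mean FPKM are broken by gene id for determinism.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param k number of top genes.
#' @return Percentage in [0, 100].
#' @export
cumulative_share <- function(expr, k) {
  stopifnot(inherits(expr, "expression_matrix"))
  m <- expr$mean_fpkm
  if (k > length(m)) stop("k exceeds the number of genes")
  tot <- sum(m)
  if (tot == 0) stop("total expression is zero")
  ord <- order(-m, expr$gene_ids)
  100 * sum(m[ord[seq_len(k)]]) / tot
}
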