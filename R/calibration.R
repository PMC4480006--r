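# RNA abundance vs ISH neuron counts: Spearman test and log-log calibration.
#
# Under the one-receptor-one-neuron rule a receptor's tissue FPKM should
# scale with the number of sensory neurons expressing it. The correlation
# is assessed with a Spearman test whose p-value is exact (full rank
# permutation enumeration) for small tie-free samples, and a power-law
# calibration is fitted on log10-log10 scale.

# All permutations of 1..n as an n! x n matrix, built recursively and
# cached per n (repeated exact tests share the table).
# n <= 10 is practical (10! rows); callers cap n well below that.
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- build_permutations(n)
  if (n <= 9L) .perm_cache[[key]] <- out
  out
}

build_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- build_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with exact small-sample significance
#'
#' Ranks use the average-rank convention for ties. For tie-free samples
#' with n <= \code{exact_limit} the two-sided p-value is exact: all n!
#' rank permutations are enumerated and p is the fraction with |rho| at
#' least as large as observed. Otherwise the t-approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) with df = n-2 is used (ties always
#' force the approximation, with a warning, because the permutation null
#' is not exchangeable-equivalent under average ranks).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param exact_limit largest n for which the exact enumeration is used
#'   (default 9; 9! = 362880 permutations).
#' @return Object of class \code{correlation_result}: \code{rho},
#'   \code{n}, \code{sum_d2} (tie-free only), \code{p_two_sided},
#'   \code{method} ("exact_permutation" or "t_approximation"),
#'   \code{t_statistic} and \code{df} (approximation only).
#' @export
spearman_test <- function(x, y, exact_limit = 9L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("Spearman test needs n >= 3")
  rx <- rank(x); ry <- rank(y)
  ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  rho <- stats::cor(rx, ry)
  sum_d2 <- if (!ties) as.integer(sum((rx - ry)^2)) else NA_integer_

  if (!ties && n <= exact_limit) {
    perms <- all_permutations(n)
    # rho for every permutation of y-ranks against the observed x-ranks;
    # by symmetry we can fix x at 1..n
    d2 <- rowSums((perms - matrix(seq_len(n), nrow(perms), n, byrow = TRUE))^2)
    rho_all <- 1 - 6 * d2 / (n * (n^2 - 1))
    p <- sum(abs(rho_all) >= abs(rho) - 1e-12) / factorial(n)
    return(structure(list(
      rho = rho, n = n, sum_d2 = sum_d2, p_two_sided = p,
      method = "exact_permutation", t_statistic = NA_real_, df = NA_integer_
    ), class = "correlation_result"))
  }

  if (ties) warning("ties present: using the t-approximation for the Spearman p-value")
  df <- n - 2L
  if (abs(rho) >= 1) {
    t_stat <- sign(rho) * Inf
    p <- 0
  } else {
    t_stat <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(
    rho = rho, n = n, sum_d2 = sum_d2, p_two_sided = p,
    method = "t_approximation", t_statistic = t_stat, df = df
  ), class = "correlation_result")
}

#' Fit a log-log calibration of neuron counts on RNA abundance
#'
#' Ordinary least squares of log10(cells/section) on log10(FPKM). Both
#' quantities span orders of magnitude, so the line models a power law
#' cells = 10^intercept * FPKM^slope.
#'
#' @param fpkm_values mean FPKM per receptor (> 0).
#' @param cells_per_section mean labeled cells per section per receptor
#'   (> 0); at least 3 pairs.
#' @return Object of class \code{calibration_model}: \code{slope},
#'   \code{intercept}, \code{residual_sd}, \code{fitted_pairs}.
#' @export
fit_calibration <- function(fpkm_values, cells_per_section) {
  if (length(fpkm_values) != length(cells_per_section)) stop("input lengths differ")
  if (length(fpkm_values) < 3L) stop("calibration needs at least 3 pairs")
  if (any(fpkm_values <= 0) || any(cells_per_section <= 0)) {
    stop("calibration requires positive FPKM and cell counts (log scale)")
  }
  lx <- log10(fpkm_values); ly <- log10(cells_per_section)
  fit <- stats::lm(ly ~ lx)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    residual_sd = stats::sigma(fit),
    fitted_pairs = data.frame(fpkm = fpkm_values, cells = cells_per_section)
  ), class = "calibration_model")
}

#' Predict labeled cells per section from FPKM
#'
#' @param model a \code{calibration_model}.
#' @param fpkm_value positive FPKM value(s).
#' @return Predicted cells/section on the original scale.
#' @export
predict_cells <- function(model, fpkm_value) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(fpkm_value <= 0)) stop("fpkm must be positive")
  10^(model$intercept + model$slope * log10(fpkm_value))
}

#' Lower-bound estimate of total labeled cells in the organ
#'
#' Mean labeled cells per section times the number of sections, floored to
#' an integer: a lower bound because sections sample the organ without
#' stereological correction.
#'
#' @param mean_per_section mean labeled cells per section (>= 0).
#' @param n_sections number of sections (>= 0).
#' @return Integer lower bound on total cells.
#' @export
estimate_total_cells <- function(mean_per_section, n_sections) {
  if (mean_per_section < 0 || n_sections < 0) stop("inputs must be non-negative")
  as.integer(floor(mean_per_section * n_sections))
}
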