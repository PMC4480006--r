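# Chemoreceptor family repertoire statistics.
#
# Under the one-receptor-one-neuron rule, the cumulative FPKM of a receptor
# family is a proxy for the share of sensory neurons expressing its members.
# Family profiles contrast each family's share of the gene repertoire with
# its share of cumulative expression; chi-squared tests compare observed
# expression with an equal-expression-per-gene null.

# Round half away from zero (presentation convention for reported shares).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Family-level summary from per-family totals
#'
#' Computes repertoire shares, expression shares and per-gene average
#' expression from per-family gene counts and cumulative FPKM totals.
#' This is the arithmetic core of \code{\link{family_profiles}}, exposed so
#' published family totals can be summarized directly.
#'
#' @param n_genes named integer vector of genes per family.
#' @param cumulative_fpkm named numeric vector of cumulative (summed) FPKM
#'   per family, in the same order.
#' @param sem_fpkm optional per-family SEM of the cumulative FPKM.
#' @return data frame with one row per family: \code{n_genes},
#'   \code{cumulative_fpkm}, \code{sem_fpkm}, \code{repertoire_share_pct},
#'   \code{expression_share_pct} (both half-up rounded to 1 decimal) and
#'   \code{per_gene_avg_fpkm}.
#' @export
family_summary <- function(n_genes, cumulative_fpkm, sem_fpkm = NA_real_) {
  stopifnot(length(n_genes) == length(cumulative_fpkm))
  if (sum(cumulative_fpkm) <= 0) stop("total cumulative FPKM must be positive")
  data.frame(
    family = if (!is.null(names(n_genes))) names(n_genes)
             else if (!is.null(names(cumulative_fpkm))) names(cumulative_fpkm)
             else paste0("family", seq_along(n_genes)),
    n_genes = as.integer(n_genes),
    cumulative_fpkm = as.numeric(cumulative_fpkm),
    sem_fpkm = as.numeric(sem_fpkm),
    repertoire_share_pct = round_half_up(100 * n_genes / sum(n_genes), 1L),
    expression_share_pct = round_half_up(100 * cumulative_fpkm / sum(cumulative_fpkm), 1L),
    per_gene_avg_fpkm = as.numeric(cumulative_fpkm) / as.numeric(n_genes),
    row.names = NULL
  )
}

#' Chemoreceptor family expression profiles
#'
#' Cumulative FPKM per family is computed per replicate, then summarized as
#' mean and SEM across replicates; shares are percentages of the
#' four-family totals.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param annotation a \code{\link{gene_annotation}}; genes with family
#'   "none" are ignored.
#' @return data frame as in \code{\link{family_summary}}, one row per
#'   family with at least one annotated gene (empty families are dropped
#'   with a warning).
#' @export
family_profiles <- function(expr, annotation) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(annotation, "gene_annotation"))
  fam <- annotation$family[match(expr$gene_ids, annotation$gene_id)]
  present <- CHEMORECEPTOR_FAMILIES[CHEMORECEPTOR_FAMILIES %in% fam]
  dropped <- setdiff(CHEMORECEPTOR_FAMILIES, present)
  if (length(dropped)) {
    warning("families with no genes excluded: ", paste(dropped, collapse = ", "))
  }
  if (length(present) == 0L) stop("no chemoreceptor genes in the annotation")
  n_reps <- ncol(expr$fpkm)
  cum_by_rep <- vapply(present, function(f) {
    colSums(expr$fpkm[fam == f, , drop = FALSE])
  }, numeric(n_reps))
  if (n_reps == 1L) cum_by_rep <- matrix(cum_by_rep, nrow = 1L, dimnames = list(NULL, present))
  means <- colMeans(cum_by_rep)
  sems <- if (n_reps >= 2L) apply(cum_by_rep, 2L, stats::sd) / sqrt(n_reps) else rep(NA_real_, length(present))
  n_genes <- vapply(present, function(f) sum(fam == f, na.rm = TRUE), integer(1))
  family_summary(n_genes, means, sems)
}

#' Chi-squared test against equal expression per gene, across families
#'
#' Null model: every receptor gene is expressed at the same level, so a
#' family's expected cumulative FPKM is proportional to its gene count.
#' Pearson chi-squared with df = n_families - 1; FPKM values are treated
#' directly as the observed quantities, so the statistic (and hence the
#' p-value) scales with the overall FPKM magnitude — the statistic and df
#' are always reported alongside p.
#'
#' @param observed per-family cumulative FPKM (replicate means).
#' @param gene_counts per-family gene counts.
#' @return Object of class \code{family_test}: \code{chi2_statistic},
#'   \code{df}, \code{p_value}, \code{observed}, \code{expected}.
#' @export
equal_expression_chi2 <- function(observed, gene_counts) {
  if (length(observed) < 2L) stop("need at least 2 families")
  if (length(observed) != length(gene_counts)) stop("observed and gene_counts lengths differ")
  tot <- sum(observed)
  if (tot <= 0) stop("total observed expression is zero")
  expected <- tot * gene_counts / sum(gene_counts)
  if (any(expected <= 0)) stop("expected values must be positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(
    chi2_statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    observed = observed, expected = expected
  ), class = "family_test")
}

#' Chi-squared test against equal expression within one family
#'
#' Expected value for every gene is the family total divided by the number
#' of genes; Pearson chi-squared with df = n_genes - 1.
#'
#' @param observed per-gene FPKM values within one family.
#' @return A \code{family_test} object as in
#'   \code{\link{equal_expression_chi2}}.
#' @export
per_gene_chi2 <- function(observed) {
  if (length(observed) < 2L) stop("need at least 2 genes")
  tot <- sum(observed)
  if (tot <= 0) stop("family total expression is zero")
  expected <- rep(tot / length(observed), length(observed))
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(
    chi2_statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    observed = observed, expected = expected
  ), class = "family_test")
}

#' Ratio of per-gene average expression between two families
#'
#' @param profiles a family profile data frame from
#'   \code{\link{family_profiles}} or \code{\link{family_summary}}.
#' @param family_a,family_b family labels; the ratio is a over b.
#' @return Scalar ratio of per-gene average FPKM.
#' @export
family_ratio <- function(profiles, family_a, family_b) {
  a <- profiles$per_gene_avg_fpkm[profiles$family == family_a]
  b <- profiles$per_gene_avg_fpkm[profiles$family == family_b]
  if (length(a) != 1L || length(b) != 1L) stop("families not found in profiles")
  if (b == 0) stop("zero denominator: family ", family_b, " has no expression")
  a / b
}
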