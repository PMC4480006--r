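# Fragment counts -> FPKM and replicate summaries.

#' Transform fragment counts to FPKM
#'
#' Fragments per kilobase of transcript per million fragments:
#' \deqn{FPKM_{g,r} = \frac{C_{g,r} \times 10^9}{L_g \times N_r}}
#' where \eqn{C_{g,r}} is the fragment count of gene g in replicate r,
#' \eqn{L_g} the gene length in bp and \eqn{N_r} the replicate's total
#' gene-assigned fragment count (the column sum of the input matrix).
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param annotation a \code{\link{gene_annotation}} covering every gene in
#'   \code{counts}.
#' @return An \code{\link{expression_matrix}} with per-gene replicate means
#'   and SEMs.
#' @export
fpkm <- function(counts, annotation) {
  stopifnot(inherits(counts, "count_matrix"), inherits(annotation, "gene_annotation"))
  missing_ids <- setdiff(counts$gene_ids, annotation$gene_id)
  if (length(missing_ids)) {
    stop("genes without annotation: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "),
         if (length(missing_ids) > 5L) sprintf(" (and %d more)", length(missing_ids) - 5L))
  }
  if (any(counts$total_counted == 0)) {
    stop("replicate with zero total counts: ",
         counts$replicate_ids[counts$total_counted == 0][1L])
  }
  len <- annotation$length_bp[match(counts$gene_ids, annotation$gene_id)]
  f <- counts$counts * 1e9 / (len %o% counts$total_counted)
  dimnames(f) <- dimnames(counts$counts)
  expression_matrix(f)
}

#' Pairwise replicate concordance
#'
#' Spearman rank correlation between every pair of replicate FPKM vectors,
#' used to verify the low technical variability the pipeline assumes.
#'
#' @param expr an \code{\link{expression_matrix}} with at least two
#'   replicates.
#' @return Symmetric matrix of Spearman correlation coefficients.
#' @export
replicate_concordance <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$fpkm) < 2L) stop("replicate concordance needs at least 2 replicates")
  stats::cor(expr$fpkm, method = "spearman")
}
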