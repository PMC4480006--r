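# Cross-species ortholog expression comparison.
#
# One-to-one ortholog pairs passing identity and expression filters are
# assembled into a pairs x samples matrix spanning both species' tissue
# replicates, log-transformed and row-standardized, then compared by
# correlation-matrix PCA and Ward hierarchical clustering with bootstrap
# node support.

#' Filter ortholog pairs and assemble their expression matrix
#'
#' Retains pairs that are (i) one-to-one orthologs, (ii) have amino-acid
#' identity >= \code{min_identity} (inclusive), and (iii) are expressed
#' (FPKM > \code{min_fpkm_expressed}) in at least \code{min_replicates} of
#' the pooled replicate columns across both species' matrices. Output row
#' order is sorted by (gene_a, gene_b) so it does not depend on table row
#' order.
#'
#' @param table an \code{\link{ortholog_table}}.
#' @param expr_a,expr_b \code{\link{expression_matrix}} objects for species
#'   A (genes of \code{gene_a}) and species B; column names should carry
#'   tissue and replicate labels.
#' @param min_identity minimum percent amino-acid identity (default 40).
#' @param min_replicates minimum number of replicate columns with
#'   expression (default 2).
#' @param min_fpkm_expressed exclusive FPKM threshold defining "expressed"
#'   (default 0).
#' @return Object of class \code{ortholog_expression}: \code{pair_ids},
#'   \code{samples}, \code{values} (FPKM; rows pairs, columns the pooled
#'   samples of both species), \code{standardized = FALSE}.
#' @export
filter_orthologs <- function(table, expr_a, expr_b, min_identity = 40,
                             min_replicates = 2L, min_fpkm_expressed = 0) {
  stopifnot(inherits(table, "ortholog_table"),
            inherits(expr_a, "expression_matrix"),
            inherits(expr_b, "expression_matrix"))
  keep <- table$orthology_type == "one2one" & table$identity_pct >= min_identity
  tab <- table[keep & table$gene_a %in% expr_a$gene_ids &
                 table$gene_b %in% expr_b$gene_ids, , drop = FALSE]
  if (nrow(tab) == 0L) {
    warning("no ortholog pairs pass the filters")
    return(structure(list(
      pair_ids = character(0),
      samples = c(colnames(expr_a$fpkm), colnames(expr_b$fpkm)),
      values = matrix(numeric(0), 0L, ncol(expr_a$fpkm) + ncol(expr_b$fpkm)),
      standardized = FALSE), class = "ortholog_expression"))
  }
  va <- expr_a$fpkm[tab$gene_a, , drop = FALSE]
  vb <- expr_b$fpkm[tab$gene_b, , drop = FALSE]
  vals <- cbind(va, vb)
  expressed <- rowSums(vals > min_fpkm_expressed) >= min_replicates
  tab <- tab[expressed, , drop = FALSE]
  vals <- vals[expressed, , drop = FALSE]
  ord <- order(tab$gene_a, tab$gene_b)
  tab <- tab[ord, , drop = FALSE]
  vals <- vals[ord, , drop = FALSE]
  pair_ids <- paste(tab$gene_a, tab$gene_b, sep = "|")
  rownames(vals) <- pair_ids
  if (nrow(vals) == 0L) warning("no ortholog pairs pass the expression filter")
  structure(list(
    pair_ids = pair_ids,
    samples = colnames(vals),
    values = vals,
    standardized = FALSE
  ), class = "ortholog_expression")
}

#' Log-transform and row-standardize an ortholog expression matrix
#'
#' Applies log10(FPKM + 1), then z-scores every pair's row across samples
#' (mean 0, unit variance with the n-1 denominator). Zero-variance rows
#' are dropped with a warning.
#'
#' @param mat an \code{ortholog_expression} from
#'   \code{\link{filter_orthologs}}.
#' @return The matrix with \code{standardized = TRUE}.
#' @export
standardize_orthologs <- function(mat) {
  stopifnot(inherits(mat, "ortholog_expression"))
  if (ncol(mat$values) < 2L) stop("standardization needs at least 2 samples")
  lv <- log10(mat$values + 1)
  sds <- apply(lv, 1L, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning(sum(drop), " zero-variance row(s) dropped before standardization")
    lv <- lv[!drop, , drop = FALSE]
  }
  z <- t(scale(t(lv)))
  mat$values <- z
  mat$pair_ids <- rownames(z)
  mat$standardized <- TRUE
  mat
}

#' PCA on the inter-sample correlation matrix
#'
#' Eigen-decomposition of the correlation matrix among samples (samples as
#' variables, ortholog pairs as observations). Loadings are sign-fixed so
#' that each component's largest-magnitude loading is positive; sample
#' scores are the loadings scaled by the square root of their eigenvalue
#' (correlation-matrix convention).
#'
#' @param mat a standardized \code{ortholog_expression}.
#' @return Object of class \code{pca_result}: \code{eigenvalues}
#'   (descending), \code{variance_explained_pct}, \code{loadings}
#'   (samples x components), \code{sample_scores}, \code{gene_scores}
#'   (pair projections).
#' @export
ortho_pca <- function(mat) {
  stopifnot(inherits(mat, "ortholog_expression"))
  if (ncol(mat$values) < 2L) stop("PCA needs at least 2 samples")
  if (nrow(mat$values) < 2L) stop("PCA needs at least 2 ortholog pairs")
  cm <- stats::cor(mat$values)
  eg <- eigen(cm, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(mat$values), paste0("PC", seq_along(ev)))
  scores <- sweep(load, 2L, sqrt(ev), `*`)
  gene_scores <- mat$values %*% load
  structure(list(
    eigenvalues = ev,
    variance_explained_pct = 100 * ev / sum(ev),
    loadings = load,
    sample_scores = scores,
    gene_scores = gene_scores
  ), class = "pca_result")
}

# Evaluate expr with a private RNG state seeded at seed.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Leaf-index sets under every internal node of an hclust merge matrix.
merge_leaf_sets <- function(merge) {
  n_nodes <- nrow(merge)
  sets <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    mem <- integer(0)
    for (j in 1:2) {
      v <- merge[k, j]
      mem <- c(mem, if (v < 0) -v else sets[[v]])
    }
    sets[[k]] <- sort(mem)
  }
  sets
}

ward_hclust <- function(values, linkage) {
  if (linkage == "ward.D") {
    stats::hclust(stats::dist(t(values))^2, method = "ward.D")
  } else {
    stats::hclust(stats::dist(t(values)), method = "ward.D2")
  }
}

#' Ward hierarchical clustering of samples with bootstrap node support
#'
#' Agglomerative clustering of samples with Euclidean distances and Ward's
#' minimum-variance linkage. The default \code{linkage = "ward.D"} applies
#' the classical Ward criterion (squared-Euclidean update), so merge
#' heights are within-cluster sum-of-squares increases (times 2);
#' \code{"ward.D2"} is the unsquared-height convention. Node support is
#' the fraction of dendrograms, recomputed on gene rows resampled with
#' replacement, that contain the identical sample set under some node.
#'
#' @param mat an \code{ortholog_expression} (standardized or not).
#' @param n_bootstrap number of bootstrap resamples (default 100).
#' @param seed RNG seed for the bootstrap.
#' @param linkage "ward.D" (classical criterion, default) or "ward.D2".
#' @return Object of class \code{dendrogram_result}: \code{hclust} (the
#'   stats::hclust tree), \code{labels}, \code{support} (per internal
#'   node, in merge order, in [0,1]), \code{support_label} (">0.999" for
#'   support 1, per the reporting convention), \code{n_bootstrap}.
#' @export
ward_cluster <- function(mat, n_bootstrap = 100L, seed = 1L, linkage = c("ward.D", "ward.D2")) {
  stopifnot(inherits(mat, "ortholog_expression"))
  linkage <- match.arg(linkage)
  if (ncol(mat$values) < 3L) stop("clustering needs at least 3 samples")
  hc <- ward_hclust(mat$values, linkage)
  ref_sets <- merge_leaf_sets(hc$merge)
  rkeys <- vapply(ref_sets, paste, character(1), collapse = ",")
  hits <- integer(length(ref_sets))
  n_genes <- nrow(mat$values)
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n_genes, n_genes, replace = TRUE)
      bhc <- ward_hclust(mat$values[idx, , drop = FALSE], linkage)
      bkeys <- vapply(merge_leaf_sets(bhc$merge), paste, character(1), collapse = ",")
      hits <- hits + as.integer(rkeys %in% bkeys)
    }
  })
  support <- hits / n_bootstrap
  structure(list(
    hclust = hc,
    labels = colnames(mat$values),
    support = support,
    support_label = ifelse(support >= 1, ">0.999", formatC(support, digits = 3, format = "f")),
    n_bootstrap = as.integer(n_bootstrap)
  ), class = "dendrogram_result")
}

#' Categorize mean expression for marker heatmaps
#'
#' On the log scale l = log10(FPKM + 1): l = 0 is not_expressed,
#' 0 < l <= 0.63 low, 0.63 < l <= 1.82 moderate, l > 1.82 high.
#'
#' @param value non-negative mean FPKM value(s).
#' @return Character vector of categories.
#' @export
categorize_expression <- function(value) {
  if (any(value < 0)) stop("expression values must be non-negative")
  l <- log10(value + 1)
  out <- character(length(l))
  out[l == 0] <- "not_expressed"
  out[l > 0 & l <= 0.63] <- "low"
  out[l > 0.63 & l <= 1.82] <- "moderate"
  out[l > 1.82] <- "high"
  out
}
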