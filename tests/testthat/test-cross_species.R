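make_expr <- function(ids, samples, values) {
  expression_matrix(matrix(values, length(ids), length(samples),
                           dimnames = list(ids, samples)))
}

test_that("ortholog filtering applies the three retention predicates", {
  tab <- ortholog_table(data.frame(
    gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
    orthology_type = c("one2many", rep("one2one", 4)),
    identity_pct = c(80, 35, 40, 55, 90)))
  # a4 expressed in only one replicate overall
  va <- rbind(a1 = c(5, 5), a2 = c(5, 5), a3 = c(5, 5), a4 = c(2, 0), a5 = c(1, 3))
  vb <- rbind(b1 = c(5, 5), b2 = c(5, 5), b3 = c(5, 5), b4 = c(0, 0), b5 = c(0, 2))
  ea <- make_expr(rownames(va), c("A_r1", "A_r2"), va)
  eb <- make_expr(rownames(vb), c("B_r1", "B_r2"), vb)

  m <- filter_orthologs(tab, ea, eb)
  expect_setequal(m$pair_ids, c("a3|b3", "a5|b5"))
  # identity exactly at the threshold is retained (inclusive)
  expect_true("a3|b3" %in% m$pair_ids)
  # a4 has one nonzero column in total -> dropped at min_replicates = 2
  expect_false("a4|b4" %in% m$pair_ids)
  expect_equal(m$samples, c("A_r1", "A_r2", "B_r1", "B_r2"))

  # row order of the table does not change the result
  m2 <- filter_orthologs(tab[sample(5), ], ea, eb)
  expect_equal(m2$values, m$values)

  empty <- ortholog_table(data.frame(gene_a = character(0), gene_b = character(0),
                                     orthology_type = character(0),
                                     identity_pct = numeric(0)))
  expect_warning(m0 <- filter_orthologs(empty, ea, eb), "no ortholog pairs")
  expect_equal(length(m0$pair_ids), 0L)
})

test_that("standardization gives zero-mean unit-variance rows and drops constants", {
  vals <- rbind(p1 = c(1, 1, 1), p2 = c(0, 10, 100),
                p3 = 10^c(0.2, 0.4, 0.6) - 1)  # log10(x+1) symmetric
  colnames(vals) <- paste0("s", 1:3)
  m <- small_ortholog_matrix(vals)
  expect_warning(z <- standardize_orthologs(m), "zero-variance")
  expect_false("p1" %in% z$pair_ids)
  expect_equal(unname(rowMeans(z$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z$values, 1, sd)), c(1, 1), tolerance = 1e-12)
  # log10(x+1) symmetric about its mean -> symmetric z-scores
  expect_equal(unname(z$values["p3", 1]), -unname(z$values["p3", 3]))
})

test_that("correlation-matrix PCA matches an independent eigensolver", {
  set.seed(12)
  vals <- matrix(rnorm(300), 50, 6,
                 dimnames = list(sprintf("p%02d", 1:50), sprintf("s%d", 1:6)))
  p <- ortho_pca(small_ortholog_matrix(vals))
  expect_equal(sum(p$variance_explained_pct), 100)
  expect_equal(sum(p$eigenvalues), 6, tolerance = 1e-10)
  # oracle: singular values of the correlation matrix
  expect_equal(p$eigenvalues, svd(cor(vals))$d, tolerance = 1e-8)
  # loadings reproduce the correlation matrix
  recon <- p$loadings %*% diag(p$eigenvalues) %*% t(p$loadings)
  expect_equal(unname(recon), unname(cor(vals)), tolerance = 1e-8)

  # two perfectly correlated samples -> PC1 carries all variance
  v2 <- cbind(s1 = rnorm(20), s2 = 0)
  v2[, 2] <- 2 * v2[, 1]
  rownames(v2) <- sprintf("p%02d", 1:20)
  expect_equal(ortho_pca(small_ortholog_matrix(v2))$variance_explained_pct,
               c(100, 0))
  # exactly uncorrelated -> 50/50
  v3 <- cbind(s1 = rep(c(-1, 1), 10), s2 = rep(c(-1, -1, 1, 1), 5))
  rownames(v3) <- sprintf("p%02d", 1:20)
  expect_equal(ortho_pca(small_ortholog_matrix(v3))$variance_explained_pct,
               c(50, 50))
})

test_that("Ward clustering matches a naive Lance-Williams oracle", {
  set.seed(23)
  vals <- matrix(rnorm(40), 10, 4,
                 dimnames = list(sprintf("p%02d", 1:10), c("w", "x", "y", "z")))
  m <- small_ortholog_matrix(vals)
  d <- ward_cluster(m, n_bootstrap = 10, seed = 1, linkage = "ward.D")
  expect_equal(d$hclust$height, naive_ward_heights(vals), tolerance = 1e-8)
  expect_false(is.unsorted(d$hclust$height))
  expect_true(all(d$support >= 0 & d$support <= 1))
})

test_that("identical samples merge first with full bootstrap support", {
  set.seed(29)
  base <- rnorm(30)
  vals <- cbind(s1 = base, s2 = base, s3 = rnorm(30, 4))
  rownames(vals) <- sprintf("p%02d", 1:30)
  d <- ward_cluster(small_ortholog_matrix(vals), n_bootstrap = 50, seed = 2)
  first <- d$hclust$merge[1, ]
  expect_setequal(d$labels[-first], c("s1", "s2"))
  expect_equal(d$support[1], 1)
  expect_equal(d$support_label[1], ">0.999")
  expect_error(ward_cluster(small_ortholog_matrix(vals[, 1:2])), "3 samples")
})

test_that("clustering heights and topology are invariant to sample order", {
  set.seed(37)
  vals <- matrix(rnorm(50 * 5), 50, 5,
                 dimnames = list(sprintf("p%02d", 1:50), paste0("s", 1:5)))
  d1 <- ward_cluster(small_ortholog_matrix(vals), n_bootstrap = 5, seed = 1)
  perm <- c(3, 1, 5, 2, 4)
  d2 <- ward_cluster(small_ortholog_matrix(vals[, perm]), n_bootstrap = 5, seed = 1)
  expect_equal(d1$hclust$height, d2$hclust$height)
  sets1 <- lapply(chemorep:::merge_leaf_sets(d1$hclust$merge),
                  function(s) sort(d1$labels[s]))
  sets2 <- lapply(chemorep:::merge_leaf_sets(d2$hclust$merge),
                  function(s) sort(d2$labels[s]))
  expect_setequal(vapply(sets1, paste, "", collapse = ","),
                  vapply(sets2, paste, "", collapse = ","))
})

test_that("species effect larger than tissue effect orders the components", {
  g <- generate_synthetic(generator_config(seed = 2))
  o <- g$orthologs
  z <- standardize_orthologs(filter_orthologs(o$table, o$expr_a, o$expr_b))
  p <- ortho_pca(z)
  pc1 <- p$sample_scores[, 1]
  pc2 <- p$sample_scores[, 2]
  sp <- o$sample_species
  ti <- o$sample_tissue
  # PC1 separates species: the two species occupy disjoint score ranges
  expect_true(max(pc1[sp == "zebrafish"]) < min(pc1[sp == "mouse"]) ||
                min(pc1[sp == "zebrafish"]) > max(pc1[sp == "mouse"]))
  # PC2 separates tissues: OM and brain sit on opposite sides in both species
  expect_true(sign(mean(pc2[ti == "OM" & sp == "zebrafish"])) ==
                sign(mean(pc2[ti == "OM" & sp == "mouse"])))
  expect_true(sign(mean(pc2[ti == "OM"])) != sign(mean(pc2[ti == "brain"])))
})

test_that("expression categories follow the log-scale bins", {
  expect_equal(categorize_expression(0), "not_expressed")
  expect_equal(categorize_expression(10^0.5 - 1), "low")       # log value 0.5
  expect_equal(categorize_expression(10^0.63 - 1), "low")      # inclusive bound
  expect_equal(categorize_expression(10^1.0 - 1), "moderate")
  expect_equal(categorize_expression(10^1.82 - 1), "moderate") # inclusive bound
  expect_equal(categorize_expression(10^2.0 - 1), "high")
  expect_error(categorize_expression(-1), "non-negative")
})
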