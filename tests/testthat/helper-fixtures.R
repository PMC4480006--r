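# Shared fixtures and independent oracles.

toy_counts <- function() {
  m <- matrix(c(3L, 5L, 7L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("rep1", "rep2")))
  count_matrix(m)
}

toy_annotation <- function(gene_ids, lengths = 1000L, family = "none") {
  gene_annotation(data.frame(
    gene_id = gene_ids,
    length_bp = rep_len(lengths, length(gene_ids)),
    family = rep_len(family, length(gene_ids)),
    species = "zebrafish"))
}

# Independent exact-permutation Spearman oracle: insertion-built
# permutation list and stats::cor per permutation.
naive_perm_list <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in naive_perm_list(n - 1L)) {
    for (k in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

naive_exact_spearman_p <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(x, y, method = "spearman")
  hits <- 0L
  for (p in naive_perm_list(n)) {
    if (abs(stats::cor(seq_len(n), p, method = "spearman")) >= abs(rho) - 1e-12) {
      hits <- hits + 1L
    }
  }
  hits / factorial(n)
}

# Independent classical Ward (squared-Euclidean Lance-Williams update);
# returns the sequence of merge heights.
naive_ward_heights <- function(values) {
  d <- as.matrix(stats::dist(t(values)))^2
  n <- ncol(d)
  active <- seq_len(n)
  sizes <- rep(1L, n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- active[ij[1L]]; j <- active[ij[2L]]
    heights <- c(heights, d[i, j])
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d[i, k] <- d[k, i] <-
        ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) / (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

small_ortholog_matrix <- function(values) {
  structure(list(pair_ids = rownames(values),
                 samples = colnames(values),
                 values = values,
                 standardized = FALSE),
            class = "ortholog_expression")
}
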