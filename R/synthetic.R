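# Synthetic olfactory-epithelium data generator.
#
# Encodes the one-receptor-one-neuron structure: each receptor gene is
# expressed by a (heavy-tailed) number of sensory neurons, so its tissue
# RNA mass is neuron count x per-neuron expression; background genes draw
# their log expression from a two-component (LE/HE) Gaussian mixture.
# Fragment counts are multinomial over expression mass x gene length, ISH
# section counts are Poisson thinnings of the true neuron numbers, and
# spatial coordinates follow configurable apical/central/dorsal biases.
# Every table carries matched ground truth for recovery tests.

#' Generator configuration
#'
#' Defaults encode the study conditions the pipeline targets: the
#' zebrafish chemoreceptor repertoire (135 or, 118 taar, 5 ora, 56 olfC
#' genes), 20000 background genes whose nonzero log10 expression is
#' bimodal with roughly three quarters of genes in the HE component, three
#' replicates at 25 million gene-assigned fragments each, and 60 ISH
#' sections sampling about 1 percent of the organ's neurons per section.
#'
#' @param family_sizes named integer vector of receptor genes per family.
#' @param n_background_genes number of non-receptor genes.
#' @param neuron_abundance_law "exponential" (default) or "powerlaw"
#'   heavy-tailed law for per-receptor neuron counts.
#' @param powerlaw_exponent Pareto tail exponent (> 1) when
#'   \code{neuron_abundance_law = "powerlaw"}.
#' @param family_scale named per-family mean neurons per receptor.
#' @param per_neuron_expression expected RNA mass contributed per neuron
#'   (arbitrary mass units).
#' @param per_neuron_noise_sd log10-scale sd of per-receptor expression
#'   noise around the neuron-count prediction.
#' @param replicate_noise_sd log10-scale sd of per-replicate jitter.
#' @param background_mixture list with \code{lambda_he} (HE weight),
#'   \code{mu} (LE, HE log10 means) and \code{sigma} (LE, HE log10 sds).
#' @param library_size fragments per replicate.
#' @param n_replicates number of replicates.
#' @param gene_length_range min/max gene length in bp.
#' @param ish_sections number of ISH sections per gene.
#' @param sampling_fraction fraction of the organ's neurons visible per
#'   section.
#' @param n_spatial_cells labeled cells measured for the spatial table.
#' @param spatial_bias named vector: \code{apical} (laminar height bias),
#'   \code{central} (radial bias toward the lamellar apex), \code{dorsal}
#'   (bias toward early sections).
#' @param n_ortholog_pairs size of the toy two-species ortholog set.
#' @param species_effect,tissue_effect,ortholog_noise_sd log10-scale sds
#'   of the species divergence, tissue, and residual effects in the toy
#'   cross-species expression model (species > tissue by default, so
#'   samples separate first by species).
#' @param seed integer RNG seed; identical configs give identical output.
#' @return Validated list of class \code{generator_config}.
#' @export
generator_config <- function(family_sizes = c(or = 135L, taar = 118L, ora = 5L, olfC = 56L),
                             n_background_genes = 20000L,
                             neuron_abundance_law = c("exponential", "powerlaw"),
                             powerlaw_exponent = 2.5,
                             family_scale = c(or = 400, taar = 150, ora = 140, olfC = 320),
                             per_neuron_expression = 0.04,
                             per_neuron_noise_sd = 0.2,
                             replicate_noise_sd = 0.03,
                             background_mixture = list(lambda_he = 0.77,
                                                       mu = c(-1.5, 1.0),
                                                       sigma = c(0.6, 0.9)),
                             library_size = 25e6,
                             n_replicates = 3L,
                             gene_length_range = c(500L, 4000L),
                             ish_sections = 60L,
                             sampling_fraction = 0.01,
                             n_spatial_cells = 300L,
                             spatial_bias = c(apical = 2, central = 1, dorsal = 1),
                             n_ortholog_pairs = 400L,
                             species_effect = 1.0,
                             tissue_effect = 0.5,
                             ortholog_noise_sd = 0.1,
                             seed = 1L) {
  neuron_abundance_law <- match.arg(neuron_abundance_law)
  cfg <- list(family_sizes = family_sizes,
              n_background_genes = as.integer(n_background_genes),
              neuron_abundance_law = neuron_abundance_law,
              powerlaw_exponent = powerlaw_exponent,
              family_scale = family_scale,
              per_neuron_expression = per_neuron_expression,
              per_neuron_noise_sd = per_neuron_noise_sd,
              replicate_noise_sd = replicate_noise_sd,
              background_mixture = background_mixture,
              library_size = library_size,
              n_replicates = as.integer(n_replicates),
              gene_length_range = gene_length_range,
              ish_sections = as.integer(ish_sections),
              sampling_fraction = sampling_fraction,
              n_spatial_cells = as.integer(n_spatial_cells),
              spatial_bias = spatial_bias,
              n_ortholog_pairs = as.integer(n_ortholog_pairs),
              species_effect = species_effect,
              tissue_effect = tissue_effect,
              ortholog_noise_sd = ortholog_noise_sd,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (is.null(names(cfg$family_sizes)) || any(cfg$family_sizes < 0)) {
    stop("family_sizes must be a named vector of non-negative integers")
  }
  if (!identical(sort(names(cfg$family_sizes)), sort(names(cfg$family_scale)))) {
    stop("family_scale must name the same families as family_sizes")
  }
  pos <- c(cfg$family_scale, cfg$per_neuron_expression, cfg$library_size,
           cfg$sampling_fraction, cfg$background_mixture$sigma)
  if (any(pos <= 0)) stop("all scales must be positive")
  lam <- cfg$background_mixture$lambda_he
  if (lam < 0 || lam > 1) stop("lambda_he must lie in [0, 1]")
  if (cfg$powerlaw_exponent <= 1) stop("powerlaw_exponent must exceed 1")
  if (cfg$n_replicates < 1L) stop("need at least 1 replicate")
  if (cfg$gene_length_range[1L] < 1L || diff(cfg$gene_length_range) < 0) {
    stop("invalid gene_length_range")
  }
  invisible(cfg)
}

draw_neuron_counts <- function(n, scale, law, alpha) {
  if (n == 0L) return(numeric(0))
  raw <- switch(law,
    exponential = stats::rexp(n, rate = 1 / scale),
    powerlaw = {
      # Pareto with mean = scale for tail exponent alpha > 1
      xm <- scale * (alpha - 1) / alpha
      xm * stats::runif(n)^(-1 / alpha)
    })
  round(raw)
}

#' Generate a synthetic olfactory-transcriptome dataset
#'
#' @param config a \code{\link{generator_config}}.
#' @return List with elements \code{counts} (\code{count_matrix}),
#'   \code{annotation} (\code{gene_annotation}), \code{expression_truth},
#'   \code{ish} (\code{ish_count_set} over all receptor genes),
#'   \code{spatial} (\code{spatial_records}), \code{orthologs} (list:
#'   \code{table}, \code{expr_a}, \code{expr_b}), and \code{truth}
#'   (class \code{synthetic_truth}: per-receptor neuron counts, per-gene
#'   true mean expression mass, per-background-gene HE/LE label, spatial
#'   bias parameters).
#' @export
generate_synthetic <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  fams <- names(config$family_sizes)
  receptor_ids <- unlist(lapply(fams, function(f) {
    sprintf("%s-%03d", f, seq_len(config$family_sizes[[f]]))
  }))
  receptor_fam <- rep(fams, config$family_sizes)
  bg_ids <- sprintf("gene%05d", seq_len(config$n_background_genes))
  gene_ids <- c(receptor_ids, bg_ids)

  # substream offsets keep each table stable when others are resized
  base <- config$seed

  lengths_bp <- with_seed(base + 101L, {
    sample(config$gene_length_range[1L]:config$gene_length_range[2L],
           length(gene_ids), replace = TRUE)
  })
  annotation <- gene_annotation(data.frame(
    gene_id = gene_ids,
    length_bp = lengths_bp,
    family = c(receptor_fam, rep("none", config$n_background_genes)),
    species = "zebrafish"
  ))

  neurons <- with_seed(base + 102L, {
    unlist(lapply(fams, function(f) {
      draw_neuron_counts(config$family_sizes[[f]], config$family_scale[[f]],
                         config$neuron_abundance_law, config$powerlaw_exponent)
    }))
  })
  names(neurons) <- receptor_ids

  mix <- config$background_mixture
  bg <- with_seed(base + 103L, {
    comp <- stats::rbinom(config$n_background_genes, 1L, mix$lambda_he) + 1L
    logmass <- stats::rnorm(config$n_background_genes,
                            mean = mix$mu[comp], sd = mix$sigma[comp])
    list(comp = comp, mass = 10^logmass)
  })
  he_label <- ifelse(bg$comp == 2L, "HE", "LE")
  names(he_label) <- bg_ids

  receptor_mass <- with_seed(base + 104L, {
    neurons * config$per_neuron_expression *
      10^stats::rnorm(length(neurons), 0, config$per_neuron_noise_sd)
  })
  mass <- c(receptor_mass, bg$mass)
  names(mass) <- gene_ids

  counts <- with_seed(base + 105L, {
    m <- matrix(0L, nrow = length(gene_ids), ncol = config$n_replicates,
                dimnames = list(gene_ids, paste0("rep", seq_len(config$n_replicates))))
    for (r in seq_len(config$n_replicates)) {
      jitter <- 10^stats::rnorm(length(mass), 0, config$replicate_noise_sd)
      w <- mass * jitter * lengths_bp
      m[, r] <- stats::rmultinom(1L, size = config$library_size, prob = w)[, 1L]
    }
    m
  })
  counts <- count_matrix(counts)

  ish <- with_seed(base + 106L, {
    sc <- lapply(receptor_ids, function(g) {
      stats::rpois(config$ish_sections, neurons[[g]] * config$sampling_fraction)
    })
    names(sc) <- receptor_ids
    ish_count_set(sc)
  })

  spatial <- with_seed(base + 107L, {
    n <- config$n_spatial_cells
    bias <- config$spatial_bias
    h_rel <- stats::rbeta(n, 1 + bias[["apical"]], 1)
    r_rel <- stats::rbeta(n, 1, 1 + bias[["central"]])
    n_sec <- config$ish_sections
    z_w <- exp(-bias[["dorsal"]] * seq_len(n_sec) / n_sec)
    section <- sample.int(n_sec, n, replace = TRUE, prob = z_w)
    thick <- stats::runif(n, 80, 120)
    extent <- stats::runif(n, 200, 400)
    spatial_records(data.frame(
      cell_id = sprintf("cell%04d", seq_len(n)),
      basal_distance = h_rel * thick,
      epithelium_thickness = thick,
      radial_distance = r_rel * extent,
      radial_extent = extent,
      section_index = section,
      n_sections = n_sec
    ))
  })

  orthologs <- with_seed(base + 108L, generate_ortholog_toy(config))

  truth <- structure(list(
    neuron_counts = neurons,
    gene_mass = mass,
    he_label = he_label,
    spatial_bias = config$spatial_bias,
    config = config
  ), class = "synthetic_truth")

  list(counts = counts, annotation = annotation, ish = ish,
       spatial = spatial, orthologs = orthologs, truth = truth)
}

# Toy two-species expression set: 14 samples (zebrafish OM x3 + brain x3;
# mouse OM x3 + VNO x3 + brain x2), log10 expression = gene base +
# per-species divergence + per-tissue effect + noise.
generate_ortholog_toy <- function(config) {
  np <- config$n_ortholog_pairs
  ga <- sprintf("dre_g%04d", seq_len(np))
  gb <- sprintf("mmu_g%04d", seq_len(np))
  type <- sample(c("one2one", "one2many", "many2many"), np,
                 replace = TRUE, prob = c(0.85, 0.1, 0.05))
  identity_pct <- stats::runif(np, 15, 95)
  tab <- ortholog_table(data.frame(gene_a = ga, gene_b = gb,
                                   orthology_type = type,
                                   identity_pct = identity_pct))
  base_expr <- stats::rnorm(np, 0.5, 0.7)
  sp_dev <- matrix(stats::rnorm(np * 2L, 0, config$species_effect), np, 2L,
                   dimnames = list(NULL, c("A", "B")))
  tissues <- c("OM", "VNO", "brain")
  ti_dev <- matrix(stats::rnorm(np * 3L, 0, config$tissue_effect), np, 3L,
                   dimnames = list(NULL, tissues))
  samples_a <- c(paste0("zf_OM_", 1:3), paste0("zf_brain_", 1:3))
  tiss_a <- c(rep("OM", 3), rep("brain", 3))
  samples_b <- c(paste0("mm_OM_", 1:3), paste0("mm_VNO_", 1:3), paste0("mm_brain_", 1:2))
  tiss_b <- c(rep("OM", 3), rep("VNO", 3), rep("brain", 2))
  build <- function(samples, tiss, sp, ids) {
    m <- matrix(0, np, length(samples), dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
      lv <- base_expr + sp_dev[, sp] + ti_dev[, tiss[j]] +
        stats::rnorm(np, 0, config$ortholog_noise_sd)
      m[, j] <- 10^lv
    }
    expression_matrix(m)
  }
  expr_a <- build(samples_a, tiss_a, "A", ga)
  expr_b <- build(samples_b, tiss_b, "B", gb)
  list(table = tab, expr_a = expr_a, expr_b = expr_b,
       sample_species = c(rep("zebrafish", length(samples_a)),
                          rep("mouse", length(samples_b))),
       sample_tissue = c(tiss_a, tiss_b))
}

#' Recovery metrics of pipeline estimates against synthetic ground truth
#'
#' @param truth a \code{synthetic_truth} from
#'   \code{\link{generate_synthetic}}.
#' @param estimates named list; recognized elements: \code{mean_fpkm}
#'   (named per-receptor mean FPKM, compared by Spearman rank correlation
#'   with the true neuron counts) and \code{he_calls} (named "HE"/"LE"
#'   calls, compared by agreement with the generating labels over shared
#'   genes).
#' @param tolerances named list of pass thresholds
#'   (\code{rank_correlation}, \code{classification_agreement}).
#' @return data frame with columns \code{metric}, \code{value}, \code{n},
#'   \code{tolerance}, \code{pass}.
#' @export
truth_report <- function(truth, estimates,
                         tolerances = list(rank_correlation = 0.9,
                                           classification_agreement = 0.9)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rows <- list()
  if (!is.null(estimates$mean_fpkm)) {
    est <- estimates$mean_fpkm
    if (is.null(names(est))) stop("estimates$mean_fpkm must be named by gene")
    shared <- intersect(names(est), names(truth$neuron_counts))
    if (length(shared) == 0L) stop("no receptor genes shared between truth and estimates")
    rho <- stats::cor(est[shared], truth$neuron_counts[shared], method = "spearman")
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "rank_correlation", value = rho, n = length(shared),
      tolerance = tolerances$rank_correlation,
      pass = rho >= tolerances$rank_correlation)
  }
  if (!is.null(estimates$he_calls)) {
    est <- estimates$he_calls
    if (is.null(names(est))) stop("estimates$he_calls must be named by gene")
    shared <- intersect(names(est), names(truth$he_label))
    if (length(shared) == 0L) stop("no background genes shared between truth and estimates")
    agree <- mean(est[shared] == truth$he_label[shared])
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "classification_agreement", value = agree, n = length(shared),
      tolerance = tolerances$classification_agreement,
      pass = agree >= tolerances$classification_agreement)
  }
  if (length(rows) == 0L) stop("no recognized estimates supplied")
  do.call(rbind, rows)
}
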