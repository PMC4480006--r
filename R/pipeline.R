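# End-to-end orchestration: simulate/load -> quantify -> mixture ->
# repertoire -> calibration -> cross-species -> spatial.

#' Pipeline configuration
#'
#' Collects input paths (or enables the simulation stage), module
#' thresholds and the global seed. Threshold defaults are the analysis
#' defaults used throughout the package: HE posterior 0.25, ortholog
#' identity 40 percent, 2 expressed replicates, 100 bootstraps, exact
#' Spearman enumeration up to n = 9, 10 histogram bins.
#'
#' @param simulate generate inputs with \code{\link{generate_synthetic}}
#'   instead of reading files.
#' @param counts,annotation,ish,spatial,orthologs,expr_a,expr_b input file
#'   paths (ignored when \code{simulate = TRUE}; \code{orthologs},
#'   \code{expr_a}, \code{expr_b} are optional — the cross-species stage
#'   is skipped when absent).
#' @param out_dir optional directory; when set, stage outputs are written
#'   as plain tables.
#' @param he_threshold,min_identity,min_replicates,n_bootstrap,exact_limit,n_bins
#'   module thresholds.
#' @param top_k number of genes for the cumulative-share summary.
#' @param seed global RNG seed.
#' @param generator list of \code{\link{generator_config}} overrides for
#'   the simulation stage.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulate = TRUE,
                            counts = NULL, annotation = NULL, ish = NULL,
                            spatial = NULL, orthologs = NULL,
                            expr_a = NULL, expr_b = NULL,
                            out_dir = NULL,
                            he_threshold = 0.25, min_identity = 40,
                            min_replicates = 2L, n_bootstrap = 100L,
                            exact_limit = 9L, n_bins = 10L, top_k = 200L,
                            seed = 1L, generator = list()) {
  structure(list(simulate = simulate, counts = counts,
                 annotation = annotation, ish = ish, spatial = spatial,
                 orthologs = orthologs, expr_a = expr_a, expr_b = expr_b,
                 out_dir = out_dir, he_threshold = he_threshold,
                 min_identity = min_identity, min_replicates = min_replicates,
                 n_bootstrap = n_bootstrap, exact_limit = exact_limit,
                 n_bins = n_bins, top_k = top_k, seed = as.integer(seed),
                 generator = generator),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

run_stage <- function(report, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  report$stages[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(report = report, result = res)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, quantification, mixture classification,
#' repertoire statistics, neuron calibration, cross-species comparison and
#' spatial quantification, collecting all stage outputs and a run report
#' (R version, seed, config echo, stage timings). Identical config and
#' seed give identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return List with elements \code{data}, \code{expression},
#'   \code{concordance}, \code{mixture}, \code{classes},
#'   \code{cumulative_share}, \code{profiles}, \code{family_test},
#'   \code{calibration}, \code{cross_species}, \code{spatial} and
#'   \code{report}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(r_version = as.character(getRversion()),
                 seed = config$seed, config = unclass(config),
                 stages = list())

  st <- run_stage(report, "load", function() {
    if (isTRUE(config$simulate)) {
      gcfg <- do.call(generator_config,
                      c(config$generator, list(seed = config$seed)))
      generate_synthetic(gcfg)
    } else {
      if (is.null(config$counts) || is.null(config$annotation)) {
        stop("counts and annotation paths are required when simulate = FALSE")
      }
      orth <- NULL
      if (!is.null(config$orthologs)) {
        orth <- list(table = read_ortholog_table(config$orthologs),
                     expr_a = read_expression_tsv(config$expr_a),
                     expr_b = read_expression_tsv(config$expr_b))
      }
      list(counts = read_count_matrix(config$counts),
           annotation = read_gene_annotation(config$annotation),
           ish = if (!is.null(config$ish)) read_ish_counts(config$ish),
           spatial = if (!is.null(config$spatial)) read_spatial_records(config$spatial),
           orthologs = orth, truth = NULL)
    }
  })
  report <- st$report; dat <- st$result

  st <- run_stage(report, "quantify", function() {
    expr <- fpkm(dat$counts, dat$annotation)
    list(expr = expr, concordance = replicate_concordance(expr))
  })
  report <- st$report; q <- st$result

  st <- run_stage(report, "mixture_model", function() {
    fs <- select_fit_set(dat$counts, q$expr)
    fit <- fit_em(fs$log_expr, seed = config$seed)
    calls <- classify_he(fit, threshold = config$he_threshold)
    names(calls) <- fs$gene_ids
    k <- min(config$top_k, length(q$expr$gene_ids))
    list(fit_set = fs, fit = fit, calls = calls,
         cumulative_share = cumulative_share(q$expr, k))
  })
  report <- st$report; mx <- st$result

  st <- run_stage(report, "receptor_repertoire", function() {
    profiles <- family_profiles(q$expr, dat$annotation)
    test <- equal_expression_chi2(profiles$cumulative_fpkm, profiles$n_genes)
    list(profiles = profiles, family_test = test)
  })
  report <- st$report; rep_res <- st$result

  st <- run_stage(report, "neuron_calibration", function() {
    if (is.null(dat$ish)) return(NULL)
    genes <- intersect(dat$ish$gene_ids, q$expr$gene_ids)
    x <- q$expr$mean_fpkm[genes]
    y <- dat$ish$mean_per_section[genes]
    pos <- x > 0 & y > 0
    cal <- if (sum(pos) >= 3L) fit_calibration(x[pos], y[pos]) else NULL
    list(correlation = spearman_test(x, y, exact_limit = config$exact_limit),
         model = cal)
  })
  report <- st$report; cal_res <- st$result

  st <- run_stage(report, "cross_species", function() {
    if (is.null(dat$orthologs)) return(NULL)
    o <- dat$orthologs
    m <- filter_orthologs(o$table, o$expr_a, o$expr_b,
                          min_identity = config$min_identity,
                          min_replicates = config$min_replicates)
    z <- standardize_orthologs(m)
    list(matrix = z, pca = ortho_pca(z),
         dendrogram = ward_cluster(z, n_bootstrap = config$n_bootstrap,
                                   seed = config$seed))
  })
  report <- st$report; cs_res <- st$result

  st <- run_stage(report, "spatial_quant", function() {
    if (is.null(dat$spatial)) return(NULL)
    norm <- normalize_coordinates(dat$spatial)
    list(cells = norm,
         histograms = list(h_rel = distribution_histogram(norm$h_rel, config$n_bins),
                           r_rel = distribution_histogram(norm$r_rel, config$n_bins),
                           z_rel = distribution_histogram(norm$z_rel, config$n_bins)),
         enrichment = enrichment_summary(norm$h_rel))
  })
  report <- st$report; sp_res <- st$result

  out <- list(data = dat, expression = q$expr, concordance = q$concordance,
              mixture = mx$fit, classes = mx$calls,
              cumulative_share = mx$cumulative_share,
              profiles = rep_res$profiles, family_test = rep_res$family_test,
              calibration = cal_res, cross_species = cs_res,
              spatial = sp_res, report = report)

  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

# Minimal expression-matrix TSV reader (gene_id + replicate columns; any
# mean/sem columns from write_table are recomputed, not trusted).
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1L] != "gene_id") stop("expression table must start with gene_id")
  df <- df[, !(names(df) %in% c("mean_fpkm", "sem_fpkm")), drop = FALSE]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_matrix(m)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(out$expression, file.path(dir, "fpkm.tsv"))
  classes <- data.frame(gene_id = names(out$classes), class = out$classes)
  write_table(classes, file.path(dir, "classes.tsv"))
  write_table(out$profiles, file.path(dir, "family_profiles.tsv"))
  if (!is.null(out$cross_species)) {
    scores <- data.frame(sample = rownames(out$cross_species$pca$sample_scores),
                         out$cross_species$pca$sample_scores[, 1:2, drop = FALSE])
    write_table(scores, file.path(dir, "pca_scores.tsv"))
  }
  if (!is.null(out$spatial)) {
    write_table(out$spatial$histograms$h_rel, file.path(dir, "h_rel_histogram.tsv"))
  }
  invisible(dir)
}
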