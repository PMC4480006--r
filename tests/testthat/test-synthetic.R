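test_that("the generator is deterministic and validates its configuration", {
  cfg <- generator_config(n_background_genes = 500L, library_size = 1e5,
                          seed = 4L)
  g1 <- generate_synthetic(cfg)
  g2 <- generate_synthetic(cfg)
  expect_identical(g1$counts, g2$counts)
  expect_identical(g1$ish, g2$ish)
  expect_identical(g1$spatial, g2$spatial)
  expect_identical(g1$orthologs$expr_a$fpkm, g2$orthologs$expr_a$fpkm)

  g3 <- generate_synthetic(generator_config(n_background_genes = 500L,
                                            library_size = 1e5, seed = 5L))
  expect_false(identical(g1$counts$counts, g3$counts$counts))

  expect_error(generator_config(family_scale = c(or = -1, taar = 1, ora = 1, olfC = 1)),
               "positive")
  expect_error(generator_config(background_mixture = list(lambda_he = 1.4,
                                                          mu = c(0, 1),
                                                          sigma = c(1, 1))),
               "lambda_he")
  expect_error(generator_config(powerlaw_exponent = 1), "exceed 1")
})

test_that("receptors with zero neurons yield zero counts and zero ISH cells", {
  # a near-zero family scale guarantees receptors with zero neurons
  cfg <- generator_config(n_background_genes = 200L, library_size = 1e5,
                          per_neuron_noise_sd = 0,
                          family_scale = c(or = 400, taar = 150, ora = 0.2,
                                           olfC = 320),
                          seed = 8L)
  g <- generate_synthetic(cfg)
  zero <- names(g$truth$neuron_counts)[g$truth$neuron_counts == 0]
  expect_gt(length(zero), 0L)
  expect_true(all(g$counts$counts[zero, ] == 0L))
  expect_true(all(vapply(g$ish$section_counts[zero], sum, numeric(1)) == 0))
})

test_that("truth dimensions match the emitted tables", {
  g <- generate_synthetic(generator_config(n_background_genes = 300L,
                                           library_size = 2e5, seed = 6L))
  expect_equal(length(g$truth$gene_mass), length(g$counts$gene_ids))
  expect_setequal(names(g$truth$neuron_counts), g$ish$gene_ids)
  expect_equal(length(g$truth$he_label),
               sum(g$annotation$family == "none"))
  expect_equal(nrow(g$orthologs$table), 400L)
  expect_equal(length(g$orthologs$sample_species), 14L)
})

test_that("emitted counts and ISH means track the configured laws", {
  cfg <- generator_config(seed = 9L)
  g <- generate_synthetic(cfg)
  # FPKM removes the length factor: mean FPKM proportional to mass
  expr <- fpkm(g$counts, g$annotation)
  big <- g$truth$gene_mass > quantile(g$truth$gene_mass, 0.5)
  rho <- cor(log10(expr$mean_fpkm[big] + 1e-6), log10(g$truth$gene_mass[big]),
             method = "spearman")
  expect_gt(rho, 0.95)
  # ISH mean cells/section ~ neurons x sampling fraction
  exp_mean <- g$truth$neuron_counts * cfg$sampling_fraction
  dense <- exp_mean >= 2
  rel_err <- abs(g$ish$mean_per_section[dense] - exp_mean[dense]) / exp_mean[dense]
  expect_lt(median(rel_err), 0.15)
})

test_that("truth_report scores perfect, good and shuffled estimates sensibly", {
  g <- generate_synthetic(generator_config(n_background_genes = 2000L,
                                           library_size = 1e6, seed = 10L))
  # perfect estimates
  perfect <- truth_report(g$truth, list(
    mean_fpkm = g$truth$neuron_counts,
    he_calls = g$truth$he_label))
  expect_true(all(perfect$pass))
  expect_equal(perfect$value[perfect$metric == "classification_agreement"], 1)

  # pipeline estimates at defaults
  g_full <- generate_synthetic(generator_config(seed = 11L))
  expr <- fpkm(g_full$counts, g_full$annotation)
  fs <- select_fit_set(g_full$counts, expr)
  fit <- fit_em(fs$log_expr)
  calls <- classify_he(fit)
  names(calls) <- fs$gene_ids
  rep_full <- truth_report(g_full$truth, list(
    mean_fpkm = expr$mean_fpkm[names(g_full$truth$neuron_counts)],
    he_calls = calls))
  expect_true(all(rep_full$pass))
  expect_gte(rep_full$value[rep_full$metric == "classification_agreement"], 0.9)

  # shuffled estimates carry no rank signal
  set.seed(1)
  shuffled <- g$truth$neuron_counts
  names(shuffled) <- sample(names(shuffled))
  null_rep <- truth_report(g$truth, list(mean_fpkm = shuffled))
  expect_lt(abs(null_rep$value[1]), 0.2)

  expect_error(truth_report(g$truth, list(mean_fpkm = unname(g$truth$neuron_counts))),
               "named")
  expect_error(truth_report(g$truth, list()), "no recognized estimates")
})
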