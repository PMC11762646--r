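test_that("zeta degree sampler matches the series oracle at the origin", {
  n <- 1e5
  d_max <- 10000
  x <- sample_zeta_degrees(n, 2.0, d_max = d_max, seed = 17)
  # truncated mass at 1: 1 / sum_{1..d_max} x^-2
  p1 <- 1 / sum((1:d_max)^(-2))
  expect_lt(abs(mean(x == 1) - p1), 0.01)
  expect_true(all(x >= 1 & x <= d_max))
})

test_that("zeta sampler is deterministic by seed and respects d_max", {
  expect_identical(sample_zeta_degrees(500, 2.2, seed = 4),
                   sample_zeta_degrees(500, 2.2, seed = 4))
  expect_true(all(sample_zeta_degrees(100, 2.2, d_max = 1, seed = 5) == 1))
  expect_error(sample_zeta_degrees(10, 1.0, seed = 1), "> 1")
})

test_that("ground-truth network has consistent degrees and heavy gene tail", {
  cfg <- synth_config(n_mirna = 300, n_gene = 1200, seed = 11)
  truth <- build_true_network(cfg)
  net <- build_network(truth$edges[, c("mirna_id", "gene_id")])
  expect_equal(sum(net$mirna_degree$degree), nrow(truth$edges))
  expect_equal(sum(net$gene_degree$degree), nrow(truth$edges))
  # weighted partner choice induces a right-skewed gene degree distribution
  gd <- net$gene_degree$degree
  expect_gte(max(gd), 10 * stats::median(gd))
  # noise labelling matches the configured fraction
  expect_equal(mean(truth$edges$label == "noise"), 0.2, tolerance = 0.02)
})

test_that("noise-free configuration labels every edge gold", {
  cfg <- synth_config(n_mirna = 50, n_gene = 200, noise_edge_fraction = 0,
                      seed = 12)
  truth <- build_true_network(cfg)
  expect_true(all(truth$edges$label == "gold"))
})

test_that("generation is a pure function of the seed", {
  cfg <- synth_config(n_mirna = 80, n_gene = 300, seed = 13)
  t1 <- build_true_network(cfg)
  t2 <- build_true_network(cfg)
  expect_identical(t1$edges, t2$edges)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_records(t1, d1)
  emit_records(t2, d2)
  for (f in c("mitab.tsv", "mirtarbase.tsv", "rnainter.tsv",
              "annotation_export.tsv", "id_mapping.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("clean emission round-trips to the exact network", {
  cfg <- synth_config(n_mirna = 60, n_gene = 250, noise_edge_fraction = 0,
                      dup_rate = 0, alias_rate = 0, seed = 14)
  truth <- build_true_network(cfg)
  dir <- withr::local_tempdir()
  ds <- emit_records(truth, dir)
  expect_equal(ds$manifest_data$n_records, nrow(truth$edges))

  records <- dplyr::bind_rows(lapply(
    c("mitab", "mirtarbase", "rnainter", "annotation_export"),
    function(d) read_interactions(ds[[d]], d)
  ))
  edges <- deduplicate(filter_evidence(records))
  expect_setequal(paste(edges$mirna_id, edges$gene_id),
                  paste(truth$edges$mirna_id, truth$edges$gene_id))
})

test_that("aliased targets need the mapping to deduplicate correctly", {
  cfg <- synth_config(n_mirna = 60, n_gene = 250, noise_edge_fraction = 0,
                      dup_rate = 0, alias_rate = 0.1, seed = 15)
  truth <- build_true_network(cfg)
  dir <- withr::local_tempdir()
  ds <- emit_records(truth, dir)

  records <- dplyr::bind_rows(lapply(
    c("mitab", "mirtarbase", "rnainter", "annotation_export"),
    function(d) read_interactions(ds[[d]], d)
  ))
  n_gold <- sum(truth$edges$label == "gold")
  without <- deduplicate(filter_evidence(records))
  expect_gt(nrow(without), n_gold)

  mapping <- read_id_mapping(ds$id_mapping)
  with_map <- deduplicate(filter_evidence(map_identifiers(records, mapping)))
  expect_equal(nrow(with_map), n_gold)
  expect_false(any(grepl("^ALS:", with_map$gene_id)))
})

test_that("TF table generator is seed-stable with strength controlling MI", {
  t1 <- plant_tf_table(200, 1.5, seed = 16)
  t2 <- plant_tf_table(200, 1.5, seed = 16)
  expect_identical(t1, t2)
  expect_named(t1, c("tf_id", "n_mirna_regulators", "n_regulated_genes"))

  strong <- plant_tf_table(300, 2, seed = 17)
  res <- resample_mi(strong$n_mirna_regulators, strong$n_regulated_genes,
                     n_boot = 100, n_perm = 199, seed = 18)
  expect_lte(res$p_perm, 0.01)

  null <- plant_tf_table(300, 0, seed = 19)
  res0 <- resample_mi(null$n_mirna_regulators, null$n_regulated_genes,
                      n_boot = 100, n_perm = 199, seed = 20)
  expect_gt(res0$p_perm, 0.05)
})

test_that("UTR table generator plants the requested correlations", {
  tab <- plant_utr_table(500, 0.7, 0.3, seed = 21)
  expect_identical(tab, plant_utr_table(500, 0.7, 0.3, seed = 21))
  ct <- correlation_table(tab)
  r <- function(a, b) ct$r[ct$var1 == a & ct$var2 == b]
  expect_lt(abs(r("utr3_length", "n_pred_A") - 0.7), 0.1)
  expect_lt(abs(r("utr3_length", "n_verified") - 0.3), 0.1)

  flat <- plant_utr_table(500, 0, 0, seed = 22)
  ct0 <- correlation_table(flat)
  r0 <- function(a, b) ct0$r[ct0$var1 == a & ct0$var2 == b]
  expect_lt(abs(r0("utr3_length", "n_pred_A")), 0.1)
  expect_lt(abs(r0("utr3_length", "n_verified")), 0.1)
})

test_that("plant_enrichment validates hubs and is seed-stable", {
  genes <- paste0("g", 1:50)
  expect_error(plant_enrichment(genes, character(0), seed = 1), "empty hub")
  expect_error(plant_enrichment(genes, "not_a_gene", seed = 1), "subset")
  a1 <- plant_enrichment(genes, genes[1:5], seed = 2)
  a2 <- plant_enrichment(genes, genes[1:5], seed = 2)
  expect_identical(a1, a2)
})
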