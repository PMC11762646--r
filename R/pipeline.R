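# End-to-end orchestration: ingest -> map -> filter -> dedup -> network ->
# (abundance fits, MI, enrichment, overlaps, UTR correlations), with a
# machine-readable run report. Fulfils the pipeline front-end: each stage
# is equally runnable standalone through the exported per-stage functions.

.pipeline_defaults <- function() {
  list(
    seed = NULL,
    output_dir = NULL,
    simulate = NULL,      # list of synth_config() overrides, or NULL
    inputs = NULL,        # named paths: mitab, mirtarbase, rnainter,
                          # annotation_export, id_mapping, tf_table, utr_table,
                          # annotations (optional per analysis)
    map_policy = "keep_unmapped",
    filter = TRUE,
    hub_threshold = 20,
    models = c("zeta_powerlaw", "logseries", "geometric"),
    mi = list(bins = 10, n_boot = 200, n_perm = 200),
    enrich_alpha = 5e-4,
    overlap_top = 3
  )
}

.validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(.pipeline_defaults()))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(.pipeline_defaults(), config)
  if (is.null(cfg$seed)) abort("config$seed is required")
  if (is.null(cfg$output_dir)) abort("config$output_dir is required")
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    abort("config needs either 'simulate' or 'inputs'")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full curation-and-analysis pipeline
#'
#' Executes ingest, identifier mapping, evidence filtering, deduplication,
#' network construction and the downstream analyses (degree abundance,
#' hubs, abundance-model selection, TF mutual information, hub term
#' enrichment, target overlaps of the most connected miRNAs, UTR
#' correlations), writing every artifact to `output_dir` and returning a
#' run report. With a `simulate` block in the config, all inputs are first
#' generated synthetically with known ground truth.
#'
#' Config fields (list or YAML path): `seed`, `output_dir`, one of
#' `simulate` (a list of [synth_config()] overrides) or `inputs` (named
#' file paths: `mitab`, `mirtarbase`, `rnainter`, `annotation_export`,
#' optional `id_mapping`, `tf_table`, `utr_table`, `annotations`), plus
#' options `map_policy`, `filter`, `hub_threshold`, `models`, `mi`
#' (`bins`, `n_boot`, `n_perm`), `enrich_alpha`, `overlap_top`. All
#' randomness derives from `seed` through fixed per-stage sub-seeds, so a
#' re-run with the same config produces byte-identical artifacts.
#'
#' @param config A config list or a path to a YAML config file.
#' @return List of class `"run_report"` with per-stage counts, artifact
#'   paths, the config echo, the seed and per-stage wall times; also
#'   written as `run_report.json` (counts) in `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- .validate_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg[setdiff(names(cfg), "output_dir")],
                 seed = cfg$seed, stages = list(), files = list())
  timing <- list()
  tic <- function() proc.time()[["elapsed"]]
  truth <- NULL

  # -- simulate ------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    t0 <- tic()
    sim_args <- cfg$simulate
    sim_args$seed <- .sub_seed(cfg$seed, 10)
    scfg <- do.call(synth_config, sim_args)
    truth <- build_true_network(scfg)
    input_dir <- file.path(cfg$output_dir, "input")
    ds <- emit_records(truth, input_dir)
    cfg$inputs <- list(
      mitab = ds$mitab, mirtarbase = ds$mirtarbase, rnainter = ds$rnainter,
      annotation_export = ds$annotation_export, id_mapping = ds$id_mapping
    )
    # companion tables for the MI and UTR analyses
    tf <- plant_tf_table(n_tf = 300, mi_link_strength = scfg$mi_link_strength,
                         seed = .sub_seed(cfg$seed, 11))
    utr <- plant_utr_table(n_genes = 500, rho_pred = scfg$utr_rho_pred,
                           rho_verified = scfg$utr_rho_verified,
                           seed = .sub_seed(cfg$seed, 12))
    cfg$inputs$tf_table <- file.path(input_dir, "tf_table.tsv")
    cfg$inputs$utr_table <- file.path(input_dir, "utr_table.tsv")
    readr::write_tsv(tf, cfg$inputs$tf_table, progress = FALSE)
    readr::write_tsv(utr, cfg$inputs$utr_table, progress = FALSE)
    report$stages$simulate <- list(
      n_true_edges = nrow(truth$edges),
      n_gold_edges = sum(truth$edges$label == "gold"),
      n_noise_edges = sum(truth$edges$label == "noise"),
      n_records = ds$manifest_data$n_records
    )
    timing$simulate <- tic() - t0
  }

  # -- ingest --------------------------------------------------------------
  t0 <- tic()
  dialect_paths <- cfg$inputs[intersect(.record_dialects, names(cfg$inputs))]
  records <- purrr::imap(dialect_paths, function(p, d) read_interactions(p, d))
  rejected <- purrr::map_dfr(records, rejected_records)
  records <- bind_rows(!!!records)
  n_read <- nrow(records) + nrow(rejected)
  report$stages$ingest <- list(records_read = n_read,
                               rejected = nrow(rejected),
                               accepted = nrow(records))
  timing$ingest <- tic() - t0

  # -- map -----------------------------------------------------------------
  t0 <- tic()
  mapping <- if (!is.null(cfg$inputs$id_mapping)) {
    read_id_mapping(cfg$inputs$id_mapping)
  } else NULL
  records <- map_identifiers(records, mapping, policy = cfg$map_policy)
  report$stages$map <- as.list(mapping_report(records))
  timing$map <- tic() - t0

  # -- filter --------------------------------------------------------------
  t0 <- tic()
  if (isTRUE(cfg$filter)) {
    kept <- filter_evidence(records, filter_policy())
    removed <- rejected_records(kept)
    removed_by_reason <- as.list(table(removed$reason))
  } else {
    kept <- records
    removed_by_reason <- list()
  }
  report$stages$filter <- list(kept = nrow(kept),
                               removed = nrow(records) - nrow(kept),
                               removed_by_reason = removed_by_reason)
  timing$filter <- tic() - t0

  # -- dedup + network -----------------------------------------------------
  t0 <- tic()
  edges <- deduplicate(kept)
  report$files$edges <- file.path(cfg$output_dir, "edges.tsv")
  write_edges(edges, report$files$edges)
  network <- build_network(edges)
  hubs <- find_hubs(network, "gene", cfg$hub_threshold)
  report$files$hubs <- file.path(cfg$output_dir, "hubs.tsv")
  readr::write_tsv(hubs, report$files$hubs, progress = FALSE)
  for (side in c("gene", "mirna")) {
    da <- degree_abundance(network, side)
    f <- file.path(cfg$output_dir, sprintf("degree_abundance_%s.tsv", side))
    readr::write_tsv(as_tibble(da), f, progress = FALSE)
    report$files[[paste0("degree_abundance_", side)]] <- f
  }
  report$stages$network <- list(
    edges = nrow(edges),
    mirna_nodes = nrow(network$mirna_degree),
    gene_nodes = nrow(network$gene_degree),
    hubs = nrow(hubs), hub_threshold = cfg$hub_threshold
  )
  timing$network <- tic() - t0

  # -- abundance model selection -------------------------------------------
  t0 <- tic()
  fits <- list()
  for (side in c("gene", "mirna")) {
    deg <- .network_side(network, side)$degree
    sel <- tryCatch(select_abundance_model(deg, cfg$models),
                    error = function(e) conditionMessage(e))
    if (is.character(sel)) {
      fits[[side]] <- list(error = sel)
    } else {
      f <- file.path(cfg$output_dir, sprintf("model_selection_%s.tsv", side))
      readr::write_tsv(sel$fits, f, progress = FALSE)
      report$files[[paste0("model_selection_", side)]] <- f
      fits[[side]] <- list(best = sel$best,
                           aic = as.list(setNames(sel$fits$aic, sel$fits$model)))
    }
  }
  report$stages$fit <- fits
  timing$fit <- tic() - t0

  # -- mutual information ---------------------------------------------------
  if (!is.null(cfg$inputs$tf_table)) {
    t0 <- tic()
    tf <- readr::read_tsv(cfg$inputs$tf_table,
                          col_types = readr::cols(
                            tf_id = readr::col_character(),
                            .default = readr::col_double()),
                          progress = FALSE)
    tf <- filter(tf, .data$n_mirna_regulators > 0, .data$n_regulated_genes > 0)
    mi <- resample_mi(tf$n_mirna_regulators, tf$n_regulated_genes,
                      bins_x = cfg$mi$bins, bins_y = cfg$mi$bins,
                      n_boot = cfg$mi$n_boot, n_perm = cfg$mi$n_perm,
                      seed = .sub_seed(cfg$seed, 20))
    report$files$mi <- file.path(cfg$output_dir, "mi_result.json")
    jsonlite::write_json(as.list(glance(mi)), report$files$mi,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$stages$mi <- list(mi_nats = mi$mi_nats, rmi = mi$rmi,
                             p_perm = mi$p_perm, n = mi$n)
    timing$mi <- tic() - t0
  }

  # -- enrichment ----------------------------------------------------------
  t0 <- tic()
  ann <- if (!is.null(cfg$inputs$annotations)) {
    read_annotations(cfg$inputs$annotations)
  } else if (!is.null(truth) && nrow(hubs) > 0) {
    plant_enrichment(genes = sort(unique(truth$edges$gene_id)),
                     hubs = hubs$id,
                     n_terms = truth$config$n_terms,
                     planted_term_odds = truth$config$planted_term_odds,
                     seed = .sub_seed(cfg$seed, 21))$annotations
  } else NULL
  if (!is.null(ann) && nrow(hubs) > 0) {
    universe <- sort(unique(network$gene_degree$id))
    enr <- enrich(hubs$id, universe, ann, alpha = cfg$enrich_alpha)
    report$files$enrichment <- file.path(cfg$output_dir, "enrichment.tsv")
    readr::write_tsv(enr, report$files$enrichment, progress = FALSE)
    report$stages$enrichment <- list(terms_tested = nrow(enr),
                                     significant = sum(enr$significant),
                                     alpha = cfg$enrich_alpha)
    timing$enrichment <- tic() - t0
  }

  # -- target overlap of the top miRNAs ------------------------------------
  if (cfg$overlap_top >= 2 && nrow(network$mirna_degree) >= cfg$overlap_top) {
    t0 <- tic()
    top <- network$mirna_degree |>
      arrange(dplyr::desc(.data$degree), .data$id) |>
      head(cfg$overlap_top)
    ov <- target_overlap(network, top$id, mode = "pairwise")
    ov_out <- mutate(ov, common = vapply(.data$common, paste, character(1),
                                         collapse = ","))
    report$files$overlap <- file.path(cfg$output_dir, "target_overlap.tsv")
    readr::write_tsv(ov_out, report$files$overlap, progress = FALSE)
    report$stages$overlap <- list(mirnas = top$id, pairs = nrow(ov))
    timing$overlap <- tic() - t0
  }

  # -- UTR correlations ----------------------------------------------------
  if (!is.null(cfg$inputs$utr_table)) {
    t0 <- tic()
    utr <- readr::read_tsv(cfg$inputs$utr_table,
                           col_types = readr::cols(
                             gene_id = readr::col_character(),
                             .default = readr::col_double()),
                           progress = FALSE)
    ct <- correlation_table(utr)
    report$files$utr_correlations <- file.path(cfg$output_dir, "utr_correlations.tsv")
    readr::write_tsv(as_tibble(ct), report$files$utr_correlations, progress = FALSE)
    key <- function(a, b) ct$r[ct$var1 == a & ct$var2 == b]
    report$stages$utr <- list(r_utr_pred_A = key("utr3_length", "n_pred_A"),
                              r_utr_pred_B = key("utr3_length", "n_pred_B"),
                              r_utr_verified = key("utr3_length", "n_verified"))
    timing$utr <- tic() - t0
  }

  report$timing <- timing
  report_path <- file.path(cfg$output_dir, "run_report.json")
  jsonlite::write_json(report[c("seed", "stages", "files", "config")],
                       report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  report$files$run_report <- report_path
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %s: %s\n", s,
                paste(names(x$stages[[s]]),
                      vapply(x$stages[[s]], function(v) paste(format(unlist(v)), collapse = "/"),
                             character(1)),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}
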