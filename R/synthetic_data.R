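# Seeded generators for every pipeline input, with known ground truth.
#
# The generators emulate the statistical structure of curated
# miRNA-target data: heavy-tailed bipartite degree structure, records
# spread over four source dialects with mixed evidence quality,
# duplicated and aliased entries, a term enriched in hub genes, a
# dependence between TF miRNA-in-degree and regulon size, and a
# correlation between 3'UTR length and predicted (but not verified)
# interactor counts. Every generator is a pure function of its seed.

# Derive a per-stage sub-seed from one top-level seed (kept < 2^31).
.sub_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 10007) %% 2147483647
}

#' Configuration for the synthetic dataset
#'
#' Defaults mirror the scale and structure of the curated human network
#' this package models: 962 miRNAs regulating 3842 genes, a zeta
#' (discrete power-law) miRNA degree distribution, hub genes defined by
#' more than 20 regulators, and a fifth of the raw records carrying only
#' weak or high-throughput evidence.
#'
#' @param n_mirna,n_gene Node counts per side.
#' @param alpha_mirna Zeta exponent of the miRNA degree distribution (> 1).
#' @param gene_weight_alpha Pareto exponent of per-gene attractiveness
#'   weights; induces a heavy-tailed gene degree distribution (> 1).
#' @param noise_edge_fraction Fraction of edges supported only by
#'   rejected-method or high-throughput records, in \[0, 1).
#' @param dup_rate Expected extra duplicate records per record (>= 0).
#' @param alias_rate Fraction of genes written under alias identifiers,
#'   in \[0, 1).
#' @param n_terms Number of annotation terms.
#' @param planted_term_odds Odds ratio of the planted term in hubs vs
#'   non-hubs.
#' @param mi_link_strength Dependence of TF regulon size on miRNA
#'   in-degree; 0 gives independence.
#' @param utr_rho_pred,utr_rho_verified Copula correlations between 3'UTR
#'   length and predicted / verified interactor counts, in (-1, 1).
#' @param seed Integer seed (mandatory); all randomness derives from it.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(n_mirna = 962, n_gene = 3842,
                         alpha_mirna = 2.2, gene_weight_alpha = 2.0,
                         noise_edge_fraction = 0.2,
                         dup_rate = 0.1, alias_rate = 0.1,
                         n_terms = 50, planted_term_odds = 5,
                         mi_link_strength = 1.5,
                         utr_rho_pred = 0.7, utr_rho_verified = 0.3,
                         seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(alpha_mirna > 1, gene_weight_alpha > 1,
            noise_edge_fraction >= 0, noise_edge_fraction < 1,
            dup_rate >= 0, alias_rate >= 0, alias_rate < 1,
            abs(utr_rho_pred) < 1, abs(utr_rho_verified) < 1,
            mi_link_strength >= 0)
  structure(
    list(n_mirna = n_mirna, n_gene = n_gene, alpha_mirna = alpha_mirna,
         gene_weight_alpha = gene_weight_alpha,
         noise_edge_fraction = noise_edge_fraction,
         dup_rate = dup_rate, alias_rate = alias_rate,
         n_terms = n_terms, planted_term_odds = planted_term_odds,
         mi_link_strength = mi_link_strength,
         utr_rho_pred = utr_rho_pred, utr_rho_verified = utr_rho_verified,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Sample degrees from a truncated zeta distribution
#'
#' Inverse-CDF sampling over the probability mass x^(-alpha) (x = 1..d_max,
#' renormalised after truncation). Truncation is applied only here, for
#' simulation; likelihood evaluation elsewhere uses the full support.
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param d_max Truncation point (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of degrees in 1..d_max.
#' @export
sample_zeta_degrees <- function(n, alpha, d_max = 10000, seed) {
  if (alpha <= 1) abort("alpha must be > 1")
  if (d_max < 1) abort("d_max must be >= 1")
  if (missing(seed)) abort("seed is mandatory")
  pmf <- (1:d_max)^(-alpha)
  cdf <- cumsum(pmf / sum(pmf))
  withr::with_seed(seed, {
    u <- runif(n)
    findInterval(u, cdf) + 1L
  })
}

#' Build the ground-truth bipartite network
#'
#' Each miRNA receives a zeta-distributed degree and selects that many
#' partner genes without replacement, with probability proportional to
#' Pareto-distributed per-gene weights — which induces a heavy-tailed
#' (right-skewed) gene degree distribution. A `noise_edge_fraction` of
#' edges is labelled `"noise"`; the rest are `"gold"`.
#'
#' @param config A [synth_config()].
#' @return List of class `"synth_truth"`: `edges` tibble (`mirna_id`,
#'   `gene_id`, `label`), `config`.
#' @export
build_true_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  mirnas <- sprintf("hsa-miR-SIM-%d", seq_len(config$n_mirna))
  genes <- sprintf("GENESIM%d", seq_len(config$n_gene))

  degrees <- sample_zeta_degrees(config$n_mirna, config$alpha_mirna,
                                 d_max = min(config$n_gene, 10000),
                                 seed = .sub_seed(config$seed, 1))
  capped <- degrees > config$n_gene
  if (any(capped)) {
    warn(sprintf("%d miRNA degree(s) capped at n_gene", sum(capped)))
    degrees[capped] <- config$n_gene
  }

  edges <- withr::with_seed(.sub_seed(config$seed, 2), {
    u <- runif(config$n_gene)
    w <- u^(-1 / (config$gene_weight_alpha - 1)) # Pareto(1) weights
    partner <- lapply(seq_len(config$n_mirna), function(i) {
      sample.int(config$n_gene, degrees[i], replace = FALSE, prob = w)
    })
    tibble(
      mirna_id = rep(mirnas, degrees),
      gene_id = genes[unlist(partner)]
    )
  })
  n_edges <- nrow(edges)
  labels <- withr::with_seed(.sub_seed(config$seed, 3), {
    lab <- rep("gold", n_edges)
    n_noise <- round(config$noise_edge_fraction * n_edges)
    if (n_noise > 0) lab[sample.int(n_edges, n_noise)] <- "noise"
    lab
  })
  edges$label <- labels
  edges <- arrange(edges, .data$mirna_id, .data$gene_id)
  structure(list(edges = edges, config = config), class = "synth_truth")
}

#' Write the synthetic dataset in all four source dialects
#'
#' Gold edges are spread across the four dialects and receive at least
#' one record with an accepted direct-binding method (luciferase reporter
#' or RNA-IP, low throughput). Noise edges are written only to the
#' filterable dialects (mirtarbase, rnainter) with either weak low-
#' throughput evidence (qPCR / western blot) or high-throughput assays
#' (CLIP-seq / microarray), so the evidence filter must remove them all.
#' `dup_rate` adds duplicate records; `alias_rate` writes a fraction of
#' genes under alias identifiers together with the matching ID-mapping
#' file (each aliased gene also gets one extra record under its canonical
#' name, so deduplication without the mapping over-counts edges).
#'
#' @param truth A [build_true_network()] result.
#' @param dir Output directory (created if needed).
#' @return List of class `"synth_dataset"` with file paths (`mitab`,
#'   `mirtarbase`, `rnainter`, `annotation_export`, `id_mapping`,
#'   `manifest`) and the `manifest` list itself.
#' @export
emit_records <- function(truth, dir) {
  stopifnot(inherits(truth, "synth_truth"))
  config <- truth$config
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- truth$edges
  n <- nrow(edges)

  rec <- withr::with_seed(.sub_seed(config$seed, 4), {
    gold <- edges$label == "gold"
    source_db <- character(n)
    source_db[gold] <- sample(.record_dialects, sum(gold), replace = TRUE)
    source_db[!gold] <- sample(c("mirtarbase", "rnainter"), sum(!gold),
                               replace = TRUE)

    methods <- vector("list", n)
    throughput <- character(n)
    acc <- sample(c("luciferase_reporter", "rna_ip"), n, replace = TRUE)
    weak_low <- sample(c("qpcr", "western_blot"), n, replace = TRUE)
    ht <- sample(c("clip_seq", "microarray"), n, replace = TRUE)
    noise_is_ht <- runif(n) < 0.5
    for (i in seq_len(n)) {
      if (gold[i]) {
        methods[[i]] <- acc[i]
        throughput[i] <- "low"
      } else if (noise_is_ht[i]) {
        methods[[i]] <- ht[i]
        throughput[i] <- "high"
      } else {
        methods[[i]] <- weak_low[i]
        throughput[i] <- "low"
      }
    }
    base <- tibble(
      source_db = source_db,
      mirna_id = edges$mirna_id,
      target_id = edges$gene_id,
      taxon = 9606L,
      methods = methods,
      throughput = throughput,
      pubmed_id = as.character(sample.int(9999999L, n, replace = TRUE)),
      score = round(runif(n), 3)
    )

    # duplicates: each record duplicated with probability dup_rate
    if (config$dup_rate > 0) {
      dup_idx <- which(runif(n) < config$dup_rate)
      base <- bind_rows(base, base[dup_idx, , drop = FALSE])
    }

    # aliases: a fraction of genes are written under an alias everywhere;
    # each aliased gene additionally re-emits its first record under the
    # canonical id so the alias split is observable without the mapping
    genes_all <- unique(edges$gene_id)
    n_alias <- round(config$alias_rate * length(genes_all))
    aliased <- sort(sample(genes_all, n_alias))
    mapping <- tibble(alias = paste0("ALS:", aliased), canonical = aliased)
    extra <- base[match(aliased[aliased %in% base$target_id], base$target_id), ,
                  drop = FALSE]
    is_aliased <- base$target_id %in% aliased
    base$target_id[is_aliased] <- paste0("ALS:", base$target_id[is_aliased])
    base <- bind_rows(base, extra)
    list(records = base, mapping = mapping)
  })

  paths <- list(
    mitab = file.path(dir, "mitab.tsv"),
    mirtarbase = file.path(dir, "mirtarbase.tsv"),
    rnainter = file.path(dir, "rnainter.tsv"),
    annotation_export = file.path(dir, "annotation_export.tsv"),
    id_mapping = file.path(dir, "id_mapping.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  for (d in .record_dialects) {
    write_interactions(filter(rec$records, .data$source_db == d), paths[[d]], d)
  }
  readr::write_tsv(rec$mapping, paths$id_mapping, progress = FALSE)

  manifest <- list(
    edges = as.data.frame(edges),
    n_records = nrow(rec$records),
    n_aliased_genes = nrow(rec$mapping),
    config = unclass(config),
    seed = config$seed
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(c(paths, list(manifest_data = manifest)), class = "synth_dataset")
}

#' Plant a term enrichment among hub genes
#'
#' One designated term (`T0001`) annotates hub genes with the configured
#' odds ratio relative to non-hubs; the remaining terms annotate genes
#' uniformly at random. Used to validate over-representation recovery.
#'
#' @param genes Character vector of all genes (the universe).
#' @param hubs Character vector of hub genes (non-empty subset).
#' @param n_terms Total number of terms (>= 1).
#' @param planted_term_odds Odds ratio for the planted term (hubs vs
#'   non-hubs); 1 plants nothing.
#' @param seed Integer seed.
#' @param base_rate Annotation probability of the planted term in
#'   non-hubs.
#' @param background_rate Annotation probability of every other term.
#' @return List: `annotations` tibble (`gene_id`, `term_id`),
#'   `planted_term` (`"T0001"`).
#' @export
plant_enrichment <- function(genes, hubs, n_terms = 50, planted_term_odds = 5,
                             seed, base_rate = 0.1, background_rate = 0.05) {
  if (length(hubs) == 0) abort("empty hub set")
  if (!all(hubs %in% genes)) abort("hubs must be a subset of genes")
  if (missing(seed)) abort("seed is mandatory")
  odds0 <- base_rate / (1 - base_rate)
  odds1 <- planted_term_odds * odds0
  p_hub <- odds1 / (1 + odds1)

  ann <- withr::with_seed(seed, {
    is_hub <- genes %in% hubs
    p_planted <- ifelse(is_hub, p_hub, base_rate)
    planted <- tibble(gene_id = genes[runif(length(genes)) < p_planted],
                      term_id = "T0001")
    others <- purrr::map_dfr(seq_len(max(n_terms - 1, 0)), function(t) {
      tibble(gene_id = genes[runif(length(genes)) < background_rate],
             term_id = sprintf("T%04d", t + 1))
    })
    bind_rows(planted, others)
  })
  list(annotations = distinct(ann, .data$gene_id, .data$term_id),
       planted_term = "T0001")
}

#' Simulate a transcription-factor pair table
#'
#' For each TF, the number of miRNA regulators is drawn from the zeta
#' sampler and the regulon size from a Poisson whose log-mean increases
#' with `mi_link_strength * log(1 + x)` (centred); strength 0 yields
#' exact independence. This is the input for the cross-talk mutual
#' information analysis.
#'
#' @param n_tf Number of transcription factors.
#' @param mi_link_strength Dependence strength (>= 0).
#' @param seed Integer seed.
#' @param alpha Zeta exponent for the miRNA in-degree.
#' @param d_max Truncation for the zeta sampler.
#' @param base_regulon Median regulon size at the centred baseline.
#' @return Tibble: `tf_id`, `n_mirna_regulators`, `n_regulated_genes`.
#' @export
plant_tf_table <- function(n_tf = 300, mi_link_strength = 1.5, seed,
                           alpha = 2.2, d_max = 100, base_regulon = 10) {
  if (missing(seed)) abort("seed is mandatory")
  x <- sample_zeta_degrees(n_tf, alpha, d_max = d_max,
                           seed = .sub_seed(seed, 1))
  y <- withr::with_seed(.sub_seed(seed, 2), {
    lx <- log1p(x)
    lambda <- base_regulon * exp(mi_link_strength * (lx - mean(lx)))
    rpois(n_tf, lambda)
  })
  tibble(tf_id = sprintf("TFSIM%d", seq_len(n_tf)),
         n_mirna_regulators = x, n_regulated_genes = y)
}

#' Simulate the 3'UTR length / interactor-count table
#'
#' Gaussian copula: a latent UTR factor drives the predicted-site counts
#' of two prediction tools with correlation `rho_pred` and the verified
#' interactor count with correlation `rho_verified`. Marginals are mapped
#' to realistic positive scales (log-normal UTR and transcript lengths,
#' Poisson counts).
#'
#' @param n_genes Number of rows.
#' @param rho_pred,rho_verified Latent correlations in (-1, 1).
#' @param seed Integer seed.
#' @return Tibble: `gene_id`, `utr3_length`, `transcript_length`,
#'   `n_verified`, `n_pred_A`, `n_pred_B`.
#' @export
plant_utr_table <- function(n_genes = 500, rho_pred = 0.7,
                            rho_verified = 0.3, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(abs(rho_pred) < 1, abs(rho_verified) < 1)
  withr::with_seed(seed, {
    z_u <- rnorm(n_genes)
    mix <- function(rho) rho * z_u + sqrt(1 - rho^2) * rnorm(n_genes)
    utr3 <- round(qlnorm(pnorm(z_u), meanlog = log(1200), sdlog = 0.4))
    cds <- round(qlnorm(pnorm(rnorm(n_genes)), meanlog = log(2000), sdlog = 0.4))
    tibble(
      gene_id = sprintf("GENESIM%d", seq_len(n_genes)),
      utr3_length = utr3,
      transcript_length = utr3 + cds,
      n_verified = qpois(pnorm(mix(rho_verified)), lambda = 4),
      n_pred_A = qpois(pnorm(mix(rho_pred)), lambda = 40),
      n_pred_B = qpois(pnorm(mix(rho_pred)), lambda = 60)
    )
  })
}
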