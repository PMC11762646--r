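# Hypergeometric over-representation of annotation terms among hub genes.

#' Upper hypergeometric tail P(X >= k)
#'
#' Probability of drawing at least `k` annotated genes when sampling `n`
#' genes without replacement from a universe of `N` genes of which `K`
#' carry the annotation. Evaluated in log space via the stable
#' distribution-function routine, so extreme tails do not underflow.
#'
#' @param k Observed annotated genes in the sample (0 <= k <= min(K, n)).
#' @param K Annotated genes in the universe.
#' @param n Sample (gene set) size.
#' @param N Universe size.
#' @return P(X >= k) in (0, 1].
#' @export
#' @examples
#' hypergeom_tail(4, K = 5, n = 4, N = 10) # 5/210
hypergeom_tail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0) abort("all arguments must be >= 0")
  if (K > N || n > N) abort("K and n must not exceed N")
  if (k > min(K, n)) abort("k must not exceed min(K, n)")
  if (k == 0) return(1)
  # P(X >= k) = 1 - P(X <= k - 1), computed from the upper tail directly
  exp(phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in the input order
#' and capped at 1.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1)) abort("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Read a gene-term annotation table
#'
#' Two-column TSV (`gene_id`, `term_id`); duplicate pairs are collapsed.
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with unique (`gene_id`, `term_id`) rows.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  .require_cols(ann, c("gene_id", "term_id"), "annotations")
  distinct(ann, .data$gene_id, .data$term_id)
}

# Transitive closure of each gene's term set under a child -> parent map.
.propagate_terms <- function(annotations, parents) {
  if (is.null(parents) || nrow(parents) == 0) return(annotations)
  .require_cols(parents, c("term_id", "parent_id"), "parent map")
  ann <- annotations
  repeat {
    up <- ann |>
      dplyr::inner_join(parents, by = "term_id",
                        relationship = "many-to-many") |>
      select(gene_id = "gene_id", term_id = "parent_id")
    new_ann <- distinct(bind_rows(ann, up), .data$gene_id, .data$term_id)
    if (nrow(new_ann) == nrow(ann)) return(new_ann)
    ann <- new_ann
  }
}

#' Term over-representation in a gene set
#'
#' For every annotation term with at least one universe gene, tests
#' whether the gene set contains more genes annotated to the term than
#' expected under hypergeometric sampling from the universe (the
#' "whole genome" benchmark). Raw p-values are BH-adjusted; either the
#' raw threshold (`alpha`, default 5e-4, the conventional strict cut for
#' this analysis) or the FDR can drive the `significant` flag.
#'
#' @param gene_set Character vector of genes of interest (e.g. hubs).
#'   Genes outside the universe are dropped with a warning.
#' @param universe Character vector of all genes (the benchmark).
#' @param annotations Tibble with columns `gene_id`, `term_id`.
#' @param alpha Significance threshold.
#' @param propagate If `TRUE`, close each gene's terms under the parent
#'   map before counting.
#' @param parents Optional tibble (`term_id`, `parent_id`).
#' @param significance `"raw"` flags `p < alpha`; `"fdr"` flags `q < alpha`.
#' @return Tibble sorted by increasing p with columns `term_id`, `k`, `K`,
#'   `n`, `N`, `p`, `q`, `significant`.
#' @export
enrich <- function(gene_set, universe, annotations, alpha = 5e-4,
                   propagate = FALSE, parents = NULL,
                   significance = c("raw", "fdr")) {
  significance <- match.arg(significance)
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d gene(s) outside the universe dropped from the gene set",
                 length(outside)))
    gene_set <- setdiff(gene_set, outside)
  }
  ann <- distinct(as_tibble(annotations), .data$gene_id, .data$term_id) |>
    filter(.data$gene_id %in% universe)
  if (propagate) ann <- .propagate_terms(ann, parents)

  n <- length(gene_set)
  N <- length(universe)
  per_term <- ann |>
    group_by(term_id = .data$term_id) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% gene_set),
              .groups = "drop")
  if (nrow(per_term) == 0) {
    return(tibble(term_id = character(0), k = integer(0), K = integer(0),
                  n = integer(0), N = integer(0), p = numeric(0),
                  q = numeric(0), significant = logical(0)))
  }
  p <- vapply(seq_len(nrow(per_term)), function(i) {
    hypergeom_tail(per_term$k[i], per_term$K[i], n, N)
  }, numeric(1))
  out <- per_term |>
    mutate(n = n, N = N, p = p, q = bh_adjust(p)) |>
    mutate(significant = if (significance == "raw") .data$p < alpha
           else .data$q < alpha) |>
    select("term_id", "k", "K", "n", "N", "p", "q", "significant") |>
    arrange(.data$p, .data$term_id)
  out
}
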