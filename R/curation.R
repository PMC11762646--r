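# Evidence filtering to the "gold standard" and collapse to unique edges.

#' Evidence-filter policy
#'
#' Encodes the curation rule used to keep only interactions demonstrated by
#' direct-binding, low-throughput experiments. By default, luciferase
#' reporter assays and RNA immunoprecipitation are accepted as proof of
#' physical binding, while western blot and qPCR alone are not (they can
#' reflect an indirect effect); IMEx-style sources (MITAB and annotation
#' exports) are treated as already curated and pass through.
#'
#' @param accepted_methods Methods sufficient on their own to keep a record.
#' @param rejected_methods Methods that are insufficient on their own. A
#'   record carrying both an accepted and a rejected method is kept: the
#'   rejected set describes weak evidence, not disqualifiers.
#' @param require_low_throughput If `TRUE` (default) non-IMEx records must
#'   be low-throughput; `unknown` throughput is treated as high.
#' @param imex_passthrough If `TRUE` (default) records with
#'   `source_db` of `"mitab"` or `"annotation_export"` bypass the method test.
#' @return A list of class `"filter_policy"`.
#' @export
filter_policy <- function(accepted_methods = c("luciferase_reporter", "rna_ip"),
                          rejected_methods = c("western_blot", "qpcr"),
                          require_low_throughput = TRUE,
                          imex_passthrough = TRUE) {
  if (length(intersect(accepted_methods, rejected_methods)) > 0) {
    abort("accepted_methods and rejected_methods must be disjoint")
  }
  structure(
    list(accepted_methods = accepted_methods,
         rejected_methods = rejected_methods,
         require_low_throughput = isTRUE(require_low_throughput),
         imex_passthrough = isTRUE(imex_passthrough)),
    class = "filter_policy"
  )
}

#' Apply the gold-standard evidence filter
#'
#' A record is kept iff it comes from an IMEx-style source (when
#' `imex_passthrough` is on), or it is low-throughput and carries at least
#' one accepted method. Removed records carry a reason:
#' `"high_throughput"` when the throughput test fails (including `unknown`
#' throughput), otherwise `"no_direct_binding_evidence"`. Retrieve them
#' with [rejected_records()].
#'
#' @param records Record tibble (parsed, species-checked, canonicalised).
#' @param policy A [filter_policy()].
#' @return The kept records, with the removed rows (plus `reason`) attached
#'   as the `"rejected"` attribute.
#' @export
filter_evidence <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(records)
  passthrough <- policy$imex_passthrough &
    records$source_db %in% c("mitab", "annotation_export")
  low <- if (policy$require_low_throughput) records$throughput == "low" else rep(TRUE, n)
  has_accepted <- vapply(records$methods, function(m) {
    any(m %in% policy$accepted_methods)
  }, logical(1))

  keep <- passthrough | (low & has_accepted)
  reason <- rep(NA_character_, n)
  reason[!keep & !low] <- "high_throughput"
  reason[!keep & low] <- "no_direct_binding_evidence"

  kept <- records[keep, , drop = FALSE]
  removed <- records[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  attr(kept, "rejected") <- removed
  kept
}

#' Collapse records to a unique edge list
#'
#' One edge per distinct (miRNA, gene) pair, aggregating the number of
#' supporting records and their provenance. Output is sorted
#' lexicographically by `(mirna_id, gene_id)` so that equal inputs in any
#' order produce byte-identical edge lists.
#'
#' @param records Record tibble with canonical identifiers.
#' @return Tibble with columns `mirna_id`, `gene_id`,
#'   `n_supporting_records`, `sources` (list-column of source databases),
#'   `pubmed_ids` (list-column).
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(mirna_id = character(0), gene_id = character(0),
                  n_supporting_records = integer(0),
                  sources = list(), pubmed_ids = list()))
  }
  records |>
    group_by(mirna_id = .data$mirna_id, gene_id = .data$target_id) |>
    summarise(
      n_supporting_records = dplyr::n(),
      sources = list(sort(unique(.data$source_db))),
      pubmed_ids = list(sort(unique(.data$pubmed_id[nzchar(.data$pubmed_id)]))),
      .groups = "drop"
    ) |>
    arrange(.data$mirna_id, .data$gene_id)
}

#' Write / read the central edge-list artifact
#'
#' The deduplicated edge list is the pipeline's central artifact, stored as
#' TSV with provenance sets comma-joined.
#'
#' @param edges Edge tibble from [deduplicate()].
#' @param path Output TSV path.
#' @return `path` invisibly (writer); edge tibble (reader).
#' @export
write_edges <- function(edges, path) {
  out <- tibble(
    mirna_id = edges$mirna_id,
    gene_id = edges$gene_id,
    n_supporting_records = edges$n_supporting_records,
    sources = vapply(edges$sources, paste, character(1), collapse = ","),
    pubmed_ids = vapply(edges$pubmed_ids, paste, character(1), collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), gene_id = readr::col_character(),
    n_supporting_records = readr::col_integer(),
    sources = readr::col_character(), pubmed_ids = readr::col_character()
  ), progress = FALSE)
  split_col <- function(x) {
    lapply(x, function(v) if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ",")[[1]])
  }
  raw |>
    mutate(sources = split_col(.data$sources),
           pubmed_ids = split_col(.data$pubmed_ids))
}
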