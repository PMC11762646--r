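# Readers for the four interaction-record dialects and identifier mapping.
#
# A parsed record set is a tibble with one row per accepted record and the
# columns: source_db, mirna_id, target_id, taxon, methods (list-column of
# vocabulary labels), throughput, pubmed_id, score. Rows that fail
# validation are never silently dropped: they are attached as the
# "rejected" attribute (with a reason column) and retrievable with
# rejected_records().

.record_dialects <- c("mitab", "mirtarbase", "rnainter", "annotation_export")

.mirtarbase_cols <- c("mirna", "species_mirna", "target_gene", "species_target",
                      "experiments", "support_type", "pmid")
.rnainter_cols <- c("id1", "id2", "category1", "category2", "species1",
                    "species2", "method", "score", "pmid", "throughput")
.annotation_cols <- c("mirna", "target", "taxon", "evidence_code", "reference")

# Taxon fields come in three shapes across dialects: bare integers,
# organism names, and MITAB "taxid:9606(Homo sapiens)" tokens.
.parse_taxon <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_integer_)
    v <- trimws(as.character(v))
    if (grepl("^taxid:", v, ignore.case = TRUE)) {
      v <- sub("^taxid:\\s*(-?[0-9]+).*$", "\\1", v, ignore.case = TRUE)
    }
    if (grepl("^-?[0-9]+$", v)) return(as.integer(v))
    name_table <- c("homo sapiens" = 9606L, "human" = 9606L,
                    "homo sapiens (human)" = 9606L,
                    "mus musculus" = 10090L, "mouse" = 10090L,
                    "rattus norvegicus" = 10116L, "rat" = 10116L,
                    "danio rerio" = 7955L,
                    "drosophila melanogaster" = 7227L,
                    "caenorhabditis elegans" = 6239L)
    taxon <- name_table[tolower(v)]
    if (!is.na(taxon)) return(unname(taxon))
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

.strip_db_prefix <- function(x) {
  ifelse(is.na(x), "", sub("^[A-Za-z0-9._-]+:", "", trimws(x)))
}

# MITAB detection-method column, e.g. psi-mi:"MI:0096"(pull down) -> pull down
.mitab_method_text <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    m <- regmatches(v, regexpr("\\(([^)]*)\\)", v))
    if (length(m) == 1 && nzchar(m)) sub("^\\((.*)\\)$", "\\1", m) else v
  }, character(1), USE.NAMES = FALSE)
}

.new_record_tibble <- function(source_db, mirna_id, target_id, taxon_a, taxon_b,
                               methods, throughput, pubmed_id, score) {
  blank_na <- function(x) ifelse(is.na(x), "", trimws(x))
  tibble(
    source_db = source_db,
    mirna_id = blank_na(mirna_id),
    target_id = blank_na(target_id),
    taxon_a = taxon_a,
    taxon_b = taxon_b,
    methods = methods,
    throughput = throughput,
    pubmed_id = ifelse(is.na(pubmed_id), "", trimws(as.character(pubmed_id))),
    score = as.numeric(score)
  )
}

# Shared validation: species and identifier checks, in the order the
# reasons are reported. Returns the accepted set with the rejected rows
# (plus reasons) attached as an attribute.
.validate_records <- function(rec) {
  reason <- rep(NA_character_, nrow(rec))
  n_methods <- lengths(rec$methods)
  reason[!nzchar(rec$mirna_id)] <- "empty mirna_id"
  reason[is.na(reason) & !nzchar(rec$target_id)] <- "empty target_id"
  reason[is.na(reason) & n_methods == 0] <- "no_evidence_method"
  bad_tax <- is.na(rec$taxon_a) | rec$taxon_a <= 0
  reason[is.na(reason) & bad_tax] <- "bad_taxon"
  conflict <- !is.na(rec$taxon_b) & rec$taxon_a != rec$taxon_b
  reason[is.na(reason) & conflict] <- "species_conflict"
  reason[is.na(reason) & rec$taxon_a != 9606L] <- "non-human"

  rec$taxon <- rec$taxon_a
  keep_cols <- c("source_db", "mirna_id", "target_id", "taxon", "methods",
                 "throughput", "pubmed_id", "score")
  accepted <- rec[is.na(reason), keep_cols]
  rejected <- rec[!is.na(reason), keep_cols]
  rejected$reason <- reason[!is.na(reason)]
  attr(accepted, "rejected") <- rejected
  accepted
}

.require_cols <- function(df, cols, dialect) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("dialect '%s': missing required column(s): %s",
                  dialect, paste(missing, collapse = ", ")))
  }
}

#' Read interaction records from one source dialect
#'
#' Parses a tab-separated export in one of four dialects (PSI-MITAB 2.7,
#' miRTarBase-style, RNAinter-style, or a GPAD/annotation-style export)
#' into a canonical record tibble. Evidence strings are tokenised on the
#' dialect's separator and normalised to [evidence_vocabulary()]. Rows that
#' fail identifier or species validation (empty IDs, non-human taxa,
#' conflicting interactor species, missing evidence) are diverted to a
#' rejected table with per-row reasons, available via [rejected_records()].
#'
#' Throughput: MITAB and annotation exports are treated as already-curated
#' low-throughput sources. The rnainter dialect carries an explicit
#' `throughput` column; for the mirtarbase dialect throughput is inferred
#' from the evidence tokens (any high-throughput assay label implies
#' `high`, a recognised low-throughput assay implies `low`, otherwise
#' `unknown`).
#'
#' @param path Path to the tab-separated file.
#' @param dialect One of `"mitab"`, `"mirtarbase"`, `"rnainter"`,
#'   `"annotation_export"`.
#' @return A tibble of accepted records with columns `source_db`,
#'   `mirna_id`, `target_id`, `taxon`, `methods` (list-column), `throughput`,
#'   `pubmed_id`, `score`, carrying the rejected rows as an attribute.
#' @seealso [rejected_records()], [map_identifiers()], [filter_evidence()]
#' @export
read_interactions <- function(path, dialect = c("mitab", "mirtarbase",
                                                "rnainter", "annotation_export")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))

  if (dialect == "mitab") {
    raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (nrow(raw) > 0 && ncol(raw) < 15) {
      abort("dialect 'mitab': expected at least 15 tab-separated columns")
    }
    if (nrow(raw) == 0) raw <- tibble(!!!setNames(rep(list(character(0)), 15), paste0("X", 1:15)))
    rec <- .new_record_tibble(
      source_db = rep("mitab", nrow(raw)),
      mirna_id = .strip_db_prefix(raw[[1]]),
      target_id = .strip_db_prefix(raw[[2]]),
      taxon_a = .parse_taxon(raw[[10]]),
      taxon_b = .parse_taxon(raw[[11]]),
      methods = normalize_methods(.mitab_method_text(raw[[7]])),
      throughput = rep("low", nrow(raw)),
      pubmed_id = .strip_db_prefix(raw[[9]]),
      score = rep(NA_real_, nrow(raw))
    )
  } else if (dialect == "mirtarbase") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    .require_cols(raw, .mirtarbase_cols, dialect)
    methods <- normalize_methods(raw$experiments)
    ht_labels <- c("clip_seq", "clash", "microarray", "sequencing")
    lt_labels <- c("luciferase_reporter", "rna_ip", "western_blot", "qpcr")
    throughput <- vapply(methods, function(m) {
      if (any(m %in% ht_labels)) "high"
      else if (any(m %in% lt_labels)) "low"
      else "unknown"
    }, character(1))
    rec <- .new_record_tibble(
      source_db = rep("mirtarbase", nrow(raw)),
      mirna_id = raw$mirna,
      target_id = raw$target_gene,
      taxon_a = .parse_taxon(raw$species_mirna),
      taxon_b = .parse_taxon(raw$species_target),
      methods = methods,
      throughput = throughput,
      pubmed_id = raw$pmid,
      score = rep(NA_real_, nrow(raw))
    )
  } else if (dialect == "rnainter") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    .require_cols(raw, .rnainter_cols, dialect)
    throughput <- tolower(trimws(raw$throughput))
    throughput[!throughput %in% c("low", "high")] <- "unknown"
    rec <- .new_record_tibble(
      source_db = rep("rnainter", nrow(raw)),
      mirna_id = raw$id1,
      target_id = raw$id2,
      taxon_a = .parse_taxon(raw$species1),
      taxon_b = .parse_taxon(raw$species2),
      methods = normalize_methods(raw$method),
      throughput = throughput,
      pubmed_id = raw$pmid,
      score = suppressWarnings(as.numeric(raw$score))
    )
  } else { # annotation_export
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    .require_cols(raw, .annotation_cols, dialect)
    rec <- .new_record_tibble(
      source_db = rep("annotation_export", nrow(raw)),
      mirna_id = raw$mirna,
      target_id = raw$target,
      taxon_a = .parse_taxon(raw$taxon),
      taxon_b = rep(NA_integer_, nrow(raw)),
      methods = normalize_methods(raw$evidence_code),
      throughput = rep("low", nrow(raw)),
      pubmed_id = raw$reference,
      score = rep(NA_real_, nrow(raw))
    )
  }
  .validate_records(rec)
}

#' Rejected rows from a parsing or filtering step
#'
#' @param x A record tibble returned by [read_interactions()] (rejected
#'   rows with reasons) or [filter_evidence()] (removed rows with reasons).
#' @return A tibble with the same record columns plus `reason`; empty if
#'   nothing was rejected.
#' @export
rejected_records <- function(x) {
  rej <- attr(x, "rejected", exact = TRUE)
  if (is.null(rej)) {
    rej <- x[0, , drop = FALSE]
    rej$reason <- character(0)
  }
  rej
}

#' Write interaction records back to a dialect file
#'
#' Serialises a record tibble to the same tab-separated layout that
#' [read_interactions()] parses, so fixtures and synthetic datasets
#' round-trip. Method sets are written as their vocabulary labels joined
#' with the dialect separator.
#'
#' @param records Record tibble (accepted records).
#' @param path Output file path.
#' @param dialect Target dialect; see [read_interactions()].
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path,
                               dialect = c("mitab", "mirtarbase", "rnainter",
                                           "annotation_export")) {
  dialect <- match.arg(dialect)
  meth <- vapply(records$methods, paste, character(1), collapse = "//")
  if (dialect == "mitab") {
    out <- tibble(
      X1 = paste0("mirbase:", records$mirna_id),
      X2 = paste0("genename:", records$target_id),
      X3 = "-", X4 = "-", X5 = "-", X6 = "-",
      X7 = vapply(records$methods, function(m) {
        paste0("psi-mi:\"MI:0000\"(", paste(m, collapse = "|"), ")")
      }, character(1)),
      X8 = "-",
      X9 = ifelse(nzchar(records$pubmed_id), paste0("pubmed:", records$pubmed_id), "-"),
      X10 = paste0("taxid:", records$taxon, "(Homo sapiens)"),
      X11 = paste0("taxid:", records$taxon, "(Homo sapiens)"),
      X12 = "-", X13 = "-", X14 = "-", X15 = "-"
    )
    readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  } else if (dialect == "mirtarbase") {
    out <- tibble(
      mirna = records$mirna_id,
      species_mirna = "Homo sapiens",
      target_gene = records$target_id,
      species_target = "Homo sapiens",
      experiments = meth,
      support_type = "Functional MTI",
      pmid = records$pubmed_id
    )
    readr::write_tsv(out, path, progress = FALSE)
  } else if (dialect == "rnainter") {
    out <- tibble(
      id1 = records$mirna_id, id2 = records$target_id,
      category1 = "miRNA", category2 = "mRNA",
      species1 = records$taxon, species2 = records$taxon,
      method = meth,
      score = ifelse(is.na(records$score), "", as.character(records$score)),
      pmid = records$pubmed_id,
      throughput = records$throughput
    )
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    out <- tibble(
      mirna = records$mirna_id, target = records$target_id,
      taxon = records$taxon,
      evidence_code = meth,
      reference = records$pubmed_id
    )
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Read an identifier-mapping table
#'
#' A two-column tab-separated file (header `alias`, `canonical`) in the
#' style of a UniProt ID-mapping export. Exact duplicate rows are
#' collapsed; the same alias mapping to two different canonical values is
#' a hard parse error.
#'
#' @param path Path to the mapping TSV.
#' @return Tibble with columns `alias`, `canonical`.
#' @export
read_id_mapping <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  map <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  .require_cols(map, c("alias", "canonical"), "id_mapping")
  map <- distinct(map, .data$alias, .data$canonical)
  dup <- map$alias[duplicated(map$alias)]
  if (length(dup) > 0) {
    abort(sprintf("conflicting canonical values for alias(es): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  map
}

#' Canonicalise target identifiers
#'
#' Replaces every `target_id` that appears as an alias in the mapping with
#' its canonical value. A mapping report (counts of mapped / unchanged /
#' unmapped / dropped targets) is attached as the `"mapping_report"`
#' attribute and retrievable with [mapping_report()]. The operation is
#' idempotent: mapping already-canonical records changes nothing.
#'
#' @param records Record tibble from [read_interactions()].
#' @param mapping Tibble with columns `alias`, `canonical`
#'   (see [read_id_mapping()]), or `NULL` for the empty mapping.
#' @param policy `"keep_unmapped"` (default) keeps records whose target is
#'   neither an alias nor a known canonical value; `"drop_unmapped"`
#'   removes them (counted as `dropped` in the report).
#' @return The records tibble with canonical `target_id`s.
#' @export
map_identifiers <- function(records, mapping = NULL,
                            policy = c("keep_unmapped", "drop_unmapped")) {
  policy <- match.arg(policy)
  if (is.null(mapping) || nrow(mapping) == 0) {
    mapping <- tibble(alias = character(0), canonical = character(0))
  }
  if (anyDuplicated(mapping$alias) > 0) {
    abort("mapping has conflicting duplicate aliases; see read_id_mapping()")
  }
  idx <- match(records$target_id, mapping$alias)
  is_alias <- !is.na(idx)
  is_canonical <- !is_alias & records$target_id %in% mapping$canonical
  unmapped <- !is_alias & !is_canonical

  out <- records
  out$target_id[is_alias] <- mapping$canonical[idx[is_alias]]

  dropped <- 0L
  if (policy == "drop_unmapped" && nrow(mapping) > 0) {
    dropped <- sum(unmapped)
    out <- out[!unmapped, , drop = FALSE]
  }
  attr(out, "rejected") <- attr(records, "rejected", exact = TRUE)
  attr(out, "mapping_report") <- tibble(
    mapped = sum(is_alias),
    unchanged = sum(is_canonical),
    unmapped = sum(unmapped) - dropped,
    dropped = dropped
  )
  out
}

#' Report from the last identifier-mapping step
#'
#' @param x Records returned by [map_identifiers()].
#' @return One-row tibble with counts `mapped`, `unchanged`, `unmapped`,
#'   `dropped`.
#' @export
mapping_report <- function(x) {
  rep <- attr(x, "mapping_report", exact = TRUE)
  if (is.null(rep)) {
    rep <- tibble(mapped = 0L, unchanged = 0L, unmapped = 0L, dropped = 0L)
  }
  rep
}
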