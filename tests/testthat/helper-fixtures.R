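# In-code fixture writers for the four record dialects.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

mitab_row <- function(mirna = "hsa-miR-155-5p", target = "PTEN",
                      method = "psi-mi:\"MI:0096\"(pull down)",
                      tax_a = "taxid:9606(Homo sapiens)",
                      tax_b = "taxid:9606(Homo sapiens)",
                      pub = "pubmed:12345") {
  paste(c(paste0("mirbase:", mirna), paste0("genename:", target),
          "-", "-", "-", "-", method, "-", pub, tax_a, tax_b,
          "-", "-", "-", "-"), collapse = "\t")
}

mirtarbase_fixture <- function(rows) {
  write_lines_tmp(
    c("mirna\tspecies_mirna\ttarget_gene\tspecies_target\texperiments\tsupport_type\tpmid",
      rows),
    ext = ".tsv"
  )
}

mirtarbase_row <- function(mirna = "hsa-miR-21-5p", target = "PDCD4",
                           experiments = "Luciferase reporter assay",
                           species = "Homo sapiens", species_t = species,
                           pmid = "111") {
  paste(mirna, species, target, species_t, experiments, "Functional MTI", pmid,
        sep = "\t")
}

rnainter_fixture <- function(rows) {
  write_lines_tmp(
    c("id1\tid2\tcategory1\tcategory2\tspecies1\tspecies2\tmethod\tscore\tpmid\tthroughput",
      rows),
    ext = ".tsv"
  )
}

rnainter_row <- function(mirna = "hsa-miR-34a-5p", target = "BCL2",
                         method = "Luciferase reporter assay",
                         throughput = "low", species1 = "9606",
                         species2 = "9606", score = "0.9", pmid = "222") {
  paste(mirna, target, "miRNA", "mRNA", species1, species2, method, score,
        pmid, throughput, sep = "\t")
}

annotation_fixture <- function(rows) {
  write_lines_tmp(c("mirna\ttarget\ttaxon\tevidence_code\treference", rows),
                  ext = ".tsv")
}

annotation_row <- function(mirna = "hsa-miR-1-3p", target = "HAND2",
                           taxon = "9606", evidence = "ECO:0000314",
                           ref = "PMID:333") {
  paste(mirna, target, taxon, evidence, ref, sep = "\t")
}

mapping_fixture <- function(aliases, canonicals) {
  write_lines_tmp(c("alias\tcanonical", paste(aliases, canonicals, sep = "\t")))
}

# Bare-hands record tibble for unit tests that skip file parsing.
make_records <- function(mirna, target, source = "mirtarbase",
                         methods = list("luciferase_reporter"),
                         throughput = "low", pubmed = "1") {
  n <- length(mirna)
  tibble::tibble(
    source_db = rep_len(source, n),
    mirna_id = mirna,
    target_id = target,
    taxon = rep(9606L, n),
    methods = rep_len(methods, n),
    throughput = rep_len(throughput, n),
    pubmed_id = rep_len(pubmed, n),
    score = rep(NA_real_, n)
  )
}

# Build a network whose gene-side degree multiset is `degrees`, using
# shared miRNA ids so only the gene side is controlled.
network_with_gene_degrees <- function(degrees) {
  edges <- purrr::map_dfr(seq_along(degrees), function(g) {
    tibble::tibble(mirna_id = sprintf("m%03d", seq_len(degrees[g])),
                   gene_id = sprintf("g%03d", g))
  })
  build_network(edges)
}
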