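#' Controlled vocabulary for experimental evidence methods
#'
#' Interaction databases describe the same assay with many spellings
#' ("Luciferase reporter assay", "luciferase assay", "reporter gene assay").
#' All readers normalise free-text evidence strings to this fixed vocabulary
#' so that downstream evidence filtering is deterministic across source
#' dialects. Anything not recognised maps to `"other"`.
#'
#' @return Character vector of the recognised method labels.
#' @export
#' @examples
#' evidence_vocabulary()
evidence_vocabulary <- function() {
  c("luciferase_reporter", "rna_ip", "western_blot", "qpcr",
    "clip_seq", "clash", "microarray", "sequencing", "other")
}

# Ordered synonym patterns; first match wins. CLIP/CLASH are matched before
# RNA-IP so that "PAR-CLIP" or "HITS-CLIP" never hits the bare "ip" patterns.
.method_patterns <- list(
  clash               = "clash",
  clip_seq            = "clip",
  luciferase_reporter = "lucif|reporter",
  rna_ip              = "rna[ -_]?immunoprecip|rna[ -_]?ip\\b|\\brip\\b|immunoprecip|pull[ -]?down",
  western_blot        = "western|immunoblot",
  qpcr                = "q ?rt[ -]?pcr|qpcr|real[ -]?time ?pcr|rt[ -]?qpcr",
  microarray          = "microarray",
  sequencing          = "sequencing|rna[ -]?seq|degradome|ngs"
)

#' Normalise free-text evidence strings to the controlled vocabulary
#'
#' Splits a raw evidence field on the separators used by the supported
#' dialects (`//`, `;`, `|`) and maps every token, case-insensitively, to
#' [evidence_vocabulary()]. Unrecognised non-empty tokens become `"other"`.
#'
#' @param x Character vector of raw evidence fields (one field may hold
#'   several tokens).
#' @return List (same length as `x`) of character vectors of unique
#'   vocabulary labels; an entirely empty field yields `character(0)`.
#' @export
#' @examples
#' normalize_methods("Luciferase reporter assay//Western blot//qRT-PCR")
normalize_methods <- function(x) {
  lapply(x, function(field) {
    if (is.na(field) || !nzchar(trimws(field))) return(character(0))
    tokens <- trimws(strsplit(field, "//|;|\\|")[[1]])
    tokens <- tokens[nzchar(tokens)]
    out <- vapply(tokens, function(tok) {
      low <- tolower(tok)
      for (lab in names(.method_patterns)) {
        if (grepl(.method_patterns[[lab]], low)) return(lab)
      }
      "other"
    }, character(1), USE.NAMES = FALSE)
    sort(unique(out))
  })
}
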