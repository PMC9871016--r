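#' Canonical mitochondrial gene vocabulary
#'
#' The controlled vocabulary used throughout the package: the 13 core
#' protein-coding genes (plus the sponge-specific `ATP9`), the two rRNA
#' genes `rrnS`/`rrnL`, and tRNA genes written `trnX` with the one-letter
#' amino-acid code and an optional isoacceptor qualifier (`trnL1` reads
#' CUN codons, `trnL2` UUR, `trnS1` AGY, `trnS2` UCN).
#'
#' @return Character vector of canonical non-tRNA symbols.
#' @export
canonical_pcg_rrna <- function() {
  c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
    "CYTB", "COX1", "COX2", "COX3", "ATP6", "ATP8", "ATP9",
    "rrnS", "rrnL")
}

#' Is a symbol a tRNA gene?
#'
#' @param symbol Character vector of canonical gene symbols.
#' @return Logical vector.
#' @export
is_trna <- function(symbol) {
  startsWith(symbol, "trn")
}

#' Category of a canonical gene symbol
#'
#' @param symbol Character vector of canonical symbols.
#' @return Character vector over `{"PCG", "rRNA", "tRNA"}`.
#' @export
symbol_category <- function(symbol) {
  ifelse(is_trna(symbol), "tRNA",
         ifelse(symbol %in% c("rrnS", "rrnL"), "rRNA", "PCG"))
}

# Synonym table shipped with the package; raw annotation labels on the
# left, canonical symbols on the right.  Versioned data file so the
# unification step is auditable.
load_synonym_table <- function() {
  path <- system.file("extdata", "gene_synonyms.tsv", package = "mitorder")
  if (!nzchar(path)) {  # during in-source testing without installation
    path <- file.path("inst", "extdata", "gene_synonyms.tsv")
  }
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             comment.char = "#")
}

#' Map raw gene labels to canonical symbols
#'
#' Labels are matched case-insensitively against the shipped synonym
#' table after stripping whitespace and hyphens/underscores.  Unknown
#' labels pass through verbatim with a warning rather than failing: the
#' unification of public annotation labels is open-ended.
#'
#' @param labels Character vector of raw gene labels (e.g. `"COI"`,
#'   `"12S ribosomal RNA"`, `"tRNA-Met"`).
#' @param quiet Suppress the unknown-label warning.
#' @return Character vector of canonical symbols (or the input verbatim
#'   where no mapping exists).
#' @export
canonical_symbol <- function(labels, quiet = FALSE) {
  syn <- load_synonym_table()
  key <- normalize_label(labels)
  idx <- match(key, normalize_label(syn$raw))
  out <- ifelse(is.na(idx), labels, syn$canonical[idx])
  # already-canonical symbols are fine as-is
  known <- !is.na(idx) | out %in% canonical_pcg_rrna() |
    grepl("^trn[A-Z][12]?$", out)
  if (any(!known) && !quiet) {
    warning("unmapped gene label(s) kept verbatim: ",
            paste(unique(labels[!known]), collapse = ", "), call. = FALSE)
  }
  out
}

normalize_label <- function(x) {
  gsub("[ _\\-]", "", toupper(trimws(x)))
}
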