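#' Reference mitochondrial gene-order presets
#'
#' Two 37-gene reference arrangements used throughout the package and
#' its simulators:
#'
#' * `human_like_order()` — the chordate arrangement: all genes on the
#'   forward strand except `ND6` and eight tRNA genes, so the non-tRNA
#'   genes form a single forward block plus a lone reverse gene (not
#'   alternating).
#' * `drosophila_like_order()` — the arthropod arrangement whose
#'   non-tRNA genes form four co-oriented blocks of sizes +7/-3/+2/-3
#'   alternating between strands.
#'
#' @param organism Organism id stored on the returned order.
#' @return A circular [gene_order()].
#' @export
human_like_order <- function(organism = "human_like") {
  parse_order(paste(
    "trnF rrnS trnV rrnL trnL2 ND1 trnI -trnQ trnM ND2 trnW -trnA -trnN",
    "-trnC -trnY COX1 -trnS2 trnD COX2 trnK ATP8 ATP6 COX3 trnG ND3 trnR",
    "ND4L ND4 trnH trnS1 trnL1 ND5 -ND6 -trnE CYTB trnT -trnP"),
    organism = organism, circular = TRUE)
}

#' @rdname human_like_order
#' @export
drosophila_like_order <- function(organism = "drosophila_like") {
  parse_order(paste(
    "trnI -trnQ trnM ND2 trnW -trnC -trnY COX1 trnL2 COX2 trnK trnD ATP8",
    "ATP6 COX3 trnG ND3 trnA trnR trnN trnS1 trnE -trnF -ND5 -trnH -ND4",
    "-ND4L trnT -trnP ND6 CYTB trnS2 -ND1 -trnL1 -rrnL -trnV -rrnS"),
    organism = organism, circular = TRUE)
}
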