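#' Mitochondrial genetic code helpers
#'
#' Thin wrappers around the NCBI genetic-code tables shipped with
#' Biostrings.  `mito_genetic_code()` returns the codon -> amino-acid
#' map (DNA alphabet) for an NCBI table id (e.g. `"2"` vertebrate
#' mitochondrial, `"5"` invertebrate mitochondrial); `start_codons()`
#' returns the admissible initiation codons (ATG plus the table's
#' alternative initiators).
#'
#' @param table_id NCBI genetic-code table id as a string.
#' @return Named character vector (codon -> amino acid) or character
#'   vector of start codons.
#' @export
mito_genetic_code <- function(table_id = "2") {
  code <- Biostrings::getGeneticCode(table_id, as.data.frame = FALSE)
  setNames(as.character(code), chartr("U", "T", names(code)))
}

#' @rdname mito_genetic_code
#' @export
start_codons <- function(table_id = "2") {
  code <- Biostrings::getGeneticCode(table_id)
  alt <- attr(code, "alt_init_codons")
  met <- names(code)[code == "M"]  # ATA is a Met initiator in table 2
  unique(chartr("U", "T", c(met, alt)))
}

#' Validate a coding sequence and extract its codons
#'
#' A CDS is accepted when a valid start codon (for the taxon's
#' mitochondrial translation table) opens the reading frame and a STOP
#' codon terminates it.  Mitochondrial STOP codons are frequently
#' completed post-transcriptionally by polyadenylation, so up to two
#' `A` bases are appended to the 3' end if that completes a STOP.
#' Sequences that still lack a terminal STOP are rejected.
#'
#' @param sequence A DNA string (character scalar).
#' @param table_id NCBI genetic-code table id.
#' @return On success, the character vector of codons *excluding* the
#'   STOP; on rejection, a zero-length character vector with attribute
#'   `"reason"`.
#' @examples
#' validate_cds("ATGGCTTAA")  # c("ATG", "GCT")
#' validate_cds("ATGGCTT")    # AA appended -> TAA -> c("ATG", "GCT")
#' @export
validate_cds <- function(sequence, table_id = "2") {
  reject <- function(reason) structure(character(0), reason = reason)
  s <- toupper(gsub("\\s", "", sequence))
  if (nchar(s) == 0) return(reject("empty sequence"))
  if (grepl("[^ACGT]", s)) return(reject("non-ACGT characters"))
  code <- mito_genetic_code(table_id)
  stops <- names(code)[code == "*"]
  for (pad in 0:2) {
    sp <- paste0(s, strrep("A", pad))
    n <- nchar(sp)
    if (n %% 3 != 0 || n < 6) next
    codons <- substring(sp, seq(1, n, 3), seq(3, n, 3))
    if (!codons[1] %in% start_codons(table_id)) {
      return(reject("no valid start codon"))
    }
    if (codons[length(codons)] %in% stops) {
      return(codons[-length(codons)])
    }
  }
  reject("no terminal STOP codon (even after appending up to two A)")
}

#' Per-organism codon count table
#'
#' Tallies codon usage over a set of validated coding sequences and
#' attaches the amino-acid grouping of the translation table (STOP
#' codons excluded).
#'
#' @param codons Character vector of codons (e.g. concatenated output
#'   of [validate_cds()] over an organism's genes), or a named list of
#'   such vectors (one per gene).
#' @param table_id NCBI genetic-code table id.
#' @return Data frame `codon`, `aa`, `count` covering all 60+ sense
#'   codons of the table (zero counts included).
#' @export
codon_count_table <- function(codons, table_id = "2") {
  if (is.list(codons)) codons <- unlist(codons, use.names = FALSE)
  code <- mito_genetic_code(table_id)
  sense <- names(code)[code != "*"]
  counts <- table(factor(codons[codons %in% sense], levels = sense))
  data.frame(codon = sense, aa = unname(code[sense]),
             count = as.integer(counts), row.names = NULL)
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon `c` of amino acid `a` with observed count `o_ac`, synonym
#' set `C_a` and degeneracy `k_a`:
#'
#' \deqn{RSCU(c) = \frac{o_{ac}}{\frac{1}{k_a}\sum_{c' \in C_a} o_{ac'}}}
#'
#' Uniform usage gives RSCU 1 for every codon, and the values of each
#' amino acid sum exactly to `k_a`.  Amino acids with zero total count
#' are skipped.
#'
#' @param counts A codon count table from [codon_count_table()] (columns
#'   `codon`, `aa`, `count`).
#' @return The input with an `rscu` column, rows of zero-total amino
#'   acids removed.
#' @export
rscu <- function(counts) {
  stopifnot(all(c("codon", "aa", "count") %in% names(counts)))
  tot <- tapply(counts$count, counts$aa, sum)
  k <- tapply(counts$count, counts$aa, length)
  keep <- tot[counts$aa] > 0
  out <- counts[keep, , drop = FALSE]
  out$rscu <- as.numeric(out$count / (tot[out$aa] / k[out$aa]))
  rownames(out) <- NULL
  out
}

#' Codons recognized by an mt-tRNA repertoire
#'
#' Maps each tRNA anticodon (5'->3') to the codon family it reads,
#' assuming each codon is recognized by at most one tRNA.  Codon
#' positions 1-2 come from reverse-complementing anticodon positions
#' 3-2; the third codon position expands from the anticodon wobble base
#' (position 34, the anticodon's 5' base) under the selected model:
#'
#' * `"strict"` — Watson-Crick only (one codon per tRNA);
#' * `"twofold"` — wobble U reads A/G, G reads C/T, A reads T, C reads G;
#' * `"superwobble"` (default) — as `"twofold"`, but a wobble-U tRNA
#'   that is the sole isoacceptor of a four-fold degenerate codon box
#'   reads all four codons of the box.
#'
#' The default reproduces the classical vertebrate families: tRNA-Leu
#' (anticodon TAA) reads TTR, tRNA-Leu(TAG) reads CTN, tRNA-Ser(GCT)
#' reads AGY, tRNA-Ser(TGA) reads TCN.  Double-claimed codons are
#' resolved in favor of the exact Watson-Crick match; unresolvable
#' conflicts are an error.
#'
#' @param anticodons Named character vector of anticodons (names are
#'   tRNA symbols), 5'->3' DNA alphabet, e.g. `c(trnM = "CAT")`.
#' @param wobble Wobble model preset.
#' @param table_id NCBI genetic-code table id (used to identify
#'   four-fold boxes).
#' @return Data frame `codon`, `aa`, `recognized`, `trna` covering all
#'   sense codons.
#' @export
recognized_codons <- function(anticodons,
                              wobble = c("superwobble", "twofold", "strict"),
                              table_id = "2") {
  wobble <- match.arg(wobble)
  code <- mito_genetic_code(table_id)
  sense <- names(code)[code != "*"]
  claims <- list()
  if (length(anticodons)) {
    stopifnot(!is.null(names(anticodons)), all(nchar(anticodons) == 3))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ac_split <- strsplit(toupper(anticodons), "")
    prefix <- vapply(ac_split, function(a) {
      paste0(comp[a[3]], comp[a[2]])
    }, "")
    wb <- vapply(ac_split, `[`, "", 1)
    wc_third <- comp[wb]  # exact Watson-Crick third base
    for (i in seq_along(anticodons)) {
      third <- switch(wobble,
        strict = wc_third[i],
        twofold = ,
        superwobble = switch(wb[i],
          T = c("A", "G"), G = c("C", "T"), A = "T", C = "G"))
      if (wobble == "superwobble" && wb[i] == "T") {
        box <- paste0(prefix[i], c("A", "C", "G", "T"))
        fourfold <- all(box %in% sense) && length(unique(code[box])) == 1
        sole <- sum(prefix == prefix[i]) == 1
        if (fourfold && sole) third <- c("A", "C", "G", "T")
      }
      claims[[i]] <- data.frame(
        codon = paste0(prefix[i], third),
        trna = names(anticodons)[i],
        exact = paste0(prefix[i], third) == paste0(prefix[i], wc_third[i]))
    }
  }
  map <- setNames(rep(NA_character_, length(sense)), sense)
  if (length(claims)) {
    cl <- do.call(rbind, claims)
    cl <- cl[cl$codon %in% sense, , drop = FALSE]
    for (cod in unique(cl$codon)) {
      sub <- cl[cl$codon == cod, , drop = FALSE]
      if (nrow(sub) > 1) {
        sub <- sub[sub$exact, , drop = FALSE]
        if (nrow(sub) != 1) {
          stop("codon ", cod, " claimed by multiple tRNAs: ",
               paste(unique(cl$trna[cl$codon == cod]), collapse = ", "))
        }
      }
      map[cod] <- sub$trna
    }
  }
  data.frame(codon = sense, aa = unname(code[sense]),
             recognized = !is.na(map), trna = unname(map),
             row.names = NULL)
}

#' The recognition map held by the majority of a group's organisms
#'
#' @param maps Named list of recognition maps (from
#'   [recognized_codons()]), one per organism.
#' @return The map shared by the largest number of organisms (ties
#'   break on the serialized map string).
#' @export
dominant_repertoire <- function(maps) {
  key <- vapply(maps, function(m) {
    paste(m$codon[m$recognized], collapse = ",")
  }, "")
  tab <- sort(table(key), decreasing = TRUE)
  maps[[match(names(tab)[1], key)]]
}

#' Test codon-usage bias toward mt-tRNA-recognized codons
#'
#' For every amino acid with at least two synonymous codons, of which
#' at least one is recognized by the group's mt-tRNA repertoire and at
#' least one is not, the per-organism RSCU values of recognized codons
#' are pooled across the phylum's organisms and compared with the
#' pooled values of unrecognized codons by a two-sided Mann-Whitney
#' test.  P values are Benjamini-Hochberg-adjusted within each phylum;
#' direction (`"mtDNA-biased"` when recognized codons have the higher
#' median RSCU, `"non-mtDNA-biased"` otherwise) is only called at
#' `q < alpha`.
#'
#' @param rscu_tables Data frame with columns `organism`, `phylum`,
#'   `codon`, `aa`, `rscu` (rows = per-organism RSCU values, e.g. from
#'   stacking [rscu()] outputs).
#' @param recognition A recognition map ([recognized_codons()] output)
#'   applied to every phylum, or a named list of maps keyed by phylum.
#' @param alpha FDR level for the direction call (default 0.05).
#' @return Data frame of per-(phylum, amino acid) results: `U`, `p`,
#'   `q`, `direction`.
#' @export
classify_and_test <- function(rscu_tables, recognition, alpha = 0.05) {
  need <- c("organism", "phylum", "codon", "aa", "rscu")
  stopifnot(all(need %in% names(rscu_tables)))
  per_phylum <- lapply(split(rscu_tables, rscu_tables$phylum), function(d) {
    rec <- if (is.data.frame(recognition)) recognition
           else recognition[[d$phylum[1]]]
    rec_codons <- rec$codon[rec$recognized]
    rows <- lapply(split(d, d$aa), function(da) {
      codons <- unique(da$codon)
      if (length(codons) < 2) return(NULL)
      is_rec <- codons %in% rec_codons
      if (!any(is_rec) || all(is_rec)) return(NULL)
      if (length(unique(da$organism)) < 2) return(NULL)
      x <- da$rscu[da$codon %in% codons[is_rec]]
      y <- da$rscu[da$codon %in% codons[!is_rec]]
      wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
      data.frame(phylum = da$phylum[1], aa = da$aa[1],
                 n_recognized = sum(is_rec),
                 n_unrecognized = sum(!is_rec),
                 U = unname(wt$statistic), p = wt$p.value,
                 median_diff = median(x) - median(y))
    })
    res <- do.call(rbind, rows)
    if (is.null(res)) return(NULL)
    res$q <- p.adjust(res$p, method = "BH")
    res
  })
  out <- do.call(rbind, per_phylum)
  if (is.null(out)) stop("no testable amino acid in any phylum")
  out$direction <- ifelse(out$q >= alpha, "nonsignificant",
                          ifelse(out$median_diff > 0, "mtDNA-biased",
                                 "non-mtDNA-biased"))
  rownames(out) <- NULL
  out
}

#' Base-composition filtration of the codon-bias test
#'
#' Strand- and position-specific base composition can confound codon
#' bias.  This filter (per phylum): (1) assigns each codon to the
#' strand whose protein-coding genes use it most; (2) finds the most
#' prevalent base at every (strand, codon position) over the phylum's
#' protein-coding genes; (3) excludes every codon that carries that
#' base at that position on its assigned strand (ties: all tied bases
#' excluded, with a message); (4) re-runs [classify_and_test()] on the
#' surviving codons.
#'
#' @param usage Data frame with columns `organism`, `phylum`, `gene`,
#'   `strand` (+1/-1), `codon`, `count` (per-gene codon counts).
#' @param rscu_tables,recognition,alpha As in [classify_and_test()].
#' @return List with `excluded` (data frame `phylum`, `codon`) and
#'   `results` (re-test output restricted to surviving codons).
#' @export
base_composition_filter <- function(usage, rscu_tables, recognition,
                                    alpha = 0.05) {
  need <- c("phylum", "strand", "codon", "count")
  stopifnot(all(need %in% names(usage)))
  excluded <- lapply(split(usage, usage$phylum), function(d) {
    # strand assignment: the strand whose genes carry the codon most
    str_tot <- tapply(d$count, list(d$codon, d$strand), sum, default = 0)
    strands <- sort(unique(d$strand))
    assigned <- strands[max.col(str_tot, ties.method = "first")]
    names(assigned) <- rownames(str_tot)
    # most prevalent base per (strand, position) over PCG codons
    bad <- character(0)
    for (st in strands) {
      dsub <- d[d$strand == st, , drop = FALSE]
      if (nrow(dsub) == 0) next
      mat <- do.call(rbind, strsplit(dsub$codon, ""))
      for (pos in 1:3) {
        freq <- tapply(dsub$count, mat[, pos], sum)
        top <- names(freq)[freq == max(freq)]
        if (length(top) > 1) {
          message("base-composition tie at strand ", st, " position ",
                  pos, " (", d$phylum[1], "): all of ",
                  paste(top, collapse = "/"), " excluded")
        }
        cods <- names(assigned)[assigned == st]
        bad <- c(bad, cods[substring(cods, pos, pos) %in% top])
      }
    }
    if (length(bad) == 0) return(NULL)
    data.frame(phylum = d$phylum[1], codon = unique(bad))
  })
  excluded <- do.call(rbind, excluded)
  rownames(excluded) <- NULL
  keep <- !paste(rscu_tables$phylum, rscu_tables$codon) %in%
    paste(excluded$phylum, excluded$codon)
  results <- classify_and_test(rscu_tables[keep, , drop = FALSE],
                               recognition, alpha = alpha)
  list(excluded = excluded, results = results)
}
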