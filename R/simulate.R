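#' Simulation specification
#'
#' Bundle of generator settings with defaults chosen to emulate the
#' statistical structure of public metazoan mtDNA corpora: a 37-gene
#' vertebrate-like ancestral order, a small phylum/class taxonomy,
#' Poisson-distributed rearrangement events per lineage, a two-fold
#' codon skew toward tRNA-recognized codons, 100-base reads, and
#' Poisson-noised coverage.
#'
#' @param seed Integer RNG seed.
#' @param ancestral A circular [gene_order()] used as the ancestor.
#' @param n_phyla,n_classes,n_per_class Taxonomy shape (classes per
#'   phylum, organisms per class).
#' @param rates Named numeric vector of expected event counts per
#'   lineage for `translocation`, `reverse_translocation`, `inversion`,
#'   `tdrl`.
#' @param codon_skew RSCU sampling ratio of recognized : unrecognized
#'   codons (default 2).
#' @param transcription_model `"two_polycistrons"` (human-like: each
#'   strand one full-length precursor) or `"block_terminated"`
#'   (Drosophila-like: precursors end at strand switches).
#' @param dsj_depletion Fold-depletion of precursor coverage across
#'   DSJs under the block-terminated model (default 10; `Inf` means no
#'   read-through at all).
#' @param read_length,depth Read length in bases and reads per sample.
#' @param mature_fraction Fraction of reads originating from mature
#'   (gene-body-confined) transcripts (default 0.5).
#' @param noise Apply per-position Poisson noise to simulated coverage.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1,
                            ancestral = human_like_order(),
                            n_phyla = 2, n_classes = 3, n_per_class = 20,
                            rates = c(translocation = 1,
                                      reverse_translocation = 0.5,
                                      inversion = 1, tdrl = 0.5),
                            codon_skew = 2,
                            transcription_model = c("two_polycistrons",
                                                    "block_terminated"),
                            dsj_depletion = 10,
                            read_length = 100, depth = 5000,
                            mature_fraction = 0.5, noise = TRUE) {
  stopifnot(all(rates >= 0), codon_skew > 0, depth > 0, read_length > 0,
            mature_fraction >= 0, mature_fraction <= 1,
            dsj_depletion >= 1)
  structure(list(seed = seed, ancestral = ancestral, n_phyla = n_phyla,
                 n_classes = n_classes, n_per_class = n_per_class,
                 rates = rates, codon_skew = codon_skew,
                 transcription_model = match.arg(transcription_model),
                 dsj_depletion = dsj_depletion,
                 read_length = read_length, depth = depth,
                 mature_fraction = mature_fraction, noise = noise),
            class = "simulation_spec")
}

# --- rearrangement operators on gene_order objects -----------------------

apply_inversion <- function(order, i, j) {
  # invert the segment i..j (i <= j): reverse and flip signs
  idx <- seq(i, j)
  order$symbols[idx] <- rev(order$symbols[idx])
  order$signs[idx] <- -rev(order$signs[idx])
  order
}

apply_translocation <- function(order, i, j, dest, invert = FALSE) {
  seg_sym <- order$symbols[i:j]
  seg_sgn <- order$signs[i:j]
  if (invert) {
    seg_sym <- rev(seg_sym); seg_sgn <- -rev(seg_sgn)
  }
  rest_sym <- order$symbols[-(i:j)]
  rest_sgn <- order$signs[-(i:j)]
  dest <- min(dest, length(rest_sym))
  order$symbols <- append(rest_sym, seg_sym, after = dest)
  order$signs <- append(rest_sgn, seg_sgn, after = dest)
  order
}

apply_tdrl <- function(order, i, j) {
  # tandem-duplicate the segment i..j, then randomly delete one copy of
  # every duplicated gene
  n <- length(order$symbols)
  seg <- seq(i, j)
  sym <- append(order$symbols, order$symbols[seg], after = j)
  sgn <- append(order$signs, order$signs[seg], after = j)
  first <- seg                 # original copy positions
  second <- seg + length(seg)  # duplicate copy positions
  keep_first <- runif(length(seg)) < 0.5
  drop <- ifelse(keep_first, second, first)
  gene_order(sym[-drop], sgn[-drop], organism = order$organism,
             circular = order$circular)
}

random_event <- function(order, type) {
  n <- length(order$symbols)
  i <- sample.int(n - 1, 1)
  j <- min(n, i + sample.int(min(5, n - i), 1))  # short segments dominate
  switch(type,
    inversion = apply_inversion(order, i, j),
    translocation = apply_translocation(order, i, j,
                                        sample.int(n - (j - i + 1), 1) - 1),
    reverse_translocation = apply_translocation(
      order, i, j, sample.int(n - (j - i + 1), 1) - 1, invert = TRUE),
    tdrl = apply_tdrl(order, i, j))
}

#' Simulate taxon-structured gene orders
#'
#' Each organism's order derives from the ancestral order by a
#' Poisson-distributed number of translocation, reverse-translocation,
#' inversion and tandem-duplication-random-loss events (TDRL is
#' implemented as duplicate-a-segment-then-randomly-drop-one-copy of
#' each duplicated gene, which preserves gene content).  Classes share
#' a class-founder order derived from the ancestor, so architecture
#' diversity is structured by taxonomy.
#'
#' @param spec A [simulation_spec()].
#' @param class_rate_multiplier Optional per-class multiplier on event
#'   rates (recycled over classes), to plant classes of differing
#'   architectural diversity.
#' @return List with `orders` (list of [gene_order()]), `taxonomy`
#'   (data frame `organism`, `phylum`, `class`) and `events` (ground
#'   truth log: `organism`, `type`).
#' @export
simulate_gene_orders <- function(spec, class_rate_multiplier = 1) {
  set.seed(spec$seed)
  orders <- list(); tax <- list(); events <- list()
  mult <- rep_len(class_rate_multiplier, spec$n_phyla * spec$n_classes)
  ci <- 0
  for (ph in seq_len(spec$n_phyla)) {
    for (cl in seq_len(spec$n_classes)) {
      ci <- ci + 1
      founder <- spec$ancestral
      for (type in names(spec$rates)) {  # class-founder divergence
        k <- rpois(1, spec$rates[type])
        for (e in seq_len(k)) founder <- random_event(founder, type)
      }
      for (org in seq_len(spec$n_per_class)) {
        id <- sprintf("p%d_c%d_o%d", ph, cl, org)
        o <- founder
        for (type in names(spec$rates)) {
          k <- rpois(1, spec$rates[type] * mult[ci])
          for (e in seq_len(k)) {
            o <- random_event(o, type)
            events[[length(events) + 1]] <-
              data.frame(organism = id, type = type)
          }
        }
        o$organism <- id
        orders[[id]] <- o
        tax[[id]] <- data.frame(organism = id,
                                phylum = paste0("phylum", ph),
                                class = sprintf("p%d_class%d", ph, cl))
      }
    }
  }
  list(orders = orders,
       taxonomy = do.call(rbind, c(tax, make.row.names = FALSE)),
       events = if (length(events))
         do.call(rbind, c(events, make.row.names = FALSE)) else
           data.frame(organism = character(), type = character()))
}

#' Simulate codon counts and coding sequences under a planted skew
#'
#' Codons of each amino acid are drawn with probability proportional to
#' the skew factor `s` for codons recognized by the supplied tRNA
#' repertoire and 1 for unrecognized codons, so a two-codon amino acid
#' with one recognized codon has expected RSCU `2s/(s+1)` (recognized)
#' and `2/(s+1)` (unrecognized).
#'
#' @param n_organisms Number of organisms.
#' @param recognition Recognition map from [recognized_codons()].
#' @param skew Skew factor `s` (1 = unbiased).
#' @param codons_per_organism Total codons drawn per organism.
#' @param table_id NCBI genetic-code table id.
#' @param sequences Also materialize each organism's draw as a single
#'   start-to-STOP coding sequence string (slower; default `FALSE`).
#' @return List with `counts` (data frame `organism`, `codon`, `aa`,
#'   `count`), `true_probs` (per-codon sampling probabilities) and,
#'   when requested, `cds` (named character vector of sequences).
#' @export
simulate_cds <- function(n_organisms, recognition, skew = 2,
                         codons_per_organism = 2000, table_id = "2",
                         sequences = FALSE) {
  stopifnot(skew > 0)
  code <- mito_genetic_code(table_id)
  sense <- recognition$codon
  w <- ifelse(recognition$recognized, skew, 1)
  # uniform amino-acid usage; within an amino acid, codon probability
  # proportional to the skew weight
  aa_w <- 1 / table(recognition$aa)[recognition$aa]
  fam_w <- tapply(w, recognition$aa, sum)[recognition$aa]
  prob <- as.numeric(aa_w) * w / as.numeric(fam_w)
  prob <- prob / sum(prob)
  counts <- lapply(seq_len(n_organisms), function(i) {
    k <- as.integer(rmultinom(1, codons_per_organism, prob))
    data.frame(organism = sprintf("org%03d", i), codon = sense,
               aa = recognition$aa, count = k)
  })
  out <- list(counts = do.call(rbind, c(counts, make.row.names = FALSE)),
              true_probs = data.frame(codon = sense, prob = prob))
  if (sequences) {
    stops <- names(code)[code == "*"]
    out$cds <- vapply(split(out$counts, out$counts$organism), function(d) {
      body <- sample(rep(d$codon, d$count))
      paste0("ATG", paste(body, collapse = ""), stops[1])
    }, "")
  }
  out
}

# Lay an anchored gene order onto genomic coordinates: protein/rRNA
# genes get realistic lengths, tRNAs ~70 bp, separated by short IGRs.
#' Assign genomic coordinates to a gene order
#'
#' @param order A [gene_order()].
#' @param pcg_length,trna_length,igr_length Feature and intergenic
#'   lengths in bases.
#' @return Data frame `gene`, `start`, `end` (0-based half-open),
#'   `strand`, plus attribute `"genome_length"`.
#' @export
layout_genome <- function(order, pcg_length = 900, trna_length = 70,
                          igr_length = 20) {
  len <- ifelse(is_trna(order$symbols), trna_length, pcg_length)
  start <- cumsum(c(igr_length, head(len + igr_length, -1)))
  out <- data.frame(gene = order$symbols, start = start,
                    end = start + len, strand = order$signs)
  attr(out, "genome_length") <- max(out$end) + igr_length
  out
}

#' Simulate junction-spanning RNA-seq reads
#'
#' Generates single-end reads for one organism under one of two
#' transcription models.  Precursor reads start uniformly within
#' precursor transcripts; mature reads start uniformly within gene
#' bodies.  Under `"two_polycistrons"` each strand is one full-length
#' precursor, so every junction (SSJ and DSJ alike) is covered; under
#' `"block_terminated"` precursors span only runs of co-oriented genes,
#' so coverage across DSJs drops by the spec's `dsj_depletion` factor
#' (modelled as a `1/dsj_depletion` fraction of precursor reads drawn
#' from full-strand read-through transcripts).
#'
#' @param spec A [simulation_spec()].
#' @param genes A [layout_genome()] table.
#' @param n_samples Number of samples to simulate.
#' @return List with `reads` (data frame `sample`, `start`, `end`),
#'   `truth` (per-junction expected relative precursor coverage) and
#'   `genome_length`.
#' @export
simulate_junction_reads <- function(spec, genes, n_samples = 1) {
  L <- attr(genes, "genome_length")
  l <- spec$read_length
  # precursor source intervals: per-strand runs of consecutive genes
  runs <- split(seq_len(nrow(genes)),
                cumsum(c(1, diff(genes$strand) != 0)))
  block_iv <- do.call(rbind, lapply(runs, function(idx) {
    data.frame(start = genes$start[min(idx)], end = genes$end[max(idx)])
  }))
  strand_iv <- do.call(rbind, lapply(c(1, -1), function(st) {
    idx <- which(genes$strand == st)
    if (length(idx) == 0) return(NULL)
    data.frame(start = genes$start[min(idx)], end = genes$end[max(idx)])
  }))
  leak <- if (spec$transcription_model == "two_polycistrons") 1 else
    1 / spec$dsj_depletion
  sample_starts <- function(iv, n) {
    # reads fully contained in their source transcript; intervals
    # shorter than a read contribute none
    w <- iv$end - iv$start - l + 1
    iv <- iv[w > 0, , drop = FALSE]; w <- w[w > 0]
    if (n == 0 || nrow(iv) == 0) return(integer(0))
    which_iv <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
    as.integer(iv$start[which_iv] +
                 pmin(floor(runif(n) * w[which_iv]), w[which_iv] - 1))
  }
  reads <- lapply(seq_len(n_samples), function(s) {
    n_mat <- rbinom(1, spec$depth, spec$mature_fraction)
    n_pre <- spec$depth - n_mat
    n_thru <- rbinom(1, n_pre, leak)
    starts <- c(
      sample_starts(data.frame(start = genes$start, end = genes$end),
                    n_mat),
      sample_starts(block_iv, n_pre - n_thru),
      sample_starts(strand_iv, n_thru))
    data.frame(sample = sprintf("s%02d", s), start = starts,
               end = starts + l)
  })
  wins <- build_junction_windows(genes, l)
  truth <- unique(wins[, c("junction", "type")])
  truth$expected_relative_coverage <- ifelse(truth$type == "DSJ", leak, 1)
  list(reads = do.call(rbind, c(reads, make.row.names = FALSE)),
       truth = truth, genome_length = L)
}

#' Simulate strand-specific nascent-RNA coverage with planted sites
#'
#' Piecewise-constant coverage: `depth` within each transcription unit,
#' `background` outside, with optional per-position Poisson noise.
#' Units may wrap past the origin on circular genomes.  Each unit
#' plants one TIS at its strand-oriented 5' end and one TTS at its 3'
#' end.
#'
#' @param genome_length Genome length in bases.
#' @param units Data frame `strand` (`"+"`/`"-"`), `start`, `end`
#'   (1-based inclusive; `end` may exceed `genome_length` to wrap).
#' @param depth Coverage depth within units.
#' @param background Coverage outside units (default 0).
#' @param noise Per-position Poisson noise (default `TRUE`).
#' @param circular Topology flag.
#' @return List with `track` (a [coverage_track()]) and `sites` (data
#'   frame `kind`, `strand`, `pos` of planted sites).
#' @export
simulate_proseq_coverage <- function(genome_length, units, depth = 50,
                                     background = 0, noise = TRUE,
                                     circular = TRUE) {
  L <- genome_length
  cov <- list("+" = rep(background, L), "-" = rep(background, L))
  sites <- list()
  for (st in c("+", "-")) {
    u <- units[units$strand == st, , drop = FALSE]
    if (nrow(u) == 0) next
    pos_used <- integer(0)
    for (k in seq_len(nrow(u))) {
      idx <- ((seq(u$start[k], u$end[k]) - 1) %% L) + 1
      if (any(idx %in% pos_used)) {
        stop("overlapping same-strand transcription units")
      }
      pos_used <- c(pos_used, idx)
      cov[[st]][idx] <- depth
      tis <- ((u$start[k] - 1) %% L) + 1
      tts <- ((u$end[k] - 1) %% L) + 1
      if (st == "-") { tmp <- tis; tis <- tts; tts <- tmp }
      sites[[length(sites) + 1]] <- data.frame(
        kind = c("TIS", "TTS"), strand = st, pos = c(tis, tts))
    }
  }
  if (noise) cov <- lapply(cov, function(v) rpois(L, v))
  list(track = coverage_track(cov[["+"]], cov[["-"]],
                              circular = circular),
       sites = do.call(rbind, c(sites, make.row.names = FALSE)))
}
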