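#' Build read-counting windows around gene-gene junctions
#'
#' For every pair of neighboring genes (excluding the junction between
#' the last and first gene, which typically crosses the long non-coding
#' control region) a counting window is laid over the junction.  The
#' window is centered on the junction point with total length at most
#' 95% of twice the sample's mean read length (`0.95 * 2l`), so that
#' only reads straddling the gene edge and the intergenic region (IGR)
#' — i.e. precursor-derived reads — can be fully contained.  When the
#' IGR is longer than `2l`, the junction is split into two windows, one
#' on each gene edge, and the junction's coverage is the sum of both.
#' Junctions are typed SSJ (same strand) or DSJ (different strands).
#'
#' @param genes Data frame with columns `gene`, `start`, `end` (0-based
#'   half-open), `strand` (+1/-1), sorted by `start`.
#' @param read_length Mean read length `l` of the sample, in bases.
#' @return Data frame of windows: `junction`, `gene5`, `gene3`, `type`,
#'   `part` (1 or 2), `start`, `end`, `igr`.
#' @export
build_junction_windows <- function(genes, read_length) {
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(genes)),
            nrow(genes) >= 2, !is.unsorted(genes$start))
  l <- read_length
  w <- floor(0.95 * 2 * l)
  half <- w %/% 2
  quarter <- w %/% 4
  rows <- list()
  for (i in seq_len(nrow(genes) - 1)) {
    g5 <- genes[i, ]; g3 <- genes[i + 1, ]
    igr <- g3$start - g5$end
    type <- if (g5$strand == g3$strand) "SSJ" else "DSJ"
    id <- paste0(g5$gene, "|", g3$gene)
    if (igr < 0) {
      message("overlapping genes at ", id,
              "; window centered on the overlap point")
    }
    if (igr <= 2 * l) {
      mid <- floor((g5$end + g3$start) / 2)
      rows[[length(rows) + 1]] <- data.frame(
        junction = id, gene5 = g5$gene, gene3 = g3$gene, type = type,
        part = 1L, start = mid - half, end = mid - half + w, igr = igr)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        junction = id, gene5 = g5$gene, gene3 = g3$gene, type = type,
        part = 1L, start = g5$end - quarter, end = g5$end + quarter,
        igr = igr)
      rows[[length(rows) + 1]] <- data.frame(
        junction = id, gene5 = g5$gene, gene3 = g3$gene, type = type,
        part = 2L, start = g3$start - quarter, end = g3$start + quarter,
        igr = igr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count reads strictly contained in features
#'
#' Intersection-strict, nonunique-none counting: a read contributes to
#' a feature only if it is wholly contained in one of the feature's
#' intervals; reads contained in intervals of two or more *different*
#' features are counted for neither.  Strand is ignored (unstranded
#' libraries), and only uniquely mapped reads should be supplied.
#'
#' @param reads Data frame with columns `start`, `end` (0-based
#'   half-open).
#' @param features Data frame with columns `feature`, `start`, `end`;
#'   several rows may share a `feature` id (split junction windows),
#'   in which case their counts are summed.
#' @return Data frame `feature`, `length` (total interval length),
#'   `reads`, plus attribute `"reads_total"` = number of reads in the
#'   library.
#' @export
count_reads <- function(reads, features) {
  stopifnot(all(c("start", "end") %in% names(reads)),
            all(c("feature", "start", "end") %in% names(features)))
  fid <- unique(features$feature)
  counts <- setNames(integer(length(fid)), fid)
  if (nrow(reads) > 0) {
    q <- IRanges::IRanges(start = reads$start + 1L, end = reads$end)
    s <- IRanges::IRanges(start = features$start + 1L, end = features$end)
    hits <- IRanges::findOverlaps(q, s, type = "within")
    if (length(hits) > 0) {
      hf <- features$feature[S4Vectors::subjectHits(hits)]
      hq <- S4Vectors::queryHits(hits)
      nfeat <- vapply(split(hf, hq), function(f) length(unique(f)), 0L)
      ok <- names(nfeat)[nfeat == 1L]
      if (length(ok)) {
        keep <- hq %in% as.integer(ok)
        tab <- table(hf[keep][!duplicated(hq[keep])])
        counts[names(tab)] <- as.integer(tab)
      }
    }
  }
  len <- tapply(features$end - features$start, features$feature, sum)
  out <- data.frame(feature = fid, length = as.numeric(len[fid]),
                    reads = as.integer(counts), row.names = NULL)
  attr(out, "reads_total") <- nrow(reads)
  out
}

#' Read-count normalization (per-million, length-corrected)
#'
#' \deqn{value = \frac{reads}{reads_{total} \cdot length} \cdot 10^9}
#'
#' applied uniformly to genes and junction windows.
#'
#' @param reads Numeric vector of read counts per feature, or a
#'   [count_reads()] result (its `reads_total` attribute is then used).
#' @param length Feature lengths in bases.
#' @param reads_total Total reads in the library.
#' @return Numeric vector of normalized values (or the input data frame
#'   with a `tpm` column).
#' @examples
#' tpm(10, 100, 1000)  # 1e5
#' @export
tpm <- function(reads, length = NULL, reads_total = NULL) {
  if (is.data.frame(reads)) {
    rt <- if (is.null(reads_total)) attr(reads, "reads_total") else
      reads_total
    reads$tpm <- tpm(reads$reads, reads$length, rt)
    return(reads)
  }
  if (is.null(reads_total) || reads_total <= 0) {
    stop("reads_total must be positive")
  }
  stopifnot(all(length > 0))
  reads / (reads_total * length) * 1e9
}

#' Junction / sample quality filters
#'
#' Applies, in order: (1) organisms with fewer than `min_samples`
#' samples are dropped; (2) within each sample, junctions whose either
#' flanking gene's normalized expression falls below the sample's mean
#' mtDNA gene expression minus two standard deviations are dropped;
#' (3) samples in which more than half of the identified junctions have
#' zero read coverage (a signature of poly-A-selected libraries) are
#' dropped; then rule (1) is re-checked.
#'
#' @param junctions Data frame with columns `organism`, `sample`,
#'   `junction`, `gene5`, `gene3`, `type`, `reads`, `tpm` (one row per
#'   junction per sample).
#' @param genes Data frame with columns `organism`, `sample`, `gene`,
#'   `tpm`.
#' @param min_samples Minimum samples per organism (default 5).
#' @param sd_mult Gene-expression threshold multiplier (default 2).
#' @return List with `junctions` (retained rows) and `report` (data
#'   frame of exclusions: `level`, `id`, `reason`).
#' @export
filter_junctions_and_samples <- function(junctions, genes,
                                         min_samples = 5, sd_mult = 2) {
  report <- list()
  note <- function(level, id, reason) {
    report[[length(report) + 1]] <<- data.frame(level = level, id = id,
                                                reason = reason)
  }
  drop_small <- function(j, stage) {
    ns <- tapply(j$sample, j$organism,
                 function(s) length(unique(s)))
    bad <- names(ns)[ns < min_samples]
    for (b in bad) note("organism", b,
                        paste0("fewer than ", min_samples, " samples"))
    j[!j$organism %in% bad, , drop = FALSE]
  }
  j <- drop_small(junctions, "initial")
  # rule 2: low-expression flanking genes, per sample
  if (nrow(j) > 0) {
    key <- paste(genes$organism, genes$sample)
    thr <- vapply(split(genes$tpm, key),
                  function(v) mean(v) - sd_mult * sd(v), 0)
    gexp <- setNames(genes$tpm, paste(key, genes$gene))
    jkey <- paste(j$organism, j$sample)
    g5 <- gexp[paste(jkey, j$gene5)]
    g3 <- gexp[paste(jkey, j$gene3)]
    low <- (g5 < thr[jkey]) | (g3 < thr[jkey])
    low[is.na(low)] <- FALSE
    if (any(low)) {
      for (id in unique(paste0(jkey[low], " ", j$junction[low]))) {
        note("junction", id, "flanking gene below mean - 2 SD")
      }
    }
    j <- j[!low, , drop = FALSE]
  }
  # rule 3: samples dominated by zero-coverage junctions
  if (nrow(j) > 0) {
    jkey <- paste(j$organism, j$sample)
    zero_frac <- vapply(split(j$reads, jkey),
                        function(v) mean(v == 0), 0)
    bad <- names(zero_frac)[zero_frac > 0.5]
    for (b in bad) note("sample", b, "over 50% zero-coverage junctions")
    j <- j[!jkey %in% bad, , drop = FALSE]
  }
  if (nrow(j) > 0) j <- drop_small(j, "final")
  list(junctions = j,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(level = character(), id = character(),
                    reason = character()))
}

#' Test for reduced DSJ expression within each organism
#'
#' Pools the log-normalized junction expression values (log10(TPM + 1))
#' of all samples of an organism and compares DSJ against SSJ values
#' with a two-sided Mann-Whitney test (exact when sample sizes permit).
#' P values are Bonferroni-corrected across organisms; the effect size
#' is Cohen's d with pooled standard deviation, negative when DSJ
#' expression is the lower.
#'
#' @param junctions Retained junction rows (see
#'   [filter_junctions_and_samples()]): columns `organism`, `sample`,
#'   `junction`, `type`, `tpm`.
#' @param alpha Significance level on the corrected p value for the
#'   `significant_reduction` flag (default 0.05).
#' @return Data frame per organism: `n_samples`, `n_ssj`, `n_dsj`, `U`,
#'   `p`, `p_bonferroni`, `cohens_d`, `significant_reduction`.
#' @export
test_ssj_vs_dsj <- function(junctions, alpha = 0.05) {
  rows <- lapply(split(junctions, junctions$organism), function(d) {
    x <- log10(d$tpm[d$type == "DSJ"] + 1)
    y <- log10(d$tpm[d$type == "SSJ"] + 1)
    if (length(unique(d$junction[d$type == "DSJ"])) < 2 ||
        length(unique(d$junction[d$type == "SSJ"])) < 2) {
      message("organism ", d$organism[1],
              " skipped: fewer than two junctions of a type")
      return(NULL)
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    d_eff <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
    data.frame(organism = d$organism[1],
               n_samples = length(unique(d$sample)),
               n_ssj = length(unique(d$junction[d$type == "SSJ"])),
               n_dsj = length(unique(d$junction[d$type == "DSJ"])),
               U = unname(wt$statistic), p = wt$p.value,
               cohens_d = d_eff)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable organism")
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant_reduction <- out$p_bonferroni < alpha & out$cohens_d < 0
  rownames(out) <- NULL
  out
}

#' Association between alternating blocks and DSJ reduction
#'
#' Cross-tabulates organisms by alternating gene-block organization
#' (yes/no) against significant DSJ reduction (yes/no) and tests
#' independence with the chi-square statistic, reported both without
#' and with the Yates continuity correction.  When any expected cell
#' count falls below 1, Fisher's exact test is reported as well.
#'
#' @param alternating Logical vector per organism.
#' @param significant Logical vector per organism (e.g.
#'   `significant_reduction` from [test_ssj_vs_dsj()]).
#' @return List with `table` (2x2), `chisq` / `chisq_yates` (htest
#'   objects) and optionally `fisher`.
#' @export
association_with_blocks <- function(alternating, significant) {
  stopifnot(length(alternating) == length(significant))
  tab <- table(alternating = factor(alternating, c(TRUE, FALSE)),
               significant = factor(significant, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("need organisms in both categories")
  }
  plain <- suppressWarnings(chisq.test(tab, correct = FALSE))
  yates <- suppressWarnings(chisq.test(tab, correct = TRUE))
  out <- list(table = tab, chisq = plain, chisq_yates = yates)
  if (any(plain$expected < 1)) {
    warning("expected cell count below 1; Fisher exact test attached",
            call. = FALSE)
    out$fisher <- fisher.test(tab)
  }
  out
}

#' Keep motifs found near DSJs in most species
#'
#' A motif is retained when, in at least `min_fraction` of the species
#' carrying DSJ annotation, at least one of its occurrences lies within
#' `max_distance` bases of a DSJ (circular distance on circular
#' genomes; the fraction boundary is inclusive).
#'
#' @param occurrences Data frame `motif`, `species`, `position`.
#' @param dsj Data frame `species`, `position` of DSJ midpoints.
#' @param genome_length Named numeric vector of genome lengths by
#'   species (used for circular distance); species absent from it are
#'   treated as linear.
#' @param max_distance Maximum distance in bases (default 500,
#'   exclusive: "within less than 500 bases").
#' @param min_fraction Minimum fraction of species (default 0.8).
#' @return Data frame `motif`, `n_species`, `n_proximal`, `fraction`,
#'   `kept`.
#' @export
filter_dsj_proximal_motifs <- function(occurrences, dsj,
                                       genome_length = NULL,
                                       max_distance = 500,
                                       min_fraction = 0.8) {
  species <- unique(occurrences$species)
  no_dsj <- setdiff(species, unique(dsj$species))
  if (length(no_dsj)) {
    message("species without DSJ annotation excluded from denominator: ",
            paste(no_dsj, collapse = ", "))
  }
  denom <- setdiff(species, no_dsj)
  circ_dist <- function(a, b, L) {
    d <- abs(a - b)
    if (!is.null(L) && !is.na(L)) pmin(d, L - d) else d
  }
  rows <- lapply(split(occurrences, occurrences$motif), function(om) {
    prox <- vapply(denom, function(sp) {
      pos <- om$position[om$species == sp]
      if (length(pos) == 0) return(FALSE)
      dpos <- dsj$position[dsj$species == sp]
      L <- genome_length[sp]
      any(vapply(pos, function(p) {
        any(circ_dist(p, dpos, L) < max_distance)
      }, FALSE))
    }, FALSE)
    data.frame(motif = om$motif[1], n_species = length(denom),
               n_proximal = sum(prox),
               fraction = mean(prox),
               kept = mean(prox) >= min_fraction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
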