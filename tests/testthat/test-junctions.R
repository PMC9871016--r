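two_gene_layout <- function(igr, strand2 = 1L, len = 500, start = 100) {
  data.frame(gene = c("gA", "gB"),
             start = c(start, start + len + igr),
             end = c(start + len, start + 2 * len + igr),
             strand = c(1L, strand2))
}

test_that("junction windows follow the 0.95*2l sizing and split rule", {
  # l = 100, IGR = 10: one 190-base window spanning the junction
  w <- build_junction_windows(two_gene_layout(10), 100)
  expect_equal(nrow(w), 1)
  expect_equal(w$end - w$start, 190)
  expect_equal(w$type, "SSJ")
  # window overlaps the upstream gene end, the IGR, and the downstream
  # gene start
  expect_lt(w$start, 600); expect_gt(w$end, 610)
  # l = 100, IGR = 500 > 2l: two windows, total length <= 190
  w2 <- build_junction_windows(two_gene_layout(500), 100)
  expect_equal(nrow(w2), 2)
  expect_equal(w2$junction[1], w2$junction[2])
  expect_lte(sum(w2$end - w2$start), 190)
  # each split window overlaps one gene edge and the adjacent IGR
  expect_true(w2$start[1] < 600 && w2$end[1] > 600)
  expect_true(w2$start[2] < 1100 && w2$end[2] > 1100)
  # different strands type the junction DSJ
  expect_equal(build_junction_windows(two_gene_layout(10, -1L),
                                      100)$type, "DSJ")
  # the wrap-around junction between last and first gene is never built
  g3 <- rbind(two_gene_layout(10), data.frame(gene = "gC", start = 1500,
                                              end = 2000, strand = 1L))
  w3 <- build_junction_windows(g3, 100)
  expect_false(any(w3$junction == "gC|gA"))
  # overlapping genes: window centered on the overlap point, logged
  expect_message(build_junction_windows(two_gene_layout(-50), 100),
                 "overlap")
})

test_that("read counting is strict-containment with ambiguity discard", {
  feats <- data.frame(feature = c("f1", "f2"),
                      start = c(100, 150), end = c(300, 350))
  reads <- data.frame(start = c(120, 90, 290, 200, 160),
                      end = c(220, 190, 390, 300, 260))
  # read 1: inside f1 only; read 2: overhangs f1's left edge; read 3:
  # overhangs f2; read 4: inside both (ambiguous, dropped); read 5:
  # inside both (dropped)
  cc <- count_reads(reads, feats)
  expect_equal(cc$reads[cc$feature == "f1"], 1L)
  expect_equal(cc$reads[cc$feature == "f2"], 0L)
  expect_equal(attr(cc, "reads_total"), 5L)
  # split windows of one junction sum into one count
  sw <- data.frame(feature = "j", start = c(0, 500), end = c(100, 600))
  cc2 <- count_reads(data.frame(start = c(10, 510), end = c(90, 590)), sw)
  expect_equal(cc2$reads, 2L)
  expect_equal(cc2$length, 200)
  # zero reads is valid
  expect_equal(count_reads(reads[0, ], feats)$reads, c(0L, 0L))
})

test_that("normalization follows reads/(reads_total*length)*1e9", {
  expect_equal(tpm(10, 100, 1000), 1e5)
  expect_equal(tpm(0, 100, 1000), 0)
  # doubling the library size halves every value
  v1 <- tpm(c(5, 10), c(100, 200), 1000)
  v2 <- tpm(c(5, 10), c(100, 200), 2000)
  expect_equal(v1, 2 * v2)
  expect_error(tpm(1, 100, 0), "reads_total")
})

test_that("QC filters drop small organisms, dim junctions, zero-heavy samples", {
  mk_j <- function(org, smp, reads) {
    data.frame(organism = org, sample = smp,
               junction = paste0("j", seq_along(reads)),
               gene5 = "g1", gene3 = "g2",
               type = rep(c("SSJ", "DSJ"), length.out = length(reads)),
               reads = reads, tpm = reads)
  }
  mk_g <- function(org, smp, tpms) {
    data.frame(organism = org, sample = smp,
               gene = paste0("g", seq_along(tpms)), tpm = tpms)
  }
  # organism with 4 samples is dropped
  j4 <- do.call(rbind, lapply(1:4, function(s) mk_j("few", s, c(5, 5))))
  g4 <- do.call(rbind, lapply(1:4, function(s) mk_g("few", s, c(10, 10))))
  out <- filter_junctions_and_samples(j4, g4)
  expect_equal(nrow(out$junctions), 0)
  expect_true(any(grepl("fewer", out$report$reason)))
  # junction flanked by a gene 3 SD below the mean is dropped
  j1 <- do.call(rbind, lapply(1:5, function(s) {
    d <- mk_j("org", s, c(5, 5, 5)); d$gene5 <- c("g1", "g2", "g3"); d
  }))
  # ten genes per sample, g3 at tpm 1 while the rest sit at 10:
  # threshold = 9.1 - 2 * 2.85 = 3.4, so g3 falls below it
  g1 <- do.call(rbind, lapply(1:5, function(s) {
    mk_g("org", s, c(10, 10, 1, 10, 10, 10, 10, 10, 10, 10))
  }))
  out1 <- filter_junctions_and_samples(j1, g1)
  expect_false("j3" %in% out1$junctions$junction)
  expect_true(all(c("j1", "j2") %in% out1$junctions$junction))
  # sample with 60% zero-coverage junctions is dropped
  j2 <- do.call(rbind, lapply(1:6, function(s) {
    mk_j("org2", s, if (s == 1) c(0, 0, 0, 5, 5) else rep(5, 5))
  }))
  g2 <- do.call(rbind, lapply(1:6, function(s) mk_g("org2", s, c(5, 5))))
  out2 <- filter_junctions_and_samples(j2, g2)
  expect_false(1 %in% out2$junctions$sample)
  expect_true(all(2:6 %in% out2$junctions$sample))
})

test_that("the SSJ/DSJ Mann-Whitney matches exact enumeration", {
  # SSJ = {1,2,3}, DSJ = {10,20,30}: all 20 labelings give p = 0.1
  j <- data.frame(organism = "o", sample = 1,
                  junction = paste0("j", 1:6),
                  type = rep(c("SSJ", "DSJ"), each = 3),
                  tpm = c(1, 2, 3, 10, 20, 30))
  res <- test_ssj_vs_dsj(j)
  expect_equal(res$p, 0.1)
  expect_equal(res$p,
               oracle_mw_exact_p(log10(c(10, 20, 30) + 1),
                                 log10(c(1, 2, 3) + 1)))
  expect_gt(res$cohens_d, 0)  # DSJ larger here
  # identical groups: d = 0
  j0 <- j; j0$tpm <- rep(c(2, 4, 8), 2)
  expect_equal(test_ssj_vs_dsj(j0)$cohens_d, 0)
  # random small samples agree with the enumeration oracle
  set.seed(14)
  for (i in 1:10) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    vals <- sample(1:100, nx + ny)  # distinct: exact test applies
    jj <- data.frame(organism = "o", sample = 1,
                     junction = paste0("j", seq_len(nx + ny)),
                     type = rep(c("DSJ", "SSJ"), c(nx, ny)),
                     tpm = vals)
    expect_equal(test_ssj_vs_dsj(jj)$p,
                 oracle_mw_exact_p(log10(vals[1:nx] + 1),
                                   log10(vals[-(1:nx)] + 1)),
                 tolerance = 1e-10)
  }
})

test_that("chi-square association handles the worked 2x2 tables", {
  # perfectly aligned table: chi-square = 20
  a <- association_with_blocks(rep(c(TRUE, FALSE), each = 10),
                               rep(c(TRUE, FALSE), each = 10))
  expect_equal(unname(a$chisq$statistic), 20)
  expect_lt(a$chisq$p.value, 1e-4)
  # equal proportions: statistic 0, p 1
  b <- association_with_blocks(rep(c(TRUE, FALSE), each = 10),
                               rep(c(TRUE, FALSE), 10))
  expect_equal(unname(b$chisq$statistic), 0)
  expect_equal(b$chisq$p.value, 1)
  # [[17,14],[4,20]]: closed-form n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d))
  alt <- rep(c(TRUE, FALSE), c(31, 24))
  sig <- c(rep(c(TRUE, FALSE), c(17, 14)), rep(c(TRUE, FALSE), c(4, 20)))
  cc <- association_with_blocks(alt, sig)
  n <- 55
  oracle <- n * (17 * 20 - 14 * 4)^2 / (31 * 24 * 21 * 34)
  expect_equal(unname(cc$chisq$statistic), oracle)
  expect_false(isTRUE(all.equal(cc$chisq$p.value,
                                cc$chisq_yates$p.value)))
})

test_that("DSJ-proximal motif filter applies circular distance and 80% rule", {
  L <- c(sp1 = 10000)
  dsj <- data.frame(species = "sp1", position = 100)
  # circular wrap: position 9800 is 300 from a DSJ at 100
  occ <- data.frame(motif = "m1", species = "sp1", position = 9800)
  out <- filter_dsj_proximal_motifs(occ, dsj, L)
  expect_true(out$kept)
  # 600 bases away in every species: dropped
  occ2 <- data.frame(motif = "m2", species = "sp1", position = 700)
  expect_false(filter_dsj_proximal_motifs(occ2, dsj, L)$kept)
  # 8 of 10 species qualify: kept (inclusive 0.8 boundary)
  occ3 <- data.frame(motif = "m3", species = paste0("s", 1:10),
                     position = c(rep(150, 8), rep(5000, 2)))
  dsj3 <- data.frame(species = paste0("s", 1:10), position = 100)
  L3 <- setNames(rep(10000, 10), paste0("s", 1:10))
  out3 <- filter_dsj_proximal_motifs(occ3, dsj3, L3)
  expect_equal(out3$fraction, 0.8)
  expect_true(out3$kept)
  # species without DSJ annotation leave the denominator
  occ4 <- data.frame(motif = "m4", species = c("sp1", "nope"),
                     position = c(150, 150))
  expect_message(out4 <- filter_dsj_proximal_motifs(occ4, dsj, L),
                 "nope")
  expect_equal(out4$n_species, 1)
})
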