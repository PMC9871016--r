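test_that("gene-order simulation is seeded and preserves gene content", {
  spec <- simulation_spec(seed = 21, n_phyla = 1, n_classes = 2,
                          n_per_class = 5)
  s1 <- simulate_gene_orders(spec)
  s2 <- simulate_gene_orders(spec)
  expect_identical(lapply(s1$orders, format_order),
                   lapply(s2$orders, format_order))
  expect_equal(nrow(s1$taxonomy), 10)
  # every rearrangement operator preserves the gene set
  for (o in s1$orders) {
    expect_setequal(o$symbols, spec$ancestral$symbols)
  }
})

test_that("zero rates give identical orders; high rates saturate AR", {
  z <- simulation_spec(seed = 22, n_phyla = 1, n_classes = 1,
                       n_per_class = 8,
                       rates = c(translocation = 0,
                                 reverse_translocation = 0,
                                 inversion = 0, tdrl = 0))
  sz <- simulate_gene_orders(z)
  archs <- vapply(lapply(sz$orders, anchor), format_order, "")
  expect_equal(ar_rate(archs), 0)
  h <- simulation_spec(seed = 23, n_phyla = 1, n_classes = 1,
                       n_per_class = 8,
                       rates = c(translocation = 15,
                                 reverse_translocation = 5,
                                 inversion = 15, tdrl = 5))
  sh <- simulate_gene_orders(h)
  archs_h <- vapply(lapply(sh$orders, anchor), format_order, "")
  expect_equal(ar_rate(archs_h), 100)
})

test_that("one two-gene inversion sits at breakpoint distance 2", {
  anc <- parse_order("A B C D E F")
  inv <- mitorder:::apply_inversion(anc, 3, 4)
  expect_equal(format_order(inv), "A B -D -C E F")
  expect_equal(breakpoint_distance(anc, inv), 2)
  expect_equal(oracle_breakpoint(anc, inv), 2)
})

test_that("codon simulation hits the closed-form expected RSCU", {
  rec <- recognized_codons(c(trnL2 = "TAA"))
  set.seed(24)
  sim <- simulate_cds(40, rec, skew = 2, codons_per_organism = 6000)
  rt <- do.call(rbind, lapply(split(sim$counts, sim$counts$organism),
                              function(d)
                                rscu(d[, c("codon", "aa", "count")])))
  # Leu: recognized TTA/TTG at weight 2, four CTN codons at weight 1;
  # k = 6 so expected RSCU = 6*2/8 = 1.5 recognized, 6/8 = 0.75 not
  leu <- rt[rt$aa == "L", ]
  expect_equal(mean(leu$rscu[leu$codon %in% c("TTA", "TTG")]), 1.5,
               tolerance = 0.05)
  expect_equal(mean(leu$rscu[leu$codon %in%
                               c("CTT", "CTC", "CTA", "CTG")]), 0.75,
               tolerance = 0.05)
  # skew 1: all RSCU near 1
  set.seed(25)
  sim1 <- simulate_cds(40, rec, skew = 1, codons_per_organism = 6000)
  rt1 <- do.call(rbind, lapply(split(sim1$counts, sim1$counts$organism),
                               function(d)
                                 rscu(d[, c("codon", "aa", "count")])))
  expect_equal(mean(rt1$rscu[rt1$aa == "L"]), 1, tolerance = 0.05)
  # sequence path agrees with the count path
  set.seed(26)
  sim_seq <- simulate_cds(2, rec, skew = 2, codons_per_organism = 300,
                          sequences = TRUE)
  for (org in names(sim_seq$cds)) {
    codons <- validate_cds(sim_seq$cds[[org]])
    tab <- codon_count_table(codons[-1])  # drop the ATG start
    cmp <- merge(tab, sim_seq$counts[sim_seq$counts$organism == org, ],
                 by = "codon")
    expect_equal(cmp$count.x[cmp$codon != "ATG"],
                 cmp$count.y[cmp$codon != "ATG"])
  }
})

test_that("junction-read models separate DSJ coverage as planted", {
  genes <- layout_genome(drop_trnas(drosophila_like_order()))
  wins <- build_junction_windows(genes, 100)
  wdf <- data.frame(feature = wins$junction, start = wins$start,
                    end = wins$end)
  jmeta <- unique(wins[, c("junction", "type")])
  ratio_for <- function(model, depletion, seed) {
    spec <- simulation_spec(seed = seed, transcription_model = model,
                            dsj_depletion = depletion, depth = 30000,
                            mature_fraction = 0)
    set.seed(seed)
    jr <- simulate_junction_reads(spec, genes, n_samples = 1)
    cc <- count_reads(jr$reads, wdf)
    m <- merge(cc, jmeta, by.x = "feature", by.y = "junction")
    mean(m$reads[m$type == "DSJ"]) / mean(m$reads[m$type == "SSJ"])
  }
  # block-terminated at 10x depletion: DSJ/SSJ within +-20% of 0.1
  r_bt <- ratio_for("block_terminated", 10, 27)
  expect_gt(r_bt, 0.08); expect_lt(r_bt, 0.12)
  # two polycistrons: DSJ and SSJ coverage statistically equal
  r_tp <- ratio_for("two_polycistrons", 10, 28)
  expect_gt(r_tp, 0.85); expect_lt(r_tp, 1.15)
  # zero precursor read-through and no mature reads: DSJ counts 0
  spec0 <- simulation_spec(seed = 29,
                           transcription_model = "block_terminated",
                           dsj_depletion = Inf, depth = 5000,
                           mature_fraction = 0)
  set.seed(29)
  jr0 <- simulate_junction_reads(spec0, genes, n_samples = 1)
  cc0 <- merge(count_reads(jr0$reads, wdf), jmeta,
               by.x = "feature", by.y = "junction")
  expect_true(all(cc0$reads[cc0$type == "DSJ"] == 0))
})

test_that("coverage simulation plants steps and rejects overlaps", {
  set.seed(30)
  units <- data.frame(strand = "+", start = 1001, end = 4000)
  sim <- simulate_proseq_coverage(8000, units, depth = 50, noise = FALSE)
  expect_equal(unique(sim$track$fwd[1001:4000]), 50)
  expect_equal(unique(sim$track$fwd[c(1:1000, 4001:8000)]), 0)
  expect_equal(nrow(sim$sites), 2)
  # circular wraparound unit
  simw <- simulate_proseq_coverage(8000,
                                   data.frame(strand = "+", start = 7501,
                                              end = 8500),
                                   depth = 10, noise = FALSE)
  expect_equal(unique(simw$track$fwd[c(7501:8000, 1:500)]), 10)
  expect_equal(unique(simw$track$fwd[501:7500]), 0)
  # overlapping same-strand units error
  expect_error(simulate_proseq_coverage(
    8000, data.frame(strand = "+", start = c(1, 500), end = c(1000, 1500)),
    depth = 10), "overlap")
})
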