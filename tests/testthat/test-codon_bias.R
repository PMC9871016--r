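test_that("CDS validation enforces start/STOP with poly-A completion", {
  expect_equal(validate_cds("ATGGCTTAA"), c("ATG", "GCT"))
  # incomplete STOP completed by appended A's
  expect_equal(validate_cds("ATGGCTT"), c("ATG", "GCT"))
  expect_equal(validate_cds("ATGGCTTA"), c("ATG", "GCT"))
  # no STOP even after +AA
  r <- validate_cds("ATGGCTGGG")
  expect_length(r, 0)
  expect_match(attr(r, "reason"), "STOP")
  # bad inputs
  expect_match(attr(validate_cds(""), "reason"), "empty")
  expect_match(attr(validate_cds("ATGNNNTAA"), "reason"), "non-ACGT")
  expect_match(attr(validate_cds("CCCGCTTAA"), "reason"), "start")
  # vertebrate-mito alternative initiators are honored
  expect_equal(validate_cds("ATAGCTTAA", table_id = "2"), c("ATA", "GCT"))
  # AGA is a STOP in the vertebrate-mito table but not in table 5
  expect_equal(validate_cds("ATGGCTAGA", table_id = "2"), c("ATG", "GCT"))
  expect_length(validate_cds("ATGGCTAGA", table_id = "5"), 0)
})

test_that("RSCU reproduces hand-evaluated values and its normalization", {
  # two-codon amino acid with counts (3, 1): RSCU 1.5 / 0.5
  counts <- data.frame(codon = c("GAT", "GAC"), aa = "D",
                       count = c(3L, 1L))
  r <- rscu(counts)
  expect_equal(r$rscu, c(1.5, 0.5))
  # uniform usage over k codons gives RSCU 1 everywhere
  u <- rscu(data.frame(codon = c("CTT", "CTC", "CTA", "CTG"), aa = "L",
                       count = 5L))
  expect_equal(u$rscu, rep(1, 4))
  # single-codon amino acid
  expect_equal(rscu(data.frame(codon = "TGG", aa = "W",
                               count = 7L))$rscu, 1)
  # zero-total amino acids are skipped
  z <- rscu(data.frame(codon = c("GAT", "GAC", "TGG"),
                       aa = c("D", "D", "W"), count = c(2L, 2L, 0L)))
  expect_false("W" %in% z$aa)
})

test_that("RSCU values of every amino acid sum to its degeneracy", {
  set.seed(8)
  code <- mito_genetic_code("2")
  for (i in 1:40) {
    tab <- codon_count_table(
      sample(names(code)[code != "*"], 500, replace = TRUE))
    r <- rscu(tab)
    sums <- tapply(r$rscu, r$aa, sum)
    k <- tapply(r$codon, r$aa, length)
    expect_equal(as.numeric(sums), as.numeric(k), tolerance = 1e-12)
  }
})

test_that("anticodon wobble expansion reproduces the vertebrate families", {
  rec <- recognized_codons(c(trnL2 = "TAA", trnL1 = "TAG",
                             trnS1 = "GCT", trnS2 = "TGA"))
  rec_of <- function(t) sort(rec$codon[rec$recognized &
                                         !is.na(rec$trna) & rec$trna == t])
  expect_equal(rec_of("trnL2"), c("TTA", "TTG"))        # TTR
  expect_equal(rec_of("trnL1"), c("CTA", "CTC", "CTG", "CTT"))  # CTN
  expect_equal(rec_of("trnS1"), c("AGC", "AGT"))        # AGY
  expect_equal(rec_of("trnS2"), c("TCA", "TCC", "TCG", "TCT"))  # UCN
  # empty repertoire recognizes nothing
  none <- recognized_codons(setNames(character(0), character(0)))
  expect_false(any(none$recognized))
  # strict model: one codon per tRNA
  s <- recognized_codons(c(trnM = "CAT"), wobble = "strict")
  expect_equal(s$codon[s$recognized], "ATG")
  # two isoacceptors in one box suppress superwobble expansion, and the
  # shared third-position codon resolves to the exact Watson-Crick match
  two <- recognized_codons(c(trnL1 = "TAG", trnLx = "CAG"))
  expect_equal(two$codon[two$recognized & two$trna == "trnL1"], "CTA")
  expect_equal(two$codon[two$recognized & two$trna == "trnLx"], "CTG")
  # an unresolvable double claim errors
  expect_error(recognized_codons(c(t1 = "TAA", t2 = "TAA")), "claimed")
})

make_rscu_tables <- function(n_org, skew, rec, seed) {
  set.seed(seed)
  sim <- simulate_cds(n_org, rec, skew = skew, codons_per_organism = 1500)
  do.call(rbind, lapply(split(sim$counts, sim$counts$organism),
                        function(d) {
    r <- rscu(d[, c("codon", "aa", "count")])
    r$organism <- d$organism[1]
    r$phylum <- "P"
    r
  }))
}

test_that("bias test recovers a planted skew and its inversion", {
  rec <- recognized_codons(c(trnL2 = "TAA", trnS1 = "GCT"))
  rt <- make_rscu_tables(50, 2, rec, seed = 10)
  res <- classify_and_test(rt, rec)
  expect_true(all(res$aa %in% c("L", "S")))
  expect_true(all(res$direction == "mtDNA-biased"))
  expect_true(all(res$q < 0.05))
  # inverted skew flips the call
  rt_inv <- make_rscu_tables(50, 0.5, rec, seed = 11)
  res_inv <- classify_and_test(rt_inv, rec)
  expect_true(all(res_inv$direction == "non-mtDNA-biased"))
  # no skew: identical sampling distributions stay nonsignificant mostly
  rt0 <- make_rscu_tables(50, 1, rec, seed = 12)
  res0 <- classify_and_test(rt0, rec)
  expect_true(mean(res0$direction == "nonsignificant") >= 0.5)
})

test_that("base-composition filter excludes by most-prevalent base", {
  # + strand usage with T dominant at position 1, T at position 2 and A
  # at position 3; brute-force expectation below
  usage <- data.frame(
    organism = "o1", phylum = "P", gene = "g1", strand = 1L,
    codon = c("TTA", "TTG", "CTA", "CTT", "GCC"),
    count = c(120L, 10L, 80L, 10L, 30L))
  rec <- recognized_codons(c(trnL2 = "TAA", trnS1 = "GCT"))
  rt <- make_rscu_tables(10, 2, rec, seed = 13)
  out <- base_composition_filter(usage, rt, rec)
  # independent tally: pos1 top T (130 vs 90/30), pos2 top T (220 vs
  # 30), pos3 top A (200): every usage codon with T at 1 or 2 or A at 3
  oracle_excluded <- c("TTA", "TTG", "CTA", "CTT")
  expect_setequal(out$excluded$codon, oracle_excluded)
  expect_false("GCC" %in% out$excluded$codon)
  # filtration never flips a planted direction
  before <- classify_and_test(rt, rec)
  merged <- merge(before, out$results, by = c("phylum", "aa"),
                  suffixes = c("_pre", "_post"))
  sig_both <- merged$direction_pre != "nonsignificant" &
    merged$direction_post != "nonsignificant"
  expect_true(all(merged$direction_pre[sig_both] ==
                    merged$direction_post[sig_both]))
})

test_that("dominant repertoire is the majority map", {
  r1 <- recognized_codons(c(trnL2 = "TAA"))
  r2 <- recognized_codons(c(trnS1 = "GCT"))
  dom <- dominant_repertoire(list(a = r1, b = r2, c = r1))
  expect_equal(dom$recognized, r1$recognized)
})
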