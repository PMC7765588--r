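# Genotype I/O, allele frequencies, HWE testing and MAF-rule coding.

test_that("VCF genotypes become minor-allele dosages", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("1", "100", "rsA", "C", "T", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "0/0"), collapse = "\t"),
    paste(c("1", "200", "rsB", "G", "A", ".", "PASS", ".", "GT",
            "1/1", "1/1", "0/1", "./."), collapse = "\t")
  ), vcf)
  g <- read_genotypes(vcf)
  # rsA: ALT freq 3/8 < 0.5, minor = ALT -> dosages as given
  expect_equal(unname(g$genotypes[, "rsA"]), c(0L, 1L, 2L, 0L))
  # rsB: ALT freq 5/6 > 0.5 -> flipped to count REF (the minor allele)
  expect_equal(unname(g$genotypes[, "rsB"]), c(0L, 0L, 1L, NA))
  expect_equal(g$variants$minor[g$variants$marker == "rsB"], "G")
})

test_that("VCF and CSV round trips preserve the dosage matrix", {
  co <- generate_cohort(small_config(), seed = 1)
  vcf <- tempfile(fileext = ".vcf")
  write_genotypes_vcf(co$genotypes, vcf, variants = co$markers)
  back <- suppressMessages(read_genotypes(vcf))
  got <- back$genotypes[, co$markers$marker]
  # the reader orients dosages to the observed minor allele, so columns
  # whose sample ALT frequency drifted above 0.5 come back flipped
  freq <- colMeans(co$genotypes) / 2
  expect_equal(unname(got[, freq <= 0.5]),
               unname(co$genotypes[, freq <= 0.5]))
  if (any(freq > 0.5))
    expect_equal(unname(got[, freq > 0.5]),
                 unname(2L - co$genotypes[, freq > 0.5]))
  csv <- tempfile(fileext = ".csv")
  write_genotypes_csv(co$genotypes, csv)
  back2 <- suppressMessages(read_genotypes(csv))
  expect_equal(unname(back2$genotypes), unname(co$genotypes))
  expect_equal(rownames(back2$genotypes), rownames(co$genotypes))
})

test_that("multi-allelic sites are rejected with the marker named", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("1", "100", "rsBad", "C", "T,G", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t")
  ), vcf)
  expect_error(read_genotypes(vcf), "rsBad")
})

test_that("allele frequencies follow the counting definition", {
  G <- matrix(0L, 10, 1, dimnames = list(NULL, "m"))
  expect_equal(unname(allele_frequencies(G)), 0)
  # counts (hom major, het, hom minor) = (91, 8, 1) -> (2 + 8)/200 = 0.05
  G2 <- matrix(c(rep(0L, 91), rep(1L, 8), rep(2L, 1)), ncol = 1,
               dimnames = list(NULL, "m"))
  expect_equal(unname(allele_frequencies(G2)), 0.05)
  # missing excluded from the denominator
  G3 <- matrix(c(0L, 1L, NA), ncol = 1)
  expect_equal(unname(allele_frequencies(G3)), 0.25)
  expect_error(allele_frequencies(G2, subset = integer(0)), "empty")
})

test_that("HWE chi-square matches hand computations", {
  h0 <- hwe_test(c(25, 50, 25))
  expect_equal(h0$chi2, 0)
  expect_equal(h0$p, 1)
  h1 <- hwe_test(c(30, 40, 30))
  expect_equal(h1$chi2, 4)
  expect_equal(h1$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(abs(h1$p - 0.0455), 5e-4)
  expect_warning(hm <- hwe_test(c(100, 0, 0)), "monomorphic")
  expect_equal(hm$p, 1)
  expect_true(hm$monomorphic)
})

test_that("HWE chi-square agrees with brute force on 1000 random triples", {
  set.seed(99)
  for (i in 1:1000) {
    cnt <- rmultinom(1, size = sample(20:500, 1),
                     prob = runif(3, 0.05, 1))[, 1]
    if (cnt[1] + cnt[2] == 0 || cnt[2] + cnt[3] == 0) next
    got <- hwe_test(cnt)$chi2
    want <- hwe_chi2_brute(cnt[1], cnt[2], cnt[3])
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("exact HWE test behaves sensibly on small counts", {
  p_ex <- hwe_test(c(5, 1, 4), method = "exact")$p
  expect_true(p_ex > 0 && p_ex <= 1)
  # near-equilibrium counts should not be flagged
  expect_gt(hwe_test(c(25, 50, 25), method = "exact")$p, 0.5)
})

test_that("MAF rule assigns additive vs presence/absence coding", {
  # frequencies engineered via the maf override
  G <- matrix(c(0L, 1L, 2L, 2L), ncol = 4,
              dimnames = list(NULL, c("hi", "lo", "edge", "below")))
  G <- G[rep(1, 6), , drop = FALSE]
  G[, "hi"] <- c(0L, 1L, 2L, 1L, 1L, 0L)
  G[, "lo"] <- c(0L, 0L, 0L, 1L, 2L, 0L)
  coded <- code_genotypes(G, maf = c(hi = 0.416, lo = 0.073,
                                     edge = 0.35, below = 0.349))
  coding <- attr(coded, "coding")
  expect_equal(unname(coding[c("hi", "lo", "edge", "below")]),
               c("additive3", "dominant2", "additive3", "dominant2"))
  expect_setequal(unique(coded[, "hi"]), c(0, 1, 2))
  expect_true(all(coded[, "lo"] %in% c(0, 1)))   # dosage 2 recoded to 1
  expect_equal(unname(coded[G[, "lo"] == 2, "lo"]), 1)
})

test_that("coding is idempotent and total", {
  co <- generate_cohort(small_config(), seed = 3)
  unrel <- co$subjects$role %in% c("proband", "control")
  c1 <- code_genotypes(co$genotypes, unrelated = unrel)
  c2 <- code_genotypes(c1, maf = attr(c1, "maf"))
  expect_equal(unname(c1), unname(c2))
  expect_false(anyNA(c1))
  expect_true(all(c1 %in% c(0, 1, 2)))
})

test_that("QC report mirrors the marker table with per-gene thresholds", {
  co <- generate_cohort(cohort_config(n_families = 200), seed = 13)
  unrel <- co$subjects$role %in% c("proband", "control")
  qc <- qc_report(co$genotypes, co$markers, unrelated = unrel)
  expect_equal(nrow(qc), 20)
  expect_equal(unique(qc$hwe_threshold[qc$gene == "DYX1C1"]), 0.017)
  expect_equal(unique(qc$hwe_threshold[qc$gene == "KIAA0319"]), 0.013)
  expect_equal(unique(qc$hwe_threshold[qc$gene == "GRIN2B"]), 0.008)
  expect_true(all(qc$coding[qc$maf >= 0.35] == "additive3"))
  expect_true(all(qc$coding[qc$maf < 0.35] == "dominant2"))
})

test_that("generated genotypes fail the HWE screen at about the alpha rate", {
  cfg <- cohort_config(n_families = 0, n_controls = 1000)
  rej <- logical(0)
  for (s in 1:10) {
    co <- generate_cohort(cfg, seed = 100 + s)
    counts <- t(apply(co$genotypes, 2, function(g)
      c(sum(g == 0), sum(g == 1), sum(g == 2))))
    rej <- c(rej, hwe_test(counts)$p < 0.05)
  }
  rate <- mean(rej)  # 200 marker draws in equilibrium
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})
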