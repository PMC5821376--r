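test_that("allele frequency follows direct allele counting", {
  expect_equal(allele_frequency(c(39, 39, 8)), 117 / 172)
  expect_equal(allele_frequency(c(10, 0, 0)), 1)
  expect_equal(allele_frequency(c(0, 0, 5)), 0)
  expect_error(allele_frequency(c(0, 0, 0)), "no genotyped")
})

test_that("HWE chi-square matches independent computation and handles edge cases", {
  res <- hwe_test(c(39, 39, 8))
  # independent oracle: direct chi-square arithmetic
  p <- 117 / 172
  exp_counts <- 86 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(39, 39, 8) - exp_counts)^2 / exp_counts)
  expect_equal(res$chi2, chi2)
  expect_equal(res$p_value, pchisq(chi2, 1, lower.tail = FALSE))
  expect_gt(res$p_value, 0.05)
  expect_equal(round(res$p_value, 2), 0.69)
  expect_equal(sum(res$expected), sum(res$observed))

  exact <- hwe_test(c(25, 50, 25))
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p_value, 1)

  extreme <- hwe_test(c(50, 0, 50))
  expect_lt(extreme$p_value, 1e-10)

  mono <- hwe_test(c(12, 0, 0))
  expect_true(mono$monomorphic)
  expect_equal(mono$p_value, 1)
})

test_that("HWE is invariant under swapping the risk/non-risk labels", {
  for (ct in list(c(39, 39, 8), c(35, 42, 9), c(44, 39, 3), c(5, 1, 30))) {
    expect_equal(hwe_test(ct)$chi2, hwe_test(rev(ct))$chi2)
  }
})

test_that("EM haplotype frequencies match the exhaustive grid-search oracle", {
  snps <- fkbp5_snps()[1:2]
  # the phase-ambiguous mixed instance
  dos <- cbind(rs3800373 = c(0L, 2L, 1L, 1L, 0L),
               rs9296158 = c(0L, 2L, 1L, 1L, 0L))
  gt <- genotype_table(sprintf("i%d", 1:5), dos, snps)
  est <- em_haplotype_frequencies(gt)
  oracle <- em_grid_oracle_2snp(dos) # order 00, 10, 01, 11
  expect_equal(unname(est$haplotype_frequencies[c("AG", "CG", "AA", "CA")]),
               unname(oracle), tolerance = 1e-3)

  # second instance with all four haplotypes plausibly present
  set.seed(42)
  dos2 <- cbind(rs3800373 = c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L),
                rs9296158 = c(1L, 1L, 2L, 0L, 0L, 2L, 1L, 2L))
  gt2 <- genotype_table(sprintf("j%d", 1:8), dos2, snps)
  est2 <- em_haplotype_frequencies(gt2)
  oracle2 <- em_grid_oracle_2snp(dos2)
  expect_equal(unname(est2$haplotype_frequencies[c("AG", "CG", "AA", "CA")]),
               unname(oracle2), tolerance = 1e-3)
})

test_that("EM handles unambiguous, single-SNP and missing-genotype inputs", {
  snps <- fkbp5_snps()[1:2]
  gt <- genotype_table(sprintf("i%d", 1:4),
                       cbind(rs3800373 = rep(0L, 4), rs9296158 = rep(0L, 4)),
                       snps)
  est <- em_haplotype_frequencies(gt)
  expect_equal(unname(est$haplotype_frequencies[["AG"]]), 1)
  expect_true(all(est$diplotypes$posterior == 1))

  # k = 1 reduces to allele frequencies
  gt1 <- genotype_table(sprintf("i%d", 1:4),
                        cbind(rs3800373 = c(0L, 1L, 1L, 2L)),
                        fkbp5_snps()[1])
  est1 <- em_haplotype_frequencies(gt1)
  expect_equal(unname(est1$haplotype_frequencies[c("A", "C")]), c(0.5, 0.5))

  # missing genotypes are excluded listwise but keep their table row
  gtm <- genotype_table(sprintf("i%d", 1:3),
                        cbind(rs3800373 = c(0L, NA, 2L),
                              rs9296158 = c(0L, 1L, 2L)), snps)
  estm <- em_haplotype_frequencies(gtm)
  expect_equal(estm$excluded_ids, "i2")
  expect_true(is.na(estm$diplotypes$hap1[2]))
  expect_equal(estm$n_used, 2)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(7)
  snps <- fkbp5_snps()[1:3]
  for (rep in 1:5) {
    dos <- matrix(sample(0:2, 3 * 12, replace = TRUE), ncol = 3,
                  dimnames = list(NULL, names(snps)))
    gt <- genotype_table(sprintf("i%d", 1:12), dos, snps)
    est <- em_haplotype_frequencies(gt)
    expect_true(all(diff(est$loglik_trace) >= -1e-9))
    expect_equal(sum(est$haplotype_frequencies), 1, tolerance = 1e-9)
  }
})

test_that("pairwise LD matches direct formula evaluation and is bounded", {
  perfect <- ld_pairwise(c(AG = 0.5, CA = 0.5, AA = 0, CG = 0))
  expect_equal(perfect$d_prime, 1)
  expect_equal(perfect$r_squared, 1)

  indep <- ld_pairwise(c(AG = 0.18, AA = 0.42, CG = 0.12, CA = 0.28))
  expect_equal(indep$d_prime, 0)
  expect_equal(indep$r_squared, 0)

  # direct arithmetic oracle
  f <- c(AG = 0.4, AA = 0.2, CG = 0.1, CA = 0.3)
  ld <- ld_pairwise(f)
  p_a <- 0.6
  p_b <- 0.5
  d <- 0.4 - p_a * p_b
  expect_equal(ld$r_squared, d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)))
  expect_equal(ld$d_prime, d / min(p_a * (1 - p_b), (1 - p_a) * p_b))

  expect_error(ld_pairwise(c(AG = 0.7, AA = 0.3, CG = 0, CA = 0)),
               "monomorphic")
})

test_that("LD is invariant to relabelling alleles at both loci", {
  set.seed(11)
  for (rep in 1:20) {
    f <- rgamma(4, 1)
    f <- f / sum(f)
    names(f) <- c("AG", "AA", "CG", "CA")
    ld1 <- ld_pairwise(f)
    swapped <- setNames(f, c("CA", "CG", "AA", "AG")) # both loci relabelled
    ld2 <- ld_pairwise(swapped)
    expect_equal(ld1$d_prime, ld2$d_prime, tolerance = 1e-12)
    expect_equal(ld1$r_squared, ld2$r_squared, tolerance = 1e-12)
    expect_true(ld1$d_prime >= 0 && ld1$d_prime <= 1)
    expect_true(ld1$r_squared >= 0 && ld1$r_squared <= 1)
  }
})

test_that("dominant SNP moderators reproduce the published group sizes", {
  gt <- study_count_genotypes()
  g1 <- assign_snp_moderator(gt, "rs3800373")
  expect_equal(as.vector(table(g1$groups$z)), c(39, 47))
  g5 <- assign_snp_moderator(gt, "rs4713916")
  expect_equal(as.vector(table(g5$groups$z)), c(44, 42))
  expect_length(g1$excluded_ids, 0)
  expect_error(assign_snp_moderator(gt, "rs3800373", coding = "recessive"),
               "unknown coding")
})

test_that("missing genotypes are excluded from SNP moderators", {
  gt <- genotype_table(c("a", "b", "c"),
                       cbind(rs3800373 = c(0L, NA, 2L)), fkbp5_snps()[1])
  g <- assign_snp_moderator(gt, "rs3800373")
  expect_equal(g$excluded_ids, "b")
  expect_equal(g$groups$z, c(0L, 1L))
})

test_that("haplotype moderator groups risk carriers vs reference and excludes others", {
  dip <- study_count_diplotypes()
  g <- assign_haplotype_moderator(dip)
  expect_equal(as.vector(table(g$groups$z)), c(41, 42))
  expect_length(g$excluded_ids, 3)
  expect_equal(nrow(g$groups) + length(g$excluded_ids), 86)

  one <- function(h1, h2) {
    assign_haplotype_moderator(tibble::tibble(individual_id = "x",
                                              hap1 = h1, hap2 = h2))
  }
  expect_equal(one("AGC", "CAT")$groups$z, 1L)
  expect_equal(one("AGC", "AAT")$groups$z, 0L)
  expect_equal(one("AAT", "CGC")$excluded_ids, "x")
})

test_that("genotype CSV reader handles allele pairs and dosages", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "individual_id,rs3800373,rs9296158",
    "a,A/A,0",
    "b,A/C,1",
    "c,C/C,2",
    "d,,NA"
  ), tmp)
  gt <- read_genotypes(tmp, fkbp5_snps()[1:2])
  expect_equal(unname(gt$dosages[, "rs3800373"]), c(0L, 1L, 2L, NA))
  expect_equal(unname(gt$dosages[, "rs9296158"]), c(0L, 1L, 2L, NA))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,rs3800373", "a,G/G"), bad)
  expect_error(read_genotypes(bad, fkbp5_snps()[1]), "allele not matching")
})

test_that("minimal VCF reader maps REF/ALT onto declared risk alleles", {
  skip_if_not_installed("vcfR")
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "6\t100\trs3800373\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "6\t200\trs9296158\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t./."
  ), tmp)
  gt <- read_vcf_genotypes(tmp, fkbp5_snps()[1:2])
  expect_equal(unname(gt$dosages[, "rs3800373"]), c(0L, 1L, 2L))
  # rs9296158 risk allele is A, here the REF: dosage counts REF alleles
  expect_equal(unname(gt$dosages[, "rs9296158"]), c(2L, 1L, NA))

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "6\t100\trs3800373\tG\tT\t.\tPASS\t.\tGT\t0/1"
  ), bad)
  expect_error(read_vcf_genotypes(bad, fkbp5_snps()[1]), "do not match")
})

test_that("snp_def validates alleles", {
  expect_error(snp_def("rs1", "A", "A"), "must differ")
  expect_error(snp_def("rs1", "A", "X"), "A/C/G/T")
})
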