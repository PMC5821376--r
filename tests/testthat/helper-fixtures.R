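# Fixture builders (all generated in code; nothing read from disk except
# the tiny text files written below at test time).

# Genotype table reproducing the published per-SNP genotype counts:
# rs3800373 39/39/8, rs9296158 39/41/6, rs1360780 36/42/8, rs9470080
# 35/42/9, rs4713916 44/39/3 (n = 86).
study_count_genotypes <- function() {
  counts <- list(
    rs3800373 = c(39, 39, 8),
    rs9296158 = c(39, 41, 6),
    rs1360780 = c(36, 42, 8),
    rs9470080 = c(35, 42, 9),
    rs4713916 = c(44, 39, 3)
  )
  dos <- sapply(counts, function(ct) rep(0:2, times = ct))
  genotype_table(sprintf("p%02d", 1:86), dos, fkbp5_snps())
}

# Diplotype table reproducing the published three-SNP haplotype groups:
# 33 AGC/AGC, 8 AGC/other, 35 AGC/CAT, 5 CAT/CAT, 2 CAT/other,
# 3 other/other (n = 86 -> 83 analysed).
study_count_diplotypes <- function() {
  rows <- rbind(
    cbind(rep("AGC", 33), rep("AGC", 33)),
    cbind(rep("AGC", 8), rep("AAT", 8)),
    cbind(rep("AGC", 35), rep("CAT", 35)),
    cbind(rep("CAT", 5), rep("CAT", 5)),
    cbind(rep("CAT", 2), rep("AAT", 2)),
    cbind(rep("AAT", 3), rep("CGC", 3))
  )
  tibble::tibble(individual_id = sprintf("p%02d", 1:86),
                 hap1 = rows[, 1], hap2 = rows[, 2])
}

# Wrap plain vectors as an analysis dataset.
fit_from_vectors <- function(x, z, y, covariate = NULL) {
  ids <- sprintf("i%03d", seq_along(x))
  phen <- data.frame(individual_id = ids, lesms = x, outcome = y)
  covs <- NULL
  if (!is.null(covariate)) {
    phen$cov1 <- covariate
    covs <- "cov1"
  }
  mod <- gxeds:::new_moderator_group(ids, z, character(0), "test")
  gxe_data(phen, outcome = "outcome", moderator = mod, covariates = covs)
}

# A noiseless study embedding given coefficients: phase-resolvable
# three-SNP genotypes whose CAT-carrier split is 41 reference / 42 risk
# (3 excluded), plus an environment spread across the observed range.
noiseless_hapl_study <- function(coefs = c(76.514, -2.724, 7.405, -12.651)) {
  dip <- rbind(
    cbind(rep("AGC", 41), rep("AGC", 41)),
    cbind(rep("AGC", 35), rep("CAT", 35)),
    cbind(rep("CAT", 5), rep("CAT", 5)),
    cbind(rep("AAT", 2), rep("CAT", 2)),
    cbind(rep("AAT", 3), rep("AAT", 3))
  )
  snps <- fkbp5_snps()[1:3]
  risk_dosage <- function(h, j) {
    (substr(h, j, j) == snps[[j]]$risk_allele)
  }
  dos <- sapply(1:3, function(j) {
    risk_dosage(dip[, 1], j) + risk_dosage(dip[, 2], j)
  })
  colnames(dos) <- names(snps)
  n <- nrow(dip)
  gt <- genotype_table(sprintf("s%02d", 1:n), dos, snps)
  z <- as.integer(dip[, 1] == "CAT" | dip[, 2] == "CAT")
  x <- seq(-1.5, 2.78, length.out = n)
  y <- coefs[1] + coefs[2] * x + coefs[3] * z + coefs[4] * x * z
  phen <- data.frame(individual_id = sprintf("s%02d", 1:n),
                     lesms = x, neuroticism = y)
  list(phenotypes = phen, genotypes = gt, z = z)
}
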