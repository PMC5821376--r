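#' Define a biallelic SNP with declared risk and non-risk alleles
#'
#' Risk/non-risk orientation is declared per SNP (as in the candidate-gene
#' literature) rather than inferred from frequency, so that dominant
#' "risk-carrier" coding is unambiguous.
#'
#' @param rsid SNP identifier (e.g. `"rs3800373"`).
#' @param non_risk_allele,risk_allele Single nucleotide characters in
#'   `A`, `C`, `G`, `T`; must differ.
#' @return An object of class `snp_def`.
#' @export
#' @examples
#' snp_def("rs3800373", "A", "C")
snp_def <- function(rsid, non_risk_allele, risk_allele) {
  stopifnot(is.character(rsid), length(rsid) == 1L, nzchar(rsid))
  for (a in c(non_risk_allele, risk_allele)) {
    if (!is.character(a) || length(a) != 1L || !a %in% c("A", "C", "G", "T")) {
      stop("alleles must be single characters in A/C/G/T", call. = FALSE)
    }
  }
  if (non_risk_allele == risk_allele) {
    stop("risk and non-risk alleles must differ", call. = FALSE)
  }
  structure(
    list(rsid = rsid, non_risk_allele = non_risk_allele,
         risk_allele = risk_allele),
    class = "snp_def"
  )
}

#' @export
print.snp_def <- function(x, ...) {
  cat(sprintf("<snp_def> %s  non-risk %s / risk %s\n",
              x$rsid, x$non_risk_allele, x$risk_allele))
  invisible(x)
}

#' The five FKBP5 SNPs analysed by the package's worked examples
#'
#' Risk/non-risk orientation follows the stress-endocrinology candidate-SNP
#' literature for FKBP5 (rs3800373 A/C, rs9296158 G/A, rs1360780 C/T,
#' rs9470080 C/T, rs4713916 G/A; risk allele second).  The first three form
#' the tag-SNP haplotype block (non-risk haplotype AGC, risk haplotype CAT).
#'
#' @return A named list of [snp_def()] objects.
#' @export
fkbp5_snps <- function() {
  defs <- list(
    snp_def("rs3800373", "A", "C"),
    snp_def("rs9296158", "G", "A"),
    snp_def("rs1360780", "C", "T"),
    snp_def("rs9470080", "C", "T"),
    snp_def("rs4713916", "G", "A")
  )
  names(defs) <- vapply(defs, `[[`, "", "rsid")
  defs
}

#' Construct a genotype table of risk-allele dosages
#'
#' @param ids Character vector of individual identifiers (unique).
#' @param dosages Numeric matrix, one row per individual and one column per
#'   SNP, holding the count of *risk* alleles (0, 1, 2) or `NA` for missing.
#'   Column names must match the rsids in `snps`.
#' @param snps List of [snp_def()] objects covering every column.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, dosages, snps) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique", call. = FALSE)
  if (nrow(dosages) != length(ids)) {
    stop("dosage rows must match number of ids", call. = FALSE)
  }
  if (is.null(colnames(dosages))) stop("dosage columns must be named by rsid",
                                       call. = FALSE)
  snps <- normalise_snp_list(snps)
  missing_def <- setdiff(colnames(dosages), names(snps))
  if (length(missing_def)) {
    stop("no snp_def supplied for: ", paste(missing_def, collapse = ", "),
         call. = FALSE)
  }
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  rownames(dosages) <- ids
  structure(
    list(ids = ids, dosages = dosages, snps = snps[colnames(dosages)]),
    class = "genotype_table"
  )
}

normalise_snp_list <- function(snps) {
  if (inherits(snps, "snp_def")) snps <- list(snps)
  stopifnot(is.list(snps), all(vapply(snps, inherits, TRUE, "snp_def")))
  names(snps) <- vapply(snps, `[[`, "", "rsid")
  snps
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d SNPs (%s)\n",
              length(x$ids), ncol(x$dosages),
              paste(colnames(x$dosages), collapse = ", ")))
  invisible(x)
}

#' Genotype counts (non-risk hom, het, risk hom) for one SNP
#'
#' @param genotypes A [genotype_table()].
#' @param rsid SNP identifier.
#' @return Integer vector of length 3, missing genotypes dropped.
#' @export
genotype_counts <- function(genotypes, rsid) {
  d <- dosage_column(genotypes, rsid)
  d <- d[!is.na(d)]
  c(sum(d == 0L), sum(d == 1L), sum(d == 2L))
}

dosage_column <- function(genotypes, rsid) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (!rsid %in% colnames(genotypes$dosages)) {
    stop("genotype table does not contain rsID '", rsid, "'", call. = FALSE)
  }
  genotypes$dosages[, rsid]
}

#' Non-risk allele frequency from genotype counts
#'
#' @param genotype_counts Integer vector `(hom non-risk, het, hom risk)`.
#' @return Frequency of the non-risk allele in `[0, 1]`.
#' @export
#' @examples
#' allele_frequency(c(39, 39, 8)) # 117/172
allele_frequency <- function(genotype_counts) {
  stopifnot(length(genotype_counts) == 3L, all(genotype_counts >= 0))
  total <- sum(genotype_counts)
  if (total == 0) stop("no genotyped individuals for this SNP", call. = FALSE)
  (2 * genotype_counts[[1]] + genotype_counts[[2]]) / (2 * total)
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit chi-square (no continuity
#' correction) of the three observed genotype counts against the p^2, 2pq,
#' q^2 expectation at the sample allele frequency.  A monomorphic SNP is
#' degenerate: chi-square 0, p = 1, flagged.
#'
#' @inheritParams allele_frequency
#' @return An object of class `hwe_test` with observed and expected counts,
#'   the statistic, the p-value and a `monomorphic` flag.
#' @export
#' @examples
#' hwe_test(c(39, 39, 8))
hwe_test <- function(genotype_counts) {
  stopifnot(length(genotype_counts) == 3L, all(genotype_counts >= 0))
  total <- sum(genotype_counts)
  if (total < 1) stop("need at least one genotyped individual", call. = FALSE)
  p <- allele_frequency(genotype_counts)
  expected <- total * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  monomorphic <- p %in% c(0, 1)
  if (monomorphic) {
    chi2 <- 0
    p_value <- 1
  } else {
    chi2 <- sum((genotype_counts - expected)^2 / expected)
    p_value <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    list(observed = as.integer(genotype_counts), expected = expected,
         allele_frequency_non_risk = p, chi2 = chi2, p_value = p_value,
         df = 1L, monomorphic = monomorphic),
    class = "hwe_test"
  )
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f (df = 1), p = %.4f%s\n", x$chi2,
              x$p_value, if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

## ---- EM haplotype-frequency estimation -------------------------------------

haplotype_labels <- function(snps) {
  k <- length(snps)
  combo <- as.matrix(expand.grid(rep(list(0:1), k))[, seq_len(k), drop = FALSE])
  apply(combo, 1L, function(h) {
    paste(mapply(function(s, a) if (a == 1L) s$risk_allele else s$non_risk_allele,
                 snps, h), collapse = "")
  }) -> labels
  list(matrix = combo, labels = labels)
}

#' Haplotype frequencies by expectation-maximisation
#'
#' Maximum-likelihood haplotype frequencies for a small set of linked
#' biallelic SNPs from unphased genotypes, assuming random union of
#' haplotypes (Hardy-Weinberg at the haplotype level).  Multiple seeded
#' random restarts guard against local optima; the best run by
#' log-likelihood is kept and each individual is assigned the
#' most-probable (posterior argmax) diplotype, with ties broken
#' lexicographically by haplotype string.  Individuals missing any of the
#' SNPs are excluded listwise.
#'
#' @param genotypes A [genotype_table()] (or dosage matrix with a matching
#'   `snps` list).
#' @param snps Optional character vector of rsids selecting/ordering the
#'   SNPs to phase; defaults to all columns.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param n_restarts Number of random restarts in addition to the uniform
#'   initialisation.
#' @param seed Integer seed controlling the restarts (results are
#'   deterministic given `seed`).
#' @return An object of class `haplotype_estimate`: haplotype frequencies
#'   (named, summing to one), a diplotype table with posterior
#'   probabilities, the log-likelihood and its per-iteration trace, and a
#'   convergence flag.
#' @export
em_haplotype_frequencies <- function(genotypes, snps = NULL, max_iter = 1000L,
                                     tol = 1e-8, n_restarts = 10L, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (is.null(snps)) snps <- colnames(genotypes$dosages)
  dos <- genotypes$dosages[, snps, drop = FALSE]
  defs <- genotypes$snps[snps]
  k <- ncol(dos)
  stopifnot(k >= 1L)
  complete <- complete.cases(dos)
  if (!any(complete)) {
    stop("no individual has complete genotypes for the requested SNPs",
         call. = FALSE)
  }
  use <- dos[complete, , drop = FALSE]
  hl <- haplotype_labels(defs)
  H <- hl$matrix
  labels <- hl$labels
  n_hap <- nrow(H)

  # Collapse identical multilocus genotypes; EM cost then depends on the
  # number of distinct patterns (<= 3^k), not on sample size.
  key <- apply(use, 1L, paste, collapse = ",")
  pat_keys <- unique(key)
  w <- as.numeric(table(factor(key, levels = pat_keys)))
  pats <- do.call(rbind, lapply(strsplit(pat_keys, ","), as.integer))

  # Compatible ordered pairs (a <= b) per pattern, with multiplicity 2 - [a==b].
  pair_idx <- lapply(seq_len(nrow(pats)), function(i) {
    g <- pats[i, ]
    out <- list()
    for (a in seq_len(n_hap)) {
      for (b in a:n_hap) {
        if (all(H[a, ] + H[b, ] == g)) out[[length(out) + 1L]] <- c(a, b)
      }
    }
    do.call(rbind, out)
  })
  if (any(vapply(pair_idx, is.null, TRUE))) {
    stop("internal error: genotype pattern with no compatible diplotype",
         call. = FALSE)
  }

  run_em <- function(f0) {
    f <- f0
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      counts <- numeric(n_hap)
      ll <- 0
      for (i in seq_along(pair_idx)) {
        pr <- pair_idx[[i]]
        coefm <- ifelse(pr[, 1L] == pr[, 2L], 1, 2)
        p_pair <- coefm * f[pr[, 1L]] * f[pr[, 2L]]
        tot <- sum(p_pair)
        ll <- ll + w[i] * log(tot)
        post <- p_pair / tot
        inc <- w[i] * post
        for (j in seq_len(nrow(pr))) {
          counts[pr[j, 1L]] <- counts[pr[j, 1L]] + inc[j]
          counts[pr[j, 2L]] <- counts[pr[j, 2L]] + inc[j]
        }
      }
      trace <- c(trace, ll)
      f <- counts / sum(counts)
      if (is.finite(ll_old) && ll - ll_old < tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(f = f, loglik = trace[length(trace)], trace = trace,
         converged = converged, n_iter = length(trace))
  }

  best <- run_em(rep(1 / n_hap, n_hap))
  if (n_restarts > 0L) {
    with_local_seed(seed, {
      for (r in seq_len(n_restarts)) {
        g <- stats::rgamma(n_hap, shape = 1)
        cand <- run_em(g / sum(g))
        if (cand$loglik > best$loglik + 1e-12) best <- cand
      }
    })
  }
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning best estimate",
            call. = FALSE)
  }
  f <- setNames(best$f, labels)

  # Posterior-argmax diplotype per complete individual, lexicographic ties.
  assign_one <- function(g) {
    i <- match(paste(g, collapse = ","), pat_keys)
    pr <- pair_idx[[i]]
    coefm <- ifelse(pr[, 1L] == pr[, 2L], 1, 2)
    p_pair <- coefm * f[pr[, 1L]] * f[pr[, 2L]]
    post <- p_pair / sum(p_pair)
    lab <- cbind(labels[pr[, 1L]], labels[pr[, 2L]])
    swap <- lab[, 1L] > lab[, 2L]
    lab[swap, ] <- lab[swap, 2:1]
    ord <- order(-round(post, 12), lab[, 1L], lab[, 2L])
    top <- ord[1L]
    c(lab[top, 1L], lab[top, 2L], post[top])
  }
  assigned <- t(apply(use, 1L, assign_one))
  diplotypes <- tibble::tibble(
    individual_id = genotypes$ids,
    hap1 = NA_character_, hap2 = NA_character_, posterior = NA_real_
  )
  diplotypes$hap1[complete] <- assigned[, 1L]
  diplotypes$hap2[complete] <- assigned[, 2L]
  diplotypes$posterior[complete] <- as.numeric(assigned[, 3L])

  structure(
    list(
      haplotype_frequencies = sort(f, decreasing = TRUE),
      diplotypes = diplotypes,
      log_likelihood = best$loglik,
      loglik_trace = best$trace,
      converged = best$converged,
      n_iter = best$n_iter,
      n_used = sum(complete),
      excluded_ids = genotypes$ids[!complete],
      snps = snps
    ),
    class = "haplotype_estimate"
  )
}

#' @export
print.haplotype_estimate <- function(x, ...) {
  cat(sprintf("<haplotype_estimate> %d SNPs (%s), n = %d, logLik = %.3f\n",
              length(x$snps), paste(x$snps, collapse = "-"), x$n_used,
              x$log_likelihood))
  f <- x$haplotype_frequencies
  shown <- f[f > 1e-6]
  cat(paste(sprintf("  %s %.4f", names(shown), shown), collapse = "\n"), "\n")
  invisible(x)
}

## ---- Linkage disequilibrium ------------------------------------------------

#' Pairwise linkage disequilibrium (D' and r^2) from haplotype frequencies
#'
#' @param haplotype_frequencies Named numeric vector of the four two-locus
#'   haplotype frequencies (names are two-character allele strings, e.g.
#'   `c(AC = 0.4, AT = 0.2, CC = 0.1, CT = 0.3)`), summing to one.  A
#'   `haplotype_estimate` over exactly two SNPs is also accepted.
#' @return An object of class `ld_stats` with `d`, `d_prime` and
#'   `r_squared`.  A monomorphic marginal is an error (LD is undefined,
#'   which is distinct from zero LD).
#' @export
ld_pairwise <- function(haplotype_frequencies) {
  if (inherits(haplotype_frequencies, "haplotype_estimate")) {
    haplotype_frequencies <- haplotype_frequencies$haplotype_frequencies
  }
  f <- haplotype_frequencies
  stopifnot(is.numeric(f), length(f) == 4L, !is.null(names(f)))
  if (abs(sum(f) - 1) > 1e-6) {
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  }
  if (any(nchar(names(f)) != 2L)) {
    stop("haplotype names must be two-character allele strings", call. = FALSE)
  }
  a1 <- substr(names(f), 1L, 1L)
  a2 <- substr(names(f), 2L, 2L)
  al1 <- sort(unique(a1))
  al2 <- sort(unique(a2))
  if (length(al1) != 2L || length(al2) != 2L) {
    stop("expected two alleles per locus", call. = FALSE)
  }
  p_a <- sum(f[a1 == al1[1L]])
  p_b <- sum(f[a2 == al2[1L]])
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    stop("monomorphic locus: linkage disequilibrium is undefined",
         call. = FALSE)
  }
  p_ab <- sum(f[a1 == al1[1L] & a2 == al2[1L]])
  d <- p_ab - p_a * p_b
  d_max <- if (d >= 0) {
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else {
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  }
  d_prime <- if (d == 0) 0 else abs(d) / d_max
  r_squared <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  structure(
    list(d = d, d_prime = min(d_prime, 1), r_squared = min(r_squared, 1)),
    class = "ld_stats"
  )
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("D' = %.4f, r^2 = %.4f\n", x$d_prime, x$r_squared))
  invisible(x)
}

#' Pairwise LD matrices across a set of SNPs
#'
#' Two-locus haplotype frequencies are estimated by EM for each SNP pair,
#' then summarised as D' and r^2.
#'
#' @inheritParams em_haplotype_frequencies
#' @return List with symmetric `d_prime` and `r_squared` matrices.
#' @export
ld_from_genotypes <- function(genotypes, snps = NULL, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (is.null(snps)) snps <- colnames(genotypes$dosages)
  stopifnot(length(snps) >= 2L)
  m <- matrix(NA_real_, length(snps), length(snps),
              dimnames = list(snps, snps))
  out <- list(d_prime = m, r_squared = m)
  for (i in seq_along(snps)[-length(snps)]) {
    for (j in (i + 1L):length(snps)) {
      est <- em_haplotype_frequencies(genotypes, snps = snps[c(i, j)],
                                      seed = seed)
      ld <- ld_pairwise(est$haplotype_frequencies)
      out$d_prime[i, j] <- out$d_prime[j, i] <- ld$d_prime
      out$r_squared[i, j] <- out$r_squared[j, i] <- ld$r_squared
    }
  }
  diag(out$d_prime) <- diag(out$r_squared) <- 1
  out
}

## ---- Moderator groups ------------------------------------------------------

new_moderator_group <- function(ids, z, excluded_ids, label) {
  structure(
    list(groups = tibble::tibble(individual_id = ids, z = as.integer(z)),
         excluded_ids = excluded_ids, label = label),
    class = "moderator_group"
  )
}

#' @export
print.moderator_group <- function(x, ...) {
  n <- table(factor(x$groups$z, levels = 0:1))
  cat(sprintf("<moderator_group> %s: %d reference (z=0) vs %d risk-carrier (z=1); %d excluded\n",
              x$label, n[["0"]], n[["1"]], length(x$excluded_ids)))
  invisible(x)
}

#' Dominant risk-carrier coding for a single SNP
#'
#' Individuals homozygous for the non-risk allele form the reference group
#' (z = 0); carriers of at least one risk allele form the risk group
#' (z = 1).  Missing genotypes are excluded.
#'
#' @param genotypes A [genotype_table()].
#' @param snp An [snp_def()] or an rsid present in the table.
#' @param coding Only `"dominant"` is implemented.
#' @return A `moderator_group`.
#' @export
assign_snp_moderator <- function(genotypes, snp, coding = "dominant") {
  if (!identical(coding, "dominant")) {
    stop("unknown coding '", coding, "'; only \"dominant\" is supported",
         call. = FALSE)
  }
  rsid <- if (inherits(snp, "snp_def")) snp$rsid else snp
  d <- dosage_column(genotypes, rsid)
  keep <- !is.na(d)
  new_moderator_group(
    ids = genotypes$ids[keep],
    z = as.integer(d[keep] > 0L),
    excluded_ids = genotypes$ids[!keep],
    label = rsid
  )
}

#' Risk-carrier coding from assigned diplotypes
#'
#' Carriers of at least one copy of the risk haplotype form the risk group
#' (z = 1).  The reference group (z = 0) carries at least one copy of the
#' reference haplotype and no risk haplotype.  Individuals carrying neither
#' haplotype (other/other diplotypes), or with unassigned diplotypes, are
#' excluded.
#'
#' @param diplotypes A `haplotype_estimate` or a data frame with columns
#'   `individual_id`, `hap1`, `hap2`.
#' @param risk_haplotype,reference_haplotype Haplotype allele strings.
#' @return A `moderator_group`.
#' @export
assign_haplotype_moderator <- function(diplotypes, risk_haplotype = "CAT",
                                       reference_haplotype = "AGC") {
  if (inherits(diplotypes, "haplotype_estimate")) {
    diplotypes <- diplotypes$diplotypes
  }
  stopifnot(all(c("individual_id", "hap1", "hap2") %in% names(diplotypes)))
  h1 <- diplotypes$hap1
  h2 <- diplotypes$hap2
  has_risk <- !is.na(h1) & (h1 == risk_haplotype | h2 == risk_haplotype)
  has_ref <- !is.na(h1) & (h1 == reference_haplotype | h2 == reference_haplotype)
  z <- ifelse(has_risk, 1L, ifelse(has_ref, 0L, NA_integer_))
  keep <- !is.na(z)
  new_moderator_group(
    ids = diplotypes$individual_id[keep],
    z = z[keep],
    excluded_ids = diplotypes$individual_id[!keep],
    label = paste0(risk_haplotype, "-carrier")
  )
}

## ---- File readers ----------------------------------------------------------

#' Read a genotype CSV/TSV
#'
#' Expects a header row with an `individual_id` column followed by one
#' column per rsid.  Genotypes may be allele pairs (`"A/C"`) or risk-allele
#' dosages (0/1/2); the format is auto-detected per column.  Empty cells,
#' `NA` and `./.` are treated as missing.
#'
#' @param path File path; tab- or comma-separated (auto-detected).
#' @param snps List of [snp_def()]s declaring risk alleles for every
#'   genotype column to read (extra columns in the file are ignored).
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, snps) {
  snps <- normalise_snp_list(snps)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE, colClasses = "character")
  if (!"individual_id" %in% names(df)) {
    stop("genotype file must contain an 'individual_id' column", call. = FALSE)
  }
  present <- intersect(names(snps), names(df))
  if (!length(present)) {
    stop("genotype file contains none of the requested rsids", call. = FALSE)
  }
  dos <- sapply(present, function(rsid) {
    parse_genotype_column(df[[rsid]], snps[[rsid]])
  })
  dos <- matrix(as.integer(dos), nrow = nrow(df),
                dimnames = list(NULL, present))
  genotype_table(df$individual_id, dos, snps[present])
}

parse_genotype_column <- function(x, snp) {
  x <- trimws(x)
  miss <- is.na(x) | x %in% c("", "NA", "./.", ".|.", ".")
  out <- rep(NA_integer_, length(x))
  vals <- x[!miss]
  if (!length(vals)) return(out)
  if (all(grepl("^[0-2]$", vals))) {
    out[!miss] <- as.integer(vals)
    return(out)
  }
  if (!all(grepl("^[ACGT][/|][ACGT]$", vals))) {
    stop("cannot parse genotypes for ", snp$rsid,
         ": expected 0/1/2 dosages or allele pairs like 'A/C'", call. = FALSE)
  }
  a1 <- substr(vals, 1L, 1L)
  a2 <- substr(vals, 3L, 3L)
  known <- c(snp$non_risk_allele, snp$risk_allele)
  if (!all(c(a1, a2) %in% known)) {
    stop("allele not matching declared risk/non-risk alleles for ", snp$rsid,
         call. = FALSE)
  }
  out[!miss] <- (a1 == snp$risk_allele) + (a2 == snp$risk_allele)
  out
}

#' Read biallelic SNP genotypes from a minimal VCF
#'
#' Reads GT fields only (requires the suggested \pkg{vcfR} package).  Each
#' requested rsid must be present as a biallelic SNP record whose REF/ALT
#' alleles match the declared non-risk/risk alleles (in either orientation);
#' any other allele pair is rejected rather than silently strand-flipped.
#'
#' @inheritParams read_genotypes
#' @return A [genotype_table()] with one column per requested rsid found.
#' @export
read_vcf_genotypes <- function(path, snps) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_genotypes() requires the 'vcfR' package", call. = FALSE)
  }
  snps <- normalise_snp_list(snps)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) { # single-record VCFs drop to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  present <- intersect(names(snps), fix[, "ID"])
  if (!length(present)) {
    stop("VCF contains none of the requested rsids", call. = FALSE)
  }
  dos <- sapply(present, function(rsid) {
    i <- match(rsid, fix[, "ID"])
    ref <- fix[i, "REF"]
    alt <- fix[i, "ALT"]
    def <- snps[[rsid]]
    if (!setequal(c(ref, alt), c(def$non_risk_allele, def$risk_allele))) {
      stop("REF/ALT alleles (", ref, "/", alt, ") do not match declared ",
           "alleles for ", rsid, call. = FALSE)
    }
    risk_code <- if (alt == def$risk_allele) "1" else "0"
    g <- gt[i, ]
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".")) return(NA_integer_)
      sum(a == risk_code)
    }, integer(1))
  })
  dos <- matrix(as.integer(dos), nrow = length(ids),
                dimnames = list(NULL, present))
  genotype_table(ids, dos, snps[present])
}
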