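#' Specify a study analysis plan
#'
#' Encodes which outcomes are regressed on which environment column under
#' which genetic moderators, with the options that govern the
#' differential-susceptibility indices.
#'
#' @param outcomes Character vector of outcome column names.
#' @param environment Environment column name (default `"lesms"`).
#' @param moderators Named list of moderator specs:
#'   `list(type = "snp", rsid = "rs3800373")` or
#'   `list(type = "haplotype", snps = c(...), risk = "CAT",
#'   reference = "AGC")`.
#' @param snps List of [snp_def()]s resolving every rsid used; defaults to
#'   [fkbp5_snps()].
#' @param covariates Optional covariate columns for Keller-adjusted models.
#' @param alpha Two-sided significance level.
#' @param eval_range Optional explicit `c(lower, upper)` evaluation-range
#'   override for the indices; default is the analysed sample's
#'   mean +/- 2 SD of the environment score.
#' @param compute_indices `"significant"` (indices only when the
#'   interaction p-value is below `alpha`, the convention of published
#'   interaction tables) or `"always"`.
#' @param out_dir Optional directory for report files and plots.
#' @param seed Seed for the (deterministic) EM restarts.
#' @return An object of class `analysis_plan`.
#' @export
analysis_plan <- function(outcomes, environment = "lesms", moderators,
                          snps = fkbp5_snps(), covariates = NULL,
                          alpha = 0.05, eval_range = NULL,
                          compute_indices = c("significant", "always"),
                          out_dir = NULL, seed = 1L) {
  compute_indices <- match.arg(compute_indices)
  stopifnot(is.character(outcomes), length(outcomes) >= 1L,
            is.list(moderators), length(moderators) >= 1L)
  snps <- normalise_snp_list(snps)
  if (is.null(names(moderators)) || any(!nzchar(names(moderators)))) {
    names(moderators) <- vapply(moderators, function(m) {
      if (m$type == "snp") m$rsid else "HAPL"
    }, "")
  }
  for (m in moderators) {
    if (!m$type %in% c("snp", "haplotype")) {
      stop("moderator type must be 'snp' or 'haplotype'", call. = FALSE)
    }
  }
  structure(
    list(outcomes = outcomes, environment = environment,
         moderators = moderators, snps = snps, covariates = covariates,
         alpha = alpha, eval_range = eval_range,
         compute_indices = compute_indices, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "analysis_plan"
  )
}

plan_rsids <- function(plan) {
  unique(unlist(lapply(plan$moderators, function(m) {
    if (m$type == "snp") m$rsid else m$snps
  })))
}

read_phenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (!nrow(df) || !"individual_id" %in% names(df)) {
    stop("phenotype file must be non-empty and contain 'individual_id'",
         call. = FALSE)
  }
  df
}

#' Run the full differential-susceptibility study analysis
#'
#' Executes, in order: descriptive statistics; per-SNP Hardy-Weinberg
#' tests, pairwise LD and (for haplotype moderators) EM haplotype
#' estimation and diplotype grouping; gene-environment correlation and sex
#' checks; environment normality; environment and genetic main-effect
#' models; and one moderated regression per (outcome, moderator) pair with
#' simple slopes.  For interactions passing the significance gate it adds
#' the curvilinearity check, the DS/DE indices with pattern
#' classification, a covariate-adjusted (Keller) model when covariates are
#' planned, and an interaction plot when an output directory is set.
#' Failures in individual pairs are recorded in the results table and
#' skipped, not silently dropped.
#'
#' @param plan An [analysis_plan()].
#' @param phenotypes Data frame or CSV/TSV path with `individual_id`, the
#'   outcome and environment columns, optionally `sex` and covariates.
#' @param genotypes A [genotype_table()] or genotype CSV/TSV path.
#' @return An object of class `study_report`; see [write_report()] for the
#'   file renderings.
#' @export
run_analysis <- function(plan, phenotypes, genotypes) {
  stopifnot(inherits(plan, "analysis_plan"))
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.character(genotypes)) {
    genotypes <- read_genotypes(genotypes, plan$snps)
  }
  stopifnot(inherits(genotypes, "genotype_table"))
  missing_cols <- setdiff(c(plan$outcomes, plan$environment, plan$covariates),
                          names(phenotypes))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rsids <- plan_rsids(plan)
  missing_rs <- setdiff(rsids, colnames(genotypes$dosages))
  if (length(missing_rs)) {
    stop("genotype data do not contain rsID(s): ",
         paste(missing_rs, collapse = ", "), call. = FALSE)
  }

  descriptives <- describe(phenotypes,
                           columns = c(plan$outcomes, plan$environment))

  hwe <- lapply(setNames(rsids, rsids), function(r) {
    hwe_test(genotype_counts(genotypes, r))
  })
  ld <- if (length(rsids) >= 2L) {
    ld_from_genotypes(genotypes, rsids, seed = plan$seed)
  } else NULL

  # Moderator construction (haplotype moderators need EM phasing first).
  haplotypes <- list()
  groups <- list()
  for (nm in names(plan$moderators)) {
    m <- plan$moderators[[nm]]
    if (m$type == "snp") {
      groups[[nm]] <- assign_snp_moderator(genotypes, m$rsid)
    } else {
      est <- em_haplotype_frequencies(genotypes, snps = m$snps,
                                      seed = plan$seed)
      haplotypes[[nm]] <- est
      risk <- if (is.null(m$risk)) "CAT" else m$risk
      ref <- if (is.null(m$reference)) "AGC" else m$reference
      groups[[nm]] <- assign_haplotype_moderator(est, risk, ref)
    }
  }

  x_all <- phenotypes[[plan$environment]]
  checks <- list(
    environment_normality = tryCatch(normality_check(x_all),
                                     error = function(e) conditionMessage(e)),
    ge_correlation = lapply(groups, function(g) {
      d <- merge(data.frame(individual_id = phenotypes$individual_id,
                            x = x_all), g$groups, by = "individual_id")
      d <- d[complete.cases(d), ]
      tryCatch(ge_correlation_check(d$x, d$z),
               error = function(e) conditionMessage(e))
    }),
    sex = sex_checks(phenotypes, c(plan$outcomes, plan$environment))
  )

  main_effects <- main_effect_models(plan, phenotypes, groups)

  rows <- list()
  plots <- character(0)
  for (oc in plan$outcomes) {
    for (nm in names(groups)) {
      rows[[paste(oc, nm)]] <- tryCatch(
        analyse_pair(plan, phenotypes, groups[[nm]], oc, nm),
        error = function(e) {
          tibble::tibble(outcome = oc, moderator = nm, n = NA_integer_,
                         error = conditionMessage(e))
        }
      )
    }
  }
  results <- do.call(rbind_fill, rows)

  report <- structure(
    list(plan = plan, descriptives = descriptives, hwe = hwe, ld = ld,
         haplotypes = haplotypes, moderators = groups, checks = checks,
         main_effects = main_effects, results = results),
    class = "study_report"
  )
  if (!is.null(plan$out_dir)) {
    write_report(report, plan$out_dir)
    report$plots <- write_interaction_plots(report, plan$out_dir)
  }
  report
}

# One moderated regression with everything the report row needs.
analyse_pair <- function(plan, phenotypes, group, outcome, moderator_name) {
  data <- suppressMessages(
    gxe_data(phenotypes, outcome = outcome, environment = plan$environment,
             moderator = group, covariates = plan$covariates)
  )
  fit <- fit_gxe(data)
  slopes <- simple_slopes(fit)
  p_b3 <- fit$p_values[["b3"]]
  significant <- is.finite(p_b3) && p_b3 < plan$alpha
  want_indices <- significant || plan$compute_indices == "always"

  row <- tibble::tibble(
    outcome = outcome, moderator = moderator_name, n = fit$n,
    b0 = fit$coefficients[["b0"]], b1 = fit$coefficients[["b1"]],
    b2 = fit$coefficients[["b2"]], b3 = fit$coefficients[["b3"]],
    adj_r_squared = fit$adj_r_squared, p_interaction = p_b3,
    significant = significant,
    slope_ref = slopes$estimate[1L], slope_ref_p = slopes$p[1L],
    slope_risk = slopes$estimate[2L],
    slope_risk_ci_lower = slopes$ci_lower[2L],
    slope_risk_ci_upper = slopes$ci_upper[2L],
    slope_risk_p = slopes$p[2L],
    error = NA_character_
  )
  if (want_indices) {
    env <- if (is.null(plan$eval_range)) {
      env_summary(x = data$x)
    } else {
      env_summary(range = plan$eval_range)
    }
    idx <- ds_indices(fit, env, alpha = plan$alpha)
    nl <- fit_nonlinear_check(data, alpha = plan$alpha)$nonlinearity
    row$ros_lower <- idx$ros_lower
    row$ros_upper <- idx$ros_upper
    row$left_side_significant <- idx$left_side_significant
    row$right_side_significant <- idx$right_side_significant
    row$poi <- idx$poi
    row$pa <- idx$pa
    row$crossover <- idx$crossover
    row$pattern <- idx$pattern
    row$nonlinearity_p <- nl$p_joint
    row$nonlinearity_detected <- nl$detected
    if (!is.null(plan$covariates) && length(plan$covariates)) {
      kfit <- fit_keller_adjusted(data)
      row$keller_p_interaction <- kfit$p_values[["b3"]]
    }
  }
  row
}

# rbind tibbles with differing columns, filling with NA.
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  filled <- lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[cols]
  })
  do.call(rbind, filled)
}

sex_checks <- function(phenotypes, columns) {
  if (!"sex" %in% names(phenotypes)) return(NULL)
  sexes <- unique(stats::na.omit(phenotypes$sex))
  if (length(sexes) != 2L) return(NULL)
  z <- as.integer(phenotypes$sex == sexes[1L])
  lapply(setNames(columns, columns), function(cc) {
    v <- phenotypes[[cc]]
    keep <- !is.na(v) & !is.na(z)
    tryCatch(ge_correlation_check(v[keep], z[keep]),
             error = function(e) conditionMessage(e))
  })
}

main_effect_models <- function(plan, phenotypes, groups) {
  x <- phenotypes[[plan$environment]]
  env_fx <- lapply(setNames(plan$outcomes, plan$outcomes), function(oc) {
    tryCatch({
      y <- phenotypes[[oc]]
      keep <- complete.cases(cbind(y, x))
      fit <- lm(y[keep] ~ x[keep])
      sm <- summary(fit)
      ci <- stats::confint(fit)[2L, ]
      list(estimate = unname(coef(fit)[2L]), p = sm$coefficients[2L, 4L],
           ci = unname(ci), n = sum(keep))
    }, error = function(e) conditionMessage(e))
  })
  gene_fx <- lapply(groups, function(g) {
    lapply(setNames(plan$outcomes, plan$outcomes), function(oc) {
      tryCatch({
        d <- merge(data.frame(individual_id = phenotypes$individual_id,
                              y = phenotypes[[oc]]), g$groups,
                   by = "individual_id")
        d <- d[complete.cases(d), ]
        fit <- lm(y ~ z, data = d)
        sm <- summary(fit)
        list(estimate = unname(coef(fit)[2L]), p = sm$coefficients[2L, 4L],
             n = nrow(d))
      }, error = function(e) conditionMessage(e))
    })
  })
  list(environment = env_fx, genetic = gene_fx)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d outcome(s) x %d moderator(s)\n",
              length(x$plan$outcomes), length(x$plan$moderators)))
  res <- x$results
  shown <- c("outcome", "moderator", "n", "b3", "p_interaction", "poi", "pa",
             "crossover", "pattern")
  print(as.data.frame(res[intersect(shown, names(res))]), digits = 3)
  invisible(x)
}

#' Write report files for a study analysis
#'
#' Two renderings of the same results: `results.tsv` with printed-style
#' rounding (3 decimals for coefficients, 2 for indices) in the column
#' order of published interaction tables, and `report.json` at full
#' precision including the dataset-level checks.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- as.data.frame(report$results)
  num3 <- intersect(c("b0", "b1", "b2", "b3", "adj_r_squared",
                      "p_interaction", "slope_ref", "slope_ref_p",
                      "slope_risk", "slope_risk_ci_lower",
                      "slope_risk_ci_upper", "slope_risk_p", "ros_lower",
                      "ros_upper", "crossover", "nonlinearity_p",
                      "keller_p_interaction"), names(res))
  num2 <- intersect(c("poi", "pa"), names(res))
  pretty <- res
  pretty[num3] <- lapply(pretty[num3], round, digits = 3)
  pretty[num2] <- lapply(pretty[num2], round, digits = 2)
  tsv <- file.path(dir, "results.tsv")
  utils::write.table(pretty, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  json <- file.path(dir, "report.json")
  payload <- list(
    descriptives = as.data.frame(report$descriptives),
    hwe = lapply(report$hwe, unclass),
    ld = report$ld,
    haplotype_frequencies = lapply(report$haplotypes, function(h) {
      as.list(h$haplotype_frequencies)
    }),
    moderator_sizes = lapply(report$moderators, function(g) {
      list(n0 = sum(g$groups$z == 0L), n1 = sum(g$groups$z == 1L),
           excluded = length(g$excluded_ids))
    }),
    checks = report$checks,
    main_effects = report$main_effects,
    results = res
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(c(tsv, json))
}

write_interaction_plots <- function(report, dir) {
  res <- report$results
  if (!"pattern" %in% names(res)) return(character(0))
  paths <- character(0)
  for (i in seq_len(nrow(res))) {
    if (is.na(res$pattern[i])) next
    fit <- as_gxe_fit(res$b0[i], res$b1[i], res$b2[i], res$b3[i])
    env_row <- report$descriptives$variable == report$plan$environment
    env <- if (is.null(report$plan$eval_range)) {
      env_summary(mean = report$descriptives$mean[env_row],
                  sd = report$descriptives$sd[env_row])
    } else {
      env_summary(range = report$plan$eval_range)
    }
    file <- file.path(dir, sprintf("interaction_%s_%s.png", res$outcome[i],
                                   res$moderator[i]))
    plot_interaction(fit, env, indices = NULL, file = file)
    paths <- c(paths, file)
  }
  paths
}

#' Descriptive statistics of phenotype columns
#'
#' Mean, SD, observed range and n per numeric column; when an item-to-scale
#' mapping is supplied, Cronbach's alpha is computed per scale from the
#' item covariance matrix.
#'
#' @param phenotypes Data frame or CSV/TSV path.
#' @param columns Columns to summarise (default: all numeric columns
#'   except `individual_id`).
#' @param items Optional named list mapping scale names to character
#'   vectors of item columns.
#' @return A tibble with one row per column (`variable`, `mean`, `sd`,
#'   `min`, `max`, `n`); scale alphas are attached as attribute
#'   `"cronbach_alpha"` (NA for degenerate scales).
#' @export
describe <- function(phenotypes, columns = NULL, items = NULL) {
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.null(columns)) {
    columns <- names(phenotypes)[vapply(phenotypes, is.numeric, TRUE)]
    columns <- setdiff(columns, "individual_id")
  }
  for (cc in columns) {
    if (!cc %in% names(phenotypes)) {
      stop("phenotype table lacks column '", cc, "'", call. = FALSE)
    }
    if (!is.numeric(phenotypes[[cc]])) {
      stop("column '", cc, "' is not numeric", call. = FALSE)
    }
  }
  col_stat <- function(f, proto = 0) {
    unname(vapply(columns, function(cc) f(phenotypes[[cc]]), proto))
  }
  out <- tibble::tibble(
    variable = columns,
    mean = col_stat(function(v) mean(v, na.rm = TRUE)),
    sd = col_stat(function(v) sd(v, na.rm = TRUE)),
    min = col_stat(function(v) suppressWarnings(min(v, na.rm = TRUE))),
    max = col_stat(function(v) suppressWarnings(max(v, na.rm = TRUE))),
    n = col_stat(function(v) sum(!is.na(v)), 0L)
  )
  if (!is.null(items)) {
    alphas <- vapply(items, function(it) {
      cronbach_alpha(as.matrix(phenotypes[it]))
    }, 0)
    attr(out, "cronbach_alpha") <- alphas
  }
  out
}

#' Cronbach's alpha from an item matrix
#'
#' Covariance-based internal consistency:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#' Returns `NA` (with a warning) when the total score has zero variance.
#'
#' @param items Numeric matrix, one column per item.
#' @return Alpha, or `NA` for degenerate input.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  stopifnot(ncol(items) >= 2L)
  items <- items[complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  total_var <- var(rowSums(items))
  if (!is.finite(total_var) || total_var == 0) {
    warning("total-score variance is zero; alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(items, 2L, var)) / total_var)
}

#' Published regression estimates reproduced by the package
#'
#' Summary statistics of a published FKBP5-by-recent-life-events study of
#' 86 nonclinical young adults (83 analysed for the haplotype moderator):
#' per (outcome, moderator) OLS coefficients of
#' `Y = b0 + b1 X + b2 Z + b3 XZ`, adjusted R-squared, the interaction
#' p-value, and — for the significant interactions — the risk-group simple
#' slope with its CI, the regions-of-significance bounds, PoI, PA and the
#' crossover point, exactly as printed.  These are inputs for worked
#' examples (the raw participant data are not public), not outputs of this
#' package.
#'
#' @return A tibble, one row per (outcome, moderator) pair.
#' @export
published_fits <- function() {
  path <- system.file("extdata", "fkbp5_les_published_fits.csv",
                      package = "gxeds", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Published environment-score summary used by the worked examples
#'
#' Mean 0.57, SD 0.98, and the +/- 2 SD evaluation range `[-1.401, 2.532]`
#' at which the published interaction plots and indices were computed.
#'
#' @return An [env_summary()].
#' @export
published_environment <- function() {
  env_summary(range = c(-1.401, 2.532))
}
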