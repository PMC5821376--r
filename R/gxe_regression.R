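#' Assemble an analysis dataset for a moderated regression
#'
#' Joins a phenotype table with a moderator group and applies listwise
#' deletion, reporting how many individuals were dropped and why.
#'
#' @param phenotypes Data frame with an `individual_id` column, the outcome
#'   and environment columns, and any covariates.
#' @param outcome Name of the outcome (criterion) column.
#' @param environment Name of the environment (predictor) column; default
#'   `"lesms"`, the mean subjective-impact score of recent life events.
#' @param moderator A `moderator_group` (see [assign_snp_moderator()]).
#' @param covariates Optional character vector of covariate column names.
#' @return A data frame of class `gxe_data` with columns `individual_id`,
#'   `y`, `x`, `z` and any covariates; attributes record the outcome name,
#'   moderator label and exclusion counts.
#' @export
gxe_data <- function(phenotypes, outcome, environment = "lesms", moderator,
                     covariates = NULL) {
  stopifnot(is.data.frame(phenotypes), inherits(moderator, "moderator_group"))
  needed <- c("individual_id", outcome, environment, covariates)
  missing_cols <- setdiff(needed, names(phenotypes))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- merge(
    data.frame(individual_id = as.character(phenotypes$individual_id),
               y = phenotypes[[outcome]], x = phenotypes[[environment]],
               phenotypes[covariates], check.names = FALSE,
               stringsAsFactors = FALSE),
    moderator$groups, by = "individual_id"
  )
  n_unmatched <- nrow(phenotypes) - nrow(df)
  complete <- complete.cases(df)
  n_incomplete <- sum(!complete)
  df <- df[complete, c("individual_id", "y", "x", "z", covariates)]
  if (n_unmatched + n_incomplete > 0) {
    message(sprintf(
      "gxe_data: %d individual(s) without moderator, %d with missing values dropped; n = %d analysed",
      n_unmatched, n_incomplete, nrow(df)))
  }
  if (!all(df$z %in% 0:1)) stop("moderator must be binary 0/1", call. = FALSE)
  p <- 4L + 3L * length(covariates)
  if (nrow(df) < p + 2L) {
    stop("too few complete observations (n = ", nrow(df), ") for ", p,
         " parameters", call. = FALSE)
  }
  structure(df, class = c("gxe_data", "data.frame"),
            outcome = outcome, environment = environment,
            moderator = moderator$label, covariates = covariates,
            n_dropped = n_unmatched + n_incomplete)
}

# Map lm term names onto the b0..b5 notation of the crossover-interaction
# model Y = b0 + b1 X + b2 Z + b3 XZ (+ b4 X^2 + b5 X^2 Z).
term_name_map <- c(
  "(Intercept)" = "b0", "x" = "b1", "z" = "b2", "x:z" = "b3",
  "I(x^2)" = "b4", "z:I(x^2)" = "b5", "I(x^2):z" = "b5"
)

rename_terms <- function(nm) {
  mapped <- term_name_map[nm]
  ifelse(is.na(mapped), nm, mapped)
}

check_design <- function(formula, data) {
  X <- model.matrix(formula, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design: column(s) ",
         paste(rename_terms(dropped), collapse = ", "),
         " are collinear with the rest of the model", call. = FALSE)
  }
  invisible(X)
}

new_gxe_fit <- function(lmfit, n, extra = list()) {
  sm <- summary(lmfit)
  co <- coef(sm)
  nm <- rename_terms(rownames(co))
  V <- vcov(lmfit)
  dimnames(V) <- list(nm, nm)
  out <- c(
    list(
      coefficients = setNames(co[, "Estimate"], nm),
      se = setNames(co[, "Std. Error"], nm),
      t_values = setNames(co[, "t value"], nm),
      p_values = setNames(co[, "Pr(>|t|)"], nm),
      vcov = V,
      df_residual = lmfit$df.residual,
      sigma = sm$sigma,
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      n = n,
      model = lmfit
    ),
    extra
  )
  structure(out, class = "gxe_fit")
}

#' Fit the crossover-interaction regression Y = b0 + b1 X + b2 Z + b3 XZ
#'
#' Ordinary least squares with the classical homoskedastic coefficient
#' covariance and two-sided t p-values on n - 4 residual degrees of
#' freedom.  By default X enters on its raw scale, so the crossover point
#' -b2/b3 is expressed in raw environment units; centring is an explicit
#' opt-in re-expression, never applied silently.
#'
#' @param data A [gxe_data()] dataset.
#' @param center If `TRUE`, X is mean-centred before fitting (re-expresses
#'   b0 and b2; slopes and the interaction are unchanged).
#' @return An object of class `gxe_fit` with coefficients named
#'   `b0`..`b3`, their covariance matrix, residual df, R-squared and
#'   adjusted R-squared, and per-coefficient p-values.
#' @export
fit_gxe <- function(data, center = FALSE) {
  stopifnot(inherits(data, "gxe_data"))
  df <- as.data.frame(data)
  x_center <- 0
  if (center) {
    x_center <- mean(df$x)
    df$x <- df$x - x_center
  }
  check_gxe_variation(df)
  f <- y ~ x + z + x:z
  check_design(f, df)
  fit <- lm(f, data = df)
  out <- new_gxe_fit(fit, n = nrow(df),
                     extra = list(centered = center, x_center = x_center))
  out
}

check_gxe_variation <- function(df) {
  if (length(unique(df$z)) < 2L) {
    stop("singular design: column z (moderator) is constant", call. = FALSE)
  }
  v <- tapply(df$x, df$z, var)
  if (any(v <= 0 | is.na(v))) {
    stop("singular design: column x has no variance within a moderator group",
         call. = FALSE)
  }
}

#' Wrap externally obtained coefficients as a `gxe_fit`
#'
#' Useful for computing crossover, PoI/PA and simple-slope point estimates
#' from published regression tables when the raw data (and hence the
#' coefficient covariance) are unavailable.
#'
#' @param b0,b1,b2,b3 Regression coefficients of
#'   `Y = b0 + b1 X + b2 Z + b3 XZ`.
#' @param vcov Optional 4x4 coefficient covariance matrix (rows/columns
#'   ordered b0..b3); required for regions of significance and standard
#'   errors.
#' @param df Residual degrees of freedom (n - 4 for the plain model).
#' @param n Analysed sample size.
#' @return A `gxe_fit`.
#' @export
as_gxe_fit <- function(b0, b1, b2, b3, vcov = NULL, df = NA_real_,
                       n = NA_integer_) {
  b <- c(b0 = unname(b0), b1 = unname(b1), b2 = unname(b2),
         b3 = unname(b3))
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    stopifnot(nrow(vcov) == 4L, ncol(vcov) == 4L)
    if (max(abs(vcov - t(vcov))) > 1e-8) {
      stop("vcov must be symmetric", call. = FALSE)
    }
    dimnames(vcov) <- list(names(b), names(b))
  }
  se <- if (is.null(vcov)) rep(NA_real_, 4L) else sqrt(diag(vcov))
  tv <- b / se
  pv <- if (is.na(df)) rep(NA_real_, 4L) else 2 * pt(-abs(tv), df)
  structure(
    list(coefficients = b, se = setNames(se, names(b)),
         t_values = tv, p_values = setNames(pv, names(b)),
         vcov = vcov, df_residual = df, sigma = NA_real_,
         r_squared = NA_real_, adj_r_squared = NA_real_, n = n,
         model = NULL, centered = FALSE, x_center = 0),
    class = "gxe_fit"
  )
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("<gxe_fit> Y = b0 + b1 X + b2 Z + b3 XZ",
      if (!is.null(x$nonlinearity)) "+ b4 X^2 + b5 X^2 Z", "\n")
  b <- x$coefficients
  p <- x$p_values
  for (nm in names(b)) {
    cat(sprintf("  %-4s %10.4f   p = %s\n", nm, b[[nm]],
                ifelse(is.na(p[[nm]]), "NA", format.pval(p[[nm]], digits = 3))))
  }
  if (!is.na(x$adj_r_squared)) {
    cat(sprintf("  n = %d, adjusted R^2 = %.3f\n", x$n, x$adj_r_squared))
  }
  invisible(x)
}

#' Simple slopes of the environment at each moderator level
#'
#' The slope of Y on X is `b1` in the reference group (Z = 0) and
#' `b1 + b3` among risk carriers (Z = 1); the latter's variance is
#' `var(b1) + var(b3) + 2 cov(b1, b3)`.  Confidence intervals use the t
#' distribution on the fit's residual degrees of freedom.
#'
#' @param fit A `gxe_fit`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per moderator level (0 then 1):
#'   `estimate`, `se`, `ci_lower`, `ci_upper`, `t`, `p`.
#' @export
simple_slopes <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gxe_fit"))
  b <- fit$coefficients
  est <- c(b[["b1"]], b[["b1"]] + b[["b3"]])
  if (is.null(fit$vcov)) {
    se <- rep(NA_real_, 2L)
  } else {
    V <- fit$vcov
    se <- sqrt(c(V["b1", "b1"],
                 V["b1", "b1"] + V["b3", "b3"] + 2 * V["b1", "b3"]))
  }
  tcrit <- if (is.na(fit$df_residual)) NA_real_ else {
    qt(1 - (1 - level) / 2, fit$df_residual)
  }
  tv <- est / se
  tibble::tibble(
    moderator_level = c(0L, 1L),
    estimate = est,
    se = se,
    ci_lower = est - tcrit * se,
    ci_upper = est + tcrit * se,
    t = tv,
    p = 2 * pt(-abs(tv), fit$df_residual)
  )
}

#' Curvilinearity check: add X^2 and X^2 Z terms
#'
#' Refits the interaction model with quadratic environment terms
#' (`b4 X^2`, `b5 X^2 Z`) to rule out nonlinear effects masquerading as a
#' linear crossover interaction — a prerequisite for reading an
#' interaction as differential susceptibility.  The detection flag uses
#' the joint F test of the two quadratic terms.
#'
#' @inheritParams fit_gxe
#' @param alpha Significance level for the detection flag.
#' @return A `gxe_fit` whose `nonlinearity` element holds `p_b4`, `p_b5`,
#'   the joint `p_joint`, and `detected`.
#' @export
fit_nonlinear_check <- function(data, center = FALSE, alpha = 0.05) {
  stopifnot(inherits(data, "gxe_data"))
  df <- as.data.frame(data)
  x_center <- 0
  if (center) {
    x_center <- mean(df$x)
    df$x <- df$x - x_center
  }
  check_gxe_variation(df)
  f_full <- y ~ x + z + x:z + I(x^2) + I(x^2):z
  check_design(f_full, df)
  fit_base <- lm(y ~ x + z + x:z, data = df)
  fit_full <- lm(f_full, data = df)
  # With an (essentially) exact linear fit the residuals are machine
  # noise and the F ratio is meaningless; there is nothing left to detect.
  if (summary(fit_base)$sigma < 1e-10 * max(sd(df$y), 1)) {
    p_joint <- NA_real_
  } else {
    cmp <- anova(fit_base, fit_full)
    p_joint <- cmp[["Pr(>F)"]][2L]
  }
  out <- new_gxe_fit(fit_full, n = nrow(df),
                     extra = list(centered = center, x_center = x_center))
  out$nonlinearity <- list(
    p_b4 = out$p_values[["b4"]],
    p_b5 = out$p_values[["b5"]],
    p_joint = p_joint,
    detected = is.finite(p_joint) && p_joint < alpha
  )
  out
}

#' Covariate-interaction (Keller) adjusted GxE model
#'
#' Guards against confounded interactions by entering, for every covariate
#' C, its main effect plus the C-by-environment and C-by-gene product
#' terms in the same model as the gene-by-environment term.  No three-way
#' terms are added.
#'
#' @inheritParams fit_gxe
#' @return A `gxe_fit` including the covariate terms; the GxE interaction
#'   p-value in the expanded model is `fit$p_values[["b3"]]`.
#' @export
fit_keller_adjusted <- function(data, center = FALSE) {
  stopifnot(inherits(data, "gxe_data"))
  covariates <- attr(data, "covariates")
  if (is.null(covariates) || !length(covariates)) {
    stop("fit_keller_adjusted() needs at least one covariate in the dataset",
         call. = FALSE)
  }
  df <- as.data.frame(data)
  x_center <- 0
  if (center) {
    x_center <- mean(df$x)
    df$x <- df$x - x_center
  }
  check_gxe_variation(df)
  cv <- paste0("`", covariates, "`")
  rhs <- paste(c("x", "z", "x:z", cv, paste0(cv, ":x"), paste0(cv, ":z")),
               collapse = " + ")
  f <- stats::as.formula(paste("y ~", rhs))
  check_design(f, df)
  fit <- lm(f, data = df)
  new_gxe_fit(fit, n = nrow(df),
              extra = list(centered = center, x_center = x_center,
                           covariates = covariates))
}

#' Gene-environment correlation check
#'
#' Pooled-variance two-sample t-test of the environment score across the
#' two moderator groups, with Cohen's d.  A genuine G-E association would
#' make a moderated-regression interaction hard to interpret, so this is
#' run before the GxE models.
#'
#' @param x Numeric environment scores.
#' @param z Binary moderator (0/1), same length.
#' @param level Confidence level for the d interval.
#' @return List with `t`, `df`, `p`, `d`, `d_ci`, and the group means.
#' @export
ge_correlation_check <- function(x, z, level = 0.95) {
  stopifnot(length(x) == length(z), all(z %in% 0:1))
  n0 <- sum(z == 0)
  n1 <- sum(z == 1)
  if (min(n0, n1) < 2L) {
    stop("each moderator group needs at least two observations", call. = FALSE)
  }
  tt <- t.test(x[z == 1], x[z == 0], var.equal = TRUE)
  sp <- sqrt(((n1 - 1) * var(x[z == 1]) + (n0 - 1) * var(x[z == 0])) /
               (n0 + n1 - 2))
  d <- if (sp == 0) 0 else (mean(x[z == 1]) - mean(x[z == 0])) / sp
  se_d <- sqrt((n0 + n1) / (n0 * n1) + d^2 / (2 * (n0 + n1)))
  zq <- qnorm(1 - (1 - level) / 2)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, d = d, d_ci = c(d - zq * se_d, d + zq * se_d),
    mean_reference = mean(x[z == 0]), mean_risk = mean(x[z == 1])
  )
}

#' Shapiro-Wilk normality check of the environment score
#'
#' The Proportion Affected index assumes a normally distributed
#' environment score; this wraps the standard Shapiro-Wilk test with
#' explicit degenerate-input handling.
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `statistic` (W) and `p`.
#' @export
normality_check <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  }
  if (sd(x) == 0) {
    stop("environment score is constant; normality is undefined",
         call. = FALSE)
  }
  sw <- shapiro.test(x)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}
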