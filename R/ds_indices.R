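#' Summarise the environment score and its evaluation range
#'
#' Regions of significance and the Proportion of Interaction depend on the
#' range of the predictor, so by convention they are evaluated at +/- 2 SD
#' around its mean.  Either supply `mean` and `sd` (range derived), or an
#' explicit `range` (mean and SD derived as midpoint and quarter-width,
#' which is what the +/- 2 SD convention implies).
#'
#' @param mean,sd Mean and standard deviation of the environment score.
#' @param range Optional explicit `c(lower, upper)` evaluation range
#'   override.
#' @param x Optional raw environment vector from which mean/sd are
#'   computed.
#' @return An object of class `env_summary` with `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
#' @examples
#' env_summary(mean = 0.57, sd = 0.98)
#' env_summary(range = c(-1.401, 2.532))
env_summary <- function(mean = NULL, sd = NULL, range = NULL, x = NULL) {
  if (!is.null(x)) {
    mean <- base::mean(x, na.rm = TRUE)
    sd <- stats::sd(x, na.rm = TRUE)
  }
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1L] < range[2L])
    if (is.null(mean)) mean <- (range[1L] + range[2L]) / 2
    if (is.null(sd)) sd <- (range[2L] - range[1L]) / 4
    lower <- range[1L]
    upper <- range[2L]
  } else {
    stopifnot(is.numeric(mean), is.numeric(sd))
    if (sd <= 0) stop("environment SD must be positive", call. = FALSE)
    lower <- mean - 2 * sd
    upper <- mean + 2 * sd
  }
  if (sd <= 0) stop("environment SD must be positive", call. = FALSE)
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper),
            class = "env_summary")
}

#' @export
print.env_summary <- function(x, ...) {
  cat(sprintf("<env_summary> mean %.3f, sd %.3f, evaluation range [%.3f, %.3f]\n",
              x$mean, x$sd, x$lower, x$upper))
  invisible(x)
}

fit_b <- function(fit, name) fit$coefficients[[name]]

#' Crossover point of a moderated regression
#'
#' The environment value at which the two moderator groups' predicted
#' outcomes coincide: the group difference is `b2 + b3 x`, so the lines
#' intersect at `x = -b2/b3`.
#'
#' @param fit A `gxe_fit`.
#' @param tol Relative tolerance below which `|b3|` (against `|b2|`) draws
#'   a far-outside-range warning.
#' @return The crossover point in environment units.
#' @export
#' @examples
#' crossover(as_gxe_fit(76.514, -2.724, 7.405, -12.651)) # 0.585
crossover <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "gxe_fit"))
  b2 <- fit_b(fit, "b2")
  b3 <- fit_b(fit, "b3")
  if (b3 == 0) {
    stop("no interaction (b3 = 0): the regression lines are parallel",
         call. = FALSE)
  }
  if (abs(b3) < tol * max(abs(b2), 1)) {
    warning("b3 is negligible relative to b2; crossover lies far outside ",
            "any plausible range", call. = FALSE)
  }
  -b2 / b3
}

# Pointwise t statistic for the group difference b2 + b3 x.
diff_t <- function(fit, x) {
  V <- fit$vcov
  num <- fit_b(fit, "b2") + fit_b(fit, "b3") * x
  den <- sqrt(V["b2", "b2"] + x^2 * V["b3", "b3"] + 2 * x * V["b2", "b3"])
  num / den
}

#' Johnson-Neyman regions of significance on the environment axis
#'
#' Solves for the environment values at which the between-group difference
#' `b2 + b3 x` is exactly at the two-sided t criterion,
#' `(b2 + b3 x)^2 = t^2 (var(b2) + x^2 var(b3) + 2 x cov(b2, b3))`,
#' a quadratic in `x`.  Outside the band between the two roots the groups
#' differ significantly.  Side significance is reported within the
#' evaluation range: the left (negative-environment) and right
#' (positive-environment) flags are the pointwise tests at the range
#' endpoints, which is also the fallback when the quadratic has no real
#' roots.
#'
#' @param fit A `gxe_fit` with a coefficient covariance matrix.
#' @param env An [env_summary()].
#' @param alpha Two-sided significance level.
#' @return An object of class `ros_x`: `lower`, `upper` (ordered roots, or
#'   `NA` when no finite boundary exists), `left_side_significant`,
#'   `right_side_significant`, and the critical t value.
#' @export
ros_on_x <- function(fit, env, alpha = 0.05) {
  stopifnot(inherits(fit, "gxe_fit"), inherits(env, "env_summary"))
  if (is.null(fit$vcov)) {
    stop("regions of significance require the coefficient covariance matrix",
         call. = FALSE)
  }
  df <- fit$df_residual
  if (is.na(df) || df < 1) stop("residual df must be >= 1", call. = FALSE)
  tcrit <- qt(1 - alpha / 2, df)
  V <- fit$vcov
  b2 <- fit_b(fit, "b2")
  b3 <- fit_b(fit, "b3")
  A <- b3^2 - tcrit^2 * V["b3", "b3"]
  B <- 2 * (b2 * b3 - tcrit^2 * V["b2", "b3"])
  C <- b2^2 - tcrit^2 * V["b2", "b2"]
  disc <- B^2 - 4 * A * C
  if (disc >= 0 && abs(A) > 0) {
    roots <- sort(c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A)))
  } else if (abs(A) == 0 && B != 0) {
    roots <- c(-C / B, NA_real_)
  } else {
    roots <- c(NA_real_, NA_real_)
  }
  structure(
    list(
      lower = roots[1L], upper = roots[2L],
      left_side_significant = abs(diff_t(fit, env$lower)) > tcrit,
      right_side_significant = abs(diff_t(fit, env$upper)) > tcrit,
      t_critical = tcrit, alpha = alpha, df = df, env = env
    ),
    class = "ros_x"
  )
}

#' @export
print.ros_x <- function(x, ...) {
  cat(sprintf(
    "RoS on X: non-significant band [%.3f, %.3f]; significant at left edge: %s, right edge: %s\n",
    x$lower, x$upper, x$left_side_significant, x$right_side_significant))
  invisible(x)
}

#' Declare whether higher outcome values are worse
#'
#' Needed to orient the "for-better" side of a crossover interaction.  All
#' four anxiety-spectrum outcomes in the package's worked examples
#' (depressive symptoms, state anxiety, neuroticism, social anxiety) are
#' higher-is-worse.
#'
#' @param higher_is_worse Logical scalar.
#' @return An object of class `outcome_polarity`.
#' @export
outcome_polarity <- function(higher_is_worse = TRUE) {
  stopifnot(is.logical(higher_is_worse), length(higher_is_worse) == 1L)
  structure(list(higher_is_worse = higher_is_worse),
            class = "outcome_polarity")
}

# The for-better side is where the risk group's predicted outcome is
# *better* than the reference group's.  The risk-minus-reference difference
# is b2 + b3 x, so with a negative interaction and a higher-is-worse
# outcome the for-better side is the right (positive-environment) side.
for_better_right <- function(b3, polarity) {
  if (b3 == 0) stop("no interaction (b3 = 0)", call. = FALSE)
  (b3 < 0) == polarity$higher_is_worse
}

#' Proportion of Interaction (PoI)
#'
#' The fraction of the total area between the two group regression lines,
#' over the evaluation range, that lies on the for-better side of the
#' crossover.  For straight lines the areas are triangles, so when the
#' for-better side is the right side the index reduces to
#' `(upper - xc)^2 / ((upper - xc)^2 + (xc - lower)^2)` with the crossover
#' clamped to the range (PoI is 1 when the crossover falls at or below the
#' lower limit, 0 at or above the upper limit).  Values between 0.40 and
#' 0.60 are read as consistent with differential susceptibility; values
#' approaching 0 as diathesis-stress.
#'
#' @param fit A `gxe_fit` (only b2 and b3 are used).
#' @param env An [env_summary()].
#' @param polarity An [outcome_polarity()].
#' @return PoI in `[0, 1]`.
#' @export
#' @examples
#' poi(as_gxe_fit(76.944, 0.013, 4.113, -12.464),
#'     env_summary(range = c(-1.401, 2.532))) # 0.62
poi <- function(fit, env, polarity = outcome_polarity()) {
  stopifnot(inherits(fit, "gxe_fit"), inherits(env, "env_summary"))
  b3 <- fit_b(fit, "b3")
  xc <- crossover(fit)
  right_better <- for_better_right(b3, polarity)
  xcc <- min(max(xc, env$lower), env$upper)
  right_area <- (env$upper - xcc)^2
  left_area <- (xcc - env$lower)^2
  if (right_better) {
    right_area / (right_area + left_area)
  } else {
    left_area / (right_area + left_area)
  }
}

#' Proportion Affected (PA)
#'
#' The proportion of the population falling on the for-better side of the
#' crossover point, under a normality assumption for the environment
#' score: `1 - pnorm((xc - mean)/sd)` when the for-better side is the
#' right side.  PA above 0.16 is read as supporting differential
#' susceptibility; below 0.02 as definitely diathesis-stress.
#'
#' @param crossover Crossover point in environment units.
#' @param env An [env_summary()] (its `mean` and `sd` are used).
#' @param for_better_right Is the for-better side the positive-environment
#'   side? (Default `TRUE`, the configuration of a negative interaction on
#'   a higher-is-worse outcome.)
#' @return PA in `[0, 1]`.
#' @export
#' @examples
#' pa(0.57, env_summary(mean = 0.57, sd = 0.98)) # 0.5
pa <- function(crossover, env, for_better_right = TRUE) {
  stopifnot(inherits(env, "env_summary"), env$sd > 0)
  p_right <- 1 - pnorm((crossover - env$mean) / env$sd)
  if (for_better_right) p_right else 1 - p_right
}

#' Classify a crossover interaction
#'
#' Decision rules combining the regions-of-significance side tests, PoI
#' and PA:
#' * `differential_susceptibility`: both sides significant, PoI in
#'   `[0.40, 0.60]` and PA > 0.16;
#' * `diathesis_stress`: only the left (negative-environment) side
#'   significant and PoI < 0.40;
#' * `vantage_sensitivity`: only the right (positive-environment) side
#'   significant and PoI > 0.60;
#' * `no_interaction`: neither side significant;
#' * otherwise `inconclusive`.
#'
#' @param indices A `ds_indices` object, or `NULL` if supplying the
#'   components directly.
#' @param left_side_significant,right_side_significant,poi,pa Components,
#'   taken from `indices` when given.
#' @return The pattern label (character scalar).
#' @export
classify_pattern <- function(indices = NULL, left_side_significant = NULL,
                             right_side_significant = NULL, poi = NULL,
                             pa = NULL) {
  if (!is.null(indices)) {
    stopifnot(inherits(indices, "ds_indices"))
    left_side_significant <- indices$left_side_significant
    right_side_significant <- indices$right_side_significant
    poi <- indices$poi
    pa <- indices$pa
  }
  if (is.na(left_side_significant) || is.na(right_side_significant)) {
    return("inconclusive")
  }
  if (!left_side_significant && !right_side_significant) {
    return("no_interaction")
  }
  if (left_side_significant && right_side_significant &&
      poi >= 0.40 && poi <= 0.60 && pa > 0.16) {
    return("differential_susceptibility")
  }
  if (left_side_significant && !right_side_significant && poi < 0.40) {
    return("diathesis_stress")
  }
  if (!left_side_significant && right_side_significant && poi > 0.60) {
    return("vantage_sensitivity")
  }
  "inconclusive"
}

#' Differential-susceptibility / diathesis-stress indices for a fit
#'
#' Computes the crossover point, regions of significance on X (when the
#' coefficient covariance is available), PoI and PA, and classifies the
#' pattern.
#'
#' @param fit A `gxe_fit`.
#' @param env An [env_summary()].
#' @param polarity An [outcome_polarity()].
#' @param alpha Two-sided significance level for the regions of
#'   significance.
#' @return An object of class `ds_indices`.
#' @export
ds_indices <- function(fit, env, polarity = outcome_polarity(),
                       alpha = 0.05) {
  stopifnot(inherits(fit, "gxe_fit"), inherits(env, "env_summary"))
  xc <- crossover(fit)
  right_better <- for_better_right(fit_b(fit, "b3"), polarity)
  ros <- NULL
  left_sig <- NA
  right_sig <- NA
  if (!is.null(fit$vcov) && !is.na(fit$df_residual)) {
    ros <- ros_on_x(fit, env, alpha = alpha)
    left_sig <- ros$left_side_significant
    right_sig <- ros$right_side_significant
  }
  poi_val <- poi(fit, env, polarity)
  pa_val <- pa(xc, env, for_better_right = right_better)
  out <- structure(
    list(
      crossover = xc,
      ros_lower = if (is.null(ros)) NA_real_ else ros$lower,
      ros_upper = if (is.null(ros)) NA_real_ else ros$upper,
      left_side_significant = left_sig,
      right_side_significant = right_sig,
      poi = poi_val,
      pa = pa_val,
      for_better_right = right_better,
      env = env, alpha = alpha
    ),
    class = "ds_indices"
  )
  out$pattern <- classify_pattern(out)
  out
}

#' @export
print.ds_indices <- function(x, ...) {
  cat(sprintf(
    "crossover %.3f | RoS [%.3f, %.3f] sig left %s / right %s | PoI %.2f | PA %.2f\npattern: %s\n",
    x$crossover, x$ros_lower, x$ros_upper, x$left_side_significant,
    x$right_side_significant, x$poi, x$pa, x$pattern))
  invisible(x)
}

#' Plot a crossover interaction with shaded regions of significance
#'
#' Draws the two group regression lines over the evaluation range, marks
#' the crossover point, and shades the sub-intervals where the groups
#' differ significantly (none when no region is significant).
#'
#' @param fit A `gxe_fit`.
#' @param env An [env_summary()].
#' @param indices Optional precomputed [ds_indices()]; computed here when
#'   omitted and the fit carries a covariance matrix.
#' @param file Optional output path (PNG/SVG/PDF by extension) written via
#'   [ggplot2::ggsave()].
#' @param labels Group labels for the legend, reference first.
#' @return The ggplot object, invisibly.
#' @export
plot_interaction <- function(fit, env, indices = NULL, file = NULL,
                             labels = c("non-risk (Z=0)", "risk carrier (Z=1)")) {
  stopifnot(inherits(fit, "gxe_fit"), inherits(env, "env_summary"))
  b <- fit$coefficients
  if (is.null(indices) && !is.null(fit$vcov) && !is.na(fit$df_residual)) {
    indices <- ds_indices(fit, env)
  }
  xs <- c(env$lower, env$upper)
  lines <- rbind(
    data.frame(group = labels[1L], x = xs, y = b[["b0"]] + b[["b1"]] * xs),
    data.frame(group = labels[2L], x = xs,
               y = b[["b0"]] + b[["b2"]] + (b[["b1"]] + b[["b3"]]) * xs)
  )
  shade <- significant_segments(fit, env)
  p <- ggplot2::ggplot()
  if (nrow(shade)) {
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = xmin, xmax = xmax, ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.6
    )
  }
  p <- p +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(x = x, y = y, colour = group),
                       linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = c("#2166ac", "black"),
                                 breaks = labels) +
    ggplot2::labs(x = "environment score", y = "predicted outcome",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(indices)) {
    p <- p + ggplot2::geom_vline(xintercept = indices$crossover,
                                 linetype = "dashed", colour = "grey40")
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
  }
  invisible(p)
}

# Sub-intervals of [env$lower, env$upper] where the pointwise group
# difference is significant; empty data frame when the covariance is
# unavailable or nothing is significant.
significant_segments <- function(fit, env, alpha = 0.05) {
  empty <- data.frame(xmin = numeric(0), xmax = numeric(0))
  if (is.null(fit$vcov) || is.na(fit$df_residual)) return(empty)
  ros <- ros_on_x(fit, env, alpha = alpha)
  cuts <- sort(unique(c(env$lower, env$upper,
                        ros$lower[!is.na(ros$lower) &
                                    ros$lower > env$lower &
                                    ros$lower < env$upper],
                        ros$upper[!is.na(ros$upper) &
                                    ros$upper > env$lower &
                                    ros$upper < env$upper])))
  segs <- data.frame(xmin = cuts[-length(cuts)], xmax = cuts[-1L])
  mid <- (segs$xmin + segs$xmax) / 2
  sig <- abs(diff_t(fit, mid)) > ros$t_critical
  segs[sig, , drop = FALSE]
}
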