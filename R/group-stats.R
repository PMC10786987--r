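# Group-statistics stage: power transformation when the data violate
# normality/homoscedasticity, a single pass of studentized-residual
# outlier screening, one-way ANOVA with Dunnett many-to-one comparisons
# against the wild-type control, Duncan multiple-range pairwise
# comparisons, and paired t tests. The pipeline order is fixed:
# transform -> outlier flagging -> refit -> ANOVA -> post hoc.

#' Validate a long-format per-cell measurement table
#'
#' @param df data frame with at least `genotype` and `value`; `cell_id`,
#'   `measurement_name` and `experiment_date` are carried when present.
#' @return The validated data frame (factor genotype, finite values).
#' @export
cell_measurement_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("genotype", "value") %in% names(df)))
  if (any(!is.finite(df$value)))
    stop("values must be finite", call. = FALSE)
  df$genotype <- factor(df$genotype)
  df
}

#' Box-Cox power transformation gated by distributional screens
#'
#' The measurement is transformed only when it fails a screen: a
#' Shapiro-Wilk test on the residuals of the one-way group model or a
#' Levene test of variance homogeneity across groups (both at
#' `screen_alpha`). The exponent is the maximum-likelihood Box-Cox
#' lambda, profiled over `lambda_range`; non-positive values are shifted
#' (recorded in the result) so the transform is invertible. The
#' transform is `(y^lambda - 1)/lambda` (`log(y)` at `lambda = 0`).
#'
#' @param values numeric measurements.
#' @param groups group labels, same length.
#' @param lambda_range search interval for lambda.
#' @param screen_alpha significance level of the screens.
#' @param force apply the transform regardless of the screens?
#' @return List with `values` (transformed or original), `lambda`,
#'   `shift`, `applied` (logical), and `screen` (p-values).
#' @export
power_transform <- function(values, groups, lambda_range = c(-3, 3),
                            screen_alpha = 0.05, force = FALSE) {
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("values and groups must have the same length", call. = FALSE)
  if (stats::var(values) == 0) {
    warning("constant data; returning identity transform")
    return(list(values = values, lambda = 1, shift = 0, applied = FALSE,
                screen = c(shapiro_p = NA_real_, levene_p = NA_real_)))
  }
  fit <- stats::lm(values ~ groups)
  shapiro_p <- tryCatch(stats::shapiro.test(stats::resid(fit))$p.value,
                        error = function(e) NA_real_)
  levene_p <- if (nlevels(droplevels(groups)) > 1L)
    car::leveneTest(values ~ droplevels(groups))[1, "Pr(>F)"] else NA_real_
  fails <- isTRUE(shapiro_p < screen_alpha) || isTRUE(levene_p < screen_alpha)
  if (!fails && !force)
    return(list(values = values, lambda = 1, shift = 0, applied = FALSE,
                screen = c(shapiro_p = shapiro_p, levene_p = levene_p)))
  shift <- if (min(values) <= 0) -min(values) + 1e-6 * diff(range(values)) +
    .Machine$double.eps else 0
  y <- values + shift
  bc <- MASS::boxcox(y ~ g, data = data.frame(y = y, g = groups),
                     lambda = seq(lambda_range[1], lambda_range[2],
                                  length.out = 601),
                     plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  yt <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  list(values = yt, lambda = lambda, shift = shift, applied = TRUE,
       screen = c(shapiro_p = shapiro_p, levene_p = levene_p))
}

#' Invert a power transform
#'
#' @param yt transformed values.
#' @param lambda,shift as returned by [power_transform()].
#' @return Values on the original scale.
#' @export
power_transform_inverse <- function(yt, lambda, shift = 0) {
  y <- if (abs(lambda) < 1e-8) exp(yt) else (lambda * yt + 1)^(1 / lambda)
  y - shift
}

#' Flag outliers by externally studentized residuals
#'
#' Fits the one-way group-means model and flags observations with
#' `|studentized residual| > threshold` in a single pass (no iteration).
#' Groups of size 1 cannot be studentized and are excluded with a
#' warning.
#'
#' @param values numeric measurements.
#' @param groups group labels.
#' @param threshold flagging threshold on `|r|` (default 3).
#' @return Integer indices of flagged observations.
#' @export
flag_outliers <- function(values, groups, threshold = 3) {
  groups <- factor(groups)
  sizes <- table(groups)
  singleton <- names(sizes)[sizes < 2]
  use <- !(groups %in% singleton)
  if (length(singleton) > 0L)
    warning("groups of size 1 excluded from studentization: ",
            paste(singleton, collapse = ", "))
  if (stats::var(values[use]) == 0) return(integer(0))
  fit <- stats::lm(values ~ groups, subset = use)
  if (all(abs(stats::resid(fit)) < 1e-12)) return(integer(0))
  r <- stats::rstudent(fit)
  flagged <- which(use)[which(!is.na(r) & abs(r) > threshold)]
  as.integer(flagged)
}

#' Two-sided Dunnett critical value
#'
#' Equicoordinate quantile of the multivariate t distribution of the
#' many-to-one comparison statistics, computed by mvtnorm quadrature.
#'
#' @param k number of treatment groups (excluding the control).
#' @param df error degrees of freedom.
#' @param alpha familywise error rate.
#' @param n_control,n_treat group sizes (scalar or length-k vector) used
#'   to build the correlation matrix; balanced designs give the familiar
#'   correlation 1/2.
#' @return Scalar critical value for `max |t_i|`.
#' @export
dunnett_critical <- function(k, df, alpha = 0.05, n_control = NULL,
                             n_treat = NULL) {
  if (is.null(n_control) || is.null(n_treat)) {
    R <- matrix(0.5, k, k)
  } else {
    n_treat <- rep_len(n_treat, k)
    lam <- sqrt(n_treat / (n_treat + n_control))
    R <- outer(lam, lam)
  }
  diag(R) <- 1
  mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df, corr = R,
                seed = 1L)$quantile
}

#' One-way ANOVA with Dunnett comparisons versus a control
#'
#' Runs the full statistics pipeline in a fixed order: optional power
#' transformation ([power_transform()]), one pass of studentized-residual
#' outlier flagging ([flag_outliers()]), refit on the cleaned data,
#' one-way ANOVA, and two-sided Dunnett many-to-one comparisons against
#' `control` at familywise level `alpha` (unequal group sizes are
#' supported). Comparisons are computed with multcomp on the transformed,
#' outlier-free data.
#'
#' @param df a [cell_measurement_table()]-conform data frame
#'   (`genotype`, `value`).
#' @param control control genotype label (the wild type).
#' @param alpha familywise error rate.
#' @param transform gate the analysis behind the power-transform screen?
#' @param outlier_threshold studentized-residual threshold.
#' @return Object of class `stats_report`: list with `lambda`, `shift`,
#'   `transform_applied`, `outlier_idx`, `anova_F`, `anova_df`,
#'   `anova_p`, and `comparisons` (data frame: comparison, estimate,
#'   t, p_adjusted, significant).
#' @export
anova_dunnett <- function(df, control, alpha = 0.05, transform = TRUE,
                          outlier_threshold = 3) {
  df <- cell_measurement_table(df)
  if (nlevels(df$genotype) < 2L)
    stop("need at least two groups including the control", call. = FALSE)
  if (!control %in% levels(df$genotype))
    stop("control genotype '", control, "' not present", call. = FALSE)
  df$genotype <- stats::relevel(df$genotype, ref = control)

  pt <- if (transform) power_transform(df$value, df$genotype)
        else list(values = df$value, lambda = 1, shift = 0, applied = FALSE,
                  screen = c(shapiro_p = NA, levene_p = NA))
  y <- pt$values
  out_idx <- flag_outliers(y, df$genotype, threshold = outlier_threshold)
  keep <- setdiff(seq_along(y), out_idx)
  d2 <- data.frame(y = y[keep], genotype = droplevels(df$genotype[keep]))

  fit <- stats::aov(y ~ genotype, data = d2)
  an <- stats::anova(fit)
  glht_fit <- multcomp::glht(fit,
    linfct = multcomp::mcp(genotype = "Dunnett"),
    alternative = "two.sided")
  sm <- summary(glht_fit)
  comparisons <- data.frame(
    comparison = names(sm$test$coefficients),
    estimate = as.numeric(sm$test$coefficients),
    t = as.numeric(sm$test$tstat),
    p_adjusted = as.numeric(sm$test$pvalues),
    significant = as.numeric(sm$test$pvalues) <= alpha,
    row.names = NULL)
  structure(list(lambda = pt$lambda, shift = pt$shift,
                 transform_applied = pt$applied, screen = pt$screen,
                 outlier_idx = out_idx,
                 anova_F = an[1, "F value"],
                 anova_df = c(an[1, "Df"], an[2, "Df"]),
                 anova_p = an[1, "Pr(>F)"],
                 alpha = alpha, control = control,
                 comparisons = comparisons),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$anova_df[1], x$anova_df[2], x$anova_F, x$anova_p))
  if (x$transform_applied)
    cat(sprintf("  power transform applied (lambda = %.2f, shift = %.3g)\n",
                x$lambda, x$shift))
  if (length(x$outlier_idx))
    cat("  outliers removed at indices:",
        paste(x$outlier_idx, collapse = ", "), "\n")
  cat(sprintf("  Dunnett comparisons vs %s (alpha = %g):\n",
              x$control, x$alpha))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Duncan's multiple-range pairwise comparisons
#'
#' The classic protected multiple-range procedure: group means are
#' ordered; the difference of a pair spanning `p` ordered means is tested
#' against the critical range `q_p * sqrt(MSE / n_h)` where `q_p` is the
#' studentized-range quantile at the stage-wise level
#' `1 - (1 - alpha)^(p - 1)` and `n_h` the harmonic mean group size; a
#' pair inside a range already declared non-significant is not declared
#' significant. Groups are then collected into homogeneous subsets
#' (maximal runs of mutually non-significant groups).
#'
#' @param values numeric measurements.
#' @param groups group labels.
#' @param alpha comparison-wise protection level.
#' @return List with `means` (sorted group means), `subsets` (list of
#'   character vectors), and `significant_pairs` (data frame).
#' @export
duncan_pairwise <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  mse <- stats::anova(fit)[2, "Mean Sq"]
  dfe <- stats::df.residual(fit)
  means <- sort(tapply(values, groups, mean))
  ns <- table(groups)[names(means)]
  n_h <- length(ns) / sum(1 / ns)
  se <- sqrt(mse / n_h)

  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  nonsig_range <- matrix(FALSE, k, k)  # [i, j] span declared non-significant
  for (span in k:2) {
    # stage-wise protection level (1-alpha)^(span-1); upper quantile of
    # the studentized range
    q <- stats::qtukey((1 - alpha)^(span - 1), span, dfe)
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1L
      inside_nonsig <- FALSE
      if (span < k) {
        for (a in seq_len(i)) for (b in j:k)
          if ((b - a + 1L) > span && nonsig_range[a, b]) inside_nonsig <- TRUE
      }
      if (inside_nonsig || (means[j] - means[i]) <= q * se) {
        nonsig_range[i, j] <- TRUE
      } else {
        sig[i, j] <- sig[j, i] <- TRUE
      }
    }
  }
  subsets <- lapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !any(sig[i:j, j + 1L])) j <- j + 1L
    names(means)[i:j]
  })
  # drop subsets fully contained in another
  keep <- vapply(seq_along(subsets), function(a)
    !any(vapply(seq_along(subsets), function(b)
      a != b && all(subsets[[a]] %in% subsets[[b]]), logical(1))),
    logical(1))
  subsets <- subsets[keep]
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  significant_pairs <- data.frame(
    group1 = rownames(sig)[pairs[, 1]],
    group2 = colnames(sig)[pairs[, 2]], row.names = NULL)
  list(means = means, subsets = subsets,
       significant_pairs = significant_pairs)
}

#' Paired t test
#'
#' Standard two-sided paired t test. Zero variance of the differences is
#' reported as a flagged degenerate result rather than an error.
#'
#' @param before,after paired measurement vectors of equal length
#'   (n >= 2).
#' @return List with `t`, `df`, `p`, `mean_difference`, `flag`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after))
    stop("before and after must be paired (equal length)", call. = FALSE)
  if (length(before) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  d <- after - before
  if (stats::var(d) == 0) {
    warning("differences have zero variance")
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else 0,
                mean_difference = mean(d), flag = "zero_variance"))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = unname(tt$estimate),
       flag = NA_character_)
}
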