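map_tail <- function(tail) {
  switch(tail,
         two_sided = "two.sided",
         one_sided_less = "less",
         one_sided_greater = "greater",
         stop("unknown tail '", tail, "'"))
}

# one-point limit of the t test on (near-)constant data
degenerate_p <- function(delta, tail) {
  if (delta == 0) return(1)
  switch(tail,
         two_sided = 0,
         one_sided_greater = if (delta > 0) 0 else 1,
         one_sided_less = if (delta < 0) 0 else 1)
}

new_test_result <- function(statistic, df, p_value, tail, effect_size_d,
                            mean_difference, se_difference, method,
                            degenerate = FALSE) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), tail = tail,
                 effect_size_d = unname(effect_size_d),
                 mean_difference = unname(mean_difference),
                 se_difference = unname(se_difference),
                 method = method, degenerate = degenerate),
            class = "nle_test")
}

#' @export
print.nle_test <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$method, x$tail))
  cat(sprintf("  t(%.2f) = %.3f, p = %.4g, Cohen's d = %.3f\n",
              x$df, x$statistic, x$p_value, x$effect_size_d))
  cat(sprintf("  mean difference = %.3f (SE %.3f)\n",
              x$mean_difference, x$se_difference))
  if (x$degenerate) cat("  note: degenerate input (zero variance)\n")
  invisible(x)
}

#' t tests with Cohen's d
#'
#' Thin wrappers around [stats::t.test()] that add the effect-size
#' conventions used throughout the analyses: independent groups use the
#' pooled-SD Cohen's d, paired and one-sample tests use the SD of the
#' (mean-centred) differences. `welch_t()` applies the Welch correction
#' (Welch-Satterthwaite degrees of freedom, possibly fractional). Tails
#' refer to the first argument: `one_sided_greater` tests mean(a) >
#' mean(b).
#'
#' @param a,b numeric vectors (for `one_sample_t()`, `x` and `mu0`).
#' @param tail `"two_sided"`, `"one_sided_less"` or `"one_sided_greater"`.
#' @return An object of class `nle_test` with elements `statistic`, `df`,
#'   `p_value`, `effect_size_d`, `mean_difference`, `se_difference`.
#' @export
welch_t <- function(a, b, tail = "two_sided") {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  delta <- mean(a) - mean(b)
  tt <- tryCatch(
    stats::t.test(a, b, var.equal = FALSE, alternative = map_tail(tail)),
    error = function(e) NULL)
  if (is.null(tt))
    return(new_test_result(if (delta == 0) 0 else sign(delta) * Inf,
                           length(a) + length(b) - 2,
                           degenerate_p(delta, tail), tail,
                           if (delta == 0) 0 else NA_real_, delta, 0,
                           "Welch two-sample t-test", degenerate = TRUE))
  sp <- sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
               (length(a) + length(b) - 2))
  new_test_result(tt$statistic, tt$parameter, tt$p.value, tail,
                  (mean(a) - mean(b)) / sp, mean(a) - mean(b), tt$stderr,
                  "Welch two-sample t-test")
}

#' @rdname welch_t
#' @export
paired_t <- function(a, b, tail = "two_sided") {
  stopifnot(length(a) == length(b), length(a) >= 2)
  one_sample_t(a - b, 0, tail, method = "Paired t-test")
}

#' @rdname welch_t
#' @param x numeric vector.
#' @param mu0 null value.
#' @param method label used in printing.
#' @export
one_sample_t <- function(x, mu0 = 0, tail = "two_sided",
                         method = "One-sample t-test") {
  stopifnot(length(x) >= 2)
  delta <- mean(x) - mu0
  tt <- if (stats::var(x) == 0) NULL else
    tryCatch(stats::t.test(x, mu = mu0, alternative = map_tail(tail)),
             error = function(e) NULL)
  if (is.null(tt))
    return(new_test_result(if (delta == 0) 0 else sign(delta) * Inf,
                           length(x) - 1, degenerate_p(delta, tail), tail,
                           if (delta == 0) 0 else NA_real_, delta, 0,
                           method, degenerate = TRUE))
  new_test_result(tt$statistic, tt$parameter, tt$p.value, tail,
                  (mean(x) - mu0) / stats::sd(x), mean(x) - mu0, tt$stderr,
                  method)
}

ges_ci <- function(f, df1, df2, ges, level = 0.90) {
  if (!is.finite(f) || f <= 0) return(c(0, 0))
  alpha <- (1 - level) / 2
  # noncentral-F pivot for the noncentrality parameter
  lo_fn <- function(ncp) stats::pf(f, df1, df2, ncp) - (1 - alpha)
  hi_fn <- function(ncp) stats::pf(f, df1, df2, ncp) - alpha
  upper_cap <- max(10 * f * df1 + 100, 1000)
  ncp_lo <- if (lo_fn(0) < 0) 0 else
    stats::uniroot(lo_fn, c(0, upper_cap))$root
  ncp_hi <- if (hi_fn(0) <= 0) 0 else if (hi_fn(upper_cap) > 0) upper_cap else
    stats::uniroot(hi_fn, c(0, upper_cap))$root
  part <- function(ncp) ncp / (ncp + df1 + df2 + 1)
  partial_point <- f * df1 / (f * df1 + df2)
  scale <- if (partial_point > 0) ges / partial_point else 1
  lo <- part(ncp_lo) * scale
  hi <- part(ncp_hi) * scale
  c(min(lo, ges), max(hi, ges))
}

#' Mixed two-way ANOVA on participant summaries
#'
#' The 3 (Mother-tongue, between) x 2 (Dimension, within) mixed ANOVA on
#' participant-level mean biases. Fitted via [stats::aov()] with a
#' participant error stratum; with a two-level within factor sphericity
#' holds by construction (Greenhouse-Geisser epsilon = 1), so no
#' correction is applied. Effect sizes are generalized eta-squared
#' (Olejnik-Algina: effect SS over effect SS plus all subject-error SS)
#' with a 90% CI from the noncentral-F pivot.
#'
#' @param summaries a [summarize_participants()] table; every participant
#'   must contribute both dimensions.
#' @param dv `"bias"` or `"absolute_bias"`.
#' @return An object of class `nle_anova`: the effect table (`table`,
#'   with F, df, p, ges and CI bounds), plus the underlying `aov` fit for
#'   marginal-means follow-ups.
#' @export
mixed_anova <- function(summaries, dv = c("bias", "absolute_bias")) {
  dv <- match.arg(dv)
  col <- if (dv == "bias") "mean_positioning_bias" else
    "mean_absolute_positioning_bias"
  d <- data.frame(participant = factor(summaries$participant_id),
                  language = factor(summaries$language),
                  dimension = factor(summaries$dimension),
                  y = summaries[[col]])
  tab <- table(d$participant)
  if (any(tab != nlevels(d$dimension)))
    stop("unbalanced within-subject data: participant(s) without both ",
         "dimensions: ", paste(names(tab)[tab != 2], collapse = ", "))
  if (any(table(unique(d[c("participant", "language")])$language) < 2))
    stop("need at least 2 participants per language")

  # do.call embeds the data in the call so marginal-means follow-ups can
  # re-evaluate the fit outside this function's environment
  fit <- do.call(stats::aov,
                 list(y ~ language * dimension + Error(participant),
                      data = d))
  s <- summary(fit)
  btw <- as.data.frame(s[["Error: participant"]][[1]])
  wth <- as.data.frame(s[["Error: Within"]][[1]])
  ss <- function(tab, term) tab[trimws(rownames(tab)) == term, "Sum Sq"]
  df_ <- function(tab, term) tab[trimws(rownames(tab)) == term, "Df"]

  ss_lang <- ss(btw, "language"); df_lang <- df_(btw, "language")
  ss_eb <- ss(btw, "Residuals"); df_eb <- df_(btw, "Residuals")
  ss_dim <- ss(wth, "dimension"); df_dim <- df_(wth, "dimension")
  ss_int <- ss(wth, "language:dimension")
  df_int <- df_(wth, "language:dimension")
  ss_ew <- ss(wth, "Residuals"); df_ew <- df_(wth, "Residuals")

  err_total <- ss_eb + ss_ew
  tot <- sum(btw[, "Sum Sq"]) + sum(wth[, "Sum Sq"])
  mkrow <- function(effect, ss_eff, df1, ss_err, df2) {
    if (ss_eff <= 1e-12 * (tot + 1)) ss_eff <- 0
    f <- if (ss_eff == 0) 0 else if (ss_err == 0) Inf else
      (ss_eff / df1) / (ss_err / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    ges <- if (ss_eff == 0) 0 else ss_eff / (ss_eff + err_total)
    ci <- ges_ci(f, df1, df2, ges)
    data.frame(effect = effect, F = f, df1 = df1, df2 = df2, p = p,
               ges = ges, ges_ci_low = ci[1], ges_ci_high = ci[2])
  }
  out <- rbind(
    mkrow("language", ss_lang, df_lang, ss_eb, df_eb),
    mkrow("dimension", ss_dim, df_dim, ss_ew, df_ew),
    mkrow("language:dimension", ss_int, df_int, ss_ew, df_ew))
  rownames(out) <- NULL
  structure(list(table = out, dv = dv, fit = fit, data = d),
            class = "nle_anova")
}

#' @export
print.nle_anova <- function(x, ...) {
  cat(sprintf("Mixed ANOVA (between: language; within: dimension) on %s\n",
              x$dv))
  tab <- x$table
  tab$F <- round(tab$F, 2); tab$p <- signif(tab$p, 3)
  tab$ges <- round(tab$ges, 3)
  tab$ges_ci_low <- round(tab$ges_ci_low, 3)
  tab$ges_ci_high <- round(tab$ges_ci_high, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tukey-adjusted pairwise language contrasts
#'
#' Pairwise contrasts of the estimated marginal means of the
#' between-subject factor, averaged over dimension, with Tukey
#' (studentized-range) adjustment of the p values; the follow-up applied
#' to significant ANOVA main effects.
#'
#' @param anova an [mixed_anova()] result.
#' @return Data frame with one row per contrast: estimate, SE, df, t,
#'   unadjusted and Tukey-adjusted p.
#' @export
emm_pairwise <- function(anova) {
  stopifnot(inherits(anova, "nle_anova"))
  if (nlevels(anova$data$language) < 2) stop("need at least 2 groups")
  em <- suppressMessages(emmeans::emmeans(anova$fit, "language",
                                          data = anova$data))
  adj <- as.data.frame(summary(emmeans::contrast(em, "pairwise"),
                               adjust = "tukey"))
  # on degenerate (zero-variance) fits emmeans reports z instead of t
  tcol <- if (!is.null(adj$t.ratio)) adj$t.ratio else adj$z.ratio
  data.frame(contrast = as.character(adj$contrast), estimate = adj$estimate,
             se = adj$SE, df = adj$df, t = tcol,
             p_unadjusted = 2 * stats::pt(-abs(tcol), adj$df),
             p_tukey = adj$p.value)
}

#' Gaussian BIC from a residual sum of squares
#'
#' `n * log(RSS/n) + k * log(n)`, the profile-likelihood Bayesian
#' information criterion for least-squares fits (constants dropped).
#' A perfect fit (RSS = 0) returns `-Inf`.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param k number of fitted parameters (`n > k >= 1`).
#' @return Numeric scalar.
#' @export
bic_rss <- function(rss, n, k) {
  stopifnot(n > k, k >= 1, rss >= 0)
  if (rss == 0) return(-Inf)
  n * log(rss / n) + k * log(n)
}
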