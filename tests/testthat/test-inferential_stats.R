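test_that("welch test matches a direct textbook evaluation", {
  a <- c(0, 0, 1, 1); b <- c(10, 10, 11, 11)
  res <- welch_t(a, b)
  # independent recomputation from the Welch formulas
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_exp <- (mean(a) - mean(b)) / se
  df_exp <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_exp <- 2 * pt(-abs(t_exp), df_exp)
  d_exp <- (mean(a) - mean(b)) /
    sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(res$statistic, t_exp)
  expect_equal(res$df, df_exp)
  expect_equal(res$p_value, p_exp)
  expect_equal(res$effect_size_d, d_exp)
  expect_lt(res$p_value, 1e-6)
  expect_gt(abs(res$effect_size_d), 5)
})

test_that("welch test is antisymmetric and null on identical groups", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 5, 7)
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  same <- welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  deg <- welch_t(c(1, 1), c(1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("welch df never exceed the pooled df", {
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), sd = runif(1, 0.2, 3))
    expect_lte(welch_t(a, b)$df, length(a) + length(b) - 2)
  }
})

test_that("one-sample and paired t follow the hand formulas", {
  res <- one_sample_t(c(-1, -2, -3), 0)
  expect_equal(res$statistic, -2 * sqrt(3))
  expect_equal(res$df, 2)
  expect_equal(res$effect_size_d, -2)

  a <- c(3, 5, 4, 6); b <- c(2, 5, 2, 3)
  pr <- paired_t(a, b)
  os <- one_sample_t(a - b, 0)
  expect_equal(pr$statistic, os$statistic)
  expect_equal(pr$p_value, os$p_value)
  expect_equal(pr$effect_size_d, os$effect_size_d)
  null <- paired_t(a, a)
  expect_equal(null$statistic, 0)
  expect_true(null$degenerate)
})

test_that("one-sided p is half the two-sided p in the favoured direction", {
  a <- c(5, 6, 7); b <- c(1, 2, 3)
  expect_equal(welch_t(a, b, "one_sided_greater")$p_value,
               welch_t(a, b)$p_value / 2)
  expect_equal(one_sample_t(a, 0, "one_sided_greater")$p_value,
               one_sample_t(a, 0)$p_value / 2)
})

make_summaries <- function(n_per_lang = 6, effects = c(English = 0,
                                                       German = 0,
                                                       Mandarin = 0),
                           dim_shift = 0, noise = 1, seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(names(effects), function(l) {
    ids <- paste0(l, seq_len(n_per_lang))
    expand.grid(participant_id = ids, dimension = c("horizontal", "vertical"),
                stringsAsFactors = FALSE)
  }))
  rows$language <- sub("[0-9]+$", "", rows$participant_id)
  pe <- rnorm(length(unique(rows$participant_id)), sd = noise)
  names(pe) <- unique(rows$participant_id)
  rows$mean_positioning_bias <- effects[rows$language] +
    pe[rows$participant_id] +
    ifelse(rows$dimension == "vertical", dim_shift, 0) +
    rnorm(nrow(rows), sd = 0.2)
  rows$mean_absolute_positioning_bias <- abs(rows$mean_positioning_bias)
  rows$mean_rt_ms <- 800
  rows$n_trials <- 100
  rows
}

test_that("mixed anova detects between, within and null effects", {
  const <- make_summaries()
  const$mean_positioning_bias <- 5
  a0 <- mixed_anova(const, "bias")
  expect_equal(a0$table$F, c(0, 0, 0))
  expect_equal(a0$table$ges, c(0, 0, 0))

  lang <- mixed_anova(make_summaries(effects = c(English = 0, German = 0,
                                                 Mandarin = -2),
                                     noise = 0.3, seed = 1), "bias")
  tab <- lang$table
  expect_lt(tab$p[tab$effect == "language"], 0.001)
  expect_gt(tab$p[tab$effect == "dimension"], 0.05)
  expect_true(all(tab$ges_ci_low <= tab$ges + 1e-12 &
                    tab$ges <= tab$ges_ci_high + 1e-12))

  dim <- mixed_anova(make_summaries(dim_shift = 1, noise = 0.3, seed = 3),
                     "bias")
  tabd <- dim$table
  expect_lt(tabd$p[tabd$effect == "dimension"], 0.001)
  expect_gt(tabd$p[tabd$effect == "language:dimension"], 0.05)
})

test_that("mixed anova rejects incomplete within-subject data", {
  s <- make_summaries()
  expect_error(mixed_anova(s[-1, ], "bias"), "unbalanced")
})

test_that("marginal-mean contrasts flag the shifted group, Tukey-adjusted", {
  s <- make_summaries(effects = c(English = 0, German = 0, Mandarin = -2),
                      noise = 0.2, seed = 4)
  an <- mixed_anova(s, "bias")
  cm <- emm_pairwise(an)
  expect_equal(nrow(cm), 3)
  expect_true(all(cm$p_tukey >= cm$p_unadjusted - 1e-12))
  sig <- cm$p_tukey < 0.05
  names(sig) <- cm$contrast
  expect_false(sig[["English - German"]])
  expect_true(sig[["English - Mandarin"]])
  expect_true(sig[["German - Mandarin"]])
})

test_that("near-equal groups yield near-unit adjusted p", {
  s <- make_summaries(n_per_lang = 8, effects = c(English = 0, German = 0,
                                                  Mandarin = 0), seed = 6)
  s <- s[s$language != "Mandarin", ]
  an <- mixed_anova(s, "bias")
  cm <- emm_pairwise(an)
  expect_gt(min(cm$p_tukey), 0.2)
})

test_that("the BIC obeys its algebra", {
  expect_equal(bic_rss(2, 50, 3) - bic_rss(1, 50, 3), 50 * log(2))
  expect_equal(bic_rss(1, 50, 4) - bic_rss(1, 50, 3), log(50))
  expect_identical(bic_rss(0, 50, 3), -Inf)
  expect_error(bic_rss(1, 3, 3))
})
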