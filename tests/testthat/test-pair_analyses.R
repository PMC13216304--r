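test_that("a veridical responder scores the true pair distances", {
  ipd <- inverted_pair_distance(perfect_trials())
  expect_equal(ipd$mean_distance, 477 / 17)
  expect_equal(ipd$n_pairs, 17)
})

test_that("pair distances are shift-invariant and scale linearly", {
  tg <- rep(nle_targets, 2)
  base <- inverted_pair_distance(analysable_trials(tg, tg))
  shifted <- inverted_pair_distance(analysable_trials(tg, tg - 3))
  expect_equal(shifted$mean_distance, base$mean_distance)
  squeezed <- inverted_pair_distance(
    analysable_trials(tg, 50 + (tg - 50) * 0.5))
  expect_equal(squeezed$mean_distance, base$mean_distance / 2)
})

test_that("missing pair members shrink the divisor with a warning", {
  tg <- nle_targets[nle_targets != 32]
  expect_warning(ipd <- inverted_pair_distance(analysable_trials(tg, tg)),
                 "skipped")
  expect_equal(ipd$n_pairs, 16)
  expect_equal(ipd$mean_distance, (477 - 9) / 16)
})

test_that("identical groups are null under the between-language pair test", {
  tg <- nle_targets
  tr <- rbind(
    analysable_trials(tg, tg, participant_id = "E1", language = "English"),
    analysable_trials(tg, tg, participant_id = "E2", language = "English"),
    analysable_trials(tg, tg + 0.5, participant_id = "E3",
                      language = "English"),
    analysable_trials(tg, tg, participant_id = "G1", language = "German"),
    analysable_trials(tg, tg, participant_id = "G2", language = "German"),
    analysable_trials(tg, tg + 0.5, participant_id = "G3",
                      language = "German"))
  h1 <- h1_test(inverted_pair_distance(tr))
  expect_gte(h1$test$p_value, 0.5)
  expect_equal(h1$groups$n, c(3, 3))
})

test_that("stronger unit influence shrinks inverted-pair distances", {
  # noise-free closed-form cohorts: German delta larger than English
  tg <- rep(nle_targets, 2)
  tr <- rbind(
    analysable_trials(tg, cpm_predict(tg, 0.9, 0.95), participant_id = "G1",
                      language = "German"),
    analysable_trials(tg, cpm_predict(tg, 0.9, 0.75), participant_id = "E1",
                      language = "English"))
  ipd <- inverted_pair_distance(tr)
  # a larger unit weight pulls digit-reversal pairs together: the small
  # member (large unit digit, e.g. 29) rises more than the large member
  # (small unit digit, e.g. 92) falls
  d_ger <- ipd$mean_distance[ipd$language == "German"]
  d_eng <- ipd$mean_distance[ipd$language == "English"]
  expect_lt(d_ger, d_eng)
})

test_that("teen and twenty biases are recovered per participant", {
  p <- teen_twenty_bias(perfect_trials())
  expect_equal(p$teen_bias, 0)
  expect_equal(p$twenty_bias, 0)

  tg <- nle_targets
  shifted <- teen_twenty_bias(analysable_trials(tg, tg - 2))
  expect_equal(shifted$teen_bias, -2)
  expect_equal(shifted$twenty_bias, -2)
  tt <- teen_twenty_tests(rbind(
    teen_twenty_bias(analysable_trials(tg, tg - 2, participant_id = "A")),
    teen_twenty_bias(analysable_trials(tg, tg - 2, participant_id = "B"))))
  expect_equal(tt$English$paired$statistic, 0)
  expect_true(tt$English$paired$degenerate)
})

test_that("injected decade offsets drive the teen/twenty comparison", {
  tg <- nle_targets
  make_p <- function(id, teen_off, twenty_off, wiggle) {
    off <- ifelse(tg %in% 13:19, teen_off,
                  ifelse(tg %in% 23:29, twenty_off, 0))
    analysable_trials(tg, tg + off + wiggle, participant_id = id)
  }
  set.seed(5)
  tr <- do.call(rbind, lapply(1:10, function(i)
    make_p(paste0("P", i), -1, -2.3, rnorm(1, 0, 0.1))))
  tt <- teen_twenty_tests(teen_twenty_bias(tr))$English
  expect_gt(tt$means[["teen"]], tt$means[["twenty"]])
  expect_lt(tt$paired$p_value, 0.001)
  expect_lt(tt$teen_vs_zero$statistic, 0)
  expect_lt(tt$twenty_vs_zero$p_value, 0.001)
  # the paired test equals the one-sample test on the differences
  d <- teen_twenty_bias(tr)
  expect_equal(tt$paired$p_value,
               one_sample_t(d$teen_bias - d$twenty_bias, 0,
                            "one_sided_greater")$p_value)
})

test_that("decade difference scores detect boundary exaggeration", {
  expect_equal(decade_difference_scores(perfect_trials())$mean_score, 0)

  tg <- nle_targets
  # push every x1 target up by 1 and every x9 target down by 1: each
  # boundary gap grows by 2
  placing <- tg + ifelse(unit_part(tg) == 1, 1,
                         ifelse(unit_part(tg) == 9, -1, 0))
  dds <- decade_difference_scores(analysable_trials(tg, placing))
  expect_equal(dds$mean_score, 2)

  # left-digit compression (delta < 1) exaggerates decade boundaries
  model <- decade_difference_scores(
    analysable_trials(tg, cpm_predict(tg, 0.9, 0.83)))
  expect_gt(model$mean_score, 0)

  tests <- decade_score_tests(
    rbind(decade_difference_scores(analysable_trials(
      tg, placing, participant_id = "A")),
      decade_difference_scores(analysable_trials(
        tg, placing + 0.1, participant_id = "B"))))
  expect_equal(tests$English$mean, 2)
  expect_equal(tests$English$n, 2)
})
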