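test_that("beta = delta = 1 reduces both cycle structures to identity", {
  for (cyc in c("two", "one")) {
    y <- cpm_predict(nle_targets, beta = 1, delta = 1, cycles = cyc)
    expect_lt(max(abs(y - nle_targets)), 1e-12)
  }
})

test_that("segment midpoints and anchors are fixed points", {
  for (beta in c(0.5, 0.9, 1.7)) {
    expect_equal(cpm_predict(25, beta, 1), 25)
    expect_equal(cpm_predict(75, beta, 1), 75)
    expect_equal(cpm_predict(50, beta, 1, cycles = "one"), 50)
  }
})

test_that("predictions match the high-precision oracle evaluation", {
  # frozen from an independent evaluation of the printed formula:
  # s = 20 + 9^0.83, two-cycle segment [0, 50]
  expect_equal(cpm_predict(29, beta = 0.9, delta = 0.83), 26.07539850519,
               tolerance = 1e-10)
  tg <- nle_targets[nle_targets > 20]
  expect_equal(cpm_predict(tg, 0.9, 0.83), oracle_two_cycle(tg, 0.9, 0.83))
})

test_that("one- and two-cycle structures disagree away from anchors", {
  y1 <- cpm_predict(29, 0.9, 1, cycles = "one")
  y2 <- cpm_predict(29, 0.9, 1, cycles = "two")
  expect_gt(abs(y1 - y2), 0.1)
})

test_that("two-cycle predictions are continuous at the midpoint", {
  eps <- 1e-7
  expect_equal(cpm_predict(50 - eps, 0.8, 1), 50, tolerance = 1e-5)
  expect_equal(cpm_predict(50 + eps, 0.8, 1), 50, tolerance = 1e-5)
})

test_that("predictions are strictly monotone over the stimulus set", {
  for (beta in c(0.7, 1, 1.3)) {
    for (delta in c(0.6, 0.83, 1)) {
      y <- cpm_predict(sort(nle_targets), beta, delta)
      expect_true(all(diff(y) > 0))
    }
  }
})

test_that("smaller delta compresses the within-decade spread", {
  gap <- function(delta) cpm_predict(29, 0.9, delta) -
    cpm_predict(21, 0.9, delta)
  gaps <- vapply(seq(0.5, 1.1, by = 0.1), gap, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("medians pool responses within language and drop teens", {
  tr <- rbind(
    analysable_trials(rep(25, 4), c(1, 2, 3, 4), participant_id = "A"),
    analysable_trials(c(31, 15), c(30, 10), participant_id = "B"))
  m <- prepare_medians(tr)
  expect_equal(m$median_position[m$target == 25], 2.5)
  expect_equal(m$median_position[m$target == 31], 30)
  expect_false(15 %in% m$target)
  expect_equal(m$x_d[m$target == 25], 20)
  expect_equal(m$x_u[m$target == 25], 5)
})

test_that("participant-first pooling differs from raw pooling as designed", {
  tr <- rbind(
    analysable_trials(rep(25, 3), c(10, 10, 10), participant_id = "A"),
    analysable_trials(25, 40, participant_id = "B"))
  pooled <- prepare_medians(tr, pooling = "pooled")
  byp <- prepare_medians(tr, pooling = "by_participant")
  expect_equal(pooled$median_position, 10)   # median of {10,10,10,40}
  expect_equal(byp$median_position, 25)      # median of {10, 40}
})

model_medians <- function(beta, delta, lambdas, cycles = "two") {
  tg <- nle_targets[nle_targets > 20]
  do.call(rbind, lapply(names(lambdas), function(l) data.frame(
    language = l, target = tg, x_d = decade_part(tg), x_u = unit_part(tg),
    median_position = cpm_predict(tg, beta, delta + lambdas[[l]], cycles),
    n_responses = 8)))
}

test_that("noise-free pair fits recover the generating parameters", {
  med <- model_medians(0.9, 0.85, c(English = 0, German = -0.25))
  fit <- fit_power_model(med, reference = "English")
  expect_equal(unname(coef(fit)),
               c(0.9, 0.85, -0.25), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  s <- summary(fit)
  expect_equal(colnames(s$coefficients),
               c("Estimate", "Std. Error", "t value", "Pr(>|t|)"))
})

test_that("identical language data yield a null language modifier", {
  tg <- nle_targets[nle_targets > 20]
  base <- cpm_predict(tg, 0.92, 0.8) + sin(tg / 5) * 0.4
  med <- do.call(rbind, lapply(c("English", "German"), function(l)
    data.frame(language = l, target = tg, x_d = decade_part(tg),
               x_u = unit_part(tg), median_position = base,
               n_responses = 8)))
  fit <- fit_power_model(med, reference = "English")
  expect_lt(abs(coef(fit)[["lambda_German"]]), 1e-6)
  expect_gt(fit$pval[["lambda_German"]], 0.99)
})

test_that("relabelling the reference negates the recovered lambda", {
  med <- model_medians(0.9, 0.85, c(English = 0, German = 0.06))
  f_en <- fit_power_model(med, reference = "English")
  f_de <- fit_power_model(med, reference = "German")
  expect_equal(coef(f_de)[["lambda_English"]],
               -coef(f_en)[["lambda_German"]], tolerance = 1e-6)
  expect_equal(coef(f_de)[["delta"]],
               coef(f_en)[["delta"]] + coef(f_en)[["lambda_German"]],
               tolerance = 1e-6)
})

test_that("three-language fits carry one modifier per comparison group", {
  med <- model_medians(0.9, 0.85,
                       c(English = 0, German = 0.05, Mandarin = -0.24))
  fit <- fit_power_model(med, reference = "English")
  expect_equal(unname(coef(fit)[c("lambda_German", "lambda_Mandarin")]),
               c(0.05, -0.24), tolerance = 1e-6)
  # dropping a language reduces to the pair fit
  pair <- fit_power_model(med[med$language != "Mandarin", ], "English")
  expect_equal(coef(pair)[["lambda_German"]], 0.05, tolerance = 1e-6)
  all_same <- model_medians(0.9, 0.85, c(English = 0, German = 0,
                                         Mandarin = 0))
  f0 <- fit_power_model(all_same, "English")
  expect_lt(max(abs(coef(f0)[c("lambda_German", "lambda_Mandarin")])), 1e-6)
})

test_that("predict and residuals methods are coherent", {
  med <- model_medians(0.9, 0.85, c(English = 0, German = -0.2))
  fit <- fit_power_model(med, "English")
  expect_equal(predict(fit), fitted(fit))
  expect_equal(fitted(fit) + residuals(fit), med$median_position)
  nd <- data.frame(target = c(29, 92), language = "German")
  expect_equal(predict(fit, nd),
               cpm_predict(c(29, 92), 0.9, 0.65), tolerance = 1e-5)
  expect_error(fit_power_model(med, reference = "Mandarin"), "not present")
})

test_that("BIC selects the generating cycle structure", {
  set.seed(31)
  med2 <- model_medians(0.7, 0.9, c(English = 0, German = -0.1))
  med2$median_position <- med2$median_position + rnorm(nrow(med2), 0, 0.3)
  cc2 <- compare_cycles(med2, "English")
  expect_equal(cc2$preferred, "two")
  expect_lt(cc2$bic$bic[cc2$bic$cycles == "two"],
            cc2$bic$bic[cc2$bic$cycles == "one"])

  med1 <- model_medians(0.7, 0.9, c(English = 0, German = -0.1),
                        cycles = "one")
  med1$median_position <- med1$median_position + rnorm(nrow(med1), 0, 0.3)
  cc1 <- compare_cycles(med1, "English")
  expect_lte(cc1$bic$bic[cc1$bic$cycles == "one"],
             cc1$bic$bic[cc1$bic$cycles == "two"])
})

test_that("simulated cohorts recover the model parameters approximately", {
  specs <- list(cohort_spec("English", 40, beta = 0.9, delta = 0.85,
                            noise_sd = 3),
                cohort_spec("Mandarin", 40, beta = 0.9, delta = 0.60,
                            noise_sd = 3))
  co <- make_cohort(specs, seed = 19)
  fit <- fit_power_model(prepare_medians(preprocess_trials(co$trials)),
                         "English")
  expect_equal(unname(coef(fit)), c(0.9, 0.85, -0.25), tolerance = 0.1)
})
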