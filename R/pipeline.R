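config_defaults <- function() {
  list(
    seed = 1,
    output_dir = "nle-output",
    input = list(trials = NULL),
    simulation = NULL,
    analyses = list(bias = TRUE, slopes = TRUE, pairs = TRUE, model = TRUE),
    model = list(cycles = "two", reference = "English",
                 pooling = "pooled", min_target = 21)
  )
}

cohort_fields <- c("n_participants", "beta", "delta", "bias_offset",
                   "noise_sd", "timeout_rate", "off_axis_sd", "rt_base",
                   "rt_slope", "rt_sd")

#' Validate and normalize a pipeline configuration
#'
#' Reads a nested YAML configuration (or takes an equivalent list),
#' type-checks every field, fills documented defaults and rejects unknown
#' keys; all errors are collected and reported together. The `simulation`
#' block holds one sub-block per language with [cohort_spec()] fields;
#' alternatively `input: trials:` names a raw trial CSV.
#'
#' @param config path to a YAML file, or a list.
#' @return Normalized configuration list of class `nle_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a list")
  defaults <- config_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, paste0("unknown top-level key(s): ",
                               paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    errors <- c(errors, "seed must be a single number")
  for (block in c("analyses", "model")) {
    unknown <- setdiff(names(cfg[[block]]), names(defaults[[block]]))
    if (length(unknown))
      errors <- c(errors, paste0("unknown ", block, " key(s): ",
                                 paste(unknown, collapse = ", ")))
  }
  if (!cfg$model$cycles %in% c("one", "two"))
    errors <- c(errors, "model$cycles must be 'one' or 'two'")
  if (!cfg$model$pooling %in% c("pooled", "by_participant"))
    errors <- c(errors, "model$pooling must be 'pooled' or 'by_participant'")
  if (!is.null(cfg$simulation)) {
    langs <- names(cfg$simulation)
    if (anyDuplicated(langs))
      errors <- c(errors, paste0("duplicate language label(s): ",
                                 paste(unique(langs[duplicated(langs)]),
                                       collapse = ", ")))
    for (l in langs) {
      blk <- cfg$simulation[[l]]
      unknown <- setdiff(names(blk), cohort_fields)
      if (length(unknown))
        errors <- c(errors, paste0("unknown simulation key(s) for ", l, ": ",
                                   paste(unknown, collapse = ", ")))
      for (f in c("noise_sd", "timeout_rate", "off_axis_sd")) {
        if (!is.null(blk[[f]]) && blk[[f]] < 0)
          errors <- c(errors, paste0(l, ": field '", f,
                                     "' must be non-negative"))
      }
      if (!is.null(blk$beta) && blk$beta <= 0)
        errors <- c(errors, paste0(l, ": field 'beta' must be positive"))
      if (is.null(blk$n_participants) || blk$n_participants < 1)
        errors <- c(errors, paste0(l, ": field 'n_participants' required"))
    }
  } else if (is.null(cfg$input$trials)) {
    errors <- c(errors,
                "either a simulation block or input$trials is required")
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  class(cfg) <- "nle_config"
  cfg
}

config_cohort_specs <- function(cfg) {
  lapply(names(cfg$simulation), function(l) {
    do.call(cohort_spec, c(list(language = l), cfg$simulation[[l]]))
  })
}

fmt_test <- function(label, x) {
  sprintf("%s: t(%.2f) = %.2f, p = %.4g, d = %.2f", label, x$df,
          x$statistic, x$p_value, x$effect_size_d)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when a simulation block is configured) or read,
#' preprocess, then the toggled analyses: bias summaries and mixed
#' ANOVAs with marginal-means follow-ups, intra-decade slopes with group
#' comparisons, the pair analyses, and the cyclical power
#' model fit. Writes one CSV per stage plus a combined markdown report
#' (with master seed and config hash embedded) to the output directory.
#' Deterministic given the seed.
#'
#' @param config a [validate_config()] result, a list, or a YAML path.
#' @param output_dir overrides the configured output directory.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (inherits(config, "nle_config")) config else
    validate_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)

  cfg_file <- tempfile(fileext = ".yaml")
  hashed <- unclass(cfg)
  hashed$output_dir <- NULL # the same analysis in another directory is the same analysis
  yaml::write_yaml(hashed, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  report <- c("# Number line estimation analysis report", "",
              sprintf("- master seed: %d", as.integer(cfg$seed)),
              sprintf("- config hash: %s", cfg_hash), "")
  results <- list(config = cfg, config_hash = cfg_hash)

  if (!is.null(cfg$simulation)) {
    cohort <- make_cohort(config_cohort_specs(cfg), seed = cfg$seed)
    trials <- cohort$trials
    write_trials(trials, out("raw_trials.csv"))
    write_participants(cohort$participants, out("participants.csv"))
    results$cohort <- cohort
  } else {
    trials <- read_trials(cfg$input$trials)
  }

  data <- preprocess_trials(trials)
  results$data <- data
  write_trials(data$trials, out("preprocessed_trials.csv"))
  utils::write.csv(data$exclusion_log, out("exclusion_log.csv"),
                   row.names = FALSE)
  report <- c(report, "## Preprocessing", "",
              sprintf("- %d raw trials, %d excluded (%s)", nrow(data$trials),
                      sum(data$trials$excluded),
                      paste(sprintf("%s %d", data$exclusion_log$reason,
                                    data$exclusion_log$n), collapse = ", ")),
              sprintf("- direction switchers removed: %d",
                      length(data$dropped_switchers)), "")

  if (isTRUE(cfg$analyses$bias)) {
    summ <- summarize_participants(data)
    utils::write.csv(summ, out("participant_summaries.csv"),
                     row.names = FALSE)
    aov_bias <- mixed_anova(summ, "bias")
    aov_abs <- mixed_anova(summ, "absolute_bias")
    emm <- emm_pairwise(aov_bias)
    utils::write.csv(rbind(cbind(dv = "bias", aov_bias$table),
                           cbind(dv = "absolute_bias", aov_abs$table)),
                     out("anova.csv"), row.names = FALSE)
    utils::write.csv(emm, out("language_contrasts.csv"), row.names = FALSE)
    results$bias <- list(summaries = summ, anova_bias = aov_bias,
                         anova_absolute = aov_abs, contrasts = emm)
    atab <- aov_bias$table
    report <- c(report, "## Positioning bias (mixed ANOVA)", "",
                sprintf("- %s: F(%d, %d) = %.2f, p = %.4g, ges = %.3f [%.3f, %.3f]",
                        atab$effect, atab$df1, atab$df2, atab$F, atab$p,
                        atab$ges, atab$ges_ci_low, atab$ges_ci_high), "")
  }

  if (isTRUE(cfg$analyses$slopes)) {
    st <- decade_slopes(data)
    ms <- participant_mean_slopes(st)
    cmp <- compare_slope_groups(ms)
    utils::write.csv(st, out("decade_slopes.csv"), row.names = FALSE)
    utils::write.csv(ms, out("mean_slopes.csv"), row.names = FALSE)
    results$slopes <- list(table = st, mean_slopes = ms, comparison = cmp)
    report <- c(report, "## Intra-decade slopes", "",
                sprintf("- %s: M = %.2f, SD = %.2f (n = %d)",
                        cmp$groups$language, cmp$groups$mean, cmp$groups$sd,
                        cmp$groups$n),
                vapply(names(cmp$tests), function(nm)
                  fmt_test(nm, cmp$tests[[nm]]), character(1)), "")
  }

  if (isTRUE(cfg$analyses$pairs)) {
    ipd <- inverted_pair_distance(data)
    h1 <- h1_test(ipd)
    tt <- teen_twenty_bias(data)
    ttt <- teen_twenty_tests(tt)
    dds <- decade_difference_scores(data)
    ddt <- decade_score_tests(dds)
    utils::write.csv(ipd, out("inverted_pair_distances.csv"),
                     row.names = FALSE)
    utils::write.csv(tt, out("teen_twenty_bias.csv"), row.names = FALSE)
    utils::write.csv(dds, out("decade_difference_scores.csv"),
                     row.names = FALSE)
    results$pairs <- list(inverted = ipd, h1 = h1, teen_twenty = tt,
                          teen_twenty_tests = ttt, decade_scores = dds,
                          decade_score_tests = ddt)
    report <- c(report, "## Pair analyses", "",
                fmt_test("inverted pairs, German < English", h1$test),
                vapply(names(ttt), function(l) fmt_test(
                  paste0(l, ", teens > twenties"), ttt[[l]]$paired),
                  character(1)),
                vapply(names(ddt), function(l) sprintf(
                  "decade difference score, %s: M = %.2f, SE = %.2f", l,
                  ddt[[l]]$mean, ddt[[l]]$se), character(1)), "")
  }

  if (isTRUE(cfg$analyses$model)) {
    med <- prepare_medians(data, min_target = cfg$model$min_target,
                           pooling = cfg$model$pooling)
    fit <- fit_power_model(med, reference = cfg$model$reference,
                           cycles = cfg$model$cycles)
    tab <- summary(fit)$coefficients
    mt <- data.frame(parameter = rownames(tab), tab, row.names = NULL,
                     check.names = FALSE)
    utils::write.csv(mt, out("model_table.csv"), row.names = FALSE)
    curves <- do.call(rbind, lapply(unique(med$language), function(l)
      data.frame(language = l, target = nle_targets,
                 predicted = predict(fit, data.frame(
                   target = nle_targets, language = l)))))
    utils::write.csv(curves, out("model_curves.csv"), row.names = FALSE)
    results$model <- list(medians = med, fit = fit, table = mt,
                          curves = curves)
    report <- c(report, "## Cyclical power model", "",
                sprintf("- reference: %s, %s-cycle, BIC = %.2f",
                        fit$reference, fit$cycles, fit$bic),
                sprintf("- %s = %.3f (SE %.3f, t = %.2f, p = %.4g)",
                        rownames(tab), tab[, "Estimate"],
                        tab[, "Std. Error"], tab[, "t value"],
                        tab[, "Pr(>|t|)"]), "")
  }

  writeLines(report, out("report.md"))
  invisible(results)
}
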