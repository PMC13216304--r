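#' Mean inverted-pair distance per participant
#'
#' For each participant, the mean placing position per target is computed
#' first; each digit-reversal pair then contributes the absolute distance
#' between its two members' mean positions, and the participant's score
#' is the unweighted mean over pairs. Under veridical responding this
#' equals the mean true difference of the 17 printed pairs, 477/17.
#' Number word inversion is expected to shrink it. Pairs with a missing
#' member are skipped (divisor adjusted) with a warning.
#'
#' @param trials analysable trials or an `nle_data` object.
#' @param pairs data frame with columns `small`, `large`; default
#'   [inverted_pairs].
#' @return Data frame with `participant_id`, `language`, `mean_distance`,
#'   `n_pairs`.
#' @export
inverted_pair_distance <- function(trials, pairs = inverted_pairs) {
  t <- analysis_trials(trials)
  skipped <- FALSE
  out <- do.call(rbind, lapply(
    split(seq_len(nrow(t)), t$participant_id), function(i) {
      m <- tapply(t$placing_position[i], t$target[i], mean)
      d <- abs(m[as.character(pairs$large)] - m[as.character(pairs$small)])
      if (anyNA(d)) skipped <<- TRUE
      data.frame(participant_id = t$participant_id[i[1]],
                 language = t$language[i[1]],
                 mean_distance = mean(d, na.rm = TRUE),
                 n_pairs = sum(!is.na(d)))
    }))
  if (skipped)
    warning("some pairs had a missing member and were skipped")
  rownames(out) <- NULL
  out
}

#' Between-language inverted-pair test
#'
#' One-tailed Welch t-test of the hypothesis that German-speakers'
#' inverted-pair distances are smaller than English-speakers' (stronger
#' unit influence pulls digit-reversal pairs together), with group means
#' and SDs reported alongside.
#'
#' @param distances an [inverted_pair_distance()] table.
#' @return List with `test` (`nle_test`) and `groups`.
#' @export
h1_test <- function(distances) {
  ger <- distances$mean_distance[distances$language == "German"]
  eng <- distances$mean_distance[distances$language == "English"]
  if (!length(ger) || !length(eng))
    stop("both German and English groups are required")
  groups <- data.frame(
    language = c("German", "English"),
    mean = c(mean(ger), mean(eng)), sd = c(stats::sd(ger), stats::sd(eng)),
    n = c(length(ger), length(eng)))
  list(test = welch_t(ger, eng, tail = "one_sided_less"), groups = groups)
}

#' Teen versus twenty positioning bias
#'
#' Per participant, the mean positioning bias over the teen targets
#' (13--19, inverted number words in English) and over the unit-matched
#' twenty targets (23--29). The group layer runs, per language, a
#' one-tailed paired t-test (teens less underestimated than twenties) and
#' two-sided one-sample t-tests of each decade mean against 0.
#'
#' @param trials analysable trials or an `nle_data` object.
#' @return Data frame with `participant_id`, `language`, `teen_bias`,
#'   `twenty_bias`.
#' @export
teen_twenty_bias <- function(trials) {
  t <- analysis_trials(trials)
  out <- do.call(rbind, lapply(
    split(seq_len(nrow(t)), t$participant_id), function(i) {
      teen <- t$bias[i][t$target[i] %in% 13:19]
      twenty <- t$bias[i][t$target[i] %in% 23:29]
      if (!length(teen) || !length(twenty)) return(NULL)
      data.frame(participant_id = t$participant_id[i[1]],
                 language = t$language[i[1]],
                 teen_bias = mean(teen), twenty_bias = mean(twenty))
    }))
  rownames(out) <- NULL
  out
}

#' @rdname teen_twenty_bias
#' @param tt a `teen_twenty_bias()` table.
#' @return `teen_twenty_tests()`: named list (per language) of lists with
#'   `paired` (teen > twenty, one-tailed), `teen_vs_zero`,
#'   `twenty_vs_zero`, and the group means/SDs.
#' @export
teen_twenty_tests <- function(tt) {
  langs <- unique(tt$language)
  stats::setNames(lapply(langs, function(l) {
    d <- tt[tt$language == l, , drop = FALSE]
    list(language = l,
         paired = paired_t(d$teen_bias, d$twenty_bias,
                           tail = "one_sided_greater"),
         teen_vs_zero = one_sample_t(d$teen_bias, 0),
         twenty_vs_zero = one_sample_t(d$twenty_bias, 0),
         means = c(teen = mean(d$teen_bias), twenty = mean(d$twenty_bias)),
         sds = c(teen = stats::sd(d$teen_bias),
                 twenty = stats::sd(d$twenty_bias)),
         n = nrow(d))
  }), langs)
}

#' Decade difference scores
#'
#' For target pairs straddling a decade break (e.g. 29/31), how much the
#' distance between the pair members' placing positions exceeds their
#' true numerical difference. Positive mean scores indicate boundary
#' exaggeration, the signature of the left-digit effect; an exactly
#' affine responder with unit slope scores 0.
#'
#' @param trials analysable trials or an `nle_data` object.
#' @param pairs data frame with columns `small`, `large`; default
#'   [decade_break_pairs].
#' @return Data frame with `participant_id`, `language`, `mean_score`,
#'   `n_pairs`.
#' @export
decade_difference_scores <- function(trials, pairs = decade_break_pairs) {
  t <- analysis_trials(trials)
  skipped <- FALSE
  out <- do.call(rbind, lapply(
    split(seq_len(nrow(t)), t$participant_id), function(i) {
      m <- tapply(t$placing_position[i], t$target[i], mean)
      placed <- m[as.character(pairs$large)] - m[as.character(pairs$small)]
      score <- placed - (pairs$large - pairs$small)
      if (anyNA(score)) skipped <<- TRUE
      data.frame(participant_id = t$participant_id[i[1]],
                 language = t$language[i[1]],
                 mean_score = mean(score, na.rm = TRUE),
                 n_pairs = sum(!is.na(score)))
    }))
  if (skipped)
    warning("some pairs had a missing member and were skipped")
  rownames(out) <- NULL
  out
}

#' @rdname decade_difference_scores
#' @param scores a `decade_difference_scores()` table.
#' @return `decade_score_tests()`: per language, the group mean, SE and a
#'   one-sample t-test of the scores against 0.
#' @export
decade_score_tests <- function(scores) {
  langs <- unique(scores$language)
  stats::setNames(lapply(langs, function(l) {
    s <- scores$mean_score[scores$language == l]
    list(language = l, mean = mean(s),
         se = stats::sd(s) / sqrt(length(s)), n = length(s),
         test = one_sample_t(s, 0))
  }), langs)
}
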