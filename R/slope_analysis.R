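#' Intra-decade regression slopes
#'
#' Ordinary least-squares slope of placing position on target number,
#' computed at the trial level individually for each participant and each
#' decade above the teens (decades 20--90; both orientations pooled). A
#' slope of 1 indicates veridical responding, slopes below 1 unit-digit
#' neglect (left-digit bias), 0 pure left-digit responding. Steeper
#' slopes under number word inversion are the operationalisation of the
#' inversion effect. Decades with fewer than two distinct responded
#' targets are omitted.
#'
#' @param trials analysable trials or an `nle_data` object.
#' @return Data frame (`SlopeTable`) with columns `participant_id`,
#'   `language`, `decade`, `slope`, `n_targets`, `n_trials`.
#' @export
decade_slopes <- function(trials) {
  t <- analysis_trials(trials)
  t <- t[t$target > 20, , drop = FALSE]
  t$decade <- decade_part(t$target)
  key <- interaction(t$participant_id, t$decade, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(t)), key), function(i) {
    x <- t$target[i]; y <- t$placing_position[i]
    if (length(unique(x)) < 2) return(NULL)
    xc <- x - mean(x)
    data.frame(participant_id = t$participant_id[i[1]],
               language = t$language[i[1]], decade = t$decade[i[1]],
               slope = sum(xc * (y - mean(y))) / sum(xc^2),
               n_targets = length(unique(x)), n_trials = length(i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$decade), , drop = FALSE]
}

#' Per-participant mean slope
#'
#' Unweighted mean of a participant's decade slopes (decades 20--90;
#' undefined decades simply reduce the divisor). These scalars are the
#' dependent variable of the group comparisons.
#'
#' @param slope_table a [decade_slopes()] table.
#' @return Data frame with `participant_id`, `language`, `mean_slope`,
#'   `n_decades`.
#' @export
participant_mean_slopes <- function(slope_table) {
  out <- do.call(rbind, lapply(
    split(seq_len(nrow(slope_table)), slope_table$participant_id),
    function(i) data.frame(
      participant_id = slope_table$participant_id[i[1]],
      language = slope_table$language[i[1]],
      mean_slope = mean(slope_table$slope[i]),
      n_decades = length(i))))
  rownames(out) <- NULL
  out
}

#' Group comparisons of mean intra-decade slopes
#'
#' The inversion-effect tests: one-tailed Welch t-tests of German >
#' English and German > Mandarin mean individual slopes, and a two-tailed
#' Welch t-test of English vs Mandarin, each with Cohen's d.
#'
#' @param mean_slopes a [participant_mean_slopes()] table containing all
#'   three languages.
#' @return List with `tests` (named list of `nle_test` objects) and
#'   `groups` (per-language mean, SD, n).
#' @export
compare_slope_groups <- function(mean_slopes) {
  need <- c("English", "German", "Mandarin")
  missing <- setdiff(need, unique(mean_slopes$language))
  if (length(missing))
    stop("missing language group(s): ", paste(missing, collapse = ", "))
  g <- function(lang) mean_slopes$mean_slope[mean_slopes$language == lang]
  groups <- do.call(rbind, lapply(need, function(l) data.frame(
    language = l, mean = mean(g(l)), sd = stats::sd(g(l)), n = length(g(l)))))
  list(
    tests = list(
      german_gt_english = welch_t(g("German"), g("English"),
                                  tail = "one_sided_greater"),
      german_gt_mandarin = welch_t(g("German"), g("Mandarin"),
                                   tail = "one_sided_greater"),
      english_vs_mandarin = welch_t(g("English"), g("Mandarin"),
                                    tail = "two_sided")),
    groups = groups)
}
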