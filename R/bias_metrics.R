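#' Signed positioning bias
#'
#' Difference between the placing position (on the 0--100 scale of the
#' line) and the target's true linear position; negative values indicate
#' underestimation. Its absolute value, averaged, is the absolute
#' positioning bias (equivalent to percent absolute error on a 0--100
#' line).
#'
#' @param placing_position,target numeric vectors on the 0--100 scale.
#' @return Numeric vector of signed biases.
#' @examples
#' positioning_bias(23.5, 25) # -1.5
#' @export
positioning_bias <- function(placing_position, target) {
  placing_position - target
}

#' Per-participant bias and response-time summaries
#'
#' Aggregates retained, non-training trials to participant-by-dimension
#' means of the signed positioning bias, the absolute positioning bias,
#' and the response time. These participant-level means are the inputs of
#' the group-level ANOVAs and t-tests.
#'
#' @param trials analysable trials or an `nle_data` object.
#' @param targets optional target filter (e.g. `13:19` for the teens).
#' @return Data frame with one row per participant and dimension:
#'   `participant_id`, `language`, `dimension`, `mean_positioning_bias`,
#'   `mean_absolute_positioning_bias`, `mean_rt_ms`, `n_trials`.
#' @export
summarize_participants <- function(trials, targets = NULL) {
  t <- analysis_trials(trials)
  if (!is.null(targets)) t <- t[t$target %in% targets, , drop = FALSE]
  if (!nrow(t)) stop("no analysable trials after filtering")
  key <- interaction(t$participant_id, t$orientation, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(t)), key), function(i) {
    data.frame(participant_id = t$participant_id[i[1]],
               language = t$language[i[1]],
               dimension = t$orientation[i[1]],
               mean_positioning_bias = mean(t$bias[i]),
               mean_absolute_positioning_bias = mean(abs(t$bias[i])),
               mean_rt_ms = mean(t$rt_ms[i], na.rm = TRUE),
               n_trials = length(i))
  }))
  rownames(out) <- NULL
  out[order(out$participant_id, out$dimension), , drop = FALSE]
}

#' Per-target response-time and accuracy profile
#'
#' Mean response time and mean absolute positioning bias per language and
#' target, the descriptive comparison used to check for a speed-accuracy
#' trade-off (similar profiles of RT and absolute bias across targets
#' speak against one).
#'
#' @param trials analysable trials or an `nle_data` object.
#' @return Data frame indexed by `language` and `target` with
#'   `mean_rt_ms`, `mean_absolute_bias` and `n_trials`.
#' @export
rt_profile <- function(trials) {
  t <- analysis_trials(trials)
  key <- interaction(t$language, t$target, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(t)), key), function(i) {
    data.frame(language = t$language[i[1]], target = t$target[i[1]],
               mean_rt_ms = mean(t$rt_ms[i], na.rm = TRUE),
               mean_absolute_bias = mean(abs(t$bias[i])),
               n_trials = length(i))
  }))
  rownames(out) <- NULL
  out[order(out$language, out$target), , drop = FALSE]
}
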