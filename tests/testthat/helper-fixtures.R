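# Builders for analysable trial tables (already-preprocessed shape), so unit
# tests can state response patterns directly without running the simulator.

analysable_trials <- function(target, placing, participant_id = "P1",
                              language = "English",
                              orientation = "horizontal", rt_ms = 800) {
  data.frame(participant_id = participant_id, language = language,
             orientation = orientation, direction = "ascending",
             target = target, repetition = 1L,
             touch_axis_px = NA_real_, touch_off_axis_px = NA_real_,
             rt_ms = rt_ms, is_training = FALSE, excluded = FALSE,
             exclusion_reason = "none", placing_position = placing)
}

# a participant responding veridically, `reps` times per target
perfect_trials <- function(targets = nle_targets, reps = 2, ...) {
  tg <- rep(targets, each = reps)
  analysable_trials(tg, placing = tg, ...)
}

# independent evaluation of the printed model equation, written from the
# formula (kept separate from the package's prediction path on purpose)
oracle_two_cycle <- function(x, beta, delta) {
  xd <- (x %/% 10) * 10
  xu <- x - xd
  s <- xd + ifelse(xu > 0, xu^delta, 0)
  LB <- ifelse(x <= 50, 0, 50)
  UB <- LB + 50
  ((s - LB)^beta) / ((s - LB)^beta + (UB - s)^beta) * 0.5 * 100 + LB
}

# raw (pixel-space) trials for one participant, given placing positions
raw_trials <- function(target, placing, direction = "ascending",
                       participant_id = "P1", language = "English",
                       orientation = "horizontal", rt_ms = 800,
                       off_axis = 0, is_training = FALSE) {
  px <- placing * 10 - 500
  if (direction == "descending") px <- -px
  data.frame(participant_id = participant_id, language = language,
             orientation = orientation, direction = direction,
             target = target, repetition = 1L, touch_axis_px = px,
             touch_off_axis_px = off_axis, rt_ms = rt_ms,
             is_training = is_training)
}

two_lang_specs <- function(n = 3, noise_sd = 0, beta = 1, delta = 1,
                           offsets = c(English = 0, German = 0), ...) {
  lapply(names(offsets), function(l)
    cohort_spec(l, n, beta = beta, delta = delta,
                bias_offset = offsets[[l]], noise_sd = noise_sd,
                timeout_rate = 0, ...))
}

design_constraints_hold <- function(design) {
  all(vapply(split(design$target, design$block), function(tg) {
    all(abs(diff(tg)) >= 10) &&
      !any((tg[-1] %% 10) == (tg[-length(tg)] %% 10))
  }, logical(1)))
}
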