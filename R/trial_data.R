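#' Specification of the presented number line
#'
#' The line spans 1000 px, from axis coordinate -500 to +500, representing
#' the 0--100 number range; its perpendicular (off-axis) coordinate is
#' fixed. Horizontal and vertical lines share one code path through the
#' generic axis / off-axis coordinate pair.
#'
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param axis_min_px,axis_max_px axis-coordinate endpoints in pixels.
#' @param off_axis_center_px the line's fixed perpendicular coordinate.
#' @return An object of class `line_spec`.
#' @export
line_spec <- function(orientation = c("horizontal", "vertical"),
                      axis_min_px = -500L, axis_max_px = 500L,
                      off_axis_center_px = 0L) {
  orientation <- match.arg(orientation)
  stopifnot(axis_min_px < axis_max_px)
  structure(list(orientation = orientation,
                 axis_min_px = axis_min_px,
                 axis_max_px = axis_max_px,
                 off_axis_center_px = off_axis_center_px),
            class = "line_spec")
}

#' Convert touch coordinates to placing positions
#'
#' Maps a raw axis-pixel coordinate onto the 0--100 scale of the target
#' numbers. Lines answered in the descending direction (small numbers at
#' the axis-max end) are numerically turned around so a smaller placing
#' position always corresponds to the "small end" of the line.
#'
#' @param touch_axis_px numeric vector of axis coordinates in pixels,
#'   within `[axis_min_px, axis_max_px]`.
#' @param direction `"ascending"` or `"descending"`, recycled.
#' @param line a [line_spec()].
#' @return Numeric vector of placing positions in `[0, 100]`.
#' @examples
#' convert_touch(-500, "ascending")  # 0
#' convert_touch(0, "descending")    # 50
#' convert_touch(250, "descending")  # 25
#' @export
convert_touch <- function(touch_axis_px, direction, line = line_spec()) {
  if (any(touch_axis_px < line$axis_min_px | touch_axis_px > line$axis_max_px,
          na.rm = TRUE))
    stop("touch coordinate outside the line axis range; such responses ",
         "must be excluded, not converted")
  span <- line$axis_max_px - line$axis_min_px
  pos <- (touch_axis_px - line$axis_min_px) * 100 / span
  desc <- rep_len(direction == "descending", length(pos))
  pos[desc] <- 100 - pos[desc]
  pos
}

#' Apply response exclusion rules
#'
#' Flags responses whose axis coordinate lies beyond the presented line
#' (`off_line_axis`), whose perpendicular coordinate deviates more than
#' `off_axis_limit` pixels from the line (`off_line_perpendicular`;
#' strict inequality, 150 px is retained), and timed-out trials
#' (`timeout`, missing response time, no coordinates). Applying the rules
#' twice changes nothing.
#'
#' @param trials data frame of raw trials with columns `touch_axis_px`,
#'   `touch_off_axis_px`, `rt_ms`.
#' @param line a [line_spec()].
#' @param off_axis_limit maximal tolerated perpendicular deviation in px.
#' @return List with `trials` (input plus `excluded`, `exclusion_reason`),
#'   `retained` (the non-excluded rows), and `log` (count and fraction per
#'   reason; fractions of touch-based reasons use all recorded touch
#'   responses as denominator, the timeout fraction all presentations).
#' @export
apply_exclusions <- function(trials, line = line_spec(),
                             off_axis_limit = 150) {
  n <- nrow(trials)
  reason <- rep("none", n)
  timeout <- is.na(trials$rt_ms) | is.na(trials$touch_axis_px)
  reason[timeout] <- "timeout"
  off_perp <- !timeout &
    abs(trials$touch_off_axis_px - line$off_axis_center_px) > off_axis_limit
  reason[off_perp] <- "off_line_perpendicular"
  off_axis <- !timeout & (trials$touch_axis_px < line$axis_min_px |
                            trials$touch_axis_px > line$axis_max_px)
  reason[off_axis] <- "off_line_axis"
  trials$excluded <- reason != "none"
  trials$exclusion_reason <- reason
  n_touch <- sum(!timeout)
  log <- data.frame(
    reason = c("off_line_axis", "off_line_perpendicular", "timeout"),
    n = c(sum(off_axis), sum(off_perp), sum(timeout)),
    fraction = c(
      if (n_touch > 0) sum(off_axis) / n_touch else 0,
      if (n_touch > 0) sum(off_perp) / n_touch else 0,
      if (n > 0) sum(timeout) / n else 0
    )
  )
  list(trials = trials, retained = trials[!trials$excluded, , drop = FALSE],
       log = log)
}

#' Infer a participant's chosen line direction
#'
#' Participants were free to choose at which end of the line small numbers
#' go; the chosen direction is recovered from the data as the sign of the
#' correlation between target number and raw axis coordinate. A sliding
#' window correlation additionally flags participants who switched
#' direction mid-task (strong positive and strong negative windows both
#' present); switchers are removed before analysis.
#'
#' @param target,touch_axis_px trial vectors of one participant in one
#'   orientation, in presentation order.
#' @param window sliding window length for the switch diagnostic.
#' @param r_threshold absolute correlation both window signs must exceed
#'   for the switch flag.
#' @param min_trials below this many trials the direction is undetermined.
#' @return List with `direction` (`"ascending"`, `"descending"` or `NA`),
#'   `r` (overall correlation), `switched` (logical) and `n`.
#' @export
infer_direction <- function(target, touch_axis_px, window = 25,
                            r_threshold = 0.5, min_trials = 10) {
  keep <- !is.na(touch_axis_px)
  target <- target[keep]; touch_axis_px <- touch_axis_px[keep]
  n <- length(target)
  if (n < min_trials)
    return(list(direction = NA_character_, r = NA_real_, switched = NA, n = n))
  r <- stats::cor(target, touch_axis_px)
  direction <- if (r >= 0) "ascending" else "descending"
  switched <- FALSE
  if (n >= 2 * window) {
    wr <- rolling_cor(target, touch_axis_px, window)
    switched <- any(wr > r_threshold, na.rm = TRUE) &&
      any(wr < -r_threshold, na.rm = TRUE)
  }
  list(direction = direction, r = r, switched = switched, n = n)
}

# Pearson correlation over every window of length w, via cumulative sums
rolling_cor <- function(x, y, w) {
  n <- length(x)
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cyy <- c(0, cumsum(y * y))
  cxy <- c(0, cumsum(x * y))
  i <- seq_len(n - w + 1L)
  sx <- cx[i + w] - cx[i]; sy <- cy[i + w] - cy[i]
  sxx <- cxx[i + w] - cxx[i]; syy <- cyy[i + w] - cyy[i]
  sxy <- cxy[i + w] - cxy[i]
  num <- w * sxy - sx * sy
  den <- sqrt(pmax(w * sxx - sx^2, 0) * pmax(w * syy - sy^2, 0))
  ifelse(den > 0, num / den, NA_real_)
}

trial_columns <- c("participant_id", "language", "orientation", "direction",
                   "target", "repetition", "touch_axis_px",
                   "touch_off_axis_px", "rt_ms", "is_training")

participant_columns <- c("participant_id", "language", "age", "gender",
                         "handedness", "start_orientation")

#' Read and write trial-level CSV files
#'
#' Plain UTF-8 comma-separated files with a header row; all trial fields
#' round-trip losslessly. Preprocessed variants may carry the derived
#' columns `placing_position`, `excluded`, `exclusion_reason`.
#'
#' @param path file path.
#' @param trials data frame of trials.
#' @return `read_trials()` a data frame of trials.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(d))
  if (length(missing))
    stop("trial file is missing required column(s): ",
         paste(missing, collapse = ", "))
  bad_lang <- !d$language %in% nle_languages
  if (any(bad_lang))
    stop("unknown language label(s) ",
         paste(unique(d$language[bad_lang]), collapse = ", "),
         " in row(s) ", paste(utils::head(which(bad_lang), 5), collapse = ", "))
  for (col in c("target", "repetition", "touch_axis_px", "touch_off_axis_px",
                "rt_ms")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- !is.na(d[[col]]) & is.na(v)
    if (any(bad))
      stop("malformed value in column '", col, "' at row ", which(bad)[1])
    d[[col]] <- v
  }
  d$is_training <- as.logical(d$is_training)
  d
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_trials
#' @export
read_participants <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(participant_columns, names(d))
  if (length(missing))
    stop("participant file is missing required column(s): ",
         paste(missing, collapse = ", "))
  d
}

#' @rdname read_trials
#' @param participants data frame of participants.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Preprocess raw trials
#'
#' The full preparation path from raw pixel coordinates to analysable
#' placing positions: exclusion rules, per participant-by-orientation
#' direction inference, removal of direction switchers, and conversion of
#' retained touches to the 0--100 scale (direction-normalised).
#'
#' @param trials raw trial data frame (see [read_trials()] for columns).
#' @param line a [line_spec()]; the same geometry is applied to both
#'   orientations.
#' @param off_axis_limit perpendicular exclusion limit in pixels.
#' @param infer if `TRUE` (default) directions are inferred from the data;
#'   otherwise the `direction` column is trusted.
#' @return An object of class `nle_data`: list with `trials` (flagged, with
#'   `placing_position`), `exclusion_log`, `directions` (one row per
#'   participant and orientation) and `dropped_switchers`.
#' @export
preprocess_trials <- function(trials, line = line_spec(),
                              off_axis_limit = 150, infer = TRUE) {
  ex <- apply_exclusions(trials, line, off_axis_limit)
  trials <- ex$trials

  key <- interaction(trials$participant_id, trials$orientation, drop = TRUE)
  dirs <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key), function(i) {
    use <- i[!trials$excluded[i] & !trials$is_training[i]]
    inf <- infer_direction(trials$target[use], trials$touch_axis_px[use])
    data.frame(participant_id = trials$participant_id[i[1]],
               orientation = trials$orientation[i[1]],
               direction = if (infer) inf$direction else trials$direction[i[1]],
               r = inf$r, switched = inf$switched, n = inf$n)
  }))
  rownames(dirs) <- NULL

  switchers <- unique(dirs$participant_id[dirs$switched %in% TRUE])
  if (length(switchers)) {
    trials <- trials[!trials$participant_id %in% switchers, , drop = FALSE]
    key <- interaction(trials$participant_id, trials$orientation, drop = TRUE)
  }

  dmap <- stats::setNames(dirs$direction,
                          paste(dirs$participant_id, dirs$orientation))
  trial_dir <- dmap[paste(trials$participant_id, trials$orientation)]
  trials$direction <- unname(trial_dir)
  trials$placing_position <- NA_real_
  ok <- !trials$excluded & !is.na(trials$direction)
  trials$placing_position[ok] <- convert_touch(trials$touch_axis_px[ok],
                                               trials$direction[ok], line)
  structure(list(trials = trials, exclusion_log = ex$log, directions = dirs,
                 dropped_switchers = switchers),
            class = "nle_data")
}

#' @export
print.nle_data <- function(x, ...) {
  t <- x$trials
  cat("Preprocessed number line estimation data\n")
  cat(sprintf("  %d trials, %d participants, languages: %s\n", nrow(t),
              length(unique(t$participant_id)),
              paste(sort(unique(t$language)), collapse = ", ")))
  cat(sprintf("  excluded: %d (%s)\n", sum(t$excluded),
              paste(sprintf("%s %d", x$exclusion_log$reason,
                            x$exclusion_log$n), collapse = ", ")))
  if (length(x$dropped_switchers))
    cat("  dropped direction switchers:",
        paste(x$dropped_switchers, collapse = ", "), "\n")
  invisible(x)
}

#' Extract analysable trials
#'
#' Retained, non-training experimental trials with placing positions and
#' the signed positioning bias (placing position minus target).
#'
#' @param x an `nle_data` object from [preprocess_trials()], or a trial
#'   data frame already carrying `placing_position` and exclusion flags.
#' @return Data frame of analysable trials with a `bias` column.
#' @export
analysis_trials <- function(x) {
  t <- if (inherits(x, "nle_data")) x$trials else x
  t <- t[!t$excluded & !t$is_training & !is.na(t$placing_position), ,
         drop = FALSE]
  t$bias <- positioning_bias(t$placing_position, t$target)
  t
}
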