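#' Experimental stimulus set
#'
#' The 50 two-digit target numbers presented in the 0--100 number line
#' estimation task. Each target is shown four times per line orientation,
#' giving 400 experimental trials per participant.
#'
#' @format Integer vector of length 50.
#' @export
nle_targets <- c(
  13L, 14L, 15L, 16L, 17L, 18L, 19L,
  21L, 23L, 24L, 25L, 26L, 27L, 28L, 29L,
  31L, 32L, 34L, 37L, 39L,
  41L, 42L, 43L, 46L, 48L,
  51L, 52L, 54L, 56L, 58L,
  62L, 63L, 65L, 67L, 69L,
  72L, 73L, 76L, 78L, 79L,
  82L, 84L, 85L, 87L, 89L,
  91L, 92L, 93L, 96L, 98L
)

#' Training targets
#'
#' Targets used in the three training trials at the start of each
#' orientation block (presented in this order). Training trials are stored
#' but flagged and never analysed.
#'
#' @format Integer vector of length 3.
#' @export
nle_training_targets <- c(70L, 30L, 50L)

#' Language groups
#'
#' The native-language groups of the cross-linguistic design. German has
#' fully inverted two-digit number words (unit spoken before decade),
#' English inverts only the teens, Mandarin never inverts.
#'
#' @format Character vector of length 3.
#' @export
nle_languages <- c("English", "German", "Mandarin")

#' Digit-reversal number pairs
#'
#' The 17 pairs of digit-reversed two-digit targets (both members > 20)
#' used by the inverted-pair distance analysis, e.g. 23--32 or 89--98.
#' The mean of their true numerical differences is 477/17.
#'
#' @format Data frame with columns `small` and `large`.
#' @export
inverted_pairs <- data.frame(
  small = c(23L, 24L, 25L, 26L, 27L, 28L, 29L, 34L, 37L, 39L, 48L, 56L,
            58L, 67L, 69L, 78L, 89L),
  large = c(32L, 42L, 52L, 62L, 72L, 82L, 92L, 43L, 73L, 93L, 84L, 65L,
            85L, 76L, 96L, 87L, 98L)
)

#' Decade-boundary number pairs
#'
#' Adjacent target pairs straddling a decade break with true distance 2,
#' restricted to pairs whose members are both in [nle_targets]. Used by the
#' decade difference score; positive scores indicate boundary exaggeration
#' (a left-digit effect).
#'
#' @format Data frame with columns `small` and `large`.
#' @export
decade_break_pairs <- data.frame(
  small = c(19L, 29L, 39L, 89L),
  large = c(21L, 31L, 41L, 91L)
)

#' Decompose two-digit targets into decade and unit parts
#'
#' @param target integer vector of targets in (0, 100].
#' @return `decade_part()` the decade component (20 of 28); `unit_part()`
#'   the unit digit (8 of 28).
#' @examples
#' decade_part(28) # 20
#' unit_part(28)   # 8
#' @export
decade_part <- function(target) (target %/% 10L) * 10L

#' @rdname decade_part
#' @export
unit_part <- function(target) target %% 10L
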