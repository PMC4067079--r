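#' Test whether a DNA string is its own reverse complement
#'
#' Odd-length strings can never be self-palindromic; `N` matches nothing,
#' so any `N` makes the test fail.
#'
#' @param seq a DNA string.
#' @return `TRUE` iff `seq` equals its reverse complement.
#' @export
is_self_palindromic <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  assert_dna(seq)
  if (nchar(seq) %% 2L == 1L) return(FALSE)
  if (grepl("N", seq, fixed = TRUE)) return(FALSE)
  identical(seq, revcomp(seq))
}

finish_hairpins <- function(seq, df) {
  span <- 2L * df$arm_len + df$loop_len
  df$seq <- if (nrow(df)) substring(seq, df$offset + 1L, df$offset + span)
            else character(0)
  class(df) <- c("palindrome_set", "data.frame")
  df
}

#' Find maximal hairpins (self-palindromic segments with a loop)
#'
#' A hairpin at `offset` consists of an arm of `arm_len` bases, a loop of
#' `loop_len` bases and the (approximate) reverse complement of the arm.
#' All maximal hairpins satisfying the constraints are returned, sorted
#' by offset then descending arm length.  A hairpin is maximal if
#' extending the stem outward by one pair, or inward into the loop,
#' violates a constraint.  `N` never pairs, so assembly gaps cannot seed
#' stems.  Offsets are 0-based.
#'
#' @param seq DNA string.
#' @param min_arm,max_arm allowed arm lengths in bp (`min_arm >= 2`).
#' @param min_loop,max_loop allowed loop lengths in bp (0 = perfect
#'   self-palindrome).
#' @param max_mismatch maximum mismatched pairs within the arms.
#' @return data frame with columns `offset`, `arm_len`, `loop_len`,
#'   `mismatches`, `seq`.
#' @export
find_palindromes <- function(seq, min_arm = 4L, max_arm = 20L,
                             min_loop = 0L, max_loop = 4L,
                             max_mismatch = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  assert_dna(seq)
  if (min_arm < 2L) stop("min_arm must be >= 2", call. = FALSE)
  if (max_arm < min_arm || max_loop < min_loop || min_loop < 0L) {
    stop("inconsistent hairpin parameters", call. = FALSE)
  }
  df <- hairpin_scan_cpp(seq, as.integer(min_arm), as.integer(max_arm),
                         as.integer(min_loop), as.integer(max_loop),
                         as.integer(max_mismatch))
  finish_hairpins(seq, df)
}

#' Find dispersed inverted-repeat pairs
#'
#' Reports all maximal arm pairs where the right arm is the reverse
#' complement of the left arm (up to `max_mismatch`) separated by a gap
#' in `[min_gap, max_gap]`.  Overlapping arms are excluded by
#' construction (the gap is never negative).  Coordinates are 0-based
#' half-open.
#'
#' @param seq DNA string.
#' @param min_arm minimum arm length in bp.
#' @param min_gap,max_gap allowed gap between the arms in bp.
#' @param max_mismatch maximum mismatched pairs within the arms.
#' @param max_arm optional cap on arm length (defaults to the sequence
#'   length, i.e. unbounded).
#' @return data frame with columns `left_start`, `left_end`,
#'   `right_start`, `right_end`, `arm_len`, `gap`, `mismatches`
#'   (0-based half-open intervals).
#' @export
find_inverted_repeat_pairs <- function(seq, min_arm = 3L, min_gap = 0L,
                                       max_gap = 30L, max_mismatch = 0L,
                                       max_arm = nchar(seq)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  assert_dna(seq)
  if (min_arm < 2L || min_gap < 0L || max_gap < min_gap) {
    stop("inconsistent inverted-repeat parameters", call. = FALSE)
  }
  df <- hairpin_scan_cpp(seq, as.integer(min_arm), as.integer(max_arm),
                         as.integer(min_gap), as.integer(max_gap),
                         as.integer(max_mismatch))
  out <- data.frame(
    left_start = df$offset,
    left_end = df$offset + df$arm_len,
    right_start = df$offset + df$arm_len + df$loop_len,
    right_end = df$offset + 2L * df$arm_len + df$loop_len,
    arm_len = df$arm_len, gap = df$loop_len, mismatches = df$mismatches)
  class(out) <- c("ir_pair_set", "data.frame")
  out
}

# internal: hairpin scan with terminal-mismatch trimming, for genome scans
# (a maximal hit under a mismatch budget may carry its mismatches at the
# stem ends; trimming them back gives the planted stem)
hairpins_trimmed <- function(seq, min_arm, max_arm, min_loop, max_loop,
                             max_mismatch) {
  df <- hairpin_scan_cpp(seq, as.integer(min_arm), as.integer(max_arm),
                         as.integer(min_loop), as.integer(max_loop),
                         as.integer(max_mismatch), trim_terminal = TRUE)
  if (nrow(df)) {
    df <- df[!duplicated(df[, c("offset", "arm_len", "loop_len")]), , drop = FALSE]
    df <- df[order(df$offset, -df$arm_len, df$loop_len), , drop = FALSE]
    rownames(df) <- NULL
  }
  finish_hairpins(seq, df)
}

# union of trimmed scans over every mismatch budget 0..max_mismatch:
# under a single budget, a clean planted stem can be absorbed into a
# chance-extended higher-mismatch stem on the same diagonal and lost;
# the budget-0 pass always retains it
hairpins_multi <- function(seq, min_arm, max_arm, min_loop, max_loop,
                           max_mismatch) {
  parts <- lapply(0:max_mismatch, function(mm)
    hairpins_trimmed(seq, min_arm, max_arm, min_loop, max_loop, mm))
  df <- do.call(rbind, parts)
  if (nrow(df)) {
    df <- df[!duplicated(df[, c("offset", "arm_len", "loop_len")]), , drop = FALSE]
    df <- df[order(df$offset, -df$arm_len, df$loop_len), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
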