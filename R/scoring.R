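# Dual-task counting scoring (with carry-forward credit after an error) and
# questionnaire scoring: SUS (0-100 rescale of the Likert mean), IMI
# (per-subscale means on the raw Likert scale), NASA Raw TLX (six 0-100
# sliders, unweighted).

#' Score one counting block (percent correct, carry-forward rule)
#'
#' Walks the block's fruit sequence keeping, per fruit category, the true
#' cumulative count (counting restarts from zero each block) and the last
#' value the participant said. A response is correct iff its spoken category
#' matches the presented fruit and the spoken number lies in the acceptance
#' set `{true count, last said + 1}` -- so after an erroneous value, a
#' participant is credited either for continuing from that value or for
#' recovering to the true count (with no prior error the set degenerates to
#' the single true count). Category-confused responses are incorrect and do
#' not advance the confused category's counter.
#'
#' @param block data frame with one row per presented fruit, in order:
#'   `category` (presented fruit), `said_category`, `said_count`.
#' @return Percentage of correct responses (0--100), with a `detail`
#'   attribute holding the per-fruit acceptance decision.
#' @examples
#' blk <- data.frame(category = rep("pear", 4),
#'                   said_category = rep("pear", 4),
#'                   said_count = c(1, 2, 4, 5))
#' score_counting_block(blk)  # 75: "4" is wrong, "5" continues correctly
#' @export
score_counting_block <- function(block) {
  .assert(all(c("category", "said_category", "said_count") %in% names(block)),
          "`block` must have columns category, said_category, said_count")
  n <- nrow(block)
  .assert(n >= 1, "empty block")
  .assert(!anyNA(block$said_count), "response count must match fruit count (missing responses)")

  cats <- as.character(block$category)
  true_count <- stats::ave(seq_len(n), cats, FUN = seq_along)
  last_said <- new.env(parent = emptyenv())
  correct <- logical(n)
  accepted <- character(n)
  for (i in seq_len(n)) {
    cc <- cats[i]
    prev <- if (exists(cc, envir = last_said)) get(cc, envir = last_said) else NULL
    accept <- unique(c(true_count[i], if (!is.null(prev)) prev + 1))
    accepted[i] <- paste(accept, collapse = "/")
    if (identical(as.character(block$said_category[i]), cc) &&
        block$said_count[i] %in% accept) {
      correct[i] <- TRUE
    }
    if (identical(as.character(block$said_category[i]), cc)) {
      assign(cc, block$said_count[i], envir = last_said)
    }
  }
  score <- 100 * sum(correct) / n
  attr(score, "detail") <- tibble::tibble(
    category = cats, true_count = true_count,
    said_count = block$said_count, accepted = accepted, correct = correct
  )
  score
}

#' Average block counting scores into one participant value
#'
#' @param block_scores numeric vector of per-block percentages (>= 1).
#' @return Unweighted mean percentage.
#' @export
aggregate_counting <- function(block_scores) {
  .assert(length(block_scores) >= 1 && is.numeric(block_scores),
          "need at least one block score")
  mean(block_scores)
}

#' Score the System Usability Scale
#'
#' Single score obtained by averaging all items and rescaling the Likert
#' scale to 0--100: `100 * (mean - 1) / (scale_max - 1)`.
#'
#' @param items numeric item responses, each in `[1, scale_max]`.
#' @param scale_max top of the Likert scale (7 in experiment 1; 5 in
#'   experiment 2's paper form).
#' @return SUS score in `[0, 100]`.
#' @export
score_sus <- function(items, scale_max = 7) {
  .assert(length(items) >= 1 && is.numeric(items), "need at least one item")
  .assert(all(items >= 1 & items <= scale_max),
          "all items must lie in [1, %d]", scale_max)
  100 * (mean(items) - 1) / (scale_max - 1)
}

#' Score the Intrinsic Motivation Inventory
#'
#' One value per subscale: the arithmetic mean of its items on the raw
#' Likert scale (no rescaling).
#'
#' @param items data frame with columns `subscale` and `value`, or a named
#'   list of numeric vectors (one per subscale).
#' @param scale_max top of the Likert scale. Default 7.
#' @return Named numeric vector of subscale means.
#' @export
score_imi <- function(items, scale_max = 7) {
  if (is.data.frame(items)) {
    .assert(all(c("subscale", "value") %in% names(items)),
            "`items` must have columns subscale, value")
    items <- split(items$value, items$subscale)
  }
  .assert(length(items) >= 1, "need at least one subscale")
  .assert(all(lengths(items) >= 1), "every subscale needs at least one item")
  vals <- unlist(items)
  .assert(all(vals >= 1 & vals <= scale_max),
          "all items must lie in [1, %d]", scale_max)
  vapply(items, mean, numeric(1))
}

RTLX_SUBSCALES <- c("mental_demand", "physical_demand", "temporal_demand",
                    "performance", "effort", "frustration")

#' Score the Raw NASA Task Load Index
#'
#' The Raw TLX uses the six slider values directly, one per subscale, with
#' no pairwise weighting. An unweighted overall mean is attached for
#' convenience but is not part of the analysis.
#'
#' @param sliders six numeric values in `[0, 100]`, optionally named by
#'   subscale.
#' @return Named numeric vector of the six subscale values, with attribute
#'   `"overall_mean"`.
#' @export
score_rtlx <- function(sliders) {
  .assert(length(sliders) == 6 && is.numeric(sliders),
          "RTLX requires exactly six slider values")
  .assert(all(sliders >= 0 & sliders <= 100), "slider values must lie in [0, 100]")
  out <- setNames(as.numeric(sliders), names(sliders) %||% RTLX_SUBSCALES)
  if (is.null(names(sliders))) names(out) <- RTLX_SUBSCALES
  attr(out, "overall_mean") <- mean(sliders)
  out
}

#' Digitize a paper-form RTLX analogue-scale response
#'
#' The paper form uses an analogue scale of physical length 122--125.5 mm
#' (printer-dependent). The measured distance from the left border to the
#' response mark is rounded to the nearest 0.5 mm, divided by the physical
#' scale length and multiplied by 100.
#'
#' @param distance_mm measured distance, mm (`0 <= distance <= scale length`).
#' @param scale_length_mm physical scale length, mm (in `[122, 125.5]`).
#' @return Value on the 0--100 scale.
#' @examples
#' digitize_rtlx_paper(61, 122)     # 50
#' digitize_rtlx_paper(61.26, 122)  # rounds to 61.5 -> ~50.41
#' @export
digitize_rtlx_paper <- function(distance_mm, scale_length_mm) {
  .assert_scalar_num(distance_mm, "distance_mm")
  .assert_scalar_num(scale_length_mm, "scale_length_mm")
  .assert(scale_length_mm >= 122 && scale_length_mm <= 125.5,
          "`scale_length_mm` must lie in [122, 125.5]")
  .assert(distance_mm >= 0, "`distance_mm` must be >= 0")
  .assert(distance_mm <= scale_length_mm,
          "`distance_mm` cannot exceed the scale length")
  rounded <- round(distance_mm * 2) / 2
  100 * rounded / scale_length_mm
}
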