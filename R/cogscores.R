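#' Stroop interference score by the Golden method
#'
#' The predicted colour-word score is `W * C / (W + C)` where `W` is the
#' number of words read correctly (word card) and `C` the number of colour
#' hues named correctly (colour card). Interference is the actual
#' incongruent-condition correct count minus this prediction:
#' `IG = CW - W*C/(W + C)`. Symmetric in W and C; the prediction never
#' exceeds `min(W, C)`.
#'
#' @param W Word-card correct count (>= 0).
#' @param C Colour-card correct count (>= 0).
#' @param CW Colour-word (incongruent) correct count (>= 0).
#' @return Interference score (real; can be negative).
#' @examples
#' golden_interference(W = 90, C = 45, CW = 40)  # predicted 30, IG = 10
#' @export
golden_interference <- function(W, C, CW) {
  stopifnot(is.numeric(W), is.numeric(C), is.numeric(CW))
  if (any(W < 0 | C < 0 | CW < 0, na.rm = TRUE)) {
    stop("Stroop counts must be nonnegative", call. = FALSE)
  }
  if (any(W + C == 0, na.rm = TRUE)) {
    stop("W + C must be positive to predict the colour-word score",
         call. = FALSE)
  }
  CW - (W * C) / (W + C)
}

#' Total DSST score
#'
#' The modified digit-symbol substitution total is the arithmetic mean of
#' the oral and written correct counts.
#'
#' @param oral,written Correct-symbol counts (>= 0).
#' @return Mean of the two counts.
#' @export
dsst_total <- function(oral, written) {
  stopifnot(is.numeric(oral), is.numeric(written))
  if (any(oral < 0 | written < 0, na.rm = TRUE)) {
    stop("DSST counts must be nonnegative", call. = FALSE)
  }
  (oral + written) / 2
}
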