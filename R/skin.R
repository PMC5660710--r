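#' Segment hand/stylus pixels by an RGB skin-color rule
#'
#' Classifies each pixel of an 8-bit RGB frame with the classic
#' uniform-daylight skin-color decision rule: R > 95, G > 40, B > 20,
#' max(R,G,B) - min(R,G,B) > 15, |R - G| > 15, R > G and R > B. All
#' thresholds are exposed so the rule can be tuned to the camera and
#' illumination. A pure per-pixel function: no spatial context is used.
#'
#' @param frame Numeric array `h x w x 3` with values in 0..255.
#' @param r_min,g_min,b_min Channel lower bounds.
#' @param spread_min Minimum max-min channel spread.
#' @param rg_min Minimum |R - G| difference.
#' @return Logical `h x w` matrix, `TRUE` where the rule fires.
#' @export
segment_hand_pixels <- function(frame, r_min = 95, g_min = 40, b_min = 20,
                                spread_min = 15, rg_min = 15) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  if (any(frame < 0 | frame > 255))
    stop("frame must contain 8-bit channel values in 0..255")
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  r > r_min & g > g_min & b > b_min &
    (mx - mn) > spread_min & abs(r - g) > rg_min & r > g & r > b
}
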