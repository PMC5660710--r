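#' Canonical hemodynamic response function
#'
#' Double-gamma impulse response (peak at ~6 s, undershoot at ~16 s,
#' undershoot ratio 1/6), the standard single-basis task model for block
#' designs. Normalized to unit peak.
#'
#' @param t Time in seconds (vector).
#' @param peak_delay,under_delay Gamma shape parameters (s).
#' @param peak_disp,under_disp Dispersions (s).
#' @param ratio Peak/undershoot amplitude ratio.
#' @return Response values at `t`.
#' @export
canonical_hrf <- function(t, peak_delay = 6, under_delay = 16,
                          peak_disp = 1, under_disp = 1, ratio = 6) {
  g <- function(x)
    dgamma(x, shape = peak_delay / peak_disp, scale = peak_disp) -
      dgamma(x, shape = under_delay / under_disp, scale = under_disp) / ratio
  h <- g(t)
  h[t < 0] <- 0
  # normalize by the peak on a dense reference grid, so the scale does
  # not depend on the requested sampling (and negative-only input is 0)
  h / max(g(seq(0, 32, by = 0.1)))
}

#' Condition regressors for a paradigm
#'
#' Convolves each condition's boxcar (sampled at the TR) with the canonical
#' hemodynamic response and truncates to the run length.
#'
#' @param paradigm A `tmt_paradigm`.
#' @param conditions Conditions to model (default all task conditions).
#' @return Matrix scans x conditions with column names.
#' @export
condition_regressors <- function(paradigm,
                                 conditions = c("TMT_A", "TMT_B")) {
  tr <- paradigm$tr
  n <- paradigm_n_scans(paradigm)
  scan_t <- (seq_len(n) - 1) * tr
  hrf <- canonical_hrf(seq(0, 32, by = tr))
  out <- sapply(conditions, function(cc) {
    box <- rep(0, n)
    bl <- paradigm$blocks[paradigm$blocks$condition == cc, , drop = FALSE]
    for (i in seq_len(nrow(bl)))
      box[scan_t >= bl$onset[i] & scan_t < bl$onset[i] + bl$duration[i]] <- 1
    convolve(box, rev(hrf), type = "open")[seq_len(n)]
  })
  colnames(out) <- conditions
  out
}
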