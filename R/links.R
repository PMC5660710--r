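#' Decompose a stylus log into per-link records
#'
#' A trial is scored as a sequence of links between consecutive targets.
#' Link `k` opens at the first inked sample inside circle `k` (scanning
#' forward from where link `k-1` opened) and closes at the first inked
#' sample inside circle `k+1`. Links are reported only up to the last
#' target actually reached, so a censored trial yields fewer than 24
#' records. "Inked" means contact force above `ink_force_threshold`.
#'
#' Per link, `path_px` is the polyline length of the inked trace *between*
#' the two items: it is summed from the last inked sample still inside the
#' start circle out to the closing sample, so detours (including passes
#' through wrong circles) lengthen it but target progress is never gated
#' on accuracy. `dwell_ms` is the duration of the first stationary run
#' (forward-difference speed below `speed_thr`) that begins while the
#' stylus is still inside the start circle; if the stylus never pauses
#' there, the dwell is zero.
#'
#' @param log A `tablet_log`.
#' @param layout The `tmt_layout` the block was drawn on.
#' @param ink_force_threshold Force (a.u.) above which samples count as
#'   inked.
#' @param speed_thr Stationarity threshold in px/ms (default 0.1).
#' @return Data frame with one row per completed link: `index`, `t_start`,
#'   `t_end` (ms), `path_px`, `dwell_ms`.
#' @export
segment_links <- function(log, layout, ink_force_threshold = 0.05,
                          speed_thr = 0.1) {
  stopifnot(inherits(log, "tablet_log"), inherits(layout, "tmt_layout"))
  s <- log$samples
  empty <- data.frame(index = integer(0), t_start = numeric(0),
                      t_end = numeric(0), path_px = numeric(0),
                      dwell_ms = numeric(0))
  if (nrow(s) == 0) return(empty)
  if (any(s$x_px < -layout$canvas[1] | s$x_px > 2 * layout$canvas[1]))
    stop("log coordinates far outside the layout canvas; block mismatch?")
  inked <- s$force > ink_force_threshold
  centers <- as.matrix(layout$items[, c("x", "y")])
  r <- layout$radius
  n_item <- nrow(centers)

  # forward-difference speed (px/ms); last sample treated as stationary
  nS <- nrow(s)
  spd <- c(sqrt(diff(s$x_px)^2 + diff(s$y_px)^2) / diff(s$t_ms), 0)

  inside <- function(k) {
    sqrt((s$x_px - centers[k, 1])^2 + (s$y_px - centers[k, 2])^2) <= r
  }

  # first inked sample inside each circle, scanning forward
  hit <- integer(n_item)
  from <- 1L
  for (k in seq_len(n_item)) {
    cand <- which(inked & inside(k))
    cand <- cand[cand >= from]
    if (length(cand) == 0) { hit[k] <- NA_integer_; break }
    hit[k] <- cand[1]
    from <- hit[k]
  }
  n_reached <- if (anyNA(hit)) which(is.na(hit))[1] - 1L else n_item
  if (n_reached < 2) return(empty)

  recs <- lapply(seq_len(n_reached - 1L), function(k) {
    i0 <- hit[k]; i1 <- hit[k + 1]
    idx <- i0:i1
    ink_idx <- idx[inked[idx]]
    # path: from last inked sample still inside circle k out to the close
    in_k <- sqrt((s$x_px[ink_idx] - centers[k, 1])^2 +
                 (s$y_px[ink_idx] - centers[k, 2])^2) <= r
    start_at <- if (any(in_k)) {
      first_out <- which(!in_k)[1]
      if (is.na(first_out)) length(ink_idx) else first_out - 1L
    } else 1L
    pi_idx <- ink_idx[start_at:length(ink_idx)]
    path <- if (length(pi_idx) >= 2)
      sum(sqrt(diff(s$x_px[pi_idx])^2 + diff(s$y_px[pi_idx])^2)) else 0
    # dwell: first stationary run starting inside circle k
    seg <- i0:(i1 - 1L)
    in_circle <- sqrt((s$x_px[seg] - centers[k, 1])^2 +
                      (s$y_px[seg] - centers[k, 2])^2) <= r
    stat <- spd[seg] < speed_thr
    first_stat <- which(stat & in_circle)[1]
    dwell <- 0
    if (!is.na(first_stat)) {
      j <- first_stat
      while (j <= length(seg) && spd[seg[j]] < speed_thr) j <- j + 1L
      end_t <- if (j <= length(seg)) s$t_ms[seg[j]] else s$t_ms[i1]
      dwell <- end_t - s$t_ms[seg[first_stat]]
    }
    data.frame(index = k, t_start = s$t_ms[i0], t_end = s$t_ms[i1],
               path_px = path, dwell_ms = dwell)
  })
  do.call(rbind, recs)
}

#' Trial-level tablet metrics
#'
#' Computes the ceiling-robust trial scores: completion time (censored at
#' the block duration when the last target is not reached), seconds per
#' link Spl = analysis time / number of links (analysis time = completion
#' time when complete, block duration otherwise), mean dwell time DT (ms)
#' and mean link length L (px) over completed links.
#'
#' @param links Data frame from [segment_links()].
#' @param block_dur Block duration in seconds (the ceiling).
#' @param n_links_total Links in a complete trial (24 for 25 items).
#' @return One-row data frame: `completion_s` (NA when censored),
#'   `censored`, `n_links`, `spl`, `dt_ms`, `l_px`. With zero links `spl`,
#'   `dt_ms` and `l_px` are NA (flagged missing, not an error).
#' @export
compute_trial_metrics <- function(links, block_dur = 60,
                                  n_links_total = 24) {
  n <- nrow(links)
  if (n == 0)
    return(data.frame(completion_s = NA_real_, censored = TRUE,
                      n_links = 0L, spl = NA_real_, dt_ms = NA_real_,
                      l_px = NA_real_))
  complete <- n >= n_links_total
  completion <- if (complete) links$t_end[n] / 1000 else NA_real_
  analysis_time <- if (complete) completion else block_dur
  data.frame(completion_s = completion, censored = !complete,
             n_links = as.integer(n), spl = analysis_time / n,
             dt_ms = mean(links$dwell_ms), l_px = mean(links$path_px))
}

#' Time-averaged stylus contact force
#'
#' Pools the force samples of every supplied task-block log, optionally
#' restricted to the first `window_s` seconds of each block, and returns
#' their mean. The 20 s window matches the analyzed portion of each task
#' block; `window_s = Inf` averages over all samples.
#'
#' @param logs List of `tablet_log` objects (one per task block).
#' @param window_s Window in seconds from block onset, or `Inf` for all.
#' @return Mean force (a.u.).
#' @export
compute_contact_force <- function(logs, window_s = 20) {
  if (length(logs) == 0) stop("no logs supplied")
  vals <- unlist(lapply(logs, function(lg) {
    s <- lg$samples
    s$force[s$t_ms <= window_s * 1000]
  }))
  if (length(vals) == 0) stop("all logs empty within the force window")
  mean(vals)
}
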