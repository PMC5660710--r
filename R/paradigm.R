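#' Build a block-design run paradigm
#'
#' The run opens with a dead-time block (to let the longitudinal
#' magnetization reach equilibrium), then alternates task and fixation
#' baseline blocks with the two TMT parts interleaved A, B, A, B, ...
#' Defaults reproduce a 9 min 30 s run: 10 s lead-in plus four trials per
#' part of 60 s task + 10 s baseline, i.e. 8 stimulus and 8 baseline
#' periods.
#'
#' @param n_trials_per_part Number of trials of each TMT part.
#' @param task_dur,baseline_dur,lead_in Block durations in seconds.
#' @param tr Repetition time in seconds; the total duration must be an
#'   integer number of scans.
#' @param part_order Order of parts within a trial pair (default `c("A","B")`).
#' @return Object of class `tmt_paradigm`: list with `blocks` (data frame
#'   `condition`, `onset`, `duration`) and `tr`.
#' @export
build_paradigm <- function(n_trials_per_part = 4, task_dur = 60,
                           baseline_dur = 10, lead_in = 10, tr = 2,
                           part_order = c("A", "B")) {
  stopifnot(n_trials_per_part >= 0, task_dur >= 0, baseline_dur >= 0,
            lead_in >= 0, tr > 0, setequal(part_order, c("A", "B")))
  cond <- character(0); dur <- numeric(0)
  if (lead_in > 0 || n_trials_per_part == 0) {
    cond <- "DEAD"; dur <- lead_in
  }
  task_names <- paste0("TMT_", part_order)
  for (trial in seq_len(n_trials_per_part)) {
    for (tk in task_names) {
      cond <- c(cond, tk, "BASELINE")
      dur <- c(dur, task_dur, baseline_dur)
    }
  }
  onset <- cumsum(c(0, dur[-length(dur)]))
  total <- sum(dur)
  if (total %% tr != 0)
    stop("total paradigm duration (", total,
         " s) is not an integer number of scans at TR = ", tr, " s")
  structure(list(blocks = data.frame(condition = cond, onset = onset,
                                     duration = dur,
                                     stringsAsFactors = FALSE),
                 tr = tr),
            class = "tmt_paradigm")
}

#' Total duration and scan count of a paradigm
#' @param paradigm A `tmt_paradigm`.
#' @return `paradigm_duration`: seconds; `paradigm_n_scans`: scans.
#' @export
paradigm_duration <- function(paradigm) sum(paradigm$blocks$duration)

#' @rdname paradigm_duration
#' @export
paradigm_n_scans <- function(paradigm)
  as.integer(round(paradigm_duration(paradigm) / paradigm$tr))

#' @export
print.tmt_paradigm <- function(x, ...) {
  tab <- table(x$blocks$condition)
  cat(sprintf("Run paradigm: %g s (%d scans at TR %g s); blocks: %s\n",
              paradigm_duration(x), paradigm_n_scans(x), x$tr,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @rdname write_layout
#' @param paradigm A `tmt_paradigm`.
#' @export
write_paradigm <- function(paradigm, path) {
  jsonlite::write_json(list(tr = paradigm$tr, blocks = paradigm$blocks),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_paradigm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(blocks = as.data.frame(j$blocks), tr = j$tr),
            class = "tmt_paradigm")
}
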