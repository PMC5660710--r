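#' Simulate a stylus log for one TMT block
#'
#' Emulates dwell-then-move drawing behavior: at each target the stylus is
#' stationary for a normally distributed dwell (visual search latency),
#' then travels at constant speed along a straight line to the next target.
#' Samples are emitted on a jittered ~`1/nominal_rate` grid, with extra
#' samples at every dwell/move transition so that segment boundaries are
#' observed exactly. The log is truncated at the block ceiling, so slow
#' profiles produce incomplete (censored) trials. Force samples are
#' Gaussian, clipped at zero.
#'
#' @param layout A `tmt_layout`.
#' @param profile A `generator_profile`; part-B blocks add
#'   `dwell_part_b_shift` to the dwell mean.
#' @param seed Integer seed (defaults to the profile seed, else 1).
#' @param block_id Identifier stored with the log.
#' @return Object of class `tablet_log`: list with `samples` (data frame
#'   `t_ms`, `x_px`, `y_px`, `force`), `block_id`, `nominal_rate`, `part`,
#'   and `truth` (the generator's per-link dwell/move durations and the
#'   number of links reachable before the ceiling).
#' @export
simulate_stylus_log <- function(layout, profile, seed = NULL,
                                block_id = "block1") {
  stopifnot(inherits(layout, "tmt_layout"),
            inherits(profile, "generator_profile"))
  centers <- as.matrix(layout$items[, c("x", "y")])
  n <- nrow(centers)
  d_link <- sqrt(rowSums((centers[-1, , drop = FALSE] -
                          centers[-n, , drop = FALSE])^2))
  if (any(d_link == 0))
    stop("degenerate layout: coincident consecutive target centers")
  seed <- seed %||% profile$seed %||% 1L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  dmean <- profile$dwell_mean +
    if (identical(layout$part, "B")) profile$dwell_part_b_shift else 0
  dwell <- pmax(0, rnorm(n - 1, dmean, profile$dwell_sd))
  move <- d_link / profile$move_speed

  # piecewise-linear trajectory: dwell at center k, then move to center k+1
  seg_dur <- as.vector(rbind(dwell, move))          # d1,m1,d2,m2,...
  tb <- cumsum(c(0, seg_dur))                       # breakpoint times
  pb <- centers[c(1, as.vector(rbind(1:(n - 1), 2:n))), , drop = FALSE]
  stopifnot(nrow(pb) == length(tb))   # c1 | c1,c2 | c2,c3 | ... aligned to tb

  end_ms <- min(profile$ceiling * 1000, tb[length(tb)])
  spacing <- 1000 / profile$nominal_rate
  n_grid <- ceiling(end_ms / spacing) + 10L
  incr <- pmax(1, spacing + rnorm(n_grid, 0, profile$t_jitter_sd))
  ts <- cumsum(c(0, incr))
  ts <- ts[ts <= end_ms]
  ts <- sort(unique(c(ts, tb[tb <= end_ms])))

  # a zero dwell duplicates a breakpoint time (at the same position);
  # deduplicate before interpolating
  ub <- !duplicated(tb)
  x <- approx(tb[ub], pb[ub, 1], xout = ts, rule = 2)$y
  y <- approx(tb[ub], pb[ub, 2], xout = ts, rule = 2)$y
  if (profile$path_noise_sd > 0) {
    seg <- findInterval(ts, tb, rightmost.closed = TRUE)
    moving <- seg %% 2 == 0 & !(ts %in% tb)        # even segments = moves
    x[moving] <- x[moving] + rnorm(sum(moving), 0, profile$path_noise_sd)
    y[moving] <- y[moving] + rnorm(sum(moving), 0, profile$path_noise_sd)
  }
  force <- pmax(0, rnorm(length(ts), profile$force_mean, profile$force_sd))

  arrive <- tb[seq(3, length(tb), by = 2)]          # arrival time at center k+1
  structure(
    list(samples = data.frame(t_ms = ts, x_px = x, y_px = y, force = force),
         block_id = block_id, nominal_rate = profile$nominal_rate,
         part = layout$part,
         truth = list(dwell_ms = dwell, move_ms = move,
                      arrival_ms = arrive,
                      completed_links = sum(arrive <= end_ms),
                      total_ms = tb[length(tb)])),
    class = "tablet_log")
}

#' @export
print.tablet_log <- function(x, ...) {
  cat(sprintf("Tablet log %s (part %s): %d samples over %.1f s at ~%g Hz\n",
              x$block_id, x$part %||% "?", nrow(x$samples),
              max(x$samples$t_ms) / 1000, x$nominal_rate))
  invisible(x)
}

#' Write / read a stylus log as a tab-separated table
#'
#' Column layout: `t_ms  x_px  y_px  force`.
#'
#' @param log A `tablet_log`.
#' @param path File path.
#' @param nominal_rate,block_id,part Metadata reattached on read.
#' @export
write_tablet_log <- function(log, path) {
  write.table(log$samples, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_tablet_log
#' @export
read_tablet_log <- function(path, nominal_rate = 40, block_id = NULL,
                            part = NULL) {
  df <- read.delim(path)
  stopifnot(identical(names(df), c("t_ms", "x_px", "y_px", "force")))
  structure(list(samples = df,
                 block_id = block_id %||% basename(path),
                 nominal_rate = nominal_rate, part = part, truth = NULL),
            class = "tablet_log")
}
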