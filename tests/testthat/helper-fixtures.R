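# Shared fixtures and independent oracles for the test suite.

# --- toy geometry -----------------------------------------------------

# Minimal layout with arbitrary centers (used to hand-construct logs).
toy_layout <- function(centers, radius = 10, part = "A",
                       canvas = c(1000, 1000)) {
  n <- nrow(centers)
  structure(list(part = part,
                 items = data.frame(label = as.character(seq_len(n)),
                                    x = centers[, 1], y = centers[, 2]),
                 radius = radius, canvas = canvas),
            class = "tmt_layout")
}

# Hand-constructed log from explicit samples.
toy_log <- function(t_ms, x, y, force = 0.3, rate = 40) {
  structure(list(samples = data.frame(t_ms = t_ms, x_px = x, y_px = y,
                                      force = rep_len(force, length(t_ms))),
                 block_id = "toy", nominal_rate = rate, part = "A",
                 truth = NULL),
            class = "tablet_log")
}

# Constant-speed straight path through a sequence of points, sampled
# every dt ms.
path_log <- function(points, speed = 1, dt = 10, force = 0.3) {
  seg <- sqrt(rowSums(diff(points)^2))
  tb <- cumsum(c(0, seg / speed))
  ts <- seq(0, tb[length(tb)], by = dt)
  ts <- sort(unique(c(ts, tb)))
  x <- approx(tb, points[, 1], ts)$y
  y <- approx(tb, points[, 2], ts)$y
  toy_log(ts, x, y, force)
}

# --- profiles ---------------------------------------------------------

noiseless_profile <- function(mode = "VFHP", dwell_mean = 500, ...) {
  generator_profile(mode, dwell_mean = dwell_mean, dwell_sd = 0,
                    path_noise_sd = 0, force_sd = 0, t_jitter_sd = 0, ...)
}

# Fast-completion profile for replicated cohort simulations.
fast_profile <- function(mode = "VFHP", dwell_mean = 200,
                         dwell_part_b_shift = 0, force_mean = NULL, ...) {
  generator_profile(mode, dwell_mean = dwell_mean, dwell_sd = 100,
                    dwell_part_b_shift = dwell_part_b_shift,
                    move_speed = 1.5, path_noise_sd = 0.5,
                    force_mean = force_mean, ...)
}

quiet_bold <- list(amp_a = 0, amp_b = 0, noise_sd = 0,
                   drift_coefs = c(0, 0, 0, 0), motion_coupling = 0,
                   physio_amp = 0, global_amp = 0, motion_amp = 0)

# Short four-trial paradigm for BOLD tests (24 s task blocks keep the
# 20 s analysis window intact while shrinking the run).
short_paradigm <- function() build_paradigm(4, 24, 10, 10, 2)

# Simulate trial-metric tables directly at the subject level (for ANOVA
# calibration, whose input contract is the cohort behavior table).
metric_cohort <- function(n_per_group, spl_part_shift = 0,
                          spl_mode_shift = 0, subj_sd = 0.25,
                          trial_sd = 0.2) {
  mk <- function(id, mode) {
    subj_eff <- rnorm(1, 0, subj_sd)
    rows <- do.call(rbind, lapply(1:8, function(i) {
      part <- if (i <= 4) "A" else "B"
      spl <- 2 + subj_eff + trial_sd * rnorm(1) +
        (part == "B") * spl_part_shift +
        (mode == "VFHP") * spl_mode_shift
      data.frame(subject_id = id, mode = mode, part = part,
                 completion_s = spl * 24, censored = FALSE, n_links = 24L,
                 spl = spl, dt_ms = 400 + 50 * subj_eff + 20 * rnorm(1),
                 l_px = 300 + 10 * rnorm(1), stringsAsFactors = FALSE)
    }))
    rows$trial <- rep(1:4, 2)
    structure(list(trials = rows, f = 0.3 + rnorm(1, 0, 0.03)),
              class = "subject_behavior")
  }
  subs <- c(lapply(seq_len(n_per_group),
                   function(i) mk(sprintf("v%02d", i), "VFHP")),
            lapply(seq_len(n_per_group),
                   function(i) mk(sprintf("n%02d", i), "NO_VFHP")))
  cohort_behavior(subs)
}

# --- independent oracles ----------------------------------------------

# Benjamini-Hochberg step-up by direct enumeration of the k*q/m bounds.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= (seq_len(m) / m) * q)
  keep <- rep(FALSE, m)
  if (length(below) > 0) keep[ord[seq_len(max(below))]] <- TRUE
  keep
}

# Recursive flood fill over an explicit neighbor list.
floodfill_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb_offsets <- expand.grid(-1:1, -1:1, -1:1)
  nb_offsets <- nb_offsets[rowSums(abs(nb_offsets)) > 0, ]
  if (connectivity == 6)
    nb_offsets <- nb_offsets[rowSums(abs(nb_offsets)) == 1, ]
  if (connectivity == 18)
    nb_offsets <- nb_offsets[rowSums(abs(nb_offsets)) <= 2, ]
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] > 0) next
    cur <- cur + 1L
    stack <- v
    while (length(stack) > 0) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[s] > 0) next
      lab[s] <- cur
      ijk <- arrayInd(s, d)
      for (r in seq_len(nrow(nb_offsets))) {
        p <- as.integer(ijk) + as.integer(nb_offsets[r, ])
        if (all(p >= 1) && all(p <= d)) {
          li <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
          if (mask[li] && lab[li] == 0) stack <- c(stack, li)
        }
      }
    }
  }
  lab
}

# Polyline length of the inked samples between two circles under the
# delimitation rule, computed directly from a log.
polyline_oracle <- function(log, layout, k, ink_thr = 0.05) {
  s <- log$samples
  centers <- as.matrix(layout$items[, c("x", "y")])
  r <- layout$radius
  inked <- which(s$force > ink_thr)
  dist_to <- function(i, kk)
    sqrt((s$x_px[i] - centers[kk, 1])^2 + (s$y_px[i] - centers[kk, 2])^2)
  hit <- integer(nrow(centers)); from <- 1
  for (kk in seq_len(nrow(centers))) {
    cand <- inked[inked >= from & dist_to(inked, kk) <= r]
    if (length(cand) == 0) return(NA_real_)
    hit[kk] <- cand[1]; from <- cand[1]
  }
  idx <- inked[inked >= hit[k] & inked <= hit[k + 1]]
  inside_k <- dist_to(idx, k) <= r
  start <- if (any(inside_k)) {
    fo <- which(!inside_k)[1]
    if (is.na(fo)) length(idx) else fo - 1
  } else 1
  idx <- idx[start:length(idx)]
  if (length(idx) < 2) return(0)
  sum(sqrt(diff(s$x_px[idx])^2 + diff(s$y_px[idx])^2))
}

# Two-class Gaussian Bayes posterior, written out with explicit normal
# densities (the package uses the logistic log-odds form).
bayes_oracle <- function(scores_test, labels_test, m1, m2, sdv) {
  sapply(seq_along(scores_test), function(i) {
    d1 <- dnorm(scores_test[i], m1, sdv)
    d2 <- dnorm(scores_test[i], m2, sdv)
    if (labels_test[i] == 1) d1 / (d1 + d2) else d2 / (d1 + d2)
  })
}

# Hand-built split design (scan indices assigned directly).
manual_design <- function(scans1, labels1, scans2, labels2,
                          contrast = c("TMT_A", "BASELINE")) {
  structure(list(contrast = contrast,
                 split1 = data.frame(scan = scans1, label = labels1,
                                     stringsAsFactors = FALSE),
                 split2 = data.frame(scan = scans2, label = labels2,
                                     stringsAsFactors = FALSE),
                 discard_initial = 0, analysis_window = Inf),
            class = "split_half_design")
}
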