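#' Score one subject's block logs
#'
#' Runs [segment_links()] and [compute_trial_metrics()] over every task
#' block of a subject and pools the contact force across blocks.
#'
#' @param logs List of `tablet_log` objects (the subject's task blocks,
#'   4 per part in the full design).
#' @param layouts List of matching `tmt_layout` objects.
#' @param mode `"VFHP"` or `"NO_VFHP"`.
#' @param subject_id Identifier.
#' @param block_dur Block ceiling (s).
#' @param ink_thr Ink force threshold (a.u.).
#' @param speed_thr Dwell speed threshold (px/ms).
#' @param force_window Force window in seconds (`Inf` for all samples).
#' @return List of class `subject_behavior`: `trials` (data frame with
#'   `subject_id`, `mode`, `part`, `trial` and the trial metrics) and `f`
#'   (time-averaged contact force).
#' @export
score_subject <- function(logs, layouts, mode, subject_id = "s1",
                          block_dur = 60, ink_thr = 0.05, speed_thr = 0.1,
                          force_window = 20) {
  stopifnot(length(logs) == length(layouts), length(logs) >= 1)
  trial_no <- list(A = 0L, B = 0L)
  rows <- lapply(seq_along(logs), function(i) {
    part <- layouts[[i]]$part
    links <- segment_links(logs[[i]], layouts[[i]], ink_thr, speed_thr)
    m <- compute_trial_metrics(links, block_dur,
                               nrow(layouts[[i]]$items) - 1L)
    cbind(data.frame(subject_id = subject_id, mode = mode, part = part,
                     stringsAsFactors = FALSE), m)
  })
  trials <- do.call(rbind, rows)
  trials$trial <- stats::ave(seq_len(nrow(trials)), trials$part,
                             FUN = seq_along)
  structure(list(trials = trials,
                 f = compute_contact_force(logs, force_window)),
            class = "subject_behavior")
}

#' Assemble a cohort behavior table
#'
#' @param subjects List of `subject_behavior` objects.
#' @return List of class `tmt_cohort_behavior`: `trials` (stacked trial
#'   metrics) and `subjects` (one row per subject: `subject_id`, `mode`,
#'   `f`).
#' @export
cohort_behavior <- function(subjects) {
  trials <- do.call(rbind, lapply(subjects, function(s) s$trials))
  subj <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$trials$subject_id[1],
               mode = s$trials$mode[1], f = s$f,
               stringsAsFactors = FALSE)))
  structure(list(trials = trials, subjects = subj),
            class = "tmt_cohort_behavior")
}

#' Group statistics for the tablet metrics
#'
#' For each time-related metric (analysis time, Spl, DT, L): Shapiro-Wilk
#' normality per mode-by-part cell, and a classical two-factor mixed-design
#' ANOVA on subject-by-part means (tablet mode between subjects, TMT part
#' within subjects, subjects random) with Bonferroni adjustment across the
#' four metrics. The contact force F is compared between modes with a rank
#' test: the groups are independent, so the default is a rank-sum
#' (Mann-Whitney) test, computed by exact permutation enumeration when
#' feasible; a paired signed-rank variant is available for comparability
#' and is flagged in the output.
#'
#' Censored trials enter the analysis-time metric at the block ceiling.
#'
#' @param cohort A `tmt_cohort_behavior`.
#' @param block_dur Block ceiling in seconds.
#' @param bonferroni_m Multiple-comparison family size (default 4, one per
#'   time-related metric).
#' @param f_test `"ranksum"` (default) or `"signedrank"`.
#' @return List of class `tmt_behavior_stats`: `anova` (metric, effect,
#'   df1, df2, F, p, p_bonf), `normality`, `force_test`, `cell_means`.
#' @export
group_behavior_stats <- function(cohort, block_dur = 60, bonferroni_m = 4,
                                 f_test = c("ranksum", "signedrank")) {
  f_test <- match.arg(f_test)
  stopifnot(inherits(cohort, "tmt_cohort_behavior"))
  tr <- cohort$trials
  modes <- unique(tr$mode)
  if (length(modes) != 2) stop("exactly two tablet modes are required")
  if (any(table(cohort$subjects$mode) < 2))
    stop("at least two subjects per mode are required")
  tr$analysis_s <- ifelse(tr$censored, block_dur, tr$completion_s)

  metrics <- c(analysis_s = "analysis_s", spl = "spl", dt_ms = "dt_ms",
               l_px = "l_px")
  # subject x part means
  agg <- stats::aggregate(tr[, metrics],
                          by = list(subject_id = tr$subject_id,
                                    mode = tr$mode, part = tr$part),
                          FUN = mean, na.rm = TRUE)
  if (any(!table(agg$subject_id) == 2))
    stop("every subject needs trials of both parts")
  agg$subject_id <- factor(agg$subject_id)
  agg$mode <- factor(agg$mode)
  agg$part <- factor(agg$part)

  anova_rows <- list(); norm_rows <- list()
  for (m in names(metrics)) {
    d <- agg; d$y <- d[[metrics[[m]]]]
    fit <- aov(y ~ mode * part + Error(subject_id), data = d)
    sm <- summary(fit)
    between <- sm[["Error: subject_id"]][[1]]
    within <- sm[["Error: Within"]][[1]]
    eff <- function(tab, name) {
      i <- match(name, trimws(rownames(tab)))
      r <- nrow(tab)  # residual row
      data.frame(metric = m, effect = name, df1 = tab$Df[i],
                 df2 = tab$Df[r], F = tab$`F value`[i],
                 p = tab$`Pr(>F)`[i], stringsAsFactors = FALSE)
    }
    anova_rows[[m]] <- rbind(eff(between, "mode"), eff(within, "part"),
                             eff(within, "mode:part"))
    for (mo in levels(d$mode)) for (pa in levels(d$part)) {
      v <- d$y[d$mode == mo & d$part == pa]
      v <- v[is.finite(v)]
      if (length(v) >= 3 && sd(v) > 0) {
        sw <- shapiro.test(v)
        norm_rows[[paste(m, mo, pa)]] <-
          data.frame(metric = m, mode = mo, part = pa, n = length(v),
                     W = unname(sw$statistic), p = sw$p.value)
      }
    }
  }
  anova_tab <- do.call(rbind, anova_rows)
  rownames(anova_tab) <- NULL
  anova_tab$p_bonf <- pmin(1, anova_tab$p * bonferroni_m)

  f1 <- cohort$subjects$f[cohort$subjects$mode == modes[1]]
  f2 <- cohort$subjects$f[cohort$subjects$mode == modes[2]]
  force_test <- if (f_test == "ranksum") {
    rt <- rank_sum_test(f1, f2)
    list(method = rt$method, statistic = rt$statistic, p = rt$p.value,
         note = "independent groups: rank-sum test")
  } else {
    if (length(f1) != length(f2))
      stop("signed-rank variant needs equal group sizes")
    wt <- wilcox.test(f1, f2, paired = TRUE, exact = FALSE)
    list(method = "Wilcoxon signed rank (paired pairing is by order)",
         statistic = unname(wt$statistic), p = wt$p.value,
         note = "groups are independent; signed-rank provided for comparability only")
  }

  cell_means <- stats::aggregate(agg[, metrics],
                                 by = list(mode = agg$mode, part = agg$part),
                                 FUN = mean, na.rm = TRUE)
  structure(list(anova = anova_tab,
                 normality = do.call(rbind, norm_rows),
                 force_test = force_test, cell_means = cell_means),
            class = "tmt_behavior_stats")
}

#' Rank-sum (Mann-Whitney) test with exact tie-safe enumeration
#'
#' For small samples the null distribution of the rank-sum statistic is
#' obtained by enumerating all group assignments of the pooled midranks
#' (two-sided p = probability of a rank sum at least as far from its null
#' mean as observed), which remains exact in the presence of ties. Larger
#' samples fall back to [stats::wilcox.test()].
#'
#' @param x,y Numeric samples.
#' @param max_comb Enumeration budget on `choose(n, n1)`.
#' @return List with `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y, max_comb = 50000) {
  n1 <- length(x); n <- n1 + length(y)
  if (choose(n, n1) <= max_comb) {
    rk <- rank(c(x, y))
    w_obs <- sum(rk[seq_len(n1)])
    ew <- n1 * (n + 1) / 2
    combs <- combn(n, n1)
    w_all <- colSums(matrix(rk[combs], nrow = n1))
    p <- mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
    list(statistic = w_obs, p.value = p,
         method = "exact permutation rank-sum")
  } else {
    wt <- wilcox.test(x, y, exact = FALSE)
    list(statistic = unname(wt$statistic) + n1 * (n1 + 1) / 2,
         p.value = wt$p.value,
         method = "Wilcoxon rank-sum (normal approximation)")
  }
}

#' Compare tablet scores against standard pen-and-paper scores
#'
#' Computes the classical scores (A, B, B-A, B/A and the per-link rates
#' Spl) from pen-and-paper completion times, summarizes them, tests B
#' against A (paired t), tests tablet Spl against standard Spl per part
#' (paired t), and reports the Pearson convergent-validity correlation
#' between tablet and standard Spl per part and tablet mode.
#'
#' @param standard Data frame with `subject_id`, `a`, `b` (completion
#'   times in seconds).
#' @param cohort A `tmt_cohort_behavior` for the same subjects (matched by
#'   `subject_id`).
#' @param n_links_a,n_links_b Link-count denominators for the standard Spl
#'   (both default 24; exposed because printed normative tables are not
#'   always consistent about the effective denominator).
#' @return List of class `tmt_validity`: `summary` (score, mean, sd,
#'   range), `b_vs_a` (paired t), `spl_paired` (per part), `correlations`
#'   (part, mode, n, r, p; NA-flagged when n < 3).
#' @export
standard_vs_tablet <- function(standard, cohort, n_links_a = 24,
                               n_links_b = 24) {
  stopifnot(all(c("subject_id", "a", "b") %in% names(standard)),
            all(standard$a > 0), all(standard$b > 0))
  std <- standard
  std$b_minus_a <- std$b - std$a
  std$b_over_a <- std$b / std$a
  std$spl_a <- std$a / n_links_a
  std$spl_b <- std$b / n_links_b

  scores <- c("a", "b", "b_minus_a", "b_over_a", "spl_a", "spl_b")
  summ <- data.frame(
    score = scores,
    mean = sapply(scores, function(s) mean(std[[s]])),
    sd = sapply(scores, function(s) sd(std[[s]])),
    range = sapply(scores, function(s) diff(range(std[[s]]))),
    row.names = NULL)

  tt <- t.test(std$b, std$a, paired = TRUE)
  b_vs_a <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = unname(tt$estimate))

  spl_paired <- NULL; correlations <- NULL
  if (!is.null(cohort)) {
    tr <- cohort$trials
    tab <- stats::aggregate(list(spl_tab = tr$spl),
                            by = list(subject_id = tr$subject_id,
                                      mode = tr$mode, part = tr$part),
                            FUN = mean, na.rm = TRUE)
    spl_paired <- do.call(rbind, lapply(c("A", "B"), function(pp) {
      m <- merge(tab[tab$part == pp, ], std[, c("subject_id", "spl_a", "spl_b")],
                 by = "subject_id")
      m$spl_std <- if (pp == "A") m$spl_a else m$spl_b
      tt <- t.test(m$spl_tab, m$spl_std, paired = TRUE)
      data.frame(part = pp, n = nrow(m), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 mean_diff = unname(tt$estimate))
    }))
    correlations <- do.call(rbind, lapply(c("A", "B"), function(pp)
      do.call(rbind, lapply(unique(tab$mode), function(mo) {
        m <- merge(tab[tab$part == pp & tab$mode == mo, ],
                   std[, c("subject_id", "spl_a", "spl_b")],
                   by = "subject_id")
        m$spl_std <- if (pp == "A") m$spl_a else m$spl_b
        m <- m[is.finite(m$spl_tab) & is.finite(m$spl_std), ]
        if (nrow(m) < 3)
          return(data.frame(part = pp, mode = mo, n = nrow(m),
                            r = NA_real_, p = NA_real_))
        ct <- cor.test(m$spl_tab, m$spl_std)
        data.frame(part = pp, mode = mo, n = nrow(m),
                   r = unname(ct$estimate), p = ct$p.value)
      }))))
  }
  structure(list(summary = summ, b_vs_a = b_vs_a, spl_paired = spl_paired,
                 correlations = correlations, standard_scores = std),
            class = "tmt_validity")
}
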