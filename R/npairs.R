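#' Build a split-half design for one contrast
#'
#' The run's trials of each task condition are assigned by acquisition
#' order: trials 1--2 to split one, trials 3--4 to split two. Each
#' baseline block follows its preceding task block into the same split.
#' Within every block only the first `analysis_window` seconds are kept
#' (equalizing variable completion times), and then the first
#' `discard_initial` scans of that window are discarded to skip the
#' hemodynamic transient. Baseline scans are excluded when the contrast is
#' task-vs-task.
#'
#' @param paradigm A `tmt_paradigm`.
#' @param contrast Length-2 character vector, e.g. `c("TMT_A",
#'   "BASELINE")` or `c("TMT_B", "TMT_A")`; the first condition carries
#'   the positive sign in downstream maps.
#' @param discard_initial Scans discarded at each block window onset.
#' @param analysis_window Seconds of each block analyzed.
#' @return Object of class `split_half_design`: `contrast`, `split1` and
#'   `split2` (data frames `scan`, `label`), and the window parameters.
#' @export
build_split_design <- function(paradigm, contrast = c("TMT_A", "BASELINE"),
                               discard_initial = 2, analysis_window = 20) {
  stopifnot(length(contrast) == 2, !anyDuplicated(contrast))
  bl <- paradigm$blocks
  tr <- paradigm$tr
  task_conds <- intersect(unique(bl$condition), c("TMT_A", "TMT_B"))
  bl$trial <- NA_integer_
  for (tc in task_conds) {
    sel <- which(bl$condition == tc)
    bl$trial[sel] <- seq_along(sel)
  }
  for (tc in setdiff(contrast, "BASELINE")) {
    if (sum(bl$condition == tc) < 2)
      stop("contrast condition ", tc, " has fewer than 2 trials")
  }
  # baseline blocks inherit the split of the preceding task block
  bl$split <- NA_integer_
  last_task_split <- NA_integer_
  for (i in seq_len(nrow(bl))) {
    if (bl$condition[i] %in% task_conds) {
      last_task_split <- if (bl$trial[i] <= 2) 1L else 2L
      bl$split[i] <- last_task_split
    } else if (bl$condition[i] == "BASELINE") {
      bl$split[i] <- last_task_split
    }
  }

  n_total <- paradigm_n_scans(paradigm)
  scan_start <- (seq_len(n_total) - 1) * tr
  block_scans <- function(i) {
    onset <- bl$onset[i]
    win <- min(bl$duration[i], analysis_window)
    sc <- which(scan_start >= onset & scan_start < onset + win)
    if (length(sc) > discard_initial) sc[-seq_len(discard_initial)]
    else integer(0)
  }

  take <- which(bl$condition %in% contrast & !is.na(bl$split))
  rows <- do.call(rbind, lapply(take, function(i) {
    sc <- block_scans(i)
    if (length(sc) == 0) return(NULL)
    data.frame(scan = sc, label = bl$condition[i], split = bl$split[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) stop("no scans selected; check the paradigm/contrast")
  s1 <- rows[rows$split == 1, c("scan", "label")]
  s2 <- rows[rows$split == 2, c("scan", "label")]
  for (s in list(s1, s2))
    if (length(unique(s$label)) < 2)
      stop("each split must contain both contrast classes")
  structure(list(contrast = contrast,
                 split1 = s1[order(s1$scan), ],
                 split2 = s2[order(s2$scan), ],
                 discard_initial = discard_initial,
                 analysis_window = analysis_window),
            class = "split_half_design")
}

#' Fisher discriminant on a PCA basis
#'
#' Regularized two-class linear discriminant: the training scans are
#' centered and projected onto their first `n_pcs` principal components;
#' the Fisher axis is computed in PC space from the pooled within-class
#' scatter and back-projected to a voxel map. The sign convention makes
#' the first class's mean score positive.
#'
#' @param data Scans x voxels matrix (training half).
#' @param labels Two-level factor/character vector, one per scan; the
#'   first level (or first unique value) is the positive class.
#' @param n_pcs Number of principal components (>= 1, <= rank).
#' @param ridge Ridge added to a singular within-class scatter (with a
#'   warning).
#' @return List: `map` (voxel discriminant weights), `scores` (training
#'   scan projections), `center`, `class_levels`, `score_means`,
#'   `score_sd` (pooled).
#' @export
fit_lda_pca <- function(data, labels, n_pcs, ridge = 1e-8) {
  if (!is.factor(labels))
    labels <- factor(labels, levels = unique(as.character(labels)))
  labels <- droplevels(labels)
  lv <- levels(labels)
  if (length(lv) != 2) stop("exactly two classes are required")
  labels <- as.character(labels)
  if (n_pcs < 1) stop("n_pcs must be >= 1")
  mu <- colMeans(data)
  Xc <- sweep(data, 2, mu)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_pcs > rank)
    stop("n_pcs (", n_pcs, ") exceeds the data rank (", rank, ")")
  V <- sv$v[, seq_len(n_pcs), drop = FALSE]
  T <- Xc %*% V
  m1 <- colMeans(T[labels == lv[1], , drop = FALSE])
  m2 <- colMeans(T[labels == lv[2], , drop = FALSE])
  Sw <- crossprod(sweep(T[labels == lv[1], , drop = FALSE], 2, m1)) +
        crossprod(sweep(T[labels == lv[2], , drop = FALSE], 2, m2))
  w <- tryCatch(solve(Sw, m1 - m2), error = function(e) {
    warning("singular within-class scatter; applying ridge fallback")
    solve(Sw + diag(ridge * (sum(diag(Sw)) / n_pcs + 1), n_pcs), m1 - m2)
  })
  map <- as.vector(V %*% w)
  scores <- as.vector(T %*% w)
  if (mean(scores[labels == lv[1]]) < mean(scores[labels == lv[2]])) {
    map <- -map; scores <- -scores
  }
  s1 <- scores[labels == lv[1]]; s2 <- scores[labels == lv[2]]
  pooled_var <- (sum((s1 - mean(s1))^2) + sum((s2 - mean(s2))^2)) /
    (length(scores) - 2)
  list(map = map, scores = scores, center = mu, class_levels = lv,
       score_means = c(mean(s1), mean(s2)), score_sd = sqrt(pooled_var))
}

# Mean Bayesian posterior probability of the true class for test scores
# under a two-class Gaussian model (training means, pooled variance,
# equal priors).
posterior_accuracy <- function(model, test_scores, test_labels,
                               var_floor = 1e-12) {
  sdv <- max(model$score_sd, sqrt(var_floor))
  flagged <- model$score_sd^2 < var_floor
  m <- model$score_means
  lv <- model$class_levels
  # log-odds of class 1 vs class 2
  lo <- (test_scores - (m[1] + m[2]) / 2) * (m[1] - m[2]) / sdv^2
  p1 <- 1 / (1 + exp(-lo))
  post_true <- ifelse(test_labels == lv[1], p1, 1 - p1)
  list(p = mean(post_true), flagged = flagged)
}

#' Evaluate one pipeline / PC-count configuration on a split-half design
#'
#' Trains the PCA-regularized discriminant on each split and tests on the
#' other: prediction P is the mean (over both directions and test scans)
#' posterior probability of the true condition; reproducibility R is the
#' Pearson correlation of the two split discriminant maps over the mask;
#' D is the Euclidean distance of (P, R) from perfect performance (1, 1).
#'
#' @param run A `bold_run`.
#' @param spec A `pipeline_spec` (applied before evaluation), or `NULL` if
#'   `run` is already preprocessed.
#' @param design A `split_half_design` built from the run's paradigm.
#' @param n_pcs Number of principal components.
#' @return Object of class `split_result`: `pipeline`, `n_pcs`, `map1`,
#'   `map2`, `p`, `r`, `d`, `flagged` (degenerate-posterior flag).
#' @export
evaluate_split <- function(run, spec, design, n_pcs) {
  proc <- if (is.null(spec)) run else apply_pipeline(run, spec)
  d4 <- dim(proc$data)
  flat <- matrix(proc$data, prod(d4[1:3]), d4[4])
  X <- t(flat[which(proc$mask), , drop = FALSE])   # scans x voxels
  res <- evaluate_split_matrix(X, design, n_pcs)
  res$pipeline <- spec
  res
}

# Core NPAIRS evaluation on a scans x voxels matrix.
evaluate_split_matrix <- function(X, design, n_pcs) {
  g1 <- design$split1; g2 <- design$split2
  lv <- design$contrast
  fit1 <- fit_lda_pca(X[g1$scan, , drop = FALSE],
                      factor(g1$label, levels = lv), n_pcs)
  fit2 <- fit_lda_pca(X[g2$scan, , drop = FALSE],
                      factor(g2$label, levels = lv), n_pcs)
  sc21 <- sweep(X[g2$scan, , drop = FALSE], 2, fit1$center) %*% fit1$map
  sc12 <- sweep(X[g1$scan, , drop = FALSE], 2, fit2$center) %*% fit2$map
  a1 <- posterior_accuracy(fit1, as.vector(sc21), g2$label)
  a2 <- posterior_accuracy(fit2, as.vector(sc12), g1$label)
  p <- mean(c(a1$p, a2$p))
  r <- cor(fit1$map, fit2$map)
  structure(list(pipeline = NULL, n_pcs = n_pcs,
                 map1 = fit1$map, map2 = fit2$map,
                 p = p, r = r, d = npairs_distance(p, r),
                 flagged = a1$flagged || a2$flagged),
            class = "split_result")
}

#' Distance from perfect prediction and reproducibility
#'
#' `D(P, R) = sqrt((1 - P)^2 + (1 - R)^2)`; 0 means a perfectly
#' predictive, perfectly reproducible model.
#'
#' @param p Prediction in \[0, 1\].
#' @param r Reproducibility in \[-1, 1\].
#' @return Non-negative distance.
#' @export
npairs_distance <- function(p, r) sqrt((1 - p)^2 + (1 - r)^2)

#' Select the pipeline and PC count minimizing D(P, R)
#'
#' Exhaustively evaluates every pipeline in `pipelines` crossed with every
#' PC count in `pc_grid`, and returns the configuration with minimal D.
#' Exact ties resolve to the first configuration in enumeration order
#' (pipelines outer, PC counts inner), so selection is deterministic.
#'
#' @param run A `bold_run`.
#' @param pipelines List of `pipeline_spec` objects.
#' @param pc_grid Integer vector of PC counts.
#' @param design A `split_half_design`.
#' @return List of class `npairs_optimization`: `best` (a `split_result`)
#'   and `table` (one row per configuration: pipeline JSON, n_pcs, p, r,
#'   d).
#' @export
optimize_subject <- function(run, pipelines, pc_grid, design) {
  stopifnot(length(pipelines) >= 1, length(pc_grid) >= 1)
  rows <- list(); results <- list(); i <- 0L
  for (spec in pipelines) {
    proc <- apply_pipeline(run, spec)
    d4 <- dim(proc$data)
    flat <- matrix(proc$data, prod(d4[1:3]), d4[4])
    X <- t(flat[which(proc$mask), , drop = FALSE])
    for (k in pc_grid) {
      i <- i + 1L
      res <- evaluate_split_matrix(X, design, k)
      res$pipeline <- spec
      results[[i]] <- res
      rows[[i]] <- data.frame(pipeline = pipeline_to_json(spec),
                              n_pcs = k, p = res$p, r = res$r, d = res$d,
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  best <- which.min(tab$d)     # first minimum wins on ties
  structure(list(best = results[[best]], table = tab),
            class = "npairs_optimization")
}

#' Reproducible Z-scored map (rSPMZ) from a split-half map pair
#'
#' Per voxel the signal is the split average `(map1 + map2) / 2`; the
#' noise scale is the standard deviation, over mask voxels, of the
#' difference-axis projection `(map1 - map2) / sqrt(2)`; z is their ratio.
#' Identical maps have zero noise spread and are flagged degenerate (the
#' scale is floored instead of erroring).
#'
#' @param map1,map2 Voxel maps on a shared mask (numeric vectors).
#' @param noise `"global"` (default, one mask-wide scale) or `"voxel"`
#'   (absolute per-voxel difference; scale differs voxel-wise).
#' @param floor Minimal noise scale.
#' @return Object of class `rspmz`: `z`, `degenerate`.
#' @export
compute_rspmz <- function(map1, map2, noise = c("global", "voxel"),
                          floor = 1e-12) {
  noise <- match.arg(noise)
  stopifnot(length(map1) == length(map2))
  signal <- (map1 + map2) / 2
  diff_ax <- (map1 - map2) / sqrt(2)
  degenerate <- FALSE
  if (noise == "global") {
    s <- sd(diff_ax)
    if (!is.finite(s) || s < floor) { s <- floor; degenerate <- TRUE }
    z <- signal / s
  } else {
    s <- abs(diff_ax)
    degenerate <- any(s < floor)
    z <- signal / pmax(s, floor)
  }
  structure(list(z = z, degenerate = degenerate), class = "rspmz")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Split result: P = %.3f, R = %.3f, D = %.4f (n_pcs = %d)\n",
              x$p, x$r, x$d, x$n_pcs))
  invisible(x)
}
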