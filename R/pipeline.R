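#' Preprocessing pipeline specification
#'
#' Toggles and parameters for the denoising steps, which are always applied
#' in a fixed order regardless of which are switched on: physiological
#' (cardiac/respiratory phase) regression, slice-timing (a pass-through on
#' slice-synchronous synthetic data, kept so pipeline arity is preserved),
#' spatial smoothing, Legendre detrending, motion regression (raw
#' parameters and/or their principal components), and global-signal PC1
#' removal. When `task_protect` is on, every regression step fits the task
#' regressors jointly with the nuisance design and subtracts only the
#' nuisance partial fit, protecting task-locked signal from
#' over-regression.
#'
#' @param motion_regress Regress the 6 raw motion parameters.
#' @param retroicor Regress cardiac/respiratory phase harmonics.
#' @param retroicor_order Fourier expansion order (default 2).
#' @param smooth_fwhm Spatial Gaussian FWHM in mm; 0 = off.
#' @param detrend Legendre polynomial order 0..3, or -1 = off.
#' @param motion_pca Regress leading motion PCs.
#' @param motion_var Cumulative variance fraction the retained motion PCs
#'   must reach (default 0.85).
#' @param task_protect Protect task regressors during nuisance regression.
#' @param global_pc1 Remove the first principal component of the in-mask
#'   global signal.
#' @return Object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(motion_regress = FALSE, retroicor = FALSE,
                          retroicor_order = 2, smooth_fwhm = 0,
                          detrend = -1, motion_pca = FALSE,
                          motion_var = 0.85, task_protect = TRUE,
                          global_pc1 = FALSE) {
  stopifnot(smooth_fwhm >= 0, detrend %in% -1:3,
            motion_var > 0, motion_var <= 1, retroicor_order >= 1)
  structure(list(motion_regress = motion_regress, retroicor = retroicor,
                 retroicor_order = retroicor_order,
                 smooth_fwhm = smooth_fwhm, detrend = detrend,
                 motion_pca = motion_pca, motion_var = motion_var,
                 task_protect = task_protect, global_pc1 = global_pc1),
            class = "pipeline_spec")
}

#' @export
format.pipeline_spec <- function(x, ...) {
  paste0("retroicor=", x$retroicor, "(", x$retroicor_order, ")",
         " smooth=", x$smooth_fwhm, "mm detrend=", x$detrend,
         " motreg=", x$motion_regress, " motpca=", x$motion_pca,
         "(", x$motion_var, ") protect=", x$task_protect,
         " gpc1=", x$global_pc1)
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat("Pipeline:", format(x), "\n"); invisible(x)
}

#' Serialize a pipeline spec to / from JSON
#' @param spec A `pipeline_spec`.
#' @return `pipeline_to_json` a JSON string; `pipeline_from_json` a spec.
#' @export
pipeline_to_json <- function(spec)
  as.character(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE))

#' @rdname pipeline_to_json
#' @param json JSON string.
#' @export
pipeline_from_json <- function(json)
  do.call(pipeline_spec, jsonlite::fromJSON(json))

#' Enumerate candidate pipelines over a value grid
#'
#' Cartesian product of the allowed values per step, in a deterministic
#' order (the last listed step varies fastest), with the fixed step order
#' encoded in each resulting spec.
#'
#' @param grid Named list of allowed values per [pipeline_spec()]
#'   argument; steps not listed keep their defaults.
#' @return List of `pipeline_spec` objects.
#' @export
enumerate_pipelines <- function(grid = list(retroicor = c(FALSE, TRUE),
                                            smooth_fwhm = c(0, 6),
                                            detrend = c(-1, 0:3),
                                            motion_pca = c(FALSE, TRUE),
                                            global_pc1 = c(FALSE, TRUE))) {
  stopifnot(length(grid) > 0, all(lengths(grid) > 0))
  combos <- expand.grid(rev(grid), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  combos <- combos[, rev(seq_len(ncol(combos))), drop = FALSE]
  lapply(seq_len(nrow(combos)), function(i)
    do.call(pipeline_spec, as.list(combos[i, , drop = FALSE])))
}

# ---- regression engine ------------------------------------------------

# Residualize Y (voxels x scans) against nuisance regressors, fitting the
# protected columns jointly and subtracting only the nuisance partial fit.
# Collinear nuisance columns are pruned; a protected column lost to rank
# pruning is an error naming the colliding columns.
residualize <- function(Y, nuisance, protected = NULL) {
  if (is.null(nuisance) || ncol(nuisance) == 0) return(Y)
  X <- cbind(protected, nuisance)
  p <- if (is.null(protected)) 0 else ncol(protected)
  labs <- c(colnames(protected), colnames(nuisance))
  qx <- qr(X)
  keep <- sort(qx$pivot[seq_len(qx$rank)])
  if (p > 0 && !all(seq_len(p) %in% keep))
    stop("rank-deficient design: protected column(s) ",
         paste(labs[setdiff(seq_len(p), keep)], collapse = ", "),
         " collide with ", paste(labs[setdiff(keep, seq_len(p))],
                                 collapse = ", "))
  Xk <- X[, keep, drop = FALSE]
  beta <- qr.coef(qr(Xk), t(Y))            # columns of t(Y) are voxels
  nuis_k <- which(keep > p)
  if (length(nuis_k) == 0) return(Y)
  fitN <- Xk[, nuis_k, drop = FALSE] %*% beta[nuis_k, , drop = FALSE]
  Y - t(fitN)
}

# Phase of a quasi-periodic trace at given times: linear 0..2*pi between
# successive peaks of the sampled trace, extrapolated with the mean period.
trace_phase <- function(trace, at_t) {
  v <- trace$value; tt <- trace$t
  pk <- which(diff(sign(diff(v))) == -2) + 1L
  if (length(pk) < 2) stop("physiological trace has fewer than two peaks")
  pt <- tt[pk]
  period <- mean(diff(pt))
  phase <- numeric(length(at_t))
  for (i in seq_along(at_t)) {
    t0 <- at_t[i]
    j <- findInterval(t0, pt)
    if (j == 0) phase[i] <- 2 * pi * (t0 - pt[1]) / period
    else if (j >= length(pt))
      phase[i] <- 2 * pi * (t0 - pt[length(pt)]) / period
    else phase[i] <- 2 * pi * (t0 - pt[j]) / (pt[j + 1] - pt[j])
  }
  phase
}

# Fourier expansion in cardiac and respiratory phase at scan times.
retroicor_design <- function(run, order = 2) {
  scan_t <- (seq_len(dim(run$data)[4]) - 1) * run$tr
  out <- NULL
  for (nm in c("cardiac", "resp")) {
    ph <- trace_phase(run[[nm]], scan_t)
    for (k in seq_len(order)) {
      out <- cbind(out, cos(k * ph), sin(k * ph))
      colnames(out)[(ncol(out) - 1):ncol(out)] <-
        paste0(nm, "_", c("cos", "sin"), k)
    }
  }
  out
}

# Leading motion PCs reaching the cumulative variance threshold.
motion_pcs <- function(motion, var_frac = 0.85) {
  pc <- prcomp(motion, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  v <- v / sum(v)
  k <- which(cumsum(v) >= var_frac - 1e-12)[1]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("motion_pc", seq_len(k))
  sc
}

#' Apply a preprocessing pipeline to a BOLD run
#'
#' Steps run in the fixed order: physiological phase regression,
#' slice-timing pass-through, spatial smoothing, Legendre detrending,
#' motion (raw and/or PCA) regression, global-signal PC1 regression.
#' Regression steps act on in-mask voxels; when `spec$task_protect` is on
#' the canonical task regressors are fitted jointly and never subtracted.
#'
#' @param run A `bold_run`.
#' @param spec A `pipeline_spec`.
#' @return A processed `bold_run` with an `applied_spec` element.
#' @export
apply_pipeline <- function(run, spec) {
  stopifnot(inherits(run, "bold_run"), inherits(spec, "pipeline_spec"))
  d <- dim(run$data)
  nt <- d[4]
  idx <- which(run$mask)
  if (length(idx) == 0) stop("empty brain mask")
  flat <- matrix(run$data, prod(d[1:3]), nt)
  Y <- flat[idx, , drop = FALSE]

  prot <- NULL
  if (isTRUE(spec$task_protect)) {
    conds <- intersect(c("TMT_A", "TMT_B"),
                       unique(run$paradigm$blocks$condition))
    if (length(conds) > 0) {
      prot <- cbind(intercept = rep(1, nt),
                    condition_regressors(run$paradigm, conds))
    }
  }
  if (is.null(prot)) prot <- matrix(1, nt, 1, dimnames = list(NULL, "intercept"))

  if (isTRUE(spec$retroicor))
    Y <- residualize(Y, retroicor_design(run, spec$retroicor_order), prot)

  # slice-timing correction: pass-through (synthetic data are
  # slice-synchronous); kept so the step order matches the pipeline list

  if (spec$smooth_fwhm > 0) {
    flat[idx, ] <- Y
    for (t in seq_len(nt)) {
      vol <- array(flat[, t], d[1:3])
      flat[, t] <- smooth_gaussian(vol, spec$smooth_fwhm, run$voxdim)
    }
    Y <- flat[idx, , drop = FALSE]
  }

  if (spec$detrend >= 0) {
    leg <- legendre_basis(nt, spec$detrend)
    # the polynomial block is the nuisance here; drop the protected
    # intercept to avoid colliding with the order-0 term
    prot_d <- prot[, colnames(prot) != "intercept", drop = FALSE]
    if (ncol(prot_d) == 0) prot_d <- NULL
    Y <- residualize(Y, leg, prot_d)
  }

  mot <- NULL
  if (isTRUE(spec$motion_regress))
    mot <- cbind(mot, scale(run$motion, center = TRUE, scale = FALSE))
  if (isTRUE(spec$motion_pca))
    mot <- cbind(mot, motion_pcs(run$motion, spec$motion_var))
  if (!is.null(mot)) Y <- residualize(Y, mot, prot)

  if (isTRUE(spec$global_pc1)) {
    Yc <- Y - rowMeans(Y)
    sv <- svd(t(Yc), nu = 1, nv = 0)
    g <- sv$u[, 1, drop = FALSE]
    colnames(g) <- "global_pc1"
    Y <- residualize(Y, g, prot)
  }

  flat[idx, ] <- Y
  out <- run
  out$data <- array(flat, d)
  out$applied_spec <- spec
  out
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Per-axis sigma is `fwhm / (2 * sqrt(2 * log(2)))` expressed in voxel
#' units; the kernel is truncated at 4 sigma and renormalized at the array
#' boundary, so a constant volume is exactly preserved.
#'
#' @param volume 3D numeric array.
#' @param fwhm Full width at half maximum in mm.
#' @param voxel_dims Voxel dimensions in mm.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_gaussian <- function(volume, fwhm, voxel_dims = c(3, 3, 4.5)) {
  stopifnot(length(dim(volume)) == 3, fwhm > 0)
  if (any(voxel_dims <= 0)) stop("voxel dimensions must be positive")
  sig <- fwhm / (2 * sqrt(2 * log(2))) / voxel_dims
  out <- volume
  for (ax in 1:3) {
    r <- max(1L, ceiling(4 * sig[ax]))
    w <- exp(-((-r:r)^2) / (2 * sig[ax]^2))
    w <- w / sum(w)
    acc <- array(0, dim(out)); norm <- array(0, dim(out))
    for (j in -r:r) {
      sh <- shift_axis(out, ax, j)
      ok <- shift_axis(array(1, dim(out)), ax, j)
      acc <- acc + w[j + r + 1] * sh
      norm <- norm + w[j + r + 1] * ok
    }
    out <- acc / norm
  }
  out
}

# Shift a 3D array by `by` voxels along `axis`, zero-filling.
shift_axis <- function(a, axis, by) {
  d <- dim(a)
  if (by == 0) return(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix <- function(which_idx) {
    l <- list(1:d[1], 1:d[2], 1:d[3])
    l[[axis]] <- which_idx
    l
  }
  out[ix(dst)[[1]], ix(dst)[[2]], ix(dst)[[3]]] <-
    a[ix(src)[[1]], ix(src)[[2]], ix(src)[[3]]]
  out
}

#' Temporal standard deviation of motion parameters, with group test
#'
#' @param motions List of per-subject motion matrices (scans x 6).
#' @param groups Group label per subject (optional; with a single group
#'   only descriptives are returned).
#' @return List of class `motion_summary`: `std` (subject x parameter Std
#'   table) and `tests` (per-parameter rank-sum test between groups, NULL
#'   for a single group).
#' @export
summarize_motion <- function(motions, groups = NULL) {
  stopifnot(length(motions) >= 1, all(sapply(motions, nrow) >= 2))
  std <- t(sapply(motions, function(m) apply(m, 2, sd)))
  rownames(std) <- names(motions) %||% paste0("s", seq_along(motions))
  tests <- NULL
  if (!is.null(groups) && length(unique(groups)) == 2) {
    gl <- unique(groups)
    tests <- do.call(rbind, lapply(colnames(std), function(p) {
      rt <- rank_sum_test(std[groups == gl[1], p], std[groups == gl[2], p])
      data.frame(parameter = p, statistic = rt$statistic, p = rt$p.value,
                 method = rt$method, stringsAsFactors = FALSE)
    }))
  }
  structure(list(std = std, tests = tests), class = "motion_summary")
}
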