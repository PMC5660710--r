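#' Simulate a block-design BOLD run with known ground truth
#'
#' Builds a 4D voxel time series as the sum of: a constant baseline;
#' per-condition activation (ground-truth amplitude maps times the
#' condition boxcar convolved with the canonical hemodynamic response);
#' low-order Legendre polynomial drift with voxel-varying coefficients;
#' motion-coupled nuisance signal (the simulated rigid-body traces mixed
#' into voxels with random weights); sinusoidal cardiac and respiratory
#' components; a global fluctuation common to all in-mask voxels; and white
#' noise. Every noise source's amplitude comes from `profile$bold`, so any
#' of them can be switched off exactly.
#'
#' @param paradigm A `tmt_paradigm`.
#' @param grid Volume dimensions, e.g. `c(12, 12, 6)`.
#' @param profile A `generator_profile` (its `bold` list is used).
#' @param seed Integer seed for the noise streams.
#' @param truth_seed Seed for the activation-blob placement. Kept separate
#'   from `seed` so a cohort of subjects (different noise seeds) shares
#'   the same active regions, as real group activation does.
#' @param voxdim Voxel dimensions in mm.
#' @return Object of class `bold_run`: list with `data` (4D array), `tr`,
#'   `mask` (3D logical), `motion` (scans x 6: translations mm, rotations
#'   deg), `cardiac`/`resp` (data frames `t`, `value` at 10 Hz), `truth`
#'   (per-condition 3D amplitude maps, zero outside the mask), `paradigm`,
#'   `voxdim`.
#' @export
simulate_bold_run <- function(paradigm, grid = c(12, 12, 6), profile,
                              seed = 1L, truth_seed = 1L,
                              voxdim = c(3, 3, 4.5)) {
  stopifnot(inherits(paradigm, "tmt_paradigm"), length(grid) == 3)
  b <- profile$bold
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  nt <- paradigm_n_scans(paradigm)
  tr <- paradigm$tr
  scan_t <- (seq_len(nt) - 1) * tr
  nv <- prod(grid)

  # ellipsoidal brain mask
  cc <- (grid + 1) / 2
  ijk <- as.matrix(expand.grid(i = 1:grid[1], j = 1:grid[2], k = 1:grid[3]))
  mask_v <- colSums((t(ijk) - cc)^2 / (grid / 2 + 0.5)^2) <= 1
  mask <- array(mask_v, grid)
  in_idx <- which(mask_v)
  n_in <- length(in_idx)

  # ground-truth activation: one contiguous blob per condition
  conds <- c("TMT_A", "TMT_B")
  amps <- c(TMT_A = b$amp_a, TMT_B = b$amp_b)
  set.seed(truth_seed)
  truth <- list()
  for (cn in conds) {
    tm <- array(0, grid)
    ctr <- ijk[sample(in_idx, 1), ]
    sel <- abs(ijk[, 1] - ctr[1]) <= 1 & abs(ijk[, 2] - ctr[2]) <= 1 &
      abs(ijk[, 3] - ctr[3]) <= 1 & mask_v
    tm[sel] <- amps[[cn]]
    truth[[cn]] <- tm
  }
  set.seed(seed)

  X_task <- condition_regressors(paradigm, conds)

  # nuisance sources
  motion <- sapply(1:6, function(j)
    b$motion_amp * sin(2 * pi * (0.004 + 0.003 * j) * scan_t + runif(1, 0, 2 * pi)) +
      b$motion_amp * 0.2 * rnorm(nt))
  colnames(motion) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")

  phys_t <- seq(0, paradigm_duration(paradigm), by = 0.1)
  cardiac <- data.frame(t = phys_t, value = sin(2 * pi * b$cardiac_hz * phys_t))
  resp <- data.frame(t = phys_t, value = sin(2 * pi * b$resp_hz * phys_t))

  dc <- rep_len(c(b$drift_coefs, 0, 0, 0, 0), 4)
  leg <- legendre_basis(nt, 3)[, -1, drop = FALSE]       # orders 1..3
  drift_scale <- matrix(rnorm(n_in * 3, 1, 0.3), n_in, 3) *
    rep(dc[2:4], each = n_in)
  W_mot <- matrix(rnorm(n_in * 6, 0, b$motion_coupling), n_in, 6)
  w_card <- abs(rnorm(n_in, 1, 0.3))
  w_resp <- abs(rnorm(n_in, 1, 0.3))
  g_t <- as.vector(stats::filter(rnorm(nt), rep(1 / 4, 4), sides = 1))
  g_t[is.na(g_t)] <- 0

  Y <- matrix(b$baseline + dc[1], n_in, nt)
  for (cn in conds)
    Y <- Y + outer(truth[[cn]][in_idx], X_task[, cn])
  Y <- Y + drift_scale %*% t(leg)
  Y <- Y + W_mot %*% t(motion)
  Y <- Y + b$physio_amp * (outer(w_card, sin(2 * pi * b$cardiac_hz * scan_t)) +
                           outer(w_resp, sin(2 * pi * b$resp_hz * scan_t)))
  Y <- Y + b$global_amp * outer(rep(1, n_in), g_t)
  Y <- Y + matrix(rnorm(n_in * nt, 0, b$noise_sd), n_in, nt)

  data <- array(b$baseline, c(grid, nt))
  flat <- matrix(data, nv, nt)
  flat[in_idx, ] <- Y
  data <- array(flat, c(grid, nt))

  structure(list(data = data, tr = tr, mask = mask, motion = motion,
                 cardiac = cardiac, resp = resp, truth = truth,
                 paradigm = paradigm, voxdim = voxdim),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run: %d x %d x %d voxels x %d scans (TR %g s), %d in mask\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Legendre polynomial basis on the scan index
#'
#' Bonnet-recurrence Legendre polynomials evaluated on the scan index
#' rescaled to \[-1, 1\]; columns are orders 0..`order`.
#'
#' @param n Number of scans.
#' @param order Maximum polynomial order.
#' @return Matrix `n x (order + 1)`.
#' @export
legendre_basis <- function(n, order) {
  stopifnot(n >= 2, order >= 0)
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2)
    for (k in 2:order)
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
  colnames(P) <- paste0("legendre", 0:order)
  P
}

#' Write / read a BOLD run on disk
#'
#' The 4D series and mask go to NIfTI-1 (TR stored in `pixdim[4]`), motion
#' and physiological traces to TSV, the paradigm to JSON, and the
#' ground-truth amplitude maps (when present) to NIfTI files tagged
#' `_truth_<condition>`.
#'
#' @param run A `bold_run`.
#' @param prefix Path prefix for the output files.
#' @return `read_bold_run` returns a `bold_run` (with `truth` restored when
#'   truth files are present).
#' @export
write_bold_run <- function(run, prefix) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxdim, run$tr)
  RNifti::writeNifti(img, paste0(prefix, ".nii"))
  mk <- RNifti::asNifti(array(as.integer(run$mask), dim(run$mask)))
  RNifti::pixdim(mk) <- run$voxdim
  RNifti::writeNifti(mk, paste0(prefix, "_mask.nii"))
  for (cn in names(run$truth)) {
    ti <- RNifti::asNifti(run$truth[[cn]])
    RNifti::pixdim(ti) <- run$voxdim
    RNifti::writeNifti(ti, paste0(prefix, "_truth_", cn, ".nii"))
  }
  write.table(run$motion, paste0(prefix, "_motion.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  phys <- data.frame(t = run$cardiac$t, cardiac = run$cardiac$value,
                     resp = run$resp$value)
  write.table(phys, paste0(prefix, "_physio.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_paradigm(run$paradigm, paste0(prefix, "_paradigm.json"))
  invisible(prefix)
}

#' @rdname write_bold_run
#' @export
read_bold_run <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii"))
  pd <- RNifti::pixdim(img)
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii")) > 0
  motion <- as.matrix(read.delim(paste0(prefix, "_motion.tsv")))
  phys <- read.delim(paste0(prefix, "_physio.tsv"))
  paradigm <- read_paradigm(paste0(prefix, "_paradigm.json"))
  truth <- list()
  for (cn in c("TMT_A", "TMT_B")) {
    f <- paste0(prefix, "_truth_", cn, ".nii")
    if (file.exists(f)) truth[[cn]] <- array(RNifti::readNifti(f),
                                             dim(mask))
  }
  structure(list(data = array(as.numeric(img), dim(img)), tr = pd[4],
                 mask = array(mask, dim(img)[1:3]), motion = motion,
                 cardiac = data.frame(t = phys$t, value = phys$cardiac),
                 resp = data.frame(t = phys$t, value = phys$resp),
                 truth = truth, paradigm = paradigm, voxdim = pd[1:3]),
            class = "bold_run")
}
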