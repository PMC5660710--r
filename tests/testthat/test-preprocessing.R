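quiet_run <- function(bold_extra = list(), grid = c(8, 8, 4), seed = 1,
                      truth_seed = 1) {
  pf <- generator_profile("VFHP",
                          bold = utils::modifyList(quiet_bold, bold_extra))
  simulate_bold_run(short_paradigm(), grid, pf, seed = seed,
                    truth_seed = truth_seed)
}

in_mask <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4])[which(run$mask), , drop = FALSE])
}

test_that("pipeline enumeration is exhaustive and deterministic", {
  pls <- enumerate_pipelines(list(detrend = c(-1, 2),
                                  motion_pca = c(FALSE, TRUE)))
  expect_length(pls, 4)
  got <- sapply(pls, function(p) paste(p$detrend, p$motion_pca))
  # last listed step varies fastest
  expect_identical(got, c("-1 FALSE", "-1 TRUE", "2 FALSE", "2 TRUE"))
  expect_length(enumerate_pipelines(), 2 * 2 * 5 * 2 * 2)
  # unlisted steps keep their defaults
  expect_true(all(sapply(pls, function(p) p$task_protect)))
  expect_error(pipeline_spec(detrend = 5))
})

test_that("pipeline specs survive the JSON round trip", {
  sp <- pipeline_spec(retroicor = TRUE, smooth_fwhm = 6, detrend = 2,
                      motion_pca = TRUE, motion_var = 0.9,
                      global_pc1 = TRUE)
  back <- pipeline_from_json(pipeline_to_json(sp))
  expect_equal(unclass(back), unclass(sp))
})

test_that("Legendre detrending removes polynomial drift exactly", {
  run <- quiet_run(list(drift_coefs = c(5, 4, 3, 2)))
  Y <- in_mask(run)                        # scans x voxels
  proc <- apply_pipeline(run, pipeline_spec(detrend = 3,
                                            task_protect = FALSE))
  Yp <- in_mask(proc)
  # drift is a cubic in the scan index: the order-3 residual is zero
  expect_lt(max(abs(Yp)), 1e-8)
  # the untouched data were far from zero
  expect_gt(max(abs(Y)), 100)
})

test_that("task protection preserves the activation amplitude exactly", {
  run <- quiet_run(list(amp_a = 20, amp_b = 10,
                        drift_coefs = c(5, 4, 3, 2)))
  proc <- apply_pipeline(run, pipeline_spec(detrend = 3,
                                            task_protect = TRUE))
  Yp <- in_mask(proc)
  X <- condition_regressors(run$paradigm)
  expected <- X %*% rbind(run$truth$TMT_A[run$mask],
                          run$truth$TMT_B[run$mask])
  # nuisance (constant + cubic drift) removed; task signal untouched
  expect_equal(unname(Yp), unname(expected), tolerance = 1e-7)
})

test_that("task protection matters when the global PC1 is task-locked", {
  # A run whose only structured signal is the task: the data-driven
  # global PC1 is then essentially the task time course. Without
  # protection its regression annihilates the effect; with protection
  # most of the amplitude survives. (The residual loss under protection
  # is task variance hidden *inside* the estimated regressor itself --
  # protection can only shield the explicit nuisance fit. Exact
  # preservation holds for model-based nuisance regressors; see the
  # detrending test above.)
  rt <- quiet_run(list(amp_a = 20, noise_sd = 0.5), seed = 5)
  vt <- which(rt$truth$TMT_A[rt$mask] > 0)[1]
  X <- condition_regressors(rt$paradigm)[, "TMT_A"]
  beta_of <- function(proc) {
    unname(coef(lm(in_mask(proc)[, vt] ~ X))[2])
  }
  prot <- apply_pipeline(rt, pipeline_spec(global_pc1 = TRUE,
                                           task_protect = TRUE))
  unprot <- apply_pipeline(rt, pipeline_spec(global_pc1 = TRUE,
                                             task_protect = FALSE))
  expect_lt(beta_of(unprot), 1)       # effect wiped out
  expect_gt(beta_of(prot), 12)        # most of the 20 a.u. retained
  expect_gt(beta_of(prot), 10 * max(beta_of(unprot), 0.1))
})

test_that("motion PCs honour the cumulative variance threshold", {
  set.seed(5)
  base <- sin(2 * pi * (0:99) / 25)
  # rank-1 motion: one PC explains everything
  m1 <- outer(base, c(1, 2, 3, 0.5, 0.2, 0.1))
  colnames(m1) <- paste0("p", 1:6)
  expect_equal(ncol(tabletTMT:::motion_pcs(m1, 0.85)), 1L)
  # near-isotropic motion needs several components to reach the threshold
  m2 <- matrix(rnorm(600), 100, 6) %*% diag(6)
  colnames(m2) <- paste0("p", 1:6)
  k <- ncol(tabletTMT:::motion_pcs(m2, 0.85))
  v <- prcomp(m2)$sdev^2
  v <- cumsum(v / sum(v))
  expect_equal(k, which(v >= 0.85 - 1e-12)[1])
})

test_that("phase regression cancels a pure physiological harmonic", {
  run <- quiet_run(list(physio_amp = 3))
  Y0 <- in_mask(run)
  before <- max(apply(Y0, 2, var))
  proc <- apply_pipeline(run, pipeline_spec(retroicor = TRUE,
                                            task_protect = FALSE))
  after <- max(apply(in_mask(proc), 2, var))
  expect_gt(before, 1)
  expect_lt(after / before, 1e-6)
})

test_that("trace phase is linear between detected peaks", {
  tt <- seq(0, 30, 0.1)
  tr <- data.frame(t = tt, value = sin(2 * pi * 0.5 * tt))
  ph <- tabletTMT:::trace_phase(tr, c(0.5, 1.5, 2.0))
  # peaks at t = 0.5, 2.5, ...: phase 0 at a peak, pi half-way
  expect_equal(ph[1] %% (2 * pi), 0, tolerance = 1e-8)
  expect_equal(ph[2], pi, tolerance = 1e-6)
  expect_error(tabletTMT:::trace_phase(
    data.frame(t = 1:10, value = 1:10), 5), "fewer than two peaks")
})

test_that("Gaussian smoothing has its closed-form kernel behavior", {
  # constant volumes are exactly preserved (boundary renormalization)
  const <- array(7, c(6, 6, 6))
  expect_equal(smooth_gaussian(const, 8), const)
  # deep-interior impulse: center value is the product of per-axis peak
  # weights, and mass is preserved (no kernel truncation in range)
  vol <- array(0, c(15, 15, 15)); vol[8, 8, 8] <- 1
  fwhm <- 4; voxdim <- c(3, 3, 4.5)
  sm <- smooth_gaussian(vol, fwhm, voxdim)
  wmax <- sapply(voxdim, function(vd) {
    sig <- fwhm / (2 * sqrt(2 * log(2))) / vd
    r <- max(1, ceiling(4 * sig))
    w <- exp(-((-r:r)^2) / (2 * sig^2))
    max(w / sum(w))
  })
  expect_equal(sm[8, 8, 8], prod(wmax))
  expect_equal(sum(sm), 1)
  expect_equal(sm[7, 8, 8], sm[9, 8, 8])
  expect_equal(sm[8, 7, 8], sm[8, 9, 8])
  expect_equal(sm[8, 8, 7], sm[8, 8, 9])
  # translation equivariance in the interior
  vol2 <- array(0, c(15, 15, 15)); vol2[9, 8, 8] <- 1
  sm2 <- smooth_gaussian(vol2, fwhm, voxdim)
  expect_equal(sm2[9, 8, 8], sm[8, 8, 8])
})

test_that("nuisance regression is idempotent", {
  run <- quiet_run(list(amp_a = 20, drift_coefs = c(2, 1, 1, 0),
                        noise_sd = 2))
  sp <- pipeline_spec(detrend = 2, motion_regress = TRUE)
  once <- apply_pipeline(run, sp)
  twice <- apply_pipeline(once, sp)
  expect_equal(in_mask(twice), in_mask(once), tolerance = 1e-8)
})

test_that("rank pruning protects task columns and errors when it cannot", {
  set.seed(8)
  Y <- matrix(rnorm(40), 4, 10)
  x <- rnorm(10)
  # a nuisance column duplicating a protected one is pruned silently:
  # the protected column survives and the result is well defined
  prot <- cbind(taskA = x)
  nuis <- cbind(dup = x, other = rnorm(10))
  out <- tabletTMT:::residualize(Y, nuis, prot)
  expect_equal(dim(out), dim(Y))
  # lm oracle on the pruned design: only the nuisance partial fit is
  # subtracted
  y <- Y[1, ]
  b <- coef(lm(y ~ 0 + x + nuis[, "other"]))
  expect_equal(out[1, ], unname(y - nuis[, "other"] * b[2]),
               tolerance = 1e-10)
  # an unresolvable collision inside the protected block is an error
  # naming the lost column
  prot2 <- cbind(taskA = x, taskB = x)
  expect_error(tabletTMT:::residualize(Y, cbind(n1 = rnorm(10)), prot2),
               "protected column\\(s\\) taskB")
  # sanity: residualizing a vector against its own span zeroes it
  nuis2 <- cbind(n1 = rnorm(10))
  Y2 <- rbind(nuis2[, 1] * 2, nuis2[, 1] * -1)
  expect_lt(max(abs(tabletTMT:::residualize(Y2, nuis2, NULL))), 1e-10)
})

test_that("motion summaries report the temporal Std and group tests", {
  tt <- (0:199) / 200
  a <- 0.4
  mot <- function(amp) {
    m <- cbind(amp * sin(2 * pi * 8 * tt), 0 * tt, 0 * tt + 5,
               amp * cos(2 * pi * 8 * tt), 0 * tt, 0 * tt)
    colnames(m) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
    m
  }
  motions <- c(lapply(1:4, function(i) mot(a)),
               lapply(1:4, function(i) mot(a)))
  ms <- summarize_motion(motions, groups = rep(c("g1", "g2"), each = 4))
  # sinusoid over integer periods: Std ~ amplitude / sqrt(2)
  expect_equal(unname(ms$std[1, "tx_mm"]), a / sqrt(2), tolerance = 0.02)
  # constant parameters have zero Std
  expect_equal(unname(ms$std[1, "tz_mm"]), 0)
  # identical groups: every rank-sum p = 1
  expect_true(all(ms$tests$p == 1))
  ms1 <- summarize_motion(motions[1:3])
  expect_null(ms1$tests)
})
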