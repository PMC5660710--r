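test_that("the split design assigns trials 1-2 vs 3-4 with their baselines", {
  p <- build_paradigm()
  des <- build_split_design(p, c("TMT_A", "BASELINE"))
  for (s in list(des$split1, des$split2)) {
    # 20 s window at TR 2 = 10 scans, minus 2 discarded = 8 per task
    # block, 2 blocks per condition per split
    expect_equal(sum(s$label == "TMT_A"), 16)
    # each 10 s baseline yields 5 - 2 = 3 scans; baselines follow both
    # A and B blocks (4 per split)
    expect_equal(sum(s$label == "BASELINE"), 12)
  }
  # splits are disjoint and ordered
  expect_length(intersect(des$split1$scan, des$split2$scan), 0)
  expect_true(!is.unsorted(des$split1$scan))
  # task blocks of trials 1-2 start before those of trials 3-4
  expect_lt(max(des$split1$scan[des$split1$label == "TMT_A"]),
            min(des$split2$scan[des$split2$label == "TMT_A"]))
})

test_that("task-vs-task contrasts exclude baseline scans", {
  p <- build_paradigm()
  des <- build_split_design(p, c("TMT_B", "TMT_A"))
  labs <- c(des$split1$label, des$split2$label)
  expect_setequal(unique(labs), c("TMT_A", "TMT_B"))
  expect_equal(sum(labs == "TMT_B"), 32)
  # a window shorter than the discard yields an error
  expect_error(build_split_design(p, c("TMT_A", "BASELINE"),
                                  discard_initial = 10,
                                  analysis_window = 20),
               "each split must contain both contrast classes|no scans")
  expect_error(build_split_design(p, c("TMT_A", "TMT_A")))
  expect_error(build_split_design(build_paradigm(1, 60, 10, 20, 2),
                                  c("TMT_A", "BASELINE")),
               "fewer than 2 trials")
})

test_that("D(P, R) identities hold", {
  expect_equal(npairs_distance(1, 1), 0)
  expect_equal(npairs_distance(0.8, 0.6), sqrt(0.04 + 0.16))
  expect_equal(round(npairs_distance(0.8, 0.6), 4), 0.4472)
  expect_equal(npairs_distance(1, 0), 1)
  expect_equal(npairs_distance(0.5, -1), sqrt(0.25 + 4))
})

test_that("the discriminant sign makes the first class mean positive", {
  set.seed(2)
  X <- rbind(matrix(rnorm(100, 2), 10), matrix(rnorm(100, -2), 10))
  labels <- rep(c("pos", "neg"), each = 10)
  fit <- fit_lda_pca(X, labels, n_pcs = 3)
  expect_gt(mean(fit$scores[labels == "pos"]),
            mean(fit$scores[labels == "neg"]))
  # reversing the level order flips the map
  fit2 <- fit_lda_pca(X, factor(labels, levels = c("neg", "pos")), 3)
  expect_gt(mean(fit2$scores[labels == "neg"]),
            mean(fit2$scores[labels == "pos"]))
  expect_equal(fit2$map, -fit$map, tolerance = 1e-8)
})

test_that("discriminant input contracts are enforced", {
  set.seed(3)
  X <- matrix(rnorm(60), 6, 10)
  expect_error(fit_lda_pca(X, rep("a", 6), 2), "two classes")
  expect_error(fit_lda_pca(X, rep(c("a", "b"), 3), 0), "n_pcs")
  expect_error(fit_lda_pca(X, rep(c("a", "b"), 3), 6), "exceeds the data rank")
})

test_that("the posterior matches an explicit Bayes oracle", {
  set.seed(4)
  X <- rbind(matrix(rnorm(80, 1), 8), matrix(rnorm(80, -1), 8),
             matrix(rnorm(80, 1), 8), matrix(rnorm(80, -1), 8))
  labels <- rep(rep(c("TMT_A", "BASELINE"), each = 8), 2)
  des <- manual_design(1:16, labels[1:16], 17:32, labels[17:32])
  res <- tabletTMT:::evaluate_split_matrix(X, des, n_pcs = 2)
  # oracle: refit each half, score the other, average explicit normal
  # posteriors in both directions
  p_dir <- sapply(list(c(1, 2), c(2, 1)), function(dir) {
    tr <- if (dir[1] == 1) 1:16 else 17:32
    te <- if (dir[1] == 1) 17:32 else 1:16
    fit <- fit_lda_pca(X[tr, ], factor(labels[tr],
                                       levels = c("TMT_A", "BASELINE")), 2)
    sc <- as.vector(sweep(X[te, ], 2, fit$center) %*% fit$map)
    lab01 <- ifelse(labels[te] == "TMT_A", 1, 2)
    mean(bayes_oracle(sc, lab01, fit$score_means[1], fit$score_means[2],
                      fit$score_sd))
  })
  expect_equal(res$p, mean(p_dir), tolerance = 1e-10)
})

test_that("well-separated classes give P near 1; identical means near 0.5", {
  set.seed(5)
  labels <- rep(rep(c("TMT_A", "BASELINE"), each = 10), 2)
  # class-dependent loading on a non-constant spatial pattern (map
  # reproducibility is a Pearson correlation, so a flat pattern would
  # have no spatial variance to reproduce)
  pattern <- seq(-2, 2, length.out = 10)
  sep <- outer(ifelse(labels == "TMT_A", 5, -5), pattern) +
    matrix(rnorm(40 * 10), 40, 10)
  des <- manual_design(1:20, labels[1:20], 21:40, labels[21:40])
  res <- tabletTMT:::evaluate_split_matrix(sep, des, 2)
  expect_gt(res$p, 0.99)
  expect_gt(res$r, 0.9)
  # chance-level problems average to P ~ 0.5 over repetitions
  ps <- sapply(1:40, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(40 * 12), 40, 12)
    tabletTMT:::evaluate_split_matrix(X, des, 2)$p
  })
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("P, R and z are invariant to swapping the splits", {
  set.seed(6)
  X <- matrix(rnorm(40 * 15), 40, 15) +
    outer(rep(c(1, 0), 20), rnorm(15))
  labels <- rep(c("TMT_A", "BASELINE"), 20)
  d12 <- manual_design(1:20, labels[1:20], 21:40, labels[21:40])
  d21 <- manual_design(21:40, labels[21:40], 1:20, labels[1:20])
  r12 <- tabletTMT:::evaluate_split_matrix(X, d12, 3)
  r21 <- tabletTMT:::evaluate_split_matrix(X, d21, 3)
  expect_equal(r12$p, r21$p, tolerance = 1e-10)
  expect_equal(r12$r, r21$r, tolerance = 1e-10)
  expect_equal(r12$d, r21$d, tolerance = 1e-10)
  expect_equal(r12$map1, r21$map2, tolerance = 1e-10)
  z12 <- compute_rspmz(r12$map1, r12$map2)
  z21 <- compute_rspmz(r21$map1, r21$map2)
  expect_equal(z12$z, z21$z, tolerance = 1e-8)
})

test_that("P and R stay in range over 100 random instances", {
  des <- manual_design(1:16, rep(c("TMT_A", "BASELINE"), 8),
                       17:32, rep(c("TMT_A", "BASELINE"), 8))
  for (s in 1:100) {
    set.seed(1000 + s)
    X <- matrix(rnorm(32 * 10, sd = runif(1, 0.5, 3)), 32, 10) +
      outer(rep(c(runif(1, -2, 2), 0), 16), rnorm(10))
    k <- sample(1:4, 1)
    res <- tabletTMT:::evaluate_split_matrix(X, des, k)
    expect_gte(res$p, 0)
    expect_lte(res$p, 1)
    expect_gte(res$r, -1)
    expect_lte(res$r, 1)
    expect_gte(res$d, 0)
  }
})

test_that("rSPMZ has its closed form, symmetries and degeneracy flag", {
  m1 <- c(1, 2, 3, 4)
  m2 <- c(1, 2, 3, 0)
  rz <- compute_rspmz(m1, m2)
  s <- sd((m1 - m2) / sqrt(2))
  expect_equal(rz$z, (m1 + m2) / 2 / s)
  expect_false(rz$degenerate)
  # identical maps: flagged degenerate, floored scale
  same <- compute_rspmz(m1, m1)
  expect_true(same$degenerate)
  expect_true(all(is.finite(same$z)))
  # anti-correlated maps: zero signal everywhere
  anti <- compute_rspmz(m1, -m1)
  expect_equal(anti$z, rep(0, 4))
  # voxel-wise noise mode
  rv <- compute_rspmz(m1, m2, noise = "voxel")
  expect_equal(rv$z[4], 2 / (4 / sqrt(2)))
  expect_true(rv$degenerate)   # voxels 1..3 have zero difference
  expect_error(compute_rspmz(m1, m2[1:3]))
})

test_that("rSPMZ ranks truly active voxels first at moderate SNR", {
  set.seed(7)
  truth <- c(rep(1, 50), rep(0, 950))
  m1 <- 3 * truth + rnorm(1000)
  m2 <- 3 * truth + rnorm(1000)
  z <- compute_rspmz(m1, m2)$z
  top <- order(-z)[1:50]
  expect_gt(mean(top <= 50), 0.8)
  # point-biserial cor: with 5% active voxels at z ~ 3 and null sd ~ 0.7
  # the theoretical value is about 0.68, so 0.6 is the calibrated bound
  expect_gt(cor(z, truth), 0.6)
})

test_that("evaluate_split recovers a planted activation map", {
  # amp_b = 0 keeps the planted structure confined to the contrast of
  # interest: baselines after B blocks carry the B response tail, which
  # would otherwise enter the A-vs-baseline discriminant
  pf <- generator_profile("VFHP", bold = utils::modifyList(
    quiet_bold, list(amp_a = 15, amp_b = 0, noise_sd = 4,
                     drift_coefs = c(0, 0, 0, 0))))
  run <- simulate_bold_run(short_paradigm(), c(10, 10, 4), pf, seed = 11,
                           truth_seed = 3)
  des <- build_split_design(run$paradigm, c("TMT_A", "BASELINE"))
  res <- evaluate_split(run, NULL, des, n_pcs = 2)
  expect_s3_class(res, "split_result")
  expect_false(res$flagged)
  expect_gt(res$p, 0.8)
  expect_gt(res$r, 0.7)
  truth_v <- which(run$truth$TMT_A[run$mask] > 0)
  avg <- (res$map1 + res$map2) / 2
  top <- order(-abs(avg))[seq_along(truth_v)]
  expect_gte(mean(top %in% truth_v), 0.8)
})

test_that("pipeline/PC optimization is exhaustive with first-wins ties", {
  pf <- generator_profile("VFHP", bold = utils::modifyList(
    quiet_bold, list(amp_a = 12, amp_b = 12, noise_sd = 6)))
  run <- simulate_bold_run(short_paradigm(), c(8, 8, 4), pf, seed = 13,
                           truth_seed = 2)
  des <- build_split_design(run$paradigm, c("TMT_A", "BASELINE"))
  pls <- enumerate_pipelines(list(detrend = c(-1, 1)))
  opt <- optimize_subject(run, pls, c(2, 3), des)
  expect_equal(nrow(opt$table), 4)
  expect_equal(opt$best$d, min(opt$table$d))
  i_best <- which(opt$table$d == min(opt$table$d))[1]
  expect_equal(opt$best$n_pcs, opt$table$n_pcs[i_best])
  expect_identical(pipeline_to_json(opt$best$pipeline),
                   opt$table$pipeline[i_best])
  # the audit table stores valid JSON for every configuration
  for (js in opt$table$pipeline)
    expect_s3_class(pipeline_from_json(js), "pipeline_spec")
})

test_that("drift-dominated runs select a detrending pipeline", {
  # one representative replicate here (the replicated suite is part of
  # the acceptance tests)
  pf <- generator_profile("VFHP", bold = utils::modifyList(
    quiet_bold, list(amp_a = 12, amp_b = 12, noise_sd = 4,
                     drift_coefs = c(0, 60, 40, 0))))
  run <- simulate_bold_run(short_paradigm(), c(8, 8, 4), pf, seed = 17,
                           truth_seed = 2)
  des <- build_split_design(run$paradigm, c("TMT_A", "BASELINE"))
  pls <- enumerate_pipelines(list(detrend = c(-1, 2)))
  opt <- optimize_subject(run, pls, 2, des)
  expect_equal(opt$best$pipeline$detrend, 2)
})
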