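#' Load, default and validate a run configuration
#'
#' The configuration is a JSON file with per-stage sections; every field
#' is optional and defaults to the standard study settings (four 60 s
#' trials per part with 10 s baselines and a 10 s lead-in at TR 2 s,
#' speed threshold 0.1 px/ms, FDR q = 0.05, cluster threshold 20 voxels,
#' 100 resampling iterations). Schema violations are collected and
#' reported exhaustively, not first-failure.
#'
#' @param path Path to a JSON config file, or `NULL` for pure defaults.
#' @return Validated config list of class `run_config`.
#' @export
validate_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nzchar(trimws(txt)))
      user <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  def <- list(
    seed = 1L,
    out_dir = "tmt_analysis",
    n_per_group = 11L,
    bold = TRUE,
    grid = c(12L, 12L, 6L),
    paradigm = list(n_trials_per_part = 4, task_dur = 60,
                    baseline_dur = 10, lead_in = 10, tr = 2),
    behavior = list(speed_thr = 0.1, ink_thr = 0.05, force_window = 20,
                    block_dur = 60),
    npairs = list(pc_grid = c(2, 4), discard_initial = 2,
                  analysis_window = 20,
                  contrasts = list(c("TMT_A", "BASELINE"),
                                   c("TMT_B", "BASELINE"),
                                   c("TMT_B", "TMT_A")),
                  pipeline_grid = list(detrend = c(-1, 2),
                                       motion_pca = c(FALSE, TRUE))),
    group = list(q = 0.05, min_cluster = 20L, n_iter = 100L,
                 connectivity = 26L))
  cfg <- utils::modifyList(def, as.list(user))

  # normalize contrasts to a list of length-2 character vectors (JSON
  # round-trips may deliver a matrix)
  ctr <- cfg$npairs$contrasts
  if (is.matrix(ctr))
    ctr <- lapply(seq_len(nrow(ctr)), function(i) ctr[i, ])
  cfg$npairs$contrasts <- lapply(ctr, function(x) as.character(unlist(x)))

  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: single integer required")
  chk(is.numeric(cfg$n_per_group) && cfg$n_per_group >= 1,
      "n_per_group: must be >= 1")
  chk(length(cfg$grid) == 3 && all(cfg$grid >= 2), "grid: three dims >= 2")
  chk(cfg$group$q > 0 && cfg$group$q < 1, "group.q: must be in (0, 1)")
  chk(cfg$group$min_cluster >= 1, "group.min_cluster: must be >= 1")
  chk(cfg$group$n_iter >= 2, "group.n_iter: must be >= 2")
  chk(cfg$group$connectivity %in% c(6, 18, 26),
      "group.connectivity: must be 6, 18 or 26")
  chk(cfg$behavior$speed_thr > 0, "behavior.speed_thr: must be > 0")
  chk(cfg$paradigm$tr > 0, "paradigm.tr: must be > 0")
  chk(length(cfg$npairs$pc_grid) >= 1 && all(cfg$npairs$pc_grid >= 1),
      "npairs.pc_grid: nonempty, all >= 1")
  chk(length(cfg$npairs$pipeline_grid) >= 1,
      "npairs.pipeline_grid: nonempty")
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

#' Run the full demonstration pipeline
#'
#' Orchestrates simulate -> behavior -> optimize -> group on a synthetic
#' cohort: generates the cohort on disk, scores the stylus logs and runs
#' the group behavioral statistics, optimizes each subject's preprocessing
#' pipeline and PC count per contrast and converts the best split maps to
#' rSPMZs, then runs group PCA with resampled z-scoring, FDR thresholding,
#' conjunction across tablet modes, cluster extraction and Jaccard
#' overlap. Every artifact is listed in a manifest together with the seed
#' and a hash of the configuration, so a rerun with the same config is
#' bit-identical.
#'
#' @param config A `run_config` from [validate_config()].
#' @param profiles Optional named list of generator profiles per mode.
#' @return Invisibly, a report list (also written to
#'   `out_dir/report.json`).
#' @export
run_full_analysis <- function(config, profiles = NULL) {
  if (!inherits(config, "run_config")) stop("config must be validated first")
  if (is.null(config$seed)) stop("missing seed")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- config$out_dir
  profiles <- profiles %||% list(VFHP = generator_profile("VFHP"),
                                 NO_VFHP = generator_profile("NO_VFHP"))
  paradigm <- do.call(build_paradigm, config$paradigm)

  manifest_files <- character(0)
  note <- function(f) manifest_files <<- c(manifest_files, f)

  stage("simulate", {
    generate_cohort(out, config$n_per_group, profiles, seed = config$seed,
                    paradigm = paradigm, bold = config$bold,
                    grid = config$grid)
    note("manifest.json")
  })

  beh <- stage("behavior", {
    cohort <- score_cohort(out, block_dur = config$behavior$block_dur,
                           ink_thr = config$behavior$ink_thr,
                           speed_thr = config$behavior$speed_thr,
                           force_window = config$behavior$force_window)
    stats <- group_behavior_stats(cohort,
                                  block_dur = config$behavior$block_dur)
    utils::write.csv(cohort$trials, file.path(out, "behavior_trials.csv"),
                     row.names = FALSE)
    utils::write.csv(stats$anova, file.path(out, "behavior_anova.csv"),
                     row.names = FALSE)
    note(c("behavior_trials.csv", "behavior_anova.csv"))
    list(cohort = cohort, stats = stats)
  })

  report <- list(seed = config$seed,
                 behavior_force_p = beh$stats$force_test$p)

  if (config$bold) {
    subj_tab <- jsonlite::read_json(file.path(out, "manifest.json"),
                                    simplifyVector = TRUE)$subjects
    opt <- stage("optimize", {
      pipelines <- enumerate_pipelines(config$npairs$pipeline_grid)
      res <- list()
      for (i in seq_len(nrow(subj_tab))) {
        sid <- subj_tab$subject_id[i]
        run <- read_bold_run(file.path(out, sid, "bold"))
        per_contrast <- list()
        for (ct in config$npairs$contrasts) {
          ct <- unlist(ct)
          design <- build_split_design(paradigm, ct,
                                       config$npairs$discard_initial,
                                       config$npairs$analysis_window)
          o <- optimize_subject(run, pipelines, config$npairs$pc_grid,
                                design)
          key <- paste(ct, collapse = "_vs_")
          utils::write.csv(o$table,
                           file.path(out, sid,
                                     paste0("npairs_", key, ".csv")),
                           row.names = FALSE)
          note(file.path(sid, paste0("npairs_", key, ".csv")))
          rz <- compute_rspmz(o$best$map1, o$best$map2)
          per_contrast[[key]] <- list(best = o$best, rspmz = rz$z,
                                      mask = run$mask)
        }
        res[[sid]] <- list(mode = subj_tab$mode[i],
                           contrasts = per_contrast)
      }
      res
    })

    grp <- stage("group", {
      g <- config$group
      out_group <- list()
      contrast_keys <- names(opt[[1]]$contrasts)
      for (key in contrast_keys) {
        masks_by_mode <- list(); maps_by_mode <- list()
        for (mode in c("VFHP", "NO_VFHP")) {
          sids <- names(opt)[sapply(opt, function(s) s$mode == mode)]
          stack <- do.call(rbind, lapply(sids, function(s)
            opt[[s]]$contrasts[[key]]$rspmz))
          comps <- group_pca_zscore(stack, n_components = 2,
                                    n_iter = g$n_iter,
                                    seed = derive_seed(config$seed, 7))
          z1 <- comps[[1]]$z
          masks_by_mode[[mode]] <- fdr_threshold(z1, g$q)
          maps_by_mode[[mode]] <- z1
        }
        cj <- conjunction_mean(masks_by_mode$VFHP, masks_by_mode$NO_VFHP,
                               maps_by_mode$VFHP, maps_by_mode$NO_VFHP)
        vol_mask <- opt[[1]]$contrasts[[key]]$mask
        to_vol <- function(v) {
          a <- array(0, dim(vol_mask)); a[which(vol_mask)] <- v; a
        }
        mean_vol <- to_vol(ifelse(is.na(cj$mean_map), 0, cj$mean_map))
        clus <- extract_clusters(mean_vol, to_vol(cj$common) > 0,
                                 g$min_cluster, g$connectivity)
        utils::write.csv(clus,
                         file.path(out, paste0("clusters_", key, ".csv")),
                         row.names = FALSE)
        img <- RNifti::asNifti(mean_vol)
        RNifti::writeNifti(img, file.path(out, paste0("mean_", key, ".nii")))
        note(c(paste0("clusters_", key, ".csv"),
               paste0("mean_", key, ".nii")))
        out_group[[key]] <- list(
          jaccard_modes = jaccard_index(masks_by_mode$VFHP,
                                        masks_by_mode$NO_VFHP),
          n_conjunction = sum(cj$common), clusters = clus)
      }
      out_group
    })
    report$group <- lapply(grp, function(x)
      list(jaccard_modes = x$jaccard_modes,
           n_conjunction = x$n_conjunction,
           n_clusters = nrow(x$clusters)))
  }

  cfg_json <- as.character(jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE, digits = NA))
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  report$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  report$files <- manifest_files
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
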