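#' Generate a full synthetic cohort on disk
#'
#' Writes everything a downstream analysis needs: the shared block
#' paradigm, one stimulus layout per task block (a different pseudo-random
#' pattern per trial, as on the tablet display), per-subject stylus logs
#' for every task block, optional simulated BOLD runs, and a ground-truth
#' manifest. One master seed spawns an independent substream per subject,
#' so any subject is reproducible in isolation.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_per_group Subjects per tablet mode.
#' @param profiles List with elements `VFHP` and `NO_VFHP`
#'   (`generator_profile` objects).
#' @param seed Master seed.
#' @param paradigm A `tmt_paradigm` (default: the standard 570 s run).
#' @param canvas,radius,min_sep Layout geometry (px).
#' @param bold Also simulate and write BOLD runs (slower).
#' @param grid BOLD volume dimensions.
#' @return The manifest (invisibly), also written to
#'   `out_dir/manifest.json`.
#' @export
generate_cohort <- function(out_dir, n_per_group = 11,
                            profiles = list(VFHP = generator_profile("VFHP"),
                                            NO_VFHP = generator_profile("NO_VFHP")),
                            seed = 1L, paradigm = build_paradigm(),
                            canvas = c(1024, 768), radius = 30,
                            min_sep = 10, bold = FALSE,
                            grid = c(12, 12, 6)) {
  stopifnot(n_per_group >= 1,
            all(c("VFHP", "NO_VFHP") %in% names(profiles)))
  dir_create <- function(p) {
    if (!dir.exists(p) && !dir.create(p, recursive = TRUE))
      stop("cannot create directory: ", p)
    p
  }
  dir_create(out_dir)
  dir_create(file.path(out_dir, "layouts"))
  write_paradigm(paradigm, file.path(out_dir, "paradigm.json"))

  n_trials <- sum(paradigm$blocks$condition == "TMT_A")
  block_ids <- c(paste0("A", seq_len(n_trials)),
                 paste0("B", seq_len(n_trials)))
  layouts <- list()
  for (b in block_ids) {
    part <- substr(b, 1, 1)
    layouts[[b]] <- generate_layout(part, canvas, radius, min_sep,
                                    seed = derive_seed(seed, match(b, block_ids)))
    write_layout(layouts[[b]],
                 file.path(out_dir, "layouts", paste0("layout_", b, ".json")))
  }

  modes <- rep(c("VFHP", "NO_VFHP"), each = n_per_group)
  subj_ids <- sprintf("sub-%02d", seq_along(modes))
  subjects <- list()
  for (i in seq_along(subj_ids)) {
    sid <- subj_ids[i]
    sdir <- dir_create(file.path(out_dir, sid))
    sseed <- derive_seed(seed, 100 + i)
    prof <- profiles[[modes[i]]]
    files <- character(0)
    for (bi in seq_along(block_ids)) {
      b <- block_ids[bi]
      log <- simulate_stylus_log(layouts[[b]], prof,
                                 seed = derive_seed(sseed, bi),
                                 block_id = b)
      f <- file.path(sdir, paste0("log_", b, ".tsv"))
      write_tablet_log(log, f)
      files <- c(files, file.path(sid, basename(f)))
    }
    if (bold) {
      run <- simulate_bold_run(paradigm, grid, prof,
                               seed = derive_seed(sseed, 999),
                               truth_seed = derive_seed(seed, 7777))
      write_bold_run(run, file.path(sdir, "bold"))
      files <- c(files, file.path(sid, "bold.nii"))
    }
    subjects[[sid]] <- list(subject_id = sid, mode = modes[i],
                            seed = sseed, files = files)
  }

  manifest <- list(
    seed = seed, n_per_group = n_per_group, bold = bold,
    grid = grid, canvas = canvas, radius = radius, min_sep = min_sep,
    profiles = lapply(profiles, function(p) unclass(p)),
    block_ids = block_ids, subjects = unname(subjects))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Score every subject of an on-disk cohort
#'
#' Reads the manifest, layouts and stylus logs written by
#' [generate_cohort()] and returns the cohort behavior table.
#'
#' @param dir Cohort directory.
#' @param ... Passed to [score_subject()] (thresholds, force window).
#' @return A `tmt_cohort_behavior`.
#' @export
score_cohort <- function(dir, ...) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  block_ids <- manifest$block_ids
  layouts <- lapply(block_ids, function(b)
    read_layout(file.path(dir, "layouts", paste0("layout_", b, ".json"))))
  names(layouts) <- block_ids
  subjects <- lapply(seq_len(nrow(manifest$subjects)), function(i) {
    sid <- manifest$subjects$subject_id[i]
    logs <- lapply(block_ids, function(b) {
      lg <- read_tablet_log(file.path(dir, sid, paste0("log_", b, ".tsv")),
                            block_id = b, part = substr(b, 1, 1))
      lg
    })
    score_subject(logs, layouts, mode = manifest$subjects$mode[i],
                  subject_id = sid, ...)
  })
  cohort_behavior(subjects)
}
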