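#' Generator profile for synthetic subjects
#'
#' Bundles the behavioral and BOLD ground-truth parameters of one simulated
#' subject group. Defaults encode the qualitative group differences the
#' tablet modes are expected to show: visual feedback of hand position
#' (VFHP) lowers the stylus contact force and lengthens the part-A dwell
#' (the hand occludes the display), while part B lengthens dwell in both
#' modes (extra visual search and set switching).
#'
#' @param mode `"VFHP"` or `"NO_VFHP"`.
#' @param dwell_mean,dwell_sd Mean/SD of the per-link stationary dwell (ms)
#'   for part A.
#' @param dwell_part_b_shift Added to `dwell_mean` for part B (ms).
#' @param move_speed Drawing speed along links (px/ms).
#' @param path_noise_sd SD of positional jitter during movement (px).
#' @param force_mean,force_sd Stylus contact force distribution (a.u.),
#'   clipped at zero.
#' @param ceiling Block duration ceiling (s); logs are truncated here.
#' @param nominal_rate Log sampling rate (Hz).
#' @param t_jitter_sd SD of timestamp jitter around the nominal spacing (ms).
#' @param bold List of BOLD simulation parameters: `baseline` (a.u.),
#'   `amp_a`, `amp_b` (task effect amplitudes, a.u.), `drift_coefs`
#'   (Legendre drift coefficients), `motion_amp` (mm), `motion_coupling`
#'   (a.u. per mm), `physio_amp`, `global_amp`, `noise_sd` (a.u.),
#'   `cardiac_hz`, `resp_hz`.
#' @param seed Optional profile-level seed.
#' @return Object of class `generator_profile`.
#' @export
generator_profile <- function(mode = c("VFHP", "NO_VFHP"),
                              dwell_mean = NULL, dwell_sd = 120,
                              dwell_part_b_shift = 300,
                              move_speed = 0.5, path_noise_sd = 1,
                              force_mean = NULL, force_sd = 0.05,
                              ceiling = 60, nominal_rate = 40,
                              t_jitter_sd = 2,
                              bold = list(), seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(dwell_mean)) dwell_mean <- if (mode == "VFHP") 500 else 400
  if (is.null(force_mean)) force_mean <- if (mode == "VFHP") 0.25 else 0.35
  bold_def <- list(baseline = 1000, amp_a = 20, amp_b = 20,
                   drift_coefs = c(0, 3, 2, 1), motion_amp = 0.3,
                   motion_coupling = 2, physio_amp = 2, global_amp = 2,
                   noise_sd = 5, cardiac_hz = 1.1, resp_hz = 0.3)
  bold_def[names(bold)] <- bold
  p <- list(mode = mode, dwell_mean = dwell_mean, dwell_sd = dwell_sd,
            dwell_part_b_shift = dwell_part_b_shift,
            move_speed = move_speed, path_noise_sd = path_noise_sd,
            force_mean = force_mean, force_sd = force_sd,
            ceiling = ceiling, nominal_rate = nominal_rate,
            t_jitter_sd = t_jitter_sd, bold = bold_def, seed = seed)
  validate_profile(p)
  structure(p, class = "generator_profile")
}

validate_profile <- function(p) {
  stopifnot(p$dwell_mean >= 0, p$dwell_sd >= 0, p$force_sd >= 0,
            p$path_noise_sd >= 0, p$t_jitter_sd >= 0,
            p$move_speed > 0, p$ceiling > 0, p$nominal_rate > 0,
            p$bold$noise_sd >= 0, p$bold$physio_amp >= 0,
            p$bold$global_amp >= 0)
  invisible(TRUE)
}

#' @export
print.generator_profile <- function(x, ...) {
  cat(sprintf(paste0("Generator profile [%s]: dwell %g±%g ms (part B +%g), ",
                     "speed %g px/ms, force %g±%g a.u., ceiling %g s\n"),
              x$mode, x$dwell_mean, x$dwell_sd, x$dwell_part_b_shift,
              x$move_speed, x$force_mean, x$force_sd, x$ceiling))
  invisible(x)
}
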