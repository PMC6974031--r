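#' Simulation configuration for a synthetic sensory-preconditioning study
#'
#' The defaults encode the reference design: 24 subjects, 8 cue sets of
#' A-B and C-D pairs plus 4 E-E control pairs, 4 analyzed preconditioning
#' runs (3 s cues separated by 300 ms, jittered 3-11 s fixation), 5
#' conditioning runs (1.5 s cues, 1.5 s feedback, two repetitions of each
#' cue per run, 10 repetitions total), and one probe run (every cue four
#' times, conditioning timing, no feedback), TR 2 s. Effect sizes are not
#' part of the published design and are the generator's own stated world;
#' see the package vignette for the rationale behind each default.
#'
#' @param n_subjects number of subjects.
#' @param rois named integer vector: voxels per ROI.
#' @param feature_step named integer vector: feature-selection step per ROI
#'   (40 for OFC-type, 20 for HPC-type regions). Every ROI must hold at
#'   least one step's worth of voxels.
#' @param voxel_size_mm isotropic voxel size.
#' @param tr_s repetition time, seconds.
#' @param runs named counts: `preconditioning` (analyzed runs),
#'   `conditioning`, `probe`.
#' @param n_cue_sets number of A-B / C-D cue sets.
#' @param precond_reps repetitions of each pair per preconditioning run.
#' @param cond_reps repetitions of each conditioned cue per run.
#' @param probe_reps repetitions of each cue in the probe run.
#' @param similarity_slope planted paired-minus-unpaired Fisher-z increase
#'   per preconditioning run.
#' @param value_amplitude planted outcome-value pattern amplitude (units of
#'   pattern SD), expressed only in `value_roi`.
#' @param reactivation_gain pull (0-1) of probe-phase A/C patterns toward
#'   their end-of-preconditioning associative state.
#' @param conditioning_reactivation_gain same for conditioning-phase B/D
#'   patterns; 0 by default (the reference finding is a null), enable for
#'   power analyses.
#' @param coupling_modulation planted increase of seed-target coupling on
#'   preconditioned-cue trials (interaction weight).
#' @param coupling_base context-independent seed-target coupling.
#' @param noise_sd marginal SD of the AR(1) voxel noise.
#' @param ar1 lag-1 autocorrelation of the voxel noise, in `[0, 1)`.
#' @param signal_amplitude BOLD amplitude of one pattern unit.
#' @param day_effect_sd SD of an additive day-2 pattern shared by all
#'   day-2 trials (0 by default; used by the scan-day control analyses).
#' @param random_effects if `TRUE`, per-subject effect sizes are drawn
#'   around the configured values with coefficient of variation
#'   `effect_cv`; if `FALSE` every subject carries the identical effect.
#' @param effect_cv between-subject coefficient of variation of effects.
#' @param value_roi ROI expressing the value code.
#' @param ppi_seed_roi,ppi_target_roi seed and target regions of the
#'   planted probe-phase coupling.
#' @param learning_rate exponential learning rate per repetition of the
#'   conditioning prediction curves.
#' @param asym_reward,asym_nonreward asymptotic P(predict reward) for B and
#'   D cues.
#' @param inference_intercept,dprime_coupling logistic intercept and slope
#'   linking recognition d-prime to probe A/C inference accuracy.
#' @param rt_intercept_s,rt_run_slope_s,rt_sd_s response-time intercept,
#'   per-run linear decrease, and trial SD (preconditioning catch task).
#' @param rt_infer_cost_s extra RT for preconditioned (A/C) over
#'   conditioned (B/D) cues in the probe run.
#' @param rt_coupling_s RT decrease per unit of a subject's coupling
#'   modulation (links connectivity to behavior; active in
#'   `random_effects` mode).
#' @param dprime_mean,dprime_sd population distribution of recognition
#'   d-prime.
#' @param n_recognition_old,n_recognition_recombined recognition-test trial
#'   counts.
#' @param nonresponse_rate probability of a missing behavioral response.
#' @param iti_range_s fixation interval range, preconditioning.
#' @param iti_cond_range_s inter-trial interval range, conditioning/probe.
#' @param run_volumes optional named list (`preconditioning`,
#'   `conditioning`, `probe`) fixing the volume count per run; runs too
#'   short for the event sequence are rejected at simulation time. By
#'   default run length is derived from the events plus a 16 s tail.
#' @param store_latents keep latent patterns in the ground truth (needed
#'   for parameter-recovery oracles; costs memory).
#' @param seed master seed; identical configs with identical seeds produce
#'   byte-identical datasets.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_subjects = 24,
                       rois = c(medial_OFC = 120L, lateral_OFC = 120L,
                                anterior_HPC = 80L, posterior_HPC = 80L),
                       feature_step = c(medial_OFC = 40L, lateral_OFC = 40L,
                                        anterior_HPC = 20L, posterior_HPC = 20L),
                       voxel_size_mm = 2,
                       tr_s = 2,
                       runs = c(preconditioning = 4L, conditioning = 5L, probe = 1L),
                       n_cue_sets = 8,
                       precond_reps = 3,
                       cond_reps = 2,
                       probe_reps = 4,
                       similarity_slope = 0.05,
                       value_amplitude = 0.3,
                       reactivation_gain = 0.3,
                       conditioning_reactivation_gain = 0,
                       coupling_modulation = 0.5,
                       coupling_base = 0.2,
                       noise_sd = 1,
                       ar1 = 0.3,
                       signal_amplitude = 1,
                       day_effect_sd = 0,
                       random_effects = FALSE,
                       effect_cv = 0.3,
                       value_roi = "medial_OFC",
                       ppi_seed_roi = "medial_OFC",
                       ppi_target_roi = "posterior_HPC",
                       learning_rate = 0.6,
                       asym_reward = 0.97,
                       asym_nonreward = 0.03,
                       inference_intercept = -1.2,
                       dprime_coupling = 1.3,
                       rt_intercept_s = 0.95,
                       rt_run_slope_s = -0.05,
                       rt_sd_s = 0.15,
                       rt_infer_cost_s = 0.15,
                       rt_coupling_s = 0.2,
                       dprime_mean = 1.5,
                       dprime_sd = 0.8,
                       n_recognition_old = 16,
                       n_recognition_recombined = 16,
                       nonresponse_rate = 0.02,
                       iti_range_s = c(3, 11),
                       iti_cond_range_s = c(3, 7.5),
                       run_volumes = NULL,
                       store_latents = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("n_subjects", "n_cue_sets", "precond_reps", "cond_reps",
              "probe_reps"))
    if (!is_count(cfg[[f]])) abort_validation("%s must be a count >= 1", f)
  if (is.null(names(rois)) || any(names(rois) == ""))
    abort_validation("rois must be a named vector")
  if (any(rois < 1)) abort_validation("all ROI voxel counts must be >= 1")
  if (!all(names(runs) == c("preconditioning", "conditioning", "probe")) ||
      any(runs < 1))
    abort_validation("runs must name preconditioning, conditioning and probe counts >= 1")
  if (ar1 < 0 || ar1 >= 1) abort_validation("ar1 must lie in [0, 1)")
  if (noise_sd <= 0) abort_validation("noise_sd must be > 0")
  if (reactivation_gain < 0 || reactivation_gain > 1 ||
      conditioning_reactivation_gain < 0 || conditioning_reactivation_gain > 1)
    abort_validation("reactivation gains must lie in [0, 1]")
  if (similarity_slope < 0) abort_validation("similarity_slope must be >= 0")
  if (nonresponse_rate < 0 || nonresponse_rate >= 1)
    abort_validation("nonresponse_rate must lie in [0, 1)")
  step <- feature_step[names(rois)]
  if (anyNA(step))
    abort_validation("feature_step must name every ROI")
  if (any(rois < step))
    abort_validation("ROI voxel count smaller than its feature-selection step: %s",
                     paste(names(rois)[rois < step], collapse = ", "))
  for (rn in c(value_roi, ppi_seed_roi, ppi_target_roi))
    if (!rn %in% names(rois)) abort_validation("unknown ROI '%s'", rn)
  cfg$rois <- setNames(as.integer(rois), names(rois))
  cfg$feature_step <- setNames(as.integer(feature_step), names(feature_step))
  cfg$runs <- setNames(as.integer(runs), names(runs))
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d subjects, %d cue sets, runs %s, seed %d\n",
    x$n_subjects, x$n_cue_sets,
    paste(sprintf("%s=%d", names(x$runs), x$runs), collapse = " "), x$seed))
  cat(sprintf("  ROIs: %s\n",
              paste(sprintf("%s(%d)", names(x$rois), x$rois), collapse = ", ")))
  cat(sprintf(
    "  effects: slope=%.3g value=%.3g react=%.3g coupling=%.3g noise=%.3g ar1=%.2f\n",
    x$similarity_slope, x$value_amplitude, x$reactivation_gain,
    x$coupling_modulation, x$noise_sd, x$ar1))
  invisible(x)
}

# Build sim_config from a plain list (e.g. parsed YAML/JSON), applying
# defaults for absent fields.
sim_config_from_list <- function(lst) {
  lst <- lst[names(lst) %in% names(formals(sim_config))]
  for (nm in c("rois", "feature_step", "runs"))
    if (!is.null(lst[[nm]])) lst[[nm]] <- unlist(lst[[nm]])
  do.call(sim_config, lst)
}
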