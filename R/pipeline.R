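#' First-level GLM for one subject, phase, run and ROI
#'
#' Builds the phase's design (events convolved with the canonical HRF,
#' run nuisance appended, constant column) and fits OLS, returning beta
#' and t patterns for the regressors of interest.
#'
#' @param dataset an `sp_dataset`.
#' @param subject subject index.
#' @param phase `"preconditioning"`, `"conditioning"` or `"probe"`.
#' @param run run index within the phase.
#' @param roi ROI name.
#' @param scheme GLM scheme (see [build_design()]).
#' @export
subject_glm <- function(dataset, subject, phase, run, roi,
                        scheme = c(preconditioning = "precond_perset",
                                   conditioning = "cond",
                                   probe = "probe")[[phase]]) {
  sub <- dataset$subjects[[subject]]
  ev <- sub$events[[phase]][[run]]
  design <- build_design(ev, sub$n_volumes[[phase]][[run]],
                         dataset$config$tr_s, scheme = scheme,
                         nuisance = sub$nuisance[[phase]][[run]])
  fit_glm(sub$bold[[phase]][[run]][[roi]], design)
}

#' Pattern-similarity analysis of preconditioning
#'
#' Per subject and ROI, fits the per-set preconditioning GLMs, computes
#' the paired-minus-unpaired Fisher-z trajectory across runs, and tests
#' the per-subject linear trends against zero (one-tailed: similarity is
#' predicted to increase).
#'
#' @param dataset an `sp_dataset`.
#' @param rois ROI names (default: all).
#' @param measure `"t"` (default) or `"beta"` patterns.
#' @return list with `table` (subject x roi x run rows) and `tests` (one
#'   trend test per ROI).
#' @export
analyze_similarity <- function(dataset, rois = names(dataset$masks),
                               measure = "t") {
  n_runs <- dataset$config$runs[["preconditioning"]]
  rows <- list(); tests <- list()
  for (roi in rois) {
    deltas <- matrix(NA_real_, length(dataset$subjects), n_runs)
    for (s in seq_along(dataset$subjects)) {
      est <- lapply(seq_len(n_runs), function(r)
        subject_glm(dataset, s, "preconditioning", r, roi))
      traj <- paired_contrast_trajectory(est, measure = measure)
      deltas[s, ] <- traj$delta
      traj$subject <- s; traj$roi <- roi
      rows[[length(rows) + 1L]] <- traj
    }
    tests[[roi]] <- linear_trend_test(deltas, tail = "greater")
  }
  table <- do.call(rbind, rows)[, c("subject", "roi", "run", "z_within",
                                    "z_between", "delta")]
  list(table = table, tests = tests)
}

# Exemplar assembly for the decoding analyses: training patterns from the
# last three conditioning runs, test patterns from the probe GLM.
subject_decode_data <- function(dataset, subject, roi, scheme) {
  n_cond <- dataset$config$runs[["conditioning"]]
  runs_used <- utils::tail(seq_len(n_cond), 3)
  per_set <- scheme == "cross_set"
  train <- list(); train_y <- c(); train_set <- c()
  for (r in runs_used) {
    est <- subject_glm(dataset, subject, "conditioning", r, roi,
                       scheme = if (per_set) "cond_perset" else "cond")
    train[[length(train) + 1L]] <- est$t
    train_y <- c(train_y, ifelse(est$labels$cue_role == "B", 1, -1))
    train_set <- c(train_set, est$labels$cue_set)
  }
  probe <- subject_glm(dataset, subject, "probe", 1, roi, scheme = "probe")
  roles <- if (scheme == "bd") c("B", "D") else c("A", "C")
  sel <- probe$labels$cue_role %in% roles
  list(train_x = do.call(rbind, train), train_y = train_y,
       train_set = if (per_set) train_set else NULL,
       test_x = probe$t[sel, , drop = FALSE],
       test_y = ifelse(probe$labels$cue_role[sel] %in% c("A", "B"), 1, -1),
       test_set = probe$labels$cue_set[sel])
}

#' Cross-phase decoding analysis for one ROI
#'
#' Trains on conditioning B-versus-D patterns (last three runs) and tests
#' on probe-phase patterns, with nested leave-one-subject-out voxel-count
#' selection and permutation-based empirical chance. Schemes: `"bd"`
#' (test B vs D), `"ac"` (test A vs C: outcome inference), `"cross_set"`
#' (train on 7 cue sets, test A vs C of the held-out set, 8 folds).
#'
#' @param dataset an `sp_dataset`.
#' @param roi ROI name.
#' @param spec a [decode_spec()]; its `feature_step` defaults to the
#'   config's per-ROI step.
#' @export
analyze_decoding <- function(dataset, roi, spec = NULL) {
  step <- dataset$config$feature_step[[roi]]
  spec <- spec %||% decode_spec(feature_step = step,
                                seed = dataset$config$seed)
  subjects <- lapply(seq_along(dataset$subjects), function(s)
    subject_decode_data(dataset, s, roi, spec$scheme))
  res <- decode_roi(subjects, spec)
  res$table$roi <- roi
  res$table$scheme <- spec$scheme
  res
}

#' Reactivation analysis
#'
#' Variants: `"conditioning_bd"` (are preconditioned cues reactivated
#' during conditioning? templates = conditioning B/D patterns, compared
#' against first- versus last-run preconditioning patterns of the same
#' cues), `"probe_ac"` (are conditioned-cue associates reactivated at the
#' probe? templates = probe A/C patterns), and `"probe_ac_daycorrected"`
#' (same, minus the first/last contrast computed on unrelated cue pairs to
#' remove scan-day effects).
#'
#' @param dataset an `sp_dataset`.
#' @param roi ROI name.
#' @param variant see Details.
#' @return list with `table` (per-subject contrast) and `group` (one-sample
#'   one-tailed t).
#' @export
analyze_reactivation <- function(dataset, roi,
                                 variant = c("probe_ac", "conditioning_bd",
                                             "probe_ac_daycorrected")) {
  variant <- match.arg(variant)
  n_pre <- dataset$config$runs[["preconditioning"]]
  n_cond <- dataset$config$runs[["conditioning"]]
  roles <- if (variant == "conditioning_bd") c("B", "D") else c("A", "C")
  vals <- vapply(seq_along(dataset$subjects), function(s) {
    first <- role_patterns(subject_glm(dataset, s, "preconditioning", 1, roi,
                                       scheme = "precond"))
    last <- role_patterns(subject_glm(dataset, s, "preconditioning", n_pre, roi,
                                      scheme = "precond"))
    template <- if (variant == "conditioning_bd") {
      ests <- lapply(seq_len(n_cond), function(r)
        subject_glm(dataset, s, "conditioning", r, roi, scheme = "cond"))
      avg_role_patterns(ests, c("B", "D"))
    } else {
      avg_role_patterns(list(subject_glm(dataset, s, "probe", 1, roi,
                                         scheme = "probe")), c("A", "C"))
    }
    if (variant == "probe_ac_daycorrected")
      scanday_corrected_contrast(template, first, last)$corrected
    else
      reactivation_contrast(template, first, last, roles)$value
  }, 0)
  table <- data.frame(subject = seq_along(vals), roi = roi,
                      variant = variant, contrast = vals)
  list(table = table, group = group_t(vals, 0, tail = "greater"))
}

role_patterns <- function(est) {
  out <- list()
  for (ro in unique(est$labels$cue_role)) {
    sel <- est$labels$cue_role == ro
    out[[ro]] <- colMeans(est$t[sel, , drop = FALSE])
  }
  out
}

avg_role_patterns <- function(ests, roles) {
  out <- list()
  for (ro in roles) {
    mats <- lapply(ests, function(e) {
      sel <- e$labels$cue_role == ro
      colMeans(e$t[sel, , drop = FALSE])
    })
    out[[ro]] <- Reduce(`+`, mats) / length(mats)
  }
  out
}

#' PPI connectivity analysis
#'
#' Seed = mean-centered ROI-average series of the seed region in the probe
#' run; target = ROI-average series of the target region. Fits the
#' BOLD-level generalized-PPI model per subject, tests the per-subject
#' interaction contrast (preconditioned minus conditioned) at the group
#' level (one-tailed) and correlates the contrast with probe-phase
#' response time on preconditioned-cue trials (one-tailed: stronger
#' coupling predicts faster inference).
#'
#' @param dataset an `sp_dataset`.
#' @param seed_roi,target_roi ROI names; default from the config.
#' @export
analyze_ppi <- function(dataset, seed_roi = dataset$config$ppi_seed_roi,
                        target_roi = dataset$config$ppi_target_roi) {
  rows <- lapply(seq_along(dataset$subjects), function(s) {
    sub <- dataset$subjects[[s]]
    ev <- sub$events$probe[[1]]
    seed <- seed_timecourse(sub$bold$probe[[1]][[seed_roi]])
    target <- rowMeans(sub$bold$probe[[1]][[target_roi]])
    fit <- ppi_fit(seed, ev, target, dataset$config$tr_s,
                   nuisance = sub$nuisance$probe[[1]])
    ac <- ev$cue_role %in% c("A", "C") & !is.na(ev$response_time)
    data.frame(subject = s, beta_precond = fit$beta_precond,
               beta_cond = fit$beta_cond, contrast = fit$contrast,
               rt_precond = mean(ev$response_time[ac]))
  })
  table <- do.call(rbind, rows)
  list(table = table,
       group = group_t(table$contrast, 0, tail = "greater"),
       rt_correlation = connectivity_behavior_correlation(
         table$contrast, table$rt_precond, tail = "less"))
}

#' Behavioral analysis
#'
#' Prediction curves and their cue-by-time repeated-measures ANOVAs
#' (conditioning), probe-phase paired t-tests (B vs D, A vs C) and
#' cue-type-by-reward ANOVA, recognition d-prime, its correlation with
#' inference (A minus C responding), and the last-run binomial exclusion
#' test.
#'
#' @param dataset an `sp_dataset` (or a `behavior_table` from
#'   [simulate_behavior()] plus `recognition` data).
#' @export
analyze_behavior <- function(dataset) {
  subs <- seq_along(dataset$subjects)
  cond_events <- lapply(subs, function(s)
    do.call(rbind, dataset$subjects[[s]]$events$conditioning))
  probe_events <- lapply(subs, function(s)
    dataset$subjects[[s]]$events$probe[[1]])
  # conditioning curves, long format for the RM-ANOVA
  curves <- do.call(rbind, lapply(subs, function(s) {
    cv <- prediction_curves(cond_events[[s]]); cv$subject <- s; cv
  }))
  an_pred <- rm_anova(curves, dv = "pct_reward", subject = "subject",
                      within = c("cue_role", "repetition"))
  an_rt <- rm_anova(curves, dv = "mean_rt", subject = "subject",
                    within = c("cue_role", "repetition"))
  # probe responding per role
  probe_pct <- do.call(rbind, lapply(subs, function(s) {
    ev <- probe_events[[s]]
    ev <- ev[!is.na(ev$response) & ev$response %in% c("plus", "minus"), ]
    agg <- tapply(ev$response == "plus", ev$cue_role, function(v) 100 * mean(v))
    rt <- tapply(ev$response_time, ev$cue_role, mean, na.rm = TRUE)
    data.frame(subject = s, cue_role = names(agg), pct_reward = as.numeric(agg),
               mean_rt = as.numeric(rt[names(agg)]))
  }))
  wide <- function(role, col) probe_pct[probe_pct$cue_role == role, col]
  t_bd <- group_t(wide("B", "pct_reward"), paired_with = wide("D", "pct_reward"))
  t_ac <- group_t(wide("A", "pct_reward"), paired_with = wide("C", "pct_reward"))
  probe_pct$cue_type <- ifelse(probe_pct$cue_role %in% c("A", "C"),
                               "preconditioned", "conditioned")
  probe_pct$reward <- ifelse(probe_pct$cue_role %in% c("A", "B"),
                             "reward", "nonreward")
  an_probe <- rm_anova(probe_pct, dv = "pct_reward", subject = "subject",
                       within = c("cue_type", "reward"))
  an_probe_rt <- rm_anova(probe_pct, dv = "mean_rt", subject = "subject",
                          within = c("cue_type", "reward"))
  # recognition and its link to inference
  dp <- vapply(subs, function(s) {
    rc <- dataset$subjects[[s]]$behavior$recognition
    dprime(rc$hits, rc$misses, rc$false_alarms, rc$correct_rejections)
  }, 0)
  ac_diff <- wide("A", "pct_reward") - wide("C", "pct_reward")
  cor_dprime <- pearson_correlation(dp, ac_diff)
  excl <- exclusion_filter(cond_events)
  list(curves = curves, probe = probe_pct,
       anova_prediction = an_pred, anova_rt = an_rt,
       t_bd = t_bd, t_ac = t_ac,
       anova_probe = an_probe, anova_probe_rt = an_probe_rt,
       d_prime = data.frame(subject = subs, d_prime = dp, ac_diff = ac_diff),
       cor_dprime_inference = cor_dprime, exclusion = excl)
}

#' Run the full pipeline on a configuration
#'
#' Simulates a dataset (unless one is supplied), then runs the similarity,
#' decoding, reactivation, connectivity and behavioral analyses, writing
#' one results table per stage when `out_dir` is given.
#'
#' @param cfg a [sim_config()] (ignored when `dataset` is given).
#' @param out_dir optional output directory for TSV results.
#' @param dataset optional pre-simulated `sp_dataset`.
#' @param decode_rois ROIs for the decoding stages (default: the value
#'   ROI); similarity/reactivation run on all ROIs.
#' @param n_permutations permutations for empirical chance.
#' @return invisible list of all stage results.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = NULL, dataset = NULL,
                         decode_rois = NULL, n_permutations = 10000) {
  dataset <- dataset %||% simulate_dataset(cfg)
  cfg <- dataset$config
  decode_rois <- decode_rois %||% cfg$value_roi
  res <- list()
  res$similarity <- analyze_similarity(dataset)
  res$decoding <- list()
  for (roi in decode_rois) {
    for (scheme in c("bd", "ac", "cross_set")) {
      spec <- decode_spec(scheme = scheme, feature_step = cfg$feature_step[[roi]],
                          n_permutations = n_permutations, seed = cfg$seed)
      res$decoding[[paste(roi, scheme, sep = ".")]] <-
        analyze_decoding(dataset, roi, spec)
    }
  }
  res$reactivation <- list()
  for (roi in names(cfg$rois)) {
    for (variant in c("conditioning_bd", "probe_ac", "probe_ac_daycorrected"))
      res$reactivation[[paste(roi, variant, sep = ".")]] <-
        analyze_reactivation(dataset, roi, variant)
  }
  res$ppi <- analyze_ppi(dataset)
  res$behavior <- analyze_behavior(dataset)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(res$similarity$table, file.path(out_dir, "similarity.tsv"),
                  config = cfg_summary(cfg), seed = cfg$seed)
    dec <- do.call(rbind, lapply(res$decoding, `[[`, "table"))
    write_results(dec, file.path(out_dir, "decoding.tsv"),
                  config = cfg_summary(cfg), seed = cfg$seed)
    rea <- do.call(rbind, lapply(res$reactivation, `[[`, "table"))
    write_results(rea, file.path(out_dir, "reactivation.tsv"),
                  config = cfg_summary(cfg), seed = cfg$seed)
    write_results(res$ppi$table, file.path(out_dir, "connectivity.tsv"),
                  config = cfg_summary(cfg), seed = cfg$seed)
    write_results(res$behavior$curves, file.path(out_dir, "behavior_curves.tsv"),
                  config = cfg_summary(cfg), seed = cfg$seed)
    write_results(res$behavior$probe, file.path(out_dir, "behavior_probe.tsv"),
                  config = cfg_summary(cfg), seed = cfg$seed)
    write_results(stat_table(res), file.path(out_dir, "group_stats.tsv"),
                  config = cfg_summary(cfg), seed = cfg$seed)
  }
  invisible(res)
}

cfg_summary <- function(cfg) {
  out <- cfg[!vapply(cfg, is.list, TRUE)]
  # keep names through JSON: named atomic vectors serialize as objects
  lapply(out, function(v)
    if (!is.null(names(v))) as.list(v) else v)
}

# flatten the group-level statistics of a pipeline result into one table
stat_table <- function(res) {
  rows <- list()
  add <- function(analysis, name, st) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, effect = name,
      statistic = st$statistic, df1 = st$df[1],
      df2 = if (length(st$df) > 1) st$df[2] else NA_real_,
      p = st$p, tail = st$tail,
      epsilon = if (!is.null(st$epsilon)) st$epsilon else NA_real_)
  }
  for (roi in names(res$similarity$tests)) {
    tt <- res$similarity$tests[[roi]]
    add("similarity_trend", roi,
        stat_result(tt$t, tt$df, tt$p, tt$tail))
  }
  for (nm in names(res$decoding)) add("decoding", nm, res$decoding[[nm]]$group)
  for (nm in names(res$reactivation))
    add("reactivation", nm, res$reactivation[[nm]]$group)
  add("ppi", "contrast", res$ppi$group)
  add("ppi", "rt_correlation", res$ppi$rt_correlation)
  bb <- res$behavior
  for (nm in names(bb$anova_prediction))
    add("anova_prediction", nm, bb$anova_prediction[[nm]])
  for (nm in names(bb$anova_probe)) add("anova_probe", nm, bb$anova_probe[[nm]])
  add("probe_t", "B_vs_D", bb$t_bd)
  add("probe_t", "A_vs_C", bb$t_ac)
  add("recognition", "dprime_inference_correlation", bb$cor_dprime_inference)
  do.call(rbind, rows)
}
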