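#' Simulate a complete synthetic sensory-preconditioning dataset
#'
#' Generates, per subject, event tables, voxel-wise BOLD time series per
#' ROI and run, behavioral responses, and a ground-truth record of the
#' planted effects. The planted statistical structure is exactly what the
#' downstream analyses assume:
#'
#' * during preconditioning the patterns of paired cues converge so that
#'   their Fisher-z correlation grows by `similarity_slope` per run while
#'   unpaired cues stay uncorrelated;
#' * from conditioning onward, reward-associated cues (B; A and B in the
#'   probe) add `+value_amplitude * v` and nonreward cues subtract it,
#'   for one fixed random unit "value axis" `v` per subject, in
#'   `value_roi` only;
#' * probe-phase A/C patterns are pulled by `reactivation_gain` toward the
#'   cue's end-of-preconditioning associative state (and conditioning B/D
#'   patterns by `conditioning_reactivation_gain`, default 0);
#' * during the probe run, target-ROI voxels gain coupling to the seed
#'   ROI's mean series that is stronger on preconditioned-cue trials by
#'   `coupling_modulation`;
#' * BOLD = HRF-convolved boxcars times pattern amplitudes plus AR(1)
#'   Gaussian noise; behavior follows saturating learning curves with
#'   recognition d-prime coupled to probe inference.
#'
#' @param cfg a [sim_config()].
#' @param phases phases to generate BOLD for (events and behavior are
#'   always generated); restricting phases speeds up simulations that only
#'   exercise part of the pipeline.
#' @return an `sp_dataset`: `config`, `masks` (one `roi_mask` per ROI) and
#'   `subjects`, each with `events`, `bold`, `nuisance`, `n_volumes`,
#'   `behavior` and `ground_truth`.
#' @export
simulate_dataset <- function(cfg, phases = c("preconditioning",
                                             "conditioning", "probe")) {
  stopifnot(inherits(cfg, "sim_config"))
  masks <- make_roi_masks(cfg)
  subjects <- lapply(seq_len(cfg$n_subjects), function(s)
    simulate_subject(cfg, s, masks, phases = phases))
  structure(list(config = cfg, masks = masks, subjects = subjects),
            class = "sp_dataset")
}

#' @export
print.sp_dataset <- function(x, ...) {
  cat(sprintf("<sp_dataset> %d subjects, ROIs: %s\n", length(x$subjects),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

make_roi_masks <- function(cfg) {
  out <- list()
  offset <- 0
  for (rn in names(cfg$rois)) {
    n <- cfg$rois[[rn]]
    side <- ceiling(n^(1 / 3))
    dims <- c(side, side, max(side, ceiling(n / side^2)))
    aff <- diag(4)
    diag(aff)[1:3] <- cfg$voxel_size_mm
    aff[1, 4] <- offset  # distinct mm origin per region
    offset <- offset + dims[1] * cfg$voxel_size_mm + 20
    out[[rn]] <- roi_mask(rn, dims = dims, voxel_size_mm = rep(cfg$voxel_size_mm, 3),
                          affine = aff, indices = seq_len(n))
  }
  out
}

# scale a vector to norm sqrt(length): per-voxel RMS of 1
nrm <- function(x) unit_vector(x) * sqrt(length(x))

#' Simulate one subject
#'
#' Deterministic given `(cfg, subject)`: every random draw flows from a
#' seed derived from the master seed and the subject index, so datasets
#' can be generated subject-by-subject (streaming) with identical results.
#'
#' @param cfg a [sim_config()].
#' @param subject subject index.
#' @param masks ROI masks from the dataset (rebuilt when omitted).
#' @param phases phases to generate BOLD for.
#' @export
simulate_subject <- function(cfg, subject, masks = NULL,
                             phases = c("preconditioning", "conditioning",
                                        "probe")) {
  masks <- masks %||% make_roi_masks(cfg)
  eff <- subject_effects(cfg, subject)
  beh <- subject_behavior(cfg, subject, eff)
  lat <- with_seed(derive_seed(cfg$seed, "latents", subject),
                   subject_latents(cfg, eff))
  events <- simulate_events(cfg, subject, beh)
  bold <- list(); nuis <- list(); nvols <- list()
  for (phase in phases) {
    bold[[phase]] <- list(); nuis[[phase]] <- list(); nvols[[phase]] <- list()
    for (r in seq_len(cfg$runs[[phase]])) {
      ev <- events[[phase]][[r]]
      nv <- run_length(cfg, phase, ev)
      x <- with_seed(derive_seed(cfg$seed, "nuis", subject, phase, r),
                     slow_nuisance(nv, cfg$tr_s))
      run_bold <- simulate_run_bold(cfg, subject, phase, r, ev, nv, lat, eff)
      bold[[phase]][[r]] <- run_bold
      nuis[[phase]][[r]] <- x
      nvols[[phase]][[r]] <- nv
    }
  }
  gt <- list(similarity_slope = eff$slope, value_amplitude = eff$value,
             reactivation_gain = eff$react, coupling_modulation = eff$coupling,
             conditioning_reactivation_gain = eff$cond_react,
             d_prime = beh$d_prime)
  if (cfg$store_latents) gt$latents <- lat
  list(subject = subject, events = events, bold = bold, nuisance = nuis,
       n_volumes = nvols, behavior = beh, ground_truth = gt)
}

subject_effects <- function(cfg, subject) {
  base <- list(slope = cfg$similarity_slope, value = cfg$value_amplitude,
               react = cfg$reactivation_gain,
               cond_react = cfg$conditioning_reactivation_gain,
               coupling = cfg$coupling_modulation)
  if (!cfg$random_effects) return(base)
  with_seed(derive_seed(cfg$seed, "effects", subject), {
    jitter <- function(v, lo = 0, hi = Inf)
      if (v == 0) 0 else min(max(v * (1 + cfg$effect_cv * rnorm(1)), lo), hi)
    list(slope = jitter(base$slope), value = jitter(base$value),
         react = jitter(base$react, 0, 1),
         cond_react = jitter(base$cond_react, 0, 1),
         coupling = jitter(base$coupling, -Inf, Inf))
  })
}

# Latent cue patterns per ROI. Pair convergence uses a shared "association"
# direction u per pair: cue(r) = cos(theta_r) * identity + sin(theta_r) * u
# with sin^2(theta_r) = tanh(slope * (r - 1)), which makes the expected
# paired correlation tanh(slope*(r-1)), i.e. Fisher-z slope per run, while
# unpaired cues stay uncorrelated.
subject_latents <- function(cfg, eff) {
  R <- cfg$runs[["preconditioning"]]
  lat <- list()
  for (rn in names(cfg$rois)) {
    nv <- cfg$rois[[rn]]
    sets <- seq_len(cfg$n_cue_sets)
    base <- lapply(sets, function(i) list(
      A = rnorm(nv), B = rnorm(nv), C = rnorm(nv), D = rnorm(nv),
      uAB = rnorm(nv), uCD = rnorm(nv)))
    Epat <- lapply(1:4, function(j) nrm(rnorm(nv)))
    v <- unit_vector(rnorm(nv))
    day <- rnorm(nv)
    w <- tanh(eff$slope * (seq_len(R) - 1))
    sinth <- sqrt(w); costh <- sqrt(1 - w)
    precond <- lapply(seq_len(R), function(r) {
      m <- lapply(sets, function(i) {
        b <- base[[i]]
        list(A = nrm(costh[r] * nrm(b$A) + sinth[r] * nrm(b$uAB)),
             B = nrm(costh[r] * nrm(b$B) + sinth[r] * nrm(b$uAB)),
             C = nrm(costh[r] * nrm(b$C) + sinth[r] * nrm(b$uCD)),
             D = nrm(costh[r] * nrm(b$D) + sinth[r] * nrm(b$uCD)))
      })
      names(m) <- sets
      m
    })
    # association-neutral anchor: equally similar to first- and last-run states
    anchor <- lapply(sets, function(i)
      lapply(c(A = "A", B = "B", C = "C", D = "D"), function(ro)
        nrm(precond[[1]][[i]][[ro]] + precond[[R]][[i]][[ro]])))
    val <- function(role) switch(role, A = , B = +1, C = , D = -1) *
      (if (rn == cfg$value_roi) eff$value else 0)
    cond <- lapply(sets, function(i) {
      g <- eff$cond_react
      lapply(c(B = "B", D = "D"), function(ro)
        nrm((1 - g) * anchor[[i]][[ro]] + g * precond[[R]][[i]][[ro]]) +
          val(ro) * v * sqrt(nv))
    })
    probe <- lapply(sets, function(i) {
      out <- list()
      for (ro in c("A", "C")) {
        g <- eff$react
        out[[ro]] <- nrm((1 - g) * anchor[[i]][[ro]] + g * precond[[R]][[i]][[ro]]) +
          val(ro) * v * sqrt(nv)
      }
      for (ro in c("B", "D")) out[[ro]] <- cond[[i]][[ro]]
      out
    })
    lat[[rn]] <- list(precond = precond, cond = cond, probe = probe,
                      E = Epat, value_axis = v, day = day)
  }
  lat
}

run_length <- function(cfg, phase, ev) {
  need <- ceiling((max(ev$onset + ev$duration) + 16) / cfg$tr_s)
  fixed <- cfg$run_volumes[[phase]]
  if (is.null(fixed)) return(need)
  if (fixed < need)
    abort_validation("%s run length (%d volumes) too short for its %d events",
                     phase, fixed, nrow(ev))
  as.integer(fixed)
}

slow_nuisance <- function(n_volumes, tr_s) {
  # a slow, respiration-like confound: low-pass filtered noise, z-scored
  raw <- rnorm(n_volumes + 40)
  k <- stats::dnorm(seq(-20, 20), sd = 8)
  sm <- stats::filter(raw, k / sum(k), sides = 2)
  sm <- sm[21:(20 + n_volumes)]
  matrix(as.numeric(scale(sm)), ncol = 1, dimnames = list(NULL, "resp"))
}

# ---- events ---------------------------------------------------------------

simulate_events <- function(cfg, subject, beh) {
  ev <- list(preconditioning = list(), conditioning = list(), probe = list())
  for (r in seq_len(cfg$runs[["preconditioning"]]))
    ev$preconditioning[[r]] <-
      with_seed(derive_seed(cfg$seed, "ev-pre", subject, r),
                precond_run_events(cfg, r))
  for (r in seq_len(cfg$runs[["conditioning"]]))
    ev$conditioning[[r]] <-
      with_seed(derive_seed(cfg$seed, "ev-cond", subject, r),
                cond_run_events(cfg, r, beh))
  ev$probe[[1]] <- with_seed(derive_seed(cfg$seed, "ev-probe", subject),
                             probe_run_events(cfg, beh))
  ev
}

precond_run_events <- function(cfg, run) {
  ns <- cfg$n_cue_sets
  kind <- c(rep("AB", ns), rep("CD", ns), rep("EE", 4))
  set <- c(seq_len(ns), seq_len(ns), rep(NA_integer_, 4))
  ee <- c(rep(NA_integer_, 2 * ns), 1:4)
  ord <- sample(rep(seq_along(kind), cfg$precond_reps))
  n <- length(ord)
  iti <- runif(n, cfg$iti_range_s[1], cfg$iti_range_s[2])
  start <- cumsum(iti) + 6.3 * (seq_len(n) - 1)     # first-cue onsets
  catch <- kind[ord] != "EE"                        # second symbol differs
  respond <- catch & runif(n) > cfg$nonresponse_rate
  rt0 <- cfg$rt_intercept_s + cfg$rt_run_slope_s * (run - 1)
  rt <- pmax(0.2, rt0 + rnorm(n, sd = cfg$rt_sd_s))
  role1 <- substring(kind[ord], 1, 1)
  role2 <- substring(kind[ord], 2, 2)
  ev <- data.frame(
    onset = as.vector(rbind(start, start + 3.3)),
    duration = 3, phase = "preconditioning", run = run,
    cue_role = as.vector(rbind(role1, role2)),
    cue_set = rep(set[ord], each = 2),
    ee_id = rep(ee[ord], each = 2),
    position_in_pair = rep(c("first", "second"), n),
    outcome = "none",
    response = as.vector(rbind(rep("none", n),
                               ifelse(respond, "pair-different", "none"))),
    press_side = NA_character_,
    response_time = as.vector(rbind(rep(NA_real_, n),
                                    ifelse(respond, rt, NA_real_))),
    stringsAsFactors = FALSE)
  validate_events(ev, "simulated preconditioning run")
}

# saturating learning curve for P(predict reward | cue, repetition)
learning_curve <- function(cfg, role, repetition) {
  asym <- if (role %in% c("B", "A")) cfg$asym_reward else cfg$asym_nonreward
  prog <- 1 - exp(-cfg$learning_rate * repetition)
  0.5 + (asym - 0.5) * prog
}

cond_run_events <- function(cfg, run, beh) {
  cues <- expand.grid(role = c("B", "D"), set = seq_len(cfg$n_cue_sets),
                      rep_in_run = seq_len(cfg$cond_reps),
                      stringsAsFactors = FALSE)
  cues <- cues[sample(nrow(cues)), ]
  n <- nrow(cues)
  iti <- runif(n, cfg$iti_cond_range_s[1], cfg$iti_cond_range_s[2])
  onset <- cumsum(iti) + 3 * (seq_len(n) - 1)
  # repetition index of each individual cue, continuing across runs
  repn <- stats::ave(seq_len(n), paste(cues$role, cues$set), FUN = seq_along) +
    (run - 1L) * cfg$cond_reps
  respond <- runif(n) > cfg$nonresponse_rate
  p_plus <- learning_curve(cfg, "D", repn)
  is_b <- cues$role == "B"
  p_plus[is_b] <- learning_curve(cfg, "B", repn[is_b])
  resp <- ifelse(respond, ifelse(runif(n) < p_plus, "plus", "minus"), "none")
  rt <- pmax(0.2, cfg$rt_intercept_s - 0.015 * (repn - 1) * is_b -
               0.005 * (repn - 1) + rnorm(n, sd = cfg$rt_sd_s))
  ev <- data.frame(
    onset = onset, duration = 1.5, phase = "conditioning", run = run,
    cue_role = cues$role, cue_set = cues$set, ee_id = NA_integer_,
    position_in_pair = NA_character_,
    outcome = ifelse(is_b, "$1", "$0"),
    response = resp,
    press_side = ifelse(respond, sample(c("left", "right"), n, replace = TRUE),
                        NA_character_),
    response_time = ifelse(respond, rt, NA_real_), stringsAsFactors = FALSE)
  validate_events(ev, "simulated conditioning run")
}

probe_run_events <- function(cfg, beh) {
  cues <- expand.grid(role = c("A", "B", "C", "D"),
                      set = seq_len(cfg$n_cue_sets),
                      rep = seq_len(cfg$probe_reps), stringsAsFactors = FALSE)
  cues <- cues[sample(nrow(cues)), ]
  n <- nrow(cues)
  final_rep <- cfg$runs[["conditioning"]] * cfg$cond_reps
  iti <- runif(n, cfg$iti_cond_range_s[1], cfg$iti_cond_range_s[2])
  onset <- cumsum(iti) + 3 * (seq_len(n) - 1)
  p_by_role <- c(
    A = 0.5 + (cfg$asym_reward - 0.5) * beh$inference,
    B = learning_curve(cfg, "B", final_rep),
    C = 0.5 + (cfg$asym_nonreward - 0.5) * beh$inference,
    D = learning_curve(cfg, "D", final_rep))
  p_plus <- p_by_role[as.character(cues$role)]
  respond <- runif(n) > cfg$nonresponse_rate
  resp <- ifelse(respond, ifelse(runif(n) < p_plus, "plus", "minus"), "none")
  infer <- cues$role %in% c("A", "C")
  rt <- pmax(0.2, cfg$rt_intercept_s + cfg$rt_infer_cost_s * infer -
               cfg$rt_coupling_s * beh$coupling_dev * infer +
               rnorm(n, sd = cfg$rt_sd_s))
  ev <- data.frame(
    onset = onset, duration = 1.5, phase = "probe", run = 1L,
    cue_role = as.character(cues$role), cue_set = cues$set,
    ee_id = NA_integer_, position_in_pair = NA_character_, outcome = "none",
    response = resp,
    press_side = ifelse(respond, sample(c("left", "right"), n, replace = TRUE),
                        NA_character_),
    response_time = ifelse(respond, rt, NA_real_), stringsAsFactors = FALSE)
  validate_events(ev, "simulated probe run")
}

# ---- behavior -------------------------------------------------------------

subject_behavior <- function(cfg, subject, eff) {
  with_seed(derive_seed(cfg$seed, "behavior", subject), {
    d_prime <- rnorm(1, cfg$dprime_mean, cfg$dprime_sd)
    inference <- stats::plogis(cfg$inference_intercept +
                                 cfg$dprime_coupling * d_prime)
    n_old <- cfg$n_recognition_old; n_new <- cfg$n_recognition_recombined
    hits <- rbinom(1, n_old, pnorm(d_prime / 2))
    fas <- rbinom(1, n_new, pnorm(-d_prime / 2))
    coupling_dev <- eff$coupling - cfg$coupling_modulation
    list(d_prime = d_prime, inference = inference,
         coupling_dev = coupling_dev,
         recognition = data.frame(hits = hits, misses = n_old - hits,
                                  false_alarms = fas,
                                  correct_rejections = n_new - fas))
  })
}

#' Simulate behavior alone
#'
#' Generates trial-level behavioral data (conditioning and probe
#' responses, recognition counts) for `n_subjects` without any imaging,
#' using the same response model as [simulate_dataset()].
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return a `behavior_table`: `trials` (long data.frame over subjects),
#'   `recognition`, and `subjects` (latent d-prime and inference levels).
#' @export
simulate_behavior <- function(cfg, seed = cfg$seed) {
  cfg$seed <- as.integer(seed)
  trials <- list(); recog <- list(); subj <- list()
  for (s in seq_len(cfg$n_subjects)) {
    eff <- subject_effects(cfg, s)
    beh <- subject_behavior(cfg, s, eff)
    ev <- simulate_events(cfg, s, beh)
    tr <- rbind(do.call(rbind, ev$conditioning), do.call(rbind, ev$probe))
    tr$subject <- s
    trials[[s]] <- tr
    rc <- beh$recognition; rc$subject <- s
    recog[[s]] <- rc
    subj[[s]] <- data.frame(subject = s, d_prime = beh$d_prime,
                            inference = beh$inference)
  }
  structure(list(trials = do.call(rbind, trials),
                 recognition = do.call(rbind, recog),
                 subjects = do.call(rbind, subj)),
            class = "behavior_table")
}

# ---- BOLD -----------------------------------------------------------------

# amplitude pattern for each modeled condition of a run, in one ROI
condition_pattern_matrix <- function(cfg, phase, run, ev, lab, uniq, lat_roi) {
  R <- cfg$runs[["preconditioning"]]
  day2 <- switch(phase, preconditioning = run > R / 2, TRUE)
  day_add <- if (day2 && cfg$day_effect_sd > 0)
    cfg$day_effect_sd * lat_roi$day else 0
  get_pat <- function(i) {
    role <- ev$cue_role[i]; set <- ev$cue_set[i]
    p <- if (role == "E") lat_roi$E[[ev$ee_id[i]]]
    else switch(phase,
                preconditioning = lat_roi$precond[[run]][[set]][[role]],
                conditioning = lat_roi$cond[[set]][[role]],
                probe = lat_roi$probe[[set]][[role]])
    p + day_add
  }
  t(vapply(uniq, function(u) get_pat(which(lab == u)[1]),
           numeric(length(lat_roi$value_axis))))
}

simulate_run_bold <- function(cfg, subject, phase, run, ev, n_volumes, lat, eff) {
  out <- list()
  seed_base <- derive_seed(cfg$seed, "bold", subject, phase, run)
  lab <- condition_labels(ev, switch(phase, preconditioning = "precond_perset",
                                     conditioning = "cond_perset", "probe"))
  uniq <- unique(lab)
  # the convolved design is shared by all ROIs of the run
  X <- vapply(uniq, function(u) {
    sel <- lab == u
    convolve_events(ev$onset[sel], ev$duration[sel], n_volumes, cfg$tr_s)
  }, numeric(n_volumes))
  # deterministic order so the probe-phase coupling can reference the seed ROI
  roi_order <- unique(c(cfg$ppi_seed_roi, names(cfg$rois)))
  seed_series <- NULL
  for (rn in roi_order) {
    P <- condition_pattern_matrix(cfg, phase, run, ev, lab, uniq, lat[[rn]])
    signal <- cfg$signal_amplitude * (X %*% P)
    noise <- with_seed(derive_seed(seed_base, rn), {
      innov <- matrix(rnorm(n_volumes * cfg$rois[[rn]],
                            sd = cfg$noise_sd * sqrt(1 - cfg$ar1^2)),
                      n_volumes, cfg$rois[[rn]])
      if (cfg$ar1 > 0) {
        f <- stats::filter(innov, cfg$ar1, method = "recursive")
        matrix(as.numeric(f), n_volumes, cfg$rois[[rn]])
      } else innov
    })
    bold <- signal + noise
    if (phase == "probe" && rn == cfg$ppi_target_roi && !is.null(seed_series)) {
      pre <- ev$cue_role %in% c("A", "C")
      x_pre <- convolve_events(ev$onset[pre], ev$duration[pre], n_volumes, cfg$tr_s)
      x_pre <- x_pre / max(x_pre)
      gain <- cfg$coupling_base + eff$coupling * x_pre
      bold <- bold + (gain * seed_series) %o% rep(1, cfg$rois[[rn]])
    }
    if (phase == "probe" && rn == cfg$ppi_seed_roi) {
      s <- rowMeans(bold)
      seed_series <- s - mean(s)
    }
    out[[rn]] <- bold
  }
  out[names(cfg$rois)]
}
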