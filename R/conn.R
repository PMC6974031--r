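#' Seed time course: mean-centered ROI-average BOLD
#'
#' @param bold volumes x voxels matrix of the seed region (already
#'   restricted to the mask's voxels), or a full-lattice matrix together
#'   with `mask`.
#' @param mask optional `roi_mask`; when supplied, `bold` columns are the
#'   full lattice and the mask's voxels are averaged.
#' @return centered numeric vector, one value per volume.
#' @export
seed_timecourse <- function(bold, mask = NULL) {
  bold <- as.matrix(bold)
  if (!is.null(mask)) {
    if (max(mask$indices) > ncol(bold))
      abort_validation("mask indices exceed BOLD voxel count")
    bold <- bold[, mask$indices, drop = FALSE]
  }
  if (ncol(bold) == 0) abort_validation("empty seed mask")
  s <- rowMeans(bold)
  s - mean(s)
}

#' Psychophysiological interaction model
#'
#' BOLD-level generalized-PPI column structure: HRF-convolved psychological
#' regressors for preconditioned-cue (A/C) and conditioned-cue (B/D)
#' trials, the physiological seed series, one interaction column per
#' condition (seed series times the convolved condition regressor),
#' button-press regressors, nuisance columns and a constant. No
#' deconvolution to the neural level is attempted (deliberate
#' simplification; see the package vignette).
#'
#' @param seed centered seed time course (one value per volume).
#' @param events probe-phase event table.
#' @param target_bold volumes x voxels matrix (or a single series) of the
#'   target region.
#' @param tr_s repetition time.
#' @param nuisance optional nuisance matrix.
#' @return a `ppi_estimate`: `beta_precond`, `beta_cond` (per target
#'   voxel), `contrast` (= beta_precond - beta_cond).
#' @export
ppi_fit <- function(seed, events, target_bold, tr_s, nuisance = NULL) {
  target_bold <- as.matrix(target_bold)
  n_vol <- nrow(target_bold)
  if (length(seed) != n_vol)
    abort_validation("seed series length (%d) != target volumes (%d)",
                     length(seed), n_vol)
  ev <- data.table::as.data.table(events)
  pre <- ev[ev$cue_role %in% c("A", "C"), ]
  con <- ev[ev$cue_role %in% c("B", "D"), ]
  if (nrow(pre) == 0 || nrow(con) == 0)
    abort_validation("PPI needs both preconditioned and conditioned cue trials")
  x_pre <- convolve_events(pre$onset, pre$duration, n_vol, tr_s)
  x_con <- convolve_events(con$onset, con$duration, n_vol, tr_s)
  if (all(seed == 0)) {
    # degenerate physiological input: no coupling estimable, by convention 0
    z <- rep(0, ncol(target_bold))
    return(structure(list(beta_precond = z, beta_cond = z, contrast = z),
                     class = "ppi_estimate"))
  }
  X <- cbind(psy_precond = x_pre, psy_cond = x_con, phys = seed,
             ppi_precond = seed * x_pre, ppi_cond = seed * x_con)
  if ("press_side" %in% names(ev)) {
    for (side in c("left", "right")) {
      sel <- !is.na(ev$press_side) & ev$press_side == side
      if (any(sel))
        X <- cbind(X, convolve_events(ev$onset[sel], rep(1e-3, sum(sel)),
                                      n_vol, tr_s))
    }
  }
  if (!is.null(nuisance)) X <- cbind(X, as.matrix(nuisance))
  X <- cbind(X, constant = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    abort_validation("rank-deficient PPI design")
  beta <- qr.coef(qrX, target_bold)
  bp <- beta["ppi_precond", ]
  bc <- beta["ppi_cond", ]
  structure(list(beta_precond = bp, beta_cond = bc, contrast = bp - bc),
            class = "ppi_estimate")
}

#' Correlation between connectivity modulation and behavior
#'
#' Pearson correlation (two-tailed by default) between per-subject PPI
#' contrasts and a behavioral measure such as probe-phase response time.
#'
#' @param contrasts per-subject connectivity contrasts.
#' @param behavior per-subject behavioral values.
#' @param tail `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a `stat_result` from [pearson_correlation()].
#' @export
connectivity_behavior_correlation <- function(contrasts, behavior,
                                              tail = "two.sided") {
  pearson_correlation(contrasts, behavior, tail = tail)
}
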