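#' Canonical double-gamma hemodynamic response function
#'
#' SPM-convention double gamma: response peak at 6 s, undershoot peaking at
#' 16 s, peak-to-undershoot ratio 6, sampled on `[0, duration]` at `dt` and
#' peak-normalized to 1. No temporal or dispersion derivatives.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param duration kernel length in seconds (default 32).
#' @return numeric vector of kernel samples at `seq(0, duration, by = dt)`.
#' @export
canonical_hrf <- function(dt, duration = 32) {
  if (!is.numeric(dt) || dt <= 0) abort_validation("dt must be > 0")
  peak_time <- 5  # mode of the gamma(shape=6, rate=1) response lobe
  if (duration < peak_time)
    abort_validation("HRF duration (%.1f s) shorter than response peak", duration)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Convolve event boxcars with the canonical HRF on a microtime grid and
# sample at volume midpoints. Onsets need not align with the TR.
convolve_events <- function(onsets, durations, n_volumes, tr_s, dt = 0.1,
                            amplitudes = NULL) {
  if (is.null(amplitudes)) amplitudes <- rep(1, length(onsets))
  t_max <- n_volumes * tr_s + 32
  n_micro <- ceiling(t_max / dt)
  box <- numeric(n_micro)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- max(a, ceiling((onsets[i] + durations[i]) / dt))
    box[a:b] <- box[a:b] + amplitudes[i]
  }
  kern <- canonical_hrf(dt)
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_micro)] * dt
  conv[abs(conv) < 1e-10] <- 0       # FFT roundoff outside the support
  mid <- (seq_len(n_volumes) - 0.5) * tr_s
  conv[pmin(n_micro, floor(mid / dt) + 1)]
}

# Condition labels for each event row under a GLM scheme.
condition_labels <- function(events, scheme) {
  role <- events$cue_role
  set <- if ("cue_set" %in% names(events)) events$cue_set else rep(NA, nrow(events))
  e_lab <- if ("ee_id" %in% names(events) && !all(is.na(events$ee_id)))
    paste0("E", events$ee_id) else rep("E", length(role))
  switch(scheme,
    precond = ifelse(role == "E", "E", role),
    precond_perset = ifelse(role == "E", e_lab, paste0(role, set)),
    cond = role,
    cond_perset = paste0(role, set),
    probe = paste0(role, set),
    abort_validation("unknown GLM scheme '%s'", scheme)
  )
}

#' Build a first-level design matrix
#'
#' One HRF-convolved boxcar column per modeled condition, plus optional
#' event regressors (outcome onsets, left/right button presses as 0-duration
#' events), nuisance columns appended unmodified, and a constant column.
#'
#' Schemes follow the three task phases: `"precond"` models pooled cue roles
#' A,B,C,D (plus a control-pair column E when control trials are present);
#' `"precond_perset"` models each role-by-set cue separately;
#' `"cond"` models cues B and D plus outcome and press regressors;
#' `"cond_perset"` models B1..B8, D1..D8 plus outcome and presses;
#' `"probe"` models each of the 32 cues separately plus presses.
#'
#' @param events event table for one run.
#' @param n_volumes number of volumes in the run.
#' @param tr_s repetition time (s).
#' @param scheme regressor scheme, see Details.
#' @param nuisance optional numeric matrix (volumes x k) appended unmodified.
#' @param conditions optional explicit condition labels; any requested
#'   condition without events is an error.
#' @param outcome_duration_s duration used for the outcome-onset regressor
#'   (default 0: an impulse event).
#' @return a `design_matrix` object: `X` (volumes x regressors), `names`,
#'   `condition_cols` (indices of regressors of interest), `tr_s`.
#' @export
build_design <- function(events, n_volumes, tr_s, scheme = "precond",
                         nuisance = NULL, conditions = NULL,
                         outcome_duration_s = 0) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) > 0 && max(ev$onset + ev$duration) > n_volumes * tr_s)
    abort_validation("events extend past the scan window (%g s > %g s)",
                     max(ev$onset + ev$duration), n_volumes * tr_s)
  cols <- list(); nms <- character(0); interest <- character(0)
  if (nrow(ev) > 0) {
    lab <- condition_labels(ev, scheme)
    want <- conditions %||% unique(lab)
    empty <- setdiff(want, lab)
    if (length(empty))
      abort_validation("condition(s) with no events: %s", paste(empty, collapse = ", "))
    for (cc in want) {
      sel <- lab == cc
      cols[[length(cols) + 1L]] <-
        convolve_events(ev$onset[sel], ev$duration[sel], n_volumes, tr_s)
      nms <- c(nms, cc)
    }
    interest <- want[!grepl("^E", want)]
    # auxiliary event regressors for conditioning/probe phases
    if (scheme %in% c("cond", "cond_perset") && "outcome" %in% names(ev)) {
      sel <- !is.na(ev$outcome) & ev$outcome != "none"
      if (any(sel)) {
        ons <- ev$onset[sel] + ev$duration[sel]
        cols[[length(cols) + 1L]] <- convolve_events(
          ons, rep(max(outcome_duration_s, 1e-3), sum(sel)), n_volumes, tr_s)
        nms <- c(nms, "outcome")
      }
    }
    if (scheme %in% c("cond", "cond_perset", "probe") && "press_side" %in% names(ev)) {
      for (side in c("left", "right")) {
        sel <- !is.na(ev$press_side) & ev$press_side == side
        if (any(sel)) {
          rt <- if ("response_time" %in% names(ev))
            ifelse(is.na(ev$response_time[sel]), 0, ev$response_time[sel]) else 0
          cols[[length(cols) + 1L]] <- convolve_events(
            ev$onset[sel] + rt, rep(1e-3, sum(sel)), n_volumes, tr_s)
          nms <- c(nms, paste0("press_", side))
        }
      }
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = n_volumes, ncol = 0)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes)
      abort_validation("nuisance rows (%d) != volumes (%d)", nrow(nuisance), n_volumes)
    nn <- colnames(nuisance) %||% paste0("nuis_", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance); nms <- c(nms, nn)
  }
  X <- cbind(X, 1); nms <- c(nms, "constant")
  colnames(X) <- nms
  structure(list(X = X, names = nms,
                 condition_cols = match(interest, nms),
                 condition_names = interest, tr_s = tr_s),
            class = "design_matrix")
}

#' Fit an ordinary least squares GLM and compute condition t-maps
#'
#' Per-voxel OLS with condition-versus-baseline contrasts:
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` with
#' `sigma2 = RSS / (volumes - rank(X))`.
#'
#' @param bold numeric matrix, volumes x voxels.
#' @param design a `design_matrix`.
#' @param conditions condition names to report (default: all regressors of
#'   interest).
#' @return a `pattern_estimates` object: `beta` and `t` (conditions x
#'   voxels), `df`, and `labels` (a data.frame parsed from condition names).
#' @export
fit_glm <- function(bold, design, conditions = NULL) {
  X <- design$X
  bold <- as.matrix(bold)
  if (nrow(bold) != nrow(X))
    abort_validation("BOLD volumes (%d) != design rows (%d)", nrow(bold), nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- design$names[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort_validation("rank-deficient design; collinear column(s): %s",
                     paste(bad, collapse = ", "))
  }
  if (qrX$rank >= nrow(X))
    abort_validation("design has no residual degrees of freedom")
  beta_all <- qr.coef(qrX, bold)
  resid <- bold - X %*% beta_all
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  conditions <- conditions %||% design$condition_names
  ci <- match(conditions, design$names)
  if (anyNA(ci))
    abort_validation("unknown condition(s): %s",
                     paste(conditions[is.na(ci)], collapse = ", "))
  beta <- beta_all[ci, , drop = FALSE]
  se <- sqrt(outer(diag(XtXinv)[ci], sigma2))
  tmap <- beta / se
  tmap[se == 0] <- 0
  rownames(beta) <- rownames(tmap) <- conditions
  structure(list(beta = beta, t = tmap, df = df,
                 labels = parse_condition_labels(conditions)),
            class = "pattern_estimates")
}

parse_condition_labels <- function(conditions) {
  role <- sub("^([A-E]).*$", "\\1", conditions)
  set <- suppressWarnings(as.integer(sub("^[A-E]", "", conditions)))
  data.frame(condition = conditions, cue_role = role, cue_set = set,
             stringsAsFactors = FALSE)
}
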