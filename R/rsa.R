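#' Fisher-z transformed Pearson similarity between two voxel patterns
#'
#' `atanh(cor(x, y))`. Correlations at or beyond `1 - 1e-12` in magnitude
#' (e.g. a pattern compared with itself) are clamped before the transform
#' and flagged via the `"clamped"` attribute, so the result is always
#' finite.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Fisher-z value (scalar).
#' @export
z_similarity <- function(x, y) {
  if (length(x) != length(y)) abort_validation("patterns differ in length")
  if (length(x) < 3) abort_validation("patterns must have length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    abort_validation("zero-variance pattern in similarity computation")
  r <- cor(x, y)
  clamped <- FALSE
  lim <- 1 - 1e-12
  if (abs(r) >= lim) { r <- sign(r) * lim; clamped <- TRUE }
  z <- atanh(r)
  if (clamped) attr(z, "clamped") <- TRUE
  z
}

#' Paired-minus-unpaired similarity trajectory across preconditioning runs
#'
#' For each run, computes the mean Fisher-z similarity between patterns of
#' paired cues (A with B, C with D) and between unpaired cues (A with D,
#' C with B), and their difference `delta`. With per-set patterns (labels
#' carrying `cue_set`), pairing is within cue set and the z values are
#' averaged over the 8 sets (Fisher-z first, then average); with pooled
#' role patterns there are two pairs of each kind. Control (E) patterns are
#' ignored.
#'
#' @param estimates_by_run list of `pattern_estimates`, one per run, all on
#'   the same voxel set.
#' @param measure `"t"` (default) or `"beta"`.
#' @param pairing list with `within` and `between` role pairs; the default
#'   is the sensory-preconditioning design.
#' @return data.frame with columns `run`, `z_within`, `z_between`, `delta`.
#' @export
paired_contrast_trajectory <- function(estimates_by_run, measure = "t",
                                       pairing = list(
                                         within = list(c("A", "B"), c("C", "D")),
                                         between = list(c("A", "D"), c("C", "B")))) {
  res <- lapply(seq_along(estimates_by_run), function(r) {
    est <- estimates_by_run[[r]]
    pat <- est[[measure]]
    lab <- est$labels
    pick <- function(role, set) {
      if (is.na(set)) sel <- which(lab$cue_role == role & is.na(lab$cue_set))
      else sel <- which(lab$cue_role == role & !is.na(lab$cue_set) & lab$cue_set == set)
      if (length(sel) != 1)
        abort_validation("run %d: missing or ambiguous pattern for role %s set %s",
                         r, role, set)
      pat[sel, ]
    }
    per_set <- any(!is.na(lab$cue_set[lab$cue_role %in% c("A", "B", "C", "D")]))
    sets <- if (per_set)
      sort(unique(lab$cue_set[!is.na(lab$cue_set)])) else NA
    mean_z <- function(role_pairs) {
      zs <- unlist(lapply(sets, function(s)
        vapply(role_pairs, function(rp)
          as.numeric(z_similarity(pick(rp[1], s), pick(rp[2], s))), 0)))
      mean(zs)
    }
    data.frame(run = r, z_within = mean_z(pairing$within),
               z_between = mean_z(pairing$between))
  })
  out <- do.call(rbind, res)
  out$delta <- out$z_within - out$z_between
  out
}

#' One-sample test on per-subject linear trends across runs
#'
#' Fits a least-squares slope against the centered run index for every
#' subject and tests the slopes against zero with a one-sample t-test.
#' A degenerate case (all slopes identical and nonzero) yields `t = Inf`
#' with the smallest representable p rather than an error.
#'
#' @param values matrix, subjects x runs (e.g. per-run `delta`).
#' @param tail `"greater"` (default, directed increase), `"less"` or
#'   `"two.sided"`.
#' @return list with `slopes` (per subject), `t`, `df`, `p`, `tail`.
#' @export
linear_trend_test <- function(values, tail = "greater") {
  values <- as.matrix(values)
  if (ncol(values) < 2) abort_validation("need >= 2 runs for a trend")
  if (nrow(values) < 2) abort_validation("need >= 2 subjects")
  x <- seq_len(ncol(values)) - (ncol(values) + 1) / 2
  if (all(x == 0)) abort_validation("constant run index")
  slopes <- drop(values %*% x) / sum(x^2)
  n <- length(slopes)
  s <- sd(slopes)
  if (s == 0) {
    t <- if (mean(slopes) == 0) 0 else sign(mean(slopes)) * Inf
    p <- if (t == 0) 1 else .Machine$double.xmin
    if (tail == "greater" && t < 0) p <- 1
    if (tail == "less" && t > 0) p <- 1
    return(list(slopes = slopes, t = t, df = n - 1L, p = p, tail = tail))
  }
  t <- mean(slopes) / (s / sqrt(n))
  p <- switch(tail,
              greater = pt(t, n - 1, lower.tail = FALSE),
              less = pt(t, n - 1),
              two.sided = 2 * pt(abs(t), n - 1, lower.tail = FALSE),
              abort_validation("unknown tail '%s'", tail))
  list(slopes = slopes, t = t, df = n - 1L, p = max(p, .Machine$double.xmin),
       tail = tail)
}

#' Reactivation contrast: template similarity to late versus early patterns
#'
#' For each requested cue role, computes
#' `z(template, last-run pattern) - z(template, first-run pattern)` and
#' averages over roles. Used with probe-test templates against the first
#' and last preconditioning run (roles A and C), or conditioning templates
#' (roles B and D).
#'
#' @param template named list of template patterns (one vector per role).
#' @param first,last named lists of first-run / last-run patterns.
#' @param roles roles to average over.
#' @return list with `value` (scalar contrast), `per_role`.
#' @export
reactivation_contrast <- function(template, first, last, roles = c("A", "C")) {
  per_role <- vapply(roles, function(ro) {
    tv <- template[[ro]]; fv <- first[[ro]]; lv <- last[[ro]]
    if (is.null(tv) || is.null(fv) || is.null(lv))
      abort_validation("missing pattern for role %s", ro)
    if (length(unique(c(length(tv), length(fv), length(lv)))) != 1)
      abort_validation("voxel-set mismatch for role %s", ro)
    as.numeric(z_similarity(tv, lv)) - as.numeric(z_similarity(tv, fv))
  }, 0)
  list(value = mean(per_role), per_role = per_role, roles = roles)
}

#' Scan-day-corrected reactivation contrast
#'
#' Subtracts the same first/last contrast computed on unrelated cue pairs
#' (e.g. the A template against C patterns), removing additive scan-day
#' effects shared by all day-2 patterns. Control pairs must pair different
#' roles; pairing a role with itself would subtract the effect of interest.
#'
#' @param template,first,last as in [reactivation_contrast()].
#' @param target_roles roles of the contrast of interest.
#' @param control_pairs list of `c(template_role, pattern_role)` pairs.
#' @return list with `corrected`, `target`, `control`.
#' @export
scanday_corrected_contrast <- function(template, first, last,
                                       target_roles = c("A", "C"),
                                       control_pairs = list(c("A", "C"), c("C", "A"))) {
  for (cp in control_pairs)
    if (cp[1] == cp[2])
      abort_validation("control pair (%s,%s) overlaps the target association",
                       cp[1], cp[2])
  target <- reactivation_contrast(template, first, last, target_roles)$value
  ctrl <- mean(vapply(control_pairs, function(cp) {
    as.numeric(z_similarity(template[[cp[1]]], last[[cp[2]]])) -
      as.numeric(z_similarity(template[[cp[1]]], first[[cp[2]]]))
  }, 0))
  list(corrected = target - ctrl, target = target, control = ctrl)
}
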