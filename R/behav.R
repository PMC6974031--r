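stat_result <- function(statistic, df, p, tail, epsilon = NA_real_,
                        extra = list()) {
  structure(c(list(statistic = statistic, df = df,
                   p = max(min(p, 1), .Machine$double.xmin),
                   tail = tail, epsilon = epsilon), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("stat = %.4f, df = %s, p = %.4g (%s)%s\n", x$statistic, dfs,
              x$p, x$tail,
              if (!is.na(x$epsilon)) sprintf(", GG eps = %.3f", x$epsilon) else ""))
  invisible(x)
}

#' One-sample / paired t-test
#'
#' One-sample t of `values - mu0`, or of paired differences when
#' `paired_with` is given. Zero variance is an error, never p = 0.
#'
#' @param values numeric vector.
#' @param mu0 null value.
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @param paired_with optional second vector for a paired test.
#' @return a `stat_result` with fields `statistic`, `df`, `p`, `tail`.
#' @export
group_t <- function(values, mu0 = 0, tail = "two.sided", paired_with = NULL) {
  if (!is.null(paired_with)) {
    if (length(paired_with) != length(values))
      abort_validation("paired vectors differ in length")
    values <- values - paired_with
  }
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort_validation("need n >= 2 for a t-test")
  s <- sd(values)
  if (s == 0) abort_validation("zero variance in t-test input")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  p <- switch(tail,
              greater = pt(t, n - 1, lower.tail = FALSE),
              less = pt(t, n - 1),
              two.sided = 2 * pt(abs(t), n - 1, lower.tail = FALSE),
              abort_validation("unknown tail '%s'", tail))
  stat_result(t, n - 1L, p, tail, extra = list(mean = mean(values), n = n))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance).
#' @param tail `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a `stat_result`; the coefficient is in `$r`.
#' @export
pearson_correlation <- function(x, y, tail = "two.sided") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort_validation("need n >= 3 for a correlation")
  if (sd(x) == 0 || sd(y) == 0)
    abort_validation("zero variance in correlation input")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- switch(tail,
                greater = if (t > 0) .Machine$double.xmin else 1,
                less = if (t < 0) .Machine$double.xmin else 1,
                .Machine$double.xmin)
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- switch(tail,
                greater = pt(t, n - 2, lower.tail = FALSE),
                less = pt(t, n - 2),
                two.sided = 2 * pt(abs(t), n - 2, lower.tail = FALSE),
                abort_validation("unknown tail '%s'", tail))
  }
  stat_result(t, n - 2L, p, tail, extra = list(r = r, n = n))
}

#' Discrimination sensitivity (d-prime) with log-linear correction
#'
#' `qnorm(hit rate) - qnorm(false-alarm rate)` where the rates always
#' receive the log-linear correction (0.5 added to each cell, 1 to each
#' denominator), so perfect or zero rates yield finite values.
#'
#' @param hits,misses,false_alarms,correct_rejections nonnegative counts.
#' @return d-prime (scalar).
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) abort_validation("negative counts")
  n_old <- hits + misses
  n_new <- false_alarms + correct_rejections
  if (n_old < 1 || n_new < 1)
    abort_validation("need >= 1 old and >= 1 recombined trial")
  hr <- (hits + 0.5) / (n_old + 1)
  fa <- (false_alarms + 0.5) / (n_new + 1)
  qnorm(hr) - qnorm(fa)
}

# Orthonormal polynomial-free contrast basis for a k-level within factor.
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  qr.Q(qr(m))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One or two within-subject factors on a complete balanced design. For
#' each effect, F is computed from orthonormalized contrast scores and the
#' Greenhouse-Geisser epsilon from the covariance of those scores;
#' corrected (possibly fractional) degrees of freedom and p-values are
#' reported. With a single two-level factor, F equals the square of the
#' paired t statistic.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject-id column.
#' @param within character vector of one or two within-factor columns.
#' @return named list of `stat_result`s (one per main effect, plus the
#'   interaction for two factors); each carries uncorrected df in
#'   `$df_uncorrected` and epsilon in `$epsilon`.
#' @export
rm_anova <- function(data, dv, subject, within) {
  if (!length(within) %in% 1:2)
    abort_validation("rm_anova supports 1 or 2 within factors")
  d <- data.table::as.data.table(data)
  for (col in c(dv, subject, within))
    if (!col %in% names(d)) abort_validation("missing column '%s'", col)
  fac <- lapply(within, function(w) sort(unique(d[[w]])))
  names(fac) <- within
  subj <- sort(unique(d[[subject]]))
  cells <- do.call(data.table::CJ, c(fac, list(s = subj)))
  # cell means per subject, in a fixed factor order
  form_key <- c(within, "s")
  d2 <- d[, .(.m = mean(.SD[[1]])), by = c(subject, within), .SDcols = dv]
  data.table::setnames(d2, subject, "s")
  merged <- merge(cells, d2, by = form_key, all.x = TRUE)
  if (anyNA(merged$.m)) abort_validation("missing cells in within-subject design")
  data.table::setorderv(merged, c("s", within))
  k <- prod(vapply(fac, length, 0L))
  n <- length(subj)
  if (n < 2) abort_validation("need >= 2 subjects")
  Y <- matrix(merged$.m, nrow = n, ncol = k, byrow = TRUE)
  # contrast matrices per effect (Kronecker structure, first factor slowest)
  basis <- lapply(fac, function(v) orthonormal_contrasts(length(v)))
  ones <- lapply(fac, function(v) matrix(1 / sqrt(length(v)), length(v), 1))
  effects <- list()
  if (length(within) == 1) {
    effects[[within[1]]] <- basis[[1]]
  } else {
    effects[[within[1]]] <- kronecker(basis[[1]], ones[[2]])
    effects[[within[2]]] <- kronecker(ones[[1]], basis[[2]])
    effects[[paste(within, collapse = ":")]] <- kronecker(basis[[1]], basis[[2]])
  }
  out <- list()
  for (nm in names(effects)) {
    M <- effects[[nm]]
    S <- Y %*% M                       # subjects x q contrast scores
    q <- ncol(S)
    mbar <- colMeans(S)
    ss_eff <- n * sum(mbar^2)
    resid <- sweep(S, 2, mbar)
    ss_err <- sum(resid^2)
    df1 <- q
    df2 <- q * (n - 1)
    Sigma <- crossprod(resid) / (n - 1)
    eps <- if (sum(Sigma^2) == 0) 1 else
      sum(diag(Sigma))^2 / (q * sum(Sigma^2))
    # guard degenerate cases against pure floating-point roundoff
    ref <- max(sum((Y - mean(Y))^2), .Machine$double.eps)
    if (ss_eff < 1e-12 * ref) ss_eff <- 0
    if (ss_err < 1e-12 * ref) ss_err <- 0
    F <- if (ss_eff == 0) 0 else if (ss_err == 0) Inf else
      (ss_eff / df1) / (ss_err / df2)
    p <- if (F == 0) 1 else if (!is.finite(F)) .Machine$double.xmin else
      pf(F, df1 * eps, df2 * eps, lower.tail = FALSE)
    out[[nm]] <- stat_result(F, c(df1 * eps, df2 * eps), p, "two.sided",
                             epsilon = eps,
                             extra = list(df_uncorrected = c(df1, df2),
                                          p_uncorrected = pf(F, df1, df2,
                                                             lower.tail = FALSE)))
  }
  out
}

#' Reward-prediction curves from conditioning or probe events
#'
#' For each cue role and repetition, the percentage of responded trials on
#' which the participant predicted reward (`response == "plus"`), pooled
#' over the 8 cues of a type, plus mean response times. Non-response
#' trials are excluded from the denominator. Repetition is the occurrence
#' index of each individual cue (role x set) across runs.
#'
#' @param events event table (one subject, one phase, possibly several
#'   runs concatenated in run order).
#' @return data.frame with `cue_role`, `repetition`, `n`, `pct_reward`,
#'   `mean_rt`.
#' @export
prediction_curves <- function(events) {
  ev <- data.table::as.data.table(events)
  if (!"response" %in% names(ev))
    abort_validation("events have no response column")
  ev <- ev[ev$cue_role %in% c("A", "B", "C", "D"), ]
  key <- paste(ev$cue_role, ev$cue_set)
  ev$repetition <- stats::ave(seq_len(nrow(ev)), key, FUN = seq_along)
  responded <- !is.na(ev$response) & ev$response %in% c("plus", "minus")
  if (!any(responded)) abort_validation("all trials are non-response")
  ev <- ev[responded, ]
  agg <- ev[, .(n = .N,
                pct_reward = 100 * mean(response == "plus"),
                mean_rt = mean(response_time, na.rm = TRUE)),
            by = .(cue_role, repetition)]
  data.table::setorderv(agg, c("cue_role", "repetition"))
  as.data.frame(agg)
}

#' Behavioral exclusion by last-run conditioning performance
#'
#' Subjects are retained when their correct predictions in the final
#' conditioning run (reward predicted after B, nonreward after D) beat
#' chance in a one-tailed binomial test at `alpha` (default 0.05).
#' Non-response trials count as incorrect is avoided: they are dropped
#' from both numerator and denominator.
#'
#' @param events_by_subject list of per-subject conditioning event tables
#'   (all runs; the last run is selected via the `run` column).
#' @param alpha significance level.
#' @return data.frame with `subject`, `n_trials`, `n_correct`, `p`,
#'   `retained`.
#' @export
exclusion_filter <- function(events_by_subject, alpha = 0.05) {
  rows <- lapply(seq_along(events_by_subject), function(s) {
    ev <- data.table::as.data.table(events_by_subject[[s]])
    if (!"run" %in% names(ev)) abort_validation("events need a run column")
    ev <- ev[ev$run == max(ev$run), ]
    ev <- ev[!is.na(ev$response) & ev$response %in% c("plus", "minus"), ]
    if (nrow(ev) == 0) abort_validation("subject %d has no last-run trials", s)
    correct <- (ev$cue_role == "B" & ev$response == "plus") |
      (ev$cue_role == "D" & ev$response == "minus")
    p <- binom.test(sum(correct), nrow(ev), 0.5, alternative = "greater")$p.value
    data.frame(subject = s, n_trials = nrow(ev), n_correct = sum(correct),
               p = p, retained = p < alpha)
  })
  do.call(rbind, rows)
}
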