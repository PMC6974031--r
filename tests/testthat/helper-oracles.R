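# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (normal equations, exhaustive
# enumeration) kept separate from the package's computational paths.

# Pearson r + Fisher z from first principles
oracle_pearson_z <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  r <- sxy / sqrt(sxx * syy)
  list(r = r, z = 0.5 * log((1 + r) / (1 - r)))
}

# OLS + condition t-values via explicit normal equations
oracle_glm <- function(X, Y, cond_idx) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% Y
  res <- Y - X %*% beta
  df <- nrow(X) - qr(X)$rank
  sigma2 <- colSums(res^2) / df
  tmap <- sapply(seq_len(ncol(Y)), function(v)
    beta[cond_idx, v] / sqrt(sigma2[v] * XtXi[cond_idx, cond_idx]))
  list(beta = beta, t = tmap, df = df)
}

# Exact C-SVM by KKT enumeration: every point is free (0<a<C), at zero, or
# at the C bound; solve the stationarity system for each assignment and
# keep the feasible one. Only suitable for n <= 8.
oracle_svm <- function(X, y, C = 1, tol = 1e-8) {
  n <- nrow(X)
  K <- X %*% t(X)
  best <- NULL
  states <- expand.grid(rep(list(0:2), n))   # 0 = zero, 1 = free, 2 = at C
  for (si in seq_len(nrow(states))) {
    st <- as.integer(states[si, ])
    Fi <- which(st == 1); Ui <- which(st == 2)
    if (length(Fi) == 0) next
    # unknowns: alpha_F, b;  eqs: y_i f(x_i) = 1 for i in F; sum alpha*y = 0
    A <- matrix(0, length(Fi) + 1, length(Fi) + 1)
    rhs <- numeric(length(Fi) + 1)
    for (a in seq_along(Fi)) {
      i <- Fi[a]
      A[a, seq_along(Fi)] <- y[Fi] * K[i, Fi]
      A[a, length(Fi) + 1] <- 1
      rhs[a] <- y[i] - sum(C * y[Ui] * K[i, Ui])
    }
    A[length(Fi) + 1, seq_along(Fi)] <- y[Fi]
    rhs[length(Fi) + 1] <- -sum(C * y[Ui])
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    aF <- sol[seq_along(Fi)]; b <- sol[length(Fi) + 1]
    if (any(aF <= tol) || any(aF >= C - tol)) next
    alpha <- numeric(n); alpha[Fi] <- aF; alpha[Ui] <- C
    f <- drop(K %*% (alpha * y)) + b
    m <- y * f
    if (any(m[st == 0] < 1 - 1e-6)) next
    if (length(Ui) && any(m[Ui] > 1 + 1e-6)) next
    w <- drop(t(X) %*% (alpha * y))
    obj <- 0.5 * sum((alpha * y) * drop(K %*% (alpha * y))) - sum(alpha)
    cand <- list(alpha = alpha, w = w, b = b, obj = obj)
    if (is.null(best) || cand$obj < best$obj - 1e-10) best <- cand
  }
  best
}

# Exact expected accuracy over all distinct permutations of a +/-1 label
# vector against fixed predictions.
oracle_chance <- function(predictions, labels) {
  n <- length(labels)
  pos <- sum(labels > 0)
  combos <- utils::combn(n, pos)
  acc <- apply(combos, 2, function(ix) {
    lab <- rep(-1, n); lab[ix] <- 1
    mean(predictions == lab)
  })
  100 * mean(acc)
}

# Small, fast simulation configuration for unit tests
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(
    n_subjects = 3,
    rois = c(medial_OFC = 48L, posterior_HPC = 32L),
    feature_step = c(medial_OFC = 16L, posterior_HPC = 8L),
    precond_reps = 1, cond_reps = 1, probe_reps = 1,
    iti_range_s = c(2, 5), iti_cond_range_s = c(2, 4),
    seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
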