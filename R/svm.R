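#' Linear soft-margin support vector machine
#'
#' Dense SMO solver for the C-SVM dual (LIBSVM conventions: maximal
#' violating pair working-set selection, offset from the KKT gap), linear
#' kernel only, no feature rescaling. Training sets in this pipeline are
#' tiny (a handful of exemplar patterns), so a pure-R solver is adequate;
#' the stopping tolerance is far tighter than LIBSVM's default so that the
#' solution matches an exact QP oracle on small problems.
#'
#' @param x numeric matrix, exemplars x features.
#' @param y labels in \{-1, +1\}.
#' @param cost soft-margin cost C (default 1).
#' @param eps KKT violation tolerance.
#' @param max_iter iteration cap.
#' @return an `svm_model`: `alpha`, `w`, `b`, `obj` (dual objective).
#' @export
svm_train <- function(x, y, cost = 1, eps = 1e-10, max_iter = 100000L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) abort_validation("svm_train: length(y) != nrow(x)")
  if (!all(y %in% c(-1, 1))) abort_validation("svm_train: labels must be -1/+1")
  if (length(unique(y)) < 2)
    abort_validation("svm_train: training data contain a single class")
  K <- tcrossprod(x)
  Q <- (y %o% y) * K
  qd <- diag(Q)
  alpha <- numeric(n)
  G <- rep(-1, n)                      # gradient of the dual objective
  tau <- 1e-12
  for (iter in seq_len(max_iter)) {
    up <- (y > 0 & alpha < cost) | (y < 0 & alpha > 0)
    low <- (y > 0 & alpha > 0) | (y < 0 & alpha < cost)
    if (!any(up) || !any(low)) break
    yg <- -y * G
    i <- which(up)[which.max(yg[up])]
    m_up <- yg[i]
    j <- which(low)[which.min(yg[low])]
    m_low <- yg[j]
    if (m_up - m_low < eps) break
    # second-order working-set selection for j (libsvm WSS2)
    cand <- which(low & yg < m_up - tau)
    if (length(cand) == 0) break
    quad <- K[i, i] + diag(K)[cand] - 2 * y[i] * y[cand] * K[i, cand]
    quad[quad <= 0] <- tau
    gain <- (m_up - yg[cand])^2 / quad
    j <- cand[which.max(gain)]
    # two-variable update (libsvm)
    if (y[i] != y[j]) {
      qc <- qd[i] + qd[j] + 2 * Q[i, j]
      if (qc <= 0) qc <- tau
      delta <- (-G[i] - G[j]) / qc
      diffv <- alpha[i] - alpha[j]
      ai <- alpha[i] + delta; aj <- alpha[j] + delta
      if (diffv > 0) { if (aj < 0) { aj <- 0; ai <- diffv } }
      else { if (ai < 0) { ai <- 0; aj <- -diffv } }
      if (diffv > 0) { if (ai > cost) { ai <- cost; aj <- cost - diffv } }
      else { if (aj > cost) { aj <- cost; ai <- cost + diffv } }
    } else {
      qc <- qd[i] + qd[j] - 2 * Q[i, j]
      if (qc <= 0) qc <- tau
      delta <- (G[i] - G[j]) / qc
      sumv <- alpha[i] + alpha[j]
      ai <- alpha[i] - delta; aj <- alpha[j] + delta
      if (sumv > cost) { if (ai > cost) { ai <- cost; aj <- sumv - cost } }
      else { if (aj < 0) { aj <- 0; ai <- sumv } }
      if (sumv > cost) { if (aj > cost) { aj <- cost; ai <- sumv - cost } }
      else { if (ai < 0) { ai <- 0; aj <- sumv } }
    }
    dai <- ai - alpha[i]; daj <- aj - alpha[j]
    if (abs(dai) < 1e-16 && abs(daj) < 1e-16) break
    G <- G + Q[, i] * dai + Q[, j] * daj
    alpha[i] <- ai; alpha[j] <- aj
  }
  # offset: average -y*grad over free vectors, else midpoint of the KKT gap
  yg <- -y * G
  free <- alpha > 1e-12 & alpha < cost - 1e-12
  rho <- if (any(free)) -mean(yg[free]) else {
    up <- (y > 0 & alpha < cost) | (y < 0 & alpha > 0)
    low <- (y > 0 & alpha > 0) | (y < 0 & alpha < cost)
    -(max(yg[up]) + min(yg[low])) / 2
  }
  w <- drop(crossprod(x, alpha * y))
  structure(list(alpha = alpha, w = w, b = -rho, cost = cost,
                 obj = sum(alpha * G) / 2 - sum(alpha) / 2),
            class = "svm_model")
}

#' @rdname svm_train
#' @param model an `svm_model`.
#' @param newx matrix of test exemplars.
#' @return `svm_decision()` returns raw decision values; a positive (or
#'   exactly zero) decision value maps to the +1 class, making prediction
#'   deterministic on ties.
#' @export
svm_decision <- function(model, newx) {
  drop(as.matrix(newx) %*% model$w + model$b)
}

#' @rdname svm_train
#' @export
svm_predict <- function(model, newx) {
  d <- svm_decision(model, newx)
  ifelse(d >= 0, 1, -1)
}
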