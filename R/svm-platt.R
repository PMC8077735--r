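# Internal SVM subclassifier with deterministic Platt-scaled
# probabilities. The sigmoid P(y = 1 | f) = plogis(-(A*f + B)) is fit
# by maximum likelihood on the training decision values with Platt's
# prior-smoothed targets, giving reproducible probability outputs
# (libsvm's built-in probability model shuffles its internal
# cross-validation with an unseeded RNG).

platt_fit <- function(f, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  t <- ifelse(y == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # stable cross-entropy: -[t*log(p) + (1-t)*log(1-p)], p = plogis(-z),
    # i.e. sum(softplus(z) - (1-t)*z)
    sum(t * z + ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z))))
  }
  start <- c(0, log((n0 + 1) / (n1 + 1)))
  fit <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(A = fit$par[1], B = fit$par[2])
}

platt_predict <- function(platt, f) {
  stats::plogis(-(platt$A * f + platt$B))
}

# Fit an SVM with probability calibration. y is an integer 0/1 vector.
fit_svm_prob <- function(x, y, svm_params = list()) {
  kernel <- svm_params$kernel %||% "radial"
  cost <- svm_params$cost %||% 1
  gamma <- svm_params$gamma %||% gamma_scale(x)
  yf <- factor(y, levels = c("0", "1"))
  fit <- e1071::svm(x, yf, kernel = kernel, cost = cost, gamma = gamma,
                    scale = FALSE, cachesize = 256)
  dv <- fit$decision.values[, 1L]
  # libsvm orients decision values by order of appearance; normalize so
  # larger values mean the positive class
  sgn <- if (mean(dv[y == 1L]) >= mean(dv[y == 0L])) 1 else -1
  list(svm = fit, sign = sgn, platt = platt_fit(sgn * dv, y))
}

# Positive-class probabilities for new data.
predict_svm_prob <- function(clf, newx) {
  pred <- stats::predict(clf$svm, newx, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1L]
  platt_predict(clf$platt, clf$sign * dv)
}

# Default RBF bandwidth: 1 / (n_features * mean feature variance),
# the variance-scaled analogue of the 1/n_features heuristic. Total
# variance is invariant under the orthonormal rotations used by the
# ensemble, so rotated and unrotated fits see the same bandwidth.
gamma_scale <- function(x) {
  v <- mean(apply(x, 2L, stats::var))
  if (!is.finite(v) || v <= 0) return(1 / ncol(x))
  1 / (ncol(x) * v)
}
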