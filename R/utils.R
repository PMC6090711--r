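# Internal regression helpers. The simulation-heavy tests fit thousands of
# small per-variant models, so these avoid formula/model-frame overhead.

# Univariable OLS of y on x (with intercept): slope, its SE, n.
uni_linear <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3L) stop("too few complete observations for linear fit")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate predictor (zero variance)")
  beta <- sum(xc * y) / sxx
  res <- y - mean(y) - beta * xc
  s2 <- sum(res^2) / (n - 2L)
  list(beta = beta, se = sqrt(s2 / sxx), n = n)
}

# Logistic regression of binary y on design X (first column = 1s).
# Returns coefficients and SEs from the dispersion-1 observed information.
logistic_fit <- function(y, X) {
  ok <- is.finite(y) & apply(is.finite(X), 1L, all)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (length(unique(y)) < 2L) {
    stop("outcome has a single level; logistic fit undefined")
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 50))
  )
  if (!fit$converged) stop("logistic fit did not converge")
  cf <- fit$coefficients
  # separation check on the per-SD scale so it is invariant to predictor units
  sdx <- apply(X[, -1L, drop = FALSE], 2L, stats::sd)
  if (any(abs(cf[-1L]) * sdx > 15)) {
    stop("apparent separation in logistic fit (|log-odds per predictor SD| ",
         "> 15): ", paste(signif(cf, 4), collapse = ", "))
  }
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(chol2inv(chol(info))))
  list(beta = cf, se = se, n = length(y))
}

# Gaussian OLS on design X (first column = 1s); returns per-coefficient
# estimates, SEs and the model R^2.
ols_fit <- function(y, X) {
  ok <- is.finite(y) & apply(is.finite(X), 1L, all)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("too few complete observations for OLS fit")
  qr_x <- qr(X)
  if (qr_x$rank < p) stop("rank-deficient design in OLS fit")
  cf <- qr.coef(qr_x, y)
  res <- y - X %*% cf
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  if (rss < .Machine$double.eps * tss || tss == 0) {
    stop("degenerate fit: residual variance is (numerically) zero")
  }
  s2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  list(beta = as.vector(cf), se = sqrt(diag(xtx_inv) * s2), n = n,
       r2 = 1 - rss / tss)
}
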