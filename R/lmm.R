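# Random-intercept linear mixed model, fitted by maximum likelihood (not REML),
# with a likelihood-ratio test for the Time fixed effect. The model is
#   y_gj = beta0 + beta1 * day_j + b_g + e_gj,   b_g ~ N(0, sigma_b^2),
#   e ~ N(0, sigma^2),
# i.e. a fixed intercept and Time slope with a random intercept per guide.
#
# For the balanced case (every guide observed at the same day vector, which is
# always true after replicate averaging) the ML solution is closed form:
# GLS equals OLS under compound symmetry with an intercept, and profiling the
# likelihood over (sigma^2, tau^2 = sigma^2 + n*sigma_b^2) splits the residual
# sum of squares into within-guide and between-guide parts. The unbalanced
# case profiles the likelihood over the variance ratio lambda = sigma_b^2 /
# sigma^2 in one dimension. Both paths compute the exact ML optimum, so the
# LRT against the intercept-only reduced model is non-negative by nesting.

.VAR_FLOOR <- 1e-12

# profile log-likelihood of the balanced random-intercept model given a
# residual matrix R (guides x days); returns ML variance components too
.ri_profile_ll <- function(R) {
  m <- nrow(R); n <- ncol(R)
  rbar <- rowMeans(R)
  SSW <- sum((R - rbar)^2)             # within-guide
  SSB <- n * sum(rbar^2)               # between-guide (n * sum of sq. means)
  sig2 <- SSW / (m * (n - 1))
  tau2 <- SSB / m
  singular <- FALSE
  if (!(tau2 > sig2) || sig2 < .VAR_FLOOR) {
    # boundary: random-intercept variance collapses to zero -> iid fit
    sig2 <- max((SSW + SSB) / (m * n), .VAR_FLOOR)
    tau2 <- sig2
    singular <- TRUE
  }
  ll <- -0.5 * (m * n * log(2 * pi) + m * (n - 1) * log(sig2) +
                  m * log(tau2) + SSW / sig2 + SSB / tau2)
  list(ll = ll, sigma2 = sig2, tau2 = tau2, singular = singular)
}

# balanced-core fit: Y is guides x days, t the shared day vector
.lmm_balanced <- function(Y, t) {
  m <- nrow(Y); n <- ncol(Y)
  dbar <- colMeans(Y)
  tc <- t - mean(t)
  stt <- sum(tc^2)
  beta1 <- if (stt > 0) sum(tc * dbar) / stt else 0
  beta0 <- mean(dbar) - beta1 * mean(t)
  full <- .ri_profile_ll(Y - matrix(beta0 + beta1 * t, m, n, byrow = TRUE))
  red <- .ri_profile_ll(Y - mean(Y))
  lrt <- 2 * (full$ll - red$ll)
  if (lrt < 0) lrt <- max(lrt, 0)      # numeric guard; exact ML => >= 0
  list(ll_full = full$ll, ll_reduced = red$ll, lrt_stat = lrt, df = 1L,
       p = pchisq(lrt, df = 1, lower.tail = FALSE),
       slope = beta1, intercept = beta0,
       sigma2 = full$sigma2, sigma_b2 = (full$tau2 - full$sigma2) / n,
       singular = full$singular, n_guides = m, n_obs = m * n)
}

# general (possibly unbalanced) ML via 1-D profiling over lambda = sb2/s2;
# X is the fixed-effect design, g an integer group index
.lmm_profile_general <- function(y, X, g) {
  groups <- split(seq_along(y), g)
  N <- length(y)
  p <- ncol(X)
  ll_at <- function(lambda, want_fit = FALSE) {
    XtWX <- matrix(0, p, p); XtWy <- numeric(p); logdet <- 0
    for (idx in groups) {
      ng <- length(idx)
      Xg <- X[idx, , drop = FALSE]; yg <- y[idx]
      a <- lambda / (1 + ng * lambda)
      cx <- colSums(Xg); cy <- sum(yg)
      XtWX <- XtWX + crossprod(Xg) - a * tcrossprod(cx)
      XtWy <- XtWy + crossprod(Xg, yg)[, 1] - a * cx * cy
      logdet <- logdet + log1p(ng * lambda)
    }
    beta <- tryCatch(solve(XtWX, XtWy), error = function(e) rep(NA_real_, p))
    if (anyNA(beta)) return(if (want_fit) NULL else -Inf)
    qf <- 0
    for (idx in groups) {
      ng <- length(idx)
      r <- y[idx] - X[idx, , drop = FALSE] %*% beta
      a <- lambda / (1 + ng * lambda)
      qf <- qf + sum(r^2) - a * sum(r)^2
    }
    sig2 <- max(qf / N, .VAR_FLOOR)
    ll <- -0.5 * (N * log(2 * pi) + N * log(sig2) + logdet + N)
    if (want_fit) list(ll = ll, beta = beta, sigma2 = sig2, lambda = lambda)
    else ll
  }
  # optimise over log-lambda; include the boundary lambda = 0
  opt <- optimize(function(l) ll_at(exp(l)), interval = c(-12, 12),
                  maximum = TRUE, tol = 1e-9)
  cand <- list(ll_at(exp(opt$maximum), want_fit = TRUE), ll_at(0, want_fit = TRUE))
  cand <- cand[!vapply(cand, is.null, logical(1))]
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "ll"))]]
  best$singular <- best$lambda < 1e-8
  best
}

#' Fit the sliding-window random-intercept mixed model and test the Time effect
#'
#' Fits, by maximum likelihood, a linear mixed model of (log-scale) guide
#' abundance with a fixed intercept, a fixed Time (day) slope and a random
#' intercept per guide, and compares it against the reduced model without the
#' Time term by a likelihood-ratio test on one degree of freedom. When the
#' random-intercept variance collapses to zero the fit degenerates to ordinary
#' least squares; the result is flagged `singular` and the same LRT applies.
#'
#' @param y numeric vector of log-transformed abundances, one per observation.
#' @param day numeric day per observation.
#' @param guide guide identifier per observation (grouping factor).
#' @return a `window_fit` list: `lrt_stat`, `df`, `p`, `slope` (log10 units
#'   per day), `intercept`, `ll_full`, `ll_reduced`, variance components,
#'   `singular` flag, `n_guides`, `n_obs`.
#' @export
fit_window_lmm <- function(y, day, guide) {
  .need(length(y) == length(day) && length(y) == length(guide),
        "y, day and guide must have equal length")
  .need(all(is.finite(y)), "y must be finite")
  g <- as.integer(factor(guide))
  .need(max(g) >= 2L, "need at least 2 guides")
  .need(length(unique(day)) >= 2L, "need at least 2 distinct days")
  days_by_g <- split(day, g)
  n1 <- length(days_by_g[[1]])
  balanced <- all(vapply(days_by_g, length, integer(1)) == n1) &&
    all(vapply(days_by_g, function(d) identical(sort(d), sort(days_by_g[[1]])),
               logical(1)))
  if (balanced) {
    o <- order(g, day)
    Y <- matrix(y[o], nrow = max(g), ncol = n1, byrow = TRUE)
    fit <- .lmm_balanced(Y, sort(days_by_g[[1]]))
  } else {
    Xf <- cbind(1, day)
    full <- .lmm_profile_general(y, Xf, g)
    red <- .lmm_profile_general(y, cbind(rep(1, length(y))), g)
    lrt <- max(2 * (full$ll - red$ll), 0)
    fit <- list(ll_full = full$ll, ll_reduced = red$ll, lrt_stat = lrt,
                df = 1L, p = pchisq(lrt, 1, lower.tail = FALSE),
                slope = full$beta[2], intercept = full$beta[1],
                sigma2 = full$sigma2,
                sigma_b2 = full$lambda * full$sigma2,
                singular = full$singular,
                n_guides = max(g), n_obs = length(y))
  }
  class(fit) <- "window_fit"
  fit
}

#' @export
print.window_fit <- function(x, ...) {
  cat(sprintf(
    "window fit: %d guides, %d obs | slope=%.4g log10/day | LRT=%.3f (df=%d) p=%.3g%s\n",
    x$n_guides, x$n_obs, x$slope, x$lrt_stat, x$df, x$p,
    if (isTRUE(x$singular)) " [singular: random intercept at boundary]" else ""))
  invisible(x)
}
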