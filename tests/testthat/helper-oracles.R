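# Independent oracles used across the suite. Each deliberately avoids the
# package's own computational path.

# Direct numerical ML of the random-intercept Gaussian model: optimises the
# exact multivariate-normal log-likelihood over (beta, log sigma2, log sb2)
# by general-purpose optimisation with several starts. Groupwise closed-form
# density (Sherman-Morrison on the compound-symmetric block) — no profiling,
# no GLS shortcut.
oracle_lmm_ll <- function(y, X, g, beta, s2, sb2) {
  ll <- 0
  for (idx in split(seq_along(y), g)) {
    r <- y[idx] - X[idx, , drop = FALSE] %*% beta
    n <- length(idx)
    # V = s2 I + sb2 J ; |V| = s2^(n-1) (s2 + n sb2)
    det <- (n - 1) * log(s2) + log(s2 + n * sb2)
    quad <- sum(r^2) / s2 - sb2 * sum(r)^2 / (s2 * (s2 + n * sb2))
    ll <- ll - 0.5 * (n * log(2 * pi) + det + quad)
  }
  ll
}

oracle_lmm_ml <- function(y, X, g) {
  obj <- function(par) {
    p <- ncol(X)
    -oracle_lmm_ll(y, X, g, par[1:p], exp(par[p + 1]), exp(par[p + 2]))
  }
  p <- ncol(X)
  ols <- qr.coef(qr(X), y)
  v <- var(y - X %*% ols)
  starts <- list(c(ols, log(v), log(v / 2)),
                 c(ols, log(v), log(1e-6)),
                 c(ols, log(v / 2), log(v)))
  best <- Inf
  for (st in starts) {
    for (meth in c("Nelder-Mead", "BFGS")) {
      o <- suppressWarnings(try(
        optim(st, obj, method = meth,
              control = list(maxit = 5000, reltol = 1e-14)), silent = TRUE))
      if (!inherits(o, "try-error") && o$value < best) best <- o$value
    }
  }
  -best  # maximized log-likelihood
}

# textbook step-up BH, written independently (explicit loop over ranks)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# brute-force pair-square maximum: plain double loop, same half-open rule
oracle_square_max <- function(pairs, scores, h) {
  out <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    best <- NA_real_
    for (k in seq_len(nrow(scores))) {
      inA <- function(p, s, e) p >= s - h && p < e + h
      m <- pairs$mid[i]; t <- pairs$tss[i]
      fwd <- scores$chromA[k] == pairs$chrom[i] &&
        scores$chromB[k] == pairs$chrom[i] &&
        inA(m, scores$startA[k], scores$endA[k]) &&
        inA(t, scores$startB[k], scores$endB[k])
      bwd <- scores$chromA[k] == pairs$chrom[i] &&
        scores$chromB[k] == pairs$chrom[i] &&
        inA(m, scores$startB[k], scores$endB[k]) &&
        inA(t, scores$startA[k], scores$endA[k])
      if (fwd || bwd) best <- max(best, scores$score[k], na.rm = TRUE)
    }
    out[i] <- best
  }
  out
}

# brute-force ABC assignment: double loop over pairs x records
oracle_abc <- function(pairs, abc, h) {
  out <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    best <- NA_real_
    for (k in seq_len(nrow(abc))) {
      mid <- (abc$start[k] + abc$end[k]) / 2
      if (abc$gene[k] == pairs$gene[i] && abc$chrom[k] == pairs$chrom[i] &&
          pairs$mid[i] >= mid - h && pairs$mid[i] < mid + h)
        best <- max(best, abc$score[k], na.rm = TRUE)
    }
    out[i] <- best
  }
  out
}

# plain IRLS logistic regression (unpenalized), independent of glm
oracle_irls_logistic <- function(X, y, max_iter = 200L) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    nb <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(nb - beta)) < 1e-12) break
    beta <- drop(nb)
  }
  beta
}

# random interaction-square instance (shared by unit and acceptance tests)
rand_square_instance <- function(seed, n = 20, m = 50) {
  set.seed(seed)
  pairs <- data.frame(chrom = "chr4", mid = sample.int(1e6, n),
                      tss_chrom = "chr4", tss = sample.int(1e6, n))
  scores <- data.frame(
    chromA = "chr4", startA = sample.int(1e6, m),
    chromB = "chr4", startB = sample.int(1e6, m),
    score = round(runif(m, 0, 50), 3))
  scores$endA <- scores$startA + sample(100:5000, m, replace = TRUE)
  scores$endB <- scores$startB + sample(100:5000, m, replace = TRUE)
  list(pairs = pairs, scores = scores)
}

# small balanced LMM instance generator for oracle comparisons
random_lmm_instance <- function(seed, balanced = TRUE) {
  set.seed(seed)
  m <- sample(2:5, 1)
  nd <- sample(2:4, 1)
  days <- sort(sample(c(5, 12, 20, 29, 33), nd))
  g <- rep(seq_len(m), each = nd)
  day <- rep(days, m)
  if (!balanced && nd >= 3) {
    drop <- sample(length(g), 1)
    g <- g[-drop]; day <- day[-drop]
  }
  b <- rnorm(m, 0, runif(1, 0.1, 0.6))
  y <- 1 + runif(1, -0.1, 0.1) * day + b[g] + rnorm(length(g), 0, runif(1, 0.05, 0.3))
  list(y = y, day = day, guide = g)
}

# shared desk-scale screen world for screenstats tests
make_screen_world <- function(seed, n_bins = 500, n_elements = 5,
                              slope = 0.05, null = FALSE) {
  reg <- list(chrom = "chr4", start = 0, end = n_bins * 100, bin_size = 100L)
  lib <- make_guide_library(reg, seed = seed)
  truth <- if (null) NULL else
    sim_screen_truth(lib, n_elements = n_elements, slope = slope, seed = seed)
  scr <- sim_screen_counts(lib, truth, seed = seed)
  list(region = reg, lib = lib, truth = truth, counts = scr$counts,
       samples = scr$samples)
}
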