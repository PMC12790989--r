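# Chromatin-feature models: RPK summaries of coverage tracks, 100 bp z-score
# feature matrices, a unified cross-validated logistic CaRE model with a
# shuffled-label baseline, per-TF controlled logistic models, and a random
# forest separating top from bottom regulatory pairs.

#' Summarize a coverage track over regions as reads per kilobase
#'
#' Track scores are binned read counts; a region's signal is the
#' width-prorated sum of overlapping bin counts, divided by the region width
#' in kb. Histone-type features are first resized to a minimum of
#' `min_width_histone` bp centred on the region midpoint.
#'
#' @param track data.frame (chrom, start, end, score) of binned counts.
#' @param regions data.frame with chrom, start, end.
#' @param histone resize regions for a histone-type feature (default FALSE).
#' @param min_width_histone minimum resized width in bp (default 1000).
#' @return numeric RPK per region (0 where the track has no signal).
#' @export
summarize_rpk <- function(track, regions, histone = FALSE,
                          min_width_histone = 1000) {
  .need(all(regions$end > regions$start), "zero-width region")
  r <- regions
  if (histone) {
    mid <- (r$start + r$end) / 2
    w <- pmax(r$end - r$start, min_width_histone)
    r$start <- floor(mid - w / 2); r$end <- r$start + w
  }
  if (is.null(track) || nrow(track) == 0) return(numeric(nrow(r)))
  rgr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1, r$end))
  tgr <- GenomicRanges::GRanges(track$chrom, IRanges::IRanges(track$start + 1, track$end))
  hits <- GenomicRanges::findOverlaps(rgr, tgr)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(rgr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(tgr)[S4Vectors::subjectHits(hits)]))
  contrib <- track$score[S4Vectors::subjectHits(hits)] * ov /
    IRanges::width(IRanges::ranges(tgr))[S4Vectors::subjectHits(hits)]
  sums <- tapply(contrib, factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(r))), sum)
  sums[is.na(sums)] <- 0
  as.numeric(sums) / ((r$end - r$start) / 1000)
}

#' z-score a feature vector (population sd)
#'
#' @param values numeric vector (>= 2 values).
#' @return `(x - mean)/sd_pop`; constant input yields zeros with a warning.
#' @export
zscore <- function(values) {
  .need(length(values) >= 2, "need >= 2 values")
  mu <- mean(values)
  s <- sqrt(mean((values - mu)^2))
  if (s == 0) {
    warning("constant input: z-scores set to 0")
    return(rep(0, length(values)))
  }
  (values - mu) / s
}

#' Assemble a 100 bp-bin feature matrix from tracks
#'
#' Summarizes each track over the bin grid as RPK, imputes missing coverage
#' as 0 and z-scores each column. No histone resizing here: the 1 kb
#' minimum-width rule applies to element-level summaries, while the bin
#' matrix works on the raw 100 bp grid.
#'
#' @param tracks named list of track data.frames.
#' @param region list with chrom/start/end (and optional bin_size).
#' @param bin_size bin width (default region's, else 100).
#' @return list: `features` (bins x tracks z-score matrix), `bins`
#'   (data.frame chrom/start/end).
#' @export
bin_feature_matrix <- function(tracks, region, bin_size = NULL) {
  bs <- bin_size %||% region$bin_size %||% 100L
  starts <- seq(region$start, region$end - bs, by = bs)
  bins <- data.frame(chrom = region$chrom, start = starts, end = starts + bs)
  X <- vapply(names(tracks), function(f) {
    zscore(summarize_rpk(tracks[[f]], bins))
  }, numeric(nrow(bins)))
  colnames(X) <- names(tracks)
  list(features = X, bins = bins)
}

# logistic fit with Wald inference; ridge fallback on separation
.logistic_report <- function(X, y, penalty = 1e-4) {
  .need(length(unique(y)) == 2, "both classes must be present")
  .need(ncol(X) >= 1, "no features")
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  if (separated) {
    co <- .ridge_logistic(cbind(1, as.matrix(X)), y, lambda = penalty)
    se <- rep(NA_real_, length(co))
  } else {
    sm <- summary(fit)
    co <- sm$coefficients[, 1]; se <- sm$coefficients[, 2]
  }
  z <- co / se
  p <- 2 * pnorm(-abs(z))
  nm <- c("(Intercept)", colnames(X))
  rep_idx <- seq_along(co) > 1      # FDR across non-intercept coefficients
  fdr <- rep(NA_real_, length(co))
  fdr[rep_idx] <- bh_adjust(p[rep_idx], nm[rep_idx])
  data.frame(term = nm, estimate = unname(co), se = unname(se),
             ci_lo = unname(co - 1.96 * se), ci_hi = unname(co + 1.96 * se),
             z = unname(z), p = unname(p), fdr = fdr,
             separated = separated, stringsAsFactors = FALSE)
}

# L2-penalized logistic IRLS (intercept unpenalized); X includes intercept col
.ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100L) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X * sqrt(w)) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < 1e-10) { beta <- drop(new); break }
    beta <- drop(new)
  }
  setNames(beta, colnames(X))
}

#' Unified logistic model predicting CaRE membership from features
#'
#' ML logistic fit of the binary CaRE label on all feature columns, with Wald
#' 95% intervals, Z-statistic p-values and BH FDR across coefficients. On
#' (quasi-)separation the fit falls back to a lightly L2-penalized refit and
#' is flagged.
#'
#' @param features bins x features matrix (z-scored).
#' @param labels logical/0-1 CaRE membership per bin.
#' @return coefficient report data.frame (see `.logistic_report`).
#' @export
fit_care_logistic <- function(features, labels) {
  .logistic_report(as.data.frame(features), as.numeric(labels))
}

# rank-based AUC
.auc <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment
.strat_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    .need(length(idx) >= folds, "class too small for %d-fold stratification", folds)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

#' Repeated stratified cross-validated AUC, with a shuffled-label baseline
#'
#' Runs `repeats` repetitions of stratified `folds`-fold cross-validation of
#' a logistic model (`folds * repeats` held-out AUCs, 50 by default) and, in
#' parallel, the same procedure with labels permuted before each repetition.
#'
#' @param features bins x features matrix.
#' @param labels binary labels.
#' @param folds folds per repetition (default 5).
#' @param repeats repetitions (default 10).
#' @param shuffle_baseline also compute the shuffled-label AUCs (default TRUE).
#' @param seed integer seed.
#' @return list: `auc_true` (length folds*repeats), `auc_shuffled` (or NULL).
#' @export
cv_auc <- function(features, labels, folds = 5L, repeats = 10L,
                   shuffle_baseline = TRUE, seed = 1L) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  one_rep <- function(yy, rep_seed) {
    set.seed(rep_seed)
    fold <- .strat_folds(yy, folds)
    vapply(seq_len(folds), function(k) {
      tr <- fold != k
      beta <- .ridge_logistic(cbind(1, X[tr, , drop = FALSE]), yy[tr],
                              lambda = 1e-6)
      score <- drop(cbind(1, X[!tr, , drop = FALSE]) %*% beta)
      .auc(score, yy[!tr])
    }, numeric(1))
  }
  auc_true <- unlist(lapply(seq_len(repeats), function(r)
    one_rep(y, sub_seed(seed, paste0("cv_true_", r)))))
  auc_sh <- NULL
  if (shuffle_baseline) {
    auc_sh <- unlist(lapply(seq_len(repeats), function(r) {
      set.seed(sub_seed(seed, paste0("cv_shuffle_", r)))
      one_rep(sample(y), sub_seed(seed, paste0("cv_shufrep_", r)))
    }))
  }
  list(auc_true = auc_true, auc_shuffled = auc_sh)
}

#' Per-TF logistic models controlled for general epigenetic features
#'
#' One logistic model per TF track: `label ~ TF + base features`; reports the
#' TF coefficient with Wald CI and Z-p, FDR-adjusted across TFs.
#'
#' @param tf_features bins x TFs z-score matrix.
#' @param base_features bins x base-feature z-score matrix
#'   (H3K27ac/H3K4me1/H3K4me3/ATAC by convention).
#' @param labels binary CaRE labels.
#' @return data.frame: tf, estimate, se, ci_lo, ci_hi, z, p, fdr, flagged.
#' @export
tf_logistic <- function(tf_features, base_features, labels) {
  tf_features <- as.matrix(tf_features)
  out <- lapply(colnames(tf_features), function(tf) {
    v <- tf_features[, tf]
    if (all(v == 0)) {
      return(data.frame(tf = tf, estimate = 0, se = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, z = NA_real_, p = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    X <- cbind(TF = v, as.matrix(base_features))
    rep <- .logistic_report(as.data.frame(X), as.numeric(labels))
    row <- rep[rep$term == "TF", ]
    data.frame(tf = tf, estimate = row$estimate, se = row$se,
               ci_lo = row$ci_lo, ci_hi = row$ci_hi, z = row$z, p = row$p,
               flagged = row$separated, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$fdr <- bh_adjust(res$p, res$tf)
  res
}

#' Random-forest separation of top vs bottom regulatory pairs
#'
#' Ranks pairs by adjusted p-value, labels the top `n_top` as 1 and the
#' bottom `n_bottom` as 0, and fits the in-package random forest
#' ([rf_fit()]). Reports out-of-bag and stratified CV accuracy, permutation
#' feature importances, and a feature correlation dendrogram (hclust on
#' `1 - |cor|`, average linkage).
#'
#' @param pair_features pairs x features matrix (rows aligned with `adj_p`).
#' @param adj_p adjusted p-value per pair (ranking key).
#' @param n_top,n_bottom class sizes (default 50/50).
#' @param ntree trees (default 200).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @return list: `oob_accuracy`, `cv_accuracy`, `importance` (named, sorted),
#'   `hclust`, `labels`, `forest`.
#' @export
rf_pairs <- function(pair_features, adj_p, n_top = 50L, n_bottom = 50L,
                     ntree = 200L, folds = 5L, seed = 1L) {
  X <- as.matrix(pair_features)
  .need(nrow(X) == length(adj_p), "features and adj_p must align")
  .need(nrow(X) >= n_top + n_bottom, "fewer pairs than requested")
  o <- order(adj_p)
  top <- o[seq_len(n_top)]
  bot <- rev(o)[seq_len(n_bottom)]
  idx <- c(top, bot)
  Xs <- X[idx, , drop = FALSE]
  y <- c(rep(1L, n_top), rep(0L, n_bottom))
  set.seed(sub_seed(seed, "rf_fit"))
  forest <- rf_fit(Xs, y, ntree = ntree)
  imp <- rf_importance(forest, Xs, y)
  set.seed(sub_seed(seed, "rf_cv"))
  fold <- .strat_folds(y, folds)
  cv_acc <- mean(vapply(seq_len(folds), function(k) {
    tr <- fold != k
    f <- rf_fit(Xs[tr, , drop = FALSE], y[tr], ntree = ntree)
    mean(rf_predict(f, Xs[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1)))
  cm <- suppressWarnings(stats::cor(Xs))
  cm[!is.finite(cm)] <- 0; diag(cm) <- 1
  hc <- stats::hclust(stats::as.dist(1 - abs(cm)), method = "average")
  list(oob_accuracy = forest$oob_accuracy, cv_accuracy = cv_acc,
       importance = sort(imp, decreasing = TRUE), hclust = hc,
       labels = data.frame(index = idx, label = y), forest = forest)
}
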