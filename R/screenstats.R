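# Tiling-screen analysis: CPM normalization, timepoint means, guide-level
# scoring against the non-targeting control null, per-bin sliding-window
# mixed-model LRTs, merging of significant bins into CaREs, and final CaRE
# scores (-log10 of the BH-adjusted p-value).

#' Counts-per-million normalization
#'
#' Divides each guide's count by the sample total and multiplies by one
#' million, per sample.
#'
#' @param counts guides x samples non-negative count matrix.
#' @return matrix of the same shape; every column sums to 1e6.
#' @export
normalize_cpm <- function(counts) {
  counts <- .densify(counts)
  .need(is.matrix(counts) && all(counts >= 0), "counts must be non-negative")
  tot <- colSums(counts)
  bad <- which(tot == 0)
  if (length(bad))
    stop(sprintf("all-zero sample(s): %s",
                 paste(colnames(counts)[bad] %||% bad, collapse = ", ")),
         call. = FALSE)
  sweep(counts, 2, tot, "/") * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average replicate columns per timepoint
#'
#' @param normalized guides x samples matrix (column names = sample ids).
#' @param samples data.frame with columns sample, replicate, day.
#' @return guides x days matrix; columns named by day, ascending.
#' @export
timepoint_means <- function(normalized, samples) {
  .need(all(colnames(normalized) %in% samples$sample),
        "every matrix column needs a samples row")
  .need(!anyNA(samples$day), "missing day annotation")
  days <- sort(unique(samples$day))
  out <- matrix(0, nrow(normalized), length(days),
                dimnames = list(rownames(normalized), as.character(days)))
  for (j in seq_along(days)) {
    cols <- samples$sample[samples$day == days[j]]
    .need(length(cols) >= 1, "no replicate for day %s", days[j])
    out[, j] <- rowMeans(normalized[, cols, drop = FALSE])
  }
  out
}

#' Per-guide log2 fold change between first and last timepoint
#'
#' @param means guides x days matrix from [timepoint_means()].
#' @param first_day,last_day days to compare (defaults: first and last column).
#' @param pseudocount non-negative pseudocount added to both (default 0.5).
#' @return named numeric vector of log2 fold changes.
#' @export
guide_lfc <- function(means, first_day = NULL, last_day = NULL,
                      pseudocount = 0.5) {
  .need(pseudocount >= 0, "pseudocount must be non-negative")
  days <- colnames(means)
  first_day <- as.character(first_day %||% days[1])
  last_day <- as.character(last_day %||% days[length(days)])
  .need(first_day %in% days && last_day %in% days,
        "requested days absent from means table")
  log2((means[, last_day] + pseudocount) / (means[, first_day] + pseudocount))
}

#' Score guide log fold changes against the control-guide null
#'
#' Fits a normal null to control-guide LFCs and computes per-guide normal-tail
#' p-values (two-sided by default), BH-adjusted; direction is the LFC sign at
#' `adj_p < alpha`.
#'
#' @param lfcs named numeric vector of guide LFCs.
#' @param control_ids ids of non-targeting control guides (>= 2 finite).
#' @param two_sided two-sided p-values (default TRUE).
#' @param alpha significance level for direction calls (default 0.05).
#' @return data.frame: guide_id, lfc, p, adj_p, direction.
#' @export
guide_pvalues <- function(lfcs, control_ids, two_sided = TRUE, alpha = 0.05) {
  ctrl <- lfcs[names(lfcs) %in% control_ids]
  ctrl <- ctrl[is.finite(ctrl)]
  .need(length(ctrl) >= 2, "need >= 2 control guides with finite lfc")
  mu <- mean(ctrl); s <- sd(ctrl)
  if (s == 0) stop("control lfc standard deviation is zero", call. = FALSE)
  z <- (lfcs - mu) / s
  p <- if (two_sided) 2 * pnorm(-abs(z)) else pnorm(-abs(z))
  p <- pmin(p, 1)
  adj <- bh_adjust(p, names(lfcs))
  data.frame(guide_id = names(lfcs), lfc = unname(lfcs), p = unname(p),
             adj_p = unname(adj),
             direction = ifelse(adj < alpha,
                                ifelse(lfcs > mu, "enriched", "depleted"),
                                "ns"),
             stringsAsFactors = FALSE)
}

#' Sliding-window mixed-model scan over the bin grid
#'
#' For every bin of the tiling grid, jointly models the log10 timepoint-mean
#' abundances of all guides targeting the bin plus `window_bins` neighbouring
#' bins on each side using [fit_window_lmm()]; bins with fewer than 2 guides
#' in the window are skipped. P-values are BH-adjusted across tested bins.
#'
#' @param means guides x days normalized timepoint means (targeting guides).
#' @param library guide library (is_control rows are ignored).
#' @param bin_size bin width in bp (default from the library's region, else 100).
#' @param window_bins neighbouring bins on each side (default 1).
#' @param pseudocount added before log10 (default 0.5).
#' @return data.frame, one row per grid bin: chrom, start, end, n_guides,
#'   tested, slope, lrt, p, adj_p, singular.
#' @export
scan_bins <- function(means, library, bin_size = NULL, window_bins = 1L,
                      pseudocount = 0.5) {
  .need(window_bins >= 0, "window_bins must be >= 0")
  reg <- attr(library, "region")
  if (is.null(bin_size)) bin_size <- reg$bin_size %||% 100L
  lib <- library[!library$is_control, , drop = FALSE]
  .need(all(lib$guide_id %in% rownames(means)),
        "means table lacks some targeting guides")
  pos <- (lib$start + lib$end) / 2
  r0 <- if (!is.null(reg)) reg$start else floor(min(pos) / bin_size) * bin_size
  r1 <- if (!is.null(reg)) reg$end else ceiling(max(pos) / bin_size) * bin_size
  n_bins <- as.integer((r1 - r0) %/% bin_size)
  bin_of <- pmin(pmax(as.integer((pos - r0) %/% bin_size), 0L), n_bins - 1L)
  by_bin <- split(match(lib$guide_id, rownames(means)), factor(bin_of, levels = 0:(n_bins - 1L)))
  day <- as.numeric(colnames(means))
  Y_all <- log10(means[, , drop = FALSE] + pseudocount)
  res <- data.frame(chrom = reg$chrom %||% lib$chrom[1],
                    start = r0 + (0:(n_bins - 1L)) * bin_size,
                    end = r0 + (1:n_bins) * bin_size,
                    n_guides = 0L, tested = FALSE, slope = NA_real_,
                    lrt = NA_real_, p = NA_real_, adj_p = NA_real_,
                    singular = FALSE, stringsAsFactors = FALSE)
  w <- as.integer(window_bins)
  for (b in seq_len(n_bins)) {
    idx <- unlist(by_bin[max(1L, b - w):min(n_bins, b + w)], use.names = FALSE)
    res$n_guides[b] <- length(idx)
    if (length(idx) < 2L) next
    fit <- .lmm_balanced(Y_all[idx, , drop = FALSE], day)
    res$tested[b] <- TRUE
    res$slope[b] <- fit$slope
    res$lrt[b] <- fit$lrt_stat
    res$p[b] <- fit$p
    res$singular[b] <- fit$singular
  }
  res$adj_p[res$tested] <- bh_adjust(res$p[res$tested])
  res
}

#' Merge adjacent significant bins into CaREs
#'
#' Bins separated by at most `max_gap` bp (end-to-start) merge into one
#' element; bins of opposite effect direction never merge. Input bins must be
#' disjoint and on one chromosome.
#'
#' @param bins data.frame with chrom, start, end and either `direction` or
#'   `slope` (direction derived from the slope sign).
#' @param max_gap maximum merge gap in bp (default 500).
#' @return data.frame: care_id, chrom, start, end, direction, n_bins.
#' @export
merge_bins <- function(bins, max_gap = 500) {
  if (nrow(bins) == 0)
    return(data.frame(care_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      direction = character(0), n_bins = integer(0)))
  .need(length(unique(bins$chrom)) == 1L, "bins must be on one chromosome")
  if (is.null(bins$direction))
    bins$direction <- ifelse(bins$slope < 0, "depleted", "enriched")
  bins <- bins[order(bins$start), , drop = FALSE]
  if (any(bins$start[-1] < bins$end[-nrow(bins)]))
    stop("input bins overlap", call. = FALSE)
  grp <- cumsum(c(1L, as.integer(
    bins$start[-1] - bins$end[-nrow(bins)] > max_gap |
      bins$direction[-1] != bins$direction[-nrow(bins)])))
  agg <- lapply(split(seq_len(nrow(bins)), grp), function(i) {
    data.frame(chrom = bins$chrom[i[1]], start = min(bins$start[i]),
               end = max(bins$end[i]), direction = bins$direction[i[1]],
               n_bins = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- cbind(care_id = sprintf("CaRE%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Score merged CaREs with a mixed model over all member guides
#'
#' Refits the random-intercept model on every guide targeting inside each
#' CaRE interval, BH-adjusts across CaREs, and reports the score
#' `-log10(adj_p)` with direction from the fitted slope sign (negative
#' abundance slope = depleted).
#'
#' @param cares output of [merge_bins()].
#' @param means guides x days normalized timepoint means.
#' @param library guide library.
#' @param pseudocount added before log10 (default 0.5).
#' @return `cares` with columns n_guides, slope, p, adj_p, score, direction,
#'   flagged (TRUE when a CaRE had < 2 member guides and was left unscored).
#' @export
score_care <- function(cares, means, library, pseudocount = 0.5) {
  if (nrow(cares) == 0) {
    for (cn in c("n_guides", "slope", "p", "adj_p", "score"))
      cares[[cn]] <- numeric(0)
    cares$flagged <- logical(0)
    return(cares)
  }
  lib <- library[!library$is_control, , drop = FALSE]
  pos <- (lib$start + lib$end) / 2
  day <- as.numeric(colnames(means))
  Y_all <- log10(means + pseudocount)
  cares$n_guides <- 0L
  cares$slope <- NA_real_; cares$p <- NA_real_
  cares$flagged <- FALSE
  members <- vector("list", nrow(cares))
  for (i in seq_len(nrow(cares))) {
    sel <- lib$chrom == cares$chrom[i] & pos >= cares$start[i] & pos < cares$end[i]
    ids <- lib$guide_id[sel]
    members[[i]] <- ids
    cares$n_guides[i] <- length(ids)
    if (length(ids) < 2L) { cares$flagged[i] <- TRUE; next }
    fit <- .lmm_balanced(Y_all[match(ids, rownames(means)), , drop = FALSE], day)
    cares$slope[i] <- fit$slope
    cares$p[i] <- fit$p
  }
  cares$adj_p <- bh_adjust(cares$p, cares$care_id)
  cares$score <- -log10(pmax(cares$adj_p, .Machine$double.xmin))
  cares$direction <- ifelse(is.na(cares$slope), cares$direction,
                            ifelse(cares$slope < 0, "depleted", "enriched"))
  attr(cares, "members") <- setNames(members, cares$care_id)
  cares
}

#' Call CaREs from screen counts end to end
#'
#' CPM-normalizes, averages replicates per timepoint, scores guides against
#' the control null, runs the sliding-window scan, merges significant bins
#' (direction-aware, `max_gap` rule) and assigns final CaRE scores.
#'
#' @param counts guides x samples count matrix.
#' @param samples sample sheet (sample, replicate, day).
#' @param library guide library.
#' @param alpha bin/guide significance level (default 0.05).
#' @param max_gap merge gap in bp (default 500).
#' @param window_bins sliding-window extension in bins (default 1).
#' @param pseudocount log-transform pseudocount (default 0.5).
#' @return list: `guide_results`, `bin_results`, `cares`, `means`.
#' @export
call_cares <- function(counts, samples, library, alpha = 0.05, max_gap = 500,
                       window_bins = 1L, pseudocount = 0.5) {
  norm <- normalize_cpm(counts)
  means <- timepoint_means(norm, samples)
  lfc <- guide_lfc(means, pseudocount = pseudocount)
  ctrl <- library$guide_id[library$is_control]
  guide_results <- if (length(ctrl) >= 2) guide_pvalues(lfc, ctrl, alpha = alpha) else NULL
  bins <- scan_bins(means, library, window_bins = window_bins,
                    pseudocount = pseudocount)
  sig <- bins[bins$tested & !is.na(bins$adj_p) & bins$adj_p < alpha, , drop = FALSE]
  cares <- merge_bins(sig, max_gap = max_gap)
  cares <- score_care(cares, means, library, pseudocount = pseudocount)
  list(guide_results = guide_results, bin_results = bins, cares = cares,
       means = means)
}
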