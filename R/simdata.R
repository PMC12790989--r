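# Synthetic-data module: generates every pipeline input with planted ground
# truth. The stated world mirrors the study design: a ~2 Mb tiled region in
# 100 bp bins with 2-3 guides per bin plus non-targeting controls; screen
# counts over days 5/20/29/33 in two replicates with planted log10-scale
# abundance slopes at CaREs; targeted single-cell NB expression with ~1 true
# guide per cell, bimodal guide-count noise, run-level batch effects and
# planted guide-to-gene log2 fold changes; chromatin feature tracks enriched
# at a subset of planted elements; and interaction score tables elevated for
# a subset of planted pairs.

#' Simulate a tiling guide library
#'
#' Tiles `region` in bins of `bin_size` bp and places a uniformly drawn
#' number of targeting guides (within `guides_per_bin`) in each bin, plus
#' `n_controls` non-targeting control guides that carry no coordinates.
#'
#' @param region list/vector with `chrom`, `start`, `end` (0-based half-open).
#' @param bin_size bin width in bp (default 100).
#' @param guides_per_bin integer range `c(lo, hi)` of guides per bin, within 1..10.
#' @param n_controls number of non-targeting control guides (default 100).
#' @param seed integer seed.
#' @return data.frame: guide_id, chrom, start, end, bin, is_control, sequence.
#' @export
make_guide_library <- function(region, bin_size = 100L,
                               guides_per_bin = c(2L, 3L),
                               n_controls = 100L, seed = 1L) {
  chrom <- as.character(region[["chrom"]])
  rs <- as.numeric(region[["start"]]); re <- as.numeric(region[["end"]])
  .need(re > rs, "empty region: end must exceed start")
  .need(bin_size >= 1, "bin_size must be >= 1")
  gpb <- as.integer(guides_per_bin)
  .need(length(gpb) == 2L && gpb[1] >= 1L && gpb[2] <= 10L && gpb[1] <= gpb[2],
        "guides_per_bin must be an increasing range within [1, 10]")
  n_bins <- (re - rs) %/% bin_size
  .need(n_bins >= 1, "region shorter than one bin")
  set.seed(sub_seed(seed, "guide_library"))
  k <- sample(seq(gpb[1], gpb[2]), n_bins, replace = TRUE)
  bin_idx <- rep.int(seq_len(n_bins), k)
  bin_start <- rs + (bin_idx - 1) * bin_size
  pos <- bin_start + floor(runif(length(bin_idx)) * (bin_size - 20))
  targ <- data.frame(
    guide_id = sprintf("g%06d", seq_along(bin_idx)),
    chrom = chrom, start = pos, end = pos + 20L,
    bin = bin_idx - 1L, is_control = FALSE,
    sequence = "N", stringsAsFactors = FALSE)
  ctrl <- if (n_controls > 0) data.frame(
    guide_id = sprintf("ctrl%04d", seq_len(n_controls)),
    chrom = NA_character_, start = NA_real_, end = NA_real_,
    bin = NA_integer_, is_control = TRUE,
    sequence = "N", stringsAsFactors = FALSE) else NULL
  out <- rbind(targ, ctrl)
  attr(out, "region") <- list(chrom = chrom, start = rs, end = re,
                              bin_size = as.integer(bin_size))
  out
}

#' Plant CaRE-like elements for a screen simulation
#'
#' Draws `n_elements` non-overlapping elements of `width_bins` bins inside the
#' library's region and assigns each a log10-abundance slope per day. Negative
#' slopes deplete (direction "depleted"), positive enrich.
#'
#' Depletion of a toxic activated element can be near-complete, while
#' enrichment is bounded by the achievable growth-rate advantage, so enriched
#' elements default to a slope of `enriched_scale` times the depletion
#' magnitude (matching the strong skew towards depleted hits in tiling
#' viability screens).
#'
#' @param library a guide library from [make_guide_library()].
#' @param n_elements number of planted elements.
#' @param width_bins element width in bins (recycled).
#' @param slope absolute depletion slope magnitude(s), log10 units per day.
#' @param prop_depleted fraction of elements given negative slope.
#' @param enriched_scale enriched-slope magnitude as a fraction of `slope`
#'   (default 0.4).
#' @param seed integer seed.
#' @return data.frame: element_id, chrom, start, end, slope, direction.
#' @export
sim_screen_truth <- function(library, n_elements = 20L, width_bins = 3L,
                             slope = 0.05, prop_depleted = 0.85,
                             enriched_scale = 0.4, seed = 1L) {
  reg <- attr(library, "region")
  .need(!is.null(reg), "library lacks region attribute")
  bs <- reg$bin_size
  n_bins <- (reg$end - reg$start) %/% bs
  set.seed(sub_seed(seed, "screen_truth"))
  width_bins <- rep_len(as.integer(width_bins), n_elements)
  slope <- rep_len(abs(slope), n_elements)
  # sample non-adjacent element start bins with a 2-bin buffer
  ok <- FALSE
  for (try in 1:50) {
    starts <- sort(sample(seq_len(n_bins - max(width_bins) - 1L) - 1L, n_elements))
    ends <- starts + width_bins
    if (all(diff(starts) > (head(width_bins, -1) + 2L))) { ok <- TRUE; break }
  }
  .need(ok, "could not place %d non-overlapping elements in %d bins",
        n_elements, n_bins)
  depl <- seq_len(n_elements) <= round(prop_depleted * n_elements)
  depl <- sample(depl)
  data.frame(
    element_id = sprintf("el%03d", seq_len(n_elements)),
    chrom = reg$chrom,
    start = reg$start + starts * bs,
    end = reg$start + ends * bs,
    slope = ifelse(depl, -slope, enriched_scale * slope),
    direction = ifelse(depl, "depleted", "enriched"),
    stringsAsFactors = FALSE)
}

# map guides to planted slopes (0 for controls and untargeted bins)
.guide_slopes <- function(library, truth) {
  sl <- numeric(nrow(library))
  if (!is.null(truth) && nrow(truth) > 0) {
    pos <- (library$start + library$end) / 2
    for (i in seq_len(nrow(truth))) {
      hit <- !library$is_control & pos >= truth$start[i] & pos < truth$end[i]
      sl[hit] <- truth$slope[i]
    }
  }
  sl
}

#' Simulate tiling-screen counts over timepoints
#'
#' Each guide has a latent log10 relative abundance `base + slope * day`;
#' per-sample expected counts are scaled to `depth` and drawn from a negative
#' binomial with dispersion `dispersion` (variance mu + mu^2/theta).
#'
#' @param library guide library.
#' @param truth planted elements from [sim_screen_truth()] (NULL for null screen).
#' @param days ascending numeric timepoints (default the study's 5/20/29/33).
#' @param replicates replicates per timepoint (default 2).
#' @param depth target reads per sample (default 2e7 scaled to library size).
#' @param dispersion NB size parameter theta (default 50).
#' @param seed integer seed.
#' @return list: `counts` (guides x samples integer matrix), `samples`
#'   (data.frame sample, replicate, day).
#' @export
sim_screen_counts <- function(library, truth = NULL, days = c(5, 20, 29, 33),
                              replicates = 2L, depth = NULL, dispersion = 50,
                              seed = 1L) {
  .need(!is.unsorted(days, strictly = TRUE), "days must be ascending")
  .need(replicates >= 1L, "replicates must be >= 1")
  if (is.null(depth)) depth <- 400 * nrow(library)
  .need(depth > 0, "depth must be positive")
  set.seed(sub_seed(seed, "screen_counts"))
  n <- nrow(library)
  base <- rnorm(n, 0, 0.25)            # log10 relative abundance at day 0
  sl <- .guide_slopes(library, truth)
  samples <- expand.grid(replicate = seq_len(replicates), day = days)
  samples$sample <- sprintf("d%02d_r%d", samples$day, samples$replicate)
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(library$guide_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    ab <- 10^(base + sl * samples$day[j])
    mu <- ab / sum(ab) * depth
    counts[, j] <- rnbinom(n, size = dispersion, mu = mu)
  }
  list(counts = counts,
       samples = samples[, c("sample", "replicate", "day")])
}

#' Plant guide/element-to-gene links for a single-cell perturbation simulation
#'
#' When `elements` (a planted-element table) is supplied, guides targeting
#' those elements are carried into the experiment first and linked guides are
#' drawn preferentially from them — mirroring the study design, where the
#' single-cell perturbation library was built from guides of top-scoring
#' screen elements.
#'
#' @param panel gene annotation data.frame (gene, chrom, tss, strand).
#' @param library guide library (targeting guides become candidate perturbations).
#' @param n_links number of planted links.
#' @param log2_fc effect size(s), log2 scale (recycled; sign kept).
#' @param baseline_mean mean of per-gene baseline NB means (lognormal draw).
#' @param dispersion per-gene NB theta (default 2).
#' @param n_guides number of targeting guides to carry into the experiment
#'   (sampled; controls always included). NULL = all.
#' @param elements optional planted-element table (element_id, start, end).
#' @param seed integer seed.
#' @return list: `links` (guide_id, element_id, gene, log2_fc),
#'   `baseline` (gene, mean, theta), `guides` (subset of library).
#' @export
sim_tesla_truth <- function(panel, library, n_links = 10L, log2_fc = 1,
                            baseline_mean = 5, dispersion = 2,
                            n_guides = NULL, elements = NULL, seed = 1L) {
  .need(nrow(panel) > 0, "panel must be nonempty")
  set.seed(sub_seed(seed, "tesla_truth"))
  targ <- library[!library$is_control, , drop = FALSE]
  pos <- (targ$start + targ$end) / 2
  el_of <- rep(NA_character_, nrow(targ))
  if (!is.null(elements) && nrow(elements) > 0) {
    for (i in seq_len(nrow(elements)))
      el_of[pos >= elements$start[i] & pos < elements$end[i]] <-
        elements$element_id[i]
  }
  if (!is.null(n_guides) && n_guides < nrow(targ)) {
    pref <- which(!is.na(el_of))
    take <- if (length(pref) >= n_guides) sort(sample(pref, n_guides))
    else sort(c(pref, sample(which(is.na(el_of)), n_guides - length(pref))))
    targ <- targ[take, , drop = FALSE]
    el_of <- el_of[take]
  }
  guides <- rbind(targ, library[library$is_control, , drop = FALSE])
  .need(n_links <= nrow(targ), "too many links requested")
  # linked guides: spread over distinct elements first, then the rest
  in_el <- which(!is.na(el_of))
  ord <- c(in_el[!duplicated(el_of[in_el])][sample.int(sum(!duplicated(el_of[in_el])))],
           sample(setdiff(seq_len(nrow(targ)), in_el[!duplicated(el_of[in_el])])))
  lg <- ord[seq_len(n_links)]
  genes <- sample(panel$gene, n_links, replace = n_links > nrow(panel))
  fc <- rep_len(log2_fc, n_links)
  baseline <- data.frame(
    gene = panel$gene,
    mean = rlnorm(nrow(panel), log(baseline_mean), 0.5),
    theta = rep_len(dispersion, nrow(panel)),
    stringsAsFactors = FALSE)
  list(links = data.frame(guide_id = targ$guide_id[lg],
                          element_id = el_of[lg],
                          gene = genes, log2_fc = fc,
                          stringsAsFactors = FALSE),
       baseline = baseline, guides = guides)
}

#' Simulate a targeted single-cell perturbation experiment
#'
#' Cells receive a Poisson(`moi`) number of true guides; true guides get raw
#' counts from a high mode (NB mean `high_mode`), and every other guide leaks
#' an ambient count from a low mode (mean `low_mode`) with probability
#' `ambient_guide_rate` — producing the bimodal guide-count pattern. Panel
#' gene counts are NB with per-gene baseline means shifted by 2^log2_fc in
#' carrier cells, multiplied by a per-cell depth factor, a per-run depth
#' factor and a per-run per-gene batch shift.
#'
#' @param panel gene annotation (gene, chrom, tss, strand).
#' @param truth output of [sim_tesla_truth()].
#' @param n_cells total cells across runs.
#' @param moi mean true guides per cell, in (0, 2\] (default 1 so the median
#'   unique true-guide count is 1).
#' @param ambient_guide_rate per-guide ambient leak probability (default 0.006).
#' @param runs number of batch runs (default 2).
#' @param low_mode,high_mode raw-scale guide-count mode means (0.15 / 20).
#'   Ambient contamination is modelled as a mostly single-molecule event
#'   (Poisson with small mean, zeros dropped); a heavier low mode would not
#'   be log10-separable from the high mode at the intended accuracy.
#' @param batch_sd sd of per-run per-gene log batch shifts (default 0.1).
#' @param seed integer seed.
#' @return list: `gene_counts` (cells x genes), `guide_counts`
#'   (cells x guides), `run` (factor per cell), `true_guides` (list per cell),
#'   `batch_factors`.
#' @export
sim_tesla_counts <- function(panel, truth, n_cells = 2000L, moi = 1,
                             ambient_guide_rate = 0.006, runs = 2L,
                             low_mode = 0.15, high_mode = 20,
                             batch_sd = 0.1, seed = 1L) {
  .need(moi > 0 && moi <= 2, "moi must lie in (0, 2]")
  .need(nrow(panel) > 0, "panel must be nonempty")
  guides <- truth$guides
  .need(all(truth$links$guide_id %in% guides$guide_id),
        "truth links reference unknown guides")
  .need(all(truth$links$gene %in% panel$gene),
        "truth links reference genes absent from panel")
  set.seed(sub_seed(seed, "tesla_counts"))
  ng <- nrow(guides); npan <- nrow(panel)
  run <- factor(rep_len(paste0("run", seq_len(runs)), n_cells))
  # depth and batch factors are contrasts (centred); the absolute expression
  # scale belongs to the per-gene baseline means
  run_depth <- exp(rnorm(runs, 0, 0.15))
  run_depth <- setNames(run_depth / exp(mean(log(run_depth))), levels(run))
  batch_shift <- matrix(rnorm(runs * npan, 0, batch_sd), runs, npan,
                        dimnames = list(levels(run), panel$gene))
  batch_shift <- sweep(batch_shift, 2, colMeans(batch_shift))
  cell_depth <- rlnorm(n_cells, 0, 0.3)
  cell_depth <- cell_depth / mean(cell_depth)
  n_true <- rpois(n_cells, moi)
  true_guides <- lapply(n_true, function(k) if (k > 0) sample.int(ng, min(k, ng)) else integer(0))
  # guide counts: ambient low mode everywhere (sparse), high mode for true guides
  n_amb <- rbinom(n_cells, ng, ambient_guide_rate)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (c in seq_len(n_cells)) {
    amb <- if (n_amb[c] > 0) sample.int(ng, n_amb[c]) else integer(0)
    tg <- true_guides[[c]]
    amb <- setdiff(amb, tg)
    if (length(amb)) {
      v <- rpois(length(amb), low_mode)
      keep <- v > 0
      ii <- c(ii, rep.int(c, sum(keep))); jj <- c(jj, amb[keep]); xx <- c(xx, v[keep])
    }
    if (length(tg)) {
      v <- rnbinom(length(tg), size = 10, mu = high_mode * cell_depth[c])
      keep <- v > 0                    # NB dropout loses the guide entirely
      ii <- c(ii, rep.int(c, sum(keep))); jj <- c(jj, tg[keep]); xx <- c(xx, v[keep])
    }
  }
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  guide_counts <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx, dims = c(n_cells, ng),
    dimnames = list(cell_ids, guides$guide_id))
  # gene counts
  base_mu <- setNames(truth$baseline$mean, truth$baseline$gene)[panel$gene]
  theta <- setNames(truth$baseline$theta, truth$baseline$gene)[panel$gene]
  lfc_mat <- matrix(0, n_cells, npan)  # per-cell log2 shifts from carried links
  if (nrow(truth$links) > 0) {
    gidx <- match(truth$links$guide_id, guides$guide_id)
    pidx <- match(truth$links$gene, panel$gene)
    for (k in seq_len(nrow(truth$links))) {
      carrier <- vapply(true_guides, function(tg) gidx[k] %in% tg, logical(1))
      lfc_mat[carrier, pidx[k]] <- lfc_mat[carrier, pidx[k]] + truth$links$log2_fc[k]
    }
  }
  scale_c <- cell_depth * run_depth[as.character(run)]
  gene_counts <- matrix(0L, n_cells, npan, dimnames = list(cell_ids, panel$gene))
  for (j in seq_len(npan)) {
    mu <- base_mu[j] * 2^lfc_mat[, j] * scale_c *
      exp(batch_shift[as.integer(run), j])
    gene_counts[, j] <- rnbinom(n_cells, size = theta[j], mu = mu)
  }
  list(gene_counts = gene_counts, guide_counts = guide_counts, run = run,
       true_guides = lapply(true_guides, function(i) guides$guide_id[i]),
       batch_factors = list(run_depth = run_depth, batch_shift = batch_shift))
}

#' Simulate chromatin feature tracks over the screen region
#'
#' Emits per-feature bedGraph-style tables of binned read counts with elevated
#' signal (about 3 background sd) at a labelled random subset of planted
#' elements. Which elements are enriched per feature is recorded in the
#' `enriched` attribute for truth checks.
#'
#' @param region list with chrom/start/end (and optional bin_size, default 100).
#' @param truth planted elements (may have zero rows).
#' @param enriched_fraction fraction of elements enriched per feature, in \[0,1\].
#' @param features track names (default ATAC + 4 histone marks).
#' @param tf_features optional extra per-TF track names.
#' @param seed integer seed.
#' @return named list of data.frames (chrom, start, end, score) with an
#'   `enriched` attribute mapping feature -> element ids.
#' @export
sim_tracks <- function(region, truth, enriched_fraction = 0.5,
                       features = c("ATAC", "H3K27ac", "H3K4me1",
                                    "H3K4me3", "H3K27me3"),
                       tf_features = character(0), seed = 1L) {
  .need(enriched_fraction >= 0 && enriched_fraction <= 1,
        "enriched_fraction must lie in [0, 1]")
  bs <- if (!is.null(region$bin_size)) region$bin_size else 100L
  starts <- seq(region$start, region$end - bs, by = bs)
  n_bins <- length(starts)
  all_feats <- c(features, tf_features)
  set.seed(sub_seed(seed, "tracks"))
  n_el <- if (is.null(truth)) 0L else nrow(truth)
  el_bins <- if (n_el > 0) lapply(seq_len(n_el), function(i) {
    which(starts >= truth$start[i] & starts < truth$end[i])
  }) else list()
  out <- list(); enr <- list()
  for (f in all_feats) {
    # background: lognormal binned counts, mean ~ 20 reads/bin
    score <- rlnorm(n_bins, log(20), 0.5)
    pick <- integer(0)
    if (n_el > 0 && enriched_fraction > 0) {
      k <- ceiling(enriched_fraction * n_el)
      pick <- sort(sample(n_el, k))
      sd_bg <- sd(score)
      for (i in pick) score[el_bins[[i]]] <- score[el_bins[[i]]] + 3 * sd_bg
    }
    out[[f]] <- data.frame(chrom = region$chrom, start = starts,
                           end = starts + bs, score = round(score, 3),
                           stringsAsFactors = FALSE)
    enr[[f]] <- if (length(pick)) truth$element_id[pick] else character(0)
  }
  attr(out, "enriched") <- enr
  out
}

#' Simulate interaction score tables for element-gene pairs
#'
#' Pairs in `truth_subset` receive scores planted above the integration
#' thresholds (Chicago > 3, Shaman >= 25, and high catalog scores for
#' epimap/abc); all other pairs score below them.
#'
#' @param pairs data.frame with columns element_id, chrom, start, end
#'   (element interval), gene, tss.
#' @param truth_subset character vector of "element_id:gene" keys to plant.
#' @param score_kind one of "chicago", "shaman", "epimap", "abc".
#' @param tissues tissue labels for abc (default two).
#' @param seed integer seed.
#' @return data.frame: chromA/startA/endA (element side), chromB/startB/endB
#'   (TSS side), score, plus gene and tissue columns for epimap/abc.
#' @export
sim_interactions <- function(pairs, truth_subset = character(0),
                             score_kind = c("chicago", "shaman", "epimap", "abc"),
                             tissues = c("tissueA", "tissueB"), seed = 1L) {
  .need(nrow(pairs) > 0, "pairs must be nonempty")
  score_kind <- match.arg(score_kind)
  set.seed(sub_seed(seed, paste0("interactions_", score_kind)))
  key <- paste(pairs$element_id, pairs$gene, sep = ":")
  hot <- key %in% truth_subset
  rng <- switch(score_kind,
                chicago = list(hi = c(4, 15), lo = c(0, 2.5)),
                shaman = list(hi = c(30, 80), lo = c(0, 20)),
                epimap = list(hi = c(0.6, 1.0), lo = c(0, 0.2)),
                abc = list(hi = c(0.05, 0.4), lo = c(0, 0.01)))
  score <- ifelse(hot, runif(nrow(pairs), rng$hi[1], rng$hi[2]),
                  runif(nrow(pairs), rng$lo[1], rng$lo[2]))
  out <- data.frame(
    chromA = pairs$chrom, startA = pairs$start, endA = pairs$end,
    chromB = pairs$chrom, startB = pairs$tss, endB = pairs$tss + 1,
    score = round(score, 4), stringsAsFactors = FALSE)
  if (score_kind %in% c("epimap", "abc")) out$gene <- pairs$gene
  if (score_kind == "abc") {
    # one record per tissue; the planted max stays in rng$hi
    out <- out[rep(seq_len(nrow(out)), each = length(tissues)), ]
    out$tissue <- rep(tissues, nrow(pairs))
    jitter <- runif(nrow(out), 0.5, 1)
    out$score <- round(out$score * ifelse(duplicated(paste(out$chromA, out$startA, out$gene)),
                                          jitter, 1), 4)
    rownames(out) <- NULL
  }
  out
}

#' Simulate a gene annotation panel around the screen region
#'
#' @param region list with chrom/start/end.
#' @param n_genes panel size.
#' @param span bp of flank on each side of the region in which TSSs may fall.
#' @param seed integer seed.
#' @return data.frame: gene, chrom, tss, strand.
#' @export
sim_gene_panel <- function(region, n_genes = 24L, span = 2e6, seed = 1L) {
  set.seed(sub_seed(seed, "gene_panel"))
  lo <- max(0, region$start - span); hi <- region$end + span
  tss <- sort(sample(seq(lo, hi), n_genes))
  data.frame(gene = sprintf("GENE%02d", seq_len(n_genes)),
             chrom = region$chrom, tss = tss,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}
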