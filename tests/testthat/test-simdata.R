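# Synthetic-data generators: planted structure, marginals, determinism.

region2mb <- list(chrom = "chr4", start = 41000000, end = 43000000,
                  bin_size = 100L)

test_that("guide library respects bin occupancy and control count", {
  lib <- make_guide_library(region2mb, seed = 3)
  targ <- lib[!lib$is_control, ]
  expect_gte(nrow(targ), 40000)
  expect_lte(nrow(targ), 60000)
  expect_equal(sum(lib$is_control), 100)
  expect_true(all(is.na(lib$start[lib$is_control])))
  expect_false(any(duplicated(lib$guide_id)))
  # per-bin occupancy within the requested range
  occ <- table(targ$bin)
  expect_true(all(occ >= 2 & occ <= 3))
  expect_error(make_guide_library(list(chrom = "c", start = 10, end = 10)),
               "empty region")
})

test_that("screen counts: determinism, depth marginals, planted fold change", {
  w <- make_screen_world(4, n_bins = 300, null = TRUE)
  w2 <- make_screen_world(4, n_bins = 300, null = TRUE)
  expect_identical(w$counts, w2$counts)
  depth <- 400 * nrow(w$lib)
  expect_true(all(abs(colSums(w$counts) / depth - 1) < 0.05))
  # planted slope -0.05/day: expected day-33/day-5 CPM ratio 10^(-0.05*28)
  expect_equal(10^(-0.05 * 28), 0.0398, tolerance = 1e-3)
  ww <- make_screen_world(7, n_bins = 300, n_elements = 3, slope = 0.05)
  cpm <- normalize_cpm(ww$counts)
  means <- timepoint_means(cpm, ww$samples)
  pos <- (ww$lib$start + ww$lib$end) / 2
  el <- ww$truth[ww$truth$direction == "depleted", ][1, ]
  gid <- ww$lib$guide_id[!ww$lib$is_control & pos >= el$start & pos < el$end]
  ratio <- mean(means[gid, "33"]) / mean(means[gid, "5"])
  expect_lt(ratio, 0.1)   # near 0.04, NB noise and composition allowed for
  expect_gt(ratio, 0.01)
})

test_that("null screen slopes are sampling noise only", {
  w <- make_screen_world(1, n_bins = 200, null = TRUE)
  means <- timepoint_means(normalize_cpm(w$counts), w$samples)
  day <- as.numeric(colnames(means))
  y <- log10(means + 0.5)
  # per-guide OLS slope CI should cover 0 for >= 90% of guides
  dc <- day - mean(day)
  covered <- apply(y, 1, function(r) {
    b <- sum(dc * r) / sum(dc^2)
    res <- r - mean(r) - b * dc
    se <- sqrt(sum(res^2) / (length(r) - 2) / sum(dc^2))
    abs(b) <= qt(0.975, length(r) - 2) * se
  })
  expect_gte(mean(covered), 0.9)
})

test_that("tesla counts: median one true guide, planted link shifts means", {
  reg <- list(chrom = "chr4", start = 0, end = 2e6, bin_size = 100L)
  # small guide pool so the linked guide has a few hundred carrier cells
  # (tight CLT bound on the carrier-cell mean)
  lib <- make_guide_library(reg, n_controls = 4, seed = 7)
  panel <- sim_gene_panel(reg, n_genes = 20, seed = 7)
  truth <- sim_tesla_truth(panel, lib, n_links = 1, log2_fc = 1,
                           n_guides = 4, seed = 7)
  truth$baseline$mean[truth$baseline$gene == truth$links$gene] <- 5
  tc <- sim_tesla_counts(panel, truth, n_cells = 2000, seed = 7)
  expect_equal(median(lengths(tc$true_guides)), 1)
  carrier <- vapply(tc$true_guides, function(g) truth$links$guide_id %in% g,
                    logical(1))
  m <- mean(tc$gene_counts[carrier, truth$links$gene])
  expect_gte(m, 8); expect_lte(m, 12)          # NB mean 10, CLT bound
  expect_error(
    sim_tesla_counts(panel, modifyList(truth, list(
      links = data.frame(guide_id = "nope", element_id = NA, gene = "GENE01",
                         log2_fc = 1))), n_cells = 10, seed = 1),
    "unknown guides")
})

test_that("feature tracks plant enrichment as stated", {
  reg <- list(chrom = "chr4", start = 0, end = 100000, bin_size = 100L)
  lib <- make_guide_library(reg, seed = 3)
  truth <- sim_screen_truth(lib, n_elements = 8, seed = 3)
  # enriched_fraction 0: element signal indistinguishable from background
  tr0 <- sim_tracks(reg, truth, enriched_fraction = 0, seed = 3)
  atac <- tr0$ATAC
  in_el <- rep(FALSE, nrow(atac))
  for (i in seq_len(nrow(truth)))
    in_el <- in_el | (atac$start >= truth$start[i] & atac$start < truth$end[i])
  ratio <- mean(atac$score[in_el]) / mean(atac$score[!in_el])
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
  # enriched_fraction 1: every element exceeds the genome-wide background
  tr1 <- sim_tracks(reg, truth, enriched_fraction = 1, seed = 3)
  fm <- bin_feature_matrix(tr1["H3K27ac"], reg)
  el_z <- vapply(seq_len(nrow(truth)), function(i) {
    sel <- fm$bins$start >= truth$start[i] & fm$bins$end <= truth$end[i]
    mean(fm$features[sel, "H3K27ac"])
  }, numeric(1))
  expect_true(all(el_z > 1))
  expect_setequal(attr(tr1, "enriched")$ATAC, truth$element_id)
  # empty truth: background only, positive coverage
  trn <- sim_tracks(reg, truth[0, ], enriched_fraction = 0.5, seed = 3)
  expect_gt(sum(trn$ATAC$score), 0)
})

test_that("interaction scores straddle the integration thresholds", {
  pairs <- data.frame(element_id = paste0("el", 1:6), chrom = "chr4",
                      start = (1:6) * 1e4, end = (1:6) * 1e4 + 300,
                      gene = paste0("G", 1:6), tss = (1:6) * 1e4 + 5e4)
  hot <- c("el1:G1", "el4:G4")
  chic <- sim_interactions(pairs, hot, "chicago", seed = 5)
  key <- paste(pairs$element_id, pairs$gene, sep = ":")
  expect_true(all(chic$score[key %in% hot] > 3))
  expect_true(all(chic$score[!key %in% hot] <= 3))
  sham <- sim_interactions(pairs, hot, "shaman", seed = 5)
  expect_true(all(sham$score[key %in% hot] >= 25))
  expect_true(all(sham$score[!key %in% hot] < 25))
  abc <- sim_interactions(pairs, hot, "abc", seed = 5)
  expect_equal(nrow(abc), 12)  # two tissues per pair
  expect_error(sim_interactions(pairs, hot, "nope"), "arg")
})

test_that("truth tables round-trip every planted id exactly once", {
  w <- make_screen_world(9, n_bins = 400, n_elements = 10)
  expect_equal(anyDuplicated(w$truth$element_id), 0)
  expect_equal(nrow(w$truth), 10)
  expect_true(all(w$truth$start >= w$region$start & w$truth$end <= w$region$end))
  expect_true(all(sign(w$truth$slope) ==
                    ifelse(w$truth$direction == "depleted", -1, 1)))
})
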