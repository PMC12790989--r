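# Single-cell perturbation analysis: thresholding, filtering, normalization,
# background construction and the hurdle test.

make_tesla_world <- function(seed, n_cells = 1500, n_links = 4,
                             log2_fc = 1.5, n_guides = 40, n_genes = 20) {
  reg <- list(chrom = "chr4", start = 0, end = 2e6, bin_size = 100L)
  lib <- make_guide_library(reg, seed = seed)
  panel <- sim_gene_panel(reg, n_genes = n_genes, seed = seed)
  truth <- sim_tesla_truth(panel, lib, n_links = n_links, log2_fc = log2_fc,
                           n_guides = n_guides, seed = seed)
  tc <- sim_tesla_counts(panel, truth, n_cells = n_cells, seed = seed)
  list(lib = lib, panel = panel, truth = truth, tc = tc)
}

test_that("guide thresholding separates the planted modes", {
  w <- make_tesla_world(2)
  thr <- threshold_guide_counts(w$tc$guide_counts)
  expect_equal(thr$method, "gmm")
  gm <- as.matrix(w$tc$guide_counts)
  keep <- as.matrix(thr$counts) > 0
  truthm <- matrix(FALSE, nrow(gm), ncol(gm))
  for (c in seq_len(nrow(gm)))
    truthm[c, match(w$tc$true_guides[[c]], colnames(gm))] <- TRUE
  nz <- gm > 0
  expect_gte(mean(keep[nz & truthm]), 0.99)    # high mode retained
  expect_gte(mean(!keep[nz & !truthm]), 0.99)  # low mode zeroed
})

test_that("degenerate guide counts trigger the fixed min-2 fallback", {
  m <- matrix(0, 10, 4, dimnames = list(paste0("c", 1:10), paste0("g", 1:4)))
  m[1:5, 1] <- 3
  thr <- expect_no_error(threshold_guide_counts(m))
  expect_equal(thr$method, "fixed")
  # two distinct values still degenerate; count 1 zeroed, count 2 kept
  # under the fixed minimum-2 fallback
  m2 <- matrix(0, 10, 4, dimnames = dimnames(m))
  m2[1:5, 1] <- 2; m2[6, 2] <- 1
  thr2 <- threshold_guide_counts(m2)
  expect_equal(thr2$method, "fixed")
  expect_equal(thr2$counts[6, 2], 0)
  expect_equal(thr2$counts[1, 1], 2)
  expect_error(threshold_guide_counts(matrix(0, 3, 3)), "all zero")
})

test_that("cell/gene filtering drops empties and is idempotent", {
  genes <- matrix(c(5, 0, 3,
                    2, 0, 1,
                    0, 0, 0), 3, 3, byrow = TRUE,
                  dimnames = list(paste0("c", 1:3), paste0("G", 1:3)))
  guides <- matrix(c(4, 0,
                     0, 0,
                     6, 0), 3, 2, byrow = TRUE,
                   dimnames = list(paste0("c", 1:3), paste0("g", 1:2)))
  run <- factor(c("r1", "r1", "r2"))
  f <- filter_cells_genes(genes, guides, run)
  expect_equal(f$cells, "c1")                 # c2: no guide signal; c3: no genes
  expect_false("G2" %in% colnames(f$gene_counts))
  expect_false("g2" %in% colnames(f$guide_counts))
  f2 <- filter_cells_genes(f$gene_counts, f$guide_counts, f$run)
  expect_identical(f$gene_counts, f2$gene_counts)
  expect_error(filter_cells_genes(genes, guides * 0, run), "everything")
})

test_that("normalization: log path, batch removal, Pearson variance", {
  w <- make_tesla_world(4)
  thr <- threshold_guide_counts(w$tc$guide_counts)
  f <- filter_cells_genes(w$tc$gene_counts, thr$counts, w$tc$run)
  expect_equal(normalize_expression(matrix(c(0, 5, 3, 8), 2, 2,
                                           dimnames = list(c("a", "b"), c("x", "y"))),
                                    factor(c("r", "r")),
                                    method = "log_normalize",
                                    batch_regress = FALSE)[1, 1], 0)
  # planted batch shift is removed to well under its magnitude
  nb <- normalize_expression(f$gene_counts, f$run, method = "log_normalize",
                             batch_regress = TRUE)
  d <- abs(colMeans(nb[f$run == "run1", , drop = FALSE]) -
             colMeans(nb[f$run == "run2", , drop = FALSE]))
  expect_lt(max(d), 0.02)
  pr <- normalize_expression(f$gene_counts, f$run, method = "pearson_nb")
  v <- apply(pr, 2, var)
  expect_true(all(v > 0.5 & v < 2))
  expect_warning(
    normalize_expression(f$gene_counts[f$run == "run1", ],
                         f$run[f$run == "run1"], batch_regress = TRUE),
    "no-op")
})

test_that("distal background applies the 400 kb boundary inclusively", {
  # perturbation locus is the interval [1000000, 1000020]; gNear's midpoint
  # sits 399,999 bp beyond its end, gFar's exactly 400,000 bp
  lib <- data.frame(
    guide_id = c("gA", "gNear", "gFar", "ctrl1"),
    chrom = c("chr4", "chr4", "chr4", NA),
    start = c(1000000, 1400009, 1400010, NA),
    end = c(1000020, 1400029, 1400030, NA),
    bin = NA, is_control = c(FALSE, FALSE, FALSE, TRUE))
  gc <- matrix(0, 4, 4, dimnames = list(paste0("c", 1:4), lib$guide_id))
  gc[1, "gA"] <- 10; gc[2, "gNear"] <- 10; gc[3, "gFar"] <- 10
  gc[4, "ctrl1"] <- 10
  carriers <- gc[, "gA"] > 0
  bg <- build_background("gA", gc, lib, carriers)
  expect_setequal(bg, c(3, 4))   # far guide and control included, near excluded
  gc2 <- gc; gc2[3, "gFar"] <- 0; gc2[4, "ctrl1"] <- 0
  expect_error(build_background("gA", gc2, lib, carriers), "gA")
  expect_error(build_background("ctrl1", gc, lib, carriers), "position")
})

test_that("hurdle test is calibrated and powered", {
  set.seed(9)
  n <- 300; carrier <- rep(c(TRUE, FALSE), c(75, 225))
  ps <- replicate(400, {
    depth <- rlnorm(n, 0, 0.3)
    cnt <- rnbinom(n, size = 2, mu = 5 * depth)
    covr <- rpois(n, 30 * depth / mean(depth))
    hurdle_test(log1p(cnt / depth * median(depth)), cnt > 0, carrier, covr)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_gte(mean(ps < 0.05), 0.03); expect_lte(mean(ps < 0.05), 0.07)
  # power at log2 fc 1 with 100 carriers
  set.seed(10)
  hits <- replicate(25, {
    depth <- rlnorm(1100, 0, 0.3)
    carrier <- rep(c(TRUE, FALSE), c(100, 1000))
    mu <- 5 * depth * ifelse(carrier, 2, 1)
    cnt <- rnbinom(1100, size = 2, mu = mu)
    covr <- rpois(1100, 30 * depth / mean(depth))
    ht <- hurdle_test(log1p(cnt / depth * median(depth)), cnt > 0, carrier, covr)
    ht$p < 0.05 / 20 && ht$lfc > 0    # survives a 20-test BH-scale correction
  })
  expect_gte(mean(hits), 0.9)
  # undetected gene: flagged null result
  ht0 <- hurdle_test(rep(0, 10), rep(FALSE, 10), rep(c(TRUE, FALSE), 5),
                     rnorm(10))
  expect_equal(ht0$p, 1); expect_equal(ht0$lfc, 0); expect_true(ht0$flagged)
})

test_that("run_de recovers planted links and agrees across levels", {
  w <- make_tesla_world(13, n_cells = 2500, n_links = 5, log2_fc = 1.5,
                        n_guides = 30)
  thr <- threshold_guide_counts(w$tc$guide_counts)
  f <- filter_cells_genes(w$tc$gene_counts, thr$counts, w$tc$run)
  norm <- normalize_expression(f$gene_counts, f$run)
  de <- run_de(f, norm, w$lib, level = "guide")
  sig <- de[de$significant, ]
  keyt <- paste(w$truth$links$guide_id, w$truth$links$gene)
  keys <- paste(sig$id, sig$gene)
  expect_gte(sum(keyt %in% keys), 4)          # >= 4 of 5 links found
  rec <- de[paste(de$id, de$gene) %in% keyt, ]
  expect_true(all(sign(rec$lfc[rec$significant]) ==
                    sign(w$truth$links$log2_fc[match(
                      paste(rec$id, rec$gene)[rec$significant], keyt)])))
  expect_true(all(de$adj_p >= de$p - 1e-12))
  # care level: one CaRE per linked guide position -> same lfc signs
  gl <- w$lib[match(w$truth$links$guide_id, w$lib$guide_id), ]
  cares <- data.frame(care_id = paste0("CaRE", seq_len(nrow(gl))),
                      chrom = gl$chrom, start = gl$start - 100,
                      end = gl$end + 100, direction = "depleted")
  dec <- run_de(f, norm, w$lib, level = "care", cares = cares)
  mg <- merge(data.frame(gk = paste(w$truth$links$gene),
                         care_id = cares$care_id),
              dec, by.x = c("care_id", "gk"), by.y = c("id", "gene"))
  mgg <- merge(mg, data.frame(care_id = cares$care_id,
                              glfc = de$lfc[match(keyt, paste(de$id, de$gene))]),
               by = "care_id")
  expect_true(all(sign(mgg$lfc) == sign(mgg$glfc)))
})
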