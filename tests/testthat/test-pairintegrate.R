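# Pair integration: interaction squares, threshold flags, ABC assignment,
# evidence classes and geometry.

test_that("pair_square_max equals the brute-force double loop", {
  for (seed in 1:15) {
    inst <- rand_square_instance(seed)
    h <- sample(c(2500, 12500), 1)
    expect_equal(pair_square_max(inst$pairs, inst$scores, h),
                 oracle_square_max(inst$pairs, inst$scores, h))
  }
  inst <- rand_square_instance(1)
  expect_true(all(is.na(pair_square_max(inst$pairs, inst$scores[0, ], 12500))))
  expect_error(pair_square_max(inst$pairs, inst$scores, -5), "half_width")
})

test_that("square boundary is half-open on the expanded interval", {
  sc <- data.frame(chromA = "c", startA = 1000, endA = 2000,
                   chromB = "c", startB = 5000, endB = 6000, score = 7)
  p_in <- data.frame(chrom = "c", mid = 2000 + 500 - 1, tss_chrom = "c",
                     tss = 5500)
  p_out <- data.frame(chrom = "c", mid = 2000 + 500, tss_chrom = "c",
                      tss = 5500)
  expect_equal(pair_square_max(p_in, sc, 500), 7)
  expect_true(is.na(pair_square_max(p_out, sc, 500)))
  # order-insensitive matching
  p_swap <- data.frame(chrom = "c", mid = 5500, tss_chrom = "c", tss = 1500)
  expect_equal(pair_square_max(p_swap, sc, 500), 7)
})

test_that("interaction flags follow strict/inclusive thresholds", {
  f <- flag_interactions(c(3.0, 3.0001, NA), c(25.0, 24.999, NA))
  expect_equal(f$chicago_interacting, c(FALSE, TRUE, FALSE))
  expect_equal(f$shaman_interacting, c(TRUE, FALSE, FALSE))
})

test_that("ABC assignment: gene identity, square, max over tissues", {
  pairs <- data.frame(chrom = "chr4", mid = 10000, gene = "G1")
  abc <- data.frame(chrom = "chr4", start = c(9000, 9000, 9000),
                    end = c(11000, 11000, 11000),
                    gene = c("G1", "G1", "G2"),
                    tissue = c("t1", "t2", "t1"),
                    score = c(0.02, 0.05, 0.9))
  expect_equal(abc_assign(pairs, abc, 2500), 0.05)
  # gene mismatch within the square stays unmatched
  expect_true(is.na(abc_assign(data.frame(chrom = "chr4", mid = 10000,
                                          gene = "G3"), abc, 2500)))
  for (seed in 1:10) {
    set.seed(seed)
    p <- data.frame(chrom = "chr4", mid = sample.int(1e5, 15),
                    gene = sample(paste0("G", 1:5), 15, replace = TRUE))
    a <- data.frame(chrom = "chr4", start = sample.int(1e5, 40),
                    gene = sample(paste0("G", 1:5), 40, replace = TRUE),
                    tissue = "t", score = runif(40))
    a$end <- a$start + sample(100:3000, 40, replace = TRUE)
    expect_equal(abc_assign(p, a, 2500), oracle_abc(p, a, 2500))
  }
})

test_that("evidence classes follow the 250 bp rule and nb precedence", {
  care <- function(s) data.frame(chrom = "chr1", start = s, end = s + 100)
  nb <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  ep <- data.frame(chrom = "chr1", start = 1000, end = 1100, class = "enhancer")
  # distances 0 / 250 / 251 from the nb element
  expect_equal(classify_evidence(care(1050), nb, NULL)$evidence_class, "nb")
  expect_equal(classify_evidence(care(1350), nb, NULL)$evidence_class, "nb")
  expect_equal(classify_evidence(care(1351), nb, NULL)$evidence_class, "noEF")
  # 251 bp from nb but overlapping an EpiMap enhancer -> other
  r <- classify_evidence(care(1351), data.frame(chrom = "chr1", start = 1000,
                                                end = 1100),
                         data.frame(chrom = "chr1", start = 1300, end = 1500,
                                    class = "enhancer"))
  expect_equal(r$evidence_class, "other")
  expect_equal(r$epimap_class, "enhancer")
  # dyad maps to promoter
  r2 <- classify_evidence(care(2000), nb,
                          data.frame(chrom = "chr1", start = 2000, end = 2100,
                                     class = "dyad"))
  expect_equal(r2$epimap_class, "promoter")
  # permutation invariance of element order; classes partition
  set.seed(3)
  cares <- data.frame(chrom = "chr1", start = seq(0, 9000, 1000),
                      end = seq(100, 9100, 1000))
  nbs <- data.frame(chrom = "chr1", start = sample.int(9000, 5), end = 0)
  nbs$end <- nbs$start + 200
  eps <- data.frame(chrom = "chr1", start = sample.int(9000, 5), end = 0,
                    class = "enhancer")
  eps$end <- eps$start + 200
  c1 <- classify_evidence(cares, nbs, eps)
  c2 <- classify_evidence(cares, nbs[sample(5), ], eps[sample(5), ])
  expect_equal(c1$evidence_class, c2$evidence_class)
  expect_true(all(c1$evidence_class %in% c("nb", "other", "noEF")))
})

test_that("pair geometry counts strictly intervening TSSs", {
  ann <- data.frame(gene = paste0("G", 1:5), chrom = "chr1",
                    tss = c(1000, 2000, 3000, 4000, 5000))
  care <- list(chrom = "chr1", start = 450, end = 550)    # midpoint 500
  g <- pair_geometry(care, list(gene = "G4", chrom = "chr1", tss = 4000), ann)
  expect_equal(g$jumped_genes, 3)
  expect_equal(g$distance, 3500)
  # adjacent gene: nothing between
  g2 <- pair_geometry(care, list(gene = "G1", chrom = "chr1", tss = 1000), ann)
  expect_equal(g2$jumped_genes, 0)
  # midpoint exactly at the TSS
  g3 <- pair_geometry(list(chrom = "chr1", start = 950, end = 1050),
                      list(gene = "G1", chrom = "chr1", tss = 1000), ann)
  expect_equal(g3$distance, 0)
  gt <- pair_geometry(care, list(gene = "GX", chrom = "chr2", tss = 1), ann)
  expect_true(gt$trans); expect_true(is.na(gt$distance))
})

test_that("integrate_pairs builds a coherent master table", {
  de <- data.frame(id = c("CaRE0001", "CaRE0002"), gene = c("G1", "G2"),
                   lfc = c(1.2, -0.3), p = c(1e-6, 0.4),
                   adj_p = c(2e-6, 0.5), significant = c(TRUE, FALSE))
  cares <- data.frame(care_id = c("CaRE0001", "CaRE0002"), chrom = "chr4",
                      start = c(10000, 50000), end = c(10400, 50400))
  ann <- data.frame(gene = c("G1", "G2"), chrom = "chr4", tss = c(30000, 20000))
  chic <- data.frame(chromA = "chr4", startA = 10100, endA = 10300,
                     chromB = "chr4", startB = 30000, endB = 30001, score = 8)
  rec <- integrate_pairs(de, cares, ann, chicago = chic,
                         nb_elements = data.frame(chrom = "chr4",
                                                  start = 10350, end = 10600))
  expect_equal(rec$chicago_score, c(8, NA))
  expect_equal(rec$chicago_interacting, c(TRUE, FALSE))
  expect_equal(rec$evidence_class, c("nb", "noEF"))
  expect_equal(rec$distance, c(abs(10200 - 30000), abs(50200 - 20000)))
  expect_equal(rec$jumped_genes, c(1L, 1L))
})
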