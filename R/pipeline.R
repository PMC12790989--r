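# Pipeline driver: configuration with paper-stated defaults, the five-stage
# synthetic run (simulate -> screen -> tesla -> features -> integrate) and a
# JSON manifest recording seeds, thresholds and output checksums.

#' Default pipeline configuration
#'
#' Every tunable defaults to the stated analysis value where one exists
#' (alpha 0.05, merge gap 500 bp, 400 kb distal background, 5x10 CV,
#' 25 kb / 5 kb interaction squares, 250 bp evidence distance); simulator
#' scales default to a desk-scale world (see the methods vignette).
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    region = list(chrom = "chr4", start = 41000000L, end = 41200000L,
                  bin_size = 100L),
    screen = list(guides_per_bin = c(2L, 3L), n_controls = 100L,
                  days = c(5, 20, 29, 33), replicates = 2L,
                  dispersion = 50, alpha = 0.05, max_gap = 500,
                  window_bins = 1L, pseudocount = 0.5,
                  n_elements = 12L, element_width_bins = 3L,
                  element_slope = 0.05),
    tesla = list(n_cells = 1200L, moi = 1, runs = 2L, n_genes = 24L,
                 n_links = 8L, link_log2_fc = 1.5, n_guides = 60L,
                 alpha = 0.05, min_background_distance = 400000,
                 min_guide_signal = 2, min_gene_signal = 1,
                 normalization = "pearson_nb"),
    features = list(enriched_fraction = 0.5, folds = 5L, repeats = 10L,
                    tf_features = c("MYCN", "HAND2", "GATA3")),
    integrate = list(half_width_hic = 12500, half_width_catalog = 2500,
                     max_dist = 250, n_top = 20L, n_bottom = 20L))
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()]; the file round-trips
#' losslessly through [write_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  .need(file.exists(path), "config not found: %s", path)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(upd[[k]]) && is.list(base[[k]]))
        merge_into(base[[k]], upd[[k]]) else upd[[k]]
    }
    base
  }
  merge_into(default_config(), user)
}

#' Write a pipeline configuration as YAML
#' @param config configuration list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, screen, tesla, features and integrate in order,
#' writing every stage's outputs under `outdir` and a `manifest.json`
#' recording the package version, master seed, thresholds used, completed
#' stages and the md5 checksum of every output file. No stage mutates its
#' inputs on disk; reruns with the same config are checksum-identical.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir output directory (created).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  .need(!missing(outdir), "outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  files <- character(0)
  out <- function(...) {
    p <- file.path(outdir, ...)
    files <<- c(files, p)
    p
  }

  ## --- simulate ----------------------------------------------------------
  sim <- stage("simulate", {
    reg <- config$region
    lib <- make_guide_library(reg, reg$bin_size, config$screen$guides_per_bin,
                              config$screen$n_controls, seed = seed)
    truth <- sim_screen_truth(lib, config$screen$n_elements,
                              config$screen$element_width_bins,
                              config$screen$element_slope, seed = seed)
    scr <- sim_screen_counts(lib, truth, config$screen$days,
                             config$screen$replicates,
                             dispersion = config$screen$dispersion, seed = seed)
    panel <- sim_gene_panel(reg, config$tesla$n_genes, seed = seed)
    ttruth <- sim_tesla_truth(panel, lib, config$tesla$n_links,
                              config$tesla$link_log2_fc,
                              n_guides = config$tesla$n_guides,
                              elements = truth, seed = seed)
    tc <- sim_tesla_counts(panel, ttruth, config$tesla$n_cells,
                           config$tesla$moi, runs = config$tesla$runs,
                           seed = seed)
    tracks <- sim_tracks(reg, truth, config$features$enriched_fraction,
                         tf_features = config$features$tf_features,
                         seed = seed)
    write_tsv_table(lib, out("guide_library.tsv"))
    write_tsv_table(truth, out("screen_truth.tsv"))
    write_tsv_table(cbind(guide_id = rownames(scr$counts),
                          as.data.frame(scr$counts)), out("screen_counts.tsv"))
    write_tsv_table(scr$samples, out("screen_samples.tsv"))
    write_tsv_table(panel, out("gene_panel.tsv"))
    write_tsv_table(ttruth$links, out("tesla_truth_links.tsv"))
    write_mtx(tc$gene_counts, file.path(outdir, "tesla_genes"))
    write_mtx(tc$guide_counts, file.path(outdir, "tesla_guides"))
    files <- c(files, file.path(outdir, paste0(
      rep(c("tesla_genes", "tesla_guides"), each = 3),
      c(".mtx", ".rows.txt", ".cols.txt"))))
    for (f in names(tracks)) write_bedgraph(tracks[[f]], out(paste0("track_", f, ".bedGraph")))
    list(lib = lib, truth = truth, scr = scr, panel = panel,
         ttruth = ttruth, tc = tc, tracks = tracks)
  })

  ## --- screen ------------------------------------------------------------
  scr_res <- stage("screen", {
    res <- call_cares(sim$scr$counts, sim$scr$samples, sim$lib,
                      alpha = config$screen$alpha,
                      max_gap = config$screen$max_gap,
                      window_bins = config$screen$window_bins,
                      pseudocount = config$screen$pseudocount)
    write_tsv_table(res$guide_results, out("guide_results.tsv"))
    write_tsv_table(res$bin_results, out("bin_results.tsv"))
    write_tsv_table(res$cares, out("cares.tsv"))
    if (nrow(res$cares) > 0)
      write_bed(data.frame(chrom = res$cares$chrom, start = res$cares$start,
                           end = res$cares$end, name = res$cares$care_id,
                           score = pmin(1000, round(100 * res$cares$score))),
                out("cares.bed"))
    res
  })

  ## --- tesla -------------------------------------------------------------
  de <- stage("tesla", {
    thr <- threshold_guide_counts(sim$tc$guide_counts)
    filt <- filter_cells_genes(sim$tc$gene_counts, thr$counts, sim$tc$run,
                               config$tesla$min_guide_signal,
                               config$tesla$min_gene_signal)
    norm <- normalize_expression(filt$gene_counts, filt$run,
                                 method = config$tesla$normalization)
    cares <- scr_res$cares
    de <- run_de(filt, norm, sim$lib, level = "care", cares = cares,
                 alpha = config$tesla$alpha,
                 min_background_distance = config$tesla$min_background_distance)
    write_tsv_table(de, out("de_results.tsv"))
    write_tsv_table(data.frame(cell = filt$cells, run = filt$run,
                               n_genes_detected = filt$n_genes_detected),
                    out("cell_qc.tsv"))
    de
  })

  ## --- features ----------------------------------------------------------
  feat <- stage("features", {
    fm <- bin_feature_matrix(sim$tracks, config$region)
    in_care <- rep(FALSE, nrow(fm$bins))
    for (i in seq_len(nrow(scr_res$cares))) {
      in_care <- in_care | (fm$bins$start < scr_res$cares$end[i] &
                              fm$bins$end > scr_res$cares$start[i])
    }
    base_feats <- intersect(c("ATAC", "H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3"),
                            colnames(fm$features))
    tf_feats <- setdiff(colnames(fm$features), base_feats)
    report <- fit_care_logistic(fm$features[, base_feats, drop = FALSE], in_care)
    cv <- cv_auc(fm$features[, base_feats, drop = FALSE], in_care,
                 config$features$folds, config$features$repeats, seed = seed)
    write_tsv_table(report, out("care_logistic.tsv"))
    write_tsv_table(data.frame(model = rep(c("true", "shuffled"),
                                           each = length(cv$auc_true)),
                               auc = c(cv$auc_true, cv$auc_shuffled)),
                    out("cv_auc.tsv"))
    tfrep <- NULL
    if (length(tf_feats) > 0) {
      tfrep <- tf_logistic(fm$features[, tf_feats, drop = FALSE],
                           fm$features[, setdiff(base_feats, "H3K27me3"), drop = FALSE],
                           in_care)
      write_tsv_table(tfrep, out("tf_logistic.tsv"))
    }
    list(fm = fm, report = report, cv = cv, tf = tfrep, in_care = in_care)
  })

  ## --- integrate ---------------------------------------------------------
  integ <- stage("integrate", {
    cares <- scr_res$cares
    if (nrow(de) == 0 || nrow(cares) == 0) return(NULL)
    # interaction tables planted from the DE-significant pairs
    pair_in <- data.frame(element_id = de$id,
                          chrom = cares$chrom[match(de$id, cares$care_id)],
                          start = cares$start[match(de$id, cares$care_id)],
                          end = cares$end[match(de$id, cares$care_id)],
                          gene = de$gene,
                          tss = sim$panel$tss[match(de$gene, sim$panel$gene)])
    hot <- paste(de$id, de$gene, sep = ":")[de$significant]
    chic <- sim_interactions(pair_in, hot, "chicago", seed = seed)
    sham <- sim_interactions(pair_in, hot, "shaman", seed = seed)
    epim <- sim_interactions(pair_in, hot, "epimap", seed = seed)
    abc <- sim_interactions(pair_in, hot, "abc", seed = seed)
    for (nm in c("chic", "sham", "epim", "abc"))
      write_tsv_table(get(nm), out(paste0("scores_", nm, ".tsv")))
    nb_ev <- list(data.frame(chrom = sim$truth$chrom, start = sim$truth$start,
                             end = sim$truth$end))
    records <- integrate_pairs(
      de, cares, sim$panel, chicago = chic, shaman = sham, epimap = epim,
      abc = abc, nb_elements = nb_ev, epimap_elements = NULL,
      half_width_hic = config$integrate$half_width_hic,
      half_width_catalog = config$integrate$half_width_catalog,
      max_dist = config$integrate$max_dist)
    write_tsv_table(records, out("pair_records.tsv"))
    # random-forest separation of top vs bottom pairs by adjusted p
    n_side <- min(config$integrate$n_top, floor(nrow(records) / 2))
    rf <- NULL
    if (n_side >= 5) {
      pf <- cbind(distance = log10(records$distance + 1),
                  capturec = ifelse(is.na(records$chicago_score), 0, records$chicago_score),
                  abc = ifelse(is.na(records$abc_score), 0, records$abc_score))
      rf <- rf_pairs(pf, records$adj_p, n_top = n_side, n_bottom = n_side,
                     seed = seed)
      write_tsv_table(data.frame(feature = names(rf$importance),
                                 importance = rf$importance,
                                 oob_accuracy = rf$oob_accuracy,
                                 cv_accuracy = rf$cv_accuracy),
                      out("rf_importance.tsv"))
    }
    list(records = records, rf = rf)
  })

  files <- unique(files[file.exists(files)])
  manifest <- list(
    package = "caretile",
    version = as.character(utils::packageVersion("caretile")),
    seed = seed,
    stages = c("simulate", "screen", "tesla", "features", "integrate"),
    thresholds = list(alpha = config$screen$alpha,
                      max_gap = config$screen$max_gap,
                      window_bins = config$screen$window_bins,
                      min_background_distance = config$tesla$min_background_distance,
                      chicago_min = 3, shaman_min = 25,
                      half_width_hic = config$integrate$half_width_hic,
                      half_width_catalog = config$integrate$half_width_catalog,
                      max_dist = config$integrate$max_dist),
    outputs = lapply(setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
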