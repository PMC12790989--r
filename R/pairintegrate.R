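# Multimodal integration of element-gene pairs: interaction-square score
# assignment (Capture-C/Hi-C, 25 kb squares; enhancer catalogs, 5 kb
# squares), threshold flags, ABC score assignment by gene identity, evidence
# classification against merged region sets, and pair geometry (linear
# distance, jumped genes).

# point anchor p inside interval [s, e) expanded by h on each side,
# half-open: s - h <= p < e + h
.in_square <- function(p, s, e, h) p >= s - h & p < e + h

#' Maximum interaction score per pair within a 2D square
#'
#' A score record (two intervals, one score) matches a pair when each of its
#' intervals, expanded by `half_width` on both sides, contains the pair's
#' corresponding point anchor (element midpoint / gene TSS); matching is
#' order-insensitive in the two record intervals. Intervals are half-open, so
#' an anchor exactly at the expanded end is outside.
#'
#' @param pairs data.frame with chrom, mid (element midpoint), tss_chrom, tss.
#' @param scores data.frame: chromA, startA, endA, chromB, startB, endB, score.
#' @param half_width square half-width in bp (12500 for Capture-C/Hi-C,
#'   2500 for catalog links).
#' @return numeric vector: max matching score per pair, NA when unmatched.
#' @export
pair_square_max <- function(pairs, scores, half_width) {
  .need(half_width >= 0, "half_width must be non-negative")
  n <- nrow(pairs)
  out <- rep(NA_real_, n)
  if (is.null(scores) || nrow(scores) == 0) return(out)
  for (i in seq_len(n)) {
    m <- pairs$mid[i]; t <- pairs$tss[i]
    cm <- pairs$chrom[i]; ct <- pairs$tss_chrom[i] %||% pairs$chrom[i]
    fwd <- scores$chromA == cm & scores$chromB == ct &
      .in_square(m, scores$startA, scores$endA, half_width) &
      .in_square(t, scores$startB, scores$endB, half_width)
    rev <- scores$chromB == cm & scores$chromA == ct &
      .in_square(m, scores$startB, scores$endB, half_width) &
      .in_square(t, scores$startA, scores$endA, half_width)
    hit <- fwd | rev
    if (any(hit)) out[i] <- max(scores$score[hit])
  }
  out
}

#' Interaction flags from Chicago and Shaman scores
#'
#' Chicago interactions require score strictly greater than 3; Shaman
#' interactions require score greater than or equal to 25. Missing scores
#' are not interacting.
#'
#' @param chicago,shaman numeric score vectors (NA allowed).
#' @param chicago_min strict Chicago threshold (default 3).
#' @param shaman_min inclusive Shaman threshold (default 25).
#' @return data.frame: chicago_interacting, shaman_interacting.
#' @export
flag_interactions <- function(chicago, shaman, chicago_min = 3,
                              shaman_min = 25) {
  data.frame(
    chicago_interacting = !is.na(chicago) & chicago > chicago_min,
    shaman_interacting = !is.na(shaman) & shaman >= shaman_min)
}

#' Assign activity-by-contact scores to pairs
#'
#' An ABC record matches a pair by gene identity and by the element midpoint
#' falling in the 2 * `half_width` square around the record's region midpoint
#' (half-open); the maximum score across tissues is taken.
#'
#' @param pairs data.frame with chrom, mid, gene.
#' @param abc data.frame: chrom, start, end (region), gene, tissue, score.
#' @param half_width slop in bp (default 2500).
#' @return numeric max ABC score per pair (NA when unmatched).
#' @export
abc_assign <- function(pairs, abc, half_width = 2500) {
  n <- nrow(pairs)
  out <- rep(NA_real_, n)
  if (is.null(abc) || nrow(abc) == 0) return(out)
  amid <- (abc$start + abc$end) / 2
  for (i in seq_len(n)) {
    hit <- abc$gene == pairs$gene[i] & abc$chrom == pairs$chrom[i] &
      .in_square(pairs$mid[i], amid, amid, half_width)
    if (any(hit)) out[i] <- max(abc$score[hit])
  }
  out
}

#' Classify elements by prior regulatory evidence
#'
#' Merges the supplied neuroblastoma evidence region sets into one union; a
#' CaRE within `max_dist` bp (closest edge-to-edge distance, 0 when
#' overlapping) of that union is class "nb"; otherwise within `max_dist` of a
#' catalog (EpiMap-style) element it is "other"; otherwise "noEF". Catalog
#' class labels are normalized (dyad -> promoter, DHS -> accessible).
#'
#' @param cares data.frame with chrom, start, end.
#' @param nb_elements list of data.frames (chrom, start, end) or one
#'   data.frame; merged as the neuroblastoma evidence union.
#' @param epimap_elements data.frame with chrom, start, end and optional
#'   `class` labels.
#' @param max_dist distance threshold in bp (default 250).
#' @return data.frame: evidence_class, nb_dist, epimap_dist, epimap_class.
#' @export
classify_evidence <- function(cares, nb_elements, epimap_elements,
                              max_dist = 250) {
  as_gr <- function(d) {
    if (is.null(d) || nrow(d) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1, d$end))
  }
  if (is.data.frame(nb_elements)) nb_elements <- list(nb_elements)
  nb_df <- do.call(rbind, lapply(nb_elements, function(d)
    d[, c("chrom", "start", "end")]))
  nb_gr <- GenomicRanges::reduce(as_gr(nb_df))
  ep_gr <- as_gr(epimap_elements)
  cg <- as_gr(cares)
  nearest_dist <- function(gr) {
    if (length(gr) == 0) return(rep(Inf, length(cg)))
    d <- rep(Inf, length(cg))
    hits <- GenomicRanges::distanceToNearest(cg, gr)
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    d
  }
  nbd <- nearest_dist(nb_gr)
  epd <- nearest_dist(ep_gr)
  ep_class <- rep(NA_character_, length(cg))
  if (length(ep_gr) > 0 && !is.null(epimap_elements$class)) {
    hits <- GenomicRanges::distanceToNearest(cg, ep_gr)
    cls <- epimap_elements$class[S4Vectors::subjectHits(hits)]
    cls[cls == "dyad"] <- "promoter"
    cls[cls == "DHS"] <- "accessible"
    ep_class[S4Vectors::queryHits(hits)] <- cls
  }
  data.frame(
    evidence_class = ifelse(nbd <= max_dist, "nb",
                            ifelse(epd <= max_dist, "other", "noEF")),
    nb_dist = nbd, epimap_dist = epd,
    epimap_class = ifelse(epd <= max_dist, ep_class, NA_character_),
    stringsAsFactors = FALSE)
}

#' Linear geometry of an element-gene pair
#'
#' Distance is |element midpoint - TSS|; jumped genes counts annotated TSSs
#' (excluding the target gene) strictly between the element midpoint and the
#' target TSS. Strand is ignored. Trans pairs (different chromosomes) return
#' NA geometry with `trans = TRUE`.
#'
#' @param care list/row with chrom, start, end.
#' @param gene list/row with gene, chrom, tss.
#' @param annotation data.frame: gene, chrom, tss.
#' @return list: distance, jumped_genes, trans.
#' @export
pair_geometry <- function(care, gene, annotation) {
  if (care$chrom != gene$chrom)
    return(list(distance = NA_real_, jumped_genes = NA_integer_, trans = TRUE))
  mid <- (care$start + care$end) / 2
  lo <- min(mid, gene$tss); hi <- max(mid, gene$tss)
  ann <- annotation[annotation$chrom == gene$chrom &
                      annotation$gene != gene$gene, , drop = FALSE]
  list(distance = abs(mid - gene$tss),
       jumped_genes = sum(ann$tss > lo & ann$tss < hi),
       trans = FALSE)
}

#' Build the master integration table for element-gene pairs
#'
#' Attaches Capture-C (Chicago) and Hi-C (Shaman) square maxima with
#' interaction flags, catalog link and ABC scores, evidence classes and
#' linear geometry to a DE pair table.
#'
#' @param de DE results (id = care_id, gene, lfc, p, adj_p, ...).
#' @param cares CaRE table (care_id, chrom, start, end, ...).
#' @param annotation gene annotation (gene, chrom, tss).
#' @param chicago,shaman,epimap,abc score tables (any may be NULL).
#' @param nb_elements,epimap_elements evidence region sets (may be NULL).
#' @param half_width_hic,half_width_catalog square half-widths (12500 / 2500).
#' @param max_dist evidence distance threshold (default 250).
#' @return data.frame of PairRecords, one row per DE pair.
#' @export
integrate_pairs <- function(de, cares, annotation, chicago = NULL,
                            shaman = NULL, epimap = NULL, abc = NULL,
                            nb_elements = NULL, epimap_elements = NULL,
                            half_width_hic = 12500, half_width_catalog = 2500,
                            max_dist = 250) {
  ci <- match(de$id, cares$care_id)
  .need(!anyNA(ci), "DE ids missing from the CaRE table")
  gi <- match(de$gene, annotation$gene)
  .need(!anyNA(gi), "DE genes missing from the annotation")
  pairs <- data.frame(
    care_id = de$id, gene = de$gene,
    chrom = cares$chrom[ci],
    mid = (cares$start[ci] + cares$end[ci]) / 2,
    tss_chrom = annotation$chrom[gi], tss = annotation$tss[gi],
    stringsAsFactors = FALSE)
  chic <- pair_square_max(pairs, chicago, half_width_hic)
  sham <- pair_square_max(pairs, shaman, half_width_hic)
  flags <- flag_interactions(chic, sham)
  epi <- pair_square_max(pairs, epimap, half_width_catalog)
  abcv <- abc_assign(pairs, abc, half_width_catalog)
  ev <- if (!is.null(nb_elements) || !is.null(epimap_elements)) {
    classify_evidence(cares[ci, , drop = FALSE],
                      nb_elements %||% list(), epimap_elements, max_dist)
  } else {
    data.frame(evidence_class = rep(NA_character_, nrow(pairs)),
               nb_dist = NA_real_, epimap_dist = NA_real_,
               epimap_class = NA_character_)
  }
  geom <- t(vapply(seq_len(nrow(pairs)), function(i) {
    g <- pair_geometry(list(chrom = pairs$chrom[i],
                            start = cares$start[ci[i]], end = cares$end[ci[i]]),
                       list(gene = pairs$gene[i], chrom = pairs$tss_chrom[i],
                            tss = pairs$tss[i]), annotation)
    c(g$distance, g$jumped_genes, as.numeric(g$trans))
  }, numeric(3)))
  cbind(de,
        data.frame(care_mid = pairs$mid, tss = pairs$tss,
                   distance = geom[, 1], jumped_genes = as.integer(geom[, 2]),
                   trans = geom[, 3] > 0,
                   chicago_score = chic, shaman_score = sham,
                   epimap_score = epi, abc_score = abcv,
                   stringsAsFactors = FALSE),
        flags, ev)
}
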