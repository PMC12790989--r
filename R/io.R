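# Standard-format I/O: TSV tables (data.table), BED/bedGraph (rtracklayer,
# with pre-validation for clear line-numbered errors), MatrixMarket matrices
# with plain-text row/column sidecars. All genomic coordinates are 0-based
# half-open internally; BED on disk.

#' Read a TSV table
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  .need(file.exists(path), "file not found: %s", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Write a TSV table
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# validate a 3+ column interval table read from disk
.validate_bedlike <- function(d, path) {
  bad <- which(!is.finite(d[[2]]) | !is.finite(d[[3]]) | d[[2]] > d[[3]] | d[[2]] < 0)
  if (length(bad))
    stop(sprintf("%s: malformed interval at line %d (start > end or negative)",
                 path, bad[1] + 1L), call. = FALSE)
  invisible(TRUE)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED3/BED6 path.
#' @return data.frame: chrom, start, end (+ name, score, strand if present).
#' @export
read_bed <- function(path) {
  .need(file.exists(path), "file not found: %s", path)
  raw <- data.table::fread(path, header = FALSE, sep = "\t")
  .validate_bedlike(raw, path)
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) out$name <- mc$name
  if (!is.null(mc$score)) out$score <- mc$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write a BED file
#'
#' @param d data.frame with chrom, start, end and optional name, score,
#'   strand columns (score clamped to 0..1000 per BED convention).
#' @param path output path.
#' @export
write_bed <- function(d, path) {
  .need(all(d$end >= d$start), "BED record with start > end")
  gr <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start + 1, d$end),
    strand = if (!is.null(d$strand)) d$strand else "*")
  if (!is.null(d$name)) S4Vectors::mcols(gr)$name <- d$name
  if (!is.null(d$score)) S4Vectors::mcols(gr)$score <- pmin(pmax(round(d$score), 0), 1000)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph track
#' @param path bedGraph path.
#' @return data.frame: chrom, start, end, score.
#' @export
read_bedgraph <- function(path) {
  .need(file.exists(path), "file not found: %s", path)
  raw <- data.table::fread(path, header = FALSE, sep = "\t")
  .validate_bedlike(raw, path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = S4Vectors::mcols(gr)$score, stringsAsFactors = FALSE)
}

#' Write a bedGraph track
#' @param d data.frame with chrom, start, end, score.
#' @param path output path.
#' @export
write_bedgraph <- function(d, path) {
  .need(all(d$end >= d$start), "bedGraph record with start > end")
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1, d$end),
                               score = d$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a matrix as MatrixMarket with name sidecars
#'
#' Writes `<prefix>.mtx`, `<prefix>.rows.txt`, `<prefix>.cols.txt`.
#'
#' @param m matrix (dense or sparse) with dimnames.
#' @param prefix path prefix.
#' @export
write_mtx <- function(m, prefix) {
  sm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sm, paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".rows.txt"))
  writeLines(colnames(m), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' Read a MatrixMarket matrix with name sidecars
#'
#' @param prefix path prefix used by [write_mtx()].
#' @param dense return a base dense matrix (default FALSE).
#' @return matrix with dimnames from the sidecars.
#' @export
read_mtx <- function(prefix, dense = FALSE) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  rn <- readLines(paste0(prefix, ".rows.txt"))
  cn <- readLines(paste0(prefix, ".cols.txt"))
  .need(length(rn) == nrow(m), "row sidecar length mismatch (%d vs %d rows)",
        length(rn), nrow(m))
  .need(length(cn) == ncol(m), "column sidecar length mismatch (%d vs %d cols)",
        length(cn), ncol(m))
  dimnames(m) <- list(rn, cn)
  if (dense) as.matrix(m) else methods::as(m, "CsparseMatrix")
}
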