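# Readers/writers for the pipeline's external formats. One TSV dialect
# throughout: tab-separated, UTF-8, '#'-prefixed header lines; all
# coordinates 1-based, fully closed, stated in every file header.

.COORD_NOTE <- "# coordinates: 1-based, fully closed"

#' Write a data frame as a commented TSV
#'
#' @param df Data frame.
#' @param path Output file.
#' @param header_lines Extra '#'-prefixed comment lines.
#' @export
write_tsv_commented <- function(df, path, header_lines = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(.COORD_NOTE, paste0("# ", header_lines)[nzchar(header_lines)]),
             con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a commented TSV
#'
#' @param path File written by [write_tsv_commented()] (or any TSV with
#'   '#' comments).
#' @return Data frame.
#' @export
read_tsv_commented <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             quote = "", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write the toy reference to a directory
#'
#' Emits `genome.fasta`, `models.tsv` (GFF3-like feature table),
#' `known_variants.tsv`, `reported_sites.tsv` and the ground-truth site
#' table `sites_truth.tsv`.
#'
#' @param reference An `editing_reference`.
#' @param dir Output directory (created if needed).
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(reference$genome, file.path(dir, "genome.fasta"))
  feats <- do.call(rbind, lapply(reference$models, function(m) {
    rows <- data.frame(chrom = m$chrom, feature = "exon",
                       start = m$exons$start, end = m$exons$end,
                       strand = m$strand, gene_id = m$gene_id,
                       transcript_id = m$transcript_id)
    if (!is.null(m$cds))
      rows <- rbind(rows, data.frame(chrom = m$chrom, feature = "CDS",
                                     start = m$cds$start, end = m$cds$end,
                                     strand = m$strand, gene_id = m$gene_id,
                                     transcript_id = m$transcript_id))
    rows
  }))
  write_tsv_commented(feats, file.path(dir, "models.tsv"),
                      "GFF3-like transcript features")
  write_tsv_commented(reference$known_variants,
                      file.path(dir, "known_variants.tsv"),
                      "known genomic variant positions")
  write_tsv_commented(reference$reported_sites,
                      file.path(dir, "reported_sites.tsv"),
                      "reported A-to-I editing positions (RADAR/GTEx-style)")
  write_tsv_commented(reference$sites, file.path(dir, "sites_truth.tsv"),
                      "ground-truth planted editing sites")
  invisible(dir)
}

#' Read transcript models from a GFF3-like feature TSV
#'
#' @param path File written by [write_reference()].
#' @return Named list of [transcript_model()].
#' @export
read_models_tsv <- function(path) {
  feats <- read_tsv_commented(path)
  out <- lapply(split(feats, feats$transcript_id), function(g) {
    ex <- g[g$feature == "exon", c("start", "end")]
    cd <- g[g$feature == "CDS", c("start", "end")]
    transcript_model(g$gene_id[1], g$transcript_id[1], g$chrom[1],
                     g$strand[1], ex, if (nrow(cd)) cd else NULL)
  })
  out[order(names(out))]
}

#' Write / read an abundance matrix with `batch` and `is_GIS` header rows
#'
#' The TSV carries two annotation rows (`batch`, `is_GIS`) above the
#' peptide rows; the first column holds peptide sequences and an
#' `is_edited` flag column follows.
#'
#' @param am An [abundance_matrix()].
#' @param path Output file.
#' @export
write_abundance_tsv <- function(am, path) {
  hdr <- data.frame(peptide = c("batch", "is_GIS"), is_edited = c(NA, NA),
                    rbind(am$batch, as.integer(am$is_gis)),
                    check.names = FALSE)
  body <- data.frame(peptide = rownames(am$values),
                     is_edited = as.integer(am$is_edited), am$values,
                     check.names = FALSE)
  colnames(hdr) <- colnames(body) <- c("peptide", "is_edited",
                                       colnames(am$values))
  write_tsv_commented(rbind(hdr, body), path,
                      "peptide abundance matrix; rows 'batch' and 'is_GIS' annotate samples")
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @return `read_abundance_tsv()` returns an [abundance_matrix()].
#' @export
read_abundance_tsv <- function(path) {
  d <- read_tsv_commented(path)
  batch <- as.character(unlist(d[d$peptide == "batch", -(1:2)]))
  is_gis <- as.logical(as.integer(unlist(d[d$peptide == "is_GIS", -(1:2)])))
  body <- d[!(d$peptide %in% c("batch", "is_GIS")), , drop = FALSE]
  values <- as.matrix(body[, -(1:2), drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- body$peptide
  abundance_matrix(values, batch, is_gis, as.logical(as.integer(body$is_edited)))
}
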