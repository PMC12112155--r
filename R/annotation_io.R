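# GFF3/GTF boundary: rtracklayer handles the formats; these helpers only
# convert between the package's 0-based half-open data.frames and GRanges.

#' Write genes and exons as GFF3
#'
#' @param genes data.frame with gene_id, chrom, start0, end0, strand
#' @param exons data.frame with gene_id, chrom, start0, end0, strand,
#'   exon_rank
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, exons, path) {
  g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start0 + 1L, genes$end0),
    strand = genes$strand)
  g$type <- "gene"; g$ID <- genes$gene_id
  e <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start0 + 1L, exons$end0),
    strand = exons$strand)
  e$type <- "exon"; e$Parent <- exons$gene_id
  e$ID <- paste0(exons$gene_id, ".exon", exons$exon_rank)
  rtracklayer::export(c(g, e), path, format = "gff3")
  invisible(path)
}

#' Read genes back from a GFF3 file
#'
#' @param path GFF3 path
#' @return data.frame with gene_id, chrom, start0, end0, strand
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  g <- gr[gr$type == "gene"]
  data.frame(gene_id = g$ID,
             chrom = as.character(GenomicRanges::seqnames(g)),
             start0 = GenomicRanges::start(g) - 1L,
             end0 = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             stringsAsFactors = FALSE)
}

#' Write transcript models as GTF
#'
#' @param models exon rows: transcript_id, gene_id, chrom, strand, start0,
#'   end0
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(models, path) {
  e <- GenomicRanges::GRanges(
    models$chrom, IRanges::IRanges(models$start0 + 1L, models$end0),
    strand = models$strand)
  e$type <- "exon"
  e$transcript_id <- models$transcript_id
  e$gene_id <- models$gene_id
  rtracklayer::export(e, path, format = "gtf")
  invisible(path)
}

#' Serialize / read a diagnostic SNP panel
#'
#' TSV with a `#rt_reference=` header line, then one row per diagnostic
#' position with per-donor allele columns.
#'
#' @param panel a [diagnostic_panel()]
#' @param path file path
#' @return `path` (write) / panel (read)
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#rt_reference=", panel$rt_reference), con)
  tab <- data.frame(position = panel$positions, t(panel$alleles),
                    check.names = FALSE)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  first <- readLines(path, n = 1)
  rt <- sub("^#rt_reference=", "", first)
  tab <- read.table(path, sep = "\t", header = TRUE, skip = 1,
                    check.names = FALSE)
  alleles <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(alleles) <- NULL
  diagnostic_panel(rt, tab$position, alleles)
}
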