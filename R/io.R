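# File format boundaries. Standard formats go through Biostrings /
# rtracklayer / Rsamtools; the modkit-style bedMethyl dialect and the
# liftover chain TSV have thin readers/writers of their own.

#' Write alignments as a SAM file
#'
#' @param aln data.frame with columns qname, flag, chrom, pos0 (0-based
#'   leftmost aligned position), mapq, cigar, seq
#' @param seqlengths named integer vector of chromosome lengths
#' @param path output path (".sam")
#' @return `path`, invisibly
#' @export
write_sam <- function(aln, seqlengths, path) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths))
  )
  aln <- aln[order(match(aln$chrom, names(seqlengths)), aln$pos0), , drop = FALSE]
  rec <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
    aln$qname, as.integer(aln$flag), aln$chrom, as.integer(aln$pos0) + 1L,
    as.integer(aln$mapq), aln$cigar, aln$seq
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read primary alignments from a SAM/BAM file
#'
#' Converts SAM to BAM via Rsamtools when needed, then loads records with
#' their CIGAR and stored (reference-oriented) sequence. Unmapped, secondary
#' and supplementary records are excluded, mirroring `samtools view -F 2308`.
#'
#' @param path SAM or BAM file
#' @return data.frame with qname, flag, chrom, pos0, end0 (0-based half-open
#'   reference span), mapq, cigar, seq, plus `n_skipped` attribute counting
#'   excluded records
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_all <- length(x$flag)
  keep <- !is.na(x$pos) & !is.na(x$cigar) &
    bitwAnd(x$flag, 4L) == 0L &     # unmapped
    bitwAnd(x$flag, 256L) == 0L &   # secondary
    bitwAnd(x$flag, 2048L) == 0L    # supplementary
  cig <- x$cigar[keep]
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  out <- data.frame(
    qname = x$qname[keep],
    flag = x$flag[keep],
    chrom = as.character(x$rname[keep]),
    pos0 = x$pos[keep] - 1L,
    mapq = x$mapq[keep],
    cigar = cig,
    seq = as.character(x$seq[keep]),
    stringsAsFactors = FALSE
  )
  out$end0 <- out$pos0 + refw
  attr(out, "n_skipped") <- n_all - sum(keep)
  out
}

#' Write per-cytosine methylation calls as bedMethyl
#'
#' modkit-style 9+2 column dialect: chrom, start, end, modification code,
#' score (valid coverage), strand, thickStart, thickEnd, color, valid
#' coverage, percent modified.
#'
#' @param records data.frame with chrom, pos0, strand, n_valid, frac_mod
#'   (and optionally context, which is not part of the format)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedmethyl <- function(records, path) {
  lines <- sprintf(
    "%s\t%d\t%d\tm\t%d\t%s\t%d\t%d\t255,0,0\t%d\t%.2f",
    records$chrom, records$pos0, records$pos0 + 1L,
    as.integer(records$n_valid), records$strand,
    records$pos0, records$pos0 + 1L,
    as.integer(records$n_valid), 100 * records$frac_mod
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedMethyl file
#'
#' @param path bedMethyl path (9+2 column modkit dialect)
#' @return data.frame with chrom, pos0, strand, n_valid, frac_mod
#' @export
read_bedmethyl <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  data.frame(
    chrom = x[[1]], pos0 = as.integer(x[[2]]), strand = x[[6]],
    n_valid = as.integer(x[[10]]), frac_mod = as.numeric(x[[11]]) / 100,
    stringsAsFactors = FALSE
  )
}

#' Serialize / read a coordinate liftover
#'
#' Chain-like TSV with columns chrom, ref_pos0 (insertion breakpoint on the
#' original reference) and ins_len (inserted block length).
#'
#' @param liftover liftover data.frame (see [build_liftover()])
#' @param path file path
#' @return `path` (write) or liftover data.frame (read)
#' @export
write_liftover <- function(liftover, path) {
  write.table(liftover[, c("chrom", "ref_pos0", "ins_len")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_liftover
#' @export
read_liftover <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  build_liftover(x)
}

#' Write a 0-based half-open BED6 file from a data.frame
#'
#' @param df data.frame with chrom, start0, end0, name (optional score,
#'   strand)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(df, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   df$chrom, as.integer(df$start0), as.integer(df$end0),
                   df$name %||% ".",
                   as.integer(df$score %||% 0),
                   df$strand %||% ".")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into a 0-based half-open data.frame
#'
#' @param path BED path
#' @return data.frame with chrom, start0, end0, name, score, strand
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

# 0-based half-open data.frame -> GRanges (1-based closed) conversion used
# by the interval statistics.
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0),
    label = if (!is.null(df$label)) df$label else df$name %||% "."
  )
}
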