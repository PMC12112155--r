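# Transcript-level consequences of TE insertions: event classification
# (intronization / ATS / ATT / other exonization / unaffected /
# not transcribed), TEI-vs-normal isoform read splitting with RPKM/TPM
# normalization, ORF prediction and protein-consequence classes.

tx_introns <- function(ex) {
  ex <- ex[order(ex$start0), , drop = FALSE]
  if (nrow(ex) < 2) return(ex[0, c("start0", "end0")])
  data.frame(start0 = ex$end0[-nrow(ex)], end0 = ex$start0[-1])
}

classify_one_transcript <- function(ex, blk, strand, tol) {
  ex <- ex[order(ex$start0), , drop = FALSE]
  intr <- tx_introns(ex)
  intronized <- nrow(intr) > 0 && any(
    abs(intr$start0 - blk[1]) <= tol & abs(intr$end0 - blk[2]) <= tol &
      intr$start0 <= blk[1] + tol & intr$end0 >= blk[2] - tol)
  in_blk <- function(p) p >= blk[1] & p < blk[2]
  end3 <- if (strand == "+") ex$end0[nrow(ex)] - 1L else ex$start0[1]
  start5 <- if (strand == "+") ex$start0[1] else ex$end0[nrow(ex)] - 1L
  att <- in_blk(end3)
  ats <- in_blk(start5)
  if (att && ats) return("ATS_and_ATT")
  if (intronized) return("intronization")
  if (att) return("ATT")
  if (ats) return("ATS")
  overlaps <- any(ex$start0 < blk[2] & blk[1] < ex$end0)
  if (overlaps) return("exonization_other")
  "unaffected"
}

DISRUPTIVE_ORDER <- c("ATS_and_ATT", "ATT", "ATS", "exonization_other",
                      "intronization", "unaffected")

#' Classify the transcriptional consequence of a TE insertion
#'
#' Rules, per expressed transcript: (1) an intron whose splice boundaries
#' lie within `boundary_tol` of the inserted block (TE + duplicated TSD)
#' boundaries and that covers the whole block -> intronization (subtype
#' existing_intron when the wild-type model already had an intron at the
#' host site, else exonic); (2) a 3'-terminal exon ending inside the TE ->
#' ATT; (3) a first exon starting inside the TE -> ATS; a transcript (or
#' gene) showing both -> ATS_and_ATT; TE partially inside an exon ->
#' exonization_other; expressed but no transcript touching the TE ->
#' unaffected; zero gene reads -> not_transcribed. The gene-level category
#' is that of the majority-support transcript, ties broken toward the more
#' disruptive category.
#'
#' @param transcripts exon rows (transcript_id, chrom, strand, start0,
#'   end0) of the gene's expressed transcripts; NULL or empty together with
#'   `gene_read_count = 0` means not transcribed
#' @param tei_block c(start0, end0): inserted block (TE + duplicated TSD)
#'   on the same coordinates
#' @param gene list/row with start0, end0, strand (the host gene)
#' @param wt_exons wild-type model exon rows for the gene (same
#'   coordinates), used for the intronization subtype
#' @param boundary_tol splice-boundary tolerance, bp
#' @param support named per-transcript read counts (optional; equal support
#'   assumed if NULL)
#' @param gene_read_count total reads over the gene
#' @return list(category, per_transcript, tei_orientation_vs_gene)
#' @export
classify_event <- function(transcripts, tei_block, gene, wt_exons,
                           boundary_tol = 10L, support = NULL,
                           gene_read_count = NULL, tei_strand = "+") {
  blk <- as.numeric(tei_block)
  if (blk[1] < gene$start0 || blk[2] > gene$end0)
    stop("insertion block does not lie within the gene interval")
  orientation <- if (is.null(gene$strand) || gene$strand == tei_strand)
    "sense" else "antisense"
  n_reads <- gene_read_count %||%
    (if (!is.null(support)) sum(support) else NULL)
  if ((!is.null(n_reads) && n_reads == 0) ||
      is.null(transcripts) || nrow(transcripts) == 0) {
    return(list(category = "not_transcribed",
                per_transcript = character(0),
                tei_orientation_vs_gene = orientation))
  }
  ids <- unique(transcripts$transcript_id)
  per_tx <- vapply(ids, function(id) {
    ex <- transcripts[transcripts$transcript_id == id, , drop = FALSE]
    classify_one_transcript(ex, blk, gene$strand %||% "+", boundary_tol)
  }, character(1))

  cats <- per_tx
  if (any(cats == "ATS_and_ATT") ||
      (any(cats == "ATS") && any(cats == "ATT"))) {
    category <- "ATS_and_ATT"
  } else {
    sup <- if (is.null(support)) setNames(rep(1, length(ids)), ids)
           else support[ids]
    by_cat <- tapply(sup, cats, sum)
    top <- names(by_cat)[by_cat == max(by_cat)]
    category <- top[order(match(top, DISRUPTIVE_ORDER))][1]
  }
  if (category == "intronization") {
    wt_exonic <- any(wt_exons$start0 < blk[2] & blk[1] < wt_exons$end0)
    category <- if (wt_exonic) "intronization_exonic"
                else "intronization_existing_intron"
  }
  list(category = category, per_transcript = per_tx,
       tei_orientation_vs_gene = orientation)
}

#' Split gene reads into TEI and normal isoform counts
#'
#' `total` is the number of reads with at least one aligned block
#' overlapping the gene; `tei_reads` those with at least one aligned base
#' inside the TEI interval; `normal = total - tei_reads`.
#'
#' @param reads aligned blocks: data.frame(read_id, chrom, start0, end0),
#'   several rows per spliced read
#' @param gene list/row with chrom, start0, end0
#' @param tei_block c(start0, end0) inside the gene
#' @return list(total_reads, tei_reads, normal_reads)
#' @export
count_isoforms <- function(reads, gene, tei_block) {
  blk <- as.numeric(tei_block)
  if (blk[1] < gene$start0 || blk[2] > gene$end0)
    stop("TEI interval outside the gene")
  r <- reads[reads$chrom == gene$chrom, , drop = FALSE]
  gene_hit <- r$start0 < gene$end0 & gene$start0 < r$end0
  tei_hit <- r$start0 < blk[2] & blk[1] < r$end0
  total <- length(unique(r$read_id[gene_hit]))
  tei <- length(unique(r$read_id[gene_hit & tei_hit]))
  list(total_reads = total, tei_reads = tei, normal_reads = total - tei)
}

#' RPKM normalization
#'
#' @param count read count
#' @param feature_len_bp feature length in bp
#' @param library_size total mapped reads
#' @return reads per kilobase per million mapped reads
#' @export
rpkm <- function(count, feature_len_bp, library_size) {
  if (any(feature_len_bp <= 0)) stop("feature length must be positive")
  if (library_size <= 0) stop("library size must be positive")
  count * 1e9 / (feature_len_bp * library_size)
}

#' TPM normalization
#'
#' @param counts read counts per feature
#' @param lengths feature lengths in bp
#' @return TPM vector (sums to 1e6)
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("feature length must be positive")
  rate <- counts / lengths
  rate / sum(rate) * 1e6
}

#' Predict open reading frames on a transcript
#'
#' All ATG-initiated frames on the transcript sense strand, extended to the
#' first in-frame stop (or to the end of the last complete codon when no
#' stop occurs); nested ORFs sharing a stop are reported once, from the
#' 5'-most ATG. Coordinates are 0-based half-open in transcript space.
#'
#' @param transcript_seq DNA string (mature transcript, sense strand)
#' @param min_len_nt minimum ORF length (start..stop inclusive), nt
#' @return data.frame: start0, end0, length_nt, has_stop
#' @export
find_orfs <- function(transcript_seq, min_len_nt = 75L) {
  n <- nchar(transcript_seq)
  empty <- data.frame(start0 = integer(), end0 = integer(),
                      length_nt = integer(), has_stop = logical())
  if (n < min_len_nt) return(empty)
  codons <- substring(transcript_seq, 1:(n - 2), 3:n)
  atg <- which(codons == "ATG")
  stp <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(atg) == 0) return(empty)
  rows <- lapply(0:2, function(fr) {
    a <- atg[(atg - 1) %% 3 == fr]
    s <- stp[(stp - 1) %% 3 == fr]
    if (length(a) == 0) return(NULL)
    ends <- vapply(a, function(st) {
      nx <- s[s > st]
      if (length(nx)) nx[1] + 2L else {
        # run to the last complete codon in this frame
        st + ((n - st + 1L) %/% 3L) * 3L - 1L
      }
    }, numeric(1))
    d <- data.frame(start1 = as.integer(a), end1 = as.integer(ends),
                    has_stop = vapply(a, function(st) any(s > st), logical(1)))
    # nested starts sharing a stop: keep the 5'-most
    d <- d[!duplicated(d$end1), , drop = FALSE]
    d
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) return(empty)
  d$length_nt <- d$end1 - d$start1 + 1L
  d <- d[d$length_nt >= min_len_nt, , drop = FALSE]
  d <- d[order(d$start1), , drop = FALSE]
  data.frame(start0 = d$start1 - 1L, end0 = d$end1,
             length_nt = d$length_nt, has_stop = d$has_stop,
             row.names = NULL)
}

#' Classify the protein consequence of an ORF
#'
#' Chimeric when the ORF spans the gene/TE junction; truncated when fully
#' gene-derived but shorter than 90% of the wild-type CDS; te_internal when
#' fully inside the TE; wild_type_like otherwise.
#'
#' @param orf list/row with start0, end0 (transcript coordinates)
#' @param te_interval_in_transcript c(start0, end0) of the TE within the
#'   transcript
#' @param wild_type_cds_len wild-type CDS length, nt
#' @return one of "chimeric", "truncated", "te_internal", "wild_type_like"
#' @export
classify_protein <- function(orf, te_interval_in_transcript,
                             wild_type_cds_len) {
  te <- as.numeric(te_interval_in_transcript)
  s <- orf$start0; e <- orf$end0
  inside <- s >= te[1] && e <= te[2]
  outside <- e <= te[1] || s >= te[2]
  if (inside) return("te_internal")
  if (!outside) return("chimeric")
  if ((e - s) < 0.9 * wild_type_cds_len) return("truncated")
  "wild_type_like"
}
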