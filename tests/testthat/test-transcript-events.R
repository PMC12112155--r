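# constructed gene: [1000, 9000), TE block planted at [3000, 7000)
GENE <- list(gene_id = "g", chrom = "chr1", start0 = 1000L, end0 = 9000L,
             strand = "+")
BLK <- c(3000L, 7000L)
WT_INTRONIC <- data.frame(gene_id = "g", chrom = "chr1",
                          start0 = c(1000L, 8000L), end0 = c(2000L, 9000L),
                          strand = "+")   # block falls in the single intron
WT_EXONIC <- data.frame(gene_id = "g", chrom = "chr1",
                        start0 = c(1000L, 2500L), end0 = c(2000L, 9000L),
                        strand = "+")     # block falls inside exon 2

mk_tx <- function(id, starts, ends, strand = "+") {
  data.frame(transcript_id = id, gene_id = "g", chrom = "chr1",
             strand = strand, start0 = as.integer(starts),
             end0 = as.integer(ends))
}

test_that("intronization is recognized with its subtype", {
  tx <- mk_tx("t1", c(1000L, 7000L), c(3000L, 9000L))  # intron == block
  ev <- classify_event(tx, BLK, GENE, WT_INTRONIC, gene_read_count = 50)
  expect_identical(ev$category, "intronization_existing_intron")
  ev2 <- classify_event(tx, BLK, GENE, WT_EXONIC, gene_read_count = 50)
  expect_identical(ev2$category, "intronization_exonic")
  # boundaries off by more than the tolerance are not intronization
  tx_off <- mk_tx("t1", c(1000L, 7020L), c(2980L, 9000L))
  ev3 <- classify_event(tx_off, BLK, GENE, WT_INTRONIC, gene_read_count = 50)
  expect_false(grepl("intronization", ev3$category))
  # within-tolerance jitter still classifies
  tx_jit <- mk_tx("t1", c(1000L, 7006L), c(2995L, 9000L))
  ev4 <- classify_event(tx_jit, BLK, GENE, WT_INTRONIC, gene_read_count = 50)
  expect_identical(ev4$category, "intronization_existing_intron")
})

test_that("ATT, ATS and their combination are strand-correct", {
  att <- mk_tx("t1", 1000L, 3500L)      # terminal exon ends 500 bp into TE
  ev <- classify_event(att, BLK, GENE, WT_INTRONIC, gene_read_count = 10)
  expect_identical(ev$category, "ATT")
  ats <- mk_tx("t2", 6500L, 9000L)      # first exon starts inside TE
  ev2 <- classify_event(ats, BLK, GENE, WT_INTRONIC, gene_read_count = 10)
  expect_identical(ev2$category, "ATS")
  # different transcripts contributing ATS and ATT -> combined category
  both <- rbind(att, ats)
  ev3 <- classify_event(both, BLK, GENE, WT_INTRONIC,
                        support = c(t1 = 5, t2 = 5), gene_read_count = 10)
  expect_identical(ev3$category, "ATS_and_ATT")
  # mirrored to the minus strand the categories are preserved
  gene_m <- modifyList(GENE, list(strand = "-"))
  att_m <- mk_tx("t1", 6500L, 9000L, strand = "-")  # 3' end at genomic start
  ev_m <- classify_event(att_m, BLK, gene_m, WT_INTRONIC, gene_read_count = 10)
  expect_identical(ev_m$category, "ATT")
  expect_identical(ev_m$tei_orientation_vs_gene, "antisense")
  ats_m <- mk_tx("t2", 1000L, 3500L, strand = "-")
  ev_m2 <- classify_event(ats_m, BLK, gene_m, WT_INTRONIC, gene_read_count = 10)
  expect_identical(ev_m2$category, "ATS")
})

test_that("exonization, unaffected and not_transcribed complete the rules", {
  exo <- mk_tx("t1", c(1000L, 2500L), c(2000L, 7500L))  # exon overlaps block
  ev <- classify_event(exo, BLK, GENE, WT_INTRONIC, gene_read_count = 10)
  expect_identical(ev$category, "exonization_other")
  clear <- mk_tx("t1", 1000L, 2000L)
  ev2 <- classify_event(clear, BLK, GENE, WT_INTRONIC, gene_read_count = 10)
  expect_identical(ev2$category, "unaffected")
  ev3 <- classify_event(clear, BLK, GENE, WT_INTRONIC, gene_read_count = 0)
  expect_identical(ev3$category, "not_transcribed")
  ev4 <- classify_event(NULL, BLK, GENE, WT_INTRONIC, gene_read_count = 0)
  expect_identical(ev4$category, "not_transcribed")
  expect_error(classify_event(clear, c(100L, 500L), GENE, WT_INTRONIC,
                              gene_read_count = 10), "gene interval")
})

test_that("majority support decides the gene category, disruptive on ties", {
  att <- mk_tx("t1", 1000L, 3500L)
  clear <- mk_tx("t2", 1000L, 2000L)
  tx <- rbind(att, clear)
  ev <- classify_event(tx, BLK, GENE, WT_INTRONIC,
                       support = c(t1 = 80, t2 = 20), gene_read_count = 100)
  expect_identical(ev$category, "ATT")
  ev2 <- classify_event(tx, BLK, GENE, WT_INTRONIC,
                        support = c(t1 = 20, t2 = 80), gene_read_count = 100)
  expect_identical(ev2$category, "unaffected")
  ev3 <- classify_event(tx, BLK, GENE, WT_INTRONIC,
                        support = c(t1 = 50, t2 = 50), gene_read_count = 100)
  expect_identical(ev3$category, "ATT")   # tie -> more disruptive
})

test_that("isoform counting splits TEI and normal reads by subtraction", {
  mk_reads <- function(n, start, end, prefix) {
    data.frame(read_id = sprintf("%s_%03d", prefix, seq_len(n)),
               chrom = "chr1", start0 = start, end0 = end)
  }
  reads <- rbind(mk_reads(30, 2900L, 3500L, "tei"),
                 mk_reads(70, 1000L, 2000L, "norm"))
  ic <- count_isoforms(reads, GENE, BLK)
  expect_identical(ic$total_reads, 100L)
  expect_identical(ic$tei_reads, 30L)
  expect_identical(ic$normal_reads, 70L)
  # spliced reads whose blocks skip the TE are normal
  spliced <- rbind(data.frame(read_id = "s1", chrom = "chr1",
                              start0 = c(1000L, 7000L), end0 = c(3000L, 9000L)))
  ic2 <- count_isoforms(spliced, GENE, BLK)
  expect_identical(ic2$tei_reads, 0L)
  expect_identical(ic2$normal_reads, 1L)
  ic0 <- count_isoforms(reads[0, ], GENE, BLK)
  expect_identical(ic0$total_reads, 0L)
  expect_error(count_isoforms(reads, GENE, c(0L, 100L)), "outside")
})

test_that("RPKM and TPM follow their formulas and conservation laws", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(tpm(5, 1000), 1e6)
  set.seed(111)
  counts <- rpois(20, 100); lens <- sample(200:5000, 20)
  expect_equal(sum(tpm(counts, lens)), 1e6, tolerance = 1e-6)
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(tpm(c(1, 2), c(100, 0)), "length")
})

test_that("ORF finder equals exhaustive enumeration", {
  # boundary: ATG + 23 codons + TAA = 75 nt including the stop
  seq75 <- paste0("ATG", strrep("GCC", 23), "TAA")
  expect_identical(nchar(seq75), 75L)
  o <- find_orfs(seq75, min_len_nt = 75L)
  expect_identical(nrow(o), 1L)
  expect_identical(o$length_nt, 75L)
  expect_true(o$has_stop)
  # one codon shorter fails the threshold
  expect_identical(nrow(find_orfs(paste0("ATG", strrep("GCC", 22), "TAA"),
                                  75L)), 0L)
  expect_identical(nrow(find_orfs(strrep("GCC", 100))), 0L)  # no ATG
  # random sequences against the brute-force oracle
  set.seed(121)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
    expect_identical(find_orfs(s, 30L), oracle_orfs(s, 30L))
  }
  # nested ORFs sharing a stop are reported once from the 5'-most ATG
  nested <- paste0("ATGAAA", "ATGCCC", strrep("GCA", 20), "TAA")
  o2 <- find_orfs(nested, 30L)
  expect_identical(nrow(o2), 1L)
  expect_identical(o2$start0, 0L)
})

test_that("protein consequence classes follow the junction rules", {
  te <- c(500L, 1500L)
  expect_identical(classify_protein(list(start0 = 100L, end0 = 700L), te, 900),
                   "chimeric")
  expect_identical(classify_protein(list(start0 = 600L, end0 = 900L), te, 900),
                   "te_internal")
  expect_identical(classify_protein(list(start0 = 0L, end0 = 360L), te, 900),
                   "truncated")
  # full-length gene-derived ORF clear of a downstream TE
  expect_identical(classify_protein(list(start0 = 0L, end0 = 450L),
                                    c(1000L, 1500L), 470),
                   "wild_type_like")
  expect_identical(classify_protein(list(start0 = 1400L, end0 = 1800L), te, 900),
                   "chimeric")
})
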