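test_that("config validation rejects out-of-range parameters", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(het_fraction = 1.2), "fractions")
  expect_error(simulation_config(tsd_length_range = c(2, 6)), "tsd_length_range")
  expect_error(simulation_config(tsd_length_range = c(5, 25)), "tsd_length_range")
  expect_error(simulation_config(ltr_length = 2000, te_body_length = 3400),
               "ltr_length")
  expect_error(simulation_config(n_donors = 1), "donors")
  expect_error(simulation_config(seed = -1), "seed")
})

test_that("reference genome has the requested geometry and compartments", {
  cfg <- simulation_config(seed = 3, n_chromosomes = 2L)
  ref <- simulate_reference(cfg)
  expect_length(ref$genome, 2)
  expect_equal(unname(Biostrings::width(ref$genome)), rep(200000L, 2))
  per <- ref$compartments[ref$compartments$name == "pericentromere", ]
  for (chrom in c("chr1", "chr2")) {
    spans <- sum(per$end0[per$chrom == chrom] - per$start0[per$chrom == chrom])
    expect_lt(abs(spans - 0.2 * cfg$chrom_length), 2)
  }
  # genes non-overlapping with >= 2 exons each
  g <- ref$genes[order(ref$genes$chrom, ref$genes$start0), ]
  by_chrom <- split(g, g$chrom)
  for (d in by_chrom) expect_true(all(diff(d$start0) > (d$end0 - d$start0)[-nrow(d)] * 0))
  expect_true(all(table(ref$exons$gene_id) >= 2))
  # state annotation tiles the genome with 36 labels
  expect_setequal(unique(sub("state", "", ref$states$name)) %in% as.character(1:36), TRUE)
  st <- ref$states[ref$states$chrom == "chr1", ]
  expect_equal(sum(st$end0 - st$start0), cfg$chrom_length)
})

test_that("identical config and seed give byte-identical artifacts", {
  cfg <- simulation_config(seed = 5, n_chromosomes = 1L, n_insertions = 3L)
  a <- simulate_reference(cfg); b <- simulate_reference(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$states, b$states)
  lib1 <- simulate_te_library(cfg); lib2 <- simulate_te_library(cfg)
  expect_identical(as.character(lib1$donors), as.character(lib2$donors))
  s1 <- plant_insertions(a, lib1, cfg); s2 <- plant_insertions(b, lib2, cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  m1 <- simulate_methylation(s1$genome, s1$elements, cfg, seed = 99)
  m2 <- simulate_methylation(s2$genome, s2$elements, cfg, seed = 99)
  f1 <- tempfile(); f2 <- tempfile()
  write_bedmethyl(m1, f1); write_bedmethyl(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("donor library has identical LTRs and a complete diagnostic panel", {
  cfg <- simulation_config(seed = 7)
  lib <- simulate_te_library(cfg)
  expect_length(lib$donors, 8)
  for (d in as.character(lib$donors)) {
    expect_identical(substr(d, 1, 300), substr(d, nchar(d) - 299, nchar(d)))
  }
  expect_length(lib$panel$positions, 16)
  expect_equal(dim(lib$panel$alleles), c(8L, 16L))
  expect_false(any(is.na(lib$panel$alleles)))
  # the configured pair shares all alleles; all other pairs differ somewhere
  al <- lib$panel$alleles
  expect_identical(al["donor1", ], al["donor3", ])
  for (i in 1:7) for (j in (i + 1):8) {
    if (i == 1 && j == 3) next
    expect_true(any(al[i, ] != al[j, ]))
  }
})

test_that("planted insertions duplicate the TSD and conserve length", {
  s <- sim_small()
  truth <- s$smp$truth
  ref_len <- sum(Biostrings::width(s$ref$genome))
  smp_len <- sum(Biostrings::width(s$smp$genome))
  expect_identical(smp_len, ref_len + sum(truth$ins_len))
  # TSD + donor + TSD contiguous at every site on the sample genome
  for (k in seq_len(nrow(truth))) {
    blk <- as.character(Biostrings::subseq(
      s$smp$genome[[truth$chrom[k]]],
      truth$blk_start0[k] - truth$tsd_len[k] + 1L,
      truth$blk_end0[k]))
    donor <- as.character(s$lib$donors[[truth$donor_id[k]]])
    expect_identical(blk, paste0(truth$tsd_seq[k], donor, truth$tsd_seq[k]))
  }
  # truth completeness: each planting appears exactly once
  expect_identical(anyDuplicated(truth[, c("chrom", "pos0")]), 0L)
  expect_identical(nrow(truth), s$cfg$n_insertions)
  expect_true(all(truth$compartment != "centromere"))
  expect_true(all(truth$donor_id %in% names(s$lib$donors)))
})

test_that("noise-free alignments carry clip signals only at planted loci", {
  s <- sim_small()
  sig <- collect_clip_signals(s$aln)
  expect_gt(nrow(sig), 0)
  near_truth <- vapply(sig$pos0, function(p)
    any(abs(s$smp$truth$pos0 - p) <= 50), logical(1))
  expect_true(all(near_truth))
  # homozygous loci: every spanning read carries the signal
  expect_true(all(table(sub("_read.*", "", sig$read_id)) == s$cfg$read_depth))
})

test_that("heterozygous carrier fraction behaves binomially at depth 40", {
  cfg <- simulation_config(seed = 13, n_chromosomes = 1L, n_insertions = 4L,
                           het_fraction = 1, read_depth = 40L, bg_depth = 0L)
  ref <- simulate_reference(cfg); lib <- simulate_te_library(cfg)
  smp <- plant_insertions(ref, lib, cfg)
  aln <- simulate_read_alignments(smp, ref, lib, cfg)
  sig <- collect_clip_signals(aln)
  frac <- table(sub("_read.*", "", sig$read_id)) / cfg$read_depth
  expect_true(all(frac >= 0.25 & frac <= 0.75))
})

test_that("empty truth with zero noise yields a clip-free SAM", {
  cfg <- simulation_config(seed = 17, n_chromosomes = 1L, n_insertions = 0L,
                           genic_fraction = 0)
  ref <- simulate_reference(cfg); lib <- simulate_te_library(cfg)
  smp <- plant_insertions(ref, lib, cfg)
  aln <- simulate_read_alignments(smp, ref, lib, cfg)
  expect_gt(nrow(aln), 0)      # background reads still tile the genome
  expect_identical(nrow(collect_clip_signals(aln)), 0L)
})

test_that("methylation regimes produce the expected CHH patterns", {
  s <- sim_small()
  meth <- simulate_methylation(s$smp$genome, s$smp$elements, s$cfg)
  expect_true(all(meth$frac_mod >= 0 & meth$frac_mod <= 1))
  for (k in seq_len(nrow(s$smp$elements))) {
    el <- s$smp$elements[k, ]
    rc <- meth[meth$context == "CHH" & meth$element_id == el$element_id, ]
    p <- bin_element(rc, el)
    body <- p$values[p$n_flank + seq_len(p$body_bins)]
    nb <- max(1, floor(el$ltr_length / (el$end0 - el$start0) * p$body_bins))
    edge <- mean(c(body[1:nb], body[(p$body_bins - nb + 1):p$body_bins]),
                 na.rm = TRUE)
    centre <- mean(body[41:60], na.rm = TRUE)
    if (el$regime == "euchromatic") expect_gt(edge, centre)
    else expect_lt(abs(edge / centre - 1), 0.5)
  }
})

test_that("transcript scenarios realize their categories and counts", {
  s <- sim_small()
  tx <- simulate_transcripts(s$ref, s$smp, s$cfg)
  host <- s$smp$truth[!is.na(s$smp$truth$gene_id), ]
  expect_identical(sort(names(tx$events)), sort(host$tei_id))
  # not_transcribed genes have zero reads
  nt <- names(tx$events)[tx$events == "not_transcribed"]
  for (id in nt) {
    expect_false(id %in% tx$counts$tei_id)
  }
  # scenario mix of all-ATT classifies every gene ATT (round trip)
  cfg2 <- simulation_config(seed = 19, n_chromosomes = 1L, n_insertions = 5L,
                            het_fraction = 0,
                            transcript_scenario_mix = c(intronization = 0,
                                                        ATT = 1, ATS = 0,
                                                        unaffected = 0,
                                                        not_transcribed = 0))
  ref2 <- simulate_reference(cfg2); lib2 <- simulate_te_library(cfg2)
  smp2 <- plant_insertions(ref2, lib2, cfg2)
  tx2 <- simulate_transcripts(ref2, smp2, cfg2)
  genes2 <- shift_annotation(ref2$genes, smp2$liftover)
  exons2 <- shift_annotation(ref2$exons, smp2$liftover)
  host2 <- smp2$truth[!is.na(smp2$truth$gene_id), ]
  for (k in seq_len(nrow(host2))) {
    tei <- host2[k, ]
    g <- genes2[genes2$gene_id == tei$gene_id, ]
    mods <- tx2$models[tx2$models$gene_id == tei$gene_id, ]
    cnt <- tx2$counts[tx2$counts$gene_id == tei$gene_id, ]
    ev <- classify_event(mods, c(tei$blk_start0, tei$blk_end0), g,
                         exons2[exons2$gene_id == tei$gene_id, ],
                         support = setNames(cnt$count, cnt$transcript_id),
                         gene_read_count = sum(cnt$count))
    expect_identical(ev$category, "ATT")
  }
})
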