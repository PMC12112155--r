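# Synthetic-data generator: genomes with arm/pericentromere/centromere
# compartments, a donor TE library with diagnostic RT SNPs, TSD-flanked
# plantings at configurable zygosity, clip-bearing read alignments,
# context-dependent methylation tables and transcript scenarios — all with
# full ground truth, so every downstream stage is testable without external
# downloads.

#' Build and validate a simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: a compact
#' two-chromosome genome, an eight-member donor family (full-length LTR
#' retrotransposons ~4 kb with 300 bp terminal repeats), 20 plantings with
#' 4-6 bp target-site duplications, about half of them heterozygous, ~10x
#' locus depth, and CHH-edge/CG-body methylation contrasts between
#' euchromatic and heterochromatic compartments.
#'
#' @param seed integer seed driving all stages (per-stage seeds are derived)
#' @param n_chromosomes number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param pericentromere_fraction fraction of each chromosome assigned to the
#'   two pericentromeric blocks flanking the centromere
#' @param centromere_fraction fraction assigned to the central centromere
#' @param n_donors donor (parental) TE copies in the library
#' @param ltr_length long terminal repeat length in bp
#' @param te_body_length internal (inter-LTR) sequence length in bp
#' @param tsd_length_range min/max target-site duplication length in bp
#' @param n_insertions plantings in the sample genome
#' @param het_fraction fraction of plantings that are heterozygous
#' @param genic_fraction fraction of plantings placed inside genes (the rest
#'   go to the pericentromere, giving them a heterochromatic regime)
#' @param read_depth mean reads per locus (alignments and methylation
#'   coverage)
#' @param read_flank aligned bases on each side of a junction per read
#' @param bg_depth coverage of plain background reads tiling the rest of
#'   the genome (they anchor the genome-wide background clip-rate estimate;
#'   junction-spanning coverage is modeled by the per-locus reads, so
#'   background reads never cross a planted breakpoint)
#' @param clip_noise_rate per-read probability of a spurious background clip
#' @param min_insertion_spacing minimum distance between plantings in bp
#' @param n_genes_per_chrom genes simulated per chromosome
#' @param methylation per-regime target levels: lists `euchromatic` and
#'   `heterochromatic` with CG_body, CHG_body, CHH_body, CHH_edge; plus
#'   `flank_baseline`, `beta_concentration` (replicate noise), and
#'   `chh_spread_bp`/`chh_spread_level` (downstream CHH spread into the
#'   right flank, recycled over euchromatic elements)
#' @param transcript_scenario_mix named proportions over intronization, ATT,
#'   ATS, unaffected, not_transcribed
#' @param tx_depth cDNA reads per expressed gene
#' @param shared_allele_pairs list of donor index pairs that intentionally
#'   share all diagnostic alleles (creating assignment ambiguity)
#' @return validated config (list of class `sim_config`)
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 200000L,
                              pericentromere_fraction = 0.2,
                              centromere_fraction = 0.1,
                              n_donors = 8L,
                              ltr_length = 300L,
                              te_body_length = 3400L,
                              tsd_length_range = c(4L, 6L),
                              n_insertions = 20L,
                              het_fraction = 0.5,
                              genic_fraction = 0.8,
                              read_depth = 10L,
                              read_flank = 400L,
                              bg_depth = 4L,
                              clip_noise_rate = 0,
                              min_insertion_spacing = 6000L,
                              n_genes_per_chrom = 12L,
                              methylation = list(
                                euchromatic = list(CG_body = 0.85, CHG_body = 0.40,
                                                   CHH_body = 0.08, CHH_edge = 0.55),
                                heterochromatic = list(CG_body = 0.90, CHG_body = 0.10,
                                                       CHH_body = 0.05, CHH_edge = 0.05),
                                flank_baseline = 0.05,
                                beta_concentration = 60,
                                chh_spread_bp = c(0L, 500L, 1000L, 2000L),
                                chh_spread_level = 0.30
                              ),
                              transcript_scenario_mix = c(intronization = 0.25,
                                                          ATT = 0.15, ATS = 0.10,
                                                          unaffected = 0.10,
                                                          not_transcribed = 0.40),
                              tx_depth = 50L,
                              shared_allele_pairs = list(c(1L, 3L))) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    pericentromere_fraction = pericentromere_fraction,
    centromere_fraction = centromere_fraction,
    n_donors = as.integer(n_donors), ltr_length = as.integer(ltr_length),
    te_body_length = as.integer(te_body_length),
    tsd_length_range = as.integer(tsd_length_range),
    n_insertions = as.integer(n_insertions), het_fraction = het_fraction,
    genic_fraction = genic_fraction, read_depth = as.integer(read_depth),
    read_flank = as.integer(read_flank), bg_depth = as.integer(bg_depth),
    clip_noise_rate = clip_noise_rate,
    min_insertion_spacing = as.integer(min_insertion_spacing),
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    methylation = methylation,
    transcript_scenario_mix = transcript_scenario_mix,
    tx_depth = as.integer(tx_depth),
    shared_allele_pairs = shared_allele_pairs
  )
  fr <- c(cfg$pericentromere_fraction, cfg$centromere_fraction,
          cfg$het_fraction, cfg$genic_fraction, cfg$clip_noise_rate)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$pericentromere_fraction + cfg$centromere_fraction >= 1)
    stop("compartment fractions exceed the chromosome")
  if (cfg$tsd_length_range[1] < 3L || cfg$tsd_length_range[2] > 20L ||
      cfg$tsd_length_range[1] > cfg$tsd_length_range[2])
    stop("tsd_length_range must lie within [3, 20]")
  if (cfg$n_insertions < 0L) stop("n_insertions must be >= 0")
  if (cfg$seed < 0L) stop("seed must be a non-negative integer")
  if (cfg$ltr_length >= cfg$te_body_length / 2)
    stop("ltr_length must be shorter than half the internal sequence")
  if (cfg$n_donors < 2L) stop("need at least 2 donors")
  if (abs(sum(cfg$transcript_scenario_mix) - 1) > 1e-8)
    stop("transcript_scenario_mix must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

# compartment layout for one chromosome: arm | pericent | cen | pericent | arm
compartment_table <- function(cfg) {
  L <- cfg$chrom_length
  cen_w <- round(L * cfg$centromere_fraction)
  per_w <- round(L * cfg$pericentromere_fraction / 2)
  cen_s <- round(L / 2 - cen_w / 2)
  do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(i) {
    chrom <- paste0("chr", i)
    data.frame(
      chrom = chrom,
      start0 = c(0L, cen_s - per_w, cen_s, cen_s + cen_w, cen_s + cen_w + per_w),
      end0 = c(cen_s - per_w, cen_s, cen_s + cen_w, cen_s + cen_w + per_w, L),
      name = c("arm", "pericentromere", "centromere", "pericentromere", "arm"),
      stringsAsFactors = FALSE
    )
  }))
}

#' Simulate a reference genome with annotation
#'
#' Each chromosome is partitioned into arm / pericentromere / centromere
#' compartments; non-overlapping multi-exon genes are placed on the arms and
#' a 36-label chromatin-state annotation tiles the genome.
#'
#' @param config a [simulation_config()]
#' @return list with `genome` (DNAStringSet), `genes` and `exons`
#'   (0-based half-open data.frames), `compartments` and `states` (BED-style
#'   data.frames)
#' @export
simulate_reference <- function(config) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, "reference"), {
    genome <- Biostrings::DNAStringSet(
      setNames(vapply(seq_len(cfg$n_chromosomes),
                      function(i) random_dna(cfg$chrom_length), character(1)),
               paste0("chr", seq_len(cfg$n_chromosomes))))
    comp <- compartment_table(cfg)

    gene_len <- 3200L
    if (cfg$n_genes_per_chrom > 0) {
      arm <- comp[comp$name == "arm", ]
      per_arm <- ceiling(cfg$n_genes_per_chrom / 2)
      slots <- do.call(rbind, lapply(seq_len(nrow(arm)), function(j) {
        a <- arm[j, ]
        usable <- (a$end0 - a$start0) - 4000L   # margin from compartment edges
        slot_w <- floor(usable / per_arm)
        if (slot_w < gene_len + 2000L)
          stop("chrom_length too small to host the requested genes")
        data.frame(chrom = a$chrom,
                   start0 = a$start0 + 2000L + (seq_len(per_arm) - 1L) * slot_w,
                   slot_w = slot_w)
      }))
      slots <- do.call(rbind, by(slots, slots$chrom, function(d)
        head(d, cfg$n_genes_per_chrom)))
      # jitter kept small so that insertions in adjacent genes always honour
      # the min_insertion_spacing constraint
      jit_max <- pmax(1, pmin(slots$slot_w - gene_len - 100, 1200))
      gs <- slots$start0 + floor(runif(nrow(slots), 0, jit_max))
      genes <- data.frame(
        gene_id = sprintf("gene%03d", seq_len(nrow(slots))),
        chrom = slots$chrom, start0 = as.integer(gs),
        end0 = as.integer(gs + gene_len),
        strand = sample(c("+", "-"), nrow(slots), replace = TRUE),
        stringsAsFactors = FALSE
      )
      # three exons of 600/800/600 bp with 500/700 bp introns (total 3200)
      exoff <- rbind(c(0L, 600L), c(1100L, 1900L), c(2600L, 3200L))
      exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(k) {
        data.frame(gene_id = genes$gene_id[k], chrom = genes$chrom[k],
                   start0 = genes$start0[k] + exoff[, 1],
                   end0 = genes$start0[k] + exoff[, 2],
                   exon_rank = seq_len(nrow(exoff)),
                   strand = genes$strand[k], stringsAsFactors = FALSE)
      }))
    } else {
      genes <- data.frame(gene_id = character(), chrom = character(),
                          start0 = integer(), end0 = integer(),
                          strand = character())
      exons <- data.frame(gene_id = character(), chrom = character(),
                          start0 = integer(), end0 = integer(),
                          exon_rank = integer(), strand = character())
    }

    tile <- 2000L
    states <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(i) {
      s <- seq(0L, cfg$chrom_length - 1L, by = tile)
      e <- pmin(s + tile, cfg$chrom_length)
      lab <- paste0("state", ((sample(36L, 1L) + seq_along(s)) %% 36L) + 1L)
      data.frame(chrom = paste0("chr", i), start0 = s, end0 = e,
                 name = lab, stringsAsFactors = FALSE)
    }))
    list(genome = genome, genes = genes, exons = exons,
         compartments = comp, states = states)
  })
}

#' Simulate the donor TE library and its diagnostic SNP panel
#'
#' Each donor is LTR + internal (GAG..RT..RH) + an identical LTR. Sixteen
#' diagnostic positions inside the RT segment carry per-donor alleles;
#' donor pairs listed in `shared_allele_pairs` share all alleles, creating
#' the intentional assignment ambiguity seen in real families whose youngest
#' members are near-identical.
#'
#' @param config a [simulation_config()]
#' @return list with `donors` (DNAStringSet), `panel` (see
#'   [diagnostic_panel()]), `ltr_length`, `rt_offset` (0-based offset of the
#'   RT segment within a donor), `rt_length`
#' @export
simulate_te_library <- function(config) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, "library"), {
    ltr <- random_dna(cfg$ltr_length)
    internal <- random_dna(cfg$te_body_length)
    # domain layout within the internal sequence (fractions of its length)
    rt_s <- floor(cfg$te_body_length * 0.5)
    rt_e <- floor(cfg$te_body_length * 0.8)
    n_pos <- 16L
    pos_internal <- rt_s + floor(seq(0.05, 0.95, length.out = n_pos) * (rt_e - rt_s))

    bases <- c("A", "C", "G", "T")
    repeat {
      alleles <- matrix(sample(bases, cfg$n_donors * n_pos, replace = TRUE),
                        nrow = cfg$n_donors)
      for (pr in cfg$shared_allele_pairs) alleles[pr[2], ] <- alleles[pr[1], ]
      shared <- vapply(cfg$shared_allele_pairs, paste, character(1), collapse = "-")
      dup <- FALSE
      for (i in seq_len(cfg$n_donors - 1)) for (j in (i + 1):cfg$n_donors) {
        if (paste(c(i, j), collapse = "-") %in% shared) next
        if (all(alleles[i, ] == alleles[j, ])) dup <- TRUE
      }
      if (!dup) break
    }

    donors <- vapply(seq_len(cfg$n_donors), function(i) {
      body <- strsplit(internal, "")[[1]]
      body[pos_internal + 1L] <- alleles[i, ]
      paste0(ltr, paste(body, collapse = ""), ltr)
    }, character(1))
    names(donors) <- paste0("donor", seq_len(cfg$n_donors))

    rt_reference <- substr(donors[[1]], cfg$ltr_length + rt_s + 1L,
                           cfg$ltr_length + rt_e)
    rownames(alleles) <- names(donors)
    panel <- diagnostic_panel(rt_reference,
                              positions = pos_internal - rt_s,
                              alleles = alleles)
    list(donors = Biostrings::DNAStringSet(donors), panel = panel,
         ltr_length = cfg$ltr_length,
         rt_offset = cfg$ltr_length + rt_s, rt_length = rt_e - rt_s)
  })
}

#' Plant TE insertions into the reference with duplicated TSDs
#'
#' At each site the target-site duplication (the `tsd_len` reference bases
#' immediately left of the breakpoint) is duplicated: the inserted block is
#' donor + TSD, so the TSD flanks the donor on both sides. Sites closer than
#' `min_insertion_spacing` (or falling in the centromere) are resampled.
#'
#' @param reference output of [simulate_reference()]
#' @param library output of [simulate_te_library()]
#' @param config a [simulation_config()]
#' @return list with `genome` (sample DNAStringSet), `truth` (one row per
#'   planting: tei_id, chrom, pos0, donor_id, tsd_len, tsd_seq, zygosity,
#'   regime, gene_id, ins_len, plus block/element coordinates on the sample
#'   genome), `liftover`, and `elements` (donor spans on the sample genome
#'   for methylation analysis)
#' @export
plant_insertions <- function(reference, library, config) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, "plant"), {
    comp <- reference$compartments
    genes <- reference$genes
    n_genic <- round(cfg$genic_fraction * cfg$n_insertions)
    n_peri <- cfg$n_insertions - n_genic
    if (n_genic > nrow(genes))
      stop("not enough genes to host the requested genic insertions")

    margin <- 300L
    host <- if (n_genic > 0) sample(genes$gene_id, n_genic) else character(0)
    sites <- data.frame(
      chrom = genes$chrom[match(host, genes$gene_id)],
      pos0 = vapply(host, function(id) {
        g <- genes[genes$gene_id == id, ]
        as.integer(floor(runif(1, g$start0 + margin, g$end0 - margin)))
      }, integer(1), USE.NAMES = FALSE),
      gene_id = host, stringsAsFactors = FALSE
    )

    if (n_peri > 0) {
      peri <- comp[comp$name == "pericentromere", ]
      tries <- 0L
      repeat {
        tries <- tries + 1L
        idx <- sample(nrow(peri), n_peri, replace = TRUE)
        p <- vapply(idx, function(j)
          as.integer(floor(runif(1, peri$start0[j] + 2500L,
                                 peri$end0[j] - 2500L))), integer(1))
        cand <- rbind(sites, data.frame(chrom = peri$chrom[idx], pos0 = p,
                                        gene_id = NA_character_))
        d <- unlist(by(cand$pos0, cand$chrom, function(x)
          diff(sort(x))), use.names = FALSE)
        if (length(d) == 0 || min(d) >= cfg$min_insertion_spacing) {
          sites <- cand; break
        }
        if (tries > 200L) stop("could not place insertions with the requested spacing")
      }
    }
    o <- order(match(sites$chrom, names(reference$genome)), sites$pos0)
    sites <- sites[o, , drop = FALSE]
    d <- unlist(by(sites$pos0, sites$chrom, function(x) diff(sort(x))),
                use.names = FALSE)
    if (length(d) && min(d) < cfg$min_insertion_spacing)
      stop("genic sites violate the spacing constraint; lower n_insertions")

    n <- nrow(sites)
    donor_id <- sample(names(library$donors), n, replace = TRUE)
    tsd_len <- sample(seq(cfg$tsd_length_range[1], cfg$tsd_length_range[2]),
                      n, replace = TRUE)
    n_het <- round(cfg$het_fraction * n)
    zyg <- sample(c(rep("het", n_het), rep("hom", n - n_het)))
    tsd_seq <- vapply(seq_len(n), function(k) {
      as.character(Biostrings::subseq(reference$genome[[sites$chrom[k]]],
                                      sites$pos0[k] - tsd_len[k] + 1L,
                                      sites$pos0[k]))
    }, character(1))
    donor_len <- Biostrings::width(library$donors)[match(donor_id, names(library$donors))]

    comp_of <- function(chrom, pos) {
      cc <- comp[comp$chrom == chrom & comp$start0 <= pos & pos < comp$end0, ]
      cc$name[1]
    }
    compartment <- mapply(comp_of, sites$chrom, sites$pos0)
    truth <- data.frame(
      tei_id = sprintf("tei%03d", seq_len(n)),
      chrom = sites$chrom, pos0 = sites$pos0,
      donor_id = donor_id, tsd_len = tsd_len, tsd_seq = tsd_seq,
      zygosity = zyg, compartment = compartment,
      regime = ifelse(compartment == "arm", "euchromatic", "heterochromatic"),
      gene_id = sites$gene_id, donor_len = donor_len,
      ins_len = donor_len + tsd_len, stringsAsFactors = FALSE
    )

    blocks <- vapply(seq_len(n), function(k)
      paste0(as.character(library$donors[[truth$donor_id[k]]]), truth$tsd_seq[k]),
      character(1))
    genome <- reference$genome
    for (chrom in unique(truth$chrom)) {
      sel <- truth$chrom == chrom
      genome[[chrom]] <- Biostrings::replaceAt(
        genome[[chrom]],
        IRanges::IRanges(start = truth$pos0[sel] + 1L, width = 0L),
        Biostrings::DNAStringSet(blocks[sel])
      )
    }

    liftover <- build_liftover(data.frame(chrom = truth$chrom,
                                          ref_pos0 = truth$pos0,
                                          ins_len = truth$ins_len))
    truth$blk_start0 <- vapply(seq_len(n), function(k)
      as.integer(lift_position(liftover, truth$chrom[k], truth$pos0[k],
                               "ref_to_pseudo") - truth$ins_len[k]),
      integer(1))
    truth$blk_end0 <- truth$blk_start0 + truth$ins_len
    truth$el_start0 <- truth$blk_start0
    truth$el_end0 <- truth$blk_start0 + truth$donor_len

    spread <- cfg$methylation$chh_spread_bp
    eu <- which(truth$regime == "euchromatic")
    truth$chh_spread_bp <- rep(0L, n)
    if (length(eu) && length(spread))
      truth$chh_spread_bp[eu] <- as.integer(rep(spread, length.out = length(eu)))

    elements <- data.frame(
      element_id = truth$tei_id, chrom = truth$chrom,
      start0 = truth$el_start0, end0 = truth$el_end0,
      strand = rep("+", n), regime = truth$regime,
      ltr_length = rep(cfg$ltr_length, n),
      spread_bp = truth$chh_spread_bp, stringsAsFactors = FALSE
    )
    list(genome = genome, truth = truth, liftover = liftover,
         elements = elements)
  })
}

#' Synthesize long-read alignments over planted insertion loci
#'
#' Alignments are emitted directly as SAM-style records against the original
#' reference; no base-error model or external aligner is involved, because
#' the downstream caller consumes CIGAR signatures only. Reads spanning an
#' insertion junction carry the full inserted block (donor + duplicated TSD)
#' as a soft clip (S) or internal insertion (I); read type cycles between
#' internal-insertion, right-clip and left-clip representations. Homozygous
#' loci: every read is a carrier; heterozygous: each read carries the signal
#' with probability 0.5. Non-carrier reads are plain matches, optionally
#' decorated with a random background clip at `clip_noise_rate`.
#'
#' @param sample output of [plant_insertions()]
#' @param reference output of [simulate_reference()]
#' @param library output of [simulate_te_library()]
#' @param config a [simulation_config()]
#' @return alignment data.frame (qname, flag, chrom, pos0, mapq, cigar, seq)
#'   suitable for [write_sam()]
#' @export
simulate_read_alignments <- function(sample, reference, library, config) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, "reads"), {
    truth <- sample$truth
    L <- cfg$read_flank
    rows <- vector("list", nrow(truth) * cfg$read_depth)
    ri <- 0L
    fetch <- function(chrom, s0, e0)
      as.character(Biostrings::subseq(reference$genome[[chrom]], s0 + 1L, e0))
    for (k in seq_len(nrow(truth))) {
      b <- truth$pos0[k]; chrom <- truth$chrom[k]
      insert <- paste0(as.character(library$donors[[truth$donor_id[k]]]),
                       truth$tsd_seq[k])
      ilen <- nchar(insert)
      carrier <- if (truth$zygosity[k] == "hom") rep(TRUE, cfg$read_depth)
                 else runif(cfg$read_depth) < 0.5
      for (i in seq_len(cfg$read_depth)) {
        ri <- ri + 1L
        qname <- sprintf("%s_read%02d", truth$tei_id[k], i)
        flag <- if (i %% 6L == 0L) 16L else 0L
        if (carrier[i]) {
          type <- i %% 3L
          if (type == 0L) {        # spanning read with internal insertion
            rows[[ri]] <- data.frame(
              qname = qname, flag = flag, chrom = chrom, pos0 = b - L,
              mapq = 60L, cigar = sprintf("%dM%dI%dM", L, ilen, L),
              seq = paste0(fetch(chrom, b - L, b), insert, fetch(chrom, b, b + L)))
          } else if (type == 1L) { # right clip: alignment ends at breakpoint
            rows[[ri]] <- data.frame(
              qname = qname, flag = flag, chrom = chrom, pos0 = b - L,
              mapq = 60L, cigar = sprintf("%dM%dS", L, ilen),
              seq = paste0(fetch(chrom, b - L, b), insert))
          } else {                 # left clip: alignment starts at breakpoint
            rows[[ri]] <- data.frame(
              qname = qname, flag = flag, chrom = chrom, pos0 = b,
              mapq = 60L, cigar = sprintf("%dS%dM", ilen, L),
              seq = paste0(insert, fetch(chrom, b, b + L)))
          }
        } else {
          noisy <- runif(1) < cfg$clip_noise_rate
          if (noisy) {
            rows[[ri]] <- data.frame(
              qname = qname, flag = flag, chrom = chrom, pos0 = b - L,
              mapq = 60L, cigar = sprintf("%dM%dS", 2L * L, 250L),
              seq = paste0(fetch(chrom, b - L, b + L), random_dna(250L)))
          } else {
            rows[[ri]] <- data.frame(
              qname = qname, flag = flag, chrom = chrom, pos0 = b - L,
              mapq = 60L, cigar = sprintf("%dM", 2L * L),
              seq = fetch(chrom, b - L, b + L))
          }
        }
      }
    }
    # plain background reads tiling the genome at bg_depth; reads that would
    # span a planted junction are dropped (locus reads model those)
    bg <- list()
    if (cfg$bg_depth > 0) {
      rlen <- 2L * L
      spacing <- max(1L, rlen %/% cfg$bg_depth)
      for (chrom in names(reference$genome)) {
        starts <- seq(0L, cfg$chrom_length - rlen, by = spacing)
        bps <- truth$pos0[truth$chrom == chrom]
        if (length(bps)) {
          spans <- vapply(starts, function(s)
            any(bps > s & bps < s + rlen), logical(1))
          starts <- starts[!spans]
        }
        if (!length(starts)) next
        noisy <- runif(length(starts)) < cfg$clip_noise_rate
        bg[[chrom]] <- data.frame(
          qname = sprintf("bg_%s_%06d", chrom, starts),
          flag = 0L, chrom = chrom, pos0 = starts, mapq = 60L,
          cigar = ifelse(noisy, sprintf("%dM250S", rlen),
                         sprintf("%dM", rlen)),
          seq = paste0(
            vapply(starts, function(s) fetch(chrom, s, s + rlen), character(1)),
            ifelse(noisy, vapply(seq_along(starts),
                                 function(i) random_dna(250L), character(1)),
                   "")))
      }
    }
    aln <- do.call(rbind, c(rows[seq_len(ri)], bg))
    if (is.null(aln)) {
      aln <- data.frame(qname = character(), flag = integer(),
                        chrom = character(), pos0 = integer(),
                        mapq = integer(), cigar = character(),
                        seq = character())
    }
    aln$end0 <- aln$pos0 +
      GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
    aln
  })
}

methyl_context_at <- function(chars, pos1, strand) {
  n <- length(chars)
  if (strand == "+") {
    if (chars[pos1] != "C") return(NA_character_)
    nxt <- if (pos1 + 1 <= n) chars[pos1 + 1] else ""
    nx2 <- if (pos1 + 2 <= n) chars[pos1 + 2] else ""
    if (nxt == "G") "CG" else if (nx2 == "G") "CHG" else "CHH"
  } else {
    if (chars[pos1] != "G") return(NA_character_)
    prv <- if (pos1 - 1 >= 1) chars[pos1 - 1] else ""
    pv2 <- if (pos1 - 2 >= 1) chars[pos1 - 2] else ""
    if (prv == "C") "CG" else if (pv2 == "C") "CHG" else "CHH"
  }
}

# vectorized cytosine discovery with context for a genome interval
cytosines_in_region <- function(chrom_seq, chrom, start0, end0) {
  chars <- strsplit(as.character(Biostrings::subseq(chrom_seq, start0 + 1L, end0)),
                    "")[[1]]
  n <- length(chars)
  nxt <- c(chars[-1], "")
  nx2 <- c(chars[-(1:2)], "", "")
  prv <- c("", chars[-n])
  pv2 <- c("", "", chars[-((n - 1):n)])
  plus <- which(chars == "C")
  minus <- which(chars == "G")
  ctx_p <- ifelse(nxt[plus] == "G", "CG", ifelse(nx2[plus] == "G", "CHG", "CHH"))
  ctx_m <- ifelse(prv[minus] == "C", "CG", ifelse(pv2[minus] == "C", "CHG", "CHH"))
  data.frame(
    chrom = chrom,
    pos0 = c(start0 + plus - 1L, start0 + minus - 1L),
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    context = c(ctx_p, ctx_m),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-cytosine methylation calls around elements
#'
#' Every cytosine within each element and its `flank_bp` flanks receives a
#' Beta-distributed methylated fraction around the regime target level.
#' Euchromatic elements: CHH at `CHH_edge` over the terminal repeats and
#' `CHH_body` elsewhere, CG-rich body; heterochromatic elements: uniformly
#' high CG and low CHH. Flanks sit at `flank_baseline`, except a CHH spread
#' of `spread_bp` into the right flank of euchromatic elements. Coverage is
#' Poisson around `read_depth`.
#'
#' @param genome DNAStringSet the elements live on
#' @param elements data.frame with element_id, chrom, start0, end0, regime,
#'   ltr_length and optional spread_bp
#' @param config a [simulation_config()]
#' @param seed replicate seed (replicates differ only by noise)
#' @param flank_bp flank width in bp
#' @return bedMethyl-style data.frame (chrom, pos0, strand, context,
#'   n_valid, frac_mod)
#' @export
simulate_methylation <- function(genome, elements, config, seed = NULL,
                                 flank_bp = 2000L) {
  cfg <- config
  mp <- cfg$methylation
  with_seed(seed %||% derive_seed(cfg$seed, "methylation"), {
    out <- lapply(seq_len(nrow(elements)), function(k) {
      el <- elements[k, ]
      chrom_seq <- genome[[el$chrom]]
      lo <- max(0L, el$start0 - flank_bp)
      hi <- min(length(chrom_seq), el$end0 + flank_bp)
      if (el$start0 < 0 || el$end0 > length(chrom_seq))
        stop("element outside genome bounds: ", el$element_id)
      cy <- cytosines_in_region(chrom_seq, el$chrom, lo, hi)
      pr <- mp[[el$regime]]
      in_body <- cy$pos0 >= el$start0 & cy$pos0 < el$end0
      in_ltr <- in_body & (cy$pos0 < el$start0 + el$ltr_length |
                           cy$pos0 >= el$end0 - el$ltr_length)
      spread <- el$spread_bp %||% 0L
      if (is.na(spread)) spread <- 0L
      in_spread <- cy$pos0 >= el$end0 & cy$pos0 < el$end0 + spread &
        cy$context == "CHH" & el$regime == "euchromatic"
      mu <- rep(mp$flank_baseline, nrow(cy))
      mu[in_body & cy$context == "CG"] <- pr$CG_body
      mu[in_body & cy$context == "CHG"] <- pr$CHG_body
      mu[in_body & cy$context == "CHH"] <- pr$CHH_body
      mu[in_ltr & cy$context == "CHH"] <- pr$CHH_edge
      mu[in_spread] <- mp$chh_spread_level
      conc <- mp$beta_concentration
      cy$frac_mod <- rbeta(nrow(cy), mu * conc, (1 - mu) * conc)
      cy$n_valid <- pmax(1L, rpois(nrow(cy), cfg$read_depth))
      cy$element_id <- el$element_id
      cy
    })
    do.call(rbind, out)
  })
}

#' Simulate baseline (control) methylation over arbitrary regions
#'
#' Used for the control sample on the original reference: every cytosine in
#' the given regions sits at the flank baseline level.
#'
#' @param genome DNAStringSet
#' @param regions data.frame with chrom, start0, end0
#' @param config a [simulation_config()]
#' @param seed replicate seed
#' @return bedMethyl-style data.frame
#' @export
simulate_baseline_methylation <- function(genome, regions, config, seed = NULL) {
  cfg <- config
  mp <- cfg$methylation
  with_seed(seed %||% derive_seed(cfg$seed, "control"), {
    out <- lapply(seq_len(nrow(regions)), function(k) {
      r <- regions[k, ]
      lo <- max(0L, r$start0)
      hi <- min(length(genome[[r$chrom]]), r$end0)
      cy <- cytosines_in_region(genome[[r$chrom]], r$chrom, lo, hi)
      conc <- mp$beta_concentration
      cy$frac_mod <- rbeta(nrow(cy), mp$flank_baseline * conc,
                           (1 - mp$flank_baseline) * conc)
      cy$n_valid <- pmax(1L, rpois(nrow(cy), cfg$read_depth))
      cy
    })
    do.call(rbind, out)
  })
}

#' Simulate transcript models and read counts realizing TE-gene scenarios
#'
#' Each gene hosting an insertion is assigned one scenario from
#' `transcript_scenario_mix`. Intronization: the scenario isoform splices
#' out exactly the inserted block (donor + duplicated TSD); ATT: the
#' terminal exon ends inside the TE; ATS: the first exon starts inside the
#' TE; unaffected: an isoform not touching the TE; not_transcribed: zero
#' reads. Expressed scenario genes also carry a minor isoform that stops
#' short of the TE, so isoform counting sees a TEI/normal split of roughly
#' 80/20.
#'
#' @param reference output of [simulate_reference()]
#' @param sample output of [plant_insertions()]
#' @param config a [simulation_config()]
#' @return list with `models` (exon rows: transcript_id, gene_id, chrom,
#'   strand, start0, end0), `counts` (per transcript), `reads` (aligned
#'   blocks: read_id, chrom, start0, end0), and `events` (tei_id ->
#'   expected category)
#' @export
simulate_transcripts <- function(reference, sample, config) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, "transcripts"), {
    truth <- sample$truth
    lo <- sample$liftover
    host <- truth[!is.na(truth$gene_id), , drop = FALSE]
    mix <- cfg$transcript_scenario_mix
    n <- nrow(host)
    n_each <- floor(mix * n)
    rem <- n - sum(n_each)
    if (rem > 0) {
      bump <- order(mix * n - n_each, decreasing = TRUE)[seq_len(rem)]
      n_each[bump] <- n_each[bump] + 1L
    }
    scen <- sample(rep(names(mix), times = n_each))
    shifted_exons <- shift_annotation(reference$exons, lo)

    models <- list(); counts <- list(); reads <- list(); events <- list()
    rid <- 0L
    for (k in seq_len(n)) {
      tei <- host[k, ]
      gx <- shifted_exons[shifted_exons$gene_id == tei$gene_id, , drop = FALSE]
      gx <- gx[order(gx$start0), ]
      strand <- gx$strand[1]; chrom <- gx$chrom[1]
      blk <- c(tei$blk_start0, tei$blk_end0)
      sc <- scen[k]
      wt_exonic <- any(gx$start0 < blk[2] & blk[1] < gx$end0)

      mk_tx <- function(id, ex) data.frame(
        transcript_id = id, gene_id = tei$gene_id, chrom = chrom,
        strand = strand, start0 = ex[, 1], end0 = ex[, 2])

      # isoform that stays clear of the TE (used as the minor "normal" form
      # and as the unaffected scenario's only form)
      before <- gx[gx$end0 <= blk[1], c("start0", "end0"), drop = FALSE]
      after <- gx[gx$start0 >= blk[2], c("start0", "end0"), drop = FALSE]
      clear_ex <- if (strand == "+") before else after
      if (nrow(clear_ex) == 0)
        clear_ex <- data.frame(start0 = gx$start0[1],
                               end0 = min(gx$end0[1], blk[1]))

      tx <- NULL
      if (sc == "intronization") {
        ex <- as.matrix(gx[, c("start0", "end0")])
        hits <- which(ex[, 1] < blk[2] & blk[1] < ex[, 2])
        if (length(hits)) {        # TE widened an exon: split it at the block
          h <- hits[1]
          ex <- rbind(ex[seq_len(h - 1), , drop = FALSE],
                      c(ex[h, 1], blk[1]), c(blk[2], ex[h, 2]),
                      ex[-seq_len(h), , drop = FALSE][-1, , drop = FALSE])
        } else {                   # TE sits in an intron: exonize its flanks
          prev <- max(which(ex[, 2] <= blk[1]))
          ex[prev, 2] <- blk[1]
          ex[prev + 1, 1] <- blk[2]
        }
        ex <- ex[ex[, 2] > ex[, 1], , drop = FALSE]
        tx <- mk_tx(paste0(tei$tei_id, ".intronized"), ex)
        events[[tei$tei_id]] <- if (wt_exonic) "intronization_exonic"
                                else "intronization_existing_intron"
      } else if (sc == "ATT") {
        if (strand == "+") {
          ex <- gx[gx$start0 < blk[1], c("start0", "end0"), drop = FALSE]
          if (nrow(ex) == 0) ex <- data.frame(start0 = gx$start0[1], end0 = blk[1])
          ex[nrow(ex), "end0"] <- blk[1] + floor(0.4 * (blk[2] - blk[1]))
        } else {
          ex <- gx[gx$end0 > blk[2], c("start0", "end0"), drop = FALSE]
          if (nrow(ex) == 0) ex <- data.frame(start0 = blk[2],
                                              end0 = gx$end0[nrow(gx)])
          ex[1, "start0"] <- blk[1] + floor(0.6 * (blk[2] - blk[1]))
        }
        tx <- mk_tx(paste0(tei$tei_id, ".att"), as.matrix(ex))
        events[[tei$tei_id]] <- "ATT"
      } else if (sc == "ATS") {
        if (strand == "+") {
          ex <- gx[gx$end0 > blk[2], c("start0", "end0"), drop = FALSE]
          if (nrow(ex) == 0) ex <- data.frame(start0 = blk[2],
                                              end0 = gx$end0[nrow(gx)])
          ex[1, "start0"] <- blk[1] + floor(0.6 * (blk[2] - blk[1]))
        } else {
          ex <- gx[gx$start0 < blk[1], c("start0", "end0"), drop = FALSE]
          if (nrow(ex) == 0) ex <- data.frame(start0 = gx$start0[1], end0 = blk[1])
          ex[nrow(ex), "end0"] <- blk[1] + floor(0.4 * (blk[2] - blk[1]))
        }
        tx <- mk_tx(paste0(tei$tei_id, ".ats"), as.matrix(ex))
        events[[tei$tei_id]] <- "ATS"
      } else if (sc == "unaffected") {
        events[[tei$tei_id]] <- "unaffected"
      } else {
        events[[tei$tei_id]] <- "not_transcribed"
      }

      if (sc == "not_transcribed") next
      normal_tx <- mk_tx(paste0(tei$tei_id, ".normal"), as.matrix(clear_ex))
      if (is.null(tx)) {           # unaffected: only the clear isoform
        iso <- list(normal_tx); frac <- 1
      } else {
        iso <- list(tx, normal_tx); frac <- c(0.8, 0.2)
      }
      total <- cfg$tx_depth
      cnt <- if (length(frac) == 1) total else {
        a <- rbinom(1, total, frac[1]); c(a, total - a)
      }
      for (j in seq_along(iso)) {
        counts[[length(counts) + 1L]] <- data.frame(
          transcript_id = iso[[j]]$transcript_id[1], gene_id = tei$gene_id,
          tei_id = tei$tei_id, count = cnt[j],
          class = if (j == 1 && !is.null(tx)) "tei" else "normal")
        if (cnt[j] > 0) {
          ids <- sprintf("%s_r%03d", iso[[j]]$transcript_id[1], seq_len(cnt[j]))
          rid <- rid + cnt[j]
          reads[[length(reads) + 1L]] <- data.frame(
            read_id = rep(ids, each = nrow(iso[[j]])),
            chrom = chrom,
            start0 = rep(iso[[j]]$start0, times = cnt[j]),
            end0 = rep(iso[[j]]$end0, times = cnt[j]))
        }
        models[[length(models) + 1L]] <- iso[[j]]
      }
    }
    list(
      models = if (length(models)) do.call(rbind, models) else NULL,
      counts = if (length(counts)) do.call(rbind, counts) else NULL,
      reads = if (length(reads)) do.call(rbind, reads) else NULL,
      events = unlist(events),
      scenarios = setNames(scen, host$tei_id)
    )
  })
}
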