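# Novel TE insertion calling from long-read alignments: soft-clip /
# insertion CIGAR signature extraction, single-linkage clustering, an exact
# binomial support test against the genome-wide background clip rate, the
# support / p-value / signal-fraction filters, TSD refinement and zygosity
# calling.

parse_cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  ops <- regmatches(cigar, list(m))[[1]]
  data.frame(
    len = as.integer(sub("[A-Z=]$", "", ops)),
    op = sub("^\\d+", "", ops),
    stringsAsFactors = FALSE
  )
}

#' Collect clipped / inserted-segment signals from alignments
#'
#' One signal per qualifying S or I CIGAR operation of a primary alignment.
#' Breakpoints: left clip at the alignment start, right clip at the
#' alignment end, internal insertion at the reference position of the I
#' operation. Segments are taken from the stored (reference-oriented) SEQ.
#'
#' @param alignments data.frame from [read_alignments()] /
#'   [simulate_read_alignments()]
#' @param min_clip_len minimum clipped/inserted length, bp
#' @param min_mapq minimum mapping quality
#' @return data.frame with read_id, chrom, pos0, side (left_clip /
#'   right_clip / internal_insertion), segment, mapq
#' @export
collect_clip_signals <- function(alignments, min_clip_len = 200L,
                                 min_mapq = 20L) {
  aln <- alignments[alignments$mapq >= min_mapq, , drop = FALSE]
  out <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    ops <- parse_cigar_ops(aln$cigar[i])
    qpos <- 0L   # consumed query bases
    rpos <- aln$pos0[i]
    sigs <- list()
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op == "S") {
        if (len >= min_clip_len) {
          side <- if (j == 1L) "left_clip" else "right_clip"
          sigs[[length(sigs) + 1L]] <- data.frame(
            read_id = aln$qname[i], chrom = aln$chrom[i],
            pos0 = rpos, side = side,
            segment = substr(aln$seq[i], qpos + 1L, qpos + len),
            mapq = aln$mapq[i], stringsAsFactors = FALSE)
        }
        qpos <- qpos + len
      } else if (op == "I") {
        if (len >= min_clip_len) {
          sigs[[length(sigs) + 1L]] <- data.frame(
            read_id = aln$qname[i], chrom = aln$chrom[i],
            pos0 = rpos, side = "internal_insertion",
            segment = substr(aln$seq[i], qpos + 1L, qpos + len),
            mapq = aln$mapq[i], stringsAsFactors = FALSE)
        }
        qpos <- qpos + len
      } else if (op %in% c("M", "=", "X")) {
        qpos <- qpos + len; rpos <- rpos + len
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + len
      } else if (op == "H") {
        # hard clip consumes neither
      } else if (op == "P") {
        # padding consumes neither
      }
    }
    if (length(sigs)) out[[i]] <- do.call(rbind, sigs)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(read_id = character(), chrom = character(),
                      pos0 = integer(), side = character(),
                      segment = character(), mapq = integer())
  res[order(res$chrom, res$pos0), , drop = FALSE]
}

#' Cluster clip signals into insertion candidates
#'
#' Single linkage: consecutive signals no more than `window` bp apart on the
#' same chromosome join one cluster. The cluster breakpoint is the (lower)
#' median signal position.
#'
#' @param signals data.frame from [collect_clip_signals()]
#' @param window linkage distance, bp
#' @return data.frame with chrom, pos0 (breakpoint), support (distinct
#'   reads), n_signals, plus a `cluster` index column added to the signals
#'   (returned as attribute "signals")
#' @export
cluster_signals <- function(signals, window = 50L) {
  if (nrow(signals) == 0) {
    return(data.frame(chrom = character(), pos0 = integer(),
                      support = integer(), n_signals = integer()))
  }
  s <- signals[order(signals$chrom, signals$pos0), , drop = FALSE]
  new_cl <- c(TRUE, diff(s$pos0) > window | s$chrom[-1] != s$chrom[-nrow(s)])
  s$cluster <- cumsum(new_cl)
  agg <- do.call(rbind, lapply(split(s, s$cluster), function(d) {
    data.frame(chrom = d$chrom[1],
               pos0 = as.integer(floor(median(d$pos0))),
               support = length(unique(d$read_id)),
               n_signals = nrow(d), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$chrom, agg$pos0), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "signals") <- s
  agg
}

#' Upper-tail exact binomial probability of a candidate's support
#'
#' P(X >= support | n = local_depth, p = bg_clip_rate), computed by exact
#' summation of binomial terms in log space.
#'
#' @param support clip-signal reads at the locus
#' @param local_depth reads overlapping the locus
#' @param bg_clip_rate background per-read clip probability
#' @return p-value in (0, 1]
#' @export
test_candidate <- function(support, local_depth, bg_clip_rate) {
  if (local_depth == 0) {
    warning("local depth is zero; p-value undefined, returning 1")
    return(1)
  }
  if (bg_clip_rate <= 0 || bg_clip_rate >= 1)
    stop("bg_clip_rate must be in (0, 1)")
  if (support > local_depth) stop("support exceeds local depth")
  if (support <= 0) return(1)
  min(1, sum(exp(dbinom(support:local_depth, local_depth, bg_clip_rate,
                        log = TRUE))))
}

#' Filter insertion candidates
#'
#' Retained iff support >= min_support AND p_value <= max_p AND
#' support / local_depth >= min_signal_fraction.
#'
#' @param candidates data.frame with support, local_depth, p_value
#' @param min_support minimum supporting reads
#' @param max_p maximum binomial p-value
#' @param min_signal_fraction minimum support / local depth
#' @return filtered data.frame
#' @export
filter_calls <- function(candidates, min_support = 4L, max_p = 0.05,
                         min_signal_fraction = 0.3) {
  keep <- candidates$support >= min_support &
    candidates$p_value <= max_p &
    candidates$support / candidates$local_depth >= min_signal_fraction
  candidates[keep, , drop = FALSE]
}

#' Detect the target-site duplication of a call
#'
#' Longest exact match (3..max_tsd bp) between the reference suffix ending
#' at the breakpoint and the terminus of the inserted segment, consistent
#' with the duplication produced by integration.
#'
#' @param reference DNAStringSet
#' @param chrom chromosome of the call
#' @param pos0 breakpoint (0-based)
#' @param segment consensus (or longest) inserted segment
#' @param max_tsd maximum TSD length considered
#' @return list(tsd_len, tsd_seq); tsd_len 0 with empty sequence if no
#'   duplication is found
#' @export
detect_tsd <- function(reference, chrom, pos0, segment, max_tsd = 20L) {
  seg_n <- nchar(segment)
  lim <- min(max_tsd, pos0, seg_n)
  if (lim >= 3) {
    ref_suffix <- as.character(Biostrings::subseq(reference[[chrom]],
                                                  pos0 - lim + 1L, pos0))
    for (L in seq(lim, 3L)) {
      rs <- substr(ref_suffix, lim - L + 1L, lim)
      if (substr(segment, seg_n - L + 1L, seg_n) == rs)
        return(list(tsd_len = L, tsd_seq = rs))
    }
  }
  list(tsd_len = 0L, tsd_seq = "")
}

#' Call zygosity from the carrier-read fraction
#'
#' @param support carrier (signal) reads
#' @param local_depth reads overlapping the locus
#' @return "hom" (fraction >= 0.8), "het" (0.2 <= fraction < 0.8) or
#'   "unknown" (fraction < 0.2 or depth < 6)
#' @export
call_zygosity <- function(support, local_depth) {
  if (local_depth < 6) return("unknown")
  f <- support / local_depth
  if (f >= 0.8) "hom" else if (f >= 0.2) "het" else "unknown"
}

#' Discover novel TE insertions from alignments
#'
#' Full caller: signal collection, clustering, local depth, exact binomial
#' test against the genome-wide background clip rate (signals per aligned
#' read, floored at 0.01), support/p/fraction filters, TSD refinement from
#' the longest supporting segment, and zygosity.
#'
#' @param alignments alignment data.frame (with end0 column)
#' @param reference DNAStringSet
#' @param min_clip_len minimum clip length, bp
#' @param min_mapq minimum mapping quality
#' @param window clustering window, bp
#' @param min_support minimum supporting reads
#' @param max_p maximum p-value
#' @param min_signal_fraction minimum support / local depth
#' @param max_tsd maximum TSD length
#' @return TEI call data.frame: tei_id, chrom, pos0, tsd_len, tsd_seq,
#'   support, local_depth, p_value, zygosity, longest_segment
#' @export
discover_teis <- function(alignments, reference,
                          min_clip_len = 200L, min_mapq = 20L,
                          window = 50L, min_support = 4L, max_p = 0.05,
                          min_signal_fraction = 0.3, max_tsd = 20L) {
  signals <- collect_clip_signals(alignments, min_clip_len, min_mapq)
  clusters <- cluster_signals(signals, window)
  if (nrow(clusters) == 0) return(empty_calls())
  sig <- attr(clusters, "signals")

  bg <- max(0.01, nrow(signals) / max(1L, nrow(alignments)))

  clusters$local_depth <- vapply(seq_len(nrow(clusters)), function(i) {
    sum(alignments$chrom == clusters$chrom[i] &
          alignments$pos0 <= clusters$pos0[i] &
          alignments$end0 >= clusters$pos0[i] &   # >=: clipped reads end AT the breakpoint
          alignments$mapq >= min_mapq)
  }, integer(1))
  clusters$local_depth <- pmax(clusters$local_depth, clusters$support)
  clusters$p_value <- vapply(seq_len(nrow(clusters)), function(i)
    test_candidate(clusters$support[i], clusters$local_depth[i], bg),
    numeric(1))

  calls <- filter_calls(clusters, min_support, max_p, min_signal_fraction)
  if (nrow(calls) == 0) return(empty_calls())
  calls$tei_id <- sprintf("tei%03d", seq_len(nrow(calls)))

  calls$tsd_len <- 0L; calls$tsd_seq <- ""; calls$longest_segment <- ""
  calls$zygosity <- "unknown"
  for (i in seq_len(nrow(calls))) {
    cl_id <- sig$cluster[sig$chrom == calls$chrom[i] &
                           abs(sig$pos0 - calls$pos0[i]) <= window][1]
    segs <- sig$segment[sig$cluster == cl_id]
    seg <- segs[which.max(nchar(segs))]
    calls$longest_segment[i] <- seg
    tsd <- detect_tsd(reference, calls$chrom[i], calls$pos0[i], seg, max_tsd)
    calls$tsd_len[i] <- tsd$tsd_len
    calls$tsd_seq[i] <- tsd$tsd_seq
    calls$zygosity[i] <- call_zygosity(calls$support[i], calls$local_depth[i])
  }
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(chrom = character(), pos0 = integer(), support = integer(),
             n_signals = integer(), local_depth = integer(),
             p_value = numeric(), tei_id = character(), tsd_len = integer(),
             tsd_seq = character(), longest_segment = character(),
             zygosity = character(), stringsAsFactors = FALSE)
}
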