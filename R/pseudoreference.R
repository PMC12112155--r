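# Pseudoreference construction: consensus reconstruction of each inserted
# sequence from clipped/inserted read segments, insertion into the reference
# with a duplicated TSD, annotation shifting, and an invertible coordinate
# liftover.

#' Extract inserted-sequence segments supporting a call
#'
#' For each primary read with a soft-clip (S) or insertion (I) CIGAR
#' operation within `window` of the call breakpoint, the clipped/inserted
#' subsequence is returned. SAM stores SEQ in reference orientation, so the
#' segments are already reference-oriented regardless of the read's strand
#' flag.
#'
#' @param alignments data.frame from [read_alignments()] or
#'   [simulate_read_alignments()]
#' @param call one-row data.frame (or list) with chrom and pos0
#' @param window max distance between the signal and the call breakpoint, bp
#' @param min_clip_len minimum segment length
#' @return character vector of DNA segments (possibly empty)
#' @export
extract_insert_segments <- function(alignments, call, window = 50L,
                                    min_clip_len = 200L) {
  sig <- collect_clip_signals(alignments, min_clip_len = min_clip_len,
                              min_mapq = 0L)
  sel <- sig$chrom == call$chrom & abs(sig$pos0 - call$pos0) <= window
  sig$segment[sel]
}

#' Build a consensus from insert segments
#'
#' The longest segment is the anchor; every other segment is globally
#' aligned to it (match +1, mismatch -1, gap -2, ends free on the anchor so
#' truncated segments vote only on the columns they cover). Per anchor
#' column a majority vote is taken over aligned bases, ties resolved to the
#' anchor base; a column where the anchor is gapped (an insertion relative
#' to the anchor) is kept only when a strict majority of all segments
#' supports an identical inserted string at that position.
#'
#' @param segments character vector of DNA strings
#' @return consensus DNA string
#' @export
build_consensus <- function(segments) {
  segments <- segments[nzchar(segments)]
  if (length(segments) == 0) stop("no segments to build a consensus from")
  if (length(segments) == 1) return(segments)
  anchor <- segments[which.max(nchar(segments))]
  others <- segments[-which.max(nchar(segments))]

  # fast path: segments that are exact substrings of the anchor carry no
  # divergent information
  exact <- vapply(others, function(s)
    Biostrings::countPattern(s, Biostrings::DNAString(anchor)) > 0, logical(1))
  if (all(exact)) return(anchor)

  n_anchor <- nchar(anchor)
  n_seg <- length(segments)
  # votes[b, p]: votes for base b at anchor column p (A C G T and deletion)
  votes <- matrix(0L, nrow = 5, ncol = n_anchor,
                  dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  anchor_chars <- strsplit(anchor, "")[[1]]
  for (p in seq_len(n_anchor))
    votes[anchor_chars[p], p] <- votes[anchor_chars[p], p] + 1L
  insertions <- list()

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (s in others) {
    if (Biostrings::countPattern(s, Biostrings::DNAString(anchor)) > 0) {
      st <- as.integer(Biostrings::matchPattern(s, Biostrings::DNAString(anchor))@ranges@start[1])
      idx <- st:(st + nchar(s) - 1L)
      ch <- strsplit(s, "")[[1]]
      for (j in seq_along(idx)) votes[ch[j], idx[j]] <- votes[ch[j], idx[j]] + 1L
      next
    }
    pa <- Biostrings::pairwiseAlignment(
      pattern = s, subject = anchor, type = "global-local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    spos <- Biostrings::start(Biostrings::subject(pa)) - 1L
    ins_buf <- ""
    for (j in seq_along(as_)) {
      if (as_[j] == "-") {
        ins_buf <- paste0(ins_buf, ap[j])
      } else {
        spos <- spos + 1L
        if (nzchar(ins_buf)) {
          key <- as.character(spos - 1L)
          insertions[[key]] <- c(insertions[[key]], ins_buf)
          ins_buf <- ""
        }
        votes[ap[j], spos] <- votes[ap[j], spos] + 1L
      }
    }
  }

  base_at <- vapply(seq_len(n_anchor), function(p) {
    v <- votes[, p]
    if (sum(v) == 0) return(anchor_chars[p])
    top <- max(v)
    winners <- rownames(votes)[v == top]
    if (anchor_chars[p] %in% winners) anchor_chars[p] else winners[1]
  }, character(1))

  out <- character(0)
  for (p in seq_len(n_anchor)) {
    key <- as.character(p)
    if (!is.null(insertions[[key]])) {
      tab <- table(insertions[[key]])
      if (max(tab) > n_seg / 2)
        out <- c(out, names(tab)[which.max(tab)])
    }
    if (base_at[p] != "-") out <- c(out, base_at[p])
  }
  paste(out, collapse = "")
}

#' Detect terminal repeats (LTR-like prefix/suffix blocks)
#'
#' Longest pair of equal-length prefix and suffix blocks with pairwise
#' identity at least 1 - max_mismatch_rate.
#'
#' @param consensus DNA string
#' @param min_len minimum repeat length, bp
#' @param max_mismatch_rate maximum tolerated mismatch fraction
#' @return list(start1, end1, start2, end2) of 0-based half-open repeat
#'   coordinates, or NULL if absent
#' @export
detect_terminal_repeats <- function(consensus, min_len = 100L,
                                    max_mismatch_rate = 0.05) {
  n <- nchar(consensus)
  if (n < 2 * min_len) return(NULL)
  ch <- strsplit(consensus, "")[[1]]
  for (L in seq(floor(n / 2), min_len)) {
    mism <- sum(ch[1:L] != ch[(n - L + 1):n])
    if (mism / L <= max_mismatch_rate)
      return(list(start1 = 0L, end1 = L, start2 = n - L, end2 = n))
  }
  NULL
}

#' Build a liftover from insertion breakpoints
#'
#' @param breakpoints data.frame with chrom, ref_pos0 and ins_len; one row
#'   per inserted block, positions on the original reference
#' @return liftover object (data.frame with cumulative offsets, class
#'   `liftover`)
#' @export
build_liftover <- function(breakpoints) {
  bp <- breakpoints[order(breakpoints$chrom, breakpoints$ref_pos0), , drop = FALSE]
  if (nrow(bp) > 1) {
    same <- duplicated(bp[, c("chrom", "ref_pos0")])
    if (any(same)) stop("overlapping insertion breakpoints")
  }
  bp$cum_offset <- ave(bp$ins_len, bp$chrom, FUN = cumsum)
  rownames(bp) <- NULL
  class(bp) <- c("liftover", "data.frame")
  bp
}

#' Map a position through the liftover
#'
#' Bijective outside inserted blocks. A pseudoreference position falling
#' inside an inserted block maps to NA in the reference direction.
#'
#' @param liftover from [build_liftover()]
#' @param chrom chromosome
#' @param pos0 0-based position(s)
#' @param direction "ref_to_pseudo" or "pseudo_to_ref"
#' @return mapped 0-based position(s); NA where undefined
#' @export
lift_position <- function(liftover, chrom, pos0,
                          direction = c("ref_to_pseudo", "pseudo_to_ref")) {
  direction <- match.arg(direction)
  if (any(pos0 < 0)) stop("position out of range")
  bp <- liftover[liftover$chrom == chrom, , drop = FALSE]
  if (nrow(bp) == 0) return(pos0)
  if (direction == "ref_to_pseudo") {
    vapply(pos0, function(p)
      p + sum(bp$ins_len[bp$ref_pos0 <= p]), numeric(1))
  } else {
    # block i occupies [ref_pos0 + cum_offset - ins_len, ref_pos0 + cum_offset)
    blk_s <- bp$ref_pos0 + bp$cum_offset - bp$ins_len
    blk_e <- bp$ref_pos0 + bp$cum_offset
    vapply(pos0, function(q) {
      if (any(q >= blk_s & q < blk_e)) return(NA_real_)
      off <- sum(bp$ins_len[blk_e <= q])
      q - off
    }, numeric(1))
  }
}

#' Insert consensus sequences into the reference with duplicated TSDs
#'
#' The inserted block at each breakpoint is consensus + one extra copy of
#' the TSD, so the TSD (the reference bases immediately left of the
#' breakpoint) flanks the insertion on both sides.
#'
#' @param reference DNAStringSet
#' @param calls data.frame with chrom, pos0, consensus, tsd_seq
#' @return list(pseudoreference = DNAStringSet, liftover = liftover)
#' @export
insert_with_tsd <- function(reference, calls) {
  if (nrow(calls) == 0) {
    lo <- build_liftover(data.frame(chrom = character(), ref_pos0 = integer(),
                                    ins_len = integer()))
    return(list(pseudoreference = reference, liftover = lo))
  }
  calls <- calls[order(calls$chrom, calls$pos0), , drop = FALSE]
  if (any(duplicated(calls[, c("chrom", "pos0")])))
    stop("overlapping insertion intervals")
  blocks <- paste0(calls$consensus, calls$tsd_seq)
  pseudo <- reference
  for (chrom in unique(calls$chrom)) {
    sel <- calls$chrom == chrom
    pseudo[[chrom]] <- Biostrings::replaceAt(
      pseudo[[chrom]],
      IRanges::IRanges(start = calls$pos0[sel] + 1L, width = 0L),
      Biostrings::DNAStringSet(blocks[sel]))
  }
  lo <- build_liftover(data.frame(chrom = calls$chrom, ref_pos0 = calls$pos0,
                                  ins_len = nchar(blocks)))
  list(pseudoreference = pseudo, liftover = lo)
}

#' Shift annotation coordinates through a liftover
#'
#' Features wholly downstream of an insertion shift by the cumulative
#' inserted length; features spanning an insertion point are widened to
#' include the insert; lengths of non-spanning features are preserved.
#'
#' @param annotation data.frame with chrom, start0, end0 (0-based half-open;
#'   any other columns are carried through)
#' @param liftover from [build_liftover()]
#' @return annotation data.frame with shifted coordinates
#' @export
shift_annotation <- function(annotation, liftover) {
  out <- annotation
  for (i in seq_len(nrow(out))) {
    chrom <- out$chrom[i]
    s <- lift_position(liftover, chrom, out$start0[i], "ref_to_pseudo")
    e_last <- lift_position(liftover, chrom, out$end0[i] - 1L, "ref_to_pseudo")
    out$start0[i] <- as.integer(s)
    out$end0[i] <- as.integer(e_last + 1L)
  }
  out
}

#' Reconstruct insertion assemblies and build the pseudoreference
#'
#' Convenience wrapper running segment extraction, consensus and insertion
#' for a table of calls.
#'
#' @param alignments alignment data.frame
#' @param calls TEI call table from [discover_teis()]
#' @param reference DNAStringSet
#' @param window breakpoint window for segment extraction
#' @param min_clip_len minimum segment length
#' @return list(pseudoreference, liftover, assemblies) where assemblies maps
#'   tei_id to list(consensus, n_segments, ltr)
#' @export
build_pseudoreference <- function(alignments, calls, reference,
                                  window = 50L, min_clip_len = 200L) {
  assemblies <- list()
  cons <- character(nrow(calls))
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    segs <- extract_insert_segments(alignments, calls[i, ], window = window,
                                    min_clip_len = min_clip_len)
    if (length(segs) == 0) {
      warning("no insert segments for ", calls$tei_id[i], "; assembly skipped")
      next
    }
    cns <- build_consensus(segs)
    # the duplicated TSD travels with the block; strip it from the consensus
    # so that insert_with_tsd adds exactly one extra copy
    tl <- calls$tsd_len[i]
    consensus <- if (!is.na(tl) && tl > 0 &&
                     substr(cns, nchar(cns) - tl + 1L, nchar(cns)) ==
                       calls$tsd_seq[i]) {
      substr(cns, 1L, nchar(cns) - tl)
    } else cns
    cons[i] <- consensus
    keep[i] <- TRUE
    assemblies[[calls$tei_id[i]]] <- list(
      consensus = consensus, n_segments = length(segs),
      ltr = detect_terminal_repeats(consensus))
  }
  calls2 <- calls[keep, , drop = FALSE]
  calls2$consensus <- cons[keep]
  ps <- insert_with_tsd(reference, calls2)
  list(pseudoreference = ps$pseudoreference, liftover = ps$liftover,
       assemblies = assemblies, calls = calls2)
}
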