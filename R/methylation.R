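# Methylation metaplot machinery: context annotation, coverage filtering,
# flank/body/flank binning (40 x 50 bp + 100 proportional + 40 x 50 bp),
# cross-sample metaplots with SD and rolling-mean smoothing, control
# subtraction through the liftover, spread distance and edge/body ratios.

#' Annotate cytosine context from the genome sequence
#'
#' Plus strand: CG if the next base is G; CHG if the pattern is C-H-G
#' (H in A/C/T); otherwise CHH. Minus strand symmetric on the reverse
#' complement. Records whose position is not a cytosine on the stated
#' strand are rejected (counted in attribute `n_rejected`).
#'
#' @param genome DNAStringSet
#' @param records data.frame with chrom, pos0, strand
#' @return records with a `context` column; rejected rows dropped
#' @export
annotate_context <- function(genome, records) {
  ctx <- rep(NA_character_, nrow(records))
  for (chrom in unique(records$chrom)) {
    idx <- which(records$chrom == chrom)
    chars <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    n <- length(chars)
    p <- records$pos0[idx] + 1L
    plus <- records$strand[idx] == "+"
    ok_p <- plus & chars[p] == "C"
    ok_m <- !plus & chars[p] == "G"
    nxt <- ifelse(p + 1 <= n, chars[pmin(p + 1, n)], "")
    nx2 <- ifelse(p + 2 <= n, chars[pmin(p + 2, n)], "")
    prv <- ifelse(p - 1 >= 1, chars[pmax(p - 1, 1)], "")
    pv2 <- ifelse(p - 2 >= 1, chars[pmax(p - 2, 1)], "")
    ctx[idx[ok_p]] <- ifelse(nxt[ok_p] == "G", "CG",
                             ifelse(nx2[ok_p] == "G", "CHG", "CHH"))
    ctx[idx[ok_m]] <- ifelse(prv[ok_m] == "C", "CG",
                             ifelse(pv2[ok_m] == "C", "CHG", "CHH"))
  }
  out <- records
  out$context <- ctx
  n_rej <- sum(is.na(ctx))
  out <- out[!is.na(ctx), , drop = FALSE]
  attr(out, "n_rejected") <- n_rej
  out
}

#' Filter methylation records by coverage
#'
#' Records with fewer than `min_valid` reads are dropped; of the remainder,
#' records whose coverage lies strictly below the `q_low` or strictly above
#' the `q_high` empirical quantile are removed as outliers.
#'
#' @param records data.frame with n_valid
#' @param min_valid minimum valid coverage
#' @param q_low,q_high empirical quantile bounds
#' @return filtered records
#' @export
filter_coverage <- function(records, min_valid = 3L, q_low = 0.05,
                            q_high = 0.95) {
  if (nrow(records) == 0) return(records)
  r <- records[records$n_valid >= min_valid, , drop = FALSE]
  if (nrow(r) == 0) return(r)
  qs <- quantile(r$n_valid, c(q_low, q_high), names = FALSE)
  r[r$n_valid >= qs[1] & r$n_valid <= qs[2], , drop = FALSE]
}

flank_body_bins <- function(element, flank_bp, flank_bin, body_bins) {
  n_flank <- flank_bp %/% flank_bin
  list(n_flank = n_flank, n_total = 2L * n_flank + body_bins)
}

#' Bin an element's methylation into flank/body/flank profile
#'
#' Fixed 50 bp bins over each 2 kb flank (40 per side) and 100 proportional
#' bins over the element body. Each cytosine lands in exactly one bin; a
#' bin value is the unweighted mean methylated fraction over its cytosines
#' (replicates pooled beforehand); bins without cytosines are NA, never 0.
#' Minus-strand elements are flipped so bin 1 is always the element 5' side.
#'
#' @param records methylation records (one context, one or more pooled
#'   replicates) with chrom, pos0, frac_mod
#' @param element list/row with chrom, start0, end0, strand
#' @param flank_bp flank width, bp
#' @param flank_bin flank bin width, bp
#' @param body_bins body bin count
#' @return list of class `binned_profile`: values (length 2*flank+body),
#'   counts, n_flank, body_bins
#' @export
bin_element <- function(records, element, flank_bp = 2000L, flank_bin = 50L,
                        body_bins = 100L) {
  if (flank_bp %% flank_bin != 0)
    stop("flank_bp must be divisible by flank_bin")
  n_flank <- flank_bp %/% flank_bin
  n_total <- 2L * n_flank + body_bins
  s <- element$start0; e <- element$end0
  len <- e - s
  if (len < 1) stop("element has non-positive length")
  r <- records[records$chrom == element$chrom &
                 records$pos0 >= s - flank_bp &
                 records$pos0 < e + flank_bp, , drop = FALSE]
  bin <- integer(nrow(r))
  left <- r$pos0 < s
  right <- r$pos0 >= e
  body <- !left & !right
  bin[left] <- (r$pos0[left] - (s - flank_bp)) %/% flank_bin + 1L
  # proportional body bins: floor(offset * body_bins / len)
  bin[body] <- n_flank + pmin(body_bins - 1L,
                              ((r$pos0[body] - s) * body_bins) %/% len) + 1L
  bin[right] <- n_flank + body_bins + (r$pos0[right] - e) %/% flank_bin + 1L
  vals <- rep(NA_real_, n_total)
  cnts <- integer(n_total)
  if (nrow(r)) {
    agg_m <- tapply(r$frac_mod, bin, mean)
    agg_n <- tapply(r$frac_mod, bin, length)
    idx <- as.integer(names(agg_m))
    vals[idx] <- as.numeric(agg_m)
    cnts[idx] <- as.integer(agg_n)
  }
  st <- element$strand %||% "+"
  if (!is.null(st) && !is.na(st) && st == "-") {
    vals <- rev(vals); cnts <- rev(cnts)
  }
  structure(list(values = vals, counts = cnts, n_flank = n_flank,
                 body_bins = body_bins, element_id = element$element_id %||% NA,
                 chrom = element$chrom, start0 = s, end0 = e),
            class = "binned_profile")
}

#' Cross-profile metaplot with SD and smoothing
#'
#' Per-bin mean and standard deviation across profiles (SD = 0 when only
#' one profile contributes), then a centered 10-bin rolling mean applied to
#' the mean track (truncated windows at the edges).
#'
#' @param profiles list of [bin_element()] results with identical geometry
#' @param smooth_window rolling-mean width, bins
#' @return list: mean, sd, smoothed, n (profiles per bin), n_flank,
#'   body_bins
#' @export
metaplot <- function(profiles, smooth_window = 10L) {
  if (length(profiles) == 0) stop("no profiles")
  geom <- vapply(profiles, function(p) c(p$n_flank, p$body_bins), numeric(2))
  if (any(geom[1, ] != geom[1, 1]) || any(geom[2, ] != geom[2, 1]))
    stop("profile bin geometry mismatch")
  m <- do.call(rbind, lapply(profiles, `[[`, "values"))
  mu <- apply(m, 2, function(x) if (all(is.na(x))) NA_real_
              else mean(x, na.rm = TRUE))
  n <- apply(m, 2, function(x) sum(!is.na(x)))
  sdv <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) <= 1) return(if (length(x) == 1) 0 else NA_real_)
    sd(x)
  })
  list(mean = mu, sd = sdv, smoothed = rolling_mean(mu, smooth_window),
       n = n, n_flank = profiles[[1]]$n_flank,
       body_bins = profiles[[1]]$body_bins)
}

#' Subtract control methylation from an element's flank bins
#'
#' Control records live on the original reference; each pseudoreference
#' flank bin is lifted back to reference coordinates (bins overlapping
#' another inserted block do not lift contiguously and become NA), the
#' control is binned with identical geometry and subtracted bin-wise. Bins
#' empty in either track are NA in the difference.
#'
#' @param sample_profile [bin_element()] result on the pseudoreference
#' @param control_records control methylation records (reference
#'   coordinates, same context, coverage-filtered)
#' @param liftover from [build_liftover()]
#' @param flank_bin flank bin width, bp
#' @return list(left, right): difference tracks, element-adjacent bin first
#'   in `right`, chromosome order in `left`
#' @export
subtract_control <- function(sample_profile, control_records, liftover,
                             flank_bin = 50L) {
  p <- sample_profile
  n_flank <- p$n_flank
  ctrl_bin_mean <- function(bin_start0) {
    # per-base lift: positions inside inserted blocks (the element's own
    # duplicated TSD, or another insertion) do not map and are skipped; a
    # bin with fewer than half its bases mapping is marked empty
    ref_pos <- lift_position(liftover, p$chrom,
                             bin_start0 + seq_len(flank_bin) - 1L,
                             "pseudo_to_ref")
    ref_pos <- ref_pos[!is.na(ref_pos)]
    if (length(ref_pos) < flank_bin / 2) return(NA_real_)
    sel <- control_records$chrom == p$chrom &
      control_records$pos0 %in% ref_pos
    if (!any(sel)) return(NA_real_)
    mean(control_records$frac_mod[sel])
  }
  left_starts <- p$start0 - n_flank * flank_bin + (seq_len(n_flank) - 1L) * flank_bin
  right_starts <- p$end0 + (seq_len(n_flank) - 1L) * flank_bin
  ctrl_left <- vapply(left_starts, ctrl_bin_mean, numeric(1))
  ctrl_right <- vapply(right_starts, ctrl_bin_mean, numeric(1))
  samp_left <- p$values[seq_len(n_flank)]
  samp_right <- p$values[n_flank + p$body_bins + seq_len(n_flank)]
  list(left = samp_left - ctrl_left, right = samp_right - ctrl_right)
}

#' Methylation spread distance from the element boundary
#'
#' Length of the contiguous run of difference-track bins at or above
#' `threshold`, starting at the element boundary, times the bin width.
#'
#' @param difference_track numeric vector of flank-bin differences, ordered
#'   with the element-adjacent bin first
#' @param threshold minimum difference
#' @param bin_bp bin width, bp
#' @return spread distance in bp
#' @export
spread_distance <- function(difference_track, threshold = 0.05, bin_bp = 50L) {
  run <- 0L
  for (v in difference_track) {
    if (is.na(v) || v < threshold) break
    run <- run + 1L
  }
  run * bin_bp
}

#' Edge/body methylation ratio of a profile
#'
#' Mean over the edge (terminal-repeat-covering) body bins divided by the
#' mean over the central 20 body bins. Infinite when the centre is 0 but
#' the edges are not; 1 when both are 0.
#'
#' @param profile [bin_element()] result
#' @param edge_bins number of body bins counted as "edge" on each side
#'   (defaults to the share of the body covered by a terminal repeat of
#'   `ltr_length`, at least 1)
#' @param ltr_length repeat length used for the default edge span, bp
#' @return ratio (numeric scalar)
#' @export
edge_body_ratio <- function(profile, edge_bins = NULL, ltr_length = 300L) {
  p <- profile
  len <- p$end0 - p$start0
  if (is.null(edge_bins))
    edge_bins <- max(1L, as.integer(floor(ltr_length / len * p$body_bins)))
  body <- p$values[p$n_flank + seq_len(p$body_bins)]
  edge <- c(body[seq_len(edge_bins)],
            body[(p$body_bins - edge_bins + 1L):p$body_bins])
  mid0 <- p$body_bins %/% 2
  centre <- body[(mid0 - 9L):(mid0 + 10L)]
  em <- mean(edge, na.rm = TRUE)
  cm <- mean(centre, na.rm = TRUE)
  if (is.nan(em) || is.nan(cm)) return(NA_real_)
  if (cm == 0) return(if (em > 0) Inf else 1)
  em / cm
}

#' Pearson correlation of methylation SD with insertion count
#'
#' @param per_donor_sd named numeric: per-donor cross-sample methylation SD
#'   (averaged over bins)
#' @param per_donor_insertions named numeric: insertions per donor
#' @return list(r, n); r is NA with a warning when either vector has zero
#'   variance
#' @export
sd_vs_insertion_count <- function(per_donor_sd, per_donor_insertions) {
  donors <- intersect(names(per_donor_sd), names(per_donor_insertions))
  if (length(donors) < 3) stop("need at least 3 donors")
  x <- per_donor_sd[donors]; y <- per_donor_insertions[donors]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, n = length(donors)))
  }
  list(r = cor(x, y), n = length(donors))
}
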