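# Positional and set statistics: interval intersection with half-open
# semantics, chromatin-state binomial enrichment against a base-pair
# background, random-site backgrounds, a two-sample Kolmogorov-Smirnov
# comparison of genomic position distributions, Fisher's exact gene-overlap
# test, and summary tables of insertion calls.

#' Intersect sites with labelled features
#'
#' Half-open semantics: a point site `p` hits feature `[s, e)` iff
#' `s <= p < e`.
#'
#' @param sites data.frame with chrom and pos0 (points) or chrom,
#'   start0, end0 (intervals)
#' @param features data.frame with chrom, start0, end0, name (labels)
#' @return list(per_site = list of label vectors, counts = named label
#'   counts, n_hit = sites with at least one label)
#' @export
intersect_sites <- function(sites, features) {
  if (is.null(sites$start0)) {
    sites$start0 <- sites$pos0
    sites$end0 <- sites$pos0 + 1L
  }
  gr_s <- df_to_granges(sites)
  gr_f <- df_to_granges(features)
  ov <- GenomicRanges::findOverlaps(gr_s, gr_f)
  lab <- features$name
  per_site <- lapply(seq_len(nrow(sites)), function(i)
    unique(lab[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]))
  hits <- unlist(per_site)
  counts <- if (length(hits)) table(hits) else table(character(0))
  list(per_site = per_site,
       counts = setNames(as.integer(counts), names(counts)),
       n_hit = sum(lengths(per_site) > 0))
}

#' Exact one-sided binomial enrichment test
#'
#' Background success probability is the genome-wide base-pair fraction
#' covered by the feature set; the p-value is the exact upper tail
#' P(X >= k | n, p0), summed in log space.
#'
#' @param k observed sites in the state
#' @param n total sites
#' @param features feature intervals (data.frame with chrom, start0, end0),
#'   or a single numeric: the covered fraction p0 directly
#' @param genome_size total genome size in bp (ignored when `features` is
#'   already a fraction)
#' @return list(k, n, p0, p_value)
#' @export
binomial_enrichment <- function(k, n, features, genome_size = NULL) {
  p0 <- if (is.numeric(features) && length(features) == 1) {
    features
  } else {
    covered <- sum(GenomicRanges::width(GenomicRanges::reduce(df_to_granges(features))))
    covered / genome_size
  }
  if (p0 <= 0 || p0 >= 1) stop("background fraction must be in (0, 1)")
  p <- if (k <= 0) 1 else
    min(1, sum(exp(dbinom(k:n, n, p0, log = TRUE))))
  list(k = k, n = n, p0 = p0, p_value = p)
}

#' Uniform random sites per chromosome
#'
#' @param genome_lengths named integer vector of chromosome lengths
#' @param per_chrom sites per chromosome
#' @param seed RNG seed
#' @return data.frame with chrom, pos0
#' @export
random_sites <- function(genome_lengths, per_chrom = 100L, seed = 1L) {
  with_seed(seed, {
    do.call(rbind, lapply(names(genome_lengths), function(chrom) {
      data.frame(chrom = chrom,
                 pos0 = as.integer(floor(runif(per_chrom, 0,
                                               genome_lengths[[chrom]]))),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic Kolmogorov distribution with the standard
#' effective-sample-size correction.
#'
#' @param a,b numeric samples (e.g. positions normalized per chromosome to
#'   `[0, 1]` and pooled)
#' @return list(D, p_value)
#' @export
ks_two_sample <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n < 2 || m < 2) stop("need at least 2 observations per sample")
  w <- c(a, b)
  o <- order(w)
  z <- cumsum(ifelse(o <= n, 1 / n, -1 / m))
  # drop within-tie positions so D is evaluated only after each tie group
  ties <- c(diff(sort(w)) == 0, FALSE)
  D <- max(abs(z[!ties]))
  ne <- n * m / (n + m)
  t <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  list(D = D, p_value = min(1, max(0, p)))
}

#' KS comparison of genomic site distributions
#'
#' Positions are normalized by chromosome length and pooled across
#' chromosomes before the test.
#'
#' @param sites_a,sites_b data.frames with chrom, pos0
#' @param genome_lengths named chromosome lengths
#' @return list(D, p_value)
#' @export
ks_positions <- function(sites_a, sites_b, genome_lengths) {
  norm <- function(s) s$pos0 / unname(genome_lengths[s$chrom])
  ks_two_sample(norm(sites_a), norm(sites_b))
}

#' Fisher's exact test for gene-set overlap
#'
#' Two-sided p by hypergeometric enumeration over the 2x2 table
#' `[[overlap, a - overlap], [b - overlap, universe - a - b + overlap]]`.
#'
#' @param n_a,n_b set sizes
#' @param overlap common elements
#' @param universe gene universe size
#' @return list(odds_ratio, p_value, table)
#' @export
fisher_overlap <- function(n_a, n_b, overlap, universe) {
  if (overlap > min(n_a, n_b)) stop("overlap exceeds a set size")
  if (universe < n_a + n_b - overlap) stop("universe smaller than the union")
  x11 <- overlap; x12 <- n_a - overlap
  x21 <- n_b - overlap; x22 <- universe - n_a - n_b + overlap
  # hypergeometric support for fixed margins
  lo <- max(0L, n_a + n_b - universe)
  hi <- min(n_a, n_b)
  dens <- dhyper(lo:hi, m = n_a, n = universe - n_a, k = n_b)
  d_obs <- dhyper(x11, m = n_a, n = universe - n_a, k = n_b)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  or <- (x11 * x22) / (x12 * x21)
  list(odds_ratio = or, p_value = min(1, p),
       table = matrix(c(x11, x12, x21, x22), 2, byrow = TRUE))
}

#' Summarize an insertion call table by plant
#'
#' Per plant and in total: insertion count, intragenic percentage (one
#' decimal, half-up), homozygous and heterozygous counts. Totals are column
#' sums over plants; the total intragenic percentage is the overall genic
#' fraction (total genic / total insertions).
#'
#' @param calls data.frame with plant, genic (logical), zygosity
#'   ("hom"/"het"/other)
#' @return list(per_plant = data.frame, total = one-row data.frame,
#'   min_per_plant, max_per_plant)
#' @export
summarize_tei_table <- function(calls) {
  if (nrow(calls) == 0) {
    tot <- data.frame(plant = "total", n = 0L, genic_pct = 0,
                      hom = 0L, het = 0L)
    return(list(per_plant = tot[0, ], total = tot,
                min_per_plant = 0L, max_per_plant = 0L))
  }
  per <- do.call(rbind, lapply(split(calls, calls$plant), function(d) {
    data.frame(plant = d$plant[1], n = nrow(d),
               genic_pct = round_half_up(100 * sum(d$genic) / nrow(d), 1),
               hom = sum(d$zygosity == "hom"),
               het = sum(d$zygosity == "het"), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  total <- data.frame(
    plant = "total", n = sum(per$n),
    genic_pct = round_half_up(100 * sum(calls$genic) / nrow(calls), 1),
    hom = sum(per$hom), het = sum(per$het), stringsAsFactors = FALSE)
  list(per_plant = per, total = total,
       min_per_plant = min(per$n), max_per_plant = max(per$n))
}

#' Percentage matrix of site sets over chromatin states
#'
#' Cell (state, set) is 100 x (sites of the set overlapping the state) /
#' (set size).
#'
#' @param site_sets named list of site data.frames (chrom, pos0)
#' @param states state intervals (chrom, start0, end0, name)
#' @return numeric matrix, rows = states, columns = site sets
#' @export
state_fraction_matrix <- function(site_sets, states) {
  state_labels <- sort(unique(states$name))
  m <- matrix(0, nrow = length(state_labels), ncol = length(site_sets),
              dimnames = list(state_labels, names(site_sets)))
  for (j in seq_along(site_sets)) {
    sites <- site_sets[[j]]
    if (nrow(sites) == 0) {
      warning("empty site set: ", names(site_sets)[j])
      next
    }
    ix <- intersect_sites(sites, states)
    for (i in seq_len(nrow(sites))) {
      for (lab in ix$per_site[[i]])
        m[lab, j] <- m[lab, j] + 1
    }
    m[, j] <- 100 * m[, j] / nrow(sites)
  }
  m
}

#' Benjamini-Hochberg adjusted enrichment over all states
#'
#' Runs [binomial_enrichment()] for every state label and reports raw and
#' FDR-adjusted p-values.
#'
#' @param sites site data.frame (chrom, pos0)
#' @param states state intervals with labels
#' @param genome_size genome size in bp
#' @return data.frame: state, k, n, p0, p_value, fdr
#' @export
state_enrichment <- function(sites, states, genome_size) {
  labs <- sort(unique(states$name))
  ix <- intersect_sites(sites, states)
  n <- nrow(sites)
  res <- do.call(rbind, lapply(labs, function(lab) {
    k <- sum(vapply(ix$per_site, function(v) lab %in% v, logical(1)))
    st <- states[states$name == lab, , drop = FALSE]
    e <- binomial_enrichment(k, n, st, genome_size)
    data.frame(state = lab, k = k, n = n, p0 = e$p0, p_value = e$p_value)
  }))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value), ]
}
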