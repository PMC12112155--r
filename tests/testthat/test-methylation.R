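test_that("context annotation follows the CG/CHG/CHH definitions", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTCAGTCATG"))
  #                                      123456789012
  rec <- data.frame(chrom = "chr1",
                    pos0 = c(1L, 4L, 8L, 2L, 11L, 0L),
                    strand = c("+", "+", "+", "-", "-", "+"))
  out <- annotate_context(genome, rec)
  # +C at "CGT" -> CG; +C at "CAG" -> CHG; +C at "CAT" -> CHH
  expect_identical(out$context[out$pos0 == 1 & out$strand == "+"], "CG")
  expect_identical(out$context[out$pos0 == 4 & out$strand == "+"], "CHG")
  expect_identical(out$context[out$pos0 == 8 & out$strand == "+"], "CHH")
  # -strand G at pos 2 preceded by C -> CG on the minus strand
  expect_identical(out$context[out$pos0 == 2 & out$strand == "-"], "CG")
  # non-cytosine positions are rejected and counted
  expect_identical(attr(out, "n_rejected"), 1L)
  expect_false(0L %in% out$pos0)
})

test_that("coverage filtering applies the min-3 and quantile rules", {
  rec <- data.frame(chrom = "chr1", pos0 = 1:10, strand = "+",
                    n_valid = c(2L, rep(10L, 9)), frac_mod = 0.5)
  out <- filter_coverage(rec)
  expect_identical(nrow(out), 9L)            # n_valid = 2 dropped
  expect_true(all(out$n_valid == 10L))       # degenerate quantiles drop none
  # coverages 3..102 uniform: the empirical 5%/95% quantiles trim the tails
  rec2 <- data.frame(chrom = "chr1", pos0 = 1:100, strand = "+",
                     n_valid = 3:102, frac_mod = 0.5)
  out2 <- filter_coverage(rec2)
  qs <- quantile(3:102, c(0.05, 0.95), names = FALSE)
  expect_identical(out2$n_valid, (3:102)[3:102 >= qs[1] & 3:102 <= qs[2]])
  expect_identical(nrow(filter_coverage(rec2[0, ])), 0L)
})

test_that("binning is positionally exact, order-invariant and strand-aware", {
  el <- list(element_id = "e1", chrom = "chr1", start0 = 10000L,
             end0 = 15000L, strand = "+")
  rec <- data.frame(chrom = "chr1",
                    pos0 = c(10130L, 9999L, 15000L, 8000L, 16999L),
                    strand = "+", context = "CHH", n_valid = 10L,
                    frac_mod = 0.8)
  p <- bin_element(rec, el)
  expect_length(p$values, 180L)
  # 5000 bp element: offset 130 -> body bin index 2 (0-based), vector slot 43
  expect_identical(p$counts[40 + 3], 1L)
  # flank boundary positions land in the adjacent flank bins
  expect_identical(p$counts[40], 1L)          # pos 9999: last left-flank bin
  expect_identical(p$counts[141], 1L)         # pos 15000: first right bin
  expect_identical(p$counts[1], 1L)           # pos 8000: first left bin
  expect_identical(p$counts[180], 1L)         # pos 16999: last right bin
  expect_true(all(p$values[!is.na(p$values)] == 0.8))
  expect_true(all(is.na(p$values[p$counts == 0])))  # empty bins NA, never 0
  # order invariance
  p2 <- bin_element(rec[sample(nrow(rec)), ], el)
  expect_identical(p2$values, p$values)
  # minus-strand elements are flipped end-for-end
  el_m <- modifyList(el, list(strand = "-"))
  pm <- bin_element(rec, el_m)
  expect_identical(pm$values, rev(p$values))
})

test_that("metaplot mean, SD and smoothing match closed forms and oracles", {
  el <- list(element_id = "e", chrom = "chr1", start0 = 0L, end0 = 1000L,
             strand = "+")
  mk_prof <- function(v) {
    rec <- data.frame(chrom = "chr1", pos0 = 0:999, strand = "+",
                      context = "CG", n_valid = 10L, frac_mod = v)
    bin_element(rec, el, flank_bp = 2000L)
  }
  mp <- metaplot(list(mk_prof(0.2), mk_prof(0.4)))
  body <- 41:140
  expect_true(all(abs(mp$mean[body] - 0.3) < 1e-12))
  expect_true(all(abs(mp$sd[body] - sd(c(0.2, 0.4))) < 1e-12))
  # identical profiles: SD exactly 0; single profile: SD 0 by convention
  mp2 <- metaplot(list(mk_prof(0.5), mk_prof(0.5)))
  expect_true(all(mp2$sd[body] == 0))
  mp1 <- metaplot(list(mk_prof(0.5)))
  expect_true(all(mp1$sd[body] == 0))
  # smoothing equals the brute-force truncated rolling mean on a step track
  x <- c(rep(0, 89), rep(1, 91))
  expect_equal(rolling_mean(x, 10), oracle_rolling_mean(x, 10),
               tolerance = 1e-12)
  geom_bad <- mk_prof(0.5); geom_bad$n_flank <- 10L
  expect_error(metaplot(list(mk_prof(0.5), geom_bad)), "geometry")
})

test_that("control subtraction is exact bin-wise arithmetic", {
  lo <- build_liftover(data.frame(chrom = character(), ref_pos0 = integer(),
                                  ins_len = integer()))
  el <- list(element_id = "e", chrom = "chr1", start0 = 10000L, end0 = 14000L,
             strand = "+")
  mk_rec <- function(v_flank) {
    pos <- c(8000:9999, 14000:15999)
    data.frame(chrom = "chr1", pos0 = pos, strand = "+", context = "CHH",
               n_valid = 10L, frac_mod = v_flank)
  }
  samp <- mk_rec(0.3)
  p <- bin_element(samp, el)
  d_same <- subtract_control(p, samp, lo)
  expect_true(all(abs(c(d_same$left, d_same$right)) < 1e-12))
  d <- subtract_control(p, mk_rec(0.1), lo)
  expect_true(all(abs(c(d$left, d$right) - 0.2) < 1e-12))
})

test_that("spread distance counts contiguous above-threshold bins", {
  expect_identical(spread_distance(rep(0.01, 40)), 0L)
  expect_identical(spread_distance(c(rep(0.2, 10), rep(0, 30))), 500L)
  expect_identical(spread_distance(c(0.2, NA, 0.2, rep(0, 37))), 50L)
  expect_identical(spread_distance(rep(0.2, 40)), 2000L)
})

test_that("edge/body ratio contrasts boundaries against the centre", {
  el <- list(element_id = "e", chrom = "chr1", start0 = 0L, end0 = 4000L,
             strand = "+")
  mk <- function(edge, centre) {
    v <- ifelse(0:3999 < 300 | 0:3999 >= 3700, edge, centre)
    rec <- data.frame(chrom = "chr1", pos0 = 0:3999, strand = "+",
                      context = "CHH", n_valid = 10L, frac_mod = v)
    bin_element(rec, el)
  }
  expect_equal(edge_body_ratio(mk(0.5, 0.5)), 1, tolerance = 1e-12)
  expect_equal(edge_body_ratio(mk(0.6, 0.1)), 6, tolerance = 1e-12)
  expect_identical(edge_body_ratio(mk(0.6, 0)), Inf)
  expect_identical(edge_body_ratio(mk(0, 0)), 1)
})

test_that("SD vs insertion count correlation matches the direct formula", {
  sd_v <- c(d1 = 0.01, d2 = 0.05, d3 = 0.03, d4 = 0.08)
  cnt <- c(d1 = 1, d2 = 10, d3 = 5, d4 = 16)
  r <- sd_vs_insertion_count(sd_v, cnt)
  brute <- sum((sd_v - mean(sd_v)) * (cnt - mean(cnt))) /
    sqrt(sum((sd_v - mean(sd_v))^2) * sum((cnt - mean(cnt))^2))
  expect_equal(r$r, brute, tolerance = 1e-12)
  # perfectly linear pairs
  lin <- sd_vs_insertion_count(c(a = 1, b = 2, c = 3), c(a = 2, b = 4, c = 6))
  expect_equal(lin$r, 1, tolerance = 1e-12)
  expect_warning(z <- sd_vs_insertion_count(c(a = 1, b = 1, c = 1),
                                            c(a = 0, b = 0, c = 0)),
                 "variance")
  expect_true(is.na(z$r))
  expect_error(sd_vs_insertion_count(c(a = 1, b = 2), c(a = 1, b = 2)),
               "3 donors")
})

test_that("bedMethyl records round-trip through the file format", {
  rec <- data.frame(chrom = "chr1", pos0 = c(10L, 20L), strand = c("+", "-"),
                    n_valid = c(12L, 7L), frac_mod = c(0.25, 0.8))
  f <- tempfile(fileext = ".bed")
  write_bedmethyl(rec, f)
  back <- read_bedmethyl(f)
  expect_identical(back$pos0, rec$pos0)
  expect_identical(back$n_valid, rec$n_valid)
  expect_equal(back$frac_mod, rec$frac_mod, tolerance = 1e-4)
})
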