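test_that("site intersection respects half-open boundaries exactly", {
  feats <- data.frame(chrom = "chr1", start0 = 100L, end0 = 200L,
                      name = "gene")
  hit <- intersect_sites(data.frame(chrom = "chr1", pos0 = 100L), feats)
  expect_identical(hit$n_hit, 1L)
  miss <- intersect_sites(data.frame(chrom = "chr1", pos0 = 200L), feats)
  expect_identical(miss$n_hit, 0L)
  edge <- intersect_sites(data.frame(chrom = "chr1", pos0 = 199L), feats)
  expect_identical(edge$n_hit, 1L)
  # hit fraction over random sites approximates the covered fraction
  set.seed(71)
  feats2 <- data.frame(chrom = "chr1", start0 = seq(0L, 90000L, by = 10000L),
                       end0 = seq(3000L, 93000L, by = 10000L), name = "s")
  sites <- data.frame(chrom = "chr1", pos0 = floor(runif(1000, 0, 100000)))
  frac <- intersect_sites(sites, feats2)$n_hit / 1000
  expect_lt(abs(frac - 0.3), 0.05)
})

test_that("binomial enrichment matches brute-force summation to 1e-12", {
  expect_equal(binomial_enrichment(2, 2, 0.5)$p_value, 0.25)
  expect_equal(binomial_enrichment(0, 50, 0.2)$p_value, 1.0)
  brute_tail <- function(k, n, p)
    sum(exp(lchoose(n, k:n) + (k:n) * log(p) + (n - k:n) * log1p(-p)))
  for (n in c(20, 56, 100)) for (k in unique(c(1, 5, n %/% 3, n))) {
    for (p0 in c(0.01, 0.03, 0.3)) {
      mine <- binomial_enrichment(k, n, p0)$p_value
      expect_equal(mine, brute_tail(k, n, p0), tolerance = 1e-12)
    }
  }
  # p0 computed from interval coverage
  feats <- data.frame(chrom = "chr1", start0 = c(0L, 100L), end0 = c(150L, 300L))
  e <- binomial_enrichment(3, 10, feats, genome_size = 1000)
  expect_equal(e$p0, 0.3)     # overlapping intervals reduced to 300 bp
  expect_error(binomial_enrichment(1, 2, 0), "fraction")
})

test_that("random sites are reproducible, bounded and counted per chromosome", {
  lens <- c(chr1 = 1000L, chr2 = 2000L, chr3 = 500L, chr4 = 800L, chr5 = 900L)
  s1 <- random_sites(lens, per_chrom = 100L, seed = 9L)
  s2 <- random_sites(lens, per_chrom = 100L, seed = 9L)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 500L)
  for (chrom in names(lens)) {
    p <- s1$pos0[s1$chrom == chrom]
    expect_length(p, 100)
    expect_true(all(p >= 0 & p < lens[[chrom]]))
  }
})

test_that("KS statistic and p-value behave on canonical cases", {
  same <- ks_two_sample(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  disj <- ks_two_sample(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(disj$D, 1)
  expect_error(ks_two_sample(1, c(1, 2)), "at least 2")
  # agreement with the reference implementation on continuous data
  set.seed(81)
  a <- runif(60); b <- rbeta(50, 2, 1)
  mine <- ks_two_sample(a, b)
  base <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(mine$D, unname(base$statistic), tolerance = 1e-12)
  # position wrapper normalizes by chromosome length before pooling
  lens <- c(chr1 = 1000L, chr2 = 10000L)
  sa <- data.frame(chrom = c("chr1", "chr1", "chr2"), pos0 = c(100L, 900L, 5000L))
  sb <- data.frame(chrom = c("chr2", "chr2", "chr1"), pos0 = c(1000L, 9000L, 500L))
  expect_silent(ks_positions(sa, sb, lens))
})

test_that("KS type-I error is calibrated at alpha = 0.05", {
  set.seed(91)
  rej <- mean(replicate(1000,
                        ks_two_sample(runif(50), runif(50))$p_value < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Fisher overlap matches hypergeometric enumeration and fisher.test", {
  flat <- fisher_overlap(2, 2, 1, 4)     # [[1,1],[1,1]]
  expect_equal(flat$p_value, 1.0)
  expect_equal(flat$odds_ratio, 1.0)
  perfect <- fisher_overlap(5, 5, 5, 10) # [[5,0],[0,5]]
  expect_equal(perfect$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  set.seed(101)
  for (i in 1:25) {
    universe <- sample(20:500, 1)
    n_a <- sample(1:(universe - 1), 1)
    n_b <- sample(1:(universe - 1), 1)
    lo <- max(0, n_a + n_b - universe)
    ov <- sample(lo:min(n_a, n_b), 1)
    mine <- fisher_overlap(n_a, n_b, ov, universe)
    ft <- stats::fisher.test(matrix(c(ov, n_a - ov, n_b - ov,
                                      universe - n_a - n_b + ov), 2))
    expect_equal(mine$p_value, ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_overlap(5, 5, 6, 100), "overlap")
  expect_error(fisher_overlap(60, 60, 0, 100), "universe")
})

test_that("TEI summary table renders counts and half-up percentages", {
  # per-plant fixture with the published layout: 6 plants, genic flags and
  # zygosity per insertion
  mk <- function(plant, n, genic, hom) {
    data.frame(plant = plant, genic = c(rep(TRUE, genic), rep(FALSE, n - genic)),
               zygosity = c(rep("hom", hom), rep("het", n - hom)))
  }
  calls <- rbind(mk("p1", 5, 4, 5), mk("p2", 2, 2, 0), mk("p3", 3, 2, 1),
                 mk("p4", 32, 29, 18), mk("p5", 8, 8, 3), mk("p6", 6, 6, 2))
  s <- summarize_tei_table(calls)
  expect_identical(s$total$n, 56L)
  expect_identical(s$total$het, 27L)
  expect_identical(s$total$hom, 29L)
  expect_identical(s$min_per_plant, 2L)
  expect_identical(s$max_per_plant, 32L)
  expect_equal(s$total$genic_pct, 91.1)             # 51 / 56
  per <- setNames(s$per_plant$genic_pct, s$per_plant$plant)
  expect_equal(unname(per["p1"]), 80.0)             # 4 / 5
  expect_equal(unname(per["p4"]), 90.6)             # 29 / 32, half-up
  # totals equal the sum of per-plant rows
  expect_identical(s$total$n, sum(s$per_plant$n))
  expect_identical(s$total$hom + s$total$het, sum(s$per_plant$hom + s$per_plant$het))
  empty <- summarize_tei_table(calls[0, ])
  expect_identical(empty$total$n, 0L)
})

test_that("state fraction matrix computes percentages per set", {
  states <- data.frame(chrom = "chr1",
                       start0 = seq(0L, 900L, by = 100L),
                       end0 = seq(100L, 1000L, by = 100L),
                       name = rep(c("s1", "s2"), 5))
  sites <- data.frame(chrom = "chr1", pos0 = c(10L, 110L, 210L, 310L, 410L,
                                               510L, 610L, 710L, 810L, 910L))
  m <- state_fraction_matrix(list(all = sites, first3 = sites[1:3, ]), states)
  expect_equal(m["s1", "all"], 50)
  expect_equal(m["s2", "all"], 50)
  expect_equal(m["s1", "first3"], 100 * 2 / 3)
  expect_warning(state_fraction_matrix(list(none = sites[0, ]), states),
                 "empty")
})

test_that("round_half_up follows the conventional rendering", {
  expect_identical(round_half_up(80.05, 1), 80.1)
  expect_identical(round_half_up(100 * 4 / 5, 1), 80)
  expect_identical(round_half_up(100 * 29 / 32, 1), 90.6)
  expect_identical(round_half_up(100 * 2 / 3, 1), 66.7)
  expect_identical(round_half_up(-1.25, 1), -1.3)
})
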