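# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# compact single-chromosome simulation for unit tests (homozygous plantings
# so the support filter is deterministic)
sim_small <- function() {
  memo("sim_small", {
    cfg <- simulation_config(seed = 11, n_chromosomes = 1L,
                             n_insertions = 6L, het_fraction = 0)
    ref <- simulate_reference(cfg)
    lib <- simulate_te_library(cfg)
    smp <- plant_insertions(ref, lib, cfg)
    aln <- simulate_read_alignments(smp, ref, lib, cfg)
    list(cfg = cfg, ref = ref, lib = lib, smp = smp, aln = aln)
  })
}

# the full noise-free study-scale run shared by the acceptance blocks:
# 2 chromosomes x 200 kb, 20 homozygous plantings, depth 10
demo_noise_free <- function() {
  memo("demo_noise_free",
       run_demo(seed = 402, sim = list(het_fraction = 0), quiet = TRUE))
}

# brute-force rolling mean oracle (truncated centered window)
oracle_rolling_mean <- function(x, w) {
  n <- length(x)
  lft <- floor((w - 1) / 2); rgt <- w - 1 - lft
  sapply(seq_len(n), function(i)
    mean(x[max(1, i - lft):min(n, i + rgt)], na.rm = TRUE))
}

# brute-force ORF enumeration oracle
oracle_orfs <- function(seq, min_len = 75L) {
  n <- nchar(seq)
  codon <- function(i) substr(seq, i, i + 2)
  res <- list()
  for (st in seq_len(n - 2)) {
    if (codon(st) != "ATG") next
    i <- st; end <- NA; has_stop <- FALSE
    while (i + 2 <= n) {
      if (i > st && codon(i) %in% c("TAA", "TAG", "TGA")) {
        end <- i + 2; has_stop <- TRUE; break
      }
      i <- i + 3
    }
    if (!has_stop) end <- st + ((n - st + 1) %/% 3) * 3 - 1
    res[[length(res) + 1]] <- data.frame(
      start1 = st, end1 = end, frame = (st - 1) %% 3, has_stop = has_stop)
  }
  if (!length(res)) return(data.frame(start0 = integer(), end0 = integer(),
                                      length_nt = integer(),
                                      has_stop = logical()))
  d <- do.call(rbind, res)
  d <- d[order(d$start1), ]
  d <- d[!duplicated(d[, c("frame", "end1")]), ]
  d$length_nt <- d$end1 - d$start1 + 1L
  d <- d[d$length_nt >= min_len, ]
  d <- d[order(d$start1), ]
  data.frame(start0 = as.integer(d$start1 - 1L), end0 = as.integer(d$end1),
             length_nt = as.integer(d$length_nt), has_stop = d$has_stop,
             row.names = NULL)
}
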