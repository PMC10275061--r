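test_that("probe Fisher test matches the enumeration oracle on 2x2 tables", {
  # build a manifest/feature fixture realizing table (a, b, c, d)
  table_fixture <- function(a, b, c, d) {
    N <- a + b + c + d
    m <- probe_manifest(sprintf("cg%03d", 1:N), "chr1",
                        seq(1000L, by = 1000L, length.out = N))
    # probes 1..(a+c) carry the feature; probes 1..a and (a+c+1)..(a+c+b)
    # are the CMU probes
    feat <- if (a + c > 0)
      feature_annotation("F", "chr1", 999, 999 + (a + c) * 1000)
    else feature_annotation("F", "chr1", 5e6, 5e6 + 10)
    cmu <- m$probe_id[c(seq_len(a), if (b > 0) (a + c + 1):(a + c + b))]
    probe_feature_test(cmu, m$probe_id, feat, m)
  }
  res <- table_fixture(5, 5, 5, 5)
  expect_equal(res$p_value, 1)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(unname(as.vector(res$table)), c(5, 5, 5, 5))
  res2 <- table_fixture(8, 2, 2, 8)
  expect_equal(res2$p_value, fisher_two_sided_oracle(8, 2, 2, 8))
  set.seed(40)
  for (i in 1:25) {
    tab <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    if (any(rowSums(matrix(tab, 2)) == 0) ||
        any(colSums(matrix(tab, 2)) == 0)) next
    r <- table_fixture(tab[1], tab[2], tab[3], tab[4])
    expect_equal(r$p_value,
                 fisher_two_sided_oracle(tab[1], tab[2], tab[3], tab[4]))
  }
  # feature covering no probes -> degenerate margin flag
  r0 <- table_fixture(0, 10, 0, 10)
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)
})

test_that("hypergeometric upper tail equals the pmf-sum oracle", {
  expect_equal(hypergeometric_test(5, 20, 10, 100),
               sum(stats::dhyper(5:10, 10, 90, 20)))  # brute-force tail
  expect_equal(hypergeometric_test(10, 10, 10, 10), 1) # k = n = K = N
  expect_equal(hypergeometric_test(0, 20, 10, 100), 1) # whole support
  expect_error(hypergeometric_test(15, 10, 20, 100), "impossible")
  expect_error(hypergeometric_test(5, 20, 10, 15), "impossible")
})

test_that("background CMUs are size-matched, seeded and window-uniform", {
  set.seed(41)
  m <- uniform_manifest(600, 2e6)
  obs <- data.frame(chrom = "chr1", start = c(10000, 300000),
                    end = c(11000, 302500))
  bg1 <- sample_background_cmus(obs, m, rng_seed = 7)
  bg2 <- sample_background_cmus(obs, m, rng_seed = 7)
  expect_identical(bg1, bg2)                       # determinism
  expect_equal(bg1$end - bg1$start, obs$end - obs$start)  # size match
  # regions stay inside their 250 kb window
  expect_true(all(floor(bg1$start / 250000) ==
                    floor((bg1$end - 1) / 250000)))
  # window selection is uniform: 10,000 draws of a 1 kb region over the
  # 8 windows -> per-window frequency within 3 sd of the multinomial mean
  one <- data.frame(chrom = "chr1", start = 0, end = 1000)
  many <- sample_background_cmus(one[rep(1, 10000), ], m, rng_seed = 8)
  counts <- table(floor(many$start / 250000))
  n_win <- nrow(cmuscan:::eligible_windows(m, "lenient", 250000L))
  expect_equal(length(counts), n_win)
  p <- 1 / n_win
  sd3 <- 3 * sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) <= sd3))
})

test_that("stringent mode drops windows with fewer than 10 probes", {
  m <- probe_manifest(sprintf("cg%02d", 1:16), "chr1",
                      c(seq(1000, by = 1000, length.out = 12),
                        seq(250001, by = 1000, length.out = 4)))
  wl <- cmuscan:::eligible_windows(m, "lenient", 250000L)
  ws <- cmuscan:::eligible_windows(m, "stringent", 250000L)
  expect_equal(nrow(wl), 2)
  expect_equal(nrow(ws), 1)
})

test_that("region enrichment flags constructed feature clusters", {
  spec <- synthetic_spec(
    n_samples = 40L, chrom_lengths = c(chr1 = 2e6), mean_gap = 1000,
    blocks = data.frame(id = sprintf("b%d", 1:6), size = 8L,
                        within_r = 0.8), seed = 42)
  sim <- generate_block_beta(spec)
  clust <- plant_features(sim$manifest, "clustered", n_intervals = 40,
                          width = 800, truth = sim$truth, rng_seed = 2)
  r <- region_enrichment(sim$truth, clust, sim$manifest, n_reps = 500,
                         rng_seed = 3)
  expect_lt(r$p_value, 0.001)
  expect_gt(r$observed, r$background_mean)
  expect_error(region_enrichment(sim$truth, clust, sim$manifest,
                                 n_reps = 1), "at least 2")
  # empty feature -> degenerate background, flagged
  none <- feature_annotation("none", "chr1", 5e6, 5e6 + 100)
  r0 <- region_enrichment(sim$truth, none, sim$manifest, n_reps = 100,
                          rng_seed = 4)
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1)
})

test_that("overlap statistics count probes, CMUs and unique hits", {
  m <- probe_manifest(sprintf("cg%02d", 1:10), "chr1",
                      seq(1000L, by = 1000L, length.out = 10L))
  feat <- feature_annotation("loop", "chr1", c(500, 3500, 8500),
                             c(1500, 4500, 9500))
  # probes at 1000, 4000, 9000 fall inside features -> hmm: 1000, 4000, 9000
  cmus <- data.frame(id = c("u1", "u2", "u3"), chrom = "chr1",
                     start = c(400, 3400, 6000), end = c(4600, 4700, 7000),
                     stringsAsFactors = FALSE)
  st <- chromatin_overlap_stats(cmus, feat, m)
  expect_equal(st$pct_cpg_overlap, 0.3)            # 3 of 10 probes
  expect_equal(st$pct_cmu_overlap, 2 / 3)          # u1, u2 hit; u3 not
  expect_equal(st$pct_unique_overlap, 0.5)         # u1 spans two loops
  expect_equal(unname(st$n_features_hit), c(2L, 1L, 0L))
  # no hits -> flagged undefined unique overlap
  far <- feature_annotation("far", "chr1", 5e5, 5e5 + 10)
  st0 <- chromatin_overlap_stats(cmus, far, m)
  expect_true(st0$degenerate)
  expect_true(is.na(st0$pct_unique_overlap))
})

test_that("compartment pair score is the log overlap ratio", {
  st <- structure(list(pct_cpg_overlap = 0.4, pct_cmu_overlap = 0.4,
                       pct_unique_overlap = 1), class = "overlap_stats")
  expect_equal(as.numeric(compartment_pair_score(st, "A")), 0)
  st$pct_cmu_overlap <- 0.8
  expect_equal(as.numeric(compartment_pair_score(st, "B")), log(2))
  st$pct_cmu_overlap <- 0
  expect_error(compartment_pair_score(st), "undefined")
})

test_that("TAD containment counts spans that cross no boundary", {
  tads <- feature_annotation("TAD", "chr1", c(0, 10000), c(10000, 30000))
  spans <- data.frame(chrom = "chr1", start = c(1000, 9000, 12000),
                      end = c(5000, 11000, 20000))
  # span 2 crosses the boundary at 10000; spans 1 and 3 are contained
  expect_equal(tad_containment_fraction(spans, tads), 2 / 3)
})
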