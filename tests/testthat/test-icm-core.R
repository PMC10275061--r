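test_that("smoothing preserves constants, symmetry and attenuates spikes", {
  K <- icm_kernel()
  C <- matrix(0.5, 9, 9); diag(C) <- 1
  # constant off-diagonal region stays constant away from the diagonal band
  S <- smooth_image(matrix(0.5, 9, 9), K)
  expect_equal(S[1, 5], 0.5)
  # single symmetric off-diagonal spike attenuates to spike x center weight
  M <- matrix(0, 11, 11); diag(M) <- 1
  M[3, 9] <- M[9, 3] <- 0.9
  out <- smooth_image(M, K)
  expect_equal(out[3, 9], 0.9 * K[2, 2])       # direct convolution oracle
  # symmetric input -> symmetric output to machine precision
  set.seed(20)
  A <- matrix(rnorm(100), 10); A <- (A + t(A)) / 2; diag(A) <- 1
  out2 <- smooth_image(A, K)
  expect_identical(out2, t(out2))
  expect_equal(diag(out2), rep(1, 10))
  expect_true(all(abs(out2) <= 1))
})

test_that("oversized kernels shrink to the image with a warning", {
  M <- diag(2)
  expect_warning(out <- smooth_image(M, icm_kernel()), "shrinking")
  expect_equal(dim(out), c(2L, 2L))
})

test_that("cutoff zeroes sub-threshold entries, keeps sign, is idempotent", {
  x <- matrix(c(1, 0.7, 0.5, -0.65), 2, 2)
  out <- apply_cutoff(x, 0.6)
  expect_equal(as.vector(out), c(1, 0.7, 0, -0.65))
  expect_equal(apply_cutoff(out, 0.6), out)        # idempotent
  expect_equal(apply_cutoff(x, 0), x)              # degenerate cutoff
})

test_that("edge detection separates exact blocks and degenerate images", {
  # blocks at rows 1..5 and 6..10 -> single boundary at cut 5
  T <- planted_image(10, list(1:5, 6:10), c(0.8, 0.8))
  expect_equal(detect_edges(T), 5L)
  # all-ones support -> no interior boundary
  expect_equal(detect_edges(matrix(1, 6, 6)), integer(0))
  # all-zero support -> empty boundary set
  expect_equal(detect_edges(matrix(0, 6, 6)), integer(0))
})

test_that("contiguous CMU calling enforces size, density and strength", {
  m <- probe_manifest(sprintf("cg%02d", 1:20), "chr1",
                      seq(1000L, by = 1000L, length.out = 20L))
  win <- list(first = 1L, last = 20L, chrom = "chr1", start = 0, end = 250000)
  # planted 6-probe block at r = 0.9 -> exactly one CMU with those probes
  T1 <- planted_image(20, list(4:9), 0.9)
  ct1 <- call_contiguous_cmus(T1, win, m, icm_params())
  expect_equal(nrow(ct1), 1)
  expect_equal(ct1$probes[[1]], sprintf("cg%02d", 4:9))
  expect_equal(ct1$start, m$pos[4] - 1)
  expect_equal(ct1$end, m$pos[9])
  # 3-probe block fails min_cpgs = 4
  T2 <- planted_image(20, list(4:6), 0.9)
  expect_equal(nrow(call_contiguous_cmus(T2, win, m, icm_params())), 0)
  # two 5-probe blocks separated by 3 null probes -> 2 CMUs, right bounds
  T3 <- planted_image(20, list(2:6, 10:14), c(0.85, 0.7))
  ct3 <- call_contiguous_cmus(T3, win, m, icm_params())
  expect_equal(nrow(ct3), 2)
  expect_equal(ct3$run_first, c(2L, 10L))
  expect_equal(ct3$run_last, c(6L, 14L))
  # a block below the density floor is rejected
  T4 <- planted_image(20, list(4:11), 0.9)
  T4[4, 7:11] <- T4[7:11, 4] <- 0                # knock out 5 of 56 entries
  T4[5, 9:11] <- T4[9:11, 5] <- 0                # 8 more -> density < 0.9
  ct4 <- call_contiguous_cmus(T4, win, m,
                              icm_params(block_density = 0.9))
  expect_equal(nrow(ct4), 0)
})

test_that("equivalence with the exhaustive block oracle on exact images", {
  set.seed(21)
  m <- probe_manifest(sprintf("cg%03d", 1:40), "chr1",
                      seq(1000L, by = 1000L, length.out = 40L))
  for (i in 1:50) {
    img <- random_block_image(40L)
    win <- list(first = 1L, last = img$p, chrom = "chr1", start = 0,
                end = 250000)
    ct <- call_contiguous_cmus(img$T, win, m, icm_params())
    oracle <- oracle_block_finder(img$T)
    expect_equal(nrow(ct), length(oracle))
    if (length(oracle))
      expect_equal(unname(cbind(ct$run_first, ct$run_last)),
                   do.call(rbind, oracle) |> unname())
  }
})

test_that("linking joins separated, strongly inter-correlated blocks", {
  m <- probe_manifest(sprintf("cg%02d", 1:20), "chr1",
                      seq(1000L, by = 1000L, length.out = 20L))
  win <- list(first = 1L, last = 20L, chrom = "chr1", start = 0, end = 250000)
  base <- planted_image(20, list(2:6, 10:14), c(0.9, 0.9))
  # inter-block rectangle at +0.8 -> one unit of 2 members, sign +1
  T <- base; T[2:6, 10:14] <- 0.8; T[10:14, 2:6] <- 0.8
  ct <- call_contiguous_cmus(T, win, m, icm_params())
  nc <- link_noncontiguous(ct, T, icm_params())
  expect_equal(nrow(nc), 1)
  expect_equal(nc$n_members, 2L)
  expect_equal(unname(nc$pairwise_sign[[1]][1, 2]), 1)
  expect_equal(nc$start, ct$start[1]); expect_equal(nc$end, ct$end[2])
  # zero inter-block correlation -> no linkage
  nc0 <- link_noncontiguous(ct, base, icm_params())
  expect_equal(nrow(nc0), 0)
  # adjacent runs without an interspersed probe are never linked
  Tadj <- planted_image(20, list(2:6, 7:11), c(0.9, 0.9))
  Tadj[2:6, 7:11] <- 0.7; Tadj[7:11, 2:6] <- 0.7
  ct_adj <- data.frame(id = c("a", "b"), chrom = "chr1",
                       start = c(1000, 6000), end = c(6000, 11000),
                       n_probes = 5L, mean_abs_r = 0.9,
                       run_first = c(2L, 7L), run_last = c(6L, 11L),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(link_noncontiguous(ct_adj, Tadj, icm_params())), 0)
})

test_that("a middle anti-correlated block yields signs (-,-,+)", {
  m <- probe_manifest(sprintf("cg%02d", 1:26), "chr1",
                      seq(1000L, by = 1000L, length.out = 26L))
  win <- list(first = 1L, last = 26L, chrom = "chr1", start = 0, end = 250000)
  T <- planted_image(26, list(2:6, 10:14, 18:22), c(0.9, 0.9, 0.9))
  T[2:6, 10:14] <- T[10:14, 2:6] <- -0.8
  T[10:14, 18:22] <- T[18:22, 10:14] <- -0.8
  T[2:6, 18:22] <- T[18:22, 2:6] <- 0.8
  ct <- call_contiguous_cmus(T, win, m, icm_params())
  nc <- link_noncontiguous(ct, T, icm_params())
  expect_equal(nrow(nc), 1)
  expect_equal(nc$n_members, 3L)
  sg <- nc$pairwise_sign[[1]]
  expect_equal(unname(c(sg[1, 2], sg[2, 3], sg[1, 3])), c(-1, -1, 1))
})

test_that("scan recovers planted blocks and stays silent on pure noise", {
  fx <- basic_fixture()
  truth <- fx$sim$truth; cmus <- fx$cmus
  best <- vapply(seq_len(nrow(truth)), function(i)
    max(0, vapply(cmus$contiguous$probes, jaccard,
                  0, b = truth$probes[[i]])), 0)
  expect_gte(sum(best >= 0.8), 19)             # >= 95% of 20 blocks
  # non-contiguous members always appear in the contiguous list
  expect_true(all(unlist(cmus$noncontiguous$members) %in%
                    cmus$contiguous$id))
  # all-noise matrix -> no CMUs
  set.seed(22)
  m <- probe_manifest(sprintf("cg%03d", 1:120), "chr1",
                      sort(sample.int(240000L, 120L)))
  noise <- matrix(runif(200 * 120), 200, 120,
                  dimnames = list(NULL, m$probe_id))
  s0 <- scan_dataset(noise, m, icm_params(), label = "null")
  expect_equal(nrow(s0$contiguous), 0)
})

test_that("higher cutoffs give nested sub-CMUs", {
  fx <- basic_fixture()
  sim <- fx$sim
  sets <- lapply(c(0.4, 0.6, 0.8), function(a)
    scan_dataset(sim$beta, sim$manifest, icm_params(alpha = a),
                 label = paste0("a", a)))
  for (k in 1:2) {
    hi <- sets[[k + 1]]$contiguous; lo <- sets[[k]]$contiguous
    if (nrow(hi) == 0) next
    contained <- vapply(hi$probes, function(pr)
      any(vapply(lo$probes, function(lp) all(pr %in% lp), TRUE)), TRUE)
    expect_true(all(contained))
  }
  # sanity: the lower cutoff does call CMUs
  expect_gt(nrow(sets[[1]]$contiguous), 0)
})
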