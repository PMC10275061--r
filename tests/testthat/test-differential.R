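toy_groups <- function(n1 = 60, n2 = 60, p = 5, r1 = 0.7, r2 = 0.3,
                       seed = 50) {
  set.seed(seed)
  draw <- function(n, r) {
    C <- matrix(r, p, p); diag(C) <- 1
    x <- matrix(rnorm(n * p), n, p) %*% chol(C)
    colnames(x) <- paste0("cg", seq_len(p))
    x
  }
  list(g1 = draw(n1, r1), g2 = draw(n2, r2))
}

test_that("paired matrices reproduce direct pairwise correlation", {
  tg <- toy_groups()
  pm <- paired_correlation_matrices(tg$g1, tg$g2, paste0("cg", 1:5))
  # direct-formula oracle on the 5-probe toy
  direct <- function(x) {
    p <- ncol(x); M <- diag(p)
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
      M[i, j] <- M[j, i] <- sum(xi * xj) /
        sqrt(sum(xi^2) * sum(xj^2))
    }
    M
  }
  expect_equal(unname(pm$R1), direct(tg$g1), tolerance = 1e-12)
  expect_equal(diag(pm$R1), rep(1, 5), ignore_attr = TRUE)
  expect_equal(diag(pm$R2), rep(1, 5), ignore_attr = TRUE)
  # identical groups give identical matrices
  pm_same <- paired_correlation_matrices(tg$g1, tg$g1, paste0("cg", 1:5))
  expect_identical(pm_same$R1, pm_same$R2)
  expect_error(paired_correlation_matrices(tg$g1, tg$g2, c("cg1", "zz")),
               "zz")
})

test_that("Steiger chi-square is exact under equality and matches Fisher z", {
  tg <- toy_groups()
  pm_same <- paired_correlation_matrices(tg$g1, tg$g1, paste0("cg", 1:5))
  st <- steiger_matrix_test(pm_same)
  expect_equal(st$chi2, 0)
  expect_equal(st$p_value, 1)
  expect_equal(st$df, 10L)                        # p(p-1)/2
  # p = 2: equals the closed-form two-sample Fisher-z test squared
  pm2 <- paired_correlation_matrices(tg$g1[, 1:2], tg$g2[, 1:2],
                                     c("cg1", "cg2"))
  st2 <- steiger_matrix_test(pm2)
  z <- (atanh(pm2$R1[1, 2]) - atanh(pm2$R2[1, 2])) /
    sqrt(1 / (pm2$n1 - 3) + 1 / (pm2$n2 - 3))
  expect_equal(st2$chi2, z^2, tolerance = 1e-10)
  expect_equal(st2$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_equal(st2$df, 1L)
  expect_error(steiger_matrix_test(pm2, n1 = 3, n2 = 50), "n > 3")
})

test_that("Steiger statistic is invariant to relabeling and group swap", {
  tg <- toy_groups()
  pm <- paired_correlation_matrices(tg$g1, tg$g2, paste0("cg", 1:5))
  st <- steiger_matrix_test(pm)
  perm <- c(3, 1, 5, 2, 4)
  pm_perm <- list(R1 = pm$R1[perm, perm], R2 = pm$R2[perm, perm],
                  n1 = pm$n1, n2 = pm$n2)
  expect_equal(steiger_matrix_test(pm_perm)$chi2, st$chi2)
  pm_swap <- list(R1 = pm$R2, R2 = pm$R1, n1 = pm$n2, n2 = pm$n1)
  expect_equal(steiger_matrix_test(pm_swap)$chi2, st$chi2)
})

test_that("perfect correlations are clipped before the z transform", {
  R1 <- matrix(1, 4, 4)
  R2 <- diag(4)
  st <- steiger_matrix_test(list(R1 = R1, R2 = R2, n1 = 50, n2 = 50))
  expect_true(is.finite(st$chi2))
  expect_equal(st$clipped, 6)
})

test_that("shifted Wilcoxon detects strong attenuation with the right sign", {
  # defining group off-diagonals all ~0.9, other ~0.5
  p <- 6
  R1 <- matrix(0.9, p, p); diag(R1) <- 1
  R2 <- matrix(0.5, p, p); diag(R2) <- 1
  set.seed(51)
  R1[lower.tri(R1)] <- R1[lower.tri(R1)] + runif(15, -0.01, 0.01)
  R2[lower.tri(R2)] <- R2[lower.tri(R2)] + runif(15, -0.01, 0.01)
  R1[upper.tri(R1)] <- t(R1)[upper.tri(R1)]
  R2[upper.tri(R2)] <- t(R2)[upper.tri(R2)]
  wx <- wilcoxon_shift_test(list(R1 = R1, R2 = R2), mu = 0.1)
  expect_lt(wx$p_value, 0.01)
  expect_equal(wx$effect_size, -0.4, tolerance = 0.05)  # other - defining
  # identical matrices: shift of 0.1 clearly not supported
  wx0 <- wilcoxon_shift_test(list(R1 = R1, R2 = R1), mu = 0.1)
  expect_gt(wx0$p_value, 0.5)
  # mu = 0 reduces to the standard one-sided rank-sum test
  wx_mu0 <- wilcoxon_shift_test(list(R1 = R1, R2 = R2), mu = 0)
  ref <- stats::wilcox.test(lower_offdiag_ref(R1), lower_offdiag_ref(R2),
                            alternative = "greater", exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(wx_mu0$p_value, ref)
  # all-tied input is flagged with p = 1
  Rt <- matrix(0.5, p, p); diag(Rt) <- 0.5
  wt <- wilcoxon_shift_test(list(R1 = Rt, R2 = Rt))
  expect_true(wt$tied); expect_equal(wt$p_value, 1)
})

test_that("collapsing removes CMUs absorbed into non-contiguous units", {
  ct <- data.frame(id = c("A", "B", "C"), chrom = "chr1",
                   start = c(0, 1000, 2000), end = c(500, 1500, 2500),
                   n_probes = c(5L, 6L, 7L),
                   probes = I(list(paste0("a", 1:5), paste0("b", 1:6),
                                   paste0("c", 1:7))),
                   stringsAsFactors = FALSE)
  nc <- data.frame(id = "N1", chrom = "chr1", start = 0, end = 1500,
                   n_members = 2L, members = I(list(c("A", "B"))),
                   stringsAsFactors = FALSE)
  out <- collapse_cmu_lists(ct, nc)
  expect_equal(out$id, c("N1", "C"))
  expect_equal(out$n_probes, c(11L, 7L))          # member probes unioned
  expect_length(out$probes[[1]], 11)
  # no non-contiguous units -> contiguous list unchanged
  out2 <- collapse_cmu_lists(ct, cmuscan:::empty_noncontiguous())
  expect_equal(out2$id, c("A", "B", "C"))
  # all contiguous absorbed -> only the non-contiguous list remains
  nc_all <- data.frame(id = "N2", chrom = "chr1", start = 0, end = 2500,
                       n_members = 3L, members = I(list(c("A", "B", "C"))),
                       stringsAsFactors = FALSE)
  expect_equal(collapse_cmu_lists(ct, nc_all)$id, "N2")
})

test_that("raising mu never increases the number of significant units", {
  spec <- synthetic_preset("casecontrol", seed = 52)
  sim <- generate_case_control(spec)
  g1 <- inverse_normal_transform(sim$cases)
  g2 <- inverse_normal_transform(sim$controls)
  res_lo <- differential_cmus(g1, g2, sim$manifest, mu = 0.1,
                              group_labels = c("cases", "controls"))
  res_hi <- differential_cmus(g1, g2, sim$manifest, mu = 0.5,
                              group_labels = c("cases", "controls"))
  expect_lte(sum(res_hi$significant), sum(res_lo$significant))
  # significance requires both corrected tests below the level
  expect_equal(res_lo$significant,
               res_lo$p_steiger_bonf < 0.05 & res_lo$p_wilcox_bonf < 0.05)
  # the attenuated blocks are found by the control-defined scan with a
  # negative effect (cases less correlated than the defining controls)
  hit <- res_lo[res_lo$significant & res_lo$defining_group == "controls", ]
  expect_gte(nrow(hit), 1)
  expect_true(all(hit$effect_size < 0))
})
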