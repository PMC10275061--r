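#' Paired correlation matrices for one CMU across two groups
#'
#' Pearson correlation over the CMU's probes computed in the CMU-defining
#' group (R1) and, with the same probes in the same order, in the other
#' group (R2).
#'
#' @param residuals_g1,residuals_g2 samples x probes matrices (residualized
#'   and/or transformed values) for the defining and the other group.
#' @param probes character vector of the CMU's probe ids (or a one-row
#'   contiguous CMU data.frame, whose `probes` list column is used).
#' @return list of class `paired_matrices`: `R1`, `R2`, `probes`, `p`,
#'   `n1`, `n2`.
#' @export
paired_correlation_matrices <- function(residuals_g1, residuals_g2, probes) {
  if (is.data.frame(probes)) probes <- probes$probes[[1L]]
  miss1 <- setdiff(probes, colnames(residuals_g1))
  miss2 <- setdiff(probes, colnames(residuals_g2))
  if (length(miss1) || length(miss2))
    stop("probes missing from group matrices: ",
         paste(unique(c(miss1, miss2)), collapse = ", "))
  n1 <- nrow(residuals_g1); n2 <- nrow(residuals_g2)
  if (min(n1, n2) < 4L) stop("need at least 4 samples per group")
  if (min(n1, n2) < 10L)
    warning("fewer than 10 samples in a group; correlations unstable")
  corr <- function(x) {
    suppressWarnings(R <- stats::cor(x, use = "pairwise.complete.obs"))
    R[is.na(R)] <- 0
    diag(R) <- 1
    (R + t(R)) / 2
  }
  structure(list(R1 = corr(residuals_g1[, probes, drop = FALSE]),
                 R2 = corr(residuals_g2[, probes, drop = FALSE]),
                 probes = probes, p = length(probes), n1 = n1, n2 = n2),
            class = "paired_matrices")
}

#' Steiger-type chi-square comparison of two correlation matrices
#'
#' Tests the null that all off-diagonal entries of R1 - R2 are zero. Each
#' off-diagonal correlation is Fisher-transformed (z = atanh r, variance
#' ~ 1/(n - 3)); the statistic is the sum over probe pairs of
#' (z1 - z2)^2 / (1/(n1 - 3) + 1/(n2 - 3)), referred to a chi-square with
#' p(p - 1)/2 degrees of freedom.
#'
#' @param pm a `paired_matrices` (or list with `R1`/`R2`).
#' @param n1,n2 group sample sizes (defaults taken from `pm`).
#' @return list: `chi2`, `df`, `p_value`, `clipped` (number of correlations
#'   clipped at |r| = 0.9999 before atanh).
#' @export
steiger_matrix_test <- function(pm, n1 = pm$n1, n2 = pm$n2) {
  if (min(n1, n2) <= 3L) stop("Steiger test requires n > 3 in both groups")
  r1 <- lower_offdiag(pm$R1); r2 <- lower_offdiag(pm$R2)
  clipped <- sum(abs(c(r1, r2)) > 0.9999)
  r1 <- pmin(pmax(r1, -0.9999), 0.9999)
  r2 <- pmin(pmax(r2, -0.9999), 0.9999)
  z1 <- atanh(r1); z2 <- atanh(r2)
  v <- 1 / (n1 - 3) + 1 / (n2 - 3)
  chi2 <- sum((z1 - z2)^2) / v
  df <- length(z1)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       clipped = clipped)
}

#' Shifted Wilcoxon rank-sum comparison of correlation levels
#'
#' One-sided unpaired rank-sum test of the defining group's off-diagonal
#' correlations against the other group's, with the alternative that the
#' defining group's distribution is shifted to the right by at least `mu`
#' (default 0.1, a deliberately sensitive cut-off; raising `mu` proxies for
#' smaller sample sizes). The effect size is the Hodges-Lehmann location
#' shift of (other - defining): negative values mean the defining group
#' (e.g. cases) is more correlated.
#'
#' @param pm a `paired_matrices`.
#' @param mu minimum right-shift under the alternative (default 0.1).
#' @return list: `effect_size`, `p_value`, `tied` (TRUE when every value is
#'   identical; then p = 1 and effect 0).
#' @export
wilcoxon_shift_test <- function(pm, mu = 0.1) {
  d <- lower_offdiag(pm$R1); o <- lower_offdiag(pm$R2)
  if (length(d) < 6L)
    stop("need at least 6 off-diagonal entries (>= 4 probes)")
  if (length(unique(c(d, o))) == 1L)
    return(list(effect_size = 0, p_value = 1, tied = TRUE))
  p <- suppressWarnings(
    stats::wilcox.test(d, o, mu = mu, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value)
  eff <- suppressWarnings(
    unname(stats::wilcox.test(o, d, conf.int = TRUE, exact = FALSE)$estimate))
  list(effect_size = eff, p_value = p, tied = FALSE)
}

#' Collapse contiguous and non-contiguous CMUs into one unit list
#'
#' The unified list contains every non-contiguous CMU plus the contiguous
#' CMUs that are not a member of any non-contiguous CMU.
#'
#' @param contiguous contiguous CMU data.frame (with `probes` list column).
#' @param noncontiguous non-contiguous CMU data.frame (with `members`).
#' @return data.frame with `id`, `kind` ("contiguous"/"noncontiguous"),
#'   `chrom`, `start`, `end`, `n_probes` and a `probes` list column (member
#'   probes unioned for non-contiguous units).
#' @export
collapse_cmu_lists <- function(contiguous, noncontiguous) {
  absorbed <- unique(unlist(noncontiguous$members))
  keep <- !(contiguous$id %in% absorbed)
  ct <- contiguous[keep, , drop = FALSE]
  ct_rows <- if (nrow(ct)) data.frame(
    id = ct$id, kind = "contiguous", chrom = ct$chrom, start = ct$start,
    end = ct$end, n_probes = ct$n_probes, probes = I(ct$probes),
    stringsAsFactors = FALSE) else NULL
  nc_rows <- if (nrow(noncontiguous)) data.frame(
    id = noncontiguous$id, kind = "noncontiguous",
    chrom = noncontiguous$chrom, start = noncontiguous$start,
    end = noncontiguous$end,
    n_probes = vapply(noncontiguous$members, function(m) {
      sum(contiguous$n_probes[match(m, contiguous$id)])
    }, 0L),
    probes = I(lapply(noncontiguous$members, function(m) {
      unlist(contiguous$probes[match(m, contiguous$id)], use.names = FALSE)
    })),
    stringsAsFactors = FALSE) else NULL
  out <- rbind(nc_rows, ct_rows)
  if (is.null(out))
    out <- data.frame(id = character(0), kind = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0),
                      probes = I(list()), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Case-control differential-correlation scan
#'
#' Runs ICM in each group separately (each group defines its own CMUs,
#' contiguous and non-contiguous collapsed into one unit list); for every
#' unit, builds paired correlation matrices, applies the Steiger matrix test
#' and the shifted Wilcoxon test, Bonferroni-corrects each test family
#' within its defining group, and flags units significant only when both
#' corrected p-values fall below `alpha_sig`.
#'
#' @param g1_beta,g2_beta samples x probes matrices for the two groups,
#'   already preprocessed (inverse-normal transformed and, if covariates are
#'   to be removed, residualized per group). Set `transform = TRUE` to
#'   transform raw beta values on the fly.
#' @param manifest shared [probe_manifest()].
#' @param params [icm_params()] used for both group scans.
#' @param mu Wilcoxon shift (default 0.1).
#' @param alpha_sig significance level applied to corrected p-values
#'   (default 0.05).
#' @param group_labels length-2 labels, defaults `c("group1", "group2")`.
#' @param transform transform inputs before scanning/correlating.
#' @return data.frame of class `differential_result`, one row per unit:
#'   ids, extent, defining group, `chi2`, `df`, `p_steiger`,
#'   `p_steiger_bonf`, `effect_size`, `p_wilcox`, `p_wilcox_bonf`,
#'   `significant`.
#' @export
differential_cmus <- function(g1_beta, g2_beta, manifest,
                              params = icm_params(), mu = 0.1,
                              alpha_sig = 0.05,
                              group_labels = c("group1", "group2"),
                              transform = FALSE) {
  if (transform) {
    g1_beta <- inverse_normal_transform(g1_beta)
    g2_beta <- inverse_normal_transform(g2_beta)
  }
  sets <- list(scan_dataset(g1_beta, manifest, params,
                            label = group_labels[1], transform = FALSE),
               scan_dataset(g2_beta, manifest, params,
                            label = group_labels[2], transform = FALSE))
  mats <- list(g1_beta, g2_beta)
  out <- list()
  for (g in 1:2) {
    units <- collapse_cmu_lists(sets[[g]]$contiguous,
                                sets[[g]]$noncontiguous)
    units <- units[units$n_probes >= 4L, , drop = FALSE]
    if (nrow(units) == 0L) next
    res <- lapply(seq_len(nrow(units)), function(i) {
      pm <- paired_correlation_matrices(mats[[g]], mats[[3 - g]],
                                        units$probes[[i]])
      st <- steiger_matrix_test(pm)
      wx <- wilcoxon_shift_test(pm, mu = mu)
      data.frame(cmu_id = units$id[i], kind = units$kind[i],
                 defining_group = group_labels[g], chrom = units$chrom[i],
                 start = units$start[i], end = units$end[i],
                 n_probes = units$n_probes[i], chi2 = st$chi2, df = st$df,
                 p_steiger = st$p_value, effect_size = wx$effect_size,
                 p_wilcox = wx$p_value, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_steiger_bonf <- pmin(1, res$p_steiger * nrow(res))
    res$p_wilcox_bonf <- pmin(1, res$p_wilcox * nrow(res))
    res$significant <- res$p_steiger_bonf < alpha_sig &
      res$p_wilcox_bonf < alpha_sig
    out[[g]] <- res
  }
  if (!length(out))
    return(structure(data.frame(), class = c("differential_result",
                                             "data.frame")))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("differential_result", "data.frame"))
}
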