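#' Rank-based inverse-normal transform of each probe
#'
#' Converts each probe's sample distribution to a standard normal via
#' Phi^-1((r - 3/8) / (n + 1/4)) where r is the average rank (ties averaged)
#' and n the number of non-missing samples (Blom offset). This tames the
#' influence of outliers before Pearson correlation. Missing entries stay
#' missing; probes with fewer than 3 observations are set entirely to NA and
#' reported in the `excluded` attribute so they drop out of correlation.
#'
#' @param beta samples x probes matrix (see [beta_matrix()]).
#' @return transformed matrix of the same shape, attribute `excluded` holding
#'   probe ids with < 3 observations.
#' @export
inverse_normal_transform <- function(beta) {
  stopifnot(is.matrix(beta))
  n_obs <- colSums(!is.na(beta))
  out <- apply(beta, 2L, function(v) {
    ok <- !is.na(v)
    n <- sum(ok)
    if (n < 3L) return(rep(NA_real_, length(v)))
    r <- rank(v[ok], ties.method = "average")
    v[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
    v
  })
  dimnames(out) <- dimnames(beta)
  excluded <- colnames(beta)[n_obs < 3L]
  if (length(excluded))
    warning(length(excluded), " probe(s) with <3 observations excluded")
  attr(out, "excluded") <- excluded
  out
}

#' Build a covariate design matrix
#'
#' Numeric covariates are used as-is; character/factor covariates are expanded
#' to treatment-coded indicator columns (reference level dropped). An
#' intercept is always included.
#'
#' @param covariates data.frame of per-sample covariates, rownames or a
#'   `sample_id` column giving sample ids.
#' @param sample_ids sample ids to align rows to.
#' @return numeric design matrix (samples x terms) including intercept.
#' @export
covariate_design <- function(covariates, sample_ids) {
  if ("sample_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  missing <- setdiff(sample_ids, rownames(covariates))
  if (length(missing))
    stop("covariates missing for sample(s): ", paste(missing, collapse = ", "))
  covariates <- covariates[sample_ids, , drop = FALSE]
  for (nm in names(covariates))
    if (is.character(covariates[[nm]])) covariates[[nm]] <- factor(covariates[[nm]])
  X <- stats::model.matrix(~ ., data = covariates)
  rownames(X) <- sample_ids
  X
}

#' Residualize probes on covariates (partial-correlation preprocessing)
#'
#' Per probe, ordinary least-squares residuals of the (transformed) values on
#' the covariate design; correlations of these residuals are partial
#' correlations given the covariates. Fitting uses complete cases per probe;
#' residuals are NA where the probe was NA.
#'
#' @param y samples x probes matrix (typically inverse-normal transformed).
#' @param design numeric design matrix from [covariate_design()], or a
#'   covariate data.frame (converted internally).
#' @return matrix of residuals, same shape as `y`.
#' @export
residualize <- function(y, design) {
  stopifnot(is.matrix(y))
  if (is.data.frame(design)) design <- covariate_design(design, rownames(y))
  stopifnot(nrow(design) == nrow(y))
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    drop_cols <- colnames(design)[qrX$pivot[(qrX$rank + 1L):ncol(design)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  out <- y
  complete_rows <- rowSums(is.na(y)) == 0L
  if (all(complete_rows)) {
    out[] <- qr.resid(qrX, y)
    return(out)
  }
  # per-probe complete cases when the matrix has missing entries
  for (j in seq_len(ncol(y))) {
    ok <- !is.na(y[, j])
    if (sum(ok) <= ncol(design)) { out[, j] <- NA_real_; next }
    fit <- stats::lm.fit(design[ok, , drop = FALSE], y[ok, j])
    out[ok, j] <- fit$residuals
    out[!ok, j] <- NA_real_
  }
  out
}
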