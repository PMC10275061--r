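#' Asymmetric similarity between two CMU sets (Tversky alpha=1, beta=0)
#'
#' The fraction of S1's contiguous CMUs whose genomic region shares at least
#' one basepair with some CMU of S2. Not symmetric: Asy(S1, S2) measures how
#' well S1's units are represented in S2.
#'
#' @param s1,s2 `cmu_set` objects (or data.frames with `chrom`/`start`/`end`).
#' @param use_noncontiguous compare non-contiguous spans instead of
#'   contiguous regions.
#' @return a number in \[0, 1\].
#' @export
asymmetric_similarity <- function(s1, s2, use_noncontiguous = FALSE) {
  pick <- function(s) {
    if (inherits(s, "cmu_set")) {
      if (use_noncontiguous) s$noncontiguous else s$contiguous
    } else s
  }
  d1 <- pick(s1); d2 <- pick(s2)
  if (nrow(d1) == 0L) stop("Asy(S1, S2) undefined: S1 is empty")
  if (nrow(d2) == 0L) return(0)
  g1 <- cmu_granges(d1); g2 <- cmu_granges(d2)
  hits <- GenomicRanges::countOverlaps(g1, g2) > 0L
  mean(hits)
}

#' All-pairs asymmetric similarity matrix across CMU sets
#'
#' scores\[i, j\] = Asy(set i, set j). Row medians (excluding the diagonal)
#' summarize how well a set is represented elsewhere; column medians how
#' representative it is of the others. A distance matrix 1 - cor(columns) is
#' returned for complete-linkage hierarchical clustering of datasets.
#'
#' @param sets named list of `cmu_set` objects (all non-empty).
#' @param use_noncontiguous compare non-contiguous spans.
#' @return list of class `asymmetric_similarity_matrix`: `scores`,
#'   `row_medians`, `col_medians`, `dist` (as a `dist` object) and `labels`.
#' @export
similarity_matrix <- function(sets, use_noncontiguous = FALSE) {
  stopifnot(length(sets) >= 2L)
  labels <- names(sets)
  if (is.null(labels))
    labels <- vapply(sets, function(s) s$label, "")
  empty <- vapply(sets, function(s) {
    d <- if (use_noncontiguous) s$noncontiguous else s$contiguous
    nrow(d) == 0L
  }, TRUE)
  if (any(empty))
    stop("empty CMU set(s): ", paste(labels[empty], collapse = ", "))
  n <- length(sets)
  scores <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n))
    scores[i, j] <- asymmetric_similarity(sets[[i]], sets[[j]],
                                          use_noncontiguous)
  offdiag <- function(v, k) v[-k]
  row_medians <- vapply(seq_len(n),
                        function(i) stats::median(offdiag(scores[i, ], i)), 0)
  col_medians <- vapply(seq_len(n),
                        function(j) stats::median(offdiag(scores[, j], j)), 0)
  names(row_medians) <- names(col_medians) <- labels
  cm <- suppressWarnings(stats::cor(scores))   # constant columns -> NA
  cm[is.na(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  structure(list(scores = scores, row_medians = row_medians,
                 col_medians = col_medians, dist = d, labels = labels),
            class = "asymmetric_similarity_matrix")
}

#' @export
print.asymmetric_similarity_matrix <- function(x, ...) {
  cat("asymmetric similarity (Tversky a=1, b=0) across",
      length(x$labels), "CMU sets\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Cluster datasets by CMU similarity
#'
#' Complete-linkage hierarchical clustering on distance 1 - cor of the
#' similarity-matrix columns.
#'
#' @param sm an `asymmetric_similarity_matrix`.
#' @return an `hclust` object.
#' @export
cluster_cmu_sets <- function(sm) {
  stats::hclust(sm$dist, method = "complete")
}
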