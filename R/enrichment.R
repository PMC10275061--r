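#' Probe-based feature enrichment (Fisher exact test)
#'
#' 2x2 contingency of probe membership (in the CMU probe set x overlapping
#' the feature) over all probes, with a two-sided Fisher exact test.
#'
#' @param cmu_probes character vector of probe ids inside CMUs (subset of
#'   `all_probes`).
#' @param all_probes character vector, the probe universe (e.g. all array
#'   probes passing QC).
#' @param feature a [feature_annotation()].
#' @param manifest a [probe_manifest()] giving probe coordinates.
#' @return list of class `enrichment_result`: `feature_class`,
#'   `test = "probe_fisher"`, `table`, `odds_ratio`, `p_value`,
#'   `degenerate` (TRUE when a margin is empty; then p = 1, OR undefined).
#' @export
probe_feature_test <- function(cmu_probes, all_probes, feature, manifest) {
  if (!all(cmu_probes %in% all_probes))
    stop("cmu_probes must be a subset of all_probes")
  m <- manifest[manifest$probe_id %in% all_probes, , drop = FALSE]
  hit <- GenomicRanges::countOverlaps(manifest_granges(m),
                                      feature_granges(feature)) > 0L
  in_cmu <- m$probe_id %in% cmu_probes
  tab <- table(factor(in_cmu, c(TRUE, FALSE)), factor(hit, c(TRUE, FALSE)))
  dimnames(tab) <- list(cmu = c("in", "out"), feature = c("in", "out"))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    res <- list(odds_ratio = NA_real_, p_value = 1, degenerate = TRUE)
  } else {
    ft <- fisher_p2x2(tab)
    res <- list(odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                degenerate = FALSE)
  }
  structure(c(list(feature_class = feature$feature_class,
                   test = "probe_fisher", table = tab), res),
            class = "enrichment_result")
}

# two-sided exact test on a 2x2 table (the probe test's p-value)
fisher_p2x2 <- function(tab) {
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Upper-tail hypergeometric enrichment test
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): of `N` probes of which `K`
#' carry the feature, `n` are drawn (the CMU probes) and `k` carry it.
#'
#' @param k observed feature-carrying probes among the drawn.
#' @param n number drawn.
#' @param K feature-carrying probes in the universe.
#' @param N universe size.
#' @return upper-tail p-value.
#' @export
hypergeometric_test <- function(k, n, K, N) {
  if (n > N || K > N || k > min(n, K) || k < max(0, n + K - N) ||
      any(c(k, n, K, N) < 0))
    stop("impossible hypergeometric parameters")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Sample size-matched random background CMUs
#'
#' For each observed CMU, picks a uniformly random eligible window (windows
#' of the manifest tiling with at least 4 \[lenient\] or 10 \[stringent\] CpG
#' sites) and a random region within it matching the observed CMU's genomic
#' size. This mirrors the observed units while ignoring inter-CpG
#' correlation, controlling for the array's biased probe placement.
#'
#' @param observed contiguous CMU data.frame (needs `start`/`end`, 0-based).
#' @param manifest a [probe_manifest()].
#' @param mode `"lenient"` (windows with >= 4 probes) or `"stringent"`
#'   (>= 10).
#' @param rng_seed optional integer seed (sampling is reproducible given it).
#' @param window_size tiling width (default 250000).
#' @return data.frame of background regions (`chrom`, `start`, `end`),
#'   one per observed CMU; CMUs longer than any eligible window are skipped
#'   with a warning.
#' @export
sample_background_cmus <- function(observed, manifest,
                                   mode = c("lenient", "stringent"),
                                   rng_seed = NULL, window_size = 250000L) {
  mode <- match.arg(mode)
  windows <- eligible_windows(manifest, mode, window_size)
  with_seed(rng_seed, {
    lens <- observed$end - observed$start
    ok <- lens <= (windows$end[1] - windows$start[1])
    if (any(!ok))
      warning(sum(!ok), " CMU(s) longer than any eligible window; skipped")
    draw_background(lens[ok], windows)
  })
}

eligible_windows <- function(manifest, mode, window_size) {
  min_sites <- if (mode == "stringent") 10L else 4L
  windows <- tile_windows(manifest, window_size)
  windows[windows$n_probes >= min_sites, , drop = FALSE]
}

# vectorized draw: one region per element of `lens`
draw_background <- function(lens, windows) {
  nw <- nrow(windows)
  wi <- sample.int(nw, length(lens), replace = TRUE)
  width <- windows$end - windows$start
  start <- windows$start[wi] +
    floor(stats::runif(length(lens)) * (width[wi] - lens + 1))
  data.frame(chrom = windows$chrom[wi], start = start, end = start + lens,
             stringsAsFactors = FALSE)
}

#' Region-based enrichment against matched random backgrounds
#'
#' The observed score is the number of distinct feature intervals hit by the
#' CMU set (a feature annotated five times scores five). The same score is
#' computed for `n_reps` random size-matched background sets
#' ([sample_background_cmus()]); the background score distribution is
#' modeled as normal and the upper-tail probability of the observed score is
#' reported.
#'
#' @param observed contiguous CMU data.frame (`chrom`/`start`/`end`,
#'   0-based).
#' @param feature a [feature_annotation()].
#' @param manifest a [probe_manifest()].
#' @param n_reps background replicates (default 10000).
#' @param rng_seed optional integer seed.
#' @param mode eligible-window preset, see [sample_background_cmus()].
#' @param window_size tiling width.
#' @return `enrichment_result` with `observed`, `background_mean`,
#'   `background_sd` and `p_value`. A degenerate background (sd = 0) is
#'   flagged and p set to 1 (observed <= mean) or 0.
#' @export
region_enrichment <- function(observed, feature, manifest, n_reps = 10000L,
                              rng_seed = NULL, mode = "lenient",
                              window_size = 250000L) {
  if (n_reps < 2L) stop("n_reps must be at least 2 for a background")
  feat_gr <- feature_granges(feature)
  obs_gr <- cmu_granges(observed)
  obs_score <- length(unique(S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(obs_gr, feat_gr))))
  windows <- eligible_windows(manifest, match.arg(mode,
                                                  c("lenient", "stringent")),
                              window_size)
  lens <- observed$end - observed$start
  lens <- lens[lens <= (windows$end[1] - windows$start[1])]
  scores <- with_seed(rng_seed, {
    all_lens <- rep(lens, n_reps)
    rep_id <- rep(seq_len(n_reps), each = length(lens))
    bg <- draw_background(all_lens, windows)
    bg_gr <- GenomicRanges::GRanges(bg$chrom,
                                    IRanges::IRanges(bg$start + 1, bg$end))
    hits <- GenomicRanges::findOverlaps(bg_gr, feat_gr)
    key <- unique(rep_id[S4Vectors::queryHits(hits)] * (length(feat_gr) + 1) +
                    S4Vectors::subjectHits(hits))
    tabulate(key %/% (length(feat_gr) + 1), nbins = n_reps)
  })
  bg_mean <- mean(scores); bg_sd <- stats::sd(scores)
  if (bg_sd == 0) {
    p <- if (obs_score <= bg_mean) 1 else 0
    degenerate <- TRUE
  } else {
    p <- stats::pnorm(obs_score, bg_mean, bg_sd, lower.tail = FALSE)
    degenerate <- FALSE
  }
  structure(list(feature_class = feature$feature_class,
                 test = "region_background", observed = obs_score,
                 background_mean = bg_mean, background_sd = bg_sd,
                 p_value = p, n_reps = n_reps, degenerate = degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment [%s] feature '%s': p = %.3g%s\n", x$test,
              x$feature_class, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Chromatin-context overlap statistics
#'
#' For a CMU set and one chromatin feature (TADs, loops, A/B compartment,
#' FIREs, ...): the fraction of array probes inside any feature interval,
#' the fraction of CMUs hitting at least one interval, and among those, the
#' fraction hitting exactly one.
#'
#' @param cmus contiguous CMU data.frame or non-contiguous spans
#'   (`chrom`/`start`/`end`, 0-based).
#' @param feature a [feature_annotation()].
#' @param manifest a [probe_manifest()].
#' @return list of class `overlap_stats`: `pct_cpg_overlap`,
#'   `pct_cmu_overlap`, `pct_unique_overlap` (NA and flagged when no CMU hits
#'   a feature), `n_features_hit` (per-CMU interval-hit counts).
#' @export
chromatin_overlap_stats <- function(cmus, feature, manifest) {
  stopifnot(nrow(cmus) > 0L, nrow(manifest) > 0L)
  feat_gr <- feature_granges(feature)
  pct_cpg <- mean(GenomicRanges::countOverlaps(manifest_granges(manifest),
                                               feat_gr) > 0L)
  hits <- GenomicRanges::countOverlaps(cmu_granges(cmus), feat_gr)
  pct_cmu <- mean(hits > 0L)
  pct_unique <- if (any(hits > 0L)) sum(hits == 1L) / sum(hits > 0L)
                else NA_real_
  structure(list(feature_class = feature$feature_class,
                 pct_cpg_overlap = pct_cpg, pct_cmu_overlap = pct_cmu,
                 pct_unique_overlap = pct_unique, n_features_hit = hits,
                 degenerate = !any(hits > 0L)),
            class = "overlap_stats")
}

#' A/B-compartment pair score
#'
#' Natural log of the ratio of the CMU overlap fraction to the CpG-probe
#' overlap fraction for one compartment's intervals. When CMUs fall in A and
#' B with frequency proportional to probe placement, the score is similar
#' across compartments.
#'
#' @param cmu_stats an `overlap_stats` for the compartment's intervals.
#' @param compartment_label `"A"` or `"B"` (recorded in the result).
#' @return single number, `log(pct_cmu_overlap / pct_cpg_overlap)`, with
#'   attribute `compartment`. Zero numerator or denominator is an error
#'   (undefined score).
#' @export
compartment_pair_score <- function(cmu_stats, compartment_label = "A") {
  if (cmu_stats$pct_cpg_overlap <= 0 || cmu_stats$pct_cmu_overlap <= 0 ||
      is.na(cmu_stats$pct_cmu_overlap))
    stop("pair score undefined: zero CpG or CMU overlap with compartment")
  structure(log(cmu_stats$pct_cmu_overlap / cmu_stats$pct_cpg_overlap),
            compartment = compartment_label)
}

#' Fraction of spans contained within a single TAD
#'
#' A span is TAD-contained when it does not cross any TAD boundary, i.e. it
#' lies entirely within at least one TAD interval.
#'
#' @param spans data.frame of spans (`chrom`/`start`/`end`, 0-based), e.g.
#'   non-contiguous CMU spans.
#' @param tads a [feature_annotation()] of TAD intervals.
#' @return fraction in \[0, 1\].
#' @export
tad_containment_fraction <- function(spans, tads) {
  stopifnot(nrow(spans) > 0L)
  within <- GenomicRanges::countOverlaps(cmu_granges(spans),
                                         feature_granges(tads),
                                         type = "within") > 0L
  mean(within)
}
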