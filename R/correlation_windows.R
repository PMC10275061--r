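#' Tile chromosomes into fixed non-overlapping windows
#'
#' Windows are \[k*W, (k+1)*W) in 0-based half-open coordinates, anchored at
#' coordinate 0 on every chromosome; windows containing no probes are
#' omitted. 250 kb is the default scan resolution: wide enough to hold
#' several co-methylated runs, small enough to keep per-window correlation
#' matrices tractable.
#'
#' @param manifest a [probe_manifest()].
#' @param window_size window width in basepairs (default 250000).
#' @return data.frame with one row per non-empty window: `chrom`, `start`,
#'   `end` (0-based half-open), `first`, `last` (manifest row range) and
#'   `n_probes`. Probe rows within a window are contiguous because the
#'   manifest is sorted.
#' @export
tile_windows <- function(manifest, window_size = 250000L) {
  stopifnot(window_size >= 1)
  pos0 <- manifest$pos - 1L            # manifest is 1-based points
  bin <- floor(pos0 / window_size)
  key <- paste(manifest$chrom, bin, sep = ":")
  # manifest sorted => identical keys are consecutive
  runs <- rle(key)
  last <- cumsum(runs$lengths)
  first <- last - runs$lengths + 1L
  data.frame(chrom = manifest$chrom[first],
             start = bin[first] * window_size,
             end = (bin[first] + 1) * window_size,
             first = first, last = last,
             n_probes = runs$lengths,
             stringsAsFactors = FALSE)
}

#' Per-window Pearson correlation matrix ("correlation image")
#'
#' Pairwise-complete Pearson correlations between all probes of a window.
#' Pairs supported by fewer than `min_overlap` samples, and pairs involving a
#' zero-variance probe, are set to r = 0 (and counted) so the image stage is
#' total. The diagonal is forced to 1.
#'
#' @param beta samples x probes matrix (manifest-aligned).
#' @param window one row of [tile_windows()] output (or any list with
#'   `first`/`last`).
#' @param min_overlap minimum number of complete sample pairs (default 30).
#' @return list with `R` (symmetric correlation matrix, diag 1),
#'   `n_pairs_used` (sample-overlap counts), `probe_idx` (manifest rows),
#'   `n_zeroed` (entries forced to 0), plus the window fields.
#' @export
correlation_image <- function(beta, window, min_overlap = 30L) {
  idx <- seq.int(window$first, window$last)
  x <- beta[, idx, drop = FALSE]
  p <- ncol(x)
  obs <- !is.na(x)
  n_pairs <- crossprod(obs)                 # sample overlap per pair
  suppressWarnings(R <- stats::cor(x, use = "pairwise.complete.obs"))
  zeroed <- is.na(R) | n_pairs < min_overlap
  diag(zeroed) <- FALSE
  R[zeroed] <- 0
  diag(R) <- 1
  R <- (R + t(R)) / 2
  R[R > 1] <- 1; R[R < -1] <- -1
  list(R = R, n_pairs_used = n_pairs, probe_idx = idx,
       n_zeroed = sum(zeroed) / 2,
       chrom = window$chrom, start = window$start, end = window$end)
}
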