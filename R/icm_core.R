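#' Smoothing kernels for the correlation image
#'
#' Unequal-weight box kernels used to smooth the per-window correlation
#' matrix before thresholding. `"center"` (default) is a center-weighted
#' 3x3 box `[[1,1,1],[1,24,1],[1,1,1]]/32`; `"pyramid"` is the separable
#' `[[1,2,1],[2,4,2],[1,2,1]]/16`. The center-weighted kernel attenuates
#' block-edge pixels less (29/32 of the block value versus 12/16), which
#' keeps the edge rows of a realistically estimated r ~ 0.75 block safely
#' above the default 0.6 cutoff; see the methods vignette.
#'
#' @param type `"center"` or `"pyramid"`, or pass a numeric matrix directly
#'   to [icm_params()].
#' @return odd-sized numeric matrix with weights summing to 1.
#' @export
icm_kernel <- function(type = c("center", "pyramid")) {
  type <- match.arg(type)
  k <- switch(type,
              center = matrix(c(1, 1, 1, 1, 24, 1, 1, 1, 1), 3, 3),
              pyramid = matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3))
  k / sum(k)
}

#' ICM tuning parameters
#'
#' @param alpha correlation cutoff in (0,1); 0.6 balances noise and signal in
#'   single-cohort scans, 0.4 is the cross-tissue preset (larger, comparable
#'   regions).
#' @param min_cpgs minimum adjacent CpGs per contiguous CMU (default 4).
#' @param kernel odd-sized smoothing weight matrix, normalized internally.
#' @param block_density minimum fraction of off-diagonal entries of a
#'   candidate block surviving the cutoff (default 0.9): operationalizes
#'   "overall strong correlation even if not every pair is high".
#' @param min_probes_per_window windows with fewer probes are skipped
#'   (default 4 = lenient preset; 10 = stringent).
#' @param band_width near-diagonal band (in probe offsets) used by edge
#'   detection (default 2).
#' @param min_overlap minimum complete sample pairs per correlation.
#' @param window_size scan window in basepairs.
#' @return list of class `icm_params`.
#' @export
icm_params <- function(alpha = 0.6, min_cpgs = 4L, kernel = icm_kernel(),
                       block_density = 0.9, min_probes_per_window = 4L,
                       band_width = 2L, min_overlap = 30L,
                       window_size = 250000L) {
  stopifnot(alpha > 0, alpha < 1, min_cpgs >= 2, block_density > 0,
            block_density <= 1, nrow(kernel) %% 2 == 1,
            ncol(kernel) %% 2 == 1, band_width >= 1)
  kernel <- kernel / sum(kernel)
  structure(list(alpha = alpha, min_cpgs = as.integer(min_cpgs),
                 kernel = kernel, block_density = block_density,
                 min_probes_per_window = as.integer(min_probes_per_window),
                 band_width = as.integer(band_width),
                 min_overlap = as.integer(min_overlap),
                 window_size = as.integer(window_size)),
            class = "icm_params")
}

#' Smooth a correlation image
#'
#' 2-D convolution with a normalized unequal-weight box kernel, symmetric
#' (reflective) border handling. The output is re-symmetrized ((M + M')/2),
#' the diagonal restored to 1 and entries clipped to \[-1, 1\]. A kernel
#' larger than the image is shrunk to the image size with a warning.
#'
#' @param R square symmetric matrix (correlation image).
#' @param kernel odd-sized weight matrix (normalized internally).
#' @return smoothed matrix, same shape.
#' @export
smooth_image <- function(R, kernel = icm_kernel()) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  p <- nrow(R)
  kernel <- kernel / sum(kernel)
  if (nrow(kernel) > p || ncol(kernel) > p) {
    warning("kernel larger than image; shrinking to image size")
    k <- min(p, nrow(kernel)); if (k %% 2 == 0) k <- k - 1L
    h0 <- (nrow(kernel) - k) %/% 2
    kernel <- kernel[(h0 + 1):(h0 + k), (h0 + 1):(h0 + k), drop = FALSE]
    kernel <- kernel / sum(kernel)
  }
  h <- (nrow(kernel) - 1L) %/% 2L
  refl <- function(i) {                       # symmetric border: 0 -> 1, p+1 -> p
    i[i < 1L] <- 1L - i[i < 1L]
    i[i > p] <- 2L * p + 1L - i[i > p]
    i
  }
  out <- matrix(0, p, p)
  for (di in -h:h) for (dj in -h:h) {
    w <- kernel[di + h + 1L, dj + h + 1L]
    if (w == 0) next
    out <- out + w * R[refl(seq_len(p) + di), refl(seq_len(p) + dj),
                       drop = FALSE]
  }
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out[out > 1] <- 1; out[out < -1] <- -1
  out
}

#' Threshold a smoothed correlation image
#'
#' Entries with |r| < alpha are set to 0; entries at or above the cutoff keep
#' their sign (strong negative correlation is CMU-forming too). Idempotent.
#'
#' @param R smoothed correlation image.
#' @param alpha cutoff in (0,1) (alpha = 0 returns the input unchanged).
#' @return thresholded matrix.
#' @export
apply_cutoff <- function(R, alpha) {
  R[abs(R) < alpha] <- 0
  R
}

#' Detect block boundaries in a thresholded correlation image
#'
#' Works on the support indicator S = (|T| > 0). A cut between adjacent
#' probes is a boundary when no support crosses it within the near-diagonal
#' band (probe offsets <= `band_width`) -- i.e. where the correlation between
#' (nearly) adjacent sites has fallen to zero. On an exact block-diagonal
#' support image this coincides with the positive-band-gradient rule and with
#' exhaustive maximal-block search; on noisy images it does not split a block
#' because of a single interior pixel dropping below the cutoff. An image
#' with no support at all yields no boundaries (and downstream, no CMUs).
#'
#' @param T thresholded smoothed image.
#' @param band_width near-diagonal band width in probe offsets (default 2).
#' @return sorted integer vector of cut positions `c`: a new run starts at
#'   0-based probe index `c` (equivalently, between 1-based probes `c` and
#'   `c + 1`). Partitions `[0, p)` together with the implicit ends.
#' @export
detect_edges <- function(T, band_width = 2L) {
  p <- nrow(T)
  if (p < 2L) return(integer(0))
  S <- abs(T) > 0
  if (!any(S)) return(integer(0))
  crossed <- logical(p - 1L)              # support crossing cut c?
  for (d in seq_len(min(band_width, p - 1L))) {
    diag_d <- S[cbind(seq_len(p - d), seq_len(p - d) + d)]  # S[i, i+d]
    # entry (i, i+d) crosses every cut c with i <= c < i+d
    for (off in 0:(d - 1L)) {
      c_idx <- seq_len(p - d) + off
      crossed[c_idx] <- crossed[c_idx] | diag_d
    }
  }
  which(!crossed)
}

#' Call contiguous CMUs from boundaries
#'
#' Each inter-boundary run of probes is accepted as a contiguous CMU iff it
#' has at least `min_cpgs` probes, the fraction of its off-diagonal entries
#' surviving the cutoff is at least `block_density`, and the mean |r| over
#' the block is at least `alpha`. Genomic extent is \[pos(first) - 1,
#' pos(last)) in BED convention (single-probe intervals have length 1).
#'
#' @param T thresholded smoothed image for one window.
#' @param window one row of [tile_windows()] (needs `first`, `chrom`,
#'   `start`, `end`).
#' @param manifest the [probe_manifest()] the window indexes into.
#' @param params [icm_params()].
#' @return data.frame of contiguous CMUs (possibly 0 rows): `id`, `chrom`,
#'   `start`, `end` (0-based half-open), `n_probes`, `mean_abs_r`, `probes`
#'   (list column of probe ids), `run_first`/`run_last` (local indices in the
#'   window) and `edge_flush` (run touches a window edge; cross-window CMUs
#'   are not attempted, so flush runs may be truncations).
#' @export
call_contiguous_cmus <- function(T, window, manifest, params = icm_params()) {
  p <- nrow(T)
  cuts <- detect_edges(T, params$band_width)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, p)
  rows <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]; j <- ends[k]
    len <- j - i + 1L
    if (len < params$min_cpgs) next
    blk <- T[i:j, i:j, drop = FALSE]
    off <- abs(blk[row(blk) != col(blk)])
    if (mean(off > 0) < params$block_density) next
    if (mean(off) < params$alpha) next
    gi <- window$first + i - 1L
    gj <- window$first + j - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%s:%d-%d", window$chrom, manifest$pos[gi] - 1L,
                   manifest$pos[gj]),
      chrom = window$chrom,
      start = manifest$pos[gi] - 1L,
      end = as.numeric(manifest$pos[gj]),
      n_probes = len,
      mean_abs_r = mean(off),
      probes = I(list(manifest$probe_id[gi:gj])),
      run_first = i, run_last = j,
      edge_flush = (i == 1L || j == p),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_contiguous())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_contiguous <- function() {
  data.frame(id = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), n_probes = integer(0), mean_abs_r = numeric(0),
             probes = I(list()), run_first = integer(0), run_last = integer(0),
             edge_flush = logical(0), stringsAsFactors = FALSE)
}

empty_noncontiguous <- function() {
  data.frame(id = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), n_members = integer(0), members = I(list()),
             pairwise_sign = I(list()), stringsAsFactors = FALSE)
}

#' Link contiguous CMUs into non-contiguous CMUs
#'
#' Two CMUs of the same window, separated by at least one probe belonging to
#' neither ("unsynced" sites), are linked when the mean |r| over the
#' inter-CMU rectangle of the thresholded image is at least `alpha`; the sign
#' of the link is the sign of the (signed) rectangle mean. Connected
#' components of the link graph with two or more members become
#' non-contiguous CMUs, spanning from the first basepair of the first member
#' to the last basepair of the last member.
#'
#' @param cmus contiguous CMU table from [call_contiguous_cmus()] (one
#'   window).
#' @param T the window's thresholded smoothed image.
#' @param params [icm_params()].
#' @return data.frame of non-contiguous CMUs: `id`, `chrom`, `start`, `end`,
#'   `n_members`, `members` (list column of member CMU ids, genomic order)
#'   and `pairwise_sign` (list column of signed member x member matrices:
#'   +1/-1 for linked pairs, 0 otherwise).
#' @export
link_noncontiguous <- function(cmus, T, params = icm_params()) {
  n <- nrow(cmus)
  if (n < 2L) return(empty_noncontiguous())
  link <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    # require an interspersed non-member probe between the runs
    if (cmus$run_first[b] - cmus$run_last[a] < 2L) next
    rect <- T[cmus$run_first[a]:cmus$run_last[a],
              cmus$run_first[b]:cmus$run_last[b], drop = FALSE]
    if (mean(abs(rect)) >= params$alpha)
      link[a, b] <- link[b, a] <- sign(mean(rect))
  }
  comp <- graph_components(link != 0)
  rows <- list()
  for (members in comp) {
    if (length(members) < 2L) next
    members <- sort(members)                    # genomic order
    ids <- cmus$id[members]
    sgn <- link[members, members, drop = FALSE]
    dimnames(sgn) <- list(ids, ids)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("nc_%s:%d-%d", cmus$chrom[members[1L]],
                   as.integer(cmus$start[members[1L]]),
                   as.integer(cmus$end[members[length(members)]])),
      chrom = cmus$chrom[members[1L]],
      start = cmus$start[members[1L]],
      end = cmus$end[members[length(members)]],
      n_members = length(members),
      members = I(list(ids)),
      pairwise_sign = I(list(sgn)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_noncontiguous())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# connected components of a logical adjacency matrix (tiny graphs)
graph_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- list()
  for (v in seq_len(n)) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[u, ] & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

new_cmu_set <- function(label, tissue, params, contiguous, noncontiguous,
                        window_log = NULL, n_samples = NA_integer_) {
  structure(list(label = label, tissue = tissue, params = params,
                 contiguous = contiguous, noncontiguous = noncontiguous,
                 window_log = window_log, n_samples = n_samples),
            class = "cmu_set")
}

#' @export
print.cmu_set <- function(x, ...) {
  cat(sprintf(paste0("cmu_set '%s' (tissue: %s): %d contiguous, ",
                     "%d non-contiguous CMU(s)\n"),
              x$label, x$tissue, nrow(x$contiguous), nrow(x$noncontiguous)))
  invisible(x)
}

#' Scan a dataset for CMUs (end-to-end ICM)
#'
#' Tiles the manifest into windows, computes each window's correlation image
#' and applies the image-clustering stages: smooth, threshold, edge
#' detection, contiguous-CMU calling and non-contiguous linking. Input beta
#' values should already be inverse-normal transformed (and residualized if
#' partial correlations are wanted); raw beta values in \[0,1\] are accepted
#' and transformed on the fly when `transform = TRUE`.
#'
#' @param beta samples x probes matrix aligned to `manifest`.
#' @param manifest a [probe_manifest()].
#' @param params [icm_params()].
#' @param label,tissue labels stored in the result.
#' @param transform apply [inverse_normal_transform()] first (default TRUE).
#' @return a `cmu_set`: contiguous and non-contiguous CMU tables, the
#'   parameters used and a per-window log (probe and CMU counts).
#' @export
scan_dataset <- function(beta, manifest, params = icm_params(),
                         label = "dataset", tissue = label,
                         transform = TRUE) {
  stopifnot(ncol(beta) == nrow(manifest))
  if (transform) beta <- inverse_normal_transform(beta)
  windows <- tile_windows(manifest, params$window_size)
  ct_list <- list(); nc_list <- list(); logs <- list()
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    if (win$n_probes < params$min_probes_per_window) {
      logs[[w]] <- data.frame(win, n_cmus = NA_integer_,
                              n_noncontiguous = NA_integer_, skipped = TRUE)
      next
    }
    img <- correlation_image(beta, win, params$min_overlap)
    T <- apply_cutoff(smooth_image(img$R, params$kernel), params$alpha)
    ct <- call_contiguous_cmus(T, win, manifest, params)
    nc <- if (nrow(ct) >= 2L) link_noncontiguous(ct, T, params)
          else empty_noncontiguous()
    ct_list[[length(ct_list) + 1L]] <- ct
    nc_list[[length(nc_list) + 1L]] <- nc
    logs[[w]] <- data.frame(win, n_cmus = nrow(ct),
                            n_noncontiguous = nrow(nc), skipped = FALSE)
  }
  contiguous <- if (length(ct_list)) do.call(rbind, ct_list)
                else empty_contiguous()
  noncontiguous <- if (length(nc_list)) do.call(rbind, nc_list)
                   else empty_noncontiguous()
  rownames(contiguous) <- rownames(noncontiguous) <- NULL
  new_cmu_set(label, tissue, params, contiguous, noncontiguous,
              window_log = do.call(rbind, logs), n_samples = nrow(beta))
}

#' Contiguous CMU regions as GRanges
#' @param x a `cmu_set` or a contiguous/non-contiguous CMU data.frame with
#'   0-based half-open `chrom`/`start`/`end` columns.
#' @return GRanges (1-based closed internally), names = CMU ids.
#' @export
cmu_granges <- function(x) {
  df <- if (inherits(x, "cmu_set")) x$contiguous else x
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  if (length(gr)) names(gr) <- df$id
  gr
}
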