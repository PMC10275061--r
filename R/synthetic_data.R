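#' Specification for synthetic methylation data with planted structure
#'
#' Describes an array-like probe layout (probes spaced along chromosomes
#' with jittered gaps) with planted correlated blocks, optional signed
#' inter-block links (non-contiguous structure), case attenuation of
#' within-block correlation, and an optional shared covariate effect.
#' Samples are drawn from a latent multivariate normal with the requested
#' block covariance and squashed through the logistic function to beta-like
#' values in (0,1); the squashing is monotone, so the downstream rank-based
#' inverse-normal transform recovers the latent correlation structure.
#'
#' @param n_samples samples to draw.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param mean_gap,gap_jitter probe spacing model: gaps are
#'   `max(2, round(rnorm(mean_gap, gap_jitter * mean_gap)))` basepairs.
#' @param blocks data.frame with columns `id`, `size` (probes) and
#'   `within_r` (|r| < 1): the planted contiguous blocks.
#' @param links optional data.frame `a`, `b`, `inter_r` (signed, |r| < 1):
#'   planted inter-block correlation; linked blocks are placed in the same
#'   window separated by unsynced probes.
#' @param attenuation named numeric: per-block within-correlation used for
#'   the case group by [generate_case_control()].
#' @param covariate_sd sd of per-probe coefficients for a standard-normal
#'   covariate injected into the latent signal (0 = none).
#' @param window_size scan window the placement respects (default 250000).
#' @param seed integer RNG seed (mandatory; all outputs are deterministic
#'   given it).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, chrom_lengths = c(chr1 = 2.5e6),
                           mean_gap = 1150, gap_jitter = 0.4,
                           blocks = data.frame(), links = NULL,
                           attenuation = NULL, covariate_sd = 0,
                           window_size = 250000L, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (nrow(blocks)) {
    stopifnot(all(abs(blocks$within_r) < 1), all(blocks$size >= 2),
              !anyDuplicated(blocks$id))
  }
  if (!is.null(links) && nrow(links))
    stopifnot(all(abs(links$inter_r) < 1),
              all(c(links$a, links$b) %in% blocks$id))
  structure(list(n_samples = as.integer(n_samples),
                 chrom_lengths = chrom_lengths, mean_gap = mean_gap,
                 gap_jitter = gap_jitter, blocks = blocks,
                 links = if (is.null(links)) data.frame() else links,
                 attenuation = attenuation, covariate_sd = covariate_sd,
                 window_size = as.integer(window_size),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# probe layout along the requested chromosomes
gen_manifest <- function(spec) {
  chrom <- character(0); pos <- integer(0)
  for (cn in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[cn]]
    n_est <- ceiling(len / spec$mean_gap) + 10L
    gaps <- pmax(2, round(stats::rnorm(n_est, spec$mean_gap,
                                       spec$gap_jitter * spec$mean_gap)))
    p <- cumsum(c(1 + gaps[1L], gaps[-1L]))
    p <- p[p <= len]
    chrom <- c(chrom, rep(cn, length(p)))
    pos <- c(pos, as.integer(p))
  }
  probe_manifest(sprintf("cg%07d", seq_along(pos)), chrom, pos)
}

# connected groups of blocks under the link table (singletons included)
link_groups <- function(spec) {
  ids <- spec$blocks$id
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(spec$links))
    for (i in seq_len(nrow(spec$links))) {
      a <- spec$links$a[i]; b <- spec$links$b[i]
      adj[a, b] <- adj[b, a] <- TRUE
    }
  lapply(graph_components(adj), function(ix) ids[sort(ix)])
}

# assign each block a run of manifest indices; linked blocks share a window,
# separated by gap probes; runs keep a margin from window edges
place_blocks <- function(manifest, spec, gap_probes = 3L, margin = 3L) {
  windows <- tile_windows(manifest, spec$window_size)
  groups <- link_groups(spec)
  cursor <- windows$first + margin
  placements <- stats::setNames(vector("list", nrow(spec$blocks)),
                                spec$blocks$id)
  w <- 1L
  for (grp in groups) {
    sizes <- spec$blocks$size[match(grp, spec$blocks$id)]
    need <- sum(sizes) + gap_probes * (length(grp) - 1L)
    tries <- 0L
    repeat {
      if (w > nrow(windows)) w <- 1L
      room <- windows$last[w] - margin - cursor[w] + 1L
      if (room >= need) break
      w <- w + 1L; tries <- tries + 1L
      if (tries > 2L * nrow(windows))
        stop("manifest too small to place the requested blocks")
    }
    at <- cursor[w]
    for (k in seq_along(grp)) {
      placements[[grp[k]]] <- seq.int(at, at + sizes[k] - 1L)
      at <- at + sizes[k] + gap_probes
    }
    cursor[w] <- at
    w <- w + 1L
  }
  placements
}

# latent covariance for one link group; nearest-PD repair if needed
group_covariance <- function(spec, grp, placements, within_r) {
  idx <- unlist(placements[grp], use.names = FALSE)
  m <- length(idx)
  C <- diag(m)
  offsets <- c(0L, cumsum(lengths(placements[grp])))
  for (k in seq_along(grp)) {
    rng <- (offsets[k] + 1L):offsets[k + 1L]
    r <- within_r[[grp[k]]]
    C[rng, rng] <- r
  }
  if (nrow(spec$links))
    for (i in seq_len(nrow(spec$links))) {
      a <- match(spec$links$a[i], grp); b <- match(spec$links$b[i], grp)
      if (is.na(a) || is.na(b)) next
      ra <- (offsets[a] + 1L):offsets[a + 1L]
      rb <- (offsets[b] + 1L):offsets[b + 1L]
      C[ra, rb] <- spec$links$inter_r[i]
      C[rb, ra] <- spec$links$inter_r[i]
    }
  diag(C) <- 1
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    warning("requested covariance not positive definite; nearest-PD repair")
    C <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
    ch <- chol(C)
  }
  list(idx = idx, chol = ch)
}

# latent draw for all probes given per-block within-correlations
draw_latent <- function(spec, manifest, placements, within_r) {
  P <- nrow(manifest)
  Z <- matrix(stats::rnorm(spec$n_samples * P), spec$n_samples, P)
  for (grp in link_groups(spec)) {
    gc <- group_covariance(spec, grp, placements, within_r)
    Z[, gc$idx] <- Z[, gc$idx, drop = FALSE] %*% gc$chol
  }
  Z
}

truth_table <- function(manifest, spec, placements) {
  if (!nrow(spec$blocks))
    return(data.frame(block_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      first_idx = integer(0), last_idx = integer(0),
                      n_probes = integer(0), within_r = numeric(0),
                      probes = I(list()), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(spec$blocks)), function(i) {
    id <- spec$blocks$id[i]; idx <- placements[[id]]
    data.frame(block_id = id, chrom = manifest$chrom[idx[1]],
               start = manifest$pos[idx[1]] - 1L,
               end = as.numeric(manifest$pos[idx[length(idx)]]),
               first_idx = idx[1], last_idx = idx[length(idx)],
               n_probes = length(idx), within_r = spec$blocks$within_r[i],
               probes = I(list(manifest$probe_id[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

squash_logistic <- function(latent, intercepts) {
  stats::plogis(sweep(latent, 2L, intercepts, `+`))
}

#' Generate a synthetic manifest + beta matrix with planted blocks
#'
#' @param spec a [synthetic_spec()].
#' @return list: `manifest`, `beta` (samples x probes, values in (0,1)),
#'   `truth` (planted block table with probe runs and genomic extents),
#'   `links` (the planted link table), `covariates` (NULL or a data.frame
#'   with the injected covariate).
#' @export
generate_block_beta <- function(spec) {
  with_seed(spec$seed, {
    manifest <- gen_manifest(spec)
    placements <- place_blocks(manifest, spec)
    within_r <- stats::setNames(as.list(spec$blocks$within_r),
                                spec$blocks$id)
    Z <- draw_latent(spec, manifest, placements, within_r)
    covariates <- NULL
    if (spec$covariate_sd > 0) {
      x <- stats::rnorm(spec$n_samples)
      coefs <- stats::rnorm(ncol(Z), 0, spec$covariate_sd)
      Z <- Z + outer(x, coefs)
      covariates <- data.frame(sample_id = sprintf("s%03d",
                                                   seq_len(spec$n_samples)),
                               age = x, stringsAsFactors = FALSE)
    }
    intercepts <- stats::runif(ncol(Z), -1.5, 1.5)
    beta <- squash_logistic(Z, intercepts)
    dimnames(beta) <- list(sprintf("s%03d", seq_len(spec$n_samples)),
                           manifest$probe_id)
    list(manifest = manifest, beta = beta,
         truth = truth_table(manifest, spec, placements),
         links = spec$links, covariates = covariates)
  })
}

#' Generate per-tissue beta matrices with shared/private blocks
#'
#' All tissues share one probe layout and block placement; a block's
#' correlation is planted only in the tissues listed for it in `share_map`
#' (elsewhere its probes are independent noise). Tissues are sampled
#' independently.
#'
#' @param spec a [synthetic_spec()].
#' @param n_tissues number of tissues.
#' @param share_map named list: block id -> integer vector of tissue indices
#'   carrying the block. Blocks absent from the map are shared by all.
#' @return list: `manifest`, `truth`, `tissues` (named list of beta
#'   matrices, `tissue01` ...), `share_map`.
#' @export
generate_multi_tissue <- function(spec, n_tissues, share_map = list()) {
  with_seed(spec$seed, {
    manifest <- gen_manifest(spec)
    placements <- place_blocks(manifest, spec)
    labels <- sprintf("tissue%02d", seq_len(n_tissues))
    intercepts <- stats::runif(nrow(manifest), -1.5, 1.5)
    tissues <- list()
    for (t in seq_len(n_tissues)) {
      within_r <- lapply(stats::setNames(spec$blocks$id, spec$blocks$id),
                         function(id) {
        share <- share_map[[id]]
        if (is.null(share) || t %in% share)
          spec$blocks$within_r[match(id, spec$blocks$id)]
        else 0
      })
      Z <- draw_latent(spec, manifest, placements, within_r)
      beta <- squash_logistic(Z, intercepts)
      dimnames(beta) <- list(sprintf("s%03d", seq_len(spec$n_samples)),
                             manifest$probe_id)
      tissues[[labels[t]]] <- beta
    }
    list(manifest = manifest,
         truth = truth_table(manifest, spec, placements),
         tissues = tissues, share_map = share_map)
  })
}

#' Generate a case-control pair with attenuated case correlation
#'
#' Controls are sampled at the spec's `within_r`; cases at the attenuated
#' within-correlation given by `spec$attenuation` (blocks not listed keep
#' their control-level correlation). A shared covariate effect
#' (`covariate_sd > 0`) is injected into both groups for residualization
#' testing.
#'
#' @param spec a [synthetic_spec()] (set `attenuation` for alternatives).
#' @return list: `manifest`, `truth` (with `case_r` column), `controls`,
#'   `cases` (beta matrices), `covariates_controls`, `covariates_cases`.
#' @export
generate_case_control <- function(spec) {
  with_seed(spec$seed, {
    manifest <- gen_manifest(spec)
    placements <- place_blocks(manifest, spec)
    intercepts <- stats::runif(nrow(manifest), -1.5, 1.5)
    ids <- spec$blocks$id
    ctrl_r <- stats::setNames(as.list(spec$blocks$within_r), ids)
    case_r <- ctrl_r
    for (id in names(spec$attenuation)) case_r[[id]] <- spec$attenuation[[id]]
    sample_group <- function(within_r, prefix) {
      Z <- draw_latent(spec, manifest, placements, within_r)
      cov_df <- NULL
      if (spec$covariate_sd > 0) {
        x <- stats::rnorm(spec$n_samples)
        coefs <- stats::rnorm(ncol(Z), 0, spec$covariate_sd)
        Z <- Z + outer(x, coefs)
        cov_df <- data.frame(sample_id = sprintf("%s%03d", prefix,
                                                 seq_len(spec$n_samples)),
                             age = x, stringsAsFactors = FALSE)
      }
      beta <- squash_logistic(Z, intercepts)
      dimnames(beta) <- list(sprintf("%s%03d", prefix,
                                     seq_len(spec$n_samples)),
                             manifest$probe_id)
      list(beta = beta, covariates = cov_df)
    }
    controls <- sample_group(ctrl_r, "ctl")
    cases <- sample_group(case_r, "cas")
    truth <- truth_table(manifest, spec, placements)
    truth$case_r <- vapply(truth$block_id, function(id)
      as.numeric(case_r[[id]]), 0)
    list(manifest = manifest, truth = truth,
         controls = controls$beta, cases = cases$beta,
         covariates_controls = controls$covariates,
         covariates_cases = cases$covariates)
  })
}

#' Plant feature annotations on a synthetic genome
#'
#' Either uniformly at random over the chromosomes or clustered over the
#' planted blocks (for constructed enrichment alternatives).
#'
#' @param manifest a [probe_manifest()] (defines the genome extent).
#' @param layout `"uniform_random"` or `"clustered"`.
#' @param n_intervals number of intervals.
#' @param width interval width in bp.
#' @param truth planted-block table (required for `"clustered"`).
#' @param rng_seed optional seed.
#' @param feature_class label for the annotation.
#' @return a [feature_annotation()].
#' @export
plant_features <- function(manifest, layout = c("uniform_random",
                                                "clustered"),
                           n_intervals = 50L, width = 1000L, truth = NULL,
                           rng_seed = NULL, feature_class = layout[1]) {
  layout <- match.arg(layout)
  with_seed(rng_seed, {
    if (layout == "uniform_random") {
      chroms <- unique(manifest$chrom)
      len <- vapply(chroms, function(cn) max(manifest$pos[manifest$chrom ==
                                                            cn]) + 1000, 0)
      ci <- sample(seq_along(chroms), n_intervals, replace = TRUE,
                   prob = len / sum(len))
      start <- floor(stats::runif(n_intervals) * pmax(1, len[ci] - width))
      feature_annotation(feature_class, chroms[ci], start, start + width)
    } else {
      stopifnot(!is.null(truth), nrow(truth) > 0L)
      bi <- sample(seq_len(nrow(truth)), n_intervals, replace = TRUE)
      center <- (truth$start[bi] + truth$end[bi]) / 2 +
        round(stats::rnorm(n_intervals, 0, width / 4))
      start <- pmax(0, floor(center - width / 2))
      feature_annotation(feature_class, truth$chrom[bi], start, start + width)
    }
  })
}

#' Built-in synthetic presets
#'
#' `"basic"`: one 2.5 Mb chromosome, ~2,200 probes, n = 200 samples, 20
#' planted blocks of 6-12 probes at within-r 0.8 and no links -- the standard
#' single-cohort recovery scenario. `"multitissue"`: 6 blocks of 12 probes
#' at within-r 0.8 with graded tissue sharing (10 of 10, 9, 8, 7, 5, 1),
#' n = 100 per tissue, for tissue-independence calling at the cross-tissue
#' cutoff. `"casecontrol"`: n = 150 per group, four 8-probe blocks at
#' within-r 0.8 of which two are attenuated to 0.4 in cases.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @return a [synthetic_spec()]; for `"multitissue"` the suggested share map
#'   is attached as attribute `share_map`, for `"casecontrol"` the
#'   attenuation is set in the spec.
#' @export
synthetic_preset <- function(preset = c("basic", "multitissue",
                                        "casecontrol"), seed) {
  preset <- match.arg(preset)
  switch(preset,
    basic = synthetic_spec(
      n_samples = 200L, chrom_lengths = c(chr1 = 2.5e6), mean_gap = 1150,
      blocks = data.frame(id = sprintf("b%02d", 1:20),
                          size = rep(c(6L, 8L, 10L, 12L), 5),
                          within_r = 0.8, stringsAsFactors = FALSE),
      seed = seed),
    multitissue = {
      spec <- synthetic_spec(
        n_samples = 100L, chrom_lengths = c(chr1 = 1.5e6), mean_gap = 1150,
        blocks = data.frame(id = sprintf("b%02d", 1:6), size = 12L,
                            within_r = 0.8, stringsAsFactors = FALSE),
        seed = seed)
      attr(spec, "share_map") <- list(b01 = 1:10, b02 = 1:9, b03 = 1:8,
                                      b04 = 1:7, b05 = 1:5, b06 = 1L)
      spec
    },
    casecontrol = synthetic_spec(
      n_samples = 150L, chrom_lengths = c(chr1 = 1e6), mean_gap = 900,
      blocks = data.frame(id = sprintf("b%02d", 1:4), size = 8L,
                          within_r = 0.8, stringsAsFactors = FALSE),
      attenuation = c(b01 = 0.4, b02 = 0.4),
      seed = seed))
}
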