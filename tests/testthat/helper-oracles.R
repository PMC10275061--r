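# shared oracles and fixture builders (independent of the code paths they
# check wherever they serve as oracles)

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# reference extraction of strict lower-triangle entries
lower_offdiag_ref <- function(M) M[lower.tri(M)]

# exhaustive maximal-interval block finder: on an image with exact
# block-diagonal support, a block is a maximal interval [i..j] all of whose
# off-diagonal entries are non-zero; filtered like the ICM acceptance rule
oracle_block_finder <- function(T, min_cpgs = 4L, alpha = 0.6) {
  p <- nrow(T)
  dense <- function(i, j) {
    blk <- T[i:j, i:j, drop = FALSE]
    all(abs(blk[row(blk) != col(blk)]) > 0)
  }
  blocks <- list()
  i <- 1L
  while (i <= p) {
    j <- i
    while (j < p && dense(i, j + 1L)) j <- j + 1L
    if (j > i) blocks[[length(blocks) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  keep <- Filter(function(b) {
    len <- b[2] - b[1] + 1L
    if (len < min_cpgs) return(FALSE)
    blk <- T[b[1]:b[2], b[1]:b[2], drop = FALSE]
    mean(abs(blk[row(blk) != col(blk)])) >= alpha
  }, blocks)
  keep
}

# random thresholded image with exact block-diagonal support: blocks of
# constant |r| >= alpha separated by >= 1 zero-support probe
random_block_image <- function(p_max = 40L, alpha = 0.6) {
  p <- sample(8:p_max, 1L)
  T <- diag(p)
  truth <- list()
  i <- 1L
  while (i <= p - 1L) {
    size <- sample(1:9, 1L)
    j <- min(p, i + size - 1L)
    if (size >= 2L && j > i) {
      r <- stats::runif(1, alpha, 0.95) * sample(c(-1, 1), 1L)
      T[i:j, i:j] <- r
      diag(T)[i:j] <- 1
      truth[[length(truth) + 1L]] <- c(i, j)
    }
    i <- j + 1L + sample(1:3, 1L)       # zero-support gap probes
  }
  diag(T) <- 1
  list(T = T, blocks = truth, p = p)
}

# thresholded image with planted constant blocks at given runs/values
planted_image <- function(p, runs, values) {
  T <- diag(p)
  for (k in seq_along(runs)) {
    idx <- runs[[k]]
    T[idx, idx] <- values[k]
  }
  diag(T) <- 1
  T
}

# quick cmu_set from a region data.frame (for similarity / TI tests)
make_set <- function(label, regions, tissue = label, n_samples = 100L,
                     noncontig = NULL) {
  k <- if (is.null(regions)) 0L else nrow(regions)
  if (k == 0L)
    regions <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0))
  ct <- data.frame(id = sprintf("%s_c%d", label, seq_len(k)),
                   chrom = regions$chrom, start = regions$start,
                   end = regions$end,
                   n_probes = if ("n_probes" %in% names(regions))
                     regions$n_probes else rep(NA_integer_, k),
                   mean_abs_r = rep(0.8, k), stringsAsFactors = FALSE)
  nc <- if (is.null(noncontig)) cmuscan:::empty_noncontiguous() else {
    data.frame(id = sprintf("%s_n%d", label, seq_len(nrow(noncontig))),
               chrom = noncontig$chrom, start = noncontig$start,
               end = noncontig$end, n_members = noncontig$n_members,
               members = I(replicate(nrow(noncontig), character(0),
                                     simplify = FALSE)),
               pairwise_sign = I(replicate(nrow(noncontig), matrix(0, 0, 0),
                                           simplify = FALSE)),
               stringsAsFactors = FALSE)
  }
  cmuscan:::new_cmu_set(label = label, tissue = tissue, params = NULL,
                        contiguous = ct, noncontiguous = nc,
                        n_samples = n_samples)
}

# uniform manifest over one chromosome
uniform_manifest <- function(n_probes, length_bp = 3e6, seed = 1) {
  pos <- sort(sample.int(length_bp, n_probes))
  probe_manifest(sprintf("cg%05d", seq_len(n_probes)), "chr1", pos)
}

# memoized basic-preset simulation + default scan (reused across tests)
.fixture_env <- new.env(parent = emptyenv())
basic_fixture <- function(seed = 101) {
  key <- paste0("basic_", seed)
  if (is.null(.fixture_env[[key]])) {
    spec <- synthetic_preset("basic", seed = seed)
    sim <- generate_block_beta(spec)
    cmus <- scan_dataset(sim$beta, sim$manifest, icm_params(),
                         label = "basic")
    .fixture_env[[key]] <- list(sim = sim, cmus = cmus)
  }
  .fixture_env[[key]]
}

# two-sided Fisher p by full enumeration of the hypergeometric support:
# sum of point probabilities not exceeding that of the observed table
fisher_two_sided_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
  support <- lo:hi
  pmf <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}
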