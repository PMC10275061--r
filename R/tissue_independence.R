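#' Deduplicate CMU sets by tissue label
#'
#' When more than one dataset is available for a tissue, keep the one with
#' the largest sample size (ties broken lexicographically by label).
#'
#' @param sets list of `cmu_set` objects.
#' @return filtered list, one set per unique tissue.
#' @export
dedup_by_tissue <- function(sets) {
  tissue <- vapply(sets, function(s) s$tissue, "")
  label <- vapply(sets, function(s) s$label, "")
  n <- vapply(sets, function(s)
    if (is.na(s$n_samples)) -Inf else as.numeric(s$n_samples), 0)
  keep <- vapply(split(seq_along(sets), tissue), function(i) {
    i[order(-n[i], label[i])][1L]
  }, 0L)
  sets[sort(unname(keep))]
}

# coverage-stack helper: maximal runs where depth > threshold * n_tissues
stack_regions <- function(granges_per_tissue, ti_threshold, kind) {
  n_tissues <- length(granges_per_tissue)
  reduced <- lapply(granges_per_tissue, GenomicRanges::reduce)
  all_gr <- do.call(c, unname(reduced))
  min_depth <- floor(ti_threshold * n_tissues) + 1L  # depth > thr (strict)
  if (length(all_gr) == 0L)
    return(ti_regions_frame(character(0), numeric(0), numeric(0),
                            integer(0), n_tissues, kind))
  cov <- GenomicRanges::coverage(all_gr)
  sl <- IRanges::slice(cov, lower = min_depth, rangesOnly = FALSE)
  chroms <- rep(names(sl), lengths(sl))
  starts <- unlist(lapply(sl, IRanges::start), use.names = FALSE)
  ends <- unlist(lapply(sl, IRanges::end), use.names = FALSE)
  support <- unlist(lapply(sl, function(v)
    if (length(v)) vapply(seq_along(v), function(i) max(v[[i]]), 0L)
    else integer(0)), use.names = FALSE)
  if (is.null(starts)) starts <- integer(0)
  if (is.null(ends)) ends <- integer(0)
  if (is.null(support)) support <- integer(0)
  ti_regions_frame(chroms, starts - 1, ends, as.integer(support),
                   n_tissues, kind)
}

ti_regions_frame <- function(chrom, start, end, support, n_tissues, kind) {
  out <- data.frame(chrom = chrom, start = start, end = end,
                    support_count = support,
                    support_fraction = if (length(support))
                      support / n_tissues else numeric(0),
                    kind = rep(kind, length(chrom)),
                    stringsAsFactors = FALSE)
  ord <- order(chrom_rank(out$chrom), out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ti_regions", "data.frame")
  out
}

#' Tissue-independent contiguous CMU regions
#'
#' Stacks every tissue's contiguous CMU intervals (one deduplicated dataset
#' per tissue) and reports the maximal basepair runs covered in strictly more
#' than `ti_threshold` of the tissues -- the largest regions of overlap.
#' Per tissue, only CMUs with more than `min_cpgs` probes are considered
#' (higher-confidence units), and regions in `exclude` (e.g. the HLA locus)
#' are removed first.
#'
#' @param sets list of `cmu_set` objects, one or more per tissue.
#' @param ti_threshold support fraction that must be exceeded (default 0.8,
#'   strict inequality: present in more than 80\% of unique tissues).
#' @param min_cpgs per-CMU probe-count filter, strict (default 10). CMU sets
#'   read back from BED (probe counts unknown) pass the filter.
#' @param exclude optional GRanges (or 0-based `chrom`/`start`/`end`
#'   data.frame) of regions to drop before stacking.
#' @return a `ti_regions` data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `support_count` (max tissues covering), `support_fraction`,
#'   `kind = "contiguous"`.
#' @export
ti_contiguous_regions <- function(sets, ti_threshold = 0.8, min_cpgs = 10L,
                                  exclude = NULL) {
  sets <- dedup_by_tissue(sets)
  if (length(sets) < 2L) stop("need at least 2 unique tissues")
  excl <- exclude_granges(exclude)
  per_tissue <- lapply(sets, function(s) {
    ct <- s$contiguous
    keep <- is.na(ct$n_probes) | ct$n_probes > min_cpgs
    gr <- cmu_granges(ct[keep, , drop = FALSE])
    if (!is.null(excl)) gr <- GenomicRanges::setdiff(gr, excl)
    gr
  })
  stack_regions(per_tissue, ti_threshold, "contiguous")
}

#' Tissue-independent non-contiguous CMU regions
#'
#' Per tissue, spans of non-contiguous CMUs with at least `min_members`
#' member CMUs (first basepair of the first member to last basepair of the
#' last) are stacked; maximal runs covered in strictly more than
#' `ti_threshold` of the tissues are reported. Only the span intersection
#' matters, which deliberately tolerates variation of member-CMU boundaries
#' across tissues.
#'
#' @inheritParams ti_contiguous_regions
#' @param min_members minimum member CMUs per non-contiguous CMU (default 3).
#' @return a `ti_regions` data.frame with `kind = "noncontiguous"`.
#' @export
ti_noncontiguous_regions <- function(sets, ti_threshold = 0.8,
                                     min_members = 3L, exclude = NULL) {
  sets <- dedup_by_tissue(sets)
  if (length(sets) < 2L) stop("need at least 2 unique tissues")
  excl <- exclude_granges(exclude)
  per_tissue <- lapply(sets, function(s) {
    nc <- s$noncontiguous
    keep <- nc$n_members >= min_members
    gr <- cmu_granges(nc[keep, , drop = FALSE])
    if (!is.null(excl)) gr <- GenomicRanges::setdiff(gr, excl)
    gr
  })
  stack_regions(per_tissue, ti_threshold, "noncontiguous")
}

exclude_granges <- function(exclude) {
  if (is.null(exclude)) return(NULL)
  if (inherits(exclude, "GRanges")) return(exclude)
  GenomicRanges::GRanges(exclude$chrom,
                         IRanges::IRanges(exclude$start + 1, exclude$end))
}

#' Write TI regions as BED (support count in the score column)
#' @param ti a `ti_regions` data.frame.
#' @param path output file.
#' @export
write_ti_bed <- function(ti, path) {
  if (nrow(ti) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  writeLines(sprintf("%s\t%d\t%d\t%s_%d\t%d\t.", ti$chrom,
                     as.integer(ti$start), as.integer(ti$end),
                     substr(ti$kind, 1, 2), seq_len(nrow(ti)),
                     ti$support_count), path)
  invisible(path)
}
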