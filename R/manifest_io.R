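#' Construct a probe manifest
#'
#' A probe manifest anchors all window and interval arithmetic: it is the
#' ordered list of CpG probes with their genomic coordinates, in the style of
#' an Illumina 450K/EPIC manifest. Positions are 1-based basepair coordinates
#' (manifest convention); all emitted intervals are BED 0-based half-open.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chrom character vector of chromosome names (with or without a
#'   "chr" prefix).
#' @param pos integer vector of 1-based probe positions.
#' @param genome_build optional build string recorded as metadata (the method
#'   itself is build-agnostic).
#' @param autosomes_only drop sex chromosomes and unplaced contigs.
#' @return a `probe_manifest` data.frame with columns `probe_id`, `chrom`,
#'   `pos`, sorted by chromosome then position.
#' @export
probe_manifest <- function(probe_id, chrom, pos, genome_build = NA_character_,
                           autosomes_only = TRUE) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(probe_id))
  stopifnot(length(probe_id) == length(chrom), length(chrom) == length(pos))
  probe_id <- as.character(probe_id)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (anyDuplicated(probe_id))
    stop("duplicate probe ids: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  if (any(is.na(pos)) || any(pos < 1L))
    stop("probe positions must be positive 1-based integers")
  m <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                  stringsAsFactors = FALSE)
  if (autosomes_only) {
    keep <- is_autosome(m$chrom)
    m <- m[keep, , drop = FALSE]
  }
  ord <- order(chrom_rank(m$chrom), m$pos)
  if (is.unsorted(ord)) {
    # caller gave unsorted input; sort silently here, read_manifest() warns
    m <- m[ord, , drop = FALSE]
  }
  rownames(m) <- NULL
  structure(m, class = c("probe_manifest", "data.frame"),
            genome_build = genome_build, sorted = TRUE)
}

#' @export
print.probe_manifest <- function(x, ...) {
  cat(sprintf("probe_manifest: %d probes on %d chromosome(s)%s\n",
              nrow(x), length(unique(x$chrom)),
              if (!is.na(attr(x, "genome_build")))
                paste0(" [", attr(x, "genome_build"), "]") else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

is_autosome <- function(chrom) {
  bare <- sub("^chr", "", chrom)
  !is.na(suppressWarnings(as.integer(bare))) &
    suppressWarnings(as.integer(bare)) >= 1L &
    suppressWarnings(as.integer(bare)) <= 22L
}

# numeric-aware chromosome ordering (chr2 before chr10, non-numeric last)
chrom_rank <- function(chrom) {
  bare <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(bare))
  num[is.na(num)] <- 1e6 + as.numeric(factor(bare[is.na(num)]))
  num
}

#' Read a probe manifest from delimited text
#'
#' Expects columns `probe_id`, `chrom`, `pos` (header required; TSV or CSV,
#' autodetected). Duplicate probe ids are a hard error; unsorted input is
#' sorted with a warning.
#'
#' @param path file path.
#' @param autosomes_only drop sex chromosomes / unplaced contigs (default
#'   TRUE; the analysis is restricted to autosomes).
#' @param genome_build optional build string stored as metadata.
#' @return a [probe_manifest()].
#' @export
read_manifest <- function(path, autosomes_only = TRUE,
                          genome_build = NA_character_) {
  df <- read_delim_auto(path)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  ord <- order(chrom_rank(df$chrom), df$pos)
  if (!identical(ord, seq_len(nrow(df))))
    warning("manifest not sorted by chromosome/position; sorting")
  probe_manifest(df$probe_id, df$chrom, df$pos, genome_build = genome_build,
                 autosomes_only = autosomes_only)
}

#' Write a probe manifest
#' @param manifest a [probe_manifest()].
#' @param path output path (TSV).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest)[c("probe_id", "chrom", "pos")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a samples x probes beta-value matrix
#'
#' The file must have a header row of probe ids, a first column of sample ids
#' and one row per sample. Columns are reordered to manifest order; probes in
#' the file but absent from the manifest are dropped with a warning giving the
#' count. In untransformed mode any value outside \[0,1\] is an error listing
#' the offending cells. Missing values (NA) are permitted and stay missing.
#'
#' @param path file path (TSV or CSV).
#' @param manifest a [probe_manifest()] the columns are aligned to.
#' @param transformed set TRUE if values are already transformed (range check
#'   skipped).
#' @return numeric matrix, rows = samples, columns = probes in manifest order.
#'   Probes in the manifest but missing from the file are columns of NA.
#' @export
read_beta_matrix <- function(path, manifest, transformed = FALSE) {
  df <- read_delim_auto(path)
  samples <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- samples
  beta_matrix(mat, manifest, transformed = transformed)
}

#' Align a beta matrix to a manifest
#'
#' @param mat numeric matrix with probe-id colnames and sample-id rownames.
#' @param manifest a [probe_manifest()].
#' @param transformed skip the \[0,1\] range check.
#' @return matrix with columns exactly in manifest order.
#' @export
beta_matrix <- function(mat, manifest, transformed = FALSE) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  extra <- setdiff(colnames(mat), manifest$probe_id)
  if (length(extra)) {
    warning(length(extra), " probe(s) in matrix absent from manifest; dropped")
    mat <- mat[, !colnames(mat) %in% extra, drop = FALSE]
  }
  if (!transformed) {
    bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
    if (nrow(bad))
      stop("beta values outside [0,1] at: ",
           paste(sprintf("[%s,%s]=%g", rownames(mat)[bad[, 1]],
                         colnames(mat)[bad[, 2]],
                         mat[bad, drop = FALSE][seq_len(nrow(bad))]),
                 collapse = ", "))
  }
  out <- matrix(NA_real_, nrow(mat), nrow(manifest),
                dimnames = list(rownames(mat), manifest$probe_id))
  common <- intersect(manifest$probe_id, colnames(mat))
  out[, common] <- mat[, common, drop = FALSE]
  if (nrow(out) < 30)
    warning("fewer than 30 samples; correlation estimates will be unstable")
  out
}

#' Manifest probes as GRanges (1-bp points)
#' @param manifest a [probe_manifest()].
#' @return GRanges with one 1-bp range per probe, names = probe ids.
#' @export
manifest_granges <- function(manifest) {
  gr <- GenomicRanges::GRanges(manifest$chrom,
                               IRanges::IRanges(manifest$pos, width = 1L))
  names(gr) <- manifest$probe_id
  gr
}

# ---- feature annotations (BED, 0-based half-open) -------------------------

#' Construct a feature annotation
#'
#' Genomic intervals of one feature class (e.g. Promoter, CTCF, TAD, loop,
#' A/B compartment) in BED convention: 0-based half-open.
#'
#' @param feature_class single string naming the class.
#' @param chrom,start,end interval vectors (start 0-based inclusive, end
#'   exclusive).
#' @return a `feature_annotation` object.
#' @export
feature_annotation <- function(feature_class, chrom, start, end) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end < start)) stop("feature intervals must have end >= start")
  ord <- order(chrom_rank(chrom), start)
  structure(list(feature_class = as.character(feature_class)[1L],
                 intervals = data.frame(chrom = as.character(chrom)[ord],
                                        start = start[ord], end = end[ord],
                                        stringsAsFactors = FALSE)),
            class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat(sprintf("feature_annotation '%s': %d interval(s)\n",
              x$feature_class, nrow(x$intervals)))
  invisible(x)
}

feature_granges <- function(feature) {
  iv <- feature$intervals
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(iv$start + 1L, iv$end))
}

#' Read feature annotations from a BED file
#'
#' BED columns chrom/start/end plus a class column (4th by default). Returns
#' one [feature_annotation()] per class.
#'
#' @param path BED file.
#' @param class_col column index holding the feature class (default 4).
#' @return named list of `feature_annotation` objects.
#' @export
read_features_bed <- function(path, class_col = 4L) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  cls <- if (ncol(df) >= class_col) as.character(df[[class_col]]) else "feature"
  out <- lapply(split(seq_len(nrow(df)), cls), function(i)
    feature_annotation(cls[i[1]], df[[1]][i], df[[2]][i], df[[3]][i]))
  out
}

# ---- CMU BED I/O ----------------------------------------------------------

#' Write contiguous CMUs as BED6
#'
#' Emits chrom, start (0-based), end (half-open), name (CMU id), score
#' (mean |r| x 1000, capped at 1000) and strand ".". Non-contiguous CMUs are
#' written by [write_noncontiguous_bed()] as a companion file with a group
#' column.
#'
#' @param cmus a `cmu_set` (see [scan_dataset()]).
#' @param path output file.
#' @export
write_cmu_bed <- function(cmus, path) {
  ct <- cmus$contiguous
  if (is.null(ct) || nrow(ct) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(1000L, as.integer(round(ct$mean_abs_r * 1000)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   ct$chrom, as.integer(ct$start), as.integer(ct$end),
                   ct$id, score)
  writeLines(lines, path)
  invisible(path)
}

#' Write non-contiguous CMU membership as grouped BED
#'
#' One line per member CMU: BED6 plus a 7th column with the non-contiguous
#' group id.
#'
#' @param cmus a `cmu_set`.
#' @param path output file.
#' @export
write_noncontiguous_bed <- function(cmus, path) {
  nc <- cmus$noncontiguous
  if (is.null(nc) || nrow(nc) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ct <- cmus$contiguous
  rows <- do.call(rbind, lapply(seq_len(nrow(nc)), function(i) {
    mem <- nc$members[[i]]
    j <- match(mem, ct$id)
    data.frame(chrom = ct$chrom[j], start = ct$start[j], end = ct$end[j],
               name = ct$id[j],
               score = pmin(1000L, as.integer(round(ct$mean_abs_r[j] * 1000))),
               group = nc$id[i], stringsAsFactors = FALSE)
  }))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s", rows$chrom,
                     as.integer(rows$start), as.integer(rows$end), rows$name,
                     rows$score, rows$group), path)
  invisible(path)
}

#' Read a contiguous-CMU BED file back into a minimal CMU set
#'
#' Only genomic extents, ids and scores survive a BED round trip; probe
#' membership does not. The result is sufficient for the similarity and
#' tissue-independence stages, which operate on genomic regions.
#'
#' @param path BED file written by [write_cmu_bed()].
#' @param label dataset label.
#' @param tissue tissue label (defaults to `label`).
#' @return a `cmu_set` with a `contiguous` table.
#' @export
read_cmu_bed <- function(path, label = basename(path), tissue = label) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    ct <- data.frame(id = character(0), chrom = character(0),
                     start = numeric(0), end = numeric(0),
                     n_probes = integer(0), mean_abs_r = numeric(0),
                     stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ct <- data.frame(id = vapply(parts, `[`, "", 4L),
                     chrom = vapply(parts, `[`, "", 1L),
                     start = as.numeric(vapply(parts, `[`, "", 2L)),
                     end = as.numeric(vapply(parts, `[`, "", 3L)),
                     n_probes = NA_integer_,
                     mean_abs_r = as.numeric(vapply(parts, `[`, "", 5L)) / 1000,
                     stringsAsFactors = FALSE)
  }
  new_cmu_set(label = label, tissue = tissue, params = NULL,
              contiguous = ct, noncontiguous = empty_noncontiguous())
}
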