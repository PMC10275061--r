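#' @name pipeline
#' @title Pipeline runners behind the `cmu-scan` command line
#' @description Each `run_*` function is a thin orchestration layer over the
#'   package API: it reads standard-format inputs, runs one stage and writes
#'   plain-text artifacts (BED/TSV) plus a JSON run log capturing the full
#'   configuration and seeds, so every output is attributable to exactly one
#'   logged run and identical configs yield byte-identical outputs.
NULL

# write through a temp file so outputs appear atomically
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  atomic_write(path, function(p)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE))
}

write_run_log <- function(out_dir, subcommand, config, counts) {
  log <- list(tool = "cmu-scan", subcommand = subcommand,
              package_version = as.character(utils::packageVersion("cmuscan")),
              config = config, counts = counts)
  atomic_write(file.path(out_dir, paste0(subcommand, "_runlog.json")),
               function(p) jsonlite::write_json(log, p, auto_unbox = TRUE,
                                                pretty = TRUE, digits = NA))
}

write_beta_tsv <- function(beta, path) {
  df <- data.frame(sample_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Simulate a synthetic dataset preset to disk
#'
#' @param preset `"basic"`, `"multitissue"` or `"casecontrol"`.
#' @param seed integer seed.
#' @param out_dir output directory (created).
#' @return invisibly, the list of files written.
#' @export
run_simulate <- function(preset, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_preset(preset, seed)
  files <- character(0)
  truth_cols <- c("block_id", "chrom", "start", "end", "n_probes", "within_r")
  if (preset == "basic") {
    sim <- generate_block_beta(spec)
    write_manifest(sim$manifest, file.path(out_dir, "manifest.tsv"))
    write_beta_tsv(sim$beta, file.path(out_dir, "beta.tsv"))
    write_tsv(sim$truth[truth_cols], file.path(out_dir, "truth.tsv"))
    files <- c("manifest.tsv", "beta.tsv", "truth.tsv")
    counts <- list(n_samples = nrow(sim$beta), n_probes = ncol(sim$beta),
                   n_blocks = nrow(sim$truth))
  } else if (preset == "multitissue") {
    sim <- generate_multi_tissue(spec, n_tissues = 10L,
                                 share_map = attr(spec, "share_map"))
    write_manifest(sim$manifest, file.path(out_dir, "manifest.tsv"))
    for (nm in names(sim$tissues))
      write_beta_tsv(sim$tissues[[nm]],
                     file.path(out_dir, paste0("beta_", nm, ".tsv")))
    write_tsv(sim$truth[truth_cols], file.path(out_dir, "truth.tsv"))
    files <- c("manifest.tsv", "truth.tsv",
               paste0("beta_", names(sim$tissues), ".tsv"))
    counts <- list(n_tissues = length(sim$tissues),
                   n_probes = nrow(sim$manifest))
  } else {
    sim <- generate_case_control(spec)
    write_manifest(sim$manifest, file.path(out_dir, "manifest.tsv"))
    write_beta_tsv(sim$controls, file.path(out_dir, "beta_controls.tsv"))
    write_beta_tsv(sim$cases, file.path(out_dir, "beta_cases.tsv"))
    write_tsv(sim$truth[c(truth_cols, "case_r")],
              file.path(out_dir, "truth.tsv"))
    files <- c("manifest.tsv", "beta_controls.tsv", "beta_cases.tsv",
               "truth.tsv")
    counts <- list(n_controls = nrow(sim$controls),
                   n_cases = nrow(sim$cases),
                   n_probes = nrow(sim$manifest))
  }
  write_run_log(out_dir, "simulate",
                list(preset = preset, seed = seed), counts)
  invisible(file.path(out_dir, files))
}

#' Scan a beta matrix for CMUs and write BED outputs
#'
#' @param beta_path beta TSV (sample_id column + probe columns).
#' @param manifest_path manifest TSV.
#' @param out_dir output directory.
#' @param alpha,min_cpgs,window_size,kernel,min_overlap ICM parameters; see
#'   [icm_params()]. `kernel` is a kernel name for [icm_kernel()].
#' @param label,tissue dataset labels.
#' @return the `cmu_set`, invisibly. Writes `cmus.bed`,
#'   `cmus_noncontiguous.bed` and `scan_runlog.json`.
#' @export
run_scan <- function(beta_path, manifest_path, out_dir, alpha = 0.6,
                     min_cpgs = 4L, window_size = 250000L,
                     kernel = "center", min_overlap = 30L,
                     label = "dataset", tissue = label) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- read_manifest(manifest_path)
  beta <- read_beta_matrix(beta_path, manifest)
  params <- icm_params(alpha = alpha, min_cpgs = min_cpgs,
                       kernel = icm_kernel(kernel),
                       window_size = window_size, min_overlap = min_overlap)
  cmus <- scan_dataset(beta, manifest, params, label = label,
                       tissue = tissue)
  atomic_write(file.path(out_dir, "cmus.bed"),
               function(p) write_cmu_bed(cmus, p))
  atomic_write(file.path(out_dir, "cmus_noncontiguous.bed"),
               function(p) write_noncontiguous_bed(cmus, p))
  write_run_log(out_dir, "scan",
                list(beta = beta_path, manifest = manifest_path,
                     alpha = alpha, min_cpgs = min_cpgs,
                     window_size = window_size, kernel = kernel,
                     min_overlap = min_overlap, label = label,
                     tissue = tissue),
                list(n_contiguous = nrow(cmus$contiguous),
                     n_noncontiguous = nrow(cmus$noncontiguous),
                     n_windows = if (is.null(cmus$window_log)) 0L
                                 else nrow(cmus$window_log)))
  invisible(cmus)
}

#' Compare CMU BED files with the asymmetric similarity matrix
#'
#' @param cmu_beds character vector of contiguous-CMU BED paths; names (or
#'   basenames) become dataset labels.
#' @param out_path output TSV for the score matrix.
#' @return the `asymmetric_similarity_matrix`, invisibly.
#' @export
run_compare <- function(cmu_beds, out_path) {
  labels <- if (!is.null(names(cmu_beds))) names(cmu_beds)
            else sub("\\.bed$", "", basename(cmu_beds))
  sets <- Map(read_cmu_bed, cmu_beds, labels)
  names(sets) <- labels
  sm <- similarity_matrix(sets)
  df <- data.frame(dataset = rownames(sm$scores), sm$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, out_path)
  invisible(sm)
}

#' Call tissue-independent regions from per-tissue CMU BED files
#'
#' @param cmu_beds named character vector (names = tissue labels) of
#'   contiguous-CMU BED paths.
#' @param out_path output BED (support count in the score column).
#' @param threshold TI support fraction (strictly exceeded; default 0.8).
#' @param min_cpgs probe-count filter (ignored for BED input, where probe
#'   counts are unknown).
#' @param exclude_bed optional BED of regions to exclude (e.g. HLA).
#' @return the `ti_regions` data.frame, invisibly.
#' @export
run_ti <- function(cmu_beds, out_path, threshold = 0.8, min_cpgs = 10L,
                   exclude_bed = NULL) {
  labels <- if (!is.null(names(cmu_beds))) names(cmu_beds)
            else sub("\\.bed$", "", basename(cmu_beds))
  sets <- Map(read_cmu_bed, cmu_beds, labels, labels)
  exclude <- NULL
  if (!is.null(exclude_bed)) {
    df <- utils::read.table(exclude_bed, sep = "\t",
                            stringsAsFactors = FALSE)
    exclude <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]])
  }
  ti <- ti_contiguous_regions(unname(sets), ti_threshold = threshold,
                              min_cpgs = min_cpgs, exclude = exclude)
  atomic_write(out_path, function(p) write_ti_bed(ti, p))
  invisible(ti)
}

#' Feature-enrichment run over a CMU BED
#'
#' @param cmus_bed contiguous-CMU BED.
#' @param features_bed BED with a feature-class column (4th).
#' @param manifest_path manifest TSV.
#' @param out_path output TSV (one row per feature class).
#' @param test `"region"` or `"probe"`. The probe test treats the probes
#'   inside CMU regions as the CMU probe set.
#' @param reps background replicates for the region test.
#' @param seed RNG seed for background sampling.
#' @return data.frame of results, invisibly.
#' @export
run_enrich <- function(cmus_bed, features_bed, manifest_path, out_path,
                       test = c("region", "probe"), reps = 10000L,
                       seed = 1L) {
  test <- match.arg(test)
  manifest <- read_manifest(manifest_path)
  cmus <- read_cmu_bed(cmus_bed)$contiguous
  features <- read_features_bed(features_bed)
  rows <- lapply(features, function(feat) {
    if (test == "region") {
      r <- region_enrichment(cmus, feat, manifest, n_reps = reps,
                             rng_seed = seed)
      data.frame(feature_class = r$feature_class, test = r$test,
                 observed = r$observed, background_mean = r$background_mean,
                 background_sd = r$background_sd, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    } else {
      ov <- GenomicRanges::countOverlaps(manifest_granges(manifest),
                                         cmu_granges(cmus)) > 0L
      r <- probe_feature_test(manifest$probe_id[ov], manifest$probe_id,
                              feat, manifest)
      data.frame(feature_class = r$feature_class, test = r$test,
                 observed = r$table[1, 1], background_mean = NA_real_,
                 background_sd = NA_real_, p_value = r$p_value,
                 odds_ratio = r$odds_ratio, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write_tsv(out, out_path)
  invisible(out)
}

#' Case-control differential-correlation run
#'
#' @param beta_cases_path,beta_controls_path beta TSVs for the two groups.
#' @param manifest_path manifest TSV.
#' @param out_dir output directory.
#' @param covariates_path optional covariate TSV (sample_id + columns)
#'   applied per group via [residualize()].
#' @param mu Wilcoxon shift.
#' @param alpha ICM cutoff for the group scans.
#' @param alpha_sig significance level on corrected p-values.
#' @return the `differential_result`, invisibly. Writes
#'   `differential_cmus.tsv` (volcano-ready: effect size and -log10
#'   corrected p) and `diff_runlog.json`.
#' @export
run_diff <- function(beta_cases_path, beta_controls_path, manifest_path,
                     out_dir, covariates_path = NULL, mu = 0.1,
                     alpha = 0.6, alpha_sig = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- read_manifest(manifest_path)
  cases <- read_beta_matrix(beta_cases_path, manifest)
  controls <- read_beta_matrix(beta_controls_path, manifest)
  prep <- function(x) {
    y <- inverse_normal_transform(x)
    if (!is.null(covariates_path)) {
      cov <- read_delim_auto(covariates_path)
      y <- residualize(y, covariate_design(cov, rownames(y)))
    }
    y
  }
  res <- differential_cmus(prep(cases), prep(controls), manifest,
                           params = icm_params(alpha = alpha), mu = mu,
                           alpha_sig = alpha_sig,
                           group_labels = c("cases", "controls"))
  tab <- as.data.frame(res)
  tab$probes <- NULL
  tab$neglog10_p_wilcox_bonf <- -log10(pmax(tab$p_wilcox_bonf,
                                            .Machine$double.xmin))
  write_tsv(tab, file.path(out_dir, "differential_cmus.tsv"))
  write_run_log(out_dir, "diff",
                list(beta_cases = beta_cases_path,
                     beta_controls = beta_controls_path,
                     manifest = manifest_path,
                     covariates = covariates_path, mu = mu, alpha = alpha,
                     alpha_sig = alpha_sig),
                list(n_units = nrow(tab),
                     n_significant = sum(tab$significant)))
  invisible(res)
}
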