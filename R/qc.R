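#' Variant / array filter configuration
#'
#' Thresholds for resequencing-variant filtering and SNP-array trimming.
#' Defaults: site QUAL >= 20, site missingness <= 0.2, per-genotype depth
#' within 1/3x to 2x of the sample's median depth (`depth_mode =
#' "sample"`) or absolute bounds on mean site depth (`depth_mode =
#' "site"`); array: minor-allele frequency >= 0.01, locus and sample
#' missingness <= 0.1.
#'
#' @param min_qual minimum site quality score.
#' @param repeat_mask `GRanges` of repeat intervals to exclude (or NULL).
#' @param depth_mode `"sample"` (relative, per-sample bounds) or `"site"`.
#' @param depth_rel relative bounds on per-genotype depth as multiples of
#'   the sample median (used when `depth_mode = "sample"`).
#' @param depth_abs absolute bounds on mean site depth (`depth_mode = "site"`).
#' @param max_missing maximum fraction of missing genotypes per site; also
#'   the tolerated fraction of out-of-depth-bounds genotypes.
#' @param array_min_maf,array_max_locus_missing,array_max_sample_missing
#'   array-trimming thresholds.
#' @export
filter_config <- function(min_qual = 20,
                          repeat_mask = NULL,
                          depth_mode = c("sample", "site"),
                          depth_rel = c(1 / 3, 2),
                          depth_abs = c(3, 100),
                          max_missing = 0.2,
                          array_min_maf = 0.01,
                          array_max_locus_missing = 0.1,
                          array_max_sample_missing = 0.1) {
  depth_mode <- match.arg(depth_mode)
  stopifnot(depth_rel[1] < depth_rel[2], depth_abs[1] < depth_abs[2],
            max_missing >= 0, max_missing <= 1,
            array_min_maf >= 0, array_min_maf <= 0.5)
  structure(list(min_qual = min_qual, repeat_mask = repeat_mask,
                 depth_mode = depth_mode, depth_rel = depth_rel,
                 depth_abs = depth_abs, max_missing = max_missing,
                 array_min_maf = array_min_maf,
                 array_max_locus_missing = array_max_locus_missing,
                 array_max_sample_missing = array_max_sample_missing),
            class = "filter_config")
}

#' Filter resequencing variants
#'
#' Applies, in this fixed order: (1) site quality, (2) repeat-interval
#' overlap, (3) depth bounds, (4) genotype missingness. A site survives iff
#' it passes all four. The report telescopes: each stage's input count is
#' the previous stage's output count.
#'
#' @param vt a [variant_table()].
#' @param cfg a [filter_config()].
#' @return list with elements `table` (filtered [variant_table()]) and
#'   `report` (data.frame with columns `stage`, `n_in`, `n_out`, `n_dropped`).
#' @export
filter_variants <- function(vt, cfg = filter_config()) {
  n0 <- nrow(vt$sites)
  pass_qual <- !is.na(vt$sites$qual) & vt$sites$qual >= cfg$min_qual
  pass_repeat <- if (is.null(cfg$repeat_mask) || length(cfg$repeat_mask) == 0) {
    rep(TRUE, n0)
  } else {
    !positions_in_mask(cfg$repeat_mask, vt$sites$scaffold, vt$sites$pos)
  }
  if (is.null(vt$dp)) {
    pass_depth <- rep(TRUE, n0)
  } else if (cfg$depth_mode == "site") {
    md <- rowMeans(vt$dp, na.rm = TRUE)
    pass_depth <- !is.na(md) & md >= cfg$depth_abs[1] & md <= cfg$depth_abs[2]
  } else {
    sample_med <- apply(vt$dp, 2, stats::median, na.rm = TRUE)
    lo <- matrix(sample_med * cfg$depth_rel[1], nrow = n0, ncol = ncol(vt$dp),
                 byrow = TRUE)
    hi <- matrix(sample_med * cfg$depth_rel[2], nrow = n0, ncol = ncol(vt$dp),
                 byrow = TRUE)
    out_of_bounds <- is.na(vt$dp) | vt$dp < lo | vt$dp > hi
    pass_depth <- rowMeans(out_of_bounds) <= cfg$max_missing
  }
  pass_missing <- rowMeans(is.na(vt$gt)) <= cfg$max_missing
  stages <- list(quality = pass_qual, repeats = pass_repeat,
                 depth = pass_depth, missingness = pass_missing)
  keep <- rep(TRUE, n0)
  report <- data.frame(stage = names(stages), n_in = NA_integer_,
                       n_out = NA_integer_, n_dropped = NA_integer_)
  for (i in seq_along(stages)) {
    report$n_in[i] <- sum(keep)
    keep <- keep & stages[[i]]
    report$n_out[i] <- sum(keep)
    report$n_dropped[i] <- report$n_in[i] - report$n_out[i]
  }
  list(table = vt[which(keep), ], report = report)
}

#' Quality-trim an array genotype matrix
#'
#' Drops loci with minor-allele frequency below `array_min_maf` or locus
#' missingness above `array_max_locus_missing`, then samples with
#' missingness above `array_max_sample_missing` (deterministic order:
#' loci first, then samples).
#'
#' @param gt loci x samples dosage matrix (0/1/2/NA).
#' @param cfg a [filter_config()].
#' @return list `gt` (trimmed matrix), `kept_loci`, `kept_samples`,
#'   `report` (telescoping stage counts for loci and samples).
#' @export
array_qc <- function(gt, cfg = filter_config()) {
  gt <- as.matrix(gt)
  p <- rowMeans(gt, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  locus_miss <- rowMeans(is.na(gt))
  keep_loci <- maf >= cfg$array_min_maf & locus_miss <= cfg$array_max_locus_missing
  if (!any(keep_loci)) {
    return(list(gt = gt[0, , drop = FALSE], kept_loci = integer(0),
                kept_samples = seq_len(ncol(gt)), empty = TRUE,
                report = data.frame(stage = c("locus_maf_missing", "sample_missing"),
                                    n_in = c(nrow(gt), ncol(gt)),
                                    n_out = c(0L, ncol(gt)))))
  }
  g2 <- gt[keep_loci, , drop = FALSE]
  sample_miss <- colMeans(is.na(g2))
  keep_samples <- sample_miss <= cfg$array_max_sample_missing
  report <- data.frame(stage = c("locus_maf_missing", "sample_missing"),
                       n_in = c(nrow(gt), ncol(gt)),
                       n_out = c(sum(keep_loci), sum(keep_samples)))
  list(gt = g2[, keep_samples, drop = FALSE],
       kept_loci = which(keep_loci),
       kept_samples = which(keep_samples),
       empty = FALSE, report = report)
}

#' Compute a callable mask from per-position depth
#'
#' A position is callable iff the fraction of samples whose depth lies
#' within bounds (and whose genotype call is non-missing, when a genotype
#' matrix is given) is at least `min_fraction`. Positions are supplied
#' explicitly, so the function applies equally to exhaustive per-base
#' depth tables or to subsampled ones.
#'
#' @param scaffold,pos vectors describing the assayed positions (1-based).
#' @param depth positions x samples depth matrix.
#' @param cfg a [filter_config()]; depth bounds follow `cfg$depth_mode`.
#' @param min_fraction minimum fraction of samples that must pass.
#' @param windows optional window tiling; when given, per-window callable
#'   counts are returned alongside the mask.
#' @return list `mask` (`GRanges`), and `window_counts` when `windows`
#'   was supplied.
#' @export
compute_callable_mask <- function(scaffold, pos, depth, cfg = filter_config(),
                                  min_fraction = 0.8, windows = NULL) {
  depth <- as.matrix(depth)
  if (cfg$depth_mode == "site") {
    ok <- depth >= cfg$depth_abs[1] & depth <= cfg$depth_abs[2]
  } else {
    sample_med <- apply(depth, 2, stats::median, na.rm = TRUE)
    lo <- matrix(sample_med * cfg$depth_rel[1], nrow = nrow(depth),
                 ncol = ncol(depth), byrow = TRUE)
    hi <- matrix(sample_med * cfg$depth_rel[2], nrow = nrow(depth),
                 ncol = ncol(depth), byrow = TRUE)
    ok <- depth >= lo & depth <= hi
  }
  ok[is.na(ok)] <- FALSE
  callable <- rowMeans(ok) >= min_fraction
  if (!any(callable)) {
    mask <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(scaffold[callable],
                                 IRanges::IRanges(pos[callable], pos[callable]))
    mask <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  }
  out <- list(mask = mask)
  if (!is.null(windows)) out$window_counts <- window_callable_counts(mask, windows)
  out
}
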