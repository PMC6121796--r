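#' Rank differentiated windows and variants
#'
#' Selects the top fraction of windows by weighted F_ST (among windows
#' passing both the callable-site and SNP-count filters; ties broken by
#' scaffold then start coordinate) and the variants at or above an F_ST
#' threshold, and counts how many of each fall inside a set of declared
#' regions.
#'
#' @param ws a `window_stats` table from [compute_window_stats()].
#' @param fst_sites variant-level F_ST from [site_fst()].
#' @param top_frac fraction of filtered windows to report (default 0.01).
#' @param fst_threshold variant threshold (default 0.7).
#' @param regions optional `GRanges` of declared divergent regions.
#' @param include_partial include partial terminal windows (default FALSE).
#' @return list `top_windows` (data.frame), `high_fst_variants`
#'   (data.frame), and `counts` (inside/outside the regions).
#' @export
rank_windows <- function(ws, fst_sites, top_frac = 0.01, fst_threshold = 0.7,
                         regions = NULL, include_partial = FALSE) {
  eligible <- ws[ws$pass_callable & ws$pass_snps & !is.na(ws$fst) &
                   (include_partial | !ws$partial), , drop = FALSE]
  k <- max(1L, floor(nrow(eligible) * top_frac))
  ord <- order(-eligible$fst, eligible$scaffold, eligible$start)
  top <- eligible[ord[seq_len(min(k, nrow(eligible)))], , drop = FALSE]
  hi <- fst_sites[!is.na(fst_sites$fst) & fst_sites$fst >= fst_threshold, ,
                  drop = FALSE]
  counts <- NULL
  if (!is.null(regions)) {
    win_in <- if (nrow(top)) {
      suppressWarnings(IRanges::overlapsAny(
        GenomicRanges::GRanges(top$scaffold,
                               IRanges::IRanges(top$start + 1, top$end)),
        regions))
    } else logical(0)
    var_in <- if (nrow(hi)) {
      positions_in_mask(regions, hi$scaffold, hi$pos)
    } else logical(0)
    counts <- data.frame(what = c("top_windows", "high_fst_variants"),
                         inside = c(sum(win_in), sum(var_in)),
                         outside = c(sum(!win_in), sum(!var_in)))
    top$in_region <- win_in
    hi$in_region <- var_in
  }
  list(top_windows = top, high_fst_variants = hi, counts = counts)
}

#' Read a gene-feature table
#'
#' TSV with columns `scaffold`, `start`, `end` (1-based inclusive span),
#' `strand` (`+`/`-`), `gene`.
#' @param path TSV path.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scaffold", "start", "end", "strand", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table missing columns: ", paste(miss, collapse = ", "))
  df[order(df$scaffold, df$start), ]
}

#' Distance and orientation of windows/variants to the nearest gene
#'
#' For each query interval, the nearest feature on the same scaffold and
#' the signed relation: `"inside"` (overlap, distance 0), `"upstream"` or
#' `"downstream"` relative to the feature's transcriptional orientation,
#' or `"none"` if the scaffold has no features.
#'
#' @param query data.frame with `scaffold`, `start`, `end` (0-based
#'   half-open, as windows) or `scaffold`, `pos` for point queries.
#' @param features a feature table from [read_features()].
#' @return data.frame with `gene`, `distance`, `relation` per query row.
#' @export
nearest_feature <- function(query, features) {
  if (!"start" %in% names(query) && "pos" %in% names(query)) {
    query <- data.frame(scaffold = query$scaffold, start = query$pos - 1,
                        end = query$pos)
  }
  qgr <- GenomicRanges::GRanges(query$scaffold,
                                IRanges::IRanges(query$start + 1, query$end))
  fgr <- GenomicRanges::GRanges(features$scaffold,
                                IRanges::IRanges(features$start, features$end))
  out <- data.frame(gene = NA_character_, distance = NA_real_,
                    relation = "none", stringsAsFactors = FALSE)
  out <- out[rep(1, length(qgr)), , drop = FALSE]
  rownames(out) <- NULL
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(qgr, fgr, ignore.strand = TRUE))
  if (length(hits) == 0) return(out)
  qi <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  d <- S4Vectors::mcols(hits)$distance
  out$gene[qi] <- features$gene[fi]
  out$distance[qi] <- d
  before <- query$end[qi] <= features$start[fi] - 1  # query entirely 5' of feature (genome axis)
  after <- query$start[qi] + 1 >= features$end[fi] + 1
  fwd <- features$strand[fi] == "+"
  rel <- rep("inside", length(qi))
  rel[d > 0 & ((before & fwd) | (after & !fwd))] <- "upstream"
  rel[d > 0 & ((after & fwd) | (before & !fwd))] <- "downstream"
  out$relation[qi] <- rel
  out
}

#' Divergence time from net divergence
#'
#' t = d_A / (2 * mu_year), evaluated over a configured range of per-year
#' substitution rates. The default range (1.5625e-9 to 3.333e-9
#' substitutions/site/year, spanning rates reported for other bird
#' genomes) maps a net divergence of 0.005 onto roughly 0.75-1.6 Myr.
#'
#' @param da net divergence (substitutions/site).
#' @param mu_year length-2 numeric range of substitution rates (> 0).
#' @return object of class `divergence_estimate`: list with `da`,
#'   `mu_year`, and `t_years` (range, ordered low-high).
#' @export
divergence_time <- function(da, mu_year = c(1.5625e-9, 3.3333e-9)) {
  if (any(mu_year <= 0)) stop("substitution rates must be positive")
  stopifnot(da >= 0)
  t <- sort(da / (2 * mu_year))
  structure(list(da = da, mu_year = sort(mu_year), t_years = t),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("d_A = %g; mu = [%.3g, %.3g] /site/year -> t = %.3g - %.3g Myr\n",
              x$da, x$mu_year[1], x$mu_year[2],
              x$t_years[1] / 1e6, x$t_years[2] / 1e6))
  invisible(x)
}
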