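#' Read a BED file of intervals into a callable mask
#'
#' BED intervals are 0-based half-open. Overlapping or bookended intervals
#' are merged and the result is sorted per scaffold. `track`/`browser`/`#`
#' lines are skipped.
#'
#' @param path BED file (>= 3 columns).
#' @return a [GenomicRanges::GRanges] holding the merged mask. An empty
#'   file yields an empty mask (total callable length 0).
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep)) return(GenomicRanges::GRanges())
  idx <- which(keep)
  f <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol_ok <- lengths(f) >= 3
  if (any(!ncol_ok)) stop("BED line ", idx[which(!ncol_ok)[1]], ": fewer than 3 columns")
  chrom <- vapply(f, `[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) stop("BED line ", idx[which(bad)[1]], ": non-numeric coordinates")
  if (any(end <= start)) {
    stop("BED line ", idx[which(end <= start)[1]], ": end <= start")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Write a mask to BED (0-based half-open)
#' @param mask a `GRanges` mask.
#' @param path output path.
#' @export
write_intervals <- function(mask, path) {
  if (length(mask) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(paste(as.character(GenomicRanges::seqnames(mask)),
                   GenomicRanges::start(mask) - 1,
                   GenomicRanges::end(mask), sep = "\t"), path)
  invisible(path)
}

#' Total number of callable bases in a mask
#' @param mask a `GRanges` mask.
#' @export
mask_total <- function(mask) sum(as.numeric(GenomicRanges::width(mask)))

#' Complement of a mask within a genome layout
#'
#' Used e.g. to turn a repeat-exclusion mask into a callable mask.
#' @param layout a [genome_layout()].
#' @param mask a `GRanges` mask (possibly empty).
#' @export
mask_complement <- function(layout, mask) {
  genome <- GenomicRanges::GRanges(layout$scaffold,
                                   IRanges::IRanges(1, layout$length))
  GenomicRanges::setdiff(genome, mask)
}

#' Per-window callable-site counts
#'
#' Intersects a callable mask with a window tiling and returns the number
#' of callable bases per window (0 for windows outside the mask).
#' @param mask a `GRanges` callable mask.
#' @param windows output of [make_windows()].
#' @return numeric vector, one count per row of `windows`.
#' @export
window_callable_counts <- function(mask, windows) {
  wgr <- GenomicRanges::GRanges(windows$scaffold,
                                IRanges::IRanges(windows$start + 1, windows$end))
  counts <- numeric(nrow(windows))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(wgr, mask))
  if (length(hits)) {
    pint <- GenomicRanges::pintersect(wgr[S4Vectors::queryHits(hits)],
                                      mask[S4Vectors::subjectHits(hits)])
    w <- as.numeric(GenomicRanges::width(pint))
    agg <- rowsum(w, S4Vectors::queryHits(hits))
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  counts
}

#' Which positions fall inside a mask?
#' @param mask a `GRanges` mask.
#' @param scaffold,pos vectors of scaffold names and 1-based positions.
#' @return logical vector.
#' @export
positions_in_mask <- function(mask, scaffold, pos) {
  if (length(mask) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(pos, pos))
  suppressWarnings(IRanges::overlapsAny(q, mask))
}
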