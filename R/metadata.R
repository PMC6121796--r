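#' Read sample metadata from TSV
#'
#' Required columns: `sample`, `site`, `lat`, `lon`, `altitude`, `sex`,
#' `d15N`, `wing`, `tarsus`, `bill_head`, `color`. Phenotype cells may be
#' empty/NA and are preserved as missing. The color score, when present,
#' must lie in 1..9.
#'
#' @param path TSV file with a header.
#' @return data.frame of typed records.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample", "site", "lat", "lon", "altitude", "sex",
            "d15N", "wing", "tarsus", "bill_head", "color")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  for (col in c("lat", "lon", "altitude", "d15N", "wing", "tarsus", "bill_head", "color")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- !is.na(df$color) & (df$color < 1 | df$color > 9)
  if (any(bad)) {
    stop("color score out of range 1-9 for sample(s): ",
         paste(df$sample[bad], collapse = ", "))
  }
  df
}

#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.window_stat_cols <- c("scaffold", "start", "end", "index", "partial",
                       "n_snps", "n_callable", "fst", "pi_S", "pi_N",
                       "tajima_D_S", "tajima_D_N", "dxy", "da",
                       "pass_callable", "pass_snps")

#' Write a window-statistics table to TSV
#'
#' One row per window in a fixed column order; statistics of windows that
#' fail the callable-site filter are written as `NA` together with their
#' filter flags, so the full tiling is always recoverable.
#' @param ws window-statistics data.frame from [compute_window_stats()].
#' @param path output path.
#' @export
write_window_stats <- function(ws, path) {
  stopifnot(nrow(ws) > 0)
  cols <- intersect(.window_stat_cols, names(ws))
  utils::write.table(ws[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a window-statistics table written by [write_window_stats()]
#' @param path TSV path.
#' @export
read_window_stats <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}
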