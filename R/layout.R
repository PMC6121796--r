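#' Genome layout: scaffolds, lengths, chromosome assignment
#'
#' A `genome_layout` records the scaffolds of an assembly, their lengths,
#' the chromosome each has been assigned to (`"Un"` for unplaced) and a
#' cumulative offset used for concatenated ("Manhattan") plotting.
#' Offsets accumulate in the order scaffolds are supplied, chromosome by
#' chromosome, and are strictly increasing within a chromosome.
#'
#' @param scaffold character vector of unique scaffold names.
#' @param length integer vector of scaffold lengths in bp (> 0).
#' @param chromosome chromosome label per scaffold; default `"Un"`.
#' @return A `data.frame` of class `genome_layout` with columns
#'   `scaffold`, `length`, `chromosome`, `offset`.
#' @export
genome_layout <- function(scaffold, length, chromosome = "Un") {
  scaffold <- as.character(scaffold)
  length <- as.numeric(length)
  chromosome <- rep_len(as.character(chromosome), base::length(scaffold))
  if (anyDuplicated(scaffold)) {
    stop("duplicate scaffold names: ",
         paste(unique(scaffold[duplicated(scaffold)]), collapse = ", "))
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("scaffold lengths must be positive")
  }
  ord <- order(match(chromosome, unique(chromosome)))
  df <- data.frame(scaffold = scaffold[ord], length = length[ord],
                   chromosome = chromosome[ord], stringsAsFactors = FALSE)
  df$offset <- cumsum(c(0, df$length[-nrow(df)]))
  class(df) <- c("genome_layout", "data.frame")
  df
}

#' Read a genome layout from a TSV file
#'
#' Expects columns `scaffold`, `length` and optionally `chromosome`.
#' @param path file path.
#' @return a [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("scaffold", "length") %in% names(df))) {
    stop("layout file must have columns 'scaffold' and 'length'")
  }
  chrom <- if ("chromosome" %in% names(df)) df$chromosome else "Un"
  genome_layout(df$scaffold, df$length, chrom)
}

#' @export
write_genome_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout)[c("scaffold", "length", "chromosome")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tile a genome into non-overlapping windows
#'
#' Windows use 0-based half-open coordinates and tile each scaffold from 0.
#' A terminal window shorter than `size` is emitted and flagged `partial`;
#' downstream summaries exclude partial windows by default.
#'
#' @param layout a [genome_layout()].
#' @param size window size in bp (default 10 kb).
#' @return data.frame with columns `scaffold`, `start`, `end`, `index`,
#'   `partial`.
#' @export
make_windows <- function(layout, size = 10000) {
  stopifnot(size > 0)
  out <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    start <- seq(0, len - 1, by = size)
    end <- pmin(start + size, len)
    data.frame(scaffold = layout$scaffold[i], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$index <- seq_len(nrow(out))
  out$partial <- (out$end - out$start) < size
  out
}

#' Map 1-based positions onto window indices
#'
#' A VCF position `p` (1-based) on a scaffold tiled from 0 with windows of
#' `size` bp falls in window number `floor((p - 1)/size)` on that scaffold.
#'
#' @param windows output of [make_windows()].
#' @param scaffold,pos vectors of scaffold names and 1-based positions.
#' @return integer vector of row indices into `windows` (NA if the
#'   position falls outside the tiling).
#' @export
assign_windows <- function(windows, scaffold, pos) {
  size <- max(windows$end - windows$start)
  key <- paste(windows$scaffold, windows$start %/% size)
  q <- paste(scaffold, (pos - 1) %/% size)
  match(q, key)
}
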