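#' Construct a variant table
#'
#' The central substrate of all statistics: a sites-by-samples diploid
#' genotype matrix (alt-allele dosage 0/1/2, `NA` = missing) plus per-site
#' metadata. Positions are 1-based, as in VCF; they are converted to
#' 0-based half-open window coordinates only at window-assignment time.
#'
#' @param sites data.frame with columns `scaffold`, `pos` (1-based),
#'   `ref`, `alt` (comma-separated when multiallelic), `qual`, and logical
#'   flags `is_snp`, `is_biallelic`.
#' @param gt integer matrix, sites x samples, values 0/1/2/NA. For
#'   multiallelic sites the dosage refers to the first alternate allele;
#'   indel dosages code presence/absence of the alternate allele.
#' @param samples character vector of sample ids (columns of `gt`).
#' @param pop named character vector mapping sample id to population label
#'   (`"southern"`, `"northern"`, `"unknown"`).
#' @param dp optional matrix of per-genotype read depths, same shape as `gt`.
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, samples, pop = NULL, dp = NULL) {
  gt <- as.matrix(gt)
  stopifnot(nrow(sites) == nrow(gt), length(samples) == ncol(gt))
  need <- c("scaffold", "pos", "ref", "alt", "qual", "is_snp", "is_biallelic")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  # positions strictly increasing within scaffold
  sp <- split(sites$pos, sites$scaffold)
  if (any(vapply(sp, function(p) any(diff(p) <= 0), logical(1)))) {
    stop("positions must be strictly increasing within each scaffold")
  }
  if (is.null(pop)) pop <- setNames(rep("unknown", length(samples)), samples)
  unknown <- setdiff(names(pop), samples)
  if (length(unknown)) {
    stop("population map names samples absent from the table: ",
         paste(unknown, collapse = ", "))
  }
  pop <- setNames(ifelse(samples %in% names(pop), pop[samples], "unknown"), samples)
  colnames(gt) <- samples
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    stopifnot(all(dim(dp) == dim(gt)))
    colnames(dp) <- samples
  }
  structure(list(sites = as.data.frame(sites), gt = gt, dp = dp,
                 samples = samples, pop = pop),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%d biallelic SNPs)\n",
              nrow(x$sites), length(x$samples), sum(x$sites$is_biallelic & x$sites$is_snp)))
  cat("populations:", paste(sprintf("%s=%d", names(table(x$pop)), table(x$pop)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a variant table by sites and/or samples
#' @param x a `variant_table`; `i` site indices, `j` sample indices/names.
#' @param i,j,... index vectors.
#' @export
`[.variant_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(j)) j <- match(j, x$samples)
  variant_table(x$sites[i, , drop = FALSE],
                x$gt[i, j, drop = FALSE],
                x$samples[j],
                x$pop[j],
                if (!is.null(x$dp)) x$dp[i, j, drop = FALSE])
}

#' Biallelic-SNP view of a variant table
#'
#' All windowed statistics operate on this view; multiallelic sites and
#' indels are retained in the full table (and in variant-level F_ST lists)
#' but never enter windowed estimates.
#' @param vt a [variant_table()].
#' @export
biallelic_snps <- function(vt) {
  vt[which(vt$sites$is_snp & vt$sites$is_biallelic), ]
}

.gt_string_to_dosage <- function(g) {
  # g: character matrix of GT strings ("0/1", "1|1", "./.", NA)
  g <- gsub("\\|", "/", g)
  al <- strsplit(g, "/", fixed = TRUE)
  d <- vapply(al, function(a) {
    if (length(a) != 2 || any(a == ".") || anyNA(a)) return(NA_integer_)
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a) || any(a > 1)) return(NA_integer_)  # non-first-alt alleles -> missing dosage
    sum(a)
  }, integer(1))
  matrix(d, nrow = nrow(g), dimnames = dimnames(g))
}

#' Read a VCF file into a variant table
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and converts genotypes to
#' alt-allele dosages. Multiallelic records and indels are retained and
#' flagged; [biallelic_snps()] gives the analysis view. Genotypes coded
#' `./.` are missing and contribute to no allele total.
#'
#' @param path VCF file (plain or gzipped).
#' @param population_map optional named character vector sample -> label;
#'   every name must be a sample of the file.
#' @return a [variant_table()].
#' @export
read_variant_table <- function(path, population_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    stop("malformed VCF record (non-numeric POS) at data line ",
         which(is.na(pos))[1])
  }
  alt <- fix$ALT
  ref <- fix$REF
  nalt <- lengths(strsplit(alt, ",", fixed = TRUE))
  is_biallelic <- nalt == 1
  alt1 <- vapply(strsplit(alt, ",", fixed = TRUE), `[`, character(1), 1)
  is_snp <- nchar(ref) == 1 & nchar(alt1) == 1 & alt1 != "*"
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  gt_str <- vcfR::extract.gt(v, element = "GT")
  gt <- .gt_string_to_dosage(gt_str)
  dp <- NULL
  fmt_ids <- tryCatch(vcfR::vcf_field_names(v, tag = "FORMAT")$ID,
                      error = function(e) character())
  if ("DP" %in% fmt_ids) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  }
  samples <- colnames(gt)
  if (!is.null(population_map)) {
    bad <- setdiff(names(population_map), samples)
    if (length(bad)) {
      stop("population_map contains samples not in the VCF: ",
           paste(bad, collapse = ", "))
    }
  }
  sites <- data.frame(scaffold = fix$CHROM, pos = pos, ref = ref, alt = alt,
                      qual = qual, is_snp = is_snp, is_biallelic = is_biallelic,
                      stringsAsFactors = FALSE)
  variant_table(sites, gt, samples, population_map, dp)
}

#' Write a variant table to a minimal VCF 4.2 file
#'
#' Round-trips through [read_variant_table()]: dosage 0/1/2 is written as
#' unphased `0/0`, `0/1`, `1/1`, `NA` as `./.`; depths go into the `DP`
#' FORMAT field when present.
#' @param vt a [variant_table()].
#' @param path output path.
#' @param layout optional [genome_layout()] used to emit `##contig` headers.
#' @export
write_variant_vcf <- function(vt, path, layout = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  has_dp <- !is.null(vt$dp)
  if (has_dp) {
    hdr <- c(hdr, '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  }
  if (!is.null(layout)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", layout$scaffold,
                          as.integer(layout$length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "FORMAT"), collapse = "\t"))
  hdr[length(hdr)] <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", vt$samples),
                            collapse = "\t")
  gtc <- matrix(c("0/0", "0/1", "1/1")[vt$gt + 1L], nrow = nrow(vt$gt))
  gtc[is.na(vt$gt)] <- "./."
  if (has_dp) {
    dpc <- ifelse(is.na(vt$dp), ".", as.character(vt$dp))
    gtc <- matrix(paste(gtc, dpc, sep = ":"), nrow = nrow(gtc))
  }
  body <- paste(vt$sites$scaffold, vt$sites$pos, ".", vt$sites$ref,
                vt$sites$alt, formatC(vt$sites$qual, format = "g"), "PASS", ".",
                if (has_dp) "GT:DP" else "GT",
                apply(gtc, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Combine variant tables over disjoint site sets (same samples)
#' @param ... variant tables sharing identical sample vectors.
#' @export
rbind_variant_tables <- function(...) {
  vts <- list(...)
  if (length(vts) == 1 && is.list(vts[[1]]) && !inherits(vts[[1]], "variant_table")) {
    vts <- vts[[1]]
  }
  samples <- vts[[1]]$samples
  for (v in vts) stopifnot(identical(v$samples, samples))
  sites <- do.call(rbind, lapply(vts, `[[`, "sites"))
  gt <- do.call(rbind, lapply(vts, `[[`, "gt"))
  dps <- lapply(vts, `[[`, "dp")
  dp <- if (all(!vapply(dps, is.null, logical(1)))) do.call(rbind, dps) else NULL
  variant_table(sites, gt, samples, vts[[1]]$pop, dp)
}
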