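#' Per-site Weir-Cockerham F_ST variance components
#'
#' Moment estimator for two alleles and `r` populations: among-population
#' (a), among-individual-within-population (b) and within-individual (c)
#' variance components, with the point estimate a/(a+b+c). Sites that are
#' monomorphic across all populations have a zero denominator and an
#' undefined (NA) estimate -- they are never coerced to 0. Negative
#' estimates are retained.
#'
#' @param gt sites x samples dosage matrix (0/1/2/NA).
#' @param pop factor (or coercible) of population labels per sample;
#'   at least two populations with data are required per site.
#' @return data.frame with columns `a`, `b`, `c`, `fst`.
#' @export
wc_fst_site <- function(gt, pop) {
  gt <- rbind(gt)  # tolerate a single-site vector
  pop <- factor(pop)
  pops <- levels(pop)
  if (length(pops) < 2) stop("need at least two populations")
  nmat <- pmat <- hmat <- matrix(0, nrow(gt), length(pops))
  for (k in seq_along(pops)) {
    sub <- gt[, pop == pops[k], drop = FALSE]
    nmat[, k] <- rowSums(!is.na(sub))
    pmat[, k] <- rowMeans(sub, na.rm = TRUE) / 2
    hmat[, k] <- rowMeans(sub == 1, na.rm = TRUE)
  }
  occupied <- rowSums(nmat > 0)
  r <- occupied  # populations actually observed at the site
  ntot <- rowSums(nmat)
  nbar <- ntot / r
  nc <- (ntot - rowSums(nmat^2) / ntot) / (r - 1)
  pmat0 <- pmat; pmat0[nmat == 0] <- 0
  hmat0 <- hmat; hmat0[nmat == 0] <- 0
  pbar <- rowSums(nmat * pmat0) / ntot
  s2 <- rowSums(nmat * (pmat0 - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * hmat0) / ntot
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  denom <- a + b + cc
  fst <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, fst = fst)
}

#' Variant-level F_ST for a variant table
#'
#' Computes [wc_fst_site()] for every site. Windowed statistics use only
#' biallelic SNPs, but the variant-level list can keep indels (their
#' dosages code presence/absence of the alternate allele).
#'
#' @param vt a [variant_table()].
#' @param populations which population labels to contrast (default the
#'   labels `"southern"` and `"northern"`).
#' @param include_indels keep non-SNP biallelic variants in the output.
#' @return data.frame `scaffold`, `pos`, `is_snp`, `a`, `b`, `c`, `fst`.
#' @export
site_fst <- function(vt, populations = c("southern", "northern"),
                     include_indels = TRUE) {
  keep_samples <- which(vt$pop %in% populations)
  if (length(keep_samples) == 0) stop("no samples in the requested populations")
  keep_sites <- vt$sites$is_biallelic & (vt$sites$is_snp | include_indels)
  sub <- vt[which(keep_sites), keep_samples]
  comp <- wc_fst_site(sub$gt, factor(sub$pop, levels = populations))
  cbind(sub$sites[c("scaffold", "pos", "is_snp")], comp)
}

#' Weighted window F_ST (ratio of sums)
#'
#' The weighted average over a window is `sum(a) / sum(a + b + c)` across
#' sites with defined components; with a single SNP it equals the
#' single-site estimate. Windows with fewer than `min_snps` SNPs are
#' flagged and excluded from F_ST summaries.
#'
#' @param fst_sites output of [site_fst()] restricted to biallelic SNPs.
#' @param windows a window tiling from [make_windows()].
#' @param min_snps minimum SNP count (default 25).
#' @return data.frame with per-window `n_snps`, `fst`, `pass_snps`.
#' @export
window_fst_weighted <- function(fst_sites, windows, min_snps = 25) {
  widx <- assign_windows(windows, fst_sites$scaffold, fst_sites$pos)
  ok <- !is.na(widx) & !is.na(fst_sites$a)
  num <- den <- nsnp <- numeric(nrow(windows))
  if (any(ok)) {
    num_agg <- rowsum(fst_sites$a[ok], widx[ok])
    den_agg <- rowsum(fst_sites$a[ok] + fst_sites$b[ok] + fst_sites$c[ok], widx[ok])
    n_agg <- rowsum(rep(1, sum(ok)), widx[ok])
    i <- as.integer(rownames(num_agg))
    num[i] <- num_agg[, 1]; den[i] <- den_agg[, 1]; nsnp[i] <- n_agg[, 1]
  }
  fst <- ifelse(den != 0, num / den, NA_real_)
  data.frame(index = windows$index, n_snps = nsnp, fst = fst,
             pass_snps = nsnp >= min_snps)
}
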