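# Windowed diversity and divergence. All estimators are genotype-based
# (unphased): per-site allele frequencies come from alt-allele dosages of
# the non-missing diploids, and pairwise-difference sums use the unbiased
# 2*p*q*n/(n-1) form with n the number of observed alleles at the site.

.site_freq <- function(gt) {
  n <- 2 * rowSums(!is.na(gt))
  p <- rowMeans(gt, na.rm = TRUE) / 2
  list(n = n, p = p)
}

# per-site sum of pairwise differences per pair, 2*p*q*n/(n-1); 0 where n < 2
.site_pi_terms <- function(gt) {
  f <- .site_freq(gt)
  term <- 2 * f$p * (1 - f$p) * f$n / (f$n - 1)
  term[f$n < 2] <- 0
  term
}

.window_sum <- function(x, widx, nwin) {
  out <- numeric(nwin)
  ok <- !is.na(widx) & !is.na(x)
  if (any(ok)) {
    agg <- rowsum(x[ok], widx[ok])
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Windowed nucleotide diversity
#'
#' pi per window = sum over biallelic SNPs of `2*p*q*n/(n-1)` divided by
#' the number of callable sites in the window; monomorphic callable sites
#' contribute 0 to the numerator and 1 to the denominator (they are part
#' of `callable`).
#'
#' @param vt a [variant_table()] (only its biallelic-SNP view is used).
#' @param samples sample ids forming the group.
#' @param windows window tiling.
#' @param callable per-window callable-site counts (same length as
#'   `nrow(windows)`); windows with 0 callable sites get `NA`.
#' @return numeric vector of per-window pi.
#' @export
window_pi <- function(vt, samples, windows, callable) {
  bs <- biallelic_snps(vt)
  gt <- bs$gt[, samples, drop = FALSE]
  terms <- .site_pi_terms(gt)
  widx <- assign_windows(windows, bs$sites$scaffold, bs$sites$pos)
  num <- .window_sum(terms, widx, nrow(windows))
  ifelse(callable > 0, num / callable, NA_real_)
}

#' Tajima (1989) coefficients
#'
#' The standard constants a1, a2, b1, b2, c1, c2, e1, e2 as functions of
#' the number of sequences `n` (here, 2x the diploid group size).
#' @param n number of sequences (>= 2; >= 4 for a usable D).
#' @return named list of coefficients, including `n`.
#' @export
tajima_coefficients <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1)), where `pi_total` is
#' the *total* (not per-callable-site) mean number of pairwise differences
#' in the window and S the number of segregating sites of the group.
#' Windows with S = 0 are undefined (`NA`) and excluded from means.
#' Coefficients use the nominal haplotype count n = 2x group size.
#'
#' @inheritParams window_pi
#' @return numeric vector of per-window D.
#' @export
window_tajimas_d <- function(vt, samples, windows) {
  bs <- biallelic_snps(vt)
  gt <- bs$gt[, samples, drop = FALSE]
  n <- 2 * length(samples)
  if (n < 4) stop("Tajima's D needs at least 4 haplotypes (2 diploids)")
  f <- .site_freq(gt)
  seg <- !is.na(f$p) & f$p > 0 & f$p < 1
  terms <- .site_pi_terms(gt)
  widx <- assign_windows(windows, bs$sites$scaffold, bs$sites$pos)
  S <- .window_sum(as.numeric(seg), widx, nrow(windows))
  pi_tot <- .window_sum(terms * seg, widx, nrow(windows))
  cf <- tajima_coefficients(n)
  denom <- sqrt(cf$e1 * S + cf$e2 * S * (S - 1))
  ifelse(S > 0, (pi_tot - S / cf$a1) / denom, NA_real_)
}

#' Windowed absolute and net divergence
#'
#' d_XY per window = sum over sites of `p_x(1-p_y) + p_y(1-p_x)` divided
#' by callable sites; d_A = d_XY - (pi_x + pi_y)/2 with the within-group
#' diversities computed on the same windows and callable counts, so the
#' identity holds exactly wherever all three are defined.
#'
#' @param vt a [variant_table()].
#' @param samples_x,samples_y sample ids of the two groups.
#' @inheritParams window_pi
#' @return data.frame with per-window `dxy`, `da`, `pi_x`, `pi_y`.
#' @export
window_dxy_da <- function(vt, samples_x, samples_y, windows, callable) {
  bs <- biallelic_snps(vt)
  fx <- .site_freq(bs$gt[, samples_x, drop = FALSE])
  fy <- .site_freq(bs$gt[, samples_y, drop = FALSE])
  dterm <- fx$p * (1 - fy$p) + fy$p * (1 - fx$p)
  dterm[fx$n == 0 | fy$n == 0] <- NA
  widx <- assign_windows(windows, bs$sites$scaffold, bs$sites$pos)
  dxy <- ifelse(callable > 0,
                .window_sum(dterm, widx, nrow(windows)) / callable, NA_real_)
  pi_x <- window_pi(vt, samples_x, windows, callable)
  pi_y <- window_pi(vt, samples_y, windows, callable)
  data.frame(dxy = dxy, da = dxy - (pi_x + pi_y) / 2, pi_x = pi_x, pi_y = pi_y)
}

#' Windowed differentiation, diversity and divergence table
#'
#' One-stop computation of the per-window statistics: SNP and callable
#' counts, weighted Weir-Cockerham F_ST between the two population labels,
#' nucleotide diversity and Tajima's D per group, and d_XY / d_A between
#' the groups. Windows with fewer than `min_callable` callable sites carry
#' `NA` statistics (flag `pass_callable`); windows with fewer than
#' `min_snps` SNPs carry their F_ST but are flagged for exclusion from
#' F_ST summaries (`pass_snps`). The diversity/divergence groups are
#' normally the "pure" southern/northern homozygous subsets identified by
#' [classify_region_genotypes()].
#'
#' @param vt a filtered [variant_table()].
#' @param windows window tiling from [make_windows()].
#' @param callable per-window callable-site counts.
#' @param groups list with sample-id vectors `S` and `N` for the
#'   diversity/divergence statistics.
#' @param populations the two population labels contrasted by F_ST.
#' @param min_callable,min_snps window filters (defaults 5000 and 25).
#' @return data.frame of class `window_stats`.
#' @export
compute_window_stats <- function(vt, windows, callable, groups,
                                 populations = c("southern", "northern"),
                                 min_callable = 5000, min_snps = 25) {
  stopifnot(length(callable) == nrow(windows), is.list(groups),
            all(c("S", "N") %in% names(groups)))
  bs <- biallelic_snps(vt)
  fst_sites <- site_fst(vt, populations, include_indels = FALSE)
  wfst <- window_fst_weighted(fst_sites, windows, min_snps)
  dd <- window_dxy_da(vt, groups$S, groups$N, windows, callable)
  out <- data.frame(windows,
                    n_snps = wfst$n_snps,
                    n_callable = callable,
                    fst = wfst$fst,
                    pi_S = dd$pi_x,
                    pi_N = dd$pi_y,
                    tajima_D_S = window_tajimas_d(vt, groups$S, windows),
                    tajima_D_N = window_tajimas_d(vt, groups$N, windows),
                    dxy = dd$dxy,
                    da = dd$da,
                    stringsAsFactors = FALSE)
  out$pass_callable <- out$n_callable >= min_callable
  out$pass_snps <- wfst$pass_snps
  statcols <- c("fst", "pi_S", "pi_N", "tajima_D_S", "tajima_D_N", "dxy", "da")
  out[!out$pass_callable, statcols] <- NA
  class(out) <- c("window_stats", "data.frame")
  out
}
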