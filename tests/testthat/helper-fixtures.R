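# Shared fixtures and independent oracles. The oracles deliberately use a
# different route than the package implementation (allele-level
# enumeration / ANOVA mean squares) so the two can disagree.

write_toy_vcf <- function(path, records,
                          samples = c("s1", "s2"),
                          with_dp = TRUE) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (with_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

make_vt <- function(gt, pop = NULL, scaffold = "sc1",
                    pos = NULL, qual = 50, dp = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(n) * 10
  samples <- colnames(gt)
  if (is.null(samples)) {
    samples <- sprintf("x%02d", seq_len(ncol(gt)))
    colnames(gt) <- samples
  }
  sites <- data.frame(scaffold = scaffold, pos = pos, ref = "A", alt = "T",
                      qual = qual, is_snp = TRUE, is_biallelic = TRUE,
                      stringsAsFactors = FALSE)
  variant_table(sites, gt, samples, pop, dp)
}

# --- oracles ---------------------------------------------------------------

# per-site allele lists from dosages, individuals with NA dropped
.allele_list <- function(g) {
  g <- g[!is.na(g)]
  unlist(lapply(g, function(d) c(rep(1L, d), rep(0L, 2L - d))))
}

# mean pairwise difference per site, summed over sites (total, not per-base)
oracle_pi_total <- function(gt) {
  sum(apply(rbind(gt), 1, function(g) {
    al <- .allele_list(g)
    n <- length(al)
    if (n < 2) return(0)
    pairs <- combn(n, 2)
    sum(al[pairs[1, ]] != al[pairs[2, ]]) / choose(n, 2)
  }))
}

# mean cross-group pairwise difference per site, summed over sites
oracle_dxy_total <- function(gt_x, gt_y) {
  gt_x <- rbind(gt_x); gt_y <- rbind(gt_y)
  sum(vapply(seq_len(nrow(gt_x)), function(i) {
    ax <- .allele_list(gt_x[i, ]); ay <- .allele_list(gt_y[i, ])
    if (!length(ax) || !length(ay)) return(NA_real_)
    mean(outer(ax, ay, "!="))
  }, numeric(1)))
}

# Weir-Cockerham components via the ANOVA mean-squares route
oracle_wc_site <- function(g, pop) {
  keep <- !is.na(g)
  g <- g[keep]; pop <- factor(pop[keep])
  pops <- levels(droplevels(pop))
  r <- length(pops)
  if (r < 2) return(c(a = NA, b = NA, c = NA))
  ni <- as.numeric(table(droplevels(pop)))
  ntot <- sum(ni)
  ybar_ind <- g / 2
  ybar_pop <- tapply(g, droplevels(pop), mean) / 2
  ybar <- mean(g) / 2
  # within-individual sum of squares: each individual has 2 alleles
  ssg <- sum(vapply(g, function(d) {
    al <- c(rep(1, d), rep(0, 2 - d))
    sum((al - mean(al))^2)
  }, numeric(1)))
  msg <- ssg / ntot
  ssi <- 2 * sum((ybar_ind - ybar_pop[as.character(droplevels(pop))])^2)
  msi <- ssi / (ntot - r)
  ssp <- 2 * sum(ni * (ybar_pop - ybar)^2)
  msp <- ssp / (r - 1)
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  c(a = (msp - msi) / (2 * nc), b = (msi - msg) / 2, c = msg)
}

oracle_tajima_d <- function(gt) {
  gt <- rbind(gt)
  n <- 2 * ncol(gt)
  p <- rowMeans(gt, na.rm = TRUE) / 2
  S <- sum(p > 0 & p < 1, na.rm = TRUE)
  if (S == 0) return(NA_real_)
  k <- oracle_pi_total(gt)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# exhaustive nearest-feature search
oracle_nearest <- function(q_start0, q_end0, q_scaffold, features) {
  best <- list(gene = NA, distance = NA, relation = "none")
  f <- features[features$scaffold == q_scaffold, ]
  if (nrow(f) == 0) return(best)
  q1 <- q_start0 + 1  # 1-based first base
  q2 <- q_end0        # 1-based last base
  d <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    if (q1 <= f$end[i] && q2 >= f$start[i]) d[i] <- 0
    else if (q2 < f$start[i]) d[i] <- f$start[i] - q2 - 1
    else d[i] <- q1 - f$end[i] - 1
  }
  i <- which.min(d)
  rel <- if (d[i] == 0) "inside"
  else if (q2 < f$start[i]) { if (f$strand[i] == "+") "upstream" else "downstream" }
  else { if (f$strand[i] == "+") "downstream" else "upstream" }
  list(gene = f$gene[i], distance = d[i], relation = rel)
}

haversine_km <- function(lat1, lon1, lat2, lon2, r = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(sqrt(a))
}
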