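# Genetic structure: genome-wide PCA, per-region MDS, and classification
# of samples into the three diploid haplotype classes (SS/NS/NN).

#' PCA of a genotype matrix with allele-frequency normalisation
#'
#' Loci are centered at twice their allele frequency and scaled by
#' `sqrt(p(1-p))` before the eigendecomposition (the normalisation
#' conventional for population-structure PCA); missing genotypes are
#' mean-imputed per locus; monomorphic loci are dropped. Loci inside
#' `exclude` regions can be removed, e.g. to test whether structure is
#' carried entirely by the divergent regions.
#'
#' @param gt loci x samples dosage matrix (0/1/2/NA).
#' @param loci optional data.frame with `scaffold`, `pos` per row of `gt`
#'   (required when `exclude` is used).
#' @param exclude optional `GRanges`; loci overlapping it are dropped.
#' @param k number of axes to return.
#' @return list with `scores` (samples x k), `varprop` (explained
#'   variance shares) and `n_loci`.
#' @export
genotype_pca <- function(gt, loci = NULL, exclude = NULL, k = 2) {
  gt <- as.matrix(gt)
  if (!is.null(exclude) && length(exclude) > 0) {
    if (is.null(loci)) stop("locus coordinates required to exclude regions")
    drop <- positions_in_mask(exclude, loci$scaffold, loci$pos)
    gt <- gt[!drop, , drop = FALSE]
  }
  if (ncol(gt) < 2) stop("need at least two samples")
  p <- rowMeans(gt, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci")
  gt <- gt[poly, , drop = FALSE]
  p <- p[poly]
  x <- sweep(gt, 1, 2 * p)
  x[is.na(x)] <- 0  # mean imputation after centering
  x <- sweep(x, 1, sqrt(p * (1 - p)), "/")
  sv <- svd(t(x))
  k <- min(k, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- colnames(gt)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, varprop = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       n_loci = nrow(gt))
}

#' Classical MDS of region genotypes on an allele-sharing distance
#'
#' The pairwise distance is the mean absolute dosage difference over loci
#' non-missing in both samples (0..2 scale); classical metric scaling of
#' that matrix gives the sample coordinates. When the region holds two
#' non-recombining haplotype clades the first axis separates the three
#' diploid classes into equally spaced clusters.
#'
#' @param gt loci x samples dosage matrix restricted to the region.
#' @param region optional region id carried through to the result.
#' @return object of class `region_mds`: `points` (samples x 2,
#'   centered), `eig` (eigenvalues), `eig_share` (share of the first
#'   axis among positive eigenvalues), `region`.
#' @export
region_mds <- function(gt, region = NA_character_) {
  gt <- as.matrix(gt)
  if (ncol(gt) < 3) stop("need at least 3 samples")
  p <- rowMeans(gt, na.rm = TRUE) / 2
  if (sum(!is.na(p) & p > 0 & p < 1) < 2) {
    stop("need at least 2 polymorphic loci in the region")
  }
  n <- ncol(gt)
  d <- matrix(0, n, n, dimnames = list(colnames(gt), colnames(gt)))
  # mean |dosage difference| over loci observed in both samples
  obs <- !is.na(gt)
  gt0 <- gt; gt0[!obs] <- 0
  for (i in seq_len(n - 1)) {
    both <- obs[, i] & obs[, (i + 1):n, drop = FALSE]
    diffs <- abs(gt0[, i] - gt0[, (i + 1):n, drop = FALSE]) * both
    d[i, (i + 1):n] <- colSums(diffs) / pmax(colSums(both), 1)
    d[(i + 1):n, i] <- d[i, (i + 1):n]
  }
  mds <- cmdscale(d, k = 2, eig = TRUE)
  pts <- mds$points
  colnames(pts) <- c("axis1", "axis2")
  pos_eig <- mds$eig[mds$eig > 0]
  structure(list(points = pts, eig = mds$eig,
                 eig_share = if (length(pos_eig)) pos_eig[1] / sum(pos_eig) else NA,
                 region = region, dist = d),
            class = "region_mds")
}

#' @export
print.region_mds <- function(x, ...) {
  cat(sprintf("region_mds (%s): %d samples, axis-1 eigenvalue share %.2f\n",
              x$region, nrow(x$points), x$eig_share))
  invisible(x)
}

#' Classify samples into SS / NS / NN within a divergent region
#'
#' Fits a three-component Gaussian mixture (equal variances, EM with
#' deterministic model-based initialisation) to the first MDS axis. The
#' middle cluster is labelled NS; the end clusters are polarised
#' southern/northern by the majority population-of-origin of their
#' members (when labels are available), falling back to axis orientation
#' with a flag when polarity cannot be resolved. Samples whose maximum
#' posterior falls below `posterior_threshold` stay unassigned. If fewer
#' than three mixture components can be fitted the classification
#' degrades to 2 or 1 clusters and is flagged.
#'
#' @param mds a [region_mds()].
#' @param pop optional named vector of population labels
#'   (`"southern"`/`"northern"`/other) used to polarise the end clusters.
#' @param posterior_threshold minimum assignment posterior (default 0.95).
#' @importFrom mclust Mclust mclustBIC
#' @return object of class `region_call`: data.frame `calls` (sample,
#'   class, posterior, axis1), `means` (cluster means on axis 1),
#'   `equidistance` (relative asymmetry of the three cluster means),
#'   `n_clusters`, `flags`.
#' @export
classify_region_genotypes <- function(mds, pop = NULL,
                                      posterior_threshold = 0.95) {
  x <- mds$points[, "axis1"]
  flags <- character(0)
  fit <- NULL
  for (G in 3:1) {
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(x, G = G, modelNames = "E",
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$classification)) == G) break
  }
  if (is.null(fit)) stop("mixture fit failed")
  G <- fit$G
  if (G < 3) flags <- c(flags, sprintf("degraded_to_%d_clusters", G))
  means <- as.numeric(fit$parameters$mean)
  ord <- order(means)
  post <- fit$z[, ord, drop = FALSE]
  cl <- match(fit$classification, ord)  # 1 = low axis1, G = high
  # map ordered clusters to classes
  if (G == 3) {
    labels <- c("end1", "NS", "end2")
  } else if (G == 2) {
    labels <- c("end1", "end2")
  } else {
    labels <- "end1"
  }
  class_by_cluster <- labels
  # polarise the end clusters by population of origin
  polarity <- NULL
  if (!is.null(pop) && G >= 2) {
    pop <- pop[rownames(mds$points)]
    n_s <- function(cluster) sum(pop[cl == cluster] == "southern", na.rm = TRUE)
    n_n <- function(cluster) sum(pop[cl == cluster] == "northern", na.rm = TRUE)
    low_south <- n_s(1) - n_n(1)
    high_south <- n_s(G) - n_n(G)
    if (low_south > high_south) {
      polarity <- c("SS", "NN")
    } else if (low_south < high_south) {
      polarity <- c("NN", "SS")
    } else {
      flags <- c(flags, "polarity_unresolved")
    }
  }
  if (is.null(polarity)) {
    if (is.null(pop)) flags <- unique(c(flags, "polarity_by_axis_orientation"))
    polarity <- c("SS", "NN")
  }
  class_by_cluster[1] <- polarity[1]
  if (G >= 2) class_by_cluster[G] <- polarity[2]
  post_max <- apply(post, 1, max)
  class <- class_by_cluster[cl]
  class[post_max < posterior_threshold] <- "unassigned"
  calls <- data.frame(sample = rownames(mds$points), class = class,
                      posterior = post_max, axis1 = as.numeric(x),
                      stringsAsFactors = FALSE)
  sorted_means <- sort(means)
  equi <- if (G == 3) {
    abs((sorted_means[2] - sorted_means[1]) - (sorted_means[3] - sorted_means[2])) /
      (sorted_means[3] - sorted_means[1])
  } else NA_real_
  structure(list(calls = calls, means = setNames(sorted_means,
                                                 class_by_cluster),
                 equidistance = equi, n_clusters = G, flags = flags,
                 region = mds$region,
                 posterior_threshold = posterior_threshold),
            class = "region_call")
}

#' @export
print.region_call <- function(x, ...) {
  cat(sprintf("region_call (%s): %d clusters, equidistance %.3f\n",
              x$region, x$n_clusters,
              ifelse(is.na(x$equidistance), NA, x$equidistance)))
  print(table(x$calls$class))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Northern-haplotype frequency per sampling site
#'
#' `freq_N = (2 * #NN + #NS) / (2 * #assigned)` per site; unassigned
#' samples are excluded from the denominator. Sites with no assigned
#' samples get `NA`.
#'
#' @param call a [classify_region_genotypes()] result.
#' @param metadata data.frame with `sample` and `site` columns.
#' @return data.frame `site`, `n_assigned`, `freq_N`.
#' @export
haplotype_site_frequencies <- function(call, metadata) {
  df <- merge(call$calls, metadata[c("sample", "site")], by = "sample")
  sites <- unique(metadata$site)
  out <- data.frame(site = sites, n_assigned = 0L, freq_N = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sites)) {
    cls <- df$class[df$site == sites[i]]
    cls <- cls[cls %in% c("SS", "NS", "NN")]
    out$n_assigned[i] <- length(cls)
    if (length(cls)) {
      out$freq_N[i] <- (2 * sum(cls == "NN") + sum(cls == "NS")) /
        (2 * length(cls))
    }
  }
  out
}

#' Cross-tabulate diploid haplotype classes of two regions
#'
#' 3x3 genotype-combination counts over samples assigned in both regions
#' (e.g. chr1 class x chr5 class); in hybrid zones all nine combinations
#' are expected to be occupied, indicating later-generation hybrids and
#' backcrosses.
#'
#' @param call1,call2 two [classify_region_genotypes()] results.
#' @return a 3x3 table (rows: region-1 class, cols: region-2 class);
#'   attribute `empty` is TRUE when no sample is assigned in both.
#' @export
combined_genotype_table <- function(call1, call2) {
  lv <- c("SS", "NS", "NN")
  m <- merge(call1$calls[c("sample", "class")],
             call2$calls[c("sample", "class")], by = "sample")
  m <- m[m$class.x %in% lv & m$class.y %in% lv, ]
  tab <- table(factor(m$class.x, lv), factor(m$class.y, lv))
  attr(tab, "empty") <- nrow(m) == 0
  tab
}
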