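#' Configuration of the synthetic study generator
#'
#' Defines a complete synthetic study shaped like a two-phenotype avian
#' migratory divide: a weakly differentiated genomic background
#' (Balding-Nichols differentiation `F_background`), three multi-Mb
#' divergent regions each carrying two deeply diverged, mutually
#' non-recombining haplotype clades, two hybrid-zone transects with
#' sigmoid haplotype-frequency clines, and site-level phenotypes linked
#' either to haplotype frequency (d15N to the chr1/chr5 analogues) or to
#' altitude/latitude (chr3 analogue).
#'
#' The generator is site-independent (infinite sites, free recombination
#' outside the clade cores), which makes the expectation of every target
#' statistic exact: E(pi) = theta, E(d_A) = 2*mu*T_split, and the
#' expected weighted Weir-Cockerham F_ST equals `F_background`.
#' Within-clade variation is shared ancestral polymorphism (the same
#' Uniform(0,1) frequency in both clades), with E(2pq) = 1/3 so that
#' `3*theta*L` segregating sites give per-site diversity theta; where a
#' clade has excess diversity the difference is added as clade-private
#' sites.
#'
#' @param seed integer seed recorded in all outputs.
#' @param background_scaffolds named numeric vector of background scaffold
#'   lengths (bp).
#' @param background_chrom chromosome labels of the background scaffolds.
#' @param regions named list (chr1/chr3/chr5 analogues); each entry a list
#'   with `scaffold`, `length`, `chromosome`, `T_split` (generations),
#'   `theta_S`, `theta_N`.
#' @param mu mutation rate per site per generation.
#' @param F_background Balding-Nichols differentiation parameter in (0,1).
#' @param snp_density background SNPs per bp.
#' @param n_per_pop diploid resequenced samples per population.
#' @param window_size analysis window size (bp).
#' @param site_plan named integer vector: number of sampling sites per
#'   transect (74 in total by default).
#' @param site_n individuals sampled per site (one female among them).
#' @param transects data.frame of transect endpoints (`id`, `lat_a`,
#'   `lon_a`, `lat_b`, `lon_b`).
#' @param clines data.frame of generative cline parameters per region x
#'   transect: `region`, `transect`, `center_frac` (fraction of transect
#'   length), `width` (km), `pmin`, `pmax`. Regions without a row on a
#'   transect follow the environmental model instead.
#' @param chr3_env coefficients of the altitude/latitude model for the
#'   chr3-analogue clade probability.
#' @param phenotypes effect sizes and noise SDs of the phenotype model.
#' @param array_loci numbers of array loci: diagnostic (`core`) and
#'   shared-polymorphism (`poly`) loci per region plus `background` loci.
#' @param mean_depth mean simulated read depth.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       background_scaffolds = c(bg1 = 2e6, bg2 = 2e6,
                                                bg3 = 2e6, bg4 = 2e6),
                       background_chrom = c("2", "4", "6", "8"),
                       regions = list(
                         chr1 = list(scaffold = "sc_chr1", length = 2e6,
                                     chromosome = "1", T_split = 250000,
                                     theta_S = 0.005, theta_N = 0.007),
                         chr3 = list(scaffold = "sc_chr3", length = 2e6,
                                     chromosome = "3", T_split = 250000,
                                     theta_S = 0.005, theta_N = 0.005),
                         chr5 = list(scaffold = "sc_chr5", length = 1e6,
                                     chromosome = "5", T_split = 150000,
                                     theta_S = 0.005, theta_N = 0.007)),
                       mu = 1e-8,
                       F_background = 0.007,
                       snp_density = 0.03,
                       n_per_pop = 9,
                       window_size = 10000,
                       site_plan = c(sweden = 40, east = 34),
                       site_n = 15,
                       transects = data.frame(
                         id = c("sweden", "east"),
                         lat_a = c(55.0, 48.5), lon_a = c(13.0, 21.5),
                         lat_b = c(68.5, 61.5), lon_b = c(20.0, 26.5),
                         stringsAsFactors = FALSE),
                       clines = data.frame(
                         region = c("chr1", "chr5", "chr1", "chr5"),
                         transect = c("sweden", "sweden", "east", "east"),
                         center_frac = c(0.5, 0.5, 0.5, 0.5),
                         width = c(271, 310, 373, 249),
                         pmin = c(0.02, 0.02, 0.02, 0.02),
                         pmax = c(0.98, 0.98, 0.98, 0.98),
                         stringsAsFactors = FALSE),
                       chr3_env = list(b_alt = 0.9, alt_ref = 500,
                                       alt_scale = 100, b_lat = 0.25,
                                       lat_ref = 58),
                       phenotypes = list(
                         d15N_intercept = 11, d15N_beta = -4.5,
                         d15N_site_sd = 0.4, d15N_ind_sd = 0.9,
                         wing_base = 67, wing_shift = 1.5, wing_sd = 1.2,
                         tarsus_base = 20.5, tarsus_shift = 0.3, tarsus_sd = 0.5,
                         bill_base = 31, bill_shift = 0.4, bill_sd = 0.7,
                         female_size_offset = -2,
                         color_mid = 5, color_beta = 2.5, color_sd = 1.2),
                       array_loci = list(core = 25, poly = 15, background = 60),
                       mean_depth = 9) {
  stopifnot(F_background > 0, F_background < 1, snp_density > 0,
            window_size > 0, n_per_pop >= 2, mu > 0)
  for (r in regions) {
    if (2 * mu * r$T_split >= 1) stop("2*mu*T_split >= 1 (saturated) for a region")
    if (r$theta_S <= 0 || r$theta_S >= 1 || r$theta_N <= 0 || r$theta_N >= 1) {
      stop("theta must lie in (0,1)")
    }
    if (r$theta_N < r$theta_S) {
      stop("theta_N < theta_S is not supported (private variation is added to N)")
    }
  }
  if (any(clines$width <= 0)) stop("cline widths must be positive")
  if (any(clines$pmin >= clines$pmax)) stop("pMin must be < pMax")
  structure(list(seed = seed, background_scaffolds = background_scaffolds,
                 background_chrom = background_chrom, regions = regions,
                 mu = mu, F_background = F_background,
                 snp_density = snp_density, n_per_pop = n_per_pop,
                 window_size = window_size, site_plan = site_plan,
                 site_n = site_n, transects = transects, clines = clines,
                 chr3_env = chr3_env, phenotypes = phenotypes,
                 array_loci = array_loci, mean_depth = mean_depth),
            class = "sim_config")
}

#' Genome layout implied by a sim_config
#' @param cfg a [sim_config()].
#' @export
sim_layout <- function(cfg) {
  sc <- c(names(cfg$background_scaffolds),
          vapply(cfg$regions, `[[`, character(1), "scaffold"))
  len <- c(unname(cfg$background_scaffolds),
           vapply(cfg$regions, function(r) as.numeric(r$length), numeric(1)))
  chrom <- c(cfg$background_chrom,
             vapply(cfg$regions, `[[`, character(1), "chromosome"))
  ord <- order(suppressWarnings(as.numeric(chrom)), chrom)
  genome_layout(sc[ord], len[ord], chrom[ord])
}

.reseq_samples <- function(cfg) {
  c(sprintf("S%02d", seq_len(cfg$n_per_pop)),
    sprintf("N%02d", seq_len(cfg$n_per_pop)))
}

.reseq_pop <- function(cfg) {
  s <- .reseq_samples(cfg)
  setNames(rep(c("southern", "northern"), each = cfg$n_per_pop), s)
}

# Default clade-pair assignment of the resequenced samples: 8 southern
# samples homozygous SS and 6 northern homozygous NN at all regions; the
# remainder are heterozygous at one region each, so the "pure" subsets
# recovered by region genotyping have sizes 8 and 6.
.reseq_clades <- function(cfg) {
  samples <- .reseq_samples(cfg)
  ns <- cfg$n_per_pop
  out <- lapply(names(cfg$regions), function(rg) {
    m <- matrix(rep(rep(c(0L, 1L), each = ns), 2), ncol = 2,
                dimnames = list(samples, c("hap1", "hap2")))
    m
  })
  names(out) <- names(cfg$regions)
  # southern sample 9 heterozygous at chr1; northern samples 7..9
  # heterozygous at chr1, chr3, chr5 respectively (when ns >= 9)
  if (ns >= 9) {
    out$chr1[sprintf("S%02d", ns), 2] <- 1L
    het_n <- sprintf("N%02d", ns - 2:0)
    for (i in seq_along(out)) out[[i]][het_n[i], 1] <- 0L
  }
  out
}

.sim_qual_dp <- function(n_sites, n_samples, mean_depth, low_frac = 0.02) {
  qual <- runif(n_sites, 30, 60)
  nlow <- round(low_frac * n_sites)
  if (nlow > 0) {
    idx <- sample.int(n_sites, nlow)
    qual[idx] <- runif(nlow, 5, 19.5)
  }
  dp <- matrix(rpois(n_sites * n_samples, mean_depth), n_sites, n_samples)
  list(qual = qual, dp = dp)
}

#' Simulate the weakly differentiated genomic background
#'
#' Balding-Nichols model: per SNP an ancestral frequency
#' p ~ Uniform(0.05, 0.95) and population frequencies
#' Beta(a*p, a*(1-p)) with a = (1-F)/F, then binomial diploid genotypes.
#' The expected weighted Weir-Cockerham estimate equals F.
#'
#' @param cfg a [sim_config()].
#' @param seed seed (NULL to use the current RNG state).
#' @return a [variant_table()] spanning the background scaffolds, with a
#'   small fraction of low-quality sites for the QC stage to remove.
#' @export
simulate_background <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  samples <- .reseq_samples(cfg)
  ns <- length(samples)
  alpha <- (1 - cfg$F_background) / cfg$F_background
  vts <- lapply(names(cfg$background_scaffolds), function(sc) {
    L <- cfg$background_scaffolds[[sc]]
    n <- round(L * cfg$snp_density)
    pos <- sort(sample.int(L, n))
    p <- runif(n, 0.05, 0.95)
    p1 <- rbeta(n, alpha * p, alpha * (1 - p))
    p2 <- rbeta(n, alpha * p, alpha * (1 - p))
    gS <- matrix(rbinom(n * cfg$n_per_pop, 2, p1), n, cfg$n_per_pop)
    gN <- matrix(rbinom(n * cfg$n_per_pop, 2, p2), n, cfg$n_per_pop)
    qd <- .sim_qual_dp(n, ns, cfg$mean_depth)
    sites <- data.frame(scaffold = sc, pos = pos, ref = "A", alt = "T",
                        qual = qd$qual, is_snp = TRUE, is_biallelic = TRUE,
                        stringsAsFactors = FALSE)
    variant_table(sites, cbind(gS, gN), samples, .reseq_pop(cfg), qd$dp)
  })
  rbind_variant_tables(vts)
}

#' Simulate a divergent haplotype-block region
#'
#' Two clade core haplotypes differ at sites drawn with per-site
#' probability `2*mu*T_split` (the region's net divergence); every
#' haplotype carries one clade label that fully determines its core
#' alleles (no recombination between clades). Within-clade variation is
#' shared ancestral polymorphism with Uniform(0,1) frequencies
#' (`3*theta_S*L` sites), plus northern-private sites for any diversity
#' excess `theta_N - theta_S`.
#'
#' @param cfg a [sim_config()].
#' @param region region id (name in `cfg$regions`).
#' @param clade_pairs integer matrix samples x 2 of haplotype clade labels
#'   (0 = southern, 1 = northern); default the resequencing assignment.
#' @param samples sample ids (rownames of `clade_pairs` by default).
#' @param seed seed (NULL to continue the current RNG state).
#' @return list with `table` (a [variant_table()]) and `truth` (core-site
#'   positions, clade pairs, generative parameters).
#' @export
simulate_divergent_region <- function(cfg, region,
                                      clade_pairs = .reseq_clades(cfg)[[region]],
                                      samples = rownames(clade_pairs),
                                      seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  rg <- cfg$regions[[region]]
  if (is.null(rg)) stop("unknown region: ", region)
  L <- rg$length
  p_core <- 2 * cfg$mu * rg$T_split
  if (p_core >= 1) stop("2*mu*T_split >= 1: divergence saturated")
  n_core <- rbinom(1, L, p_core)
  S_shared <- round(3 * rg$theta_S * L)
  S_priv <- round(3 * (rg$theta_N - rg$theta_S) * L)
  total <- n_core + S_shared + S_priv
  pos <- sort(sample.int(L, total))
  kind <- sample(rep(c("core", "shared", "privN"),
                     c(n_core, S_shared, S_priv)))
  nsamp <- nrow(clade_pairs)
  ndose <- rowSums(clade_pairs)  # northern haplotypes per sample (0/1/2)
  gt <- matrix(0L, total, nsamp)
  is_core <- kind == "core"
  gt[is_core, ] <- matrix(rep(as.integer(ndose), each = sum(is_core)),
                          nrow = sum(is_core))
  is_shared <- kind == "shared"
  if (any(is_shared)) {
    p <- runif(sum(is_shared))
    gt[is_shared, ] <- matrix(rbinom(sum(is_shared) * nsamp, 2, p),
                              ncol = nsamp)
  }
  is_priv <- kind == "privN"
  if (any(is_priv)) {
    p <- runif(sum(is_priv))
    # alternate allele only on northern haplotypes
    gt[is_priv, ] <- matrix(rbinom(sum(is_priv) * nsamp,
                                   rep(as.integer(ndose), each = sum(is_priv)),
                                   p),
                            ncol = nsamp)
  }
  qd <- .sim_qual_dp(total, nsamp, cfg$mean_depth, low_frac = 0)
  sites <- data.frame(scaffold = rg$scaffold, pos = pos, ref = "A", alt = "T",
                      qual = qd$qual, is_snp = TRUE, is_biallelic = TRUE,
                      stringsAsFactors = FALSE)
  pop <- if (all(samples %in% .reseq_samples(cfg))) .reseq_pop(cfg)[samples] else NULL
  vt <- variant_table(sites, gt, samples, pop, qd$dp)
  truth <- list(region = region, core_pos = pos[is_core],
                clade_pairs = clade_pairs, T_split = rg$T_split,
                mu = cfg$mu, theta_S = rg$theta_S, theta_N = rg$theta_N,
                expected_da = 2 * cfg$mu * rg$T_split)
  list(table = vt, truth = truth)
}

#' Simulate a single panmictic group of diploid genotypes
#'
#' Site-independent generator for one group of `n_diploids` samples over
#' a region of `L` bp at per-site diversity `theta`. Two site-frequency
#' spectra are available:
#' * `"uniform"`: `3*theta*L` segregating sites with population
#'   frequencies Uniform(0,1); E(2pq) = 1/3 makes the expected per-site
#'   diversity exactly `theta`.
#' * `"neutral"`: `round(theta*a1*L)` segregating sites (a1 the harmonic
#'   number of n-1) whose sample allele counts follow the neutral
#'   equilibrium spectrum P(i) proportional to 1/i; both the
#'   pairwise-difference and the segregating-site estimators of theta are
#'   then unbiased, so Tajima's D is centered near zero.
#'
#' @param L region length (bp).
#' @param n_diploids number of diploid samples.
#' @param theta per-site diversity of the group.
#' @param spectrum `"uniform"` or `"neutral"`.
#' @param scaffold scaffold name of the emitted sites.
#' @param seed seed (NULL to continue the RNG state).
#' @return a [variant_table()] with samples `G01`, `G02`, ...
#' @export
simulate_group_variants <- function(L, n_diploids, theta,
                                    spectrum = c("uniform", "neutral"),
                                    scaffold = "sim", seed = NULL) {
  spectrum <- match.arg(spectrum)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(theta > 0, theta < 1, n_diploids >= 1)
  n_hap <- 2 * n_diploids
  if (spectrum == "uniform") {
    S <- round(3 * theta * L)
    pos <- sort(sample.int(L, S))
    p <- runif(S)
    hap <- matrix(rbinom(S * n_hap, 1, p), S, n_hap)
  } else {
    i <- seq_len(n_hap - 1)
    a1 <- sum(1 / i)
    S <- round(theta * a1 * L)
    pos <- sort(sample.int(L, S))
    counts <- sample(i, S, replace = TRUE, prob = 1 / i)
    hap <- matrix(0L, S, n_hap)
    for (s in seq_len(S)) hap[s, sample.int(n_hap, counts[s])] <- 1L
  }
  gt <- hap[, seq(1, n_hap, by = 2), drop = FALSE] +
    hap[, seq(2, n_hap, by = 2), drop = FALSE]
  samples <- sprintf("G%02d", seq_len(n_diploids))
  sites <- data.frame(scaffold = scaffold, pos = pos, ref = "A", alt = "T",
                      qual = 50, is_snp = TRUE, is_biallelic = TRUE,
                      stringsAsFactors = FALSE)
  variant_table(sites, gt, samples)
}

#' Simulate repeat intervals for the QC stage
#' @keywords internal
.sim_repeats <- function(cfg) {
  layout <- sim_layout(cfg)
  grs <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    k <- max(1, round(L / 2e5))
    starts <- sort(sample.int(L - 2000, k))
    GenomicRanges::GRanges(layout$scaffold[i],
                           IRanges::IRanges(starts + 1, starts + 2000))
  })
  GenomicRanges::reduce(suppressWarnings(do.call(c, grs)))
}

#' Simulate sampling sites along hybrid-zone transects
#'
#' Sites are spaced along each transect; per site and region the northern
#' haplotype frequency follows the configured sigmoid cline
#' (see [cline_predict()]) or, for regions without a cline on that
#' transect, the altitude/latitude logistic model. Individuals then draw
#' two clade labels per region under Hardy-Weinberg within the site.
#'
#' @param cfg a [sim_config()].
#' @param seed seed (NULL to continue the RNG state).
#' @return list: `sites` (site table with true frequencies),
#'   `individuals` (sample, site, sex), `clades` (list per region of
#'   samples x 2 clade matrices).
#' @export
simulate_transect_sampling <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  tr <- cfg$transects
  site_rows <- list()
  for (i in seq_len(nrow(tr))) {
    tid <- tr$id[i]
    n <- cfg$site_plan[[tid]]
    len <- transect_length(tr[i, ])
    x <- seq(0.03, 0.97, length.out = n) * len
    frac <- x / len
    site_rows[[i]] <- data.frame(
      site = sprintf("%s%02d", substr(tid, 1, 2), seq_len(n)),
      transect = tid, distance = x,
      lat = tr$lat_a[i] + frac * (tr$lat_b[i] - tr$lat_a[i]),
      lon = tr$lon_a[i] + frac * (tr$lon_b[i] - tr$lon_a[i]),
      altitude = runif(n, 0, 1000),
      length = len, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  for (rg in names(cfg$regions)) {
    f <- numeric(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      row <- cfg$clines[cfg$clines$region == rg &
                          cfg$clines$transect == sites$transect[i], ]
      if (nrow(row) == 1) {
        f[i] <- cline_predict(sites$distance[i],
                              center = row$center_frac * sites$length[i],
                              width = row$width, pmin = row$pmin,
                              pmax = row$pmax)
      } else {
        env <- cfg$chr3_env
        f[i] <- plogis(env$b_alt * (sites$altitude[i] - env$alt_ref) / env$alt_scale +
                         env$b_lat * (sites$lat[i] - env$lat_ref))
      }
    }
    sites[[paste0("freq_", rg)]] <- f
  }
  ids <- sprintf("A%04d", seq_len(nrow(sites) * cfg$site_n))
  individuals <- data.frame(
    sample = ids,
    site = rep(sites$site, each = cfg$site_n),
    sex = rep(c(rep("M", cfg$site_n - 1), "F"), nrow(sites)),
    stringsAsFactors = FALSE)
  clades <- lapply(names(cfg$regions), function(rg) {
    f <- rep(sites[[paste0("freq_", rg)]], each = cfg$site_n)
    m <- cbind(rbinom(length(f), 1, f), rbinom(length(f), 1, f))
    rownames(m) <- ids
    m
  })
  names(clades) <- names(cfg$regions)
  list(sites = sites, individuals = individuals, clades = clades)
}

#' Simulate individual phenotypes
#'
#' Site-mean d15N is linear in the site's true northern-haplotype
#' frequency at the chr1 analogue plus Gaussian site noise; individuals
#' add individual noise. Size traits shift weakly with the individual's
#' chr1 clade dosage (females carry a fixed size offset), and the color
#' score is a discretised 1-9 scale.
#'
#' @param cfg a [sim_config()].
#' @param sites site table from [simulate_transect_sampling()].
#' @param individuals individual table from the same call.
#' @param clades clade list from the same call.
#' @param seed seed (NULL to continue the RNG state).
#' @return `individuals` with phenotype columns appended.
#' @export
simulate_phenotypes <- function(cfg, sites, individuals, clades,
                                seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  ph <- cfg$phenotypes
  sidx <- match(individuals$site, sites$site)
  f1 <- sites$freq_chr1[sidx]
  site_noise <- rnorm(nrow(sites), 0, ph$d15N_site_sd)[sidx]
  nind <- nrow(individuals)
  d15N <- ph$d15N_intercept + ph$d15N_beta * f1 + site_noise +
    rnorm(nind, 0, ph$d15N_ind_sd)
  dose1 <- rowSums(clades$chr1)[individuals$sample] / 2
  female <- individuals$sex == "F"
  size_off <- ifelse(female, ph$female_size_offset, 0)
  individuals$d15N <- round(d15N, 2)
  individuals$wing <- round(ph$wing_base + ph$wing_shift * dose1 + size_off +
                              rnorm(nind, 0, ph$wing_sd), 1)
  individuals$tarsus <- round(ph$tarsus_base + ph$tarsus_shift * dose1 +
                                size_off / 4 + rnorm(nind, 0, ph$tarsus_sd), 1)
  individuals$bill_head <- round(ph$bill_base + ph$bill_shift * dose1 +
                                   size_off / 3 + rnorm(nind, 0, ph$bill_sd), 1)
  color <- round(ph$color_mid + ph$color_beta * (2 * dose1 - 1) +
                   rnorm(nind, 0, ph$color_sd))
  individuals$color <- pmin(9, pmax(1, color))
  individuals
}

#' Simulate SNP-array genotypes for the transect samples
#'
#' Per region: `core` diagnostic loci whose alleles are fully determined
#' by the clade labels plus `poly` shared-polymorphism loci; plus
#' `background` Balding-Nichols loci (populations defined by which side
#' of the chr1 cline a site lies on).
#'
#' @param cfg a [sim_config()].
#' @param transect output of [simulate_transect_sampling()].
#' @param seed seed (NULL to continue the RNG state).
#' @return list `loci` (scaffold, pos, region) and `gt` (loci x samples).
#' @export
simulate_array_genotypes <- function(cfg, transect, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  ids <- transect$individuals$sample
  nind <- length(ids)
  blocks <- list()
  loci <- list()
  for (rg in names(cfg$regions)) {
    sc <- cfg$regions[[rg]]$scaffold
    L <- cfg$regions[[rg]]$length
    ncore <- cfg$array_loci$core
    npoly <- cfg$array_loci$poly
    pos <- sort(sample.int(L, ncore + npoly))
    which_core <- sort(sample.int(ncore + npoly, ncore))
    ndose <- rowSums(transect$clades[[rg]])
    g <- matrix(0L, ncore + npoly, nind)
    g[which_core, ] <- matrix(rep(as.integer(ndose), each = ncore), ncore)
    poly_rows <- setdiff(seq_len(ncore + npoly), which_core)
    p <- runif(length(poly_rows))
    g[poly_rows, ] <- matrix(rbinom(length(poly_rows) * nind, 2, p), ncol = nind)
    blocks[[rg]] <- g
    loci[[rg]] <- data.frame(scaffold = sc, pos = pos, region = rg,
                             stringsAsFactors = FALSE)
  }
  nb <- cfg$array_loci$background
  if (nb > 0) {
    sc <- names(cfg$background_scaffolds)
    bsc <- sample(sc, nb, replace = TRUE)
    bpos <- vapply(bsc, function(s) sample.int(cfg$background_scaffolds[[s]], 1),
                   integer(1))
    sidx <- match(transect$individuals$site, transect$sites$site)
    north <- transect$sites$freq_chr1[sidx] >= 0.5
    alpha <- (1 - cfg$F_background) / cfg$F_background
    p <- runif(nb, 0.05, 0.95)
    p1 <- rbeta(nb, alpha * p, alpha * (1 - p))
    p2 <- rbeta(nb, alpha * p, alpha * (1 - p))
    g <- matrix(0L, nb, nind)
    g[, !north] <- matrix(rbinom(nb * sum(!north), 2, p1), nb)
    g[, north] <- matrix(rbinom(nb * sum(north), 2, p2), nb)
    blocks$background <- g
    loci$background <- data.frame(scaffold = bsc, pos = bpos,
                                  region = "background",
                                  stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, blocks)
  colnames(gt) <- ids
  list(loci = do.call(rbind, loci), gt = gt)
}

#' @export
write_array_genotypes <- function(array, path) {
  df <- cbind(array$loci, as.data.frame(array$gt))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
read_array_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gt <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(gt) <- "integer"
  list(loci = df[, 1:3], gt = gt)
}

#' Region definitions implied by a sim_config (whole region scaffolds)
#' @param cfg a [sim_config()].
#' @return `GRanges` with a `region` metadata column.
#' @export
sim_region_definitions <- function(cfg) {
  gr <- GenomicRanges::GRanges(
    vapply(cfg$regions, `[[`, character(1), "scaffold"),
    IRanges::IRanges(1, vapply(cfg$regions, function(r) as.numeric(r$length),
                               numeric(1))))
  S4Vectors::mcols(gr)$region <- names(cfg$regions)
  gr
}

.sim_features <- function(cfg) {
  layout <- sim_layout(cfg)
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    k <- max(2, round(L / 4e5))
    start <- round(seq(0.1, 0.9, length.out = k) * L)
    data.frame(scaffold = layout$scaffold[i], start = start,
               end = pmin(start + 20000, L),
               strand = rep_len(c("+", "-"), k),
               gene = sprintf("g_%s_%02d", layout$scaffold[i], seq_len(k)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic study on disk
#'
#' Runs every generator under a single seed and writes an internally
#' consistent input set: resequencing VCF, repeat and callable BED masks,
#' genome layout, region definitions (BED), transect endpoints, sample
#' metadata, array genotypes, a gene-feature table and a JSON truth file
#' echoing all generative parameters. Two runs with the same seed produce
#' byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) list of file paths plus the in-memory `truth`.
#' @export
simulate_study <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  layout <- sim_layout(cfg)
  path <- function(f) file.path(outdir, f)

  bg <- simulate_background(cfg, seed = NULL)
  reseq_clades <- .reseq_clades(cfg)
  region_sims <- lapply(names(cfg$regions), function(rg) {
    simulate_divergent_region(cfg, rg, reseq_clades[[rg]],
                              samples = .reseq_samples(cfg), seed = NULL)
  })
  names(region_sims) <- names(cfg$regions)
  vt <- rbind_variant_tables(c(list(bg), lapply(region_sims, `[[`, "table")))
  write_variant_vcf(vt, path("reseq.vcf"), layout)

  repeats <- .sim_repeats(cfg)
  write_intervals(repeats, path("repeats.bed"))
  write_intervals(mask_complement(layout, repeats), path("callable.bed"))
  write_genome_layout(layout, path("layout.tsv"))

  regions <- sim_region_definitions(cfg)
  writeLines(paste(as.character(GenomicRanges::seqnames(regions)),
                   GenomicRanges::start(regions) - 1,
                   GenomicRanges::end(regions),
                   S4Vectors::mcols(regions)$region, sep = "\t"),
             path("regions.bed"))

  utils::write.table(cfg$transects, path("transects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  transect <- simulate_transect_sampling(cfg, seed = NULL)
  ind <- simulate_phenotypes(cfg, transect$sites, transect$individuals,
                             transect$clades, seed = NULL)
  sidx <- match(ind$site, transect$sites$site)
  meta <- data.frame(sample = ind$sample, site = ind$site,
                     lat = round(transect$sites$lat[sidx], 4),
                     lon = round(transect$sites$lon[sidx], 4),
                     altitude = round(transect$sites$altitude[sidx]),
                     sex = ind$sex, d15N = ind$d15N, wing = ind$wing,
                     tarsus = ind$tarsus, bill_head = ind$bill_head,
                     color = ind$color, stringsAsFactors = FALSE)
  # resequenced individuals live at two allopatric reference sites
  rq <- data.frame(sample = .reseq_samples(cfg),
                   site = rep(c("refS", "refN"), each = cfg$n_per_pop),
                   lat = rep(c(50.0, 67.0), each = cfg$n_per_pop),
                   lon = rep(c(10.0, 25.0), each = cfg$n_per_pop),
                   altitude = 100, sex = "M", d15N = NA, wing = NA,
                   tarsus = NA, bill_head = NA, color = NA,
                   stringsAsFactors = FALSE)
  write_sample_metadata(rbind(meta, rq), path("metadata.tsv"))

  array <- simulate_array_genotypes(cfg, transect, seed = NULL)
  write_array_genotypes(array, path("array_genotypes.tsv"))

  utils::write.table(.sim_features(cfg), path("features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("transects", "clines"))],
    clines = cfg$clines,
    reseq_clades = lapply(reseq_clades, function(m) {
      data.frame(sample = rownames(m), hap1 = m[, 1], hap2 = m[, 2])
    }),
    region_truth = lapply(region_sims, function(x) {
      x$truth[c("region", "T_split", "mu", "theta_S", "theta_N", "expected_da")]
    }),
    site_freqs = transect$sites,
    array_clades = lapply(transect$clades, function(m) {
      data.frame(sample = rownames(m), ndose = rowSums(m))
    }))
  jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(list(dir = outdir,
                 files = list(vcf = path("reseq.vcf"),
                              repeats = path("repeats.bed"),
                              callable = path("callable.bed"),
                              layout = path("layout.tsv"),
                              regions = path("regions.bed"),
                              transects = path("transects.tsv"),
                              metadata = path("metadata.tsv"),
                              array = path("array_genotypes.tsv"),
                              features = path("features.tsv"),
                              truth = path("truth.json")),
                 truth = truth))
}
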