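# End-to-end orchestration: (optional) simulation -> QC -> region
# genotyping of the resequenced samples -> windowed statistics ->
# array-based region genotyping -> site frequencies -> clines ->
# phenotype association -> report.

#' Pipeline configuration
#'
#' @param outdir output directory.
#' @param sim a [sim_config()] to generate the inputs, or NULL to use
#'   pre-existing files given in `inputs`.
#' @param inputs named list of input paths (`vcf`, `callable`, `repeats`,
#'   `layout`, `regions`, `transects`, `metadata`, `array`, `features`);
#'   filled automatically when `sim` is used.
#' @param population_map named vector sample -> population label for the
#'   resequenced samples; derived from the simulation when `sim` is used.
#' @param filters a [filter_config()].
#' @param window_size,min_callable,min_snps windowed-statistic settings.
#' @param top_frac,fst_threshold ranking thresholds.
#' @param posterior_threshold assignment posterior for region calls.
#' @param boot bootstrap replicates per cline fit.
#' @param seed seed controlling all pipeline randomness.
#' @export
pipeline_config <- function(outdir, sim = sim_config(), inputs = NULL,
                            population_map = NULL,
                            filters = filter_config(), window_size = 10000,
                            min_callable = 5000, min_snps = 25,
                            top_frac = 0.01, fst_threshold = 0.7,
                            posterior_threshold = 0.95, boot = 100,
                            seed = if (!is.null(sim)) sim$seed else 1) {
  structure(list(outdir = outdir, sim = sim, inputs = inputs,
                 population_map = population_map, filters = filters,
                 window_size = window_size, min_callable = min_callable,
                 min_snps = min_snps, top_frac = top_frac,
                 fst_threshold = fst_threshold,
                 posterior_threshold = posterior_threshold, boot = boot,
                 seed = seed),
            class = "pipeline_config")
}

.read_regions_bed <- function(path) {
  lines <- readLines(path)
  f <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  gr <- GenomicRanges::GRanges(
    vapply(f, `[`, character(1), 1),
    IRanges::IRanges(as.numeric(vapply(f, `[`, character(1), 2)) + 1,
                     as.numeric(vapply(f, `[`, character(1), 3))))
  S4Vectors::mcols(gr)$region <- vapply(f, function(x) {
    if (length(x) >= 4) x[4] else NA_character_
  }, character(1))
  gr
}

.stage <- function(log, name, expr) {
  message("[divscan] stage: ", name)
  cat(sprintf("%s\tstage %s\n", format(Sys.time(), "%H:%M:%S"), name),
      file = log, append = TRUE)
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# assign sampling sites to the transect they are least off-axis from,
# and polarise array samples by the geographic ends of their transect
.assign_transects <- function(site_tab, transects) {
  n <- nrow(site_tab)
  best <- data.frame(transect = rep(NA_character_, n), distance = NA_real_,
                     off_axis = NA_real_)
  for (i in seq_len(nrow(transects))) {
    td <- transect_distance(site_tab$lat, site_tab$lon, transects[i, ])
    take <- is.na(best$off_axis) | td$off_axis < best$off_axis
    best$transect[take] <- transects$id[i]
    best$distance[take] <- td$distance[take]
    best$off_axis[take] <- td$off_axis[take]
  }
  cbind(site_tab, best)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on simulated or user-supplied inputs.
#' Reruns with the same configuration and seed reproduce identical
#' numeric outputs. Any stage failure halts with a stage-named error;
#' outputs of completed stages remain on disk.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) an object of class `divscan_result` collecting
#'   every stage's tables and fits.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(cfg$outdir, "pipeline.log")
  cat(sprintf("divscan pipeline; seed %d\n", cfg$seed), file = log)
  out <- function(f) file.path(cfg$outdir, f)
  set.seed(cfg$seed)

  inputs <- cfg$inputs
  population_map <- cfg$population_map
  if (!is.null(cfg$sim)) {
    simres <- .stage(log, "simulate",
                     simulate_study(cfg$sim, file.path(cfg$outdir, "inputs")))
    inputs <- simres$files
    if (is.null(population_map)) population_map <- .reseq_pop(cfg$sim)
  }
  need <- c("vcf", "callable", "repeats", "layout", "regions", "transects",
            "metadata", "array", "features")
  missing_in <- setdiff(need, names(inputs))
  if (length(missing_in)) {
    stop("pipeline inputs missing: ", paste(missing_in, collapse = ", "))
  }
  gone <- !vapply(inputs[need], file.exists, logical(1))
  if (any(gone)) {
    stop("input file(s) do not exist: ",
         paste(unlist(inputs[need][gone]), collapse = ", "))
  }

  loaded <- .stage(log, "load", {
    list(layout = read_genome_layout(inputs$layout),
         vt = read_variant_table(inputs$vcf, population_map),
         callable = read_intervals(inputs$callable),
         repeats = read_intervals(inputs$repeats),
         regions = .read_regions_bed(inputs$regions),
         transects = utils::read.delim(inputs$transects,
                                       stringsAsFactors = FALSE),
         metadata = read_sample_metadata(inputs$metadata),
         array = read_array_genotypes(inputs$array),
         features = read_features(inputs$features))
  })

  qc <- .stage(log, "qc", {
    fcfg <- cfg$filters
    fcfg$repeat_mask <- loaded$repeats
    res <- filter_variants(loaded$vt, fcfg)
    utils::write.table(res$report, out("qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })
  vt <- qc$table

  region_ids <- S4Vectors::mcols(loaded$regions)$region
  reseq_calls <- .stage(log, "genotype-regions-reseq", {
    calls <- list()
    for (i in seq_along(region_ids)) {
      rg <- loaded$regions[i]
      bs <- biallelic_snps(vt)
      inside <- positions_in_mask(rg, bs$sites$scaffold, bs$sites$pos)
      sub <- bs[which(inside), ]
      mds <- region_mds(sub$gt, region = region_ids[i])
      calls[[region_ids[i]]] <-
        classify_region_genotypes(mds, pop = vt$pop,
                                  posterior_threshold = cfg$posterior_threshold)
    }
    calls
  })
  pure <- .stage(log, "pure-subsets", {
    cls <- sapply(reseq_calls, function(x) x$calls$class)
    rownames(cls) <- reseq_calls[[1]]$calls$sample
    list(S = rownames(cls)[apply(cls == "SS", 1, all)],
         N = rownames(cls)[apply(cls == "NN", 1, all)])
  })

  stats <- .stage(log, "stats", {
    windows <- make_windows(loaded$layout, cfg$window_size)
    callable <- window_callable_counts(loaded$callable, windows)
    ws <- compute_window_stats(vt, windows, callable, pure,
                               min_callable = cfg$min_callable,
                               min_snps = cfg$min_snps)
    write_window_stats(ws, out("window_stats.tsv"))
    fst_sites <- site_fst(vt, include_indels = TRUE)
    ranked <- rank_windows(ws, fst_sites, cfg$top_frac, cfg$fst_threshold,
                           loaded$regions)
    near <- nearest_feature(ranked$top_windows, loaded$features)
    topw <- cbind(ranked$top_windows, near)
    utils::write.table(topw, out("top_windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ranked$high_fst_variants, out("high_fst_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # highest per-region average of windowed d_A drives the divergence time
    rg_of <- rep(NA_character_, nrow(ws))
    for (i in seq_along(region_ids)) {
      hit <- positions_in_mask(loaded$regions[i], ws$scaffold, ws$start + 1)
      rg_of[hit] <- region_ids[i]
    }
    da_region <- tapply(ws$da[ws$pass_callable & !is.na(rg_of)],
                        rg_of[ws$pass_callable & !is.na(rg_of)],
                        mean, na.rm = TRUE)
    div_t <- divergence_time(max(c(da_region, 0), na.rm = TRUE))
    list(windows = windows, callable = callable, window_stats = ws,
         fst_sites = fst_sites, ranked = ranked, top_windows = topw,
         divergence = div_t)
  })

  array_calls <- .stage(log, "genotype-regions-array", {
    aqc <- array_qc(loaded$array$gt, cfg$filters)
    loci <- loaded$array$loci[aqc$kept_loci, , drop = FALSE]
    meta <- loaded$metadata
    site_tab <- unique(meta[meta$sample %in% colnames(aqc$gt),
                            c("site", "lat", "lon")])
    site_tab <- .assign_transects(site_tab, loaded$transects)
    # polarise by geographic origin: samples from the first/last fifth of
    # their transect act as southern/northern anchors
    anchor <- setNames(rep(NA_character_, ncol(aqc$gt)), colnames(aqc$gt))
    for (tid in unique(site_tab$transect)) {
      st <- site_tab[site_tab$transect == tid, ]
      qs <- quantile(st$distance, c(0.2, 0.8))
      lab <- ifelse(st$distance <= qs[1], "southern",
                    ifelse(st$distance >= qs[2], "northern", NA))
      idx <- meta$site[match(colnames(aqc$gt), meta$sample)] %in% st$site
      anchor[idx] <- lab[match(meta$site[match(colnames(aqc$gt)[idx],
                                               meta$sample)], st$site)]
    }
    calls <- list()
    mds_list <- list()
    for (rg in region_ids) {
      rows <- which(loci$region == rg)
      mds <- region_mds(aqc$gt[rows, , drop = FALSE], region = rg)
      mds_list[[rg]] <- mds
      calls[[rg]] <- classify_region_genotypes(
        mds, pop = anchor, posterior_threshold = cfg$posterior_threshold)
      utils::write.table(
        cbind(calls[[rg]]$calls, region = rg),
        out(sprintf("region_calls_%s.tsv", rg)), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    list(qc = aqc, calls = calls, mds = mds_list, site_tab = site_tab)
  })

  freqs <- .stage(log, "site-frequencies", {
    fr <- lapply(array_calls$calls, haplotype_site_frequencies,
                 metadata = loaded$metadata)
    for (rg in names(fr)) {
      utils::write.table(fr[[rg]], out(sprintf("site_freq_%s.tsv", rg)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    fr
  })

  clines <- .stage(log, "clines", {
    st <- array_calls$site_tab
    fits <- list()
    for (rg in region_ids) {
      f <- merge(freqs[[rg]], st, by = "site")
      for (tid in unique(f$transect)) {
        sub <- f[f$transect == tid & !is.na(f$freq_N) & f$n_assigned > 0, ]
        if (nrow(sub) < 4) next
        n <- 2 * sub$n_assigned
        fits[[paste(rg, tid, sep = ":")]] <-
          fit_cline(sub$distance, n, round(sub$freq_N * n), boot = cfg$boot)
      }
    }
    tab <- do.call(rbind, lapply(names(fits), function(nm) {
      ft <- fits[[nm]]
      data.frame(fit = nm, t(coef(ft)), logLik = ft$logLik,
                 width_lo = if (!is.null(ft$ci)) ft$ci[1, "width"] else NA,
                 width_hi = if (!is.null(ft$ci)) ft$ci[2, "width"] else NA,
                 converged = ft$converged,
                 flags = paste(ft$flags, collapse = ";"))
    }))
    utils::write.table(tab, out("cline_fits.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(fits = fits, table = tab,
         neutral = neutral_diffusion_width(50, 100))
  })

  assoc <- .stage(log, "association", {
    summaries <- site_trait_means(loaded$metadata, freqs)
    st <- array_calls$site_tab
    rows <- list()
    for (rg in region_ids) {
      for (tr in c("d15N", "size_pc1", "color", "altitude")) {
        rows[[paste(rg, tr)]] <- correlate_frequency_trait(summaries, rg, tr)
        for (tid in unique(st$transect)) {
          stratum <- st$site[st$transect == tid]
          rr <- correlate_frequency_trait(summaries, rg, tr, stratum)
          rr$stratum <- tid
          rows[[paste(rg, tr, tid)]] <- rr
        }
      }
    }
    rows <- lapply(rows, function(r) {
      if (!"stratum" %in% names(r)) r$stratum <- "all"
      r
    })
    tab <- do.call(rbind, rows)
    utils::write.table(tab, out("associations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(summaries = summaries, table = tab)
  })

  res <- structure(list(config = cfg, inputs = inputs, qc = qc,
                        reseq_calls = reseq_calls, pure = pure,
                        stats = stats, array_calls = array_calls,
                        freqs = freqs, clines = clines, assoc = assoc,
                        layout = loaded$layout, regions = loaded$regions,
                        metadata = loaded$metadata, vt = vt,
                        outdir = cfg$outdir),
                   class = "divscan_result")
  invisible(res)
}

#' @export
print.divscan_result <- function(x, ...) {
  cat("divscan pipeline result in ", x$outdir, "\n", sep = "")
  cat(sprintf("  %d variants after QC; %d windows\n", nrow(x$vt$sites),
              nrow(x$stats$window_stats)))
  cat(sprintf("  pure subsets: %d southern, %d northern\n",
              length(x$pure$S), length(x$pure$N)))
  cat(sprintf("  %d cline fits; divergence time %.2f-%.2f Myr\n",
              length(x$clines$fits), x$stats$divergence$t_years[1] / 1e6,
              x$stats$divergence$t_years[2] / 1e6))
  invisible(x)
}

#' Render summary figures for a pipeline result
#'
#' Writes deterministic PDF panels into the result directory: a
#' concatenated per-chromosome F_ST track, PCA with and without the
#' divergent regions, the per-region MDS clusters, per-region windowed
#' statistic tracks, and the fitted clines.
#'
#' @param res a `divscan_result` from [run_pipeline()].
#' @return (invisibly) the vector of figure paths.
#' @export
report <- function(res) {
  stopifnot(inherits(res, "divscan_result"))
  figs <- character(0)
  out <- function(f) file.path(res$outdir, f)
  ws <- res$stats$window_stats
  lay <- res$layout
  off <- setNames(lay$offset, lay$scaffold)

  p1 <- out("fig_fst_track.pdf")
  pdf(p1, width = 9, height = 3)
  xs <- off[ws$scaffold] + (ws$start + ws$end) / 2
  plot(xs / 1e6, ws$fst, pch = 16, cex = 0.3, col = "grey30",
       xlab = "concatenated position (Mb)", ylab = expression(F[ST]),
       main = "Windowed differentiation")
  for (i in seq_along(res$regions)) {
    sc <- as.character(GenomicRanges::seqnames(res$regions[i]))
    abline(v = (off[sc] + c(GenomicRanges::start(res$regions[i]),
                            GenomicRanges::end(res$regions[i]))) / 1e6,
           lty = 3, col = "steelblue")
  }
  dev.off(); figs <- c(figs, p1)

  bs <- biallelic_snps(res$vt)
  p2 <- out("fig_pca.pdf")
  pdf(p2, width = 8, height = 4)
  par(mfrow = c(1, 2))
  pc_all <- genotype_pca(bs$gt, bs$sites)
  pc_no <- genotype_pca(bs$gt, bs$sites, exclude = res$regions)
  cols <- ifelse(res$vt$pop == "southern", "forestgreen", "royalblue")
  plot(pc_all$scores, col = cols, pch = 19, main = "All SNPs")
  plot(pc_no$scores, col = cols, pch = 19, main = "Divergent regions excluded")
  dev.off(); figs <- c(figs, p2)

  p3 <- out("fig_mds.pdf")
  pdf(p3, width = 9, height = 3.2)
  par(mfrow = c(1, length(res$array_calls$mds)))
  for (rg in names(res$array_calls$mds)) {
    mds <- res$array_calls$mds[[rg]]
    cl <- res$array_calls$calls[[rg]]$calls$class
    plot(mds$points, col = c(SS = "forestgreen", NS = "orange",
                             NN = "royalblue",
                             unassigned = "grey")[cl],
         pch = 19, cex = 0.6, main = rg)
  }
  dev.off(); figs <- c(figs, p3)

  p4 <- out("fig_region_tracks.pdf")
  pdf(p4, width = 8, height = 6)
  par(mfrow = c(3, 1), mar = c(3, 4, 2, 1))
  for (rg in seq_along(res$regions)) {
    sc <- as.character(GenomicRanges::seqnames(res$regions[rg]))
    sub <- ws[ws$scaffold == sc, ]
    plot(sub$start / 1e6, sub$fst, type = "p", pch = 16, cex = 0.4,
         xlab = "", ylab = expression(F[ST]),
         main = S4Vectors::mcols(res$regions)$region[rg], ylim = c(0, 1))
    lines(sub$start / 1e6, sub$pi_S * 50, col = "forestgreen")
    lines(sub$start / 1e6, sub$pi_N * 50, col = "royalblue")
  }
  dev.off(); figs <- c(figs, p4)

  p5 <- out("fig_clines.pdf")
  pdf(p5, width = 8, height = 5)
  n <- length(res$clines$fits)
  par(mfrow = c(ceiling(n / 3), min(3, max(n, 1))), mar = c(4, 4, 2, 1))
  for (nm in names(res$clines$fits)) {
    plot(res$clines$fits[[nm]], main = nm)
  }
  dev.off(); figs <- c(figs, p5)

  invisible(figs)
}
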