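# Site-level phenotype summaries and haplotype-frequency/trait
# correlations. All associations are computed on sampling-site means of
# males, not on individuals: the migratory proxy (feather d15N) varies
# widely between individuals of the same population, while site means
# are stable.

#' Per-site phenotype means and haplotype frequencies
#'
#' Restricts to males, computes a single size axis (first principal
#' component of standardized wing, tarsus and bill-head lengths, sign
#' fixed so that larger birds score positive) and averages each trait per
#' sampling site. Haplotype frequencies per region are merged in from
#' [haplotype_site_frequencies()] results.
#'
#' @param metadata sample metadata (see [read_sample_metadata()]).
#' @param freqs named list of per-region site-frequency tables.
#' @param min_n minimum number of males for an unflagged site mean.
#' @return data.frame of class `site_summary` with one row per site:
#'   coordinates, `n_males`, `freq_<region>` columns, trait means
#'   (`d15N`, `size_pc1`, `color`, `wing`, `tarsus`, `bill_head`),
#'   `size_pc1_var` (variance share of the size axis) as an attribute.
#' @export
site_trait_means <- function(metadata, freqs = list(), min_n = 3) {
  males <- metadata[!is.na(metadata$sex) & metadata$sex == "M", ]
  if (nrow(males) == 0) stop("no male samples in metadata")
  size_vars <- c("wing", "tarsus", "bill_head")
  cc <- complete.cases(males[size_vars])
  males$size_pc1 <- NA_real_
  size_share <- NA_real_
  if (sum(cc) >= 3) {
    pc <- prcomp(males[cc, size_vars], center = TRUE, scale. = TRUE)
    sgn <- if (sum(pc$rotation[, 1]) < 0) -1 else 1
    males$size_pc1[cc] <- sgn * pc$x[, 1]
    size_share <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  agg <- function(v) {
    s <- tapply(males[[v]], males$site, mean, na.rm = TRUE)
    s[is.nan(s)] <- NA
    s
  }
  sites <- sort(unique(males$site))
  out <- data.frame(site = sites,
                    lat = tapply(males$lat, males$site, mean)[sites],
                    lon = tapply(males$lon, males$site, mean)[sites],
                    altitude = tapply(males$altitude, males$site, mean)[sites],
                    n_males = as.integer(table(males$site)[sites]),
                    stringsAsFactors = FALSE)
  for (v in c("d15N", "size_pc1", "color", "wing", "tarsus", "bill_head")) {
    out[[v]] <- as.numeric(agg(v)[sites])
  }
  for (rg in names(freqs)) {
    f <- freqs[[rg]]
    out[[paste0("freq_", rg)]] <- f$freq_N[match(sites, f$site)]
  }
  dropped <- metadata$site[!metadata$site %in% sites]
  if (length(dropped)) {
    warning("site(s) without males dropped: ",
            paste(unique(dropped), collapse = ", "))
  }
  out$low_n <- out$n_males < min_n
  attr(out, "size_pc1_var") <- size_share
  class(out) <- c("site_summary", "data.frame")
  out
}

#' Pearson correlation between haplotype frequency and a site trait mean
#'
#' @param summaries a [site_trait_means()] table.
#' @param region region id (matching a `freq_<region>` column).
#' @param trait trait column name (`"d15N"`, `"size_pc1"`, `"color"`,
#'   `"altitude"`, ...).
#' @param stratum optional site subset (character vector of site ids),
#'   e.g. one transect.
#' @param min_sites minimum number of complete sites for a reported r.
#' @return data.frame with `region`, `trait`, `r`, `n_sites`, `flag`.
#' @export
correlate_frequency_trait <- function(summaries, region, trait,
                                      stratum = NULL, min_sites = 3) {
  fcol <- paste0("freq_", region)
  if (!fcol %in% names(summaries)) stop("no frequency column for region ", region)
  df <- summaries
  if (!is.null(stratum)) df <- df[df$site %in% stratum, ]
  ok <- !is.na(df[[fcol]]) & !is.na(df[[trait]])
  df <- df[ok, ]
  flag <- NA_character_
  r <- NA_real_
  if (nrow(df) < min_sites) {
    flag <- "too_few_sites"
  } else if (sd(df[[fcol]]) == 0 || sd(df[[trait]]) == 0) {
    flag <- "zero_variance"
  } else {
    r <- cor(df[[fcol]], df[[trait]])
  }
  data.frame(region = region, trait = trait, r = r, n_sites = nrow(df),
             flag = flag, stringsAsFactors = FALSE)
}
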