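# Geographic cline analysis: transect projection, the 4-parameter sigmoid
# cline, maximum-likelihood fitting with deterministic multi-start, and
# parametric-bootstrap confidence intervals.

.EARTH_RADIUS_KM <- 6371

#' Great-circle length of a transect (km)
#' @param transect one-row data.frame with `lat_a`, `lon_a`, `lat_b`, `lon_b`.
#' @export
transect_length <- function(transect) {
  geosphere::distHaversine(c(transect$lon_a, transect$lat_a),
                           c(transect$lon_b, transect$lat_b),
                           r = .EARTH_RADIUS_KM)
}

#' Project sampling sites onto a transect
#'
#' Signed great-circle distance (km, Earth radius 6371 km) from endpoint A
#' to the orthogonal projection of each site onto the A-to-B great
#' circle. Sites whose cross-track (off-axis) distance exceeds
#' `off_axis_tol` km, or whose projection falls outside `[0, |AB|]` by
#' more than the tolerance, are flagged.
#'
#' @param lat,lon site coordinates in decimal degrees.
#' @param transect one-row data.frame with `lat_a`, `lon_a`, `lat_b`, `lon_b`.
#' @param off_axis_tol off-axis tolerance in km (default 300).
#' @return data.frame with `distance` (km along the transect),
#'   `off_axis` (km) and logical `flagged`.
#' @export
transect_distance <- function(lat, lon, transect, off_axis_tol = 300) {
  a <- c(transect$lon_a, transect$lat_a)
  b <- c(transect$lon_b, transect$lat_b)
  p <- cbind(lon, lat)
  along <- as.numeric(geosphere::alongTrackDistance(a, b, p, r = .EARTH_RADIUS_KM))
  cross <- abs(as.numeric(geosphere::dist2gc(a, b, p, r = .EARTH_RADIUS_KM)))
  len <- transect_length(transect)
  flagged <- cross > off_axis_tol | along < -off_axis_tol |
    along > len + off_axis_tol
  data.frame(distance = as.numeric(along), off_axis = as.numeric(cross),
             flagged = flagged)
}

#' Sigmoid cline equation
#'
#' `p(x) = pmin + (pmax - pmin) / (1 + exp(-4 (x - center) / width))`:
#' the tail-free four-parameter cline. At `x = center` the frequency is
#' `(pmin + pmax)/2`, and the maximum slope, reached at the center, is
#' `(pmax - pmin)/width`.
#'
#' @param x distance(s) along the transect (km).
#' @param center cline center (km).
#' @param width cline width (km, inverse of the maximum relative slope).
#' @param pmin,pmax tail frequencies, `0 <= pmin < pmax <= 1`.
#' @return expected northern-haplotype frequency at `x`.
#' @export
cline_predict <- function(x, center, width, pmin, pmax) {
  pmin + (pmax - pmin) * plogis(4 * (x - center) / width)
}

.cline_unpack <- function(par) {
  pmin <- plogis(par[3])
  pmax <- pmin + (1 - pmin) * plogis(par[4])
  c(center = unname(par[1]), width = exp(unname(par[2])),
    pmin = unname(pmin), pmax = unname(pmax))
}

.cline_negll <- function(par, x, n, k) {
  th <- .cline_unpack(par)
  p <- cline_predict(x, th["center"], th["width"], th["pmin"], th["pmax"])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

.cline_pack <- function(center, width, pmn, pmx) {
  c(center, log(width), qlogis(pmn), qlogis((pmx - pmn) / (1 - pmn)))
}

.fit_cline_ml <- function(x, n, k, starts) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], .cline_negll, x = x, n = n, k = k,
            method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

.cline_starts <- function(x, n, k) {
  f <- k / n
  span <- diff(range(x))
  cs <- unname(quantile(x, c(0.25, 0.5, 0.75)))
  ws <- c(span / 4, span)
  pmn <- min(max(min(f), 0.01), 0.2)
  pmx <- max(min(max(f), 0.99), 0.8)
  if (pmx <= pmn) { pmn <- 0.02; pmx <- 0.98 }
  grid <- expand.grid(center = cs, width = ws)
  t(apply(grid, 1, function(g) .cline_pack(g[1], g[2], pmn, pmx)))
}

#' Fit a sigmoid geographic cline by maximum likelihood
#'
#' Maximises the binomial log-likelihood of the northern-haplotype counts
#' over the four parameters of [cline_predict()], using six deterministic
#' starts on a center x width grid and bounded transforms (log width,
#' logit tail frequencies with `pmin < pmax` enforced by construction).
#' Parametric-bootstrap confidence intervals resimulate binomial counts
#' at the fitted cline and refit.
#'
#' @param distance distance of each site along the transect (km).
#' @param n number of alleles sampled per site (2 x diploids assigned).
#' @param k number of northern alleles per site.
#' @param boot number of parametric bootstrap replicates (0 to skip).
#' @param boot_seed seed for the bootstrap (NULL: continue RNG state).
#' @param level confidence level of the percentile intervals.
#' @return an object of class `cline_fit`: coefficients `center`,
#'   `width`, `pmin`, `pmax`; `logLik`; `ci` (percentile bootstrap
#'   bounds); `converged` and degeneracy `flags`; the data.
#' @export
fit_cline <- function(distance, n, k, boot = 200, boot_seed = NULL,
                      level = 0.95) {
  stopifnot(length(distance) == length(n), length(n) == length(k),
            all(k <= n), all(k >= 0))
  if (length(distance) < 4) stop("need at least 4 sites to fit a cline")
  x <- as.numeric(distance)
  starts <- .cline_starts(x, n, k)
  best <- .fit_cline_ml(x, n, k, starts)
  if (is.null(best)) {
    out <- structure(list(coefficients = c(center = NA, width = NA,
                                           pmin = NA, pmax = NA),
                          logLik = NA_real_, converged = FALSE,
                          flags = "no_convergence",
                          data = data.frame(distance = x, n = n, k = k),
                          ci = NULL, boot = NULL, level = level),
                     class = "cline_fit")
    return(out)
  }
  est <- .cline_unpack(best$par)
  flags <- character(0)
  span <- diff(range(x))
  if (est["width"] < span / 1e3) flags <- c(flags, "width_at_lower_bound")
  if (est["width"] > span * 10) flags <- c(flags, "width_exceeds_transect")
  if (est["pmax"] - est["pmin"] < 0.05) flags <- c(flags, "flat_frequency")
  if (all(k == 0) || all(k == n)) flags <- c(flags, "boundary_data")
  ci <- NULL
  boot_mat <- NULL
  if (boot > 0) {
    if (!is.null(boot_seed)) set.seed(boot_seed)
    p_hat <- cline_predict(x, est["center"], est["width"], est["pmin"],
                           est["pmax"])
    boot_mat <- matrix(NA_real_, boot, 4,
                       dimnames = list(NULL, names(est)))
    start1 <- rbind(best$par, starts[c(2, 5), , drop = FALSE])
    for (b in seq_len(boot)) {
      kb <- rbinom(length(x), n, p_hat)
      fb <- .fit_cline_ml(x, n, kb, start1)
      if (!is.null(fb)) boot_mat[b, ] <- .cline_unpack(fb$par)
    }
    alpha <- (1 - level) / 2
    ci <- apply(boot_mat, 2, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
  }
  structure(list(coefficients = est, logLik = -best$value,
                 converged = best$convergence == 0, flags = flags,
                 data = data.frame(distance = x, n = n, k = k),
                 ci = ci, boot = boot_mat, level = level),
            class = "cline_fit")
}

#' @export
coef.cline_fit <- function(object, ...) object$coefficients

#' @export
logLik.cline_fit <- function(object, ...) {
  structure(object$logLik, df = 4, class = "logLik")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat("Sigmoid cline fit (binomial ML)\n")
  cat(sprintf("  center = %.1f km, width = %.1f km, pmin = %.3f, pmax = %.3f\n",
              x$coefficients["center"], x$coefficients["width"],
              x$coefficients["pmin"], x$coefficients["pmax"]))
  cat(sprintf("  logLik = %.2f over %d sites (%d alleles)\n", x$logLik,
              nrow(x$data), sum(x$data$n)))
  if (!is.null(x$ci)) {
    cat(sprintf("  %d%% bootstrap CI width: [%.1f, %.1f] km\n",
                round(100 * x$level), x$ci[1, "width"], x$ci[2, "width"]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cline_fit <- function(object, ...) {
  est <- object$coefficients
  tab <- data.frame(estimate = est)
  if (!is.null(object$ci)) {
    tab$ci_lo <- object$ci[1, names(est)]
    tab$ci_hi <- object$ci[2, names(est)]
  }
  structure(list(coefficients = tab, logLik = object$logLik,
                 n_sites = nrow(object$data), n_alleles = sum(object$data$n),
                 converged = object$converged, flags = object$flags,
                 level = object$level),
            class = "summary.cline_fit")
}

#' @export
print.summary.cline_fit <- function(x, ...) {
  cat(sprintf("Cline fit: %d sites, %d alleles, logLik %.2f%s\n", x$n_sites,
              x$n_alleles, x$logLik,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$coefficients, 4))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.cline_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$distance else {
    if (is.list(newdata)) newdata$distance else newdata
  }
  est <- object$coefficients
  cline_predict(x, est["center"], est["width"], est["pmin"], est["pmax"])
}

#' @export
residuals.cline_fit <- function(object, ...) {
  object$data$k / object$data$n - predict(object)
}

#' Simulate haplotype counts from a fitted cline
#' @param object a `cline_fit`.
#' @param nsim number of replicate count vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame of `nsim` simulated `k` vectors.
#' @export
simulate.cline_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  as.data.frame(replicate(nsim, rbinom(length(p), object$data$n, p)))
}

#' @export
confint.cline_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$ci)) stop("fit was run without bootstrap replicates")
  ci <- t(object$ci)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.cline_fit <- function(x, ...) {
  d <- x$data
  xs <- seq(min(d$distance), max(d$distance), length.out = 200)
  plot(d$distance, d$k / d$n, pch = 19, xlab = "distance (km)",
       ylab = "northern-haplotype frequency", ylim = c(0, 1), ...)
  lines(xs, cline_predict(xs, x$coefficients["center"], x$coefficients["width"],
                          x$coefficients["pmin"], x$coefficients["pmax"]),
        lwd = 2)
  abline(v = x$coefficients["center"], lty = 3)
  invisible(x)
}

#' Expected cline width under neutral diffusion
#'
#' After `T` generations of diffusive mixing with per-generation dispersal
#' `sigma`, a neutral cline is expected to have flattened to width
#' `w = 2.51 * sigma * sqrt(T)` (diffusion approximation). With the
#' conventional post-contact scenario (sigma = 50 km, T = 100
#' generations) this gives 1255 km.
#'
#' @param sigma dispersal distance per generation (km).
#' @param T generations since secondary contact.
#' @return list with `sigma`, `T` and `width` (km).
#' @export
neutral_diffusion_width <- function(sigma = 50, T = 100) {
  stopifnot(sigma > 0, T > 0)
  list(sigma = sigma, T = T, width = 2.51 * sigma * sqrt(T))
}
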