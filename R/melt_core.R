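# Derivative machinery and melting-domain analysis.
#
# All peak logic operates on the negative derivative -dF/dT (the "negative
# derivative plot"): melting transitions appear as peaks, domain boundaries
# as the flanking local minima.

#' Smoothing and domain-detection parameters
#'
#' The window default (61 points, about 2.4 degC at the default 0.04 degC
#' grid spacing) is chosen so that the Savitzky-Golay first-derivative
#' noise stays well below the 10% domain threshold at realistic
#' instrument noise (0.5-1% of the melt amplitude), while transitions
#' separated by 4 degC or more are still resolved exactly. Narrower
#' windows over-resolve the derivative: its noise excursions then exceed
#' the domain threshold and spurious peaks appear on the transition
#' flanks.
#'
#' @param window Savitzky-Golay window, an odd number of grid points
#'   (default 61).
#' @param polyorder Polynomial order of the local fit (default 3);
#'   must satisfy `window > polyorder >= 2`.
#' @param domain_threshold Minimum relative height *and* prominence for a
#'   reported domain peak, as a fraction of the global maximum of -dF/dT
#'   (default 0.10); smaller peaks are treated as noise.
#' @param region_pad Degrees C added on each side of a domain to form its
#'   melting region (default 2.0).
#' @param min_domain_width Domains narrower than this (degC) are merged
#'   into their nearest neighbour (default 0.5).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(window = 61L, polyorder = 3L,
                             domain_threshold = 0.10, region_pad = 2.0,
                             min_domain_width = 0.5) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop_hrm("ConfigError", "window must be odd")
  if (!(window > polyorder && polyorder >= 2L)) {
    stop_hrm("ConfigError", "need window > polyorder >= 2")
  }
  if (!(domain_threshold > 0 && domain_threshold < 1)) {
    stop_hrm("ConfigError", "domain_threshold must lie in (0, 1)")
  }
  if (region_pad < 0) stop_hrm("ConfigError", "region_pad must be >= 0")
  if (min_domain_width < 0) stop_hrm("ConfigError", "min_domain_width must be >= 0")
  structure(list(window = window, polyorder = polyorder,
                 domain_threshold = domain_threshold,
                 region_pad = region_pad,
                 min_domain_width = min_domain_width),
            class = "smoothing_config")
}

#' Savitzky-Golay derivatives of a melt curve
#'
#' Fits a local polynomial (order `cfg$polyorder`, window `cfg$window`
#' points) to the fluorescence trace and evaluates its derivatives
#' analytically: `neg_dFdT` is \eqn{-dF/dT} (RFU/degC) and `d2` its
#' derivative \eqn{-d^2F/dT^2} (RFU/degC^2).
#'
#' @param curve A [melt_curve()] on a uniform grid.
#' @param cfg A [smoothing_config()].
#' @return An object of class `derivative_pair` with elements `grid`,
#'   `neg_dFdT`, `d2` and `sample_id`.
#' @export
smooth_derivatives <- function(curve, cfg = smoothing_config()) {
  stopifnot(inherits(curve, "melt_curve"))
  if (!grid_is_uniform(curve$temperatures, tol = 1e-6)) {
    stop_hrm("GridNotUniform",
             "sample %s: grid not uniform; resample_to_common_grid() first",
             curve$sample_id)
  }
  n <- length(curve$temperatures)
  if (cfg$window >= n) {
    stop_hrm("WindowTooLarge", "window %d >= %d grid points", cfg$window, n)
  }
  step <- (curve$temperatures[n] - curve$temperatures[1]) / (n - 1)
  neg1 <- -signal::sgolayfilt(curve$fluorescence, p = cfg$polyorder,
                              n = cfg$window, m = 1, ts = step)
  neg2 <- -signal::sgolayfilt(curve$fluorescence, p = cfg$polyorder,
                              n = cfg$window, m = 2, ts = step)
  structure(list(grid = curve$temperatures, neg_dFdT = neg1, d2 = neg2,
                 sample_id = curve$sample_id),
            class = "derivative_pair")
}

# Strict local maxima / minima of a numeric vector, as indices.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}
local_minima <- function(y) local_maxima(-y)

# Topographic prominence of each peak index: height above the higher of
# the two saddle minima separating it from higher ground (or the curve
# ends). Noise wiggles riding a transition flank have prominence on the
# scale of the noise; true transition peaks have prominence on the scale
# of their height.
peak_prominence <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(p) {
    higher_l <- which(y[seq_len(p - 1)] > y[p])
    higher_r <- which(y[seq(p + 1, length.out = n - p)] > y[p]) + p
    base_l <- min(y[(if (length(higher_l)) max(higher_l) else 1L):p])
    base_r <- min(y[p:(if (length(higher_r)) min(higher_r) else n)])
    y[p] - max(base_l, base_r)
  }, numeric(1))
}

new_melt_domain <- function(index, peak_idx, lo_idx, hi_idx, grid, neg, cfg) {
  peak_temp <- grid[peak_idx]
  structure(list(
    index = index,
    peak_temp = peak_temp,
    peak_height_rel = neg[peak_idx] / max(neg),
    domain_start = grid[lo_idx],
    domain_end = grid[hi_idx],
    region_start = max(grid[1], grid[lo_idx] - cfg$region_pad),
    region_end = min(grid[length(grid)], grid[hi_idx] + cfg$region_pad),
    peak_idx = peak_idx, lo_idx = lo_idx, hi_idx = hi_idx
  ), class = "melt_domain")
}

#' @export
print.melt_domain <- function(x, ...) {
  cat(sprintf(
    "<melt_domain %d> Tm %.2f degC (rel. height %.2f), domain %.2f-%.2f, region %.2f-%.2f\n",
    x$index, x$peak_temp, x$peak_height_rel,
    x$domain_start, x$domain_end, x$region_start, x$region_end))
  invisible(x)
}

#' Detect melting domains on a negative-derivative curve
#'
#' Peaks are the points where the slope of \eqn{-dF/dT} changes sign from
#' positive to negative (strict local maxima). A peak is reported as a
#' domain only if both its height and its topographic prominence reach
#' `domain_threshold` times the global maximum of \eqn{-dF/dT}; smaller
#' peaks are noise. Domain boundaries are the derivative valley (argmin
#' of \eqn{-dF/dT}) between adjacent reported peaks and, on the outer
#' flanks, the first point where \eqn{-dF/dT} drops back below the
#' threshold (the domain's return to the noise floor), falling back to
#' the grid ends. Domains narrower than `min_domain_width` are merged
#' into their nearest neighbour. When no peak survives, an empty list is
#' returned with a `hrm_NoDomainsFound` warning (not an error).
#'
#' @param deriv A [smooth_derivatives()] result.
#' @param cfg A [smoothing_config()].
#' @return List of `melt_domain` objects sorted by peak temperature.
#' @export
find_domains <- function(deriv, cfg = smoothing_config()) {
  stopifnot(inherits(deriv, "derivative_pair"))
  neg <- deriv$neg_dFdT
  grid <- deriv$grid
  n <- length(grid)
  if (!any(is.finite(neg)) || max(neg) <= 1e-8) {
    warn_hrm("NoDomainsFound",
             "negative derivative never meaningfully positive (no melt signal)")
    return(list())
  }
  cut <- cfg$domain_threshold * max(neg)
  peaks <- local_maxima(neg)
  peaks <- peaks[neg[peaks] >= cut]
  if (length(peaks) > 0) {
    peaks <- peaks[peak_prominence(neg, peaks) >= cut]
  }
  if (length(peaks) == 0) {
    warn_hrm("NoDomainsFound", "no derivative peak above threshold %.2f",
             cfg$domain_threshold)
    return(list())
  }
  peaks <- peaks[order(grid[peaks])]

  # boundaries: inter-peak valleys; outer flanks end where the derivative
  # sinks below the threshold
  lo <- hi <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    if (i > 1) {
      lo[i] <- peaks[i - 1] - 1L + which.min(neg[peaks[i - 1]:p])
    } else {
      below <- which(neg[seq_len(p)] < cut)
      lo[i] <- if (length(below)) max(below) else 1L
    }
    if (i < length(peaks)) {
      hi[i] <- p - 1L + which.min(neg[p:peaks[i + 1]])
    } else {
      below <- which(neg[seq(p, n)] < cut)
      hi[i] <- if (length(below)) p - 1L + min(below) else n
    }
  }
  doms <- data.frame(peak = peaks, lo = lo, hi = hi)

  # merge domains narrower than min_domain_width into the nearest neighbour
  while (nrow(doms) > 1) {
    width <- grid[doms$hi] - grid[doms$lo]
    narrow <- which(width < cfg$min_domain_width)
    if (length(narrow) == 0) break
    i <- narrow[1]
    nb <- if (i == 1) 2L
          else if (i == nrow(doms)) i - 1L
          else if (grid[doms$peak[i]] - grid[doms$peak[i - 1]] <=
                   grid[doms$peak[i + 1]] - grid[doms$peak[i]]) i - 1L
          else i + 1L
    doms$lo[nb] <- min(doms$lo[nb], doms$lo[i])
    doms$hi[nb] <- max(doms$hi[nb], doms$hi[i])
    if (neg[doms$peak[i]] > neg[doms$peak[nb]]) doms$peak[nb] <- doms$peak[i]
    doms <- doms[-i, , drop = FALSE]
  }

  lapply(seq_len(nrow(doms)), function(i) {
    new_melt_domain(i, doms$peak[i], doms$lo[i], doms$hi[i], grid, neg, cfg)
  })
}

#' Melting region of a domain
#'
#' The melting region extends `region_pad` degrees before the domain start
#' and after the domain end (default 2 degC each side), clipped to the
#' grid span.
#'
#' @param domain A `melt_domain`.
#' @param grid Temperature grid of the curve the domain was found on.
#' @param cfg A [smoothing_config()] supplying `region_pad`.
#' @return `c(start, end)` in degrees C.
#' @export
melting_region <- function(domain, grid, cfg = smoothing_config()) {
  stopifnot(inherits(domain, "melt_domain"))
  c(max(grid[1], domain$domain_start - cfg$region_pad),
    min(grid[length(grid)], domain$domain_end + cfg$region_pad))
}

#' Melting temperature of a domain
#'
#' The Tm of a domain is the temperature of its \eqn{-dF/dT} peak, i.e.
#' the temperature of maximal fluorescence loss rate.
#'
#' @param domain A `melt_domain`.
#' @return Tm in degrees C.
#' @export
melting_temperature <- function(domain) {
  stopifnot(inherits(domain, "melt_domain"))
  domain$peak_temp
}

#' Normalize a melting region with two-baseline background subtraction
#'
#' Fits one least-squares line to the leading `baseline_frac` of the
#' region (the pre-melt upper baseline U(T)) and one to the trailing
#' fraction (the post-melt lower baseline L(T)), then maps fluorescence to
#' `(F - L) / (U - L)`. A final affine rescale pins the mean of the
#' leading window at exactly 1 and the trailing window at exactly 0.
#' Values are clipped to [-0.05, 1.05]. Linear baselines absorb any
#' affine background exactly.
#'
#' @param curve A [melt_curve()] on a uniform grid.
#' @param region `c(start, end)` in degrees C, spanning >= 20 grid points.
#' @param baseline_frac Fraction of the region used for each baseline
#'   window (default 0.10, at least 5 points).
#' @return An object of class `normalized_domain_curve` with elements
#'   `grid`, `values` (0..1, reported to users as 0-100%), `region`,
#'   `sample_id` and `meta`.
#' @export
normalize_domain <- function(curve, region, baseline_frac = 0.10) {
  stopifnot(inherits(curve, "melt_curve"))
  sel <- which(curve$temperatures >= region[1] - 1e-9 &
               curve$temperatures <= region[2] + 1e-9)
  if (length(sel) < 20) {
    stop_hrm("RegionTooNarrow", "region spans %d grid points (< 20)", length(sel))
  }
  g <- curve$temperatures[sel]
  f <- curve$fluorescence[sel]
  nb <- max(5L, ceiling(baseline_frac * length(sel)))
  lead <- seq_len(nb)
  trail <- seq(length(sel) - nb + 1L, length(sel))
  fitU <- lm(f[lead] ~ g[lead])
  fitL <- lm(f[trail] ~ g[trail])
  U <- coef(fitU)[1] + coef(fitU)[2] * g
  L <- coef(fitL)[1] + coef(fitL)[2] * g
  if (any(U - L <= 0)) {
    stop_hrm("DegenerateBaselines",
             "upper baseline does not exceed lower baseline across the region")
  }
  v <- (f - L) / (U - L)
  # pin window means at exactly 1 / 0 (affine, so baseline absorption holds)
  mu1 <- mean(v[lead]); mu0 <- mean(v[trail])
  if (mu1 - mu0 <= 0) {
    stop_hrm("DegenerateBaselines", "leading window mean does not exceed trailing")
  }
  v <- (v - mu0) / (mu1 - mu0)
  v <- pmin(pmax(v, -0.05), 1.05)
  structure(list(grid = g, values = v, region = c(g[1], g[length(g)]),
                 baseline_frac = baseline_frac,
                 sample_id = curve$sample_id, meta = curve$meta),
            class = "normalized_domain_curve")
}

#' @export
print.normalized_domain_curve <- function(x, ...) {
  cat(sprintf("<normalized_domain_curve> %s, region %.2f-%.2f degC, %d points\n",
              x$sample_id, x$region[1], x$region[2], length(x$grid)))
  invisible(x)
}
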