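# Independent oracles and small fixture builders used across the suite.

# Naive exhaustive scan: strict local maxima of a derivative curve with
# height at least thr * max. Deliberately a plain loop, independent of the
# package's vectorised peak logic.
oracle_peaks <- function(neg, thr = 0.10) {
  keep <- integer()
  cut <- thr * max(neg)
  for (i in 2:(length(neg) - 1)) {
    if (neg[i] > neg[i - 1] && neg[i] > neg[i + 1] && neg[i] >= cut) {
      keep <- c(keep, i)
    }
  }
  keep
}

# Closed-form logistic melt: F(T) = amp / (1 + exp((T - tm)/slope)).
logistic_melt <- function(temps, tm = 80, slope = 1, amp = 100) {
  amp / (1 + exp((temps - tm) / slope))
}

default_grid <- function(lo = 65, hi = 95, step = 0.04) seq(lo, hi, by = step)

# Noise-free multi-transition curve with a linear background, wrapped as a
# melt_curve.
make_curve <- function(tms, slopes, weights, grid = default_grid(),
                       amp = 1000, bg0 = 100, bg_slope = -1, noise = 0,
                       id = "s1", meta = sample_meta("test")) {
  f <- bg0 + bg_slope * (grid - grid[1])
  for (i in seq_along(tms)) {
    f <- f + amp * weights[i] / (1 + exp((grid - tms[i]) / slopes[i]))
  }
  if (noise > 0) f <- f + rnorm(length(grid), 0, noise)
  melt_curve(id, grid, pmax(f, 0), meta)
}

# Random well-separated transition layout: the regime where height-only
# and prominence-filtered peak sets provably coincide.
random_layout <- function() {
  n <- sample(1:4, 1)
  first <- runif(1, 70, 88 - 6 * (n - 1))
  gaps <- if (n > 1) runif(n - 1, 6, (88 - first) / (n - 1)) else numeric()
  tms <- first + cumsum(c(0, gaps))
  w <- runif(n, 0.25, 0.4)
  list(tms = tms, slopes = runif(n, 0.6, 1.0), weights = w / sum(w))
}

# Bare normalized-curve object for reference/difference unit tests.
fake_norm <- function(values, grid = seq(70, 90, 0.1), id = "c",
                      sex = "unknown", role = "control") {
  structure(list(grid = grid, values = values,
                 region = c(grid[1], grid[length(grid)]),
                 baseline_frac = 0.1, sample_id = id,
                 meta = sample_meta(role, sex = sex)),
            class = "normalized_domain_curve")
}

fake_diff <- function(z, grid = seq_along(z)) {
  structure(list(grid = grid, z = z, diff = z, max_abs_z = max(abs(z)),
                 longest_run = NA, k = 2, scope = "amplicon",
                 sample_id = "s"),
            class = "difference_result")
}

write_wide_fixture <- function(dir, temps, samples, meta_rows) {
  curve_path <- file.path(dir, "curves.csv")
  meta_path <- file.path(dir, "meta.csv")
  tab <- cbind(data.frame(temperature = temps), as.data.frame(samples))
  write.csv(tab, curve_path, row.names = FALSE, quote = FALSE)
  write.csv(meta_rows, meta_path, row.names = FALSE, quote = FALSE)
  list(curves = curve_path, meta = meta_path)
}
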