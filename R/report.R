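# Run configuration, report writers, plotting, and the benchmark loop
# behind the command-line interface (inst/cli/hrm.R).

run_config_defaults <- function() {
  list(
    # smoothing / domain detection
    window = 61L, polyorder = 3L, threshold = 0.10, region_pad = 2.0,
    min_domain_width = 0.5, baseline_frac = 0.10,
    # classification
    k = 2.0, m = 10L, stratify_by_sex = FALSE, combine_preparations = TRUE,
    center = "median",
    # io
    curves = NULL, metadata = NULL, out_dir = ".", plots = FALSE,
    # simulation
    seed = 1L, n_controls = 16L, n_variants = 50L, n_wildtype_tests = 0L,
    wt_tm = 80, slope = 1.0, amplitude = 1000, noise_sd = 5,
    grid_lo = 65, grid_hi = 95, grid_step = 0.04,
    hom_delta = -0.3, het_delta = -2, het_delta_lo = NULL, het_delta_hi = NULL,
    fractions = c(0.25, 0.25, 0.5),
    # benchmark
    n_seeds = 20L)
}

#' Build and validate a run configuration
#'
#' Collects every tunable of the pipeline (smoothing window and order,
#' domain threshold, region pad, band parameters k and m, stratification
#' flags, simulation parameters, paths) with the package defaults.
#' Unknown keys are rejected so typos in a config file fail loudly.
#'
#' @param ... Named overrides of the defaults.
#' @param base Optional named list (e.g. parsed from a YAML file) applied
#'   before `...`.
#' @return A validated named list of class `run_config`.
#' @export
run_config <- function(..., base = list()) {
  cfg <- run_config_defaults()
  for (src in list(base, list(...))) {
    if (length(src) == 0) next
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown) > 0) {
      stop_hrm("ConfigError", "unknown config key(s): %s",
               paste(unknown, collapse = ", "))
    }
    cfg[names(src)] <- src
  }
  # delegate numeric validation to the underlying constructors
  smoothing_config(cfg$window, cfg$polyorder, cfg$threshold,
                   cfg$region_pad, cfg$min_domain_width)
  if (cfg$k <= 0 || cfg$m < 1) stop_hrm("ConfigError", "need k > 0 and m >= 1")
  structure(cfg, class = "run_config")
}

smoothing_from_config <- function(cfg) {
  smoothing_config(cfg$window, cfg$polyorder, cfg$threshold,
                   cfg$region_pad, cfg$min_domain_width)
}

base_spec_from_config <- function(cfg) {
  simulation_spec(list(transition_spec(cfg$wt_tm, cfg$slope, 1.0)),
                  amplitude = cfg$amplitude, noise_sd = cfg$noise_sd,
                  grid = c(cfg$grid_lo, cfg$grid_hi, cfg$grid_step))
}

#' Write the per-(sample, scope) calls table as TSV
#'
#' @param analysis An `hrm_analysis`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calls_tsv <- function(analysis, path) {
  stopifnot(inherits(analysis, "hrm_analysis"))
  write.table(analysis$scope_calls, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write the per-amplicon JSON summary
#'
#' Records the detected domains (Tm, relative peak height, melting
#' region), the per-sample domain tally, final calls with their
#' supporting scopes, and the parameters used. Calls are screening
#' results: positives need confirmation by Sanger sequencing.
#'
#' @param analysis An `hrm_analysis`.
#' @param path Output path.
#' @param seed Optional seed recorded for reproducibility.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(analysis, path, seed = NULL) {
  stopifnot(inherits(analysis, "hrm_analysis"))
  s <- summary(analysis)
  out <- list(
    amplicon_id = if (nrow(s$calls) > 0) s$calls$amplicon_id[1]
                  else analysis$set$curves[[1]]$meta$amplicon_id,
    parameters = analysis$config[c("k", "m", "stratify_by_sex",
                                   "combine_preparations", "baseline_frac",
                                   "center")],
    smoothing = unclass(analysis$config$cfg),
    seed = seed,
    domains = s$domains,
    domain_tally_per_sample = as.list(s$domain_tally),
    calls = s$calls,
    note = "screening result: variant calls require confirmation by sequencing")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Three-panel HRM plot for one analysis scope
#'
#' Mirrors the standard HRM display: normalized melt curves, the negative
#' derivative, and the difference plot with the control band (centre
#' +/- k*sd) shaded grey. Controls are drawn in grey, test samples in
#' colour.
#'
#' @param x An `hrm_analysis`.
#' @param scope Scope name (`"amplicon"` or `"domain_<i>"`; default the
#'   first domain if any, else the amplicon).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.hrm_analysis <- function(x, scope = NULL, ...) {
  scopes <- unique(x$scope_calls$scope)
  if (length(scopes) == 0) scopes <- "amplicon"
  if (is.null(scope)) scope <- scopes[1]
  region <- if (scope == "amplicon") {
    c(x$set$grid[1], x$set$grid[length(x$set$grid)])
  } else {
    d <- x$domains[[as.integer(sub("domain_", "", scope))]]
    melting_region(d, x$set$grid, x$config$cfg)
  }
  cfg <- x$config$cfg
  norm <- lapply(x$set$curves, normalize_domain, region = region,
                 baseline_frac = x$config$baseline_frac)
  is_ctl <- vapply(x$set$curves, function(cv) cv$meta$role == "control",
                   logical(1))
  ref <- build_reference(norm[is_ctl], stratum = "all",
                         center = x$config$center)
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  # panel 1: normalized melt curves (percent scale)
  plot(NA, xlim = region, ylim = c(-5, 105), xlab = "Temperature (°C)",
       ylab = "Normalized fluorescence (%)", main = paste("Melt curves:", scope))
  for (i in seq_along(norm)) {
    lines(norm[[i]]$grid, 100 * norm[[i]]$values,
          col = if (is_ctl[i]) "grey60" else i + 1)
  }
  # panel 2: negative derivative
  derivs <- lapply(x$set$curves, smooth_derivatives, cfg = cfg)
  dmax <- max(vapply(derivs, function(dv) max(dv$neg_dFdT), numeric(1)))
  plot(NA, xlim = range(x$set$grid), ylim = c(0, 1.05 * dmax),
       xlab = "Temperature (°C)", ylab = "-dF/dT (RFU/°C)",
       main = "Negative derivative")
  for (i in seq_along(derivs)) {
    lines(derivs[[i]]$grid, derivs[[i]]$neg_dFdT,
          col = if (is_ctl[i]) "grey60" else i + 1)
  }
  for (d in x$domains) abline(v = d$peak_temp, lty = 3, col = "grey40")
  # panel 3: difference plot with grey control band
  band <- x$config$k * pmax(ref$sd, max(quantile(ref$sd, 0.10), 1e-6))
  dd <- Filter(function(d) d$scope == scope, x$diffs)
  ylim <- range(c(-band, band,
                  unlist(lapply(dd, function(d) d$diff))), na.rm = TRUE)
  plot(NA, xlim = region, ylim = 100 * ylim, xlab = "Temperature (°C)",
       ylab = "Difference from control median (%)",
       main = sprintf("Difference plot (±%.1f sd)", x$config$k))
  polygon(c(ref$grid, rev(ref$grid)), 100 * c(band, rev(-band)),
          col = adjustcolor("grey", 0.5), border = NA)
  for (i in seq_along(dd)) {
    lines(dd[[i]]$grid, 100 * dd[[i]]$diff, col = i + 1)
  }
  abline(h = 0, col = "grey30")
  invisible(x)
}

#' Run the full analysis from files and write report artifacts
#'
#' Reads the curve and metadata tables named in the config, runs
#' [analyze_experiment()], and writes `calls.tsv`, `summary.json` and
#' (optionally) one three-panel PNG per scope into `out_dir`.
#'
#' @param config A [run_config()] with `curves` and `metadata` paths set.
#' @return The `hrm_analysis`, invisibly.
#' @export
run_analyze <- function(config = run_config()) {
  if (is.null(config$curves) || is.null(config$metadata)) {
    stop_hrm("ConfigError", "config must name 'curves' and 'metadata' files")
  }
  set <- read_melt_export(config$curves, config$metadata,
                          step = config$grid_step)
  analysis <- analyze_experiment(
    set, cfg = smoothing_from_config(config), k = config$k, m = config$m,
    stratify_by_sex = config$stratify_by_sex,
    combine_preparations = config$combine_preparations,
    baseline_frac = config$baseline_frac, center = config$center)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_calls_tsv(analysis, file.path(config$out_dir, "calls.tsv"))
  write_summary_json(analysis, file.path(config$out_dir, "summary.json"),
                     seed = config$seed)
  if (isTRUE(config$plots)) {
    for (sc in unique(analysis$scope_calls$scope)) {
      png(file.path(config$out_dir, paste0("plot_", sc, ".png")),
          width = 1500, height = 500)
      plot(analysis, scope = sc)
      dev.off()
    }
  }
  invisible(analysis)
}

#' Simulate a cohort and write it in the analyzable file formats
#'
#' Writes `curves.csv` (wide), `metadata.csv` and `truth.json` into
#' `out_dir`; the first two round-trip through [read_melt_export()].
#'
#' @param config A [run_config()].
#' @return The cohort list from [simulate_cohort()], invisibly.
#' @export
run_simulate <- function(config = run_config()) {
  hdr <- if (!is.null(config$het_delta_lo) && !is.null(config$het_delta_hi)) {
    c(config$het_delta_lo, config$het_delta_hi)
  } else NULL
  cohort <- simulate_cohort(
    n_controls = config$n_controls, n_variants = config$n_variants,
    mix = duplex_mixture_spec(config$wt_tm, config$hom_delta,
                              config$het_delta, config$fractions),
    base = base_spec_from_config(config), seed = config$seed,
    het_delta_range = hdr, n_wildtype_tests = config$n_wildtype_tests)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_melt_export(cohort$set, file.path(config$out_dir, "curves.csv"),
                    file.path(config$out_dir, "metadata.csv"))
  jsonlite::write_json(
    list(seed = cohort$truth$seed, labels = as.list(cohort$truth$labels),
         control_ids = cohort$truth$control_ids),
    file.path(config$out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(cohort)
}

#' Benchmark end-to-end detection performance over seeded cohorts
#'
#' For each of `n_seeds` seeds (`seed`, `seed + 1`, ...): simulate a
#' cohort, run the full analysis, and score calls against truth. Reports
#' the per-seed confusion counts and the mean sensitivity/specificity.
#'
#' @param config A [run_config()]; `n_seeds`, `seed` and the simulation
#'   fields control the sweep.
#' @param quiet Suppress the per-seed printout.
#' @return A list with `per_seed` (data frame), `mean_sensitivity` and
#'   `mean_specificity` (NA when undefined in every seed).
#' @export
run_benchmark <- function(config = run_config(), quiet = FALSE) {
  rows <- lapply(seq_len(config$n_seeds), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    hdr <- if (!is.null(config$het_delta_lo) && !is.null(config$het_delta_hi)) {
      c(config$het_delta_lo, config$het_delta_hi)
    } else NULL
    cohort <- simulate_cohort(
      n_controls = cfg_i$n_controls, n_variants = cfg_i$n_variants,
      mix = duplex_mixture_spec(cfg_i$wt_tm, cfg_i$hom_delta,
                                cfg_i$het_delta, cfg_i$fractions),
      base = base_spec_from_config(cfg_i), seed = cfg_i$seed,
      het_delta_range = hdr, n_wildtype_tests = cfg_i$n_wildtype_tests)
    analysis <- suppressWarnings(analyze_experiment(
      cohort$set, cfg = smoothing_from_config(cfg_i), k = cfg_i$k, m = cfg_i$m,
      stratify_by_sex = cfg_i$stratify_by_sex,
      combine_preparations = cfg_i$combine_preparations,
      baseline_frac = cfg_i$baseline_frac, center = cfg_i$center))
    met <- evaluate_detection(analysis, cohort$truth)
    data.frame(seed = cfg_i$seed, tp = met$tp, fn = met$fn, tn = met$tn,
               fp = met$fp, sensitivity = met$sensitivity,
               specificity = met$specificity)
  })
  per_seed <- do.call(rbind, rows)
  res <- list(per_seed = per_seed,
              mean_sensitivity = mean(per_seed$sensitivity, na.rm = TRUE),
              mean_specificity = mean(per_seed$specificity, na.rm = TRUE))
  if (!quiet) {
    print(per_seed, row.names = FALSE)
    cat(sprintf("mean sensitivity: %.4f   mean specificity: %s\n",
                res$mean_sensitivity,
                if (is.finite(res$mean_specificity))
                  sprintf("%.4f", res$mean_specificity) else "undefined"))
  }
  invisible(res)
}
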