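# Median/SD reference bands, difference curves, and variant/normal calling.

#' Build a reference band from control curves
#'
#' Collapses a set of normalized control curves into a per-temperature
#' centre curve and spread. The median is the default centre because it is
#' less affected by an outlying control than the mean; the per-point
#' sample standard deviation of the controls describes the variability of
#' the control set (the grey band of a difference plot).
#'
#' @param controls List of [normalize_domain()] results on one grid.
#' @param stratum Sex filter recorded with the band: `"all"`, `"male"` or
#'   `"female"`. Curves are filtered by `meta$sex` unless `"all"`.
#' @param center `"median"` (default) or `"mean"`.
#' @return An object of class `reference_band` with elements `grid`,
#'   `median`, `sd`, `n_controls`, `stratum`, `center`, `control_ids`.
#' @export
build_reference <- function(controls, stratum = c("all", "male", "female"),
                            center = c("median", "mean")) {
  stratum <- match.arg(stratum)
  center <- match.arg(center)
  if (stratum != "all") {
    controls <- Filter(function(x) x$meta$sex == stratum, controls)
  }
  if (length(controls) < 2) {
    stop_hrm("TooFewControls",
             "need >= 2 controls to form a reference band (have %d, stratum %s)",
             length(controls), stratum)
  }
  if (length(controls) < 3) {
    warn_hrm("FewControls", "only %d controls; >= 3 recommended", length(controls))
  }
  grid <- controls[[1]]$grid
  ok <- vapply(controls, function(x) {
    length(x$grid) == length(grid) && max(abs(x$grid - grid)) <= 1e-9
  }, logical(1))
  if (!all(ok)) stop_hrm("GridMismatch", "control curves are on different grids")
  mat <- vapply(controls, function(x) x$values, numeric(length(grid)))
  ctr <- apply(mat, 1, if (center == "median") stats::median else mean)
  structure(list(grid = grid, median = ctr, sd = apply(mat, 1, stats::sd),
                 n_controls = length(controls), stratum = stratum,
                 center = center,
                 control_ids = vapply(controls, function(x) x$sample_id,
                                      character(1))),
            class = "reference_band")
}

#' @export
print.reference_band <- function(x, ...) {
  cat(sprintf(
    "<reference_band> %d controls (%s, %s centre), %.2f-%.2f degC, max sd %.3g\n",
    x$n_controls, x$stratum, x$center, min(x$grid), max(x$grid), max(x$sd)))
  invisible(x)
}

longest_true_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Difference curve of a sample against a reference band
#'
#' Point-wise difference `sample - median` and the standardized deviation
#' `z = diff / sd`. Because baseline-window points have near-zero sd by
#' construction, the per-point sd is floored at the 10th percentile of the
#' band's sd values (and at 1e-6 absolute) before forming `z`.
#'
#' @param sample A [normalize_domain()] result on the reference grid.
#' @param ref A [build_reference()] band.
#' @param k SD multiplier used to fill the `longest_run` summary
#'   (default 2); [classify_sample()] recomputes runs for its own `k`.
#' @param scope Label for the analysis scope (`"amplicon"` or a domain
#'   index).
#' @return An object of class `difference_result` with elements `grid`,
#'   `diff`, `z`, `max_abs_z`, `longest_run`, `k`, `scope`, `sample_id`.
#' @export
difference_curve <- function(sample, ref, k = 2.0, scope = "amplicon") {
  stopifnot(inherits(sample, "normalized_domain_curve"),
            inherits(ref, "reference_band"))
  if (length(sample$grid) != length(ref$grid) ||
      max(abs(sample$grid - ref$grid)) > 1e-9) {
    stop_hrm("GridMismatch", "sample %s grid differs from reference grid",
             sample$sample_id)
  }
  d <- sample$values - ref$median
  floor_sd <- max(stats::quantile(ref$sd, 0.10, names = FALSE), 1e-6)
  z <- d / pmax(ref$sd, floor_sd)
  structure(list(grid = sample$grid, diff = d, z = z,
                 max_abs_z = max(abs(z)),
                 longest_run = longest_true_run(abs(z) > k),
                 k = k, scope = scope, sample_id = sample$sample_id,
                 ref = ref),
            class = "difference_result")
}

#' Classify a difference curve as variant or normal
#'
#' A sample is called `variant` when its standardized deviation exceeds
#' `k` in absolute value for at least `m` consecutive grid points — a
#' sustained excursion outside the control band (about 0.4 degC at the
#' default m = 10 and 0.04 degC spacing), which suppresses single-point
#' noise.
#'
#' @param result A [difference_curve()] result.
#' @param k SD multiplier defining the band half-width (default 2).
#' @param m Minimum run length in grid points (default 10).
#' @return `"variant"` or `"normal"`.
#' @export
classify_sample <- function(result, k = 2.0, m = 10L) {
  stopifnot(inherits(result, "difference_result"), k > 0, m >= 1)
  run <- longest_true_run(abs(result$z) > k)
  if (run >= m) "variant" else "normal"
}

# Point-wise median curve of the control wells, used so that domains (and
# hence analysis scopes) are detected once per experiment and shared by
# every sample.
median_control_curve <- function(set) {
  ctl <- Filter(function(cv) cv$meta$role == "control", set$curves)
  mat <- vapply(ctl, function(cv) cv$fluorescence, numeric(length(set$grid)))
  melt_curve("median_control", set$grid, apply(mat, 1, stats::median),
             sample_meta("control", amplicon_id = ctl[[1]]$meta$amplicon_id))
}

pick_stratum <- function(stratify, sex, n_by_sex) {
  if (!stratify || sex == "unknown") return("all")
  if (n_by_sex[[sex]] >= 2) sex else {
    warn_hrm("MissingStratumControls",
             "fewer than 2 %s controls; falling back to unstratified reference",
             sex)
    "all"
  }
}

#' Analyse an HRM experiment: two-step, sex-stratified variant scanning
#'
#' Runs the full screening analysis on one amplicon's curves:
#' \enumerate{
#'   \item Whole-amplicon pass: every curve is normalized over the full
#'     temperature span and compared against the control band.
#'   \item Per-domain pass: melting domains are detected once, on the
#'     median control curve, so all samples share identical scopes; each
#'     domain's padded melting region is then normalized and compared
#'     separately. Long amplicons (> 300 bp) melting in several domains
#'     gain sensitivity from this pass.
#' }
#' A sample is called `variant` when any scope, in any of its
#' preparations, shows a sustained excursion beyond the `k` SD band for
#' `m` consecutive points. With `stratify_by_sex`, male and female test
#' samples are compared against same-sex control bands (falling back to
#' all controls, with a warning, when fewer than 2 same-sex controls
#' exist). With `combine_preparations`, the mixed (artificial
#' heterozygote) and unmixed preparations of one individual — linked by
#' `preparation_group` — are OR-combined into a single call, since either
#' preparation may show the clearer deviation.
#'
#' @param set An [experiment_set()] containing >= 2 control curves.
#' @param cfg A [smoothing_config()].
#' @param k SD multiplier for the normality band (default 2).
#' @param m Minimum run length in grid points (default 10).
#' @param stratify_by_sex Compare test samples against same-sex controls.
#' @param combine_preparations OR-combine calls across preparations of the
#'   same individual (default TRUE).
#' @param baseline_frac Baseline window fraction for [normalize_domain()].
#' @param center Reference centre, `"median"` (default) or `"mean"`.
#' @return An object of class `hrm_analysis`; see [summary.hrm_analysis()],
#'   [residuals.hrm_analysis()] and [plot.hrm_analysis()].
#' @export
analyze_experiment <- function(set, cfg = smoothing_config(), k = 2.0, m = 10L,
                               stratify_by_sex = FALSE,
                               combine_preparations = TRUE,
                               baseline_frac = 0.10,
                               center = c("median", "mean")) {
  stopifnot(inherits(set, "experiment_set"))
  center <- match.arg(center)
  roles <- vapply(set$curves, function(cv) cv$meta$role, character(1))
  controls <- set$curves[roles == "control"]
  queries <- set$curves[roles != "control"]
  if (length(controls) < 2) {
    stop_hrm("TooFewControls", "need >= 2 control curves, have %d",
             length(controls))
  }
  n_by_sex <- list(
    male = sum(vapply(controls, function(cv) cv$meta$sex == "male", logical(1))),
    female = sum(vapply(controls, function(cv) cv$meta$sex == "female", logical(1))))

  # scopes: the whole amplicon, then each domain detected on the median
  # control derivative
  med_curve <- median_control_curve(set)
  med_deriv <- smooth_derivatives(med_curve, cfg)
  domains <- find_domains(med_deriv, cfg)
  scopes <- c(list(list(name = "amplicon",
                        region = c(set$grid[1], set$grid[length(set$grid)]))),
              lapply(domains, function(d) {
                list(name = sprintf("domain_%d", d$index),
                     region = melting_region(d, set$grid, cfg), domain = d)
              }))

  # stratum choice is per sample, not per scope: warn once per sample
  strata <- vapply(queries, function(cv) {
    pick_stratum(stratify_by_sex, cv$meta$sex, n_by_sex)
  }, character(1))

  # per-sample domain tally diagnostic (domains found on each sample's own
  # derivative)
  tally <- vapply(set$curves, function(cv) {
    length(suppressWarnings(find_domains(smooth_derivatives(cv, cfg), cfg)))
  }, integer(1))

  diffs <- list()
  refs <- list()
  rows <- list()
  for (sc in scopes) {
    norm_ctl <- tryCatch(
      lapply(controls, normalize_domain, region = sc$region,
             baseline_frac = baseline_frac),
      hrm_error = function(e) {
        warn_hrm("ScopeSkipped", "scope %s skipped for all samples: %s",
                 sc$name, conditionMessage(e))
        NULL
      })
    if (is.null(norm_ctl)) next
    band <- list()  # lazily built per stratum
    get_band <- function(stratum) {
      if (is.null(band[[stratum]])) {
        band[[stratum]] <<- build_reference(norm_ctl, stratum = stratum,
                                            center = center)
      }
      band[[stratum]]
    }
    for (cv in queries) {
      stratum <- strata[[cv$sample_id]]
      ref <- suppressWarnings(get_band(stratum))
      ns <- tryCatch(
        normalize_domain(cv, sc$region, baseline_frac = baseline_frac),
        hrm_DegenerateBaselines = function(e) {
          warn_hrm("ScopeSkipped", "sample %s, scope %s: %s",
                   cv$sample_id, sc$name, conditionMessage(e))
          NULL
        })
      if (is.null(ns)) next
      dres <- difference_curve(ns, ref, k = k, scope = sc$name)
      diffs[[length(diffs) + 1L]] <- dres
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = cv$sample_id, scope = sc$name, stratum = ref$stratum,
        max_abs_z = dres$max_abs_z,
        longest_run = longest_true_run(abs(dres$z) > k),
        call = classify_sample(dres, k = k, m = m),
        stringsAsFactors = FALSE)
    }
    refs[[sc$name]] <- band
  }
  scope_calls <- do.call(rbind, rows)

  # aggregate scopes into one call per preparation, then OR-combine the
  # preparations of one individual
  prep_call <- do.call(rbind, lapply(queries, function(cv) {
    sub <- scope_calls[scope_calls$sample_id == cv$sample_id, , drop = FALSE]
    data.frame(sample_id = cv$sample_id,
               preparation_group = cv$meta$preparation_group,
               mixed = cv$meta$mixed, sex = cv$meta$sex,
               amplicon_id = cv$meta$amplicon_id,
               call = if (any(sub$call == "variant")) "variant" else "normal",
               supporting_scopes = paste(sub$scope[sub$call == "variant"],
                                         collapse = ","),
               stringsAsFactors = FALSE)
  }))

  calls <- list()
  if (!is.null(prep_call) && nrow(prep_call) > 0) {
    grp <- ifelse(combine_preparations & !is.na(prep_call$preparation_group) &
                    prep_call$preparation_group != "NA",
                  prep_call$preparation_group, prep_call$sample_id)
    for (g in unique(grp)) {
      sub <- prep_call[grp == g, , drop = FALSE]
      calls[[g]] <- structure(list(
        sample_id = g,
        amplicon_id = sub$amplicon_id[1],
        call = if (any(sub$call == "variant")) "variant" else "normal",
        supporting_scopes = unique(unlist(strsplit(
          sub$supporting_scopes[sub$supporting_scopes != ""], ","))),
        preparation_calls = sub[, c("sample_id", "mixed", "call")],
        parameters = c(k = k, m = m)), class = "variant_call")
    }
  }

  structure(list(calls = calls, scope_calls = scope_calls,
                 preparation_calls = prep_call,
                 domains = domains, domain_tally = tally,
                 references = refs, diffs = diffs, set = set,
                 config = list(cfg = cfg, k = k, m = m,
                               stratify_by_sex = stratify_by_sex,
                               combine_preparations = combine_preparations,
                               baseline_frac = baseline_frac,
                               center = center)),
            class = "hrm_analysis")
}

#' Extract final calls as a data frame
#'
#' @param x An `hrm_analysis`.
#' @return One row per individual (preparation group) with its call and
#'   supporting scopes.
#' @export
calls_table <- function(x) {
  stopifnot(inherits(x, "hrm_analysis"))
  if (length(x$calls) == 0) {
    return(data.frame(sample_id = character(), amplicon_id = character(),
                      call = character(), supporting_scopes = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$calls, function(vc) {
    data.frame(sample_id = vc$sample_id, amplicon_id = vc$amplicon_id,
               call = vc$call,
               supporting_scopes = paste(vc$supporting_scopes, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.variant_call <- function(x, ...) {
  cat(sprintf("<variant_call> %s [%s]: %s%s\n", x$sample_id, x$amplicon_id,
              toupper(x$call),
              if (length(x$supporting_scopes))
                paste0(" (", paste(x$supporting_scopes, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' @export
print.hrm_analysis <- function(x, ...) {
  tab <- calls_table(x)
  cat(sprintf("HRM variant-scanning analysis: %d samples vs %d controls, %d domain(s)\n",
              nrow(tab),
              sum(vapply(x$set$curves, function(cv) cv$meta$role == "control",
                         logical(1))),
              length(x$domains)))
  cat(sprintf("  band: centre %s +/- %.1f sd, run >= %d points\n",
              x$config$center, x$config$k, x$config$m))
  if (nrow(tab) > 0) {
    cat(sprintf("  calls: %d variant, %d normal\n",
                sum(tab$call == "variant"), sum(tab$call == "normal")))
  }
  cat("Screening result only: variant calls require confirmation by sequencing.\n")
  invisible(x)
}

#' Summarize an HRM analysis
#'
#' @param object An `hrm_analysis`.
#' @param ... Unused.
#' @return A list with the calls table, per-scope detail, detected domain
#'   Tm values, and the per-sample domain tally, printed compactly.
#' @export
summary.hrm_analysis <- function(object, ...) {
  out <- list(
    calls = calls_table(object),
    scope_calls = object$scope_calls,
    domains = data.frame(
      index = vapply(object$domains, function(d) d$index, integer(1)),
      tm = vapply(object$domains, melting_temperature, numeric(1)),
      peak_height_rel = vapply(object$domains, function(d) d$peak_height_rel,
                               numeric(1)),
      region_start = vapply(object$domains, function(d) d$region_start,
                            numeric(1)),
      region_end = vapply(object$domains, function(d) d$region_end, numeric(1))),
    domain_tally = object$domain_tally)
  class(out) <- "summary.hrm_analysis"
  out
}

#' @export
print.summary.hrm_analysis <- function(x, ...) {
  cat("Detected melting domains (on median control curve):\n")
  print(x$domains, row.names = FALSE)
  cat("\nCalls:\n")
  print(x$calls, row.names = FALSE)
  invisible(x)
}

#' Standardized residual curves of an HRM analysis
#'
#' @param object An `hrm_analysis`.
#' @param ... Unused.
#' @return Long data frame of per-point differences and z scores for every
#'   (sample, scope) comparison.
#' @export
residuals.hrm_analysis <- function(object, ...) {
  do.call(rbind, lapply(object$diffs, function(d) {
    data.frame(sample_id = d$sample_id, scope = d$scope,
               temperature = d$grid, diff = d$diff, z = d$z,
               stringsAsFactors = FALSE)
  }))
}
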