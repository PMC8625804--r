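# Synthetic melt curves and cohorts with known ground truth.
#
# Melting is modelled as a weighted sum of two-state (logistic) helix-to-
# coil transitions; this is not a thermodynamic sequence model, but the
# analysis only consumes curve shape, and logistic transitions have
# closed-form derivatives that make oracle checks exact.

# Evaluate expr with a temporary RNG state when seed is given; the
# caller's .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' One melting transition
#'
#' @param tm Melting temperature (degC): midpoint of the logistic.
#' @param slope Logistic width parameter (degC); the -dF/dT peak height of
#'   a unit-weight transition is `amplitude / (4 * slope)`.
#' @param weight Fraction of the total amplitude lost in this transition.
#' @return An object of class `transition_spec`.
#' @export
transition_spec <- function(tm, slope = 1.0, weight = 1.0) {
  if (slope <= 0) stop_hrm("ConfigError", "slope must be > 0")
  if (weight <= 0) stop_hrm("ConfigError", "weight must be > 0")
  structure(list(tm = tm, slope = slope, weight = weight),
            class = "transition_spec")
}

#' Generative description of a synthetic amplicon melt
#'
#' Fluorescence is modelled as
#' \deqn{F(T) = B(T) + A \sum_i w_i / (1 + e^{(T - tm_i)/s_i}) + \epsilon}
#' with background \eqn{B(T) = (b_0 + b_1 (T - lo)) e^{-b_2 (T - lo)}} and
#' i.i.d. Gaussian noise \eqn{\epsilon \sim N(0, noise\_sd^2)}.
#'
#' @param transitions List of [transition_spec()]; weights must sum to 1.
#' @param amplitude Total melt amplitude A in RFU (default 1000).
#' @param background `c(intercept, slope, decay)`: intercept RFU, linear
#'   slope RFU/degC and exponential decay rate 1/degC (default
#'   `c(100, -1, 0)`).
#' @param noise_sd Gaussian noise SD in RFU (default 5, i.e. 0.5% of the
#'   default amplitude — a realistic post-PCR instrument noise floor).
#' @param grid `c(lo, hi, step)` in degC (default 65-95 at 0.04, i.e. 25
#'   readings per degree). Must cover every `tm +/- 5 * slope`.
#' @param seed Optional integer making the draw reproducible.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(transitions = list(transition_spec(80)),
                            amplitude = 1000,
                            background = c(100, -1, 0),
                            noise_sd = 5,
                            grid = c(65, 95, 0.04),
                            seed = NULL) {
  if (inherits(transitions, "transition_spec")) transitions <- list(transitions)
  w <- vapply(transitions, function(tr) tr$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) {
    stop_hrm("ConfigError", "transition weights must sum to 1 (got %g)", sum(w))
  }
  if (noise_sd < 0) stop_hrm("ConfigError", "noise_sd must be >= 0")
  for (tr in transitions) {
    if (tr$tm - 5 * tr$slope < grid[1] || tr$tm + 5 * tr$slope > grid[2]) {
      stop_hrm("ConfigError",
               "grid %g-%g must cover tm %g +/- 5 * slope %g",
               grid[1], grid[2], tr$tm, tr$slope)
    }
  }
  structure(list(transitions = transitions, amplitude = amplitude,
                 background = background, noise_sd = noise_sd,
                 grid = grid, seed = seed),
            class = "simulation_spec")
}

sim_grid <- function(spec) seq(spec$grid[1], spec$grid[2], by = spec$grid[3])

sim_deterministic <- function(spec) {
  temps <- sim_grid(spec)
  bg <- (spec$background[1] + spec$background[2] * (temps - spec$grid[1])) *
    exp(-spec$background[3] * (temps - spec$grid[1]))
  sig <- 0
  for (tr in spec$transitions) {
    sig <- sig + tr$weight / (1 + exp((temps - tr$tm) / tr$slope))
  }
  bg + spec$amplitude * sig
}

#' Simulate a single melt curve
#'
#' Deterministic given `spec$seed`; with `seed = NULL` the current RNG
#' stream is used (so cohort draws are independent).
#'
#' @param spec A [simulation_spec()].
#' @param sample_id Sample identifier (default `"sim"`).
#' @param meta A [sample_meta()] (default a test sample).
#' @return A [melt_curve()].
#' @export
simulate_melt_curve <- function(spec, sample_id = "sim",
                                meta = sample_meta("test")) {
  stopifnot(inherits(spec, "simulation_spec"))
  temps <- sim_grid(spec)
  f <- sim_deterministic(spec)
  if (spec$noise_sd > 0) {
    f <- f + with_seed(spec$seed, rnorm(length(temps), 0, spec$noise_sd))
  }
  melt_curve(sample_id, temps, pmax(f, 0), meta)
}

#' Duplex mixture of a heterozygous (or artificially mixed) sample
#'
#' A heterozygote melts as a mixture of three duplex species: the wildtype
#' homoduplex, the variant homoduplex (shifted by `hom_delta`, usually a
#' fraction of a degree), and heteroduplexes whose mismatch destabilizes
#' the duplex so they melt `het_delta` degrees lower (typically -1 to
#' -3 degC). Mixing hemizygous male DNA with wildtype DNA creates the same
#' species artificially, which is what makes variants detectable in males.
#'
#' @param wt_tm Wildtype homoduplex Tm (degC), default 80.
#' @param hom_delta Tm shift of the variant homoduplex (default -0.3).
#' @param het_delta Tm shift of the heteroduplex species (default -2).
#' @param fractions `c(wt homoduplex, variant homoduplex, heteroduplex)`,
#'   non-negative and summing to 1 (default `c(0.25, 0.25, 0.5)`, the
#'   equimolar-mix expectation).
#' @return An object of class `duplex_mixture_spec`.
#' @export
duplex_mixture_spec <- function(wt_tm = 80, hom_delta = -0.3, het_delta = -2,
                                fractions = c(0.25, 0.25, 0.5)) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop_hrm("ConfigError", "fractions must be non-negative and sum to 1")
  }
  structure(list(wt_tm = wt_tm, hom_delta = hom_delta, het_delta = het_delta,
                 fractions = fractions),
            class = "duplex_mixture_spec")
}

#' Simulate a heterozygote melt curve as a duplex mixture
#'
#' The curve is the fraction-weighted sum of three single-transition
#' curves at `wt_tm`, `wt_tm + hom_delta` and `wt_tm + het_delta`, sharing
#' the base spec's background, noise level, grid and seed. With fractions
#' `c(1, 0, 0)` (and the same seed) the result is identical to the
#' wildtype curve.
#'
#' @param mix A [duplex_mixture_spec()].
#' @param base A [simulation_spec()] with a single reference transition
#'   whose `tm` is taken as `wt_tm` unless `mix$wt_tm` differs.
#' @param sample_id,meta Passed to the resulting [melt_curve()].
#' @return A [melt_curve()].
#' @export
simulate_heterozygote <- function(mix, base = simulation_spec(),
                                  sample_id = "het",
                                  meta = sample_meta("test", sex = "male",
                                                     mixed = TRUE)) {
  stopifnot(inherits(mix, "duplex_mixture_spec"),
            inherits(base, "simulation_spec"))
  if (length(base$transitions) != 1) {
    stop_hrm("ConfigError", "base spec must have a single reference transition")
  }
  slope <- base$transitions[[1]]$slope
  tms <- mix$wt_tm + c(0, mix$hom_delta, mix$het_delta)
  keep <- mix$fractions > 0
  trans <- mapply(function(tm, w) transition_spec(tm, slope, w),
                  tms[keep], mix$fractions[keep], SIMPLIFY = FALSE)
  spec <- simulation_spec(trans, amplitude = base$amplitude,
                          background = base$background,
                          noise_sd = base$noise_sd, grid = base$grid,
                          seed = base$seed)
  simulate_melt_curve(spec, sample_id = sample_id, meta = meta)
}

#' Simulate a control/variant cohort with known truth
#'
#' Controls are independent wildtype draws from `base`; variants are
#' heterozygote duplex-mixture draws. Optionally the heteroduplex shift is
#' drawn per variant, uniformly from `het_delta_range`, to emulate a
#' spread of variant destabilization strengths. Extra wildtype draws can
#' be labelled as test samples (`n_wildtype_tests`) for specificity
#' checks. Fully reproducible given `seed`.
#'
#' @param n_controls Number of wildtype control curves (>= 2; default 16).
#' @param n_variants Number of heterozygous variant curves (default 50).
#' @param mix A [duplex_mixture_spec()].
#' @param base A [simulation_spec()] (single wildtype transition).
#' @param seed Integer seed.
#' @param het_delta_range Optional `c(lo, hi)`; each variant's `het_delta`
#'   is drawn uniformly from this interval.
#' @param n_wildtype_tests Wildtype draws labelled role = test (default 0).
#' @return A list with `set` (an [experiment_set()]) and `truth` (class
#'   `cohort_truth`: labels for every non-control sample, the generating
#'   specs and the seed).
#' @export
simulate_cohort <- function(n_controls = 16, n_variants = 50,
                            mix = duplex_mixture_spec(),
                            base = simulation_spec(),
                            seed = 1L, het_delta_range = NULL,
                            n_wildtype_tests = 0) {
  if (n_controls < 2) stop_hrm("TooFewControls", "need >= 2 controls")
  base$seed <- NULL
  curves <- with_seed(seed, {
    out <- list()
    for (i in seq_len(n_controls)) {
      out[[length(out) + 1L]] <- simulate_melt_curve(
        base, sample_id = sprintf("C%02d", i),
        meta = sample_meta("control",
                           sex = if (i %% 2 == 1) "male" else "female"))
    }
    for (i in seq_len(n_wildtype_tests)) {
      out[[length(out) + 1L]] <- simulate_melt_curve(
        base, sample_id = sprintf("W%02d", i),
        meta = sample_meta("test", sex = if (i %% 2 == 1) "male" else "female"))
    }
    for (i in seq_len(n_variants)) {
      m <- mix
      if (!is.null(het_delta_range)) {
        m$het_delta <- runif(1, het_delta_range[1], het_delta_range[2])
      }
      out[[length(out) + 1L]] <- simulate_heterozygote(
        m, base, sample_id = sprintf("V%02d", i),
        meta = sample_meta("test", sex = "male", mixed = TRUE))
    }
    out
  })
  set <- experiment_set(curves, provenance = sprintf("simulate_cohort(seed=%d)", seed))
  labels <- c(setNames(rep("wildtype", n_wildtype_tests),
                       sprintf("W%02d", seq_len(n_wildtype_tests))),
              setNames(rep("variant", n_variants),
                       sprintf("V%02d", seq_len(n_variants))))
  truth <- structure(list(labels = labels,
                          control_ids = sprintf("C%02d", seq_len(n_controls)),
                          mix = mix, base = base, seed = seed,
                          het_delta_range = het_delta_range),
                     class = "cohort_truth")
  list(set = set, truth = truth)
}

#' Score variant calls against simulated ground truth
#'
#' @param calls An `hrm_analysis`, a [calls_table()] data frame, or a list
#'   of `variant_call` objects.
#' @param truth A `cohort_truth`.
#' @return An object of class `detection_metrics` with confusion counts
#'   `tp, fn, tn, fp` and `sensitivity`/`specificity` (`NA` when
#'   undefined, flagged via `sensitivity_defined`/`specificity_defined` —
#'   never reported as 0).
#' @export
evaluate_detection <- function(calls, truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (inherits(calls, "hrm_analysis")) calls <- calls_table(calls)
  if (!is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(vc) {
      data.frame(sample_id = vc$sample_id, call = vc$call,
                 stringsAsFactors = FALSE)
    }))
  }
  ids <- names(truth$labels)
  if (length(ids) != nrow(calls) || !setequal(ids, calls$sample_id) ||
      anyDuplicated(calls$sample_id)) {
    stop_hrm("SampleMismatch",
             "truth lists %d samples but calls cover %d matching ids",
             length(ids), sum(calls$sample_id %in% ids))
  }
  call_of <- setNames(calls$call, calls$sample_id)[ids]
  is_var <- truth$labels == "variant"
  tp <- sum(is_var & call_of == "variant")
  fn <- sum(is_var & call_of == "normal")
  tn <- sum(!is_var & call_of == "normal")
  fp <- sum(!is_var & call_of == "variant")
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 sensitivity_defined = tp + fn > 0,
                 specificity_defined = tn + fp > 0),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> TP %d  FN %d  TN %d  FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity: %s   specificity: %s\n",
              if (x$sensitivity_defined) sprintf("%.3f", x$sensitivity)
              else "undefined (no true variants)",
              if (x$specificity_defined) sprintf("%.3f", x$specificity)
              else "undefined (no true wildtypes)"))
  invisible(x)
}
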