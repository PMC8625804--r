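# Reading/writing melt-curve tables and placing curves on a common grid.

ROLES <- c("control", "test", "positive_control")
SEXES <- c("male", "female", "unknown")

#' Sample metadata for one well
#'
#' @param role One of `"control"`, `"test"`, `"positive_control"`.
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param mixed Logical; `TRUE` for an artificial heterozygote, i.e. a
#'   hemizygous (male) DNA preparation deliberately mixed with wildtype DNA
#'   so that a variant forms heteroduplexes. Only meaningful for males; a
#'   warning (not an error) is raised otherwise.
#' @param amplicon_id Amplicon identifier (curves are analysed per amplicon).
#' @param preparation_group Identifier linking the mixed and unmixed
#'   preparations of the same individual; defaults to `NA`.
#' @return An object of class `sample_meta`.
#' @export
sample_meta <- function(role, sex = "unknown", mixed = FALSE,
                        amplicon_id = "amplicon", preparation_group = NA_character_) {
  role <- match.arg(role, ROLES)
  sex <- match.arg(sex, SEXES)
  mixed <- isTRUE(as.logical(mixed))
  if (mixed && sex != "male") {
    warn_hrm("MixedNonMale",
             "mixed = TRUE is only meaningful for male samples (sex = %s)", sex)
  }
  structure(list(role = role, sex = sex, mixed = mixed,
                 amplicon_id = as.character(amplicon_id),
                 preparation_group = as.character(preparation_group)),
            class = "sample_meta")
}

#' One well's melt curve
#'
#' A fluorescence-vs-temperature trace. Temperatures must be strictly
#' increasing (duplicate temperatures signal a malformed export and are an
#' error, not averaged) with at least 10 readings; fluorescence values must
#' be finite and non-negative.
#'
#' @param sample_id Sample identifier.
#' @param temperatures Numeric vector of temperatures (degrees C).
#' @param fluorescence Numeric vector of relative fluorescence units (RFU).
#' @param meta A [sample_meta()] object.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(sample_id, temperatures, fluorescence,
                       meta = sample_meta("test")) {
  temperatures <- as.numeric(temperatures)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperatures) != length(fluorescence)) {
    stop_hrm("LengthMismatch",
             "sample %s: %d temperatures but %d fluorescence values",
             sample_id, length(temperatures), length(fluorescence))
  }
  if (length(temperatures) < 3) {
    stop_hrm("EmptyInput", "sample %s: need >= 3 readings, got %d",
             sample_id, length(temperatures))
  }
  if (anyNA(temperatures) || any(diff(temperatures) <= 0)) {
    stop_hrm("NonMonotonicGrid",
             "sample %s: temperatures must be strictly increasing (duplicates are an error)",
             sample_id)
  }
  if (anyNA(fluorescence) || any(!is.finite(fluorescence)) || any(fluorescence < 0)) {
    stop_hrm("InvalidFluorescence",
             "sample %s: fluorescence must be finite and >= 0", sample_id)
  }
  structure(list(sample_id = as.character(sample_id),
                 temperatures = temperatures,
                 fluorescence = fluorescence,
                 meta = meta),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %s [%s/%s%s]  %d points, %.2f-%.2f degC\n",
              x$sample_id, x$meta$role, x$meta$sex,
              if (isTRUE(x$meta$mixed)) "/mixed" else "",
              length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

grid_is_uniform <- function(temps, tol = 1e-9) {
  d <- diff(temps)
  length(d) > 0 && (max(d) - min(d)) <= tol
}

#' A set of melt curves sharing one amplicon and one temperature grid
#'
#' @param curves List of [melt_curve()] objects on an identical grid.
#' @param provenance Character vector of source file paths (optional).
#' @return An object of class `experiment_set` with elements `curves`,
#'   `grid` and `provenance`.
#' @export
experiment_set <- function(curves, provenance = character()) {
  if (length(curves) == 0) stop_hrm("EmptyInput", "no curves supplied")
  ids <- vapply(curves, function(cv) cv$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop_hrm("DuplicateSample", "duplicate sample ids: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  grid <- curves[[1]]$temperatures
  same <- vapply(curves, function(cv) {
    length(cv$temperatures) == length(grid) &&
      max(abs(cv$temperatures - grid)) <= 1e-9
  }, logical(1))
  if (!all(same)) {
    stop_hrm("GridMismatch",
             "curves are not on an identical grid; resample_to_common_grid() first")
  }
  structure(list(curves = setNames(curves, ids), grid = grid,
                 provenance = provenance),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  roles <- vapply(x$curves, function(cv) cv$meta$role, character(1))
  cat(sprintf("<experiment_set> %d curves (%s), grid %.2f-%.2f degC, step %.4g\n",
              length(x$curves),
              paste(sprintf("%d %s", as.vector(table(roles)),
                            names(table(roles))), collapse = ", "),
              min(x$grid), max(x$grid), stats::median(diff(x$grid))))
  invisible(x)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop_hrm("EmptyInput", "file %s is empty", path)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

parse_meta_table <- function(meta_path) {
  delim <- detect_delim(meta_path)
  meta <- read.table(meta_path, header = TRUE, sep = delim,
                     stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("sample_id", "role", "sex", "mixed", "amplicon_id")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop_hrm("MetadataError", "metadata %s lacks column(s): %s",
             meta_path, paste(missing, collapse = ", "))
  }
  if (!"preparation_group" %in% names(meta)) meta$preparation_group <- NA_character_
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop_hrm("MetadataError", "duplicate sample_id rows in %s", meta_path)
  }
  meta
}

#' Read a melt-curve export plus sample metadata
#'
#' Accepts comma- or tab-delimited text (delimiter auto-detected) in either
#' a wide layout (first column temperature, one fluorescence column per
#' well) or a long layout (columns `sample_id`, `temperature`,
#' `fluorescence`). Every fluorescence column/sample must have a metadata
#' row; curves are placed on a common uniform grid by linear interpolation
#' when they do not already share one.
#'
#' @param curve_path Path to the curve table.
#' @param meta_path Path to the metadata table with required columns
#'   `sample_id,role,sex,mixed,amplicon_id` and optional
#'   `preparation_group`.
#' @param layout `"auto"` (default; long format is detected by the presence
#'   of a sample-id column), `"wide"` or `"long"`.
#' @param step Grid step in degrees C used if resampling is needed
#'   (default 0.04, i.e. 25 readings per degree).
#' @return An [experiment_set()].
#' @export
read_melt_export <- function(curve_path, meta_path,
                             layout = c("auto", "wide", "long"),
                             step = 0.04) {
  layout <- match.arg(layout)
  delim <- detect_delim(curve_path)
  tab <- read.table(curve_path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    stop_hrm("EmptyInput", "curve file %s holds no data", curve_path)
  }
  meta <- parse_meta_table(meta_path)
  lname <- tolower(names(tab))
  if (layout == "auto") {
    layout <- if (any(lname %in% c("sample", "sample_id", "well"))) "long" else "wide"
  }

  make_meta <- function(id) {
    row <- meta[meta$sample_id == id, , drop = FALSE]
    if (nrow(row) == 0) {
      stop_hrm("UnknownSample", "sample %s has no metadata row", id)
    }
    sample_meta(role = row$role, sex = row$sex, mixed = row$mixed,
                amplicon_id = row$amplicon_id,
                preparation_group = row$preparation_group)
  }

  if (layout == "wide") {
    temps <- as.numeric(tab[[1]])
    curves <- lapply(names(tab)[-1], function(id) {
      melt_curve(id, temps, as.numeric(tab[[id]]), make_meta(id))
    })
  } else {
    idcol <- names(tab)[lname %in% c("sample", "sample_id", "well")][1]
    tcol <- names(tab)[lname %in% c("temperature", "temp", "t")][1]
    fcol <- names(tab)[lname %in% c("fluorescence", "rfu", "f", "signal")][1]
    if (is.na(idcol) || is.na(tcol) || is.na(fcol)) {
      stop_hrm("MetadataError",
               "long layout needs sample, temperature and fluorescence columns")
    }
    curves <- lapply(split(tab, tab[[idcol]]), function(d) {
      d <- d[order(d[[tcol]]), , drop = FALSE]
      melt_curve(d[[idcol]][1], d[[tcol]], d[[fcol]], make_meta(d[[idcol]][1]))
    })
    curves <- unname(curves)
  }

  shared <- grid_is_uniform(curves[[1]]$temperatures) &&
    all(vapply(curves, function(cv) {
      length(cv$temperatures) == length(curves[[1]]$temperatures) &&
        max(abs(cv$temperatures - curves[[1]]$temperatures)) <= 1e-9
    }, logical(1)))
  if (!shared) curves <- resample_to_common_grid(curves, step = step)
  experiment_set(curves, provenance = c(curve_path, meta_path))
}

#' Write an experiment set back to wide CSV + metadata CSV
#'
#' Values round-trip through [read_melt_export()] to within 1e-9 RFU.
#'
#' @param set An [experiment_set()].
#' @param curve_path,meta_path Output paths.
#' @return Invisibly, `c(curve_path, meta_path)`.
#' @export
write_melt_export <- function(set, curve_path, meta_path) {
  stopifnot(inherits(set, "experiment_set"))
  tab <- data.frame(temperature = set$grid, check.names = FALSE)
  for (cv in set$curves) tab[[cv$sample_id]] <- cv$fluorescence
  write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
              curve_path, sep = ",", quote = FALSE, row.names = FALSE)
  meta <- do.call(rbind, lapply(set$curves, function(cv) {
    data.frame(sample_id = cv$sample_id, role = cv$meta$role,
               sex = cv$meta$sex, mixed = cv$meta$mixed,
               amplicon_id = cv$meta$amplicon_id,
               preparation_group = cv$meta$preparation_group,
               stringsAsFactors = FALSE)
  }))
  write.table(meta, meta_path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(c(curve_path, meta_path))
}

#' Resample melt curves onto one common uniform grid
#'
#' Curves are linearly interpolated (no extrapolation) onto a uniform grid
#' covering the intersection of the input temperature spans, or the given
#' `range`. Curves that already share a uniform grid matching the request
#' are returned unchanged.
#'
#' @param curves List of [melt_curve()] objects.
#' @param step Grid step in degrees C (default 0.04).
#' @param range Optional `c(lo, hi)` to override the span intersection.
#' @return List of resampled [melt_curve()] objects.
#' @export
resample_to_common_grid <- function(curves, step = 0.04, range = NULL) {
  if (length(curves) == 0) stop_hrm("EmptyInput", "no curves supplied")
  if (!is.numeric(step) || step <= 0) stop_hrm("StepTooCoarse", "step must be > 0")
  lo <- max(vapply(curves, function(cv) min(cv$temperatures), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$temperatures), numeric(1)))
  if (!is.null(range)) {
    lo <- max(lo, range[1]); hi <- min(hi, range[2])
  }
  if (hi <= lo) stop_hrm("DisjointSpans", "no common temperature interval")

  # fixed point: identical uniform grids at the requested span and step
  g0 <- curves[[1]]$temperatures
  if (grid_is_uniform(g0) &&
      abs(g0[1] - lo) <= 1e-9 && abs(g0[length(g0)] - hi) <= 1e-9 &&
      abs(g0[2] - g0[1] - step) <= 1e-9 &&
      all(vapply(curves, function(cv) {
        length(cv$temperatures) == length(g0) &&
          max(abs(cv$temperatures - g0)) <= 1e-9
      }, logical(1)))) {
    return(curves)
  }

  grid <- seq(lo, hi, by = step)
  if (length(grid) < 10) {
    stop_hrm("StepTooCoarse", "grid of %d points (< 10) at step %g",
             length(grid), step)
  }
  lapply(curves, function(cv) {
    f <- approx(cv$temperatures, cv$fluorescence, xout = grid,
                method = "linear", rule = 1)$y
    melt_curve(cv$sample_id, grid, f, cv$meta)
  })
}
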