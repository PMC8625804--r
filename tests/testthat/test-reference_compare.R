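test_that("reference bands: degenerate spread, order invariance, median oracle", {
  g <- seq(70, 90, 0.1)
  v <- (1 + cos((g - 70) / 20 * pi)) / 2
  same <- lapply(1:5, function(i) fake_norm(v, g, id = paste0("c", i)))
  band <- build_reference(same)
  expect_equal(band$median, v)
  expect_true(all(band$sd == 0))

  set.seed(9)
  mixed <- lapply(1:6, function(i) fake_norm(v + rnorm(length(g), 0, 0.01),
                                             g, id = paste0("c", i)))
  b1 <- build_reference(mixed)
  b2 <- build_reference(rev(mixed))
  expect_identical(b1$median, b2$median)
  expect_identical(b1$sd, b2$sd)

  # median resists the outlier a mean would absorb: sort-and-pick-middle oracle
  vals <- c(0, 0, 0, 0, 10)
  outl <- lapply(seq_along(vals), function(i)
    fake_norm(rep(vals[i], length(g)), g, id = paste0("c", i)))
  b3 <- build_reference(outl)
  mid <- apply(vapply(vals, function(x) rep(x, length(g)), numeric(length(g))),
               1, function(row) sort(row)[(length(row) + 1) / 2])
  expect_equal(b3$median, mid)
  expect_true(all(b3$median == 0))
  b4 <- build_reference(outl, center = "mean")
  expect_true(all(b4$median == 2))
})

test_that("reference bands respect strata and refuse thin control sets", {
  g <- seq(70, 90, 0.1)
  ctl <- c(lapply(1:3, function(i) fake_norm(rep(0.5, length(g)), g,
                                             id = paste0("m", i), sex = "male")),
           lapply(1:2, function(i) fake_norm(rep(0.7, length(g)), g,
                                             id = paste0("f", i), sex = "female")))
  bm <- build_reference(ctl, stratum = "male")
  expect_equal(bm$n_controls, 3)
  expect_true(all(bm$median == 0.5))
  expect_setequal(bm$control_ids, c("m1", "m2", "m3"))
  expect_error(build_reference(ctl[1:1]), class = "hrm_TooFewControls")
  expect_warning(build_reference(ctl[1:2]), class = "hrm_FewControls")
  bad <- fake_norm(rep(0.5, 50), seq(70, 90, length.out = 50), id = "x")
  expect_error(suppressWarnings(build_reference(list(ctl[[1]], bad))),
               class = "hrm_GridMismatch")
})

test_that("difference curves: self-comparison, z construction, antisymmetry", {
  g <- seq(70, 90, 0.1)
  set.seed(4)
  base <- pmin(pmax((1 + cos((g - 70) / 20 * pi)) / 2, 0), 1)
  ctl <- lapply(1:6, function(i) fake_norm(base + rnorm(length(g), 0, 0.02),
                                           g, id = paste0("c", i)))
  band <- build_reference(ctl)

  self <- fake_norm(band$median, g, id = "self")
  d0 <- difference_curve(self, band)
  expect_true(all(d0$diff == 0))
  expect_equal(d0$max_abs_z, 0)
  expect_equal(d0$longest_run, 0L)

  # constant-spread controls give z identically 3 for median + 3 sd
  lv <- c(0.40, 0.45, 0.50, 0.55, 0.60, 0.65)
  flat <- lapply(seq_along(lv), function(i)
    fake_norm(rep(lv[i], length(g)), g, id = paste0("f", i)))
  fband <- build_reference(flat)
  up <- fake_norm(fband$median + 3 * fband$sd, g, id = "up")
  expect_lt(max(abs(difference_curve(up, fband)$z - 3)), 1e-9)

  pert <- 0.1 * sin(g)
  dp <- difference_curve(fake_norm(band$median + pert, g), band)
  dm <- difference_curve(fake_norm(band$median - pert, g), band)
  expect_equal(dp$diff, -dm$diff, tolerance = 1e-12)

  off <- fake_norm(band$median[-1], g[-1], id = "off")
  expect_error(difference_curve(off, band), class = "hrm_GridMismatch")
})

test_that("classification needs a sustained excursion and is monotone in k, m", {
  expect_equal(classify_sample(fake_diff(rep(0, 100))), "normal")
  z <- rep(0, 100); z[40:52] <- 2.5
  expect_equal(classify_sample(fake_diff(z)), "variant")
  z2 <- rep(0, 100); z2[seq(10, 90, 4)] <- 5  # isolated spikes
  expect_equal(classify_sample(fake_diff(z2)), "normal")

  set.seed(12)
  for (r in 1:20) {
    zr <- rnorm(120, 0, 1.5)
    calls <- expand.grid(k = c(1, 1.5, 2, 3), m = c(3, 8, 15))
    res <- mapply(function(k, m) classify_sample(fake_diff(zr), k, m),
                  calls$k, calls$m)
    for (ki in c(1, 1.5, 2)) {
      for (mi in c(3, 8)) {
        # increasing k or m never converts normal to variant
        idx <- function(k, m) which(calls$k == k & calls$m == m)
        if (res[idx(ki, mi)] == "normal") {
          expect_equal(res[idx(3, mi)], "normal")
          expect_equal(res[idx(ki, 15)], "normal")
        }
      }
    }
  }
})

test_that("a simulated heterozygote is flagged against simulated controls", {
  base <- simulation_spec()  # noise 0.5% of amplitude
  mix <- duplex_mixture_spec(het_delta = -2, fractions = c(0.5, 0, 0.5))
  region <- c(65, 95)
  hits <- 0
  for (r in 1:100) {
    set.seed(r)
    ctl <- lapply(1:8, function(i)
      normalize_domain(simulate_melt_curve(base, sprintf("c%d", i),
                                           sample_meta("control")), region))
    band <- build_reference(ctl)
    het <- normalize_domain(simulate_heterozygote(mix, base), region)
    if (classify_sample(difference_curve(het, band)) == "variant") hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("leave-one-out controls are finite and usually normal", {
  base <- simulation_spec()
  region <- c(65, 95)
  normal <- 0; total <- 0
  for (s in 1:3) {
    set.seed(100 + s)
    ctl <- lapply(1:8, function(i)
      normalize_domain(simulate_melt_curve(base, sprintf("c%d", i),
                                           sample_meta("control")), region))
    for (i in seq_along(ctl)) {
      band <- build_reference(ctl[-i])
      d <- difference_curve(ctl[[i]], band)
      expect_true(is.finite(d$max_abs_z))
      total <- total + 1
      if (classify_sample(d) == "normal") normal <- normal + 1
    }
  }
  expect_gte(normal / total, 0.8)
})

test_that("two-step analysis: shared scopes, pass agreement on one domain", {
  coh <- simulate_cohort(n_controls = 8, n_variants = 4, seed = 21,
                         n_wildtype_tests = 2)
  an <- suppressWarnings(analyze_experiment(coh$set))
  # domains are detected once, on the median control curve: all samples
  # share the identical scope set
  per_sample <- split(an$scope_calls$scope, an$scope_calls$sample_id)
  expect_true(all(vapply(per_sample, function(s)
    identical(sort(s), sort(unique(an$scope_calls$scope))), logical(1))))
  # single-transition amplicon: per-domain call agrees with whole-amplicon
  wide <- reshape(an$scope_calls[, c("sample_id", "scope", "call")],
                  direction = "wide", idvar = "sample_id", timevar = "scope")
  expect_equal(wide$call.amplicon, wide$call.domain_1)
})

test_that("sex stratification selects same-sex control bands", {
  coh <- simulate_cohort(n_controls = 8, n_variants = 2, seed = 31,
                         n_wildtype_tests = 2)
  an <- suppressWarnings(analyze_experiment(coh$set, stratify_by_sex = TRUE))
  sex_of <- vapply(coh$set$curves, function(cv) cv$meta$sex, character(1))
  for (i in seq_len(nrow(an$scope_calls))) {
    expect_equal(an$scope_calls$stratum[i], sex_of[[an$scope_calls$sample_id[i]]])
  }
  # references for male samples were built from male controls only
  for (sc in names(an$references)) {
    b <- an$references[[sc]][["male"]]
    if (!is.null(b)) {
      expect_true(all(sex_of[b$control_ids] == "male"))
    }
  }
})

test_that("falling back to unstratified controls warns when a stratum is thin", {
  base <- simulation_spec()
  curves <- with(list(), {
    out <- list()
    set.seed(77)
    for (i in 1:4) out[[i]] <- simulate_melt_curve(
      base, sprintf("c%d", i), sample_meta("control", sex = "male"))
    out[[5]] <- simulate_melt_curve(base, "t1", sample_meta("test", sex = "female"))
    out
  })
  set <- experiment_set(curves)
  expect_warning(an <- analyze_experiment(set, stratify_by_sex = TRUE),
                 class = "hrm_MissingStratumControls")
  expect_true(all(an$scope_calls$stratum == "all"))
})

test_that("mixed and unmixed preparations of one male are OR-combined", {
  base <- simulation_spec()
  mix <- duplex_mixture_spec(het_delta = -2)
  pure <- duplex_mixture_spec(het_delta = -2, fractions = c(0, 1, 0),
                              hom_delta = -0.05)
  curves <- with(list(), {
    set.seed(55)
    out <- lapply(1:8, function(i) simulate_melt_curve(
      base, sprintf("c%d", i), sample_meta("control")))
    # unmixed hemizygote: homoduplex shift too small to call
    out$unmixed <- simulate_heterozygote(
      pure, base, "P1_unmixed",
      sample_meta("test", "male", mixed = FALSE, preparation_group = "P1"))
    # artificial heterozygote of the same individual: clear heteroduplex
    out$mixed <- simulate_heterozygote(
      mix, base, "P1_mixed",
      sample_meta("test", "male", mixed = TRUE, preparation_group = "P1"))
    out
  })
  an <- suppressWarnings(analyze_experiment(experiment_set(curves)))
  tab <- calls_table(an)
  expect_equal(nrow(tab), 1)  # one call for the individual
  expect_equal(tab$sample_id, "P1")
  prep <- an$calls[["P1"]]$preparation_calls
  expect_setequal(prep$sample_id, c("P1_unmixed", "P1_mixed"))
  expect_equal(prep$call[prep$sample_id == "P1_mixed"], "variant")
  expect_equal(an$calls[["P1"]]$call, "variant")  # OR over preparations
})

test_that("experiments without enough controls are rejected", {
  base <- simulation_spec()
  set.seed(1)
  lone <- list(simulate_melt_curve(base, "c1", sample_meta("control")),
               simulate_melt_curve(base, "t1", sample_meta("test")))
  expect_error(analyze_experiment(experiment_set(lone)),
               class = "hrm_TooFewControls")
})
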