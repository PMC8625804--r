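test_that("derivatives of constant and affine curves are exact", {
  grid <- default_grid(70, 90)
  const <- melt_curve("c", grid, rep(1000, length(grid)))
  d <- smooth_derivatives(const)
  expect_lt(max(abs(d$neg_dFdT)), 1e-9)
  expect_lt(max(abs(d$d2)), 1e-9)

  aff <- melt_curve("a", grid, 300 + 2 * (90 - grid))  # F = -2T + c
  da <- smooth_derivatives(aff)
  expect_lt(max(abs(da$neg_dFdT - 2)), 1e-9)  # polynomial reproduction
  expect_lt(max(abs(da$d2)), 1e-8)
})

test_that("logistic melt: derivative peak sits at the closed-form midpoint", {
  cv <- make_curve(80, 1, 1, bg_slope = 0)
  d <- smooth_derivatives(cv)
  expect_lt(abs(d$grid[which.max(d$neg_dFdT)] - 80), 0.05)
})

test_that("smoothing config and derivative preconditions are validated", {
  expect_error(smoothing_config(window = 10), class = "hrm_ConfigError")
  expect_error(smoothing_config(window = 5, polyorder = 5),
               class = "hrm_ConfigError")
  expect_error(smoothing_config(domain_threshold = 1.2),
               class = "hrm_ConfigError")
  short <- melt_curve("s", seq(70, 71, 0.1), seq(11, 1))
  expect_error(smooth_derivatives(short), class = "hrm_WindowTooLarge")
  bumpy_t <- c(seq(70, 75, 0.1), seq(75.3, 80, 0.1))
  bumpy <- melt_curve("b", bumpy_t, rev(seq_along(bumpy_t)))
  expect_error(smooth_derivatives(bumpy), class = "hrm_GridNotUniform")
})

test_that("find_domains recovers single and double transitions at their Tm", {
  cfg <- smoothing_config()
  one <- find_domains(smooth_derivatives(make_curve(80, 1, 1)), cfg)
  expect_length(one, 1)
  expect_lt(abs(one[[1]]$peak_temp - 80), 0.05)

  two <- find_domains(smooth_derivatives(
    make_curve(c(75, 85), c(1, 1), c(0.6, 0.4))), cfg)
  expect_length(two, 2)
  expect_lt(abs(two[[1]]$peak_temp - 75), 0.1)
  expect_lt(abs(two[[2]]$peak_temp - 85), 0.1)

  # shared boundary at the derivative valley between the peaks
  d <- smooth_derivatives(make_curve(c(75, 85), c(1, 1), c(0.6, 0.4)))
  sel <- d$grid > 75 & d$grid < 85
  valley <- d$grid[sel][which.min(d$neg_dFdT[sel])]
  expect_equal(two[[1]]$domain_end, valley, tolerance = 1e-9)
  expect_equal(two[[2]]$domain_start, valley, tolerance = 1e-9)
})

test_that("sub-threshold shoulders are excluded as noise", {
  # second transition engineered below 10% relative derivative height
  cv <- make_curve(c(80, 88), c(1, 1), c(0.95, 0.05))
  doms <- find_domains(smooth_derivatives(cv))
  expect_length(doms, 1)
  expect_lt(abs(doms[[1]]$peak_temp - 80), 0.05)
})

test_that("domain invariants hold on random multi-transition curves", {
  cfg <- smoothing_config()
  set.seed(101)
  for (r in 1:25) {
    lay <- random_layout()
    doms <- find_domains(smooth_derivatives(
      make_curve(lay$tms, lay$slopes, lay$weights)), cfg)
    for (d in doms) {
      expect_lt(d$domain_start, d$peak_temp)
      expect_gt(d$domain_end, d$peak_temp)
      expect_lte(d$region_start, d$domain_start)
      expect_gte(d$region_end, d$domain_end)
      expect_gte(d$peak_height_rel, cfg$domain_threshold)
    }
    tm <- vapply(doms, melting_temperature, numeric(1))
    expect_true(!is.unsorted(tm))
  }
})

test_that("peak set matches the exhaustive local-maximum oracle", {
  cfg <- smoothing_config(min_domain_width = 0)
  set.seed(7)
  for (r in 1:30) {
    lay <- random_layout()
    d <- smooth_derivatives(make_curve(lay$tms, lay$slopes, lay$weights), cfg)
    got <- vapply(find_domains(d, cfg), function(x) x$peak_temp, numeric(1))
    expect_identical(got, d$grid[oracle_peaks(d$neg_dFdT, cfg$domain_threshold)])
  }
})

test_that("raising the domain threshold never increases the domain count", {
  set.seed(55)
  for (r in 1:10) {
    lay <- random_layout()
    d <- smooth_derivatives(make_curve(lay$tms, lay$slopes, lay$weights,
                                       noise = 5))
    counts <- vapply(c(0.05, 0.10, 0.20, 0.40), function(th) {
      length(suppressWarnings(
        find_domains(d, smoothing_config(domain_threshold = th))))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a flat curve yields no domains with a warning, not an error", {
  grid <- default_grid(70, 90)
  flat <- melt_curve("f", grid, rep(500, length(grid)))
  expect_warning(doms <- find_domains(smooth_derivatives(flat)),
                 class = "hrm_NoDomainsFound")
  expect_length(doms, 0)
})

test_that("melting regions pad domain boundaries by 2 degC and clip to the grid", {
  cfg <- smoothing_config(region_pad = 2.0)
  grid <- default_grid(65, 95)
  dom <- structure(list(domain_start = 78.0, domain_end = 84.0,
                        peak_temp = 81.0), class = "melt_domain")
  expect_equal(melting_region(dom, grid, cfg), c(76.0, 86.0))

  grid2 <- default_grid(65, 72)
  dom2 <- structure(list(domain_start = 65.5, domain_end = 70.0,
                         peak_temp = 68.0), class = "melt_domain")
  expect_equal(melting_region(dom2, grid2, cfg), c(65.0, 72.0))

  # region always contains the domain
  reg <- melting_region(dom, grid, smoothing_config(region_pad = 0))
  expect_equal(reg, c(78.0, 84.0))
})

test_that("melting temperature is the derivative peak and is shift-equivariant", {
  d80 <- find_domains(smooth_derivatives(make_curve(80, 1, 1)))
  d81 <- find_domains(smooth_derivatives(make_curve(81, 1, 1)))
  expect_equal(melting_temperature(d81[[1]]) - melting_temperature(d80[[1]]),
               1.0, tolerance = 0.05)
  deriv <- smooth_derivatives(make_curve(80, 1, 1))
  expect_equal(melting_temperature(d80[[1]]),
               deriv$grid[which.max(deriv$neg_dFdT)])
})

test_that("normalization pins baseline windows at 1 and 0 exactly", {
  set.seed(2)
  cv <- make_curve(80, 1, 1, noise = 5)
  nd <- normalize_domain(cv, c(74, 86))
  nb <- max(5L, ceiling(0.10 * length(nd$grid)))
  expect_lt(abs(mean(nd$values[seq_len(nb)]) - 1), 1e-9)
  expect_lt(abs(mean(tail(nd$values, nb))), 1e-9)
  expect_true(all(nd$values >= -0.05 - 1e-12 & nd$values <= 1.05 + 1e-12))
})

test_that("linear backgrounds are absorbed exactly by the baselines", {
  grid <- default_grid(70, 90)
  clean <- make_curve(80, 1, 1, grid = grid, bg0 = 0, bg_slope = 0)
  dirty <- melt_curve("d", grid,
                      clean$fluorescence + 400 + 3 * (grid - 70))
  n1 <- normalize_domain(clean, c(74, 86))
  n2 <- normalize_domain(dirty, c(74, 86))
  expect_lt(max(abs(n1$values - n2$values)), 1e-6)
})

test_that("a symmetric logistic crosses 0.5 at its Tm after normalization", {
  cv <- make_curve(80, 1, 1, bg_slope = 0)
  nd <- normalize_domain(cv, c(74, 86))
  expect_equal(nd$values[which.min(abs(nd$grid - 80))], 0.5, tolerance = 0.02)
})

test_that("normalization is idempotent up to affine maps", {
  cv <- make_curve(80, 1, 1, bg_slope = 0)
  n1 <- normalize_domain(cv, c(74, 86))
  # re-wrap the normalized values (affinely rescaled to positive RFU)
  again <- melt_curve("n", n1$grid, 1000 * n1$values + 10)
  n2 <- normalize_domain(again, c(n1$grid[1], n1$grid[length(n1$grid)]))
  expect_lt(max(abs(n1$values - n2$values)), 1e-6)
})

test_that("degenerate baselines and too-narrow regions raise classed errors", {
  grid <- default_grid(70, 90)
  rising <- melt_curve("r", grid, 100 + 5 * (grid - 70))  # melts "backwards"
  expect_error(normalize_domain(rising, c(72, 88)),
               class = "hrm_DegenerateBaselines")
  cv <- make_curve(80, 1, 1, grid = grid)
  expect_error(normalize_domain(cv, c(80, 80.4)), class = "hrm_RegionTooNarrow")
})
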