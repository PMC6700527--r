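# Brute-force oracle for GR50: bisection on the fitted curve, independent
# of the closed-form solver.
bisectGR50 <- function(gr_inf, gec50, h, lo = 1e-12, hi = 1e12) {
  f <- function(c) gr_inf + (1 - gr_inf) / (1 + (c / gec50)^h) - 0.5
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

test_that("noiseless sigmoid data are refit to high accuracy", {
  conc <- doseSeries(10, 9)
  gr <- -0.5 + 1.5 / (1 + (conc / 0.1)^2)
  fit <- fitGRCurve(conc, gr)
  expect_equal(fit$fit_kind, "sigmoid")
  expect_equal(fit$gr_inf, -0.5, tolerance = 1e-3)
  expect_equal(fit$gec50, 0.1, tolerance = 1e-3)
  expect_equal(fit$h_gr, 2, tolerance = 1e-3)
  # gr50 = 0.1 / sqrt(2), and the closed form agrees with bisection
  expect_equal(fit$gr50, 0.1 / sqrt(2), tolerance = 1e-4)
  expect_equal(solveGR50(-0.5, 0.1, 2), bisectGR50(-0.5, 0.1, 2),
               tolerance = 1e-6)
  expect_equal(fit$gr50_cens, "exact")
  expect_false(fit$gr50_undefined)
})

test_that("closed-form GR50 agrees with bisection across parameters", {
  set.seed(7)
  for (i in 1:25) {
    gi <- runif(1, -1, 0.4)
    g5 <- 10^runif(1, -3, 1)
    h <- runif(1, 0.3, 4)
    expect_equal(solveGR50(gi, g5, h), bisectGR50(gi, g5, h),
                 tolerance = 1e-6)
  }
  expect_true(is.na(solveGR50(0.6, 0.1, 1)))  # curve never reaches 0.5
})

test_that("uninhibited responses fall back to the flat model", {
  conc <- doseSeries(10, 9)
  set.seed(3)
  gr <- 0.95 + rnorm(9, 0, 0.01)
  fit <- fitGRCurve(conc, gr)
  expect_equal(fit$fit_kind, "flat")
  expect_true(is.na(fit$gec50))
  expect_true(is.na(fit$h_gr))
  expect_equal(fit$gr50_cens, "greater_than_cmax")
  expect_true(fit$gr50_undefined)
  expect_gte(fit$f_pvalue, 0.05)

  # all-identical GR values: flat with zero residual
  fit <- fitGRCurve(conc, rep(1, 9))
  expect_equal(fit$fit_kind, "flat")
  expect_equal(fit$rss_flat, 0)
  expect_equal(fit$gr_aoc, 0)
  expect_equal(fit$gr_max, 1)
})

test_that("sigmoid residual never exceeds the flat residual", {
  set.seed(11)
  conc <- doseSeries(1, 8)
  for (i in 1:20) {
    gr <- runif(8, -1, 1)
    fit <- fitGRCurve(conc, gr)
    expect_lte(fit$rss_sigmoid, fit$rss_flat + 1e-12)
    expect_gte(fit$f_pvalue, 0)
    expect_lte(fit$f_pvalue, 1)
  }
})

test_that("fitGRCurve enforces its preconditions", {
  expect_error(fitGRCurve(c(1, 0.1, 0.01), c(1, 0.5, 0)), ">= 4")
})

test_that("area over the curve matches closed forms and is monotone", {
  conc <- doseSeries(1, 5, fold = 10)
  expect_equal(grAOC(rep(0, 5), conc), 1)   # complete arrest
  expect_equal(grAOC(rep(1, 5), conc), 0)   # no effect
  # GR linear in log10(c) from 1 down to 0: mean deficit 0.5
  lx <- log10(sort(conc))
  gr_lin <- (lx - min(lx)) / diff(range(lx))
  expect_equal(grAOC(rev(gr_lin), sort(conc, decreasing = TRUE)), 0.5)
  # pointwise-lower curves never decrease the AOC
  set.seed(5)
  for (i in 1:20) {
    g1 <- runif(5, -1, 1)
    g2 <- g1 - runif(5, 0, 0.5)
    expect_gte(grAOC(g2, conc), grAOC(g1, conc))
  }
  expect_error(grAOC(0.5, 1), ">= 2")
})

test_that("dose-range flags identify out-of-range midpoints and missing plateaus", {
  conc <- doseSeries(10, 9)
  # midpoint at the geometric mid-dose, steep: plateau reached, no flags
  gmid <- sqrt(max(conc) * min(conc))
  gr <- -0.5 + 1.5 / (1 + (conc / gmid)^3)
  fit <- fitGRCurve(conc, gr)
  flags <- doseRangeFlags(fit, conc)
  expect_false(flags[["gec50_out_of_range"]])
  expect_false(flags[["no_lower_plateau"]])

  # true midpoint 10x above the top dose
  gr <- -0.5 + 1.5 / (1 + (conc / 100)^1.5)
  fit <- fitGRCurve(conc, gr)
  flags <- doseRangeFlags(fit, conc)
  expect_true(flags[["gec50_out_of_range"]])
  expect_true(flags[["no_lower_plateau"]])
})

test_that("dose-range truncation inflates gr_inf for biphasic responses", {
  # first decline to a plateau near 0.3, second decline above 1 uM
  biphasic <- function(c) {
    0.3 + 0.7 / (1 + (c / 0.01)) - 0.8 * (c / 3)^2 / (1 + (c / 3)^2)
  }
  extended <- doseSeries(10, 9)
  truncated <- extended[extended <= 1]
  fit_ext <- fitGRCurve(extended, biphasic(extended))
  fit_tru <- fitGRCurve(truncated, biphasic(truncated))
  expect_gt(fit_tru$gr_inf, fit_ext$gr_inf + 0.2)
  # the extended range reveals negative GR the truncated range misses
  expect_lt(min(biphasic(extended)), 0)
  expect_gt(min(biphasic(truncated)), 0)
})

test_that("assay comparison reports deltas, discordance, incomparables", {
  conc <- doseSeries(1, 8)
  mk <- function(drug, gr_inf) {
    cbind(data.frame(drug = drug),
          fitGRCurve(conc, gr_inf + (1 - gr_inf) / (1 + conc / 0.03)))
  }
  fitsA <- rbind(mk("d1", -0.6), mk("d2", 0.55))
  fitsB <- rbind(mk("d1", -0.6), mk("d3", -0.2))

  self <- compareAssays(fitsA, fitsA)
  expect_true(all(self$comparable))
  expect_equal(self$delta_gr_max, c(0, 0))
  expect_false(any(self$gr50_discordant))

  cmp <- compareAssays(fitsA, fitsB)
  expect_equal(cmp$comparable, c(TRUE, FALSE, FALSE))
  expect_equal(sum(is.na(cmp$delta_gr_max)), 2L)

  # d2 crosses 0.5 in one set only -> discordant where comparable
  fitsB2 <- rbind(mk("d1", -0.6), mk("d2", -0.6))
  cmp2 <- compareAssays(fitsA, fitsB2)
  d2 <- cmp2[cmp2$drug == "d2", ]
  expect_true(d2$gr50_discordant)

  # empty intersection
  cmp3 <- compareAssays(mk("dA", -0.5), mk("dB", -0.5))
  expect_true(all(!cmp3$comparable))
})

test_that("surrogate bias inflates fitted GRmax end to end", {
  cfg <- noiselessConfig(
    drugs = list(arrestor = trueDoseResponse(grInf = 0.05, gec50 = 0.02)),
    atpBias = c(arrestor = 4)
  )
  d <- surrogateSignal(simulateEndpoint(cfg, seed = 2), cfg)
  fit_cnt <- fitDoseResponse(grTable(d, "viable_count"))
  fit_sur <- fitDoseResponse(grTable(d, "surrogate_signal"))
  cmp <- compareAssays(fit_sur, fit_cnt)
  expect_gt(cmp$delta_gr_max, 0)
  # the surrogate curve stays above GR = 0.5 -> GR50 defined in counts only
  expect_true(cmp$gr50_discordant)
})
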