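test_that("SE values match the hand oracle on fixed and random vectors", {
  # worked example: GR values 0.10/0.20/0.30
  o <- oracleSE(c(0.10, 0.20, 0.30))
  expect_equal(o$sigma, 0.10, tolerance = 1e-12)
  expect_equal(o$se, 0.10 / sqrt(3), tolerance = 1e-12)
  s <- grmetrology:::seStats(c(0.10, 0.20, 0.30))
  expect_equal(s$sigma, o$sigma, tolerance = 1e-12)
  expect_equal(s$se, o$se, tolerance = 1e-12)
  # constant replicates
  expect_equal(grmetrology:::seStats(c(0.5, 0.5, 0.5))$se, 0)
  # random vectors
  set.seed(21)
  for (i in 1:30) {
    x <- rnorm(sample(2:9, 1))
    s <- grmetrology:::seStats(x)
    o <- oracleSE(x)
    expect_equal(s$se, o$se, tolerance = 1e-12)
    expect_equal(s$sigma, o$sigma, tolerance = 1e-12)
  }
})

test_that("technical SE enumerates one value per drug-dose-day cell", {
  cfg <- noisyConfig()  # 2 drugs x 6 doses x 2 bio reps
  g <- grTable(simulateEndpoint(cfg, seed = 9))
  tech <- technicalSE(g)
  expect_equal(nrow(tech), 2 * 6 * 2)
  # each SE pools wells x plates within the day: n = 2 wells x 2 plates
  expect_true(all(tech$n == 4))
  # spot-check one cell against the oracle
  cell <- g[g$drug == tech$drug[1] &
              g$concentration == tech$concentration[1] &
              g$bio_rep == tech$bio_rep[1], ]
  expect_equal(tech$se[1], oracleSE(cell$gr)$se, tolerance = 1e-12)
})

test_that("technical SE skips cells with a single value", {
  g <- data.frame(
    drug = "d", concentration = c(1, 1, 0.1), bio_rep = c(1L, 1L, 1L),
    gr = c(0.2, 0.4, 0.3)
  )
  expect_warning(tech <- technicalSE(g), "skipped")
  expect_equal(nrow(tech), 1L)
})

test_that("biological SE enumerates one-technical-unit-per-day combinations", {
  cfg <- noisyConfig(nBio = 3L, nPlates = 3L)
  g <- grTable(simulateEndpoint(cfg, seed = 9))
  bio <- biologicalSE(g)
  # 3 plates x 3 days: 27 combinations per drug-dose pair
  per_pair <- table(paste(bio$drug, bio$concentration))
  expect_true(all(per_pair == 27))
  expect_equal(nrow(bio), 2 * 6 * 27)
  expect_true(all(bio$n == 3))

  # spot-check one combination against a direct plate-mean computation
  d1 <- g[g$drug == bio$drug[1] & g$concentration == bio$concentration[1], ]
  pm <- aggregate(gr ~ bio_rep + plate_id, d1, mean)
  first <- vapply(split(pm$gr, pm$bio_rep), `[`, numeric(1), 1L)
  expect_equal(bio$se[1], oracleSE(as.numeric(first))$se, tolerance = 1e-12)
})

test_that("biological SE requires at least two biological replicates", {
  cfg <- noisyConfig(nBio = 1L)
  g <- grTable(simulateEndpoint(cfg, seed = 1))
  expect_error(biologicalSE(g), "fewer than 2 biological")
})

test_that("identical replicates give zero SE everywhere", {
  cfg <- noiselessConfig(nBio = 3L, nPlates = 2L)
  g <- grTable(simulateEndpoint(cfg, seed = 1))
  expect_true(all(technicalSE(g)$se < 1e-12))
  expect_true(all(biologicalSE(g)$se < 1e-12))
})

test_that("SE counting laws hold for arbitrary replicate structures", {
  for (p in list(c(d = 2L, k = 4L, b = 2L, t = 2L),
                 c(d = 1L, k = 5L, b = 3L, t = 2L),
                 c(d = 2L, k = 4L, b = 2L, t = 3L))) {
    cfg <- noisyConfig(
      drugs = setNames(
        replicate(p[["d"]], trueDoseResponse(-0.4, 0.05), simplify = FALSE),
        paste0("drug", seq_len(p[["d"]]))
      ),
      atpBias = setNames(rep(1, p[["d"]]), paste0("drug", seq_len(p[["d"]]))),
      dosesPerDrug = p[["k"]], nBio = p[["b"]], nPlates = p[["t"]],
      nWells = 2L
    )
    g <- grTable(simulateEndpoint(cfg, seed = 4))
    expect_equal(nrow(technicalSE(g)), prod(p[c("d", "k", "b")]))
    expect_equal(nrow(biologicalSE(g)),
                 p[["d"]] * p[["k"]] * p[["t"]]^p[["b"]])
  }
})

test_that("SE is label-permutation invariant and scales linearly", {
  set.seed(33)
  x <- rnorm(9, 0.3, 0.1)
  s0 <- grmetrology:::seStats(x)$se
  expect_equal(grmetrology:::seStats(sample(x))$se, s0, tolerance = 1e-12)
  expect_equal(grmetrology:::seStats(2.5 * x)$se, 2.5 * s0,
               tolerance = 1e-12)
})

test_that("technical SE tracks well noise; biological SE tracks day effects", {
  med_se <- function(wellCV, dayEffect, scope) {
    vals <- vapply(1:10, function(s) {
      cfg <- noiselessConfig(
        wellCV = wellCV, daySigmaEffect = dayEffect,
        nBio = 3L, nPlates = 2L, nWells = 2L, dosesPerDrug = 4L
      )
      g <- grTable(simulateEndpoint(cfg, seed = s))
      if (scope == "technical") mean(technicalSE(g)$se)
      else mean(biologicalSE(g)$se)
    }, numeric(1))
    median(vals)
  }
  tech <- vapply(c(0.02, 0.05, 0.10), med_se, numeric(1),
                 dayEffect = 0.05, scope = "technical")
  expect_true(all(diff(tech) > 0))
  bio <- vapply(c(0.02, 0.10, 0.30), function(de) {
    med_se(0.02, de, "biological")
  }, numeric(1))
  expect_true(all(diff(bio) > 0))
})

test_that("metric SE applies the oracle per metric and handles censoring", {
  conc <- doseSeries(1, 8)
  mkfit <- function(bio_rep, gr_inf, shift = 1) {
    cbind(data.frame(drug = "d", bio_rep = bio_rep),
          fitGRCurve(conc, gr_inf + (1 - gr_inf) /
                       (1 + (conc / (0.03 * shift)))))
  }
  fits <- rbind(mkfit(1, -0.5, 1), mkfit(2, -0.5, 2), mkfit(3, -0.5, 4))
  mse <- metricSE(fits)
  expect_equal(sort(unique(mse$metric)),
               c("gr_aoc", "gr_max", "log10_gr50"))
  m50 <- mse[mse$metric == "log10_gr50", ]
  expect_equal(m50$se, oracleSE(log10(fits$gr50))$se, tolerance = 1e-10)
  expect_equal(m50$n_excluded, 0L)

  # identical fits: all SEs zero
  fits_same <- rbind(mkfit(1, -0.5), mkfit(2, -0.5), mkfit(3, -0.5))
  expect_true(all(metricSE(fits_same)$se < 1e-12, na.rm = TRUE))

  # worked example: gr50 of 0.05/0.1/0.2 uM on the log scale
  o <- oracleSE(log10(c(0.05, 0.1, 0.2)))
  expect_equal(o$sigma, 0.30103, tolerance = 1e-4)
  expect_equal(o$se, 0.17381, tolerance = 1e-4)

  # censoring bookkeeping: one of three censored
  fits_c <- fits
  fits_c$gr50_cens[2] <- "greater_than_cmax"
  m50 <- metricSE(fits_c)
  m50 <- m50[m50$metric == "log10_gr50", ]
  expect_equal(m50$n_used, 2L)
  expect_equal(m50$n_excluded, 1L)
  expect_equal(m50$se, oracleSE(log10(fits_c$gr50[c(1, 3)]))$se,
               tolerance = 1e-10)

  # all censored: SE unavailable
  fits_c$gr50_cens <- "greater_than_cmax"
  m50 <- metricSE(fits_c)
  expect_true(is.na(m50$se[m50$metric == "log10_gr50"]))
})

test_that("SE summaries use the interpolated percentile and normalized KDE", {
  se_df <- data.frame(se = c(rep(0.01, 9), 0.1))
  s <- summarizeSE(se_df)
  # h = (n-1)p + 1 = 9.1: interpolate between 9th and 10th order statistic
  expect_equal(s$summary$mean_se, 0.019)
  expect_equal(s$summary$p90_se, 0.019)
  kde <- s$kde$all
  total <- sum(diff(kde$grid) *
                 (head(kde$density, -1) + tail(kde$density, -1)) / 2)
  expect_equal(total, 1, tolerance = 1e-3)
  expect_equal(nrow(kde), 256L)
  # KDE peaks near the dominant value
  expect_lt(abs(kde$grid[which.max(kde$density)] - 0.01), 0.02)

  # grouped summaries keep groups separate
  se_df2 <- data.frame(
    scope = rep(c("technical", "biological"), each = 5),
    se = c(rep(0.01, 5), rep(0.05, 5))
  )
  s2 <- summarizeSE(se_df2, groupBy = "scope")
  expect_equal(nrow(s2$summary), 2L)
  expect_equal(s2$summary$mean_se[s2$summary$scope == "technical"], 0.01)
})

test_that("log10 SE converts to fold change at the printed rounding", {
  expect_equal(round(foldChangeLog10SE(0.07), 2), 1.17)
  expect_equal(round(foldChangeLog10SE(0.18), 1), 1.5)
  expect_equal(foldChangeLog10SE(0), 1)
})
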