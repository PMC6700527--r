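# Shared fixtures: small simulation configs and independent oracles.

# Two-drug, noise-free configuration: every count is an analytic identity.
noiselessConfig <- function(drugs = NULL, ...) {
  if (is.null(drugs)) {
    drugs <- list(
      drugA = trueDoseResponse(grInf = -0.5, gec50 = 0.1, hill = 2),
      drugB = trueDoseResponse(grInf = 0.2, gec50 = 0.05, hill = 1)
    )
  }
  args <- list(
    drugs = drugs, dosesPerDrug = 6L, topDose = 1,
    nBio = 2L, nPlates = 2L, nWells = 2L, nControlWells = 6L,
    plateDims = c(8L, 12L), wellCV = 0, plateSigma = 0,
    daySigmaGrowth = 0, daySigmaEffect = 0, edgeFrac = 0
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulationConfig, args)
}

# Small noisy configuration for property sweeps.
noisyConfig <- function(...) noiselessConfig(wellCV = 0.05, ...)

# Independent oracle for the standard-error formulas: explicit loop over
# the defining sums, no calls to sd()/var() or package code.
oracleSE <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  ss <- 0
  for (xi in x) ss <- ss + (xi - mu)^2
  sigma <- sqrt(ss / (n - 1))
  list(mu = mu, sigma = sigma, se = sigma / sqrt(n))
}

# Independent GR oracle: the defining ratio of log-fold-changes.
oracleGR <- function(x_c, x_0, x_ctrl) {
  2^(log(x_c / x_0, base = 2) / log(x_ctrl / x_0, base = 2)) - 1
}

# Build a minimal endpoint WellData by hand (one bio rep, one plate).
manualEndpoint <- function(treated_counts, conc, ctrl_counts = c(3000, 3000),
                           t0_counts = c(750, 750), drug = "drugX") {
  n_t <- length(treated_counts)
  rec <- rbind(
    data.frame(
      center_id = "c1", scientist_id = "s1", bio_rep = 1L,
      plate_id = "T0", row = 1L, col = seq_along(t0_counts),
      drug = "untreated_t0", concentration = 0, timepoint_h = 0,
      readout_type = "viable_count", value = t0_counts
    ),
    data.frame(
      center_id = "c1", scientist_id = "s1", bio_rep = 1L,
      plate_id = "P1", row = 1L, col = seq_along(ctrl_counts),
      drug = "control", concentration = 0, timepoint_h = 72,
      readout_type = "viable_count", value = ctrl_counts
    ),
    data.frame(
      center_id = "c1", scientist_id = "s1", bio_rep = 1L,
      plate_id = "P1", row = 2L, col = seq_len(n_t),
      drug = drug, concentration = conc, timepoint_h = 72,
      readout_type = "viable_count", value = treated_counts
    )
  )
  wellData(rec, c(8L, 12L))
}

# Manual timecourse: one control and one treated well growing exponentially
# at rates k_ctrl and k_treated (doublings/h), sampled every 2 h.
manualTimecourse <- function(k_treated, k_ctrl = 0.05, duration = 48,
                             x0 = 750) {
  times <- seq(0, duration, by = 2)
  mk <- function(row, drug, conc, k) {
    data.frame(
      center_id = "c1", scientist_id = "s1", bio_rep = 1L,
      plate_id = "P1", row = row, col = 1L, drug = drug,
      concentration = conc, timepoint_h = times,
      readout_type = "viable_count", value = x0 * 2^(k * times)
    )
  }
  wellData(rbind(mk(1L, "control", 0, k_ctrl),
                 mk(2L, "drugX", 1, k_treated)), c(8L, 12L))
}
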