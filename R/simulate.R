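# Synthetic plate-data generator: endpoint, time-course and surrogate-assay
# datasets with the nested replicate structure, noise hierarchy, edge field
# and drug-dependent surrogate bias that the downstream analysis assumes.

#' Default drug panel for the simulator
#'
#' Eight drugs with qualitatively distinct ground-truth behaviours chosen to
#' exercise every analysis stage: a potent full-arrest MEK inhibitor
#' (GEC50 well inside the dose range), a SRC-family inhibitor whose
#' mid-point sits near the top dose (dose-range truncation exemplar), an
#' EGFR/HER2 inhibitor with strong early efficacy that adapts away over
#' time, a CDK4/6 inhibitor and a topoisomerase inhibitor whose arrested
#' cells carry inflated per-cell ATP (surrogate-assay bias exemplars), a
#' PI3K inhibitor whose surrogate curve never drops below GR = 0.5, and two
#' intermediate cytotoxic/cytostatic compounds. Parameter values are
#' illustrative calibrations, not measured constants.
#'
#' @return Named list with elements \code{drugs} (named list of
#'   [TrueDoseResponse-class]) and \code{atpBias} (named numeric).
#' @export
defaultDrugPanel <- function() {
  drugs <- list(
    Paclitaxel  = trueDoseResponse(grInf = -0.70, gec50 = 0.005, hill = 1.3),
    Alpelisib   = trueDoseResponse(grInf =  0.20, gec50 = 0.10,  hill = 1.0),
    Neratinib   = trueDoseResponse(grInf = -0.60, gec50 = 0.05,  hill = 1.5,
                                   adaptationTau = 40),
    Dasatinib   = trueDoseResponse(grInf = -0.40, gec50 = 1.5,   hill = 1.2),
    Trametinib  = trueDoseResponse(grInf =  0.00, gec50 = 0.005, hill = 2.0),
    Palbociclib = trueDoseResponse(grInf =  0.05, gec50 = 0.02,  hill = 1.0),
    Vorinostat  = trueDoseResponse(grInf = -0.20, gec50 = 0.50,  hill = 1.5),
    Etoposide   = trueDoseResponse(grInf = -0.30, gec50 = 0.30,  hill = 1.0)
  )
  atpBias <- c(
    Paclitaxel = 1.1, Alpelisib = 1.8, Neratinib = 1.0, Dasatinib = 1.1,
    Trametinib = 1.2, Palbociclib = 2.0, Vorinostat = 1.2, Etoposide = 2.5
  )
  list(drugs = drugs, atpBias = atpBias)
}

#' Construct a SimulationConfig
#'
#' Defaults reproduce the study design the package is built around: 8 drugs
#' at 8 doses in sqrt(10)-fold steps from 1 uM, 384-well plates seeded at
#' 750 cells/well, 72 h of treatment, 3 biological replicates x 3 plates x
#' 3 wells per condition, 24 randomized vehicle-control wells per plate,
#' and one full untreated plate per biological replicate assayed at t = 0.
#'
#' @param drugs named list of [TrueDoseResponse-class]; default
#'   [defaultDrugPanel()].
#' @param atpBias named numeric per-drug surrogate bias multiplier.
#' @param dosesPerDrug,topDose,dilutionFold dose-series design.
#' @param nBio,nPlates,nWells nested replicate structure (days, plates per
#'   day, wells per plate per condition).
#' @param nControlWells vehicle wells per treated plate.
#' @param seeding cells per well at plating.
#' @param kCtrl control growth rate (doublings/h); default 0.05 (20 h
#'   doubling time).
#' @param duration treatment duration (h).
#' @param wellCV well-level multiplicative count CV (0 = exact counts).
#' @param plateSigma,daySigmaGrowth log-scale SDs of the plate- and
#'   day-level multiplicative growth-rate effects (expectation 1).
#' @param daySigmaEffect log-scale SD of the day-level multiplicative
#'   effect on drug efficacy.
#' @param edgeFrac,edgeDepth edge-field depression and band depth.
#' @param deadBaseline,deadSlope dead-cell fraction model.
#' @param plateDims integer (rows, cols).
#' @param centerId,scientistId labels stamped on generated records.
#' @param seed default RNG seed.
#' @return A validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(drugs = NULL, atpBias = NULL,
                             dosesPerDrug = 8L, topDose = 1,
                             dilutionFold = sqrt(10),
                             nBio = 3L, nPlates = 3L, nWells = 3L,
                             nControlWells = 24L,
                             seeding = 750, kCtrl = 0.05, duration = 72,
                             wellCV = 0.05, plateSigma = 0.02,
                             daySigmaGrowth = 0.05, daySigmaEffect = 0.1,
                             edgeFrac = 0, edgeDepth = 2,
                             deadBaseline = 0.05, deadSlope = 0.3,
                             plateDims = c(16L, 24L),
                             centerId = "center1", scientistId = "scientistB",
                             seed = 1L) {
  if (is.null(drugs)) {
    panel <- defaultDrugPanel()
    drugs <- panel$drugs
    if (is.null(atpBias)) atpBias <- panel$atpBias
  }
  if (is.null(atpBias)) {
    atpBias <- stats::setNames(rep(1, length(drugs)), names(drugs))
  }
  new("SimulationConfig",
    drugs = drugs, atpBias = atpBias[names(drugs)],
    dosesPerDrug = as.integer(dosesPerDrug), topDose = as.numeric(topDose),
    dilutionFold = as.numeric(dilutionFold), nBio = as.integer(nBio),
    nPlates = as.integer(nPlates), nWells = as.integer(nWells),
    nControlWells = as.integer(nControlWells), seeding = as.numeric(seeding),
    kCtrl = as.numeric(kCtrl), duration = as.numeric(duration),
    wellCV = as.numeric(wellCV), plateSigma = as.numeric(plateSigma),
    daySigmaGrowth = as.numeric(daySigmaGrowth),
    daySigmaEffect = as.numeric(daySigmaEffect),
    edgeFrac = as.numeric(edgeFrac), edgeDepth = as.numeric(edgeDepth),
    deadBaseline = as.numeric(deadBaseline),
    deadSlope = as.numeric(deadSlope), plateDims = as.integer(plateDims),
    centerId = as.character(centerId), scientistId = as.character(scientistId),
    seed = as.integer(seed)
  )
}

#' Ground-truth GR curve of a drug
#'
#' Evaluates GR(c) = grInf + (1 - grInf) / (1 + (c / gec50)^hill), the
#' time-asymptotic truth of a [TrueDoseResponse-class].
#'
#' @param tdr a [TrueDoseResponse-class] object.
#' @param concentration concentrations (uM), >= 0 (0 gives GR = 1).
#' @return Numeric GR values.
#' @export
grTrue <- function(tdr, concentration) {
  stopifnot(is(tdr, "TrueDoseResponse"))
  ifelse(concentration <= 0, 1,
         tdr@grInf + (1 - tdr@grInf) /
           (1 + (concentration / tdr@gec50)^tdr@hill))
}

# Fractional receptor-occupancy-style effect in [0, 1): 0 at dose 0,
# -> 1 at saturating dose. Drives surrogate bias and the dead-cell model.
fracEffect <- function(tdr, concentration) {
  r <- (concentration / tdr@gec50)^tdr@hill
  ifelse(concentration <= 0, 0, r / (1 + r))
}

# Growth-rate fraction implied by a GR value: g = log2(GR + 1), so a well
# growing at fraction g of the control rate has GR = 2^g - 1.
grToGrowthFraction <- function(gr) log2(gr + 1)

# Integral over [0, t] of the efficacy shape
# s(u) = (1 - exp(-u/onsetTau)) * exp(-u/adaptationTau)
# (factors drop out when the corresponding tau is 0). Closed form, so the
# generated counts are exact, not quadrature approximations.
effectShapeIntegral <- function(t, onsetTau, adaptationTau) {
  if (onsetTau == 0 && adaptationTau == 0) return(t)
  if (onsetTau > 0 && adaptationTau == 0) {
    return(t - onsetTau * (1 - exp(-t / onsetTau)))
  }
  if (onsetTau == 0 && adaptationTau > 0) {
    return(adaptationTau * (1 - exp(-t / adaptationTau)))
  }
  tc <- onsetTau * adaptationTau / (onsetTau + adaptationTau)
  adaptationTau * (1 - exp(-t / adaptationTau)) - tc * (1 - exp(-t / tc))
}

# Cumulative growth-fraction exponent at time t for dose c:
# integral of g(c, u) du = t - e * S(t), where e = (1 - g_inf(c)) scaled by
# the day-level efficacy multiplier and S is the effect-shape integral.
growthExponent <- function(tdr, concentration, t, effectMult = 1) {
  gAsym <- grToGrowthFraction(grTrue(tdr, concentration))
  e <- (1 - gAsym) * effectMult
  t - e * effectShapeIntegral(t, tdr@onsetTau, tdr@adaptationTau)
}

# Edge-field multiplier: wells in edge band d (0 = outermost) are depressed
# by frac * max(0, 1 - d / depth).
edgeMultiplier <- function(row, col, dims, frac, depth) {
  d <- pmin(row - 1L, col - 1L, dims[1] - row, dims[2] - col)
  1 - frac * pmax(0, 1 - d / depth)
}

# Multiplicative log-normal well noise with the given CV; mean exactly 1.
# Rounds to integer counts when cv > 0; cv = 0 leaves counts exact so that
# noise-free runs are analytic identities.
applyWellNoise <- function(expected, cv) {
  if (cv <= 0) return(expected)
  sdlog <- sqrt(log(1 + cv^2))
  noisy <- expected * stats::rlnorm(length(expected), -sdlog^2 / 2, sdlog)
  pmax(0, round(noisy))
}

# Log-normal multiplicative effect with expectation exactly 1.
unitMeanLogNormal <- function(n, sigma) {
  if (sigma <= 0) return(rep(1, n))
  stats::rlnorm(n, -sigma^2 / 2, sigma)
}

# Dead-cell fraction tied to drug effect, clipped to [0, 1]; capped just
# below 1 when inverting to nuclei counts.
deadFraction <- function(config, gr_true) {
  pmin(1, pmax(0, config@deadBaseline +
                 config@deadSlope * (1 - (gr_true + 1) / 2)))
}

# Expand viable counts into the three count readouts
# (viable/nuclei/dead), given the dead fraction per well.
countReadouts <- function(viable, dead_frac, cv) {
  f <- pmin(dead_frac, 0.99)
  nuclei <- viable / (1 - f)
  if (cv > 0) nuclei <- round(nuclei)
  dead <- nuclei - viable
  list(viable_count = viable, nuclei_count = nuclei, dead_count = dead)
}

# Build the per-plate treatment multiset for a treated plate.
plateTreatments <- function(config) {
  doses <- doseSeries(config@topDose, config@dosesPerDrug,
                      config@dilutionFold)
  treated <- expand.grid(drug = names(config@drugs), dose = doses,
                         well = seq_len(config@nWells),
                         stringsAsFactors = FALSE)
  rbind(
    data.frame(drug = treated$drug, concentration = treated$dose,
               role = "treated", stringsAsFactors = FALSE),
    data.frame(drug = rep("control", config@nControlWells),
               concentration = 0, role = "control",
               stringsAsFactors = FALSE)
  )
}

wellRows <- function(config, bio, plate_id, layout_df, timepoint, values,
                     dead_frac) {
  ro <- countReadouts(values, dead_frac, config@wellCV)
  do.call(rbind, lapply(names(ro), function(rt) {
    data.frame(
      center_id = config@centerId, scientist_id = config@scientistId,
      bio_rep = bio, plate_id = plate_id,
      row = layout_df$row, col = layout_df$col,
      drug = layout_df$drug, concentration = layout_df$concentration,
      timepoint_h = timepoint, readout_type = rt, value = ro[[rt]],
      stringsAsFactors = FALSE
    )
  }))
}

#' Simulate an endpoint drug-response dataset
#'
#' Generates a full tidy well table: per biological replicate (day), one
#' untreated plate assayed at t = 0 (the pre-treatment count estimate) and
#' \code{nPlates} treated plates assayed at the end of treatment, each with
#' every drug x dose condition in \code{nWells} wells plus randomized
#' vehicle controls. The expected treated count is
#' \code{seeding * 2^(kCtrl * g * duration)} with
#' \code{g = log2(GR_true + 1)} the growth-rate fraction implied by the
#' ground truth, modulated by the day/plate growth-rate effects, the
#' day-level efficacy effect, the edge field and well noise. Viable,
#' nuclei and dead counts are emitted consistently with the dead-fraction
#' model.
#'
#' @param config a [SimulationConfig-class] object.
#' @param seed integer RNG seed; defaults to \code{config@seed}. Identical
#'   (config, seed) pairs give identical tables.
#' @return A [WellData-class] object.
#' @export
simulateEndpoint <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  seed <- if (is.null(seed)) config@seed else as.integer(seed)
  treatments <- plateTreatments(config)
  capacity <- prod(config@plateDims)
  if (nrow(treatments) > capacity) {
    stop(sprintf(
      "plate capacity exceeded: %d condition wells for a %d-well plate",
      nrow(treatments), capacity
    ))
  }
  withr::with_seed(seed, {
    out <- vector("list", config@nBio)
    for (bio in seq_len(config@nBio)) {
      dayGrowth <- unitMeanLogNormal(1, config@daySigmaGrowth)
      dayEffect <- stats::setNames(
        unitMeanLogNormal(length(config@drugs), config@daySigmaEffect),
        names(config@drugs)
      )
      # untreated t=0 plate: full plate of seeded wells, no growth yet
      t0_grid <- expand.grid(row = seq_len(config@plateDims[1]),
                             col = seq_len(config@plateDims[2]))
      t0_layout <- data.frame(
        row = t0_grid$row, col = t0_grid$col,
        drug = "untreated_t0", concentration = 0,
        stringsAsFactors = FALSE
      )
      t0_counts <- applyWellNoise(rep(config@seeding, nrow(t0_layout)),
                                  config@wellCV)
      plates <- list(wellRows(
        config, bio, sprintf("B%d_T0", bio), t0_layout, 0, t0_counts,
        rep(config@deadBaseline, nrow(t0_layout))
      ))
      for (p in seq_len(config@nPlates)) {
        plateGrowth <- unitMeanLogNormal(1, config@plateSigma)
        layout <- randomizeLayout(
          treatments, config@plateDims,
          seed = sample.int(.Machine$integer.max, 1)
        )
        a <- layoutAssignment(layout)
        k <- config@kCtrl * dayGrowth * plateGrowth
        exponent <- vapply(seq_len(nrow(a)), function(i) {
          if (a$role[i] == "control") return(config@duration)
          tdr <- config@drugs[[a$drug[i]]]
          growthExponent(tdr, a$concentration[i], config@duration,
                         dayEffect[[a$drug[i]]])
        }, numeric(1))
        expected <- config@seeding * 2^(k * exponent) *
          edgeMultiplier(a$row, a$col, config@plateDims,
                         config@edgeFrac, config@edgeDepth)
        counts <- applyWellNoise(expected, config@wellCV)
        gr_true <- vapply(seq_len(nrow(a)), function(i) {
          if (a$role[i] == "control") return(1)
          grTrue(config@drugs[[a$drug[i]]], a$concentration[i])
        }, numeric(1))
        plates[[p + 1L]] <- wellRows(
          config, bio, sprintf("B%d_P%d", bio, p), a[, 1:4],
          config@duration, counts, deadFraction(config, gr_true)
        )
      }
      out[[bio]] <- do.call(rbind, plates)
    }
    wellData(do.call(rbind, out), config@plateDims)
  })
}

#' Simulate a live-cell time-course dataset
#'
#' Generates per-well viable counts on a regular time grid
#' t = 0, interval, 2*interval, ..., duration. Drug efficacy at time t is
#' scaled by the onset and adaptation factors of each drug's
#' [TrueDoseResponse-class], so windowed instantaneous GR values can rise
#' or fall over the course of the assay. With both time constants zero and
#' no noise, log2(count) is exactly linear in time for every well.
#'
#' @param config a [SimulationConfig-class] object.
#' @param interval_h sampling interval (h), > 0; default 2.
#' @param duration_h assay duration (h); default \code{config@duration}.
#' @param seed integer RNG seed; defaults to \code{config@seed}.
#' @return A [WellData-class] object with viable_count records only.
#' @export
simulateTimecourse <- function(config, interval_h = 2,
                               duration_h = config@duration, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (!is.numeric(interval_h) || length(interval_h) != 1L || interval_h <= 0)
    stop("'interval_h' must be a positive scalar")
  seed <- if (is.null(seed)) config@seed else as.integer(seed)
  times <- seq(0, duration_h, by = interval_h)
  treatments <- plateTreatments(config)
  capacity <- prod(config@plateDims)
  if (nrow(treatments) > capacity) {
    stop(sprintf(
      "plate capacity exceeded: %d condition wells for a %d-well plate",
      nrow(treatments), capacity
    ))
  }
  withr::with_seed(seed, {
    out <- list()
    for (bio in seq_len(config@nBio)) {
      dayGrowth <- unitMeanLogNormal(1, config@daySigmaGrowth)
      dayEffect <- stats::setNames(
        unitMeanLogNormal(length(config@drugs), config@daySigmaEffect),
        names(config@drugs)
      )
      for (p in seq_len(config@nPlates)) {
        plateGrowth <- unitMeanLogNormal(1, config@plateSigma)
        layout <- randomizeLayout(
          treatments, config@plateDims,
          seed = sample.int(.Machine$integer.max, 1)
        )
        a <- layoutAssignment(layout)
        k <- config@kCtrl * dayGrowth * plateGrowth
        edge <- edgeMultiplier(a$row, a$col, config@plateDims,
                               config@edgeFrac, config@edgeDepth)
        per_time <- lapply(times, function(t) {
          exponent <- vapply(seq_len(nrow(a)), function(i) {
            if (a$role[i] == "control") return(t)
            growthExponent(config@drugs[[a$drug[i]]], a$concentration[i],
                           t, dayEffect[[a$drug[i]]])
          }, numeric(1))
          expected <- config@seeding * 2^(k * exponent) *
            edge^(t / duration_h)
          data.frame(
            center_id = config@centerId, scientist_id = config@scientistId,
            bio_rep = bio, plate_id = sprintf("B%d_P%d", bio, p),
            row = a$row, col = a$col, drug = a$drug,
            concentration = a$concentration, timepoint_h = t,
            readout_type = "viable_count",
            value = applyWellNoise(expected, config@wellCV),
            stringsAsFactors = FALSE
          )
        })
        out[[length(out) + 1L]] <- do.call(rbind, per_time)
      }
    }
    wellData(do.call(rbind, out), config@plateDims)
  })
}

#' Derive a surrogate (ATP-proxy) readout from viable counts
#'
#' Emulates a lysate-ATP viability assay: the per-well signal is
#' \code{viable_count * per_cell_signal}, where the per-cell signal
#' interpolates linearly from 1 (no drug effect) to the drug's
#' \code{atpBias} at full effect, as a function of the drug's fractional
#' effect at that dose. Control and untreated wells carry unit per-cell
#' signal, so their surrogate values equal their counts exactly. Drugs
#' whose treatment arrests cells while they enlarge have
#' \code{atpBias > 1}, inflating the apparent GR relative to direct
#' counting.
#'
#' @param x a [WellData-class] object containing viable_count records.
#' @param config the [SimulationConfig-class] supplying the per-drug truth
#'   and \code{atpBias}.
#' @return A [WellData-class] with the original records plus one
#'   surrogate_signal record per viable_count record.
#' @export
surrogateSignal <- function(x, config) {
  stopifnot(is(x, "WellData"), is(config, "SimulationConfig"))
  rec <- wellRecords(x)
  vi <- rec[rec$readout_type == "viable_count", , drop = FALSE]
  if (nrow(vi) == 0L) stop("no viable_count records in input")
  treated <- !vi$drug %in% CONTROL_DRUGS
  unknown <- setdiff(unique(vi$drug[treated]), names(config@drugs))
  if (length(unknown)) {
    stop("drug(s) missing from config: ", paste(unknown, collapse = ", "))
  }
  per_cell <- rep(1, nrow(vi))
  for (d in unique(vi$drug[treated])) {
    i <- vi$drug == d
    fe <- fracEffect(config@drugs[[d]], vi$concentration[i])
    per_cell[i] <- 1 + (config@atpBias[[d]] - 1) * fe
  }
  sur <- vi
  sur$readout_type <- "surrogate_signal"
  sur$value <- vi$value * per_cell
  wellData(rbind(rec, sur), plateDims(x))
}
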