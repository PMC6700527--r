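#' @import methods
NULL

REQUIRED_WELL_COLUMNS <- c(
  "center_id", "scientist_id", "bio_rep", "plate_id", "row", "col",
  "drug", "concentration", "timepoint_h", "readout_type", "value"
)

READOUT_TYPES <- c("viable_count", "nuclei_count", "dead_count", "surrogate_signal")

CONTROL_DRUGS <- c("control", "untreated_t0")

#' True dose-response curve used by the simulator
#'
#' Parameterises the ground-truth growth-rate inhibition (GR) curve of one
#' drug: a sigmoid in log-concentration with lower asymptote \code{grInf},
#' mid-point \code{gec50} (uM) and Hill slope \code{hill}, optionally with
#' first-order time constants for delayed onset (\code{onsetTau}, h) and
#' adaptation/decay of efficacy (\code{adaptationTau}, h). With both time
#' constants zero the implied GR value is constant in time.
#'
#' @slot grInf asymptotic GR at infinite dose, in [-1, 1].
#' @slot gec50 half-effect concentration in uM, > 0.
#' @slot hill Hill slope, > 0.
#' @slot onsetTau time constant (h, >= 0) for onset of efficacy; 0 = instant.
#' @slot adaptationTau time constant (h, >= 0) for decay of efficacy; 0 = none.
#'
#' @seealso [trueDoseResponse()], [grTrue()]
#' @export
setClass("TrueDoseResponse",
  representation(
    grInf = "numeric",
    gec50 = "numeric",
    hill = "numeric",
    onsetTau = "numeric",
    adaptationTau = "numeric"
  )
)

setValidity("TrueDoseResponse", function(object) {
  msg <- character()
  sc <- function(x) length(x) == 1L && is.finite(x)
  if (!sc(object@grInf) || object@grInf < -1 || object@grInf > 1)
    msg <- c(msg, "'grInf' must be a scalar in [-1, 1]")
  if (!sc(object@gec50) || object@gec50 <= 0)
    msg <- c(msg, "'gec50' must be a positive scalar (uM)")
  if (!sc(object@hill) || object@hill <= 0)
    msg <- c(msg, "'hill' must be a positive scalar")
  if (!sc(object@onsetTau) || object@onsetTau < 0)
    msg <- c(msg, "'onsetTau' must be a non-negative scalar (h)")
  if (!sc(object@adaptationTau) || object@adaptationTau < 0)
    msg <- c(msg, "'adaptationTau' must be a non-negative scalar (h)")
  if (length(msg)) msg else TRUE
})

#' Construct a TrueDoseResponse
#'
#' @param grInf asymptotic GR at infinite dose, in [-1, 1].
#' @param gec50 half-effect concentration (uM), > 0.
#' @param hill Hill slope, > 0.
#' @param onsetTau onset time constant (h), >= 0.
#' @param adaptationTau adaptation time constant (h), >= 0.
#' @return A [TrueDoseResponse-class] object.
#' @examples
#' trueDoseResponse(grInf = -0.5, gec50 = 0.1, hill = 2)
#' @export
trueDoseResponse <- function(grInf, gec50, hill = 1,
                             onsetTau = 0, adaptationTau = 0) {
  new("TrueDoseResponse",
    grInf = as.numeric(grInf), gec50 = as.numeric(gec50),
    hill = as.numeric(hill), onsetTau = as.numeric(onsetTau),
    adaptationTau = as.numeric(adaptationTau)
  )
}

setMethod("show", "TrueDoseResponse", function(object) {
  cat(sprintf(
    "TrueDoseResponse: GR_inf=%.3g, GEC50=%.4g uM, h=%.3g",
    object@grInf, object@gec50, object@hill
  ))
  if (object@onsetTau > 0 || object@adaptationTau > 0) {
    cat(sprintf(
      " (onset tau=%.3g h, adaptation tau=%.3g h)",
      object@onsetTau, object@adaptationTau
    ))
  }
  cat("\n")
})

#' Full generative model for a synthetic plate-based dose-response study
#'
#' Holds the ground truth, design, and noise hierarchy used by
#' [simulateEndpoint()], [simulateTimecourse()] and [surrogateSignal()].
#' The replicate structure is nested: \code{nBio} biological replicates
#' (days), each with \code{nPlates} plates, each plate carrying
#' \code{nWells} wells per drug-dose condition plus randomized vehicle
#' controls, and one full untreated plate assayed at t = 0 per biological
#' replicate to estimate the pre-treatment cell count.
#'
#' @slot drugs named list of [TrueDoseResponse-class] objects.
#' @slot atpBias named numeric, per-drug surrogate signal multiplier at full
#'   drug effect (1 = unbiased, >= 0).
#' @slot dosesPerDrug number of doses per drug.
#' @slot topDose highest dose (uM).
#' @slot dilutionFold fold between adjacent doses (> 1).
#' @slot nBio number of biological replicates (days).
#' @slot nPlates technical plates per biological replicate.
#' @slot nWells wells per plate per drug-dose condition.
#' @slot nControlWells vehicle-control wells per treated plate (>= 1).
#' @slot seeding cells per well at plating (t = 0 count).
#' @slot kCtrl control growth rate, doublings per hour.
#' @slot duration treatment duration (h).
#' @slot wellCV coefficient of variation of well-level multiplicative count
#'   noise (0 disables noise and integer rounding, giving exact counts).
#' @slot plateSigma log-scale SD of the plate-level multiplicative
#'   growth-rate effect.
#' @slot daySigmaGrowth log-scale SD of the day-level multiplicative
#'   growth-rate effect (cancels in GR by design).
#' @slot daySigmaEffect log-scale SD of the day-level multiplicative effect
#'   on drug efficacy (the generative source of biological variability).
#' @slot edgeFrac fractional growth depression in the outermost edge band.
#' @slot edgeDepth number of edge bands over which the depression decays.
#' @slot deadBaseline baseline dead-cell fraction.
#' @slot deadSlope increase in dead fraction per unit of drug effect.
#' @slot plateDims integer (rows, cols) of the plate, e.g. c(16L, 24L).
#' @slot centerId,scientistId labels stamped on generated records.
#' @slot seed default RNG seed for the generators.
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    drugs = "list",
    atpBias = "numeric",
    dosesPerDrug = "integer",
    topDose = "numeric",
    dilutionFold = "numeric",
    nBio = "integer",
    nPlates = "integer",
    nWells = "integer",
    nControlWells = "integer",
    seeding = "numeric",
    kCtrl = "numeric",
    duration = "numeric",
    wellCV = "numeric",
    plateSigma = "numeric",
    daySigmaGrowth = "numeric",
    daySigmaEffect = "numeric",
    edgeFrac = "numeric",
    edgeDepth = "numeric",
    deadBaseline = "numeric",
    deadSlope = "numeric",
    plateDims = "integer",
    centerId = "character",
    scientistId = "character",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@drugs) == 0L)
    msg <- c(msg, "at least one drug is required")
  if (is.null(names(object@drugs)) || anyDuplicated(names(object@drugs)))
    msg <- c(msg, "'drugs' must be a uniquely named list")
  if (!all(vapply(object@drugs, is, logical(1), "TrueDoseResponse")))
    msg <- c(msg, "every element of 'drugs' must be a TrueDoseResponse")
  if (any(names(object@drugs) %in% CONTROL_DRUGS))
    msg <- c(msg, "drug names 'control'/'untreated_t0' are reserved")
  if (!identical(sort(names(object@atpBias)), sort(names(object@drugs))))
    msg <- c(msg, "'atpBias' must be named after the drugs")
  if (any(object@atpBias < 0))
    msg <- c(msg, "'atpBias' must be >= 0")
  if (object@dosesPerDrug < 2L) msg <- c(msg, "'dosesPerDrug' must be >= 2")
  if (object@topDose <= 0) msg <- c(msg, "'topDose' must be > 0")
  if (object@dilutionFold <= 1) msg <- c(msg, "'dilutionFold' must be > 1")
  for (f in c("nBio", "nPlates", "nWells", "nControlWells")) {
    if (slot(object, f) < 1L) msg <- c(msg, sprintf("'%s' must be >= 1", f))
  }
  if (object@seeding < 1) msg <- c(msg, "'seeding' must be >= 1")
  if (object@kCtrl <= 0) msg <- c(msg, "'kCtrl' must be > 0 (doublings/h)")
  if (object@duration <= 0) msg <- c(msg, "'duration' must be > 0 (h)")
  for (f in c("wellCV", "plateSigma", "daySigmaGrowth", "daySigmaEffect")) {
    if (slot(object, f) < 0) msg <- c(msg, sprintf("'%s' must be >= 0", f))
  }
  if (object@edgeFrac < 0 || object@edgeFrac > 1)
    msg <- c(msg, "'edgeFrac' must be in [0, 1]")
  if (object@edgeDepth < 1) msg <- c(msg, "'edgeDepth' must be >= 1")
  if (object@deadBaseline < 0 || object@deadBaseline > 1)
    msg <- c(msg, "'deadBaseline' must be in [0, 1]")
  if (object@deadSlope < 0) msg <- c(msg, "'deadSlope' must be >= 0")
  if (length(object@plateDims) != 2L || any(object@plateDims < 2L))
    msg <- c(msg, "'plateDims' must be two integers >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0(
      "SimulationConfig: %d drugs x %d doses (top %.4g uM, %.3g-fold)\n",
      "  replicates: %d bio x %d plates x %d wells; %d control wells/plate\n",
      "  plate %dx%d; seeding %.0f cells/well; k_ctrl %.3g doublings/h; %g h\n",
      "  noise: well CV %.3g, plate sigma %.3g, day sigma %.3g (growth) / %.3g (effect)\n",
      "  edge: %.0f%% over %g bands; dead fraction %.2g + %.2g x effect\n"
    ),
    length(object@drugs), object@dosesPerDrug, object@topDose,
    object@dilutionFold, object@nBio, object@nPlates, object@nWells,
    object@nControlWells, object@plateDims[1], object@plateDims[2],
    object@seeding, object@kCtrl, object@duration, object@wellCV,
    object@plateSigma, object@daySigmaGrowth, object@daySigmaEffect,
    100 * object@edgeFrac, object@edgeDepth, object@deadBaseline,
    object@deadSlope
  ))
})

#' Tidy collection of per-well observations
#'
#' The central data container: one row per well x timepoint x readout in
#' long format, with the plate geometry attached. Validity enforces the
#' tidy dialect: required columns, non-negative values, coordinates within
#' the plate, known readout types, concentration 0 exactly for control and
#' untreated-t0 wells, and uniqueness of
#' (plate_id, row, col, timepoint_h, readout_type).
#'
#' @slot records data.frame with columns center_id, scientist_id, bio_rep,
#'   plate_id, row, col, drug, concentration, timepoint_h, readout_type,
#'   value.
#' @slot plateDims integer (rows, cols).
#' @seealso [wellData()], [readWellData()], [writeWellData()]
#' @export
setClass("WellData",
  representation(records = "data.frame", plateDims = "integer")
)

setValidity("WellData", function(object) {
  msg <- validateWellRecords(object@records, object@plateDims)
  if (length(msg)) msg else TRUE
})

setMethod("show", "WellData", function(object) {
  rec <- object@records
  cat(sprintf(
    "WellData: %d records on %d plate(s) (%dx%d wells)\n",
    nrow(rec), length(unique(rec$plate_id)),
    object@plateDims[1], object@plateDims[2]
  ))
  drugs <- setdiff(unique(rec$drug), CONTROL_DRUGS)
  cat(sprintf(
    "  %d drug(s); timepoints: %s h; readouts: %s\n",
    length(drugs), paste(sort(unique(rec$timepoint_h)), collapse = ", "),
    paste(sort(unique(rec$readout_type)), collapse = ", ")
  ))
})

#' Assignment of treatments to plate positions
#'
#' @slot dims integer (rows, cols).
#' @slot assignment data.frame with columns row, col, drug, concentration,
#'   role ("treated" or "control").
#' @seealso [randomizeLayout()]
#' @export
setClass("PlateLayout",
  representation(dims = "integer", assignment = "data.frame")
)

setValidity("PlateLayout", function(object) {
  msg <- character()
  a <- object@assignment
  need <- c("row", "col", "drug", "concentration", "role")
  if (!all(need %in% names(a))) {
    return(paste("assignment must have columns", paste(need, collapse = ", ")))
  }
  if (length(object@dims) != 2L) msg <- c(msg, "'dims' must be length 2")
  if (nrow(a)) {
    if (any(a$row < 1L | a$row > object@dims[1] |
            a$col < 1L | a$col > object@dims[2]))
      msg <- c(msg, "assigned positions outside plate dimensions")
    if (anyDuplicated(a[, c("row", "col")]))
      msg <- c(msg, "duplicate well positions in assignment")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlateLayout", function(object) {
  a <- object@assignment
  cat(sprintf(
    "PlateLayout: %dx%d plate, %d assigned wells (%d treated, %d control)\n",
    object@dims[1], object@dims[2], nrow(a),
    sum(a$role == "treated"), sum(a$role == "control")
  ))
})
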