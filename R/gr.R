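# GR core: viable counts, endpoint GR values, windowed instantaneous GR
# from time courses, and doubling times.

#' Viable cell count from nuclei and dead-cell stains
#'
#' The standard counting rule excludes stain-positive dead nuclei:
#' viable = nuclei - dead. The dead-inclusive variant (viable = nuclei)
#' emulates image-processing pipelines that count every nucleus; on
#' cytotoxic drugs it systematically inflates downstream GR values.
#'
#' @param nuclei,dead non-negative counts (vectorized).
#' @param includeDead logical; if TRUE, return the dead-inclusive variant.
#' @return Viable counts. When dead > nuclei the result is clamped to 0
#'   with a warning.
#' @export
viableCounts <- function(nuclei, dead, includeDead = FALSE) {
  stopifnot(all(nuclei >= 0), all(dead >= 0))
  if (includeDead) return(nuclei)
  v <- nuclei - dead
  if (any(v < 0)) {
    warning(sum(v < 0), " well(s) with dead > nuclei; clamped to 0")
    v <- pmax(0, v)
  }
  v
}

#' Growth-rate inhibition (GR) value
#'
#' GR = 2^(log2(x_c / x_0) / log2(x_ctrl / x_0)) - 1, where x_c is the
#' treated count, x_0 the pre-treatment count and x_ctrl the vehicle
#' control count at the same endpoint. GR = 1 means uninhibited growth,
#' 0 complete arrest, -1 complete killing; the value is invariant to
#' rescaling all three counts and, unlike relative viability, to the
#' division rate of the untreated cells.
#'
#' @param x_c treated count (>= 0; 0 is the complete-kill limit, GR = -1).
#' @param x_0 pre-treatment count, > 0.
#' @param x_ctrl control count; must exceed \code{x_0} (controls must have
#'   grown).
#' @return GR values (vectorized over \code{x_c}). Values are not clipped:
#'   GR > 1 indicates treated wells outgrowing controls.
#' @examples
#' grValue(1500, 750, 3000) # 2^(1/2) - 1
#' @export
grValue <- function(x_c, x_0, x_ctrl) {
  stopifnot(all(x_0 > 0))
  if (any(x_ctrl <= x_0)) {
    stop("control growth insufficient: x_ctrl must exceed x_0")
  }
  ifelse(x_c <= 0, -1,
         2^(log2(x_c / x_0) / log2(x_ctrl / x_0)) - 1)
}

#' Per-well GR table from an endpoint dataset
#'
#' For each biological replicate, x_0 is the mean of its untreated t = 0
#' counts (one dedicated plate is assayed at the time of drug addition);
#' x_ctrl is the mean (or median) of the vehicle-control wells on the same
#' plate as the treated well, so plate-level growth effects are absorbed.
#' One GR record is emitted per treated well.
#'
#' @param x a [WellData-class] endpoint dataset.
#' @param readout which readout to use: "viable_count" (default),
#'   "surrogate_signal", or "derived" to recompute viable counts from
#'   nuclei_count/dead_count records via [viableCounts()].
#' @param ctrlStat "mean" (default) or "median" statistic for x_ctrl.
#' @param includeDead passed to [viableCounts()] when
#'   \code{readout = "derived"}.
#' @return data.frame with one row per treated well: replicate address,
#'   drug, concentration, gr, x_c, x_0, x_ctrl, plus \code{flagged}
#'   (|GR| > 1, retained not clipped) and \code{censored} (x_c = 0).
#' @export
grTable <- function(x, readout = c("viable_count", "surrogate_signal",
                                   "derived"),
                    ctrlStat = c("mean", "median"), includeDead = FALSE) {
  stopifnot(is(x, "WellData"))
  readout <- match.arg(readout)
  ctrlStat <- match.arg(ctrlStat)
  cfun <- if (ctrlStat == "mean") mean else stats::median
  rec <- wellRecords(x)
  if (readout == "derived") {
    nuc <- rec[rec$readout_type == "nuclei_count", , drop = FALSE]
    ded <- rec[rec$readout_type == "dead_count", , drop = FALSE]
    key <- function(d) paste(d$plate_id, d$row, d$col, d$timepoint_h,
                             sep = "\r")
    m <- match(key(nuc), key(ded))
    if (anyNA(m)) stop("nuclei_count records without matching dead_count")
    vals <- nuc
    vals$value <- viableCounts(nuc$value, ded$value[m], includeDead)
  } else {
    vals <- rec[rec$readout_type == readout, , drop = FALSE]
    if (nrow(vals) == 0L) stop("no '", readout, "' records in dataset")
  }
  t0 <- vals[vals$drug == "untreated_t0", , drop = FALSE]
  if (nrow(t0) == 0L) stop("no untreated_t0 records: cannot estimate x_0")
  x0_by_bio <- tapply(t0$value, t0$bio_rep, mean)
  endpoint <- vals[vals$drug != "untreated_t0", , drop = FALSE]
  ctrl <- endpoint[endpoint$drug == "control", , drop = FALSE]
  treated <- endpoint[!endpoint$drug %in% CONTROL_DRUGS, , drop = FALSE]
  if (nrow(treated) == 0L) stop("no treated wells in dataset")
  missing_ctrl <- setdiff(unique(treated$plate_id), unique(ctrl$plate_id))
  if (length(missing_ctrl)) {
    stop("plate(s) without control wells: ",
         paste(missing_ctrl, collapse = ", "))
  }
  missing_t0 <- setdiff(unique(treated$bio_rep), names(x0_by_bio))
  if (length(missing_t0)) {
    stop("biological replicate(s) without untreated t=0 plate: ",
         paste(missing_t0, collapse = ", "))
  }
  xctrl_by_plate <- tapply(ctrl$value, ctrl$plate_id, cfun)
  x_0 <- as.numeric(x0_by_bio[as.character(treated$bio_rep)])
  x_ctrl <- as.numeric(xctrl_by_plate[treated$plate_id])
  gr <- grValue(treated$value, x_0, x_ctrl)
  out <- data.frame(
    center_id = treated$center_id, scientist_id = treated$scientist_id,
    bio_rep = treated$bio_rep, plate_id = treated$plate_id,
    row = treated$row, col = treated$col, drug = treated$drug,
    concentration = treated$concentration,
    gr = gr, x_c = treated$value, x_0 = x_0, x_ctrl = x_ctrl,
    flagged = abs(gr) > 1, censored = treated$value <= 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# OLS slope of y on x; NA when fewer than 2 distinct x.
olsSlope <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (n < 2L || sxx == 0) return(NA_real_)
  sum((x - mx) * (y - mean(y))) / sxx
}

#' Instantaneous GR from a live-cell time course
#'
#' Slides a window of width \code{window_h} over the time course in steps
#' of \code{step_h}. In each window, the growth rate k (doublings/h) of
#' every treated well and of the plate-matched control (mean of control
#' wells' log2 counts) is estimated by ordinary least squares of
#' log2(count) on time, and the windowed GR is 2^(k / k_ctrl) - 1. Windows
#' whose control rate is non-positive are flagged and omitted.
#'
#' @param x a [WellData-class] time-course dataset (viable_count records).
#' @param window_h window width in hours (default 12).
#' @param step_h step between window centers in hours (default 2).
#' @return data.frame with one row per treated well x window: replicate
#'   address, drug, concentration, window_center, k_treated, k_ctrl, gr_t.
#'   Omitted windows are reported via attribute "omitted_windows".
#' @export
instantaneousGR <- function(x, window_h = 12, step_h = 2) {
  stopifnot(is(x, "WellData"), window_h > 0, step_h > 0)
  rec <- wellRecords(x)
  rec <- rec[rec$readout_type == "viable_count", , drop = FALSE]
  out <- list()
  omitted <- list()
  for (pid in unique(rec$plate_id)) {
    pl <- rec[rec$plate_id == pid, , drop = FALSE]
    times <- sort(unique(pl$timepoint_h))
    span <- range(times)
    centers <- seq(span[1] + window_h / 2, span[2] - window_h / 2,
                   by = step_h)
    if (length(centers) == 0L) next
    ctrl <- pl[pl$drug == "control", , drop = FALSE]
    if (nrow(ctrl) == 0L) stop("plate without control wells: ", pid)
    # control trajectory: per-timepoint mean of log2 counts
    ctrl_log <- tapply(log2(pmax(ctrl$value, .Machine$double.eps)),
                       ctrl$timepoint_h, mean)
    ctrl_t <- as.numeric(names(ctrl_log))
    treated <- pl[!pl$drug %in% CONTROL_DRUGS, , drop = FALSE]
    wells <- unique(treated[, c("bio_rep", "row", "col", "drug",
                                "concentration")])
    for (ci in seq_along(centers)) {
      ctr <- centers[ci]
      lo <- ctr - window_h / 2 - 1e-9
      hi <- ctr + window_h / 2 + 1e-9
      in_w <- ctrl_t >= lo & ctrl_t <= hi
      if (sum(in_w) < 3L) next
      k_ctrl <- olsSlope(ctrl_t[in_w], as.numeric(ctrl_log)[in_w])
      if (is.na(k_ctrl) || k_ctrl <= 0) {
        omitted[[length(omitted) + 1L]] <-
          data.frame(plate_id = pid, window_center = ctr,
                     reason = "non-positive control growth rate")
        next
      }
      tw <- treated[treated$timepoint_h >= lo & treated$timepoint_h <= hi, ,
                    drop = FALSE]
      wk <- paste(tw$row, tw$col, sep = "\r")
      ks <- vapply(split(seq_len(nrow(tw)), wk), function(i) {
        olsSlope(tw$timepoint_h[i],
                 log2(pmax(tw$value[i], .Machine$double.eps)))
      }, numeric(1))
      first <- tw[!duplicated(wk), , drop = FALSE]
      first_key <- paste(first$row, first$col, sep = "\r")
      k_treated <- as.numeric(ks[first_key])
      out[[length(out) + 1L]] <- data.frame(
        center_id = first$center_id, scientist_id = first$scientist_id,
        bio_rep = first$bio_rep, plate_id = pid,
        row = first$row, col = first$col, drug = first$drug,
        concentration = first$concentration, window_center = ctr,
        k_treated = k_treated, k_ctrl = k_ctrl,
        gr_t = 2^(k_treated / k_ctrl) - 1,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    stop("no complete windows in time course")
  rownames(res) <- NULL
  attr(res, "omitted_windows") <- if (length(omitted))
    do.call(rbind, omitted) else NULL
  res
}

#' Doubling time of a control time course
#'
#' Fits a single log2-linear slope k (doublings/h) to the whole series and
#' returns 1/k in hours. Scale-invariant: multiplying all counts by a
#' positive constant leaves the estimate unchanged.
#'
#' @param timepoint_h observation times (h), >= 3 values.
#' @param counts positive counts at those times.
#' @return Doubling time in hours.
#' @examples
#' doublingTime(c(0, 24, 48), c(750, 1500, 3000)) # 24
#' @export
doublingTime <- function(timepoint_h, counts) {
  if (length(timepoint_h) < 3L) stop("need at least 3 timepoints")
  stopifnot(length(timepoint_h) == length(counts), all(counts > 0))
  k <- olsSlope(timepoint_h, log2(counts))
  if (is.na(k) || k <= 0) stop("no net growth: non-positive slope")
  1 / k
}
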