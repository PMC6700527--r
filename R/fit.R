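# Dose-response fitting: sigmoidal GR curves with a flat-model fallback,
# derived metrics (GR50, GRmax, GEC50, GR_inf, h_GR, GR_AOC), dose-range
# adequacy flags, and assay concordance comparison.

grSigmoid <- function(conc, gr_inf, gec50, h_gr) {
  gr_inf + (1 - gr_inf) / (1 + (conc / gec50)^h_gr)
}

#' Closed-form GR50 of a fitted GR sigmoid
#'
#' Solves gr_inf + (1 - gr_inf) / (1 + (c / gec50)^h) = 0.5 for c.
#'
#' @param gr_inf fitted lower asymptote; must be < 0.5 for a crossing.
#' @param gec50 fitted mid-point (uM).
#' @param h_gr fitted Hill slope.
#' @return GR50 in uM, or NA when the curve never reaches 0.5.
#' @examples
#' solveGR50(-0.5, 0.1, 2) # 0.1 / sqrt(2)
#' @export
solveGR50 <- function(gr_inf, gec50, h_gr) {
  if (gr_inf >= 0.5) return(NA_real_)
  r <- (1 - gr_inf) / (0.5 - gr_inf) - 1
  gec50 * r^(1 / h_gr)
}

#' Normalized area over a GR curve
#'
#' Trapezoidal integral of (1 - GR) over log10(concentration), divided by
#' the log10 dose range: the mean growth-rate deficit across the tested
#' range. 0 for a drug with no effect (GR = 1 everywhere), 1 for complete
#' arrest (GR = 0 everywhere); larger values mean greater sensitivity.
#'
#' @param gr GR values.
#' @param concentration matching concentrations (uM), > 0; need >= 2
#'   distinct values. Replicate GR values per concentration are averaged.
#' @return GR_AOC (unitless).
#' @export
grAOC <- function(gr, concentration) {
  stopifnot(length(gr) == length(concentration), all(concentration > 0))
  mu <- tapply(gr, concentration, mean)
  conc <- as.numeric(names(mu))
  if (length(conc) < 2L) stop("need >= 2 distinct concentrations")
  o <- order(conc)
  lx <- log10(conc[o])
  y <- 1 - as.numeric(mu)[o]
  area <- sum(diff(lx) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  area / (max(lx) - min(lx))
}

# Bounded multi-start least-squares fit of the GR sigmoid to
# per-concentration mean GR values. Parameters: gr_inf in [-1, 1],
# log10(gec50) in [log10(cmin) - 2, log10(cmax) + 2], h in [0.1, 5].
fitSigmoidCore <- function(conc, gr) {
  lx <- log10(conc)
  lo <- c(-1, min(lx) - 2, 0.1)
  hi <- c(1, max(lx) + 2, 5)
  obj <- function(p) {
    sum((gr - grSigmoid(conc, p[1], 10^p[2], p[3]))^2)
  }
  inf0 <- min(max(stats::median(gr), -1), 1)
  starts <- list(
    c(inf0, mean(range(lx)), 1),
    c(inf0, min(lx), 1),
    c(inf0, max(lx), 1),
    c(mean(gr), max(lx) + 2, 0.1)  # near-flat start
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("sigmoid fit failed to converge from any start")
  list(gr_inf = best$par[1], gec50 = 10^best$par[2], h_gr = best$par[3],
       rss = best$value)
}

#' Fit a GR dose-response curve for one drug and replicate group
#'
#' Fits GR(c) = gr_inf + (1 - gr_inf) / (1 + (c / gec50)^h_gr) by bounded
#' multi-start least squares to the per-concentration mean GR, and
#' compares it to the flat model GR(c) = mean by an F-test (nested models
#' with 3 vs 1 parameters). If the sigmoid is not significantly better the
#' fit falls back to flat and the sigmoid parameters are not reported.
#' GR50 is solved in closed form from the fitted parameters and censored
#' to a bound when the fitted curve does not cross 0.5 inside the tested
#' range; GRmax is the mean measured GR at the highest tested
#' concentration (not the fitted asymptote, which is reported separately
#' as gr_inf).
#'
#' @param concentration tested concentrations (uM), > 0.
#' @param gr matching GR values (replicates allowed; >= 4 distinct
#'   concentrations required).
#' @param alpha F-test significance level for retaining the sigmoid
#'   (default 0.05).
#' @return One-row data.frame: fit_kind ("sigmoid"/"flat"), gr_inf, gec50,
#'   h_gr (NA for flat), gr50, gr50_cens ("exact", "greater_than_cmax",
#'   "less_than_cmin"), gr_max, gr_aoc, rss_sigmoid, rss_flat, f_pvalue,
#'   n_conc, and logical flags gr50_undefined, gec50_out_of_range,
#'   no_lower_plateau.
#' @export
fitGRCurve <- function(concentration, gr, alpha = 0.05) {
  stopifnot(length(concentration) == length(gr), all(concentration > 0))
  mu <- tapply(gr, concentration, mean)
  conc <- as.numeric(names(mu))
  y <- as.numeric(mu)
  o <- order(conc)
  conc <- conc[o]
  y <- y[o]
  n <- length(conc)
  if (n < 4L) stop("need >= 4 distinct concentrations, got ", n)
  cmin <- min(conc)
  cmax <- max(conc)
  flat_mean <- mean(y)
  rss_flat <- sum((y - flat_mean)^2)
  sig <- fitSigmoidCore(conc, y)
  rss_sig <- min(sig$rss, rss_flat)
  # nested-model F-test: sigmoid (3 params) vs flat (1 param)
  df1 <- 2
  df2 <- n - 3
  if (rss_sig <= 0 && rss_flat <= 0) {
    f_p <- 1  # all values identical: flat, zero residual
  } else if (rss_sig <= .Machine$double.eps * max(1, rss_flat)) {
    f_p <- if (rss_flat > rss_sig) 0 else 1
  } else {
    fstat <- ((rss_flat - rss_sig) / df1) / (rss_sig / df2)
    f_p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  is_sigmoid <- df2 >= 1 && f_p < alpha && rss_flat > rss_sig
  gr_max <- mean(gr[concentration == cmax])
  gr_aoc <- grAOC(gr, concentration)
  if (is_sigmoid) {
    curve_min <- grSigmoid(cmin, sig$gr_inf, sig$gec50, sig$h_gr)
    curve_max <- grSigmoid(cmax, sig$gr_inf, sig$gec50, sig$h_gr)
    if (curve_max > 0.5) {
      gr50 <- cmax
      cens <- "greater_than_cmax"
    } else if (curve_min < 0.5) {
      gr50 <- cmin
      cens <- "less_than_cmin"
    } else {
      gr50 <- solveGR50(sig$gr_inf, sig$gec50, sig$h_gr)
      cens <- "exact"
    }
    out <- data.frame(
      fit_kind = "sigmoid", gr_inf = sig$gr_inf, gec50 = sig$gec50,
      h_gr = sig$h_gr, gr50 = gr50, gr50_cens = cens,
      gr_max = gr_max, gr_aoc = gr_aoc,
      rss_sigmoid = rss_sig, rss_flat = rss_flat, f_pvalue = f_p,
      n_conc = n,
      gr50_undefined = cens != "exact",
      gec50_out_of_range = sig$gec50 < cmin || sig$gec50 > cmax,
      no_lower_plateau = abs(curve_max - sig$gr_inf) > 0.1,
      stringsAsFactors = FALSE
    )
  } else {
    cens <- if (flat_mean >= 0.5) "greater_than_cmax" else "less_than_cmin"
    out <- data.frame(
      fit_kind = "flat", gr_inf = flat_mean, gec50 = NA_real_,
      h_gr = NA_real_, gr50 = if (cens == "greater_than_cmax") cmax else cmin,
      gr50_cens = cens, gr_max = gr_max, gr_aoc = gr_aoc,
      rss_sigmoid = rss_sig, rss_flat = rss_flat, f_pvalue = f_p,
      n_conc = n, gr50_undefined = TRUE,
      gec50_out_of_range = FALSE, no_lower_plateau = FALSE,
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Fit GR curves per drug and replicate group
#'
#' Splits a GR table (see [grTable()]) by drug and the given grouping
#' columns and fits each cell with [fitGRCurve()].
#'
#' @param gr_table data.frame with at least drug, concentration, gr.
#' @param groupBy character vector of additional grouping columns (e.g.
#'   "bio_rep"); empty (default) pools all replicates per drug.
#' @param alpha F-test level passed to [fitGRCurve()].
#' @return data.frame, one row per drug x group, with the grouping columns
#'   followed by the [fitGRCurve()] columns.
#' @export
fitDoseResponse <- function(gr_table, groupBy = character(), alpha = 0.05) {
  stopifnot(all(c("drug", "concentration", "gr") %in% names(gr_table)))
  stopifnot(all(groupBy %in% names(gr_table)))
  keys <- c("drug", groupBy)
  fac <- interaction(gr_table[keys], drop = TRUE, sep = "\r")
  pieces <- lapply(split(gr_table, fac), function(d) {
    fit <- fitGRCurve(d$concentration, d$gr, alpha = alpha)
    cbind(d[1, keys, drop = FALSE], fit, row.names = NULL)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$drug), , drop = FALSE]
}

#' Dose-range adequacy flags for a sigmoid fit
#'
#' A dose range is only adequate when it spans the response mid-point and
#' reaches the lower plateau; otherwise fitted parameters (gr_inf in
#' particular) are extrapolations. Flags: \code{gec50_out_of_range} when
#' the fitted GEC50 lies outside [cmin, cmax]; \code{no_lower_plateau}
#' when the fitted curve at the top tested dose is still more than 0.1 GR
#' units above the fitted asymptote.
#'
#' @param fit one-row data.frame from [fitGRCurve()] with
#'   \code{fit_kind == "sigmoid"}.
#' @param concentration the tested concentrations (uM).
#' @return Named logical vector with the two flags.
#' @export
doseRangeFlags <- function(fit, concentration) {
  stopifnot(nrow(fit) == 1L)
  if (fit$fit_kind != "sigmoid") stop("flags are defined for sigmoid fits")
  cmin <- min(concentration)
  cmax <- max(concentration)
  curve_max <- grSigmoid(cmax, fit$gr_inf, fit$gec50, fit$h_gr)
  c(
    gec50_out_of_range = fit$gec50 < cmin || fit$gec50 > cmax,
    no_lower_plateau = abs(curve_max - fit$gr_inf) > 0.1
  )
}

#' Compare GR metrics between two assay readouts
#'
#' Per-drug differences between two fit sets (e.g. direct cell counts vs
#' an ATP surrogate): delta GRmax = gr_max_A - gr_max_B, delta
#' log10(GR50) where both are uncensored, and a discordance flag when
#' GR50 is defined in one readout but censored in the other. Drugs present
#' in only one set are reported as incomparable rather than dropped.
#'
#' @param fitsA,fitsB data.frames from [fitDoseResponse()] (one row per
#'   drug).
#' @return data.frame with drug, comparable, delta_gr_max,
#'   delta_log10_gr50, gr50_discordant.
#' @export
compareAssays <- function(fitsA, fitsB) {
  drugs <- union(fitsA$drug, fitsB$drug)
  ia <- match(drugs, fitsA$drug)
  ib <- match(drugs, fitsB$drug)
  comparable <- !is.na(ia) & !is.na(ib)
  defA <- !is.na(ia) & fitsA$gr50_cens[ia] == "exact"
  defB <- !is.na(ib) & fitsB$gr50_cens[ib] == "exact"
  delta_log10_gr50 <- ifelse(
    comparable & defA & defB,
    log10(fitsA$gr50[ia]) - log10(fitsB$gr50[ib]), NA_real_
  )
  out <- data.frame(
    drug = drugs,
    comparable = comparable,
    delta_gr_max = ifelse(comparable,
                          fitsA$gr_max[ia] - fitsB$gr_max[ib], NA_real_),
    delta_log10_gr50 = delta_log10_gr50,
    gr50_discordant = comparable & xor(defA, defB),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
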