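# Spatial plate QC: detection of edge effects and uneven growth on full
# plates of untreated cell counts.

#' Extract one plate of one readout as a matrix
#'
#' @param x a [WellData-class] object.
#' @param plate_id plate identifier.
#' @param readout readout type (default "viable_count").
#' @param timepoint_h timepoint to extract; default the single timepoint
#'   present.
#' @return Numeric matrix (rows x cols); unobserved wells are NA.
#' @export
plateMatrix <- function(x, plate_id, readout = "viable_count",
                        timepoint_h = NULL) {
  stopifnot(is(x, "WellData"))
  rec <- wellRecords(x)
  rec <- rec[rec$plate_id == plate_id & rec$readout_type == readout, ,
             drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for plate ", plate_id)
  if (is.null(timepoint_h)) {
    tp <- unique(rec$timepoint_h)
    if (length(tp) > 1L) stop("multiple timepoints; specify 'timepoint_h'")
    timepoint_h <- tp
  }
  rec <- rec[rec$timepoint_h == timepoint_h, , drop = FALSE]
  dims <- plateDims(x)
  m <- matrix(NA_real_, dims[1], dims[2])
  m[cbind(rec$row, rec$col)] <- rec$value
  m
}

edgeDistance <- function(dims) {
  r <- row(matrix(0, dims[1], dims[2]))
  c <- col(matrix(0, dims[1], dims[2]))
  pmin(r - 1L, c - 1L, dims[1] - r, dims[2] - c)
}

#' Edge-effect analysis of a plate of counts
#'
#' Quantifies spatial growth irregularities on a full rectangular plate of
#' untreated cell counts: the fractional deviation of each row, column and
#' edge-distance band from the plate mean, and a Welch two-sample test of
#' each row/column against all other wells, Bonferroni-adjusted across the
#' rows + columns tests. Edge effects -- depressed growth in wells near
#' the plate border caused by evaporation and temperature gradients --
#' show up as negative deviations concentrated in band 0 and flagged
#' outer rows/columns.
#'
#' @param counts numeric matrix of well counts (rows x cols), no missing
#'   wells.
#' @param alpha significance level on the Bonferroni-adjusted p-values
#'   (default 0.01).
#' @param bandDepth bands 0..bandDepth-1 are reported individually, deeper
#'   wells pooled (default 2, i.e. bands 0, 1, 2+).
#' @return List of class "edgeEffectReport": plate_mean, alpha, and
#'   data.frames \code{row} / \code{col} (index, n, mean, deviation, p,
#'   p_adj, flag) and \code{band} (band, n, mean, deviation). Deviations
#'   are (group mean - plate mean) / plate mean; their count-weighted
#'   mean over all wells is 0 by construction.
#' @export
edgeEffectAnalysis <- function(counts, alpha = 0.01, bandDepth = 2L) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix")
  }
  if (anyNA(counts)) {
    idx <- which(is.na(counts), arr.ind = TRUE)
    labs <- wellLabel(idx[, 1], idx[, 2])
    stop("missing wells: ", paste(utils::head(labs, 12), collapse = ", "),
         if (nrow(idx) > 12) sprintf(" (and %d more)", nrow(idx) - 12) else "")
  }
  m <- mean(counts)
  if (m == 0) stop("zero plate mean")
  dims <- dim(counts)
  groupTest <- function(in_group) {
    g <- counts[in_group]
    rest <- counts[!in_group]
    p <- tryCatch(stats::t.test(g, rest, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
    if (is.na(p)) {
      # degenerate limit: essentially zero variance in both groups
      p <- if (isTRUE(all.equal(mean(g), mean(rest)))) 1 else 0
    }
    c(n = length(g), mean = mean(g), p = p)
  }
  n_tests <- dims[1] + dims[2]
  rowStats <- t(vapply(seq_len(dims[1]), function(i) {
    groupTest(row(counts) == i)
  }, numeric(3)))
  colStats <- t(vapply(seq_len(dims[2]), function(j) {
    groupTest(col(counts) == j)
  }, numeric(3)))
  mk <- function(stats) {
    p_adj <- pmin(1, stats[, "p"] * n_tests)
    data.frame(
      index = seq_len(nrow(stats)), n = stats[, "n"],
      mean = stats[, "mean"],
      deviation = (stats[, "mean"] - m) / m,
      p = stats[, "p"], p_adj = p_adj,
      flag = !is.na(p_adj) & p_adj < alpha
    )
  }
  d <- edgeDistance(dims)
  band_id <- pmin(d, bandDepth)
  band <- do.call(rbind, lapply(sort(unique(as.vector(band_id))), function(b) {
    g <- counts[band_id == b]
    data.frame(
      band = if (b == bandDepth) paste0(b, "+") else as.character(b),
      n = length(g), mean = mean(g), deviation = (mean(g) - m) / m,
      stringsAsFactors = FALSE
    )
  }))
  out <- list(plate_mean = m, alpha = alpha,
              row = mk(rowStats), col = mk(colStats), band = band)
  class(out) <- "edgeEffectReport"
  out
}

#' @export
print.edgeEffectReport <- function(x, ...) {
  cat(sprintf("Edge-effect report: plate mean %.1f, alpha = %g\n",
              x$plate_mean, x$alpha))
  cat(sprintf("  flagged rows: %s\n  flagged columns: %s\n",
              paste(x$row$index[x$row$flag], collapse = ", "),
              paste(x$col$index[x$col$flag], collapse = ", ")))
  cat("  deviation by edge band:\n")
  for (i in seq_len(nrow(x$band))) {
    cat(sprintf("    band %-3s %+.1f%%\n", x$band$band[i],
                100 * x$band$deviation[i]))
  }
  invisible(x)
}
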