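# Replicate metrology: technical and biological standard errors of GR
# values with the nested replicate combinatorics, SE of derived GR
# metrics, and distribution summaries (mean, 90th percentile, KDE).

# SE = sigma / sqrt(n), sigma = sqrt(sum((x - mu)^2) / (n - 1)).
seStats <- function(x) {
  n <- length(x)
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / (n - 1))
  list(n = n, mu = mu, sigma = sigma, se = sigma / sqrt(n))
}

#' Technical standard error of GR values
#'
#' One SE per (drug, dose, biological replicate), computed across all of
#' that replicate's technical GR values (all wells on all plates of the
#' same day). With d drugs, k doses and b biological replicates the
#' result has exactly d * k * b rows; e.g. the reference design of 8
#' drugs x 8 doses x 3 biological replicates yields 192 SE values.
#'
#' @param gr_table data.frame from [grTable()] (needs drug, concentration,
#'   bio_rep, gr).
#' @return data.frame: drug, concentration, bio_rep, scope ("technical"),
#'   n, mu, sigma, se. Cells with fewer than 2 technical values are
#'   skipped with a warning.
#' @export
technicalSE <- function(gr_table) {
  stopifnot(all(c("drug", "concentration", "bio_rep", "gr") %in%
                  names(gr_table)))
  fac <- interaction(gr_table[c("drug", "concentration", "bio_rep")],
                     drop = TRUE, sep = "\r")
  pieces <- lapply(split(gr_table, fac), function(d) {
    if (nrow(d) < 2L) return(NULL)
    s <- seStats(d$gr)
    data.frame(
      drug = d$drug[1], concentration = d$concentration[1],
      bio_rep = d$bio_rep[1], scope = "technical",
      n = s$n, mu = s$mu, sigma = s$sigma, se = s$se,
      stringsAsFactors = FALSE
    )
  })
  skipped <- sum(vapply(pieces, is.null, logical(1)))
  if (skipped > 0L) {
    warning(skipped, " drug-dose-replicate cell(s) with < 2 technical ",
            "values skipped")
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Biological standard error of GR values
#'
#' For each drug-dose pair, every combination that picks exactly one
#' technical unit per biological replicate is enumerated, and each
#' combination yields one SE across the b chosen GR values. The technical
#' unit is the plate-level mean GR (wells averaged per plate first), so a
#' design with t plates per biological replicate and b biological
#' replicates yields t^b SE values per drug-dose pair: 3 plates x 3 days
#' gives 3^3 = 27 combinations, and 64 drug-dose pairs give 1728 SE
#' values in total.
#'
#' @param gr_table data.frame from [grTable()].
#' @param maxCombos safety cap on combinations per drug-dose pair
#'   (default 1e5).
#' @return data.frame: drug, concentration, combo (index), scope
#'   ("biological"), n (= b), mu, sigma, se.
#' @export
biologicalSE <- function(gr_table, maxCombos = 1e5) {
  stopifnot(all(c("drug", "concentration", "bio_rep", "plate_id", "gr") %in%
                  names(gr_table)))
  if (length(unique(gr_table$bio_rep)) < 2L) {
    stop("biological SE undefined with fewer than 2 biological replicates")
  }
  fac <- interaction(gr_table[c("drug", "concentration")],
                     drop = TRUE, sep = "\r")
  pieces <- lapply(split(gr_table, fac), function(d) {
    # plate-level mean GR per biological replicate
    pm <- stats::aggregate(gr ~ bio_rep + plate_id, data = d, FUN = mean)
    units <- split(pm$gr, pm$bio_rep)
    b <- length(units)
    if (b < 2L) return(NULL)
    n_combo <- prod(vapply(units, length, integer(1)))
    if (n_combo > maxCombos) {
      stop("combination count ", n_combo, " exceeds maxCombos for ",
           d$drug[1], " at ", d$concentration[1], " uM")
    }
    grid <- do.call(expand.grid, lapply(units, seq_along))
    res <- lapply(seq_len(nrow(grid)), function(i) {
      x <- vapply(seq_len(b), function(j) units[[j]][grid[i, j]],
                  numeric(1))
      s <- seStats(x)
      data.frame(
        drug = d$drug[1], concentration = d$concentration[1],
        combo = i, scope = "biological",
        n = s$n, mu = s$mu, sigma = s$sigma, se = s$se,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Standard error of derived GR metrics across replicate fits
#'
#' Applies the SE formula to GRmax, GR_AOC and log10(GR50) across
#' per-replicate curve fits of each drug. Censored GR50 values are
#' excluded from the log10(GR50) SE and the exclusion count is reported;
#' if all are censored the SE is reported as NA.
#'
#' @param fits data.frame from
#'   \code{fitDoseResponse(..., groupBy = "bio_rep")} (or any one-fit-per-
#'   replicate table with drug, gr_max, gr_aoc, gr50, gr50_cens).
#' @return data.frame: drug, metric, n_used, n_excluded, mu, sigma, se.
#' @export
metricSE <- function(fits) {
  stopifnot(all(c("drug", "gr_max", "gr_aoc", "gr50", "gr50_cens") %in%
                  names(fits)))
  pieces <- lapply(split(fits, fits$drug), function(d) {
    if (nrow(d) < 2L) {
      warning("drug ", d$drug[1], " has < 2 replicate fits; skipped")
      return(NULL)
    }
    rows <- list()
    for (metric in c("gr_max", "gr_aoc")) {
      s <- seStats(d[[metric]])
      rows[[metric]] <- data.frame(
        drug = d$drug[1], metric = metric, n_used = s$n, n_excluded = 0L,
        mu = s$mu, sigma = s$sigma, se = s$se, stringsAsFactors = FALSE
      )
    }
    ok <- d$gr50_cens == "exact"
    n_exc <- sum(!ok)
    if (sum(ok) >= 2L) {
      s <- seStats(log10(d$gr50[ok]))
      rows$log10_gr50 <- data.frame(
        drug = d$drug[1], metric = "log10_gr50", n_used = s$n,
        n_excluded = n_exc, mu = s$mu, sigma = s$sigma, se = s$se,
        stringsAsFactors = FALSE
      )
    } else {
      rows$log10_gr50 <- data.frame(
        drug = d$drug[1], metric = "log10_gr50", n_used = sum(ok),
        n_excluded = n_exc, mu = NA_real_, sigma = NA_real_, se = NA_real_,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Summarize a set of standard errors
#'
#' Per group: the mean SE, the 90th percentile (linear interpolation
#' between order statistics, h = (n - 1) p + 1), and a Gaussian kernel
#' density estimate (Scott bandwidth) evaluated on 256 points spanning
#' [0, 1.1 * max], renormalized so it integrates to 1 on its grid.
#'
#' @param se_df data.frame with an \code{se} column (e.g. from
#'   [technicalSE()] or [biologicalSE()]).
#' @param groupBy character vector of grouping columns (e.g. "scope",
#'   "drug"); empty = one global group.
#' @return List with \code{summary} (data.frame: group columns, n,
#'   mean_se, p90_se) and \code{kde} (named list of data.frames with
#'   columns grid, density; groups with < 2 values get no KDE). Empty
#'   groups are omitted with a warning.
#' @export
summarizeSE <- function(se_df, groupBy = character()) {
  stopifnot("se" %in% names(se_df))
  if (length(groupBy)) {
    stopifnot(all(groupBy %in% names(se_df)))
    fac <- interaction(se_df[groupBy], drop = TRUE, sep = " | ")
    groups <- split(se_df, fac)
  } else {
    groups <- list(all = se_df)
  }
  kde <- list()
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]$se
    x <- x[is.finite(x)]
    if (length(x) == 0L) {
      warning("group '", g, "' empty; omitted")
      return(NULL)
    }
    if (length(x) >= 2L) kde[[g]] <<- kdeNonNegative(x)
    meta <- groups[[g]][1, groupBy, drop = FALSE]
    cbind(meta, data.frame(
      group = g, n = length(x), mean_se = mean(x),
      p90_se = as.numeric(stats::quantile(x, 0.9, type = 7)),
      stringsAsFactors = FALSE
    ), row.names = NULL)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, kde = kde)
}

# Gaussian KDE with Scott bandwidth on 256 grid points over
# [0, 1.1 * max(x)], renormalized by its trapezoid integral so the density
# integrates to 1 on the grid (SE values are non-negative; an untruncated
# kernel would leak mass below 0).
kdeNonNegative <- function(x, n = 256L) {
  hi <- max(x) * 1.1
  if (hi <= 0) hi <- 1e-6
  grid <- seq(0, hi, length.out = n)
  bw <- tryCatch(stats::bw.nrd(x), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- max(hi / n, 1e-9)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = bw)),
                 numeric(1))
  total <- sum(diff(grid) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2)
  data.frame(grid = grid, density = dens / total)
}

#' Fold-change implied by an SE in log10(GR50)
#'
#' An SE of s in log10(GR50) corresponds to a 10^s-fold variation in
#' GR50: 0.07 corresponds to 1.17-fold, 0.18 to ~1.5-fold.
#'
#' @param se_log10 non-negative SE(s) on the log10 scale.
#' @return Fold change(s), 10^se_log10.
#' @export
foldChangeLog10SE <- function(se_log10) {
  stopifnot(all(se_log10 >= 0))
  10^se_log10
}
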