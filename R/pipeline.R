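# End-to-end pipeline: simulate -> GR -> fit -> variability -> QC ->
# assay comparison, with a run manifest for provenance.

pipelineLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

configDigestList <- function(config) {
  drugs <- lapply(config@drugs, function(d) {
    list(gr_inf = d@grInf, gec50 = d@gec50, hill = d@hill,
         onset_tau = d@onsetTau, adaptation_tau = d@adaptationTau)
  })
  list(
    drugs = drugs, atp_bias = as.list(config@atpBias),
    doses_per_drug = config@dosesPerDrug, top_dose = config@topDose,
    dilution_fold = config@dilutionFold, n_bio = config@nBio,
    n_plates = config@nPlates, n_wells = config@nWells,
    n_control_wells = config@nControlWells, seeding = config@seeding,
    k_ctrl = config@kCtrl, duration = config@duration,
    well_cv = config@wellCV, plate_sigma = config@plateSigma,
    day_sigma_growth = config@daySigmaGrowth,
    day_sigma_effect = config@daySigmaEffect,
    edge_frac = config@edgeFrac, edge_depth = config@edgeDepth,
    dead_baseline = config@deadBaseline, dead_slope = config@deadSlope,
    plate_dims = config@plateDims, center_id = config@centerId,
    scientist_id = config@scientistId
  )
}

#' Run the full drug-response reproducibility pipeline
#'
#' Orchestrates all stages on a simulated study: endpoint simulation with
#' surrogate readout, GR tables for both readouts, per-replicate and
#' pooled curve fits, technical/biological/metric SE tables with
#' summaries, edge-effect QC of the untreated t = 0 plates, and
#' count-vs-surrogate assay comparison. All outputs are written as tidy
#' CSV (re-readable by [readWellData()] where applicable) plus JSON
#' summaries, with a run manifest (config snapshot, seed, file digests,
#' timestamps) at the root. The pipeline is a pure function of
#' (config, seed): rerunning reproduces byte-identical CSV outputs.
#'
#' @param config a [SimulationConfig-class] object.
#' @param seed integer RNG seed (default \code{config@seed}).
#' @param outDir output directory, created if needed.
#' @param alpha significance level for curve-fit fallback and QC flags.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
runPipeline <- function(config, seed = NULL, outDir, alpha = 0.05) {
  stopifnot(is(config, "SimulationConfig"))
  seed <- if (is.null(seed)) config@seed else as.integer(seed)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  dirs <- file.path(outDir, c("simulate", "gr", "fits", "variability",
                              "qc", "compare"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)

  pipelineLog("simulate", "generating endpoint dataset (seed %d)", seed)
  endpoint <- simulateEndpoint(config, seed = seed)
  endpoint <- surrogateSignal(endpoint, config)
  writeWellData(endpoint, file.path(outDir, "simulate", "endpoint.csv"))
  pipelineLog("simulate", "%d records", nrow(wellRecords(endpoint)))

  pipelineLog("gr", "computing GR tables")
  gr_counts <- grTable(endpoint, readout = "viable_count")
  gr_surrogate <- grTable(endpoint, readout = "surrogate_signal")
  utils::write.csv(gr_counts, file.path(outDir, "gr", "gr_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(gr_surrogate,
                   file.path(outDir, "gr", "gr_surrogate.csv"),
                   row.names = FALSE)

  pipelineLog("fit", "fitting dose-response curves")
  fits_by_rep <- fitDoseResponse(gr_counts, groupBy = "bio_rep",
                                 alpha = alpha)
  fits_pooled <- fitDoseResponse(gr_counts, alpha = alpha)
  fits_surrogate <- fitDoseResponse(gr_surrogate, alpha = alpha)
  utils::write.csv(fits_by_rep,
                   file.path(outDir, "fits", "fits_by_bio_rep.csv"),
                   row.names = FALSE)
  utils::write.csv(fits_pooled,
                   file.path(outDir, "fits", "fits_pooled.csv"),
                   row.names = FALSE)
  utils::write.csv(fits_surrogate,
                   file.path(outDir, "fits", "fits_surrogate.csv"),
                   row.names = FALSE)

  pipelineLog("variability", "computing SE tables")
  tech <- technicalSE(gr_counts)
  utils::write.csv(tech,
                   file.path(outDir, "variability", "technical_se.csv"),
                   row.names = FALSE)
  bio <- NULL
  if (config@nBio >= 2L) {
    bio <- biologicalSE(gr_counts)
    utils::write.csv(bio,
                     file.path(outDir, "variability", "biological_se.csv"),
                     row.names = FALSE)
  } else {
    pipelineLog("variability",
                "skipping biological SE: only %d biological replicate",
                config@nBio)
  }
  mse <- NULL
  if (config@nBio >= 2L) {
    mse <- metricSE(fits_by_rep)
    utils::write.csv(mse, file.path(outDir, "variability", "metric_se.csv"),
                     row.names = FALSE)
  } else {
    pipelineLog("variability",
                "skipping metric SE: only %d biological replicate",
                config@nBio)
  }
  se_all <- rbind(tech[c("drug", "scope", "se")],
                  if (!is.null(bio)) bio[c("drug", "scope", "se")])
  se_summary <- summarizeSE(se_all, groupBy = "scope")
  jsonlite::write_json(
    list(summary = se_summary$summary,
         by_drug = summarizeSE(se_all, c("scope", "drug"))$summary),
    file.path(outDir, "variability", "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )

  pipelineLog("qc", "edge-effect analysis of untreated t=0 plates")
  qc <- list()
  for (bio_rep in seq_len(config@nBio)) {
    pid <- sprintf("B%d_T0", bio_rep)
    mat <- plateMatrix(endpoint, pid, "viable_count", 0)
    rep <- edgeEffectAnalysis(mat, alpha = 0.01)
    qc[[pid]] <- rep
    utils::write.csv(mat, file.path(outDir, "qc",
                                    sprintf("heatmap_%s.csv", pid)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(qc, function(r) list(
      plate_mean = r$plate_mean,
      band = r$band,
      flagged_rows = r$row$index[r$row$flag],
      flagged_cols = r$col$index[r$col$flag]
    )),
    file.path(outDir, "qc", "edge_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )

  pipelineLog("compare", "comparing count vs surrogate readouts")
  deltas <- compareAssays(fits_surrogate, fits_pooled)
  utils::write.csv(deltas, file.path(outDir, "compare", "assay_deltas.csv"),
                   row.names = FALSE)

  outputs <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    seed = seed,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("grmetrology")),
    config = configDigestList(config),
    outputs = data.frame(
      path = sub(paste0("^", outDir, "/?"), "", outputs),
      md5 = as.character(tools::md5sum(outputs)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pipelineLog("done", "outputs in %s", outDir)
  invisible(list(
    endpoint = endpoint, gr_counts = gr_counts,
    gr_surrogate = gr_surrogate, fits_by_rep = fits_by_rep,
    fits_pooled = fits_pooled, fits_surrogate = fits_surrogate,
    technical_se = tech, biological_se = bio, metric_se = mse,
    se_summary = se_summary, qc = qc, assay_deltas = deltas,
    manifest = manifest
  ))
}
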