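# YAML configuration files mirroring SimulationConfig.

#' Read a simulation configuration from a YAML file
#'
#' The file is a flat key-value document mirroring the
#' [simulationConfig()] arguments (snake_case keys accepted), with one
#' nested block per drug:
#'
#' \preformatted{
#' doses_per_drug: 8
#' top_dose: 1
#' n_bio: 3
#' drugs:
#'   Trametinib: {gr_inf: 0.0, gec50: 0.005, hill: 2, atp_bias: 1.2}
#' }
#'
#' Unset keys fall back to the [simulationConfig()] defaults; omitting the
#' \code{drugs} block selects the default panel.
#'
#' @param path path to a YAML file.
#' @return A validated [SimulationConfig-class] object.
#' @export
readSimulationConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  toCamel <- function(x) {
    x <- gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
    # initialisms the camel-case rule cannot infer
    x[x == "wellCv"] <- "wellCV"
    x
  }
  args <- list()
  scalar_keys <- setdiff(names(raw), c("drugs", "atp_bias"))
  for (k in scalar_keys) {
    ck <- toCamel(k)
    args[[ck]] <- if (ck == "plateDims") as.integer(unlist(raw[[k]]))
                  else raw[[k]]
  }
  if (!is.null(raw$drugs)) {
    drugs <- list()
    atp <- c()
    for (nm in names(raw$drugs)) {
      d <- raw$drugs[[nm]]
      need <- setdiff(c("gr_inf", "gec50"), names(d))
      if (length(need)) {
        stop("drug '", nm, "' missing field(s): ",
             paste(need, collapse = ", "))
      }
      drugs[[nm]] <- trueDoseResponse(
        grInf = d$gr_inf, gec50 = d$gec50,
        hill = if (is.null(d$hill)) 1 else d$hill,
        onsetTau = if (is.null(d$onset_tau)) 0 else d$onset_tau,
        adaptationTau = if (is.null(d$adaptation_tau)) 0 else
          d$adaptation_tau
      )
      atp[nm] <- if (is.null(d$atp_bias)) 1 else d$atp_bias
    }
    args$drugs <- drugs
    args$atpBias <- atp
  }
  bad <- setdiff(names(args), names(formals(simulationConfig)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(simulationConfig, args)
}
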