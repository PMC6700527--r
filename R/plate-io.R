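# Tidy plate I/O: dialect validation, CSV reader/writer, dose series,
# well labels, and randomized plate layouts.

#' Construct a WellData object from a data.frame
#'
#' @param records data.frame in the tidy dialect (see
#'   [WellData-class]).
#' @param plateDims integer (rows, cols); default 384-well (16 x 24).
#' @return A validated [WellData-class] object.
#' @export
wellData <- function(records, plateDims = c(16L, 24L)) {
  records <- as.data.frame(records)
  if (all(REQUIRED_WELL_COLUMNS %in% names(records))) {
    records$bio_rep <- as.integer(records$bio_rep)
    records$row <- as.integer(records$row)
    records$col <- as.integer(records$col)
    for (col in c("concentration", "timepoint_h", "value")) {
      records[[col]] <- as.numeric(records[[col]])
    }
    for (col in c("center_id", "scientist_id", "plate_id", "drug",
                  "readout_type")) {
      records[[col]] <- as.character(records[[col]])
    }
    records <- records[, REQUIRED_WELL_COLUMNS]
  }
  rownames(records) <- NULL
  new("WellData", records = records, plateDims = as.integer(plateDims))
}

#' Extract the tidy record table from a WellData object
#'
#' @param x a [WellData-class] object.
#' @return A data.frame, one row per well x timepoint x readout.
#' @export
wellRecords <- function(x) {
  stopifnot(is(x, "WellData"))
  x@records
}

#' Plate dimensions of a WellData or PlateLayout object
#'
#' @param x a [WellData-class] or [PlateLayout-class] object.
#' @return Integer vector (rows, cols).
#' @export
plateDims <- function(x) {
  if (is(x, "WellData")) return(x@plateDims)
  if (is(x, "PlateLayout")) return(x@dims)
  stop("'x' must be a WellData or PlateLayout")
}

#' Layout assignment table
#'
#' @param x a [PlateLayout-class] object.
#' @return data.frame with columns row, col, drug, concentration, role.
#' @export
layoutAssignment <- function(x) {
  stopifnot(is(x, "PlateLayout"))
  x@assignment
}

# Validate a tidy well table; returns a character vector of problems
# (empty when valid), each naming the offending rows.
validateWellRecords <- function(records, plateDims = c(16L, 24L)) {
  msg <- character()
  missing <- setdiff(REQUIRED_WELL_COLUMNS, names(records))
  if (length(missing)) {
    return(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0L) return(msg)
  rows <- function(idx) paste(utils::head(which(idx), 10L), collapse = ", ")
  bad <- !is.finite(records$value) | records$value < 0
  if (any(bad)) {
    msg <- c(msg, sprintf("negative or non-finite 'value' at row(s) %s",
                          rows(bad)))
  }
  bad <- !records$readout_type %in% READOUT_TYPES
  if (any(bad)) {
    msg <- c(msg, sprintf("unknown 'readout_type' at row(s) %s", rows(bad)))
  }
  bad <- records$row < 1L | records$row > plateDims[1] |
    records$col < 1L | records$col > plateDims[2]
  if (any(bad)) {
    msg <- c(msg, sprintf("well coordinates outside a %dx%d plate at row(s) %s",
                          plateDims[1], plateDims[2], rows(bad)))
  }
  bad <- !is.finite(records$concentration) | records$concentration < 0
  if (any(bad)) {
    msg <- c(msg, sprintf("negative or non-finite 'concentration' at row(s) %s",
                          rows(bad)))
  }
  is_ctrl <- records$drug %in% CONTROL_DRUGS
  bad <- is_ctrl & records$concentration != 0
  if (any(bad)) {
    msg <- c(msg, sprintf(
      "control/untreated_t0 wells must have concentration 0; row(s) %s",
      rows(bad)
    ))
  }
  bad <- !is_ctrl & records$concentration == 0
  if (any(bad)) {
    msg <- c(msg, sprintf(
      "treated wells must have concentration > 0; row(s) %s", rows(bad)
    ))
  }
  bad <- !is.finite(records$timepoint_h) | records$timepoint_h < 0
  if (any(bad)) {
    msg <- c(msg, sprintf("negative 'timepoint_h' at row(s) %s", rows(bad)))
  }
  key <- paste(records$plate_id, records$row, records$col,
               records$timepoint_h, records$readout_type, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- which(dup)[1]
    msg <- c(msg, sprintf(
      "duplicate (plate_id, row, col, timepoint_h, readout_type) key(s) at row(s) %s (e.g. plate %s well %s t=%g h %s)",
      rows(dup), records$plate_id[first],
      wellLabel(records$row[first], records$col[first]),
      records$timepoint_h[first], records$readout_type[first]
    ))
  }
  msg
}

#' Read a tidy well table from CSV
#'
#' Reads the package's tidy CSV dialect (comma-separated, UTF-8, one header
#' row, one readout per row) and validates it. All violations are collected
#' and reported together with the offending row numbers.
#'
#' @param path path to a CSV file.
#' @param plateDims integer (rows, cols); default 384-well.
#' @return A validated [WellData-class] object.
#' @seealso [writeWellData()]
#' @export
readWellData <- function(path, plateDims = c(16L, 24L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  problems <- if (all(REQUIRED_WELL_COLUMNS %in% names(records))) {
    validateWellRecords(records, plateDims)
  } else {
    validateWellRecords(records, plateDims)
  }
  if (length(problems)) {
    stop("invalid well table '", path, "':\n  ",
         paste(problems, collapse = "\n  "))
  }
  wellData(records, plateDims)
}

#' Write a tidy well table to CSV
#'
#' @param x a [WellData-class] object.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeWellData <- function(x, path) {
  stopifnot(is(x, "WellData"))
  utils::write.csv(x@records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Serial-dilution dose series
#'
#' Builds the descending concentration series c_i = topDose / fold^i,
#' i = 0..nPoints-1, the standard design being nine points at sqrt(10)-fold
#' spacing covering four orders of magnitude from the top dose.
#'
#' @param topDose highest dose (uM), > 0.
#' @param nPoints number of concentrations, >= 2.
#' @param fold dilution ratio between adjacent doses, > 1; default
#'   \code{sqrt(10)}.
#' @return Numeric vector of concentrations (uM), descending; the span
#'   max/min equals \code{fold^(nPoints - 1)}.
#' @examples
#' doseSeries(10, 9) # nine half-log steps spanning 1e4
#' @export
doseSeries <- function(topDose, nPoints, fold = sqrt(10)) {
  if (!is.numeric(topDose) || length(topDose) != 1L || topDose <= 0)
    stop("'topDose' must be a positive scalar (uM)")
  if (nPoints < 2L) stop("'nPoints' must be >= 2")
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 1)
    stop("'fold' must be > 1")
  topDose / fold^(seq_len(nPoints) - 1)
}

#' A1-style well labels
#'
#' Converts between 1-based (row, col) coordinates and plate labels such as
#' "C05" (row 3, column 5). Rows beyond "Z" continue "AA", "AB", ...
#'
#' @param row,col 1-based integer coordinates (vectorized).
#' @return \code{wellLabel}: character labels.
#' @examples
#' wellLabel(3, 5) # "C05"
#' parseWellLabel("C05") # row 3, col 5
#' @export
wellLabel <- function(row, col) {
  stopifnot(all(row >= 1L), all(col >= 1L))
  letter <- function(r) {
    ifelse(r <= 26L, LETTERS[r],
           paste0(LETTERS[(r - 1L) %/% 26L], LETTERS[(r - 1L) %% 26L + 1L]))
  }
  sprintf("%s%02d", letter(as.integer(row)), as.integer(col))
}

#' @rdname wellLabel
#' @param label character labels such as "C05".
#' @return \code{parseWellLabel}: data.frame with columns row, col.
#' @export
parseWellLabel <- function(label) {
  m <- regmatches(label, regexec("^([A-Z]+)([0-9]+)$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed well label(s): ",
                     paste(label[bad], collapse = ", "))
  letters_part <- vapply(m, `[`, character(1), 2L)
  row <- vapply(strsplit(letters_part, ""), function(ch) {
    Reduce(function(acc, c) acc * 26L + match(c, LETTERS), ch, accumulate = FALSE, init = 0L)
  }, integer(1))
  data.frame(row = row, col = as.integer(vapply(m, `[`, character(1), 3L)))
}

#' Randomize a treatment multiset onto a plate
#'
#' Assigns the given treatments uniformly at random to distinct wells.
#' Randomizing compound positions converts systematic spatial error (edge
#' effects, uneven growth) into random error, which curve fitting handles
#' far better.
#'
#' @param treatments data.frame with columns drug, concentration and
#'   optionally role ("treated"/"control"; inferred from the drug name when
#'   absent). One row per well to place.
#' @param dims integer (rows, cols) of the plate.
#' @param seed integer RNG seed; same seed, same layout.
#' @return A [PlateLayout-class] object; the treatment multiset is conserved
#'   exactly.
#' @export
randomizeLayout <- function(treatments, dims = c(16L, 24L), seed = 1L) {
  treatments <- as.data.frame(treatments)
  stopifnot(all(c("drug", "concentration") %in% names(treatments)))
  if (is.null(treatments$role)) {
    treatments$role <- ifelse(treatments$drug %in% CONTROL_DRUGS,
                              "control", "treated")
  }
  dims <- as.integer(dims)
  capacity <- dims[1] * dims[2]
  if (nrow(treatments) > capacity) {
    stop(sprintf("plate capacity exceeded: %d treatments for %d wells",
                 nrow(treatments), capacity))
  }
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(capacity, nrow(treatments)))
  assignment <- data.frame(
    row = as.integer((idx - 1L) %/% dims[2] + 1L),
    col = as.integer((idx - 1L) %% dims[2] + 1L),
    drug = treatments$drug,
    concentration = treatments$concentration,
    role = treatments$role,
    stringsAsFactors = FALSE
  )
  new("PlateLayout", dims = dims, assignment = assignment)
}
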