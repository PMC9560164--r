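# Shared vocabularies ------------------------------------------------------

# Per-cell end events: bipolar division, tripolar/tetrapolar (multipolar)
# division, cell death, cell fusion, and right-censoring at the end of the
# observation or simulation window.
.EVENT_TYPES <- c("BD", "MD3", "MD4", "CD", "CF", "NONE")

# Interval-class keys of Operation data-Time ("Ltime" histograms): start
# event -> end event.  FIRST is the progenitor class (time 0 to first event),
# DIVCFDIV the post-fusion-to-division class, NONDIVCD deaths of cells that
# were not born of a division.
.TIME_KEYS <- c("FIRST",
                "BDBD", "BDMD", "BDCD", "BDCF",
                "MDBD", "MDMD", "MDCD", "MDCF",
                "DIVCFDIV", "BDCFCD", "MDCFCD", "NONDIVCD")

# Context keys of Operation data-Events (end-event frequency lists per start
# event) and the event symbols each may hold.  MD aggregates MD3 + MD4.
.LIST_KEYS <- c("FIRST_LIST", "BD_LIST", "MD_LIST", "BDCF_LIST", "MDCF_LIST")
.LIST_SYMBOLS <- list(
  FIRST_LIST = c("BD", "MD", "CD", "NONDIV"),
  BD_LIST    = c("BD", "MD", "CD", "CF"),
  MD_LIST    = c("BD", "MD", "CD", "CF"),
  BDCF_LIST  = c("BD", "MD", "CD", "CF"),
  MDCF_LIST  = c("BD", "MD", "CD", "CF"))

.RECORD_COLUMNS <- c("lineage_id", "cell_id", "parent_cell_id",
                     "birth_min", "end_min", "end_event",
                     "fusion_partner_lineage", "fusion_partner_cell")
.POSITION_COLUMNS <- c("lineage_id", "cell_id", "frame", "t_min", "x_px", "y_px")

.SIM_MODES <- c("standard", "dose", "mixed", "switch", "mixed_switch")

.emptyRecords <- function() {
  data.frame(lineage_id = integer(0), cell_id = integer(0),
             parent_cell_id = integer(0),
             birth_min = numeric(0), end_min = numeric(0),
             end_event = character(0),
             fusion_partner_lineage = integer(0),
             fusion_partner_cell = integer(0),
             stringsAsFactors = FALSE)
}

.emptyPositions <- function() {
  data.frame(lineage_id = integer(0), cell_id = integer(0), frame = integer(0),
             t_min = numeric(0), x_px = numeric(0), y_px = numeric(0),
             stringsAsFactors = FALSE)
}

# LineageDB -----------------------------------------------------------------

#' LineageDB: a forest of tracked or simulated cell lineages
#'
#' A \code{LineageDB} holds one record per cell (real or virtual).  A lineage
#' is one progenitor plus all of its progeny; a database is a forest of such
#' lineages.  Each record carries the lineage and cell identifiers, the parent
#' link, birth and end times in minutes, the end event (\code{BD}, \code{MD3},
#' \code{MD4}, \code{CD}, \code{CF} or \code{NONE} for right-censoring) and,
#' for fusing cells, a reference to the fusion partner.  Per-frame XY positions
#' are optional and live in a companion table.
#'
#' Structural requirements (column names and types, scalar slots) are enforced
#' by the class validity; the full semantic invariants (arity of divisions,
#' fusion symmetry, parent/child time agreement, ...) are checked by
#' \code{\link{validateLineageDB}}, which reports violations as data rather
#' than errors so that defective databases can be inspected.
#'
#' @slot records data.frame with columns \code{lineage_id}, \code{cell_id},
#'   \code{parent_cell_id} (NA for progenitors), \code{birth_min},
#'   \code{end_min}, \code{end_event}, \code{fusion_partner_lineage},
#'   \code{fusion_partner_cell}; extra columns (e.g. \code{population}) are
#'   preserved.
#' @slot positions data.frame of optional per-frame positions with columns
#'   \code{lineage_id}, \code{cell_id}, \code{frame}, \code{t_min},
#'   \code{x_px}, \code{y_px}.
#' @slot frameInterval imaging frame interval in minutes (default 10).
#' @slot trackingDuration length of the observation/simulation window in
#'   minutes.
#' @slot metadata free-form named list (condition label, source, seed, ...).
#'
#' @seealso \code{\link{LineageDB}}, \code{\link{readLineageDB}},
#'   \code{\link{validateLineageDB}}, \code{\link{populationCurve}}
#' @export
setClass("LineageDB",
         representation(records = "data.frame",
                        positions = "data.frame",
                        frameInterval = "numeric",
                        trackingDuration = "numeric",
                        metadata = "list"),
         prototype(records = .emptyRecords(),
                   positions = .emptyPositions(),
                   frameInterval = 10,
                   trackingDuration = 0,
                   metadata = list()))

setValidity("LineageDB", function(object) {
  msg <- character(0)
  rec <- object@records
  miss <- setdiff(.RECORD_COLUMNS, names(rec))
  if (length(miss))
    msg <- c(msg, paste0("records lacks column(s): ", paste(miss, collapse = ", ")))
  pmiss <- setdiff(.POSITION_COLUMNS, names(object@positions))
  if (length(pmiss))
    msg <- c(msg, paste0("positions lacks column(s): ", paste(pmiss, collapse = ", ")))
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number")
  if (length(object@trackingDuration) != 1L || !is.finite(object@trackingDuration) ||
      object@trackingDuration < 0)
    msg <- c(msg, "trackingDuration must be a single non-negative number")
  if (!length(miss) && nrow(rec)) {
    if (!all(rec$end_event %in% .EVENT_TYPES))
      msg <- c(msg, paste0("unknown end_event value(s): ",
                           paste(unique(setdiff(rec$end_event, .EVENT_TYPES)),
                                 collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

# OperationData -------------------------------------------------------------

#' OperationData: the empirical model driving the cell-fate simulator
#'
#' Operation data is the pair of histogram collections extracted from a
#' cell-lineage database: \emph{Operation data-Time} (distributions of the
#' interval, "Ltime", between a cell's start event and its end event, one
#' histogram per start/end class) and \emph{Operation data-Events} (frequency
#' lists of end events per start-event context), plus the recovery fraction
#' (share of bipolar divisions falling in the late tracking window, used to
#' let non-growing virtual cells re-enter proliferation) and the tracking
#' duration.
#'
#' Histograms are stored as named numeric vectors: names are interval values
#' in minutes, values are counts.  Counts may be real-valued after dose
#' interpolation (\code{\link{interpolateOperationData}}); they are only
#' discretised when expanded into \code{\link{buildSimulationArrays}}.
#'
#' @slot timeHistograms named list over the interval classes
#'   \code{FIRST, BDBD, BDMD, BDCD, BDCF, MDBD, MDMD, MDCD, MDCF, DIVCFDIV,
#'   BDCFCD, MDCFCD, NONDIVCD}.
#' @slot eventLists named list over the contexts \code{FIRST_LIST, BD_LIST,
#'   MD_LIST, BDCF_LIST, MDCF_LIST}; each a named count vector over the
#'   symbols \code{BD, MD, CD, CF} (\code{NONDIV} instead of \code{CF} for
#'   \code{FIRST_LIST}).
#' @slot recoveryPercent percentage (0-100) of all bipolar divisions occurring
#'   in the late recovery window.
#' @slot mdAritySplit named numeric \code{c(MD3 = , MD4 = )} giving the
#'   proportion of tripolar vs tetrapolar divisions among multipolar ones.
#' @slot trackingDuration tracking time of the source database, minutes.
#' @slot doseLabel optional numeric dose label (NA when unlabelled).
#'
#' @seealso \code{\link{extractOperationData}},
#'   \code{\link{interpolateOperationData}}, \code{\link{buildSimulationArrays}}
#' @export
setClass("OperationData",
         representation(timeHistograms = "list",
                        eventLists = "list",
                        recoveryPercent = "numeric",
                        mdAritySplit = "numeric",
                        trackingDuration = "numeric",
                        doseLabel = "numeric"))

setValidity("OperationData", function(object) {
  msg <- character(0)
  if (!identical(names(object@timeHistograms), .TIME_KEYS))
    msg <- c(msg, "timeHistograms must have exactly the canonical interval-class keys")
  if (!identical(names(object@eventLists), .LIST_KEYS))
    msg <- c(msg, "eventLists must have exactly the canonical context keys")
  for (k in names(object@timeHistograms)) {
    h <- object@timeHistograms[[k]]
    if (length(h)) {
      if (is.null(names(h)) || anyNA(suppressWarnings(as.numeric(names(h)))))
        msg <- c(msg, paste0("timeHistograms$", k, " must be named by numeric intervals"))
      if (any(h < 0)) msg <- c(msg, paste0("timeHistograms$", k, " has negative counts"))
    }
  }
  for (k in names(object@eventLists)) {
    e <- object@eventLists[[k]]
    if (length(e) && any(e < 0))
      msg <- c(msg, paste0("eventLists$", k, " has negative counts"))
    if (length(e) && !all(names(e) %in% .LIST_SYMBOLS[[k]]))
      msg <- c(msg, paste0("eventLists$", k, " has unknown event symbols"))
  }
  if (length(object@recoveryPercent) != 1L || is.na(object@recoveryPercent) ||
      object@recoveryPercent < 0 || object@recoveryPercent > 100)
    msg <- c(msg, "recoveryPercent must lie in [0, 100]")
  if (!identical(names(object@mdAritySplit), c("MD3", "MD4")) ||
      any(object@mdAritySplit < 0))
    msg <- c(msg, "mdAritySplit must be a non-negative vector named MD3, MD4")
  s <- sum(object@mdAritySplit)
  if (s > 0 && abs(s - 1) > 1e-8)
    msg <- c(msg, "mdAritySplit must sum to 1 when multipolar divisions are present")
  if (length(msg)) msg else TRUE
})

# SimulationArrays ----------------------------------------------------------

#' SimulationArrays: expanded sampling arrays derived from OperationData
#'
#' The simulator does not sample histograms directly; following the original
#' description it expands each interval histogram into a flat value sequence
#' (a histogram entry "20:4" becomes \code{20, 20, 20, 20}) and converts each
#' event list into an array of exactly 100 event symbols whose composition
#' reflects the percentage of each end event relative to the divisions in the
#' list (largest-remainder rounding; shortfalls, which only arise for lists
#' without divisions, are padded with \code{NONDIV} entries).  Empty
#' histograms yield empty arrays, signalling "no data" so that the documented
#' fallbacks apply.
#'
#' Convenience quantities consumed by the assignment rules are precomputed:
#' the mean bipolar-division and mean cell-death times (used when an array is
#' empty) and the cell-death share of total divisions (used by the
#' non-dividing branch).
#'
#' @slot timeArrays named list of numeric vectors (minutes), one per interval
#'   class; length equals the histogram mass.
#' @slot eventArrays named list of character vectors, each of length 100 or 0.
#' @slot recoveryPercent,trackingDuration copied from the source
#'   \code{OperationData}.
#' @slot cdSharePercent cell-death events as a percentage of total divisions.
#' @slot meanBD,meanCD fallback mean interval times in minutes.
#' @slot mdAritySplit proportions of MD3 vs MD4 draws.
#'
#' @seealso \code{\link{buildSimulationArrays}}, \code{\link{sampleArray}}
#' @export
setClass("SimulationArrays",
         representation(timeArrays = "list",
                        eventArrays = "list",
                        recoveryPercent = "numeric",
                        trackingDuration = "numeric",
                        cdSharePercent = "numeric",
                        meanBD = "numeric",
                        meanCD = "numeric",
                        mdAritySplit = "numeric"))

setValidity("SimulationArrays", function(object) {
  msg <- character(0)
  if (!identical(names(object@timeArrays), .TIME_KEYS))
    msg <- c(msg, "timeArrays must have the canonical interval-class keys")
  if (!identical(names(object@eventArrays), .LIST_KEYS))
    msg <- c(msg, "eventArrays must have the canonical context keys")
  for (k in names(object@eventArrays)) {
    n <- length(object@eventArrays[[k]])
    if (!(n %in% c(0L, 100L)))
      msg <- c(msg, paste0("eventArrays$", k, " must hold exactly 100 entries or none"))
  }
  for (k in names(object@timeArrays)) {
    v <- object@timeArrays[[k]]
    if (length(v) && any(v <= 0))
      msg <- c(msg, paste0("timeArrays$", k, " must hold strictly positive intervals"))
  }
  if (length(msg)) msg else TRUE
})

# SimConfig -----------------------------------------------------------------

#' SimConfig: configuration of one cell-fate simulation run
#'
#' Bundles the mode (\code{standard}, \code{dose}, \code{mixed},
#' \code{switch}, \code{mixed_switch}), the simulation horizon, the initial
#' number of progenitors per population, the random seed, and the
#' OperationData attached to each population and phase.  Use the
#' \code{\link{simConfig}} constructor rather than \code{new()}.
#'
#' @slot mode one of the five simulation modes.
#' @slot simTimeEnd simulation horizon ("Sim. Time end"), minutes.
#' @slot initialCounts named integer vector: progenitors per population tag.
#' @slot seed integer seed; identical configs give record-identical output.
#' @slot switchTime minutes at which switch modes change Operation data (NA
#'   otherwise).
#' @slot doseA,doseB,doseX dose-interpolation parameters (dose mode only).
#' @slot opData named list (per population tag) of lists
#'   \code{list(phase1 = OperationData, phase2 = OperationData or NULL)}.
#' @slot parentChildTolerance fractional tolerance of the parent/child
#'   bipolar-division interval restraint (default 0.10).
#' @slot maxResampleAttempts bound on interval resampling before clamping.
#' @slot maxCells safety cap on the number of virtual cells.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulateCellFates}}
#' @export
setClass("SimConfig",
         representation(mode = "character",
                        simTimeEnd = "numeric",
                        initialCounts = "numeric",
                        seed = "numeric",
                        switchTime = "numeric",
                        doseA = "numeric", doseB = "numeric", doseX = "numeric",
                        opData = "list",
                        parentChildTolerance = "numeric",
                        maxResampleAttempts = "numeric",
                        maxCells = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (!(object@mode %in% .SIM_MODES))
    msg <- c(msg, paste0("mode must be one of: ", paste(.SIM_MODES, collapse = ", ")))
  if (object@simTimeEnd <= 0) msg <- c(msg, "simTimeEnd must be positive")
  if (!length(object@initialCounts) || is.null(names(object@initialCounts)) ||
      any(object@initialCounts < 1))
    msg <- c(msg, "initialCounts must be a named vector of positive counts")
  if (object@mode %in% c("switch", "mixed_switch")) {
    if (is.na(object@switchTime) || object@switchTime <= 0 ||
        object@switchTime >= object@simTimeEnd)
      msg <- c(msg, "switchTime must lie strictly between 0 and simTimeEnd")
  }
  if (!identical(sort(names(object@opData)), sort(names(object@initialCounts))))
    msg <- c(msg, "opData must carry one entry per population tag")
  if (object@parentChildTolerance < 0 || object@parentChildTolerance >= 1)
    msg <- c(msg, "parentChildTolerance must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})
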