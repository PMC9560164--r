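#' @import methods
NULL

#' Accessors for LineageDB and OperationData objects
#'
#' Slot access goes through accessors: \code{lineageRecords} returns the
#' per-cell record table, \code{cellPositions} the optional positions table,
#' \code{frameInterval} the imaging interval in minutes,
#' \code{trackingDuration} the observation window, \code{dbMetadata} the
#' free-form metadata list, and \code{nCells}/\code{nLineages} the obvious
#' counts.  \code{timeHistograms}, \code{eventLists} and
#' \code{recoveryPercent} access the components of an
#' \code{\linkS4class{OperationData}} model.
#'
#' @param x a \code{\linkS4class{LineageDB}} or
#'   \code{\linkS4class{OperationData}} object.
#' @return The corresponding component.
#' @name accessors
#' @aliases lineageRecords cellPositions frameInterval trackingDuration
#'   dbMetadata nCells nLineages timeHistograms eventLists recoveryPercent
#' @examples
#' db <- generateSyntheticDB(synthParams(nProgenitors = 5, seed = 1))
#' nLineages(db)
#' head(lineageRecords(db))
NULL

#' @rdname accessors
#' @export
setGeneric("lineageRecords", function(x) standardGeneric("lineageRecords"))
#' @rdname accessors
#' @export
setGeneric("cellPositions", function(x) standardGeneric("cellPositions"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("trackingDuration", function(x) standardGeneric("trackingDuration"))
#' @rdname accessors
#' @export
setGeneric("dbMetadata", function(x) standardGeneric("dbMetadata"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("nLineages", function(x) standardGeneric("nLineages"))
#' @rdname accessors
#' @export
setGeneric("timeHistograms", function(x) standardGeneric("timeHistograms"))
#' @rdname accessors
#' @export
setGeneric("eventLists", function(x) standardGeneric("eventLists"))
#' @rdname accessors
#' @export
setGeneric("recoveryPercent", function(x) standardGeneric("recoveryPercent"))
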