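# LineageDB construction, IO, validation and population accounting.

#' Construct a LineageDB
#'
#' @param records data.frame of per-cell records (see
#'   \code{\linkS4class{LineageDB}}); missing fusion-partner columns are added
#'   as NA.
#' @param frameInterval imaging frame interval in minutes.
#' @param trackingDuration observation window in minutes; defaults to the
#'   largest end time present.
#' @param positions optional per-frame positions table.
#' @param metadata named list of free-form metadata.
#' @return A \code{\linkS4class{LineageDB}}.
#' @examples
#' rec <- data.frame(lineage_id = 1L, cell_id = 1L, parent_cell_id = NA,
#'                   birth_min = 0, end_min = 4000, end_event = "NONE")
#' LineageDB(rec, trackingDuration = 4000)
#' @export
LineageDB <- function(records = .emptyRecords(), frameInterval = 10,
                      trackingDuration = NULL, positions = NULL,
                      metadata = list()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("fusion_partner_lineage", "fusion_partner_cell"))
    if (!col %in% names(records)) records[[col]] <- rep(NA_integer_, nrow(records))
  if (!"parent_cell_id" %in% names(records))
    records$parent_cell_id <- rep(NA_integer_, nrow(records))
  if (is.null(trackingDuration))
    trackingDuration <- if (nrow(records)) max(records$end_min) else 0
  if (is.null(positions)) positions <- .emptyPositions()
  new("LineageDB", records = records, positions = positions,
      frameInterval = frameInterval, trackingDuration = trackingDuration,
      metadata = metadata)
}

#' @rdname accessors
#' @export
setMethod("lineageRecords", "LineageDB", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("cellPositions", "LineageDB", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("frameInterval", "LineageDB", function(x) x@frameInterval)
#' @rdname accessors
#' @export
setMethod("trackingDuration", "LineageDB", function(x) x@trackingDuration)
#' @rdname accessors
#' @export
setMethod("dbMetadata", "LineageDB", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("nCells", "LineageDB", function(x) nrow(x@records))
#' @rdname accessors
#' @export
setMethod("nLineages", "LineageDB", function(x) length(unique(x@records$lineage_id)))

setMethod("show", "LineageDB", function(object) {
  rec <- object@records
  cat("LineageDB with", nrow(rec), "cells in",
      length(unique(rec$lineage_id)), "lineages\n")
  cat("  tracking duration:", object@trackingDuration, "min; frame interval:",
      object@frameInterval, "min\n")
  if (nrow(rec)) {
    ev <- table(factor(.aggEvent(rec$end_event),
                       levels = c("BD", "MD", "CD", "CF", "NONE")))
    cat("  end events:", paste(names(ev), ev, sep = "=", collapse = " "), "\n")
  }
  if (nrow(object@positions))
    cat("  positions:", nrow(object@positions), "rows\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  invisible(NULL)
})

# IO ------------------------------------------------------------------------

#' Read and write cell-lineage tables (native TSV dialect)
#'
#' The native dialect is a UTF-8 tab-separated table with the header
#' \code{lineage_id cell_id parent_cell_id birth_min end_min end_event
#' fusion_partner_lineage fusion_partner_cell}; empty fields encode NA.
#' Additional columns (such as the \code{population} tag written by mixed
#' simulations) are round-tripped untouched and their names recorded in
#' \code{dbMetadata(db)$extra_columns}.  A companion positions table
#' (\code{lineage_id cell_id frame t_min x_px y_px}) may sit next to the main
#' table.
#'
#' @param path file path of the lineage table.
#' @param positionsPath optional path of the companion positions table.
#' @param dialect table dialect; only \code{"native-tsv"} is defined.
#' @param frameInterval,trackingDuration,metadata passed to
#'   \code{\link{LineageDB}}; \code{trackingDuration} defaults to the value
#'   stored in the file comment header when present, else the maximum end
#'   time.
#' @return \code{readLineageDB} returns a \code{\linkS4class{LineageDB}};
#'   \code{writeLineageDB} returns \code{path} invisibly.
#' @examples
#' db <- generateSyntheticDB(synthParams(nProgenitors = 3, seed = 7))
#' f <- tempfile(fileext = ".tsv")
#' writeLineageDB(db, f)
#' db2 <- readLineageDB(f)
#' identical(lineageRecords(db), lineageRecords(db2))
#' @export
readLineageDB <- function(path, dialect = "native-tsv", positionsPath = NULL,
                          frameInterval = 10, trackingDuration = NULL,
                          metadata = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("lineage table not found: ", path)
  headerLines <- readLines(path, n = 50L)
  meta <- headerLines[startsWith(headerLines, "#")]
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  miss <- setdiff(.RECORD_COLUMNS, names(tab))
  if (length(miss))
    stop("parse failure in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (col in c("lineage_id", "cell_id", "parent_cell_id",
                "fusion_partner_lineage", "fusion_partner_cell"))
    tab[[col]] <- as.integer(tab[[col]])
  for (col in c("birth_min", "end_min")) tab[[col]] <- as.numeric(tab[[col]])
  tab$end_event <- as.character(tab$end_event)

  rowOf <- function(i) i + 1L  # header occupies row 1
  dup <- duplicated(tab[c("lineage_id", "cell_id")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop("duplicate (lineage_id, cell_id) = (", tab$lineage_id[i], ", ",
         tab$cell_id[i], ") at row ", rowOf(i), " of ", path)
  }
  key <- paste(tab$lineage_id, tab$cell_id)
  pk <- paste(tab$lineage_id, tab$parent_cell_id)
  dangling <- which(!is.na(tab$parent_cell_id) & !(pk %in% key))
  if (length(dangling)) {
    i <- dangling[1L]
    stop("dangling parent reference: cell (", tab$lineage_id[i], ", ",
         tab$cell_id[i], ") at row ", rowOf(i), " of ", path,
         " names absent parent ", tab$parent_cell_id[i])
  }
  bad <- which(!(tab$end_event %in% .EVENT_TYPES))
  if (length(bad)) {
    i <- bad[1L]
    stop("parse failure: unknown end_event '", tab$end_event[i],
         "' at row ", rowOf(i), " of ", path)
  }

  extra <- setdiff(names(tab), .RECORD_COLUMNS)
  if (length(extra)) metadata$extra_columns <- extra
  durLine <- grep("^# tracking_duration=", meta, value = TRUE)
  if (is.null(trackingDuration) && length(durLine))
    trackingDuration <- as.numeric(sub("^# tracking_duration=", "", durLine[1L]))
  fiLine <- grep("^# frame_interval=", meta, value = TRUE)
  if (length(fiLine))
    frameInterval <- as.numeric(sub("^# frame_interval=", "", fiLine[1L]))
  positions <- NULL
  if (!is.null(positionsPath) && file.exists(positionsPath)) {
    positions <- utils::read.delim(positionsPath, sep = "\t",
                                   comment.char = "#", stringsAsFactors = FALSE)
    pmiss <- setdiff(.POSITION_COLUMNS, names(positions))
    if (length(pmiss))
      stop("parse failure in ", positionsPath, ": missing column(s) ",
           paste(pmiss, collapse = ", "))
  }
  LineageDB(tab, frameInterval = frameInterval,
            trackingDuration = trackingDuration, positions = positions,
            metadata = metadata)
}

#' @param db a \code{\linkS4class{LineageDB}}.
#' @rdname readLineageDB
#' @export
writeLineageDB <- function(db, path, positionsPath = NULL) {
  stopifnot(is(db, "LineageDB"))
  rec <- db@records
  # 17 significant digits make the numeric round trip exact
  fmt <- function(x) ifelse(is.na(x), NA_character_,
                            formatC(x, digits = 17, format = "g"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# tracking_duration=", fmt(db@trackingDuration)),
               paste0("# frame_interval=", fmt(db@frameInterval))), con)
  cols <- c(.RECORD_COLUMNS, setdiff(names(rec), .RECORD_COLUMNS))
  out <- rec[, cols, drop = FALSE]
  for (col in names(out)) if (is.double(out[[col]])) out[[col]] <- fmt(out[[col]])
  utils::write.table(out, con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(positionsPath) && nrow(db@positions)) {
    pos <- db@positions
    for (col in names(pos)) if (is.double(pos[[col]])) pos[[col]] <- fmt(pos[[col]])
    utils::write.table(pos, positionsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

# Validation ----------------------------------------------------------------

.violation <- function(rule, lineage, cell, message) {
  data.frame(rule = rule, lineage_id = lineage, cell_id = cell,
             message = message, stringsAsFactors = FALSE)
}

#' Validate the semantic invariants of a LineageDB
#'
#' Checks the lineage semantics: unique identifiers, resolvable parent links
#' forming a forest, division arity (a BD cell has exactly 2 children, MD3 ->
#' 3, MD4 -> 4, CD and NONE -> 0, a fusion pair exactly one joint child),
#' fusion symmetry (partner set iff the end event is CF, the partner points
#' back, same end time), time consistency (birth >= 0, end >= birth, a
#' child's birth equals its parent's end, no end beyond the tracking
#' duration) and position-table sanity.  Violations are returned as data, one
#' row each, naming the rule and the offending cell; an empty report means
#' the database is valid.
#'
#' @param db a \code{\linkS4class{LineageDB}}.
#' @return data.frame with columns \code{rule}, \code{lineage_id},
#'   \code{cell_id}, \code{message}; zero rows iff valid.
#' @examples
#' db <- generateSyntheticDB(synthParams(nProgenitors = 10, seed = 1))
#' nrow(validateLineageDB(db)) == 0
#' @export
validateLineageDB <- function(db) {
  stopifnot(is(db, "LineageDB"))
  rec <- db@records
  out <- list()
  if (!nrow(rec))
    return(.violation(character(0), integer(0), integer(0), character(0))[0, ])
  key <- paste(rec$lineage_id, rec$cell_id)

  dup <- which(duplicated(rec[c("lineage_id", "cell_id")]))
  for (i in dup)
    out[[length(out) + 1L]] <- .violation("unique id", rec$lineage_id[i],
      rec$cell_id[i], "duplicate (lineage_id, cell_id)")

  pk <- paste(rec$lineage_id, rec$parent_cell_id)
  parentIdx <- match(pk, key)
  dangle <- which(!is.na(rec$parent_cell_id) & is.na(parentIdx))
  for (i in dangle)
    out[[length(out) + 1L]] <- .violation("parent resolves", rec$lineage_id[i],
      rec$cell_id[i], paste0("parent ", rec$parent_cell_id[i], " absent"))

  # cycle check: follow parents; a forest never revisits a node
  for (i in seq_len(nrow(rec))) {
    seen <- integer(0); j <- i
    while (!is.na(j)) {
      if (j %in% seen) {
        out[[length(out) + 1L]] <- .violation("forest", rec$lineage_id[i],
          rec$cell_id[i], "cycle in parent references")
        break
      }
      seen <- c(seen, j)
      j <- parentIdx[j]
    }
  }

  bad <- which(rec$birth_min < 0 | rec$end_min < rec$birth_min)
  for (i in bad)
    out[[length(out) + 1L]] <- .violation("time order", rec$lineage_id[i],
      rec$cell_id[i], "birth_min < 0 or end_min < birth_min")
  over <- which(rec$end_min > db@trackingDuration + 1e-9)
  for (i in over)
    out[[length(out) + 1L]] <- .violation("within duration", rec$lineage_id[i],
      rec$cell_id[i], "end_min exceeds trackingDuration")

  ok <- !is.na(parentIdx)
  drift <- which(ok & abs(rec$birth_min - rec$end_min[parentIdx]) > 1e-9)
  for (i in drift)
    out[[length(out) + 1L]] <- .violation("birth = parent end",
      rec$lineage_id[i], rec$cell_id[i],
      "child birth_min differs from parent end_min")

  nChildren <- tabulate(parentIdx[ok], nbins = nrow(rec))
  expected <- c(BD = 2L, MD3 = 3L, MD4 = 4L, CD = 0L, NONE = 0L)
  for (ev in names(expected)) {
    idx <- which(rec$end_event == ev & nChildren != expected[[ev]])
    for (i in idx)
      out[[length(out) + 1L]] <- .violation(paste(ev, "arity"),
        rec$lineage_id[i], rec$cell_id[i],
        paste0(ev, " cell has ", nChildren[i], " children, expected ",
               expected[[ev]]))
  }

  # fusion symmetry and joint-child arity
  cf <- which(rec$end_event == "CF")
  partnerIdx <- match(paste(rec$fusion_partner_lineage,
                            rec$fusion_partner_cell), key)
  for (i in cf) {
    p <- partnerIdx[i]
    if (is.na(rec$fusion_partner_cell[i]) || is.na(p)) {
      out[[length(out) + 1L]] <- .violation("fusion symmetry",
        rec$lineage_id[i], rec$cell_id[i],
        "CF cell lacks a resolvable fusion_partner")
      next
    }
    if (is.na(partnerIdx[p]) || partnerIdx[p] != i ||
        rec$end_event[p] != "CF")
      out[[length(out) + 1L]] <- .violation("fusion symmetry",
        rec$lineage_id[i], rec$cell_id[i],
        "fusion partner does not point back with end_event CF")
    else if (abs(rec$end_min[i] - rec$end_min[p]) > 1e-9)
      out[[length(out) + 1L]] <- .violation("fusion timing",
        rec$lineage_id[i], rec$cell_id[i],
        "fusion partners end at different times")
    else if (i < p && nChildren[i] + nChildren[p] != 1L)
      out[[length(out) + 1L]] <- .violation("CF arity",
        rec$lineage_id[i], rec$cell_id[i],
        paste0("fusion pair has ", nChildren[i] + nChildren[p],
               " joint children, expected 1"))
  }
  noCF <- which(rec$end_event != "CF" & !is.na(rec$fusion_partner_cell))
  for (i in noCF)
    out[[length(out) + 1L]] <- .violation("fusion symmetry",
      rec$lineage_id[i], rec$cell_id[i],
      "fusion_partner set on a non-CF cell")

  pos <- db@positions
  if (nrow(pos)) {
    pkey <- paste(pos$lineage_id, pos$cell_id)
    orphan <- which(!(pkey %in% key))
    for (i in orphan)
      out[[length(out) + 1L]] <- .violation("positions reference",
        pos$lineage_id[i], pos$cell_id[i], "position row for unknown cell")
    for (k in unique(pkey[pkey %in% key])) {
      rows <- pos[pkey == k, , drop = FALSE]
      ri <- match(k, key)
      if (is.unsorted(rows$frame, strictly = TRUE) ||
          is.unsorted(rows$t_min) ||
          any(rows$t_min < rec$birth_min[ri] - 1e-9) ||
          any(rows$t_min > rec$end_min[ri] + 1e-9))
        out[[length(out) + 1L]] <- .violation("positions order",
          rows$lineage_id[1L], rows$cell_id[1L],
          "frames not strictly increasing or times outside [birth, end]")
    }
  }

  if (!length(out))
    return(data.frame(rule = character(0), lineage_id = integer(0),
                      cell_id = integer(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Population accounting -----------------------------------------------------

#' Alive-cell counts over time
#'
#' Counts the cells alive at every multiple of \code{step} minutes.  A cell is
#' alive on the half-open interval [birth, end): at the frame on which a cell
#' divides the parent is no longer counted and its children are, which keeps
#' the accounting identity alive(t) = progenitors + sum over divisions of
#' (arity - 1) - deaths - fusions exact at every time point.  Cells censored
#' at the end of the window (\code{NONE}) are counted through their end time
#' inclusive.
#'
#' @param db a \code{\linkS4class{LineageDB}}.
#' @param step sampling step in minutes (defaults to the frame interval).
#' @param normalizeTo if non-NULL, counts are scaled so that the progenitor
#'   count equals this value (the original work normalises progenitors to
#'   100 when comparing simulated and tracked populations).
#' @return data.frame with columns \code{time} and \code{count}.
#' @examples
#' rec <- data.frame(lineage_id = 1L, cell_id = 1:3,
#'                   parent_cell_id = c(NA, 1L, 1L),
#'                   birth_min = c(0, 100, 100), end_min = c(100, 400, 400),
#'                   end_event = c("BD", "NONE", "NONE"))
#' populationCurve(LineageDB(rec, trackingDuration = 400), step = 100)
#' @export
populationCurve <- function(db, step = frameInterval(db), normalizeTo = NULL) {
  stopifnot(is(db, "LineageDB"), step > 0)
  rec <- db@records
  times <- seq(0, db@trackingDuration, by = step)
  if (!nrow(rec)) return(data.frame(time = times, count = 0))
  censored <- rec$end_event == "NONE"
  count <- vapply(times, function(t) {
    sum(rec$birth_min <= t &
        (t < rec$end_min | (censored & t <= rec$end_min)))
  }, numeric(1))
  if (!is.null(normalizeTo)) {
    n0 <- sum(is.na(rec$parent_cell_id))
    count <- count / n0 * normalizeTo
  }
  data.frame(time = times, count = count)
}
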