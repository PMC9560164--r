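# Operation data: the empirical model extracted from a lineage database,
# its dose interpolation, and its expansion into sampling arrays.

#' Construct an OperationData object
#'
#' Low-level constructor; most users obtain Operation data with
#' \code{\link{extractOperationData}}.  Missing histogram keys are filled
#' with empty histograms and missing event-list contexts with all-zero count
#' vectors over their canonical symbols.
#'
#' @param timeHistograms named list of interval histograms (named numeric
#'   vectors, names = minutes, values = counts).
#' @param eventLists named list of end-event count vectors.
#' @param recoveryPercent recovery percentage in [0, 100].
#' @param mdAritySplit proportions \code{c(MD3 = , MD4 = )}; defaults to
#'   tripolar-only.
#' @param trackingDuration tracking time in minutes.
#' @param doseLabel optional numeric dose label.
#' @return An \code{\linkS4class{OperationData}}.
#' @export
OperationData <- function(timeHistograms = list(), eventLists = list(),
                          recoveryPercent = 0,
                          mdAritySplit = c(MD3 = 1, MD4 = 0),
                          trackingDuration = 0, doseLabel = NA_real_) {
  th <- stats::setNames(vector("list", length(.TIME_KEYS)), .TIME_KEYS)
  for (k in .TIME_KEYS) {
    h <- timeHistograms[[k]]
    th[[k]] <- if (is.null(h)) stats::setNames(numeric(0), character(0)) else .tidyHist(h)
  }
  el <- stats::setNames(vector("list", length(.LIST_KEYS)), .LIST_KEYS)
  for (k in .LIST_KEYS) {
    base <- stats::setNames(numeric(length(.LIST_SYMBOLS[[k]])), .LIST_SYMBOLS[[k]])
    e <- eventLists[[k]]
    if (!is.null(e)) base[names(e)] <- as.numeric(e)
    el[[k]] <- base
  }
  new("OperationData", timeHistograms = th, eventLists = el,
      recoveryPercent = recoveryPercent, mdAritySplit = mdAritySplit,
      trackingDuration = trackingDuration, doseLabel = doseLabel)
}

#' @rdname accessors
#' @export
setMethod("timeHistograms", "OperationData", function(x) x@timeHistograms)
#' @rdname accessors
#' @export
setMethod("eventLists", "OperationData", function(x) x@eventLists)
#' @rdname accessors
#' @export
setMethod("recoveryPercent", "OperationData", function(x) x@recoveryPercent)
#' @rdname accessors
#' @export
setMethod("trackingDuration", "OperationData", function(x) x@trackingDuration)

setMethod("show", "OperationData", function(object) {
  nt <- sum(vapply(object@timeHistograms, sum, numeric(1)))
  cat("OperationData (tracking", object@trackingDuration, "min",
      if (!is.na(object@doseLabel)) paste0(", dose ", object@doseLabel), ")\n")
  cat("  interval observations:", nt, "; recovery:",
      round(object@recoveryPercent, 2), "%\n")
  el <- object@eventLists
  for (k in .LIST_KEYS) {
    e <- el[[k]]
    if (sum(e) > 0)
      cat("  ", k, ": ", paste(names(e), round(e, 2), sep = "=", collapse = " "),
          "\n", sep = "")
  }
  invisible(NULL)
})

# Extraction ----------------------------------------------------------------

#' Extract Operation data from a cell-lineage database
#'
#' Decomposes every cell into a unit bounded by its start event (its birth:
#' progenitor selection, bipolar/multipolar division, or fusion) and its end
#' event, and accumulates (i) the interval between the two into the matching
#' Operation data-Time histogram and (ii) the end event into the matching
#' Operation data-Events list.  Progenitors feed the \code{FIRST} class;
#' censored cells (\code{NONE}) contribute only a \code{NONDIV} entry for
#' progenitors and nothing otherwise.  A fusion pair contributes one
#' observation (interval taken from the member that carries the merged
#' cell), mirroring the event counting of \code{\link{countEvents}}.
#' Progenitor deaths additionally populate the \code{NONDIVCD} histogram,
#' which the simulator uses to time deaths of non-dividing cells.
#'
#' @param db a validated \code{\linkS4class{LineageDB}}.
#' @param recoveryWindowFraction fraction of the tracking time, counted from
#'   its end, forming the recovery window (default 0.2, generalising a
#'   3200-4000 min window over 4000 min of tracking).
#' @param doseLabel optional numeric dose label stored with the model.
#' @return An \code{\linkS4class{OperationData}}.
#' @examples
#' db <- generateSyntheticDB(synthParams(nProgenitors = 50, seed = 2))
#' extractOperationData(db)
#' @export
extractOperationData <- function(db, recoveryWindowFraction = 0.2,
                                 doseLabel = NA_real_) {
  stopifnot(is(db, "LineageDB"))
  rec <- db@records
  if (!nrow(rec)) stop("cannot extract Operation data from an empty LineageDB")
  dur <- db@trackingDuration
  bc <- .birthClasses(rec)
  pc <- .preFusionClasses(rec, bc)
  interval <- rec$end_min - rec$birth_min
  agg <- .aggEvent(rec$end_event)

  th <- list(); addT <- function(key, x) th[[key]] <<- c(th[[key]], x)
  el <- list(); addE <- function(key, sym, n = 1) {
    cur <- el[[key]]
    if (is.null(cur)) cur <- numeric(0)
    cur[sym] <- if (is.na(cur[sym])) n else cur[sym] + n
    el[[key]] <<- cur
  }

  pairs <- .fusionPairs(rec)
  noncf <- setdiff(seq_len(nrow(rec)), which(rec$end_event == "CF"))
  for (i in noncf) {
    ev <- agg[i]
    switch(bc[i],
      ROOT = {
        if (ev == "NONE") { addE("FIRST_LIST", "NONDIV") } else {
          addT("FIRST", interval[i]); addE("FIRST_LIST", ev)
          if (ev == "CD") addT("NONDIVCD", interval[i])
        }
      },
      BD_CHILD = if (ev != "NONE") {
        addT(paste0("BD", ev), interval[i]); addE("BD_LIST", ev)
      },
      MD_CHILD = if (ev != "NONE") {
        addT(paste0("MD", ev), interval[i]); addE("MD_LIST", ev)
      },
      CF_PRODUCT = if (ev != "NONE") {
        lk <- if (identical(pc[i], "MD")) "MDCF_LIST" else "BDCF_LIST"
        if (ev %in% c("BD", "MD")) addT("DIVCFDIV", interval[i])
        else if (ev == "CD")
          addT(if (lk == "MDCF_LIST") "MDCFCD" else "BDCFCD", interval[i])
        addE(lk, ev)
      })
  }
  if (nrow(pairs)) for (j in seq_len(nrow(pairs))) {
    i <- pairs$carrier[j]
    switch(bc[i],
      BD_CHILD = { addT("BDCF", interval[i]); addE("BD_LIST", "CF") },
      MD_CHILD = { addT("MDCF", interval[i]); addE("MD_LIST", "CF") },
      CF_PRODUCT = {
        addE(if (identical(pc[i], "MD")) "MDCF_LIST" else "BDCF_LIST", "CF")
      })
  }

  nBD <- sum(rec$end_event == "BD")
  recov <- if (nBD > 0)
    recoveryPercentage(db, c((1 - recoveryWindowFraction) * dur, dur)) else 0
  nMD3 <- sum(rec$end_event == "MD3"); nMD4 <- sum(rec$end_event == "MD4")
  split <- if (nMD3 + nMD4 > 0)
    c(MD3 = nMD3, MD4 = nMD4) / (nMD3 + nMD4) else c(MD3 = 1, MD4 = 0)

  OperationData(timeHistograms = lapply(th, .histFromValues),
                eventLists = el, recoveryPercent = recov,
                mdAritySplit = split, trackingDuration = dur,
                doseLabel = doseLabel)
}

#' Percentage of bipolar divisions in a time window
#'
#' The recovery percentage: bipolar divisions whose end time falls inside
#' \code{window} (boundaries inclusive) as a percentage of all bipolar
#' divisions in the database.  Used by the simulator to decide how many
#' non-dividing virtual cells regain reproductive ability late in the run.
#'
#' @param db a \code{\linkS4class{LineageDB}} with at least one bipolar
#'   division.
#' @param window numeric length-2 vector (start, end) in minutes.
#' @return A percentage in [0, 100].
#' @examples
#' # 10 of 300 bipolar divisions in the final 800 min of a 4000-min tracking
#' # give 3.3%.
#' @export
recoveryPercentage <- function(db, window) {
  stopifnot(is(db, "LineageDB"), length(window) == 2L, window[1] <= window[2])
  rec <- db@records
  bd <- rec$end_min[rec$end_event == "BD"]
  if (!length(bd)) stop("recoveryPercentage requires at least one bipolar division")
  sum(bd >= window[1] & bd <= window[2]) / length(bd) * 100
}

# Dose interpolation --------------------------------------------------------

#' Interpolate Operation data between two reference doses
#'
#' Creates virtual Operation data for an intermediate dose by bin-wise linear
#' interpolation of every histogram count:
#' \deqn{c_x = c_a + \frac{c_b - c_a}{d_b - d_a} (d_x - d_a)}
#' applied to all Operation data-Time histograms, all Operation data-Events
#' lists, and the recovery percentage; negative results are clamped to zero.
#' Interpolated counts are kept real-valued (they are only discretised when
#' expanded into simulation arrays), so the interpolation is exact at both
#' endpoints and bin-wise monotone between them.
#'
#' @param a,b \code{\linkS4class{OperationData}} at doses \code{doseA} and
#'   \code{doseB}.
#' @param doseA,doseB,doseX reference and target doses with
#'   \code{doseA < doseB} and \code{doseX} in \code{[doseA, doseB]}.
#' @return An \code{\linkS4class{OperationData}} labelled with \code{doseX}.
#' @examples
#' a <- OperationData(eventLists = list(BD_LIST = c(BD = 10)),
#'                    trackingDuration = 4000)
#' b <- OperationData(eventLists = list(BD_LIST = c(BD = 1)),
#'                    trackingDuration = 4000)
#' eventLists(interpolateOperationData(a, b, 2, 5, 3))$BD_LIST[["BD"]]  # 7
#' @export
interpolateOperationData <- function(a, b, doseA, doseB, doseX) {
  stopifnot(is(a, "OperationData"), is(b, "OperationData"))
  if (!(doseA < doseB)) stop("doseA must be smaller than doseB")
  if (doseX < doseA || doseX > doseB)
    stop("doseX must lie within [doseA, doseB]")
  if (!isTRUE(all.equal(a@trackingDuration, b@trackingDuration)))
    stop("Operation data have different tracking durations")
  f <- (doseX - doseA) / (doseB - doseA)
  lerp <- function(ca, cb) {
    out <- pmax(0, ca + (cb - ca) * f)
    names(out) <- names(ca)
    out
  }

  th <- lapply(.TIME_KEYS, function(k) {
    ha <- a@timeHistograms[[k]]; hb <- b@timeHistograms[[k]]
    bins <- union(names(ha), names(hb))
    if (!length(bins)) return(stats::setNames(numeric(0), character(0)))
    ca <- stats::setNames(rep(0, length(bins)), bins); ca[names(ha)] <- ha
    cb <- stats::setNames(rep(0, length(bins)), bins); cb[names(hb)] <- hb
    .tidyHist(lerp(ca, cb))
  })
  names(th) <- .TIME_KEYS
  el <- lapply(.LIST_KEYS, function(k) lerp(a@eventLists[[k]], b@eventLists[[k]]))
  names(el) <- .LIST_KEYS
  split <- lerp(a@mdAritySplit, b@mdAritySplit)
  split <- if (sum(split) > 0) split / sum(split) else c(MD3 = 1, MD4 = 0)
  OperationData(timeHistograms = th, eventLists = el,
                recoveryPercent = min(100, lerp(a@recoveryPercent,
                                                b@recoveryPercent)),
                mdAritySplit = split, trackingDuration = a@trackingDuration,
                doseLabel = doseX)
}

# Simulation arrays ---------------------------------------------------------

.weightedMean <- function(h) {
  if (!length(h)) return(NA_real_)
  sum(as.numeric(names(h)) * h) / sum(h)
}

#' Expand Operation data into simulation sampling arrays
#'
#' Each interval histogram becomes a flat sequence with one entry per count
#' (a bin "20:4" becomes \code{20, 20, 20, 20}; real-valued interpolated
#' counts are apportioned by largest remainder so the array length equals the
#' rounded histogram mass).  Each event list becomes an array of exactly 100
#' symbols: counts are converted to percentages of the divisions (BD + MD)
#' recorded in that list (or of the list total when it holds no divisions),
#' scaled to a total of 100 where they exceed it, rounded by largest
#' remainder, and padded with \code{NONDIV} entries on the rare shortfall.
#' Lists and histograms without observations yield empty arrays, which
#' downstream assignment treats as "no data".
#'
#' @param od an \code{\linkS4class{OperationData}}.
#' @return A \code{\linkS4class{SimulationArrays}} object.
#' @examples
#' od <- OperationData(timeHistograms = list(BDBD = c("20" = 4)),
#'                     eventLists = list(BD_LIST = c(BD = 1, MD = 1, CD = 1)),
#'                     trackingDuration = 4000)
#' arr <- buildSimulationArrays(od)
#' arr@timeArrays$BDBD          # 20 20 20 20
#' table(arr@eventArrays$BD_LIST)  # BD 34, MD 33, CD 33
#' @export
buildSimulationArrays <- function(od) {
  stopifnot(is(od, "OperationData"))
  ta <- lapply(od@timeHistograms, function(h) {
    if (!length(h)) return(numeric(0))
    vals <- as.numeric(names(h))
    if (all(abs(h - round(h)) < 1e-9)) return(rep(vals, times = round(h)))
    n <- max(1L, as.integer(round(sum(h))))
    rep(vals, times = .largestRemainder(h, n))
  })
  ea <- lapply(.LIST_KEYS, function(k) {
    counts <- od@eventLists[[k]]
    total <- sum(counts)
    if (total <= 0) return(character(0))
    divisions <- sum(counts[intersect(names(counts), c("BD", "MD"))])
    denom <- if (divisions > 0) divisions else total
    perc <- counts / denom * 100
    if (sum(perc) > 100) perc <- perc * 100 / sum(perc)
    target <- min(100L, max(1L, as.integer(round(sum(perc)))))
    n <- .largestRemainder(perc, target)
    arr <- rep(names(counts), times = n)
    c(arr, rep("NONDIV", 100L - length(arr)))
  })
  names(ea) <- .LIST_KEYS

  pooledDiv <- unlist(ta[c("BDBD", "BDMD", "MDBD", "MDMD", "DIVCFDIV")],
                      use.names = FALSE)
  meanBD <- if (length(ta$BDBD)) mean(ta$BDBD)
            else if (length(pooledDiv)) mean(pooledDiv)
            else max(1, od@trackingDuration / 2)
  pooledCD <- unlist(ta[c("BDCD", "MDCD", "NONDIVCD", "BDCFCD", "MDCFCD")],
                     use.names = FALSE)
  meanCD <- if (length(pooledCD)) mean(pooledCD)
            else max(1, od@trackingDuration / 2)

  totalDiv <- sum(vapply(od@eventLists, function(e)
    sum(e[intersect(names(e), c("BD", "MD"))]), numeric(1)))
  totalCD <- sum(vapply(od@eventLists, function(e)
    sum(e[intersect(names(e), "CD")]), numeric(1)))
  cdShare <- if (totalDiv > 0) totalCD / totalDiv * 100 else 0

  new("SimulationArrays", timeArrays = ta, eventArrays = ea,
      recoveryPercent = od@recoveryPercent,
      trackingDuration = od@trackingDuration,
      cdSharePercent = min(100, cdShare),
      meanBD = meanBD, meanCD = meanCD, mdAritySplit = od@mdAritySplit)
}

setMethod("show", "SimulationArrays", function(object) {
  cat("SimulationArrays (tracking", object@trackingDuration, "min)\n")
  nt <- vapply(object@timeArrays, length, integer(1))
  cat("  time arrays:", paste(names(nt)[nt > 0], nt[nt > 0], sep = ":",
                              collapse = " "), "\n")
  ne <- vapply(object@eventArrays, length, integer(1))
  cat("  event arrays populated:", paste(names(ne)[ne > 0], collapse = " "), "\n")
  cat("  recovery:", round(object@recoveryPercent, 2), "%; CD share:",
      round(object@cdSharePercent, 2), "%\n")
  invisible(NULL)
})

#' Draw one entry from a simulation array
#'
#' Uniform draw over the entries of the named array, equivalent to sampling
#' the underlying empirical histogram weighted by its counts.  An empty array
#' returns \code{NULL} ("no data"), letting callers apply the documented
#' fallbacks.  Draws consume the current R random stream, so a
#' \code{set.seed} call makes the sequence reproducible.
#'
#' @param arrays a \code{\linkS4class{SimulationArrays}} object.
#' @param key an interval-class key (e.g. \code{"BDBD"}) or event-list key
#'   (e.g. \code{"BD_LIST"}).
#' @return A numeric interval, a character event symbol, or \code{NULL}.
#' @examples
#' arr <- buildSimulationArrays(OperationData(
#'   timeHistograms = list(BDBD = c("20" = 4)), trackingDuration = 100))
#' sampleArray(arr, "BDBD")  # always 20
#' @export
sampleArray <- function(arrays, key) {
  stopifnot(is(arrays, "SimulationArrays"))
  pool <- if (key %in% names(arrays@timeArrays)) arrays@timeArrays[[key]]
          else if (key %in% names(arrays@eventArrays)) arrays@eventArrays[[key]]
          else stop("unknown array key: ", key)
  if (!length(pool)) return(NULL)
  pool[[sample.int(length(pool), 1L)]]
}

# JSON serialisation --------------------------------------------------------

#' Read and write OperationData as JSON
#'
#' Operation data travels as a single JSON document with an explicit
#' \code{schema_version} field; histogram bins are stored as parallel
#' interval/count arrays so real-valued (interpolated) counts survive the
#' round trip.
#'
#' @param od an \code{\linkS4class{OperationData}}.
#' @param path file path of the JSON document.
#' @return \code{readOperationData} returns an
#'   \code{\linkS4class{OperationData}}; \code{writeOperationData} returns
#'   \code{path} invisibly.
#' @export
writeOperationData <- function(od, path) {
  stopifnot(is(od, "OperationData"))
  doc <- list(
    schema_version = 1L,
    tracking_duration = od@trackingDuration,
    dose_label = od@doseLabel,
    recovery_percent = od@recoveryPercent,
    md_arity_split = as.list(od@mdAritySplit),
    time_histograms = lapply(od@timeHistograms, function(h)
      list(interval = as.numeric(names(h)), count = unname(as.numeric(h)))),
    event_lists = lapply(od@eventLists, as.list))
  if (is.na(od@doseLabel)) doc$dose_label <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeOperationData
#' @export
readOperationData <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    stop("unsupported OperationData schema version in ", path)
  th <- lapply(doc$time_histograms, function(h) {
    if (!length(h$interval)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(as.numeric(h$count), as.character(h$interval))
  })
  el <- lapply(doc$event_lists, function(e) unlist(e))
  OperationData(timeHistograms = th, eventLists = el,
                recoveryPercent = doc$recovery_percent,
                mdAritySplit = unlist(doc$md_arity_split),
                trackingDuration = doc$tracking_duration,
                doseLabel = if (length(doc$dose_label) == 1L)
                              as.numeric(doc$dose_label) else NA_real_)
}
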