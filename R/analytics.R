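# Lineage-level and population-level analyses of a cell-lineage database:
# event counting and rates, reproductive-ability grouping, doubling times,
# multipolar-division tracebacks, in-silico removal of cell death, density
# maps, and damage-response attribution.

#' Count cellular events in a time window
#'
#' Each cell's end event is counted once, at its end time, iff that time
#' falls inside \code{window} (boundaries inclusive).  Tripolar and
#' tetrapolar divisions aggregate to MD; a fusion pair counts as ONE cell
#' fusion event; censored cells (\code{NONE}) are not events.
#'
#' @param db a \code{\linkS4class{LineageDB}}.
#' @param window numeric (start, end) in minutes, inside the tracking
#'   window; defaults to the whole tracking time.  An empty window gives
#'   all-zero counts.
#' @return A list with \code{window}, \code{counts} (named numeric over BD,
#'   MD, CD, CF), \code{n_lineages} and \code{n_frames}.
#' @examples
#' db <- generateSyntheticDB(synthParams(nProgenitors = 20, seed = 3))
#' countEvents(db)$counts
#' @export
countEvents <- function(db, window = c(0, trackingDuration(db))) {
  stopifnot(is(db, "LineageDB"), length(window) == 2L)
  rec <- db@records
  counts <- c(BD = 0, MD = 0, CD = 0, CF = 0)
  inWin <- function(t) t >= window[1] & t <= window[2]
  if (nrow(rec) && window[1] <= window[2]) {
    agg <- .aggEvent(rec$end_event)
    for (e in c("BD", "MD", "CD"))
      counts[[e]] <- sum(agg == e & inWin(rec$end_min))
    pairs <- .fusionPairs(rec)
    if (nrow(pairs))
      counts[["CF"]] <- sum(inWin(rec$end_min[pairs$carrier]))
  }
  list(window = window, counts = counts,
       n_lineages = length(unique(rec$lineage_id)),
       n_frames = as.integer(round((max(window[2], window[1]) - window[1]) /
                                   db@frameInterval)))
}

#' Per-frame event rates per 100 lineages
#'
#' The chance of observing each event type at a given imaging frame,
#' estimated as total events / (frames x lineages) x 100 — the scale on
#' which per-frame probabilities of bipolar division, multipolar division,
#' cell death and cell fusion are reported per 100 lineages.
#'
#' @param db a \code{\linkS4class{LineageDB}} with at least one frame and
#'   one lineage.
#' @return Named numeric rates over BD, MD, CD, CF.
#' @export
eventRatePerFrame <- function(db) {
  stopifnot(is(db, "LineageDB"))
  nFrames <- round(db@trackingDuration / db@frameInterval)
  nLin <- nLineages(db)
  if (nFrames < 1) stop("eventRatePerFrame requires at least one frame")
  if (nLin < 1) stop("eventRatePerFrame requires at least one lineage")
  ce <- countEvents(db)
  ce$counts / (nFrames * nLin) * 100
}

.groupLabel <- function(idx) {
  ifelse(idx <= 26L, LETTERS[pmax(idx, 1L)], paste0("Z", idx - 26L))
}

#' Group lineages by reproductive ability
#'
#' A lineage's reproductive ability is the total number of cells it
#' comprises (progenitor plus all progeny, including cells that underwent
#' multipolar division, cell death or fusion).  Lineages producing 1-2,
#' 3-4, 5-6, ... cells form groups A, B, C, ...; lineages beyond 16 cells
#' continue in 2-cell-wide groups (and beyond 52 cells as Z1, Z2, ...), so
#' the group totals always conserve the number of cells in the database.
#'
#' @param db a \code{\linkS4class{LineageDB}}.
#' @return data.frame with columns \code{group}, \code{lineages},
#'   \code{cells}, one row per group from A up to the largest occupied one.
#' @examples
#' # a lineage of 5 cells falls in group C, one of 13 cells in group G
#' @export
groupLineages <- function(db) {
  stopifnot(is(db, "LineageDB"))
  rec <- db@records
  if (!nrow(rec))
    return(data.frame(group = character(0), lineages = integer(0),
                      cells = integer(0), stringsAsFactors = FALSE))
  sizes <- table(rec$lineage_id)
  idx <- ceiling(as.numeric(sizes) / 2)
  maxIdx <- max(idx)
  lineages <- tabulate(idx, nbins = maxIdx)
  cells <- vapply(seq_len(maxIdx), function(g) sum(sizes[idx == g]),
                  numeric(1))
  data.frame(group = .groupLabel(seq_len(maxIdx)), lineages = lineages,
             cells = as.integer(cells), stringsAsFactors = FALSE)
}

#' Cell doubling times
#'
#' Returns the interval between birth and division for every cell that was
#' produced by a bipolar division and itself ended in bipolar division
#' (progenitors are excluded: their birth event is unknown).
#'
#' @param db a \code{\linkS4class{LineageDB}}.
#' @return Numeric vector of doubling times in minutes (possibly empty).
#' @export
doublingTimes <- function(db) {
  stopifnot(is(db, "LineageDB"))
  rec <- db@records
  if (!nrow(rec)) return(numeric(0))
  bc <- .birthClasses(rec)
  sel <- bc == "BD_CHILD" & rec$end_event == "BD"
  rec$end_min[sel] - rec$birth_min[sel]
}

#' Trace the origins of multipolar cell divisions
#'
#' For every multipolar division the lineage is traced backward: Pattern 1a
#' if the dividing cell was produced by cell fusion, Pattern 1b otherwise.
#' Each Pattern-1a division is classified further: Pattern 2a if the two
#' fused cells were siblings (same parent), Pattern 2b otherwise.  The
#' survival of multipolar progeny is summarised as the number of children
#' of multipolar divisions that underwent bipolar division
#' (\code{reproductive_md_progeny}) out of all such children
#' (\code{total_md_progeny}).
#'
#' @param db a \code{\linkS4class{LineageDB}}.
#' @return A list with \code{pattern1a}, \code{pattern1b}, \code{pattern2a},
#'   \code{pattern2b}, \code{reproductive_md_progeny},
#'   \code{total_md_progeny}.
#' @export
traceMultipolarOrigins <- function(db) {
  stopifnot(is(db, "LineageDB"))
  rec <- db@records
  out <- list(pattern1a = 0L, pattern1b = 0L, pattern2a = 0L, pattern2b = 0L,
              reproductive_md_progeny = 0L, total_md_progeny = 0L)
  if (!nrow(rec)) return(out)
  bc <- .birthClasses(rec)
  key <- paste(rec$lineage_id, rec$cell_id)
  md <- which(rec$end_event %in% c("MD3", "MD4"))
  if (!length(md)) return(out)
  fromCF <- bc[md] == "CF_PRODUCT"
  out$pattern1a <- sum(fromCF)
  out$pattern1b <- sum(!fromCF)
  for (i in md[fromCF]) {
    memberA <- match(paste(rec$lineage_id[i], rec$parent_cell_id[i]), key)
    memberB <- match(paste(rec$fusion_partner_lineage[memberA],
                           rec$fusion_partner_cell[memberA]), key)
    sibs <- !is.na(memberB) &&
      rec$lineage_id[memberA] == rec$lineage_id[memberB] &&
      !is.na(rec$parent_cell_id[memberA]) &&
      !is.na(rec$parent_cell_id[memberB]) &&
      rec$parent_cell_id[memberA] == rec$parent_cell_id[memberB]
    if (isTRUE(sibs)) out$pattern2a <- out$pattern2a + 1L
    else out$pattern2b <- out$pattern2b + 1L
  }
  mdKeys <- key[md]
  progeny <- which(paste(rec$lineage_id, rec$parent_cell_id) %in% mdKeys)
  out$total_md_progeny <- length(progeny)
  out$reproductive_md_progeny <- sum(rec$end_event[progeny] == "BD")
  out
}

# In-silico cell-death removal ----------------------------------------------

.subtreeIndices <- function(rec, root) {
  key <- paste(rec$lineage_id, rec$cell_id)
  out <- root
  frontier <- root
  while (length(frontier)) {
    kids <- which(paste(rec$lineage_id, rec$parent_cell_id) %in% key[frontier])
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Remove cell death from a lineage database in silico
#'
#' Rebuilds the database under the assumption that dying cells would have
#' proliferated like their siblings: every cell that underwent cell death
#' and has a surviving sibling is replaced by a deep copy of that sibling's
#' subtree (times shifted so the copied root keeps the dead cell's birth
#' time; the sibling's own interval is reused verbatim).  Dead cells with no
#' surviving sibling — and progenitor deaths — are assumed to survive
#' without dividing and become censored (\code{NONE}) records reaching the
#' tracking end.  Replacement is iterated until no cell-death record
#' remains, so the output never falls below the input population curve.
#'
#' Siblings whose subtree contains a fusion with a partner outside the
#' subtree cannot be copied without breaking fusion symmetry and are skipped
#' as donors.
#'
#' @param db a validated \code{\linkS4class{LineageDB}}.
#' @return A \code{\linkS4class{LineageDB}} without CD records.
#' @export
removeCellDeathInSilico <- function(db) {
  stopifnot(is(db, "LineageDB"))
  rec <- db@records
  dur <- db@trackingDuration
  repeat {
    cd <- which(rec$end_event == "CD")
    if (!length(cd)) break
    cd <- cd[order(rec$lineage_id[cd], rec$cell_id[cd])]
    i <- cd[1L]
    sibs <- which(rec$lineage_id == rec$lineage_id[i] &
                  !is.na(rec$parent_cell_id) &
                  !is.na(rec$parent_cell_id[i]) &
                  rec$parent_cell_id == rec$parent_cell_id[i] &
                  rec$cell_id != rec$cell_id[i] &
                  rec$end_event != "CD")
    donor <- NA_integer_
    for (s in sibs[order(rec$end_event[sibs] == "CF", rec$cell_id[sibs])]) {
      sub <- .subtreeIndices(rec, s)
      partners <- sub[rec$end_event[sub] == "CF"]
      external <- FALSE
      if (length(partners)) {
        subKey <- paste(rec$lineage_id[sub], rec$cell_id[sub])
        pKey <- paste(rec$fusion_partner_lineage[partners],
                      rec$fusion_partner_cell[partners])
        external <- !all(pKey %in% subKey)
      }
      if (!external) { donor <- s; break }
    }
    if (is.na(donor)) {
      rec$end_event[i] <- "NONE"
      rec$end_min[i] <- dur
      next
    }
    sub <- .subtreeIndices(rec, donor)
    shift <- rec$birth_min[i] - rec$birth_min[donor]
    copy <- rec[sub, , drop = FALSE]
    nextId <- max(rec$cell_id[rec$lineage_id == rec$lineage_id[i]]) + 1L
    newIds <- c(rec$cell_id[i], nextId + seq_len(length(sub) - 1L) - 1L)
    idMap <- stats::setNames(newIds, rec$cell_id[sub])
    copy$cell_id <- newIds
    inMap <- as.character(copy$parent_cell_id) %in% names(idMap)
    copy$parent_cell_id[inMap] <-
      idMap[as.character(copy$parent_cell_id[inMap])]
    copy$parent_cell_id[1L] <- rec$parent_cell_id[i]
    pin <- !is.na(copy$fusion_partner_cell)
    copy$fusion_partner_cell[pin] <-
      idMap[as.character(copy$fusion_partner_cell[pin])]
    copy$birth_min <- copy$birth_min + shift
    copy$end_min <- pmin(copy$end_min + shift, dur)
    rec <- rbind(rec[-i, , drop = FALSE], copy)
  }
  rec <- rec[order(rec$lineage_id, rec$cell_id), , drop = FALSE]
  rownames(rec) <- NULL
  LineageDB(rec, frameInterval = db@frameInterval, trackingDuration = dur,
            metadata = c(db@metadata, list(silico_cell_death_removed = "yes")))
}

# Density maps ---------------------------------------------------------------

#' Disk-kernel density map of cells or events
#'
#' Each contributing point stamps a value of 1 on every pixel whose centre
#' lies within \code{radiusPx} (Euclidean distance, boundary inclusive) of
#' the point; overlapping disks sum, so a pixel's value is the number of
#' nearby points — the heat-map construction with a 20-pixel diameter area
#' per cell and a 100-pixel diameter area per multipolar-division or
#' cell-death event.
#'
#' @param db a \code{\linkS4class{LineageDB}} with a positions table.
#' @param time map time in minutes: for \code{kind = "cell"} the positions
#'   at the nearest imaging frame are used; for \code{kind = "event"} the
#'   last recorded position of every MD/CD cell whose event occurred at or
#'   before \code{time}.
#' @param kind \code{"cell"} or \code{"event"}.
#' @param radiusPx disk radius in pixels; defaults to 10 for cells and 50
#'   for events.
#' @param grid integer (width, height) of the pixel grid.
#' @return Integer matrix (\code{height} rows by \code{width} columns) with
#'   attributes \code{radius} and \code{kind}.
#' @export
densityMap <- function(db, time, kind = c("cell", "event"), radiusPx = NULL,
                       grid = c(512L, 512L)) {
  kind <- match.arg(kind)
  stopifnot(is(db, "LineageDB"), length(grid) == 2L)
  if (is.null(radiusPx)) radiusPx <- if (kind == "cell") 10L else 50L
  pos <- db@positions
  if (!nrow(pos)) stop("densityMap requires a positions table")
  if (kind == "cell") {
    fr <- round(time / db@frameInterval)
    pts <- pos[pos$frame == fr, c("x_px", "y_px"), drop = FALSE]
  } else {
    rec <- db@records
    ev <- which(rec$end_event %in% c("MD3", "MD4", "CD") &
                rec$end_min <= time)
    pts <- do.call(rbind, lapply(ev, function(i) {
      rows <- pos[pos$lineage_id == rec$lineage_id[i] &
                  pos$cell_id == rec$cell_id[i], , drop = FALSE]
      if (!nrow(rows)) return(NULL)
      rows[which.max(rows$frame), c("x_px", "y_px"), drop = FALSE]
    }))
    if (is.null(pts)) pts <- data.frame(x_px = numeric(0), y_px = numeric(0))
  }
  w <- as.integer(grid[1L]); h <- as.integer(grid[2L])
  m <- matrix(0L, nrow = h, ncol = w)
  r2 <- radiusPx^2 + 1e-9
  for (p in seq_len(nrow(pts))) {
    x0 <- pts$x_px[p]; y0 <- pts$y_px[p]
    if (x0 - radiusPx > w || x0 + radiusPx < 1 ||
        y0 - radiusPx > h || y0 + radiusPx < 1) next
    xs <- max(1L, floor(x0 - radiusPx)):min(w, ceiling(x0 + radiusPx))
    ys <- max(1L, floor(y0 - radiusPx)):min(h, ceiling(y0 + radiusPx))
    d2 <- outer((ys - y0)^2, (xs - x0)^2, "+")
    m[ys, xs] <- m[ys, xs] + (d2 <= r2)
  }
  structure(m, radius = radiusPx, kind = kind)
}

#' Export a density map
#'
#' \code{writeDensityMapTSV} writes the pixel matrix as a plain TSV;
#' \code{writeDensityMapPNG} writes an 8-bit grayscale PNG scaled to the
#' maximum pixel value.
#'
#' @param map matrix returned by \code{\link{densityMap}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDensityMapTSV <- function(map, path) {
  utils::write.table(unclass(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeDensityMapTSV
#' @export
writeDensityMapPNG <- function(map, path) {
  m <- unclass(map)
  mx <- max(m)
  png::writePNG(if (mx > 0) m / mx else m * 0, path)
  invisible(path)
}

#' Attribute growth suppression to DNA breaks vs p53 accumulation
#'
#' Population doubling times (time for a population to grow from 100 to 200
#' cells) dissect a damage response: the delay of the treated p53-proficient
#' population relative to its untreated control reflects both DNA-break
#' formation and p53 accumulation, while the delay measured in p53-silenced
#' cells reflects breaks alone.  The break fraction is the silenced-arm
#' delay as a percentage of the total delay; the remainder is attributed to
#' p53-mediated responses.
#'
#' @param doublingControl,doublingControlTreated population doubling times
#'   (minutes) of the untreated and treated p53-proficient populations.
#' @param delaySilenced doubling-time delay (minutes) measured in the
#'   p53-silenced arm.
#' @return A list with \code{total_delay} (minutes), \code{break_fraction}
#'   and \code{p53_fraction} (percent).
#' @examples
#' attributeDamageResponse(2501, 9651, 4510)  # 7150 min; 63% / 37%
#' @export
attributeDamageResponse <- function(doublingControl, doublingControlTreated,
                                    delaySilenced) {
  total <- doublingControlTreated - doublingControl
  if (!(total > 0)) stop("treated doubling time must exceed the control's")
  if (delaySilenced < 0 || delaySilenced > total)
    stop("delaySilenced must lie in [0, total delay]")
  bf <- delaySilenced / total * 100
  list(total_delay = total, break_fraction = bf, p53_fraction = 100 - bf)
}

#' Plot population expansion curves
#'
#' Convenience base-graphics plot of one or more population curves.
#'
#' @param ... one or more \code{\linkS4class{LineageDB}} objects (named
#'   arguments become legend labels).
#' @param step sampling step in minutes.
#' @param normalizeTo passed to \code{\link{populationCurve}}.
#' @return Invisibly, the list of curves.
#' @export
plotPopulationCurves <- function(..., step = 10, normalizeTo = NULL) {
  dbs <- list(...)
  curves <- lapply(dbs, populationCurve, step = step,
                   normalizeTo = normalizeTo)
  ylim <- range(unlist(lapply(curves, `[[`, "count")))
  graphics::plot(curves[[1L]]$time, curves[[1L]]$count, type = "n",
                 xlab = "time (min)", ylab = "cells", ylim = ylim)
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$time, curves[[i]]$count, col = i, lwd = 2)
  if (!is.null(names(dbs)) && any(nzchar(names(dbs))))
    graphics::legend("topleft", legend = names(dbs),
                     col = seq_along(dbs), lwd = 2, bty = "n")
  invisible(curves)
}
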