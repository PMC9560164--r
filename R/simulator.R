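# Cell-fate simulator: generates virtual cell-lineage databases from
# Operation data under the five simulation modes (standard, dose, mixed,
# switch, mixed_switch).  The per-cell blueprint during a run is the "cell
# data information" (CDI) state: lineage/cell identifiers, birth time, the
# assigned end event and interval (Ltime), kinship links and bookkeeping
# flags.  All randomness flows through the single R random stream seeded
# from the SimConfig, and cells are processed in (lineage_id, cell_id)
# order, so identical configurations give record-identical databases.

.pick <- function(v) v[[sample.int(length(v), 1L)]]
.pickOr <- function(arrays, key, fallback) {
  arr <- arrays@timeArrays[[key]]
  if (length(arr)) .pick(arr) else fallback
}

.drawEvent <- function(arrays, key, excludeCF = FALSE) {
  arr <- arrays@eventArrays[[key]]
  if (excludeCF && length(arr)) arr <- arr[arr != "CF"]
  if (!length(arr)) return(NULL)
  .pick(arr)
}

.chooseArity <- function(arrays) {
  p3 <- arrays@mdAritySplit[["MD3"]]
  tot <- sum(arrays@mdAritySplit)
  if (tot <= 0 || stats::runif(1) < p3 / tot) "MD3" else "MD4"
}

# Division-interval draw with the parent/child restraint: when the parent
# was itself a BD-born cell that divided bipolarly, the child's interval is
# redrawn until it falls within +/- tol of the parent's, then clamped to the
# nearest bound after maxAtt attempts (guarantees termination on disjoint
# supports).
.divDraw <- function(arrays, key, parentInterval = NA_real_, tol = 0.1,
                     maxAtt = 100L) {
  arr <- arrays@timeArrays[[key]]
  v <- if (length(arr)) .pick(arr) else arrays@meanBD
  if (!is.na(parentInterval)) {
    lo <- (1 - tol) * parentInterval
    hi <- (1 + tol) * parentInterval
    att <- 0L
    while ((v < lo || v > hi) && att < maxAtt && length(arr)) {
      v <- .pick(arr)
      att <- att + 1L
    }
    if (v < lo) v <- lo else if (v > hi) v <- hi
  }
  v
}

# Non-dividing branch: a cell assigned NONDIV gets one recovery chance
# (probability = recovery percent; on success it re-enters growth via BD
# with an Ltime of 80-100% of the tracking time), otherwise dies with
# probability equal to the cell-death share of total divisions (Ltime from
# the NONDIVCD array), otherwise idles to the simulation horizon.
.assignNonDiv <- function(arrays, birth, simEnd, recovUsed) {
  if (!recovUsed && stats::runif(1) * 100 < arrays@recoveryPercent) {
    return(list(event = "BD",
                interval = arrays@trackingDuration * stats::runif(1, 0.8, 1.0),
                recov = TRUE))
  }
  if (stats::runif(1) * 100 < arrays@cdSharePercent) {
    return(list(event = "CD",
                interval = .pickOr(arrays, "NONDIVCD", arrays@meanCD),
                recov = recovUsed))
  }
  list(event = "NONE", interval = max(simEnd - birth, 0), recov = recovUsed)
}

# First-event assignment for one progenitor (see assignFirstEvents).
.assignFirst <- function(arrays, simEnd, recovUsed = FALSE) {
  firstArr <- arrays@timeArrays$FIRST
  itv <- if (length(firstArr)) .pick(firstArr) else NA_real_
  if (!is.na(itv) && abs(itv - arrays@trackingDuration) < 1e-9)
    itv <- arrays@trackingDuration * stats::runif(1, 0.7, 1.3)
  e <- .drawEvent(arrays, "FIRST_LIST")
  if (is.null(e)) {
    if (is.na(itv))
      return(list(event = "BD",
                  interval = arrays@meanBD * stats::runif(1, 0.75, 1.25),
                  recov = recovUsed))
    e <- "NONDIV"
  }
  if (e == "NONDIV") return(.assignNonDiv(arrays, 0, simEnd, recovUsed))
  if (is.na(itv)) itv <- arrays@meanBD * stats::runif(1, 0.75, 1.25)
  if (e == "CD") itv <- .pickOr(arrays, "NONDIVCD", itv)
  if (e == "MD") e <- .chooseArity(arrays)
  list(event = e, interval = itv, recov = recovUsed)
}

# Cohort event/interval assignment for the children of one division.
# `events` holds NA for members still to draw; pre-assigned members (kept
# across an Operation-data switch) participate in fusion bookkeeping but are
# not redrawn.  Returns parallel vectors evt/itv/partner (local index)/recov.
.assignCohortCore <- function(arrays, cohortClass, birth, events, simEnd,
                              parentInterval = NA_real_,
                              parentIsBDBD = FALSE, tol = 0.1,
                              maxAtt = 100L, locked = NULL) {
  k <- length(events)
  evt <- events
  itv <- rep(NA_real_, k)
  partner <- rep(NA_integer_, k)
  recov <- rep(FALSE, k)
  if (is.null(locked)) locked <- rep(FALSE, k)
  drawn <- !is.na(evt)  # pre-assigned entries are not drawn again
  listKey <- if (cohortClass == "BD") "BD_LIST" else "MD_LIST"
  divKey  <- if (cohortClass == "BD") "BDBD" else "MDMD"
  cdKey   <- if (cohortClass == "BD") "BDCD" else "MDCD"
  cfKey   <- if (cohortClass == "BD") "BDCF" else "MDCF"
  pairExists <- any(!is.na(evt) & evt == "CF")

  for (i in seq_len(k)) {
    if (drawn[i]) next
    drawn[i] <- TRUE
    e <- .drawEvent(arrays, listKey, excludeCF = pairExists)
    if (is.null(e)) e <- if (cohortClass == "BD") "BD" else "NONDIV"
    if (e == "CF") {
      # eligible partner: a division sibling not yet fusion-paired and not
      # dead, first in cell-id order (an already assigned sibling is
      # overridden to fuse)
      elig <- which(seq_len(k) != i & is.na(partner) & !locked &
                    (is.na(evt) | !(evt %in% "CD")))
      cfArr <- arrays@timeArrays[[cfKey]]
      if (!length(elig) || !length(cfArr)) {
        # no sibling to fuse with (or no fusion timing data): the event is
        # changed to cell death at the average death time
        evt[i] <- "CD"
        itv[i] <- .pickOr(arrays, cdKey, arrays@meanCD)
        next
      }
      j <- elig[1L]
      drawn[j] <- TRUE
      # the pair shares one Ltime; a conflicting draw is shortened to the
      # partner's
      common <- min(.pick(cfArr), .pick(cfArr))
      evt[c(i, j)] <- "CF"
      itv[c(i, j)] <- common
      partner[i] <- j
      partner[j] <- i
      pairExists <- TRUE
      next
    }
    if (e == "BD") {
      evt[i] <- "BD"
      pi <- if (cohortClass == "BD" && parentIsBDBD) parentInterval else NA_real_
      itv[i] <- .divDraw(arrays, divKey, pi, tol, maxAtt)
    } else if (e == "MD") {
      evt[i] <- .chooseArity(arrays)
      itv[i] <- .divDraw(arrays, divKey, NA_real_, tol, maxAtt)
    } else if (e == "CD") {
      evt[i] <- "CD"
      itv[i] <- .pickOr(arrays, cdKey, arrays@meanCD)
    } else {  # NONDIV
      nd <- .assignNonDiv(arrays, birth, simEnd, FALSE)
      evt[i] <- nd$event
      itv[i] <- nd$interval
      recov[i] <- nd$recov
    }
  }
  list(evt = evt, itv = itv, partner = partner, recov = recov)
}

# Assignment for a fusion product (merged cell): the next event comes from
# the BDCF/MDCF list matching the fusing cells' pre-fusion class; divisions
# take their Ltime from DIVCFDIV, deaths from BDCFCD/MDCFCD.  A merged cell
# has no division sibling, so a CF draw (and an empty list) falls back to
# cell death at the average death time.
.assignMergedCore <- function(arrays, preClass, birth, simEnd,
                              recovUsed = FALSE) {
  listKey <- if (identical(preClass, "MD")) "MDCF_LIST" else "BDCF_LIST"
  cdTimeKey <- if (identical(preClass, "MD")) "MDCFCD" else "BDCFCD"
  e <- .drawEvent(arrays, listKey)
  if (is.null(e) || e == "CF")
    return(list(event = "CD",
                interval = .pickOr(arrays, cdTimeKey, arrays@meanCD),
                recov = recovUsed))
  if (e == "NONDIV") return(.assignNonDiv(arrays, birth, simEnd, recovUsed))
  if (e == "CD")
    return(list(event = "CD",
                interval = .pickOr(arrays, cdTimeKey, arrays@meanCD),
                recov = recovUsed))
  ev <- if (e == "MD") .chooseArity(arrays) else "BD"
  list(event = ev,
       interval = .pickOr(arrays, "DIVCFDIV", arrays@meanBD),
       recov = recovUsed)
}

# CDI state store: parallel growable vectors in an environment -------------

.cdiNew <- function(cap = 256L) {
  st <- new.env(parent = emptyenv())
  st$n <- 0L
  st$cap <- cap
  for (f in c("lid", "cid", "parent", "partner"))
    assign(f, rep(NA_integer_, cap), st)
  for (f in c("birth", "itv")) assign(f, rep(NA_real_, cap), st)
  for (f in c("evt", "bcl", "pre")) assign(f, rep(NA_character_, cap), st)
  for (f in c("recov", "final")) assign(f, rep(FALSE, cap), st)
  st
}

.cdiGrow <- function(st, need) {
  while (st$n + need > st$cap) {
    st$cap <- st$cap * 2L
    for (f in c("lid", "cid", "parent", "partner", "birth", "itv",
                "evt", "bcl", "pre", "recov", "final")) {
      v <- get(f, st)
      length(v) <- st$cap
      if (f %in% c("recov", "final")) v[is.na(v)] <- FALSE
      assign(f, v, st)
    }
  }
}

.cdiAdd <- function(st, k, lid, cid, parent, birth, bcl, pre = NA_character_) {
  .cdiGrow(st, k)
  idx <- st$n + seq_len(k)
  st$lid[idx] <- lid
  st$cid[idx] <- cid
  st$parent[idx] <- parent
  st$birth[idx] <- birth
  st$bcl[idx] <- bcl
  st$pre[idx] <- pre
  st$evt[idx] <- NA_character_
  st$itv[idx] <- NA_real_
  st$partner[idx] <- NA_integer_
  st$recov[idx] <- FALSE
  st$final[idx] <- FALSE
  st$n <- st$n + k
  idx
}

.cdiSet <- function(st, idx, res) {
  st$evt[idx] <- res$evt
  st$itv[idx] <- res$itv
  st$recov[idx] <- res$recov
  if (!is.null(res$partner)) {
    loc <- res$partner
    st$partner[idx] <- ifelse(is.na(loc), NA_integer_, st$cid[idx[loc]])
  }
}

# Finalize one cell: fix its end, and spawn + assign its offspring.
.finalizeCell <- function(st, i, arrays, simEnd, tol, maxAtt, nextCid,
                          maxCells) {
  end <- st$birth[i] + st$itv[i]
  ev <- st$evt[i]
  st$final[i] <- TRUE
  if (ev %in% c("BD", "MD3", "MD4")) {
    k <- c(BD = 2L, MD3 = 3L, MD4 = 4L)[[ev]]
    lid <- st$lid[i]
    cids <- nextCid$v[lid] + seq_len(k) - 1L
    nextCid$v[lid] <- nextCid$v[lid] + k
    bcl <- if (ev == "BD") "BD_CHILD" else "MD_CHILD"
    idx <- .cdiAdd(st, k, lid, cids, st$cid[i], end, bcl)
    if (st$n > maxCells)
      stop("simulation exceeded maxCells (", maxCells, ") virtual cells")
    res <- .assignCohortCore(arrays, if (ev == "BD") "BD" else "MD",
                             birth = end, events = rep(NA_character_, k),
                             simEnd = simEnd,
                             parentInterval = st$itv[i],
                             parentIsBDBD = (st$bcl[i] == "BD_CHILD" &&
                                             ev == "BD"),
                             tol = tol, maxAtt = maxAtt)
    .cdiSet(st, idx, res)
  } else if (ev == "CF") {
    # the lower cell_id of the pair carries the merged continuation
    if (!is.na(st$partner[i]) && st$cid[i] < st$partner[i]) {
      lid <- st$lid[i]
      cidm <- nextCid$v[lid]
      nextCid$v[lid] <- nextCid$v[lid] + 1L
      pre <- if (st$bcl[i] == "MD_CHILD") "MD" else "BD"
      idx <- .cdiAdd(st, 1L, lid, cidm, st$cid[i], end, "CF_PRODUCT", pre)
      if (st$n > maxCells)
        stop("simulation exceeded maxCells (", maxCells, ") virtual cells")
      m <- .assignMergedCore(arrays, pre, end, simEnd)
      .cdiSet(st, idx, list(evt = m$event, itv = m$interval, recov = m$recov))
    }
  }
  invisible(NULL)
}

# Repeated assignment cycle up to `horizon`.
.runCycles <- function(st, arrays, horizon, simEnd, tol, maxAtt, nextCid,
                       maxCells) {
  repeat {
    live <- seq_len(st$n)
    due <- live[!st$final[live] & !is.na(st$itv[live]) &
                st$birth[live] + st$itv[live] <= horizon + 1e-9]
    if (!length(due)) break
    due <- due[order(st$lid[due], st$cid[due])]
    for (i in due)
      .finalizeCell(st, i, arrays, simEnd, tol, maxAtt, nextCid, maxCells)
  }
  invisible(NULL)
}

# Censor every still-pending assignment to NONE at the horizon.
.censorPending <- function(st, horizon) {
  idx <- seq_len(st$n)
  idx <- idx[!st$final[idx]]
  if (length(idx)) {
    st$evt[idx] <- "NONE"
    st$itv[idx] <- pmax(horizon - st$birth[idx], 0)
    st$partner[idx] <- NA_integer_
    st$final[idx] <- TRUE
  }
  invisible(NULL)
}

# Trim-and-reassign at the Operation-data switch: every pending assignment
# crossing switchTime is voided and redrawn under the new arrays, with birth
# state (and the once-only recovery flag) preserved.
.reassignPending <- function(st, arrays, simEnd, tol, maxAtt) {
  idx <- seq_len(st$n)
  idx <- idx[!st$final[idx]]
  if (!length(idx)) return(invisible(NULL))
  st$evt[idx] <- NA_character_
  st$itv[idx] <- NA_real_
  st$partner[idx] <- NA_integer_

  roots <- idx[st$bcl[idx] == "ROOT"]
  for (i in roots[order(st$lid[roots])]) {
    a <- .assignFirst(arrays, simEnd, recovUsed = st$recov[i])
    st$evt[i] <- a$event; st$itv[i] <- a$interval; st$recov[i] <- a$recov
  }
  merged <- idx[st$bcl[idx] == "CF_PRODUCT"]
  for (i in merged[order(st$lid[merged], st$cid[merged])]) {
    a <- .assignMergedCore(arrays, st$pre[i], st$birth[i], simEnd,
                           recovUsed = st$recov[i])
    st$evt[i] <- a$event; st$itv[i] <- a$interval; st$recov[i] <- a$recov
  }
  kids <- idx[st$bcl[idx] %in% c("BD_CHILD", "MD_CHILD")]
  if (length(kids)) {
    pkey <- paste(st$lid[kids], st$parent[kids])
    for (g in unique(pkey[order(st$lid[kids], st$parent[kids])])) {
      members <- kids[pkey == g]
      lid <- st$lid[members[1L]]
      pidx <- which(st$lid[seq_len(st$n)] == lid &
                    st$cid[seq_len(st$n)] == st$parent[members[1L]])[1L]
      # full cohort, finalized siblings included, in cell_id order
      sibs <- which(st$lid[seq_len(st$n)] == lid &
                    !is.na(st$parent[seq_len(st$n)]) &
                    st$parent[seq_len(st$n)] == st$parent[members[1L]] &
                    st$bcl[seq_len(st$n)] %in% c("BD_CHILD", "MD_CHILD"))
      sibs <- sibs[order(st$cid[sibs])]
      events <- ifelse(st$final[sibs], st$evt[sibs], NA_character_)
      res <- .assignCohortCore(arrays,
                               if (st$bcl[members[1L]] == "BD_CHILD") "BD"
                               else "MD",
                               birth = st$birth[members[1L]],
                               events = events, simEnd = simEnd,
                               parentInterval = st$itv[pidx],
                               parentIsBDBD = (st$bcl[pidx] == "BD_CHILD" &&
                                               st$evt[pidx] == "BD"),
                               tol = tol, maxAtt = maxAtt,
                               locked = st$final[sibs])
    redrawn <- !st$final[sibs]
    st$evt[sibs[redrawn]] <- res$evt[redrawn]
    st$itv[sibs[redrawn]] <- res$itv[redrawn]
    st$recov[sibs[redrawn]] <- st$recov[sibs[redrawn]] | res$recov[redrawn]
    loc <- res$partner
    st$partner[sibs[redrawn]] <- ifelse(is.na(loc[redrawn]), NA_integer_,
                                        st$cid[sibs[loc[redrawn]]])
    }
  }
  invisible(NULL)
}

.simPopulation <- function(npro, arrays1, arrays2, switchTime, simEnd,
                           tol, maxAtt, lidOffset, maxCells) {
  st <- .cdiNew(max(256L, 2L * npro))
  lids <- lidOffset + seq_len(npro)
  nextCid <- new.env(parent = emptyenv())
  nextCid$v <- integer(lidOffset + npro)
  nextCid$v[lids] <- 2L
  idx <- .cdiAdd(st, npro, lids, rep(1L, npro), rep(NA_integer_, npro),
                 rep(0, npro), rep("ROOT", npro))
  for (i in idx) {
    a <- .assignFirst(arrays1, simEnd)
    st$evt[i] <- a$event; st$itv[i] <- a$interval; st$recov[i] <- a$recov
  }
  if (!is.null(arrays2)) {
    .runCycles(st, arrays1, switchTime, simEnd, tol, maxAtt, nextCid, maxCells)
    .reassignPending(st, arrays2, simEnd, tol, maxAtt)
    .runCycles(st, arrays2, simEnd, simEnd, tol, maxAtt, nextCid, maxCells)
  } else {
    .runCycles(st, arrays1, simEnd, simEnd, tol, maxAtt, nextCid, maxCells)
  }
  .censorPending(st, simEnd)
  n <- st$n
  data.frame(lineage_id = st$lid[seq_len(n)],
             cell_id = st$cid[seq_len(n)],
             parent_cell_id = st$parent[seq_len(n)],
             birth_min = st$birth[seq_len(n)],
             end_min = st$birth[seq_len(n)] + st$itv[seq_len(n)],
             end_event = st$evt[seq_len(n)],
             fusion_partner_lineage = ifelse(is.na(st$partner[seq_len(n)]),
                                             NA_integer_, st$lid[seq_len(n)]),
             fusion_partner_cell = st$partner[seq_len(n)],
             stringsAsFactors = FALSE)
}

# Public constructors and operations ----------------------------------------

#' Configure a cell-fate simulation
#'
#' @param mode one of \code{"standard"}, \code{"dose"}, \code{"mixed"},
#'   \code{"switch"}, \code{"mixed_switch"}.
#' @param simTimeEnd simulation horizon in minutes.
#' @param initialCounts progenitors per population: a single count (named
#'   \code{pop1} if unnamed) or a named vector for mixed modes.
#' @param operationData an \code{\linkS4class{OperationData}} (standard,
#'   dose, switch) or a named list of them, one per population tag (mixed
#'   modes).
#' @param operationData2 second \code{OperationData} (or named list): the
#'   post-switch model for switch modes, or the second reference dose for
#'   dose mode.
#' @param seed integer random seed.
#' @param switchTime minutes at which switch modes change Operation data.
#' @param doseA,doseB,doseX dose-mode reference and target doses.
#' @param parentChildTolerance fractional parent/child bipolar-interval
#'   restraint (default 0.10).
#' @param maxResampleAttempts resampling bound before clamping.
#' @param maxCells safety cap on the virtual-cell count.
#' @return A validated \code{\linkS4class{SimConfig}}.
#' @examples
#' od <- makePaperLikeFixtures(nProgenitors = 100, seed = 1)$control
#' cfg <- simConfig("standard", simTimeEnd = 3000, initialCounts = 50,
#'                  operationData = od, seed = 1)
#' @export
simConfig <- function(mode, simTimeEnd, initialCounts, operationData,
                      operationData2 = NULL, seed = 1, switchTime = NA_real_,
                      doseA = NA_real_, doseB = NA_real_, doseX = NA_real_,
                      parentChildTolerance = 0.10, maxResampleAttempts = 100,
                      maxCells = 2e6) {
  mode <- match.arg(mode, .SIM_MODES)
  if (is.null(names(initialCounts)))
    names(initialCounts) <- paste0("pop", seq_along(initialCounts))
  wrap <- function(x) if (is(x, "OperationData"))
    stats::setNames(list(x), names(initialCounts)[1L]) else x
  od1 <- wrap(operationData)
  od2 <- if (is.null(operationData2)) NULL else wrap(operationData2)
  needsSecond <- mode %in% c("dose", "switch", "mixed_switch")
  if (needsSecond && is.null(od2))
    stop("mode '", mode, "' requires operationData2")
  opData <- lapply(names(initialCounts), function(tag) {
    p1 <- od1[[tag]]
    if (is.null(p1)) stop("no OperationData for population '", tag, "'")
    list(phase1 = p1, phase2 = if (needsSecond) od2[[tag]] else NULL)
  })
  names(opData) <- names(initialCounts)
  if (mode == "dose" && (is.na(doseA) || is.na(doseB) || is.na(doseX)))
    stop("dose mode requires doseA, doseB and doseX")
  new("SimConfig", mode = mode, simTimeEnd = simTimeEnd,
      initialCounts = initialCounts, seed = seed, switchTime = switchTime,
      doseA = doseA, doseB = doseB, doseX = doseX, opData = opData,
      parentChildTolerance = parentChildTolerance,
      maxResampleAttempts = maxResampleAttempts, maxCells = maxCells)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@mode, "mode,", object@simTimeEnd,
      "min horizon, seed", object@seed, "\n")
  cat("  progenitors:", paste(names(object@initialCounts),
                              object@initialCounts, sep = "=",
                              collapse = " "), "\n")
  if (!is.na(object@switchTime))
    cat("  switch at", object@switchTime, "min\n")
  if (!is.na(object@doseX))
    cat("  dose interpolation:", object@doseA, "->", object@doseB,
        "evaluated at", object@doseX, "\n")
  invisible(NULL)
})

#' Simulate virtual cell lineages
#'
#' Runs the cell-fate simulation: progenitors receive a first event and
#' Ltime from the FIRST arrays, and the assignment cycle then repeatedly
#' turns each completed division into a cohort of children with freshly
#' assigned end events and Ltimes (fusion products are reassigned from the
#' post-fusion arrays) until every pending event crosses the horizon, where
#' cells are censored as \code{NONE}.  Mixed modes run each population with
#' its own Operation data (populations never interact); dose mode first
#' interpolates the two reference models; switch modes void every assignment
#' crossing \code{switchTime} and redraw it under the second model.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return A \code{\linkS4class{LineageDB}} of virtual cells whose records
#'   carry a \code{population} column; output always passes
#'   \code{\link{validateLineageDB}} and is deterministic given the config.
#' @examples
#' od <- OperationData(timeHistograms = list(FIRST = c("500" = 1),
#'                                           BDBD = c("500" = 1)),
#'                     eventLists = list(FIRST_LIST = c(BD = 1),
#'                                       BD_LIST = c(BD = 1)),
#'                     trackingDuration = 1600)
#' db <- simulateCellFates(simConfig("standard", 1600, 10, od, seed = 1))
#' populationCurve(db, step = 1600)  # 10 cells become 80
#' @export
simulateCellFates <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(config@seed)
  switching <- config@mode %in% c("switch", "mixed_switch")
  lidOffset <- 0L
  out <- vector("list", length(config@initialCounts))
  for (p in seq_along(config@initialCounts)) {
    tag <- names(config@initialCounts)[p]
    entry <- config@opData[[tag]]
    od1 <- if (config@mode == "dose")
      interpolateOperationData(entry$phase1, entry$phase2,
                               config@doseA, config@doseB, config@doseX)
    else entry$phase1
    arrays1 <- buildSimulationArrays(od1)
    arrays2 <- if (switching) buildSimulationArrays(entry$phase2) else NULL
    npro <- as.integer(config@initialCounts[[p]])
    df <- .simPopulation(npro, arrays1, arrays2, config@switchTime,
                         config@simTimeEnd, config@parentChildTolerance,
                         as.integer(config@maxResampleAttempts), lidOffset,
                         config@maxCells)
    df$population <- tag
    out[[p]] <- df
    lidOffset <- lidOffset + npro
  }
  rec <- do.call(rbind, out)
  rec <- rec[order(rec$lineage_id, rec$cell_id), , drop = FALSE]
  rownames(rec) <- NULL
  LineageDB(rec, frameInterval = 10, trackingDuration = config@simTimeEnd,
            metadata = list(mode = config@mode, seed = config@seed,
                            populations = paste(names(config@initialCounts),
                                                collapse = ",")))
}

# Exported assignment operations (CDI data.frame surface) -------------------

.cdiFrame <- function(n) {
  data.frame(lineage_id = integer(n), cell_id = integer(n),
             parent_cell_id = rep(NA_integer_, n),
             birth_min = numeric(n),
             assigned_interval = rep(NA_real_, n),
             assigned_event = rep(NA_character_, n),
             birth_class = rep("ROOT", n),
             pre_class = rep(NA_character_, n),
             partner_cell_id = rep(NA_integer_, n),
             recovery_used = logical(n),
             finalized = logical(n),
             stringsAsFactors = FALSE)
}

#' Assign first events and Ltimes to progenitors
#'
#' Draws each progenitor's Ltime from the FIRST time array and its event from
#' the FIRST event list.  Fallbacks: an empty FIRST array with a populated
#' list uses the mean bipolar-division time perturbed by -25\% to +25\%; an
#' empty list yields a non-dividing cell (or, with no first-event data at
#' all, bipolar division); a drawn Ltime equal to the tracking time is
#' replaced by -30\% to +30\% of the tracking time; cell-death draws take
#' their Ltime from the NONDIVCD array.  Non-dividing assignments pass
#' through the recovery branch once.
#'
#' @param states CDI data.frame of progenitors (see
#'   \code{\link{newCellStates}}), all with \code{birth_min} 0.
#' @param arrays a \code{\linkS4class{SimulationArrays}} object.
#' @param simTimeEnd simulation horizon (defaults to the tracking duration).
#' @return The states with \code{assigned_event}, \code{assigned_interval}
#'   and \code{recovery_used} filled in.
#' @export
assignFirstEvents <- function(states, arrays,
                              simTimeEnd = arrays@trackingDuration) {
  stopifnot(is(arrays, "SimulationArrays"))
  for (i in seq_len(nrow(states))) {
    a <- .assignFirst(arrays, simTimeEnd, recovUsed = states$recovery_used[i])
    states$assigned_event[i] <- a$event
    states$assigned_interval[i] <- a$interval
    states$recovery_used[i] <- a$recov
  }
  states
}

#' Assign events and Ltimes to one division cohort
#'
#' Applies the cohort rules to the children of one bipolar or multipolar
#' division: events are drawn from the BD/MD list array; a cell-fusion draw
#' pairs the cell with its first sibling that is neither fusion-paired nor
#' dead, overriding that sibling's assignment if it already has one (the
#' pair shares the shorter of the two fusion Ltimes), is excluded once the
#' cohort holds a pair, and becomes cell death when no sibling is
#' available; bipolar-to-bipolar intervals are redrawn until within the
#' parent/child tolerance of the parent's interval when the parent was
#' itself a BD-born bipolar divider.
#'
#' @param cohort CDI data.frame of the cohort, in \code{cell_id} order; rows
#'   with a non-NA \code{assigned_event} are kept fixed.
#' @param arrays a \code{\linkS4class{SimulationArrays}} object.
#' @param cohortClass \code{"BD"} or \code{"MD"}: the division that produced
#'   the cohort.
#' @param parentInterval,parentWasBDBD the parent's Ltime and whether the
#'   parent was a BD-born cell ending in bipolar division.
#' @param simTimeEnd simulation horizon.
#' @param tolerance,maxResampleAttempts parent/child restraint parameters.
#' @return The cohort with assignments and \code{partner_cell_id} filled in.
#' @export
assignNextEvents <- function(cohort, arrays, cohortClass = c("BD", "MD"),
                             parentInterval = NA_real_,
                             parentWasBDBD = FALSE,
                             simTimeEnd = arrays@trackingDuration,
                             tolerance = 0.10, maxResampleAttempts = 100) {
  cohortClass <- match.arg(cohortClass)
  res <- .assignCohortCore(arrays, cohortClass,
                           birth = cohort$birth_min[1L],
                           events = cohort$assigned_event,
                           simEnd = simTimeEnd,
                           parentInterval = parentInterval,
                           parentIsBDBD = parentWasBDBD,
                           tol = tolerance,
                           maxAtt = as.integer(maxResampleAttempts),
                           locked = cohort$finalized)
  upd <- !cohort$finalized
  cohort$assigned_event[upd] <- res$evt[upd]
  newItv <- !is.na(res$itv) & upd
  cohort$assigned_interval[newItv] <- res$itv[newItv]
  cohort$recovery_used <- cohort$recovery_used | res$recov
  cohort$partner_cell_id <- ifelse(is.na(res$partner), cohort$partner_cell_id,
                                   cohort$cell_id[res$partner])
  cohort
}

#' Readjust Ltime in cells produced by cell fusion
#'
#' Fusion changes the timing of the merged cell, so its next event is drawn
#' from the BDCF or MDCF list (by the fusing cells' pre-fusion class) and
#' its Ltime from DIVCFDIV for divisions or BDCFCD/MDCFCD for deaths; empty
#' lists fall back to cell death at the average death time.  Fusion between
#' non-siblings is never generated.
#'
#' @param states CDI data.frame of merged cells (birth_class
#'   \code{CF_PRODUCT}) with \code{pre_class} \code{"BD"} or \code{"MD"}.
#' @param arrays a \code{\linkS4class{SimulationArrays}} object.
#' @param simTimeEnd simulation horizon.
#' @return The states with fresh assignments.
#' @export
readjustFusionTimes <- function(states, arrays,
                                simTimeEnd = arrays@trackingDuration) {
  stopifnot(is(arrays, "SimulationArrays"))
  for (i in seq_len(nrow(states))) {
    a <- .assignMergedCore(arrays, states$pre_class[i], states$birth_min[i],
                           simTimeEnd, recovUsed = states$recovery_used[i])
    states$assigned_event[i] <- a$event
    states$assigned_interval[i] <- a$interval
    states$recovery_used[i] <- a$recov
  }
  states
}

#' Void pending assignments at an Operation-data switch
#'
#' Marks every non-finalized cell whose pending event time would exceed
#' \code{switchTime} for reassignment: the assigned event, interval and
#' fusion pairing are cleared while birth state (identity, birth time, birth
#' class, recovery flag) is preserved.  Completed events at or before the
#' switch are untouched.
#'
#' @param states CDI data.frame.
#' @param switchTime minutes.
#' @return The states with voided assignments (NA event/interval).
#' @export
trimAtSwitch <- function(states, switchTime) {
  cross <- !states$finalized & !is.na(states$assigned_interval) &
    states$birth_min + states$assigned_interval > switchTime
  states$assigned_event[cross] <- NA_character_
  states$assigned_interval[cross] <- NA_real_
  states$partner_cell_id[cross] <- NA_integer_
  states
}

#' Create blank progenitor states
#'
#' @param n number of progenitors.
#' @param lineageIds lineage identifiers (default \code{1:n}).
#' @return A CDI data.frame of \code{n} unassigned progenitors at time 0.
#' @export
newCellStates <- function(n, lineageIds = seq_len(n)) {
  states <- .cdiFrame(n)
  states$lineage_id <- as.integer(lineageIds)
  states$cell_id <- rep(1L, n)
  states
}
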