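# Ground-truth branching-process generator.  Produces lineage databases
# with KNOWN event probabilities and interval distributions, independent of
# the simulator's machinery, so extraction, analytics and simulator round
# trips can be tested against first-principles expectations without any
# external data.

.DIST_KINDS <- c("fixed", "uniform", "lognormal")

.checkDist <- function(d, name) {
  if (!is.list(d) || is.null(d$kind) || !(d$kind %in% .DIST_KINDS))
    stop("interval distribution '", name,
         "' must be list(kind = fixed|uniform|lognormal, ...)")
  invisible(TRUE)
}

.drawDist <- function(d) {
  switch(d$kind,
         fixed = d$value,
         uniform = stats::runif(1, d$min, d$max),
         lognormal = stats::rlnorm(1, d$meanlog, d$sdlog))
}

.distMean <- function(d) {
  switch(d$kind,
         fixed = d$value,
         uniform = (d$min + d$max) / 2,
         lognormal = exp(d$meanlog + d$sdlog^2 / 2))
}

#' Parameters of the synthetic-lineage generator
#'
#' Defines a branching process over the four birth classes (\code{root},
#' \code{bdChild}, \code{mdChild}, \code{cfProduct}): per-class end-event
#' probabilities over \code{BD, MD3, MD4, CD, CF, NONE}, and interval
#' distributions per (class, event) as named families.  Intervals crossing
#' the tracking duration censor the cell to \code{NONE}; fusion is only
#' generated between division siblings (members drawing \code{CF} pair up
#' in cell-id order; an unpaired draw is redrawn without \code{CF}).
#'
#' The defaults emulate an unstressed p53-proficient culture tracked for
#' 4000 min at 10-min frames: a cell doubling time around 38-40 h with
#' modest spread, rare multipolar division, death and fusion, and
#' multipolar progeny that mostly die without dividing.
#'
#' @param nProgenitors number of lineages to seed (default 335).
#' @param duration tracking time in minutes (default 4000).
#' @param frameInterval imaging interval in minutes (default 10).
#' @param eventProbs named list of per-class probability vectors over
#'   \code{BD, MD3, MD4, CD, CF, NONE}; each must sum to 1.
#' @param intervals named list of distributions keyed \code{"class.event"}
#'   (e.g. \code{"bdChild.BD"}), with event-only fallbacks (\code{"BD"},
#'   \code{"CD"}, ...); each is \code{list(kind, ...)} with kind
#'   \code{fixed} (\code{value}), \code{uniform} (\code{min}, \code{max})
#'   or \code{lognormal} (\code{meanlog}, \code{sdlog}).
#' @param seed integer seed; generation is deterministic given the params.
#' @return A validated \code{SynthParams} list.
#' @examples
#' p <- synthParams(nProgenitors = 10, seed = 1)
#' db <- generateSyntheticDB(p)
#' @export
synthParams <- function(nProgenitors = 335, duration = 4000,
                        frameInterval = 10,
                        eventProbs = NULL, intervals = NULL, seed = 1) {
  defProbs <- list(
    root      = c(BD = 0.95, MD3 = 0, MD4 = 0, CD = 0.003, CF = 0,
                  NONE = 0.047),
    bdChild   = c(BD = 0.96, MD3 = 0.0005, MD4 = 0.00025, CD = 0.003,
                  CF = 0.006, NONE = 0.03025),
    mdChild   = c(BD = 0.03, MD3 = 0, MD4 = 0, CD = 0.90, CF = 0,
                  NONE = 0.07),
    cfProduct = c(BD = 0.20, MD3 = 0.50, MD4 = 0.10, CD = 0.15, CF = 0,
                  NONE = 0.05))
  if (!is.null(eventProbs)) defProbs[names(eventProbs)] <- eventProbs
  defInt <- list(
    "root.BD" = list(kind = "lognormal", meanlog = log(1300), sdlog = 0.25),
    "BD"      = list(kind = "lognormal", meanlog = log(2300), sdlog = 0.10),
    "MD3"     = list(kind = "lognormal", meanlog = log(2300), sdlog = 0.10),
    "MD4"     = list(kind = "lognormal", meanlog = log(2300), sdlog = 0.10),
    "CD"      = list(kind = "uniform", min = 500, max = 3500),
    "CF"      = list(kind = "uniform", min = 300, max = 1500))
  if (!is.null(intervals)) defInt[names(intervals)] <- intervals
  for (cl in names(defProbs)) {
    p <- defProbs[[cl]]
    if (!identical(names(p), .EVENT_TYPES))
      stop("eventProbs$", cl, " must be named ",
           paste(.EVENT_TYPES, collapse = ", "))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("eventProbs$", cl, " must be a probability vector summing to 1")
  }
  for (nm in names(defInt)) .checkDist(defInt[[nm]], nm)
  structure(list(nProgenitors = as.integer(nProgenitors),
                 duration = duration, frameInterval = frameInterval,
                 eventProbs = defProbs, intervals = defInt,
                 seed = as.integer(seed)),
            class = "SynthParams")
}

.synthInterval <- function(params, class, event) {
  key <- paste0(class, ".", event)
  d <- params$intervals[[key]]
  if (is.null(d)) d <- params$intervals[[event]]
  if (is.null(d)) d <- list(kind = "lognormal", meanlog = log(2300),
                            sdlog = 0.10)
  max(.drawDist(d), 1e-6)
}

.synthDrawEvent <- function(probs, allowCF = TRUE) {
  p <- probs
  if (!allowCF) { p[["CF"]] <- 0; p <- p / sum(p) }
  sample(names(p), 1L, prob = p)
}

#' Generate a synthetic cell-lineage database
#'
#' Runs the branching process of \code{\link{synthParams}}: each cell draws
#' an end event from its birth class's probabilities and an interval from
#' the matching distribution; divisions spawn child cohorts, sibling
#' \code{CF} draws pair up and produce a merged \code{cfProduct} cell, and
#' any event crossing the tracking duration is censored to \code{NONE}.
#' Output always passes \code{\link{validateLineageDB}} and is
#' deterministic given the seed.
#'
#' @param params a \code{SynthParams} object.
#' @return A \code{\linkS4class{LineageDB}}.
#' @export
generateSyntheticDB <- function(params) {
  stopifnot(inherits(params, "SynthParams"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(params$seed)
  dur <- params$duration
  rows <- vector("list", 4096L)
  nr <- 0L
  emit <- function(lid, cid, parent, birth, end, event, plid = NA_integer_,
                   pcid = NA_integer_) {
    nr <<- nr + 1L
    if (nr > length(rows)) length(rows) <<- 2L * length(rows)
    rows[[nr]] <<- list(lid, cid, parent, birth, end, event, plid, pcid)
  }

  for (l in seq_len(params$nProgenitors)) {
    nextCid <- 2L
    # queue entries: cid, parent, birth, class, event (NA = draw on dequeue)
    queue <- list(list(cid = 1L, parent = NA_integer_, birth = 0,
                       class = "root", event = NA_character_))
    qi <- 1L
    while (qi <= length(queue)) {
      cell <- queue[[qi]]; qi <- qi + 1L
      ev <- cell$event
      if (is.na(ev))
        ev <- .synthDrawEvent(params$eventProbs[[cell$class]], allowCF = FALSE)
      if (ev == "NONE") { emit(l, cell$cid, cell$parent, cell$birth, dur, "NONE"); next }
      end <- cell$birth + .synthInterval(params, cell$class, ev)
      if (end > dur) { emit(l, cell$cid, cell$parent, cell$birth, dur, "NONE"); next }
      emit(l, cell$cid, cell$parent, cell$birth, end, ev)
      if (!.isDivision(ev)) next
      k <- c(BD = 2L, MD3 = 3L, MD4 = 4L)[[ev]]
      childClass <- if (ev == "BD") "bdChild" else "mdChild"
      cids <- nextCid + seq_len(k) - 1L
      nextCid <- nextCid + k
      evts <- vapply(seq_len(k), function(j)
        .synthDrawEvent(params$eventProbs[[childClass]]), character(1))
      # a CF draw initiates fusion with the next unpaired sibling (whose own
      # draw is overridden), so each cell's chance of ending in fusion is
      # the configured CF probability; a draw with no partner available is
      # redrawn without CF
      cfs <- integer(0)
      pairsLocal <- list()
      for (j in seq_len(k)) {
        if (evts[j] != "CF" || j %in% cfs) next
        cand <- setdiff(seq_len(k), c(seq_len(j), cfs))
        if (length(cand)) {
          partner <- cand[1L]
          evts[partner] <- "CF"
          cfs <- c(cfs, j, partner)
          pairsLocal[[length(pairsLocal) + 1L]] <- c(j, partner)
        } else {
          evts[j] <- .synthDrawEvent(params$eventProbs[[childClass]],
                                     allowCF = FALSE)
        }
      }
      for (j in seq_len(k)) {
        if (j %in% cfs) next
        cev <- evts[j]
        if (cev == "NONE") {
          emit(l, cids[j], cell$cid, end, dur, "NONE")
        } else if (.isDivision(cev)) {
          # expand on dequeue with its event fixed, so the per-class
          # probabilities are exactly the configured ones
          queue[[length(queue) + 1L]] <-
            list(cid = cids[j], parent = cell$cid, birth = end,
                 class = childClass, event = cev)
        } else {
          cend <- end + .synthInterval(params, childClass, cev)
          if (cend > dur) {
            emit(l, cids[j], cell$cid, end, dur, "NONE")
          } else {
            emit(l, cids[j], cell$cid, end, cend, cev)
          }
        }
      }
      # realise the fusion pairs
      for (pr in pairsLocal) {
        a <- pr[1L]; b <- pr[2L]
        fend <- end + .synthInterval(params, childClass, "CF")
        if (fend > dur) {
          emit(l, cids[a], cell$cid, end, dur, "NONE")
          emit(l, cids[b], cell$cid, end, dur, "NONE")
          next
        }
        emit(l, cids[a], cell$cid, end, fend, "CF", l, cids[b])
        emit(l, cids[b], cell$cid, end, fend, "CF", l, cids[a])
        mcid <- nextCid; nextCid <- nextCid + 1L
        queue[[length(queue) + 1L]] <-
          list(cid = mcid, parent = cids[a], birth = fend,
               class = "cfProduct", event = NA_character_)
      }
    }
  }
  rows <- rows[seq_len(nr)]
  rec <- data.frame(
    lineage_id = vapply(rows, `[[`, integer(1), 1L),
    cell_id = vapply(rows, `[[`, integer(1), 2L),
    parent_cell_id = vapply(rows, function(r) as.integer(r[[3L]]), integer(1)),
    birth_min = vapply(rows, `[[`, numeric(1), 4L),
    end_min = vapply(rows, `[[`, numeric(1), 5L),
    end_event = vapply(rows, `[[`, character(1), 6L),
    fusion_partner_lineage = vapply(rows, function(r) as.integer(r[[7L]]),
                                    integer(1)),
    fusion_partner_cell = vapply(rows, function(r) as.integer(r[[8L]]),
                                 integer(1)),
    stringsAsFactors = FALSE)
  rec <- rec[order(rec$lineage_id, rec$cell_id), , drop = FALSE]
  rownames(rec) <- NULL
  LineageDB(rec, frameInterval = params$frameInterval,
            trackingDuration = dur,
            metadata = list(source = "synthetic",
                            seed = as.character(params$seed)))
}

#' Paper-like Operation data fixtures
#'
#' Builds two synthetic Operation data models emulating, at the
#' order-of-magnitude level, an unstressed p53-proficient culture
#' ("control-like": per-frame event chances near 0.54 BD, 0.001 MD, 0.004
#' CD, 0.004 CF per 100 lineages) and a p53-silenced culture
#' ("silenced-like": elevated death, fusion and multipolar division, with a
#' cell-death chance about 9x the control's).  They are synthetic stand-ins
#' generated from \code{\link{synthParams}} branching processes and
#' extracted with \code{\link{extractOperationData}} — not fits to any
#' empirical database — and serve integration tests of mixed-culture and
#' dose simulations.
#'
#' @param nProgenitors lineages per fixture (default 2000, enough to
#'   stabilise the rare-event rates).
#' @param duration tracking minutes (default 4000).
#' @param seed integer seed.
#' @return \code{list(control = OperationData, silenced = OperationData)}.
#' @export
makePaperLikeFixtures <- function(nProgenitors = 2000, duration = 4000,
                                  seed = 2009) {
  control <- synthParams(nProgenitors = nProgenitors, duration = duration,
                         seed = seed)
  silenced <- synthParams(
    nProgenitors = nProgenitors, duration = duration, seed = seed + 1L,
    eventProbs = list(
      root    = c(BD = 0.9253, MD3 = 0, MD4 = 0, CD = 0.02775, CF = 0,
                  NONE = 0.04695),
      bdChild = c(BD = 0.90, MD3 = 0.008, MD4 = 0.0025, CD = 0.02775,
                  CF = 0.034, NONE = 0.02775)))
  list(control = extractOperationData(generateSyntheticDB(control)),
       silenced = extractOperationData(generateSyntheticDB(silenced)))
}
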