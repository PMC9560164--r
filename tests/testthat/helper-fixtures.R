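# Shared fixtures and independent oracles, built in code.

# --- hand-built lineage databases ------------------------------------------

# one progenitor, BD at 100; one child dies at 300, the other is censored
minimalDB <- function() {
  rec <- data.frame(
    lineage_id = 1L, cell_id = 1:3, parent_cell_id = c(NA, 1L, 1L),
    birth_min = c(0, 100, 100), end_min = c(100, 300, 4000),
    end_event = c("BD", "CD", "NONE"), stringsAsFactors = FALSE)
  LineageDB(rec, trackingDuration = 4000)
}

# one progenitor, BD at 100; the two children fuse at 200; merged cell
# censored
fusionDB <- function(duration = 400) {
  rec <- data.frame(
    lineage_id = 1L, cell_id = 1:4, parent_cell_id = c(NA, 1L, 1L, 2L),
    birth_min = c(0, 100, 100, 200), end_min = c(100, 200, 200, duration),
    end_event = c("BD", "CF", "CF", "NONE"),
    fusion_partner_lineage = c(NA, 1L, 1L, NA),
    fusion_partner_cell = c(NA, 3L, 2L, NA), stringsAsFactors = FALSE)
  LineageDB(rec, trackingDuration = duration)
}

# a full binary lineage with `gens` generations of bipolar division
# (2^gens - 1 BD events), leaves censored
binaryLineage <- function(lid, gens, step = 500, duration = 4000) {
  rows <- list(list(cid = 1L, parent = NA_integer_, birth = 0, depth = 0L))
  nextCid <- 2L
  out <- list()
  while (length(rows)) {
    cell <- rows[[1L]]; rows <- rows[-1L]
    if (cell$depth < gens) {
      end <- cell$birth + step
      out[[length(out) + 1L]] <- data.frame(
        lineage_id = lid, cell_id = cell$cid, parent_cell_id = cell$parent,
        birth_min = cell$birth, end_min = end, end_event = "BD",
        stringsAsFactors = FALSE)
      for (j in 1:2) {
        rows[[length(rows) + 1L]] <- list(cid = nextCid, parent = cell$cid,
                                          birth = end,
                                          depth = cell$depth + 1L)
        nextCid <- nextCid + 1L
      }
    } else {
      out[[length(out) + 1L]] <- data.frame(
        lineage_id = lid, cell_id = cell$cid, parent_cell_id = cell$parent,
        birth_min = cell$birth, end_min = duration, end_event = "NONE",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# --- pure-BD Operation data (closed-form geometric growth) -----------------

pureBDOperationData <- function(interval = 500, duration = 1600) {
  OperationData(
    timeHistograms = list(FIRST = stats::setNames(1, interval),
                          BDBD = stats::setNames(1, interval)),
    eventLists = list(FIRST_LIST = c(BD = 1), BD_LIST = c(BD = 1)),
    trackingDuration = duration)
}

# Operation data for round-trip parameter recovery: no cell death, shared
# interval support across event types so censoring is independent of the
# drawn event.
roundTripOperationData <- function() {
  # first events complete by 800 min and division-born generations either
  # complete fully (gen 1: ends <= 3600) or censor fully (gen 2: ends >=
  # 4200), so extraction is free of interval-dependent censoring bias
  support <- c("2000" = 1, "2400" = 2, "2800" = 1)
  OperationData(
    timeHistograms = list(FIRST = c("400" = 1, "800" = 2),
                          BDBD = support, BDMD = support, BDCF = support,
                          MDMD = support, MDBD = support,
                          DIVCFDIV = support),
    eventLists = list(FIRST_LIST = c(BD = 95, NONDIV = 5),
                      BD_LIST = c(BD = 80, MD = 3, CF = 5),
                      MD_LIST = c(BD = 1, MD = 1),
                      BDCF_LIST = c(BD = 1)),
    recoveryPercent = 0, trackingDuration = 4000)
}

# --- independent oracles ----------------------------------------------------

# accounting identity: alive(t) = progenitors + sum(divisions <= t)(arity-1)
#                      - deaths <= t - fusion pairs <= t
expectAccountingIdentity <- function(db, step = 500) {
  rec <- lineageRecords(db)
  curve <- populationCurve(db, step = step)
  arity <- c(BD = 2, MD3 = 3, MD4 = 4)
  pairs <- rec[rec$end_event == "CF", ]
  nPairs <- nrow(pairs) / 2
  for (k in seq_len(nrow(curve))) {
    t <- curve$time[k]
    divs <- rec[rec$end_event %in% names(arity) & rec$end_min <= t, ]
    expect_equal(
      curve$count[k],
      sum(is.na(rec$parent_cell_id)) +
        sum(arity[divs$end_event] - 1) -
        sum(rec$end_event == "CD" & rec$end_min <= t) -
        sum(pairs$end_min <= t) / 2,
      info = paste("accounting identity at t =", t))
  }
}

# per-pixel brute-force rasterisation (the exact density-map oracle)
bruteForceDensity <- function(pts, radius, grid) {
  w <- grid[1]; h <- grid[2]
  m <- matrix(0L, nrow = h, ncol = w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    v <- 0L
    for (p in seq_len(nrow(pts)))
      if ((x - pts$x_px[p])^2 + (y - pts$y_px[p])^2 <= radius^2 + 1e-9)
        v <- v + 1L
    m[y, x] <- v
  }
  m
}

# a CDI cohort of k unassigned division siblings
.cdiCohort <- function(k, birth = 1000) {
  st <- newCellStates(k, lineageIds = rep(1L, k))
  st$cell_id <- seq_len(k) + 1L
  st$parent_cell_id <- 1L
  st$birth_min <- birth
  st$birth_class <- "BD_CHILD"
  st
}

finalCount <- function(db) {
  pc <- populationCurve(db, step = trackingDuration(db))
  pc$count[nrow(pc)]
}
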