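# Lineage and population analytics.

# hand-built forest: 4 BD, 1 MD3 (three censored children), 2 CD, 1 fusion
# pair, assorted censored leaves
eventMixDB <- function() {
  rows <- list(
    # lineage 1: BD -> (BD -> 2 NONE, CD)
    data.frame(lineage_id = 1L, cell_id = 1:5,
               parent_cell_id = c(NA, 1L, 1L, 2L, 2L),
               birth_min = c(0, 500, 500, 1500, 1500),
               end_min = c(500, 1500, 800, 4000, 4000),
               end_event = c("BD", "BD", "CD", "NONE", "NONE")),
    # lineage 2: BD -> (MD3 -> 3 NONE, CD)
    data.frame(lineage_id = 2L, cell_id = 1:6,
               parent_cell_id = c(NA, 1L, 1L, 2L, 2L, 2L),
               birth_min = c(0, 600, 600, 2000, 2000, 2000),
               end_min = c(600, 2000, 2600, 4000, 4000, 4000),
               end_event = c("BD", "MD3", "CD", "NONE", "NONE", "NONE")),
    # lineage 3: BD -> siblings fuse -> merged censored
    data.frame(lineage_id = 3L, cell_id = 1:4,
               parent_cell_id = c(NA, 1L, 1L, 2L),
               birth_min = c(0, 700, 700, 1900),
               end_min = c(700, 1900, 1900, 4000),
               end_event = c("BD", "CF", "CF", "NONE"),
               fusion_partner_lineage = c(NA, 3L, 3L, NA),
               fusion_partner_cell = c(NA, 3L, 2L, NA)))
  rows[[1]]$fusion_partner_lineage <- NA_integer_
  rows[[1]]$fusion_partner_cell <- NA_integer_
  rows[[2]]$fusion_partner_lineage <- NA_integer_
  rows[[2]]$fusion_partner_cell <- NA_integer_
  db <- LineageDB(do.call(rbind, rows), trackingDuration = 4000)
  expect_equal(nrow(validateLineageDB(db)), 0L)
  db
}

test_that("event counting aggregates MD and counts fusion pairs once", {
  db <- eventMixDB()
  ce <- countEvents(db)
  expect_equal(unname(ce$counts), c(4, 1, 2, 1))
  expect_equal(ce$n_lineages, 3L)
  expect_equal(ce$n_frames, 400L)
  # empty window gives zeros
  expect_equal(unname(countEvents(db, c(10, 5))$counts), rep(0, 4))
  # a BD-only database counts only BD
  bd <- LineageDB(binaryLineage(1L, gens = 2), trackingDuration = 4000)
  expect_equal(unname(countEvents(bd)$counts), c(3, 0, 0, 0))
})

test_that("event counts are additive over a window partition", {
  db <- generateSyntheticDB(synthParams(nProgenitors = 150, seed = 71))
  whole <- countEvents(db, c(0, 4000))$counts
  cuts <- c(0, 1000, 2500, 3210, 4000)
  parts <- lapply(1:4, function(i)
    countEvents(db, c(cuts[i] + ifelse(i > 1, 1e-9, 0), cuts[i + 1]))$counts)
  expect_equal(Reduce(`+`, parts), whole)
})

test_that("per-frame event rates follow events/(frames x lineages) x 100", {
  # 335 lineages holding exactly 1000 BD events over 400 frames
  rows <- lapply(1:333, function(l) binaryLineage(l, gens = 2))   # 999 BD
  rows[[334]] <- binaryLineage(334L, gens = 1)                    # 1 BD
  rows[[335]] <- data.frame(lineage_id = 335L, cell_id = 1L,
                            parent_cell_id = NA_integer_, birth_min = 0,
                            end_min = 4000, end_event = "NONE")
  db <- LineageDB(do.call(rbind, rows), trackingDuration = 4000)
  expect_equal(nLineages(db), 335L)
  rates <- eventRatePerFrame(db)
  expect_equal(unname(rates[["BD"]]), 1000 / (400 * 335) * 100)
  expect_equal(round(unname(rates[["BD"]]), 3), 0.746)
  expect_equal(unname(rates[["CD"]]), 0)
})

test_that("lineages are grouped by total cell count in 2-cell-wide bins", {
  # 5 cells -> C, 13 cells -> G, singleton -> A; five 3-cell lineages give
  # a group B total of 15
  rows <- list(
    data.frame(lineage_id = 1L, cell_id = 1:5,
               parent_cell_id = c(NA, 1L, 1L, 2L, 2L),
               birth_min = c(0, 100, 100, 200, 200),
               end_min = c(100, 200, 400, 400, 400),
               end_event = c("BD", "BD", "NONE", "NONE", "NONE")),
    binaryLineage(2L, gens = 3, step = 100, duration = 400)[1:13, ])
  rows[[2]]$end_event[rows[[2]]$cell_id > 7] <- "NONE"
  rows[[2]]$end_min[rows[[2]]$cell_id > 7] <- 400
  for (l in 3:7)
    rows[[length(rows) + 1L]] <- data.frame(
      lineage_id = l, cell_id = 1:3, parent_cell_id = c(NA, 1L, 1L),
      birth_min = c(0, 100, 100), end_min = c(100, 400, 400),
      end_event = c("BD", "NONE", "NONE"))
  rows[[length(rows) + 1L]] <- data.frame(
    lineage_id = 8L, cell_id = 1L, parent_cell_id = NA_integer_,
    birth_min = 0, end_min = 400, end_event = "NONE")
  db <- LineageDB(do.call(rbind, rows), trackingDuration = 400)
  gh <- groupLineages(db)
  expect_equal(gh$cells[gh$group == "A"], 1L)
  expect_equal(gh$cells[gh$group == "B"], 15L)
  expect_equal(gh$cells[gh$group == "C"], 5L)
  expect_equal(gh$cells[gh$group == "G"], 13L)
  # conservation: group totals sum to the database size
  expect_equal(sum(gh$cells), nCells(db))
})

test_that("group totals conserve cells on synthetic databases", {
  for (seed in c(81, 82)) {
    db <- generateSyntheticDB(synthParams(nProgenitors = 60, seed = seed))
    expect_equal(sum(groupLineages(db)$cells), nCells(db))
  }
})

test_that("doubling times cover exactly the BD-to-BD cells", {
  # intervals 480, 520, 600 for the BD-born dividers; progenitor excluded
  rec <- rbind(
    data.frame(lineage_id = 1L, cell_id = 1L, parent_cell_id = NA_integer_,
               birth_min = 0, end_min = 500, end_event = "BD"),
    data.frame(lineage_id = 1L, cell_id = 2:3, parent_cell_id = 1L,
               birth_min = 500, end_min = c(980, 1020),
               end_event = c("BD", "BD")),
    data.frame(lineage_id = 1L, cell_id = 4:7, parent_cell_id = c(2L, 2L, 3L, 3L),
               birth_min = c(980, 980, 1020, 1020),
               end_min = c(1580, 4000, 4000, 4000),
               end_event = c("BD", "NONE", "NONE", "NONE")),
    data.frame(lineage_id = 1L, cell_id = 8:9, parent_cell_id = 4L,
               birth_min = 1580, end_min = 4000, end_event = "NONE"))
  db <- LineageDB(rec, trackingDuration = 4000)
  expect_equal(nrow(validateLineageDB(db)), 0L)
  expect_equal(sort(doublingTimes(db)), c(480, 520, 600))

  fixed <- generateSyntheticDB(synthParams(
    nProgenitors = 20, seed = 91,
    eventProbs = list(root = c(BD = 1, MD3 = 0, MD4 = 0, CD = 0, CF = 0,
                               NONE = 0)),
    intervals = list("root.BD" = list(kind = "fixed", value = 500),
                     "BD" = list(kind = "fixed", value = 500))))
  expect_true(all(doublingTimes(fixed) == 500))
})

test_that("synthetic doubling times agree with the generator mean", {
  p <- synthParams(nProgenitors = 400, seed = 92,
                   intervals = list(
                     "root.BD" = list(kind = "fixed", value = 300),
                     "BD" = list(kind = "lognormal", meanlog = log(1500),
                                 sdlog = 0.1)))
  dt <- doublingTimes(generateSyntheticDB(p))
  expect_gt(length(dt), 300)
  mu <- exp(log(1500) + 0.1^2 / 2)
  expect_lt(abs(mean(dt) - mu), 3 * sd(dt) / sqrt(length(dt)))
})

test_that("multipolar tracebacks classify fusion origins", {
  # no MD: all-zero summary
  expect_equal(unlist(traceMultipolarOrigins(minimalDB())),
               stats::setNames(rep(0L, 6),
                               c("pattern1a", "pattern1b", "pattern2a",
                                 "pattern2b", "reproductive_md_progeny",
                                 "total_md_progeny")))
  # BD -> sibling fusion -> merged cell MD3 -> one child divides again
  rec <- rbind(
    data.frame(lineage_id = 1L, cell_id = 1L, parent_cell_id = NA_integer_,
               birth_min = 0, end_min = 100, end_event = "BD",
               fusion_partner_lineage = NA_integer_,
               fusion_partner_cell = NA_integer_),
    data.frame(lineage_id = 1L, cell_id = 2:3, parent_cell_id = 1L,
               birth_min = 100, end_min = 200, end_event = "CF",
               fusion_partner_lineage = 1L, fusion_partner_cell = c(3L, 2L)),
    data.frame(lineage_id = 1L, cell_id = 4L, parent_cell_id = 2L,
               birth_min = 200, end_min = 300, end_event = "MD3",
               fusion_partner_lineage = NA_integer_,
               fusion_partner_cell = NA_integer_),
    data.frame(lineage_id = 1L, cell_id = 5:7, parent_cell_id = 4L,
               birth_min = 300, end_min = c(800, 400, 400),
               end_event = c("BD", "NONE", "NONE"),
               fusion_partner_lineage = NA_integer_,
               fusion_partner_cell = NA_integer_),
    data.frame(lineage_id = 1L, cell_id = 8:9, parent_cell_id = 5L,
               birth_min = 800, end_min = 400 * 10, end_event = "NONE",
               fusion_partner_lineage = NA_integer_,
               fusion_partner_cell = NA_integer_))
  db <- LineageDB(rec, trackingDuration = 4000)
  expect_equal(nrow(validateLineageDB(db)), 0L)
  tb <- traceMultipolarOrigins(db)
  expect_equal(tb$pattern1a, 1L)
  expect_equal(tb$pattern1b, 0L)
  expect_equal(tb$pattern2a, 1L)
  expect_equal(tb$pattern2b, 0L)
  expect_equal(tb$reproductive_md_progeny, 1L)
  expect_equal(tb$total_md_progeny, 3L)
})

test_that("pattern counts partition the multipolar divisions", {
  db <- generateSyntheticDB(synthParams(
    nProgenitors = 150, seed = 95,
    eventProbs = list(bdChild = c(BD = 0.7, MD3 = 0.05, MD4 = 0.02,
                                  CD = 0.03, CF = 0.15, NONE = 0.05))))
  tb <- traceMultipolarOrigins(db)
  md <- sum(lineageRecords(db)$end_event %in% c("MD3", "MD4"))
  expect_equal(tb$pattern1a + tb$pattern1b, md)
  expect_equal(tb$pattern2a + tb$pattern2b, tb$pattern1a)
  expect_gt(md, 0)
})

test_that("in-silico cell-death removal replaces dead cells with siblings", {
  # no CD: identity
  db0 <- fusionDB()
  out0 <- removeCellDeathInSilico(db0)
  expect_equal(lineageRecords(out0), lineageRecords(db0))

  # parent BD at 0...: child A dies at 100, child B divides at 200 into two
  # censored cells; A is replaced by a copy of B's subtree
  rec <- rbind(
    data.frame(lineage_id = 1L, cell_id = 1L, parent_cell_id = NA_integer_,
               birth_min = 0, end_min = 50, end_event = "BD"),
    data.frame(lineage_id = 1L, cell_id = 2L, parent_cell_id = 1L,
               birth_min = 50, end_min = 100, end_event = "CD"),
    data.frame(lineage_id = 1L, cell_id = 3L, parent_cell_id = 1L,
               birth_min = 50, end_min = 200, end_event = "BD"),
    data.frame(lineage_id = 1L, cell_id = 4:5, parent_cell_id = 3L,
               birth_min = 200, end_min = 400, end_event = "NONE"))
  db <- LineageDB(rec, trackingDuration = 400)
  out <- removeCellDeathInSilico(db)
  expect_equal(nrow(validateLineageDB(out)), 0L)
  expect_false(any(lineageRecords(out)$end_event == "CD"))
  expect_equal(finalCount(out), 4)  # the revived branch contributes 2 cells
  expect_equal(finalCount(db), 2)

  # the dead cell's replacement divides at the sibling's time
  copyRoot <- lineageRecords(out)
  copyRoot <- copyRoot[copyRoot$cell_id == 2L, ]
  expect_equal(copyRoot$end_event, "BD")
  expect_equal(copyRoot$end_min, 200)
})

test_that("death removal never lowers the population curve", {
  for (seed in c(101, 102)) {
    db <- generateSyntheticDB(synthParams(
      nProgenitors = 60, seed = seed,
      eventProbs = list(bdChild = c(BD = 0.8, MD3 = 0.002, MD4 = 0.001,
                                    CD = 0.12, CF = 0.006, NONE = 0.071))))
    out <- removeCellDeathInSilico(db)
    expect_equal(nrow(validateLineageDB(out)), 0L)
    expect_false(any(lineageRecords(out)$end_event == "CD"))
    before <- populationCurve(db, step = 500)$count
    after <- populationCurve(out, step = 500)$count
    expect_true(all(after >= before))
  }
})

test_that("density maps equal the brute-force rasterisation", {
  mkdb <- function(pts) {
    rec <- data.frame(lineage_id = seq_len(nrow(pts)), cell_id = 1L,
                      parent_cell_id = NA_integer_, birth_min = 0,
                      end_min = 100, end_event = "NONE")
    pos <- data.frame(lineage_id = seq_len(nrow(pts)), cell_id = 1L,
                      frame = 1L, t_min = 10, x_px = pts$x_px,
                      y_px = pts$y_px)
    LineageDB(rec, trackingDuration = 100, positions = pos)
  }
  # single cell: a disk of ones
  one <- mkdb(data.frame(x_px = 20, y_px = 20))
  m1 <- densityMap(one, time = 10, kind = "cell", radiusPx = 10,
                   grid = c(40, 40))
  expect_equal(max(m1), 1L)
  expect_equal(unclass(m1),
               bruteForceDensity(data.frame(x_px = 20, y_px = 20), 10,
                                 c(40, 40)), ignore_attr = TRUE)
  # two cells 10 px apart: a lens of twos
  two <- mkdb(data.frame(x_px = c(15, 25), y_px = c(20, 20)))
  m2 <- densityMap(two, time = 10, kind = "cell", radiusPx = 10,
                   grid = c(40, 40))
  expect_equal(max(m2), 2L)
  expect_equal(unclass(m2),
               bruteForceDensity(data.frame(x_px = c(15, 25),
                                            y_px = c(20, 20)), 10,
                                 c(40, 40)), ignore_attr = TRUE)
  # no points at the requested frame: all zeros
  m0 <- densityMap(one, time = 90, kind = "cell", radiusPx = 10,
                   grid = c(40, 40))
  expect_true(all(m0 == 0L))
  # a database without positions cannot be mapped
  expect_error(densityMap(minimalDB(), 10, "cell"), "positions")
})

test_that("damage attribution splits the doubling-time delay", {
  res <- attributeDamageResponse(2501, 9651, 4510)
  expect_equal(res$total_delay, 7150)
  expect_equal(round(res$break_fraction), 63)
  expect_equal(round(res$p53_fraction), 37)
  expect_equal(attributeDamageResponse(100, 300, 50),
               list(total_delay = 200, break_fraction = 25,
                    p53_fraction = 75))
  full <- attributeDamageResponse(100, 300, 200)
  expect_equal(full$break_fraction, 100)
  expect_equal(full$p53_fraction, 0)
  expect_error(attributeDamageResponse(300, 300, 0), "exceed")
  expect_error(attributeDamageResponse(100, 300, 250), "delaySilenced")
})
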