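# Cell-fate simulator: assignment rules, modes, determinism, invariants.

test_that("pure-BD Operation data grows geometrically (10 x 2^3)", {
  od <- pureBDOperationData(interval = 500, duration = 1600)
  db <- simulateCellFates(simConfig("standard", 1600, 10, od, seed = 1))
  expect_equal(finalCount(db), 80)
  expect_equal(nrow(validateLineageDB(db)), 0L)
  # synchronous doublings at 500, 1000, 1500
  pc <- populationCurve(db, step = 500)
  expect_equal(pc$count, c(10, 20, 40, 80))
})

test_that("all-NONDIV Operation data keeps the population constant", {
  od <- OperationData(eventLists = list(FIRST_LIST = c(NONDIV = 1)),
                      recoveryPercent = 0, trackingDuration = 4000)
  db <- simulateCellFates(simConfig("standard", 4000, 25, od, seed = 2))
  expect_equal(nCells(db), 25L)
  expect_true(all(populationCurve(db, step = 1000)$count == 25))
})

test_that("simulation is deterministic given the seed", {
  od <- extractOperationData(
    generateSyntheticDB(synthParams(nProgenitors = 80, seed = 5)))
  cfg <- simConfig("standard", 5000, 120, od, seed = 42)
  db1 <- simulateCellFates(cfg)
  db2 <- simulateCellFates(cfg)
  expect_identical(lineageRecords(db1), lineageRecords(db2))
  db3 <- simulateCellFates(simConfig("standard", 5000, 120, od, seed = 43))
  expect_false(identical(lineageRecords(db1), lineageRecords(db3)))
})

test_that("simulator output validates and balances across seeds", {
  od <- extractOperationData(
    generateSyntheticDB(synthParams(
      nProgenitors = 120, seed = 6,
      eventProbs = list(bdChild = c(BD = 0.85, MD3 = 0.01, MD4 = 0.005,
                                    CD = 0.04, CF = 0.05, NONE = 0.045)))))
  for (seed in 1:20) {
    db <- simulateCellFates(simConfig("standard", 5000, 40, od, seed = seed))
    expect_equal(nrow(validateLineageDB(db)), 0L,
                 info = paste("seed", seed))
  }
  # accounting identity spot-checked on a few seeds
  for (seed in c(3, 11, 17)) {
    db <- simulateCellFates(simConfig("standard", 5000, 40, od, seed = seed))
    expectAccountingIdentity(db, step = 1000)
  }
})

test_that("first-event assignment follows the FIRST arrays and fallbacks", {
  # a constant FIRST histogram assigns that interval to every progenitor
  od <- pureBDOperationData(interval = 500, duration = 1600)
  arr <- buildSimulationArrays(od)
  st <- newCellStates(50)
  set.seed(1)
  st <- assignFirstEvents(st, arr)
  expect_true(all(st$assigned_interval == 500))
  expect_true(all(st$assigned_event == "BD"))

  # empty first-event data: mean BD time perturbed by -25% to +25%
  od2 <- OperationData(timeHistograms = list(BDBD = c("600" = 5)),
                       eventLists = list(BD_LIST = c(BD = 1)),
                       trackingDuration = 4000)
  arr2 <- buildSimulationArrays(od2)
  set.seed(2)
  st2 <- assignFirstEvents(newCellStates(1000), arr2)
  expect_true(all(st2$assigned_event == "BD"))
  expect_true(all(st2$assigned_interval >= 450 - 1e-9))
  expect_true(all(st2$assigned_interval <= 750 + 1e-9))

  # first events drawn as CD take their Ltime from the NONDIVCD array
  od3 <- OperationData(
    timeHistograms = list(FIRST = c("1000" = 10), NONDIVCD = c("333" = 1)),
    eventLists = list(FIRST_LIST = c(BD = 5, CD = 5)),
    trackingDuration = 4000)
  set.seed(3)
  st3 <- assignFirstEvents(newCellStates(400), buildSimulationArrays(od3))
  cd <- st3$assigned_event == "CD"
  expect_gt(sum(cd), 50)
  expect_true(all(st3$assigned_interval[cd] == 333))
  expect_true(all(st3$assigned_interval[!cd] == 1000))
})

test_that("a drawn first Ltime equal to the tracking time is perturbed", {
  od <- OperationData(timeHistograms = list(FIRST = c("4000" = 1)),
                      eventLists = list(FIRST_LIST = c(BD = 1)),
                      trackingDuration = 4000)
  set.seed(4)
  st <- assignFirstEvents(newCellStates(500), buildSimulationArrays(od))
  expect_true(all(st$assigned_interval >= 2800 - 1e-9))
  expect_true(all(st$assigned_interval <= 5200 + 1e-9))
  expect_gt(stats::sd(st$assigned_interval), 0)
})

test_that("BD children stay within the parent/child interval tolerance", {
  od <- OperationData(
    timeHistograms = list(FIRST = c("500" = 1),
                          BDBD = c("400" = 1, "500" = 2, "600" = 1)),
    eventLists = list(FIRST_LIST = c(BD = 1), BD_LIST = c(BD = 1)),
    trackingDuration = 4000)
  arr <- buildSimulationArrays(od)
  set.seed(5)
  for (rep in 1:200) {
    cohort <- .cdiCohort(2)
    out <- assignNextEvents(cohort, arr, cohortClass = "BD",
                            parentInterval = 500, parentWasBDBD = TRUE,
                            tolerance = 0.10)
    expect_true(all(out$assigned_interval >= 450 - 1e-9 &
                    out$assigned_interval <= 550 + 1e-9))
  }
  # disjoint support clamps to the nearest bound after the attempt budget
  set.seed(6)
  out2 <- assignNextEvents(.cdiCohort(2), arr, cohortClass = "BD",
                           parentInterval = 2000, parentWasBDBD = TRUE,
                           tolerance = 0.10, maxResampleAttempts = 20)
  expect_true(all(out2$assigned_interval == 1800))
})

test_that("the interval restraint also holds end-to-end in simulations", {
  od <- extractOperationData(
    generateSyntheticDB(synthParams(nProgenitors = 120, seed = 7)))
  db <- simulateCellFates(simConfig("standard", 8000, 150, od, seed = 8))
  rec <- lineageRecords(db)
  key <- paste(rec$lineage_id, rec$cell_id)
  pidx <- match(paste(rec$lineage_id, rec$parent_cell_id), key)
  gidx <- pidx[pidx]  # grandparent
  childItv <- rec$end_min - rec$birth_min
  sel <- !is.na(pidx) & rec$end_event == "BD" &
    rec$end_event[pidx] == "BD" & !is.na(gidx) &
    rec$end_event[gidx] == "BD"
  ratio <- childItv[sel] / (rec$end_min[pidx][sel] - rec$birth_min[pidx][sel])
  expect_gt(sum(sel), 100)
  expect_true(all(ratio >= 0.9 - 1e-9 & ratio <= 1.1 + 1e-9))
})

test_that("fusion draws pair siblings and fall back to death when alone", {
  # 100% CF list: the first child pairs with the second
  odCF <- OperationData(
    timeHistograms = list(BDCF = c("700" = 1), BDCD = c("900" = 1),
                          BDBD = c("500" = 1)),
    eventLists = list(BD_LIST = c(CF = 1, BD = 1)),
    trackingDuration = 4000)
  arr <- buildSimulationArrays(odCF)
  set.seed(9)
  sawPair <- FALSE; sawLoneToCD <- FALSE
  for (rep in 1:100) {
    out <- assignNextEvents(.cdiCohort(2), arr, cohortClass = "BD")
    if (all(out$assigned_event == "CF")) {
      sawPair <- TRUE
      expect_equal(out$assigned_interval[1], out$assigned_interval[2])
      expect_equal(out$partner_cell_id, rev(out$cell_id))
    }
    # a CF draw with the only sibling already dead becomes cell death
    cohort <- .cdiCohort(2)
    cohort$assigned_event[2] <- "CD"
    out2 <- assignNextEvents(cohort, arr, cohortClass = "BD")
    if (out2$assigned_event[1] == "CD") sawLoneToCD <- TRUE
    expect_false(out2$assigned_event[1] == "CF" &&
                 is.na(out2$partner_cell_id[1]))
  }
  expect_true(sawPair)
  expect_true(sawLoneToCD)
})

test_that("an MD cohort holds at most one fusion pair", {
  od <- OperationData(
    timeHistograms = list(MDCF = c("700" = 1), MDMD = c("500" = 1),
                          MDCD = c("900" = 1)),
    eventLists = list(MD_LIST = c(CF = 10, BD = 1)),
    mdAritySplit = c(MD3 = 0, MD4 = 1),
    trackingDuration = 4000)
  arr <- buildSimulationArrays(od)
  set.seed(10)
  for (rep in 1:100) {
    out <- assignNextEvents(.cdiCohort(4), arr, cohortClass = "MD")
    expect_lte(sum(out$assigned_event == "CF"), 2L)
    expect_equal(sum(!is.na(out$partner_cell_id)) %% 2L, 0L)
  }
})

test_that("merged cells are reassigned from the post-fusion arrays", {
  od <- OperationData(
    timeHistograms = list(DIVCFDIV = c("800" = 3), BDCFCD = c("450" = 1)),
    eventLists = list(BDCF_LIST = c(BD = 1)),
    trackingDuration = 4000)
  arr <- buildSimulationArrays(od)
  st <- .cdiCohort(1)
  st$birth_class <- "CF_PRODUCT"; st$pre_class <- "BD"
  set.seed(11)
  out <- readjustFusionTimes(st, arr)
  expect_equal(out$assigned_event, "BD")
  expect_equal(out$assigned_interval, 800)

  # empty BDCF list: falls back to cell death at the mean death time
  od2 <- OperationData(timeHistograms = list(BDCD = c("900" = 1)),
                       eventLists = list(BD_LIST = c(BD = 1)),
                       trackingDuration = 4000)
  out2 <- readjustFusionTimes(st, buildSimulationArrays(od2))
  expect_equal(out2$assigned_event, "CD")
  expect_equal(out2$assigned_interval, 900)
})

test_that("without CF in the Operation data no fusion is ever simulated", {
  od <- extractOperationData(
    generateSyntheticDB(synthParams(
      nProgenitors = 80, seed = 12,
      eventProbs = list(bdChild = c(BD = 0.9, MD3 = 0.01, MD4 = 0.005,
                                    CD = 0.03, CF = 0, NONE = 0.055)))))
  expect_equal(unname(eventLists(od)$BD_LIST[["CF"]]), 0)
  db <- simulateCellFates(simConfig("standard", 6000, 100, od, seed = 13))
  expect_false(any(lineageRecords(db)$end_event == "CF"))
})

test_that("trimAtSwitch voids exactly the assignments crossing the switch", {
  st <- newCellStates(3)
  st$assigned_event <- c("BD", "BD", "CD")
  st$assigned_interval <- c(400, 900, 1200)
  out <- trimAtSwitch(st, switchTime = 800)
  expect_equal(out$assigned_event, c("BD", NA, NA))
  expect_equal(out$assigned_interval, c(400, NA, NA))
  # nothing crossing: unchanged
  expect_identical(trimAtSwitch(st, 2000), st)
})

test_that("switch mode re-draws crossing events from the second model", {
  od1 <- pureBDOperationData(interval = 500, duration = 4000)
  od2 <- pureBDOperationData(interval = 480, duration = 4000)
  db <- simulateCellFates(simConfig("switch", 2000, 20, od1,
                                    operationData2 = od2, seed = 14,
                                    switchTime = 1250))
  rec <- lineageRecords(db)
  itv <- rec$end_min - rec$birth_min
  bd <- rec$end_event == "BD"
  # phase-1 divisions keep the 500-min clock; every division completing
  # after the switch was redrawn on the second model's 480-min clock
  expect_true(all(abs(itv[bd & rec$end_min <= 1250] - 500) < 1e-9))
  post <- bd & rec$end_min > 1250
  expect_gt(sum(post), 0)
  expect_true(all(abs(itv[post] - 480) < 1e-9))
  expect_equal(nrow(validateLineageDB(db)), 0L)
})

test_that("switching to the identical model barely perturbs the dynamics", {
  # voiding-and-redrawing pending assignments at the switch lets crossing
  # events be replaced by unconditioned draws, which can pull events
  # slightly earlier; with identical models the population dynamics must
  # nevertheless agree closely
  od <- extractOperationData(
    generateSyntheticDB(synthParams(nProgenitors = 100, seed = 15)))
  straight <- vapply(1:10, function(s) finalCount(
    simulateCellFates(simConfig("standard", 5000, 150, od, seed = 100 + s))),
    numeric(1))
  switched <- vapply(1:10, function(s) finalCount(
    simulateCellFates(simConfig("switch", 5000, 150, od,
                                operationData2 = od, seed = 200 + s,
                                switchTime = 2500))), numeric(1))
  expect_lt(abs(mean(switched) - mean(straight)) / mean(straight), 0.05)
})

test_that("mixed mode tags populations and keeps them independent", {
  odA <- pureBDOperationData(interval = 500, duration = 4000)
  odB <- pureBDOperationData(interval = 800, duration = 4000)
  db <- simulateCellFates(simConfig(
    "mixed", 1700, c(ctrl = 12, alt = 8),
    operationData = list(ctrl = odA, alt = odB), seed = 16))
  rec <- lineageRecords(db)
  expect_setequal(unique(rec$population), c("ctrl", "alt"))
  itv <- rec$end_min - rec$birth_min
  bd <- rec$end_event == "BD"
  expect_true(all(itv[bd & rec$population == "ctrl"] == 500))
  expect_true(all(itv[bd & rec$population == "alt"] == 800))
  # 12 * 2^3 + 8 * 2^2
  expect_equal(finalCount(db), 12 * 8 + 8 * 4)
  expect_equal(nrow(validateLineageDB(db)), 0L)
})

test_that("dose mode at an endpoint equals the standard run", {
  fx <- makePaperLikeFixtures(nProgenitors = 120, seed = 17)
  dose <- simulateCellFates(simConfig("dose", 4000, 60, fx$control,
                                      operationData2 = fx$silenced,
                                      seed = 18, doseA = 0, doseB = 7,
                                      doseX = 0))
  std <- simulateCellFates(simConfig("standard", 4000, 60, fx$control,
                                     seed = 18))
  expect_identical(lineageRecords(dose)[, .RECORD_COLUMNS],
                   lineageRecords(std)[, .RECORD_COLUMNS])
  mid <- simulateCellFates(simConfig("dose", 4000, 60, fx$control,
                                     operationData2 = fx$silenced,
                                     seed = 18, doseA = 0, doseB = 7,
                                     doseX = 3.5))
  expect_equal(nrow(validateLineageDB(mid)), 0L)
})

test_that("run-to-run variation shrinks with more progenitors", {
  od <- extractOperationData(
    generateSyntheticDB(synthParams(nProgenitors = 100, seed = 19)))
  cv <- function(n) {
    finals <- vapply(1:5, function(s) finalCount(
      simulateCellFates(simConfig("standard", 4000, n, od,
                                  seed = 300 + s))), numeric(1))
    stats::sd(finals) / mean(finals)
  }
  expect_lt(cv(900), cv(100))
  expect_lt(cv(900), 0.05)
})
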