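test_that("active dilution solves the density inequality with maximal A", {
  set.seed(31)
  ids <- sprintf("m%05d", seq_len(10200))
  lab <- activityLabels(ids, sample(ids, 200))
  dil <- diluteActives(lab, density = 0.005, seed = 3)
  A <- length(actives(dil)); N <- length(libraryIds(dil))
  expect_lte(A / N, 0.005)
  # maximal: adding back any removed active would break the density
  expect_gt((A + 1) / (N + 1), 0.005)
  # brute-force the inequality on the fixed inactive count
  nInact <- 10000
  bruteA <- max(Filter(function(a) a / (nInact + a) <= 0.005, 0:200))
  expect_equal(A, bruteA)
  expect_equal(A, 50)
  # inactives never touched; removed actives leave the library entirely
  expect_setequal(setdiff(libraryIds(lab), actives(lab)),
                  setdiff(libraryIds(dil), actives(dil)))
  expect_true(all(actives(dil) %in% actives(lab)))
})

test_that("dilution is deterministic, idempotent on dilute inputs, and guarded", {
  set.seed(32)
  ids <- sprintf("m%04d", 1:3000)
  lab <- activityLabels(ids, sample(ids, 60))
  expect_identical(actives(diluteActives(lab, 0.005, seed = 11)),
                   actives(diluteActives(lab, 0.005, seed = 11)))
  already <- activityLabels(ids, sample(ids, 9))  # 0.3 % < 0.5 %
  expect_identical(already, diluteActives(already, 0.005, seed = 1))
  tiny <- activityLabels(sprintf("x%02d", 1:60), sprintf("x%02d", 1:10))
  expect_error(diluteActives(tiny, 0.005, seed = 1),
               class = "vSDCConfigError")
  expect_error(diluteActives(lab, 0.005), class = "vSDCConfigError")
})

test_that("diluting a bundle drops the eliminated actives from every table", {
  b <- generateTarget(generatorConfig(n_molecules = 1500,
                                      active_fraction = 0.05, seed = 5))
  dil <- diluteBundle(b, density = 0.005, seed = 2)
  lab <- bundleLabels(dil)
  expect_lte(length(actives(lab)) / length(libraryIds(lab)), 0.005)
  for (tab in bundleTables(dil))
    expect_setequal(moleculeIds(tab), libraryIds(lab))
})

test_that("runMethods agrees across methods when all programs agree", {
  tab <- randomTables(300, k = 2, seed = 41, sens = 3)[[1]]
  copies <- lapply(1:4, function(i) { t <- tab
    t@programName <- sprintf("prog%d", i); t })
  lib <- moleculeIds(tab)
  set.seed(41)
  lab <- activityLabels(lib, members(topN(tab, 3)),  # top 3 are "active"
                        target_name = "toy")
  b <- new("TargetBundle", targetName = "toy", tables = copies, labels = lab)
  out <- runMethods(b, 10)
  expect_true(all(out$h == 3))
  expect_true(all(out$Y_C == 1))
})

test_that("a toy with all-active consensus gives a perfect vSDC outcome", {
  b <- generateTarget(generatorConfig(n_molecules = 2000, seed = 17,
                                      sensitivity = 6))
  out <- runMethods(b, 5, methods = "vSDC")
  expect_equal(out$h, 5)
  expect_equal(out$Y_C, 1)
})

test_that("zero common stand-outs yields an SDC outcome of nCM = 0, h = 0", {
  a <- makeRankedTable(c(onlyA = 1), 100, "pA")
  bb <- makeRankedTable(c(onlyB = 100), 100, "pB")
  lab <- activityLabels(unique(c(moleculeIds(a), moleculeIds(bb))),
                        "onlyA", target_name = "toy")
  bundle <- new("TargetBundle", targetName = "toy", tables = list(a, bb),
                labels = lab)
  out <- suppressWarnings(runMethods(bundle, 5, methods = "SDC", sdc_x = 2))
  expect_equal(out$n_selected, 0L)
  expect_equal(out$h, 0)
  expect_equal(out$Y_C, 0)
})

test_that("vSDC infeasibility degrades to a flagged zero-hit outcome", {
  a <- makeRankedTable(c(u = 1), 30, "pA")
  bb <- makeRankedTable(c(u = 1), 30, "pB")
  bb@scores$molecule_id[2:30] <- sprintf("zz%02d", 2:30)
  lab <- activityLabels(unique(c(moleculeIds(a), moleculeIds(bb))), "u")
  bundle <- new("TargetBundle", targetName = "t", tables = list(a, bb),
                labels = lab)
  out <- suppressWarnings(runMethods(bundle, 10, methods = c("vSDC", "USC")))
  expect_true(out$infeasible[out$method == "vSDC"])
  expect_equal(out$h[out$method == "vSDC"], 0)
  expect_false(out$infeasible[out$method == "USC"])
})

test_that("SDC-comparison mode evaluates the baselines at the target's nCM", {
  b <- generateTarget(generatorConfig(seed = 23, sensitivity = 3))
  out <- runMethods(b, 999, methods = c("SDC", "prog1", "prog2"),
                    sdc_comparison = TRUE)
  n <- out$n_selected[out$method == "SDC"]
  expect_gt(n, 0)
  expect_true(all(out$n_selected == n))
})

test_that("sweep summaries recompute exactly from the per-target outcomes", {
  co <- generateCohort(6, generatorConfig(n_molecules = 800, seed = 2),
                       seed = 55)
  grid <- c(3, 8)
  sm <- benchmarkSweep(co, n_test_grid = grid,
                       methods = c("vSDC", "USC", "prog1"),
                       reference = "vSDC")
  pt <- perTargetOutcomes(sm)
  su <- summaryTable(sm)
  for (n in grid) for (m in c("vSDC", "USC", "prog1")) {
    o <- pt[pt$n_test == n & pt$method == m, ]
    row <- su[su$n_test == n & su$method == m, ]
    expect_equal(row$T_h_gt0, mean(o$h > 0))
    expect_equal(row$mean_Y_C, mean(o$Y_C))
    expect_equal(row$sem_Y_C, sd(o$Y_C) / sqrt(nrow(o)))
    ref <- pt[pt$n_test == n & pt$method == "vSDC", ]
    expect_equal(row$delta_p,
                 (sum(ref$h > o$h) - sum(o$h > ref$h)) / nrow(o))
  }
  expect_true(all(su$delta_p[su$method == "vSDC"] == 0))
})

test_that("equal-share USC averages the flanking multiples of k", {
  co <- generateCohort(3, generatorConfig(n_molecules = 600, seed = 3),
                       seed = 77)
  smAvg <- benchmarkSweep(co, n_test_grid = 50L, methods = "USC",
                            reference = "USC", usc_equal_share = TRUE)
  lo <- benchmarkSweep(co, n_test_grid = 48L, methods = "USC",
                       reference = "USC")
  hi <- benchmarkSweep(co, n_test_grid = 52L, methods = "USC",
                       reference = "USC")
  ptP <- perTargetOutcomes(smAvg); ptL <- perTargetOutcomes(lo)
  ptH <- perTargetOutcomes(hi)
  ord <- order(ptP$target)
  expect_equal(ptP$h[ord], (ptL$h[order(ptL$target)] +
                              ptH$h[order(ptH$target)]) / 2)
  # multiples of k pass through unchanged
  smEx <- benchmarkSweep(co, n_test_grid = 48L, methods = "USC",
                         reference = "USC", usc_equal_share = TRUE)
  expect_equal(perTargetOutcomes(smEx)$h, ptL$h)
})

test_that("T_h>0 is non-decreasing in n_test for nested selections", {
  co <- generateCohort(8, generatorConfig(n_molecules = 800, seed = 4),
                       seed = 91)
  sm <- benchmarkSweep(co, n_test_grid = c(2, 5, 10, 20),
                       methods = c("USC", "prog1", "prog2"),
                       reference = "USC")
  su <- summaryTable(sm)
  for (m in unique(su$method)) {
    curve <- su$T_h_gt0[su$method == m][order(su$n_test[su$method == m])]
    expect_false(is.unsorted(curve))
  }
})

test_that("benchmark output files are reproducible and well-formed", {
  co <- generateCohort(2, generatorConfig(n_molecules = 400, seed = 6),
                       seed = 101)
  sm <- benchmarkSweep(co, n_test_grid = c(2, 4), methods = c("vSDC", "USC"),
                       reference = "vSDC")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  exportBenchmark(sm, d1)
  exportBenchmark(sm, d2)
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  got <- read.csv(file.path(d1, "summary.csv"))
  expect_setequal(names(got), c("method", "n_test", "T_h_gt0", "mean_Y_C",
                                "sem_Y_C", "delta_p"))
})
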