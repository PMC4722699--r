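test_that("standardization matches the closed form and its invariants", {
  st <- standardize(scoreTable(c("a", "b", "c"), c(-1, 0, 1), "higher_better"))
  expect_equal(st@zscores$z, c(-1, 0, 1), tolerance = 1e-6)  # sample SD = 1
  st4 <- standardize(scoreTable(letters[1:4], c(2, 4, 6, 8), "higher_better"))
  expect_equal(max(st4@zscores$z), (8 - 5) / sd(c(2, 4, 6, 8)),
               tolerance = 1e-9)

  lo <- standardize(scoreTable(c("a", "b", "c"), c(-1, 0, 1), "lower_better"))
  expect_equal(lo@zscores$z, -st@zscores$z, tolerance = 1e-12)

  # z has mean 0 and unit sample SD; recorded mean/SD are in score units
  set.seed(2)
  tab <- scoreTable(sprintf("m%04d", 1:500), rnorm(500, -8, 1.7), "lower_better")
  st <- standardize(tab)
  expect_equal(mean(st@zscores$z), 0, tolerance = 1e-9)
  expect_equal(sd(st@zscores$z), 1, tolerance = 1e-9)
  expect_equal(st@scoreSD, sd(as.data.frame(tab)$score), tolerance = 1e-12)

  expect_error(standardize(scoreTable(c("a", "b"), c(3, 3), "lower_better")),
               class = "vSDCDegenerateError")
})

test_that("the fraction beyond z >= 2 matches the normal tail", {
  set.seed(77)
  tab <- scoreTable(sprintf("m%05d", 1:10000), rnorm(10000), "higher_better")
  frac <- length(members(standoutSet(standardize(tab), 2))) / 10000
  expect_equal(frac, pnorm(2, lower.tail = FALSE), tolerance = 0.25)
})

test_that("stand-out sets equal the brute-force filter and nest in x", {
  for (seed in 1:5) {
    tab <- randomTables(500, k = 2, seed = seed)[[1]]
    st <- standardize(tab)
    prev <- NULL
    for (x in c(-1, 0, 1, 2, 3)) {
      got <- sort(members(standoutSet(st, x)))
      expect_identical(got, oracleStandout(tab, x))
      if (!is.null(prev)) expect_true(all(got %in% prev))  # nesting
      prev <- got
    }
    expect_length(members(standoutSet(st, 1e9)), 0L)
    expect_length(members(standoutSet(st, -1e9)), nMolecules(tab))
  }
})

test_that("ranking is dense, direction-aware and lexicographic on ties", {
  r <- rankMolecules(scoreTable(c("a", "b"), c(-9, -7), "lower_better"))
  expect_equal(r$rank[r$molecule_id == "a"], 1L)
  r2 <- rankMolecules(scoreTable(c("b", "a"), c(5, 5), "higher_better"))
  expect_identical(r2$molecule_id, c("a", "b"))

  set.seed(4)
  sc <- rnorm(1000)
  tab <- scoreTable(sprintf("m%04d", sample(1000)), sc, "higher_better")
  r3 <- rankMolecules(tab)
  df <- as.data.frame(tab)
  expect_identical(r3$molecule_id, df$molecule_id[order(-df$score)])
  expect_identical(r3$rank, seq_len(1000L))
})

test_that("topN equals the sort-based selection and checks its bounds", {
  set.seed(6)
  tab <- scoreTable(sprintf("m%03d", sample(40)), rnorm(40), "lower_better")
  sel <- topN(tab, 9)
  df <- as.data.frame(tab)
  expect_identical(members(sel), df$molecule_id[order(df$score)][1:9])
  expect_equal(nCM(topN(tab, 40)), 40L)
  expect_equal(nCM(topN(tab, 1)), 1L)
  expect_error(topN(tab, 0), class = "vSDCConfigError")
  expect_error(topN(tab, 41), class = "vSDCConfigError")
})

test_that("SDC reduces to the single-program stand-out set on identical tables", {
  tab <- randomTables(200, k = 2, seed = 3)[[1]]
  twin <- tab; twin@programName <- "copy"
  res <- sdc(list(tab, twin), x = 2)
  expect_setequal(members(res), members(standoutSet(standardize(tab), 2)))
  # members are ordered by decreasing summed z
  zs <- standardize(tab)@zscores
  z <- setNames(zs$z, zs$molecule_id)
  expect_false(is.unsorted(rev(z[members(res)])))
})

test_that("an empty stand-out set absorbs the SDC intersection", {
  tabs <- randomTables(100, k = 3, seed = 8)
  flat <- scoreTable(moleculeIds(tabs[[1]]),
                     seq_len(100) * 1e-3, "lower_better",
                     program_name = "flat")
  # flat's z max is ~1.7 < 5, so its stand-out set at x=5 is empty
  expect_equal(nCM(sdc(c(tabs, list(flat)), x = 5)), 0L)
})

test_that("vSDC handles the degenerate single-table mode and infeasibility", {
  tab <- randomTables(60, k = 2, seed = 12)[[1]]
  one <- vsdc(list(tab), n_test = 7)
  expect_identical(members(one), members(topN(tab, 7)))

  # more molecules requested than the programs share
  a <- makeRankedTable(c(u = 1), 30, "pA")
  b <- makeRankedTable(c(u = 1), 30, "pB")
  b@scores$molecule_id[2:30] <- sprintf("other%02d", 2:30)
  err <- tryCatch(suppressWarnings(vsdc(list(a, b), n_test = 5)),
                  vSDCInfeasibleError = function(e) e)
  expect_s3_class(err, "vSDCInfeasibleError")
  expect_equal(err$maxAchievable, 1L)  # only "u" is shared
})

test_that("vSDC equals a literal scan over the cutoff grid", {
  tabs <- randomTables(30, k = 3, seed = 21)
  got <- vsdc(tabs, n_test = 5, trim = FALSE)
  ora <- oracleVsdc(tabs, 5)
  expect_equal(xUsed(got), ora$x, tolerance = 1e-9)
  expect_identical(sort(members(got)), ora$ids)

  # trimming keeps the highest summed z and exactly n_test members
  trimmed <- vsdc(tabs, n_test = 5, trim = TRUE)
  expect_equal(nCM(trimmed), 5L)
  expect_true(all(members(trimmed) %in% members(got)))
})

test_that("every vSDC member is stand-out in every program at x_used", {
  for (seed in c(2, 13)) {
    tabs <- randomTables(150, k = 4, seed = seed)
    res <- vsdc(tabs, n_test = 8, trim = FALSE)
    for (tab in tabs) {
      z <- oracleZ(tab)
      expect_true(all(z[members(res)] >= xUsed(res)))
    }
  }
})

test_that("vSDC x_used is non-increasing in n_test and |SDC| non-increasing in x", {
  tabs <- randomTables(300, k = 3, seed = 31)
  xs <- vapply(c(1, 3, 6, 10, 20), function(n) xUsed(vsdc(tabs, n)),
               numeric(1))
  expect_false(is.unsorted(rev(xs)))
  sizes <- vapply(c(0.5, 1, 1.5, 2, 2.5), function(x) nCM(sdc(tabs, x)),
                  integer(1))
  expect_false(is.unsorted(rev(sizes)))
})

test_that("USC covers the boundary cases of its contract", {
  # 4 programs with fully disjoint top lists: 2 from each at n_test = 8
  tabs <- lapply(1:4, function(p) {
    ids <- c(sprintf("top%d_%d", p, 1:2), sprintf("fill%d_%d", p, 1:18))
    scoreTable(ids, seq_len(20), "lower_better",
               program_name = sprintf("prog%d", p))
  })
  # make the pooled library shared so ids exist everywhere except top slots
  res <- usc(tabs, 8)
  expect_equal(nCM(res), 8L)
  expect_setequal(members(res), unlist(lapply(1:4, function(p)
    sprintf("top%d_%d", p, 1:2))))

  # identical rankings: union collapses, top-up must refill to n_test
  tab <- randomTables(50, k = 2, seed = 14)[[1]]
  twin <- tab; twin@programName <- "copy"
  res2 <- usc(list(tab, twin), 10)
  expect_identical(sort(members(res2)), sort(members(topN(tab, 10))))

  expect_error(usc(tabs, 3), class = "vSDCConfigError")

  # |USC| = min(n_test, pooled library size)
  small <- lapply(1:2, function(p)
    scoreTable(letters[1:5], rnorm(5), "lower_better",
               program_name = sprintf("p%d", p)))
  set.seed(1)
  expect_equal(nCM(usc(small, 5)), 5L)
})

test_that("USC equals an independent re-simulation of the round-robin", {
  for (seed in c(7, 22, 35)) {
    tabs <- randomTables(40, k = 4, seed = seed)
    for (n in c(4, 7, 12))
      expect_identical(members(usc(tabs, n)), oracleUsc(tabs, n))
  }
})

test_that("Venn partitions count disjoint, identical and random sets exactly", {
  mk <- function(p, ids) new("StandoutSet", programName = p, x = 2,
                             cutoffC = 1, members = ids)
  disj <- vennPartition(list(mk("A", c("a1", "a2")), mk("B", c("b1"))))
  rc <- regionCounts(disj)
  expect_equal(unname(rc[c("A", "B", "A+B")]), c(2L, 1L, 0L))

  same <- vennPartition(list(mk("A", c("x", "y")), mk("B", c("x", "y"))))
  expect_equal(unname(regionCounts(same)[c("A", "B", "A+B")]), c(0L, 0L, 2L))

  # conservation: regions containing P sum to |standout(P)|
  set.seed(9)
  sets <- lapply(c("P1", "P2", "P3", "P4"), function(p)
    mk(p, sample(sprintf("m%03d", 1:120), sample(20:60, 1))))
  part <- vennPartition(sets)
  for (s in sets)
    expect_equal(regionTotal(part, programName(s)), length(members(s)))
  expect_equal(sum(regionCounts(part)),
               length(unique(unlist(lapply(sets, members)))))
})

test_that("consensus methods reduce to single-program selection on identical tables", {
  tab <- randomTables(100, k = 2, seed = 18)[[1]]
  copies <- lapply(1:3, function(i) { t <- tab
    t@programName <- sprintf("c%d", i); t })
  expect_setequal(members(sdc(copies, x = 2)),
                  members(standoutSet(standardize(tab), 2)))
  expect_identical(sort(members(vsdc(copies, 6))),
                   sort(members(topN(tab, 6))))
})
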