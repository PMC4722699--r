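#' @include metrics.R synthetic.R
NULL

#' Dilute the active density of a library
#'
#' Benchmark libraries are often generous with actives compared with a
#' genuinely new target, where active densities around 0.5 % are more
#' realistic. This operation removes randomly chosen actives — from the
#' labels AND from the library, so the density is exact on the
#' shrunken library — until the active fraction is at or below
#' `density`, keeping the retained count maximal. Already-dilute
#' libraries pass through unchanged; inactives are never touched.
#'
#' @param labels an [ActivityLabels] object.
#' @param density target maximal active fraction (default 0.005).
#' @param seed integer seed controlling which actives are removed.
#' @return A new [ActivityLabels]; at least one active is always
#'   retained (an error is raised if the density would force A = 0).
#' @export
diluteActives <- function(labels, density = 0.005, seed) {
  stopifnot(is(labels, "ActivityLabels"))
  if (missing(seed)) .configError("'seed' is required for reproducible dilution")
  if (density <= 0 || density >= 1)
    .configError("'density' must be strictly between 0 and 1")
  A <- length(labels@actives)
  nInactive <- length(labels@library) - A
  if (A == 0L || A / length(labels@library) <= density) return(labels)
  ## largest A' with A' / (nInactive + A') <= density
  keepA <- floor(density * nInactive / (1 - density))
  if (keepA < 1)
    .vsdcStop("vSDCConfigError",
              "diluting to %.3g %% would leave no active (library has only %d inactives)",
              100 * density, nInactive)
  kept <- .withSeed(seed, sample(labels@actives, keepA))
  removed <- setdiff(labels@actives, kept)
  activityLabels(library = setdiff(labels@library, removed),
                 actives = kept, target_name = labels@targetName)
}

#' Remove molecules from a score table
#'
#' Companion to [diluteActives()]: drops the diluted-away molecules
#' from a program's score table so the bundle stays consistent.
#'
#' @param table a [ScoreTable].
#' @param keep character vector of molecule ids to retain.
#' @return A [ScoreTable] restricted to `keep`.
#' @export
subsetScoreTable <- function(table, keep) {
  stopifnot(is(table, "ScoreTable"))
  sc <- table@scores
  sel <- sc$molecule_id %in% keep |
    (!is.na(sc$parent_id) & sc$parent_id %in% keep)
  out <- sc[sel, ]
  rownames(out) <- NULL
  new("ScoreTable", programName = table@programName,
      targetName = table@targetName, direction = table@direction,
      scores = out)
}

#' Dilute a whole target bundle
#'
#' Applies [diluteActives()] to the bundle's labels and removes the
#' eliminated actives from every program's score table.
#'
#' @param bundle a [TargetBundle].
#' @param density target maximal active fraction.
#' @param seed integer seed.
#' @return A diluted [TargetBundle].
#' @export
diluteBundle <- function(bundle, density = 0.005, seed) {
  stopifnot(is(bundle, "TargetBundle"))
  lab <- diluteActives(bundle@labels, density, seed)
  new("TargetBundle", targetName = bundle@targetName,
      tables = lapply(bundle@tables, subsetScoreTable, keep = lab@library),
      labels = lab)
}

.METHOD_TOKENS <- c("vSDC", "USC", "SDC")

## one zeroed outcome row (used when vSDC is infeasible or nCM = 0)
.zeroOutcome <- function(target, method, n_test, A, infeasible = FALSE) {
  data.frame(target = target, method = method, n_test = as.integer(n_test),
             n_selected = 0L, h = 0, A = as.integer(A), Y = 0, E = 0,
             Y_C = 0, x_used = NA_real_, infeasible = infeasible,
             stringsAsFactors = FALSE)
}

.outcomeRow <- function(target, method, n_test, sel, labels, x_used = NA_real_) {
  n_sel <- nCM(sel)
  if (n_sel == 0L) return(.zeroOutcome(target, method, n_test,
                                       length(labels@actives)))
  hc <- countHits(sel, labels)
  m <- correctedYield(data.frame(n_test = n_sel, h = hc$h, A = hc$A))
  data.frame(target = target, method = method, n_test = as.integer(n_test),
             n_selected = n_sel, h = as.numeric(hc$h), A = hc$A, Y = m$Y,
             E = m$E, Y_C = m$Y_C, x_used = x_used, infeasible = FALSE,
             stringsAsFactors = FALSE)
}

#' Run a panel of selection methods on one target
#'
#' Evaluates the requested methods on one target bundle at a given
#' `n_test` and counts hits. Recognised method tokens are `"vSDC"`,
#' `"USC"`, `"SDC"` (fixed cutoff `sdc_x`, its own nCM as selection
#' size) and any program name of the bundle (that program's top-n
#' baseline). In SDC-comparison mode the single-program baselines are
#' evaluated at the target's own nCM instead of `n_test` — the
#' head-to-head protocol in which each program gets exactly as many
#' picks as the fixed-cutoff consensus produced.
#'
#' A vSDC infeasibility (the programs share fewer molecules than
#' `n_test`) is recorded as a flagged zero-hit outcome rather than
#' aborting a cohort run; likewise USC at `n_test` below the number of
#' programs, where the union construction is undefined.
#'
#' @param bundle a [TargetBundle].
#' @param n_test number of molecules to select.
#' @param methods character vector of method tokens; default: vSDC,
#'   USC, and every program's top-n baseline.
#' @param sdc_x fixed cutoff multiplier for `"SDC"` (default 2).
#' @param sdc_comparison evaluate single-program baselines at the SDC
#'   nCM instead of `n_test`.
#' @param trim passed to [vsdc()].
#' @return data.frame with one row per method: `target`, `method`,
#'   `n_test` (requested), `n_selected`, `h`, `A`, `Y`, `E`, `Y_C`,
#'   `x_used`, `infeasible`.
#' @export
runMethods <- function(bundle, n_test, methods = NULL, sdc_x = 2.0,
                       sdc_comparison = FALSE, trim = TRUE) {
  stopifnot(is(bundle, "TargetBundle"))
  progs <- vapply(bundle@tables, programName, character(1))
  if (is.null(methods)) methods <- c("vSDC", "USC", progs)
  unknown <- setdiff(methods, c(.METHOD_TOKENS, progs))
  if (length(unknown))
    .configError("unknown method(s): %s", paste(unknown, collapse = ", "))
  labels <- bundle@labels
  tgt <- bundle@targetName
  ## warn once per bundle about ids not scored by all programs
  idSets <- lapply(bundle@tables, moleculeIds)
  nMissing <- length(unique(unlist(idSets))) -
    length(Reduce(intersect, idSets))
  if (nMissing > 0)
    warning(sprintf("%s: %d molecule id(s) not shared by all programs",
                    tgt, nMissing), call. = FALSE)
  sdcRes <- NULL
  if ("SDC" %in% methods || sdc_comparison)
    sdcRes <- suppressWarnings(sdc(bundle@tables, x = sdc_x))
  rows <- lapply(methods, function(mth) {
    if (mth == "vSDC") {
      res <- tryCatch(suppressWarnings(
        vsdc(bundle@tables, n_test = n_test, trim = trim)),
        vSDCInfeasibleError = function(e) NULL)
      if (is.null(res))
        .zeroOutcome(tgt, mth, n_test, length(labels@actives),
                     infeasible = TRUE)
      else .outcomeRow(tgt, mth, n_test, res, labels, x_used = xUsed(res))
    } else if (mth == "USC") {
      ## below one molecule per program USC is undefined; inside a
      ## sweep that is recorded, not raised
      if (n_test < length(progs))
        .zeroOutcome(tgt, mth, n_test, length(labels@actives),
                     infeasible = TRUE)
      else .outcomeRow(tgt, mth, n_test, usc(bundle@tables, n_test), labels)
    } else if (mth == "SDC") {
      .outcomeRow(tgt, mth, nCM(sdcRes), sdcRes, labels,
                  x_used = xUsed(sdcRes))
    } else {
      tab <- bundle@tables[[match(mth, progs)]]
      n <- if (sdc_comparison) nCM(sdcRes) else n_test
      nAvail <- nrow(collapseVariants(tab)@scores)
      if (n == 0L) .zeroOutcome(tgt, mth, 0L, length(labels@actives))
      else .outcomeRow(tgt, mth, n, topN(tab, min(n, nAvail)), labels)
    }
  })
  do.call(rbind, rows)
}

## USC outcomes honouring the multiple-of-k convention: evaluate at the
## flanking multiples of k and average the per-target results.
.uscEqualShareOutcome <- function(bundle, n_test, k) {
  lo <- max(k, (n_test %/% k) * k)
  hi <- as.integer(ceiling(n_test / k) * k)
  o1 <- runMethods(bundle, lo, methods = "USC")
  if (hi == lo) {
    o1$n_test <- as.integer(n_test)
    return(o1)
  }
  o2 <- runMethods(bundle, hi, methods = "USC")
  out <- o1
  out$n_test <- as.integer(n_test)
  out$n_selected <- as.integer(round((o1$n_selected + o2$n_selected) / 2))
  for (cl in c("h", "Y", "E", "Y_C")) out[[cl]] <- (o1[[cl]] + o2[[cl]]) / 2
  out
}

#' Sweep selection methods over a cohort and an n_test grid
#'
#' The multi-target evaluation protocol: every method is run on every
#' target at every value of the `n_test` grid, and the per-target
#' outcomes are aggregated into the three cohort criteria —
#' `T_h>0` (fraction of targets with at least one hit), the unweighted
#' mean corrected yield `<Y_C>` with its standard error of the mean,
#' and `delta_p`, the net balance of targets of the reference method
#' over each other method (ties excluded from both tallies; positive
#' values favour the reference).
#'
#' With `usc_equal_share = TRUE`, USC is evaluated at the multiples of
#' k flanking each requested `n_test` and the flanking results are
#' averaged (e.g. the mean of n_test 48 and 52 stands for n_test 50
#' with four programs), honouring USC's requirement of an equal
#' per-program share; by default the round-robin top-up generalisation
#' evaluates USC at the exact `n_test`.
#'
#' @param bundles list of [TargetBundle] objects.
#' @param n_test_grid integer grid (default `1:50`).
#' @param methods method tokens as in [runMethods()]; default vSDC,
#'   USC and each program's top-n baseline.
#' @param reference method whose hit counts anchor the `delta_p`
#'   curves (default `"vSDC"`; it must be among `methods`).
#' @param usc_equal_share average USC over the flanking multiples of k.
#' @param sdc_x,trim passed through to [runMethods()].
#' @return A [BenchmarkSummary].
#' @export
benchmarkSweep <- function(bundles, n_test_grid = 1:50, methods = NULL,
                           reference = "vSDC", usc_equal_share = FALSE,
                           sdc_x = 2.0, trim = TRUE) {
  if (!length(bundles)) .configError("no target bundles given")
  if (!length(n_test_grid)) .configError("empty n_test grid")
  n_test_grid <- as.integer(n_test_grid)
  progs <- vapply(bundles[[1]]@tables, programName, character(1))
  k <- length(progs)
  if (is.null(methods)) methods <- c("vSDC", "USC", progs)
  if (!reference %in% methods)
    .configError("reference method '%s' is not among the evaluated methods",
                 reference)
  perTarget <- vector("list", length(bundles) * length(n_test_grid))
  i <- 0L
  for (b in bundles) {
    for (n in n_test_grid) {
      i <- i + 1L
      base <- setdiff(methods, if (usc_equal_share) "USC" else character())
      rows <- runMethods(b, n, methods = base, sdc_x = sdc_x, trim = trim)
      if (usc_equal_share && "USC" %in% methods)
        rows <- rbind(rows, .uscEqualShareOutcome(b, n, k))
      perTarget[[i]] <- rows
    }
  }
  perTarget <- do.call(rbind, perTarget)
  sumRows <- list()
  for (n in n_test_grid) {
    ref <- perTarget[perTarget$method == reference &
                       perTarget$n_test == n, ]
    for (mth in methods) {
      o <- perTarget[perTarget$method == mth & perTarget$n_test == n, ]
      ## positive delta_p favours the reference over this method, the
      ## convention of reference-vs-program comparison curves
      dp <- if (mth == reference) 0 else netBalance(ref, o)$delta_p
      sumRows[[length(sumRows) + 1L]] <- data.frame(
        method = mth, n_test = n,
        T_h_gt0 = mean(o$h > 0),
        mean_Y_C = mean(o$Y_C),
        sem_Y_C = stats::sd(o$Y_C) / sqrt(nrow(o)),
        delta_p = dp, stringsAsFactors = FALSE)
    }
  }
  new("BenchmarkSummary", methods = methods, reference = reference,
      nTestGrid = n_test_grid, summary = do.call(rbind, sumRows),
      perTarget = perTarget)
}

#' Write benchmark results as tidy CSV files
#'
#' @param summary a [BenchmarkSummary].
#' @param dir output directory (created if missing); writes
#'   `summary.csv` (cohort curves) and `per_target.csv` (per-target
#'   outcomes, including the per-target `x_used` of vSDC).
#' @return Invisibly, the paths written.
#' @export
exportBenchmark <- function(summary, dir) {
  stopifnot(is(summary, "BenchmarkSummary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("summary.csv", "per_target.csv"))
  fmt <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    df
  }
  utils::write.csv(fmt(summary@summary), paths[1], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fmt(summary@perTarget), paths[2], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
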