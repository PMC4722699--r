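#' @include AllGenerics.R scoreTable.R
NULL

## goodness: larger is always better, whatever the program reports
.goodness <- function(score, direction) {
  if (direction == "higher_better") score else -score
}

#' Standardize a score table to goodness z-scores
#'
#' Expresses every molecule's score as a z-score relative to the
#' program's own score distribution over the full library:
#' `z = s * (score - mean) / SD`, with `s = +1` for fitness-like
#' (higher-is-better) scores and `s = -1` for free-energy-like
#' (lower-is-better) scores, so larger z always means a better-scored
#' molecule. The SD is the sample standard deviation (n - 1
#' denominator). Structure variants are collapsed onto unique compounds
#' first (a no-op when no parent ids are present), since the consensus
#' cutoffs of the SDC family are defined on the unique-compound
#' distribution.
#'
#' @param table a [ScoreTable] with at least 2 entries and non-constant
#'   scores.
#' @param ... unused.
#' @return A [StandardizedTable]; its recorded mean and SD are in the
#'   original score units.
#' @examples
#' standardize(scoreTable(c("a", "b", "c"), c(-1, 0, 1), "higher_better"))
#' @export
setMethod("standardize", "ScoreTable", function(table, ...) {
  tab <- collapseVariants(table)
  sc <- tab@scores
  if (nrow(sc) < 2L)
    .degenerateError("program '%s' scored fewer than 2 unique compounds: the standard deviation is undefined",
                     tab@programName)
  m <- mean(sc$score)
  s <- stats::sd(sc$score)
  if (!is.finite(s) || s == 0)
    .degenerateError("all scores of program '%s' are identical: the score distribution is degenerate (SD = 0)",
                     tab@programName)
  sign <- if (tab@direction == "higher_better") 1 else -1
  new("StandardizedTable", programName = tab@programName,
      zscores = data.frame(molecule_id = sc$molecule_id,
                           z = sign * (sc$score - m) / s,
                           stringsAsFactors = FALSE),
      scoreMean = m, scoreSD = s, direction = tab@direction)
})

#' Extract the stand-out set at a cutoff of x standard deviations
#'
#' The stand-out molecules of a program are those whose standardized
#' goodness is at or beyond `x` standard deviations above the library
#' mean (`z >= x`, boundary inclusive). These are the molecules the
#' program singles out as candidate actives; at `x = 2` they are the
#' compounds beyond the `2 * SD` cutoff on the rank curve.
#'
#' @param std_table a [StandardizedTable].
#' @param x finite standard-deviation multiplier.
#' @return A [StandoutSet]; `cutoffC` is `x * SD` in original score
#'   units.
#' @export
standoutSet <- function(std_table, x) {
  stopifnot(is(std_table, "StandardizedTable"))
  if (length(x) != 1L || !is.finite(x))
    .configError("'x' must be a single finite number")
  zs <- std_table@zscores
  new("StandoutSet", programName = std_table@programName, x = x,
      cutoffC = x * std_table@scoreSD,
      members = zs$molecule_id[zs$z >= x])
}

#' Rank the molecules of a score table
#'
#' Dense 1-based ranks over unique compounds: rank 1 is the
#' best-scoring molecule under the table's direction; equal scores are
#' broken lexicographically by molecule id, so ranks are a permutation
#' of `1..N` and the ranking is deterministic.
#'
#' @param table a [ScoreTable] (variants are collapsed first).
#' @return data.frame with columns `molecule_id` and `rank`, ordered by
#'   rank.
#' @export
rankMolecules <- function(table) {
  tab <- collapseVariants(table)
  sc <- tab@scores
  g <- .goodness(sc$score, tab@direction)
  ord <- order(-g, sc$molecule_id)
  data.frame(molecule_id = sc$molecule_id[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

## standardize + cache ranks and named z vectors for a list of tables
.prepareTables <- function(tables, caller) {
  if (!is.list(tables) || !all(vapply(tables, is, logical(1), "ScoreTable")))
    .configError("%s expects a list of ScoreTable objects", caller)
  progs <- vapply(tables, function(t) t@programName, character(1))
  if (anyDuplicated(progs))
    .configError("program names must be unique (got duplicated %s)",
                 sQuote(progs[duplicated(progs)][1]))
  std <- lapply(tables, standardize)
  zvecs <- lapply(std, function(s) {
    z <- s@zscores$z
    names(z) <- s@zscores$molecule_id
    z
  })
  ranks <- lapply(tables, function(t) {
    r <- rankMolecules(t)
    setNames(r$rank, r$molecule_id)
  })
  allIds <- unique(unlist(lapply(zvecs, names)))
  common <- Reduce(intersect, lapply(zvecs, names))
  nMissing <- length(allIds) - length(common)
  if (nMissing > 0)
    warning(sprintf(paste0("%d molecule id(s) are not shared by all %d ",
                           "programs; they can never be consensus members"),
                    nMissing, length(tables)), call. = FALSE)
  list(std = std, zvecs = zvecs, ranks = ranks, progs = progs,
       common = common)
}

## per-member provenance table: z and rank per program
.detailsFor <- function(ids, prep) {
  det <- data.frame(molecule_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(prep$progs)) {
    det[[paste0("z_", prep$progs[i])]] <- unname(prep$zvecs[[i]][ids])
    det[[paste0("rank_", prep$progs[i])]] <- unname(prep$ranks[[i]][ids])
  }
  det
}

## sum of z over programs for ids present in all programs
.zSum <- function(ids, prep) {
  Reduce(`+`, lapply(prep$zvecs, function(z) unname(z[ids])))
}

## order ids by decreasing summed z, ties lexicographic by id
.orderBySummedZ <- function(ids, prep) {
  ids[order(-.zSum(ids, prep), ids)]
}

.consensusResult <- function(method, ids, prep, xUsed = NA_real_,
                             trimmed = FALSE, cutoffs = numeric()) {
  new("ConsensusResult", method = method, members = ids,
      nCM = length(ids), xUsed = xUsed, perProgramCutoffs = cutoffs,
      trimmed = trimmed, details = .detailsFor(ids, prep))
}

.cutoffsAt <- function(prep, x) {
  setNames(vapply(prep$std, function(s) x * s@scoreSD, numeric(1)),
           prep$progs)
}

#' SDC: standard-deviation consensus at a fixed cutoff
#'
#' The consensus molecules (CM) at a fixed standard-deviation
#' multiplier `x` are the molecules that are stand-out (`z >= x`) in
#' EVERY program, i.e. the intersection of the k stand-out sets. With
#' the default `x = 2` this is the `2 * SD` cutoff read off the rank
#' curves; the number of consensus molecules (nCM) then varies from
#' target to target. Members are ordered by decreasing sum of
#' standardized scores across programs (ties broken lexicographically).
#'
#' Molecules absent from any one program's table are treated as not
#' stand-out for that program and can never be consensus members; a
#' warning reports how many ids are not shared by all tables.
#'
#' @param tables list of at least 2 [ScoreTable] objects with
#'   comparable molecule ids.
#' @param x standard-deviation multiplier (default 2).
#' @return A [ConsensusResult] with `method = "SDC"`.
#' @seealso [vsdc()] for the fixed-nCM variant, [usc()] for the union
#'   construction.
#' @export
sdc <- function(tables, x = 2.0) {
  prep <- .prepareTables(tables, "sdc")
  if (length(tables) < 2L)
    .configError("sdc needs at least 2 score tables")
  sets <- lapply(prep$std, standoutSet, x = x)
  ids <- Reduce(intersect, lapply(sets, members))
  .consensusResult("SDC", .orderBySummedZ(ids, prep), prep, xUsed = x,
                   cutoffs = .cutoffsAt(prep, x))
}

#' vSDC: variable standard-deviation consensus at a fixed nCM
#'
#' Where SDC fixes the cutoff and lets the number of consensus
#' molecules vary, vSDC fixes the number of molecules to test
#' (`n_test`) and searches for the cutoff: starting from `x = 3.5` the
#' multiplier is lowered in steps of 0.001 until the intersection of
#' the k stand-out sets holds at least `n_test` molecules. Because the
#' intersection grows in jumps, the scan can overshoot; by default the
#' overshooting set is trimmed to exactly `n_test` members by keeping
#' those with the highest summed z across programs (ties broken
#' lexicographically). `trim = FALSE` exposes the raw intersection at
#' the selected cutoff.
#'
#' With a single table the method degenerates to the top-`n_test`
#' molecules of that program.
#'
#' @param tables list of [ScoreTable] objects.
#' @param n_test required number of consensus molecules (>= 1).
#' @param x_start top of the scanned multiplier grid (default 3.5).
#' @param x_step scan step (default 0.001).
#' @param trim trim an overshooting intersection to exactly `n_test`
#'   members (default `TRUE`).
#' @param x_min floor of the scan; if the grid is exhausted before the
#'   intersection reaches `n_test`, an infeasibility error reports the
#'   maximum achievable nCM (only molecules scored by ALL programs can
#'   ever be consensus members).
#' @return A [ConsensusResult] with `method = "vSDC"`, the selected
#'   multiplier in `xUsed` and the per-program cutoffs `x * SD` in
#'   score units.
#' @export
vsdc <- function(tables, n_test, x_start = 3.5, x_step = 0.001,
                 trim = TRUE, x_min = -10.0) {
  if (length(n_test) != 1L || is.na(n_test) || n_test < 1)
    .configError("'n_test' must be a single integer >= 1")
  n_test <- as.integer(n_test)
  if (x_step <= 0) .configError("'x_step' must be positive")
  prep <- .prepareTables(tables, "vsdc")
  common <- prep$common
  ## a molecule is in the intersection at cutoff x iff its worst
  ## per-program z is still >= x
  minz <- Reduce(pmin, lapply(prep$zvecs, function(z) unname(z[common])))
  names(minz) <- common
  nGrid <- floor((x_start - x_min) / x_step + 1e-9)
  xLast <- x_start - nGrid * x_step
  if (length(common) < n_test || sum(minz >= xLast) < n_test) {
    maxA <- if (length(common)) sum(minz >= xLast) else 0L
    .infeasibleError(as.integer(maxA),
                     paste0("vSDC cannot reach n_test = %d: at the cutoff floor ",
                            "x = %.3f only %d molecules are common to all %d ",
                            "programs' stand-out sets"),
                     n_test, xLast, maxA, length(tables))
  }
  ## largest grid value x_start - k * x_step at which the intersection
  ## holds >= n_test molecules, i.e. the first grid point at or below
  ## the n_test-th largest worst-program z
  thr <- sort(minz, decreasing = TRUE)[n_test]
  k <- max(0, ceiling((x_start - thr) / x_step - 1e-9))
  xUsed <- x_start - k * x_step
  while (sum(minz >= xUsed) < n_test) {       # guard against FP edge cases
    k <- k + 1L
    xUsed <- x_start - k * x_step
  }
  ids <- names(minz)[minz >= xUsed]
  ids <- .orderBySummedZ(ids, prep)
  trimmed <- FALSE
  if (trim && length(ids) > n_test) {
    ids <- ids[seq_len(n_test)]
    trimmed <- TRUE
  }
  .consensusResult("vSDC", ids, prep, xUsed = xUsed, trimmed = trimmed,
                   cutoffs = .cutoffsAt(prep, xUsed))
}

#' USC: united subset consensus
#'
#' Rather than intersecting stand-out sets, USC pools each program's
#' short top list: the top `floor(n_test / k)` ranked molecules of each
#' of the k programs are gathered, and while the union holds fewer than
#' `n_test` molecules it is topped up round-robin over the programs in
#' input order, each contributing its next-best not-yet-selected
#' molecule. The result has exactly `n_test` members unless the pooled
#' library itself is smaller. Members are ordered program by program by
#' rank, then in top-up order.
#'
#' @param tables list of [ScoreTable] objects.
#' @param n_test number of molecules to select; must be at least the
#'   number of programs so every program contributes.
#' @return A [ConsensusResult] with `method = "USC"`.
#' @export
usc <- function(tables, n_test) {
  prep <- suppressWarnings(.prepareTables(tables, "usc"))
  k <- length(tables)
  if (length(n_test) != 1L || is.na(n_test) || n_test < k)
    .configError("USC needs n_test >= the number of programs (%d) so that every program contributes at least one molecule",
                 k)
  n_test <- as.integer(n_test)
  rankedIds <- lapply(tables, function(t) rankMolecules(t)$molecule_id)
  m <- n_test %/% k
  selected <- character()
  for (p in seq_len(k))
    selected <- c(selected,
                  setdiff(utils::head(rankedIds[[p]], m), selected))
  pooled <- unique(unlist(rankedIds))
  ptr <- rep(m + 1L, k)
  while (length(selected) < min(n_test, length(pooled))) {
    for (p in seq_len(k)) {
      if (length(selected) >= n_test) break
      ids <- rankedIds[[p]]
      while (ptr[p] <= length(ids) && ids[ptr[p]] %in% selected)
        ptr[p] <- ptr[p] + 1L
      if (ptr[p] <= length(ids)) {
        selected <- c(selected, ids[ptr[p]])
        ptr[p] <- ptr[p] + 1L
      }
    }
  }
  .consensusResult("USC", selected, prep)
}

#' Top-n selection from a single program (baseline)
#'
#' The single-program baseline the consensus methods are compared
#' against: the first `n` molecules of the program's ranking.
#'
#' @param table a [ScoreTable].
#' @param n number of molecules, `1 <= n <=` library size.
#' @return A [ConsensusResult] with `method = "top_n_single"`.
#' @export
topN <- function(table, n) {
  prep <- .prepareTables(list(table), "topN")
  sz <- length(prep$zvecs[[1]])
  if (length(n) != 1L || is.na(n) || n < 1 || n > sz)
    .configError("'n' must lie between 1 and the library size (%d)", sz)
  ids <- utils::head(rankMolecules(table)$molecule_id, as.integer(n))
  .consensusResult("top_n_single", ids, prep)
}

#' Exact Venn partition of k stand-out sets
#'
#' Counts, for every non-empty subset of programs (2^k - 1 regions),
#' the molecules that are stand-out in exactly that subset. Summing the
#' counts of all regions containing a given program recovers the size
#' of that program's stand-out set.
#'
#' @param standout_sets list of at least 2 [StandoutSet] objects.
#' @return A [VennPartition]; region names are `'+'`-joined program
#'   names in input order.
#' @export
vennPartition <- function(standout_sets) {
  if (!is.list(standout_sets) || length(standout_sets) < 2L ||
      !all(vapply(standout_sets, is, logical(1), "StandoutSet")))
    .configError("vennPartition needs a list of at least 2 StandoutSet objects")
  progs <- vapply(standout_sets, programName, character(1))
  if (anyDuplicated(progs))
    .configError("program names must be unique")
  k <- length(progs)
  ids <- unique(unlist(lapply(standout_sets, members)))
  memb <- vapply(standout_sets, function(s) ids %in% members(s),
                 logical(length(ids)))
  if (length(ids) == 1L) memb <- matrix(memb, nrow = 1L)
  ## region key of each molecule: bitmask over programs
  mask <- if (length(ids)) as.integer(memb %*% 2^(seq_len(k) - 1)) else integer()
  allMasks <- seq_len(2^k - 1L)
  labels <- vapply(allMasks, function(m)
    paste(progs[bitwAnd(m, 2^(seq_len(k) - 1)) > 0], collapse = "+"),
    character(1))
  counts <- as.integer(tabulate(match(mask, allMasks), nbins = length(allMasks)))
  names(counts) <- labels
  new("VennPartition", programs = progs, regionCounts = counts)
}

#' Aggregate Venn regions covering a set of programs
#'
#' Total number of molecules common to all the named programs (i.e. the
#' size of the plain intersection of their stand-out sets), obtained by
#' summing every Venn region whose program subset contains all of them
#' — e.g. the pairwise total of two programs adds their exclusive
#' pairwise region and all higher-order regions containing both.
#'
#' @param partition a [VennPartition].
#' @param programs character vector of program names to cover.
#' @return Integer count.
#' @export
regionTotal <- function(partition, programs) {
  stopifnot(is(partition, "VennPartition"))
  if (!all(programs %in% partition@programs))
    .configError("unknown program(s): %s",
                 paste(setdiff(programs, partition@programs), collapse = ", "))
  covered <- vapply(names(partition@regionCounts), function(lab) {
    all(programs %in% strsplit(lab, "+", fixed = TRUE)[[1]])
  }, logical(1))
  sum(partition@regionCounts[covered])
}

#' Export a Venn partition as a data.frame
#'
#' @param x a [VennPartition].
#' @param ... unused.
#' @return data.frame with columns `region` and `count`.
#' @export
setMethod("as.data.frame", "VennPartition", function(x, ...) {
  data.frame(region = names(x@regionCounts),
             count = unname(x@regionCounts), stringsAsFactors = FALSE)
})
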