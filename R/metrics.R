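#' @include consensus.R
NULL

#' Count the hits in a selection
#'
#' A hit is an active molecule retrieved within the tested selection.
#' Given a consensus (or top-n) selection and the target's activity
#' annotation, returns the selection outcome used by all downstream
#' metrics.
#'
#' @param selection a [ConsensusResult], or a character vector of
#'   molecule ids.
#' @param labels an [ActivityLabels] object whose library covers every
#'   selected id.
#' @param n_test the number of molecules the selection stands for;
#'   defaults to the selection size (it differs only when an
#'   infeasible selection is recorded against its requested size).
#' @return A one-row data.frame with columns `target`, `n_test`, `h`
#'   (hits) and `A` (actives in the library).
#' @export
countHits <- function(selection, labels, n_test = NULL) {
  stopifnot(is(labels, "ActivityLabels"))
  ids <- if (is(selection, "ConsensusResult")) members(selection)
         else as.character(selection)
  unknown <- setdiff(ids, labels@library)
  if (length(unknown))
    .validationError("selected molecule id(s) not in the library: %s%s",
                     paste(utils::head(unknown, 5), collapse = ", "),
                     if (length(unknown) > 5) ", ..." else "")
  if (is.null(n_test)) n_test <- length(ids)
  data.frame(target = labels@targetName, n_test = as.integer(n_test),
             h = as.integer(sum(ids %in% labels@actives)),
             A = length(labels@actives), stringsAsFactors = FALSE)
}

#' Yield of actives, docking enrichment and corrected yield
#'
#' For a selection of `n_test` molecules containing `h` hits from a
#' library with `A` actives:
#' * the yield of actives `Y = h / n_test` — the probability that a
#'   tested molecule is active;
#' * the docking enrichment `E = h / A` — the fraction of all actives
#'   retrieved;
#' * the corrected yield `Y_C = h / min(A, n_test)` — the fraction of
#'   FINDABLE hits found, which equals `Y` when fewer molecules are
#'   tested than there are actives and `E` otherwise. `Y` alone
#'   under-reads a method when `n_test > A` and `E` alone under-reads
#'   it when `n_test < A`; `Y_C` is the one comparable across targets
#'   at equal active density.
#'
#' @param outcome a one-row data.frame (or list) with fields `n_test`,
#'   `h`, `A`, as returned by [countHits()].
#' @return A one-row data.frame with columns `Y`, `E`, `Y_C`.
#' @examples
#' correctedYield(data.frame(n_test = 5, h = 5, A = 100))   # Y = Y_C = 1
#' correctedYield(data.frame(n_test = 50, h = 5, A = 5))    # E = Y_C = 1
#' @export
correctedYield <- function(outcome) {
  n_test <- outcome$n_test; h <- outcome$h; A <- outcome$A
  if (is.null(n_test) || is.null(h) || is.null(A))
    .configError("outcome needs fields n_test, h and A")
  if (length(n_test) != 1L || n_test < 1)
    .configError("'n_test' must be a single integer >= 1")
  if (h < 0 || h > min(n_test, max(A, 0)))
    .validationError("h = %d is impossible with n_test = %d and A = %d",
                     h, n_test, A)
  if (A == 0)
    .metricError("no actives in the library (A = 0): the docking enrichment and corrected yield are undefined")
  data.frame(Y = h / n_test, E = h / A, Y_C = h / min(A, n_test))
}

#' Fraction of targets with at least one hit
#'
#' Cohort-level success measure: the fraction `T_h>0 = n_p^(h>0) / N_p`
#' of protein targets for which the method retrieved at least one hit.
#'
#' @param outcomes data.frame of per-target outcomes (one row per
#'   target, columns `target` and `h`), e.g. stacked [countHits()]
#'   rows.
#' @return list with `n_p_with_hits`, `N_p` and `T_h_gt0`.
#' @export
targetsWithHits <- function(outcomes) {
  if (NROW(outcomes) == 0L)
    .configError("no outcomes given")
  if (anyDuplicated(outcomes$target))
    .validationError("one outcome per target expected (duplicated target)")
  n <- sum(outcomes$h > 0)
  list(n_p_with_hits = as.integer(n), N_p = nrow(outcomes),
       T_h_gt0 = n / nrow(outcomes))
}

#' Net balance of targets between two methods
#'
#' Direct per-target comparison of two methods at equal `n_test`:
#' counts the targets where the method finds strictly more hits than
#' the reference and vice versa, and reports the net balance
#' `delta_p = (n_method_gt - n_ref_gt) / N_p`. Targets where both find
#' the same number of hits count in neither tally (but stay in `N_p`).
#'
#' @param outcomes_method,outcomes_ref data.frames of per-target
#'   outcomes over the SAME targets (columns `target`, `h`).
#' @return list with `n_p_method_gt`, `n_p_ref_gt`, `N_p`, `delta_p`.
#' @export
netBalance <- function(outcomes_method, outcomes_ref) {
  if (NROW(outcomes_method) != NROW(outcomes_ref) ||
      !setequal(outcomes_method$target, outcomes_ref$target) ||
      anyDuplicated(outcomes_method$target))
    .validationError("the two outcome lists must cover the same targets exactly once")
  hm <- outcomes_method$h[order(outcomes_method$target)]
  hr <- outcomes_ref$h[order(outcomes_ref$target)]
  Np <- length(hm)
  list(n_p_method_gt = as.integer(sum(hm > hr)),
       n_p_ref_gt = as.integer(sum(hr > hm)),
       N_p = Np,
       delta_p = (sum(hm > hr) - sum(hr > hm)) / Np)
}

#' Spearman rank correlation between two programs' rankings
#'
#' Measures how much two docking programs agree on one target: both
#' score lists are restricted to their common molecules,
#' direction-normalized so that better always means a lower rank, and
#' correlated with Spearman's rho (average ranks on ties). Between
#' independent docking programs this is typically low (|rho| of a few
#' percent up to ~0.3) — the divergence that motivates consensus
#' selection.
#'
#' @param tableA,tableB [ScoreTable] objects sharing at least 3
#'   molecule ids.
#' @return Spearman's rho, with the absolute value attached as
#'   attribute `"abs"`.
#' @export
rankCorrelation <- function(tableA, tableB) {
  ta <- collapseVariants(tableA); tb <- collapseVariants(tableB)
  common <- intersect(ta@scores$molecule_id, tb@scores$molecule_id)
  if (length(common) < 3L)
    .validationError("need at least 3 common molecules (got %d)",
                     length(common))
  ga <- .goodness(ta@scores$score[match(common, ta@scores$molecule_id)],
                  ta@direction)
  gb <- .goodness(tb@scores$score[match(common, tb@scores$molecule_id)],
                  tb@direction)
  ## correlate "badness" so that better = lower rank on both sides
  rho <- stats::cor(-ga, -gb, method = "spearman")
  structure(rho, abs = abs(rho))
}

#' Pairwise Spearman correlation matrix over programs
#'
#' @param tables list of [ScoreTable] objects.
#' @param absolute return |rho| (the usual reporting convention for
#'   program-divergence plots) instead of signed rho.
#' @return symmetric matrix of correlations with program names on the
#'   dimnames.
#' @export
rankCorrelationMatrix <- function(tables, absolute = FALSE) {
  k <- length(tables)
  if (k < 2L) .configError("need at least 2 tables")
  progs <- vapply(tables, programName, character(1))
  m <- diag(1, k)
  dimnames(m) <- list(progs, progs)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    r <- as.numeric(rankCorrelation(tables[[i]], tables[[j]]))
    m[i, j] <- m[j, i] <- if (absolute) abs(r) else r
  }
  m
}

#' Docking enrichment curve
#'
#' Cumulative docking enrichment `E = h / A` of one program as a
#' function of the fraction of the ranked library screened, evaluated
#' on a regular grid of fractions. The curve is monotone non-decreasing
#' and reaches 1 at fraction 1; a program ranking actives no better
#' than chance tracks the diagonal.
#'
#' @param table a [ScoreTable].
#' @param labels [ActivityLabels] with at least one active.
#' @param points number of grid points (default 100).
#' @return data.frame with columns `fraction_screened` and `E`.
#' @export
enrichmentCurve <- function(table, labels, points = 100L) {
  stopifnot(is(labels, "ActivityLabels"))
  A <- length(labels@actives)
  if (A < 1L)
    .metricError("no actives in the library (A = 0): the enrichment curve is undefined")
  if (points < 1L) .configError("'points' must be >= 1")
  ranked <- rankMolecules(table)$molecule_id
  N <- length(ranked)
  cumHits <- cumsum(ranked %in% labels@actives)
  frac <- seq_len(points) / points
  nSel <- pmin(N, ceiling(frac * N))
  data.frame(fraction_screened = frac, E = cumHits[nSel] / A)
}
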