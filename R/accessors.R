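#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("programName", "ScoreTable", function(x) x@programName)
#' @rdname accessors
#' @export
setMethod("programName", "StandardizedTable", function(x) x@programName)
#' @rdname accessors
#' @export
setMethod("programName", "StandoutSet", function(x) x@programName)

#' @rdname accessors
#' @export
setMethod("targetName", "ScoreTable", function(x) x@targetName)
#' @rdname accessors
#' @export
setMethod("targetName", "ActivityLabels", function(x) x@targetName)
#' @rdname accessors
#' @export
setMethod("targetName", "TargetBundle", function(x) x@targetName)

#' @rdname accessors
#' @export
setMethod("scoreDirection", "ScoreTable", function(x) x@direction)
#' @rdname accessors
#' @export
setMethod("scoreDirection", "StandardizedTable", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("moleculeIds", "ScoreTable", function(x) x@scores$molecule_id)
#' @rdname accessors
#' @export
setMethod("moleculeIds", "StandardizedTable", function(x) x@zscores$molecule_id)

#' @rdname accessors
#' @export
setMethod("nMolecules", "ScoreTable", function(x) nrow(x@scores))
#' @rdname accessors
#' @export
setMethod("nMolecules", "StandardizedTable", function(x) nrow(x@zscores))

#' @rdname accessors
#' @export
setMethod("members", "StandoutSet", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("members", "ConsensusResult", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("nCM", "ConsensusResult", function(x) x@nCM)
#' @rdname accessors
#' @export
setMethod("xUsed", "ConsensusResult", function(x) x@xUsed)
#' @rdname accessors
#' @export
setMethod("perProgramCutoffs", "ConsensusResult", function(x) x@perProgramCutoffs)
#' @rdname accessors
#' @export
setMethod("consensusMethod", "ConsensusResult", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("actives", "ActivityLabels", function(x) x@actives)
#' @rdname accessors
#' @export
setMethod("libraryIds", "ActivityLabels", function(x) x@library)

#' @rdname accessors
#' @export
setMethod("regionCounts", "VennPartition", function(x) x@regionCounts)

#' @rdname accessors
#' @export
setMethod("bundleTables", "TargetBundle", function(x) x@tables)
#' @rdname accessors
#' @export
setMethod("bundleLabels", "TargetBundle", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("summaryTable", "BenchmarkSummary", function(x) x@summary)
#' @rdname accessors
#' @export
setMethod("perTargetOutcomes", "BenchmarkSummary", function(x) x@perTarget)

#' Coerce a ScoreTable to a data.frame of its entries
#'
#' @param x a [ScoreTable].
#' @param ... unused.
#' @return data.frame with columns `molecule_id`, `score`, `parent_id`.
#' @export
setMethod("as.data.frame", "ScoreTable", function(x, ...) x@scores)

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %s on %s (%s)\n", object@programName,
              object@targetName, object@direction))
  cat(sprintf("  %d molecules, score range [%.4g, %.4g]\n",
              nrow(object@scores), min(object@scores$score),
              max(object@scores$score)))
  nv <- sum(!is.na(object@scores$parent_id) &
              object@scores$parent_id != object@scores$molecule_id)
  if (nv > 0) cat(sprintf("  %d entries carry a distinct parent compound id\n", nv))
})

setMethod("show", "StandardizedTable", function(object) {
  cat(sprintf("StandardizedTable: %s (%d molecules)\n", object@programName,
              nrow(object@zscores)))
  cat(sprintf("  raw score mean %.4g, SD %.4g; z in [%.3f, %.3f]\n",
              object@scoreMean, object@scoreSD, min(object@zscores$z),
              max(object@zscores$z)))
})

setMethod("show", "StandoutSet", function(object) {
  cat(sprintf("StandoutSet: %s, x = %.4g (cutoff %.4g score units): %d molecules\n",
              object@programName, object@x, object@cutoffC,
              length(object@members)))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult (%s): nCM = %d\n", object@method, object@nCM))
  if (!is.na(object@xUsed))
    cat(sprintf("  x used: %.3f%s\n", object@xUsed,
                if (object@trimmed) " (overshoot trimmed)" else ""))
  if (length(object@perProgramCutoffs))
    cat("  per-program cutoffs (score units):",
        paste(sprintf("%s = %.4g", names(object@perProgramCutoffs),
                      object@perProgramCutoffs), collapse = ", "), "\n")
  if (object@nCM > 0)
    cat("  members:", paste(utils::head(object@members, 8), collapse = ", "),
        if (object@nCM > 8) "..." else "", "\n")
})

setMethod("show", "ActivityLabels", function(object) {
  cat(sprintf("ActivityLabels: %s — %d actives in a library of %d (%.3g %%)\n",
              object@targetName, length(object@actives),
              length(object@library),
              100 * length(object@actives) / max(1L, length(object@library))))
})

setMethod("show", "VennPartition", function(object) {
  cat(sprintf("VennPartition over %d programs (%s): %d regions\n",
              length(object@programs),
              paste(object@programs, collapse = ", "),
              length(object@regionCounts)))
  nz <- object@regionCounts[object@regionCounts > 0]
  if (length(nz)) {
    cat("  non-empty regions:\n")
    for (i in seq_along(nz))
      cat(sprintf("    %s: %d\n", names(nz)[i], nz[i]))
  }
})

setMethod("show", "TargetBundle", function(object) {
  cat(sprintf("TargetBundle: %s — %d programs (%s)\n", object@targetName,
              length(object@tables),
              paste(vapply(object@tables, programName, character(1)),
                    collapse = ", ")))
  show(object@labels)
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(paste0("GeneratorConfig: %d molecules, %.3g %% active, ",
                     "%d programs\n  shared signal weight %.2f, ",
                     "sensitivities %s, seed %d\n"),
              object@nMolecules, 100 * object@activeFraction,
              object@kPrograms, object@sharedSignalWeight,
              paste(sprintf("%.2f", object@sensitivity), collapse = "/"),
              object@seed))
})

setMethod("show", "BenchmarkSummary", function(object) {
  cat(sprintf("BenchmarkSummary: %d methods over n_test grid of %d values\n",
              length(object@methods), length(object@nTestGrid)))
  cat("  methods:", paste(object@methods, collapse = ", "),
      sprintf("(reference: %s)\n", object@reference))
  cat(sprintf("  %d per-target outcomes across %d targets\n",
              nrow(object@perTarget), length(unique(object@perTarget$target))))
})
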