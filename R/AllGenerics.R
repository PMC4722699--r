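#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers; slot access
#' through `@` is not part of the supported interface.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("programName", function(x) standardGeneric("programName"))

#' @rdname accessors
#' @export
setGeneric("targetName", function(x) standardGeneric("targetName"))

#' @rdname accessors
#' @export
setGeneric("scoreDirection", function(x) standardGeneric("scoreDirection"))

#' @rdname accessors
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' @rdname accessors
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("nCM", function(x) standardGeneric("nCM"))

#' @rdname accessors
#' @export
setGeneric("xUsed", function(x) standardGeneric("xUsed"))

#' @rdname accessors
#' @export
setGeneric("perProgramCutoffs", function(x) standardGeneric("perProgramCutoffs"))

#' @rdname accessors
#' @export
setGeneric("consensusMethod", function(x) standardGeneric("consensusMethod"))

#' @rdname accessors
#' @export
setGeneric("actives", function(x) standardGeneric("actives"))

#' @rdname accessors
#' @export
setGeneric("libraryIds", function(x) standardGeneric("libraryIds"))

#' @rdname accessors
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

#' @rdname accessors
#' @export
setGeneric("bundleTables", function(x) standardGeneric("bundleTables"))

#' @rdname accessors
#' @export
setGeneric("bundleLabels", function(x) standardGeneric("bundleLabels"))

#' @rdname accessors
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))

#' @rdname accessors
#' @export
setGeneric("perTargetOutcomes", function(x) standardGeneric("perTargetOutcomes"))

#' Standardize a score table to goodness z-scores
#'
#' @param table a [ScoreTable].
#' @param ... unused.
#' @export
setGeneric("standardize", function(table, ...) standardGeneric("standardize"))
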