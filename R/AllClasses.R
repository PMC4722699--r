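#' @import methods
NULL

## Structured conditions: every user-facing failure carries a class so that
## callers (and the CLI) can react without matching message strings.
.vsdcStop <- function(class, fmt, ..., call. = FALSE) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "vSDCError")))
}

.configError     <- function(fmt, ...) .vsdcStop("vSDCConfigError", fmt, ...)
.parseError      <- function(fmt, ...) .vsdcStop("vSDCParseError", fmt, ...)
.validationError <- function(fmt, ...) .vsdcStop("vSDCValidationError", fmt, ...)
.degenerateError <- function(fmt, ...) .vsdcStop("vSDCDegenerateError", fmt, ...)
.metricError     <- function(fmt, ...) .vsdcStop("vSDCMetricError", fmt, ...)
.ioError         <- function(fmt, ...) .vsdcStop("vSDCIOError", fmt, ...)

.infeasibleError <- function(maxAchievable, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("vSDCInfeasibleError", "vSDCError"),
                      maxAchievable = maxAchievable))
}

.DIRECTIONS <- c("lower_better", "higher_better")

#' ScoreTable: one docking program's scores for one target's library
#'
#' Container for the ranked output of a single structure-based
#' virtual-screening program on a single target: one row per docked
#' structure, with its score and an optional parent-compound identifier
#' used to collapse enantiomers/tautomers/protomers onto unique
#' compounds. The score direction records whether the program reports a
#' free-energy-like score (lower is better) or a fitness (higher is
#' better).
#'
#' @slot programName single character label for the docking program.
#' @slot targetName single character label for the protein target.
#' @slot direction `"lower_better"` or `"higher_better"`.
#' @slot scores data.frame with columns `molecule_id` (character),
#'   `score` (finite numeric) and `parent_id` (character, `NA` when the
#'   row is its own parent compound).
#'
#' @seealso [scoreTable()] for the user-facing constructor,
#'   [readScoreTable()], [collapseVariants()], [standardize()].
#' @export
setClass("ScoreTable",
  slots = c(programName = "character",
            targetName  = "character",
            direction   = "character",
            scores      = "data.frame"))

setValidity("ScoreTable", function(object) {
  msg <- character()
  if (length(object@programName) != 1L || is.na(object@programName) ||
      !nzchar(object@programName))
    msg <- c(msg, "'programName' must be a single non-empty string")
  if (length(object@direction) != 1L || !object@direction %in% .DIRECTIONS)
    msg <- c(msg, sprintf("'direction' must be one of %s",
                          paste(sQuote(.DIRECTIONS), collapse = ", ")))
  sc <- object@scores
  if (!all(c("molecule_id", "score", "parent_id") %in% names(sc))) {
    msg <- c(msg, "'scores' needs columns molecule_id, score, parent_id")
  } else {
    if (nrow(sc) < 1L)
      msg <- c(msg, "a score table needs at least 1 entry")
    if (!is.numeric(sc$score) || anyNA(sc$score) || any(!is.finite(sc$score)))
      msg <- c(msg, "scores must be finite numbers")
    if (anyDuplicated(sc$molecule_id))
      msg <- c(msg, "molecule_id values must be unique within a table")
  }
  if (length(msg)) msg else TRUE
})

#' StandardizedTable: z-standardized "goodness" scores for one program
#'
#' Result of [standardize()]: every molecule's score expressed as a
#' z-score relative to the program's own score distribution, with the
#' sign chosen so that larger z always means a better-scored molecule
#' whatever the program's native score direction. The original-unit mean
#' and standard deviation are retained so that cutoffs `c = x * SD` can
#' be reported in score units.
#'
#' @slot programName program label carried over from the [ScoreTable].
#' @slot zscores data.frame with columns `molecule_id` and `z`.
#' @slot scoreMean mean of the raw scores (original units).
#' @slot scoreSD sample standard deviation of the raw scores
#'   (original units).
#' @slot direction score direction of the source table.
#' @export
setClass("StandardizedTable",
  slots = c(programName = "character",
            zscores     = "data.frame",
            scoreMean   = "numeric",
            scoreSD     = "numeric",
            direction   = "character"))

setValidity("StandardizedTable", function(object) {
  msg <- character()
  if (!all(c("molecule_id", "z") %in% names(object@zscores)))
    msg <- c(msg, "'zscores' needs columns molecule_id and z")
  if (length(object@scoreSD) != 1L || !is.finite(object@scoreSD) ||
      object@scoreSD <= 0)
    msg <- c(msg, "'scoreSD' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' StandoutSet: molecules beyond x standard deviations for one program
#'
#' The set of "stand-out" molecules of one program: those whose
#' standardized goodness z is at or beyond the cutoff of `x` standard
#' deviations above the library mean (boundary inclusive, `z >= x`).
#'
#' @slot programName program label.
#' @slot x the standard-deviation multiplier.
#' @slot cutoffC the cutoff `x * SD` expressed in original score units.
#' @slot members character vector of molecule identifiers.
#' @export
setClass("StandoutSet",
  slots = c(programName = "character",
            x           = "numeric",
            cutoffC     = "numeric",
            members     = "character"))

#' ConsensusResult: the molecules selected by a consensus method
#'
#' The selection produced by [sdc()], [vsdc()], [usc()] or [topN()],
#' together with its provenance: the standard-deviation multiplier used
#' (where applicable), the per-program cutoffs in original score units,
#' and whether an overshooting vSDC intersection was trimmed down to the
#' requested size.
#'
#' @slot method one of `"SDC"`, `"vSDC"`, `"USC"`, `"top_n_single"`.
#' @slot members ordered character vector of selected molecule ids.
#' @slot nCM number of consensus molecules, `length(members)`.
#' @slot xUsed the SD multiplier at which the selection was made
#'   (`NA` for USC/top-n).
#' @slot perProgramCutoffs named numeric, cutoff `x * SD` per program in
#'   that program's original score units (empty for USC/top-n).
#' @slot trimmed whether an overshooting intersection was trimmed to the
#'   requested size.
#' @slot details data.frame with one row per member: `molecule_id`, a
#'   `z_<program>` and a `rank_<program>` column per program (`NA` where
#'   a program did not retain the molecule at all).
#' @export
setClass("ConsensusResult",
  slots = c(method            = "character",
            members           = "character",
            nCM               = "integer",
            xUsed             = "numeric",
            perProgramCutoffs = "numeric",
            trimmed           = "logical",
            details           = "data.frame"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  if (!object@method %in% c("SDC", "vSDC", "USC", "top_n_single"))
    msg <- c(msg, "unknown consensus method")
  if (object@nCM != length(object@members))
    msg <- c(msg, "nCM must equal the number of members")
  if (anyDuplicated(object@members))
    msg <- c(msg, "consensus members must be unique")
  if (length(msg)) msg else TRUE
})

#' ActivityLabels: active/inactive annotation for one target's library
#'
#' Which molecules of a target's screened library are confirmed actives.
#' `A = length(actives)` is the number of findable hits used by the
#' docking-enrichment and corrected-yield metrics.
#'
#' @slot targetName target label.
#' @slot actives character vector of active molecule ids (a subset of
#'   `library`).
#' @slot library character vector of all molecule ids in the screened
#'   library.
#' @export
setClass("ActivityLabels",
  slots = c(targetName = "character",
            actives    = "character",
            library    = "character"))

setValidity("ActivityLabels", function(object) {
  msg <- character()
  if (anyDuplicated(object@library))
    msg <- c(msg, "library ids must be unique")
  if (anyDuplicated(object@actives))
    msg <- c(msg, "active ids must be unique")
  if (!all(object@actives %in% object@library))
    msg <- c(msg, "actives must be a subset of the library")
  if (length(msg)) msg else TRUE
})

#' VennPartition: exact region counts over k stand-out sets
#'
#' The disjoint Venn regions of k programs' stand-out sets: one count
#' per non-empty subset of programs (2^k - 1 regions), each region
#' holding the molecules that are stand-out in exactly that subset of
#' programs.
#'
#' @slot programs character vector of program names (input order).
#' @slot regionCounts named integer vector; names are `'+'`-joined
#'   program names identifying the region.
#' @export
setClass("VennPartition",
  slots = c(programs     = "character",
            regionCounts = "integer"))

#' TargetBundle: everything needed to evaluate one target
#'
#' One protein target's evaluation unit: the per-program score tables
#' (at least two) and the activity annotation of the screened library.
#'
#' @slot targetName target label.
#' @slot tables list of [ScoreTable] objects, one per program.
#' @slot labels an [ActivityLabels] object covering every table's ids.
#' @export
setClass("TargetBundle",
  slots = c(targetName = "character",
            tables     = "list",
            labels     = "ActivityLabels"))

setValidity("TargetBundle", function(object) {
  msg <- character()
  if (length(object@tables) < 2L)
    msg <- c(msg, "a target bundle needs at least 2 score tables")
  if (!all(vapply(object@tables, is, logical(1), class2 = "ScoreTable")))
    msg <- c(msg, "'tables' must all be ScoreTable objects")
  else {
    ids <- unique(unlist(lapply(object@tables,
                                function(t) t@scores$molecule_id)))
    if (!all(ids %in% object@labels@library))
      msg <- c(msg, "labels library must cover every table's molecule ids")
    progs <- vapply(object@tables, function(t) t@programName, character(1))
    if (anyDuplicated(progs))
      msg <- c(msg, "program names must be unique within a bundle")
  }
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: parameters of the synthetic score-table generator
#'
#' Parameters of the latent-signal model used to simulate per-program
#' score tables with planted actives; see [generateTarget()] for the
#' model itself.
#'
#' @slot nMolecules library size.
#' @slot activeFraction fraction of the library that is active.
#' @slot kPrograms number of scoring programs (>= 2).
#' @slot sensitivity per-program mean z-shift of the actives
#'   (length `kPrograms`, recycled from length 1).
#' @slot sharedSignalWeight weight in `[0, 1]` of the shared latent
#'   goodness relative to program-private noise; controls inter-program
#'   rank correlation.
#' @slot sharedShift additional goodness shift applied to actives in the
#'   shared latent component.
#' @slot directions per-program score direction.
#' @slot seed integer seed making the bundle reproducible.
#' @export
setClass("GeneratorConfig",
  slots = c(nMolecules         = "integer",
            activeFraction     = "numeric",
            kPrograms          = "integer",
            sensitivity        = "numeric",
            sharedSignalWeight = "numeric",
            sharedShift        = "numeric",
            directions         = "character",
            seed               = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nMolecules < 10L)
    msg <- c(msg, "'nMolecules' must be at least 10")
  if (object@activeFraction <= 0 || object@activeFraction >= 1)
    msg <- c(msg, "'activeFraction' must be strictly between 0 and 1")
  if (object@kPrograms < 2L)
    msg <- c(msg, "'kPrograms' must be at least 2")
  if (length(object@sensitivity) != object@kPrograms ||
      any(object@sensitivity < 0))
    msg <- c(msg, "'sensitivity' must be one non-negative value per program")
  if (object@sharedSignalWeight < 0 || object@sharedSignalWeight > 1)
    msg <- c(msg, "'sharedSignalWeight' must lie in [0, 1]")
  if (length(object@directions) != object@kPrograms ||
      !all(object@directions %in% .DIRECTIONS))
    msg <- c(msg, "'directions' must be one valid direction per program")
  if (length(msg)) msg else TRUE
})

#' BenchmarkSummary: metric curves of a multi-target n_test sweep
#'
#' The aggregated output of [benchmarkSweep()]: for every method and
#' every value of the n_test grid, the fraction of targets with at least
#' one hit, the unweighted mean corrected yield with its standard error,
#' and the net balance of targets versus the reference method.
#'
#' @slot methods methods evaluated.
#' @slot reference the reference method for the net-balance curves.
#' @slot nTestGrid integer grid of tested-molecule counts.
#' @slot summary data.frame with columns `method`, `n_test`, `T_h_gt0`,
#'   `mean_Y_C`, `sem_Y_C`, `delta_p`.
#' @slot perTarget data.frame of per-target outcomes with columns
#'   `target`, `method`, `n_test`, `n_selected`, `h`, `A`, `Y`, `E`,
#'   `Y_C`, `x_used`, `infeasible`.
#' @export
setClass("BenchmarkSummary",
  slots = c(methods   = "character",
            reference = "character",
            nTestGrid = "integer",
            summary   = "data.frame",
            perTarget = "data.frame"))
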