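#' @include AllClasses.R
NULL

#' Construct a ScoreTable from vectors
#'
#' User-facing constructor for [ScoreTable]. Scores are the raw numbers
#' a docking program reports; `direction` says which end of the scale is
#' good (free-energy-like scores are `"lower_better"`, fitness scores
#' such as Gold's are `"higher_better"`).
#'
#' @param molecule_id character vector of molecule (or structure
#'   variant) identifiers, unique.
#' @param score numeric vector of finite scores, same length.
#' @param direction `"lower_better"` or `"higher_better"`.
#' @param program_name label of the docking program.
#' @param target_name label of the protein target.
#' @param parent_id optional character vector mapping structure variants
#'   (enantiomers, tautomers, protomers) to their parent compound; `NA`
#'   entries are their own parent.
#' @return A [ScoreTable].
#' @examples
#' scoreTable(c("a", "b", "c"), c(-7.1, -6.0, -9.9),
#'            direction = "lower_better", program_name = "progA")
#' @export
scoreTable <- function(molecule_id, score, direction,
                       program_name = "program", target_name = "target",
                       parent_id = NULL) {
  if (length(molecule_id) != length(score))
    .configError("molecule_id and score must have the same length")
  if (is.null(parent_id)) parent_id <- rep(NA_character_, length(score))
  new("ScoreTable", programName = program_name, targetName = target_name,
      direction = direction,
      scores = data.frame(molecule_id = as.character(molecule_id),
                          score = as.numeric(score),
                          parent_id = as.character(parent_id),
                          stringsAsFactors = FALSE))
}

#' Construct ActivityLabels
#'
#' @param library character vector of all molecule ids screened for the
#'   target.
#' @param actives character vector of the active ids (subset of
#'   `library`).
#' @param target_name target label.
#' @return An [ActivityLabels] object.
#' @export
activityLabels <- function(library, actives = character(),
                           target_name = "target") {
  new("ActivityLabels", targetName = target_name,
      actives = as.character(actives), library = as.character(library))
}

#' Collapse structure variants onto parent compounds
#'
#' Docking runs typically enumerate several structures per compound
#' (enantiomers, tautomers, protonation states). Consensus selection and
#' hit counting operate on unique compounds, so a table is first
#' collapsed to one entry per parent: the retained score is the BEST
#' score among that parent's variants under the table's direction, and
#' the entry's id becomes the parent id. Entries without a parent id
#' pass through as their own parent. The operation is idempotent.
#'
#' @param table a [ScoreTable].
#' @return A [ScoreTable] with one entry per unique compound and empty
#'   `parent_id`.
#' @examples
#' t <- scoreTable(c("m1a", "m1b", "m2"), c(-5, -8, -3), "lower_better",
#'                 parent_id = c("p1", "p1", NA))
#' as.data.frame(collapseVariants(t))
#' @export
collapseVariants <- function(table) {
  stopifnot(is(table, "ScoreTable"))
  sc <- table@scores
  parent <- ifelse(is.na(sc$parent_id) | !nzchar(sc$parent_id),
                   sc$molecule_id, sc$parent_id)
  goodness <- if (table@direction == "higher_better") sc$score else -sc$score
  ## keep, per parent, the row with the best goodness
  ord <- order(parent, -goodness)
  keep <- !duplicated(parent[ord])
  out <- sc[ord, ][keep, ]
  out$molecule_id <- parent[ord][keep]
  out$parent_id <- NA_character_
  rownames(out) <- NULL
  new("ScoreTable", programName = table@programName,
      targetName = table@targetName, direction = table@direction,
      scores = out)
}

## Detect the delimiter of a header line: tab wins if present, else comma.
.detectDelim <- function(header) {
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

## First non-comment, non-blank line of a file plus the file's lines.
.readDelimited <- function(path) {
  if (!file.exists(path)) .ioError("file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) .parseError("no data lines in %s", path)
  list(lines = lines[keep], lineno = which(keep),
       delim = .detectDelim(lines[keep][1]))
}

#' Read a delimited score file into a ScoreTable
#'
#' Reads one docking program's score table from a comma- or
#' tab-separated text file (delimiter auto-detected from the header
#' line; `#`-prefixed lines are ignored). Column names are configurable
#' so native export headers can be consumed without editing.
#'
#' @param path path to the file.
#' @param program_name label for the docking program.
#' @param direction `"lower_better"` or `"higher_better"`; there is no
#'   default because getting it wrong silently inverts every ranking.
#' @param id_column name of the molecule-identifier column.
#' @param score_column name of the score column.
#' @param parent_column optional name of a parent-compound column used
#'   by [collapseVariants()].
#' @param target_name target label to attach.
#' @return A validated [ScoreTable]. Rows whose score does not parse as
#'   a number raise an error naming the offending file line.
#' @export
readScoreTable <- function(path, program_name, direction,
                           id_column = "id", score_column = "score",
                           parent_column = NULL, target_name = "target") {
  if (!direction %in% .DIRECTIONS)
    .configError("'direction' must be 'lower_better' or 'higher_better'")
  raw <- .readDelimited(path)
  fields <- strsplit(raw$lines, raw$delim, fixed = TRUE)
  header <- trimws(fields[[1]])
  need <- c(id_column, score_column, parent_column)
  missing <- setdiff(need, header)
  if (length(missing))
    .configError("column(s) %s not found in header of %s (header: %s)",
                 paste(sQuote(missing), collapse = ", "), path,
                 paste(header, collapse = ", "))
  idI <- match(id_column, header)
  scI <- match(score_column, header)
  paI <- if (is.null(parent_column)) NA_integer_ else match(parent_column, header)
  rows <- fields[-1]
  lineno <- raw$lineno[-1]
  getcol <- function(i) vapply(rows, function(f)
    if (length(f) >= i) trimws(f[[i]]) else NA_character_, character(1))
  ids <- getcol(idI)
  scoreChr <- getcol(scI)
  score <- suppressWarnings(as.numeric(scoreChr))
  bad <- which(is.na(score))
  if (length(bad))
    .parseError("non-numeric score %s at line %d of %s",
                sQuote(scoreChr[bad[1]]), lineno[bad[1]], path)
  parent <- if (is.na(paI)) rep(NA_character_, length(ids)) else {
    p <- getcol(paI); p[!nzchar(p)] <- NA_character_; p
  }
  if (is.na(paI) && anyDuplicated(ids))
    .validationError("duplicate molecule id %s in %s (no parent column given)",
                     sQuote(ids[duplicated(ids)][1]), path)
  scoreTable(ids, score, direction, program_name = program_name,
             target_name = target_name, parent_id = parent)
}

#' Write a ScoreTable to a CSV file
#'
#' Writes the format [readScoreTable()] reads back (columns `id`,
#' `score` and, when any variant mapping is present, `parent`).
#'
#' @param table a [ScoreTable].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeScoreTable <- function(table, path) {
  stopifnot(is(table, "ScoreTable"))
  sc <- table@scores
  df <- data.frame(id = sc$molecule_id,
                   score = sprintf("%.10g", sc$score),
                   stringsAsFactors = FALSE)
  if (any(!is.na(sc$parent_id))) df$parent <- ifelse(is.na(sc$parent_id), "",
                                                     sc$parent_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity-label file
#'
#' Two-column delimited file (molecule id, label), where the label is
#' `1`/`0` or `active`/`inactive` (case-insensitive). The library is the
#' full set of ids listed; the actives are those labelled active.
#'
#' @param path path to the file; `#` comment lines and a recognisable
#'   header line (`id,label`-like) are skipped.
#' @param target_name target label to attach.
#' @return An [ActivityLabels] object.
#' @export
readActivityLabels <- function(path, target_name = "target") {
  raw <- .readDelimited(path)
  fields <- strsplit(raw$lines, raw$delim, fixed = TRUE)
  lineno <- raw$lineno
  ## tolerate a header row: its label token will not parse as a label
  first <- tolower(trimws(fields[[1]][2]))
  if (length(fields[[1]]) >= 2 &&
      !first %in% c("0", "1", "active", "inactive")) {
    fields <- fields[-1]; lineno <- lineno[-1]
  }
  if (!length(fields)) .parseError("no label rows in %s", path)
  ids <- vapply(fields, function(f) trimws(f[[1]]), character(1))
  lab <- tolower(vapply(fields, function(f)
    if (length(f) >= 2) trimws(f[[2]]) else NA_character_, character(1)))
  ok <- lab %in% c("0", "1", "active", "inactive")
  if (!all(ok))
    .parseError("unknown activity label %s at line %d of %s",
                sQuote(lab[!ok][1]), lineno[!ok][1], path)
  activityLabels(library = ids,
                 actives = ids[lab %in% c("1", "active")],
                 target_name = target_name)
}

#' Write an activity-label file
#'
#' @param labels an [ActivityLabels] object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeActivityLabels <- function(labels, path) {
  stopifnot(is(labels, "ActivityLabels"))
  df <- data.frame(id = labels@library,
                   label = as.integer(labels@library %in% labels@actives))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a consensus selection to a CSV file
#'
#' The file carries `#`-prefixed metadata lines (method, x used, nCM,
#' trimmed flag, per-program cutoffs in score units) followed by one CSV
#' row per consensus molecule with its per-program standardized score
#' and rank.
#'
#' @param result a [ConsensusResult].
#' @param path output path.
#' @return Invisibly, `path`.
#' @seealso [readConsensus()] for the reader.
#' @export
writeConsensus <- function(result, path) {
  stopifnot(is(result, "ConsensusResult"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) .ioError("cannot write %s: %s", path,
                                               conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(sprintf("# method: %s", result@method),
               sprintf("# x_used: %s",
                       if (is.na(result@xUsed)) "NA"
                       else sprintf("%.10g", result@xUsed)),
               sprintf("# nCM: %d", result@nCM),
               sprintf("# trimmed: %s", result@trimmed)), con)
  if (length(result@perProgramCutoffs))
    writeLines(sprintf("# cutoff_%s: %.10g", names(result@perProgramCutoffs),
                       result@perProgramCutoffs), con)
  det <- result@details
  num <- vapply(det, is.numeric, logical(1))
  det[num] <- lapply(det[num], function(v) ifelse(is.na(v), "NA",
                                                  sprintf("%.10g", v)))
  utils::write.csv(det, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a consensus selection written by writeConsensus
#'
#' @param path path to a file produced by [writeConsensus()].
#' @return A [ConsensusResult]; per-program cutoffs and member details
#'   are restored from the metadata header and the data rows.
#' @export
readConsensus <- function(path) {
  if (!file.exists(path)) .ioError("file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  meta <- lines[grepl("^#", lines)]
  kv <- sub("^#\\s*([^:]+):\\s*(.*)$", "\\1\t\\2", meta)
  kvs <- strsplit(kv, "\t", fixed = TRUE)
  keys <- vapply(kvs, `[[`, character(1), 1)
  vals <- vapply(kvs, function(f) if (length(f) > 1) f[[2]] else "",
                 character(1))
  getMeta <- function(k) vals[match(k, keys)]
  cut_i <- grep("^cutoff_", keys)
  cuts <- as.numeric(vals[cut_i])
  names(cuts) <- sub("^cutoff_", "", keys[cut_i])
  body <- lines[!grepl("^#", lines)]
  det <- if (sum(nzchar(body)) > 1)
    utils::read.csv(text = body, stringsAsFactors = FALSE)
  else data.frame(molecule_id = character())
  det$molecule_id <- as.character(det$molecule_id)
  new("ConsensusResult",
      method = getMeta("method"),
      members = det$molecule_id,
      nCM = as.integer(getMeta("nCM")),
      xUsed = suppressWarnings(as.numeric(getMeta("x_used"))),
      perProgramCutoffs = cuts,
      trimmed = as.logical(getMeta("trimmed")),
      details = det)
}
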