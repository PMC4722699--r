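# Fixture builders and independent brute-force oracles used across the
# test files. The oracles deliberately avoid the package's own code
# paths (scale(), explicit grid loops, rank(); not standardize()/vsdc()).

# A score table in which the named molecules occupy prescribed ranks
# (rank 1 = best) and filler molecules occupy the rest.
makeRankedTable <- function(rankedIds, N, program = "prog",
                            direction = "lower_better") {
  ids <- sprintf("lib%05d", seq_len(N))
  ids[as.integer(rankedIds)] <- names(rankedIds)
  score <- if (direction == "lower_better") seq_len(N) else -seq_len(N)
  scoreTable(ids, score, direction, program_name = program)
}

# k random but correlated tables over a common library, via the
# package generator; returns plain ScoreTable list.
randomTables <- function(n, k = 3L, seed = 1L, w = 0.5, sens = 2) {
  cfg <- generatorConfig(n_molecules = n, active_fraction = 0.01,
                         k_programs = k, sensitivity = sens,
                         shared_signal_weight = w, seed = seed)
  bundleTables(generateTarget(cfg))
}

# goodness z-scores computed the "other way": base scale() on the raw
# score vector, sign-flipped for lower_better.
oracleZ <- function(table) {
  df <- as.data.frame(collapseVariants(table))
  z <- as.numeric(scale(df$score))
  if (scoreDirection(table) == "lower_better") z <- -z
  names(z) <- df$molecule_id
  z
}

oracleStandout <- function(table, x) {
  z <- oracleZ(table)
  sort(names(z)[z >= x])
}

# literal scan of the x grid by repeated subtraction, intersecting
# freshly recomputed per-program stand-out sets at every step
oracleVsdc <- function(tables, n_test, x_start = 3.5, x_step = 0.001,
                       x_min = -10) {
  zs <- lapply(tables, oracleZ)
  x <- x_start
  repeat {
    sets <- lapply(zs, function(z) names(z)[z >= x])
    common <- Reduce(intersect, sets)
    if (length(common) >= n_test) return(list(x = x, ids = sort(common)))
    x <- x - x_step
    if (x < x_min - 1e-12) return(NULL)
  }
}

# straight re-simulation of the USC procedure with a different control
# structure (explicit per-program queues)
oracleUsc <- function(tables, n_test) {
  k <- length(tables)
  queues <- lapply(tables, function(tab) {
    df <- as.data.frame(collapseVariants(tab))
    g <- if (scoreDirection(tab) == "higher_better") df$score else -df$score
    df$molecule_id[order(-g, df$molecule_id)]
  })
  sel <- character()
  for (q in queues) for (id in head(q, n_test %/% k))
    if (!id %in% sel) sel <- c(sel, id)
  pooledN <- length(unique(unlist(queues)))
  while (length(sel) < min(n_test, pooledN)) {
    for (p in seq_len(k)) {
      if (length(sel) >= n_test) break
      nxt <- setdiff(queues[[p]], sel)
      if (length(nxt)) sel <- c(sel, nxt[1])
    }
  }
  sel
}

# Spearman's rho from its definition: Pearson correlation of
# average-tie ranks, computed by hand.
oracleSpearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  da <- ra - mean(ra); db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Build stand-out sets realising prescribed Venn region counts.
# regionSpec: named integer vector, names are '+'-joined program names.
setsFromRegions <- function(programs, regionSpec) {
  memb <- setNames(vector("list", length(programs)), programs)
  i <- 0L
  for (r in seq_along(regionSpec)) {
    inProgs <- strsplit(names(regionSpec)[r], "+", fixed = TRUE)[[1]]
    ids <- sprintf("cmpd%05d", i + seq_len(regionSpec[r]))
    i <- i + regionSpec[r]
    for (p in inProgs) memb[[p]] <- c(memb[[p]], ids)
  }
  lapply(programs, function(p)
    new("StandoutSet", programName = p, x = 2, cutoffC = 2,
        members = as.character(memb[[p]])))
}

# labels marking given ids active within a table's library
labelsFor <- function(table, activeIds, target = "t") {
  activityLabels(moleculeIds(collapseVariants(table)), activeIds,
                 target_name = target)
}
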