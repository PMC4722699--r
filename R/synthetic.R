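#' @include scoreTable.R
NULL

## Evaluate expr under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## derived per-target seeds, kept inside 32-bit integer range
.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483647)
}

#' Configuration of the synthetic score-table generator
#'
#' Builds a [GeneratorConfig] describing one simulated target. The
#' defaults describe the screening regime the toolkit is designed for:
#' a moderate library (2000 molecules) with 0.5 % actives screened by 4
#' programs whose rankings agree only weakly (`shared_signal_weight`
#' 0.3 gives pairwise Spearman rho around 0.15), each program carrying
#' a genuine but modest preference for actives (sensitivity 2 SD).
#'
#' @param n_molecules library size (default 2000).
#' @param active_fraction fraction of actives (default 0.005).
#' @param k_programs number of programs (default 4).
#' @param sensitivity per-program mean z-shift of actives; a single
#'   value is recycled (default 2).
#' @param shared_signal_weight weight of the shared latent goodness in
#'   `[0, 1]` (default 0.3); 0 gives independent rankings, 1 identical
#'   ones.
#' @param shared_shift extra shift of actives carried by the shared
#'   latent component only (default 0).
#' @param directions per-program score direction; the default makes all
#'   programs free-energy-like except the last, which reports a
#'   fitness, so both conventions are exercised.
#' @param seed integer seed (default 1).
#' @return A [GeneratorConfig].
#' @export
generatorConfig <- function(n_molecules = 2000L, active_fraction = 0.005,
                            k_programs = 4L, sensitivity = 2,
                            shared_signal_weight = 0.3, shared_shift = 0,
                            directions = NULL, seed = 1L) {
  k <- as.integer(k_programs)
  if (is.null(directions))
    directions <- c(rep("lower_better", max(0L, k - 1L)), "higher_better")
  if (length(sensitivity) == 1L) sensitivity <- rep(sensitivity, k)
  new("GeneratorConfig", nMolecules = as.integer(n_molecules),
      activeFraction = active_fraction, kPrograms = k,
      sensitivity = as.numeric(sensitivity),
      sharedSignalWeight = shared_signal_weight,
      sharedShift = as.numeric(shared_shift),
      directions = directions, seed = as.integer(seed))
}

#' Generate one synthetic target bundle
#'
#' Simulates the statistical structure consensus selection relies on
#' with a latent-signal model. Every molecule i has a latent goodness
#' `L_i ~ N(0, 1)` shared by all programs (actives additionally shifted
#' by `shared_shift`); program p observes
#'
#' `z_p(i) = w * L_i + (1 - w) * eps_p(i) + sensitivity_p * active_i`
#'
#' with program-private noise `eps_p(i) ~ N(0, 1)` and
#' `w = shared_signal_weight`, and reports a raw score that is an
#' affine map of z respecting its direction (a free-energy-like score
#' around -8 for `lower_better` programs, a fitness around 50 for
#' `higher_better` ones). The generator thus reproduces the two
#' features real score lists show: unimodal score distributions with a
#' small stand-out tail of well-scored molecules, and weak
#' inter-program rank correlation tunable through `w`.
#'
#' @param config a [GeneratorConfig].
#' @return A [TargetBundle] (deterministic under the config's seed,
#'   caller's RNG untouched).
#' @export
generateTarget <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  .withSeed(config@seed, {
    n <- config@nMolecules
    k <- config@kPrograms
    w <- config@sharedSignalWeight
    ids <- sprintf("mol%06d", seq_len(n))
    A <- max(1L, as.integer(round(config@activeFraction * n)))
    activeIds <- sample(ids, A)
    isActive <- ids %in% activeIds
    latent <- stats::rnorm(n) + config@sharedShift * isActive
    tables <- vector("list", k)
    for (p in seq_len(k)) {
      z <- w * latent + (1 - w) * stats::rnorm(n) +
        config@sensitivity[p] * isActive
      raw <- if (config@directions[p] == "lower_better") -8 - 1.2 * z
             else 50 + 10 * z
      tables[[p]] <- scoreTable(ids, raw, config@directions[p],
                                program_name = sprintf("prog%d", p),
                                target_name = "synthetic")
    }
    new("TargetBundle", targetName = "synthetic", tables = tables,
        labels = activityLabels(ids, activeIds, target_name = "synthetic"))
  })
}

#' Generate a cohort of synthetic targets
#'
#' Independent target bundles whose per-program sensitivities are
#' jittered around the template's values, so that — as across real
#' protein targets — which program performs best differs from target
#' to target.
#'
#' @param n_targets number of targets (>= 1).
#' @param config_template a [GeneratorConfig] providing the shared
#'   settings.
#' @param per_target_jitter half-width of the uniform jitter applied to
#'   each program's sensitivity per target (default 0.75; jittered
#'   sensitivities are clamped at 0).
#' @param seed cohort seed; per-target seeds are derived from it.
#' @return list of [TargetBundle] objects named `target01`,
#'   `target02`, ...
#' @export
generateCohort <- function(n_targets, config_template = generatorConfig(),
                           per_target_jitter = 0.75, seed = 1L) {
  if (n_targets < 1L) .configError("'n_targets' must be >= 1")
  stopifnot(is(config_template, "GeneratorConfig"))
  k <- config_template@kPrograms
  jit <- .withSeed(seed,
    matrix(stats::runif(n_targets * k, -per_target_jitter, per_target_jitter),
           nrow = n_targets))
  bundles <- vector("list", n_targets)
  for (t in seq_len(n_targets)) {
    cfg <- config_template
    cfg@sensitivity <- pmax(0, config_template@sensitivity + jit[t, ])
    cfg@seed <- .deriveSeed(seed, t)
    b <- generateTarget(cfg)
    nm <- sprintf("target%02d", t)
    b@targetName <- nm
    b@labels@targetName <- nm
    b@tables <- lapply(b@tables, function(tab) {
      tab@targetName <- nm
      tab
    })
    bundles[[t]] <- b
  }
  names(bundles) <- vapply(bundles, targetName, character(1))
  bundles
}
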