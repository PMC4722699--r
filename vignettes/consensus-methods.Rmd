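---
title: "Standard-deviation consensus for virtual screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard-deviation consensus for virtual screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vSDC)
```

## The problem and the model

Structure-based virtual screening produces, per docking program, a
ranked score list over a chemical library. Different programs rank the
same library almost independently — pairwise Spearman correlations of a
few percent are typical — yet the experimental budget is tiny: often 10
to 50 assays. The consensus idea implemented here is that while each
program makes many mistakes in its top ranks, *different* programs
rarely make the *same* mistake, so molecules ranked exceptionally by
every program are enriched in true actives.

"Exceptionally" is defined on each program's own score distribution.
With mean $\mu_p$ and standard deviation $\sigma_p$ of program $p$'s
scores over the library, the standardized goodness is

$$z_p(m) = s_p \, \frac{\mathrm{score}_p(m) - \mu_p}{\sigma_p},$$

with $s_p = +1$ for fitness-like scores and $-1$ for free-energy-like
scores, so larger $z$ is always better. The stand-out set of program
$p$ at multiplier $x$ is $\{m : z_p(m) \ge x\}$, i.e. the molecules
beyond the cutoff $c_p = x \sigma_p$ in the program's own score units.

* **SDC** intersects the $k$ stand-out sets at a fixed $x$ (default 2,
  where the stand-out tail visibly separates from the unimodal bulk of
  typical score histograms). The selection size nCM is whatever the
  intersection happens to contain.
* **vSDC** inverts the control: the user fixes the selection size
  `n_test` and the multiplier is scanned downward over the grid
  $x = 3.5, 3.499, 3.498, \dots$ until the intersection holds at least
  `n_test` molecules. Each target gets its own data-driven cutoff.
* **USC** takes the union of each program's top
  $\lfloor n_{test}/k \rfloor$ molecules and tops the union up
  round-robin. Unions reward molecules that any one program loves;
  intersections demand unanimity. Empirically the intersection-based
  methods are the stronger choice at small `n_test`, the union becomes
  competitive as the budget grows.

The package assumes the score lists are comparable by molecule
identifier across programs, that each program's score distribution is
non-degenerate (SD > 0), and nothing about the distributions' shape:
standardization is used as a per-program normalization, not a normality
claim.

## Metrics

For a selection of $n_{test}$ molecules containing $h$ hits from a
library with $A$ actives:

$$Y = h / n_{test}, \qquad E = h / A, \qquad
Y_C = \frac{h}{\min(A,\, n_{test})}.$$

$Y$ saturates blindly when $n_{test} > A$, $E$ when $n_{test} < A$;
$Y_C$ — the fraction of *findable* hits found — switches between them
at $n_{test} = A$ and is the quantity averaged across targets
($\langle Y_C \rangle$, unweighted, which presumes comparable active
densities; hence the dilution step below). Cohort success is
$T_{h>0}$, the fraction of targets with at least one hit, and direct
pairwise comparison uses the net balance
$\Delta p = (n^{A>B} - n^{B>A}) / N_p$, where targets on which both
methods find equally many hits count in neither tally.

Whole-library indicators (ROC-AUC, BEDROC) are deliberately out of
scope: at $n_{test} \le 50$ out of thousands they do not measure what
the experimentalist buys.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `x` (SDC) | 2 | SDs | the rank-curve elbow where stand-outs separate from the bulk |
| `x_start` (vSDC) | 3.5 | SDs | above the stand-out tail of realistic libraries, so the scan starts empty |
| `x_step` | 0.001 | SDs | fine enough that the scan stops as close as possible to the jump |
| `x_min` | −10 | SDs | diagnosable floor instead of an unbounded loop on pathological inputs |
| `trim` | `TRUE` | — | guarantee exactly `n_test` molecules (see below) |
| `density` (dilution) | 0.005 | fraction | realistic active density for a novel target |
| `n_test` grid | 1–50 | molecules | the assay budgets of low-throughput experiments |

## Numerical and procedural choices

* **Sample SD** ($n-1$ denominator). At library scale the difference
  from the population SD is far below the 0.001 grid step; the
  convention is pinned so toy-size tests are exact.
* **Boundary inclusive**: stand-out membership is $z \ge x$. With
  continuous scores the choice is immaterial; inclusivity makes the
  grid scan deterministic.
* **Variant collapse before standardization.** Libraries are docked as
  enantiomers/tautomers/protomers; selection and hit counting operate
  on unique compounds, and the retained score per parent is the best
  variant's under the program's direction — the only choice consistent
  with ranking by score. Hit counting is likewise per unique compound.
* **The vSDC scan in closed form.** A molecule is in the intersection
  at cutoff $x$ iff its worst per-program z-score is $\ge x$, so the
  scan's stopping point is the first grid value at or below the
  `n_test`-th largest of these minima. The implementation computes
  that directly; the test suite holds it equal to a literal
  step-by-step scan.
* **Overshoot trimming.** The intersection grows in jumps, so the
  first grid $x$ with $|{\cap}| \ge n_{test}$ may overshoot. By
  default the overshoot is trimmed to exactly `n_test` by keeping the
  members with the highest summed z across programs — the user-facing
  contract is "you get `n_test` molecules" — and `trim = FALSE`
  exposes the raw intersection. Whether the original procedure trimmed
  or reported slightly larger selections is not documented; both
  behaviours are available.
* **Ordering and ties.** Consensus members are ordered by decreasing
  summed z (a choice; no canonical ordering of consensus molecules is
  established elsewhere), ranks are dense with lexicographic
  tie-breaks on molecule id, and all tie-breaking in the package is
  lexicographic: deterministic and seed-free.
* **Missing molecules.** A molecule absent from one program's output
  is treated as not stand-out for that program at any $x$, so it can
  never enter an intersection-based consensus; the consensus functions
  warn with the count of ids not shared by all tables. USC, a union
  construction, can still select it.
* **Degenerate inputs.** Constant score vectors (SD = 0) and
  single-compound tables raise a typed degenerate-distribution error;
  vSDC requests beyond the shared-id pool raise a typed infeasibility
  error carrying the maximum achievable nCM. Inside a cohort sweep
  these degrade to flagged zero-hit outcomes instead of aborting the
  run — one pathological target should not kill a 100-target
  benchmark. The same graceful route records USC at
  $n_{test} < k$, where an equal per-program share is impossible.
* **SDC with nCM = 0** contributes $Y_C = 0$ (and no hit) to cohort
  aggregates; $Y_C$'s denominator is undefined at $n_{test} = 0$ and a
  zero-size selection finds nothing by construction.
* **Dilution rounding.** The retained active count solves
  $A' / (N_{inact} + A') \le d$ with $A'$ maximal, i.e.
  $A' = \lfloor d N_{inact} / (1 - d) \rfloor$; eliminated actives
  leave the library entirely (keeping the density exact), inactives
  are never touched, at least one active is always retained, and the
  removal is seeded. Dilution is performed once per target with a
  recorded seed, not resampled.
* **USC at non-multiples of `k`.** The equal-share construction needs
  $k \mid n_{test}$; the package generalizes with a round-robin top-up
  so any $n_{test} \ge k$ is valid. `usc_equal_share` in the sweep
  instead evaluates the flanking multiples of $k$ and averages them
  (e.g. 48 and 52 standing for 50 with four programs), reproducing the
  equal-share averaging convention.
* **$\langle Y_C \rangle$ error bars** are reported as the standard
  error of the mean across targets; the estimator behind historically
  quoted "about 3 %" errors is unstated, so the package names its own.
* **Spearman rho** uses average ranks on ties (the standard
  definition) and is computed on the common-id subset after direction
  normalization; it is the divergence diagnostic, preferred over
  Pearson because only rank agreement matters for selection.

## The synthetic generator

`generateTarget()` draws a shared latent goodness
$L_i \sim \mathcal N(0,1)$ per molecule and gives program $p$ the
standardized view
$z_p(i) = w L_i + (1-w)\,\varepsilon_{p,i} + s_p \mathbf 1\{i\
\mathrm{active}\}$, mapped affinely to a raw score respecting the
program's direction. Defaults (chosen once as a realistic screening
regime, and the conditions under which the package's statistical tests
run): 2000 molecules, 0.5 % active, 4 programs, shared-signal weight
$w = 0.3$ — which yields pairwise Spearman correlations around 0.15,
inside the weak-correlation band observed between real programs — and
per-program sensitivity 2 (actives shifted two noise-SDs up), jittered
by ±0.75 per target in cohorts so that which program "wins" varies by
target. One program reports a fitness (higher better), the rest
free-energy-like scores, so both direction conventions are exercised
everywhere.

The generator reproduces the features the methods rely on — unimodal
score distributions with a small well-scored tail, weak and tunable
inter-program rank correlation, planted actives at controllable
density and per-program detectability, molecules optionally missing
from individual programs (via table subsetting) — and deliberately not
the features they don't: no chemistry, no pose geometry, no
heavy-tailed score artifacts, no score–molecular-size correlation (a
nuisance correlation real scoring functions can show). Passing the
statistical acceptance tests therefore shows the *selection machinery*
behaves as designed under the stated statistical structure, not that
any particular docking program combination will enrich on a particular
real target.

Test and benchmark problem sizes in this package (cohorts of 20
targets × 2000 molecules, 100-trial oracle-equivalence sweeps on
30–500-molecule toys) were chosen as the smallest scales at which the
statistical assertions are stable across seeds.

## Known limitations

* Consensus requires identifier-level correspondence across program
  outputs; no structure-based matching is attempted (score files, not
  SDF/mol2, are the interface).
* Intersection methods inherit every program's blind spots: an active
  scored poorly by even one program is invisible to SDC/vSDC at any
  cutoff (USC is the within-package hedge).
* $\langle Y_C \rangle$ comparisons across targets assume equalized
  active densities; the dilution step provides that for benchmarks,
  but real prospective screens have unknown $A$, where only the
  selection (not the metric) is available.
* The vSDC grid scan's 0.001 step bounds how precisely the reported
  $x$ tracks the jump point; member sets, the quantity that matters,
  are exact at the reported $x$.
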