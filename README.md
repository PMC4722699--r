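# vSDC: standard-deviation consensus for structure-based virtual screening

Docking programs disagree. On the same target and the same chemical
library, the molecule one program ranks first is routinely ranked in the
thousands by another, because scoring functions and positioning
algorithms err differently. For an experimentalist who can only afford a
handful of assays — often 10 to 50 molecules, far fewer than the 1–10 %
of the library that classical enrichment analyses assume — picking the
molecules to test from any single program's ranking is a gamble.

This package implements consensus selection over the *rankings* of
several docking programs, aimed exactly at that small-`n_test` regime,
together with the early-recognition metrics and the multi-target
benchmark protocol needed to evaluate such selections. It is intended
for computational chemists running structure-based virtual screens with
two or more docking programs, and for method developers benchmarking
selection strategies.

## The methods

For each program *p*, scores are standardized over the library:
*z* = ±(score − mean)/SD, signed so that larger *z* is always better.
The molecules with *z* ≥ *x* are that program's **stand-out set** at
cutoff *c* = *x* × SD.

* **SDC** (standard-deviation consensus): fix *x* (canonically *x* = 2,
  where the stand-out tail separates from the score histogram) and take
  the molecules common to all *k* programs' stand-out sets. The number
  of consensus molecules, nCM, varies by target.
* **vSDC** (variable SDC): fix nCM = `n_test` instead, and lower *x*
  from 3.5 in steps of 0.001 until the intersection holds `n_test`
  molecules. Each target gets its own cutoff; the user gets exactly the
  number of molecules they can assay.
* **USC** (united subset consensus): the union of each program's top
  `n_test/k` molecules, topped up round-robin to `n_test`. The
  complementary construction — unions favour breadth, intersections
  precision.

Selections are scored with metrics built for small selections rather
than whole-library AUCs: the yield of actives *Y* = *h*/*n_test*, the
docking enrichment *E* = *h*/*A*, the corrected yield
*Y*<sub>C</sub> = *h*/min(*A*, *n_test*) (the fraction of *findable*
hits found), the fraction of targets with at least one hit
*T*<sub>h>0</sub>, and the net balance of targets Δ*p* on which one
method beats another (ties excluded).

The benchmark harness dilutes each target's actives to a realistic
density (0.5 % by default), sweeps `n_test` over a grid, and aggregates
the three cohort criteria across targets. A synthetic generator
(latent-signal model with planted actives, tunable inter-program
correlation and per-program sensitivity) makes the whole pipeline
testable without any docking output.

## Worked example

```r
library(vSDC)

cfg    <- generatorConfig(seed = 101)      # 2000 molecules, 0.5 % active, 4 programs
bundle <- generateTarget(cfg)
tabs   <- bundleTables(bundle)

res <- vsdc(tabs, n_test = 10)
res
#> ConsensusResult (vSDC): nCM = 10
#>   x used: 1.058
#>   per-program cutoffs (score units): prog1 = 0.979, prog2 = 0.9917, prog3 = 0.9874, prog4 = 8.443
#>   members: mol001454, mol000956, mol001865, mol000825, mol001466, mol000095, mol001853, mol001233 ...

out <- countHits(res, bundleLabels(bundle))
out
#>      target n_test h  A
#> 1 synthetic     10 8 10
correctedYield(out)
#>     Y   E Y_C
#> 1 0.8 0.8 0.8
```

The scan settled at *x* = 1.058 (per-program cutoffs *c* = *x* × SD are
reported in each program's own score units — around 1 kcal/mol-like
units for the three free-energy-style programs, 8.4 fitness points for
the fourth). Of the 10 consensus molecules, 8 are true actives
(*Y* = 0.8); with 10 actives plantable and 10 molecules tested,
*Y*<sub>C</sub> = 0.8 of the findable hits were found. The best single
program's top 10 finds 3:

```r
countHits(topN(tabs[[1]], 10), bundleLabels(bundle))
#>      target n_test h  A
#> 1 synthetic     10 3 10
```

That gap persists even though the programs' rankings barely agree —
pairwise |Spearman rho| ≈ 0.17–0.19 here:

```r
round(rankCorrelationMatrix(tabs, absolute = TRUE), 2)
#>       prog1 prog2 prog3 prog4
#> prog1  1.00  0.18  0.19  0.17
#> prog2  0.18  1.00  0.19  0.17
#> prog3  0.19  0.19  1.00  0.18
#> prog4  0.17  0.17  0.18  1.00
```

## Command line

A thin `vsdc` Rscript installs with the package (`exec/vsdc`):

```sh
vsdc simulate  --out sim --targets 5 --seed 1
vsdc benchmark --manifest sim/manifest.yaml --out bench --n-max 20 --seed 1
vsdc consensus --method vsdc --n-test 10 --directions lower_better \
               --out sel.csv glide.csv surflex.csv flexx.csv gold.csv
vsdc correlate glide.csv surflex.csv --directions lower_better
```

Score files are plain CSV/TSV (`id,score[,parent]`, configurable column
names, `#` comments ignored); activity labels are two-column
(`id,0/1` or `id,active/inactive`); benchmark runs are described by a
YAML manifest (see `?readBenchmarkManifest`).

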