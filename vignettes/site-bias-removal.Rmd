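---
title: "Removing acquisition-site bias from slide representations by many-objective feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing acquisition-site bias from slide representations by many-objective feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidesieve)
```

## The problem

Deep features extracted from whole-slide histopathology images (WSIs) are
meant to encode tissue morphology, but in multi-centre archives they also
encode *where* a slide was scanned: stain protocols, scanner hardware and
patient demographics differ between hospitals, and a classifier can learn to
recognise the contributing institution from the features alone. When the
downstream task is diagnosis-level image search, this site signal is a
shortcut that inflates internal benchmarks and collapses on data from an
unseen hospital.

slidesieve treats bias removal as wrapper feature selection over the feature
dimensions. A candidate subset is a binary mask
$m = (m_1, \dots, m_D) \in \{0,1\}^D$, scored on three objectives, all
minimised:

* $f_1 = 1 - \mathrm{macroF1}$ of $k$-nearest-neighbour diagnosis retrieval
  ($k = 3$, Euclidean distance on the selected dimensions; validation slides
  queried against the training slides). Macro averaging weights every
  diagnosis equally, so small subtypes count as much as common ones.
* $f_2 = \tfrac1D \sum_i m_i$, the fraction of dimensions kept — compact
  codes retrieve faster and store smaller.
* $f_3$ = accuracy of a one-vs-all linear SVM trained to predict the source
  institution from the selected dimensions — the *bias indicator*. A subset
  on which no classifier can recover the site carries no exploitable site
  signal.

The three objectives genuinely conflict (dropping site-informative
dimensions can cost retrieval accuracy; compactness fights both), so the
result of an optimisation is not one subset but a Pareto front of
trade-offs. For reporting, the convention is to pick the front member with
maximum validation search F1 and examine how much site classifiability it
gave up.

## The optimizer

`run_nsga3()` is a binary-encoded NSGA-III:

1. random initial population (each bit set with probability `init_density`);
2. binary tournament on non-domination rank for mating selection;
3. one-point crossover (probability 0.9) and independent per-bit mutation
   (rate $1/D$); all-zero offspring are repaired to a random single bit,
   because an empty subset cannot be evaluated;
4. parents and offspring compete in environmental selection: fast
   non-dominated sorting admits whole fronts until one would overflow the
   population size, and the splitting front is filled by reference-point
   niching — candidates associate to the nearest of the
   $\binom{p+2}{2}$ Das–Dennis reference lines (perpendicular distance in
   normalised objective space) and seats go to the least-crowded lines;
5. an external archive accumulates every evaluated individual and keeps the
   non-dominated set, so the reported front never depends on what the final
   population happened to retain.

Both the final population's front and the archive are returned; the archive
is what the reporting helpers use.

Decisions the NSGA-III literature leaves open, pinned here:

* **Normalisation.** Objectives are shifted by the per-generation ideal
  point and divided by the component range over the union population, with
  zero ranges replaced by 1. All three objectives are already bounded in
  $[0,1]$, which makes the canonical extreme-point/hyperplane-intercept
  construction unnecessary in the common case; it remains available as
  `normalization = "hyperplane"` and falls back to the range form whenever
  the extreme-point system is degenerate.
* **Niching tie-breaks.** Least-crowded reference point, ties broken
  uniformly at random; an empty niche takes its closest associated
  candidate, a non-empty one a random associated candidate.
* **Mating selection.** Binary tournament on rank, ties uniform.
* **Duplicate masks** are served from an evaluation cache but still consume
  fitness budget, keeping the budget an honest count of fitness *calls*.
* **Determinism.** All randomness flows from `config$seed` through R's RNG;
  the SVM solver uses a fixed internal permutation stream. Two runs with
  the same config are bit-identical, and replicate $r$ of an experiment
  uses seed $\texttt{base} + r$.

Defaults are the method's full-scale operating point (population 50,
$k = 3$, linear SVM, fitness budget 512,000 — desk-scale runs pass a
smaller budget explicitly), with standard values for everything else
(crossover 0.9, mutation $1/D$, Das–Dennis divisions 12 giving 91 reference
points for three objectives, initialisation density 0.5; a sparse
`init_density` such as 0.05 is available because selected subsets tend to be
very small).

## The objective implementations

Retrieval prediction is majority vote among the $k = 3$ nearest training
slides; a majority tie goes to the tied label with the nearest
representative, and equal distances resolve to the lower training-row
index, so evaluation is deterministic. Precision, recall and F1 use the
0-when-0/0 convention, keeping every score defined and bounded.

The site probe is a one-vs-all linear SVM (regularisation $C = 1$, features
unstandardised by default; both exposed in `moo_config()`). It is refit
from scratch at every fitness call — exact but the dominant cost of a run —
so the solver is compiled code: dual coordinate descent with shrinking for
the L1-loss linear SVC, stopping when the projected-gradient spread falls
below 0.1 or after 100 passes. The iteration cap changes the probe's
validation accuracy by well under 0.01 on the benchmark while roughly
halving its cost; the test suite cross-checks the probe against an
independent libsvm-based one-vs-all implementation. Site accuracy is plain
micro accuracy (the correct-prediction fraction over all evaluation
slides), not a per-site macro average.

During optimisation the fitness queries the validation split against the
train split; final reporting (`evaluate_on_test()`) queries the test split
against the train split, and validation rows take no part in it.

## The synthetic benchmark

Real multi-centre slide archives cannot ship with a package, so
`generate_biased_dataset()` plants a known version of the phenomenon. Four
kinds of dimensions are generated around Gaussian centroids
(`noise_sd` = 1): *class* dimensions shift with the diagnosis, *site*
dimensions with the institution, *confounded* dimensions with both added,
and *noise* dimensions with neither. Centroids within a block of $d$
dimensions are vertices of a seeded random orthonormal frame scaled so
every pair sits $\mathrm{effect} \cdot \sqrt{d/2}$ apart — total separation
grows with the block size the way accumulating per-dimension signal does,
and never falls below the stated effect. At the default effect of 2, the
16-dimension class block alone supports near-ceiling retrieval only when
most of its dimensions are kept, and the site block makes the institution
almost perfectly classifiable from the full feature set — the regime
observed in real multi-centre archives such as TCGA, where deep features
(KimiaNet, DenseNet) identify the contributing institution with
accuracies far above chance, scaled to desk size.

Label confounding is modelled on the label distribution, not the features:
each diagnosis draws its sites from a mixture of a uniform distribution
(weight $1-c$) and a round-robin block of "its own" sites (weight $c$).
At $c = 0$ site and diagnosis are independent; at $c = 1$ each diagnosis
lives on its own disjoint sites, which requires at least as many sites as
diagnoses and is otherwise rejected. This mirrors cohorts in which single
hospitals contribute predominantly one subtype, the regime in which site
shortcuts masquerade as diagnostic signal. One consequence worth keeping in
mind when reading results: under confounding, a probe can infer the site
*from legitimate diagnosis signal alone*, so site accuracy has a floor above
chance (about 0.52 at the benchmark's $c = 0.6$ with 4 diagnoses and 6
sites) that no feature subset retaining diagnosis information can go below.

The benchmark defaults — 128 dimensions (16 class, 16 site, 8 confounded,
88 noise), 4 diagnoses, 6 sites, effects 2.0, confounding 0.6, 60/20/20
samples per diagnosis per split — are calibrated to reproduce the
headline phenomenon at desk scale: high site classifiability
with all features, and a large drop at little or no retrieval cost after
selection. What the generator does *not* model: patch-level structure,
stain or scanner physics, heavy-tailed feature distributions, correlated
noise, class imbalance. Passing recovery tests on it shows the optimizer
does what is claimed on a feature table with planted structure — not that
any particular real archive will yield the same margins.

## Desk-scale protocol and problem sizes

At full scale the method runs 512,000 fitness calls per tumour type and
31 replicates. The package's own experiments (tests and the acceptance script)
use the benchmark above with population 50, 10,000 fitness calls (199
generations), Das–Dennis divisions 12, and medians over 5 seeds — sizes
chosen so a full recovery experiment runs in minutes on one core while
leaving the algorithm enough budget to strip the planted site block. On
this protocol the picked max-F1 subset typically keeps around half to two
thirds of the class dimensions, none (or almost none) of the pure-site
dimensions, and a few confounded/noise dimensions, reducing site accuracy
by 50+ percentage points while validation search F1 does not degrade.

```{r, eval = FALSE}
gen <- generate_biased_dataset(synthetic_spec(seed = 1))
cfg <- moo_config(fitness_budget = 10000, seed = 1)
run <- run_nsga3(gen$table, cfg)
pick <- pick_max_f1_solution(tidy(run))
ground_truth_report(pick$mask[[1]], gen$truth)
autoplot(run)
```

## Statistical reporting

`wilcoxon_compare()` implements the paired two-sided Wilcoxon signed-rank
test used to compare selected-feature metrics against all-feature metrics
across replicates: zero differences dropped, mid-ranks for ties, exact
p-values (sign-pattern enumeration by convolution, so ties are honoured) up
to 25 non-zero pairs and a tie-corrected normal approximation with
continuity correction beyond. A single surviving pair yields p = 1 rather
than an error. The report flags p < 0.05. The pairing — per-replicate
selected metric against the fixed all-features metric on the same data — is
one reading of a protocol that names the test but not the comparison, and
is therefore kept in one place (`render_report()`).

## Known limitations

* The site probe is refit per fitness call; budgets far beyond $10^5$ calls
  on large tables are expensive in this implementation.
* The SVM probe is linear by design (the standard bias indicator); a subset can
  in principle carry nonlinearly decodable site signal that $f_3$ does not
  see.
* `external_validation()` evaluates leave-one-out retrieval *within* the
  external cohort; it does not re-run selection, so it measures transfer of
  a mask, not of the optimiser.
* Tumour types with a single diagnosis have no defined retrieval objective
  and are skipped (with a warning) by `run_experiment()`.
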