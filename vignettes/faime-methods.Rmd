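---
title: "Mechanism scoring, signatures and prognosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism scoring, signatures and prognosis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faime)
```

## The model

The package turns a gene-by-sample log-expression matrix into a
mechanism-by-sample score matrix, one sample at a time. Within sample $s$
over the measured universe $G$, genes get average-tie ranks
$r_{g,s} \in [1, |G|]$ (highest expression $\mapsto |G|$) and weights

$$w_{g,s} = r_{g,s}\, e^{-r_{g,s}/|G|},$$

monotone increasing on $[1, |G|]$: the transformation deliberately
prioritizes each sample's most abundant transcripts and discounts the
noisy low end. A mechanism $i$ (any geneset $GO_i \subset G$) scores

$$\mathrm{FM}^{raw}_{i,s} = \frac{1}{|GO_i|}\sum_{g \in GO_i} w_{g,s}
 \;-\; \frac{1}{|G \setminus GO_i|}\sum_{g \notin GO_i} w_{g,s},$$

the difference between the set's *normalized centroid* and its
complement's. Because most pathways are assumed unchanged between groups,
scores are normalized within each sample:
$\mathrm{FM}_{i,s} = \mathrm{FM}^{raw}_{i,s} - \min_j \mathrm{FM}^{raw}_{j,s}$,
taken across the mechanisms of one collection only (GO and Cancer-Module
scores are never pooled for the minimum — the minimum is a
collection-level reference point).

Assumptions worth stating plainly:

* input is pre-normalized log-scale expression; the transformation is
  rank-based within sample, hence invariant to any strictly monotone
  per-sample transform, but not to gene-level artifacts that reorder genes;
* scores are *relative*: a mechanism's score moves when other genes'
  ranks move, so large perturbations (many genes shifted) propagate to
  every mechanism (see "what a green test establishes" below);
* the complement mean makes a set equal to the whole measured universe
  degenerate — such sets are rejected (`filter_collection()` drops them).

## Rank orientation

The weight formula is increasing in rank, and the construction's intent is
to prioritize highly expressed genes, so the package maps the
highest-expressed gene to rank $|G|$ (maximal weight). A textual reading of
"descending sort + decreasing weight" would invert this; the inverse is
available as `orientation = "low-is-max"` for sensitivity analysis, never
as a silent default.

## Downstream pipeline

1. **Differential mechanisms** (`test_mechanisms()`): per-mechanism
   two-sided two-sample t-test on the rescaled scores; Student
   (pooled-variance) by default — the older "standard" test — with a Welch
   flag since the choice is not forced; `use = "raw"` is available for
   audit. Benjamini–Hochberg step-up adjustment (`bh_adjust()`, written
   out and cross-checked against an independent oracle). A signature at
   FDR $\alpha$ (`build_signature()`) is the set of mechanisms with
   $q \le \alpha$, each tagged with direction
   $\mathrm{sign}(\bar{x}_{tumor} - \bar{x}_{normal})$; exact-zero
   differences carry no direction and are excluded.
2. **Cross-dataset overlap** (`directional_intersect()`): a mechanism is
   shared only if present in *every* signature with the *same* direction;
   sizes are reported as a percentage of each parent signature. The
   pairwise Fisher exact p is the one-sided hypergeometric upper tail on
   the common tested universe (mechanisms tested in both datasets — the
   only support on which overlap is defined; the direction requirement is
   not modeled in this null, making the p conservative in scale).
3. **Gene-level bootstrap** (`bootstrap_overlap_p()`): signatures are
   converted to their constituent gene unions and compared by drawing
   fixed-size uniform subsets without replacement from each signature's
   measured background (default 10,000 draws), counting draws whose
   intersection reaches the observed overlap. The empirical p uses the
   permutation-style add-one correction $(b+1)/(B+1)$, never exactly 0.
   Fixed-size subset draws (not per-gene Bernoulli resampling) match the
   set-overlap semantics. The seed is a required, recorded argument.
4. **Prognosis** (`pam_partition()`, `logrank_test()`): validation scores
   are restricted to the signature, samples are split by classic
   deterministic PAM ($k=2$, BUILD then best-improving SWAP to a local
   optimum, Euclidean distance, ties by input order — no random restarts,
   hence "parameter-free" and reproducible without a seed), and
   recurrence-free survival separation is tested with the product-limit
   estimator and the standard log-rank statistic (hypergeometric variance
   per distinct event time; simultaneous events share one risk table).
   Which cluster is "good prognosis" is read off the KM curves post hoc,
   never from the cluster index. Distances are unstandardized by default
   (`standardize = TRUE` available): rescaled scores share a common scale
   within a collection, and per-mechanism z-scaling would erase the size
   differences the clustering is meant to exploit.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `min_size` (`filter_collection`) | 5 genes | tiny sets make the centroid noise-dominated; overridable to mimic unfiltered runs (no upper limit by default) |
| `fdr_level` | 0.05 (0.01 conventional alternative) | signature stringency |
| `variant` | `"student"` | pooled-variance t; `"welch"` flag kept for audit |
| `orientation` | `"high-is-max"` | see above |
| `n_draws` | 10,000 | bootstrap resolution; smallest attainable p is $1/(B+1)$ |
| `standardize` (PAM) | `FALSE` | distances on scores as given |
| CV (probe collapse) | sd$/$mean, $n-1$ denominator, on stored values | conventional definition; ties to the lexicographically smallest probe id; zero-mean probes rank last with a warning. Whether collapse happens before or after log transformation is a caller decision — the function operates on the matrix as given |
| gene2go reading | direct annotations only, `NOT` qualifiers excluded, branch `"Process"` | no ontology-graph propagation (explicit non-goal) |

## The synthetic generator: what a green test establishes

`sim_config()` defaults state the simulated world: 1000 genes, 200 sets of
10–50 genes, 10 planted sets at a standardized gene-level effect of 1.5
noise-SDs in 25+25 tumor/normal samples, unit Gaussian noise on the log
scale, dataset-specific per-gene offsets (SD $0.3\sigma$) modelling
cross-cohort heterogeneity, and an exponential recurrence model with
hazards 0.01 vs 0.03 per month (ratio 3), 20% uniform censoring, 120-month
horizon — sizes in the range of the prostate-cancer cohorts this pipeline
is aimed at. Deregulation is planted at the *gene* level (member means
shifted), so recovery tests exercise the whole chain rank → weight →
centroid → rescale → t-test, not just the statistics.

What the generator does **not** emulate: probe-level artifacts,
cross-hybridization, batch structure, stromal contamination,
heavy-tailed intensity distributions, correlated gene–gene noise within
pathways. A green recovery test therefore establishes algorithmic
correctness under the stated model, not robustness to microarray
pathology.

Two emergent properties of the stated world deserve a note, because they
look surprising but are *correct* behavior:

* **Signature density.** Because scores are rank-relative, shifting the
  ~300 member genes of 10 planted sets reorders the ranks of all 1000
  genes, and the per-sample minimum subtracted by the rescaling is itself
  group-dependent. At effect 1.5 with $n = 25+25$ essentially the whole
  collection becomes significant (signatures near 100%); at milder
  effects signatures are selective. Real cohorts in this family show the
  same spread (tens of percent of the search space, strongly
  heterogeneous across datasets).
* **Bootstrap saturation.** When both signatures cover nearly the whole
  collection, their gene unions equal the background and the gene-level
  bootstrap p is 1 by construction (the saturated boundary case): every
  draw reproduces the observed overlap. The end-to-end smoke test asserts
  the bootstrap runs and returns a valid probability; calibration is
  tested separately on sparse nulls.

## Numerical choices

* Ties in expression: average ranks (deterministic, input-order
  independent). Probe-CV ties: lexicographically smallest probe id.
* `bh_adjust` validates $p \in [0,1]$, caps at 1; agreement with an
  independent step-up implementation is tested to $10^{-12}$.
* Zero-variance mechanisms: $t = 0, p = 1$ when the means agree (logged);
  exact separation with zero variance gives $p = 0$.
* PAM uses a $10^{-12}$ improvement tolerance in SWAP to guard float
  noise; the final configuration is verified (in tests) to admit no
  improving single-medoid swap.
* Log-rank with no events returns statistic 0, $p = 1$, with a warning,
  and degenerate variance is guarded ($n_j = 1$ risk sets contribute 0).
* The bootstrap-calibration acceptance test uses a null design (universe
  1000, sets of 200 and 300) whose hypergeometric overlap has modal atom
  probability ≈ 0.07: with small sets the overlap distribution is so
  discrete (atoms ≈ 0.2) that *no* valid p-value could sit within the
  stated KS band of U(0,1); the chosen design makes near-uniformity
  assessable rather than vacuously false.

## Known limitations

* Mechanism-level FET treats mechanisms as exchangeable units; gene
  sharing between sets is ignored at that level (the gene-level bootstrap
  exists precisely to compensate).
* PAM is $O(n^2)$ in samples via the full distance matrix — fine for
  cohort-scale data, not for atlas-scale single-cell matrices.
* No Cox modelling or covariate adjustment; the survival layer is
  two-group KM/log-rank by design.
* Single-mechanism collections are allowed but degenerate (the rescaling
  pins the lone score at 0); a warning is emitted.
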