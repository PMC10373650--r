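---
title: "Detecting pre-disease states with single-sample Markov flow entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pre-disease states with single-sample Markov flow entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many complex diseases progress through three qualitatively different
regimes: a relatively normal state, a pre-disease (critical) state poised
just before a drastic transition, and the disease state proper. The
critical state is the clinically valuable one — it is still reversible —
but it is hard to see in mean expression levels, which often change little
until after the transition. Dynamic network biomarker (DNB) theory
predicts that near the tipping point a group of interacting molecules
becomes highly volatile: within the group, pairwise Pearson correlation
(PCC~in~) and standard deviation (SD~in~) rise sharply while correlation
with molecules outside the group (PCC~out~) falls.

Classic DNB statistics need many samples per time point. This package
implements a single-sample formulation: given a cohort of reference
samples (e.g. tumor-adjacent tissue) and **one** case sample, it measures
how much that single sample perturbs an entropy functional defined on a
directed gene-interaction network.

## The score

Expression is first normalized per gene to $[0,1]$ by the min–max
transform fitted on the reference cohort; case samples are transformed
with the same fit and clipped, so one extreme sample can never rescale the
reference. For a center gene $g^k$ with $M$ first-order neighbors
$g^k_1,\dots,g^k_M$ in the directed network, the transition probability to
neighbor $i$ over a cohort is

$$p_{ki} \;=\; \frac{|PCC(g^k_i,\,g^k)|}{1+\sum_{j=1}^{M}|PCC(g^k_j,\,g^k)|},$$

where the constant 1 in the denominator is the self term (the center's
correlation with itself). The local Markov flow entropy of $g^k$ is

$$MFE_k \;=\; -\sum_{i=1}^{M} \bar x_k\, p_{ki}\,\log(\bar x_k\, p_{ki}),$$

with $\bar x_k$ the cohort mean of the center's normalized expression,
natural logarithms, and $0\log 0 = 0$. Both quantities are computed twice:
on the $n$ reference samples alone, and on the $n+1$ "mixed" cohort formed
by adding the single case sample. The differential score of gene $k$ for
that sample is

$$sMFE_k \;=\; \frac{1}{\log M}\,\bigl|\,SD^{n}\cdot MFE^{n}_k \;-\;
SD^{n+1}\cdot MFE^{n+1}_k \,\bigr|,$$

where $SD$ is the population standard deviation of the center's
normalized expression in the corresponding cohort. The per-sample global
score averages the $Q=\lceil 0.05\,L\rceil$ largest local scores over the
$L$ scoreable genes; those $Q$ genes are the sample's *signaling genes*.

For fixed $\bar x_k$ and fixed total probability mass, the entropy is
maximal when the transition probabilities are uniform (concavity of
$-u\log u$) and minimal when the flow concentrates on a single neighbor;
`local_mfe()` carries a property test of both facts. Near a tipping point
the DNB group's correlation structure reorganizes, the case sample drags
the mixed-cohort SD and correlations away from the reference values, and
the top tail of the local scores — hence the global score — rises.

### A note on the differential form

The printed form of the differential combines the mixed-cohort terms
additively ($SD^{n}\,MFE^{n}_k - SD^{n+1} + MFE^{n+1}_k$), which is
dimensionally asymmetric between the two cohorts. The package's default is
the symmetric SD-weighted difference shown above, which is what
"differential entropy" between an $n$- and an $(n{+}1)$-cohort means; the
additive combination remains available via `eq6_form = "literal"` for
comparison.

## Choices the formulas do not pin down

* **Neighbors are out-neighbors.** The transition probability describes
  mass flowing *from* the center along directed edges, so the local
  network of a gene is its out-neighborhood by default
  (`neighbor_mode = "out"`; `"in"` and `"both"` are available).
* **Genes with fewer than 2 neighbors are not scoreable.** The $1/\log M$
  normalizer is infinite at $M=1$ and undefined at $M=0$. Such genes are
  excluded from $L$ but still serve as neighbors of other centers.
* **Population (divide-by-$n$) SD.** The two cohorts differ by exactly one
  sample; the $n/(n-1)$ sample-variance correction would inject a spurious
  difference unrelated to the case sample.
* **Zero-variance conventions.** The PCC of any pair involving a
  zero-variance vector is 0; a gene constant in the reference normalizes
  to 0 everywhere; a constant center yields $sMFE_k = 0$.
* **Deterministic ordering.** Neighbors are sorted lexicographically and
  ties at the signaling cutoff break by descending score then ascending
  gene id, so every run is bit-reproducible.
* **Per-gene normalization.** Min–max is taken per gene across reference
  samples (not per sample across genes), keeping each gene's $[0,1]$ scale
  anchored to its own reference dynamics.

## Calling the tipping point

Samples are scored one at a time, grouped by clinical stage in the
user-supplied order, and the stage with the largest mean global score is
the candidate critical state. Its scores are compared against all other
samples pooled with a two-sided Welch t-test; the candidate is reported as
critical when $P<0.05$. The increase direction is enforced by the argmax,
not by one-sidedness.

Because the tested stage is *selected* as the argmax, the null
(family-wise) rate of the call exceeds the nominal level and grows with
the number of stages: with 20 samples per stage it is roughly 7.5% for
three stages and above 10% for five. The package's null-calibration
checks therefore use three stages; users comparing many stages should
expect this mild selection inflation — a known limitation of
argmax-then-test procedures.

## Prognostic biomarkers

Signaling genes feed a survival screen for two biomarker classes:

1. Samples are split at the **median survival time** (raw time, censored
   or not); ties at the median go to the long-survival group (the strict
   greater/less rule leaves them unassigned; the rule is switchable).
2. A candidate biomarker is a **non-differentially-expressed** signaling
   gene whose identified samples (signaling set contains the gene) skew
   toward one survival group: $n/(n+m) > A$ or $m/(n+m) > A$ with
   $A = 0.6$, where $n$ and $m$ count identified samples in the long and
   short group.
3. Each candidate is classified by a **log-rank test** between identified
   and unidentified samples: optimistic (O-sMFE) when identified samples
   survive significantly longer, pessimistic (P-sMFE) when shorter.

Two sub-choices are deliberately explicit because no single convention is
standard. The *direction* of "longer survival" is measured by the
difference in restricted-mean survival over the common follow-up window
(curve medians can be undefined under heavy censoring, and curves may
cross). The *non-DE screen* — never specified beyond "non-differently
expressed" in this literature — is a per-gene Welch t-test with
Benjamini–Hochberg adjustment at FDR 0.05, keeping genes with adjusted
$P \ge 0.05$; genes constant in both cohorts are kept as non-DE.
Censoring enters the log-rank test but not the median split.

## What the simulator emulates

`dnb_scenario()` + `make_dnb_dataset()` generate the minimal model that
realizes the three DNB conditions: per stage, samples are drawn from a
multivariate Gaussian with block covariance. The planted module uses
(`sd_base`, `rho_in_base`) everywhere except the designated critical
stage, where (`sd_crit`, `rho_in_crit`) apply and the module-to-outside
correlation drops to `rho_out_crit`. Defaults: 200 genes, a 20-gene
module, four stages × 30 samples plus 30 reference samples, SD tripling
(1 → 3), `rho_in` 0.2 → 0.8 and `rho_out` 0.2 → 0.05 at stage III, gene
mean 10. Values are clipped at 0 to keep expression nonnegative — a mild
distortion of the target moments, negligible at mean 10 with SD ≤ 3.
Stage effects enter only through the covariance, so mean expression stays
flat across stages and differential-expression analysis sees nothing
(a `mean_shift` knob exists for DE testing).

Because the module's covariance is compound-symmetric — every member pair
is dependent — the generator also wires the module as a complete directed
subgraph of the returned network (`wire_module = TRUE`). This matches the
DNB picture of a group of *interacting* molecules; without it the planted
correlation jump would mostly fall on gene pairs that are not network
neighbors and would be invisible to a local-network score.

What the simulator does **not** emulate: RNA-seq count noise (negative
binomial mean–variance coupling), batch effects, realistic expression
marginals, or network modularity beyond the planted block. Passing the
recovery checks therefore demonstrates that the method detects the DNB
signature it targets, not that it will show the same power on real tumor
cohorts.

Survival is exponential with the hazard multiplied by `hazard_ratio` for
marker-positive samples; each sample is independently censored with
probability `censor_rate`, the censoring time drawn uniformly before the
event.

## Problem sizes used by the checks

The statistical guarantees shipped with the package are computed at desk
scale, chosen to give clear separation at modest cost: formula-oracle
agreement on all labelled digraphs with 2–3 nodes plus random 4–5-node
graphs (tolerance $10^{-10}$); entropy maximality over 1000 random
probability vectors; tipping recovery over 50 replicates of the default
scenario (≥ 90% required); null calibration over 1000 three-stage
replicates (≤ 8%); biomarker power at hazard ratio 3 with 50+50 samples
over 100 replicates (≥ 80%) and a matched null rate (≤ 10%); and
byte-level determinism of a full pipeline run.

## Known limitations

* The score of a case sample depends on the reference cohort's size: one
  sample among $n+1$ has leverage $\sim 1/n$, so very large reference
  cohorts dilute the signal and very small ones make correlations noisy.
* Argmax-selection inflates the critical-state call rate with many stages
  (see above); a selection-adjusted test is not provided.
* The undirected fallback (`directed = FALSE`) doubles every edge and
  makes local networks symmetric; orientation from an external network
  inference method is preferred when available.
* The enrichment parameter $A$ gates candidacy only; final classification
  relies on the log-rank test alone.
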