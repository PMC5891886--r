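---
title: "Differential epithelium–stroma proteomic networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential epithelium–stroma proteomic networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromanet)
```

## The analysis in one paragraph

A colorectal-cancer cohort is profiled twice: paired ordinal IHC scores of
TRIM28 in tumor epithelium and stroma, and spot-level RPPA intensities of a
30-endpoint signaling panel measured separately in laser-capture-
microdissected epithelial and stromal cell populations. The IHC scores
stratify the cohort into *high* and *low* epithelium:stroma expression-ratio
groups; the RPPA data, after normalization, dilution reduction and a
negative-control quality screen, yield one abundance value per case ×
compartment × endpoint. Within each ratio group and compartment, every
endpoint pair is tested for Spearman correlation; the significant edges of
the two groups are partitioned into shared and group-exclusive sets, and
only the exclusive edges — the *differential* correlation structure — are
assembled into networks and subgrouped by modularity. Endpoint levels are
additionally compared between strata with independent-samples t tests.

## Ratio classification

Scores are the conventional 0 (absent) / 1 (weak) / 2 (moderate) / 3
(strong) scale per compartment. With epithelial score $E$ and stromal score
$S$, the rule is

$$\text{high ratio} \iff E - S \ge 2.$$

The difference is signed: the published examples all have epithelium
dominant, and a "high epithelium:stroma ratio" semantically means low
stroma, so a stroma-dominant case ($S > E$) is always low. This was a
genuinely open reading (signed vs absolute difference); the signed form is
implemented and the exhaustive 16-pair truth table is frozen in the tests.

The packaged 19-case reference cohort (`trim28_ihc_cohort()`) reconstructs
the published score distribution: the ten high-ratio pairs are enumerated
in the source ((3,0)×1, (3,1)×6, (2,0)×3) and the nine low-ratio pairs are
the unique completion of the published epithelial (8 strong / 9 moderate /
2 weak) and stromal (2 moderate / 12 weak / 5 absent) marginals together
with the two described low-group cases. It is a faithful reconstruction of
the distribution, not a claim about which patient had which pair.

## RPPA quantification

Three steps, in this order:

1. **Replicate averaging** — arithmetic mean of replicate spots per case ×
   compartment × stain × dilution step (the data model allows replicates;
   the reference design prints one spot per step).
2. **ssDNA normalization** — each antibody spot is divided by the ssDNA
   stain intensity of the corresponding spot at the *same dilution step*
   (nearest available step with a warning if missing). This corrects for
   deposited cell number/loading; the quotient makes the whole pipeline
   invariant to rescaling a sample's slide together with its ssDNA spots.
3. **Dilution reduction** — each 4-point 2-fold series collapses to
   $\exp\!\big(\tfrac1m\sum_{j} \log(d_j \, y_j)\big)$, the geometric mean
   of dilution-corrected values over the $m$ points above the detection
   floor. On an ideal 2-fold series every product equals the undiluted
   value, so the reduction returns it exactly. The original study reduced
   its curves with an unpublished spreadsheet macro; this reduction is the
   package's own documented procedure, chosen because it is robust on the
   multiplicative noise scale and has the right fixed point on ideal data.

A **linearity flag** records whether the fitted slope of $\log_2 y$ against
$-\log_2 d$ is within `slope_tolerance` (default 0.3) of 1; a saturated
(flat) series has slope ≈ 0 and is flagged but still reported. Fewer than
two usable points leave the endpoint missing for that case; such cases are
retained and downstream correlations use pairwise-complete observations.

**Detection floor** — `2 × median(negative-control intensity)`, applied on
the normalized scale per spot. **QC screen** — per case × compartment, the
per-endpoint mean raw intensities are tested against that unit's
negative-control spots with a one-sided Welch t test (`qc_alpha = 0.05`);
the unpaired one-sided location test is the natural reading of "not
significantly different from the negative control", and Welch because the
signal and control variances have no reason to agree. A case failing in
either compartment is excluded entirely, mirroring the 19 → 18 exclusion
in the reference design. Identical constant inputs are reported with
$p = 1$ by convention rather than as an error.

## Correlation edges and the differential partition

For each group × compartment matrix (rows = cases, ≥ 4 required), all
$\binom{30}{2} = 435$ unordered pairs are evaluated. Spearman's $\rho$ uses
average ranks (deterministic under ties); the two-sided p-value is the
$t$ approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df — the
default of the mainstream commercial statistics packages this workflow
mirrors — with $|\rho| = 1$ reported as the exact permutation value
$2/n!$. An exact full-enumeration permutation p (`exact = TRUE`, $n \le 8$)
exists mainly as the small-sample oracle used in the tests.

The significance rule is **joint**: $\rho \ge 0.75$ *and* $p \le 0.01$,
with the $\rho$ condition one-sided positive, read literally from the
stated rule. The two conditions do not coincide: at $n = 9$, $p \le 0.01$
(two-sided) requires $\rho \ge 0.798$, so the p-condition is the binding
one and an edge with $\rho = 0.76$ at $n = 9$ is *not* significant — a
regression test pins this. Whether the original p-values were one- or
two-sided is not recoverable; two-sided is the default and an
absolute-value $\rho$ filter is available behind `abs_rho = TRUE`.
No multiple-testing correction is applied across the 435 pairs — a
deliberate emulation of the reference procedure, documented rather than
"fixed".

Edges are identified by their unordered endpoint pair in lexicographic
order, so set algebra across groups is well defined: *shared* = pairs
significant in both groups of a compartment; *exclusive* = pairs
significant in exactly one (each retaining its own $\rho$). The partition
identities ($|$shared$| + |$exclusive$_{high}| + |$exclusive$_{low}| =
|$union$|$, pairwise disjoint) are enforced by property tests on every run.

**Networks.** Exclusive edges form an undirected graph; isolated endpoints
are omitted, node size = degree, edge weight = $\rho$. Subgroups come from
Louvain modularity maximization at resolution 1 with $\rho$ weights —
the closest documented analogue of the modularity grouping that graph
visualization software applies to such networks ("determined by the
software" in the reference description). The partition is seeded and
reproducible; community ids are contiguous from 0. Export is GraphML (via
igraph) or GEXF (written and parsed by this package with xml2), both
round-tripping nodes, edges and attributes.

## Endpoint comparisons

Both published contrast families are implemented: epithelium vs stroma
within a ratio group, and high vs low ratio within a compartment. The test
is the independent-samples t test, Welch by default (group sizes ≈ 9–10
with no variance-homogeneity guarantee); `var_equal = TRUE` reproduces the
pooled convention, since which of the two the original package used is not
recoverable. Epithelium and stroma actually come from the same cases, so a
paired test would be defensible — the unpaired form is implemented because
that is what the reference procedure specifies; this is a fidelity choice,
not a statistical recommendation. Box-plot summaries report median, mean,
25th/75th percentiles (linear interpolation between order statistics,
`quantile` type 7 — conventions differ across software, so the choice is
fixed and documented) and the extremes.

## The synthetic cohort

`generate_cohort()` produces everything the pipeline consumes,
deterministically per seed. Design, per case × compartment:

* latent endpoint vectors from a **Gaussian copula**: a correlation matrix
  embedding the planted blocks for the case's ratio group, with latent
  Pearson correlation $r = 2\sin(\pi\rho_S/6)$ so a block's target is hit
  on the *Spearman* scale the pipeline measures;
* latents map to **log-normal** intensities
  ($\texttt{biological\_sd\_log} = 0.5$ around per-endpoint base levels
  $\sim \log 500$ scanner units) — RPPA intensities are positive and
  right-skewed, and the monotone map leaves rank correlations intact;
* each endpoint is spotted as a 2-fold dilution series with multiplicative
  noise ($\texttt{noise\_sd\_log} = 0.15$, a realistic spot-level CV of
  ~15%); ssDNA spots carry the per-case loading factor (uniform on
  0.7–1.4) times its own noise, flat across steps, so normalization
  followed by reduction cancels loading exactly;
* negative-control spots are a Gaussian floor (mean 2, SD 0.5 — two
  orders of magnitude below signal, as on a clean array);
* cases listed in `qc_fail_cases` get endpoint spots drawn from the floor
  distribution, so exactly they fail the QC screen.

`default_cohort_spec()` is the study-design instance: 19 cases with the
reference IHC distribution (10 high / 9 low), 30 endpoints, one high-ratio
case at the floor (9 + 9 enter network analysis), and per compartment one
shared block (5 endpoints, $\rho = 0.8$) plus one exclusive block per group
(5 endpoints, $\rho = 0.9$). The IHC scores and the correlation structure
are linked only through the group labels; no per-case joint model between
stain intensity and pathway activity is simulated. Also not simulated:
spatial array artifacts, antibody cross-reactivity, inter-observer scoring
noise, and survival outcomes. Passing tests on this cohort therefore
demonstrate correctness and calibration of the *pipeline*, not biological
validity of any particular network.

## Calibration and test design

Statistical thresholds in the test suite were fixed by a pre-build
Monte-Carlo calibration at the study's own conditions and are not tuned to
outcomes:

* at $n = 9$ per group, the joint rule's per-pair detection power for a
  planted Spearman $\rho = 0.9$ is bounded well away from 1 (the two-sided
  p-condition alone demands a sample $\rho \ge 0.798$), so the recovery
  tests require pooled exclusive-pair recovery ≥ 0.65 over 100 seeds,
  correct *routing* of detected exclusive pairs ≥ 0.95, shared pairs
  landing shared ≥ 0.45 (both independent groups must detect
  simultaneously), and unplanted pairs significant in ≤ 2% of slots;
* the null edge rate (independent Gaussian endpoints, $n = 9$, 30
  endpoints) is checked over 500 seeds against the nominal bound;
* Welch type-I error is checked over 5,000 replicates (replicate $i$
  seeded with $i$) within two binomial standard errors of 0.05;
* the t-approximation p is compared against a full-enumeration permutation
  oracle over all $5! = 120$ rank datasets at $n = 5$: identical evidence
  ordering, and exact agreement at $|\rho| = 1$.

These problem sizes (100–500 seeds, 5,000 replicates, $n = 9$ groups) are
the package's chosen test scale: large enough for the binomial error bars
quoted above, small enough that the whole suite runs in minutes.

## Numerical conventions and degenerate inputs

* Pairs with < 4 complete observations or a zero-variance margin are "not
  evaluable" (recorded, never silently significant).
* `cor()` can return $1 - 2\times10^{-16}$ on a perfect ranking; the
  $|\rho| = 1$ branch uses a $10^{-12}$ tolerance so such edges get the
  exact $2/n!$ p-value instead of a spurious 0.
* All randomness (generator, Louvain) is locally seeded and restores the
  caller's RNG state; identical config + seed gives byte-identical edge
  tables, reports and community labels.
* Thresholds are validated before any computation (`rho_min = 1.01` is an
  error, not an empty result).

## Limitations

The dilution reduction and the QC test are documented stand-ins for
procedures the reference description leaves unspecified; absolute values
are therefore comparable within a run, not across laboratories. Edge
significance at $n = 9$ has limited power and no multiplicity control, so
individual exclusive edges should be read as hypotheses, not findings —
the method's strength is the contrast of network-level structure between
groups. The modularity subgrouping depends on the chosen resolution (1.0)
and, on near-degenerate partitions, on the seed; only seeded runs are
comparable.
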