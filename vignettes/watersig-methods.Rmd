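---
title: "Methods: water-use microbiome signatures at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-use microbiome signatures at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watersig)
```

# The question and the data model

Water systems intended for different uses — conventional potable supply,
potable reuse, nonpotable reuse — carry microbial communities whose
composition tracks the intended use more strongly than treatment,
climate, or sequencing covariates. `watersig` implements the analysis
that makes this comparison quantitative, starting from three plain-text
inputs: a taxa × samples count matrix of non-negative integers
(`feature_table`), a Silva-style ragged lineage per taxon
(`taxonomy_map`), and per-sample metadata (`sample_frame`) carrying the
water use, the sampling stratum (POC: immediately after final treatment;
POU: after distribution), a blank flag, and an `atypical` flag for
systems excluded from the detection-frequency analysis (in the motivating
setting: potable systems fed a mixed surface/ground source with limited
treatment, which beta diversity places among nonpotable systems).

Identifier matching is exact and case-sensitive throughout; silent
normalization hides data errors we would rather surface.

# Stage by stage

## Decontamination (prevalence method)

Negative controls (field, trip, filtration and extraction blanks) identify
reagent and handling contaminants. For each taxon we form the 2×2 table of
presence (count ≥ 1) against sample type and score the one-sided
alternative "more prevalent in blanks": a Yates-corrected chi-square when
all expected cells are ≥ 5, otherwise Fisher's exact test. Taxa with score
below the threshold (default 0.1, the conventional default for this
method) are removed together with the blank columns before any downstream
stage. Two deliberate choices: the score depends only on the presence
pattern (abundance magnitudes carry batch effects we do not model), and
the test is one-sided because two-sided flagging would also delete
genuinely rare sample-side taxa. The threshold is configurable because the
appropriate stringency depends on the blank-to-sample ratio.

## Taxonomy collapsing

Features sharing a classification down to the analysis rank are summed,
conserving per-sample totals exactly in integer arithmetic. Silva
lineages are ragged; a lineage unassigned at the requested rank collapses
into an `unclassified_<parent>` bucket under its deepest assigned label,
one bucket per parent, so that unclassified mass is neither discarded nor
pooled across unrelated clades. This treatment is exposed rather than
hard-wired: collapsing at genus and then re-collapsing at phylum equals
collapsing at phylum directly, a property the tests assert.

## Primer harmonization

Mixed archives contain V4 (515f/806r) and V4–V5 (515f/926r) amplicons. The
longer amplicons are truncated at the 806r primer site in two passes:
pass 1 is an IUPAC-aware exact scan (a degenerate primer symbol matches
any base in its set at zero cost); survivors go to pass 2, a semi-global
alignment permitting substitutions and indels, accepting the best hit with
at most `floor(max_error_rate × primer_length)` errors (default rate 0.2,
i.e. 4 errors on a 20-mer). Ties on error count break toward the 3'-most
site because the primer sits at the 3' end of the amplicon region.
Sequences unmatched after both passes are retained and flagged
`untrimmed` rather than discarded — the discard rule is genuinely
underdetermined in practice, so it is the caller's decision. Trimming is
idempotent, and every tolerant hit's error count is checked in the tests
against a brute-force dynamic-programming alignment oracle.

## Diversity and the homogeneity-gated permutation stack

Alpha diversity reports richness (count ≥ 1), Shannon entropy (natural
log by default; the base is configurable) and Simpson diversity
(Gini–Simpson 1 − Σp² by default; the inverse form is available). Group
contrasts of alpha metrics use Wilcoxon rank-sum tests with
Benjamini–Yekutieli adjustment — the conservative FDR correction valid
under arbitrary dependence — at a significance cutoff of 0.01.

Beta diversity uses Bray–Curtis dissimilarities. Three permutation tests
run on the resulting `dist`:

* **ANOSIM**: R = (mean between-group rank − mean within-group rank) /
  (M/2), M = n(n−1)/2, so R ∈ [−1, 1] and is invariant to monotone
  transforms of the dissimilarities. For two-group designs an exhaustive
  mode enumerates every distinct relabelling and reports the exact
  permutation p.
* **Betadisper**: principal-coordinate embedding of the semimetric
  (negative eigenvalues are kept as an imaginary subspace), per-sample
  distance to the group centroid combined as
  sqrt(max(0, d_real² − d_imag²)), one-way ANOVA F, p by permutation of
  the least-squares residuals. Group centroids (not spatial medians) are
  used — the simpler estimator, and nothing in the motivating analysis
  requires medians.
* **PERMANOVA**: sequential (Type I) partitioning of the Gower-centered
  inner-product matrix G = −(1/2) C D² C via hat matrices of the
  cumulative design, per-term R² = SS/SS_total (terms plus residual sum
  to 1), pseudo-F against the full-model residual, p by free permutation
  of samples. Term order is the caller's, matching the convention of
  sequential distance-based ANOVA; the package does not guess an order.

Location tests on dissimilarities confound location with dispersion, so
ANOSIM/PERMANOVA results pass through a gate: they are marked "report"
only when Betadisper's p ≥ α (default 0.01); otherwise they carry
"heterogeneous – interpret conservatively". The gate annotates rather
than suppresses, since heterogeneous factors are still informative as
cofactors.

All permutation p-values use the +1 correction, p = (1 + #{T\* ≥ T}) /
(1 + n_perm), and are therefore never exactly zero; the default is 1000
permutations. Every test reproduces exactly under a fixed seed.

NMDS minimizes Kruskal stress-1 with monotone (isotonic) regression of
configuration distances on dissimilarity ranks. The first restart starts
from the principal coordinates of the input; subsequent restarts are
random with per-restart seeds derived from the top-level seed, so the
best-of-restarts stress is deterministic and non-increasing in the number
of restarts. Convergence tolerances: stress change below 1e-6 or 500
iterations. The iterative engine is `vegan::monoMDS`; the restart and
seeding policy is the package's.

## The signature classifier

Detection frequencies, core calls and discriminatory calls follow strict
inequalities deliberately: core means detected in *greater than* 80% of a
use's samples (exactly 0.80 is not core), discriminatory means core in
one use and *less than* 20% detection in the contrast **or** a gap
*greater than* 60%. Strictness matters at these round thresholds because
group sizes make exact boundary frequencies (e.g. 36/45 = 0.8000)
perfectly possible; the tests pin the boundary behavior.

Frequencies pool the samples of a group directly. An alternative —
averaging per-subsystem frequencies before pooling — would weight small
systems up; pooling was chosen as the primary definition because the
sampling design is already stratified by POC/POU, and the per-system
average is a plausible extension rather than a default.

The differential-abundance test follows the ANCOM construction: with
pseudocount 1 (abundance zeros are structural in presence-based
communities; 1 is the standard choice and is configurable), all pairwise
log-ratios are compared between potable (conventional ∪ reuse) and
nonpotable groups by rank-sum tests, BY-adjusted within each taxon's
family, and W_i counts the significant partners. The detection cutoff
w_frac = 0.7 of the family is the commonly used operating point. Classic
ANCOM defines no fold change; the LFC reported here is defined as the
difference in group means of centered-log-ratio transformed abundances
(natural log, nonpotable minus potable). This is a stated method choice:
it is antisymmetric under group swap (tested exactly) and reduces to the
log ratio of geometric means. ANCOM runs on the unmodified sample set
(blanks excluded, atypical systems retained), whereas the
detection-frequency classifier excludes atypical systems — the two
channels intentionally see slightly different denominators.

Consensus signature taxa must be ANCOM-significant in all three
comparisons (POC, POU, combined) with |average LFC| strictly above 1.5,
and are annotated with the strata in which they are also discriminatory
by frequency in the direction of their LFC. Requiring agreement between a
presence/absence channel and an abundance channel is the core robustness
idea: taxa that survive both are insensitive to the choice of rare-taxon
handling.

# The synthetic community generator

`community_spec` / `simulate_study` generate studies with known ground
truth. The model is a hurdle Dirichlet-multinomial: presence is Bernoulli
per taxon and group (the channel the core/discriminatory classifier
sees), relative abundances of present taxa are Dirichlet with group mean
profiles on the log scale and total concentration c = 50 (overdispersion
is required for ANCOM to be exercised non-trivially; a plain multinomial
would make counts nearly noiseless at these depths), and counts are
multinomial at lognormal depths (meanlog = log 20000, sdlog = 0.4 —
typical MiSeq per-sample depths). Per-sample totals equal the drawn
depths exactly. Blanks are drawn from a sparse background (occurrence
0.05, shallow depths) with contaminant taxa enriched tenfold.

`default_paper_like_spec(scale)` mirrors a 474-sample, three-use,
POC/POU-stratified survey with 30 blanks at `scale = 1` — group sizes
(244, 53, 177), each `ceiling(scale × n)` and split evenly across
strata. The planted structure: three nonpotable-enriched and three
potable-enriched discriminatory taxa (occurrence 0.9 in the core group vs
0.1 in the contrast, |log-fold change| = 2), a shared high-occurrence
backbone, three blank-enriched contaminants, and a background whose
between-group occurrence gaps stay below 0.3 — the false-positive
controls for the classifier.

One generator design point deserves emphasis: planted core and
discriminatory taxa sit at the community-mean base abundance. With a
random low baseline, a taxon's Dirichlet concentration α_i = c·share_i
falls well below 1 and its realized relative abundance frequently
collapses to ~0 even when the presence draw succeeded — realized
detection then falls far below the planted occurrence, and the generator
would violate its own contract that empirical detection frequencies track
the Bernoulli occurrence probabilities within binomial error. Pinning
planted taxa at moderate abundance is what makes "occurrence 0.9" mean
what it says; background taxa keep random N(0, 1) baselines.

What the generator does **not** emulate: sequencing error, chimeras,
compositional correlation structure between taxa beyond the shared
Dirichlet, per-system (batch) effects within a water use, phylogenetic
relatedness, and any POC→POU drift (locations share one community
distribution per use). Passing tests therefore demonstrate that the
statistical machinery behaves as specified under its own model — rank
boundary behavior, calibration under the null, recovery of planted
effects — not that any particular real-world water system will show these
effect sizes.

# Test and validation design

The suite validates every operation against an independent route:
exhaustive relabelling enumeration for ANOSIM (n = 6), ordinary ANOVA
variance partitioning for single-factor PERMANOVA on Euclidean
coordinates, direct geometry for Betadisper on Euclidean inputs,
hypergeometric enumeration for the exact decontamination branch, a
dynamic-programming alignment oracle for primer trimming, hand-applied
closed forms for Shannon/Simpson/Bray–Curtis/BY, and `vegan`
(`anosim`, `betadisper`, `adonis2`) as an independent implementation
cross-check of the permutation stack. Null calibration uses 50 seeds of a
structureless community (n = 40, 999 permutations) and checks both
rejection rates at α = 0.01 and KS uniformity of the p-value
distributions. Recovery uses the quarter-scale design (groups 61/14/45)
over a fixed ten-seed panel.

A known limitation, visible in that panel and worth stating plainly:
with 45 nonpotable samples, a planted occurrence of 0.9 lands at or below
the strict 80% core cutoff with probability ≈ 0.05 per taxon and seed
(36/45 = 0.8000 exactly occurs in the panel), and the ANCOM W statistic
in the smallest stratum (23 vs 38 samples) can fall marginally below the
0.7 operating point. Perfect per-seed recovery of every planted
relationship at this scale is therefore not a property the rules can
guarantee — pooled sensitivity across the panel is ≥ 0.9 with zero false
positives among the gap < 0.3 controls, and that pooled form is what the
package asserts as an invariant. At `scale = 1` the same boundaries are
comfortably cleared.

Problem sizes in the default test run were chosen to keep the full suite
in the low tens of seconds on a single core (calibration at n = 40,
recovery at quarter scale, 99–999 permutations in unit tests); the
statistics themselves are O(n²) per permutation and run comfortably at
the full 474-sample design.

# Known limitations

* Bray–Curtis is a semimetric; the triangle inequality is neither assumed
  nor asserted, and Betadisper's imaginary-subspace correction is the
  standard way of coping with the resulting negative eigenvalues.
* The ANCOM W statistic is only asymptotically invariant to sample-wise
  count rescaling (the pseudocount breaks exact invariance at low
  depths).
* The LFC definition (CLR group-mean difference) is one of several
  reasonable fold-change constructions for compositional data; magnitudes
  are comparable within an analysis, not across pseudocount choices.
* UniFrac-style phylogenetic beta diversity and bias-corrected
  differential abundance estimators are out of scope.
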