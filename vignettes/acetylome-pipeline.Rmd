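---
title: "Methods: the acetylome atlas analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the acetylome atlas analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind each stage of
`acetylatlas`, the tunable parameters and their defaults, the numerical
conventions, what the synthetic-data generator emulates (and what it does
not), and the design choices made where the design was genuinely open.

## Identification filtering

A site-report row survives when all three hold:

* modification title contains `Acetyl (K)`;
* site localization probability **strictly greater** than 0.75 — a
  probability of exactly 0.75 is rejected;
* protein-group and precursor q-values both **at or below** 0.01.

The asymmetry (strict `>` for probability, inclusive `<=` for q-values) is
deliberate: localization is quoted as "greater than" while q-value cutoffs
conventionally include the boundary. Duplicate collapse keys (several
precursors quantifying one residue) are merged by the per-run **maximum**:
order-independent, and conservative in the sense of taking the best
supported quantification. How duplicate evidence should be combined is not
dictated by the report format; the maximum is our choice and the merge
function is isolated so sensitivity to it is testable.

## Abundance model

Zero intensities are treated as missing: DIA software writes 0 and NA
interchangeably for non-quantified cells, and 0 is not a valid log2 input.

*Detection.* A site is detected in a tissue when at least
`min_replicates = 2` replicates are quantified within a single sex of that
tissue; sites detected nowhere are dropped. The rule is monotone: adding
observations can never remove a site.

*Normalization.* Each run is shifted (log2 scale, shift-only, so within-run
contrasts are untouched) so its observed median equals its tissue's pooled
median — the median over all observed values of the tissue's runs, both
sexes. Whether alignment should target a per-tissue or a global constant
is a genuine choice; per-tissue is the default (it removes within-tissue
batch effects without erasing between-tissue level differences) and
`normalize_target = "global"` is the alternative.

*Imputation.* Missing cells are drawn feature-wise from
$N(\mu - 1.8\,\sigma,\ (0.3\,\sigma)^2)$ with $\mu,\sigma$ the feature's
observed mean and **sample** (n−1) standard deviation. This is the standard
down-shifted Gaussian for left-censored proteomics data: missing values are
assumed to sit below the detection limit, so draws are centered 1.8 sd
below the observed mean with a narrowed width. Features with $\sigma = 0$
(identical observed values) fall back to the matrix-wide median of feature
sds. All draws come from the configured `rng_seed`; identical seeds give
bit-identical matrices. Observed cells are never touched.

*Summarization.* Tissue×sex cells are the mean of **detected** replicate
values; only all-missing cells fall back to the mean of the imputed draws.
Final per-site z-scores use the population (n) denominator — a display
convention for standardized heatmap rows; the selectable sample convention
changes nothing qualitative.

## Clustering, ORA, PCA

Row clustering is Euclidean/average-linkage (`stats::hclust`), cut into
`n_cut_groups = 400` groups (`stats::cutree`). Per group × term we form the
2×2 table (in-group vs all other groups; term-annotated vs not, at the site
level through the protein's closed annotation set) and compute a Fisher
exact p. Sidedness is not specified by the phrase "overrepresentation
analysis" alone; we default to the one-sided (greater) test because
over-representation names a direction, and expose `two.sided`.

PCA treats tissue×sex columns as observations and sites as features
(`stats::prcomp` on the transposed standardized matrix). Component signs
are fixed by making the largest-magnitude loading positive, so results are
reproducible across platforms; features are ranked by |loading| for the
loadings plot.

## Ontology enrichment and term selection

Annotations are propagated upward through is-a edges (ancestor closure), so
a protein annotated to a term counts for every ancestor. Tissue enrichment
tests each tissue's acetyl proteins against the rest of the universe. The
universe is the detected (non-enriched) proteome by default; the phrase
"all detected proteins" could also mean the union of acetyl proteins, so
`enrichment_universe = "acetyl"` exists. Tissues with no acetyl proteins
get p = 1.0 exactly for every term (the non-computable convention), and
$-\log_{10} 1 = 0$ exactly.

Term selection keeps terms with across-tissue sd of $-\log_{10} p$
strictly > 0.6, some tissue strictly < 0.6 and some tissue strictly > 3 —
i.e. strongly enriched somewhere, absent elsewhere. The sd convention
(sample vs population) is configurable; the worked 14-zeros-and-a-4
fixture passes under both (sd 1.03 sample / 1.00 population). Overlap
pruning removes one member of any pair with
$|A \cap B| / \min(|A|,|B|) > 0.9$ (strictly; exactly 90 % keeps both),
keeping the term with the larger maximum $-\log_{10} p$, ties broken by
lexicographic id — deterministic and informativeness-preserving. Parent–
child pruning then keeps only the most specific term of every
ancestor–descendant pair. Uniqueness ranking z-scores each term's profile
across tissues and scores tissue $t$ as $z_t - \overline{z_{\neq t}}$;
constant terms score 0 by the sd-zero rule. The "other 14 tissues" of the
15-tissue design generalizes to other $n-1$.

## Motif logos

Foreground flanks are the report's ±7 windows; the background is every
lysine of the proteome FASTA, termini padded with `_`. Padding is excluded
from the per-position denominators so edge columns are not diluted toward
the pad symbol. Information content per position is
$\mathrm{IC}_j = \log_2 20 + \sum_a p_{aj} \log_2 p_{aj}$ against the
uniform 20-residue background (no small-sample correction; a composition
background is a config option). Fore/background comparison uses
$\log_2(p_f / p_b)$ with a pseudocount of 0.5 per residue per position —
finite values with minimal distortion — and excludes the center position
(always K by construction). Probabilities, counts, IC and log-ratios are
all emitted since published logos vary in which they plot.

## Structural context

The PDB parser reads fixed-column v3.3 ATOM records; predicted models carry
per-residue confidence (pLDDT 0–100) replicated on every atom's B-factor,
collapsed per residue (mean with a warning if atoms disagree). SASA is
computed with the Shrake–Rupley algorithm implemented in the package:
`sasa_n_points = 100` quasi-uniform points per atom on the expanded sphere
$r_i + r_\text{probe}$, probe 1.4 Å (water), Bondi-style radii (C 1.70,
N 1.55, O 1.52, S 1.80, H 1.20, P 1.80, default 1.70 Å). Points are placed
by the deterministic golden-section spiral, so no RNG is involved; a point
exactly on a neighbor's expanded surface counts as accessible (strict
interior test), which keeps coincident-atom corner cases deterministic.
Neighbor candidates are restricted to atoms within the sum of expanded
radii. Hydrogens are included when present and HETATM records excluded by
default; both are toggles, since published workflows rarely state either.
Per-residue SASA is the sum over member atoms. Residue numbering of
predicted models equals sequence position, so sites join on (protein,
position); joins landing on a non-lysine residue are flagged and excluded
from distributions.

Accuracy of the point-sampling: an isolated C atom gives
$4\pi(1.7+1.4)^2 = 120.76$ Å$^2$ to machine precision (all points
accessible), and the two-intersecting-spheres case agrees with the
closed-form spherical-cap area within 2 % at 960 points — both are frozen
tests.

## Variant mapping

Sites join human variants on (mouse protein, mouse position); joined rows
whose reference residue is not K are excluded with a warning. K→Q is
flagged as an acetyl-mimic (removes the ε-amine's positive charge, as
acetylation does), K→R as charge-preserving, K→E as charge-reversing.
Free-text clinical labels normalize via a small table ("Pathogenic",
"Likely pathogenic" → pathogenic; "Benign", "Likely benign" →
non-pathogenic; everything else uncertain). Fold enrichment ranks sites by
mean **detected** abundance (imputed draws are model draws, not
measurements), splits them into `n_rank_bins = 10` equal-count bins —
published enrichment curves of this kind rarely state their binning;
deciles are our default — and reports each bin's pathogenic fraction over
the overall fraction. The site-weighted mean fold is exactly 1 by
construction.

## The synthetic generator

`simulate_atlas()` emulates an atlas-scale design — 15 tissues × 2 sexes × 3
replicates, 2,000 sites on 400 proteins — as one pure function of its seed.
Sizing keeps a full pipeline run around ten seconds on one CPU, and the
test suite uses smaller designs where the full scenario adds nothing.

* **Abundance.** Site base abundances are $N(20, 2^2)$ on the log2 scale
  (i.e. log-normal intensities around $2^{20}$, a realistic DIA intensity
  scale); replicate noise sd 0.4; per-run batch shifts sd 0.3 (removed by
  normalization).
* **Missingness.** A cell of latent log2 intensity $x$ is missing with
  probability $\mathrm{logit}^{-1}((17 - x)/1)$ — midpoint 3 log2 units
  below the global mean — plus a hard limit of detection at 13: cells
  below it are never quantified. Together these give realistic
  left-censored MNAR missingness with an instrument floor.
* **Tissue structure.** 12 proteins per tissue are tissue-specific (all
  their sites expressed only there; elsewhere their cells sit at
  background level 8, far below the LOD); the remaining proteins are
  expressed in a random half of tissues. Planted tissue-specific sites are
  truncated to base abundance ≥ 18.5 — above the censoring midpoint — the
  spike-in convention: a spike below the detection limit measures the
  censoring model, not the pipeline.
* **Identification noise.** 5 % of rows each get a failing localization
  probability, failing q-value, or a phospho label; 5 % of sites get a
  second precursor row under the same collapse key.
* **Planted signals.** One ontology term per tissue annotates exactly that
  tissue's specific proteins (terms sit directly under the root so closure
  adds no competing ancestors); a glutamate is written at position −1 of
  half the acetyl sites; each decoy structure (ideal helical backbone,
  N/CA/C/O per residue, planted pLDDT in the B-factor) carries one lysine
  enclosed in a 24-atom crowding shell (buried) and one free (exposed);
  pathogenic variant labels follow a truncated logistic in the site's
  abundance percentile (zero below the 60th percentile, rising to ~0.7),
  or a flat 0.3 when `variant_association = "none"`.

What the generator does **not** emulate: correlated peptide evidence,
shared peptides across proteins, interference and ratio compression,
nonlinear intensity-dependent variance, realistic ontology topology and
annotation depth, real protein folds (the decoy helix only separates
buried from exposed), or orthology ambiguity in the variant mapping.
Passing the recovery tests therefore demonstrates correctness of the
pipeline's logic under a faithful abstraction of the experimental design — not
performance on real tissue data.

## Numerical conventions

* Fisher p-values are exact hypergeometric tail sums
  (`stats::phyper`/`dhyper`); the two-sided variant sums densities
  $\le d_\text{obs}(1+10^{-7})$, matching the conventional relative-error
  guard.
* $-\log_{10}$ of p = 1 is exactly 0; degenerate 2×2 tables (an all-zero
  margin) give p = 1.
* Dendrogram and ranking ties break deterministically (lowest index /
  lexicographic id).
* Constant rows standardize to zeros with a warning rather than NaN.
* All stochastic steps flow from a single integer seed; the RNG state is
  saved and restored around seeded sections so library calls do not
  perturb user code.

## Known limitations

The ORA counts sites (not proteins) per cluster group, so multi-site
proteins weigh more — consistent with clustering rows being sites. SASA at
100 points carries ~1–3 % sampling error on crowded atoms (raise
`sasa_n_points` for publication-grade values). The OBO reader handles
`is_a` relationships only, by design; `part_of` and regulatory edges are
ignored. The uniqueness ranking assumes tissues are exchangeable under the
null; strongly unbalanced designs would need a weighted variant.
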