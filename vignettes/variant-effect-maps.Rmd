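---
title: "Scoring and calibrating variant effect maps from tiled selection experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and calibrating variant effect maps from tiled selection experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavescore)
```

# The experiment being modeled

`mavescore` implements the analysis chain of a multiplexed assay of variant
effect (MAVE) built on functional complementation: a library of protein
variants rescues (or fails to rescue) growth of a strain whose essential
ortholog is disabled, so a variant's frequency trajectory through selective
growth measures its function. Frequencies are read out by *tile
sequencing*: short (~150 bp) amplicons spanning the coding region are
sequenced deeply in paired-end mode before and after selection, with both
reads of a pair covering the same tile so that each strand confirms the
other ("duplex" calling). The package covers five stages:

1. **Synthetic data** — a generative model of the whole experiment, used as
   ground truth for validation;
2. **Tile counting** — duplex variant calling and depth-normalized count
   tables;
3. **Scoring** — enrichment ratios and rescaled functional impact scores
   with regularized errors;
4. **Clinical calibration** — log likelihood ratios of pathogenicity and
   ACMG/AMP evidence strengths;
5. **Evaluation** — ROC, balanced precision-recall and auxiliary
   positional/population analyses.

# The generative model

## Ground truth

`generate_ground_truth()` enumerates, for a random coding sequence, every
amino-acid substitution at every position: 19 missense changes, one stop
gain and one synonymous codon change. True functional scores live on the
scale where 0 is null and 1 is wild-type-like:

* synonymous variants score exactly 1;
* nonsense variants score exactly 0, except in the last 14 residues where
  truncation is treated as tolerated (score 1) — the same window that the
  scoring stage later excludes from its nonsense median;
* missense variants draw from a two-component mixture: a low mode
  N(0.05, 0.15) and a high mode folded below 1 (`1 − |N(0, 0.15)|`), with
  weights 0.35/0.65. The folding guarantees that the only variants with
  true score above 1 are the designated *hyper-complementing* fraction
  (default 2.5% of missense), drawn as `1 + Exp(rate 8)`.

The mode weights and widths were chosen once to mirror the broad bimodal
missense distributions that complementation maps display; they are
parameters, not fitted quantities. Reference codons exclude ATG and TGG so
that a synonymous alternative codon always exists; each variant carries one
canonical codon change (the most common human codon of the target residue),
fixing the nucleotide edits the read simulator emits.

## Library, selection, sequencing

`simulate_clone_pool()` assigns each clone one mutagenesis region and a
Poisson number of changes (mean 1.7 amino-acid changes per clone, the
typical load of oligo-directed codon randomization), at distinct positions
within its region; abundances are normalized exponential draws. The
defaults use 100,000 clones — a desk-scale stand-in for the millions of
transformants of a production library that preserves realistic per-variant
clone counts.

`simulate_selection()` needs a rule for clones carrying several variants;
the assay phenotype is rescue of an essential function, for which loss of
function is epistatically dominant, so a clone's fitness is the **minimum**
true score among its variants. Growth is exponential and affine in score:
abundances are multiplied by `exp(generations × gap × score)` plus
per-clone log-normal noise (sd 0.05), then renormalized. With the defaults
(4 generations × gap 1.0) score-0 and score-1 clones separate by 4 natural
log units — enough that depleted nonsense variants remain countable at the
default depth, which is what anchors the score scale. A threshold-shaped
fitness map would serve equally for rank recovery; the affine form is the
simplest monotone choice and admits a closed-form two-clone test.

`simulate_read_pairs()` sequences each tile to a fixed depth (default
5×10⁵ pairs/tile), injecting independent per-base errors in each read of a
pair (default 10⁻³) with Phred qualities matching that rate. Internally
the simulator stores a *sparse mismatch representation* — one record per
(pair, read, position) at which a read differs from the reference — which
is exactly equivalent to full read strings while scaling to millions of
pairs; `materialize_pairs()` expands any subset into explicit strings (and
FASTQ via `write_fastq_pairs()`), and the test suite asserts that counting
the sparse and materialized representations gives identical tables. Error
cells are drawn as a Binomial count over the pair×position grid placed
uniformly without replacement, which reproduces the independent
Bernoulli-per-base model exactly.

## What the simulator does not capture

PCR jackpots and amplification bias, position- and context-dependent
sequencing error, alignment and demultiplexing artifacts, bottleneck
effects during pool transfers, codon-usage effects, indels, and any
biology beyond the single min-rule epistasis. Passing recovery tests
therefore demonstrate correctness of the analysis chain under a clean but
structurally faithful error model, not robustness to every real-data
pathology.

# Duplex calling

A mismatch is considered only where **both** reads of a pair agree on the
same non-reference base. The posterior that such a call is real compares
two hypotheses — a real variant (likelihood `(1−e₁)(1−e₂)`) versus a
coincident miscall of the reference to this particular base on both reads
(likelihood `(e₁/3)(e₂/3)`; the error probability is spread uniformly over
the three non-reference bases) — at equal prior odds:

$$P = \frac{(1-e_1)(1-e_2)}{(1-e_1)(1-e_2) + (e_1/3)(e_2/3)}$$

Calls with posterior ≤ 0.9 are dropped. The published pipelines this
follows state the 90% threshold but not the formula; this construction is
documented so its consequences are reproducible: two Phred-40 reads give
posterior 1−10⁻⁹ (called), two Phred-3 reads give 0.8991 (suppressed).
Concordance makes the error background quadratic: the apparent frequency of
a specific false variant in a wild-type control is (e/3)² per base pair,
about 10⁻⁷ at e = 10⁻³.

Multiple nucleotide changes within one codon of the same pair are
translated jointly through the standard genetic code. Coordinates are
0-based half-open for nucleotides internally; residue positions are 1-based
everywhere, as in HGVS strings. Read pairs are required to sit within one
tile, and tiles respect codon boundaries (tile length divisible by 3).

# From counts to scores

Per condition and replicate, counts are normalized by covering-tile depth.
The filters and transforms, in order:

1. **Count filter**: variants with fewer than 10 raw reads in either the
   selective or non-selective library are removed. A counts-per-million
   reading of the same rule is available (`min_cpm`) for designs where
   depth varies; the raw-count reading is the default.
2. **WT percentile filter**: variants whose frequency falls below the 90th
   percentile of the frequencies observed in the wild-type control library
   are removed (quantile type 7; an all-zero control removes nothing).
3. **Background subtraction**: matched WT-control frequencies are
   subtracted in both conditions. A non-positive adjusted *selective*
   frequency is floored at 0.5 reads over tile depth, keeping fully
   depleted variants scoreable as strongly null; a non-positive adjusted
   *non-selective* frequency makes the variant unusable (nothing was there
   to select on).
4. **Enrichment ratio**: Φ = adjusted selective / adjusted non-selective
   frequency.
5. **Rescaling**: per mutagenesis region,
   $$FS = \frac{\ln(\Phi/\Phi_{STOP})}{\ln(\Phi_{SYN}/\Phi_{STOP})}$$
   where Φ_STOP and Φ_SYN are the region's median nonsense and synonymous
   ratios; nonsense variants in the last 14 residues are excluded from
   Φ_STOP since near-C-terminal truncations are rarely consequential. By
   construction the nonsense median scores exactly 0 and the synonymous
   median exactly 1; values above 1 (hyper-complementation) and below 0
   are legitimate.

## Error regularization

With two replicates the empirical per-variant spread is itself noisy, so
it is shrunk toward the spread *expected at that variant's coverage*:
variants are ordered by log non-selective frequency, a running median
(window 51) of replicate standard deviations — divided by `qnorm(0.75)` to
unbias the half-normal median to the SD scale — gives the trend t(f), and

$$\sigma^2_{shrunk} = \frac{m\,t^2 + n_{rep}\,s^2}{m + n_{rep}},\qquad
\sigma = \sqrt{\sigma^2_{shrunk}/n_{rep}}$$

with m = 2 prior pseudo-replicates by default. `m = 0` recovers the plain
empirical standard error; single-replicate variants take the trend value
and are flagged. Scores with σ above 0.3, or non-selective frequency below
0.005%, fail quality filtering ("above"/"below" read strictly: equality
passes; rows are flagged, never deleted).

## Combining isoform maps

Two maps of the same protein (e.g. two isoforms) are put on a common scale
by an affine least-squares fit over shared well-measured variants — the
simplest transform minimizing mean squared distance between maps; a
monotone-spline alternative could be slotted in where curvature between
assay scales is evident, at the cost of a less auditable transform. Scores
passing filters in both maps combine by inverse-variance weighting, with
combined variance `1/(1/σ₁² + 1/σ₂²)` — the standard form, which some
published descriptions typeset ambiguously as `1/(1/(σ₁²+σ₂²))`; the
inverse-variance form is the one whose combined error never exceeds either
input error, a contract the test suite asserts. The *delta score* is the
first map's score minus the second's where both exist.

## Preference transforms

For phylogenetic hypothesis testing about hyper-complementation,
WT-normalized score matrices convert to per-position amino-acid
preferences π = s/Σs under three transforms of above-1 scores: kept
(advantageous), capped at 1 (neutral), or inverted to 1/s (damaging).
Scores ≤ 0 are clipped to 10⁻⁶ first so preferences stay defined.
Phylogenetic likelihood fitting itself is out of scope; only the
transforms are provided.

# Clinical calibration

Positive (pathogenic/likely pathogenic) and negative (benign/likely
benign, plus *proxy-benign*: unannotated variants with MAF < 0.0005 and at
least one homozygote) reference sets feed Gaussian kernel density
estimates (Silverman bandwidth by default). The log likelihood ratio of
pathogenicity of a score s is log₁₀ of the density ratio, with each
density floored at 10⁻⁶ of its own maximum so the LLR stays finite in the
tails; no boundary reflection is applied because functional scores are not
bounded (hyper-complementation exceeds 1). Base 10 is used throughout: the
canonical "very strong" cut equals log₁₀ of the solved per-item odds.

`solve_acmg_thresholds()` models posterior odds as
`prior_odds × X^w`, with evidence weights in very-strong units (strong =
1/2, moderate = 1/4, supporting = 1/8; benign evidence negative), and
finds the smallest X for which every evidence-combining rule meets its
posterior constraint (pathogenic > 99%, likely pathogenic > 90%, likely
benign < 10%, benign < 1%) at the default prior 0.1, by a log-grid scan
plus bisection. "Most conservative" is read as *smallest* feasible X — the
weakest evidence claim consistent with the rules. The rule list is data
(`acmg_rules()`), so it can be audited or edited; the combination of two
strong pathogenic criteria is flagged exempt, as the framework's
documented exception whose posterior (0.975 at prior 0.1) lands in the
likely-pathogenic range. With these conventions the solver yields X =
350.5 and the cut ladder 2.54 / 1.27 / 0.64 / 0.32 / −0.32 / −1.27
(log₁₀, descending by factors of 2, mirrored for benign); the
moderate/supporting cuts are sometimes quoted as 0.63/0.31 from rounding
the same ladder downward. `assign_evidence()` maps LLRs to categories with
strict inequalities — an LLR exactly at a cut takes the weaker category —
and flags scores outside the calibration's observed range as extrapolated.

# Evaluation conventions

* **Orientation**: lower functional score = more damaging = positive
  class, fixed at the interface.
* **Balanced precision**: TPR/(TPR+FPR), the precision under equal class
  priors; with balanced inputs it equals ordinary precision exactly.
  R90BP is the maximum recall at balanced precision ≥ 90% (0, with a
  warning, if never reached).
* **Curve areas**: AUROC by the rank formula (equal to the normalized
  Mann-Whitney U); AUBPRC by step-wise integration over recall — no linear
  interpolation between operating points, so each recall increment
  contributes the balanced precision achieved at that threshold.
* **Δmedian**: negative-set median minus positive-set median, so a
  well-oriented map gives a positive value.
* **Odds ratios**: cross-product with a Haldane 0.5 correction when a cell
  is zero; p values from the exact hypergeometric test, uncorrected for
  multiple testing (raw p values are reported wherever several
  comparisons are made).
* **Excluded regions**: performance analyses can mask residue windows
  where the assay is suspected not to reflect pathogenicity
  (`flag_excluded_positions()`, defaults 160–215, 255, 355); the filtered
  metric uses exactly the unflagged variants.

# Problem sizes, determinism and degenerate inputs

The validation suite exercises the full chain at a 100-residue protein,
two 50-residue mutagenesis regions (one 150-bp tile each), two replicates,
100,000 clones and 5×10⁵ pairs per tile — sizes chosen so that every
stage, including depleted-variant counting, operates in its intended
regime while a complete run stays in the tens of seconds. Under these
conditions the pipeline recovers true scores with Spearman ≥ 0.95 and RMSE
≤ 0.1 and anchors the class medians at 0/1.

Every stochastic operation takes an explicit seed, restores the caller's
RNG state, and is bit-reproducible given the seed; no function touches
global random state. Degenerate inputs fail loudly and specifically:
empty WT tables (percentile undefined), unseparated class medians
(Φ_SYN ≤ Φ_STOP), fewer than three usable anchor variants per region,
zero-variance rescaling sets, constant predictor scores, infeasible
posterior constraints. Empty read streams tabulate to empty tables with a
warning rather than an error, since a tile with no variant reads is a
legitimate observation.

# Known limitations

Alignment is out of scope (inputs carry known offsets); pairs spanning
tile boundaries are rejected rather than split; no indel calling or
quality recalibration; no imputation of missing scores; reference-set
construction implements the stated label and frequency rules but no
aggregation of conflicting submissions beyond exclusion. The bundled
evaluation compares maps with DeLong's test for AUROC; for AUBPRC
differences only a simple paired bootstrap would be appropriate and none
is bundled.
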