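# mavescore

Functional scoring and clinical calibration of variant effect maps from
tiled selection experiments.

## The problem

Multiplexed assays of variant effect (MAVEs) measure the function of
thousands of protein variants at once: a mutagenized library complements a
disabled essential gene, pooled cells grow under selection, and each
variant's frequency change — read out by deep paired-end sequencing of
short amplicon "tiles" before and after selection — quantifies its
functional impact. Turning those read pairs into clinically usable
evidence takes a chain of statistical steps that this package implements
end to end, for analysts building or evaluating such maps:

1. **Duplex variant calling.** A mismatch is accepted only where both
   reads of a pair agree on the same non-reference base, with posterior

   $$P = \frac{(1-e_1)(1-e_2)}{(1-e_1)(1-e_2) + (e_1/3)(e_2/3)} > 0.9$$

   where $e_i$ are the reads' Phred error probabilities. Counts are
   normalized by covering-tile depth.

2. **Functional impact scores.** After count and wild-type-control
   percentile filters and background subtraction, each variant's
   enrichment ratio $\Phi$ (selective over non-selective adjusted
   frequency) is rescaled per mutagenesis region so the nonsense median
   scores 0 and the synonymous median scores 1:

   $$FS = \frac{\ln(\Phi/\Phi_{STOP})}{\ln(\Phi_{SYN}/\Phi_{STOP})}$$

   Replicate errors are shrunk toward a coverage-conditional trend;
   isoform maps are rescaled onto a common scale and combined by
   inverse-variance weighting.

3. **Clinical calibration.** Kernel density estimates over pathogenic and
   benign reference scores give a log likelihood ratio of pathogenicity
   $LLR = \log_{10}\,\pi_+(s)/\pi_-(s)$, and a Bayesian points solver
   derives the ACMG/AMP evidence-strength cut points (2.54 / 1.27 / 0.64 /
   0.32 / −0.32 / −1.27 at prior 0.1).

4. **Evaluation.** AUROC (with DeLong comparisons), balanced
   precision-recall (precision under equal class priors) with recall at
   90% balanced precision (R90BP), Mann-Whitney distribution comparisons,
   moving-window positional profiles, solvent-accessibility classification
   and allele-depletion odds ratios.

A first-class synthetic-data module simulates the entire experiment —
ground-truth fitness maps, codon-randomized clone libraries (Poisson 1.7
changes/clone), exponential selection and tiled duplex sequencing with
per-base errors — so the whole chain is testable and parameter recovery
can be asserted without any external data.

## Worked example

```r
library(mavescore)

# 1. Simulate a tiled selection experiment (60-residue protein, two
#    mutagenesis regions, two replicates)
truth <- generate_ground_truth(60, hyper_fraction = 0.025, seed = 1)
lib   <- library_model(n_clones = 30000)             # 1.7 changes/clone
seqm  <- sequencing_model(depth_per_tile = 1e5, tile_length = 90,
                          per_base_error = 1e-3)
sel   <- selection_model(generations = 3)

ex <- run_tile_experiment(truth, lib, seqm, sel, n_rep = 2, seed = 1)
scores <- score_tile_experiment(ex$counts, 60, list(c(1, 30), c(31, 60)))

m <- merge(scores[scores$passed_filters, ],
           truth$variants[, c("key", "true_score")], by = "key")
cat(sprintf("scored %d/%d variants; Spearman vs truth %.3f\n",
            sum(scores$passed_filters), nrow(truth$variants),
            cor(m$fs, m$true_score, method = "spearman")))
#> scored 1219/1260 variants; Spearman vs truth 0.899
cat(sprintf("median score: nonsense %.3f, synonymous %.3f\n",
            median(m$fs[m$class == "nonsense" & m$pos <= 46]),
            median(m$fs[m$class == "synonymous"])))
#> median score: nonsense -0.002, synonymous 1.002
```

Scores recover the simulated truth (at this reduced depth, 10⁵ pairs/tile,
rank correlation is 0.90; at the full 5×10⁵ it exceeds 0.95), and the
scale anchors where it should: nonsense variants at 0, synonymous at 1.

```r
# 2. Calibrate scores into ACMG/AMP evidence strengths
set.seed(1)
path_keys   <- sample(m$key[m$true_score < 0.3], 40)
benign_keys <- sample(m$key[m$true_score > 0.8 & m$class == "missense"], 40)
calib <- estimate_densities(m$fs[m$key %in% path_keys],
                            m$fs[m$key %in% benign_keys])
th <- solve_acmg_thresholds(prior = 0.1)
round(th$llr_cuts, 2)
#>  PVSt   PSt    PM   PSu   BSu   BSt
#>  2.54  1.27  0.64  0.32 -0.32 -1.27

assign_evidence(score = c(0.05, 0.5, 1.0), calib = calib, thresholds = th)
#>   score       llr               category extrapolated
#> 1  0.05  5.756359 pathogenic_very_strong        FALSE
#> 2  0.50  4.088543 pathogenic_very_strong        FALSE
#> 3  1.00 -6.169953          benign_strong        FALSE
```

A score of 0.05 (null-like) carries very strong evidence of
pathogenicity on this simulated calibration; a wild-type-like score of
1.0 carries strong evidence of benignity; the cut ladder descends by
factors of two in log₁₀-odds units.

```r
# 3. Evaluate the map against the reference sets
lab <- ifelse(m$key %in% path_keys, "positive",
       ifelse(m$key %in% benign_keys, "negative", NA))
perf_summary(m$fs[!is.na(lab)], lab[!is.na(lab)])
#> Map performance (40 positive / 40 negative):
#>   AUROC  1.000
#>   AUBPRC 1.000
#>   R90BP  1.000
```

With cleanly separated simulated reference sets the map classifies
perfectly; on real reference variants these numbers quantify how much of
the pathogenic set a map captures at stringent balanced precision.

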