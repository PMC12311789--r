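# editscreen

Analysis tools for comparing two pooled variant-function readouts of the
same protein in a growth-selected cell system: **deep mutational scanning
(DMS)**, where every single amino-acid substitution is measured directly
from a cDNA library, and **adenine base-editor (ABE) screens**, where each
sgRNA's depletion is a proxy for the A>G edits it makes inside its editing
window. The package is written for screen analysts who need to (i) turn
pooled counts into growth rates, (ii) call deleterious variants and
depleting guides, (iii) quantify how well guide-level measurements agree
with variant-level truth under successive quality filters, and (iv)
deconvolute multi-edit guides by sequencing the edited locus directly.

## The models at the core

**Growth rate from two timepoints.** For mutant allele frequency (MAF)
and viable-cell count at a baseline and a final timepoint,

    r = ln( (MAF1 * Count1) / (MAF0 * Count0) ) / (t1 - t0)   [h^-1]

**Hit calling.** Variant growth rates are bimodal; a two-component
skew-normal mixture is fitted and variants with z = (r − μ_WT)/σ_WT < −2
against the WT-like component are deleterious. Guides are called against
the negative-control rate distribution at z < −2 (and by the
fold-change rule log2FC < 0 with BH-adjusted p < .05).

**Weighted sgRNA model.** An sgRNA's expected rate is the
proportion-weighted mean over its cell population,
`r_sgRNA = Σ p_i r_i + p_unedited · r_WT`, with multi-amino-acid alleles
assigned the no-epistasis multiplicative null
`r = r_WT · Π (r_i / r_WT)` (two mutants each at 0.7× WT predict a
0.49× WT double mutant).

**Concordance ladder.** Guide-vs-variant agreement (Pearson r, odds
ratio, TPR, accuracy over TP/FP/FN/TN quadrants) is tracked across
cumulative filters: broad editing window (spacer positions 2–12) → core
window (4–8) → sgRNA efficiency score > 50 → single core-window edit.

**Direct edit calling.** In staggered validation pools, paired amplicon
reads yield bona fide edits only where both mates agree and exceed Q20;
cis edits on one pair form one allele, rates are anchored to the
no-mismatch (WT) read fraction, and each guide's *major edit* is the
allele holding >50% of its edited frequency.

A synthetic-data module simulates all of this — bimodal fitness
landscape, exponential growth with multinomial sequencing, product-model
bystander editing, paired reads with quality-annotated substitution
errors — with complete ground truth.

## Worked example

```r
library(editscreen)

res <- run_pipeline(default_config(seed = 1, demo = TRUE))

print(res$dms$fit)
#> Two-component skew-normal mixture fit
#>    location       scale       shape   weight       mean          sd       label
#>  0.01269626 0.009655644  1.97262079 0.561643 0.01956783 0.006783291 deleterious
#>  0.05492863 0.005020951 -0.00597698 0.438357 0.05490468 0.005020894     wt_like
#> WT-like mean 0.0549, sd 0.0050; cutoff (Z = -2): 0.0449 h^-1

ladder_table(res$concordance$ladder)
#>          rung   n TP FP FN TN         r odds_ratio       tpr  accuracy
#> 1       broad 206 97 77  1 31 0.3787929   39.05195 0.9897959 0.6213592
#> 2        core  91 44 35  0 12 0.4413827   31.33803 1.0000000 0.6153846
#> 3  efficiency  69 28 29  0 12 0.5222347   24.15254 1.0000000 0.5797101
#> 4 single_edit  24 14  4  0  6 0.8912607   41.88889 1.0000000 0.8333333

res$weighted$r          # weighted-model prediction vs observed guide rates
#> [1] 0.9664199
res$validation$major_r  # guide rate vs directly sequenced major edit
#> [1] 0.9389486
```

Reading the output: the mixture fit recovers the two fitness modes
(deleterious ≈ 0.02 h⁻¹, WT-like ≈ 0.055 h⁻¹) and sets the −2 Z hit
cutoff near 0.045 h⁻¹. Down the filter ladder the guide-vs-variant
Pearson correlation rises (0.38 → 0.89 here) as unlikely edits,
inefficient guides and bystander-ambiguous guides are removed — the
qualitative behaviour that motivates filtering raw base-editor screens.
The weighted model explains observed guide rates well (r ≈ 0.97), and
directly sequenced major edits track their guides' rates (r ≈ 0.94),
the basis for validating multi-edit guides in medium-sized pools.

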