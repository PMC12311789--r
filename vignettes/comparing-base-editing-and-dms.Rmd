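---
title: "Comparing base-editing and deep mutational scanning screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing base-editing and deep mutational scanning screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscreen)
```

## The measurement problem

Two pooled technologies annotate coding variants in growth-selected cell
systems such as Ba/F3 cells transformed by an activated kinase. Deep
mutational scanning (DMS) expresses a saturating cDNA library of single
amino-acid substitutions and reads variant abundance directly. Adenine
base-editor (ABE) screens tile the coding sequence with sgRNAs and read
sgRNA abundance as a *proxy* for the A>G edits each guide makes inside its
editing window. The proxy is imperfect for three reasons this package
models explicitly: only a fraction of cells carrying a guide are edited
(the unedited fraction grows at the wild-type rate and compresses the
measured dynamic range); a guide can make several window edits in cis
(bystanders), blurring which variant caused the phenotype; and editing
activity depends on the position of the target base in the spacer.

`editscreen` implements both analysis arms, the models connecting them,
and a synthetic-data generator with complete ground truth, so that every
analysis step can be validated end to end.

## Growth rates from two timepoints

Both arms estimate a variant's (or guide's) growth rate from its allele
frequency and the viable-cell count at two timepoints:

$$ r = \frac{\ln\left( \mathrm{MAF}_1 \cdot \mathrm{Count}_1 \,/\,
  \mathrm{MAF}_0 \cdot \mathrm{Count}_0 \right)}{t_1 - t_0} \quad
  [\mathrm{h}^{-1}] $$

`growth_rate_from_counts()` implements the estimator; cell counts must be
split-corrected totals so the product MAF × Count is an absolute
abundance. On noiseless expected counts the estimator inverts the
generator's forward model exactly (a property the test suite asserts to
1e-12 relative error). Zero final counts are floored at a configurable
pseudocount (default 0.5 reads) and flagged; the floor makes strongly
depleted variants' rates a censored lower bound rather than a noisy
extrapolation, a limitation to keep in mind when interpreting the most
deleterious tail.

## The bimodal fitness landscape and hit calling

Growth rates of variants of an essential kinase are bimodal: a
deleterious mode (around 0.02 h⁻¹ here) and a WT-like mode at the
wild-type rate 0.055 h⁻¹. `fit_growth_mixture()` fits a two-component
skew-normal mixture to a density-normalised histogram (Freedman–Diaconis
bins) by nonlinear least squares (`minpack.lm::nlsLM`), initialised from a
deterministic 2-means split with shapes seeded at zero. Two
interpretations of a fitted component's "mean and SD" are possible — the
Gaussian kernel's location/scale, or the skew-normal distribution
moments. We report moments
($\mu = \xi + \omega\delta\sqrt{2/\pi}$,
$\sigma = \omega\sqrt{1 - 2\delta^2/\pi}$, $\delta = \alpha/\sqrt{1+\alpha^2}$),
because the hit threshold is meant to sit two standard deviations of
*observed rates* below the WT-like centre; with $|\alpha| \le 2.5$ the two
conventions differ by well under one bin width, and both parameter sets
are retained in the fit object. Hits are variants with
$z = (r - \mu_{WT})/\sigma_{WT} < -2$. Fits are flagged (not errored) when
a component weight drops below 0.02 or the component means are closer
than one pooled SD — the data are then effectively unimodal and the
cutoff unreliable.

## The guide arm

Guide counting (`count_guides()`) removes the fixed 5′ context and matches
the 20-mer spacer exactly (an optional single-mismatch rescue is off by
default, since a mismatched spacer usually indicates a synthesis or
sequencing artefact rather than a real guide). Fold changes use
median-of-ratios size factors and a pseudocount of 0.5 on normalised
means; p-values come from a normal test on per-replicate log-ratios with
Benjamini–Hochberg adjustment. This deliberately lightweight engine is
deterministic and sufficient for the two hit definitions used: the
Z-score rule against negative-control guides (z < −2) and the
depleting-guide rule (log2FC < 0 and adjusted p < 0.05). Fold changes
convert to rates by
$r = r_{WT} + (\mathrm{log2FC} - \bar c)\ln 2/\Delta t$, with $\bar c$
the mean control log2FC — human-targeting controls in a large screen,
spike-in controls in validation pools. Δt is a required configuration
value (144 h for the simulated DMS selection, 216 h for the guide
screens, matching the emulated 6- and 9-day designs).
`sliding_window_profile()` summarises regional essentiality as the
fraction of guides below z = −4 in 40-guide windows stepping one guide at
a time (the finest resolution; the step size is not critical).

## Predicting window edits

`find_protospacers()` scans both strands for 20-mers followed by an NGN
PAM. Spacer position 1 is the PAM-distal 5′ end; the broad editing window
is positions 2–12 and the core window 4–8, both inclusive.
`enumerate_window_edits()` lists one candidate A>G edit per window
adenine on the protospacer strand ('−' strand guides produce T>C on the
coding strand) and all cis combinations (capped at 2⁸ alleles — guides
beyond 8 window adenines are refused rather than silently truncated).
`map_edit_to_protein()` recomputes affected codons with all cis edits
applied. Predicted synonymous edits are retained but assigned the
wild-type rate in comparisons; predicted stop gains are excluded unless a
measurement exists (with an ABE profile A>G cannot create a stop codon,
so this path matters only for C>T editors).

## The weighted model and the multiplicative null

The expected sgRNA growth rate is the proportion-weighted mean over its
cell population:

$$ r_{sgRNA} = \sum_i p_i\, r_i + p_{unedited}\, r_{WT} $$

with outcome proportions $p_i$ from measured or predicted editing-outcome
tables. Alleles spanning $n$ amino-acid changes get the no-epistasis
multiplicative null rate $r = r_{WT} \prod_{i=1}^n (r_i / r_{WT})$ — two
mutants each at 0.7× WT predict a 0.49× WT double mutant. Epistasis is
deliberately not modelled; real interactions surface as residuals from
this null. `predict_vs_observe()` drops outcomes at or below a 0.05
proportion and renormalises the remainder (including the unedited
fraction) before applying the weighted model; renormalisation keeps the
proportions a probability vector, the natural reading of the filter.

## Concordance and the filter ladder

`join_guide_variant()` produces one row per (guide, predicted variant)
pair — comparisons are at variant granularity, matching how each
predicted mutation is an observation about its guide. Quadrants follow
the two −2-Z cutoffs: both deplete = TP, guide only = FP, variant only =
FN, neither = TN. `concordance_metrics()` reports Pearson r, the odds
ratio TP·TN/(FP·FN) (Haldane–Anscombe 0.5 correction when a cell is
empty, flagged), a two-sided Fisher exact p, TPR and accuracy.
`filter_ladder()` applies the cumulative rungs broad window → core window
→ efficiency score > 50 → single core edit. Each rung removes a known
noise source (unlikely edits, inefficient guides, bystander ambiguity),
so the correlation should be non-decreasing along the ladder up to
sampling noise; the suite asserts this within a 0.03 tolerance on seeded
simulations. Efficiency scores are consumed as an input column (the
generator emits its true per-guide efficiency on a 0–100 scale); no
scoring model is implemented.

## Direct edit sequencing of validation pools

For guides whose interpretation is ambiguous from sgRNA counts alone, the
validation arm sequences the edited locus directly in pools of guides
with staggered, non-overlapping windows. `call_edits_paired()` aligns
both mates gaplessly (anchored offset search across the read-start
stagger of 0–7 nt), and accepts a mismatch as an edit only when both
mates cover the position, agree on the substituted base, and both
qualities exceed Q20; mate agreement is required in addition to the
quality gate because a substitution seen in only one mate is almost
always a sequencing error. All accepted mismatches on a pair form one cis
allele; zero-edit pairs are the wild-type anchor. Only the mate-overlap
region is callable — with full-length mates over a short amplicon this is
nearly the whole target.

Edit growth rates anchor to the wild-type (no-mismatch) read fraction:
$r_i = r_{WT} + \ln[(f_{i1}/f_{WT,1})/(f_{i0}/f_{WT,0})]/\Delta t$. Two
frequency thresholds gate the tables: a permissive threshold (default
0.00015, the scale set by the mean 95th percentile of per-position
mutant frequencies in negative-control libraries,
`background_threshold()`) for edit discovery, and a stringent
1%-of-reads threshold for high-confidence growth-rate measurement.
Alleles are linked to the unique guide whose window interval contains
all their positions (ambiguous alleles are flagged and excluded), and the
major edit is the allele holding a strict majority of its guide's edited
frequency. The per-guide comparison of guide rate versus major-edit rate
uses the stringent table: rates of near-detection-limit alleles are
dominated by the pseudocount floor and would otherwise dilute the
comparison — the same reason a stringent cutoff sharpens the edit-vs-DMS
comparison.

## What the generator emulates — and what it does not

`generate_reference()` builds a random single-ORF coding sequence;
`generate_fitness_landscape()` draws each substitution's true rate from
the two-component skew-normal mixture (weight 0.56 deleterious, means
0.02/0.055 h⁻¹, SDs 0.006/0.004, shapes +2/−2 — mild skews of the kind
mixture fits to real rate distributions show). Screens propagate
frequencies exponentially and sample counts multinomially at fixed depth;
the baseline library is even by default (a symmetric Dirichlet models
uneven libraries when wanted). Editing outcomes follow an
independent-position product model over a bell-shaped positional activity
curve (peak 0.8 at spacer position 6, width 2, zero outside 2–12),
scaled per guide by a Beta(6, 4) efficiency draw whose 0–100 score is
also the efficiency input of the filter ladder. Guide abundances evolve
at the weighted-model rate — the population-average growth rate of the
guide's cell mixture — keeping the generator and Equation-style analysis
self-consistent; validation-pool *allele* fractions evolve at their own
allele rates, which is what direct edit sequencing measures. Paired reads
carry true edits at Q37 and substitution errors at rates ≤ 0.005 with
qualities drawn from 3–20; a two-point quality mixture is enough to
exercise the Q>20 both-mates rule without modelling a full error profile.

Problem sizes are chosen for fast, reproducible runs: an 80-aa reference
(79 mutagenised positions × 19 substitutions = 1501 variants), depth 10⁶
for screens, three guide-screen replicates, and a validation arm of four
pools of up to 16 disjoint-window guides (plus five ~12% spike-in
controls each) at 2 × 10⁴ read pairs per sample — the same order as a
real medium-throughput validation design, where pool sizes of tens of
guides keep edited-allele frequencies above the error-corrected detection
limit. The demo configuration (`default_config(demo = TRUE)`) shrinks
these further for a complete run in well under ten minutes on one CPU.

The generator does not simulate indels, PCR-duplicate structure beyond
UMI families, off-target (out-of-protospacer) editing, splice effects, or
editing chemistry beyond a single source→target base pair; passing tests
therefore say nothing about those features of real data. Real libraries
are also less even, real error profiles are position- and
context-dependent, and real editing efficiencies are not Beta-distributed
— the generator's distributions are declared defaults, not estimates.

## Numerical choices and degenerate inputs

* Histogram mixture fitting can be sensitive to initialisation; the
  2-means split is deterministic, and non-convergence raises an error
  carrying the optimiser's message rather than returning a silent bad fit.
* Pseudocounts: 0.5 on normalised guide means (log2 of zero) and 0.5
  reads for vanished alleles (flagged `floored`).
* Ties: a per-column base vote tie in a UMI family yields `N` (ignored in
  variant calling); an exact 50/50 edited-frequency split yields no major
  edit.
* Degenerate correlation inputs (zero variance, n < 3) report `NA` rather
  than erroring, and empty ladder rungs produce an n = 0 summary.
* All randomness flows through R's RNG seeded per stage from one master
  seed; reruns with the same configuration are identical.

## Known limitations

Strongly deleterious alleles deplete below one expected read at realistic
depths and long selections; their estimated rates are then pseudocount
floors (censored values near the deleterious mode), which is why the
stringent threshold exists and why the deleterious tail should be read as
"at most this fit". The guide forward model is the weighted-mean rate; a
cell-mixture forward model (each outcome class growing exponentially on
its own) departs from it over long selections, and with a 216-h window
that departure is dominated by the unedited fraction — the package keeps
the weighted-model convention throughout for self-consistency. Finally,
the fold-change engine is intentionally simpler than shrinkage-based
count models; with three replicates and strong effects this costs little,
but near-threshold calls on two replicates should not be over-read.
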