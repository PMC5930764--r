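---
title: "ribostress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribostress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostress)
```

## What this package computes

Mouse ribosomal DNA exists as hundreds of tandem-repeated 45S units whose
promoter copies differ both genetically and epigenetically. Two features
make the rDNA promoter a sensitive readout of early-life dietary stress:
an A/C single-base variant 104 bp upstream of the transcription start
site, and a functional CpG 133 bp upstream whose methylation silences
that particular repeat. Only A-variant copies respond epigenetically to
nutritional exposure, so the informative quantities are *per-read joint
calls*: each targeted bisulfite read is classified by allele at −104
*and* methylation state at CpG −133, giving the four classes
A^m/A^u/C^m/C^u. Per sample these reduce to

* `pct_a` — the percentage of accepted reads carrying A,
* `a_meth_pct` = 100·A^m/(A^m + A^u) — CpG −133 methylation among
  A-copies (and the analogous `c_meth_pct`),
* `ratio_a_to_c` = (A^m + A^u)/(C^m + C^u) — the raw A:C abundance
  ratio.

The second stress readout is the sperm small-RNA pool: class composition
(tRNA fragments, piRNA, miRNA, rRNA, ...) as percentages of
genome-mapped reads, and per-fragment differential abundance of
tRNA-derived fragments (tRFs), the 28–34 nt cleavage products of mature
tRNAs.

Both readouts sit on a litter-structured cohort: siblings share a dam,
her in-utero environment and her rDNA pool, so observations are
correlated within litters and every per-animal analysis uses
cluster-robust standard errors.

The package provides all three layers — bisulfite read calling, small-RNA
profiling, and cohort statistics — together with synthetic-data
generators that emulate a four-group pre-/post-weaning protein-restriction
design (CTCT, CTPR, PRCT, PRPR: control or protein-restricted diet before
and after weaning), so the full pipeline is testable without any external
data.

## Per-read calling model

**Coordinates.** Positions are TSS-relative: +1 at the TSS, negative
upstream, no position 0, and string position = `tss_pos + offset` for
negative offsets. This keeps the assay's −104/−133 labelling intact in
code and output.

**Converted consensus.** A fully converted top-strand bisulfite read can
differ from the genomic reference only at cytosines. `converted_templates()`
expands the reference into per-position allowed-base sets:

* assayed CpG cytosines: `{C, T}` (methylated / unmethylated);
* the variant position: `{A, C, T}` (either allele, or a converted C
  allele);
* every other cytosine: `{T}` in strict mode, since an unmethylated
  non-CpG cytosine must convert; `strict_mismatch = FALSE` additionally
  tolerates residual `C` (incomplete conversion);
* all remaining positions: the reference base only.

A literal string-equality filter would discard every methylated read, so
"perfect match" is implemented bisulfite-aware, against these sets.

**Acceptance and discards.** A read must cover both assayed positions
(`too_short` otherwise). The first 12 bases (configurable) act as a start
anchor: if more than a third of them disagree with the consensus the read
did not come from the amplicon start (`wrong_start`). An isolated
disallowed base anywhere — including inside the anchor — is a
`consensus_mismatch`; this distinction matters because a single sequencing
error near the 5′ end is evidence of error, not of mis-mapping. A `T` at
the variant site is called as the C allele when the variant is not in CpG
context (the default): a non-CpG cytosine is unmethylated and therefore
reads T. If the user declares the variant to be in CpG context, a T there
is ambiguous (it could be an unmethylated C whose methylation state
confounds the call) and the read is discarded.

Whether the C allele at −104 actually sits in CpG context is not
something the package can decide; it is exposed as
`variant_is_cpg_context` with default `FALSE`.

**%A versus the A:C ratio.** The assay literature writes the A-abundance
formula as a ratio of A reads to C reads, yet plots it on a 0–100 scale.
The package reports `pct_a` as a percentage of accepted reads (bounded by
construction) and retains the raw ratio as `ratio_a_to_c`; it does not
guess which was plotted. Low-coverage samples (fewer than `min_reads`
accepted, default 100) raise an error naming the sample rather than
returning unstable percentages.

**Sperm purity.** Imprinting control regions are uniformly unmethylated
(maternal ICRs) or methylated (paternal ICRs) in sperm, so
`purity_score()` summarises somatic contamination as
`1 − mean(|observed − expected|)` over the assayed ICR amplicons.

## The synthetic-data generators

The generators are first-class, tested code: their role is to produce
data with exactly the statistical structure the analysis assumes, so
every downstream estimator can be validated as an inverse.

**Bisulfite reads** (`simulate_rdna_reads()`): each read draws an allele
(Bernoulli, `pct_a/100`), then a methylation state at every assayed CpG
(the −133 rate is allele-specific), then chemistry — unmethylated C → T
with probability `conversion_rate` (default 0.995, typical bisulfite
efficiency), methylated C → T with probability
`inappropriate_conversion` (default 0) — and finally uniform substitution
errors (default 0.001/base). Reads start exactly at the amplicon start;
indels are not simulated because anchored perfect-match filtering would
discard them anyway. Methylation states across CpGs within a read are
independent: only CpG −133 is analysed, so within-read co-methylation
structure is irrelevant to the assayed statistic. The generator tallies
its realised allele × methylation truth, which makes the caller testable
as an *exact* inverse in the noise-free regime
(`conversion_rate = 1, seq_error_rate = 0`).

The bundled `synthetic_rdna_ref()` amplicon is deliberately synthetic: it
reproduces the geometry of the real assay (variant at −104, assayed CpG
at −133, additional CpGs and non-CpG cytosines, all within a 150 bp
read) without reproducing any genomic sequence.

**Cohort** (`simulate_cohort()`): four diet groups with
`n_litters_per_group` independent litters each (default 10) and 5–10
male pups per litter. Litter (dam) effects are additive Gaussian random
intercepts — the minimal structure that makes naive OLS anti-conservative,
which is precisely what cluster-robust inference exists to fix. Three
quantities carry litter components: adult body weights (`litter_sd`),
the %A genotype (`pct_a_litter_sd`; siblings share the dam's rDNA pool)
and A-meth% (`meth_litter_sd`). Pre-weaning PR litters have weaning
weights scaled by `1 − pr_weaning_deficit` (default 0.34). Group-level
death-weight and fasting-loss means default to the values reported for
this four-group design (28.53/26.05/24.06/21.76 g;
10.6/8.87/11.99/9.37 %), so the phenotype layer operates at realistic
effect sizes. The PRCT group — and only that group — carries a linear
%A → A-meth% effect with slope `slope_prct` (default 0.5). The slope is
applied to *centred* %A: the uncentred form would shift the PRCT group
methylation mean by ~35 points, whereas the observed phenomenon is a
within-group correlation at a similar mean, and centring is the same
model up to the intercept.

The variance components (`pct_a_litter_sd = 2.5`, `pct_a_sd = 6`,
`meth_litter_sd = 3`, `meth_noise_sd = 2`) were fixed jointly so that, at
the default 10 litters/group, the design exhibits the three properties it
exists to demonstrate: the litter-clustered test is approximately
calibrated (null rejection ≈ 0.06 at α = 0.05), naive OLS on the same
data is materially anti-conservative (≈ 0.14), and the PRCT slope of 0.5
is reliably detected after a four-way Bonferroni correction. Pushing the
%A litter share higher makes even the cluster-robust test
anti-conservative at 10 clusters — a known small-G failure mode — so the
defaults keep the between-litter share of %A moderate. Under these
defaults the implied PRCT correlation is ≈ 0.65.

**Small RNA** (`simulate_smallrna()`): per-sample class counts are
multinomial with Dirichlet-distributed proportions centred on the group's
class proportions (concentration `overdispersion`, default 500 — mild
biological spread around the group mean). Default proportions give CTPR a
marked composition shift (more tRFs and mitochondrial tRNA, less piRNA
and snoRNA), PRCT a small shift, and PRPR identical to control,
mirroring the diet-response pattern the design emulates. tRF species
counts are negative binomial (dispersion 0.2) with means proportional to
library size, and a `de_fraction` subset of species perturbed by
`de_log2fc` in one group. tRF read lengths follow a distribution with
92% of its mass on 28–34 nt. In this synthetic world every
length-passing read counts as genome-mapped; real genome prefiltering,
multi-mapping and ligation biases are out of scope, so passing tests
demonstrate correctness of the estimators under the stated model, not
robustness to alignment artefacts.

## Small-RNA annotation

`annotate_reads()` reimplements sequential class annotation in its
simplest defensible form: a read is assigned to the first class, in
priority order (miRNA, tRNA, rRNA, Mt_tRNA, Mt_rRNA, piRNA, snRNA,
snoRNA, lincRNA, other), holding a reference sequence in which the read
occurs as an exact substring; no mismatches. tRNA references are also
indexed with a CCA-appended copy because mature tRNAs carry a
post-transcriptional 3′ CCA absent from genomic references. tRNA reads
become fragments keyed by `(tRNA id, 1-based start, length)`; fragments
are not collapsed across isodecoders unless the reference set is
pre-collapsed. Composition-level analysis consumes only class totals, so
alignment heuristics (seeded mismatch alignment, multi-mapper
apportioning) would add machinery without changing the tested
quantities.

The 28–34 nt tRF band summary uses a *strict* majority (> 0.5) when
flagging that most tRNA-aligned reads are fragment-sized.

## Cohort statistics

**Cluster-robust OLS** (`ols_cluster_robust()`): OLS point estimates with
the sandwich covariance
$(X'X)^{-1}\bigl[\sum_g X_g'\hat u_g \hat u_g' X_g\bigr](X'X)^{-1}$
scaled by the CR1 factor $\frac{G}{G-1}\cdot\frac{N-1}{N-k}$, and t
tests on $G-1$ degrees of freedom. The robust-SE flavour is otherwise
unspecified in the assay literature; CR1 with $t_{G-1}$ is the standard
conservative small-sample choice, and with singleton clusters it reduces
exactly to HC1. All mice are used rather than litter means — litter
averaging discards within-litter information, while clustering retains
it and still controls type-I error; the one exception is the
weaning-weight contrast, which is defined on litter means
(`welch_on_litter_means()`, Welch–Satterthwaite df) because pre-weaning
weights are measured as whole-litter averages.

**Correlation analysis** (`cor_meth_analysis()`): per diet group, the
Pearson correlation between %A and A-meth% is descriptive; inference
comes from the cluster-robust linear model of A-meth% on %A, Bonferroni
× 4 (one test per group). A group with zero %A variance reports an
absent correlation rather than failing. Phenotype contrasts
(`phenotype_lm()`) model `phenotype ~ group` with the control group as
reference and Bonferroni × 3 (one per non-control group). Two-sided
p-values throughout.

**Welch degenerate case**: simulated configurations can produce litter
means with zero variance in both groups; equal means return t = 0,
p = 1, separated means return the p → 0 limit with a warning and a
`degenerate` flag instead of crashing a pipeline.

**One-way ANOVA** (`one_way_anova()`): the classical equal-variance F
test, used to compare %A and methylation levels across the four groups;
a constant response returns F = 0, p = 1.

**Fisher's exact test** (`fisher_exact_rxc()`): two-sided by the
conventional rule — the null probability of all tables (fixed margins)
no more probable than the observed one, with the usual 1 + 1e-7 relative
tolerance on the probability comparison. Three tiers: 2×2 tables use a
closed-form hypergeometric sum; small r×c tables (total ≤ 40) use full
own-code enumeration of the fixed-margin table set; larger tables up to
total 500 use the network algorithm in `stats::fisher.test`, and larger
still a seeded Monte-Carlo estimate (10^5 tables) with its standard
error reported. Non-integer input is an error by design: the caller must
round percentages first, making the rounding step explicit.

**Composition shift test** (`composition_test()`): a 2×K table of
rounded class percentages for the two groups, Fisher-tested and
Bonferroni-corrected for the three against-control comparisons. The
default builds rows from the two groups' *mean* percentages (each row
totalling ~100). Note the power implication: with rows of ~100, only
large composition shifts can reach small p-values. `method = "pooled"`
instead sums the rounded per-sample percentages within each group (rows
totalling ~100 × n samples), which weights the same shifts by cohort
size and is considerably more sensitive. Both are exposed because the
assay literature's description ("percentages … in each sample") is
ambiguous between them; the group-mean form is the default.

**tRF differential abundance** (`de_trf()`): per fragment, a negative
binomial model with `log(genome-mapped total)` offsets — library-size
normalisation is by genome-mapped reads, not by tRF totals, so a global
tRF expansion registers as a fold change rather than being normalised
away. A single common dispersion is estimated by pooled method of
moments across fragments, solving `Var(y) = μ + φμ²` in aggregate with a
degrees-of-freedom inflation of the squared residuals and a floor of
1e-8; each fragment is then tested by a 1-df likelihood-ratio test of
the group coefficient, with Benjamini–Hochberg adjustment across
fragments. This is a deliberate, documented approximation to
quasi-likelihood NB pipelines: it preserves the model (NB, offsets,
per-fragment test) without empirical-Bayes dispersion shrinkage.
Fragments with zero counts across a comparison are dropped before
testing. On simulated data the fold changes and p-value rankings track
an edgeR quasi-likelihood fit closely (correlation > 0.98 on log2FC),
while null simulations keep the raw p < 0.05 fraction near nominal.

## The pipeline

`run_pipeline()` wires the stages together — cohort simulation, per-mouse
bisulfite read simulation and calling (2 assayed mice per litter by
default, ~20 per group, matching realistic sperm-assay cohort sizes),
correlation and phenotype statistics, small-RNA composition/DE — and
emits a JSON report with TSV side-tables. One global seed is split
deterministically into independent per-stage streams, so identical
configurations reproduce identical numeric output; a skipped section
(e.g. `smallrna: false`) is marked `skipped` in the report rather than
silently absent. Every reported quantity is computed by an exported
module function; the orchestrator contains no statistics of its own.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic
data at these scales, chosen to give stable Monte-Carlo estimates at
interactive runtimes: 20,000 reads for caller-inverse checks (exact
binomial 99% CI comparisons); 100 seeds for the correlation-recovery and
phenotype-ordering checks; 500 group-level null replicates for the
robust-SE calibration; 200 fragments × 8 vs 8 samples for DE
calibration; exhaustive enumeration of all 2×2 and 2×3 contingency
tables with totals ≤ 20 against an independent oracle for the Fisher
implementation.

Numerical details worth knowing: probabilities in the Fisher tests are
compared on the log scale with the 1e-7 relative tolerance; the NB
log-likelihood floors fitted means at 1e-12 to keep zero-mean groups
finite; likelihood-ratio statistics are clamped at 0; `bonferroni()`
caps at 1 and is idempotent at the cap; the weaning-weight floor (0.5 g)
and the [0, 100] clamps on simulated percentages only bind in extreme
configurations.

## Limitations

* The read caller handles single-end, top-strand (OT) converted reads
  anchored at the amplicon start; bottom-strand and paired-end support
  and genome-wide alignment are out of scope.
* The annotator requires exact substring matches; reads with sequencing
  errors fall into `unannotated` rather than being rescued by alignment.
* The common-dispersion NB test has no per-fragment dispersion
  moderation; with strongly fragment-specific dispersion its p-values
  will be less accurate than shrinkage-based pipelines.
* The synthetic generators do not model PCR duplication, ligation bias,
  copy-number variation of the rDNA array, or correlated methylation
  across CpGs; conclusions from simulation transfer to real data only to
  the extent those features do not dominate.
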