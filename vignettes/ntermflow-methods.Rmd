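---
title: "Methods: N-terminome annotation and quantitative differential analysis"
author: "ntermflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: N-terminome annotation and quantitative differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntermflow)
```

# Scope and model

`ntermflow` implements the computational core of a quantitative
N-terminomics (degradomics) study design: an organism's protein N-termini
are enriched after reductive dimethylation of free amines, identified by
mass spectrometry, positionally annotated against predicted targeting
presequences, and tested for abundance differences between genotypes;
in parallel, a label-free proteome is analysed for differential protein
accumulation, and affinity-purification experiments are filtered for
candidate interaction partners. The package ships a synthetic-data module
that emulates the structure of such an experiment — three genotypes
(wild type, overexpressor `oe`, knock-down `kd`) with four biological
replicates each — so that every downstream stage can be exercised and
validated against known ground truth without any external data.

# Mass accounting for the labeling chemistry

In the dimethyl labeling scheme, free primary amines (the peptide
N-terminal alpha-amine and Lys epsilon-amines) are reductively
dimethylated with isotopic formaldehyde variants. Each modification is
represented by its elemental composition change and its monoisotopic
shift is computed from IUPAC atomic masses:

| modification | composition change | shift (Da) |
|---|---|---|
| light dimethyl (CH2O/NaBH3CN) | +2 C, +4 H | +28.031300 |
| heavy dimethyl (13CD2O/NaBD3CN) | +2 13C, +6 D, −2 H | +36.075670 |
| N-terminal acetylation | +C2H2O | +42.010565 |
| pyroGlu from Glu | −H2O | −18.010565 |
| pyroGlu from Gln | −NH3 | −17.026549 |

The invariant checked in the tests is that each shift equals the dot
product of the composition change with an independently typed
monoisotopic mass table to 1e-6 Da.

A chemical consequence of the labeling carried through the simulator:
an endogenously acetylated N-terminus has no free alpha-amine, so it can
only be quantified across isotope channels if the peptide contains a
labelable Lys. The simulator draws peptide sequences from the synthetic
proteins and reads Lys presence off the sequence itself, so the
quantifiability flag and the peptide are always mutually consistent.

# Positional annotation

Coordinates are 1-based and inclusive throughout; position 1 is the
initiator Met. Targeting predictions report the cleavage position as the
last residue of the presequence, so the mature N-terminus is
`cleavage_pos + 1`. Each observed terminus is assigned exactly one
category with the precedence POS1 > POS2 > CLEAVAGE_WINDOW >
UNANNOTATED:

* **POS1** — the database start site;
* **POS2** — position 2 with residue 1 = Met (initiator-Met excision);
* **CLEAVAGE_WINDOW** — within `window_W` residues of the predicted
  mature N-terminus, i.e. `|start − (cleavage_pos + 1)| ≤ W`;
* **UNANNOTATED** — everything else.

The window is read as *inclusive and two-sided* (`W = 5` by default):
observed mature termini of imported proteins are frequently "ragged",
shifted by one or two residues to either side of the predicted site, so a
one-sided or exclusive reading would misclassify genuine maturation
sites. This is a design choice: the boundary convention is not uniquely
determined by the phrase "within five amino acids", and the tests pin the
chosen convention (both `W` offsets inclusive, symmetric).

Start-site evidence outranks a prediction window: a terminus at position
1 or 2 is classified POS1/POS2 even if a (short) presequence window would
also cover it, because the observed start is direct evidence while the
window comes from a predictor. Peptides matching more than one protein
are reassigned to the lexicographically smallest accession, flagged
ambiguous, and excluded from category tallies by default — protein-group
handling is genuinely underdetermined in this kind of data, and the flag
keeps the choice visible.

Candidate unprocessed precursors are termini of presequence-bearing
proteins observed at least `W` residues upstream of the predicted
cleavage site (`start ≤ cleavage_pos − W`), including POS1/POS2 termini
of proteins that should have been imported and processed. Each candidate
carries a flag for whether its peptide contains a Lys, since without one
an acetylated precursor terminus cannot be quantified in this assay.

# Moderated t-tests for terminus abundance

Terminus intensities are log2-transformed; zeros are treated as missing
and **no imputation is performed on the terminome side** — a terminus
either was quantified in a channel or it was not, and fabricating values
for unlabeled termini would manufacture fold changes. Features need at
least `min_quant_reps = 2` present values per group; otherwise they are
skipped with a reason code.

The test is a pooled two-sample t-test with empirical-Bayes variance
shrinkage. With per-feature sample variance $s^2$ on $d$ residual df and
a scaled inverse-chi-square prior $(d_0, s_0^2)$, the posterior variance
is

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},$$

and the moderated statistic $\tilde t = \Delta / \sqrt{\tilde s^2 (1/n_A
+ 1/n_B)}$ is referred to a t distribution on $d_0 + d$ df. The
hyperparameters are estimated by **moment matching of log sample
variances against a scaled F distribution**: under the model
$s^2 \sim s_0^2 F(d, d_0)$,

$$\operatorname{Var}[\log s^2] = \psi'(d/2) + \psi'(d_0/2),$$

so $d_0$ is obtained by inverting the trigamma function on the excess
dispersion of $\log s^2$, and $s_0^2$ from the mean with the matching
digamma correction. Moment matching was chosen over marginal maximum
likelihood because it is simple, closed-form up to one monotone
inversion, and testable against simulation; at the data sizes involved
the difference is immaterial, and the test suite cross-checks the fit
against an independent reference implementation of the same hierarchy.
Two limits matter numerically: when the dispersion of log variances is
at or below its theoretical sampling minimum the prior df is infinite
and the prior variance is the pooled mean of sample variances (for
identical variances $v$ this returns exactly $v$); with $d_0 = 0$ the
test reduces to the ordinary pooled t-test, which the tests verify
against `t.test()`.

Significance uses the conjunction `p < 0.05` **and** `|log2 FC| > 0.58`
(0.58 is the two-decimal log2 equivalent of a 50% abundance change).
No multiple-testing correction is applied to terminome p-values by
default — the fold-change floor acts as the second filter — but
`significance_filter(use_fdr = TRUE)` substitutes BH-adjusted values.

The correlation between terminus log2 fold changes and parent-protein
log2 fold changes is summarized by Pearson r with a 95% Fisher-transform
confidence interval (`cor.test`). In the simulation, termini inherit
their parent protein's genotype effect, so this correlation is positive
by construction but attenuated by replicate noise and by imputation on
the protein side; with the default settings it comes out near 0.3,
substantially below the attenuation-free value, which is itself a useful
reminder that observed terminus/protein correlations are lower bounds on
the underlying coupling.

# Label-free proteome analysis

The proteome pipeline follows the standard label-free workflow:

1. **Quantifiability filter** — keep proteins with ≥ 2 of 4 present
   values in at least one genotype.
2. **log2 transform + imputation** — missing values are drawn per sample
   from a downshifted Gaussian with mean `sample mean − 1.8 · SD` and SD
   `0.3 · SD`. These width/downshift defaults are the documented standard
   settings of the Perseus platform's imputation; both are exposed in the
   configuration. Samples with fewer than 3 observed values fall back to
   global parameters with a warning.
3. **One-way ANOVA** across genotypes per protein, **BH** step-up FDR at
   `q < 0.05` (the row-wise ANOVA is vectorized for simulation scale and
   is verified against `anova(lm(...))` per protein).
4. **Tukey HSD post-hoc** on the ANOVA-significant set: studentized-range
   (Tukey–Kramer) p-values from `ptukey` at family-wise alpha 0.05,
   verified against `TukeyHSD(aov(...))` and against the published
   critical value q(0.05; k = 3, df = 9) = 3.948.
5. **Pairwise two-tailed t-tests** per genotype pair (pooled by default,
   Welch optional), usable on unimputed tables — summary tables in this
   field sometimes report zero averages for undetected proteins, which
   suggests observed-value testing, so both modes are provided.
6. **Clustering and PCA** — ANOVA-significant proteins are z-scored per
   protein across the 12 samples and clustered by agglomerative
   hierarchical clustering (Euclidean distance, average linkage), with
   the tree cut at a fixed `k = 7`. A fixed-k cut (rather than a height
   threshold) is a deliberate choice: it makes cluster granularity an
   explicit, reproducible parameter. PCA projects samples on the
   significant-protein submatrix; when fewer than three proteins are
   significant the projection falls back to the full quantifiable set.

A practical caveat the synthetic data reproduces faithfully: downshifted
imputation inserts low values into otherwise mid- or high-abundance
rows whose missingness was not abundance-driven, inflating within-group
variance and compressing ratios. At the default 20% missing-not-at-random
missingness this costs the ANOVA most of its power at a 1.0 log2 effect
(order of 20% of true effects detected at FDR 0.05) — the same
ratio-compression that real imputed datasets exhibit for low-abundance
proteins. The FDR calibration targets are therefore checked on
missingness-free null simulations, where the test's size is the property
under test, separate from the power cost of imputation.

# Pull-down interactor filtering

The stringent rule keeps a protein iff it is identified (non-missing
LFQ intensity) in **all** bait replicates, absent from **all** control
pull-downs, and annotated to the chloroplast; "identified" is
operationalized as a non-missing intensity, with an optional minimum
unique-peptide count (default 1) since no intensity floor is part of the
rule. Controls must be fully absent — a ratio-threshold variant is
deliberately not implemented, as full absence is the stricter and
simpler reading. The relaxed subset keeps proteins seen in ≥ 1 bait
replicate and no control, flagging single-replicate candidates. The
stringent set is a subset of the relaxed set for every input, the filter
is idempotent and order-independent, and on simulated pull-downs with
zero background it recovers the true interactor set exactly; with
background presence probability p per sample, the expected false-positive
count is `n_chloroplast_background · p² (1−p)²`, which the tests verify
by simulation.

# The synthetic-data generator

The generator's defaults define the study conditions:

| parameter | default | basis |
|---|---|---|
| genotypes × replicates | 3 × 4 | study design |
| proteins | 600 | desk-scale stand-in for a few-thousand-protein proteome |
| N-termini | 1300 | matches the ~1300-peptide terminome scale |
| presequence fractions | 0.30 plastid / 0.10 mito / 0.10 secretory | plastid-enriched tissue |
| cleavage position | uniform 30–80 | typical transit/signal peptide lengths |
| acetylation | POS1 0.89, POS2 0.78, plastid-mature 0.27, SP 0.0 | reported category frequencies |
| ragged offsets | {−2..+2} w. (0.05, 0.15, 0.60, 0.15, 0.05) | shifts of 1–2 residues to either side |
| intensity | log2 ~ N(25, 2), replicate SD 0.25 | typical LFQ dynamic range / CV |
| effect | 15% of proteins, 1.0 log2 | minority of proteome responding |
| missingness | 20% overall, MNAR logistic in intensity | observed quantification losses |

Sequences are i.i.d. uniform over the 20 amino acids with Met fixed at
position 1; no homology is simulated, so peptide-to-protein ambiguity is
negligible by construction and is instead tested with crafted fixtures.
Proteome missingness uses a logistic weight decreasing in log2 intensity,
normalized so the expected overall missing fraction equals the requested
rate exactly — missing-not-at-random in direction, calibrated in total.
Every generator is a pure function of its parameters and seed: each
operation derives its own RNG stream from the master seed plus a hash of
the operation name, so adding termini does not perturb the proteome
draw, and identical (params, seed) reproduce byte-identical outputs.

What the simulation does **not** emulate: spectra and identification
error (every simulated peptide is correctly identified), retention-time
or detectability structure beyond the Lys rule, protein groups and
shared peptides, correlated replicate effects (batch structure), and
heavy-tailed intensity noise. Passing tests therefore demonstrate that
the *computational* pipeline is correct and calibrated under its stated
model; they do not certify performance against search-engine artifacts
or non-Gaussian noise in real data.

# Numerical and procedural choices

* Problem sizes in tests and the acceptance script: annotation recovery
  on 1,000 termini over 400 proteins; calibration on 10,000-feature null
  simulations; CI coverage on 1,000 replicates of n = 500. These sizes
  make binomial/Monte-Carlo error small relative to the tolerances while
  keeping a full run in well under a minute.
* The trigamma inversion uses Newton iteration with the asymptotic
  endpoints `1/x` (small x) and `1/sqrt(x)` (large x) as guards.
* Degenerate inputs: all-zero variances error with an instruction to
  apply a pseudo-variance floor; identical groups give t = 0, p = 1;
  zero-SD profiles z-score to all-zero rows rather than NaN; identical
  samples yield identical PCA scores.
* Ties in hierarchical clustering follow `hclust`'s deterministic
  merge order; reruns are bit-identical.
* TSV outputs record the seed in a comment header; the pipeline writes a
  manifest of config values and output checksums, and the tests assert
  checksum-identical reruns.

# Known limitations

* The moderated-t hyperparameter fit assumes a common residual-df regime
  per fit; wildly heterogeneous per-feature df (heavy missingness) are
  handled but push the moment estimates toward their robust fallbacks.
* iBAQ-style absolute quantification is consumed, not computed;
  theoretical-peptide enumeration is out of scope.
* Lumenal (secondary) transit-peptide cleavages have no predictor input
  here and surface as UNANNOTATED termini.
* The cluster count k is a parameter, not an inference; use the emitted
  profiles to judge granularity.
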