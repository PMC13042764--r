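---
title: "splicemark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicemark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

TDP-43 is a splicing repressor whose nuclear loss — the pathological
hallmark of most ALS and roughly half of FTD — de-represses cryptic
splice sites. The resulting *aberrant junctions* are essentially absent
from normal tissue, appear in a heterogeneous subset of patients, and
frequently introduce premature termination codons (PTCs) that route the
transcript into nonsense-mediated decay (NMD), which is why they sit at
low PSI even in affected samples. splicemark implements the downstream
analysis that turns junction read counts, a gene annotation, a
single-nucleus expression matrix and RBP peak sets into: aberrant
junction calls, cell-type attribution, disease- and cell-type-specific
biomarker panels, a classifier over those panels, transcript-level
consequence predictions (ORFs, PTC/NMD, de novo tryptic peptides), and
RBP binding context. Because the patient data this style of analysis is
usually run on are access-restricted, the package ships a synthetic
cohort generator with a machine-readable truth table; every statistical
claim the test suite makes is a claim about recovery of that planted
truth.

## PSI over local splicing variations

Junctions sharing a donor splice site form a local splicing variation
(LSV); junctions whose donor is unique are regrouped by shared acceptor,
and the remainder quantify alone. PSI is the plug-in count ratio

$$\mathrm{PSI}(j,s) = \frac{c_{js}}{\sum_{k \in \mathrm{LSV}(j)} c_{ks}},$$

defined only when the denominator reaches the coverage floor
(`min_coverage`, default 10 reads); singleton LSVs get PSI 1 when
covered. Dedicated splicing quantifiers estimate a posterior PSI from a
Bayesian model; every downstream rule here consumes point PSI, group
medians and ranks, for which the plug-in ratio with a coverage floor is
an adequate and much simpler estimator. The floor of 10 keeps the
binomial noise of a ratio below ~0.15 s.d. at the default coverage.

## The three-test heterogeneity rule

Patient cohorts are heterogeneous — an aberrant junction is typically
carried by a subset of patients — so a junction is called *changed* only
when three two-sided tests agree at $\alpha = 0.05$ on the case vs
control PSI values: a Welch t-test, a Wilcoxon rank-sum test, and TNOM.

TNOM (total number of mistakes) is the minimum, over all thresholds on
the pooled values and both orientations, of misclassified samples.
Thresholds are only meaningful between distinct values, so tied data
restrict the candidate cut set. Its p-value is $P(\mathrm{TNOM} \le
\mathrm{obs})$ under uniform permutation of the group labels: exact by
enumeration whenever $\binom{n_a+n_b}{n_a} \le 50{,}000$, otherwise by
10,000 seeded label permutations with add-one smoothing $p =
(b+1)/(m+1)$, which keeps permutation p-values valid (never zero) at
small sample sizes. The permutation null distribution of TNOM depends
only on the group sizes and the tie structure of the pooled values, so
the implementation memoises it per (sizes, tie-pattern) within a run;
this is an exact optimisation, not an approximation. When every pooled
value is identical the statistic degenerates to $\min(n_a, n_b)$ with
$p = 1$.

Welch's unequal-variance t-test is used deliberately: case groups mix
carriers and non-carriers and have inflated variance. No
multiple-testing correction is applied to the junction p-values — the
calling rule operates on raw per-test thresholds; Benjamini–Hochberg
can be applied downstream by the user if desired.

Changed junctions split by the sign of the median difference (no ΔPSI
floor on this path). Up-regulated junctions with control median PSI
strictly below 0.05 are *aberrant*; the boundary case (median exactly
0.05) is *normal*. For two-condition cell-line designs a separate
pooled path applies: replicates are summed, the p-value is a two-sided
Fisher's exact test on `[junction, rest-of-LSV] x condition`, and
significance requires $p < 0.01$ and $|\Delta\mathrm{PSI}| > 0.1$.

The *positivity rate* of a junction is the fraction of patient samples
with PSI strictly above the 75th percentile of the control distribution,
computed with the linear-interpolation quantile ($h = p\,(n-1)$ on the
sorted values — R's type 7); both the quantile type and the strict
inequality are pinned so the rate is reproducible.

## Cell types, markers, enrichment

Nuclei are normalised to 10,000 counts and log1p-transformed; profiles
(mean and detection fraction per gene per type) are computed over
control-group nuclei only. Marker calling is one-vs-rest:
$\log_2\mathrm{FC} = \log_2\!\big((\mu_{in}+\varepsilon)/(\mu_{out}+
\varepsilon)\big)$ with $\varepsilon = 0.01$ bounding fold changes on
sparse means, a Wilcoxon p over cells, and detection rates `pct1` (in
the target type) and `pct2`. *Strict* markers need log2FC > 1, pct1 >
0.7 and pct2 < 0.1 — all strict inequalities; *enriched* markers need
log2FC > 1 and p < 0.05. `pct2` is the **maximum** detection among the
other types rather than their pooled mean: a gene detected in 30% of one
other type should not pass as specific because the remaining types
dilute the pool. The Neuron-to-Oligo score is
$\log_2\!\big((\bar\mu_N + \varepsilon)/(\mu_O + \varepsilon)\big)$
where $\bar\mu_N$ averages the per-neuron-subtype means — an unweighted
mean so the score does not drift with neuron subtype composition. The
log2 form (rather than a raw ratio) makes the score antisymmetric.

Gene-set enrichment uses the 2x2 table of query vs cell-type-specific
genes over an explicit universe. The odds ratio is the sample
$ad/bc$ with Haldane's +0.5 correction when any cell is zero (the
conditional-MLE estimate that `fisher.test` reports is deliberately not
used — the plain sample OR is what the row-scaled enrichment heatmaps
in this field display); the p-value is the usual two-sided
hypergeometric tail sum, and the test suite checks it against
`stats::fisher.test` exhaustively on small tables.

## Biomarker nomination and leakage-safe classification

A junction is a biomarker for disease D iff (i) its gene is a strict
marker of D's designated cell type (ALS → oligodendrocyte, FTD →
neuron), (ii) it is aberrant-up for D in at least one eligible tissue
(cerebellum is excluded from eligibility — its splicing profile is an
outlier among CNS tissues), and (iii) it is not aberrant-up for the
other disease in any tissue. Support is recorded per tissue so a
two-tissue requirement is one config switch away.

Classification (ALS vs FTD patients) uses per-sample PSI of the
nominated junctions as features, with missing PSI encoded as 0 —
"absent" is the biologically meaningful value for a junction that is
effectively unspliced in that sample. The ensemble is a standard random
forest (500 trees, $\sqrt{p}$ features per split, seeded); class
confidence is the fraction of ensemble votes. Feature selection is the
dominant leakage risk, so nomination is re-run inside every training
split and every CV fold using only that split's patients; all control
samples remain available to the in-split heterogen runs, since controls
are never classified and contribute nothing to the ALS-vs-FTD label
being predicted. The suite asserts the no-leakage property directly:
deleting the held-out samples before nomination leaves the selected
feature list unchanged.

The permutation null of the classifier keeps the (training-)nominated
feature set fixed and permutes the labels, averaging the held-out AUC
over 20 seeded permutations. Re-running nomination under permuted
labels would be even stricter but typically selects zero features —
there is then no model to evaluate — and a single permutation's AUC on
a 7+7 test split has a standard deviation near 0.15, so the average is
the stable chance-level reference. External samples are labelled only
when the top vote fraction strictly exceeds 0.8, otherwise
"unclassified"; feature junctions missing from an external matrix are
zero-filled and counted in a coverage warning.

## Transcript effects

The aberrant transcript of a junction is reconstructed from the
canonical transcript's pre-mRNA span by splicing out (i) every
annotated intron with zero overlap (half-open, ≥1 shared base) with the
aberrant intron and (ii) the aberrant intron itself; annotated introns
touched by the event are retained as sequence. A junction identical to
an annotated intron therefore reproduces the canonical mature transcript
exactly, which the suite asserts byte-for-byte. "Canonical" means the
longest-CDS transcript of the gene unless one is named.

ORFs are every ATG-to-stop span in the three forward frames with no
internal stop — nested ATGs each count — with a 7-aa floor matching the
digest's detectable-peptide floor. PTC prediction translates from the
canonical start codon mapped onto the aberrant transcript and applies
the field-standard 50-nt boundary rule: PTC iff the first in-frame stop
ends strictly more than 50 nt upstream of the transcript's last
exon-exon junction (the signed distance is reported). If the start
codon is lost, or no in-frame stop exists, the call is NA with a
reason. The peptide database merges the reference proteome with all
aberrant ORF peptides (novel headers `NOVEL|<junction>|<orf>`); the
in-silico tryptic digest cleaves after K/R except before P, allows up
to 2 missed cleavages, and keeps 7–40 aa peptides; a digest peptide is
novel iff absent from the identically-digested reference.

## RBP context

An RBP binds a junction iff any peak overlaps (≥1 base, half-open) the
window `[site − 150, site + 150)` around either splice site. The
windows are strand-agnostic — the rule is stated symmetrically around
both splice sites, so strand adds nothing — and are clipped at
position 0. Binding is translation-invariant and monotone in the flank
width, both asserted on randomized fixtures.

## The synthetic cohort

The generator emulates exactly the statistical structure the analysis
assumes, at desk scale: 200 multi-exon genes on 4 chromosomes, one
canonical CDS-bearing transcript each, GT/AG written at every annotated
and planted splice site; 2 cortical tissues with 12 control / 12 ALS /
12 FTD samples each; 30 planted aberrant junctions per disease, 15
normal-up junctions per disease, 300 null alternative junctions;
Poisson LSV coverage with mean 50; 7,200 nuclei over 4 cell types with
70 planted strict markers; oligodendrocyte fraction shifted −0.15 in
ALS and neuron fraction −0.10 in FTD; peaks placed near planted splice
sites with per-RBP probabilities (0.9 for the TDP-43-like anchor, 0.5
for co-factors, 0.1 background-like). These sizes give stable recovery
statistics while keeping a full run of the pipeline in the low minutes
on one CPU.

Choices worth recording:

* **Per-junction baseline PSI.** Each planted aberrant junction has one
  true control PSI drawn from Beta(0.5, 60) truncated below 0.02 (the
  aberrant regime); per-sample variation then comes from count sampling
  alone. This matches the truth table's semantics — one true control
  PSI per junction — and avoids a per-sample-redraw model whose extra
  between-sample variance manufactures null flukes the analysis cannot
  distinguish from real signal.
* **Heterogeneity as carriers.** Case shift Δ = 0.25 is added only in a
  60% carrier subset per junction per tissue, drawn independently per
  junction — patients are not replicates of one another.
* **Event classes chosen to exercise every reconstruction branch.** Per
  disease: 20 cryptic 5' splice-site extensions (retained intronic
  piece carries an in-frame stop, and the retained length ≥ 80 nt keeps
  that stop > 50 nt upstream of the new junction, so the class is
  PTC-positive by construction); 4 exon skips (the skipped exon's
  length is forced off a multiple of 3 and an annotated junction is
  kept downstream of the frameshift, so a PTC arises with high
  probability but not certainty — the residual is genuine translation
  stochasticity); 6 3'UTR events whose cryptic donor sits within 45 nt
  of the stop codon, leaving the CDS intact and the call PTC-negative.
  The planted PTC fraction is therefore 0.8 by design, realised up to
  the exon-skip stochasticity.
* **Null alternative junctions** share a donor with an annotated intron
  and have one base PSI drawn uniformly in (0.05, 0.95), identical in
  law across groups — these carry the type-I calibration.
* **Compositions** are Dirichlet draws (concentration 100) around
  group-level proportions; disease shifts subtract from the target type
  and renormalise the rest proportionally.
* **Markers** are detection-rate constructs: detected with probability
  0.9 in the home type vs 0.02 elsewhere, with a shifted-Poisson level —
  detection rates, not just means, are what the strict thresholds test.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: read-level artifacts (alignment error,
multimapping, positional bias), batch and library-size confounding,
correlated junctions within a gene beyond the LSV constraint,
non-canonical splice sites, annotation incompleteness, donor-level
correlation between tissues from the same patient, ambient RNA and
doublets in the nuclei, and any relationship between expression level
and splicing detectability. Recovery at the default design demonstrates
that the implementations are correct and the thresholds behave as
stated, not that the pipeline would achieve comparable sensitivity on
patient cohorts.

## Numerical conventions

All internal coordinates are 0-based half-open; GTF is converted at the
read/write boundary, BED taken verbatim. Junction equality includes
strand. Quantiles are type 7. Ties in sample selection break
lexicographically by sample id. All stochastic steps take explicit
seeds, and derived seeds stay below $2^{31}$. Permutation p-values are
clamped into $(0, 1]$. The acceptance script recomputes every reported
quantity from scratch at the seed the caller provides; the test suite's
reference cohort is fixed at seed 42.

## Problem sizes and runtime

The reference analyses use the default design throughout: 1,007
junctions x 72 samples for the splicing screen, 2,000 null junctions for
type-I calibration, 200 x 7,200 for the nuclei matrix, 48 patients for
classification (5-fold CV with in-fold nomination re-runs the heterogen
screen 20 extra times), and 60 reconstructed transcripts. A full
pipeline run takes roughly two minutes on one CPU; the complete test
suite about five.

## Known limitations

The heterogen path assumes two comparable groups within one tissue and
does not model donor-level pairing across tissues. The plug-in PSI has
no shrinkage, so low-coverage LSVs are simply censored rather than
stabilised. The classifier's confidence is a raw vote fraction, not a
calibrated probability. The peptide database enumerates ORFs without
ribosome-occupancy evidence, so it over-generates candidates by design
— the intended consumer is an MS search engine that supplies its own
statistics.
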