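# splicemark

Aberrant splice-junction biomarkers for ALS/FTD from junction read
counts.

TDP-43 pathology — nuclear loss of a splicing repressor — marks ~97% of
ALS and ~45% of FTD and de-represses cryptic splice sites. The resulting
*aberrant junctions* are essentially absent in normal tissue (control
median PSI < 0.05), appear in a heterogeneous subset of patients, and
mostly introduce premature termination codons, so the transcripts are
degraded by NMD and the junctions sit at low PSI even in carriers.
splicemark is the downstream analysis for this setting, for
transcriptomicists who have junction counts, an annotation, a
single-nucleus expression matrix and RBP peak intervals:

* **PSI over LSVs** — percent-spliced-in as the junction's count ratio
  over its local splicing variation (shared donor, else shared
  acceptor), with a coverage floor;
* **three-test heterogen screen** — a junction is *changed* when TNOM
  (total number of mistakes: the minimum threshold misclassification
  count, with an exact or permutation p), Welch's t and Wilcoxon all
  give p < 0.05; up-regulated junctions split into *aberrant*
  (control median PSI < 0.05) vs *normal*; a pooled Fisher path
  (p < 0.01, |ΔPSI| > 0.1) serves two-condition knockdown designs;
* **cell-type attribution** — strict one-vs-rest markers from
  single-nucleus profiles (log2FC > 1, pct1 > 0.7, pct2 < 0.1), Fisher
  enrichment of splicing-altered genes per cell type,
  Neuron-to-Oligo scores, composition summaries;
* **biomarker panels and classification** — disease- and
  cell-type-specific junctions (ALS → oligodendrocyte, FTD → neuron;
  aberrant in ≥ 1 eligible tissue, absent from the other disease), a
  per-junction positivity rate (fraction of patients above the
  controls' 75th percentile), and a leakage-safe random forest whose
  feature nomination is re-run inside every training split and CV fold;
  external samples are labelled only above a 0.8 vote-fraction
  confidence;
* **transcript effects** — reconstruction of the aberrant transcript
  (remove all annotated introns untouched by the event, plus the
  aberrant intron), ORF enumeration from every ATG, the 50-nt NMD
  boundary rule for PTC calls, and a tryptic peptide database (novel
  ORFs + reference proteome) for MS search;
* **RBP context** — binding calls within ±150 nt of either splice site
  against CLIP-like peak sets, binding fractions and co-binding
  matrices.

Patient datasets of this kind are access-restricted, so the package
ships a **synthetic cohort generator** (toy genome with GT/AG splice
sites, LSV-structured junction counts with planted aberrant/normal/null
junctions, nuclei with planted strict markers and disease-shifted
compositions, peaks enriched near planted splice sites) plus a truth
table; the test suite validates every stage by recovering that planted
truth and by brute-force oracles.

## Worked example

The `analysis/` directory is the full study as numbered drivers; each
stage reads the previous stage's files through the package's readers.

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_differential_splicing.R
Rscript analysis/03_cell_types.R
Rscript analysis/04_biomarkers_classifier.R
Rscript analysis/05_transcript_effects.R
Rscript analysis/06_rbp_context.R
```

Output of the run at the reference seed (42), abridged:

```
  junctions: 1007 (60 planted aberrant, 30 normal-up, 300 null alternative)
  median oligodendrocyte proportion — ALS: 0.16, control: 0.29, FTD: 0.35
ALS vs control in frontal_cortex: 30 aberrant_up, 23 normal_up, 53 down
planted-truth check: 60/60 aberrant discoveries are planted (60 planted total)
strict markers: 70 (Astrocyte 5, Microglia 5, Neuron 30, Oligodendrocyte 30)
ALS splicing genes most enriched in: Oligodendrocyte (OR 109.3)
FTD splicing genes most enriched in: Neuron (OR 109.3)
biomarkers: 24 ALS/oligodendrocyte, 24 FTD/neuron
highest positivity rate: chr2:93378-93642:+ (ALS, 0.83)
held-out AUC: 1.000 (48 features)
5-fold CV AUC per fold: 1.00 1.00 1.00 1.00 1.00; mean 1.000
permuted-label null AUC: 0.511 (chance reference)
external scoring: 95% of disease samples labelled ALS; 100% of controls unclassified
PTC fraction: 0.77 (46 of 60 with a defined call)
binding fractions over 60 aberrant junctions:
  TARDBP   0.93
  CELF2    0.60
  PTBP1    0.60
  RBFOX1   0.18
of 56 TDP-43-bound junctions, 47 are co-bound by CELF2 or PTBP1
```

Reading the numbers: every planted aberrant junction is recovered with
no false discoveries; the splicing-altered genes land in the designed
cell types; the 48 nominated biomarkers separate ALS from FTD perfectly
on held-out samples while permuted labels sit at chance; the PTC
fraction reflects the planted 80% frameshifting mix; and the
TDP-43-like anchor binds ~90% of aberrant junctions, matching its
designed peak placement probability.

An equivalent single call is available in R:

```r
library(splicemark)
report <- run_pipeline(default_run_config(seed = 42))
report$holdout_auc        # 1
report$ptc_fraction       # 0.767
```

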