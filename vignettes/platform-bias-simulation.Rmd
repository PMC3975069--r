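---
title: "Simulating and diagnosing platform-specific bias in CAGE and RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and diagnosing platform-specific bias in CAGE and RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagecompare)
```

## The problem

Cap analysis of gene expression (CAGE) sequences the 5' ends of capped RNAs
and quantifies transcription start sites (TSSs) at single-base resolution.
The two protocol families in wide use — a PCR-amplified tag protocol on
short-read sequencers and a PCR-free protocol on a single-molecule
sequencer — distort the same underlying transcriptome in different,
mechanism-specific ways, and both differ from polyA-selected RNA-seq.
When two platforms disagree on a gene or a TSS, the disagreement could be
biology, sampling noise, or a protocol artifact; telling these apart
requires knowing what each artifact looks like quantitatively.

`cagecompare` approaches this by simulation with planted ground truth. A
synthetic genome is generated with every sequence context the artifacts
act on; platform models distort simulated readouts with known parameter
values; and a set of diagnostics measures each distortion from the data
alone. Because every mechanism is planted with a known magnitude, every
diagnostic can be validated by parameter recovery — no external data
download is needed.

## The platform models

A `platform_model()` bundles the distortion parameters of one protocol.

* **Nontemplated 5' G addition** (`g_add_prob`, default 0.87 for the PCR
  tag protocol): the reverse transcriptase appends a guanine to the cDNA
  5' end at a high, previously estimated rate. If the genomic base one
  position upstream of the true start (strand-aware) is a G, the extra
  base aligns and the observed start moves 1 bp upstream; otherwise the
  mismatching leading base is trimmed during alignment and the start is
  recovered exactly, but the raw leading base was a G. The single-molecule
  protocol suppresses the artifact via fill-and-lock template treatment
  (`g_add_prob = 0`).
* **T-stretch shifting** (`tstretch_shift_enabled`, `tstretch_min_run`):
  the fill-and-lock treatment conversely locks the observed start just
  downstream of a genomic T run beginning at the TSS, displacing it by the
  run length. The minimal triggering run length is not established;
  the default of 4 bp is configurable, and the generator plants runs
  of 4-15 bp.
* **GC-dependent amplification** (`gc_bias_coef`): PCR-amplified protocols
  weight each gene by `exp(gc_bias_coef * (GC - 0.5))`, with GC measured
  over the promoter (CAGE, +/-500 bp of the TSS) or the exons (RNA-seq).
  The default for the PCR tag platform, -1.0 on the natural-log scale, is
  a free parameter chosen to give a clearly detectable but moderate
  depletion of high-GC promoters; PCR-free models use 0.
* **EcoP15I internal-site competition** (`ecop15i_boost`,
  `ecop15i_max_dist`): the tag protocol cuts tags with the type III
  restriction enzyme EcoP15I (recognition site CAGCAG, cleaving 25-27 bp
  downstream). A native recognition site on the antisense strand near the
  TSS — CTGCTG on the sense strand — offers an extra cleavage opportunity
  and inflates the gene's tag yield. This is modeled as a gene-level
  multiplicative boost (default 1.5) for genes with a site within 400 bp,
  rather than as mechanistic cleavage kinetics, because the observable is
  the yield change, not the cut-site distribution.
* **Linker first-base preference** (`first_base_weights`): the tag
  protocol's 5' linker pool is 80% G-starting, which favors capture of
  G-starting TSSs and disfavors C-starting ones. The deficit is not
  quantified anywhere; the defaults G = 1.3, C = 0.6 (A = T = 1) are free
  parameters chosen only to reproduce the qualitative ordering
  G > A = T > C that the diagnostics must detect.
* **PolyA selection** (`polya_select`, `polya_escape_rate`): RNA-seq
  retains non-polyadenylated (histone-like) transcripts only with a small
  escape probability (default 0.05), making them CAGE-enriched outliers in
  cross-platform scatter.
* **Ribosomal carryover** (`rrna_rate_mean`, `rrna_rate_sd`): each
  replicate draws its rRNA read fraction once from a truncated normal, so
  replicate-level variability in rRNA content is reproducible. The presets
  (tag protocol 2% +/- 0.5%, single-molecule 10% +/- 1%, RNA-seq
  8% +/- 3%) encode the observed ordering: the tag protocol excludes rRNA
  best, and RNA-seq's oligo(dT) selection is the most variable.
* **Start jitter** (`jitter_frac`, default 0.2): a fraction of transcripts
  initiates 1 bp up- or downstream of the annotated TSS, giving CTSS peaks
  a realistic 3-bp shape. This is biological heterogeneity, applied before
  the artifact transforms; `shifted_by` records only artifact
  displacement.

## The synthetic reference

`generate_reference()` lays genes out in fixed slots on alternating
strands, with three exons spanning about 1.2 kb downstream of each TSS
and at least 2.5 kb between neighbouring slots so planted contexts cannot
interfere. It plants, in disjoint gene groups: promoter GC uniform on
0.30-0.70; sense-strand CTGCTG at a drawn offset within 400 bp (20% of
genes) or between 401 and 800 bp (10%); TSS T runs (10%); histone-like
genes (10%); and one ribosomal gene. Accidental CTGCTG matches in the
scanned window and accidental TSS T runs are scrubbed (a middle base is
rewritten to A, which can extend neither pattern), so the strata stay
controlled. All stored features are then *recomputed from the emitted
sequence*, so annotation and FASTA agree exactly — a property the test
suite asserts through a write/read round trip.

Coordinates are 0-based and half-open throughout; "upstream" of a TSS
means position `tss - 1` on the plus strand and `tss + 1` on the minus
strand.

Simulation operates at the level of aligned coordinates plus a recorded
raw leading base. Sequencing error and alignment are deliberately out of
scope: mapping-quality and identity filters act upstream of everything
modeled here, and none of the diagnostics consume base-level read
sequence. Only a single nontemplated G is modeled (multi-base additions
are rare and change nothing qualitatively), and T-stretch shifting is
deterministic displacement by the full run length.

## What the generator does and does not emulate

The mixture design follows the study design the package reproduces: two
cell-line-like RNA sources mixed by mass at 100:0, 99:1, 95:5, 90:10,
50:50 and 0:100. Source abundances are log-normal (log-sd 2 by default,
matching the several-orders-of-magnitude dynamic range of real
transcriptomes). Each source carries a `quantifiable_fraction` — the share
of its RNA mass attributable to annotated, mappable genes (the rest being
rRNA and unannotated sequence). The defaults 0.84 and 0.36 are chosen so
that an equal-mass mixture has an effective read share of
`0.5*0.84 / (0.5*0.84 + 0.5*0.36) = 70%` — the magnitude of the
50:50-reads-as-70:30 phenomenon the mixing analysis measures.

The generator does **not** emulate: promoter shape diversity beyond 1-bp
jitter (real CTSS clusters are broader and multi-modal), mapping
ambiguity, PCR duplicates, annotation error, or inter-gene correlation of
expression. Passing tests therefore demonstrate that the diagnostics
measure what they claim under the planted mechanisms, not that real data
contain no further distortions.

## Quantification rules

CAGE tags are collapsed to CTSS tables (exact per-base aggregation;
ribosomal tags are excluded and reported separately). Gene-level CAGE
counts assign a CTSS to a gene when it lies on the same strand within
500 bp of the TSS, inclusive at the boundary — the distance at which the
capture-vs-distance curve saturates (and inclusive because "within"
is taken at face value; the choice moves single positions at the
boundary). Positions inside several windows go to the nearest TSS, ties
to the lexicographically smaller gene id, so no tag is counted twice.
RNA-seq fragments count for a gene when they overlap any exon by at least
1 bp; counting ignores strand by default (a strict-strand mode is a
flag), and multi-gene overlaps resolve by nearest exon start, then
smaller id. `tpm_tags` divides by total mapped non-ribosomal reads (the
normalization denominator excludes rRNA, a choice the package fixes
explicitly); `rpkm` additionally divides by exonic length in kb.

## The statistics

**Reproducibility.** Replicate Spearman correlations use midranks over
genes nonzero in at least one of the pair. Because correlation rises with
depth, the depth-independent metric is the *relative standard error*:
the square root of a common negative-binomial overdispersion fitted
across replicates. The fit models `x_gi ~ NB(s_i * mu_g, phi)` with
library-size factors `s_i`, moment plug-in gene means, and maximizes the
Cox-Reid adjusted profile likelihood over `phi` in [1e-6, 1] by
golden-section search (tolerance 1e-6). The adjustment — subtracting half
the log Fisher information of each fitted mean — matters: with triplicates
the unadjusted profile likelihood underestimates `phi` by roughly a third
(the plug-in mean absorbs one of three degrees of freedom per gene), and
recovery of planted `sqrt(phi)` would fail. Genes with mean count below 5
are excluded for stability; both thresholds are arguments. The estimator
is validated against planted dispersions (0.0025-0.04) and cross-checked
against an independent reference implementation in the test suite.

**Mixing.** Synthetic mixes are formed in tags-per-million space,
`alpha * A + (1 - alpha) * B` — read-share mixing, which is what
sequencing a physical mixture measures. The effective ratio estimator
minimizes the mean squared M statistic (`M = log2((x+c)/(y+c))`,
pseudocount c = 0.5 TPM, over genes with `A >= 0`) on a 1% alpha grid,
ties toward the smaller alpha. The matching criterion in the original
analysis was visual comparison of MA plots; mean squared M is this
package's formalization of it. The objective is convex in alpha for
noiseless input (checked numerically in the tests), so the grid cannot
trap a spurious minimum.

**Bias reports.** Stratified relative-expression reports use per-gene
`log2(X/Y)` on TPM with pseudocount 0.5 and summarize strata by median
and IQR (medians for outlier robustness, matching the distributional
style of the figures this mirrors); GC uses 10 equal-width bins over the
observed range (the original bin scheme is unpublished) plus a
least-squares slope, which recovers `gc_bias_coef / ln 2` per GC unit.
Start-base activity compares TPM-scaled CTSS ratios at positions with at
least 5 counts in both samples, keyed by the genomic base on the CTSS
strand; whether the original single-base ratios were TPM-scaled is not
stated, and TPM scaling is used here so that the report is depth-free.
T-stretch shift detection examines reference positions with at least 5
counts whose sense sequence starts with a T run of at least 4 bp, and
flags a shift when the query table concentrates at the run end instead.
Platform-specific TSSs require strictly more than 10 counts (the
published rule is "more than 10") in one sample, at most 10 in the other,
and "unneighbored" means no opposing position with at least 3 counts
within +/-20 bp (the neighborhood width is unpublished; 20 bp is a
configurable default spanning typical CTSS cluster spread).

**Sample comparison.** Clustering uses 1 - Spearman distance on the top
8000 genes by mean expression, average linkage (the default of the
package the original analysis cited), and ordinary gene-bootstrap
support: the fraction of resampled dendrograms containing each edge's
leaf bipartition. Ordinary bootstrap probabilities replace multiscale/AU
probabilities; the testable claims here are topological (which samples
are siblings), which ordinary bootstrap answers without the extra
machinery. The differential test is a Wald-style NB approximation —
`z = (log mu_A - log mu_B) / sqrt(1/sum(x_A) + 1/sum(x_B) + 2*phi)` with
pseudocount 0.5 and BH adjustment at FDR 0.05 — defined by this package
(the original differential method is unnamed); its acceptance is
simulation-based type-I control and power, never equality with any
published gene count, and the `2*phi` term is deliberately conservative
for more than one replicate.

## Numerical choices and degenerate inputs

Golden-section search brackets `phi` in [1e-6, 1]; identical replicate
columns drive the estimate to the lower bound. Constant vectors make
Spearman undefined and raise errors rather than returning NA. Empty read
sets make signal metrics an error; an all-ribosomal read set reports a
promoter rate of 0 with a warning. Identical pure profiles make the
mixing ratio unidentifiable and raise an error. The BH step, quantile and
rank computations, chi-square tests, and the linear fits all go through
base R (`p.adjust`, `cor`, `lm`); dendrogram bipartition counting goes
through `ape`.

## Problem sizes

The bundled analyses and tests run at desk scale, chosen so the whole
suite completes in a few minutes while keeping every recovery
well-powered: reference genomes of 300-2000 genes (0.75-5 Mb), read
depths of 2e5-3e5 tags for coordinate-level simulations, and profile-level
experiments (mixtures, replicate panels) at 10,000-20,000 genes and
2e6 reads, where no genome is needed. Recovery tolerances in the tests
(e.g. +/-15% on the GC slope, +/-0.15 log2 on the EcoP15I class
difference) correspond to roughly 3 standard errors at these sizes.

## Known limitations

The EcoP15I effect is a yield boost, not a cleavage-position model, so
the package cannot predict where internal cleavage places tag 3' ends.
The G-addition estimator conditions on TSSs whose upstream and start
bases are both non-G; at G-rich promoters the artifact remains
fundamentally confounded with genuine upstream starts, exactly as in real
data. Sense-strand EcoP15I sites are reported as a stratum but carry no
planted effect. The differential test assumes a common dispersion and
will be anticonservative when dispersion varies strongly across genes.
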