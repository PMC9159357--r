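---
title: "Isoform-resolved RNA stability from labeled 3'-end sequencing: models and methods"
author: "apastab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-resolved RNA stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
labeling model behind the Stability Score, the decisions taken at every
point where the method leaves room, what the synthetic-data generator does
and does not emulate, and the numerical conventions that make the pipeline
deterministic. It states no empirical result beyond what the package's own
tests and `scripts/acceptance.R` compute.

## 1. The labeling model

A 4sU pulse of length $t$ splits the steady-state poly(A)$^+$ pool of a
transcript with synthesis rate $s$ (transcripts/h) and first-order decay
rate $k$ (1/h) into

$$ N_{\mathrm{total}} = s/k, \qquad
   N_{\mathrm{4sU}} = \frac{s}{k}\,(1 - e^{-kt}), \qquad
   N_{\mathrm{FT}} = \frac{s}{k}\,e^{-kt}, $$

with total = labeled + unlabeled exactly (`expected_fractions()`). The
Stability Score of a PAS isoform,

$$ \mathrm{SS} = \log_2 \frac{\mathrm{RPM}_{\mathrm{FT}} + 1}
                             {\mathrm{RPM}_{\mathrm{4sU}} + 1}, $$

is therefore, in the noiseless limit and without pseudocount,
$\log_2\!\big(e^{-kt}/(1-e^{-kt})\big)$ — a strictly decreasing, invertible
function of $k t$ (`implied_ss()`). Two assumptions are baked in and carried
by the generator as its null model: transcription is constant during the
pulse, and decay is first-order. If transcription changes within the pulse
window the score confounds synthesis and decay; the score is a relative
stability measure, not a half-life in hours, and the package deliberately
does not convert it to one.

The pseudocount of 1 RPM-unit on both numerator and denominator keeps SS
finite at zero counts; the expression filter (below) bounds its influence,
and `pseudocount = 0` is available where the caller guarantees positivity.

## 2. PAS discovery

**PAS reads.** A read supports a poly(A) site iff its mapping quality is at
least 10 and it carries at least 2 consecutive non-genomic Ts at the 5' end
of its soft-clip, in read orientation. "Non-genomic" is decided by laying
the clip back onto the reference along the extended alignment: a clip T that
matches the base it would occupy is genomic and terminates the run. This is
the minimal reading of the calling rule that actually uses the alignment
context; without the genomic check, A-rich genomic stretches downstream of a
cleavage site (the classic internal-priming signature) would masquerade as
tails. The cleavage site is the position of the read base adjacent to the
clip on the transcribed strand, and the site strand is the strand implied by
the clip side: a reference-reverse record with a trailing clip is a
plus-strand transcript, and vice versa. A defensive filter additionally
drops reads whose aligned portion is shorter than 23 nt (adapter trimming
and length filtering are upstream of this package, which consumes
alignments).

**Clustering.** Sites are clustered within 24 nt by greedy summit
absorption: repeatedly take the unassigned site with the highest total
count, breaking ties toward the smaller coordinate, and absorb all
unassigned same-strand sites within the window. The published description
of 24-nt clustering does not fix an algorithm; greedy summit absorption was
chosen because it is deterministic, single-pass, and fully specified
including tie-breaks, and the summit (not the most distal member) is used
as the cluster's reported position — a convention, flagged as such. Two
consequences are tested as invariants: cluster counts conserve read counts
exactly, and summits of distinct same-strand clusters end up more than
24 nt apart.

**Assignment.** A cluster belongs to the strand-matched gene whose span
contains its summit: 3'-most exon → TPA, intron → IPA (host intron
recorded), other exon → `other_exonic`, no gene → `intergenic`. No 3'-end
extension of gene models is attempted. Genes overlapping on opposite strands
are unproblematic; for same-strand overlap the gene with the closest 3' end
wins, with a warning. All internal coordinates are 0-based half-open; GTF is
converted on read/write and BED output is 0-based, to keep off-by-one drift
out of the code.

## 3. Quantification and normalization

Rows need at least 5 reads in at least one sample (`filter_expressed()`;
the methods text elsewhere says "greater than five", so `strict_gt = TRUE`
exposes that reading — `>= 5` is the default). Size factors are
median-of-ratios: each sample's median ratio of counts to the per-row
geometric mean, over rows containing no zeros, with the median taken on the
log scale (geometric interpolation at even counts, as in DESeq). Two
conventions are deliberate and documented:

* **Factors are rescaled to geometric mean 1 within each normalization
  set.** Median-ratio factors are only identified up to a common constant;
  fixing the geometric mean makes renormalization of an already-normalized
  matrix return unit factors exactly, which is tested to 1e-9. Note that
  rescaling *one* sample's counts by $c$ moves every row geometric mean by
  $c^{1/m}$, so its factor moves by $c^{(m-1)/m}$ relative to nothing and by
  $c$ relative to the other samples: only factor ratios, and normalized
  cross-sample ratios, are meaningful — the tests assert exactly those.
* **RPM values use one common per-million constant per normalization set**
  ($10^6$ divided by the set's mean raw library size), applied to the
  factor-divided counts. Rescaling each sample to its own per-million total
  would cancel the size factors algebraically ($c/sf \cdot 10^6/(C/sf) =
  c\cdot 10^6/C$) and reintroduce the composition bias the median-ratio
  method exists to remove; with a common constant, cross-sample ratios are
  exactly the median-ratio-normalized ones while the scale stays per-million
  so the pseudocount keeps its meaning.
* **Factors are estimated within fraction type** (total, 4sU, FT as
  separate sets) by default. The three fractions have grossly different
  compositions by construction — the 4sU fraction over-represents unstable
  transcripts — and SS is a within-isoform ratio, so per-fraction
  normalization is the conservative default; `by_fraction = FALSE` gives one
  global set.

## 4. Stability analysis

SS is computed per (condition, replicate) from the matched FT/4sU sample
pair, then replicates are averaged per condition (computing per-replicate
scores first and averaging second keeps replicate variability visible to the
ANOVA; averaging RPM first would discard it). Differential stability across
conditions is a fixed-effects one-way ANOVA on the replicate scores
(`stats::oneway.test` with equal variances, i.e. the classical $F$ with
$(g-1, N-g)$ degrees of freedom), with the degenerate all-equal case defined
as $F = 0$, $p = 1$ and zero within-group variance with non-zero
between-group variance as $p = 0$. Raw $p < 0.05$ is the default call
threshold, with BH-adjusted $q$ always reported alongside — the raw-p
convention follows the analysis this package reimplements; reporting both
costs nothing and keeps the multiplicity information available.

## 5. APA isoform analytics

For 3'UTR isoforms, the two terminal-exon clusters with the highest combined
expression (total-fraction counts summed across conditions) form the
gene's pair, labeled proximal/distal by strand-aware genomic order;
expression ties prefer the more proximal cluster (determinism). The aUTR
size is the genomic distance between the two summits — no splicing within
the 3'UTR is assumed. Relative expression is
$\mathrm{RE} = \log_2\big((d + 1)/(p + 1)\big)$ in RPM, and RED is the RE
difference between two samples or conditions (positive = lengthening).

Usage shifts between two samples are tested by a two-sided Fisher's exact
test on the raw-count table $[p, d] \times [s_1, s_2]$, called
lengthened/shortened only when $p < 0.05$ *and* the absolute change in the
distal isoform's relative abundance $d/(p+d)$ exceeds 5% (the absolute
value is used; the source text does not say per-direction). Isoform
stability differences within a condition use the same exact test on
$[p, d] \times [\mathrm{4sU}, \mathrm{FT}]$ with replicates pooled —
fraction-level scale factors cancel in this within-sample contrast, which is
why pooled raw counts are legitimate here — and the sign of
$\Delta SS = SS(d) - SS(p)$ gives the direction (red = distal more stable,
blue = proximal more stable, FDR < 0.05). The exact test replaces a GLM
(DEXSeq-style) analysis: the exact test is fully specifiable, needs no
dispersion estimation at desk scale, and is itself one of the two
alternatives named in the methods being reimplemented. Pooling replicates
trades replicate-variance modeling for exactness; the ANOVA stage, not this
test, carries the replicate-level inference.

Quintile binning is rank-based with stable tie order, bin sizes differing by
at most one, and a Wilcoxon rank-sum comparison of the first versus last
bin. IPA events pair each intronic cluster with a reference terminal-exon
isoform — the most abundant TPA cluster by default (`tpa_ref = "sum"` pools
all of them instead; the choice is exposed because the source is ambiguous)
— and report per-condition $\Delta SS(\mathrm{IPA} - \mathrm{TPA})$,
relative abundance, and quintile analyses of IPA stability against
host-intron size and splice-site strengths (MaxEnt-style scores are consumed
from the annotation, never computed).

## 6. Sequence features, regression, hexamers

Features are computed on the sense strand: GC/U content of the gene body,
3'-most exon, 3'UTR (3'-most exon start to the distal PAS) and aUTR
(proximal→distal PAS interval); region sizes; junctions per kb of mature
transcript; and the number of terminal-exon PASs counted from the input
clusters (no external PAS database). Individual $R^2$ is the squared
Pearson correlation with the response; features are ranked by it, and the
cumulative $R^2$ at rank $j$ is the OLS fit on the top-$j$ features
combined. Features are z-scored before the cumulative fit purely for
numerical conditioning — $R^2$ is scale-invariant, and an affine-rescaling
invariance test pins that down. Constant features get $R^2 = 0$ and are
excluded from the cumulative fit; rows with missing values are dropped and
tallied.

Hexamer enrichment counts overlapping occurrences pooled across sequences
(occurrence-level test; a per-sequence presence/absence mode is available
behind `mode = "presence"` since "frequency" is ambiguous), tests each
hexamer against all others between foreground and background with Fisher's
exact test and BH adjustment, and stacks the top enriched hexamers ungapped
into a 4×6 position-frequency matrix — a deliberate simplification of logo
building; no offset alignment is attempted.

## 7. Structure scoring

Sequences are tiled into 100-nt windows with 50-nt overlap; the last window
must fit entirely, and sequences shorter than 100 nt get a single
full-length window rather than being discarded (the windowing source is
silent on short sequences). The region's score is the median window MFE.

The default folding engine is a Nussinov-style maximum base-pairing dynamic
program (Rcpp) with minimum loop length 3 and GC/AU/GU pairs scored −1: a
surrogate pseudo-energy in pair units, explicitly non-thermodynamic. The
`rnafold_engine()` adapter shells out to ViennaRNA's `RNAfold` for kcal/mol
when thermodynamic energies are wanted; both satisfy the same contract
(vectorized `fold()`, scores ≤ 0). The two engines agree in rank across
sequences of varying base composition (tested at Spearman ≥ 0.6 on 50
sequences with Dirichlet-drawn compositions); within a fixed symmetric
composition, maximum pairing saturates and the surrogate discriminates
poorly — a known limitation of pair-counting scores, which is why the
engine is pluggable.

Gini indices of per-position probing signal use
$G = \sum_{ij} |x_i - x_j| / (2 n^2 \bar x)$ (computed via the sorted-order
identity), per 100/50 window with the median per region — the same windowing
as MFE, adopted for internal consistency since the probing-signal windowing
convention is not published. All-zero windows are undefined and skipped.

## 8. The synthetic-data generator

`sim_config()` defaults *are* the emulated study design: 3 conditions ×
{total, 4sU, FT} × 2 replicates, 1-h pulse, genes with 1–3 terminal-exon
PASs (probabilities 0.5/0.4/0.1) and optional intronic PASs, aUTR spacings
of 200–2000 nt, half-lives log-normal with median 4 h and `sdlog` 0.8
(mammalian mRNA scale), lncRNAs at half that, distal isoforms destabilized
1.5-fold per rank step and intronic isoforms 3-fold (the global
pPAS-more-stable and IPA-less-stable patterns), and one condition doubling
decay for 10% of genes (cell-type-specific stability). Counts are
multinomial over isoforms within each sample with Poisson library sizes
around the configured depth; reads are single-end, fixed 50 nt of genomic
sequence plus a 2–3-nt poly(A) soft-clip, emitted as minimal valid SAM.
Noise channels — 3'-end microheterogeneity, internal-priming-like decoy
reads with 0–1 clipped Ts, sub-threshold mapping qualities, and
fractionation cross-contamination — all default to 0 so that the exact
round trip (called clusters ≡ simulated truth) is the null condition, and
are switched on explicitly to probe robustness. The biotin-pulldown
fractionation efficiency of the real protocol is unknown, so no attempt is
made to calibrate the contamination parameter to it.

Two generator properties matter for interpretation:

* The bases a tail clip lays back onto (sense-downstream of each PAS) are
  forced non-A, so every clean simulated read is recoverable by the
  non-genomic-T rule. Real genomes are the opposite — cleavage sites sit in
  A-rich context — so the round trip validates the *implementation*, not
  the rule's sensitivity on real data.
* Replicate variability is pure counting noise; there is no biological
  replicate dispersion, no sequencing-error model, no PCR duplication.
  Power and false-positive-rate results on the simulation are therefore
  upper bounds on real-data performance.

Determinism: every generator function seeds the RNG from `config$seed`
(with fixed offsets per stage), so identical configurations reproduce
identical annotations, sequences, counts and SAM records byte for byte.

## 9. Problem sizes in the checks

The package's self-checks run at desk scale, chosen once: 500 genes at
2×10⁵ reads/sample for Stability-Score recovery and ANOVA power/FPR;
300 genes at 10⁵ reads/sample for isoform directionality; 200–250 genes for
IPA analyses; 2000 genes for feature-sign recovery (100 noise replicates);
1000 random instances for the clustering oracle; a 25-gene, 2500-read
simulation for the byte-identical end-to-end golden run. The real study's
headline numbers derive from deposited sequencing data and external
resources (decay-rate compendia, probing data, tissue atlases) that the
package intentionally does not fetch; its claims are therefore
property-based (exactness, oracle equivalence, directional recovery), not
numeric reproductions.

## 10. Known limitations

* SS is relative; between-condition comparisons assume the labeling time
  and fractionation behaved identically across conditions.
* The exact-test APA calls pool replicates; genes with strong replicate
  heterogeneity can be called on pooled evidence alone.
* The Nussinov surrogate ranks, but does not estimate, folding energies.
* Gene assignment requires the summit inside the annotated span; without
  3'-end extension, clusters just downstream of an annotated gene end are
  left intergenic.
* Joint models of more than two 3'UTR isoforms are out of scope; the
  top-two selection follows the source analysis.
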