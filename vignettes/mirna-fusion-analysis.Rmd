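---
title: "Methods: miRNA inclusion in fusion transcripts"
author: "mirfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA inclusion in fusion transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfusion)
```

## The question and the model

Intronic pre-miRNAs are processed co-transcriptionally from their host
transcript. A fusion transcript whose breakpoint lies upstream of the
hairpin therefore transfers transcriptional control of the miRNA to the
5' partner's promoter, whatever the reading frame of the chimera. This
package asks three quantitative questions about a cohort of tumors with
RNA-seq fusion calls:

1. Which pre-miRNAs are *included* in fusion transcripts, in which
   tumors, and with their host gene in which position?
2. Are miRNA host genes *over-represented* among fusion genes once gene
   size is accounted for?
3. Is inclusion in a 3' host-gene fusion associated with *overexpression*
   of the mature miRNAs?

### Host assignment

A hairpin is **intragenic** in a gene when its genomic span is fully
contained in the gene span; by default the strands must match, because
co-transcriptional processing requires the hairpin on the transcribed
strand. An antisense-tolerant variant (`same_strand = FALSE`) is
provided for sensitivity analyses. A hairpin with no intragenic host
anywhere is **rescued** when it lies fully within the `downstream_bp`
(default 2000 bp) window immediately 3' of some gene's end, on the
reasoning that transcription frequently runs past annotated 3' ends.
Ambiguities are resolved deterministically: the smallest enclosing gene
wins (the most specific host), then the smaller downstream gap, then
lexicographic gene id. Where one host gene carries a cluster of
hairpins, `reduce_to_single_precursor()` keeps the precursor whose
strand-aware 5' end is most upstream — host-level overlap statistics
would otherwise count one fusion event once per clustered hairpin.

### Fused segments and inclusion

Fusion breakpoints are taken verbatim as the exon-junction coordinates
the caller reports; no re-anchoring to genomic DNA is attempted. For a
5' partner the fused segment runs from the gene's transcription 5' end
to the breakpoint; for a 3' partner from the breakpoint to the gene's
3' end, extended by the downstream window only for hairpins that were
assigned by the rescue rule (the rescue is defined for 3' partners
only). The gene's annotated strand, not the breakpoint's strand field,
orients the segment: junction coordinates inherit their orientation
from the partner transcript. Intervals are 1-based and closed
throughout (the native `GRanges` convention; conversion to and from
GTF/GFF3 is then the identity), so the breakpoint base belongs to both
segments and the two segment lengths sum to the gene span plus one.

A hairpin is **included** when it is fully contained in the fused
segment of its host. A hairpin straddling the breakpoint is never
called included — a known blind spot: a precursor spanning the junction
could still be transcribed as part of the fusion, but its inclusion
cannot be established from the junction coordinate alone.

Breakpoints falling outside the partner gene span (annotation-version
mismatches) are clipped to the span and logged rather than rejected,
preserving boundary events for audit. Calls listing partner genes
absent from the annotation are processed but can never yield
miRNA events.

### Filtering and frame classes

The default exclusion list is the 26 description flags associated with
high false-positive rates in FusionCatcher output (`banned`, `bodymap2`,
..., `ucsc_same_strand_overlapping`); a call carrying any of them is
dropped. Calls flagged `healthy` (fusion seen in normal tissue) are
kept but annotated, so downstream summaries can treat them separately.
Predicted effects map to three frame classes: exactly `in-frame`,
exactly `out-of-frame`, and everything else (`truncated`, `UTR/CDS`,
intergenic, unknown) as `other`. Isoform duplicates — identical
(sample, partners, breakpoints) tuples — collapse to one call; distinct
breakpoints remain distinct calls, so transcript-level and tumor-level
granularities are both preserved.

### Recurrence and convergence

Recurrence of a miRNA requires inclusion in at least `min_tumors`
(default 3) distinct tumors with the host gene in the same relative
position. The convergence summary counts, per miRNA, the distinct
annotated 5' partner genes across all tumors where the host is the 3'
partner, and the tumors carrying more than one distinct partner.
Unannotated partners count toward tumor totals but not toward distinct
partner counts (they cannot be identified as distinct genes). Overlaps
between miRNA sets (for example against an external catalogue) use
Fisher's exact test with the conditional maximum-likelihood odds ratio —
the convention of `fisher.test` — which differs slightly from the
sample cross-product ratio; users comparing against hand-computed
`ad/bc` values should expect small discrepancies. The universe for
overlap tests is configurable because two natural choices exist (all
analyzed precursors vs precursors with an assigned host); the default
is the assigned-host set, and the single-precursor-reduced universe is
supported by passing the reduced set.

External catalogues without breakpoint coordinates can only be matched
by gene symbol; that mode counts every hairpin of a named host gene and
therefore over-approximates the coordinate rule (symbol matches are a
superset of coordinate matches, a property the tests assert).

### The enrichment model

Longer genes are both more likely to host a miRNA and more likely to be
hit by a fusion, so host status alone would confound with size. The
per-gene model is logistic:

$$\mathrm{logit}\, P(F_g = 1) = \beta_0 + \beta_H H_g + \beta_S S_g
  + \beta_{HS} H_g S_g$$

with $H_g$ the host indicator, $S_g = \log_2(\text{size in bp})$, and
$F_g$ the fusion outcome (any fusion, or fusions recurrent in at least
three tumors with a maintained role). The table is restricted to
protein-coding genes and, when an expression matrix is supplied, to
genes with median FPKM at or above 1 — a reproducible stand-in for
"expressed in this cohort" (configurable). Fitting is by IRLS
(`glm`, binomial family, tolerance 1e-8, at most 50 iterations); Wald
tests use the normal approximation. Without the interaction,
$e^{\beta_H}$ is the size-adjusted odds ratio. With it, host and
non-host probabilities cross at $2^{-\beta_H/\beta_{HS}}$ bp; when
$\beta_H \ge 0$ and $\beta_{HS} \ge 0$ the host advantage holds at every
size and no crossover is reported rather than extrapolating a negative
solution. Separation or non-convergence flags the fit rather than
returning misleading numbers.

As negative controls, element classes (RepeatMasker-style annotations)
whose per-gene occurrence rate lies within a relative tolerance
(default 25%) of the host-gene rate are refit in place of $H$; an
association that appears for hosts but not for frequency-matched
elements is evidence that the miRNA, not generic gene content, carries
the signal.

### Expression association

For one miRNA, tumors partition into those with at least one included
3' host fusion (`fused_3p`; 3' takes precedence when both roles occur),
those with only 5' events, and the rest. Mature-arm expression is
compared between `fused_3p` and `no_host_fusion` by a two-sided
pooled-variance Student t-test on $\log_2(\text{cpm} + 1)$; the classic
Student form is the default because equal-variance testing is the
stated convention of the analyses this package reproduces, with Welch
available behind `var_equal = FALSE`. The pseudocount (default 1 cpm)
and log base are configurable. Bonferroni correction spans all mature
miRNAs actually tested in a screen — the test family is the computed
set, recorded in the output, since restricting the family to an
expression floor is equally defensible and the choice is exposed rather
than hidden. The headline screen keeps upregulated miRNAs
(`mean_fused > mean_unfused`), applied after adjustment and
configurable. Groups below two samples, and features with no variation
at all (e.g. zero counts everywhere), are flagged skipped instead of
being silently dropped.

## The synthetic cohort generator

`synthetic_config()` fixes the study conditions the pipeline is
validated under; its defaults emulate a large breast-tumor cohort:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 19,000 | genes, 90% protein coding |
| `size_log2_mean`, `size_log2_sd` | 14.5, 2.0 | log-normal sizes, median ~23 kb |
| `host_fraction` | 0.065 | coding genes hosting a hairpin (~1100 hosts) |
| `mirna_downstream_fraction` | 0.024 | hairpins in downstream rescue windows |
| `mirna_intergenic_fraction` | 0.298 | hairpins with no host |
| `mirna_cluster_prob` | 0.155 | second hairpin per host (~1.16 precursors/host) |
| `n_samples`, `n_expr_samples` | 1552, 186 | cohort, small-RNA subset |
| `beta0, betaH, betaS, betaHS` | -3.22, 2.8121, 0.25, -0.15 | true fusion model; crossover exactly 440 kb; ~61% of genes fused |
| `frame_probs` | 0.08 / 0.09 / 0.83 | in-frame / out-of-frame / other |
| `inframe_depletion` | 0.8 | in-frame multiplier when the 3' segment contains a hairpin |
| `recurrence_mu`, `recurrence_size` | 2.2, 3 | per-fused-gene extra tumor count, 1 + NB |
| `convergent_tumors` | 155, 49, 34, 29, 19 | planted hotspot tumor counts |
| `convergent_partners` | 338, 107, 103, 38, 20 | planted distinct 5' partners |
| `mirna_fold_change` | 4 | cpm multiplier under 3' inclusion |
| `dispersion` | 0.5 | NB dispersion of mature counts |
| `partner5_shift` | 1 | log2-FPKM shift of 5' partners of including fusions |

Genes are placed without overlap and with 5–50 kb gaps, so downstream
rescue windows never touch a neighbouring gene and the planted host map
is exactly recoverable — `assign_hosts()` on a simulated annotation must
reproduce the generator's truth record, and the tests require exactly
that.

Two generator choices deserve explanation. First, the fused indicator is
drawn from the logistic model at the **gene level** — the level the
enrichment regression models and the level at which recovery is
validated — and the number of tumors carrying each fused gene is then
`1 + NB(mu = 2.2, size = 3)` spread over random tumors. Independent
per-sample Bernoulli draws cannot jointly match a ~60% marginal fused
fraction and the strong tumor-level recurrence real cohorts show; a
gene-level draw with an overdispersed tumor count can, and it keeps the
planted odds ratio exactly refittable. Within each tumor the
participating genes are paired at random into calls (an odd one out
receives an unannotated partner, exercising the absent-partner path).
Second, the background tumor-count distribution is deliberately
light-tailed, and the extreme convergent hotspots are *planted
explicitly* with tumor/partner counts mirroring the most convergent
host genes reported in breast tumors. Hotspot 3' breakpoints are drawn
transcript-upstream of the hairpin, so planted calls always include it;
the hotspot rows of the convergence table are therefore ground truth
and the end-to-end test asserts they are exactly its top rows.

What the generator does **not** emulate: sequence content (no reads, no
alignment), isoform structure (genes are single spans, so
transcript-level host assignment is out of reach), copy-number-driven
hotspots (planted, not emergent), correlated expression between miRNAs
sharing a host, and library-specific biases in cpm. Passing tests
therefore demonstrate the correctness of the interval logic, the
statistics and their calibration under the stated generative model —
not robustness to annotation noise or quantification artifacts in real
data.

## Numerical choices and degenerate inputs

* Coordinates: 1-based closed everywhere (`GRanges` native). The
  alternative — 0-based half-open internally with conversion at the
  boundary — buys nothing in R and doubles the conversion surface.
* Logistic fits: IRLS tolerance 1e-8, 50 iterations; fits with
  |coefficient| > 25 or SE > 50 are flagged unconverged (separation
  guard).
* Fisher p-values: two-sided by summing hypergeometric point
  probabilities at or below the observed one (with the customary 1e-7
  relative slack); a zero margin returns p = 1 with the odds ratio
  flagged undefined rather than an error.
* t-tests: identical non-constant groups give t = 0, p = 1; groups that
  are constant and different give |t| = Inf, p = 0; all-constant
  features are skipped.
* Pseudocounts: 1 cpm (miRNA), 0.1 FPKM (genes), both configurable.
* Ties: every tie in the package (host choice, precursor reduction,
  deduplication, output ordering) breaks lexicographically after the
  scientific criterion, so all outputs are permutation-invariant and
  byte-reproducible.
* Randomness: each generator stage seeds its own stream from the master
  seed by a fixed offset, so annotation, fusions and expression are
  independently reproducible.

## Problem sizes used in validation

The test suite validates interval logic against an all-pairs brute
force on 1000 random geometries; the Fisher machinery against full
fixed-margin enumeration of all 135,751 tables with total n <= 40;
odds-ratio recovery at n = 19,000 genes over 50 seeded replicates
(planted size-adjusted OR 2.3, recovered within [1.9, 2.8] in at least
90%); crossover recovery against a planted 440 kb crossover, asserted
on the median of 25 replicate fits within a factor of two — a single
fit at this sample size is median-unbiased but has roughly a
two-fold interquartile spread, so the median over replicates is the
honest summary of what the estimator recovers; differential-expression
calibration on 2000 null features (uniform p-values) and power at
fold-change 4 with 13 vs 150 tumors (at least 80% at alpha = 0.001);
and end-to-end hotspot recovery on the full default cohort. Two
further checks — the host census against miRBase v21 + GENCODE v22 and
recounts from the published per-fusion listing — require external
downloads and report failures when those files are absent.

## Known limitations

* Junction-straddling hairpins are invisible to the inclusion rule.
* Host assignment is gene-span based; isoform-specific introns are not
  modelled, so a hairpin inside the span but outside every transcript
  of the gene would still be called intragenic.
* The symbol-matching catalogue mode over-counts by construction.
* The enrichment model treats genes as exchangeable given (H, S);
  genomic covariates such as fragile-site proximity or expression level
  beyond the binary filter are not modelled.
* Bonferroni across the tested family is conservative when many
  correlated mature arms of the same hairpin are tested.
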