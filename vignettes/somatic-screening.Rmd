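---
title: "Screening somatic variants in matched tumor-normal amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening somatic variants in matched tumor-normal amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticsieve)
library(dplyr)
```

## The problem

Targeted deep amplicon sequencing of matched tumor and normal tissue is a
standard way to find somatic mutations in a small gene panel: PCR amplicons
tile the coding sequence, each amplicon is sequenced to hundreds or thousands
of reads, and a permissive caller lists every plausible non-reference allele.
At that depth, two artifact classes dominate the candidate list:

* **germline variants**, present in both tissues, which are not somatic; and
* **read-end artifacts**, false calls driven by the error-prone terminal
  bases of each read. In amplicon data these are systematic: a genomic
  position near an amplicon boundary sits near the same read end on *every*
  read, so an elevated terminal error rate produces a consistent, convincing-
  looking pile of support.

`somaticsieve` implements a screening cascade for this setting, together
with a simulator that generates matched pairs with planted truth, a
codon-level protein-effect annotator, and the summary statistics that
typically accompany such screens (per-gene E&rarr;K missense enrichment,
Fisher's exact test for rescue experiments, and &Delta;&Delta;Ct relative
expression from qPCR).

## The screening cascade

Candidates are called per (site, alternate allele) with depth $D$, alt
support $A$, allele frequency $\mathrm{AF} = A/D$, and the *offset fraction*
of the variant base within each supporting read's aligned bases. The cascade
then applies, in order:

1. **Matched-normal subtraction.** A tumor candidate whose exact
   (contig, position, ref, alt) key is also called in the normal sample is
   removed (`in_normal`). Matching is allele-exact after left-anchoring of
   indels: position-only matching would discard a genuine somatic allele
   arising at a germline-variant site.
2. **Read-end re-evaluation.** A supporting read is *end-flagged* when its
   offset fraction $f$ satisfies $f < 0.15$ or $f \ge 0.85$. With $E$
   flagged supports, the core support is $A^\ast = A - E$ and the
   re-evaluated frequency is
   $\mathrm{AF}^\ast = A^\ast / (D - E)$ (0/0 defined as 0). A candidate is
   rejected as an end-read event (`end_read`) exactly when $A^\ast = 0$: the
   per-read removal followed by re-evaluation subsumes a whole-event
   positional exclusion.
3. **Multi-allele gate** (`multiallelic`): more than 2 distinct alternate
   alleles at the site, counted in the raw tumor pileup (before subtraction
   and end-read removal), rejects the candidate. Tri-allelic sites at low AF
   are characteristic of noise, not clonal somatic events.
4. **Depth floor** (`min_depth`): raw $D < 100$ rejects.
5. **Tiered support** (`tier_support`): if
   $0.02 \le \mathrm{AF}^\ast \le 0.05$, at least 10 core supports are
   required; if $\mathrm{AF}^\ast > 0.05$, at least 25. Below 2% the
   candidate is rejected outright (`low_af`) — the callable regime starts
   at 2%.

All five filters are evaluated for every candidate (no short-circuiting), so
the verdict trail is a complete diagnostic. `low_af` is defined as *interior
support remains but its frequency is below 2%* ($A^\ast > 0$ and
$\mathrm{AF}^\ast < 0.02$): a candidate whose support vanishes entirely at
step 2 is an end-read event and carries that single label, rather than also
being tagged as a sub-threshold frequency on a 0/... ratio.

### Numerical conventions

* Coordinates are 0-based half-open everywhere internally; VCF emission is
  1-based, and the conversion is its own inverse.
* Boundary convention for the terminal region: "first 15%" is
  $f < 0.15$, "last 15%" is $f \ge 0.85$ — half-open on both sides, so the
  flagged region is exactly 30% of the bases for read lengths divisible
  by 20. The tier boundary $\mathrm{AF}^\ast = 0.05$ belongs to the *low*
  tier (the 2–5% band is inclusive; "above 5%" is strict).
* The $\mathrm{AF}^\ast$ denominator removes flagged *alt* reads but keeps
  all reference reads. This slightly raises the re-evaluated frequency
  relative to dividing by $D$; both the raw and core values are written to
  the VCF INFO field (`DP/AO/AF/AO_CORE/AF_CORE`) so the choice is
  auditable.
* Soft-clipped bases are not aligned evidence and are excluded from read
  length before offsets are computed.
* Ties at one site are broken lexicographically by alternate allele, so
  output order is deterministic.

### A known non-monotonicity

Relaxing the count thresholds (depth floor, tier supports, allele cap) can
only grow the PASS set. The terminal fraction is different: shrinking
`end_frac` retains more near-end supports, which *raises*
$\mathrm{AF}^\ast$ and can push a candidate across the 5% tier boundary,
where the required support jumps from 10 to 25 reads — so a candidate that
passed under the stricter cut can fail under the milder one. This is
inherent to tiered support (any denominator convention produces the same
crossing) and is pinned down by a deterministic case in the test suite:
depth 400, 21 alt reads of which 11 sit at offset 0.10, passes at
`end_frac = 0.15` ($\mathrm{AF}^\ast = 2.6\%$, low tier) and fails at
`end_frac = 0.05` ($\mathrm{AF}^\ast = 5.25\%$, high tier). Treat `end_frac`
as part of the filter's definition, not as a knob to relax.

## What the simulator emulates — and what it does not

`simulate_pair()` reproduces the geometry that makes read-end artifacts
systematic: every read spans its amplicon exactly, so a variant's offset in
the read is fixed by its offset in the amplicon. Planted germline variants
are written into both samples and somatic variants into the tumor only, each
with independent per-read Bernoulli(af) draws; substitution errors are drawn
per base at `e_end` within the terminal 15% of the read and `e_interior`
elsewhere. One seeded generator with a documented draw order (samples, then
amplicons in table order; carriers per variant, then error positions read by
read 5'&rarr;3', then substituted bases) makes output byte-identical across
runs. A uniform-random-start shotgun mode exists for property tests.

Defaults `e_interior = 0.001`, `e_end = 0.01` are tool parameters chosen as
plausible for semiconductor-type amplicon platforms, not measured values.
The simulator does not model base qualities, homopolymer/flow-space errors,
indel sequencing errors (planted variants may be indels; errors are
substitutions only), paired ends, or contamination. Consequently, passing
tests demonstrate that the cascade removes the artifact classes it targets
under these idealized conditions; they do not certify sensitivity or
specificity on real flow-space data, where error modes are richer.

## The bundled study conditions

`run_demo()` fixes a panel of five overlapping 200-bp amplicons at 1,000
reads per amplicon per sample over a synthetic 900-bp single-ORF gene, and
plants: two germline heterozygous SNVs, three clean somatic SNVs at AF
3%/8%/20%, one somatic 1-bp deletion at AF 15% (a frameshift), and one
somatic SNV at 8% positioned in the terminal 15% of its amplicon (the
end-artifact). The error model is zero in the demo so that every verdict is
exactly attributable to a planted variant; elevated-end errors are exercised
separately in the simulator's own tests. The panel design (reference
sequence and positions) is generated from a fixed design seed so annotation
labels are stable; the sequencing randomness follows the user seed. Problem
sizes throughout the test suite (depth 1,000; 200 replicate simulations for
the binomial-recovery property; 10,000 reads for the AF-convergence
property) were chosen so the whole suite runs comfortably on one CPU.

At AF 3% and depth 1,000 the planted support is a Binomial(1000, 0.03) draw
whose lower 2% tail falls below the 20 reads needed to clear the 2% floor,
so over repeated random seeds roughly one run in fifty reports 3 instead of
4 passing variants; this is the sampling behaviour of the planted
conditions, not a defect.

## Protein-effect annotation

Annotation is codon-based against an explicit transcript model (gene,
contig, strand, ordered 0-based half-open CDS intervals whose total length
is divisible by 3); the model is an input rather than a fixed transcript, so
amino-acid numbering follows whatever model the user supplies. SNVs are
translated before and after with the standard genetic code; minus-strand
models are handled by complementing through the transcript orientation.
Indels are classified by length modulo 3 and labelled by the reference amino
acid of the first codon whose composition changes — `"Frameshift at G488"`
style — with no downstream-consequence prediction, since the compact
clinical nomenclature this follows does not use one. Variants outside the
CDS, or indels straddling a CDS boundary, are returned as `non_coding` (the
latter with a warning).

## Statistics

* `ek_fraction()` computes $100 \times$ (#E&rarr;K missense)/(#missense)
  per gene from a MAF-like table. Unparseable missense labels stay in the
  denominator (they are missense calls, just unlabelled) and are reported
  via a message.
* `fisher_exact_2x2()` is the two-sided exact hypergeometric test under the
  sum-of-smaller-probabilities convention, computed from log-binomial
  coefficients with a $10^{-7}$ relative tolerance on the inclusion
  comparison (no mid-p). It is checked against exhaustive enumeration for
  every 2&times;2 table with $N \le 30$ and against `stats::fisher.test()`
  on random tables.
* `relative_expression()` implements &Delta;&Delta;Ct:
  $\mathrm{fold} = 2^{-(\overline{\Delta Ct}_{test} - \overline{\Delta Ct}_{control})}$
  with $\Delta Ct = Ct_{target} - Ct_{reference}$ per reaction.

## Worked example

```{r demo}
res <- run_demo(out_dir = NULL, seed = 1)
tidy(res$screen)
res$annotated[, c("pos0", "ref_allele", "alt_allele", "af_core", "kind", "label")]
glance(res$screen)
```

The two germline variants carry the `in_normal` label, the planted
end-artifact carries `end_read` with `AF_CORE = 0`, and the four clean
somatic variants pass and are annotated (three E&rarr;K missense changes and
one frameshift, by construction of the demo gene).

```{r plot, fig.width = 6, fig.height = 4}
autoplot(res$screen)
plot_af_reeval(res$screen)
```

## Limitations

* Single matched normal only — no panel of normals, no contamination or
  copy-number-aware AF correction.
* SNVs and simple left-anchored indels; no multi-nucleotide variants.
* The caller is a deliberately permissive stand-in: it feeds the cascade
  the fields the filters need and makes no claim of equivalence to any
  production caller's internal scoring.
* Single-transcript annotation without full HGVS compliance.
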