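---
title: "Methods: gene-burden testing of premature-terminating variants"
author: "ptvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-burden testing of premature-terminating variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptvburden)
```

## The scientific question

Rare loss-of-function variants in a single gene can raise disease risk even
when no individual variant recurs often enough to test on its own. The
gene-burden design collapses all qualifying variants in the gene to a single
per-individual carrier indicator and compares carrier frequency between a
disease cohort and presumed-healthy control panels. This package implements
that design for *premature-terminating variants* (PTVs) — stop gains,
frameshift indels and canonical splice-site disruptions — the pattern used
to establish monoallelic *ALPK3* truncating variants as a risk factor for
adult-onset hypertrophic cardiomyopathy, where a cohort of 2,366 cases was
contrasted with population panels of up to 38,749 individuals.

## The statistical model

Let $a$ and $b$ be carrier and non-carrier counts among cases and $c$, $d$
the same among controls. The effect measure is the cross-product odds ratio

$$\widehat{OR} = \frac{a\,d}{b\,c},$$

with the Woolf (log-normal) confidence interval

$$\exp\!\left(\log \widehat{OR} \pm z \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right).$$

Design choices worth stating explicitly:

* **Critical value.** `woolf_ci()` defaults to the tabulated two-decimal
  normal quantile for the requested level — $z = 1.96$ at 95% — which is the
  convention under which the reference results for this design were
  produced; one of the published bounds (39.10) differs in the second
  decimal from the value obtained with the full-precision quantile
  1.959964 (39.09), and the tabulated value reproduces all published bounds
  exactly. The full-precision quantile is available through the `z`
  argument.
* **No continuity correction** by default: the published counts have no zero
  cells. The Haldane–Anscombe 0.5 correction is available via
  `correction = TRUE` for degenerate tables; a zero $b$ or $c$ cell without
  correction yields an infinite/undefined estimate with a warning, and
  `woolf_ci()` refuses zero cells outright.
* **Non-carrier cells are always derived** ($b = N_{case} - a$), never taken
  as input, so published denominators such as 2,330 = 2,366 − 36 arise by
  construction.
* **Rounding only at serialisation.** All computation is at full precision;
  `burden_report()` rounds ORs and bounds to 2 decimals and frequencies to
  the printed precision, and always writes an unrounded JSON sidecar.
* **No multiple-testing adjustment**: the design tests a single gene against
  several panels; the comparisons are reported side by side, not corrected.
* Pooling control panels (`pool_controls()`) sums sizes and carrier counts
  under an explicit *no-overlap* assumption that is recorded in the result;
  it cannot be verified from counts alone.

A `burden_test()` fit is an ordinary S3 model object: `coef()` returns the
log odds ratio, `vcov()` its squared standard error, `confint()` the Woolf
interval, `residuals()` Pearson residuals against independence, and
`simulate()` draws replicate tables at the fitted per-panel carrier
frequencies.

## From variant calls to carriers

The filtering pipeline reproduces the variant-interpretation conventions of
diagnostic exome analysis:

* **Genotype QC** (`genotype_qc()`): alternate allele depth ≥ 20 reads and,
  for heterozygous calls only, variant allele fraction ≥ 0.25. Both
  thresholds are inclusive; zero coverage fails with its own reason.
* **Rarity** (`rarity_filter()`): population minor allele frequency
  strictly below 0.1% in the matched population. A variant absent from the
  reference panel has, by definition, no observed frequency; it is treated
  as 0 and passes. This matters: novel variants are a large fraction of
  qualifying PTVs (6 of 14 in the reference analysis).
* **P/LP rule** (`classify_acmg_lite()`): a deliberately minimal
  PVS1+PM2-style surrogate for the full ACMG framework. A rare PTV with
  prior evidence (ClinVar entry or literature report) is *pathogenic*; a
  rare novel PTV is *likely pathogenic*; non-PTVs are not reportable. This
  reproduces the fixture classifications exactly but is not a general ACMG
  engine (no functional, segregation or de novo evidence).
* **CNV exon-span rule** (`cnv_exon_span_filter()`): an already-called copy
  number variant is flagged when it overlaps at least three *consecutive*
  exons. CNV calling itself is out of scope.
* **Collapsing** (`collapse_carriers()`): a sample is a carrier if it has at
  least one qualifying genotype; several qualifying variants still count
  once. Homozygous carriers are counted (the contrast is carrier versus
  non-carrier) with a warning, since the monoallelic design expects
  heterozygotes. Relatedness inference is out of scope; a manifest column
  `exclude_related` drops flagged individuals before collapsing.

The three filters are independent predicates, so their composition is
order-invariant; a property test permutes the order and compares carrier
sets. Multi-allelic VCF sites are decomposed into biallelic records before
any filtering.

## The consequence engine

Consequences are called against a single transcript model (one transcript
per gene; no multi-transcript prioritisation). Genomic edits arrive in VCF
convention (1-based, anchor bases on indels), are trimmed to their minimal
representation, mapped into spliced-transcript space (reverse-complemented
for minus-strand transcripts), and then normalised to the 3'-most
equivalent position on the transcript strand, as HGVS requires — names such
as c.3580dup presuppose the 3' rule. Shifting is performed on the spliced
sequence, so it crosses exon junctions correctly.

Classification rules, in priority order:

1. **Canonical splice**: the variant touches a +1/+2 (donor) or −1/−2
   (acceptor) intronic base of an intron flanking a coding exon. Protein
   effect is unknowable without a splice model, so the name is `p.?`.
   Deeper intronic positions are *never* PTVs here; learned splice
   predictors are deliberately out of scope, and an optional free-text
   annotation field carries any external prediction.
2. **Start loss** when the edit destroys the initiator ATG.
3. **Frameshift** when the net coding length change is not a multiple of 3.
4. **Stop gain** when an in-frame substitution or indel introduces a stop
   upstream of the expected stop position.
5. **Stop loss / in-frame indel / missense / synonymous** otherwise;
   stop-retained substitutions come out synonymous, and stop loss is its
   own class and *not* a PTV.

Edits spanning an exon/intron junction without touching a canonical
dinucleotide are classified conservatively by the length of coding sequence
they remove (frameshift or in-frame), with `p.?` for the protein effect.

Frameshift protein names use `fsTer<k>`, where the count starts at 1 *at
the first changed residue*: a new stop k−1 codons downstream of it gives
`fsTer<k>` (so p.Gly948GlufsTer3 has two intervening residues), and a stop
at the changed residue itself is written as a plain substitution to Ter —
the k = 1 case. When a frameshift abolishes the natural stop codon,
translation continues into the 3' UTR to find the new termination; if none
exists before the transcript end, the name ends `fsTer?` and a warning is
raised. Translation uses the standard nuclear code only.

The engine never attempts to reproduce the protein-level names of any real
gene: no reference transcript sequence is packaged, and the fixture tables
carry the published names verbatim rather than recomputed ones.

## The synthetic-data generator

`simulate_transcript()` builds a transcript that satisfies every structural
invariant the engine assumes — exons sorted and disjoint, GT..AG introns on
the transcript strand, a CDS that starts ATG, contains no in-frame internal
stop and ends with a stop codon — on a synthetic contig, on either strand.
`sample_variant_pool()` rejection-samples stop-gain, frameshift and
canonical-splice variants (verified through the classifier) plus
missense/synonymous/deep-intronic decoys.

`simulate_cohort()` emulates the study conditions: by default 2,366 cases
at carrier frequency 1.52% against 22,448 controls at 0.071% (the observed
frequencies of the reference cohort and its largest control panel), each
carrier heterozygous for one pool PTV with sequencing depth drawn around
60× (DP uniform on 40–80, AD binomial at 0.5, redrawn until QC-passing),
ages from a truncated normal (mean 53, SD 17.1, minimum 17, maximum 99 —
the carrier age structure), and male fractions of 0.66 in cases and 0.5 in
controls. Dials exist for QC corruption (`qc_fail_rate`: allele depth
forced below 20 or VAF below 0.25, chosen uniformly), rarity-filter
failures (`common_variant_rate`), decoy carriage (`decoy_rate`, default 5%)
and multi-variant carriers (`multi_variant_rate`). Everything is
deterministic under the seed.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: linkage disequilibrium, relatedness and
population stratification, sequencing-read artefacts beyond the AD/DP
summary, variant-calling error modes, panel-specific annotation differences
between control databases, and overlap between control panels. The
no-overlap pooling assumption is exactly as unverifiable here as in the
published design.

## Validation strategy and problem sizes

The test suite checks the engine against independent oracles implemented
from scratch: exhaustive position scans for coordinate projection, direct
string surgery plus Biostrings translation for edit application, and a
truncation predicate (premature stop, net frame change, canonical-site hit)
for PTV status — over 1,100 random variants per run on both strands, with
the start and stop codons excluded from the random domain because
start-loss/stop-loss semantics fall outside the truncation predicate.
Junction-spanning indels are likewise excluded from the random domain and
covered by targeted cases. Interval calibration is checked empirically:
95% Woolf coverage over 2,000 simulated tables (binomial sampling at
moderate cell sizes, accepted within ±2 percentage points), and parameter
recovery — the mean pipeline-estimated OR across 200 cohorts simulated at
the study's sizes and frequencies must land within 10% of the odds ratio
implied by the generating frequencies (≈21.7). These sizes keep the whole
suite to a few minutes on one CPU while leaving the Monte-Carlo error
comfortably inside the acceptance bands.

Two published numbers are deliberately *not* asserted. The age-restricted
sensitivity odds ratio printed as 25.07 does not follow from the
cross-product estimator on its printed cells (36/2,319 vs 2/3,383 gives
26.26), and the estimator actually used, as well as the origin of those
denominators, is unstated; the package implements the age-restricted
re-analysis generically (`subgroup_reanalysis()`) and a test documents the
discrepancy. And protein-level HGVS strings for the real gene require its
reference transcript, which is not packaged. Where the two transcribed
fixture tables disagree with each other (one variant missing from the
unique-variant table; one recurrence count off by one), the loader warns
and preserves both verbatim.

## Known limitations

Single-transcript annotation only; no Fisher/exact or regression-based
burden models (no covariate or kinship adjustment); the P/LP rule is a
two-criterion surrogate; selenoproteins and non-standard genetic codes are
unsupported; and in-frame indel protein names fall back to `p.?` when the
peptide-level alignment is ambiguous.
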