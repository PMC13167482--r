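---
title: "plasmaconcord: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plasmaconcord: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaconcord)
```

## What the package models

Circulating tumor DNA (ctDNA) is the tumor-derived subset of plasma
cell-free DNA (cfDNA). Two questions dominate the analytical validation of a
ctDNA workflow:

1. **Concordance** — of the somatic mutations called in a patient's tumor
   tissue, what fraction is re-detected in the matched plasma sample? This
   is the tumor-mutation detection rate, a binomial proportion over
   mutations (not patients), reported with a confidence interval.
2. **Fragmentomics** — ctDNA fragments are typically shorter than
   background cfDNA because of differences in nucleosome wrapping and
   apoptotic fragmentation. At a known variant locus, read pairs can be
   split into mutant (tumor-derived) and non-mutant pools and their insert
   sizes compared.

The package implements both, plus the somatic filter cascade that sits
between annotation and any of these metrics, and a synthetic generator that
makes the whole chain testable offline.

## The filter cascade

Six criteria are applied in a fixed order; a removed variant is charged to
the *first* criterion it fails, so the tallies sum to the number of removals
and are reproducible regardless of how many criteria a row fails.

| # | criterion | default | notes |
|---|-----------|---------|-------|
| 1 | tumor VAF | ≥ 0.05 tissue, ≥ 0.001 plasma | inclusive, as printed |
| 2 | hard-filter status | `"PASS"` | string equality |
| 3 | panel of normals | not flagged | consumed as a boolean column |
| 4 | population AF | every *present* gnomAD AF < 0.001 | strict `<`; missing AF passes |
| 5 | ClinVar | significance ∈ {benign, not_provided, uncertain_significance} **OR** germline origin | see below |
| 6 | noncoding | coding, or splice region/site/promoter | label-driven |

**The ClinVar conjunction.** The criterion as usually stated — "exclude
variants reported as benign/not_provided/uncertain_significance and germline
in origin" — is grammatically ambiguous between OR and AND. The default here
is the disjunctive (OR) reading: it is the stricter one, removes more
likely-non-somatic calls, and matches the cascade's stated purpose of
retaining high-confidence somatic mutations. `filter_config(clinvar_combine
= "and")` selects the conjunctive reading; nothing else in the package
depends on the choice. Origin matching is by substring
(`"germline/somatic"` counts as germline) and significance matching is
case-insensitive.

**Criterion numbering.** Upstream descriptions of this cascade number both
the ClinVar rule and the noncoding rule "(5)"; here the noncoding rule is
criterion 6 so tally keys are unambiguous.

**Missing annotation.** A missing gnomAD AF passes criterion 4: somatic
variants are expected to be absent from population databases, and treating
absence as commonness would invert the filter's intent. Missing ClinVar
fields likewise trigger no exclusion. The table reader maps empty cells to
`NA`, never to zero.

**Promoters.** No gene models or promoter coordinates are consulted;
promoter status is read from the classification column. This keeps the
package agnostic to the upstream annotator, at the cost that an annotator
using a different vocabulary needs `filter_config(retained_noncoding = ...)`
adjusted. The exact classification vocabulary of any given caller is the
one genuinely open compatibility question, which is why both the coding
whitelist and the retained-noncoding set are plain configurable label sets.

## Detection rates and intervals

`detection_rate(k, n)` reports 100·k/n rounded half away from zero (base R's
round-half-to-even would print 81.2 for 13/16 where 81.3 is conventional)
and a Wilson score interval by default. The Wilson choice is empirical as
well as principled: for k = 262, n = 357 it reproduces the published bounds
(0.6857, 0.7771) to four decimal places with either z = 1.96 or
z = Φ⁻¹(0.975) (the bounds agree at that precision, so the z question is
moot), while the Wald interval gives (0.6881, 0.7797). Wald and
Clopper–Pearson remain available via `ci_method` for sensitivity analysis.
A zero denominator yields a flagged `undefined` result rather than an error
or a division.

Two counting units coexist deliberately:

* **mutation-level** (`detection_rate`, `cohort_detection_rates`): every
  tissue mutation is a Bernoulli trial; the overall rate pools per-patient
  numerators and denominators.
* **patient-level** (`gene_positive_rate`): a patient counts once per gene
  regardless of multiplicity. `plasma_given_tissue` conditions on tissue
  positivity and requires an *exact-key* plasma match; `tissue_only`,
  `plasma_only` and `combined` are prevalences over the cohort size.

They are separate modes, never inferred from the data. One convention worth
recording: a patient whose plasma carries an additional, different mutation
in the same gene (e.g. a second KRAS substitution) counts as detected only
if at least one tissue mutation is exactly matched; the packaged fixtures
keep all such rows so either convention is computable.

Matching uses exact string equality on gene + HGVS-c (fixture data) or on
chrom/start/ref/alt (synthetic data). No HGVS parsing or normalisation is
attempted — a documented limitation; calls from annotators that differ in
HGVS style will not match.

## Fragmentomics

**Projection.** `project_locus` walks the CIGAR with a (reference, query)
cursor pair: M/=/X advance both, I/S the query, D/N the reference, H/P
neither. A position inside D/N is "not covered".

**Classification.** `classify_read` demands positional exactness: an
insertion matches only as an I operation of exactly the inserted length,
carrying exactly the inserted sequence, at exactly the junction between the
anchor base and the next reference base; a deletion only as a D operation
covering exactly the deleted span. Near-miss gaps (wrong length, offset by
one) are `other_allele` — they are evidence of a *different* allele, not of
poor coverage — while reads that simply do not span the locus plus
`min_anchor` aligned bases on each side are `not_covered`. The anchor
default is 1 base; there is no published value for it, and raising it trades
sensitivity for indel-placement robustness.

**Fragment aggregation.** Duplicates, secondary and supplementary alignments
are removed first (fragment-level counting needs unique templates); mates
below `min_mapq` (default 20, unpublished, the field's customary cutoff) are
ignored. Agreeing mates or a single informative mate give the fragment
label; disagreeing informative mates exclude the fragment as ambiguous —
conservative and order-invariant, rather than resolving by quality.

**Sizes.** The analysis unit is the *fragment* (template), one size per read
pair, taken from the positive-TLEN mate — even though narrative descriptions
of such analyses often say "reads". Counts in this package are therefore
fragment counts throughout. "Below 150 bp" is strict `<` (plain-language
reading; configurable), and the mono- (50–220 bp) and di-nucleosome
(221–400 bp) windows are inclusive at both ends, so 220 is mono and 221 is
di. `max_size` (default 1000 bp) guards against aberrant TLENs.

**Rank-sum test.** `rank_sum_less(a, b)` tests the one-sided alternative
that `a` is stochastically smaller. Exact enumeration of all C(n, n_a) rank
assignments (midranks for ties) runs when min(n) ≤ 8 and total ≤ 20 — exact
where it is cheap; above that, the normal approximation with tie correction
and a 0.5 continuity correction. The implementation is independent of
`stats::wilcox.test`, which the test suite uses as an oracle on both
branches.

## The synthetic generator: what it does and does not emulate

`simulate_read_pairs` states a world matching the fragment biology the
package analyses:

* **Sizes**: a two-component truncated normal mixture per allele class.
  Mono-nucleosome means default to 153 bp (mutant) and 162 bp (non-mutant) —
  the observed patient-plasma mono-nucleosome means — with sd 20 bp (chosen
  once as realistic for cfDNA mono-nucleosome peaks; not a published value),
  a di-nucleosome component offset +150 bp with weight 0.15 (the di/mono
  mass ratio visible in typical cfDNA electropherograms; not published), and
  truncation to [50, 400] bp, the union of the two nucleosome windows.
* **Alleles**: each fragment is mutant with probability `mutant_fraction`;
  mutant mates covering the locus carry the alt base or an exact I/D CIGAR.
  A mutant mate that only partially overlaps a deleted span is trimmed back
  to the anchor base so no emitted read ever contradicts its fragment's
  truth label — the price is that such mates are slightly shorter than
  `read_length`, which the classifier correctly reports as `not_covered`.
* **Geometry**: fragment "size" is the outer reference span, which is
  exactly what |TLEN| measures; placement guarantees at least one mate
  spans the variant core with one anchor base on each side, except for an
  optional `background_fraction` of off-locus fragments (default 0, so the
  label-conservation invariant mutant + non-mutant = total holds by
  default).
* **Errors**: `error_rate` defaults to 0 so generator truth labels are
  exact and the 100%-agreement acceptance property is meaningful, not
  statistical.

Not emulated: base-quality variation, PCR duplicates, UMIs, soft-clipping,
multi-chromosome references, GC bias, and the size-selection effects of real
library preparation. A green truth-recovery test therefore establishes that
the CIGAR classifier is *logically* correct against well-formed alignments,
not that it is robust to aligner idiosyncrasies on real BAMs.

`simulate_variant_table` builds rows that fail exactly one named criterion
each (the ClinVar stratum sets both an excluded significance and a germline
origin, so it fails under either conjunction reading), making the cascade's
expected output exact by construction. `simulate_cohort` defaults to 16
patients with 11–24 mutations each (the observed per-patient range,
excluding one 99-mutation outlier) and a per-mutation plasma detection
probability of 0.734, the cohort estimate the package reproduces.

## Numerical and degenerate-input choices

* Rounding is half away from zero everywhere a percentage is reported;
  intervals are never rounded internally, only at display.
* Empty size vectors yield n = 0 summaries with `NA` fractions, flagged
  rather than erroring, so multi-locus runs with an empty pool still report.
* Identical-sample rank-sum input returns p ≈ 0.5 (never significant).
* All generator randomness derives from the single config seed through a
  save/restore wrapper, so library calls never perturb the caller's RNG and
  identical configs give byte-identical SAM output.
* Duplicate identity keys within one sample abort matching (upstream should
  deduplicate); silently keeping them would double-count the denominator.

## Known limitations

* HGVS matching is verbatim string equality.
* The SAM reader handles the tag-free, single-reference SAM this package
  emits; it is not a general-purpose BAM interface (the test suite verifies
  emitted SAM against Rsamtools where available).
* Promoter/splice membership is vocabulary-dependent (see above).
* The published mono/di window means (153/162, 291/308 bp) and their
  p-values depend on the study's raw reads and are not reproduced at desk
  scale; the package instead verifies the *direction* of the shift with a
  seeded power property (one-sided p < 0.01 in ≥ 95% of replicates at
  n = 500/5000 under the stated size model).
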