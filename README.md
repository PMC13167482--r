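# plasmaconcord

Tools for evaluating how well plasma liquid biopsies recover the somatic
mutations found in matched tumor tissue, and for asking whether the
tumor-derived fraction of cell-free DNA (ctDNA) is physically shorter than
the background cfDNA.

## Who this is for

Bioinformaticians validating a ctDNA targeted-sequencing workflow — for
example a new cfDNA extraction chemistry or a low-input panel assay — who
need, downstream of alignment, variant calling and annotation:

1. a reproducible **somatic filter cascade** that reduces annotated calls to
   high-confidence, functionally relevant somatic mutations, with
   per-criterion accounting;
2. **tissue–plasma concordance metrics**: the tumor-mutation detection rate
   (mutation-level), per-gene positive-detection rates (patient-level), and
   reference-standard VAF-panel detection rates, all with binomial
   confidence intervals;
3. **allele-aware fragmentomics**: classify read pairs at variant loci as
   mutant or non-mutant by positional CIGAR matching, extract per-fragment
   insert sizes, and test whether mutant fragments are shorter;
4. a **seeded synthetic-data generator** so all of the above runs and is
   testable without any sequencing data or network access.

## The statistics in brief

**Filter cascade.** A call is retained iff all six criteria hold, in order:
(1) tumor VAF ≥ 0.05 (tissue) or ≥ 0.001 (plasma); (2) caller hard-filter
status "PASS"; (3) not flagged by the panel of normals; (4) every present
gnomAD population AF < 0.001 (strict); (5) not excluded by the ClinVar rule
(significance ∈ {benign, not_provided, uncertain_significance} OR germline
origin; the conjunction is configurable); (6) coding, or a retained
noncoding class (splice region/site, promoter). Removals are tallied against
the *first* failing criterion.

**Detection rate.** For k of n tumor mutations re-detected in plasma the
rate is k/n with a Wilson score interval

    ( p̂ + z²/2n  ±  z·√( p̂(1−p̂)/n + z²/4n² ) ) / ( 1 + z²/n ),   z = Φ⁻¹(0.975)

Wald and Clopper–Pearson are available but the Wilson interval is the
default: it reproduces the published bounds (0.6857, 0.7771) for 262/357 to
four decimals, which the Wald interval does not. Reported percentages round
half away from zero (13/16 → 81.3%, 2/16 → 13%).

**Fragmentomics.** A read covers a variant via a CIGAR walk (M/=/X advance
reference+query, I/S query only, D/N reference only). SNVs compare the
projected base; indels require an I/D operation of exactly the right length
(and inserted sequence) at exactly the right junction/span, with ≥1 aligned
anchor base on each side. Mates vote per fragment; conflicts are excluded.
One insert size per fragment (the positive TLEN) feeds sub-150 bp fractions
and mono- (50–220 bp) / di-nucleosome (221–400 bp) window summaries, and a
one-sided Wilcoxon rank-sum test (exact enumeration for small samples,
tie- and continuity-corrected normal approximation otherwise) for the
"mutant shorter" alternative.

## Worked example

```r
library(plasmaconcord)

# Cohort concordance from the packaged per-patient counts (16 patients)
t4 <- load_fixture("table4_counts")
detection_rate(sum(t4$matched_n), sum(t4$tissue_n))
#> detection rate: 73.4% (262/357; 95% CI: 0.6857 to 0.7771)

# Patient-level APC rate: of 13 patients with an APC mutation in tissue,
# 8 had the same mutation (gene + HGVS-c) detected in plasma
t3 <- load_fixture("table3_tissue_plasma")
gene_positive_rate(t3, "APC", "plasma_given_tissue")
#> detection rate: 61.5% (8/13; 95% CI: 0.3552 to 0.8229)

# Synthetic fragmentomics: 2000 read pairs, 10% mutant fraction, mutant
# fragments centred at 153 bp vs 162 bp non-mutant
cfg <- sim_config(seed = 7, n_fragments = 2000, mutant_fraction = 0.1)
sim <- simulate_read_pairs(cfg)
fc  <- classify_fragments(sim$records, cfg$variant)
fs  <- fragment_sizes(fc, sim$records)
size_summary(fs$sizes$mutant)
#> all   n=208    mean=177.0   median=160.0  below 150 bp: 33.2%
#> mono  n=178    mean=155.4   median=155.0  below 150 bp: 38.8%
#> di    n=30     mean=305.2   median=304.0  below 150 bp: 0.0%
size_summary(fs$sizes$non_mutant)
#> all   n=1792   mean=182.6   median=167.0  below 150 bp: 22.9%
#> mono  n=1545   mean=162.3   median=163.0  below 150 bp: 26.5%
#> di    n=247    mean=309.5   median=311.0  below 150 bp: 0.0%
rank_sum_less(fs$sizes$mutant, fs$sizes$non_mutant)$p_value
#> [1] 0.000647  (mutant fragments are significantly shorter)
```

The mutant pool shows the expected shift: a larger sub-150 bp fraction
(33.2% vs 22.9%) and a smaller mono-nucleosome mean (155 vs 162 bp), and the
one-sided test rejects at p < 0.001.

## Command line

```sh
inst/cli/ctdna-concord simulate --type reads --seed 7 --out out/
inst/cli/ctdna-concord filter   --input calls.tsv --out filtered.tsv --report report.json
inst/cli/ctdna-concord concord  --tissue tissue.tsv --plasma plasma.tsv --key hgvs --out concord.json
inst/cli/ctdna-concord fragsize --alignments reads.sam --variants loci.tsv --out out/
inst/cli/ctdna-concord refeval  --panel table2_refmat --arm liquid_liquid --out ref.json
inst/cli/ctdna-concord run      --config pipeline.yaml --seed 1
```

## Package layout

- `R/synthetic-reads.R`, `R/synthetic-tables.R` — seeded generators (SAM
  read pairs, annotated variant tables, paired cohorts)
- `R/somatic-filter.R` — filter cascade and MAF-style table I/O
- `R/concordance.R` — matching, detection rates, intervals, reporting
- `R/fragmentomics.R` — CIGAR projection, classification, sizes, rank-sum
- `R/pipeline.R`, `R/cli.R` — YAML-driven orchestration and CLI
- `inst/extdata/` — transcribed evaluation tables used as fixtures
- `vignettes/plasmaconcord-methods.Rmd` — models, assumptions, design notes
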