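---
title: "Methods: WGS-based diagnosis of congenital skeletal disorders in ruminants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WGS-based diagnosis of congenital skeletal disorders in ruminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelscope)
```

## The diagnostic problem

Congenital skeletal disorders in cattle and sheep mostly occur sporadically:
an affected calf or lamb appears in a herd with unaffected parents, and the
question is whether a single causal genomic lesion explains the phenotype.
Whole-genome sequencing of the case, of whatever relatives are available
(complete trios, a single parent, affected paternal half-siblings), and a
large cohort of unrelated control genomes supports a hypothesis-driven
search: each plausible mode of inheritance (MOI) implies a genotype
configuration across the pedigree that very few genomic positions satisfy,
and the control cohort removes segregating population variation. When no
small variant survives any hypothesis, read-depth profiles across the
chromosomes can still reveal aneuploidies — a whole-chromosome trisomy or a
terminal deletion — and per-allele read counts can attribute such events to
a parental germline, or expose a parent who is a low-level germline mosaic.

`mendelscope` implements this workflow end to end: format readers and a
variant container, the MOI filters, de novo and mosaicism assessment from
allele depths, the windowed coverage scan with parental-origin inference,
identity-by-descent parentage verification, HGVS coordinate arithmetic, a
machine-readable nosology of ruminant skeletal disorders, and a seeded
synthetic-data generator that stands in for restricted real sequencing data.

## Data model and coordinate conventions

All coordinates are 1-based inclusive, matching both VCF and HGVS `g.`
notation. A `variant_set` holds one row per biallelic REF/ALT pair;
multiallelic sites are decomposed at load time with per-sample dosages
recomputed against each ALT, which conserves each sample's total allele
count at the site. Only the GT and AD FORMAT fields of a VCF are consumed.
Missing genotypes (`./.`) stay missing — nothing is imputed; each filter
states its own missing-data policy below. X-chromosome calls in males are
re-coded hemizygous at load time from the pedigree sex (an apparent diploid
heterozygote on the male X becomes a missing call, since outside
pseudoautosomal regions — which are not modelled — that state is
impossible).

## Mode-of-inheritance filters

Two MOI scenarios drive the search, mirroring how an isolated case is
analysed in practice:

* **Recessive, homozygous**: the variant is homozygous-alt (or
  hemizygous-alt) in every case and *never homozygous-alt in any control*;
  heterozygous control carriers are permitted, because a recessive allele
  may segregate at low frequency in the population. Every available parent
  with a non-missing call must be a heterozygous carrier.
* **Recessive, compound heterozygous**: within one gene, two alleles are
  each heterozygous in every case, no control is homozygous for either, and
  no control carries *both* simultaneously. When both parents are genotyped
  the pair must be pedigree-consistent with a trans configuration (one
  allele attributable to each parent); a pair explainable only in cis is
  rejected.
* **Dominant (and X-linked) private**: the variant is heterozygous (or
  hemizygous-alt on the male X) in every case and carried by *no control in
  any state*. In trio and single-parent designs every available parental
  call must be homozygous reference. The single X-linked configuration of
  interest in the case series is a heterozygous female, which passes the
  dominant filter unchanged; hemizygous male X cases are also accepted.

Missing-data policy: a missing case call fails the filter (presence cannot
be asserted); a missing control call is treated as reference by default (the
permissive reading of "absent in controls"), with a strict `"exclude"` knob
for sensitivity analyses; a missing parental call leaves that parental check
uninformative rather than failing the variant, because parental evidence is
corroborative while case/control evidence is definitional.

Every filter emits an audit table giving, per variant, whether it was
retained and the first check that failed — the intermediate accounting a
diagnostic report needs. Retained variants are always sorted by
(chromosome, position, alt) so output is deterministic. The filters carry
no tuning parameters beyond these policies; their correctness is checked
against naive, loop-based re-evaluations of the textual definitions on
1000 random toy cohorts, plus a monotonicity property (adding a control can
only shrink the retained set).

## De novo assessment and germline mosaicism

A dominant candidate in a trio is assessed against parental read evidence.
Both parents homozygous reference with zero alt-supporting reads (the
`max_parent_alt` knob, default 0) at depth at least 10 gives `de_novo`. A
parent called 0/0 whose alt reads exceed what the per-read error rate
explains — a one-sided exact binomial test at rate ε = 0.005, level
α = 0.05 — yields `mosaic_parent_suspected`; three alt reads in thirty is
already far beyond error at these settings. A missing parent leaves the
status `undetermined`.

For a putatively mosaic parent with multiple tissues sampled (blood, semen),
`test_mosaicism()` applies the same one-sided exact binomial test per
tissue, then bands the point fraction: a significant excess below 0.35 is a
low-level mosaic; a fraction in [0.35, 0.65] is a constitutive
heterozygote; otherwise the allele is absent. The 0.35/0.65 band and ε are
operational defaults — the source case series reports only a qualitative
"low proportion" in semen — and both are exposed in `mosaic_config()`. At
ε = 0.005 and depth 40 the exact test rejects from 2 alt reads upward, an
actual type-I error near 0.017, comfortably below α; a 10% germline mosaic
at semen depth 40 is detected in roughly 92% of replicates. Semen-positive,
blood-negative is reported as `germline_mosaic`; both tissues positive as
`somatic_and_germline`; two clean or two constitutive tissues as
`not_mosaic`; any missing or undetermined tissue leaves the verdict
`indeterminate`.

## Read-depth karyotype scanning

Coverage is consumed as per-window read counts (10 kb and 200 kb are the
two resolutions of interest; any width works). Counts are normalized to
ratios against a robust disomic baseline: within each autosome the extreme
windows are masked (two-sided trimming, 1% of mass by default) and the
per-autosome means are combined by a **median across autosomes**. The
median step matters at desk scale: the bundled toy genome has three
autosomes, so a trisomic chromosome can be ~40% of all autosomal windows
and any global trimmed mean would absorb it; the median of per-chromosome
means is immune as long as most autosomes are euploid, and at real genome
scale (29 bovine autosomes) it coincides with the global trimmed mean. No
GC or mappability correction is applied — the generator produces none of
that structure, and conclusions about GC-biased real data are accordingly
out of scope.

Expected ratios come from a sex-aware ploidy model: autosomes 1.0, X 0.5 in
males and 1.0 in females, Y 0.5 in males and 0.0 in females. A chromosome's
call compares its median ratio `m` to its expectation `e`: trisomy when
`m/e` is within δ of 1.5, monosomy within δ of 0.5, disomy within δ of 1,
else no call. δ = 0.15 with at least 10 supporting windows; both knobs are
exposed, and the defaults are wide enough that Poisson noise at 14–20x
never straddles a band yet narrow enough that an intermediate ratio (e.g. a
50% mosaic trisomy at 1.25) is deliberately left uncalled. "Disomy" here
means *consistent with the sex-expected ploidy* (so a quiet female Y is
unremarkable).

Chromosomes left uncalled go to a terminal-segment scan, since the
partial-monosomy archetype in this disease domain is a terminal deletion: a
single changepoint anchored at either chromosome end is fit by least
squares, modelling the terminal segment at half (loss) or 1.5x (gain) of
expectation and the remainder at expectation. A call requires at least 10
terminal windows, an improvement over the no-event fit, and a terminal mean
ratio within δ of the event level. Interior events are visible in the
exported Manhattan-style table but are not called — the scan is a targeted
detector, not a general segmentation. At 14x and 10-kb windows the
breakpoint of a 2.7 Mb terminal loss is recovered exactly in essentially
every seeded replicate; at 200 kb the quantization alone makes the
positional error larger, which the tests assert as a resolution-consistency
property.

## Parental origin of an extra chromosome copy

On a trisomic chromosome the case carries two copies from one parent and
one from the other. Trio genotypes label sites by which single parent
carries the alt allele (`sire_only_alt` / `dam_only_alt`); at sites where
the duplicated parent contributed the alt on both copies the case's alt
read fraction concentrates at 2/3, and at sites where the single-copy
parent contributed it, at 1/3. Pooling reads across sites (not per-site
voting) matches how the aggregate evidence is reported in practice;
`estimate_alt_fraction()` attaches an exact Clopper–Pearson interval. The
origin call itself is a pooled binomial log-likelihood ratio of
paternal-extra versus maternal-extra expectations, called at |LLR| > 10
nats (an intentionally conservative default; anything near the disomic 1/2
stays `undetermined`). The generator plants the extra copy as a duplicated
parental gamete, which realises exactly these canonical fractions; the
package does not attempt to distinguish meiosis-I from meiosis-II
non-disjunction, and no reference-bias correction is applied to the 2/3 and
1/3 expectations.

## Parentage verification by identity by descent

Recorded pedigree links are verified before filtering, since a wrong sire
invalidates segregation reasoning. Two statistics are computed per pair:
the opposing-homozygote rate (sites where one sample is hom-ref and the
other hom-alt — incompatible with direct parentage up to genotyping error;
an allowance of 0.001 reflects ~20x short-read calling) and method-of-
moments IBD following the classic PLINK `--genome` formulation: observed
identity-by-state counts are equated with their frequency-conditional
expectations under IBD 0/1/2, solved sequentially, truncated to [0, 1] and
renormalized, with `pi_hat = P(IBD=1)/2 + P(IBD=2)`. Sites with control
allele frequency outside [0.05, 0.95] are excluded as uninformative. A
link is parent-offspring-consistent when `pi_hat` lies in [0.4, 0.6],
P(IBD=0) < 0.05 and the opposing-homozygote rate is within the allowance;
a near-zero `pi_hat` is unrelated-like; a related pair contradicted by
opposing homozygotes is excluded. The band and window are operational
defaults (the source workflow names its tool, not thresholds) and are
arguments. The orchestrator aborts on an excluded or unrelated-like link
unless explicitly overridden, reporting the evidence.

## Variant classification

Surviving candidates are classified by a deterministic rule ladder that
approximates domestic-animal variant classification practice:
**pathogenic** requires a truncating consequence (or a known disease-allele
match) that is private, segregation-consistent, and supported by de novo
evidence or multiple affected carriers; **likely pathogenic** relaxes the
consequence to missense/in-frame backed by a predictor consensus (at least
two recognised in-silico tools calling the variant deleterious — the
consensus rule is reimplemented, the predictors themselves are consumed as
annotations, never run); everything else is **uncertain**. Unknown evidence
never counts in favour. This ladder is an approximation validated only
against the classification labels of the packaged case series; it is not a
general implementation of any guideline document. Gene–phenotype
prioritisation is deliberately not reimplemented: an optional user gene
panel may rank candidates but never excludes them.

## HGVS coordinate arithmetic

The per-case variant descriptions are triplets of genomic, coding-DNA and
protein notation, and the package reproduces their internal arithmetic:
`cds_to_codon(c) = ceiling(c/3)`, span lengths from `c.start_end`
coordinates, frame effects from net length change modulo 3, and the codon
range of an in-frame deletion as the spanned codons. Two deliberate
choices: intron-anchored positions with offsets (`c.320-443G>C`) are parsed
and stored but excluded from codon arithmetic, and non-codon-aligned
in-frame deletions report the spanned codon range *without* 3'-rule
re-normalisation — the catalogued protein descriptions are not normalized,
and silently re-shifting them would desynchronise the catalog from its
source. One catalogued triplet (CNTNAP1 `c.1495G>A; p.Ala734Thr`) is
arithmetically inconsistent (position 1495 belongs to codon 499); it is
flagged in the allele table and excluded from the consistency property
test rather than silently corrected. Likewise the genomic span printed for
the collagen in-frame deletion is 13 bp while the coding span is 12 bp;
the catalog records both and treats the coding description (12 bp, four
residues) as authoritative. Full HGVS grammar, transcript models and
translation are out of scope.

## The nosology catalog

The package ships three UTF-8 TSVs: the nosology of previously reported
ruminant skeletal disorders with a known molecular cause (one row per
disorder/breed/gene entry, including horn-trait rows that can be toggled
out of queries), the 39-case series (one row per catalogued finding, with
comma-separated case ids), and the SNV/indel alleles underlying those cases
(one row per distinct allele; an allele shared by two half-sib cases
appears once and lists both). Disorder identity is the (disorder, species)
pair, which is what makes the case series resolve to 19 distinct disorders.
Classification tallies intentionally mix two conventions, because that is
the only reading under which the published 11 / 6 / 4 tallies are jointly
consistent: pathogenic calls are counted per distinct allele (shared
alleles deduplicated, aneuploidies excluded), likely-pathogenic calls per
finding row. `diagnostic_rate()` computes solved cases over all cases —
27/39 ≈ 69% from the shipped table (25/39 excluding the two aneuploidies).
The headline rate printed alongside the source tables (64%) is not
reconstructible from the tables themselves; the package computes rather
than transcribes rates, and records the discrepancy in its notes. The
catalog validator enforces unique case ids, at least one case per row, and
the declared MOI vocabulary.

## The synthetic-data generator

The generator defines the study conditions under which everything above is
tested, and its defaults are fixed to the conditions the framework targets:
control cohorts under Hardy–Weinberg with site frequencies from a truncated
Beta(0.5, 0.5) (the U-shaped spectrum of neutral polymorphism, clamped to
[0.01, 0.99]); mean depth 20x (14x for the terminal-monosomy coverage
experiments, matching the depths of the two published structural events);
per-read error ε = 0.005 shared with the mosaicism test; Mendelian
transmission within families; and per-window Poisson counts with rate
depth x width / read-length x ploidy/2. Planted scenarios configure the
causal lesion per MOI: de novo dominant (absent in parents), recessive
(parents het, case hom), compound het (one allele per parent, a few
controls carrying each allele singly but never both), X-linked de novo
(heterozygous female case), mosaic sire (sire called 0/0, all half-sibs
het, semen alt fraction 0.1), and whole-chromosome trisomy or a 2.7 Mb
terminal monosomy in coverage. Background variants are unlinked — no LD,
recombination maps or demography — because none of the implemented
inferences uses linkage. The default genome is a toy model (three autosomes
of 25/20/15 Mb plus X and Y) sized so scans have thousands of windows but
every test runs in seconds; problem sizes used by the shipped tests are
200–1000 simulated cohorts/replicates per property, 300–500 background
sites, and 200–500 controls. Everything is byte-identical under a fixed
seed.

What passing these tests shows — and what it does not: the simulator
reproduces the *statistical* structure the methods rely on (HWE controls,
Mendelian transmission, binomial read sampling, Poisson coverage with
ploidy steps), so green tests certify the inference logic. It does not
emulate alignment artefacts, GC/mappability waves, batch effects between
cohorts, population structure, or genotyping-error correlation, so
performance numbers here are upper bounds on real-data behaviour.

## Orchestration

`run_case()` chains the stages in the order a diagnostic write-up follows:
parentage verification (aborts on exclusion unless overridden), all
applicable MOI filters, de novo assessment of dominant candidates in
trio/single-parent designs, classification, and — only when no SNV/indel
candidate survives — the coverage scan, with origin inference when an
aneuploidy is found and trio genotypes exist. Both stages can be forced or
disabled by flags, and disabling the CNV stage never changes SNV findings.
`cohort_summary()` tabulates outcomes by cohort design and computes the
solved-case rate with the same semantics as the catalog's diagnostic rate.
Reports are plain lists, deterministic for identical inputs.

## Known limitations

Beyond the simulator caveats above: the compound-het trans test uses
pedigree carriage, not read-backed phasing, so a pair whose parents both
carry both alleles is conservatively unresolvable; the terminal-segment
scan will not call interior deletions; the classification ladder is a
documented approximation; and the IBD estimator is the uncorrected
method-of-moments form, adequate for verification against a large control
cohort's frequencies but not for small-sample relatedness surveys.
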