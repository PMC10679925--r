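---
title: "Rare-variant prioritization in trio and sporadic immunodeficiency cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant prioritization in trio and sporadic immunodeficiency cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triovar)
```

## The analysis problem

Common variable immunodeficiency (CVID) is the most frequent symptomatic
primary antibody deficiency in adults. Its genetics are heterogeneous:
a minority of patients carry a clear monogenic cause, while many appear
to carry several rare heterozygous variants across immune genes — an
oligogenic pattern. Cohorts in this field are typically small: a
handful of affected probands sequenced together with their healthy
first-degree relatives (trios), plus unrelated sporadic cases with no
sequenced relatives.

`triovar` implements the desk-scale analysis such a cohort needs once
variant calling and annotation are done: site quality control,
rare/deleterious filtering, pedigree-aware segregation screening,
structural-variant co-occurrence analysis, ACMG-style classification,
and cohort-level reporting. It deliberately consumes standard upstream
outputs (a multi-sample VCF with ANNOVAR-style INFO annotations, a PED
pedigree, CNV/SV interval tables) and produces candidate tables in the
layout clinical papers print.

## The filter cascade

Six stages run in a fixed order, each recorded in a per-variant audit
trail (`run_cascade()`):

1. **Site QC** — per-sample read depth > 4, site RMS mapping quality
   > 30, variant quality > 20. All bounds are strict, exactly as
   commonly stated for raw short-read calls.
2. **Region** — exonic variants, or splicing variants within 10 bp of
   a junction. The window is inclusive (a +10 duplication is kept):
   splice-affecting variants at the window edge are documented disease
   alleles in this cohort type.
3. **Synonymous** — synonymous SNVs are discarded unless a dbscSNV
   splice-impact score rescues them (default cutoff 0.6, the
   conventional operating point for both dbscSNV scores).
4. **Repeat indels** — non-frameshift indels shorter than 10 bp inside
   RepeatMasker regions are discarded (likely alignment artifacts).
5. **Frequency** — every configured population database (defaults:
   1000 Genomes all, ESP6500siv2 all, gnomAD all and East-Asian) must
   report either no entry or a frequency strictly below 0.01. An
   absent entry is treated as "rare", never as frequency 0; the two
   are kept distinct end to end.
6. **Deleteriousness vote** — four voters: SIFT (`D`), PolyPhen2 (one
   merged vote from HVAR and HDIV, supporting on `D` or `P`),
   MutationTaster (`D` or `A`), and CADD (phred score at or above the
   cutoff).

### The vote rule, and why the default is "half of available"

Two decisions here were genuinely open and deserve explanation.

First, the *pass rule*. A strict more-than-half-of-four rule
(`vote_rule = "majority4"`) requires three supporting voters and counts
a missing predictor as non-supporting. Applied to real clinical
candidate tables, that rule is too aggressive: published candidate
variants frequently carry verdicts like `T|B|B|D` with a mid-range
CADD score — only MutationTaster and CADD support, and no CADD cutoff
can raise such a variant to three votes. Tool disagreement of exactly
this shape is well documented for missense predictors, and missing
scores (e.g. no CADD for multi-nucleotide changes) should not count as
evidence against. The shipped default therefore passes a variant when
its supporting voters are **at least half of the voters that actually
have data**, and the strict rule remains available as configuration.
The bundled 32-locus candidate table passes the cascade in full under
the default, while the strict rule would discard several of its
published candidates.

Second, the *CADD cutoff*. CADD phred 10 (top 10% of possible
substitutions) is the shipped default; 20 is offered by configuration
for stricter screens. The lower default keeps the CADD voter
informative in the 10–20 band where several published candidates sit.

Variants the missense predictors cannot score do not go through the
vote: stopgain, stoploss and frameshift consequences, and annotated
splicing variants, bypass the stage (their evidence is the consequence
itself). A missense variant with *no* predictor data at all fails with
reason `no_predictions` — conservative, because nothing supports it.

Monotonicity holds by construction: tightening `max_af` or raising the
CADD cutoff can only shrink the passing set, and the test suite checks
this property on randomized variants.

## Segregation screening

Per affected proband, depending on family structure:

* **De novo** — proband carries the allele, both parents observed
  homozygous-reference *with depth above the QC bound* (the depth
  condition re-uses the site-QC threshold to avoid calling dropout
  artifacts de novo). With a missing parent the model is not callable.
  On the male X only the mother is informative.
* **Homozygous / X-linked recessive** — homozygous (or male-X
  hemizygous) proband with each observed parent carrying one allele.
  Hemizygous genotypes are displayed as `hom`, the clinical
  convention. An autosomal homozygote with a well-covered
  homozygous-reference parent is reported as
  `possible_denovo_or_error` and excluded from candidates: soundness
  (never calling the same observation both inherited and de novo)
  takes priority over sensitivity.
* **Compound heterozygotes** — two heterozygous variants in one gene
  with opposite single-parent origins (trans by transmission). Pairs
  that cannot be phased (a parent carries both, or parents missing)
  are flagged `possible_cis` rather than silently dropped or promoted.
* **Sporadic cases** — a variant is kept only when the alternate
  allele is absent from every control sample. A missing control
  genotype counts as "not detected" (a presence rule should not turn
  absence of data into presence) but flags the call `control_missing`.
* **Oligogenic aggregation** — heterozygous candidates inherited from
  unaffected parents become reportable only when a proband carries
  them in two or more distinct genes (or alongside de novo hits). The
  definition is structural; no joint statistical model is claimed,
  because none is established for cohorts of this size.

## CNV/SV co-occurrence

Two events of the same type and source on the same chromosome are "the
same" when their reciprocal overlap strictly exceeds 50%
(`min(overlap/len(a), overlap/len(b)) > 0.5`; exactly 0.5 does not
qualify). Clusters are the connected components of this pairwise
relation (single linkage), which means a cluster may chain pairs that
individually fall below the bound — documented, with a strict
`"clique"` mode available when that matters. The recurrence screen
keeps clusters observed in at least two distinct patients and zero
controls; counts are of distinct samples, not events. CNVs and SVs are
clustered separately, and the screen runs cohort-wide.

## ACMG-style classification

Eleven evidence codes are implemented — PVS1, PS2, PM2, PM3, PP1, PP2,
PP3, PP4, BP4, BS1, BA1 — chosen because they can be computed from the
data the pipeline already has. Codes that require literature or
database curation (PS1, PM5, PP5, ...) are out of scope. The
combination table is the standard five-tier one; contradictory
pathogenic and benign evidence yields VUS with a `conflict` flag, and
the engine is total over all 2^11 profiles.

One weighting decision matters and is configurable: **de novo evidence
defaults to moderate strength** (the assumed-de-novo weighting,
`denovo_strength = "moderate"`), not full strength. Sequencing a trio
makes the transmission pattern clear but does not by itself confirm
parentage or relate the gene to the phenotype; treating every de novo
missense hit as strong evidence would classify essentially any
database-absent de novo missense variant with computational support as
Likely Pathogenic, which does not match how clinical panels of this
kind report such variants (they overwhelmingly report them VUS).
Under the moderate default, null de novo variants (stopgain, canonical
splice) still reach Pathogenic through PVS1 plus two moderates, while
de novo missense variants stay VUS unless further evidence accrues —
exactly the behaviour seen in the bundled cohort table (two Pathogenic
null variants, one Likely Pathogenic X-linked recessive missense
variant via PM2 + PM3 + PP2 + PP3, all else VUS).

The PP2 gene list (missense-constrained genes) is configuration; the
default contains only `CD40LG`, where missense in the TNF-homology
domain is an established disease mechanism.

## Gene-set over-representation

`enrich()` is a hypergeometric upper-tail test against a configured
background universe (default 20,000 protein-coding genes) with
Benjamini–Hochberg adjustment. Gene sets come from user-supplied GMT
files; no live pathway-database queries are performed. Zero-overlap
sets are reported with p = 1 rather than dropped.

## The synthetic cohort generator

`simulate_cohort()` exists so that every pipeline stage is testable
without any sequencing data. Its defaults mirror the target study
design: 12 trio families plus 4 sporadic cases (40 samples), 5,000
sites, mean depth 34x, a log-uniform true allele-frequency spectrum on
[1e-6, 0.5], four database frequency fields that are independently
absent with probability 0.3, and a latent-deleteriousness model in
which each predictor supports with probability 0.9 for deleterious
sites and 0.05 otherwise (10% missing scores per tool). Founder
genotypes are Hardy–Weinberg draws from the site's true frequency;
children receive one allele per parent; the male X is hemizygous and
maternally derived. Causal variants are spiked per inheritance model
with annotations that pass the cascade and all non-carrier samples
forced homozygous-reference, and a truth table is emitted alongside.

What the generator does *not* emulate: linkage disequilibrium,
recombination, sequencing reads (no FASTQ/BAM), population structure,
mosaicism, and realistic per-gene variant densities. Passing spike-in
recovery therefore demonstrates the correctness of the segregation
logic and filter plumbing under clean Mendelian transmission — not
calibration against real sequencing noise. The genotyping-error knob
gives a first-order handle on robustness: with error rate 0 the
pipeline must recover 100% of spiked variants with zero
Mendelian-inconsistent calls, and the de novo false-call count must
grow monotonically over error rates {0, 0.001, 0.01}.

Problem sizes used by the shipped validation suites: 1,000 randomized
variants for cascade-oracle equivalence, 5,000-site cohorts for
spike-in recovery, 50 random intervals for clustering equivalence, and
universes up to 50 genes for exact enrichment checks — all chosen to
make the full suite run in well under a minute per module on one CPU
while exercising every code path.

## Numerical and degenerate-input choices

* All threshold comparisons are strict (`>`, `<`) except the splice
  window (`<=`), matching the stated bounds.
* Absent allele frequencies are `NA`, never 0, and never compare equal
  to 0 in any filter.
* Coordinates: VCF positions are 1-based inclusive; BED and event
  tables are 0-based half-open. Conversions live in the IO layer only.
* Ordering is deterministic everywhere (karyotype order, then
  position, ref, alt); cluster and candidate output is
  permutation-invariant in the input.
* Empty inputs (no candidates, no events, no exon table) return empty
  but well-formed results; malformed rows are rejected with reasons,
  not silently dropped.
* The bundled candidate-table fixture reports no raw QC fields, so its
  variant-set form carries nominal within-bounds values (depth 30,
  QUAL 60, MQ 60) and synthetic coordinates; its per-patient phenotype
  assignments beyond the individually described cases are a
  reconstruction whose aggregates match the published counts.

## Known limitations

* No statistical phasing: compound-het calls rely purely on parental
  transmission, so cases where both parents carry both variants remain
  `possible_cis`.
* The ACMG engine computes only data-driven codes; its classes
  reproduce the bundled table under the shipped configuration but are
  not a clinical classification service.
* The sporadic rule is presence/absence only; it does not model
  contamination or low-level mosaicism.
* Site QC runs per sample (depth is per-sample); a per-site summary
  helper exists, but joint genotype refinement is out of scope.
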