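---
title: "Star-allele diplotype calling: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele diplotype calling: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starcall)
```

## The problem

CYP2D6 metabolizes roughly a fifth to a quarter of prescribed drugs, and
its activity varies person to person through *star alleles*: named
haplotypes defined by specific combinations of sequence variants
(SNVs and small indels), plus structural states such as whole-gene
deletion (\*5) and duplication (\*1x2). Genotyping the locus from
short-read sequencing is hard for two reasons: the highly similar CYP2D7
paralog attracts mismapped reads, and the clinically relevant unit is
not a single variant but an entire haplotype pair — the *diplotype* —
from which an activity score and a metabolizer phenotype (PM/IM/NM/UM)
are derived.

`starcall` implements the full path: a versioned star-allele definition
database (with an importer for PharmVar-style downloads), a
haplotype-insertion read simulator producing reads with exact truth
alignments, a pileup-based diplotype caller with copy-number estimation
against a control gene, an activity-score phenotyper, and a benchmark
module that scores calls against simulated truth with alias-aware,
function-aware accounting.

## The allele database

Definitions live in a versioned TSV (one row per allele-variant pair;
the reference allele contributes one row with empty variant fields) plus
a JSON sidecar carrying per-major clinical annotation: function category
(`normal`, `decreased`, `no`, `unknown`, `uncertain`, `unassigned`),
activity value on the quarter-step grid, evidence strength, and
population frequencies. The PharmVar importer converts that consortium's
file layout (haplotype FASTA plus variant table, including gap-notation
indels that are re-anchored to VCF minimal representation) into the
native schema, so no other component ever parses upstream formats. This
isolation is deliberate: stale or drifting upstream definitions are the
canonical failure mode for this class of tool, and confining them to one
converter keeps revisions local.

Two structural rules matter downstream:

* **Alias groups.** Minor alleles with byte-identical variant sets are
  grouped; the canonical representative is the current name with the
  lowest major number, then the lowest suffix. Distinct names with one
  variant set (a current designation and a legacy one, such as a
  \*36 suballele and its former \*57 name) are indistinguishable from
  read data by construction, so the caller reports the canonical name
  and lists the others as aliases, and the benchmark scores any group
  member as correct.
* **Coordinates.** Variants are 1-based VCF-style with anchored,
  left-minimal indels; contig names are normalized (`chr12` and `12`
  collapse to one form) at every boundary, so files in either GRCh38
  naming convention work unchanged.

## The simulator

Validation data are built by extracting the analysis regions from a
reference FASTA, blanking a placeholder span with `N`s, and splicing a
haplotype sequence (built by applying an allele's variant set to the
reference, or taken from an imported haplotype FASTA) into that span.
Each spliced base keeps a map back to its genomic coordinate, so every
simulated read carries an exact truth placement — position and CIGAR —
without running an external aligner. An optional SAM rendering of the
truth alignments allows the same pileups to be rebuilt through
samtools/Rsamtools as a cross-check, and real BAMs from an aligner can
be substituted at the same interface.

The read model is intentionally plain: uniform fragment placement,
Gaussian insert size (mean 400 bp, SD 50 bp), 150 bp paired reads,
constant base quality 30, substitution-only errors (default rate 0.001).
Read-pair counts per sequence are deterministic (the rounded expectation
`depth/2 × length / (2 × read length)` per chromosome copy), which makes
depth conservation exact and output byte-reproducible from the seed;
fragment positions, strands and errors remain random. Homozygous
simulation is the default validation mode — with both copies carrying
the same allele, every definition site is expected homozygous, which
isolates the question "can this allele be recognized at all?" from
phasing. Heterozygous and copy-number modes (0, 1 or 3 gene copies) are
provided to exercise the caller's structural logic.

What the generator does **not** emulate: indel sequencing errors,
quality-score structure, GC bias, and — most importantly — systematic
cross-mapping between the gene and its paralog. A green simulation sweep
therefore demonstrates that definitions, genotyping and resolution are
internally consistent at realistic depth and error rates; it does not
certify performance on real WGS, where paralog mismapping and alignment
post-processing dominate the residual error.

## The caller

**Site genotyping.** For every distinct definition variant the pileup
yields reference and alternate evidence: base counts for SNVs, spanning
deletion events for deletions, anchored insertion events for insertions.
With alternate fraction *f* and imbalance tolerance δ (default 0.15),
a site is homozygous-alternate at *f* ≥ 1−δ, homozygous-reference at
*f* ≤ δ, heterozygous inside 0.5 ± 0.15, and otherwise a no-call;
sites below `min_site_depth` (default 10) are no-calls. The tolerance
exists because homozygous sites in real data rarely sit at fraction
exactly 0 or 1 — mismapped paralog reads and sampling noise displace
them — and a strict model turns each displacement into a dropped
haplotype. Both band widths are configuration, not constants, and the
configuration forbids the heterozygous and homozygous bands from
touching. One approximation is worth knowing: reference evidence at an
insertion junction is anchor-depth minus insertion count, so a read
ending exactly at the junction counts as reference; the resulting bias
is about one part in a read length, far inside δ.

**Copy number.** The estimate is `2 × (gene mean depth / control mean
depth)`, rounded; the control is a copy-number-stable gene (VDR,
`chr12:47841537-47905022`, by default). The deviation of the raw ratio
from its rounded value is reported, with a low-confidence flag above
0.35. Depth means stay `cn_trim` (500 bp) away from the ends of the
containing analysis region, because coverage of an extracted region
tapers over roughly a fragment length at its boundaries; without the
clamp the gene/control ratio inherits a region-size-dependent bias. A
gene/control ratio under 5% is called a homozygous whole-gene deletion
(\*5/\*5) directly, since rounding alone cannot distinguish "absent"
from "barely covered".

**Diplotype resolution.** Candidate unordered pairs of canonical minor
alleles are enumerated exhaustively; a pair is consistent when its
expected dosage (0, 1 or 2 alternate copies; hemizygous and duplicated
states rescale to "none / some / all") matches every informative site
call. Among consistent pairs the fewest total defining variants wins,
which makes the reference diplotype the call for variant-free samples
and prevents a parsimonious truth from being explained by a baroque
pair. If distinct pairs remain tied after that, the sample is filtered
`no_call_ambiguous` with candidates listed in canonical-name order —
the name ordering is a reporting order, not a selector, because
choosing between biologically different pairs by alphabet would
manufacture confidence. The other failure modes are explicit:
`no_call_depth` when more than 25% of sites lack depth, and
`no_call_unmatched` when no pair explains the calls. Copy-number one
restricts candidates to single haplotypes paired with \*5; copy-number
three gives one haplotype an `x2` multiplier.

## Phenotyping

The activity score sums per-haplotype activity values, multiplying by
the copy multiplier for duplicated alleles (the standard CPIC
convention). Bins follow the published thresholds — 0 is PM, 0.25–1 IM,
1.25–2.25 NM, above 2.25 UM. Because activity values move on a
quarter-step grid those closed ranges leave formal gaps (e.g. 1.1), so
the implementation is total via half-open intervals (0,1], (1,2.25],
(2.25,∞); on the grid the two formulations coincide exactly. Any
haplotype with `unknown`/`uncertain`/`unassigned` function makes the
score indeterminate and the phenotype `Indeterminate` — never a
metabolizer category — so annotation gaps cannot masquerade as
biology. The report (text or schema-stable JSON) adds per-haplotype
function, activity, evidence and population frequencies; the
diplotype-level frequency is the per-population product of haplotype
frequencies unless a diplotype table is supplied, and is labelled with
the method used.

## Benchmarking rules

Comparison is unordered and alias-closed at the minor level; major-level
agreement (same star numbers, possibly different suballeles) is tracked
separately; copy multipliers must match. A *function mismatch* is scored
when an unassignable-function haplotype (unknown/uncertain/unassigned)
is reported as an assigned-function one (no/decreased/normal), or when
one assigned category is called as a different assigned category;
calling an assigned-function haplotype as unassignable is excluded.
Summary percentages use all samples as denominator (the simulated-sweep
convention); a called-only concordance is emitted alongside because
real-sample benchmarks condition on a call being made. Counts are
conserved: correct + miscalled + uncalled always equals the sample
count.

## Validation design and problem sizes

The test suite and `scripts/acceptance.R` regenerate everything from
seeds at desk scale: a 20-allele synthetic database (one reference
allele, one deliberate alias pair, one unassigned-function allele, at
least one insertion and one deletion variant) on a two-contig toy
genome, simulated homozygous at 40× with error rate 0.001 across five
seeds (100 samples); copy-number recovery over 60 replicates of CN 1/2/3
plus homozygous-deletion checks; resolver-versus-oracle agreement on
hundreds of random site-genotype vectors over databases of 10–50
alleles, where the oracle is an independently coded exhaustive
enumeration; and exact checks of the phenotype grid and the 36-entry
function-mismatch truth table. The toy control gene spans several
kilobases so that the control-depth mean has variance comparable to its
role (the real VDR control is tens of kilobases; a very short control
window would make the copy-number ratio needlessly noisy).

Determinism is structural: one master seed derives per-sample seeds, so
any individual sample of a sweep can be regenerated alone, and repeated
runs are identical file-for-file.

## Known limitations

* CYP2D6–CYP2D7 hybrid and fusion alleles are out of scope; structural
  handling covers whole-gene deletion and duplication only.
* Pileup-level genotyping discards read-pair phase; alleles
  distinguishable only by phase within a fragment are resolved by the
  parsimony rule, not by evidence.
* The simulator's error model is substitution-only and uniform; it will
  not reveal sensitivity to indel sequencing error or quality-dependent
  miscalls.
* GRCh37 coordinates are not supported.
* Heterozygous performance on real data depends on phasing complexity
  that homozygous sweeps do not probe; the heterozygous simulation mode
  exists for caller logic tests, not as a claim about real-sample
  heterozygote accuracy.
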