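---
title: "Methods: rule-based triage of transcriptome variants, editing candidates and lncRNA interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based triage of transcriptome variants, editing candidates and lncRNA interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseditr)
```

## Scope and data model

`aseditr` post-processes single-nucleotide variants called from bulk RNA-Seq
of a two-group design (here: two conditions with five biological replicates
each). The unit of analysis is a biallelic SNV with per-sample reference and
alternative allele depths (the VCF `AD` field, or an equivalent TSV). The
package does not call variants, align reads or compute coding-potential
scores; those are consumed as inputs. What it owns is everything after
calling: the multi-stage filter cascade, the differential allelic-expression
statistic, the RNA-editing branch, a native microsatellite scanner, the
consensus lncRNA cascade, and cis/trans interaction triage — plus a seeded
synthetic-data generator with a complete planted-truth ledger that makes all
of it testable without any external download.

All genomic intervals are held internally as `GRanges` (1-based, closed),
the native Bioconductor convention; BED input (0-based, half-open) is
converted on ingest and back on output, and GTF coordinates are used as-is.
Committing to the single `GRanges` convention everywhere removes the
off-by-one class of errors that mixing conventions invites, and lets every
interval operation go through `findOverlaps`.

## The filter cascade

Stages run in a fixed order; each records how many sites entered, were
removed and survived, and the chain is auditable (`run_cascade()` returns
the per-stage report; survivors re-run to an empty removal set).

1. **Quality** — a site survives iff every *present* annotation satisfies
   its strict inequality: RMS mapping quality > 40, total depth > 10,
   quality-by-depth > 2, read-position rank sum > −8, mapping-quality rank
   sum > −12.5. Absent annotations pass by default because the GATK-style
   callers emit the rank-sum statistics only where they are computable;
   `strict_quality = TRUE` inverts that choice for pipelines that guarantee
   complete annotations.
2. **Genomic context** — removal within 5 bp of any exon–intron boundary
   (both sides; the boundary is the coordinate between the last exonic and
   first intronic base, and a variant base at signed distance *d* from it is
   removed when |*d*| ≤ 5), within paralog intervals expanded by 50 bp on
   both sides, inside microsatellite (SSR) intervals, and inside
   *bidirectional* regions — bases covered by gene bodies of two or more
   genes on opposite strands, the minimal literal reading of that concept.
   A site may carry several removal reasons; all are recorded, and the four
   sub-rules commute.
3. **Proximity** — any two sites within 45 bp, or any three spanning
   ≤ 35 bp, are all removed. At the default windows the triplet rule is
   implied by the pair rule; both are implemented independently so
   non-default windows behave as documented. All participants are removed
   (the conservative choice; keeping one member of a pair would require an
   arbitrary tie-break).
4. **Prevalence** — a site survives iff the number of samples with
   alternative-allele support is at least `ceiling(0.5 × n_samples)`
   ("at least half"; the fraction is configurable).

## Differential allelic expression

Let sample *j* of group *g* contribute `alt` count \(a_{gj}\) out of depth
\(n_{gj}\), and write the alternative-allele fraction AAF = alt/(ref+alt).
Group AAFs pool counts, \(\hat p_g = \sum_j a_{gj} / \sum_j n_{gj}\), which
weights samples by coverage; ΔAAF = \(\hat p_1 - \hat p_2\).

The differential test is a binomial likelihood-ratio test: under H0 both
groups share one AAF, under H1 each group has its own, and
\(2(\ell_1-\ell_0)\) is referred to \(\chi^2_1\). The upstream tool the
procedure descends from uses an unpublished hierarchical model; this package
deliberately *defines* its test as the closed-form LRT instead —
deterministic, dependency-free, and validated by simulation: at depth
~ Poisson(50) and 5 + 5 samples the empirical size at α = 0.05 lies within
[0.035, 0.065] (checked in the acceptance suite), and a planted ΔAAF of 0.3
is recovered with sensitivity above 0.95. Sites with zero pooled depth in a
whole group are untestable and carry `NA`; they are excluded from the BH
family. FDR control is Benjamini–Hochberg step-up over all tested sites
(`stats::p.adjust`; an independently hand-written step-up implementation
serves as the oracle in the tests). The FDR family is all tested surviving
sites — the source procedure does not state its family, and this is the
least surprising choice.

A site is flagged ASE iff |ΔAAF| > 0.1, BH *q* < 0.001, **and** the
allelic-balance confirmation rejects: a χ² goodness-of-fit of the pooled
(ref, alt) totals against 1:1, \(\chi^2 = (\mathrm{ref}-\mathrm{alt})^2 /
(\mathrm{ref}+\mathrm{alt})\), 1 df, no continuity correction (the textbook
form), at p < 0.05. Flagged sites are categorised `true_heterozygote` when
the balance test does not reject, otherwise `HeteroRef`/`HeteroAlt` by the
direction of the excess; the category is bound to this test because the
source narrative ("ratio close to 1:1") names no other operationalisation.

### Consequence classes

Each site receives exactly one class by severity precedence CDS > UTR >
noncoding exon > intron > upstream/downstream > intergenic, with ties among
transcripts of equal severity broken by the lexicographically smallest
transcript id (gene id for the flank classes, with upstream preferred over
downstream) for determinism. For CDS sites the codon containing the site is
read on the coding strand — minus-strand transcripts are
reverse-complemented — and ref/alt codons are translated with the standard
genetic code; identical amino acids give `cds_synonymous`, otherwise
`cds_missense`. The upstream/downstream flank is 1000 bp; the source states
none, and 1 kb is the common promoter-proximal convention. A reference base
disagreeing with the genome is an error, not a warning: it means the inputs
are inconsistent.

## RNA-editing branch

Canonical editing is A-to-I (read A>G) or C-to-U (read C>T) *on the strand
of the overlapping gene*; the substitution is complemented for minus-strand
genes. Intergenic sites are resolved by evaluating both strand readings —
for an SNV at most one can be canonical — and recording the implied strand.
Sites overlapping genes on both strands with conflicting canonical readings
would be ambiguous and are excluded (the configuration cannot arise for
SNVs, but the guard is cheap).

A canonical candidate survives iff (a) no sample has AAF > 0.7 — an editing
efficiency above 70% is considered implausible; the ceiling is strict, so
exactly 0.7 passes; (b) it has no known-SNP identifier; (c) its position
overlaps a SINE interval (flank 0 bp, the minimal reading of "along" the
repeats; configurable); and (d) *q* < 0.05 with |ΔAAF| > 0.1. The four
rules are evaluated as a simultaneous conjunction — their order cannot
change the final set — and the full per-rule audit is returned so that any
exclusion names its violated rule. Surviving candidates are intersected
with a known-editing-site table on (chrom, pos, type).

## SSR scanner

The microsatellite mask is produced natively: for each period *p* = 1…6 a
lag-*p* equality scan finds maximal perfect tandem runs; a run is reported
once, under its shortest period (primitive motif), at its leftmost phase,
with the interval truncated to complete repeats (`length = p × count`) and
the full periodic region kept alongside (`run_start`/`run_end`). Runs
containing a non-ACGT base are excluded. Default minimum repeat counts are
mono 12, di 7, tri 5, tetra/penta/hexa 4 — conservative genome-scanner
conventions, since the mask's purpose is exclusion and the source names no
thresholds. Only perfect repeats are scanned; imperfect or compound
microsatellites are out of scope because a conservative mask need not chase
them. The scanner is verified against an independent PCRE
backreference-regex enumeration on random sequences.

## lncRNA consensus and interaction triage

The identification cascade is a pure set intersection. Structure first:
length ≥ 200 nt, ≥ 2 exons, biotype not protein-coding, expression at or
above a floor (default 0 — the source excludes "low expression" transcripts
without stating a threshold, so the knob exists but defaults to inert; the
synthetic study sets it to 1 abundance unit and documents that choice in its
config). Then the 3-of-5 coding-potential vote with strict per-tool
verdicts: CPAT score < 0.78, CPC2 score < 0, FEELnc score < 0.558, CNCI and
PLEK label "noncoding". A transcript with fewer than three available
verdicts is excluded for insufficient evidence rather than voted on a
rump panel. Finally Pfam/Rfam exclusion: best Pfam e-value absent or
> 10⁻³, and no Rfam hit. Transcripts already annotated with a lncRNA
biotype bypass the vote and domain step (they are known) but still satisfy
the structural rules.

Interactions between differentially expressed lncRNAs (DELs) and genes
(DEGs): *cis* when the loci share a chromosome with an edge-to-edge gap
≤ 10,000 bp (overlap counts as gap 0; edge-to-edge is the most inclusive
literal reading of the distance, since the source does not say whether the
10 kb is measured between edges or transcription starts); *trans* when the
expression profiles across all ten pooled samples give |Pearson r| > 0.9
with two-sided p < 0.05 (t transform on n−2 df, raw p as written — no
multiplicity adjustment is stated in the source) **and** at least one line
of binding evidence holds: normalized free energy ndG < −0.1 or binding
probability > 0.9. The correlation sign is reported as the interaction
direction.

## The synthetic study and what passing it shows

The generator emulates the study conditions: two chromosomes of 400 kb,
twenty gene slots per chromosome (multi-exon models with CDS and UTRs on
both strands, one opposite-strand overlapping pair per chromosome for the
bidirectional rule), SINE and paralog tracks, literal SSR runs, 10,000
variant sites over 5 + 5 samples, per-sample depth ~ Poisson(50) and alt
counts binomial at the site's group AAF (a beta-binomial overdispersion
knob exists for robustness experiments, default off). Planted fractions:
5% ASE sites, 0.8% editing sites, 2% each of quality, context, proximity
and prevalence violations — each failure class violating exactly one rule —
and twelve editing decoys violating exactly one editing rule each. Every
emitted site belongs to exactly one ledger class.

Three generator choices deserve their rationale:

* **ASE effect model.** Planted ASE sites hold one group at AAF 0.5 and
  shift the other by ±0.3. A symmetric shift (0.35 vs 0.65) would pool back
  to 1:1 coverage and, by construction, fail the χ² balance confirmation
  that the flag requires; condition-induced imbalance on one side is also
  the biologically coherent picture of an allele activated by one state.
* **Bounded-band sampling for exact checks.** Planted editing sites and the
  "non-significant" decoy draw their counts by bounded rejection: binomial
  draws are retried until the per-sample AAF falls within a band around its
  target (±0.10, and ≤ 0.65 for editing; ±0.04 for the non-significant
  decoy), with a deterministic fallback. The editing-containment check is
  an *exact* acceptance criterion, so the generator must make those
  verdicts certain by construction; the ASE recovery check, by contrast, is
  stochastic, and its sites are pure binomials.
* **SSR scrubbing.** A random 800 kb genome contains a handful of
  incidental microsatellites. After planting, the generator re-scans and
  mutates one base in each incidental run (never touching planted loci) so
  the SSR mask equals the planted truth and the cascade ledger balances
  exactly.

What the synthetic data does **not** emulate: mapping bias toward the
reference allele (WASP-style correction is out of scope), genotyping error,
linkage between sites, realistic SINE sequence content (the intervals are
positional), overdispersed depths, or library-size effects on the
expression matrix. Passing the suite therefore demonstrates that the rules,
statistics and bookkeeping are implemented exactly as specified and that
the test has its nominal operating characteristics under the stated
sampling model — not that those thresholds are optimal for any particular
real tissue.

## Numerical choices and degenerate inputs

* All threshold comparisons are strict (`>` / `<`) exactly as written:
  CPAT 0.78, FEELnc 0.558 and Pfam 10⁻³ are coding/removed at the boundary;
  AAF exactly 0.7 passes the editing ceiling; length 200 passes, 199 fails.
* `0·log 0 := 0` in the binomial log-likelihood; the LRT statistic is
  clamped at 0 against floating-point negatives; p-values at r² = 1 are 0
  by convention.
* Equal pooled ref/alt totals give χ² = 0, p = 1 (guarded anyway).
* Zero-depth samples yield `NA` per-sample AAFs; zero-depth groups make a
  site untestable; constant expression vectors are skipped with a warning.
* Multiallelic VCF records are split into biallelic sites by default
  (droppable); indels are skipped with a warning count; missing `AD`
  records count as 0/0 and are flagged.
* The empty input is a fixed point of every stage: empty tables and empty
  masks propagate without special cases.

## Problem sizes

The test suite exercises the cascade end to end at 10,000 sites (the
acceptance cohort), with smaller 200–2,000-site cohorts for unit and
property tests and 2,000 null sites for the size check of the LRT; oracle
comparisons use 100 random 10 kb sequences for the SSR scanner and 1,000
random layouts for the proximity filter. These sizes were chosen so that
every stochastic check has comfortable statistical resolution while the
whole suite stays quick on a laptop.

## Known limitations

* The differential statistic is a group-pooled binomial LRT; genuine
  biological overdispersion across replicates will inflate its size (the
  generator's `overdispersion_rho` knob exists precisely to study this).
* Balance categories use pooled counts across all samples and both groups.
* Consequence annotation reports one class per site (most severe); it does
  not enumerate per-transcript effects, and splice-region consequences are
  handled by exclusion (the junction filter) rather than annotation.
* Paralog regions are taken as a user-provided BED; the package does not
  derive them.
* No tabix/BGZF indexing; inputs are read whole, which is the intended
  scale for post-calling site lists.
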