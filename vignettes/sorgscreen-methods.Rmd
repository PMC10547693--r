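---
title: "Methods: locus-targeted screening for deleterious sorghum alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-targeted screening for deleterious sorghum alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorgscreen)
```

# The screening procedure

`sorgscreen` genotypes germplasm panels for deleterious alleles at the
sorghum *Maturity* (*Ma1*, *Ma2*, *Ma3*, *Ma5*, *Ma6*) and *Dwarf* (*Dw1*,
*Dw2*, *Dw3*) loci. The pipeline has five stages:

1. **Region restriction.** Panel VCF records are kept when their REF span
   overlaps a candidate-locus interval. This is a plain interval filter —
   equivalent to intersecting the VCF with a BED of gene spans — and it is
   where a ~37-million-variant panel collapses to the few hundred variants
   the rest of the pipeline sees.
2. **Normalization.** Multiallelic records are split into biallelic
   variants; shared allele prefixes/suffixes are trimmed (keeping one
   anchor base for pure indels) and indels are left-aligned to their
   leftmost equivalent position. Variant identity everywhere downstream is
   the normalized key `chrom:pos:ref:alt`.
3. **Consequence prediction.** For a coding variant, the CDS-projected
   edit is applied to the reference coding sequence, reference and mutant
   proteins are translated, and the protein change is derived by string
   comparison (details below). Intronic variants receive positional splice
   labels instead.
4. **Classification.** Each (variant, gene) pair receives one effect
   category; substitution scores (SIFT-like, lower = more damaging) enter
   here as an input channel and are never recomputed.
5. **Panel genotyping.** Every accession × locus is matched against the
   catalog of characterized allele signatures and called `named`,
   `novel_deleterious`, `heterozygous_carrier`, `wildtype`, or
   `uncharacterized`.

Only primary transcripts are modeled. All coordinates, external and
internal, are 1-based inclusive (the GFF3/VCF convention); BED input is
converted on read. A single convention eliminates a whole class of
off-by-one errors at the cost of converting once at the boundary.

# Position classification and splice windows

Intron offsets are defined on the coding strand: `+k` is the k-th base from
the intron's 5′ end (the donor side; the highest genomic coordinate for a
`-` strand gene), `−k` the k-th base from its 3′ end (the acceptor side).
Offsets +1/+2 and −1/−2 are the GT/AG consensus dinucleotides
(`splice_donor` / `splice_acceptor`); offsets +3..+5 and −3..−10 are
`splice_region` — the windows in which variants outside the consensus may
still perturb splicing. For introns shorter than 12 bases the windows can
overlap; donor-side classification then takes precedence, a deterministic
tie-break (such introns do not occur in the characterized loci and the
generator never produces them; the rule only guarantees the partition
property for arbitrary inputs).

Variants touching a consensus dinucleotide, or spanning an exon/intron
junction, are labeled `splice_disrupting` with no protein prediction: the
transcript outcome is unknowable without a splicing model, and pretending
otherwise would fabricate a protein change.

# Protein-change derivation and HGVS p. conventions

The consequence engine never bookkeeps codons. It mutates the CDS string,
translates both sequences with the standard nuclear code, and compares the
proteins. For frameshifts the mutant translation continues past the
reference stop into the 3′ transcript, because a shifted frame's new stop
can lie downstream of the reference stop codon (observed in real alleles,
e.g. frameshifts annotated with stop offsets in the hundreds). The
conventions, applied identically in the package and in the test oracle:

* identical proteins → synonymous, `p.(=)`;
* any change leaving a non-Met first residue → `start_loss`, `p.(Met1?)`;
* a change whose first altered codon is itself a stop → nonsense
  `p.(Xaa#Ter)`; `fsTer1` is never emitted;
* frameshifts report the first changed residue and the stop position in
  the shifted frame counting that residue as 1 (`p.(Glu94AspfsTer6)`
  means the stop is the 6th codon); a frameshift with no downstream
  in-frame stop is flagged (`fsTer?`), never silently numbered;
* in-frame indels are placed at the 3′-most equivalent position (the HGVS
  rule); inserted residues equal to the residues immediately 5′ of the
  insertion point are a duplication (`p.(His31dup)`);
* translation past the reference stop → `stop_loss`,
  `p.(Ter#XaaextTer?)` with the extension length unevaluated.

Two placement standards coexist deliberately: variant *identity* uses
VCF-style left alignment (stage 2), while protein *naming* uses the HGVS
3′ rule. The two standards genuinely disagree, so each is applied in its
own domain and nowhere else.

The HGVS p. parser is the exact inverse of the formatter on its image and
tolerates missing prediction parentheses. It validates every three-letter
residue token, which in practice catches typos in transcribed allele
tables (`Typ`, unbalanced parentheses) rather than silently mis-reading
them.

# Effect classification

Categories: `same_sense`, `tolerated_missense`, `deleterious_missense`,
`nonsense`, `frameshift`, `splice_disrupting`, `splice_region`,
`other_noncoding`, `unscored_missense`. Rules:

* missense with score < 0.05 → deleterious; ≥ 0.05 → tolerated. The
  published convention states "< 0.05 deleterious" and "> 0.05 tolerated",
  leaving a score of exactly 0.05 unassigned; the strict-deleterious
  reading is used (0.05 → tolerated) and pinned by a test.
* missense without a score → `unscored_missense`, reported separately so
  missing annotations cannot pass as benign.
* nonsense, frameshift, and splice labels pass through regardless of score.
* in-frame protein events (del/ins/dup/delins, start/stop loss) use the
  score channel like missense when a score exists. This is a package
  decision: such events vary from benign to null, and the score channel is
  the only evidence available at this stage.

The **deleterious set** is {deleterious missense, nonsense, frameshift,
splice-disrupting}. Whether non-consensus `splice_region` variants count
as deleterious is genuinely indeterminate in the field's tallies, so it is
a flag (`count_splice_region`, default `FALSE`).

# The allele catalog

`builtin_catalog()` encodes each characterized allele as one or more
component matchers, all required jointly, at homozygous-alternate zygosity
by default (heterozygous carriers are reported separately). Matchers come
in two modes:

* **consequence** — gene + HGVS p. string, compared as parsed changes (so
  `p.Lys184Asn` and `p.(Lys184Asn)` match). Where the exact change was
  never published — *Sbprr37-1* is only described as a 1-bp deletion
  upstream of the pseudoreceiver motif (residues 99–207) — the matcher
  carries a change kind plus a residue range (frameshift before residue
  99) instead of inventing a coordinate.
* **coordinate** — the exact normalized key, or, for imprecise signatures,
  a position window plus a minimum insertion length. *Sbghd7-2* is the one
  window matcher: insertions ≥ 10 bp at Chr06:698,150–698,185 within
  intron 2, the short-read hallmark of the large characterized insertion.

*Sbprr37-3* is encoded as the conjunction of `p.(Gln270Ter)` and
`p.(Lys184Asn)`; the literature also carries a conflicting `p.(Gln292Ter)`
statement for the same allele, which is recorded in the provenance note
but not used as a matcher. The *Sbphyb-2* in-frame event is reported as
either `p.(His31dup)` or `p.(His31del)`; the dup reading is matched, the
ambiguity noted. `dw3-ref` is catalog metadata only: its 882-bp tandem
duplication cannot be detected from short-read panels, so the matcher is
flagged unmatchable and always yields `unknown`.

A component whose defining variant is absent from the panel VCF counts as
homozygous-reference (allele absent): merged panel VCFs in this workflow
assert every discovered site, so absence of the record means no carrier.

**Locus-call precedence** (total and order-independent, pinned by a
permutation test): homozygous catalog allele → `named` (all matching
names listed); else homozygous deleterious variant → `novel_deleterious`;
else heterozygous allele or heterozygous deleterious variant →
`heterozygous_carrier`; else missing-data fraction at the interrogated
sites (signature plus deleterious sites) above the threshold →
`uncharacterized`; else `wildtype`. The missingness threshold defaults to
0.5 of interrogated sites — the published screens report "poor or missing
data" without a number, so the knob is explicit.

# Genotype–phenotype statistics

Association per locus is a one-way group-means linear model with treatment
coding against the wildtype level, two-sided t-tests per coefficient, and
α = 0.05 by default. Accessions called `uncharacterized` or
`heterozygous_carrier` are excluded by default — their allele level is
ambiguous — with a switch to keep them as their own levels. Residual
normality is assessed by Shapiro–Wilk (Royston's approximation, as
implemented in base R's `shapiro.test`; the package's contract is
agreement with an independently vetted implementation to 1e-4, verified in
the tests against a frozen cross-implementation value). The
Kruskal–Wallis rank-sum test is the non-parametric fallback
(`H = 12/(N(N+1)) Σ nᵢ(r̄ᵢ − (N+1)/2)²`, mid-ranks with the standard tie
correction, chi-square upper tail on k − 1 df; the all-ties case is an
error since the statistic is undefined after correction). The combined
multi-locus model is additive in locus factors with no interactions;
aliased columns are dropped and reported as singularities, which is what
happens when allele combinations do not segregate independently in a
panel.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. It emulates:

* **gene structure** — 2–6 exons of 90–240 coding bases, introns of
  60–180 bases starting GT and ending AG, 12–45-base UTRs, ATG start,
  single in-frame stop, CDS length divisible by 3, both strands. The 3′
  UTR ends in a stop-rich tail (a stop codon in all three frames) so
  shifted reading frames terminate within the transcript, as they almost
  always do in real genes.
* **panel structure** — inbred (mostly homozygous) diploid lines: each
  accession draws at most one catalog allele per locus, homozygous with
  probability 1 − `het_rate`. Heterozygosity is a separate dial rather
  than Hardy–Weinberg because germplasm panels are inbred and
  heterozygotes are the exception. Default planting frequencies mirror
  each characterized allele's observed share of the 860-accession panel,
  clipped to [0.05, 0.5] so every planted allele is recoverable at
  desk-scale panel sizes (e.g. *Sbghd7-1* 0.45, *dw1* 0.33, *Sbprr37-1*
  0.21, rare alleles 0.05; race-specific alleles absent from the map are
  not planted and must stay absent from every genotype).
* **variant content** — catalog signatures are planted by consequence
  (same change kind, residue re-chosen to the nearest feasible codon), so
  synthetic models need not replicate real exon structures; exon
  boundaries and phases of the real loci are not public in usable form
  and are never fabricated. Each locus also gets one novel deleterious
  nonsense variant and neutral variants (synonymous, deep intronic,
  tolerated missense). Planted edits are restricted to codons that are
  genomically contiguous — a single edit cannot straddle an exon
  junction.
* **scores** — deleterious-planted missense/in-frame variants draw from
  [0, 0.05), tolerated from [0.05, 1], so the score channel is concordant
  with the planted category by construction.
* **phenotypes** — `value = baseline + Σ effects(true alleles) + N(0, σ)`,
  homozygous alleles contributing fully and heterozygous carriers half;
  defaults are plant height in cm (baseline 250, dwarfing alleles −35 to
  −50) and days to anthesis (maturity alleles −6 to −18).

All randomness flows from the single config seed. What the generator does
**not** emulate — linkage disequilibrium, population structure, sequencing
depth variation, genotype error, structural variants — bounds what passing
tests show: they demonstrate that the pipeline's logic is correct under
clean inbred-panel assumptions, not that real-data artifacts (reference
bias, collapsed repeats, the undetectable *dw3-ref* duplication) are
handled. The published panel-level headline counts depend on the two
external resequencing datasets and are out of reach at desk scale by
design.

# Numerical and degenerate-input choices

* Normalization is idempotent and validated against the reference; a
  REF/reference mismatch is an error, never a silent repair.
* Genotypes are unphased; `0|1` ≡ `0/1`; any half-missing genotype is
  missing.
* Merging panels defaults to setting discordant calls to missing (with a
  logged conflict table) and absent cells to missing rather than
  hom-ref — merged VCFs do not assert reference calls at sites they lack.
  Both policies are selectable. This inflates `uncharacterized` rather
  than fabricating wildtype calls.
* Codons containing non-ACGT bases translate to `X` with a warning.
* `effect_counts` and `summarize_panel` conserve totals by construction
  and are pinned by property tests.

# Validation strategy and problem sizes

The test suite validates the consequence engine against an independent
brute-force oracle that applies the variant to the chromosome sequence,
shifts the exon/CDS coordinates, re-extracts and re-translates the mutant
transcript with its own codon loop, and derives the change by enumerating
every equivalent indel placement. Implementation and oracle share only the
translation table. Exact agreement is required on 10,000 random
(synthetic gene, coding variant) pairs per run (~1 minute). Panel
recovery uses 500 accessions × 8 loci with zero missingness (exact match
against the truth manifest, plus a masking experiment in which exactly the
masked accessions change status); statistical calibration uses 1,000
permutation replicates at n = 60. These sizes were chosen so the whole
suite runs in a few minutes while keeping binomial test intervals tight
enough to detect real miscalibration.

# Known limitations

* Consequence prediction assumes the annotated transcript: no splice
  outcome prediction, no multi-transcript support, no HGVS c./g.
  nomenclature (variant identity at the DNA level is the normalized key).
* The fixture models of the real loci are metadata-only; sequence-level
  work on the real genes requires a user-supplied GFF3 + FASTA.
* Allele tallies count homozygous carriers; whether published per-locus
  tallies included heterozygotes is not stated, so carriers are reported
  in their own category rather than folded in.
* Structural variants beyond small indels (notably the 882-bp *dw3-ref*
  duplication) are out of scope; the catalog records the allele but the
  genotyper reports it `unknown` for every accession.
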