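---
title: "Clone haplotype detection and quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone haplotype detection and quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Ultra-deep amplicon sequencing of one mixed sample — tumour subclones under
targeted therapy, a viral or bacterial population, a graft/host mixture —
produces tens of thousands of reads over a small region of interest
(typically up to ~10 kb; deep coverage and a small target trade off against
each other). Each read is a physical observation of one DNA molecule, so
*combinations* of variants carried in cis ("clones", compound mutations) can
be counted directly: no statistical phasing across samples is involved, and
no error model is imposed on the result. ampliclone extracts every
fragment's variant set from its alignment, tabulates exact haplotype counts
— each fragment counted exactly once — and converts counts to
coverage-adjusted percentages with a wild-type complement.

## The counting model

**Fragment.** The unit of counting is the fragment: a single read, or a
forward/reverse mate pair merged into one observation. A variant seen on one
mate but contradicted by confident reference-matching coverage on the other
is discarded and the position is masked for that fragment — by definition
one of the two bases is a sequencing error. A variant opposite an `N` on the
other mate is kept: an ambiguous base is absence of evidence, not
contradiction (the merge rule the package commits to; the contract only
fixes the contradiction case).

**Key sets.** Given a selection of variants of interest (everything
detected, or a panel loaded from a label list), each fragment is reduced to
its key set: its variants intersected with the selection. A fragment that
covers only part of a multi-variant clone contributes to the partial
haplotype it actually shows — sub-clones are reported as their own rows, not
absorbed into supersets, because "exactly matching" is evaluated over the
positions the fragment covers.

**Percentages.** For a haplotype row with `hits` carrier fragments,

    percentage = 100 * hits / informative

where `informative` is the number of fragments (carriers or not) covering
*all* of the row's variant positions unmasked. The historically printed
formula for this quantity divides by the *sum* of per-variant coverages
instead; on multi-variant clones that denominator grows with the number of
variants and shrinks percentages in a way that contradicts published
per-clone tables computed at realistic coverages. This ambiguity cannot be
resolved from the printed material alone, so both readings are implemented:
`denominator = "informative"` (default) and `"sum_positions"` (the literal
formula). The wild type is estimated as `max(0, 100 − Σ percentages)`;
percentages can legitimately sum above 100 when rows have different
denominators, which is logged but never an error.

## Variant extraction and labels

Internally all coordinates are 0-based half-open; every report label is
1-based. Walking the alignment operations gives SNVs from mismatching
aligned columns, insertions anchored at the following reference position,
and deletions whose deleted positions remain *covered* (a spanning read
observes the deletion; a read ending inside one does not). Soft clips
contribute nothing; an `N` masks its column. Indels are left-aligned to
their homopolymer/repeat context so that alignments from gap-placement-happy
aligners collapse onto one canonical key — label coordinates may therefore
differ from a non-normalising tool's output.

Adjacent SNVs are combined into a single multi-nucleotide record for
display, as are non-adjacent SNVs sharing one codon (given a CDS
annotation); combination is reporting-only and haplotype identity always
uses atomic variants, which keeps counting unambiguous. Deletion/insertion
labels carry the *length* (`c.1423_1424ins35`), matching the established
dialect for this assay class; the allele sequence is kept in a separate
report column. Amino-acid labels use the single-letter `T315A` convention,
with `fs`/`del`/`ins` markers for frame-affecting changes; a CDS whose
length is not a multiple of 3 is accepted with a warning and the trailing
partial codon is ignored for translation.

## Scattered haplotypes over overlapping amplicons

When the region is tiled by overlapping amplicons shorter than the clone
span, no single fragment shows a full clone. The inference builds a
symmetric, unweighted co-occurrence graph — nodes are selected variants, an
edge means joint occurrence on at least one fragment — and repeatedly
extracts the maximum clique (exact search; NP-complete but tractable at the
enforced caps of 15 rounds and 20 variants). Each clique defines a new
haplotype; its count is deducted from the pool and the search repeats.
Clique-derived rows are flagged `inferred`: a connection may be deduced that
is never observable on one read, and designs exist (many variants,
overlapping subgraphs, variant pairs never co-covered by any amplicon)
where no connection can be made at all — residual per-amplicon haplotypes
are then reported directly, with a warning.

Two quantities in this loop are under-determined by the published
description and are fixed here as explicit design choices:

* **Consistency.** Fragments contributing to clique `C` on amplicon `a` are
  those whose key set *equals* `C` restricted to the positions `a` covers. A
  fragment covering a `C` position without `C`'s variant cannot come from
  clone `C`; subset matching alone would conflate wild-type segments.
* **Bottleneck counts.** The clique's clone-unit count is the minimum over
  `C`-covering amplicons of the consistent remaining count. This is the
  weakest assignment that never over-counts any amplicon's observed
  fragments, and it is exact on noise-free fixtures (verified against an
  exhaustive mixture-enumeration oracle). Deduction subtracts that count per
  amplicon; a round that can only emit 0 terminates the loop. A clique may
  be re-emitted over several rounds until one amplicon runs dry; rows are
  aggregated by haplotype.

In inferred mode counts are clone units, not fragments: each unit
contributes one fragment per amplicon, so the percentage denominator is
`floor(total fragments / number of amplicons)`.

## The simulator's stated world

`simulate_mixture()` stands in for an external read simulator and emits
pre-aligned SAM (the true alignment is recorded; no aligner runs), so every
stage is testable offline. Its defaults are the conditions of the published
simulation experiment and of 454-class amplicon data:

* reference length 924 bp, read length 600 bp;
* substitution error 1% per base (`error_rate = 0.01`), uniform — replacing
  an empirical 454 profile — plus a homopolymer-biased indel rate
  (`indel_error_rate = 0.002`, positions drawn weighted by run length,
  pyrosequencing's characteristic failure mode);
* clone counts per case 3–8, with 1–9 variants each, mean ≈ 4.2;
* allocation of fragments to clones by largest remainder (exact and
  deterministic, so zero-noise recovery tests are sharp) or multinomially
  for sampling experiments;
* a mandatory seed; identical config and seed give byte-identical SAM.

For the linearity experiment the 100k-read original is scaled to 10 cases ×
10,000 fragments. Reads are amplicon reads: 600 bp from both ends of the
924 bp fragment (two overlapping amplicons, `[0,600)` and `[324,924)`), and
each clone's variants are drawn inside a 276 bp window so that one read
direction always spans a whole clone — the way amplicon panels are actually
designed for phasing, and the only world in which per-clone percentages are
identifiable without inference. Clones within a case occupy disjoint
positions. What a green linearity test establishes is therefore: on
amplicon-style data whose clones are readable within one fragment type, the
counting and normalisation are linear in the true proportions (R² ≥ 0.96 at
1% substitution noise). It does not establish robustness to an empirical
flowgram error profile, to alignment artefacts of a real mapper, or to
clones sharing variants with each other — the latter produce the documented
sub-clone rows and upward-biased partial haplotypes.

## Numerical and degenerate-input choices

* Percentages are carried at full precision and printed to one decimal.
* Rows with a zero denominator get 0% and a warning; rows with zero hits
  after selection are dropped silently.
* Maximum-clique ties break deterministically: larger total supporting
  fragment count first, then the lexicographically smallest sorted position
  tuple. Exports are byte-identical across runs on identical input.
* Only primary alignments are used; duplicates are *not* filtered —
  quantification assumes amplicon data, where duplicates are the signal.
  Unmapped/secondary/supplementary records are counted and reported;
  parsing aborts if more than 1% of records are malformed.
* The padded SAM dialect is supported per record: `P` operations consume
  neither query nor reference, so a padded record parses identically to its
  unpadded equivalent.
* Base qualities are read but unused; there is no quality filter in the
  counting model.
* A multi-reference SAM contributes only records on the configured
  reference; a single differently-named target is accepted with a warning.

## Known limitations

* No statistical error correction or probabilistic assignment: sequencing
  errors at selected positions leak into haplotype rows at the error rate,
  which is why a reporting threshold (default 1%) exists.
* A fragment whose only selected-variant evidence is masked counts as
  uninformative, not as wild type.
* Inference assumes every clone contributes the same number of fragments
  per amplicon (uniform unit multiplicity); designs violating this are out
  of scope.
* Full HGVS canonicalisation (dup, delins) and splice-aware annotation are
  out of scope; labels follow the length-suffixed dialect above.
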