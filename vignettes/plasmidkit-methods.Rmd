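---
title: "plasmidkit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plasmidkit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidkit)
```

plasmidkit is a headless engine for everyday plasmid work: it models DNA
records, reads and writes the GenBank flat-file format (including the
ApEinfo display dialect used by a popular desktop plasmid editor), scans
sequences with degenerate feature libraries, simulates restriction
digestion and agarose gels, designs and simulates the common cloning
reactions (restriction ligation, Golden Gate, Gibson, recombinase-mediated
joining, PCR), designs dCAPS genotyping assays, and aligns sequences with
an anchored affine-gap global aligner.  This vignette records the models
behind each piece, the conventions the code commits to, and the choices
made where the underlying methods are conventionally under-specified.

## The record model and coordinates

A `dna_record` holds the sequence text (case preserved), a topology flag,
a feature table, a free-text comment, and every header record of the file
it came from, verbatim.  All coordinates are **1-based and inclusive**,
matching GenBank.  On circular records a feature segment with
`start > end` wraps the origin; the GenBank writer renders such a segment
as `join(a..L,1..b)` and the reader folds that form back into a single
wrapping segment.  Sequences may use the plain `ACGT` alphabet, `ACGTN`,
or the full IUPAC degenerate code; every matching routine in the package
goes through one shared bit-set representation (A=1, C=2, G=4, T=8; a
pattern letter matches a sequence letter when the bit sets intersect), so
degenerate codes behave identically in search, feature scanning, enzyme
sites and primer analysis.

## Sequence statistics

**%GC.** Degenerate bases contribute their expected GC fraction: S
counts 1, W counts 0, N and R count 0.5, B counts 2/3, and so on.  This
makes the statistic deterministic and testable on any alphabet level.

**Melting temperature.** Tm uses unified nearest-neighbor
thermodynamics: `Tm = 1000*dH / (dS + R ln(C/4)) - 273.15` with the
entropy salt-corrected by `0.368 (N-1) ln[Na+]`.  Defaults are 50 mM
monovalent salt and 250 nM oligo, both arguments of `tm_nn()`.
Sequences shorter than 8 nt fall back to the Wallace 2+4 rule.  The
desktop program this engine mirrors does not publish its Tm formula, so
numerical parity with it is not promised — only internal consistency;
the implementation is checked against an independent nearest-neighbor
implementation to within 0.5 °C.  Degenerate bases are resolved to the
first base of their set before the thermodynamic sum, a deliberate,
documented simplification.

## GenBank and the auxiliary databases

The reader keeps unknown header records and unknown `/ApEinfo_*`
qualifiers verbatim; interpreted display qualifiers (`label`,
`ApEinfo_fwdcolor`, `ApEinfo_revcolor`, `ApEinfo_z`, `ApEinfo_hidden`)
are lifted into typed feature fields and re-emitted on write, which is
what makes read–write–read an identity.  With both dialect switches off
the writer produces plain GenBank; the test suite parses that output
with an independent parser (Biopython) under warnings-as-errors.

The auxiliary databases are versioned, line-oriented, tab-delimited text
with `#` comments — deliberately so, to keep them diffable and
exchangeable.  The enzyme format stores recognition, two cut offsets,
methylation rules and group tags.  Methylation blocking is encoded as
`methylase:pattern@offset`, read as: the site is *not* cut when the
methylase's target pattern matches at that offset relative to the
recognition start (negative offsets reach upstream).  A site is
suppressed only when the corresponding Dam/Dcm flag is on and a rule
fires.  Recombination prototypes are YAML because they are nested
(sites with core spans, ordered slot definitions, product renaming
maps); the shipped site sequences are synthetic demonstration arms, not
natural att sequences, and the file documents that.

## Cut-site model

Cut offsets count inter-base positions from the 5' start of the
top-strand recognition match, both measured on the top-strand coordinate
line; EcoRI (`G^AATTC`) is `top_cut = 1`, `bottom_cut = 5`.  Type IIS
enzymes simply carry offsets beyond the recognition span.  A site whose
cut would fall off the end of a linear record is reported but flagged
uncuttable.  Site search runs on a hexamer position index seeded by the
least-degenerate 6-base window of the recognition (degenerate seed
letters expanded, capped at 4096 expansions, with a naive-scan
fallback); its contract, enforced by test, is exact equality with a
naive sliding-window IUPAC scan.

Fragments store the full top-strand extent between their outermost cut
positions plus typed ends (5', 3' or blunt; window text in top-strand
coordinates; a phosphorylation flag).  With this convention a right end
ligates to a left end exactly when the window texts are equal, and
joining two fragments drops the downstream fragment's left window once —
which reconstitutes both parental cut sites and makes
digest-then-religate an identity up to rotation.  Two enzymes cutting at
the same inter-base position collapse into one cut event.

**Gels.** Band migration is `a - b log10(size)` scaled to [0, 1] on the
ladder extrema; bands within one lane closer than 2% in size merge into
a flagged doublet.  Only monotonicity and mass conservation are promised
— the desktop program's exact migration curve is unpublished.  Partial
digests enumerate all cut subsets exactly (capped at 16 sites, 65,536
species); each species' molar abundance is the product of per-site cut
and non-cut probabilities, and mass share is abundance times size,
normalised to 100.

## Simulators and designers

**Ligation** accepts one to three fragments, tries every order and
orientation, and requires each junction to be end-compatible with at
least one phosphorylated partner.  All distinct circular products are
returned (distinctness judged on rotation- and strand-invariant
canonical form); more than one flags ambiguity.  Products are
canonically comparable via `canonical_rotation()`.

**Golden Gate.** Assembly digests the inputs, keeps fragments free of
residual recognition sites (the signature of inward-facing type IIS
sites), and enumerates closed circles by overhang matching without
fragment reuse.  The designer picks one overhang per junction inside a
±3 nt window around the nominal junction, minimising a penalty with hard
constraints (identical pairs, reverse-complement-identical pairs,
palindromes) and a soft term (maximum pairwise positional similarity
over the overhang set and its reverse complements), by a seeded
hill-climb of 500 moves per restart with up to 10 restarts.  These walk
parameters are exposed as arguments; the published description of the
original tool names the strategy (a random walk over overhang choices)
but none of the parameters.  Primer tails are recognition + an A-pad
sized to the cut offset + the junction bases, so that simulating the
PCRs, digesting, and reassembling reproduces the designed product
byte-for-byte — that closure is the module's acceptance property.

**Gibson.** The product is the ordered concatenation of the spans plus
any non-templated inserted bases, closed circularly.  Each junction
overlap is grown base by base until its nearest-neighbor Tm reaches the
threshold (default 50 °C — a default of this artifact; the original
publishes the existence of a minimum, not its value).  The overlap tail
is carried by the downstream fragment's forward primer when that
fragment can take tails, otherwise by the upstream reverse primer; a
junction between two tail-less fragments is an error.  Stand-alone
fragments with sticky ends are resolved by the exonuclease direction
switch: 5' exo keeps the full extent, 3' exo trims the overhang windows.

**Recombinase joining.** A prototype names per-slot ordered site pairs,
whether the slot contributes the region between the sites (`inner`) or
around the outside (`outer`, for backbones), and how hybrid sites are
renamed.  The crossover point is the start of the shared core.  With the
shipped synthetic sites, a BP-type reaction followed by its declared
inverse LR-type reaction regenerates the original insert-bearing
arrangement, which the tests assert.

**PCR.** Binding-site search anchors at the primer 3' end and walks
5'-ward; the annealed region is the longest 3'-terminal run that stays
within the mismatch budget and ends on a matched base, so any remaining
5' bases are tail and excluded from the mismatch count.  "Mismatches at
the 3' end" is interpreted as a 3-base terminal window (the source
material names the control but not the window size).  At most ten
mismatches are accepted, by specification.  The hexamer index provides
candidates when the terminal window must match exactly; otherwise the
scan is exhaustive.  The search is property-tested against an exhaustive
anchored scan.  Products are forward primer (tail included) + template
span + reverse-complemented reverse primer; circular templates amplify
across the origin, tested by rotation equivalence.

**dCAPS.** Primer edits are confined to the last 6 primer bases
excluding the 3'-terminal base (a terminal mismatch would kill
amplification; 6 nt mirrors common dCAPS practice; both are arguments).
Every candidate design is verified internally by digesting both allele
amplicons, and the suite re-verifies designs through the independent
`find_binding_sites()` → `simulate_pcr()` → `digest()` route.  The
textbook illustration — a 250 bp amplicon where one allele cuts into
200 + 50 — is reproduced by a planted fixture scenario that uses a 50 nt
genotyping primer so the created site falls 50 bases into the amplicon;
the primer length there is illustrative, not a recommendation.

## Alignment

`nw_affine_align()` is a three-state affine-gap global DP; a gap of
length k costs `gap_open + k*gap_extend` (defaults +1/−1/−3/−1, all
config-exposed since the mirrored program publishes none).  Ties prefer
diagonal, then gap-in-b, then gap-in-a, making tracebacks reproducible.
`anchored_align()` finds maximal exact shared blocks (default minimum
12 nt) as anchors and aligns only the inter-anchor regions; a region
whose length product exceeds `max_unaligned_product` (default 250,000)
is left unaligned and recorded.  The source description of this
threshold is an incomplete sentence; the reading implemented is
"product of the two region lengths greater than the configured maximum".
When the threshold is disabled entirely the heuristic has nothing to
bound, so the exact DP runs directly — that is why anchored mode with
thresholds disabled equals full NW exactly.  `combine_pairwise()` stacks
pairwise alignments by taking, between each pair of reference positions,
the widest gap run required by any input; it is deliberately not a
multiple sequence alignment.

## Palette, gels-as-figures, and the calculator

The palette generator spaces hues at `i*360/n`, draws saturation and a
target luminance from the seeded RNG, and bisects HSL lightness until
the color's WCAG relative luminance lands strictly inside (0.10, 0.30) —
the open interval in which the contrast ratio `(L1+0.05)/(L2+0.05)`
exceeds 3 against both black and white.  The target band (0.12, 0.28)
leaves margin for 8-bit quantisation.  The molar calculator uses
650 g·mol⁻¹·bp⁻¹ for double-stranded DNA.

## The synthetic fixtures and what they do not show

`make_fixture()` generates the study material: a 3 kb circular
plasmid with one EcoRI site, two HindIII sites and two library-findable
features planted into an otherwise site-free random background; Golden
Gate amplicon sets whose natural junction overhangs are rerolled until
they carry no hard orthogonality violation; Gibson fragment sets tiling
a random product; and the dCAPS scenario described above.  All fixtures
are deterministic per seed.  Random uniform-composition DNA is easier
than real plasmid sequence in two ways the reader should keep in mind:
it lacks long repeats (flattering the anchored aligner and the Golden
Gate overhang search) and it lacks the skewed base composition and
methylation landscape of real vectors.  Passing tests demonstrate
correctness of the bookkeeping and the stated contracts, not performance
claims about hard repetitive genomes.

Problem sizes used by the test suite — 1000 random digests, 100 × 5 kb
site-search comparisons, 200 GenBank round-trips, 200 alignment oracle
pairs, 100 verified dCAPS scenarios — were chosen as the smallest sizes
at which the property suites exercise every code path and corner
(wrapping features, type IIS ends, doublets, ambiguous ligations) while
staying desk-scale.

## Known limitations

* EMBL, GCG, GFF3, chromatogram (ABI/SCF) and other vendor formats are
  out of scope; GenBank, FASTA and raw text are the interchange surface.
* Methylation handling covers Dam and Dcm only, and assumes complete
  methylation when the flag is on.
* Ligation is combinatorial, not kinetic: no efficiency or fidelity
  modelling, and Golden Gate overhang choice does not use empirical
  ligation-fidelity tables.
* The amino-acid search mode matches exact residue strings (no
  mismatches), on standard or the bundled alternative code tables
  (1, 2, 5, 11).
* Degenerate bases in a *sequence* (not pattern) match permissively by
  set intersection; a run of N in a record will therefore match most
  patterns, which is the conventional, permissive reading.
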