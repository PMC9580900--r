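# plasmidkit

Headless plasmid editing and *in silico* cloning for R.  plasmidkit is for
molecular biologists and tool builders who want the computational engine
of a plasmid editor — sequence records, automatic feature annotation,
restriction analysis with virtual gels, and simulators/designers for the
standard cloning reactions — as scriptable, testable library functions
rather than a GUI.

What it does:

* **DNA records and GenBank I/O.** A `dna_record` models sequence text,
  linear/circular topology, a feature table and preserved header records.
  The GenBank reader/writer round-trips files exactly, including the
  `ApEinfo:` COMMENT line and `/ApEinfo_*` display qualifiers used by a
  widely used desktop editor's dialect; a strict mode emits plain GenBank
  with no dialect content.  FASTA and raw ASCII are sniffed automatically.
* **Feature libraries.** Definitions over the IUPAC code with
  variable-length wildcards `#` (≥0 nt) and `+` (≥1 nt), `<`/`>` context
  that extends matches outward after the core is found, and
  lowercase-as-gap semantics for intron-style features.
* **Restriction analysis.** Hexamer-indexed site search (contractually
  equal to a naive IUPAC scan), Dam/Dcm methylation blocking, full and
  exact partial digests, typed sticky/blunt fragment ends, an enzyme-set
  calculator, silent/diagnostic site-creating mutagenesis proposals, and
  virtual agarose gels (`a − b·log10(size)` migration, mass-percent band
  intensities, doublet merging) rendered as SVG or ggplot2.
* **Cloning simulators.** Restriction ligation (1–3 fragments, all
  orders/orientations, phosphorylation-aware), Golden Gate assembly and a
  designer that picks orthogonal overhangs by a seeded random walk and
  emits ready-to-order primers, a Gibson designer that grows each junction
  overlap to a target nearest-neighbor Tm, and recombinase-mediated
  joining driven by editable YAML reaction prototypes.  Designs close the
  loop: simulating the designed PCRs and reassembling reproduces the
  designed product byte-for-byte.
* **PCR and dCAPS.** 3'-anchored primer binding-site search with mismatch
  budgets, PCR product simulation (circular templates amplify across the
  origin), constraint-based primer scanning with hybridization screens,
  and dCAPS genotyping-assay design verified end-to-end by digesting both
  allele amplicons.
* **Alignment.** Affine-gap Needleman–Wunsch with deterministic
  tie-breaking, an exact-block anchor heuristic with an unaligned-region
  threshold, and stacking of pairwise alignments onto a shared reference.

At its core the Tm model is unified nearest-neighbor thermodynamics,

    Tm = 1000·ΔH / (ΔS + 0.368·(N−1)·ln[Na+] + R·ln(C/4)) − 273.15,

the gel model is migration ∝ a − b·log10(size), molarity is
concentration / (650 g·mol⁻¹·bp⁻¹ × length), and the Golden Gate overhang
search minimises a hard/soft orthogonality penalty over junction windows.
See the methods vignette (`vignettes/plasmidkit-methods.Rmd`) for every
convention and default.

## Worked example

```r
library(plasmidkit)

fx  <- make_fixture("plasmid", seed = 42)   # 3 kb synthetic circular plasmid
rec <- fx$record
glance(rec)
#> # A tibble: 1 × 5
#>   name               length topology n_features gc_percent
#> 1 synthetic_puc_like   3000 circular          2       50.5

enz <- default_db("enzymes")
frs <- digest(rec, enz[enz$name %in% c("EcoRI", "HindIII"), ])
fragments_tbl(frs)
#>    size left  right provenance
#> 1   700 5p    5p    synthetic_puc_like cut 201..900 (EcoRI+HindIII)
#> 2   900 5p    5p    synthetic_puc_like cut 901..1800 (EcoRI+HindIII)
#> 3  1400 5p    5p    synthetic_puc_like cut 1801..200 (EcoRI+HindIII)
```

The three fragment sizes sum to the 3000 bp parent — digestion conserves
length — and each end records its 4-nt 5' overhang, so `ligate(frs)`
can rebuild the plasmid.  On a virtual gel the digest lane reads:

```r
gel <- gel_lanes(list(ladder = "ladder", digest = fragments_tbl(frs)$size),
                 default_db("ladders")[1, ])
dplyr::filter(tibble::as_tibble(gel), lane == "digest")
#>   lane    size molar_abundance mass_percent migration doublet
#> 1 digest  1400               1         46.7     0.533 FALSE
#> 2 digest   900               1         30       0.653 FALSE
#> 3 digest   700               1         23.3     0.721 FALSE
autoplot(gel)   # ggplot2 rendering; render_svg(gel) for a figure file
```

The 1400 bp band carries 46.7% of the lane's mass (mass share is
proportional to molar abundance × size) and migrates least.  Selection
statistics work the same way on any subsequence:

```r
selection_stats(subseq_bases(rec, 101, 120))
#>   length gc_percent tm_celsius frame_offset
#> 1     20         35       48.2            0
```

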