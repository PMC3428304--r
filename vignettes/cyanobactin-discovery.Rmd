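---
title: "Mining and mass-based verification of cyanobactin macrocycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and mass-based verification of cyanobactin macrocycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanomine)
```

## The problem

Cyanobactins are ribosomally synthesized and post-translationally modified
peptides (RiPPs) of cyanobacteria. A short precursor protein (~50 aa)
carries a conserved N-terminal leader, a hypervariable core of 7–22
residues, and a short C-terminal recognition region. Maturation proteases
excise the core and join its ends head-to-tail into a macrocycle; some
products additionally carry a heteroatom-bound prenyl (C5H8) or geranyl
(C10H16) group, or an intramolecular disulfide bridge when the core holds a
cysteine pair. Because the product is genetically encoded, its mass is
predictable from DNA — which makes discovery a joint genome-mining and
mass-spectrometry problem: find the precursor genes, predict the cyclic
product masses and their modified variants, and confirm candidate peaks
with orthogonal evidence (diagnostic neutral losses, stable-isotope label
shifts, derivatization shifts).

`cyanomine` implements that workflow for the piricyclamide family of
*Microcystis*: leader motif `KKNxxPxxxxPVxR`, recognition motif `FAGD`.

## The mass model

All arithmetic runs on elemental formulas over C, H, N, O, S. A peptide is
the element-wise sum of its residue (dehydrated monomer) compositions; a
head-to-tail macrocycle is exactly that sum, while a free linear peptide
adds one H2O. Positive-mode electrospray observes `(M + z·1.007276)/z`.

```{r}
protonated_mz(peptide_formula("GTHLYTITP", "cyclic"))
```

Modifications are signed formula increments (`modification_table()`):
prenyl +C5H8, geranyl +C10H16 (exactly two prenyl equivalents), disulfide
−H2 per bridge, methionine sulfoxide +O, and carbamidomethyl-cysteine
+C2H3NO per alkylated thiol. Carboxyamidomethylation of a bridged peptide
is therefore (+2H reduction) + 2×C2H3NO = +116 Da nominal relative to the
bridged ion, the diagnostic shift for a single disulfide. Per-cysteine
bookkeeping was chosen over a single "CAM" lump so partial derivatization
is expressible; the invariant `2·disulfide + cam_cys ≤ nCys` keeps the two
from claiming the same thiols.

Two mass scales are exposed deliberately:

* `monoisotopic_mass()` — sum of monoisotopic atomic masses (constants
  embedded to ≥6 decimals), for high-accuracy work;
* `nominal_mass()` — the classical sum of integer atomic masses (C 12, H 1,
  N 14, O 16, S 32; proton 1). This is the integer a low-resolution
  instrument reports. It is **not** the rounded monoisotopic value: a
  1.5 kDa peptide ion carries a mass excess of ~+0.7 Da, so rounding would
  overshoot the printed integer by one (1544.70 → 1545, where the
  instrument prints 1544).

Met-sulfoxide is modeled as a sample-preparation artifact applied to the
intact product, never as a precursor-encoded feature.

### Isotope labeling

Cultivation on fully labeled medium shifts a product's mass by
`count(element) × Δ_per_atom` (¹⁵N−¹⁴N = 0.997035 Da, ³⁴S−³²S =
1.995796 Da). Although labeling media are typically 90–98 atom%, the
monoisotopic peak of a labeled compound corresponds to complete
substitution, so `enrichment` defaults to 1.0 and remains configurable.
`infer_atom_count()` inverts the arithmetic — an observed +4 Da nominal
shift under ³⁴S counts two sulfur atoms — and flags residuals beyond 30%
of one atom's shift as inconsistent; that threshold is the point at which
rounding to the nearest atom count stops being reliable.

### Formula search

`formula_search()` enumerates integer compositions within a tolerance of a
target mass (default 50 mDa) and filters by chemical plausibility: RDBE
`C − H/2 + N/2 + 1 ≥ −0.5` and integral or half-integral, plus the
saturation bound `H ≤ 2C + 2 + N`. The −0.5 floor (rather than 0) admits
even-electron fragment compositions. Applied to the 84.0311 Da adduct on
the 1068.546 ion of the GTHLYTITP-like peptide, the CHO search returns
C4H4O2 and C5H8O among its candidates; the ranking is by |Δ| with a
lexicographic tie-break so output order is a pure function of the input.

## Mining

`translate_six_frames()` reports amino-acid segments between stop codons on
both strands, with no start-codon requirement (amplicons may be gene
fragments) and a 30 aa minimum (precursors are ~48–53 aa). Codons
containing N translate to X, which never satisfies a motif position —
wildcards included — so ambiguous sequence cannot fake a match.
`scan_motif()` counts substitutions at non-wildcard positions only; the
default budgets (leader ≤2, recognition ≤1) reflect that the family was
originally screened by degenerate PCR, which tolerates variation.

The core is defined as the segment strictly between the leader-motif end
and the first downstream recognition-motif start. Exact protease offsets
are not part of the model; every catalogued core sits flush against both
anchors and ends in proline immediately before the recognition region, so
the interstitial definition with a 5–30 aa sanity window is the natural
choice. Amino-acid spans are reported 1-based inclusive (the R/IRanges
convention); nucleotide spans are 0-based half-open internally and printed
1-based in reports, with minus-strand features given in forward
coordinates plus a strand flag.

`dedupe_cores()` collapses clone records to unique cores with counts
(descending, then lexicographic) and `catalog_summary()` reports the
diversity statistics: on the bundled bloom-library table, 122 clones
collapse to 19 unique cores, two of which show the double-cysteine pattern
(lengths 10 and 22 aa) while the remaining 17 span 7–17 aa.

## Variant enumeration and matching

`enumerate_variants()` builds the modification grid per core: prenyl 0–2,
geranyl 0–1 under a combined isoprenoid cap of 2 units (geranyl counts as
two), disulfide up to `floor(nCys/2)`, sulfoxide up to nMet. Geranyl and
2×prenyl are isobaric at MS1; both variants are enumerated and the
parsimony tie-break (fewer modification instances) ranks the geranyl
reading first, which matches how such pairs are resolved in practice
(fragmentation, not MS1). Disulfide/isoprenoid co-occurrence is allowed by
default and can be switched off.

`match_peaks()` reports every (variant, peak) pair within tolerance —
default ±20 mDa for high-accuracy data, ±0.3 Da recommended for ion-trap
spectra — ranked per peak by |Δ|, then parsimony, then label, so results
are invariant to the order of inputs. MS2 evidence
(`detect_neutral_losses()`: losses 68.0626, 136.1252, 91.0092,
63.9983 Da at ±0.3 Da and ≥5% relative intensity) and label shifts
(`verify_labels()`) only ever annotate mass matches; they never create
one.

## The synthetic forward model

`sim_config()` fixes the study conditions the generator emulates: 19 unique
cores over 122 clones (the shape of the natural bloom library), core
lengths 7–22 aa with a terminal proline, ~10% of cores carrying a planted
cysteine pair, ~20% a methionine (oxidized with probability 0.3), and an
isoprenoid spectrum of 50% unmodified / 25% prenyl / 25% geranyl —
proportions read off the characterized strain products. Clone counts
follow a rank^(−s) law (s = 1) via deterministic largest-remainder
allocation; MS1 peaks get Gaussian m/z error (default σ = 5 mDa) and
uniform decoys confined to the instrument scan range m/z 300–2200.

Design choices worth knowing:

* the background residue alphabet excludes Cys and Met, which are planted
  explicitly — ground truth for the disulfide/sulfoxide flags is therefore
  exact by construction;
* codons are drawn uniformly among synonyms (mining is codon-agnostic, so
  a GC-content model would add nothing testable);
* MS2 spectra contain only the diagnostic losses implied by the planted
  modifications plus random fragments — no b/y ladder. Passing tests show
  the loss detector and the matching logic are correct, not that the
  package can interpret real fragmentation spectra;
* everything is a pure function of `(seed, config)`; the MS noise stream
  is seeded at `seed + 1` so peak error is independent of library
  composition.

Real data differ in ways the simulator does not attempt: correlated mass
errors, isotope envelopes, co-eluting isobars, chimeric amplicons and
sequencing errors in the clone library. Results on synthetic data bound
what the pipeline can do when its assumptions hold.

## Numerical and scale choices

The test suite and the benchmark script use deliberately modest problem
sizes — 20-precursor libraries, 40-clone FASTA inputs, 1000-sequence motif
oracle sweeps, formula-search oracle bounds ≤ 12 per element — chosen so
the full suite exercises every code path in a few minutes on one core
while keeping every statistical check comfortably powered. The end-to-end
benchmark (`analysis/03_synthetic_benchmark.R`, seed 42, σ = 5 mDa,
tolerance 20 mDa) recovers 20/20 planted (core, modification) truths as
rank-1 matches.

## Known limitations

* Only protonated ions, z ≤ 3; no adducts, no average masses, no isotope
  envelope simulation.
* The element set is fixed to C/H/N/O/S — sufficient for peptides and the
  modifications modeled here.
* One core per precursor ORF: a single leader match yields the first
  downstream recognition cut only.
* The published mDa deviations quoted for the two CHO candidate formulas
  of the 84.0311 Da adduct do not reproduce from standard constants by
  direct subtraction; the package reports its own signed deltas (−10.0 and
  +26.4 mDa) and treats candidate membership within 50 mDa, not those
  printed deltas, as the reproducible quantity.
* The bridged TLGCMNGTERCLGLP composition contains three sulfur atoms
  (two Cys, one Met), so full ³⁴S labeling predicts a +6 Da nominal shift;
  an observed +4 Da shift is consistent with two labeled sulfurs, which is
  how `infer_atom_count()` reports it. The package exposes both numbers
  rather than forcing agreement.
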