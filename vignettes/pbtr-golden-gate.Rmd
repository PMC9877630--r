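---
title: "Modelling one-pot Golden Gate cloning into the pBTR vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling one-pot Golden Gate cloning into the pBTR vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtrkit)
```

# The system being modelled

The pBTR vectors are plant binary expression vectors engineered for
Golden Gate cloning with a single type-IIS enzyme. The chemistry the
package models is:

* **BsaI cut geometry.** BsaI recognises `GGTCTC` and cuts 1 nt (top
  strand) and 5 nt (bottom strand) downstream of the recognition
  sequence's 3′ end — `GGTCTC(N1)/(N5)` — leaving a 4-nt 5′ overhang
  whose sequence is whatever the substrate carries at that position.
  Internally a cut is a pair of strand cut indices $(t, b)$; the
  overhang is the interval between them, read 5′→3′ on the protruding
  strand. The same representation covers classical enzymes
  (`cut_inside = TRUE`, offsets from the recognition 5′ start), which is
  how HindIII, XbaI, SacI (a 3′-overhang cutter), PmeI (blunt) and the
  other enzymes used to build the vectors are shipped in the built-in
  table.
* **Vector architecture.** Each destination vector carries two tandem
  BsaI sites in *reverse orientation* flanking a bacterial
  PnptII::mScarlet-I cassette. Both recognition sequences sit on the
  excised (cassette-side) fragment, so the linearised backbone carries
  no BsaI site and exposes two *different*, non-complementary 4-nt
  overhangs: `CATC`/`GGAT` for the BTR1 set and `TCTA`/`GAGC` for BTR2.
  Non-self-religation is therefore a property of the construction, and
  the package asserts it for every registry entry.
* **Adapters.** Inserts get their matching sticky ends from constant
  primer 5′ tails, verbatim from the vector registry:
  `NNNN GGTCTC N` + fusion 4-mer. The reverse complement of each
  adapter's 3′-terminal 4-mer equals the corresponding vector overhang —
  an invariant tested row by row.
* **The one-way reaction.** Cycling between 37 °C (digestion) and
  16/12 °C (ligation) re-cuts every species that still contains a BsaI
  site; the correct backbone+insert circle has lost both sites and
  accumulates. The terminal hold decides the end state: 37 °C/10 min
  re-digests anything still cuttable (suppressing empty vectors), while
  4 °C/60 min favours ligation so an insert that was split at *internal*
  BsaI sites can re-ligate intact before collection.

# The species-set simulation

The reaction is simulated as **species-set logic**: the question answered
is *which circular molecules can exist at the end*, not their
concentrations. Molar ratios are annotations driving the planning
advice, never rate constants — the source system's quantitative claims
(colony counts, 90–100% white-colony rates) are wet-lab outcomes that a
desk model cannot and does not predict.

`ligate()` enumerates every distinct circle of at most `max_fragments`
pieces (default 6) in which each junction joins an overhang to its exact
reverse complement. Fragments are species with unlimited copies;
rotationally and reflectively equivalent circles are reported once,
using the lexicographically least rotation of the sequence and of its
reverse complement (Booth's algorithm) as the canonical identity. The
test suite checks this enumeration against a brute-force oracle that
expands the full (species × orientation) cross product.

`simulate_one_pot()` iterates digestion and ligation to a fixpoint:

1. every input molecule is digested; the fragments form the species pool;
2. all circles up to `max_fragments` pieces are enumerated;
3. a circle is **terminal** if it contains no BsaI site, or — under the
   4 °C hold — if every remaining site is an *exact restoration of a
   contiguous stretch of one input molecule* (checked through fragment
   provenance); anything else is re-digested and the loop repeats.

Classification of terminal circles is provenance-based: `desired`
(backbone + one complete insert payload, in order), `empty_vector`
(backbone rejoined with vector-derived stuffer), `cassette_circle`,
`concatemer` (≥ 2 backbones), `chimera` (anything mis-joined, including
the junction-collision products that arise when an insert's internal
overhang matches a vector overhang — the situation the set-switching
rule exists to avoid).

Three modelling decisions deserve justification:

* **4 °C hold admits restored vectors.** The stated purpose of the cold
  hold is to let a linearised insert re-ligate; but the same chemistry
  necessarily allows the excised cassette to rejoin its backbone. The
  simulator therefore reports such re-formed (empty) vectors as terminal
  under the 4 °C hold — consistent with the reddish-pink
  non-recombinant colonies actually observed under that program —
  rather than special-casing inserts only.
* **Re-digestion does not propagate fused species.** Cutting a
  concatemeric circle at its BsaI sites can produce pieces spanning
  ligated junctions (e.g. backbone–insert–backbone). Within the
  `max_fragments` bound, every circle such a piece could form is already
  enumerated from its elementary pieces, because the enumeration
  explores all orderings; admitting fused species to the pool only
  re-derives the same circles while making the pool grow without bound.
  Re-digestion therefore re-admits only fragments that are contiguous
  slices of one source molecule. This also guarantees the fixpoint is
  reached within the documented iteration bound (total sites + 2).
* **Blunt joins are off in the one-pot enumeration.** T4 ligase joins
  blunt ends far less efficiently than cohesive ends, and the only blunt
  ends in a pBTR pool are PCR amplicon termini destined to be cut off.
  Classical `subclone()` (used to replay vector-construction steps, some
  of which are genuinely blunt/sticky mixtures) does support blunt–blunt
  junctions; a blunt end facing a sticky end is an error either way.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| protective bases | `CAGT` | the `NNNN` primer 5′ terminus; only "four protective bases" is specified, so a fixed default keeps outputs deterministic (configurable) |
| spacer base | `A` | the single `N` in `GGTCTCN`; chemically arbitrary |
| gene-specific length | 18–28 nt | shortest length whose Wallace-rule (2AT+4GC) Tm reaches 55 °C, else 28; only the 18–28 window is specified, and the deliberately simple Tm rule is documented in `wallace_tm()` |
| molar ratio | 1:1 | raised to 3:1 (range 3–5:1 reported) when an internal site yields a palindromic overhang, which can self-ligate whatever the set |
| terminal hold | 37 °C/10 min | switched to 4 °C/60 min iff any insert carries an internal BsaI site |
| cycle presets | 16 °C step 3 or 5 min | both published variants ship (`pbtr_program(variant=)`); they are equivalent for species-set simulation |
| `max_fragments` | 6 | enumeration bound; the real constructs never exceed backbone + 1 insert (+ insert sub-fragments) |

The forward overhang of the BTR1 overexpression vectors is `GATG`, whose
`ATG` may or may not be intended as the insert's start codon; the tool
reproduces the published adapters literally and leaves the insert's own
initiation context untouched.

# What the synthetic data emulates — and what it does not

`generate_fdi()` produces uniform-random fragments with an exact number
of planted BsaI sites (`GGTCTCA` + chosen overhang motifs, accidental
sites scrubbed), emulating the three site architectures of the real
cloning targets: none (AtMyb75-like), two internal sites
(GUSPlus-like), and an internal site with a palindromic overhang
(GmbHLH293-like). `mock_vector()` builds a minimal circular destination
vector with the authentic junction geometry of any registry entry and a
synthetic stand-in for the PnptII::mScarlet-I cassette; full pBTR
sequences are not redistributed, and `synthetic_egfp()` is a
deterministic stand-in ORF used only for fusion-frame arithmetic.

A green test therefore establishes the *combinatorial* correctness of
cut geometry, overhang pairing, product enumeration and classification —
not enzyme kinetics, ligation efficiency, transformation yield, base
composition biases of real genomes, or anything about expression in
plants. Real sequences bring features the generator does not emulate:
repeats, extreme GC, methylation (ignored by the model), and star
activity (out of scope).

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GenBank's 1-based
  inclusive convention applies only at the I/O boundary.
* Ambiguity codes are legal in records but any cut whose overhang window
  touches a non-ACGT base is an error — overhang identity must be
  concrete.
* Two cuts with overlapping windows (possible in pathological synthetic
  input) are an error: no single-molecule outcome is defined.
* A type-IIS site whose cut window falls off the end of a linear
  molecule is physically uncuttable and is skipped.
* An uncut circular record is returned intact, flagged `uncut`, by both
  `digest()` and `restriction_map()`.
* Fragment lengths are measured on the top strand between top-strand cut
  positions, so they always sum to the parent length and circular
  products conserve length exactly.
* Features fully contained in a retained interval travel through
  digestion and ligation; split features are dropped with a warning.

# Known limitations

* Species-set logic cannot rank product abundances; it reports which
  colonies *can* arise, matching the screening logic, not how many.
* Registry vectors ship as specifications (adapters, overhangs, markers);
  sequence-level work runs on mocks unless the user supplies the real
  GenBank files (e.g. from Addgene), which is also why the two
  restriction-fragment checks that need the full intermediate vectors
  (3846/3851 bp) are not reproduced offline.
* The p-SBTR1/2 entries have no published adapter row; the registry
  assumes the set-default overexpression adapters for them.
* The GenBank parser handles the flat-file subset the package writes
  (simple and complemented locations with labels); exotic location
  operators (`join`, `order`) are not reconstructed.
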