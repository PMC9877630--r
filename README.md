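# pbtrkit

In-silico Golden Gate cloning with the pBTR plant binary expression
vectors.

## The problem

The pBTR series is a family of plant binary expression vectors (for
overexpression, promoter analysis and protein subcellular localisation)
built for one-step Golden Gate cloning with a single type-IIS enzyme,
BsaI, and T4 ligase. BsaI recognises `GGTCTC` and cuts outside its
recognition sequence — `GGTCTC(N1)` on the top strand, `(N5)` on the
bottom — leaving programmable 4-nt 5′ overhangs. Each vector carries two
tandem BsaI sites in reverse orientation flanking a
PnptII::mScarlet-I screening cassette, so that digestion releases a
backbone with two different, non-complementary sticky ends (set BTR1:
`CATC`/`GGAT`; set BTR2: `TCTA`/`GAGC`). The insert is PCR-amplified with
adapter-tailed primers (`NNNN GGTCTC N` + 4-nt fusion sequence) whose
overhangs complement the backbone, and the whole mix is cycled through
digestion and ligation temperatures in one tube. Correct products lose
the BsaI sites and become immune to re-digestion — a one-way reaction —
while colonies still carrying the cassette stay reddish-pink and
recombinants turn white.

`pbtrkit` models this system end to end for anyone planning or debugging
such a cloning step: type-IIS and classical restriction digestion into
sticky-ended fragments, exhaustive enumeration of circular ligation
products, the one-pot digestion–ligation fixpoint (including inserts
with internal BsaI sites and multiplexed reactions), adapter/primer
design from the built-in registry of all pBTR vectors, colony-colour
prediction, and restriction-map screening. A synthetic-fragment
generator and mock vectors make the whole toolkit runnable and testable
with zero downloads.

## Worked example

Clone a synthetic 900-bp fragment (no internal BsaI site) into a mock
pK35BTR1:

```r
library(pbtrkit)

vec  <- mock_vector("BTR1", seed = 3)       # circular mock destination vector
fdi  <- generate_fdi(900, 0, seed = 7)      # insert, no internal BsaI site
pair <- design_primers(fdi, "pK35BTR1")
pair
#> <primer_pair> for synthFDI_L900_n0_seed7 on pK35BTR1
#>   F: 5'-CAGTGGTCTCAGATGAGTTTAGATGTTATGTCTAGC-3' (gene-specific Tm 56 C)
#>   R: 5'-CAGTGGTCTCAATCCTCACAAAATATGTCGGGTCC-3' (gene-specific Tm 58 C)
```

The forward primer reads: 4 protective bases (`CAGT`), `GGTCTC`, a 1-nt
spacer, the `GATG` fusion 4-mer (reverse complement of the vector's
`CATC` overhang), then 18–28 gene-specific bases sized to a Wallace-rule
Tm of 55 °C.

```r
rx <- plan_reaction(fdi, vec)               # PCR + reaction planning
rx$program
#> <reaction_program> 10 cycles of [37 C/3 min, 16 C/3 min, 12 C/2 min]; hold 37 C/10 min

products <- simulate_one_pot(rx)
product_table(products, bsai())[, c("klass", "length", "n_fragments", "sites")]
#>        klass length n_fragments sites
#> 1    desired   2908           2     0
#> 2 concatemer   5816           4     0
#> 3 concatemer   8724           6     0
```

With the 37 °C/10 min terminal hold (used when the insert has no
internal site) every terminal species is BsaI-free: the desired
backbone+insert circle and backbone/insert tandem concatemers. No empty
vector survives — the backbone's `CATC`/`GGAT` ends cannot re-ligate.

```r
d <- Filter(function(p) p$klass == "desired", products)[[1]]
predict_colony(vec, vec)
#> <colony_prediction> reddish_pink (intact PnptII::mScarlet-I cassette present; bright red under green excitation)
predict_colony(d$record, vec)
#> <colony_prediction> white (cassette absent or disrupted; no red fluorescence)

screen_by_digest(d$record, list("HindIII", "XbaI"),
                 expected = c(500, 2408), tolerance = 20)
#> <screen_report> PASS
#>  expected observed delta match
#>      2408     2408     0  TRUE
#>       500      500     0  TRUE
```

Inserts with internal BsaI sites work the same way: `plan_reaction()`
switches the terminal hold to 4 °C/60 min so the insert split at its own
sites re-ligates intact, `select_vector_set()` checks whether any
internal overhang collides with a set's junctions (and flags palindromic
overhangs, which call for a 3–5:1 insert:vector molar ratio), and
`simulate_multiplex()` handles several inserts sharing one adapter pair
in a single tube.

## Command line

A thin CLI is installed with the package:

```sh
pbtr=$(Rscript -e 'cat(file.path(find.package("pbtrkit"), "exec", "pbtr"))')
Rscript "$pbtr" design   --fdi insert.fa --vector pK35BTR1 --out out/
Rscript "$pbtr" verify   --plasmid clone.gb --enzymes HindIII,XbaI --expect 500,2408 --tolerance 20
Rscript "$pbtr" fixtures --out fixtures/ --seed 1
Rscript "$pbtr" simulate --config reaction.json --out products/
```

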