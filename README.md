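# rnachord

Circular chord diagrams that unite an RNA's minimum-free-energy (MFE)
secondary structure with its full base-pair probability ensemble in a single
image, plus a pairwise-comparison pipeline for short RNA (or DNA) sequences.

Predicted RNA secondary structures are conventionally inspected through two
separate pictures: a planar graph or arc diagram of the single MFE structure
and a dot-plot of Boltzmann base-pair probabilities. `rnachord` is for
biologists and bioinformaticians who need to read both at once and to
compare two sequences — e.g. a wild-type and a variant — structure against
structure. It draws each sequence as a circle: an outer ring of
colour-coded, letter-labelled bases, and an inner layer of chords, one per
base pair with ensemble probability above a cutoff. A chord's colour and
thickness encode its probability in five 0.2-wide bins (thin blue = weakly
supported, thick dark orange = strongly supported, thickness `2k+1` for bin
`k`), and the MFE pairing is overlaid last in dark red. A two-panel
comparative view bolds the nucleotide differences inferred from a
Smith–Waterman local alignment, and a statistics report counts shared and
differing base pairs through the alignment mapping — which is what makes
sequences of unequal length comparable.

Folding is done either by the self-contained simplified engine — Nussinov
interval dynamic programming for the MFE plus McCaskill inside–outside
recursions for pair probabilities, over a three-parameter pair-energy model
(GC −3, AU −2, GU −1 model units, minimum hairpin size θ = 3, Boltzmann
weight `exp(−e·310.15/(273.15+T))`) — or by any RNAfold-compatible external
folder found on the `PATH`, whose text output and PostScript dot-plot
(`i j √p ubox`) files the package parses. Internal MFE values are in model
units by design; kcal/mol values come from the external backend.

## Worked example

```r
library(rnachord)

f <- fold("GGGAAACCC")          # internal backend, 37 °C
f
#> <fold_result> seq (9 nt, internal backend, T = 37 C)
#> GGGAAACCC
#> (((...))) (-9.00 model units)
#> 3 MFE pairs, 9 base-pair probability entries

tidy(f)
#> # A tibble: 9 × 4
#>       i     j       p is_mfe
#>   <int> <int>   <dbl> <lgl>
#> 1     1     7 0.00169 FALSE
#> 2     1     8 0.0694  FALSE
#> 3     1     9 0.817   TRUE
#> 4     2     7 0.0694  FALSE
#> 5     2     8 0.749   TRUE
#> 6     2     9 0.0694  FALSE
#> 7     3     7 0.817   TRUE
#> 8     3     8 0.0694  FALSE
#> 9     3     9 0.00169 FALSE
```

The three MFE pairs (1–9, 2–8, 3–7 — the `(((...)))` hairpin, −9 model
units) carry ensemble probabilities of 0.75–0.82: the hairpin dominates the
Boltzmann ensemble but alternative registers (e.g. pair 1–8 at p ≈ 0.07)
retain visible support — exactly the information a chord plot shows that an
MFE-only drawing hides.

```r
write_svg(render_chordplot(f), "hairpin.svg")   # the chord diagram
autoplot(f)                                     # quick ggplot2 view

# full pairwise pipeline: fold all records, compare two, bundle everything
bundle <- run_pipeline(make_fixture_fasta(3, c(30, 50), seed = 5),
                       pipeline_config(select = c("fixture_01", "fixture_03"),
                                       output_dir = "out"))
glance(bundle$report)    # shared/differing pairs, alignment score, ...
```

The bundle directory holds, per sequence, a dot-bracket fold file and a
chord-plot SVG, plus the two-panel comparison SVG, plain-text and key-value
reports, the alignment text and a deterministic `bundle.zip` of all of it.
The same pipeline is available from the shell:

```sh
rnachord input.fa --out results --temp 37 --select wt,mutant --backend external
```

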