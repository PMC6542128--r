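---
title: "Models and methods behind rnachord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rnachord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnachord)
```

# The problem

A predicted RNA secondary structure is usually shown twice: once as a planar
graph or arc diagram of the single minimum-free-energy (MFE) structure, and
once as a dot-plot of the full base-pair probability ensemble. Reading the
two side by side is tedious, and comparing two sequences that way is worse.
`rnachord` draws both in one circular chord diagram -- an outer ring of
colour-coded bases, an inner layer of arcs whose colour and thickness encode
the Boltzmann probability of each pair, and the MFE pairing overlaid in dark
red -- plus a two-panel comparative view for a pair of sequences with their
nucleotide differences in bold.

# The folding model

## Internal engine

The self-contained engine scores a nested (pseudoknot-free) structure $S$ as
the sum of independent pair energies,

$$E(S) = \sum_{(i,j) \in S} e_{ij}, \qquad
  e_{ij} \in \{e_{GC} = -3,\; e_{AU} = -2,\; e_{GU} = -1\}
  \text{ (model units)},$$

with a minimum hairpin size $\theta = 3$ (every pair must satisfy
$j - i > \theta$, i.e. enclose at least three unpaired bases). This is a
deliberate simplification: there are no stacking, loop or dangle terms, so
internal MFE values are in model units and are **not** comparable to
kcal/mol values from a thermodynamic folder. What the simplification buys is
exact testability -- every routine is validated against exhaustive structure
enumeration, which a full nearest-neighbour model would make impractical.
When physical energies matter, the external backend (any RNAfold-compatible
folder on the `PATH`) is a drop-in replacement and reports kcal/mol.

The MFE structure is found by interval dynamic programming over
$E(i,j) = \min\big(E(i,j-1),\ \min_k E(i,k-1) + e_{kj} + E(k+1,j-1)\big)$,
with a deterministic traceback: pairing beats leaving $j$ unpaired on ties,
and the smallest pairing partner $k$ wins. Determinism matters because the
rendered SVG is specified to be byte-reproducible.

## Ensemble probabilities

The partition function follows the McCaskill inside recursion

$$Q(i,j) = Q(i,j-1) + \sum_{k} Q(i,k-1)\, w_{kj}\, Q(k+1,j-1),$$

where $w_{ij} = \exp(-e_{ij}/kT_{rel})$ is the Boltzmann weight of a pair,
and the outside pass distributes each pair's exterior weight either through
the unpaired exterior or through every admissible enclosing pair. The pair
probability is the total weight of structures containing $(i,j)$ divided by
$Q$. Both passes are compiled (Rcpp); the outside pass iterates enclosing
pairs in order of decreasing span so each probability is available before
any pair nested inside it is processed.

## Temperature

Temperature enters only through the relative thermal factor
$kT_{rel} = (273.15 + T)/(273.15 + 37)$, so a pair of energy $e$ weighs
$\exp(-e)$ at 37 °C and every weight shrinks toward 1 as $T$ rises. There is
no enthalpy/entropy decomposition; the model melts structures qualitatively,
which is exactly the behaviour needed to visualise thermal transitions of
bi-stable RNAs. For a sequence admitting a single pair of energy $e$ the
pair probability has the closed form $P = w/(1+w)$ with
$w = \exp(-e \cdot 310.15/(273.15+T))$, which the tests verify exactly and
use to confirm strict monotone melting between 25 and 75 °C.

## Numerical safety

Inputs are capped at 200 bases at the pipeline level, so at most 100 pairs
fit in a structure. The largest attainable Boltzmann weight of a structure
is then $\exp(100 \cdot 3 / kT_{rel}) < 10^{160}$ even at 0 °C, far below
double-precision overflow ($\sim 10^{308}$); the partition function over at
most $\sim 3^{200}$ structures stays finite in practice and an explicit
guard raises an error should $Q$ ever become non-finite. Plain doubles are
therefore used throughout -- no log-space or rescaled arithmetic, which
keeps the inside/outside code straightforward and exactly testable at
tolerance $10^{-9}$ against enumeration.

## Structure-level filters

`--noLP` (no lonely pairs) and `--noClosingGU` are implemented in the
internal engine as post-hoc filters on the MFE structure only: pairs with no
stacked neighbour (respectively GU pairs at a helix end) are removed
iteratively until stable. The probability matrix is left untouched -- a
documented limitation; the external backend applies both constraints inside
the folder itself, affecting the ensemble too. G-quadruplexes and circular
molecules are not modelled internally at all: requesting them with the
internal backend is an error, never a silent approximation.

# Alignment and difference highlighting

Two sequences are compared through a Smith–Waterman local alignment with
linear gap costs (+2 match, −1 mismatch, −2 per gap position). A dedicated
local aligner replaces a multiple-alignment tool here because only two
sequences are ever aligned, and the alignment's sole job is to transfer
highlight positions and map base pairs between coordinate systems -- the
absolute score is incidental, so simple hand-checkable parameters were
preferred. The traceback is deterministic (first maximum in row-major
order; diagonal, then up, then left on ties).

A position is highlighted as a difference when it sits in a mismatch
column, sits opposite a gap, or lies outside the locally aligned span of
its own sequence. The third rule is a design choice for a case the source
material leaves open: unaligned flanks are flagged so that a local
alignment covering only part of a sequence cannot hide genuinely differing
ends. Base-pair sharing is likewise computed through the alignment mapping
(pair $(i,j)$ is shared when both endpoints map to non-gap positions that
are paired in the other structure), which is what makes sequences of
unequal length comparable at all.

# Visual encoding

* Probability bins: bin $k$ covers $[0.2k,\, 0.2(k+1))$ for $k < 4$ and
  $[0.8, 1.0]$ for $k = 4$. Bin boundaries are half-open low-side by
  decision so that each probability lands in exactly one bin and 1.0 is
  included.
* Each bin fixes both the arc colour (blue → light blue → green → orange →
  dark orange) and the stroke thickness $2k + 1 \in \{1,3,5,7,9\}$ -- a
  deliberately redundant encoding, readable in greyscale and at small
  sizes. The default hexes are configurable; the contract is ordering and
  distinctness, not the specific values.
* MFE arcs are drawn dark red, after (hence on top of) all probability
  arcs, keeping the bin thickness of their own probability. The probability
  arc underneath an MFE pair is *not* suppressed, so ensemble support under
  the MFE pairing stays visible.
* Arcs below the display cutoff (default 0.01, configurable) are omitted,
  mirroring how dot-plot files themselves truncate tiny entries.
* Chords are quadratic Béziers whose control point is pulled from the chord
  midpoint toward the centre by $f = \mathrm{span}/n$: short-range pairs hug
  the rim, long-range pairs sweep through the middle, so helices read as
  parallel bundles.
* An 8° gap at 12 o'clock separates positions $n$ and 1, so the circular
  drawing is not mistaken for a circular molecule. Position ticks appear at
  1, every 10th position, and $n$.
* The renderer emits SVG text directly with fixed element ordering and
  fixed 4-decimal coordinates, so identical inputs give byte-identical
  files; `autoplot()` offers a ggplot2 view for interactive sessions.

# The synthetic fixtures

`make_fixture_fasta()` emulates the package's target inputs: short
(≤ 200 nt) sequences with at least one clear stem-loop. Each record plants a
GC-biased stem of 4–8 pairs (with occasional GU wobble) around a loop of
4–8 bases and pads with uniform random flanks. This guarantees a non-trivial
MFE structure plus realistic spurious pairing from the flanks. What it does
*not* emulate: multi-branch architectures of natural ncRNAs, biased
dinucleotide composition, or kcal/mol-scale energetics -- so green tests
certify algorithmic correctness and pipeline reproducibility, not biological
accuracy of the simplified model on real molecules.

# Problem sizes and determinism in the test-suite

The suite validates the engine against exhaustive enumeration on 200 random
sequences of 5–14 nt (enumeration is exact there; the 18-nt cap on the
enumerator avoids combinatorial blow-up), the aligner against brute-force
substring enumeration on 100 pairs of length ≤ 8, and round trips on 500
random structures up to 150 nt. All stochastic tests run under fixed seeds.
These sizes were chosen so the entire suite completes in well under a
minute while still exercising every recursion branch.

# Known limitations

* Internal energies are model units; never compare them to kcal/mol.
* No pseudoknots, no G-quadruplexes, no circular folding in the internal
  engine; `dangles` is passed through to the external folder and otherwise
  ignored.
* `--noLP`/`--noClosingGU` do not reshape the internal probability matrix.
* The external-backend parser reads the standard dot-bracket alphabet; the
  extended annotations emitted for G-quadruplex or circular folds are not
  parsed.
* One comparison pair per run; multiple sequence alignment is out of scope.
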