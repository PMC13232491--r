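---
title: "Snail plots and snail scores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snail plots and snail scores: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snailplot)
```

## The model

A snail plot is a polar presentation of an assembly's scaffold length
distribution. Scaffolds are sorted by length (descending, ties kept in
input order for determinism) and laid end-to-end along a cumulative-span
axis that is wrapped clockwise around a circle starting at 12 o'clock. The
circle is drawn as a polygon with `segments` sides (default 1000); each
side is one summary bin of width `max_span / segments` bases of cumulative
span. Within a bin the plot summarises all scaffolds whose half-open
`[start, end)` interval intersects the bin's half-open interval — half-open
on both sides so that no base is counted twice at a boundary.

Per bin the package records the minimum and maximum overlapping scaffold
length, the unweighted mean/min/max of the per-scaffold GC proportion
(GC / (GC + AT)), the mean per-scaffold N fraction, and the cumulative
scaffold count. Two of these feed a documented ambiguity: the drawn radial
value is the *minimum* overlapping length (the conservative choice — the
shading never overstates contiguity), while the maximum is retained in the
statistics export for consumers who prefer the other reading.

The radial axis is scaled to the longest scaffold (or a larger configured
or reference-derived maximum) under one of three scale functions: linear
(default), square-root, or log10 with sub-base lengths clamped to zero.
Badge mode forces the linear scale, since the visual cue distinguishing
scale functions (the gridline spacing) is illegible at badge sizes.

### Base classification

Every base is classified case-insensitively into GC, AT, or N. IUPAC
ambiguity codes other than N, and gap characters, are counted as N. This
is a policy, not a community standard: the score's premise is that only
unambiguous ACGT bases carry assembly information, so any non-ACGT symbol
is treated as missing information. The counts always satisfy
`gc + at + n = length`, and zero-length records are rejected because their
composition proportions are undefined.

### The snail score

With scaffold lengths $L_i$, span $S = \sum L_i$, ACGT counts
$A_i = L_i - N_i$ and longest scaffold $L_{max}$:

$$\mathrm{auN} = \frac{\sum L_i^2}{S}, \qquad
  \mathrm{auN}_{adj} = \frac{\sum A_i^2}{S}, \qquad
  \text{snail score} = \frac{\mathrm{auN}_{adj}}{L_{max}}.$$

The denominator of the adjusted auN is deliberately the full span
*including* Ns, and the score divides by the longest scaffold *including*
Ns. This choice is pinned by an oracle test: on an assembly with a uniform
N fraction $f$ per scaffold, the adjusted/unadjusted ratio is $(1-f)^2$
under the full-span denominator but $(1-f)$ under an ACGT-sum denominator.
The published Nelumbo nucifera ratio (adjusted 91.26 / unadjusted 119.46
at roughly 13% N) matches $(1-f)^2$; the test suite asserts both that the
implementation lands in the $(0.87)^2 \pm 0.01$ band and that the
ACGT-denominator alternative falls outside it.

Nx values use an inclusive threshold (cumulative length $\ge x\%$ of span,
first scaffold in descending order), with a $10^{-9} S$ tolerance
absorbing binary rounding of $x/100 \cdot S$ at exact boundaries.

### Expected-size corrections

Given an expected genome size $G$ and expected longest scaffold $C$
(explicit values, or the span and longest scaffold of a reference
assembly; explicit values win when both are supplied), with
$r_G = S/G$ and $r_S = L_{max}/C$:

* clamped: $g = \text{base} \cdot \min(1, r_G)$,
  $gs = g \cdot \min(1, r_S)$;
* absolute: $ag = \text{base} \cdot f(r_G)$, $ags = g \cdot f(r_S)$ with
  $f(r) = r$ if $r \le 1$, else $1/r$.

Note that $ags$ chains from the *clamped* $g$, not from $ag$. This is the
only chaining consistent with the published correction table: for the
mouse example (base 0.683, spans 2771.0/2731.3 Mb, longest 200.1/206.8
Mb) it yields $ags = 0.683 \times 200.1/206.8 = 0.661$ as printed, whereas
chaining from $ag$ would give 0.651. The same source contains a prose
sentence attributing 0.661 to the $ag$ variant; the table is
arithmetically self-consistent ($ag = 0.683 \times 2731.3/2771.0 =
0.673$) and the prose is treated as a typo.

Scores are stored at full precision and rounded only for display (3
decimal places in terminal and on-plot output).

## Rendering

The SVG canvas is 1000 by 1000 units with the plot centered at (500, 500)
and radius 400. The radius budget — cumulative count region in 0–0.25 of
the radius, scaffold lengths in 0.25–0.85, composition track in 0.85–1.0 —
is invented plumbing; nothing in the score depends on it. The count axis
is log10 with count 1 at the outer edge of its band and
$10^{\lceil \log_{10}(\text{count}) \rceil}$ at the center, with white
gridline circles at each power of ten from 10 up to the scaffold count.
The N50/N90 overlays sweep exactly 50% and 90% of the assembly's swept
angle at the radius of the N50/N90 length; the red longest-scaffold
overlay is drawn only when the first bin contains exactly one scaffold,
so fragmented assemblies get no red wedge. In the composition track the
mean N fraction is split as white space equally at both track edges, and
the GC min–max range is drawn as intermediate shades about the GC/AT
boundary. Exact hues are fixed package constants (ColorBrewer-adjacent
hex values in `snail_palette`); they are plumbing, chosen for contrast,
and tests address layers by their stable group `id` attributes rather
than by color.

Rendering is deterministic: all coordinates are formatted with fixed
`sprintf` precision, so identical inputs produce byte-identical SVG. PNG
output rasterizes the SVG via the rsvg package (or an `rsvg-convert`
executable); JSON/YAML outputs carry the full processed statistics
instead of an image, with YAML written at 15 significant digits so that
statistics round-trip within double precision.

## The synthetic-assembly generator

The generator emulates only the statistical structure the statistics
consume: scaffold length distributions, per-scaffold GC levels, and
interspersed N runs. It makes no attempt at biological sequence content
(no repeats, genes, or telomeres), so passing tests demonstrate correct
*computation* on realistic length/composition structure, not performance
on real genomes.

Two profile kinds cover the qualitative regimes seen in public
assemblies:

* **chromosomal** — `chromosome_count` near-equal chromosomes (normal,
  5% relative sd) plus a log-normal short-scaffold tail holding 4% of the
  span by default, mirroring the stepped length curve and small unplaced
  fraction typical of chromosome-level assemblies;
* **fragmented** — heavy-tailed log-normal lengths with `sdlog = 1.5`
  by default. The target scaffold N50 sets the location parameter through
  the length-biased median of the log-normal
  (`meanlog = log(N50) - sdlog^2`), because the N50 of a large sample is
  the median scaffold length weighted by length.

N runs are placed as Poisson-count runs of geometric length (mean 100 b)
to reach an expected `n_run_rate` N bases per kb. The truth record is
tallied from the actually generated bases, not from the sampling targets,
so the end-to-end identity `read_fasta(generate_assembly(p)) == truth` is
exact. All sampling flows from one explicit seed and the RNG state of the
caller is restored, so equal seeds give byte-identical FASTA output.

The canonical `contiguity_profiles()` family used in the directional
quality check spans scaffold N50 targets $10^3$–$10^7$ at a 10 Mb genome:
three fragmented profiles with N-run rates 80/50/30 per kb (8–3% N, the
range seen in scaffolded short-read assemblies) and two chromosomal
profiles (~1.25 Mb chromosomes, then a single chromosome) with few or no
Ns. These parameters were fixed from the realism anchors above; the test
then asserts that snail scores increase monotonically along the family
and that the chromosomal/fragmented kinds separate at 0.6/0.4.

## Problem sizes and numerical choices

Unit tests run on genomes of 20 kb–2 Mb and 50–400 scaffolds; the
directional check generates five 10 Mb assemblies; the auN oracle check
compares the closed form against the brute-force mean of the N(x) step
curve at 1000 grid points on 50 random assemblies of up to 100 scaffolds
(agreement within 0.5%; the residual is the discretisation error of the
step-curve mean). These sizes exercise every code path while keeping the
default suite under a minute of compute for the statistics and a few
seconds for rendering.

Display rounding offers three strategies (half-away-from-zero, toward
zero, away from zero) applied to significant digits for absolute values
and decimal places for percentages; a one-part-in-$10^{15}$ upward nudge
before the floor/ceiling guards against binary representations of exact
decimals truncating one unit low.

## Known limitations

* Coverage- and hit-based dataset fields from full analysis pipelines are
  out of scope; filters operate on the fields the minimal dataset stores
  (length, gc, n, ncount, id).
* Composition values are averaged over whole scaffolds, so a single
  chromosome contributes a flat band; windowed GC tracks are not
  supported.
* Remote sources are fetched over http(s) only.
* The maximum achievable score depends on karyotype: a genome with one
  dominant chromosome caps well below 1 even when assembled
  telomere-to-telomere, so cross-taxon comparisons should consult the
  plot, not just the score.
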