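---
title: "Methods: how dotquilt builds triangular alignment-matrix figures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how dotquilt builds triangular alignment-matrix figures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotquilt)
```

## The procedure

`dotquilt` turns *n* annotated DNA sequences into one figure holding all
`n(n+1)/2` pairwise dot plots, self-comparisons included. The pipeline has
two conceptually separate halves:

1. **Alignment.** Every ordered pair `(i, j)` with `i <= j` (the
   lower-index sequence is the target, so geometry is deterministic) is
   aligned with an external local aligner — minimap2, LastZ or MashMap —
   unless its raw output is already cached in the run directory. The cache
   stores the aligner's own output verbatim, not a re-serialization, so
   reuse is bit-faithful and a rerun on the same directory performs zero
   aligner invocations. Parsers normalize both supported dialects (PAF;
   LastZ "general" tabular) into one record model: 0-based half-open
   coordinates on both sequences, query coordinates on the forward strand,
   a `+`/`-` strand, and a percent identity (PI) in `[0, 100]`.
2. **Visualization.** Records are filtered by length, colored by PI,
   converted to line segments, and drawn into a triangular matrix with
   optional annotation tracks, breakpoint lines and a PI legend, written
   as PNG (raster) and PDF (vector).

A dot-plot segment for an alignment starting at positions `x` (target)
and `y` (query) with spans `l1`, `l2` runs from `(x, y)` to
`(x + l1, y + l2)` for `+` records; `-` records run from `(x, y + l2)` to
`(x + l1, y)`, so the slope sign always equals the strand sign.

## Percent identity

The aligners do not report PI uniformly, so it is derived per dialect:
from PAF as `100 * matches / alignment_block_length` (columns 10/11),
overridden by MashMap's `id:f:` identity tag when present (trusted
verbatim; values at or below 1 are read as fractions); from LastZ general
output as the `id%` field. PI is assumed in `[0, 100]` and validated, not
clamped, at parse time — clamping is a display decision and happens in
styling.

## Orientation relative to the first sequence

Dot plots are easiest to read when homologous regions run along the main
diagonal, so every sequence after the first is shown either forward or
reverse-complemented. The decision rule sums the aligned **target-span bp
per strand** over all alignments of that sequence to the first one and
reverses the sequence when the minus strand carries strictly more. We
deliberately aggregate instead of trusting the single longest alignment:
one spurious long hit should not flip a whole sequence, and for clean
inversions the two rules agree. Ties and sequences with no reference
alignment stay forward (logged as a fallback); there is no transitive
orientation through third sequences, because orientation is defined only
with respect to the reference. A `Strand` value declared in the
configuration always wins.

Reversal itself is pure coordinate algebra: the interval map
`[s, e) -> [L - e, L - s)` applied to the flipped side(s) of every
alignment and to the sequence's annotation intervals, with the record
strand toggling iff exactly one side flips. The map is an involution, which
the test suite exercises as a property (reorienting twice restores the
input exactly, and final strand = original XOR flip_target XOR
flip_query).

## Styling parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `min_len` | 5000 | bp | hide alignments whose longer span is shorter |
| `min_pi`, `max_pi` | 85, 100 | % | PI range mapped onto the colormap; PI outside is clamped to the nearest bound |
| `cmap` | `"rainbow"` | — | colormap; any `grDevices::hcl.colors()` palette also works |
| `reverse_cmap` | `TRUE` | — | flip the colormap direction |
| `single_color` | unset | — | one color for all segments (legend becomes a swatch) |
| `lwidth` | 1 | lines | alignment segment width |
| `transparent` | `FALSE` | — | transparent PNG background (PDF unaffected) |
| `show_bp` | `FALSE` | — | breakpoint lines at alignment starts/ends |
| `bp_color`, `bp_lwidth` | `#7F7F7F`, 0.2 | — | breakpoint line appearance |
| `bp_min_len` | 10000 | bp | length threshold for breakpoint-contributing alignments, independent of `min_len` |

Two choices here were genuinely open and are worth recording. First, an
alignment's "length" for both thresholds is `max(l1, l2)`: the rule is
symmetric in the pair and errs toward showing structure; counts quoted in
figure legends depend on it. The comparison is inclusive (`>=`). Second,
colormap reversal is implemented as evaluating the colormap at `1 - u`
rather than reversing the legend axis, so the legend can keep reading in
PI units left-to-right. PI maps to `u` affinely after clamping:
`u = (clamp(pi) - min_pi) / (max_pi - min_pi)`. Colors are resolved at
styling time, not at draw time, so tests assert on exact hex values
without a graphics device.

## Layout and rendering

Cell `(i, j)` of the upper triangle sits at row `i`, column `j`; the
lower triangle is its transpose. In both modes column `k` carries
sequence `k` on the x axis. Cell extents are proportional to sequence
lengths, and the figure's height/width ratio is chosen so the bp-per-inch
scale is identical on both axes — equal-length sequences always get
equal-size (and diagonal cells square) panels. The default figure width
maps 50 kbp to an inch, clamped to 5–16 in and user-overridable; PNGs
are written at 300 dpi by default.

Annotation strips sit on the outer margin adjacent to each column (above
for the upper triangle, below for the lower), one per sequence, with
intervals drawn black unless the BED `itemRgb` column supplies a color.
Breakpoint lines span only their own cell and are deduplicated per
(axis, coordinate) so shared boundaries are drawn once; they are painted
beneath the alignment segments. Self-cells draw whatever the aligner (or
ground truth) reports, including the trivial full-length identity
diagonal — parsers and renderers do not editorialize.

PDF output has its embedded creation/modification timestamps overwritten
with a fixed epoch (a byte-length-preserving in-place patch, so the
cross-reference table stays valid); identical inputs therefore produce
byte-identical vector files, which the suite checks across a >1 s clock
boundary.

## The synthetic-locus generator

The generator builds each sequence as a concatenation of shared library
blocks — optionally reverse-complemented, point-mutated copies — separated
by random spacers. Substitutions are sampled at distinct positions and
always change the base, so the PI between two copies of a block is an
exact mismatch count, not an expectation; ground-truth alignment records
(one per pair of copies sharing a block, plus a full-length identity
record per self-pair) carry their exact match counts and round-trip
through the PAF writer/parser bit-exactly. The default scenario
(`default_locus_spec()`) emulates the intended use case at desk scale:
five sequences of 70–103 kbp assembled from five blocks of 8–30 kbp, with
a tandem duplication, one inverted block copy, one globally
reverse-complemented sequence, 1 kbp spacers and per-copy divergences of
0–8 %. These sizes keep a full generate–align(cache)–render cycle in the
tens of seconds on one CPU while leaving every block above the default
5 kbp display threshold.

What the generator does **not** emulate: insertions and deletions (all
ground-truth alignments are gap-free, so `l1 = l2`), realistic repeat
families or GC structure, and aligner artifacts such as split or chained
hits. Passing tests on generated loci therefore validate the coordinate
bookkeeping, orientation logic, styling and rendering — not the behavior
of any particular aligner on real repeats; the suite exercises minimap2
separately on generated sequences to cover that interface.

## Degenerate inputs and numerical choices

Empty record sets flow through filtering, styling and layout as empty
primitive lists; a sequence with no reference alignments keeps `+` with a
logged warning; a PAF line with zero block length is skipped with a
warning rather than producing a division by zero; `min_pi >= max_pi` is
rejected at configuration time. Ties in orientation support break to
`+`. Coordinates are validated against sequence lengths at every module
boundary (parse, reorientation, segment building), and violations raise
typed contract errors rather than drawing out of bounds.

## Known limitations

- Orientation is global per sequence; partially inverted sequences keep
  their majority orientation and show the inversion as negative-slope
  segments instead.
- PI from PAF without an identity tag reflects the aligner's
  `matches/block_length` ratio, which for gappy alignments differs from
  gap-compressed identity.
- SAM/BAM input and SVG output are out of scope; LastZ and MashMap are
  supported through their file formats and command templates but are not
  shipped with the package.
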