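# dotquilt

Triangular-matrix dot plots of pairwise local alignments among multiple
annotated DNA sequences.

## What it is for

Comparing a repeat-rich locus — an immunoglobulin gene cluster, a
segmental-duplication block, an inversion region — across several
haplotypes or species means inspecting every pairwise dot plot at once.
`dotquilt` automates that figure: it computes (or ingests) all local
alignments among *n* input sequences, arranges the *n(n+1)/2* pairwise dot
plots (self-alignments included) into a single upper- or lower-triangular
matrix, and writes publication-ready PNG and PDF output with
percent-identity coloring, BED annotation tracks and breakpoint guide
lines. It is aimed at anyone assessing structural variation visually:
duplications, inversions and their boundaries stand out as off-diagonal
and negative-slope segments.

## The model

A dot plot of sequences *S1* and *S2* draws each local alignment of
substrings of lengths *l1* and *l2* as a line segment from *(x, y)* to
*(x + l1, y + l2)*, where *x*, *y* are the alignment start positions in
*S1* and *S2*; reverse-strand alignments get a negative slope. On top of
this, `dotquilt`:

- **arranges** all pairwise plots in a triangular matrix whose cell
  *(i, j)* (*i ≤ j*) compares sequences *i* and *j*, with self-alignments
  on the diagonal; cell sizes are proportional to sequence lengths so one
  bp maps to the same distance everywhere;
- **orients** every sequence relative to the first: a sequence is shown
  reverse-complemented when the minus strand carries more aligned bp to
  the reference than the plus strand (a declared `Strand` column always
  wins); coordinates of its alignments and annotations are rewritten by
  the involution *[s, e) → [L − e, L − s)*;
- **colors** each alignment by percent identity PI, clamped into
  `[--min-pi, --max-pi]` (default 85–100 %) and mapped affinely onto a
  colormap (default `rainbow`, reversed); alignments shorter than
  `--min-len` (default 5 kbp, on the longer of the two spans) are hidden;
- **annotates** with BED intervals drawn as margin rectangles (black
  unless the BED `itemRgb` column says otherwise) and optional breakpoint
  lines at alignment starts/ends (`--show-bp`, with `--bp-color #7F7F7F`,
  `--bp-lwidth 0.2`, `--bp-min-len` 10 kbp defaults).

Alignments come from minimap2, LastZ or MashMap (PAF and LastZ
general-format parsers are built in); every pair's raw aligner output is
cached under the run directory, so reruns re-style and re-render without
realigning.

## Worked example

The package ships a seeded locus generator whose default scenario is five
sequences of 70–103 kbp built from shared blocks, with a tandem
duplication in S2, an inverted block copy in S3, and S4 planted fully
reverse-complemented. Its exact ground-truth alignments can stand in for
aligner output:

```r
library(dotquilt)
locus <- generate_locus_set(default_locus_spec(seed = 1))
paths <- write_locus(locus, "demo_input")
cache <- write_truth_cache(locus, "demo_run")   # stands in for minimap2 output
res <- run_pipeline(list(
  input = paths$config, bed = NULL, out_dir = "demo_run",
  aligner = "minimap2", input_dialect = "config",
  style = render_style(show_annot = TRUE, show_bp = TRUE),
  fig_width = 6, quiet = FALSE))
```

which logs:

```
INFO | input | 5 sequence(s), 10 annotation interval(s)
INFO | align | 15 pair(s): 0 aligner call(s), 15 loaded from cache
INFO | orient | S1: strand + (reference; +0 bp / -0 bp)
INFO | orient | S2: strand + (inferred; +97000 bp / -0 bp)
INFO | orient | S3: strand + (inferred; +42000 bp / -15000 bp)
INFO | orient | S4: strand - (inferred; +0 bp / -77000 bp)
INFO | orient | S5: strand + (inferred; +62000 bp / -0 bp)
INFO | style | 42/42 alignment record(s) pass min_len=5000 over 15 cell(s)
INFO | render | wrote 32 file(s) to 'demo_run'
```

Reading the log: all 15 pairs came from the cache; S4 was recovered as
reverse-complemented (all 77 kbp of its reference alignment are on the
minus strand) while S3's single 15 kbp inverted block was — correctly —
not enough to flip the whole sequence. The 32 files are the combined
matrix (`demo_run/dotquilt.png` / `.pdf`) and one PNG + PDF per pair
under `demo_run/pairwise/`.

The same run works from a shell via the bundled script:

```sh
Rscript inst/cli/dotquilt -i demo_input/config.tsv -o demo_run \
    --show-annot --show-bp
```

`-i` also accepts a combined multi-record FASTA (optionally with
`--bed`); see `Rscript inst/cli/dotquilt --help` for all flags.

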