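---
title: "Track layout and rendering methods in featuretrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track layout and rendering methods in featuretrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featuretrack)
```

# The coordinate model

`featuretrack` models annotations of exactly one nucleotide or protein
sequence per viewer. All coordinates are 1-based and inclusive on both
ends, and every internal algorithm works in this convention; conversion
to pixels happens only at the rendering edge. The choice follows the
way sequence annotations are reported in practice (a domain "spanning
residues 2–10" includes both residues), and it determines the overlap
predicate: two intervals overlap if and only if they share at least one
position. Intervals at 1–5 and 6–9 abut visually but share no position,
so they are *not* overlapping — they stay separate blocks in a collapsed
row and never trigger the expand indicator.

Only the sequence length is stored, never the residue letters: layout
and rendering need positions, not sequence content.

# Collapsed and expanded rows

A row holds all annotations from one source. Because overlapping
annotations drawn naively would hide one another, each row supports two
display modes.

**Collapsed** (the default): the row shows the merged blocks of its
annotations — the minimal set of disjoint intervals whose covered
positions equal the union of the annotations' position sets
(`merge_blocks()`). A row that contains at least one overlapping pair
gets a small plus-box indicator left of its label; in a static SVG the
expansion choice is made at render time (`expanded =` /
`--expand`), the indicator simply marks that more detail exists.

**Expanded**: every annotation gets its own rectangle, stacked on
sub-tracks. Sub-tracks are assigned by greedy first-fit: annotations
are sorted by (start, end, original input order) — a stable sort, so
identical coordinates keep their input order and results are
deterministic across platforms — and each takes the lowest-numbered
sub-track whose previously placed interval it does not overlap.
Interval graphs are perfect, so this greedy scheme uses exactly
`max_depth()` sub-tracks, the maximum number of annotations covering
any single position; no assignment can use fewer. This optimality is
not taken on faith: the test suite compares the greedy track count
against an exhaustive backtracking minimum-coloring oracle on hundreds
of random interval sets.

Duplicate identical intervals are distinct records — two observed
peptides with the same coordinates are still two observations — so each
receives its own sub-track when expanded.

Degenerate inputs: an empty row yields zero blocks and `max_depth()`
0; a single annotation yields one block; expanding a row with no
overlaps is a no-op (logged as a message), since its collapsed blocks
already show every annotation.

# Pixel geometry

Position `p` of a sequence of length `L` maps to the horizontal band
`[label_width + (p-1)·W/L, label_width + p·W/L]` where `W` is
`plot_width`; a block spanning `(s, e)` runs from the left edge of
`s`'s band to the right edge of `e`'s band, so its width is exactly
`(e - s + 1)·W/L`. Marker lines are drawn at the midpoint of their
position's band. The mapping is strictly increasing, position 1 starts
at the plot's left edge and position `L` ends at its right edge.

Multiple viewers on one page share `label_width` and `plot_width` and
must share one sequence length (anything else is an alignment error
listing the offending lengths), which guarantees equal positions render
at equal x across viewers — the property that makes stacked viewers of
different annotation types directly comparable. Coordinates are written
with six decimal places, so cross-viewer alignment is exact at the
10⁻⁶ px level and output is byte-stable.

All pixel defaults (`render_config()`: row height 20 px, row gap 4 px,
label gutter 150 px, plot width 600 px, summary bar 80 px, font 12 px,
indicator 10 px) are this package's choices, sized for a readable
single-column figure; every one of them is overridable per call or via
a flat `key: value` config file, with CLI flags taking precedence over
the file and the file over the defaults.

# Styling, tooltips and links

Colors, tooltips and link targets are produced by a pluggable
`style_rule()` — a set of pure, total functions receiving the
annotation (or summary value, or marker) and its row. Purity matters:
rendering the same spec twice must produce byte-identical SVG, which
the suite asserts.

The default style resolves an annotation's color as: its own `color`
if set; otherwise, if it carries a score, the row's base color shaded
linearly from black (weakest observed score in the row) to the full
base color (strongest), via `shade_color()`; otherwise the base color
directly. The observed-range normalization keeps the model agnostic
about score semantics — scores are unconstrained reals, and turning
them into shades is deliberately the style's job, not the data
model's. A row whose scores are all equal renders at full base color.

Interactivity is rendered statically: tooltip text becomes an SVG
`<title>` child (shown on hover by every major SVG viewer) and a link
target wraps the rectangle in an SVG hyperlink. A merged block covering
several annotations is colored by its first member's style (first in
(start, end) order) and carries a count tooltip instead of a single
member's text; a link is attached only to single-member blocks, where
the target is unambiguous.

# File formats

The generic annotation JSON dialect is the package's interchange
format (`?write_generic_json` documents the schema). Required keys are
`sequenceLength`, `rows`, per-row `label` and `annotations`, and
per-annotation `start`/`end`; everything else is optional and omitted
on write when absent, with fixed key order, so writing is
deterministic and write-then-read is the identity on valid specs.
Unknown keys are ignored with a warning rather than rejected, so
documents written for richer future dialects still load. Validation
failures are reported as data — one record per violated rule with row
and annotation indices — and surfaced with JSON paths (1-based, e.g.
`$.rows[2].annotations[1]`).

The three prediction formats are read by whitespace-tolerant parsers
with `#` comment lines: `.ss2` rows are
`pos aa state coil helix strand` with state C/H/E; `.pc2` rows carry at
least `pos aa register p_score` (register a–g, extra columns ignored);
`.diso` rows are `pos aa state confidence` with state `*`/`.`.
Vendor column layouts vary by program version, so these dialects are
this package's contract; files
that deviate need preprocessing, not silent guessing. Positions must
run contiguously 1..N — a gap is a hard, line-numbered format error,
because a silent gap would shift every downstream interval.

Converter rules: helix/strand annotations score the mean of their own
state's per-residue score (an average confidence for the region);
coiled-coil runs keep residues with p-score ≤ threshold and score the
*minimum* p-score — for p-values lower is stronger, so the minimum
preserves the run's best evidence; disorder runs score mean
confidence. The Paircoil2 threshold defaults to 0.025, the program's
customary cutoff, and is exposed (`--p-threshold`) because filtering
on the p-score is how these predictions are consumed; annotated
residue count is antitone in the threshold, which the suite checks.
Transmembrane/signal-peptide predictions are not parsed from files —
the upstream tool is a remote web service — but such results can be
supplied through the generic JSON dialect.

# Synthetic data

`gen_viewer()` and `gen_format_file()` generate the inputs for tests
and the acceptance script. Both take an explicit integer seed, run
under it, and restore the caller's RNG state, so outputs are
reproducible and no test depends on ambient randomness.

`gen_viewer()` constructs each row from disjoint segments of the
sequence: one segment receives a stack of `k` intervals sharing an
anchor position, the others one interval each, so the row's maximum
depth is exactly `k` by construction — not by rejection sampling. The
first row uses the requested `target_max_depth`, later rows draw
`k ≤ target`, so the viewer-wide maximum equals the target. Scores are
uniform on a configurable range (rounded to 4 decimals so JSON
round-trips are bit-exact), rows get palette colors and coverage-style
summary values, and a subset of annotations carries tooltips and URLs
to exercise those paths.

`gen_format_file()` lays down random state runs (lengths 2–8, after
coalescing same-state neighbors so every truth run is maximal) and
computes the expected annotation intervals and scores directly from
that run structure and the rounded per-residue values exactly as
written — independently of the package's run-length encoder — giving
the converters a ground-truth oracle. Paircoil2 p-scores are kept away
from the threshold (≤ 80% of it inside runs, ≥ 2× outside) so the
truth is insensitive to floating-point comparison at the boundary.

What the generators emulate is the *structure* of annotation data:
overlap depth, run lengths, score ranges, format syntax. They are
statistical fixtures, not biophysics — generated "helices" have no
sequence propensity, disorder does not correlate with composition, and
scores are uniform rather than program-shaped. Passing tests therefore
demonstrate correctness of parsing, layout and rendering on
structurally realistic inputs, not anything about real predictor
behavior.

# Problem sizes and verification

The test and acceptance workloads are sized to make the oracles
airtight while staying quick on one CPU: exhaustive minimum coloring
is compared on 500 random sets of up to 8 intervals (where
backtracking is instant and exact), block merging against per-position
unions on sets of up to 100 intervals over length-500 sequences,
converter truth on 105 generated files across the three formats, and
the JSON round trip on 200 generated specs. The layout suite
additionally cross-checks merging and depth against IRanges
(`reduce(min.gapwidth = 0)`, `coverage()`) as an independent reference
implementation.

# Limitations

* One sequence per viewer; no multiple-sequence alignment model.
* No zooming, no animation, no scripting inside the SVG, and no
  live cross-viewer mouseover highlighting — interactivity is limited
  to what static SVG offers (hover titles, hyperlinks).
* No PNG rasterization; the deliverable is SVG 1.1 text.
* Collapsed blocks show first-member styling only; heterogeneous
  overlapping annotations are only fully visible expanded.
* The format dialects are fixed contracts; vendor-format drift across
  program versions is out of scope.
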