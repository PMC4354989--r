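# featuretrack

Sequence feature annotations — protein domain boundaries, binding sites,
secondary-structure or disorder predictions, observed peptides — are
regions of one nucleotide or protein sequence defined by inclusive
1-based start and end positions. `featuretrack` is an R package and
command-line tool for collecting such annotations from several sources,
laying them out as horizontal tracks over the sequence, and rendering
publication-quality, coordinate-aligned SVG views: position 1 at the
left edge of the plot, the final position at the right, one row per
annotation source, with per-row summary bars, vertical marker lines,
tooltips and hyperlinks baked into the static document.

It is aimed at anyone who needs to disseminate per-sequence annotation
data — e.g. peptide coverage across mass-spectrometry runs next to
secondary-structure, coiled-coil and disorder predictions for the same
protein — without running a genome browser or a scripting runtime: the
output is a standalone SVG 1.1 file.

## The underlying model

Annotations on one row frequently overlap. For inclusive intervals
$a = [s_a, e_a]$ and $b = [s_b, e_b]$, overlap means a shared position:
$s_a \le e_b \land s_b \le e_a$. The package supports two display
modes per row:

* **Collapsed** — overlapping annotations are merged into maximal
  disjoint blocks (the union of their position sets); a plus-box
  indicator marks rows that contain hidden overlaps. Two annotations at
  2–10 and 8–19 collapse into one block spanning 2–19.
* **Expanded** — each annotation is drawn individually on stacked
  sub-tracks assigned by greedy first-fit after sorting by
  (start, end, input order). Interval overlap graphs are perfect, so
  this greedy assignment is optimal: the number of sub-tracks equals
  the maximum coverage depth
  $\max_p\,\lvert\{i : s_i \le p \le e_i\}\rvert$.

Pixel geometry is linear: position $p$ of a sequence of length $L$
occupies the band
$[\,\mathrm{label\_width} + (p-1)\,W/L,\ \mathrm{label\_width} + p\,W/L\,]$
for a plot of width $W$, so multiple viewers of equal $L$ stacked on
one page place equal positions at identical x coordinates.

Inputs are a generic annotation JSON dialect (documented in
`?write_generic_json`) plus three per-residue prediction formats that
are converted to rows by run-length encoding: PSIPRED `.ss2` (VFORMAT;
helix/strand runs, mean state score), Paircoil2 `.pc2` (runs with
p-score at or below a threshold, default 0.025 — lower p-scores mean
stronger coiled-coil evidence; run score is the minimum p-score) and
DISOPRED `.diso` (runs of `*` residues, mean confidence).

## Worked example

```r
library(featuretrack)

spec <- viewer_spec(30, list(annotation_row("run 471",
  list(feature_annotation(2, 10, label = "peptide A"),
       feature_annotation(8, 19, label = "peptide B")),
  summary = summary_value(0.6, label = "coverage"))))

iv <- data.frame(start = c(2, 8), end = c(10, 19))
merge_blocks(iv)
#>   start end n_members members
#> 1     2  19         2    1, 2
assign_tracks(iv)
#> $track_index
#> [1] 0 1
#>
#> $n_tracks
#> [1] 2
max_depth(iv)
#> [1] 2

svg <- render_svg(layout_viewer(spec, expanded = "run 471"))
```

The two peptides share positions 8–10, so the collapsed view shows a
single block from 2 to 19 with the plus-box indicator; expanded, they
occupy two sub-tracks (`track_index` 0 and 1), which is exactly the
maximum depth. The rendered document is plain SVG — the expanded
viewer above begins:

```
<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" ... width="840" height="48" viewBox="0 0 840 48" ...>
  <rect class="background" x="0" y="0" width="840" height="48" fill="white"/>
  <rect class="frame" x="150" y="0" width="600" height="44" fill="none" stroke="gray" .../>
  <text class="label" x="142" y="14.2" text-anchor="end">run 471</text>
  <rect class="indicator" x="4" y="5" width="10" height="10" ...>
    <title>overlapping annotations present</title>
  </rect>
  ...
```

Each annotation rectangle carries its tooltip as an SVG `<title>` child
and is wrapped in an `<a xlink:href=...>` element when a link target is
set; `class` attributes (`block`, `annotation`, `summary`, `marker`,
`indicator`) make the output scriptable downstream.

## Command line

```sh
featuretrack render IN.json [IN2.json ...] -o OUT.svg [--config C] \
    [--expand LABEL]... [--expand-all] [--markers P1,P2,...] [--no-markers]
featuretrack convert IN --format ss2|pc2|diso -o OUT.json \
    [--p-threshold X] [--label TEXT]
featuretrack validate IN.json
```

The script lives at `system.file("cli", "featuretrack", package =
"featuretrack")`. Exit codes: 0 success; 1 `validate` found coordinate
violations; 2 parse/schema/format error; 3 viewers with differing
sequence lengths on one page; 4 parameter misuse (e.g. `--p-threshold`
with a non-pc2 format).

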