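# moleculecloud

Compact cloud diagrams of large compound collections.

Analyzing a large set of molecules — a corporate archive, a screening deck,
a vendor catalogue — almost always ends with someone paging through grids
of structure drawings. `moleculecloud` condenses that into a single image:
the collection is reduced to its most frequent structural cores, and the
cores are drawn as a cloud in which **image size encodes log-frequency**,
in direct analogy with word clouds for text. One glance shows what the
collection is made of; colored boxes can additionally encode the fraction
of bioactive molecules per core, or the dominant protein target class.

## What it computes

* **Scaffolds (Murcko frameworks).** Each molecule is reduced to its ring
  systems plus the linker atoms connecting them; all other substituent
  atoms are pruned (atoms multiple-bonded to the framework, such as a ring
  carbonyl oxygen, are retained by convention). Ring-free molecules are
  represented by their **major chain**: the longest simple heavy-atom
  path, ties broken by heteroatom count. A substituent mode counts
  fragments cut from the scaffold boundary instead (≤ 15 heavy atoms,
  attachment marked `*`).
* **Selection and scaling.** Core frequencies follow a long-tail
  distribution, so displayed sizes interpolate linearly in *log*
  frequency between a minimum and maximum magnification. Benzene — the
  most frequent and least informative scaffold in any large collection —
  is removed by default, like a stop word; the `top_n` (default 200) most
  frequent cores are displayed.
* **Two-pass layout.** A chemistry-free engine places the rectangles
  framing the depictions: items sorted by size, largest in the center,
  each next item fixed at the grid point minimizing an overlap score
  (weighted sum of pairwise overlap areas and center distances); then an
  iterative refinement pass hill-climbs the total score, with slight
  repulsive forces in the canvas corners for an oval look.
* **Rendering.** Depiction goes through a pluggable provider interface
  (`parse` / `canonical` / `extent` / `draw`); an OpenBabel-backed provider
  is included, plus a mock provider used in tests. Output is SVG (primary)
  or PNG.

## Worked example

A synthetic 400-molecule collection ships with the package:

```r
library(moleculecloud)

smi <- system.file("extdata", "synthetic_collection.smi",
                   package = "moleculecloud")
cfg <- run_config(smi, "smiles",
                  spec   = cloud_spec(top_n = 20),
                  layout = layout_config(canvas_width = 1200,
                                         canvas_height = 800),
                  out    = "cloud.svg")
rep <- run_cloud(cfg)
rep$counts
#> $parsed            [1] 400     molecules read and parsed
#> $failed            [1] 0       unparseable SMILES
#> $records           [1] 24      distinct scaffold/chain records
#> $displayed         [1] 20      records in the cloud (top_n)
#> $drawn             [1] 20      records successfully depicted
#> $stop_removed      [1] 1       benzene, suppressed as a stop-structure
#> $singleton_removed [1] 0
#> $below_top_n       [1] 3       records cut by the top-N rule
rep$score
#> $after_greedy       [1] 40828  overlap score after the greedy pass
#> $final              [1] 10977  after hill-climbing refinement
#> $sweeps             [1] 26     refinement sweeps to convergence
#> $final_overlap_area [1] 6380   residual frame overlap (canvas px^2)
```

The 400 molecules collapse to 24 distinct cores; benzene is dropped, the
20 most frequent cores are drawn, and refinement cuts the layout score to
about a quarter of the greedy starting point. Next to `cloud.svg` the run
writes the selected/scaled table (`cloud.tsv`) and a JSON run report
(`cloud.json`) echoing every setting, so any figure can be reproduced from
its report alone.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/moleculecloud build --in mols.smi --format smiles \
    --top-n 200 --width 2000 --height 1400 --color none --out cloud.svg
Rscript inst/scripts/moleculecloud fixtures --scaffolds 150 \
    --molecules 100000 --exponent 1.5 --seed 1 --out fixture.tsv
```

(after installation the script is at
`system.file("scripts", "moleculecloud", package = "moleculecloud")`).

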