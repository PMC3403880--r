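---
title: "Molecule clouds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecule clouds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moleculecloud)
```

## The method

A molecule cloud summarizes a large compound collection the way a word
cloud summarizes a text: the most common structural cores are drawn large,
the rarer ones small, and one glance conveys what the collection is made
of. The pipeline has four stages.

**1. Reduction.** Every molecule is reduced to its *scaffold* (Murcko
framework): the ring atoms plus the linker atoms on paths between rings,
with all other substituent atoms pruned. Ring-free molecules fall back to
their *major chain* — the longest simple heavy-atom path, ties broken by
heteroatom count. Identical cores are aggregated under a canonical SMILES
key, giving a frequency per core. A substituent mode instead cuts every
single bond between a scaffold atom and a non-scaffold atom and counts the
detached fragments (up to 15 heavy atoms, attachment point marked `*`).

**2. Selection and scaling.** Core frequencies in real collections follow
a long-tail (power-law) distribution: a handful of cores are enormously
common, most occur once. Raw counts are therefore useless as direct size
factors; the magnification of a displayed core is interpolated linearly in
*log* frequency between `min_scale` (default 1.0) and `max_scale` (default
3.5). Benzene is removed by default before selection — it is the most
frequent scaffold in essentially every large collection and carries no
information, exactly like a stop word in a text cloud. The display set is
the `top_n` most frequent remaining cores; 100–250 is the useful range
(default 200), of which roughly 30–50 end up large enough to recognize
instantly.

**3. Two-pass layout.** The layout engine needs no chemical intelligence:
it operates on the rectangles framing the depictions.

* *Greedy pass.* Items are sorted by area, the largest is centered on the
  canvas, and each further item is evaluated at every point of a dense
  grid of candidate positions. The placement score is
  `w_overlap * Σ overlap area with placed items +
  w_distance * Σ center distance to placed items`; the item is fixed at
  the scoring minimum (ties keep the first point in row-major scan
  order). Positions whose frame would cross the canvas edge are skipped,
  never clipped.
* *Refinement pass.* Sweeps over the items; each tries the 8 compass
  moves of length `step_size` and accepts the best only if it lowers the
  total score (its pairwise terms plus its corner penalty), so the total
  is non-increasing by construction. A slight repulsion from the four
  canvas corners (`corner_strength / (corner_eps + distance)`) rounds the
  cloud into an oval. When a sweep stalls the step halves, down to 1/8 of
  its initial value, then the loop stops.

**4. Depiction and composition.** All chemistry funnels through a small
provider contract — `parse`, `canonical`, `extent`, `draw` — so any
toolkit can supply depictions. The package ships an OpenBabel-backed
provider (2D coordinates from the toolkit, bonds drawn as line segments,
heteroatoms as element labels) and a chemistry-free mock provider (labeled
boxes) that exercises the full pipeline in tests. Structures are composed
onto a white canvas in ascending area order, so a large structure is never
completely buried; behind each structure an optional rounded box (5%
padding) encodes annotations:

* *activity intensity*: magenta box, opacity equal to the fraction of
  bioactive molecules containing the scaffold (linear; ratio 0 means no
  box);
* *target class*: the box takes a class color (magenta GPCRs, blue
  kinases, red proteases, green other enzymes, brown nuclear receptors,
  yellow ion channels) only if at least 70% of the molecules containing
  the scaffold are active on exactly one class; scaffolds spread across
  classes stay uncolored.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `top_n` | 200 | structures | middle of the useful 100–250 display range |
| `min_scale`, `max_scale` | 1.0, 3.5 | linear magnification | spreads ~30–50 structures into the "instantly readable" size band without letting rank 1 dominate |
| `stop_structures` | benzene | canonical SMILES | ubiquitous, uninformative |
| `w_overlap` | 1 | 1/area | reference weight of the overlap term |
| `w_distance` | `1/canvas diagonal` | 1/length | a full-canvas separation costs about one unit square of overlap; compaction stays gentle |
| `corner_strength` | `1e-5 * diagonal^3` | area·length | "slight" corner forces: a few percent of a typical item overlap near the corners; the cubic scaling keeps the whole score homogeneous under uniform rescaling |
| grid pitch | ¼ median item dimension | length | fine enough that frames can interleave, capped at 200×200 points |
| `step_size` | 2% of diagonal | length | "slightly moved": small against item sizes, halved on stalls |
| `max_iterations` | 500 | sweeps | convergence is far faster in practice (tens of sweeps) |
| `tolerance` | `1e-6 ×` initial total | score | scale-free stall detection |

Magnification multiplies linear dimensions (width and height), not area:
with log-frequency driving the factor, area scaling would compress the
visible dynamic range to the point where the top handful of structures
look alike.

## The synthetic study conditions

The fixture generator emulates what the method actually consumes:

* `generate_powerlaw_fixture()` — aggregated records whose rank-frequency
  curve is `frequency(rank) ∝ rank^(-exponent)` (default exponent 1.5,
  typical of scaffold counts in large databases), totalling exactly
  `n_molecules`, over a built-in library of 48 common drug-like ring
  systems; beyond the library, distinct scaffolds are composed as
  linker-joined ring pairs. Optional annotations: a random activity ratio
  per scaffold, or a dominant target class (clear dominance for ~70% of
  scaffolds, mixed for the rest).
* `generate_molecule_fixture()` — raw molecules built by decorating those
  scaffolds with small substituents, so the reduction stage has real work
  to do and provably recovers the parent distribution.
* `random_acyclic_smiles()` — random heavy-atom trees over C/N/O/S with
  standard valences, for exercising major-chain extraction against
  exhaustive path enumeration.

What these fixtures do *not* emulate: tautomer and aromaticity ambiguity
across drawing conventions, salts and mixtures beyond simple cases,
macrocycles, very large ring assemblies, and the extreme singleton tail of
real databases (50% of scaffolds in a 35-million-compound collection occur
once). Passing tests therefore demonstrate correctness of the reduction,
selection, layout and composition machinery — not robustness to every
registration artifact found in production registries.

## Numerical choices and degenerate inputs

* Ties everywhere are broken deterministically: equal frequencies by
  canonical SMILES (C locale), equal placement scores by the first grid
  point in row-major order, equal major-chain candidates by the
  lexicographically smallest canonical SMILES. Two runs on the same input
  are byte-identical; no stage consumes randomness (the layout seed is
  reserved for optional jitter, off by default).
* `scale_factor` returns the midpoint of the scale range when all
  displayed frequencies are equal (the log interpolation is undefined
  there).
* The corner penalty is regularized by `corner_eps` (1% of the diagonal)
  so it stays finite at the corner itself.
* Refinement accepts only strict improvements, which makes per-sweep
  totals non-increasing exactly, not just approximately.
* Stereochemistry is stripped before canonicalization (the cloud shows
  flat 2D cores, so stereoisomeric scaffolds should aggregate); charges
  and isotopes are preserved; multi-fragment inputs (salts) keep the
  largest covalent fragment.
* Exocyclic multiple-bond atoms (a ring-attached carbonyl oxygen) are kept
  in the scaffold by default, following the established Murcko-framework
  convention, with `keep_exocyclic = FALSE` available for the pure pruned
  framework. The substituent size cutoff counts heavy atoms only; the
  attachment dummy is free.
* Unparseable SMILES never abort a run: they are skipped, counted, and
  reported.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
finish in minutes on one core while still exercising every code path:
collections of 10^2–10^3 raw molecules, aggregated tables up to 10^5
frequency mass over 150 scaffolds, layouts of 100–150 rectangles on grids
of up to 200×200 points, and exhaustive oracles on instances small enough
to enumerate (≤ 12 heavy atoms for paths, ≤ 5 rectangles × 10×10 grids
for placement).

## Known limitations

* Canonicalization and aromaticity perception are the toolkit's; scaffold
  keys from a different toolkit will not match string-for-string.
* The built-in depiction is a skeletal line drawing (no implicit-hydrogen
  labels on terminal heteroatoms beyond the element symbol, no wedge
  bonds); for publication-quality structures plug in a dedicated
  depiction engine through the provider interface.
* Greedy + hill climbing is a heuristic: it converges to a local minimum
  of the overlap score, which is the intended behavior (speed and
  aesthetics), not a global packing optimum.
* Ring-system decomposition, scaffold trees/networks and generic
  carbon-skeleton scaffolds are out of scope.
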