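---
title: "Scanning septin sequences for amphipathic helices and related features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning septin sequences for amphipathic helices and related features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahscan)
```

## Scope and model

Septins are membrane-associated cytoskeletal GTPases built around a
conserved GTPase domain flanked by variable N- and C-terminal extensions
(NTE, CTE). Several sequence features in those extensions and in the domain
itself carry functional signal: membrane-binding amphipathic helices (AHs),
lysine/arginine-rich polybasic stretches in the NTE, a GAP-like arginine
finger in the S3 region that supports G-interface homodimerization, and the
switch-I threonine/serine required for GTP hydrolysis. `ahscan` implements
the corresponding sequence computations as a small, testable toolkit:

1. candidate helical 18-mer extraction from a secondary-structure track,
2. amphipathicity scoring on the helical wheel,
3. reference-anchored GTPase-domain delimitation by global alignment,
4. sliding-window isoelectric-point profiling of the NTE,
5. anchored single-residue classification, and
6. per-group feature-conservation summaries.

Secondary structure, coiled-coil and transmembrane annotations are
*consumed*, never predicted: the package reads PSIPRED-style `.ss2` files
(or a FASTA-like H/E/C states dialect) and plain TSV annotation tables.

## Candidate windows

A candidate is any 18-residue window that is **fully helical** (all 18
states `H`) or **partially helical**: the six residues at each end of the
window are all `H`, while the interior six are unconstrained. This is the
unique reading consistent with the two defining examples — a
`HHHHHHCCCCCCHHHHHH` window qualifies, a `HHHHHCCCCCCHHHHHHH` window does
not — and it deliberately admits helices interrupted by a short loop, a
geometry observed in some membrane-bound AHs. `E` and `C` both count as
non-helical. All overlapping windows are kept at this stage; reduction to a
single hit per protein happens only after domain filtering, because septins
commonly show dense runs of overlapping candidate windows.

## Amphipathicity scoring

Residue `k` (0-based) of a window sits at wheel angle `100k mod 360`
degrees, the canonical rotation per residue of an alpha helix; for an
18-mer the angles are 18 distinct multiples of 20 degrees. With
per-residue hydrophobicities `h_k` (Fauchère–Pliska octanol scale, the
HeliQuest convention; `X` contributes 0):

* the **mean hydrophobic moment** is
  `muH = (1/18) * | sum_k h_k (cos t_k, sin t_k) |`, with the moment
  direction (the *pole*) given by the vector sum;
* the **net charge** is `z = #(K,R) − #(D,E)`; histidine and the termini
  are neutral;
* the **discriminant** is `D = 0.944 muH + 0.33 z`.

A window is called amphipathic iff all three criteria hold:

* **(i)** `D > 0.68`, or (`muH > 0.4` and `z = 0`);
* **(ii)** the hydrophobic *face* — the half-wheel within ±90° of the pole,
  ordered by signed angular offset — contains at least three consecutive
  bulky hydrophobic residues (L, V, F, I, W, M, Y); the ordered face
  `SYALLVT`, for example, qualifies through its `LLV` run;
* **(iii)** the *core* — the 90° sector centred on the pole — contains no
  charged residue (D, E, K, R).

### Numerical choices

Threshold comparisons are exact and strict (no epsilon): a window with `D`
exactly 0.68 fails criterion (i), as does `muH` exactly 0.4. Because the 18
wheel unit vectors sum to zero analytically, hydrophobicities are
mean-centred before the vector sum; this is mathematically a no-op but
makes a uniform-hydrophobicity window yield `muH = 0` *exactly* in floating
point. A moment-vector norm below a relative 1e-12 tolerance is treated as
zero: such a window has no pole, hence no face, and is classified not
amphipathic rather than erroring mid-pipeline. Face and core boundaries
(±90°, ±45°) are inclusive. Only angular *offsets* matter, so the choice of
origin is observationally irrelevant (pinned by a rotation-equivariance
property test).

Two conventions are under-determined by the underlying method description
and are our documented choices: the face is the boundary-inclusive
half-wheel (only the core is defined by the method; the half-wheel is the
standard HeliQuest face heuristic), and "consecutive" in criterion (ii)
means adjacent in the angular ordering of the face. Histidine is treated as
uncharged throughout, the HeliQuest default. Both choices are isolated in
small functions so they can be revised.

## Domain delimitation and hit reduction

The GTPase-domain span of each query is obtained by Needleman–Wunsch global
alignment (BLOSUM62, affine gaps, open 10 / extend 1, via Biostrings) to a
reference record carrying annotated anchor coordinates. The query span is
the image of the reference span's first and last aligned columns; coverage
(fraction of reference domain columns aligned to query residues) below a
configurable floor (default 0.5) flags the projection as unreliable, and a
projection with no aligned domain column at all yields an "all extension"
outcome rather than an error. Candidate windows sharing at least one
residue with the projected span are excluded, and among the remaining
amphipathic windows the one with the largest `D` is marked `is_best` (ties:
smaller start, then fully-helical before partially-helical).

Pairwise alignment to the reference replaces the multiple-alignment step a
corpus analysis would use: it is order-independent, deterministic, and
reproducible one protein at a time. Anchors for real analyses (e.g. the
*S. cerevisiae* Cdc3 GTPase domain) are supplied via a `key = value` config
file; the packaged default anchor is built on a deterministically generated
**synthetic** septin-like record (`synthetic_reference_septin()`), not a
natural sequence.

## Polybasic profiling and anchored residues

The NTE polybasic scan computes, for every full 10-residue window inside
the NTE, the arithmetic mean of per-residue isoelectric points (Lehninger
free-amino-acid values; `X` = 6.0). We read "local average isoelectric
point" as a residue-value average rather than a Henderson–Hasselbalch
whole-peptide pI; the table is swappable, and absolute profile levels shift
with the table while the basic/acidic contrast is robust. `pb_region_call()`
turns a profile into spans by reporting maximal runs of at least 3
consecutive windows with mean pI ≥ 8.0; these thresholds are automation
defaults chosen here (profiles were judged visually in the source
analyses) and are flagged as such in the CLI help.

The arginine-finger and switch-I calls read the query residue aligned to
the anchored reference column: R → `present`, H → `histidine_variant`
(a variant observed in ciliate septins), anything else or a gap →
`absent`; switch-I accepts T *or* S as `active`, since either hydroxyl
residue supports catalysis.

## Summaries

`summarize_feature_conservation()` reports, per phylogenetic group, the
count and percentage of proteins with a best AH call, a coiled-coil
annotation, and a transmembrane annotation (AH positivity is defined on
best hits, i.e. post-filter; pre-reduction positivity is available for
comparison). `venn_partition()` assigns each protein to exactly one of the
eight regions of the AH/CC/TM partition, so region counts always sum to
the protein total.

## The synthetic-fixture generators

`generate_amphipathic_peptide()` builds peptides directly on wheel
geometry: under *strong* segregation, bulky hydrophobics occupy a
160° sector and charged/polar residues the remainder, with charged
residues placed farthest from the sector centre and tuned to a requested
net charge; *none* permutes the same residue multiset, destroying the
angular structure while preserving composition. Calibrated once and then
frozen: strong 18-mers are accepted by the scorer in 100% of 200 seeds,
permuted ones in 9.5% (the residual reflects chance angular clustering of
the 9 bulky residues — real low-complexity sequence would score lower).

`generate_toy_septin()` assembles `NTE ⊕ reference GTPase core ⊕ CTE` with
optional planted features (a K/R 12-mer in the NTE, a strong amphipathic
18-mer in the CTE, a substituted arginine-finger residue) and records the
ground-truth spans. The core is the *reference's own* domain subsequence,
so alignment-based recovery is exercised under the exact anchor used for
projection; its edge residues are deliberately distinctive relative to the
low-complexity flank pool so that the projected boundary has a unique
optimal alignment (with compositionally confusable edges, score-neutral gap
placements make "the" boundary ill-defined at ±1 residue). Flank lengths,
feature placement and residue identities are drawn deterministically from
the seed; regeneration is byte-identical.

What the fixtures do *not* emulate: real secondary-structure prediction
error (tracks are exact by construction), homology between query and
reference beyond the identical core (real septins diverge substantially
from Cdc3), compositional drift of real extensions, and multi-domain
architectures. Passing the recovery suites therefore demonstrates
correctness of the computations and of the plumbing between them — not
field performance of the upstream predictors the toolkit consumes.

## Problem sizes and verification

The test suite verifies every scoring quantity against independent oracles:
a naive per-residue loop for the moment, exhaustive angular enumeration for
face/core membership, a hand-written Gotoh dynamic program for alignment
scores (on random short pairs over a reduced alphabet), and brute-force
predicate evaluation for window extraction. Recovery suites run 50 clean
and 50 mutated (5% core substitution) toy septins for domain projection,
200 seeds each for planted-AH detection and unstructured false-call rates,
50 for polybasic recovery, and all 20 site substitutions for the
arginine-finger call; summary conservation laws are checked over 200
randomized cohorts. These sizes give stable rates while keeping the default
suite fast on a single CPU.

## Worked example

```{r example}
fasta <- system.file("extdata", "toy_septins.fasta", package = "ahscan")
ss <- system.file("extdata", "toy_septins.ss", package = "ahscan")
records <- read_protein_fasta(fasta)
tracks <- read_ss_track(ss, "states")

scan <- find_amphipathic_helices(records, tracks)
scan
scan$calls[scan$calls$is_best,
           c("protein_id", "start", "end", "muH", "z", "D")]

groups <- read_group_map(system.file("extdata", "toy_groups.tsv",
                                     package = "ahscan"))
ann <- read_annotation_table(system.file("extdata", "toy_annotations.tsv",
                                         package = "ahscan"))
summarize_feature_conservation(records, scan$calls, ann, groups)
venn_partition(records, scan$calls, ann)
```

## Known limitations

* The default anchor is synthetic; biological conclusions require a real
  reference anchor supplied via config.
* Criterion (ii)'s face definition and the polybasic thresholds are
  documented conventions, not derived quantities; sensitivity to them is
  not explored automatically.
* The pI profile is a residue-average, not a peptide titration model.
* Corpus-scale figures (thousands of windows across hundreds of septins)
  depend on external predictors and annotation databases that this package
  intentionally does not bundle.
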