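# ahscan

Sequence-feature scanning for septin proteins: detection of candidate
membrane-binding **amphipathic helices** (AHs) from secondary-structure-
annotated protein sequences, **GTPase-domain delimitation** against an
annotated reference, **polybasic-region** profiling of N-terminal
extensions, classification of the GAP-like **arginine finger** and
**switch-I** catalytic residue, and per-group **feature-conservation**
summaries.

Septins are membrane-associated cytoskeletal GTPases whose conserved
GTPase domain is flanked by variable N- and C-terminal extensions (NTE,
CTE). Whether a septin can bind membranes, hydrolyse GTP, or homodimerise
across its G-interface is legible in a handful of sequence features in and
around those extensions. `ahscan` computes them reproducibly for anyone
comparing septins (or septin-like GTPases) across species: evolutionary
cell biologists mapping feature gain/loss over a phylogeny, and anyone who
needs HeliQuest-style amphipathicity calls in scriptable, testable form.

## The scoring model

Residue *k* (0-based) of an 18-residue helical window sits at helical-wheel
angle 100*k* mod 360°. With Fauchère–Pliska hydrophobicities *h<sub>k</sub>*:

- mean hydrophobic moment ⟨µH⟩ = (1/18)·|Σ<sub>k</sub> h<sub>k</sub>(cos θ<sub>k</sub>, sin θ<sub>k</sub>)|,
  with the moment direction defining the *pole* of the hydrophobic face;
- net charge z = #(K,R) − #(D,E), histidine neutral;
- discriminant **D = 0.944·⟨µH⟩ + 0.33·z** (the HeliQuest convention).

A window is called amphipathic iff (i) D > 0.68, or ⟨µH⟩ > 0.4 with z = 0;
(ii) the hydrophobic face (the ±90° half-wheel about the pole, in angular
order) contains ≥ 3 consecutive bulky hydrophobics (L, V, F, I, W, M, Y);
and (iii) the 90° core about the pole contains no charged residue.
Candidate windows are 18-mers that are fully helical, or helical over at
least the six residues at each end (`HHHHHHCCCCCCHHHHHH` qualifies,
`HHHHHCCCCCCHHHHHHH` does not). Windows overlapping the GTPase domain —
projected from a reference anchor by global alignment — are excluded, and
the largest-D amphipathic window per protein is reported as its best hit.

Secondary structure (PSIPRED-style `.ss2` or a FASTA-like H/E/C dialect)
and coiled-coil/transmembrane annotations (TSV) are consumed, not
predicted. See `vignettes/amphipathic-helix-scanning.Rmd` for the full
model description, conventions, and limitations.

## Worked example

Using the packaged toy inputs (three synthetic septin-like records, two of
which carry a planted amphipathic 18-mer in the CTE):

```r
library(ahscan)
records <- read_protein_fasta(system.file("extdata", "toy_septins.fasta", package = "ahscan"))
tracks  <- read_ss_track(system.file("extdata", "toy_septins.ss", package = "ahscan"), "states")

scan <- find_amphipathic_helices(records, tracks)
scan
#> Amphipathic-helix scan
#>   proteins scanned : 3
#>   candidate windows: 2 (2 fully helical, 0 partially)
#>   amphipathic      : 2
#>   GTPase-overlap excluded: 0
#>   best hits        : 2 protein(s)

scan$calls[scan$calls$is_best, c("protein_id", "start", "end", "muH", "z", "D", "face")]
#>   protein_id start end       muH z         D      face
#> 1     toy_s1   382 399 0.6017467 0 0.5680489 YVIYLYYLF
#> 2     toy_s2   364 381 0.6725701 0 0.6349062 LMIYIWVYW
```

Both best hits sit in the CTE (the GTPase domain spans residues 61–360 of
these toys), carry zero net charge and ⟨µH⟩ > 0.4, so they pass criterion
(i) by the uncharged branch; the `face` column shows the angularly ordered
hydrophobic face whose bulky runs satisfy criterion (ii). `toy_s3` has no
helical window at all (and so is scanned but yields no hit).

Group-level conservation and the AH/CC/TM partition:

```r
groups <- read_group_map(system.file("extdata", "toy_groups.tsv", package = "ahscan"))
ann <- read_annotation_table(system.file("extdata", "toy_annotations.tsv", package = "ahscan"))
summarize_feature_conservation(records, scan$calls, ann, groups)
#>   group n n_ah n_cc n_tm pct_ah pct_cc pct_tm bold_ah bold_cc bold_tm
#> 1    6A 2    2    1    0    100     50      0    TRUE    TRUE   FALSE
#> 2     8 1    0    0    1      0      0    100   FALSE   FALSE    TRUE
venn_partition(records, scan$calls, ann)
#>       AH       CC       TM    AH+CC    AH+TM    CC+TM AH+CC+TM     none
#>        1        0        1        1        0        0        0        0
```

`pct_ah` is the percentage of proteins in the group with a best AH call;
`bold_*` flags values above 30, a conventional notability cut for such
tables. The partition assigns each protein to exactly one region, so the
counts sum to the number of proteins.

A command-line interface wrapping the same functions ships as
`inst/scripts/ahscan` (subcommands `find-ah`, `map-domains`, `scan-pb`,
`scan-sites`, `summarize`, `make-fixtures`); run it with `--help` for
usage. Reference anchors for real data are supplied as a `key = value`
config (see `inst/extdata/example_anchor.conf`).

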