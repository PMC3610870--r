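---
title: "Methods: TSS detection, orthology clustering and repeat analysis in nodtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS detection, orthology clustering and repeat analysis in nodtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodtx)
```

# Scope

nodtx re-implements, as a reusable and tested pipeline, the computational
core of a cyanobacterial genome–transcriptome study of the brackish-water,
bloom-forming, dinitrogen-fixing *Nodularia spumigena* type: primary
transcriptome analysis by differential RNA-seq (dRNA-seq), positional
classification of transcriptional start sites (TSS), NtcA-type promoter
motif scanning, a comparative-proteome orthology pipeline, and sequence
utilities for the direct-repeat-flanked DNA elements excised during
heterocyst differentiation. A seeded synthetic-data generator provides
inputs with the statistical structure every stage assumes, so the pipeline
is fully testable without the original sequencing data.

# The TSS model

dRNA-seq enriches 5'-triphosphorylated primary transcripts, so read 5' ends
pile up sharply at genuine TSS while processed or read-through RNA
contributes diffuse coverage. Per contig and strand we keep two integer
tracks: `starts[p]`, the number of reads whose 5' end maps to position `p`
(for a minus-strand read the 5' end is its rightmost aligned base), and
`coverage[p]`, the number of reads overlapping `p`. Duplicate reads are
retained — the detection thresholds are absolute read counts, and the
pile-up *is* the signal. Soft-clipped bases are excluded: a TSS is defined
on the reference.

Detection applies, per strand:

1. **Window sum.** `W(p)` is the sum of `starts` over a centred window of
   `window` nt (default 7, truncated at contig ends). A site requires
   `W(p) >= min_window_reads` (default 280, the published threshold for a
   ~40 M-read library) and `starts[p] >= 1`.
2. **Peak rule.** `starts[p]` must be the maximum of `starts` inside the
   window; ties break toward the 5'-most position on the strand, so a
   plateau yields exactly one site.
3. **Read-through enrichment.** `starts[p]` must be at least
   `(1 + enrichment_factor)` times (default: 50 % larger than) the coverage
   at the first position strand-upstream of the window
   (`p - (window+1)/2` on `+`). Zero upstream coverage passes: a start
   rising out of silence is maximal enrichment.
4. **Close-peak suppression.** Among surviving candidates closer than
   `window` nt apart, the one with more starts wins (ties again 5'-most).

Two numerical choices deserve comment. First, the literal published rule —
starts at a position 50 % larger than the coverage *at that same position*
— is unsatisfiable, because a starting read covers its own first base;
some displaced denominator is unavoidable. Second, we place that
denominator just *outside* the detection window rather than immediately
adjacent to the peak. The adjacent base sees the left tail of the peak's
own positional jitter (with ±1 nt jitter roughly a third of the peak's
reads start one base early and cover it), so an adjacent-base denominator
systematically rejects genuine jittered peaks; the first base outside the
window cannot be covered by any read starting inside the window, so it
measures pure read-through. For `window = 1` the two conventions coincide.
The detector is checked against an exhaustive per-position oracle on
random profiles, and `normalize_per_million` rescales the absolute
threshold for libraries of other depths.

# Positional classification

Against an annotation, each TSS receives exactly one class:

* **gTSS** — same strand, within `upstream_max` nt (default 200) upstream
  of a gene's strand-aware start; offset 0 is allowed (leaderless
  transcripts).
* **iTSS** — same strand, strictly inside the gene body (first base
  excluded).
* **aTSS** — opposite strand, within the gene body extended by
  `antisense_flank` nt (default 0).
* **nTSS** — none of the above: intergenic, candidate non-coding RNA.

Because one position can satisfy several definitions, an explicit priority
order (default `gTSS > aTSS > iTSS > nTSS`) makes the assignment exclusive;
the published class counts sum exactly to the published total, so the
original scheme was also a partition, though its precedence order is not
recorded. The reported gene is the nearest qualifying one (smallest
absolute offset, then lexicographic id), and offsets are signed with
negative values upstream, so a 5' UTR length is simply the negative of a
gTSS offset.

# Promoter motif scanning

NtcA, the global nitrogen-control regulator, binds a spaced dyad
(canonically `GTA-N8-TAC`, with variants such as a `GTG` left box) centred
near position −41 of activated promoters. `scan_upstream()` extracts the
strand-aware upstream window of each TSS (default offsets −60..−20 for the
motif start), matches the dyad IUPAC-aware, and reports both the start
offset and the centre offset, defined as
`start + floor((motif_length - 1) / 2)` — the left-of-centre base of an
even-length motif. Under this convention a 14-nt dyad starting 47 nt
upstream is centred at −41, matching how such sites are conventionally
quoted; since centring conventions differ between tools, both offsets are
reported so users can translate. `N` in the genome matches nothing, so
assembly gaps cannot fake motifs.

# Orthology: HSP merging, filtering, Markov clustering

The comparative-proteome stage consumes all-vs-all BLASTp tabular output
plus per-protein lengths and genome assignments.

**Merging.** High-scoring segment pairs (HSPs) for the same unordered
protein pair are merged: the merged alignment length is the length of the
union of their intervals on one consistent axis — the coordinates of the
lexicographically smaller protein, so both hit directions merge
symmetrically — while merged identity is the alignment-length-weighted mean
of the HSP identities (order-independent), and coverage is the merged
length as a percentage of the longer sequence. Self-hits are dropped and an
e-value pre-filter (default 1e−8, the published BLASTp cut-off) applies.

**Filtering.** Hits covering less than 10 % of the longer sequence are
removed. Then, within the hit group of each protein, the best hit (highest
merged identity; ties by coverage, then partner id) anchors two windows:
hits more than 10 identity points below it, or more than 20 coverage
points below its coverage, are dropped. The published description groups
hits "sharing the same query or subject"; we take the conservative
intersection — a hit must survive in the groups of both of its proteins —
and apply the rule to a fixed point, which makes the operation idempotent
(a single pass is not, in rare configurations where removing a group's
best hit raises another group's coverage anchor).

**Clustering.** The surviving hits define an undirected graph weighted by
merged identity (the quantity this pipeline curates; configurable). Markov
clustering is implemented in-package on sparse matrices: add self-loops
(each node's maximum incident weight, or 1 if isolated), column-normalise,
then alternate expansion (matrix squaring) and inflation (elementwise power
2.0, the canonical default, with renormalisation), pruning entries below
1e−6, until the matrix changes by less than 1e−8 or 200 iterations
(non-convergence warns and returns the current interpretation). Clusters
are the weakly connected components of the converged matrix's nonzero
pattern; proteins without hits become singletons. Node order is
canonicalised, so permuting the input leaves the result byte-identical,
and disconnected components can never merge.

**Categorisation.** Each cluster is assigned to the subset of genomes its
members span; counts of clusters and proteins per subset reproduce a
Venn-style core/shared/unique breakdown, and both totals are conserved.

# Direct repeats and excision elements

During heterocyst differentiation, elements interrupting *nifD*, *hupL*
and (here) *nifH1* are excised by site-specific recombinases acting on
short flanking direct repeats. Three utilities mirror that analysis:
`hamming()` (mismatches between equal-length repeats, case-insensitive),
`count_kmer()` (overlapping occurrences by default, optionally both
strands with palindromes counted once per site — both conventions exist in
the literature and the published genome-wide count does not state one),
and `find_flanking_repeats()`, which scans a margin (default 100 nt)
on each side of an element for equal-length pairs (8–20 nt) within a
mismatch budget and reports only maximal pairs (a pair contained in a
longer reported pair at the same left/right alignment is suppressed).
`N` never matches, so draft-genome gaps cannot create phantom repeats.

# The synthetic world

`simulate_genome()` lays non-overlapping genes on both strands left to
right (lengths 800–1600 nt, gaps 600–1000 nt — compact, bacteria-like
spacing), gives every gene one gTSS at an offset uniform in −150..−20
(typical bacterial 5' UTR lengths), and plants quotas of iTSS and aTSS
(inside gene bodies, at least 300 nt from either edge) and nTSS (gap
midpoints); the separations guarantee that each planted site classifies as
intended under default parameters and that no site's read-through probe
falls inside another site's 100-nt reads. Half of the gTSS (by default)
receive a `GTA-N8-TAC` motif centred at −41, and one 200-nt element
flanked by 11-nt direct repeats differing at one position — the *nifD*
configuration — is planted after the last gene.

`simulate_reads()` sheds `Poisson(600)` reads per TSS with 5' ends
jittered by a rounded `Normal(0, 1)` and a uniform background Poisson
process of 0.2 reads/nt/strand — a sharp step over diffuse background,
the structure the detector assumes, at a depth comfortably above the
280-read threshold. It does not model base-composition bias, sequencing
error, rRNA contamination or operon-internal processing, so a green
recovery test establishes that the detector finds the planted step
structure at the stated depth, not that it would reproduce a real
library's site list.

`simulate_hsp_tables()` draws, per family, a characteristic identity
(`Normal(80, 5)`) and coverage (`Uniform(65, 95)` % of the longer
sequence); individual pairs jitter by at most 1 identity point and 5
coverage points. The family-level draw (rather than fully independent
per-pair draws) reflects that ortholog pairs within one family share a
common divergence, and it keeps the within-family spread strictly inside
the best-hit filter windows — which is what makes the planted families
recoverable *by construction* and the end-to-end recovery test exact
rather than probabilistic. There are no between-family hits; genomes drop
out of families independently with the configured probability.

All generators take an explicit seed, are bit-reproducible, and restore
the session RNG state.

# Worked example

```{r example, eval = FALSE}
truth <- simulate_genome(n_genes = 50, genome_length = 200000, seed = 1)
reads <- simulate_reads(truth, seed = 1)
profiles <- build_profiles(reads, truth$genome)
tss <- classify_tss(detect_tss(profiles), truth$genes)
summarize_classes(tss)
```

On this stated world the detector recovers every planted site exactly
(the acceptance suite asserts recall, precision and class agreement of at
least 0.95; see `tests/testthat/test-acceptance.R`, which computes these
quantities rather than quoting them).

# Degenerate inputs and tie-breaks

Empty profiles, empty annotations, empty hit lists and empty record lists
all produce valid empty outputs. Every tie in the pipeline is broken
deterministically (5'-most position for detection; coverage then partner
id for best hits; smallest member id for cluster labels), so identical
inputs give byte-identical output files. Reads or features beyond contig
bounds, even-width windows, inconsistent alignments longer than the
sequences they align and unclassified records in a summary all raise
typed errors rather than propagating silently.

# Known limitations

* The published study's headline numbers (6,519 TSS; 764 nTSS; 111
  genome-wide `CCGTGAAG` occurrences) require its deposited raw reads and
  genome scaffold; this package reproduces the printed arithmetic and
  sequence examples and validates the algorithms on planted synthetic
  truth instead.
* The detector models a single condition; no differential TSS activity,
  operon reconstruction or 5'-UTR analysis beyond the offset field.
* Orthology edge weights default to merged identity, not bit-score or
  e-value derived weights; the merge axis resolves overlap on one
  protein's coordinates only. Both choices are configurable points in the
  code and documented above.
* Motif scanning is literal IUPAC dyad matching, not a position weight
  matrix; it will not rank degenerate sites.
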