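---
title: "Methods: contact-map guided curation of scaffolded assemblies"
author: "hicCurator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-map guided curation of scaffolded assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicCurator)
```

## The problem

Hi-C scaffolding joins contigs into chromosome-scale sequences using
proximity-ligation contact frequencies, but the resulting assemblies
routinely carry structural mistakes that are visible on the contact
heatmap: a **translocation** (a fragment placed at the wrong position)
shows up as an off-diagonal band, an **inversion** (a fragment in the
wrong orientation) as an anti-diagonal "butterfly" block, and
**debris** as a stripe of depleted signal. Curators traditionally fix
these by eye in an interactive viewer. hicCurator implements the
computational core of an automated alternative: render heatmap tiles,
let a bounding-box detector flag suspicious regions, map the boxes back
to genomic coordinates, edit the assembly, regenerate the map and
repeat until no errors remain; then cut the assembly into chromosome
territories and report quality statistics.

The detector itself is a pluggable contract — any
`function(tile, doc)` returning boxes `category, x1, y1, x2, y2,
score`. The package ships a ground-truth **oracle** detector backed by
its misassembly simulator, so the entire loop runs and is testable
without a trained model; a neural detector can be slotted in through
the same contract.

## Coordinates and data structures

All coordinates are zero-based, half-open, in bp; bin $b$ at resolution
$r$ covers $[br, (b+1)r)$. The `ContactStore` holds one dense symmetric
matrix per resolution with side $\lceil L_g / r\rceil$, where $L_g$ is
the genome length; values are raw observed counts (no balancing). The
`AssemblyDoc` mirrors the 3D-DNA `.assembly` dialect: a fragment table
plus scaffolds of signed fragment ids. Assembly coordinates are the
gapless concatenation of fragments in layout order — matching the
contact axis, which knows nothing of N gaps. Fragment names carry
`contig:start-end` provenance in native contig coordinates; the
provenance survives every cut and is what `buildScaffoldFasta()` uses
to emit sequence. (3D-DNA instead renames split products with
`:::fragment_k` suffixes; coordinate provenance is self-maintaining and
makes conservation properties directly checkable, so we prefer it.)

## Tiling and detection

Sliding windows of length $700r$ advance along the diagonal in steps of
$400r$ (consecutive windows overlap by $300r$), for every resolution in
the store; the final window is clipped at $L_g$ so coverage of the
diagonal is complete. Each window is rendered as one pixel per bin on a
linear white-to-red ramp clipped at the window's Q95 — the 95th
percentile of its contact values under a 1-based-rank rule: with
ascending sorted values $X$ and $k = 0.95\,n$, the threshold is $X_k$
for integral $k$ and
$X_{\lfloor k\rfloor} + (k - \lfloor k\rfloor)(X_{\lceil k\rceil} -
X_{\lfloor k\rfloor})$ otherwise. The same Q95 rule sets the peak
height threshold below and the global-map ceiling. (The rule is stated
for the global map and training images; applying it per tile is our
reading of the unspecified per-tile case.)

Detector boxes are mapped to the genome by the linear ratio between
pixel and bp axes, e.g. $E_{s,x} = x_1 (L_{e,x} - L_{s,x})/I_w +
L_{s,x}$ with $(x_1,y_1)$ the top-left and $(x_2,y_2)$ the bottom-right
corner in continuous pixels. Calls are filtered by x-interval length
(defaults 50 kb to $L_g$, configurable — desk-scale studies lower the
minimum to 5 kb because simulated pieces are 10–50 kb) and
deduplicated across overlapping windows and resolutions by clustering
same-category calls with rectangle IOU at least `merge_iou` (0.5); the
cluster survivor is the highest score, ties broken by larger area then
smaller start. Correction acts on the x-axis interval; the y interval
is kept for diagnostics.

## The insertion-site (peak) algorithm

A translocation is repaired by cutting it out and re-inserting it at
the position its contacts argue for:

1. choose the resolution minimizing $|{\rm errorLen}/3 - R_i|$ (ties to
   the smaller), so the error spans about three bins;
2. extract the strip of the contact matrix with all genome rows and the
   error's columns;
3. for each error column, find local maxima of the genome-axis profile
   with height at least the strip's Q95 and minimum separation equal to
   the error's width in bins (scipy `find_peaks` semantics: height is
   inclusive, distance pruning removes the lower of two close peaks);
4. discard candidate bins inside the exclusion band
   $[\lfloor E_s/r\rfloor - 2,\ \lfloor E_e/r\rfloor + 2]$ — the
   error's own diagonal;
5. the most frequent surviving bin wins (ties: larger summed strip
   contact, then smaller index); the insertion position is
   $i \cdot r$. (A printed variant multiplies the index by the bin
   *count* instead of the bin size, which is dimensionally
   inconsistent; the bin-size form is the standard index-to-coordinate
   map and is what we implement.) Rows with several qualifying peaks
   contribute one vote per peak.

Three deliberate extensions harden the textbook algorithm, each
reachable through `findInsertionSite()` arguments:

* **Endpoint eligibility.** Interior-only maxima can never vote for the
  first or last genome bin, so insertion sites at the genome ends would
  be systematically undetectable. A profile endpoint qualifies when it
  is strictly higher than its single neighbour; flat (featureless)
  profiles still produce no peaks, so degenerate inputs still raise
  `noInsertionSite`.
* **Finer-resolution fallback.** The exclusion band spans the error
  ±2 bins in *bins*; when a piece sits within two bins of its own
  target junction the junction is inside the band and no vote can name
  it. Retrying at the next finer stored resolution shrinks the blind
  zone in bp until either a vote survives or resolutions are exhausted.
* **Two-stage refinement** (`refine = TRUE`, default). The coarse vote
  is only about one-bin accurate, which can snap to the wrong fragment
  junction when the flanking fragment is shorter than ~1.5 coarse bins.
  A second vote at the finest stored resolution, restricted to ±2
  coarse bins around the coarse site, pins the insertion to a fine bin.

## Applying corrections

Cut positions (call boundaries and the peak site) are snapped to the
nearest existing fragment junction within `boundary_snap_bins` bins
(default 2) at the relevant resolution: misjoins exist only at
junctions, and both detector boxes and peak sites are bin-quantized.
Positions farther than the tolerance are cut exactly where stated.
Translocations are cut at both boundaries and the insertion site and
moved there; inversions are cut and sign-flipped (an involution);
debris is relegated to a trailing leftover scaffold only when
`debris_mode = "adjust"` — the default leaves debris untouched, since
depleted signal has many non-error causes. Every edit returns a new
document; total length and the native-coordinate partition are
invariant under all edits (property-tested via FASTA reconstruction).

### Iteration orchestration

`runIterations()` repeats detect-and-correct until no translocation or
inversion remains, a `max_iterations` cap (safety default 5; the
round-trip studies below use 10, since the method's stated behaviour is
to iterate until all adjustments are complete), or `stall_patience`
consecutive iterations without a decreasing error count. Within one
iteration:

1. all cuts are executed first — cuts never shift assembly
   coordinates, so iteration-start call coordinates stay valid;
2. edits are then executed as *fragment-name plans*: inversions first
   (they shift no coordinates), translocations one at a time,
   debris relegations last. Before each insertion search the contact
   map is regenerated for the current document and detection is
   re-run on it; a call whose region is no longer flagged is dropped as
   resolved (an earlier move may have restored its neighbourhood).
3. mutually attracted pairs — two flagged translocations whose
   proposed sites abut each other, typically two pieces that were
   adjacent before shuffling — are handled in two passes: the first
   call defers; its partner then searches with the deferred span
   excluded, so the pair's mutual pull cannot override independent
   evidence (with no other evidence it stays put); the deferred call
   finally executes with the pair's geometry settled.

The stale-map hazard motivates this choreography: planning every move
against the iteration-start map lets two mutually dependent moves
cement each other in the wrong place, and the resulting two-cycles
never terminate. With per-move refreshes the loop restored the exact
pre-shuffle arrangement in 659 of 660 simulated multi-event genomes in
our development sweeps; the residual case parks a whole chromosome head
inside another chromosome, which junction-local moves cannot fix (see
Limitations).

## Chromosome assignment

The whole-genome map is rendered at the smallest resolution $r$ with
$1440\,r \ge L_g$ (so it fits a 1440-pixel image) and a Q95 ceiling;
chromosome-category boxes are mapped to diagonal genomic intervals.
Overlapping neighbours are reconciled at the midpoint of their overlap,
gaps go to the leftover list — the reconciliation rule is ours, as
imperfect boxes need one. `partitionAssembly()` cuts at every boundary,
joins each territory's fragments into one scaffold in assembly order,
and appends everything unassigned to a single trailing leftover
scaffold; lengths are conserved exactly, and two FASTA variants (with
and without the leftover) can be emitted.

## Report statistics

`contiguityStats()` implements Nx/Lx natively (smallest piece of the
minimal descending prefix reaching x% of the total). The CC ratio is
scaffolds over chromosomes. The structural error ratio
$R_{\rm error} = (\sum T_i + \sum I_j)/L_g$ uses the corrected length
(excluding leftover sequence) and decomposes exactly —
$R_{\rm error} = R_{\rm translocation} + R_{\rm inversion}$, which we
guarantee in floating point by composing it from the per-category
rates. The per-category rates are additionally reported against the
uncorrected genome size (the convention used for per-iteration
tracking), and the anchor rate is input contig size over uncorrected
size ×100; because the two denominators genuinely differ in the source
conventions, every ratio in the output names its denominator. GC is
computed over unambiguous A/C/G/T only. The report renders four
sections (summary; pre/post heatmaps; up to five exhibits per error
category, all when fewer; per-iteration counts and chromosome length
proportions) into a versioned JSON plus self-contained HTML.

## Detector evaluation

IOU uses the general clamped intersection (the printed special-case
formula assumes a particular overlap geometry and equals the clamped
form there). The confusion matrix matches predictions to truths
greedily by descending score with IOU at least the threshold, category
*not* required to match — category confusion is the point; unmatched
truths and predictions land in background row/column. PR curves sweep
the score threshold over all distinct prediction scores (the sweep grid
is unspecified in the source conventions; score levels are the natural
choice), requiring category agreement for a true positive, and AUPRC is
the composite trapezoid sum $\sum (p_j + p_{j+1})(r_{j+1} - r_j)/2$.

## The simulator

`makeGenome()` draws contigs with i.i.d. bases at a target GC;
`fragmentAndShuffle()` cuts every contig into pieces uniform in
10–50 kb and disturbs `round(0.6 n)` of them — each moved to a
uniformly chosen foreign fragment boundary or sign-flipped in place
with equal probability (the move/flip split is unstated in the source;
we use 50/50, and candidate insertion points are uniform over piece
boundaries). A trailing remainder shorter than the 10 kb minimum is
folded into the last piece: sub-minimum slivers are smaller than any
usable contact bin and would be undetectable by construction.

`simulateContactStore()` replaces read realignment with a standard
distance-decay phenomenology: expected contact between assembly bins
$p, q$ is $s_0 (1 + d)^{-\alpha}$ with $d$ the distance in bins between
the bins' *true* genomic midpoints (via provenance), attenuated by 0.1
across chromosomes; defaults $\alpha = 1$, $s_0 = 100$ contacts.
Optional Poisson sampling perturbs the upper triangle and mirrors it.
Planted inversions yield butterfly blocks and translocations
off-diagonal bands by construction. Debris pieces zero their rows and
columns (signal dropout).

What the simulator does **not** emulate: restriction-site and coverage
biases, repeat-driven spurious contacts, heterozygosity and diploid
phasing, distance-dependent noise structure beyond Poisson, and any
positional preference between chromosomes — cross-chromosome expected
contact is position-independent here, so chromosome *order* is
unidentifiable from these maps. Passing round-trip tests therefore
demonstrates the correctness of the coordinate arithmetic, editing
algebra and peak logic under clean decay signal, not detector
performance on real Hi-C maps.

## Study sizes and numerical choices

The bundled studies use 3-contig genomes of 250–400 kb per contig
(~1 Mb total), resolutions {2.5, 5, 10} kb, and the oracle detector:
formula oracles on 1000 random instances each; 100 noisy
single-translocation genomes for insertion-site recovery (±2 bins,
single-stage search, matching the stated tolerance); 60 mixed-event
round trips (k ∈ {1, 2, 5} × 20 seeds); 10 three-chromosome
assignments. These sizes keep every bin structure several bins wide at
the finest resolution while a full run finishes in seconds.
Floating-point details: symmetry is validated to 1e-9 relative,
archive matrices are stored as little-endian float32 (integer counts
round trip bit-exactly), quantile and trapezoid arithmetic is checked
against independent oracles to 1e-12. Layout equality after a round
trip is assessed at sequence level: `mergeAdjacentFragments()`
canonicalizes cuts at identical coordinates (invisible in the emitted
FASTA) and scaffold grouping is collapsed, since pre-assignment
grouping is bookkeeping that chromosome assignment re-derives.

## Limitations

* Junction-local evidence cannot re-order whole chromosomes: if a run
  of pieces ends up embedded inside another chromosome with both seams
  foreign, no sequence of tracked-piece moves can be argued for from
  the decay model, and such draws (about 1 in 300 five-event genomes in
  our sweeps) stall honestly rather than converge.
* The oracle detector flags tracked pieces only; a box detector trained
  on images would also flag composite mispositioned runs. The loop's
  behaviour with imperfect real detectors (false positives, box jitter
  beyond one bin) is exercised only indirectly via the stall guard.
* The `.hic` binary format is not read natively; contact data enter
  through the documented archive or in memory. No KR/ICE balancing.
* Reference-based statistics (NGA50 and kin) require an external
  reference and are out of scope.
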