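---
title: "Two-neighborhood extraction: model, parameters and design notes"
author: "voc2n"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-neighborhood extraction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voc2n)
```

## The problem and the model

Annotating a repertoire of stereotyped vocalizations from a continuous
recording requires solving segmentation and classification together.
Amplitude thresholding alone answers "where is sound?" but not "where is
the vocalization?": noises abutting a syllable stretch its apparent extent,
and noises bridging a gap merge two syllables into one sound interval.
Classifying pre-cut segments therefore propagates segmentation errors into
every downstream analysis.

The two-neighborhood (2N) model sidesteps the commitment. The recording is
reduced to a log-power spectrogram (`compute_log_spectrogram()`; 512-sample
Hamming windows, hop 128 at 32 kHz, i.e. a 4 ms column clock that every
later stage shares). Band-limited power (312 Hz–8 kHz by default) is
thresholded at five standard deviations above the mean of a known silent
stretch to produce *sound intervals* — a deliberately permissive
pre-segmentation whose only job is to say where sound is.

Each interval, extended by a margin of `delta_on` = 4 columns before its
onset and `delta_off` = 6 columns after its offset, is dissected into
snippets of `width_w` = 16 columns hopped by one column
(`dissect_snippets()`). The first snippet has forward lag *d* = 1, the
last backward lag *d* = −1. Because the margins put a slice of surrounding
silence into the terminal snippets, each vocalization type traces an
elongated one-dimensional cloud in the planar embedding of all snippets
(`embed_snippets()`), with self-similar onset content at one end and
self-similar offset content at the other.

A vocalization type is *defined* by one blob per side. At lag *d* the
slice contains the points at lag *d* or *d*+1 (mirror for *d* < 0); a disk
of radius *r* is stamped on each slice point, and the pixels where at
least *θ* disks overlap form 8-connected components — blobs
(`density_map()`, `threshold_blobs()`). Harvesting (`harvest_points()`)
collects **all** points inside a blob, whatever their true lag. The
harvested point at snippet start column *s* anchored at the blob's lag
implies an amplitude crossing at *s* + `delta_on` − (*d* − 1) for onsets
and at the mirror position for offsets (`implied_crossing()`): a noisy
rendition whose content resembles cleanly segmented renditions inherits
its boundary from that resemblance, not from the (corrupted) amplitude
trace. This lag-oblivious harvest is the entire rescue mechanism, and it
is what the single-neighborhood baselines lack.

Runs of adjacent harvested snippets collapse to one anchor event — the
earliest snippet for onsets and, by mirror symmetry, the latest for
offsets, so that for a cleanly segmented rendition the collapsed event's
implied crossing lands exactly on the interval boundary
(`collapse_adjacent()`). The pairing scan (`pair_2n()`) then emits a
vocalization per onset event followed by a same-type offset event. Three
deliberate rules control the false-positive rate:

* an onset followed by an *offset of another type* is discarded together
  with that offset;
* an onset interrupted by another onset (noise onsets included), the end
  of its sound interval, or the end of the file is truncated one column
  before the interrupting event (`mode = "truncate"`, the default) or
  discarded (`mode = "strict"`) — both behaviors appear in practice and
  the flag preserves the choice;
* offsets with no pending same-type onset are discarded.

Emitted boundaries are clamped to the owning sound interval: without
sound there is no vocalization, so an anchor that (through positional
jitter of an interior blob, see below) overshoots the interval edge is
pulled back to it. Noise clusters have no distinct offset behavior, so a
noise pseudo-type owns onset blobs only and its events become noise
segments running to the interval end or the next vocalization onset
(`extract_noise()`).

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| `window_length`, `hop` | samples | 512, 128 | 4 ms column clock at 32 kHz |
| `band_low`, `band_high` | Hz | 312, 8000 | analysis band for thresholding and features |
| `n_sd` | — | 5 | silence-threshold multiplier on the log trace |
| `width_w` | columns | 16 | snippet duration (64 ms); large enough to separate types, small enough not to cut into neighbors |
| `delta_on`, `delta_off` | columns | 4, 6 | margins protruding beyond the interval; give terminal snippets their silent rim |
| `lag_d`, `radius_r`, `threshold_theta` | —, embedding units, disks | per blob | the three selection parameters of each blob |
| `smoothing_width`, `min_gap`, `min_dur` | columns | 1, 0, 0 | amplitude-trace smoothing and interval cleanup; smoothing lets split syllables come out as one interval |

The embedding method is a pluggable contract: everything downstream
consumes coordinates only. UMAP is the default (library-default
neighborhood parameters, logged with the run); t-SNE gives comparable
geometry; PCA is a fast deterministic backend for tests and debugging and
is not expected to separate real repertoires. UMAP and t-SNE run in a
single-threaded Python subprocess with `random_state = seed`, so identical
inputs and seed give bit-identical coordinates.

## Numerical choices

* Columns are 0-based and intervals half-open `[onset, offset)`; all
  times are integer columns, converted to seconds only at the I/O edge.
* Power is clipped at `1e-12` before the log — far below any signal of a
  waveform in [−1, 1] but far above double-precision rounding noise — so
  silence maps to a finite floor; margins outside the recording reuse it.
* "Exceeds the threshold" is implemented inclusively (`density >= theta`,
  `trace >= threshold`); both are configurable where it matters.
* Blob components are 8-connected and ordered by size with ties broken by
  the smallest pixel index, so `blob_index` is stable for identical input.
* The density grid is 512×512 over the point bounding box plus a 2%
  margin; radii and thresholds are expressed in data coordinates and so
  rescale with the grid only through pixel quantization.
* Degenerate cases are explicit: intervals too short for one snippet are
  skipped with a message, empty pairings return empty (typed) tables, a
  type with no extracted bins scores `f = NA`, never 0.

## The synthetic generator

`render_scene()` emulates what the method assumes about real data:
stereotyped syllable types rendered from deterministic spectro-temporal
recipes with ±2% pitch and duration jitter (so types form elongated
1-D clouds); variable silent gaps; and three classes of non-vocal noise.
The default repertoire includes a confound pair — E is D's 48-column body
preceded by a 6-column down-sweep — so the two types share their entire
ending and are separable only near their onsets.

Noise is deliberately two-class. *Standalone* events (nominal amplitude
0.15, vocalizations peak at 0.5) model distinct cage noises: they earn
their own sound intervals and populate the embedding's noise cluster.
*Boundary* artifacts — bursts abutting an onset or offset, and bursts
bridging a gap — are drawn 3–10 dB above the recording floor (s.d.
2 × 10⁻³, about −48 dB re vocal peak): with the silence threshold sitting
only a few log-units above the floor, even such faint sounds corrupt
amplitude segmentation, and they are precisely the class the similarity
rescue is designed for. A loud noise hard against a boundary rewrites the
snippet margins beyond recognition and is not recoverable by *any*
similarity-based method; the generator therefore models it only as
standalone events. This is the main respect in which passing tests
overstate real data: real boundary noises span a continuum of levels and
spectra, and the rescue rate degrades as they approach the vocal
amplitude.

Ground truth is computed, not assumed: the generator renders the same
scene without noise, runs the package's own amplitude segmentation on it
(same silence-derived threshold — the silent lead-in is identical in both
renderings), and takes those crossings as the per-rendition truth. A
rendition's truth boundary then coincides with the noisy recording's
amplitude crossing exactly when no noise touched it, which makes the
"cleanly segmented" bookkeeping exact; the realized clean flags are
re-measured on the noisy rendering, so a planned burst that stayed
sub-threshold still counts as clean.

## The blob oracle

`oracle_blob_defs()` replaces the human in headless runs. For each type
and side it scans lags of increasing |d|; at each lag it takes the clean
renditions' slice points, sets candidate radii from their nearest-neighbor
spacing (disks must fuse the cluster without swallowing neighbors, capped
at 5% of the embedding diagonal), and thresholds ascending from 1. A
candidate blob may be a union of components (a type may own K blobs).
Candidates must satisfy a hard no-confound constraint — every collapsed
anchor event within 4 columns of a true boundary of the owning type — and
are ranked by a target-centric score: the fraction of cleanly segmented
boundaries receiving an exactly placed event plus the fraction of all
boundaries receiving one within 1 column, ties broken by harvest size
(the radius-as-large, threshold-as-low-as-possible rule). The scan
continues four lags past the first success to fine-tune the anchor, and
evaluates candidates after interval clamping, which lets interior blobs
sit one column "late" and have the clamp absorb the overshoot.

Two tolerances are distinct on purpose. Interior blobs — required for the
confound pair, whose separating content lies near the syllable onsets —
anchor the offset relative to content near the *other* end of the
syllable, so ±2% duration jitter converts to a column or two of
positional scatter. That scatter is segmentation error, not evidence of a
confounding type, hence the wider (4-column) confound band around the
strict (1-column) accuracy band. With the clamp and the late-anchor
preference this scatter collapses to exact boundaries for cleanly
segmented renditions; for noise-extended renditions it survives as a
±1-column error, which is visible as the small residual extraction error
on the confound types.

The oracle reads the generator's truth; it exists so the pipeline is
testable without a human, and its decision criterion (no confounding
points in the blob, blob as large as possible) is the one an expert
applies by eye.

## Validation scope and problem sizes

The validation scenes use 300 syllables (≈60 renditions per type, about
70 s of audio, 8–10k snippets): large enough that each type's clean slice
forms an unambiguous density core, small enough that a full pipeline run
(UMAP included) takes about 1.5 minutes on one CPU. The noisy condition
uses boundary-contamination probability 0.3 and bridge rate 0.1 — the
regime where roughly a quarter of renditions lose a clean boundary — with
five fixed scene seeds. On these conditions the package's checks verify:
exact integer agreement of the density/blob machinery with brute-force
oracles; complete noiseless recovery to within one column with zero type
misclassifications; a ≥2× (in practice ~10×) reduction of bin-wise
extraction error relative to the better 1N baseline; a retrieved-bin cost
within 10%; and lag-zero masses of the onset/offset lag CDFs matching the
realized cleanly segmented fractions to within three percentage points.

## Known limitations

* The method needs a pre-segmentation into sound intervals; with so much
  noise that almost nothing is cleanly segmented, the lag structure that
  defines blobs dissolves.
* Rescue presumes faint boundary noise (see above); loud abutting noise
  defeats similarity.
* Interior offset anchors (forced by shared-ending confound pairs) carry
  residual ±1-column scatter under natural duration jitter.
* Blob definitions are per-recording: embeddings are not comparable
  across runs, so definitions must be re-fitted (or re-drawn) per
  embedding.
* The `strict` pairing mode trades recall for precision; duration-outlier
  pruning of call-string merges is out of scope.
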