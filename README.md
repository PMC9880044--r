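# voc2n — two-neighborhood extraction of vocal units

`voc2n` extracts and classifies animal vocalizations from continuous audio
without committing to a prior segmentation. It addresses a problem familiar
to anyone annotating birdsong or other bioacoustic recordings: amplitude
thresholding segments sound from silence cheaply, but a cage noise abutting
a syllable makes that syllable look too long, and a noise inside a gap fuses
two calls into one. Classifiers that operate on pre-segmented units inherit
every one of those mistakes.

The package implements a semi-supervised alternative. Sound intervals are
dissected into densely overlapping spectrogram **snippets** (hop = one
4 ms column), each carrying a *forward lag* from the interval onset and a
*backward lag* from its offset. All snippets are embedded into the plane
(UMAP by default; t-SNE and PCA are interchangeable backends). A
vocalization type is then defined by a **pair of high-density regions**
("blobs") of that embedding:

- an **onset blob**: the supra-threshold region of the disk-count density
  over points at lag *d* or *d*+1 (*d* > 0), parameterized by lag *d*,
  disk radius *r*, and density threshold *θ*;
- an **offset blob**: the mirror construction at negative lags.

Every embedded point falling in a blob — *whatever its own lag* — is
harvested as an anchor event, and its boundary is the amplitude crossing
it implies at the blob's lag: `start + δ_on − (d − 1)` for onsets,
`end − δ_off + (|d| − 1)` for offsets. A vocalization is emitted for each
onset event followed by a same-type offset event (2N pairing); onsets
followed by a different type's offset are discarded, and onsets interrupted
by another onset or the interval end are truncated one bin before the
interrupting event. Because harvesting is lag-oblivious, a rendition whose
amplitude segmentation was wrecked by an adjacent noise still lands next to
its cleanly segmented siblings in the embedding and inherits correct
boundaries from the blob — this is what single-neighborhood (1N) baselines
cannot do, and the package ships both 1N baselines plus bin-wise
precision/recall scoring and onset/offset lag cumulative densities to
quantify the difference.

Because no public recordings accompany the method, the package includes a
synthetic scene generator (`render_scene()`) producing stereotyped syllable
repertoires with exact ground truth — including a pair of long syllables
distinguishable only by an initial down-sweep (a classic confound), faint
boundary-abutting artifacts, gap-bridging noises, and standalone cage
noises — and `oracle_blob_defs()`, a headless stand-in for the interactive
blob selection that a GUI user would perform.

## Worked example

```r
library(voc2n)

sc   <- render_scene(scene_config(n_syllables = 60, p_boundary_noise = 0.2, seed = 7))
prep <- voc2n_prepare(sc$wave, silence = sc$silence_cols, method = "umap", seed = 1)
defs <- oracle_blob_defs(sc$truth, prep$emb, prep$intervals, prep$snips$params,
                         prep$grid, noise_onsets = sc$noise_events$start_col)
ex   <- voc2n_extract(prep, defs)
binwise_score(ex$vocalizations, sc$truth[, c("type_label", "onset_col", "offset_col")])
```

prints (verbatim from the run above):

```
realized cleanly segmented: 76.7% of renditions
voc2n preparation: 66 sound intervals, 2041 snippets embedded
   type_label   side lag_d radius_r threshold_theta
1           B  onset     1     0.25               1
2           B offset    -1     0.50               1
3           D  onset     1     0.36               6
4           D offset   -44     0.57               1
...
10          E offset   -42     0.13               1
11      noise  onset     2     0.13               3
  type_label     f epsilon recall n_bins_extracted n_bins_truth
1          A 0.997 0.00332      1              301          300
2          B 0.989 0.01136      1              352          348
3          C 0.992 0.00787      1              254          252
4          D 0.997 0.00325      1              616          614
5          E 0.997 0.00291      1              688          686
pooled extraction error: 0.0050 over 2211 bins
```

Reading this: 23% of renditions had a boundary corrupted by noise, yet
every rendition is recovered with its type (`recall = 1`) and more than
99% of extracted 4 ms bins carry the correct label. Note the offset blobs
of the confound pair D/E sitting at lags −44/−42 — near the syllable
*onsets*, where the two types first differ — exactly the maneuver an expert
performs manually when two types share their endings.

A thin command-line dispatcher covers the headless workflow:

```sh
exec/voc2n synth     --n-syllables 300 --seed 1 --out-wav s.wav --out-truth t.csv
exec/voc2n intervals --wav s.wav --silence-cols 4,200 --out iv.csv
exec/voc2n extract   --wav s.wav --blobs blobs.yaml --out ann.csv --audacity ann.txt
exec/voc2n eval      --extracted ann.csv --truth t.csv
```

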