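Package: voc2n
Title: Two-Neighborhood Extraction of Vocal Units from Planar Spectrogram Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous segmentation and clustering of animal vocalizations
    from continuous audio without committing to a prior segmentation. Sound
    intervals detected by amplitude thresholding are dissected into densely
    overlapping spectrogram snippets carrying forward and backward lags to the
    interval boundaries; snippets are embedded into the plane (UMAP, t-SNE or
    PCA) and each vocalization type is defined by a pair of high-density
    regions ("blobs") of the embedding, one anchored near onsets and one near
    offsets. Vocalizations are harvested as the spectrogram spans between
    matched onset and offset blob points, which rescues renditions whose
    amplitude segmentation was corrupted by noise. Includes single-neighborhood
    baselines, bin-wise extraction-error evaluation, onset/offset lag
    cumulative densities, and a synthetic birdsong scene generator with exact
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
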