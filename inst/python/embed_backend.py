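"""Planar embedding backend: reads a raw float64 matrix, writes N x 2 coords.

argv: method infile n m seed outfile n_neighbors min_dist perplexity
Run single-threaded with a fixed random_state so results are reproducible.
"""
import sys

import numpy as np


def main(argv):
    method, fin, n, m, seed, fout = argv[1:7]
    n, m, seed = int(n), int(m), int(seed)
    n_neighbors = int(float(argv[7]))
    min_dist = float(argv[8])
    perplexity = float(argv[9])
    x = np.fromfile(fin, dtype=np.float64).reshape(n, m)
    if method == "umap":
        import umap
        reducer = umap.UMAP(n_components=2, random_state=seed,
                            n_neighbors=min(n_neighbors, n - 1),
                            min_dist=min_dist, n_jobs=1, verbose=False)
        xy = reducer.fit_transform(x)
    elif method == "tsne":
        from sklearn.manifold import TSNE
        xy = TSNE(n_components=2, random_state=seed,
                  perplexity=min(perplexity, (n - 1) / 3.0),
                  init="pca", n_jobs=1).fit_transform(x)
    else:
        raise SystemExit(f"unknown method: {method}")
    np.asarray(xy, dtype=np.float64).tofile(fout)


if __name__ == "__main__":
    main(sys.argv)
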