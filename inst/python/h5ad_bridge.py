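"""Bridge between the R package and HDF5-based single-cell formats.

Converts H5AD / Loom files to and from a plain exchange directory of
float64 binaries (Fortran order, genes x cells) plus JSON/TSV sidecars,
so the R side never needs HDF5 bindings and float64 payloads round-trip
bit-identically.
"""
import json
import os
import sys

import numpy as np


def _write_mat(path, m):
    # m: genes x cells float64; Fortran order on disk (tofile always emits
    # logical C order, so flatten explicitly)
    np.asarray(m, dtype=np.float64).flatten(order="F").tofile(path, sep="")


def _read_mat(path, n_genes, n_cells):
    a = np.fromfile(path, dtype=np.float64)
    return a.reshape((n_genes, n_cells), order="F")


def _dense(x):
    if hasattr(x, "toarray"):
        x = x.toarray()
    return np.asarray(x, dtype=np.float64)


def export_h5ad(src, out_dir):
    import anndata
    ad = anndata.read_h5ad(src)
    _export_common(out_dir, ad.shape[0], ad.shape[1],
                   list(ad.var_names), list(ad.obs_names),
                   {k: _dense(v).T for k, v in ad.layers.items()},
                   ad.obs, {k: np.asarray(v, dtype=np.float64)
                            for k, v in ad.obsm.items()})


def export_loom(src, out_dir):
    import h5py
    with h5py.File(src, "r") as f:
        layers = {"matrix": _dense(f["matrix"][:])}   # genes x cells
        if "layers" in f:
            for k in f["layers"]:
                layers[k] = _dense(f["layers"][k][:])
        n_genes, n_cells = layers["matrix"].shape
        genes = None
        for key in ("Gene", "var_names", "gene_names"):
            if "row_attrs" in f and key in f["row_attrs"]:
                genes = [g.decode() if isinstance(g, bytes) else str(g)
                         for g in f["row_attrs"][key][:]]
                break
        cells = None
        for key in ("CellID", "obs_names", "cell_names"):
            if "col_attrs" in f and key in f["col_attrs"]:
                cells = [c.decode() if isinstance(c, bytes) else str(c)
                         for c in f["col_attrs"][key][:]]
                break
        if genes is None:
            genes = [f"gene_{i+1}" for i in range(n_genes)]
        if cells is None:
            cells = [f"cell_{i+1}" for i in range(n_cells)]
        obs_cols = {}
        if "col_attrs" in f:
            for k in f["col_attrs"]:
                if k in ("CellID", "obs_names", "cell_names"):
                    continue
                v = f["col_attrs"][k][:]
                if v.ndim == 1:
                    obs_cols[k] = [x.decode() if isinstance(x, bytes)
                                   else x for x in v]
    _export_common(out_dir, n_cells, n_genes, genes, cells, layers,
                   obs_cols, {})


def _export_common(out_dir, n_cells, n_genes, genes, cells, layers,
                   obs, obsm):
    os.makedirs(os.path.join(out_dir, "layers"), exist_ok=True)
    os.makedirs(os.path.join(out_dir, "obs"), exist_ok=True)
    os.makedirs(os.path.join(out_dir, "obsm"), exist_ok=True)
    meta = {"n_genes": n_genes, "n_cells": n_cells,
            "layers": sorted(layers), "obs": {}, "obsm": {}}
    for name, m in layers.items():
        assert m.shape == (n_genes, n_cells), (name, m.shape)
        _write_mat(os.path.join(out_dir, "layers", name + ".bin"), m)
    with open(os.path.join(out_dir, "genes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, genes)) + "\n")
    with open(os.path.join(out_dir, "cells.tsv"), "w") as fh:
        fh.write("\n".join(map(str, cells)) + "\n")
    obs_items = (obs.items() if isinstance(obs, dict)
                 else ((c, obs[c].tolist()) for c in obs.columns))
    for col, vals in obs_items:
        vals = list(vals)
        numeric = all(isinstance(v, (int, float, np.floating, np.integer))
                      for v in vals)
        meta["obs"][col] = "numeric" if numeric else "character"
        with open(os.path.join(out_dir, "obs", col + ".tsv"), "w") as fh:
            if numeric:
                fh.write("\n".join(repr(float(v)) for v in vals) + "\n")
            else:
                fh.write("\n".join(str(v) for v in vals) + "\n")
    for name, m in obsm.items():
        meta["obsm"][name] = int(m.shape[1])
        _write_mat(os.path.join(out_dir, "obsm", name + ".bin"),
                   np.asarray(m, dtype=np.float64).T)
    with open(os.path.join(out_dir, "meta.json"), "w") as fh:
        json.dump(meta, fh)


def import_h5ad(src_dir, dst):
    import anndata
    import pandas as pd
    with open(os.path.join(src_dir, "meta.json")) as fh:
        meta = json.load(fh)
    ng, nc = meta["n_genes"], meta["n_cells"]
    layers = {}
    for name in meta["layers"]:
        layers[name] = _read_mat(
            os.path.join(src_dir, "layers", name + ".bin"), ng, nc).T
    genes = [l.rstrip("\n") for l in open(os.path.join(src_dir, "genes.tsv"))]
    cells = [l.rstrip("\n") for l in open(os.path.join(src_dir, "cells.tsv"))]
    obs = pd.DataFrame(index=pd.Index(cells, name="obs_names"))
    for col, kind in meta["obs"].items():
        vals = [l.rstrip("\n")
                for l in open(os.path.join(src_dir, "obs", col + ".tsv"))]
        obs[col] = ([float(v) for v in vals] if kind == "numeric" else vals)
    X = layers.get("spliced", next(iter(layers.values())))
    ad = anndata.AnnData(X=X.copy(), obs=obs,
                         var=pd.DataFrame(index=pd.Index(genes,
                                                         name="var_names")))
    for name, m in layers.items():
        ad.layers[name] = m
    for name, k in meta["obsm"].items():
        ad.obsm[name] = _read_mat(
            os.path.join(src_dir, "obsm", name + ".bin"), k, nc).T
    ad.write_h5ad(dst)


def main(argv):
    cmd = argv[0]
    if cmd == "export-h5ad":
        export_h5ad(argv[1], argv[2])
    elif cmd == "export-loom":
        export_loom(argv[1], argv[2])
    elif cmd == "import-h5ad":
        import_h5ad(argv[1], argv[2])
    else:
        sys.stderr.write(f"unknown command {cmd}\n")
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1:]))
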