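"""Batched chemistry/embedding helper for the pfascluster R package.

Reads a JSON request from argv[1] and writes a JSON response to argv[2].
The request is a list of operation objects; the response is a list of result
objects in the same order.  All heavy cheminformatics goes through RDKit; the
t-SNE op goes through scikit-learn.  Everything is deterministic for a fixed
request (FMCS is exact; TSNE gets an explicit random_state).

Supported ops (each object carries "op" plus its arguments):
  canonicalize: {smiles: [str]}                  -> {canonical: [str|None], valid: [bool]}
  morgan:       {smiles: [str], n_bits, radius}  -> {bits: [[int 0-based]]}
  match:        {smiles: [str], smarts: str}     -> {match: [bool]}
  mcs:          {smiles: [str], threshold, timeout} -> {smarts: str, num_atoms: int}
  tsne:         {x: [[float]], perplexity, seed} -> {y: [[float, float]]}
"""

import json
import sys


def _mols(smiles):
    from rdkit import Chem
    return [Chem.MolFromSmiles(s) for s in smiles]


def op_canonicalize(req):
    from rdkit import Chem
    mols = _mols(req["smiles"])
    return {
        "canonical": [Chem.MolToSmiles(m) if m is not None else None for m in mols],
        "valid": [m is not None for m in mols],
    }


def op_morgan(req):
    from rdkit.Chem import rdFingerprintGenerator
    n_bits = int(req.get("n_bits", 2048))
    radius = int(req.get("radius", 2))
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)
    out = []
    for m in _mols(req["smiles"]):
        if m is None:
            out.append(None)
        else:
            fp = gen.GetFingerprint(m)
            out.append(sorted(fp.GetOnBits()))
    return {"bits": out}


def op_match(req):
    from rdkit import Chem
    patt = Chem.MolFromSmarts(req["smarts"])
    if patt is None:
        return {"error": "invalid SMARTS: %s" % req["smarts"]}
    res = []
    for m in _mols(req["smiles"]):
        res.append(bool(m is not None and m.HasSubstructMatch(patt)))
    return {"match": res}


def op_mcs(req):
    from rdkit import Chem
    from rdkit.Chem import rdFMCS
    mols = [m for m in _mols(req["smiles"]) if m is not None]
    if len(mols) < 2:
        return {"error": "mcs needs >= 2 valid molecules"}
    params = rdFMCS.MCSParameters()
    params.Threshold = float(req.get("threshold", 1.0))
    params.Timeout = int(req.get("timeout", 20))
    params.BondCompareParameters.RingMatchesRingOnly = True
    res = rdFMCS.FindMCS(mols, params)
    if res.numAtoms < 2 or not res.smartsString:
        return {"smarts": "", "num_atoms": 0}
    return {"smarts": res.smartsString, "num_atoms": int(res.numAtoms)}


def op_tsne(req):
    import numpy as np
    from sklearn.manifold import TSNE
    x = np.asarray(req["x"], dtype=float)
    perplexity = float(req.get("perplexity", 30.0))
    seed = int(req.get("seed", 0))
    emb = TSNE(
        n_components=2,
        perplexity=perplexity,
        random_state=seed,
        init="pca",
    ).fit_transform(x)
    return {"y": emb.tolist()}


OPS = {
    "canonicalize": op_canonicalize,
    "morgan": op_morgan,
    "match": op_match,
    "mcs": op_mcs,
    "tsne": op_tsne,
}


def main():
    with open(sys.argv[1]) as fh:
        requests = json.load(fh)
    out = []
    for req in requests:
        fn = OPS.get(req.get("op"))
        if fn is None:
            out.append({"error": "unknown op: %r" % req.get("op")})
            continue
        try:
            out.append(fn(req))
        except Exception as exc:  # surfaced as an R error by the bridge
            out.append({"error": "%s: %s" % (type(exc).__name__, exc)})
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
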