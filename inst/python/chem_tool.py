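"""Batched RDKit worker for the molcontrast R package.

Reads one JSON request object on stdin, writes one JSON response on stdout.
Every operation is batched so that R pays the interpreter start-up cost once
per call, not once per molecule.  stdout carries nothing but the response.
"""
import json
import os
import random
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, DataStructs, Descriptors, QED, RDConfig

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def _mol(smiles):
    # the empty string parses as an empty Mol; treat it as invalid input
    if not isinstance(smiles, str) or smiles == "":
        return None
    return Chem.MolFromSmiles(smiles)


def op_canonicalize(req):
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        out.append(Chem.MolToSmiles(m) if m is not None else None)
    return {"canonical": out}


def _random_writing(mol, rng):
    n = mol.GetNumAtoms()
    perm = list(range(n))
    rng.shuffle(perm)
    shuffled = Chem.RenumberAtoms(mol, perm)
    return Chem.MolToSmiles(shuffled, canonical=False)


def op_enumerate(req):
    # seed -> per-molecule, per-draw stream; str seeding is sha512-based and
    # stable across Python versions, unlike hash().
    n = int(req["n"])
    seed = int(req["seed"])
    out = []
    for i, s in enumerate(req["smiles"]):
        m = _mol(s)
        if m is None:
            out.append(None)
            continue
        writings = []
        for j in range(n):
            rng = random.Random("%d:%d:%d" % (seed, i, j))
            writings.append(_random_writing(m, rng))
        out.append(writings)
    return {"writings": out}


def op_descriptors(req):
    rows = []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            rows.append(None)
            continue
        rows.append(
            {
                "qed": QED.qed(m),
                "sascore": sascorer.calculateScore(m),
                "logp": Crippen.MolLogP(m),
                "tpsa": Descriptors.TPSA(m),
                "mw": Descriptors.MolWt(m),
            }
        )
    return {"rows": rows}


def _fingerprint(mol, spec):
    radius = int(spec.get("radius", 2))
    nbits = int(spec.get("nbits", 2048))
    kind = spec.get("type", "morgan_count")
    if kind == "morgan_count":
        return AllChem.GetHashedMorganFingerprint(mol, radius, nBits=nbits)
    if kind == "morgan_bits":
        return AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=nbits)
    raise ValueError("unknown fingerprint type: %r" % kind)


def op_fingerprints(req):
    spec = req.get("fp", {})
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
            continue
        fp = _fingerprint(m, spec)
        if hasattr(fp, "GetNonzeroElements"):
            elems = fp.GetNonzeroElements()
            idx = sorted(elems)
            out.append({"idx": idx, "val": [elems[i] for i in idx]})
        else:
            idx = list(fp.GetOnBits())
            out.append({"idx": idx, "val": [1] * len(idx)})
    return {"fps": out}


def op_tanimoto_oracle(req):
    spec = req.get("fp", {})
    fps = [_fingerprint(_mol(s), spec) for s in req["smiles"]]
    n = len(fps)
    mat = [[DataStructs.TanimotoSimilarity(fps[i], fps[j]) for j in range(n)] for i in range(n)]
    return {"matrix": mat}


OPS = {
    "canonicalize": op_canonicalize,
    "enumerate": op_enumerate,
    "descriptors": op_descriptors,
    "fingerprints": op_fingerprints,
    "tanimoto_oracle": op_tanimoto_oracle,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"error": "unknown op: %r" % op}, sys.stdout)
        return 2
    try:
        resp = OPS[op](req)
    except Exception as exc:  # surfaced to R as a structured error
        json.dump({"error": "%s: %s" % (type(exc).__name__, exc)}, sys.stdout)
        return 1
    json.dump(resp, sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
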