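"""Batch chemistry backend for the wwbreak R package.

Called as a subprocess, one invocation per batch:

    python chemtool.py standardize  <in.csv>  <out.csv>
    python chemtool.py fingerprint  <in.csv>  <out.csv>  <maccs|ecfp|rdkit>
    python chemtool.py smarts       <in.csv>  <out.csv>  <rules.tsv>
    python chemtool.py checkrules   <out.csv>  <rules.tsv>

Input CSV always has columns: substance_id, smiles.
All outputs are plain CSV; fingerprints/match rows are serialized as strings
of '0'/'1' so the R side stays format-agnostic about bit width.
"""
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, MACCSkeys
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

_UNCHARGER = rdMolStandardize.Uncharger()


def _read_input(path):
    with open(path, newline="") as fh:
        rows = list(csv.DictReader(fh))
    return [(r["substance_id"], r["smiles"]) for r in rows]


def _standardize_one(smiles):
    """largest organic fragment -> neutralize -> canonicalize.

    Returns (canonical_smiles, structure_key, valid, reason). Mixtures that
    keep >1 distinct organic fragment after counterion/solvent stripping are
    flagged invalid (breakthrough of a mixture is ill-defined per structure).
    Stereo is retained in the canonical SMILES but the structure key is the
    stereo-insensitive first block of the InChIKey.
    """
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return "", "", 0, "unparseable"
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    organic = []
    for f in frags:
        if any(a.GetSymbol() == "C" for a in f.GetAtoms()):
            organic.append(f)
    if not organic:
        return "", "", 0, "no organic fragment"
    distinct = {Chem.MolToSmiles(f) for f in organic}
    if len(distinct) > 1:
        return "", "", 0, "multi-fragment mixture"
    frag = max(organic, key=lambda m: m.GetNumHeavyAtoms())
    try:
        frag = _UNCHARGER.uncharge(frag)
        Chem.SanitizeMol(frag)
        can = Chem.MolToSmiles(frag)
        key = Chem.MolToInchiKey(frag)
    except Exception:
        return "", "", 0, "standardization failed"
    if not key:
        return "", "", 0, "no inchikey"
    return can, key.split("-")[0], 1, ""


def cmd_standardize(inp, outp):
    with open(outp, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["substance_id", "smiles_canonical", "structure_key",
                    "valid", "reason"])
        for sid, smi in _read_input(inp):
            can, key, valid, reason = _standardize_one(smi)
            w.writerow([sid, can, key, valid, reason])


def _fp_bits(mol, kind):
    if kind == "maccs":
        # drop the unused bit 0 so exactly the 166 public keys remain
        return MACCSkeys.GenMACCSKeys(mol).ToBitString()[1:]
    if kind == "ecfp":
        return AllChem.GetMorganFingerprintAsBitVect(
            mol, radius=2, nBits=2048).ToBitString()
    if kind == "rdkit":
        return Chem.RDKFingerprint(mol, fpSize=2048).ToBitString()
    raise SystemExit("unknown fingerprint kind: %s" % kind)


def cmd_fingerprint(inp, outp, kind):
    nbits = {"maccs": 166, "ecfp": 2048, "rdkit": 2048}[kind]
    with open(outp, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["substance_id", "valid", "bits"])
        for sid, smi in _read_input(inp):
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                w.writerow([sid, 0, "0" * nbits])
            else:
                w.writerow([sid, 1, _fp_bits(mol, kind)])


def _read_rules(path):
    rules = []
    with open(path, newline="") as fh:
        rd = csv.DictReader(fh, delimiter="\t")
        for r in rd:
            rules.append((r["rule_id"], r["smarts"]))
    return rules


def cmd_smarts(inp, outp, rulefile):
    rules = _read_rules(rulefile)
    pats = []
    for rid, sm in rules:
        p = Chem.MolFromSmarts(sm)
        if p is None:
            raise SystemExit("SMARTS for rule %s does not compile: %s"
                             % (rid, sm))
        pats.append(p)
    with open(outp, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["substance_id", "valid", "bits"])
        for sid, smi in _read_input(inp):
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                w.writerow([sid, 0, "0" * len(pats)])
            else:
                bits = "".join(
                    "1" if mol.HasSubstructMatch(p) else "0" for p in pats)
                w.writerow([sid, 1, bits])


def cmd_checkrules(rulefile, outp):
    with open(outp, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["rule_id", "compiles"])
        for rid, sm in _read_rules(rulefile):
            w.writerow([rid, 1 if Chem.MolFromSmarts(sm) is not None else 0])


def main(argv):
    cmd = argv[1]
    if cmd == "standardize":
        cmd_standardize(argv[2], argv[3])
    elif cmd == "fingerprint":
        cmd_fingerprint(argv[2], argv[3], argv[4])
    elif cmd == "smarts":
        cmd_smarts(argv[2], argv[3], argv[4])
    elif cmd == "checkrules":
        cmd_checkrules(argv[3], argv[2])
    else:
        raise SystemExit("unknown command: %s" % cmd)


if __name__ == "__main__":
    main(sys.argv)
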