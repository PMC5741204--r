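"""Structure parsing/normalization bridge.

Reads a JSON array of jobs from stdin:
    [{"id": ..., "text": ..., "dialect": "InChI"|"SMILES", "normalize": bool}, ...]
and writes a JSON array of results to stdout, one per job, in order:
    {"id": ..., "ok": true, "atoms": [{"element","aromatic","charge","stereo"}...],
     "bonds": [{"from","to","order"}...]}   (1-based atom indices; order in 1/2/3/"a")
or  {"id": ..., "ok": false, "error": "..."}.

Normalization: keep largest covalent fragment, neutralize formal charges,
perceive aromaticity, drop explicit hydrogens, keep stereo descriptors.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

_ORDER = {
    Chem.BondType.SINGLE: 1,
    Chem.BondType.DOUBLE: 2,
    Chem.BondType.TRIPLE: 3,
    Chem.BondType.AROMATIC: "a",
}

_CHIRAL = {
    Chem.ChiralType.CHI_TETRAHEDRAL_CW: "CW",
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW: "CCW",
}


def _parse(text, dialect):
    if dialect == "InChI":
        mol = Chem.MolFromInchi(text, sanitize=True, treatWarningAsError=False)
    elif dialect == "SMILES":
        mol = Chem.MolFromSmiles(text, sanitize=True)
    else:
        raise ValueError("unknown dialect: %r" % dialect)
    if mol is None:
        raise ValueError("unparsable %s: %r" % (dialect, text))
    if mol.GetNumAtoms() == 0:
        raise ValueError("empty molecule: %r" % text)
    return mol


def _normalize(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    mol = max(frags, key=lambda m: m.GetNumAtoms())
    mol = rdMolStandardize.Uncharger().uncharge(mol)
    if any(a.GetFormalCharge() != 0 for a in mol.GetAtoms()):
        # Uncharger leaves charge-separated groups (nitro, quaternary N).
        # Try zeroing them all with implicit-H recomputation; keep the
        # uncharged-as-far-as-possible form when that violates valence
        # (e.g. nitro would need pentavalent N).
        trial = Chem.RWMol(mol)
        for atom in trial.GetAtoms():
            if atom.GetFormalCharge() != 0:
                atom.SetFormalCharge(0)
                atom.SetNoImplicit(False)
        try:
            trial = trial.GetMol()
            Chem.SanitizeMol(trial)
            mol = trial
        except Exception:
            pass
    Chem.SetAromaticity(mol)
    mol = Chem.RemoveHs(mol)
    Chem.AssignStereochemistry(mol, cleanIt=True, force=True)
    return mol


def _emit(mol):
    atoms = []
    for atom in mol.GetAtoms():
        stereo = _CHIRAL.get(atom.GetChiralTag(), "")
        if atom.HasProp("_CIPCode"):
            stereo = atom.GetProp("_CIPCode")
        atoms.append(
            {
                "element": atom.GetSymbol(),
                "aromatic": atom.GetIsAromatic(),
                "charge": atom.GetFormalCharge(),
                "stereo": stereo,
            }
        )
    bonds = []
    for bond in mol.GetBonds():
        order = _ORDER.get(bond.GetBondType())
        if order is None:
            raise ValueError("unsupported bond type: %s" % bond.GetBondType())
        bonds.append(
            {
                "from": bond.GetBeginAtomIdx() + 1,
                "to": bond.GetEndAtomIdx() + 1,
                "order": order,
            }
        )
    return {"atoms": atoms, "bonds": bonds}


def main():
    jobs = json.load(sys.stdin)
    out = []
    for job in jobs:
        try:
            mol = _parse(job["text"], job["dialect"])
            if job.get("normalize", False):
                mol = _normalize(mol)
            res = _emit(mol)
            res.update(id=job["id"], ok=True)
        except Exception as exc:  # report per-job, never crash the batch
            res = {"id": job["id"], "ok": False, "error": str(exc)}
        out.append(res)
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
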