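#!/usr/bin/env python
"""Structure backend for the probescore R package.

Reads a two-column TSV (compound_id, smiles) and writes a TSV with one row
per compound: parse status, ring count, canonical level-1 scaffold-tree
scaffold, and PAINS alert names / score. All chemistry is delegated to
RDKit so the R side never parses a structure itself.

Level-1 scaffold convention: the scaffold tree is rooted at a single ring
(level 0); level 1 is the two-ring scaffold selected by prioritized ring
removal. Murcko frameworks with <= 2 rings are their own level-1 scaffold.
Ring-removal prioritization implements the core of the published rule set
(3-membered heterocycles removed first; macrocycles of >= 12 atoms kept
while smaller rings can go; parents with fewer acyclic linker bonds
preferred; heteroatom-poor rings removed before heteroatom-rich ones) with
residual ties broken by canonical-SMILES order, so the assignment is fully
deterministic.

PAINS: defaults to RDKit's built-in FilterCatalog families A/B/C (the
published pan-assay-interference filters); an optional plain-text SMARTS
file (lines: SMARTS<TAB>name, '#' comments) overrides the catalog.

Usage: chem_backend.py IN.tsv OUT.tsv [--pains-file FILE] [--sdf]
With --sdf, IN is an SDF file; compound_id is the molecule title (_Name).
"""

import sys
import argparse

from rdkit import Chem, RDLogger
from rdkit.Chem import FilterCatalog
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")


def load_pains_matcher(path=None):
    if path is None:
        params = FilterCatalog.FilterCatalogParams()
        for fam in ("PAINS_A", "PAINS_B", "PAINS_C"):
            params.AddCatalog(
                getattr(FilterCatalog.FilterCatalogParams.FilterCatalogs, fam))
        cat = FilterCatalog.FilterCatalog(params)

        def match(mol):
            return sorted(e.GetDescription() for e in cat.GetMatches(mol))
        return match

    patterns = []
    with open(path) as fh:
        for line in fh:
            line = line.strip()
            if not line or line.startswith("#"):
                continue
            parts = line.split("\t")
            smarts = parts[0]
            name = parts[1] if len(parts) > 1 else smarts
            patt = Chem.MolFromSmarts(smarts)
            if patt is None:
                sys.stderr.write("bad SMARTS skipped: %s\n" % smarts)
                continue
            patterns.append((patt, name))

    def match(mol):
        return sorted(n for p, n in patterns if mol.HasSubstructMatch(p))
    return match


def largest_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) <= 1:
        return mol
    frag = max(frags, key=lambda m: m.GetNumHeavyAtoms())
    Chem.SanitizeMol(frag)
    return frag


def n_rings(mol):
    return mol.GetRingInfo().NumRings()


def linker_bond_count(mol):
    """Acyclic single bonds between ring systems / linker atoms."""
    return sum(1 for b in mol.GetBonds() if not b.IsInRing())


def ring_heteroatoms(mol, ring):
    return sum(1 for i in ring if mol.GetAtomWithIdx(i).GetAtomicNum() not in (6,))


def candidate_children(scaf):
    """All valid one-ring-removal children of a Murcko scaffold.

    A ring may be removed when deleting its exclusive atoms (atoms in no
    other SSSR ring) leaves a single connected, sanitizable fragment whose
    re-derived Murcko framework has exactly one ring fewer.
    """
    ri = scaf.GetRingInfo()
    rings = [set(r) for r in ri.AtomRings()]
    out = []
    for k, ring in enumerate(rings):
        shared = set().union(*(r for j, r in enumerate(rings) if j != k)) \
            if len(rings) > 1 else set()
        exclusive = sorted(ring - shared, reverse=True)
        if not exclusive:
            continue
        em = Chem.RWMol(scaf)
        for idx in exclusive:
            em.RemoveAtom(idx)
        child = em.GetMol()
        try:
            Chem.SanitizeMol(child)
        except Exception:
            continue
        if len(Chem.GetMolFrags(child)) != 1:
            continue
        child = MurckoScaffold.GetScaffoldForMol(child)
        if child.GetNumAtoms() == 0 or n_rings(child) != n_rings(scaf) - 1:
            continue
        info = {
            "removed_size": len(ring),
            "removed_hetero": ring_heteroatoms(scaf, ring),
            "child": child,
            "child_smiles": Chem.MolToSmiles(child),
            "child_linkers": linker_bond_count(child),
        }
        out.append(info)
    return out


def pick_child(cands):
    # rule: remove 3-membered heterocycles first
    hits = [c for c in cands if c["removed_size"] == 3 and c["removed_hetero"] > 0]
    if hits:
        cands = hits
    # rule: do not remove macrocycles (>= 12 atoms) while smaller rings exist
    small = [c for c in cands if c["removed_size"] < 12]
    if small:
        cands = small
    # rule: prefer the parent scaffold with fewest acyclic linker bonds
    m = min(c["child_linkers"] for c in cands)
    cands = [c for c in cands if c["child_linkers"] == m]
    # rule: remove heteroatom-poor rings first (retain heterocycles)
    m = min(c["removed_hetero"] for c in cands)
    cands = [c for c in cands if c["removed_hetero"] == m]
    # residual tie-break: canonical-SMILES order of the child
    return min(cands, key=lambda c: c["child_smiles"])


def level1_scaffold(mol):
    """Canonical level-1 scaffold-tree scaffold SMILES ('' if acyclic)."""
    scaf = MurckoScaffold.GetScaffoldForMol(mol)
    if scaf.GetNumAtoms() == 0 or n_rings(scaf) == 0:
        return "", 0
    total = n_rings(scaf)
    while n_rings(scaf) > 2:
        cands = candidate_children(scaf)
        if not cands:
            break  # e.g. fully bridged cage: keep as its own scaffold
        scaf = pick_child(cands)["child"]
    return Chem.MolToSmiles(scaf), total


def iter_input(path, sdf=False):
    if sdf:
        for i, mol in enumerate(Chem.SDMolSupplier(path, sanitize=True)):
            if mol is None:
                yield "sdf_record_%d" % (i + 1), None
            else:
                cid = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
                yield (cid or "sdf_record_%d" % (i + 1)), mol
        return
    with open(path) as fh:
        header = fh.readline()
        if not header:
            return
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            cid, smi = line.split("\t", 1)
            yield cid, Chem.MolFromSmiles(smi)


def main(argv=None):
    ap = argparse.ArgumentParser()
    ap.add_argument("infile")
    ap.add_argument("outfile")
    ap.add_argument("--pains-file", default=None)
    ap.add_argument("--sdf", action="store_true")
    args = ap.parse_args(argv)

    match_pains = load_pains_matcher(args.pains_file)

    with open(args.outfile, "w") as out:
        out.write("compound_id\tparse_ok\tn_rings\tlevel1_scaffold\t"
                  "pains_alerts\tpains_score\tcanonical_smiles\n")
        for cid, mol in iter_input(args.infile, sdf=args.sdf):
            if mol is None:
                # unparseable: no alert observable -> PAINS score 1 by policy
                out.write("%s\tFALSE\t0\t\t\t1\t\n" % cid)
                continue
            mol = largest_fragment(mol)
            scaffold, nr = level1_scaffold(mol)
            alerts = match_pains(mol)
            out.write("%s\tTRUE\t%d\t%s\t%s\t%d\t%s\n" % (
                cid, nr, scaffold, ";".join(alerts),
                0 if alerts else 1, Chem.MolToSmiles(mol)))
    return 0


if __name__ == "__main__":
    sys.exit(main())
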