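"""External structural-alignment oracle.

Reads a JSON manifest [{"id": ..., "query": path, "reference": path}, ...],
aligns each pair with biotite's sequence-independent structural-homolog
superimposition, and prints "<id> <TM-score>" per line, TM normalised by
the reference length. Used to cross-check the package's own aligner.
"""
import json
import sys

import biotite.structure as bs
import biotite.structure.io.pdbx as pdbx


def load_ca(path):
    arr = pdbx.get_structure(pdbx.CIFFile.read(path), model=1)
    return arr[arr.atom_name == "CA"]


def main():
    pairs = json.load(open(sys.argv[1]))
    for item in pairs:
        query = load_ca(item["query"])
        ref = load_ca(item["reference"])
        fitted, _tf, ref_idx, q_idx = bs.superimpose_structural_homologs(
            ref, query)
        tm = bs.tm_score(ref, fitted, ref_idx, q_idx,
                         reference_length=len(ref))
        print(item["id"], tm)


if __name__ == "__main__":
    main()
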