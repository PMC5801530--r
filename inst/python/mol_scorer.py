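"""Molecular property worker.

Serves chemical validity checks and descriptor calculations (Crippen logP,
Ertl-Schuffenhauer synthetic accessibility, largest-SSSR ring size) over a
line-oriented JSON protocol on a localhost socket, so the calling process
pays the RDKit import cost once per session instead of once per molecule.

Protocol: each request line is {"smiles": [...]}; the response line is a
JSON array with one object per input:
  {"valid": bool, "logp": float|null, "sa": float|null,
   "largest_ring": int|null, "canonical": str|null}
The worker exits when the client closes the connection.
"""

import json
import os
import socket
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, RDConfig

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def score_one(smiles):
    mol = Chem.MolFromSmiles(smiles) if smiles else None
    if mol is None:
        return {"valid": False, "logp": None, "sa": None,
                "largest_ring": None, "canonical": None}
    ring_info = mol.GetRingInfo()
    sizes = [len(r) for r in ring_info.AtomRings()]
    return {
        "valid": True,
        "logp": Crippen.MolLogP(mol),
        "sa": sascorer.calculateScore(mol),
        "largest_ring": max(sizes) if sizes else 0,
        "canonical": Chem.MolToSmiles(mol),
    }


def main():
    port_file = sys.argv[1]
    srv = socket.socket()
    srv.bind(("127.0.0.1", 0))
    with open(port_file, "w") as fh:
        fh.write(str(srv.getsockname()[1]))
    srv.listen(1)
    conn, _ = srv.accept()
    stream = conn.makefile("rw", encoding="utf-8")
    for line in stream:
        line = line.strip()
        if not line:
            continue
        req = json.loads(line)
        out = [score_one(s) for s in req["smiles"]]
        stream.write(json.dumps(out) + "\n")
        stream.flush()


if __name__ == "__main__":
    main()
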