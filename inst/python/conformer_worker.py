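"""Socket worker generating seeded MMFF94-optimized conformers with RDKit.

Started by the R package; speaks a line protocol over a local TCP socket:
  request : CONF\t<seed>\t<max_attempts>\t<molblock with newlines as \x1e>
  reply   : one JSON line {"ok": true, "attempts": k, "coords": [[x,y,z],...]}
            or {"ok": false, "error": "..."}
The worker exits when the connection closes.
"""
import json
import socket
import sys
import time

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def conformer(molblock, seed, max_attempts):
    mol = Chem.MolFromMolBlock(molblock, removeHs=False)
    if mol is None:
        return {"ok": False, "error": "molblock did not parse"}
    n_heavy = mol.GetNumAtoms()
    molh = Chem.AddHs(mol)
    attempts = 0
    for k in range(max_attempts):
        attempts += 1
        if AllChem.EmbedMolecule(molh, randomSeed=seed + 1009 * k) == 0:
            try:
                if AllChem.MMFFOptimizeMolecule(molh) != 0:
                    AllChem.UFFOptimizeMolecule(molh)
            except Exception:
                try:
                    AllChem.UFFOptimizeMolecule(molh)
                except Exception:
                    pass
            conf = molh.GetConformer()
            coords = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
                       conf.GetAtomPosition(i).z] for i in range(n_heavy)]
            return {"ok": True, "attempts": attempts, "coords": coords}
    return {"ok": False, "attempts": attempts,
            "error": "embedding failed after %d attempts" % attempts}


def main():
    port = int(sys.argv[1])
    sock = None
    deadline = time.time() + 60
    while time.time() < deadline:
        try:
            sock = socket.create_connection(("127.0.0.1", port), timeout=5)
            break
        except OSError:
            time.sleep(0.1)
    if sock is None:
        sys.exit(1)
    f = sock.makefile("rw", encoding="utf-8", newline="\n")
    f.write("HELLO\n")
    f.flush()
    for line in f:
        line = line.rstrip("\n")
        if not line or line == "QUIT":
            break
        if line == "PING":
            f.write("PONG\n")
            f.flush()
            continue
        try:
            cmd, seed, max_attempts, payload = line.split("\t", 3)
            assert cmd == "CONF"
            molblock = payload.replace("\x1e", "\n")
            out = conformer(molblock, int(seed), int(max_attempts))
        except Exception as exc:  # malformed request: report, keep serving
            out = {"ok": False, "error": str(exc)}
        f.write(json.dumps(out) + "\n")
        f.flush()
    sock.close()


if __name__ == "__main__":
    main()
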