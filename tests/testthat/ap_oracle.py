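"""Reference affinity propagation (scikit-learn) for cross-checking apc().

Reads a JSON list of {"S": matrix, "preference": float, "damping": float}
instances on stdin; writes a JSON list of {"exemplars": [...], "labels":
[...]} (1-based) on stdout.
"""
import sys
import json
import numpy as np
from sklearn.cluster import AffinityPropagation

data = json.load(sys.stdin)
out = []
for inst in data:
    S = np.array(inst["S"], dtype=float)
    ap = AffinityPropagation(affinity="precomputed",
                             preference=inst["preference"],
                             damping=inst["damping"],
                             max_iter=inst.get("max_iter", 2000),
                             convergence_iter=inst.get("convergence_iter", 200),
                             random_state=0)
    labels = ap.fit_predict(S)
    ex = ap.cluster_centers_indices_
    out.append({"exemplars": (ex + 1).tolist() if ex is not None else [],
                "labels": (labels + 1).tolist()})
print(json.dumps(out))
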