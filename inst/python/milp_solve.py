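"""Batched exact 0/1 MILP solves via scipy.optimize.milp (HiGHS).

Reads a JSON file {"time_limit": s, "models": [...]} where each model is
{"sense": "min"|"max", "vars": [names], "obj": {name: coef},
 "constraints": [{"coefs": {name: coef}, "dir": "<="|">="|"==", "rhs": r}]}
and writes a JSON list with one entry per model:
{"status": "optimal"|"infeasible"|"limit-reached", "objective": v, "x": [...]}.
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp


def solve_one(model, time_limit):
    names = list(model["vars"])
    idx = {v: i for i, v in enumerate(names)}
    n = len(names)
    c = np.zeros(n)
    for v, coef in model.get("obj", {}).items():
        c[idx[v]] = coef
    sign = 1.0
    if model["sense"] == "max":
        sign = -1.0
    cons = model.get("constraints", [])
    rows = np.zeros((len(cons), n))
    lb = np.full(len(cons), -np.inf)
    ub = np.full(len(cons), np.inf)
    for k, ct in enumerate(cons):
        for v, coef in ct["coefs"].items():
            rows[k, idx[v]] = coef
        rhs = float(ct["rhs"])
        if ct["dir"] == "<=":
            ub[k] = rhs
        elif ct["dir"] == ">=":
            lb[k] = rhs
        else:
            lb[k] = rhs
            ub[k] = rhs
    constraints = []
    if len(cons) > 0:
        constraints = [LinearConstraint(rows, lb, ub)]
    res = milp(
        c=sign * c,
        constraints=constraints,
        integrality=np.ones(n),
        bounds=Bounds(0, 1),
        options={"time_limit": time_limit},
    )
    # scipy milp status codes: 0 optimal, 1 iteration/time limit,
    # 2 infeasible, 3 unbounded, 4 other
    if res.status == 0:
        x = [int(round(v)) for v in res.x]
        obj = float(np.dot(c, res.x))
        return {"status": "optimal", "objective": obj, "x": x}
    if res.status == 2:
        return {"status": "infeasible", "objective": None, "x": None}
    if res.status == 1:
        return {"status": "limit-reached", "objective": None, "x": None}
    raise RuntimeError(f"unexpected solver status {res.status}: {res.message}")


def main(argv):
    fin, fout = argv[1], argv[2]
    with open(fin) as fh:
        payload = json.load(fh)
    time_limit = float(payload.get("time_limit", 60))
    out = [solve_one(m, time_limit) for m in payload["models"]]
    with open(fout, "w") as fh:
        json.dump(out, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
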