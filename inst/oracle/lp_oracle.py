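#!/usr/bin/env python
"""Independent LP/QP oracle for the test suite.

Reads a JSON file holding a list of problems and writes a JSON list of
results. Each problem is one of:

  {"type": "lp", "obj": [...], "A": [[...]], "b": [...],
   "lb": [...], "ub": [...], "maximize": bool}
      -> solved with scipy.optimize.linprog (HiGHS)

  {"type": "qp", "A": [[...]], "b": [...], "lb": [...], "ub": [...],
   "vref": [...]}
      -> minimize sum((v - vref)^2) s.t. A v = b, lb <= v <= ub,
         solved with scipy.optimize.minimize(method="trust-constr")

Results: {"status": "optimal"|"infeasible"|"unbounded"|"error",
          "objective": float or None}
"""
import json
import sys

import numpy as np
from scipy.optimize import LinearConstraint, linprog, minimize


def solve_lp(p):
    A = np.asarray(p["A"], dtype=float)
    if A.ndim == 1:
        A = A.reshape(1, -1)
    b = np.atleast_1d(np.asarray(p["b"], dtype=float))
    c = np.asarray(p["obj"], dtype=float)
    sense = -1.0 if p.get("maximize", False) else 1.0
    bounds = list(zip(p["lb"], p["ub"]))
    res = linprog(sense * c, A_eq=A, b_eq=b, bounds=bounds, method="highs")
    if res.status == 0:
        return {"status": "optimal", "objective": float(sense * res.fun)}
    if res.status == 2:
        return {"status": "infeasible", "objective": None}
    if res.status == 3:
        return {"status": "unbounded", "objective": None}
    return {"status": "error", "objective": None}


def solve_qp(p):
    A = np.asarray(p["A"], dtype=float)
    if A.ndim == 1:
        A = A.reshape(1, -1)
    b = np.atleast_1d(np.asarray(p["b"], dtype=float))
    lb = np.asarray(p["lb"], dtype=float)
    ub = np.asarray(p["ub"], dtype=float)
    vref = np.asarray(p["vref"], dtype=float)
    # feasibility check via LP first
    feas = linprog(np.zeros(len(lb)), A_eq=A, b_eq=b,
                   bounds=list(zip(lb, ub)), method="highs")
    if feas.status != 0:
        return {"status": "infeasible", "objective": None}

    # reduce to the null space of the equality block: v = v0 + N z
    from scipy.linalg import null_space, lstsq
    v0, *_ = lstsq(A, b)
    N = null_space(A)
    if N.shape[1] == 0:
        return {"status": "optimal", "objective": float(np.sum((v0 - vref) ** 2))}

    def f(z):
        d = v0 + N @ z - vref
        return float(d @ d)

    def g(z):
        return 2.0 * N.T @ (v0 + N @ z - vref)

    def h(z):
        return 2.0 * N.T @ N

    z0, *_ = lstsq(N, np.clip(feas.x, lb, ub) - v0)
    res = minimize(f, z0, jac=g, hess=h, method="trust-constr",
                   constraints=[LinearConstraint(N, lb - v0, ub - v0)],
                   options={"gtol": 1e-12, "xtol": 1e-14, "maxiter": 5000})
    return {"status": "optimal", "objective": float(res.fun)}


def main():
    inp, outp = sys.argv[1], sys.argv[2]
    with open(inp) as fh:
        problems = json.load(fh)
    results = []
    for p in problems:
        try:
            if p["type"] == "lp":
                results.append(solve_lp(p))
            elif p["type"] == "qp":
                results.append(solve_qp(p))
            else:
                results.append({"status": "error", "objective": None})
        except Exception:
            results.append({"status": "error", "objective": None})
    with open(outp, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
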