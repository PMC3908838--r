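"""Independent LP-SVM oracle: assemble the weighted-slack LP directly and
solve it with scipy.optimize.linprog (HiGHS). Reads a JSON list of
instances (K, y, yprime, theta, c), writes a JSON list of objectives."""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(inst):
    K = np.asarray(inst["K"], dtype=float)
    y = np.asarray(inst["y"], dtype=float)
    yp = np.asarray(inst["yprime"], dtype=float)
    theta = np.asarray(inst["theta"], dtype=float)
    c = float(inst["c"])
    l, lp = K.shape
    # variables x = [alpha (lp), b, r, xi (l)]
    n = lp + 2 + l
    cv = np.zeros(n)
    cv[lp + 1] = -1.0
    cv[lp + 2:] = c * theta
    # margin rows: y_i (sum_j alpha_j yp_j K_ij + b) - r + xi_i >= 0
    A = np.zeros((l, n))
    A[:, :lp] = -(y[:, None] * K * yp[None, :])
    A[:, lp] = -y
    A[:, lp + 1] = 1.0
    A[:, lp + 2:] = -np.eye(l)
    bounds = [(-1, 1)] * lp + [(None, None)] + [(0, None)] * (1 + l)
    res = linprog(cv, A_ub=A, b_ub=np.zeros(l), bounds=bounds,
                  method="highs")
    return {"objective": res.fun, "status": int(res.status)}


def main():
    with open(sys.argv[1]) as fh:
        instances = json.load(fh)
    out = [solve(inst) for inst in instances]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
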