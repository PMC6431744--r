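#!/usr/bin/env python
"""Batch LP/MILP solving service for optcoupleR.

Reads a JSON file describing a list of linear or mixed-integer linear
programs, solves each with the HiGHS solver via scipy.optimize, and writes a
JSON file with statuses, objective values, solution vectors and (for MILPs)
a solution pool harvested with no-good integer cuts.

Every scalar in the input is encoded as a one-element list (the R side
serialises with auto_unbox=FALSE so that one-element vectors stay arrays);
helper `s()` unwraps them.  Infinite bounds are encoded as +/-1e30.

Usage: python lp_backend.py <input.json> <output.json>
"""

import json
import sys
import time

import numpy as np
import scipy.sparse as sp
from scipy.optimize import milp, Bounds, LinearConstraint

INF_SENTINEL = 1e29

STATUS = {
    0: "optimal",
    1: "time_limit",
    2: "infeasible",
    3: "unbounded",
    4: "error",
}


def s(value):
    """Unwrap a length-one list to a scalar."""
    if isinstance(value, list):
        return value[0]
    return value


def decode_inf(values):
    arr = np.asarray(values, dtype=float)
    arr[arr >= INF_SENTINEL] = np.inf
    arr[arr <= -INF_SENTINEL] = -np.inf
    return arr


def row_bounds(sense, rhs):
    lo = np.where(np.isin(sense, ["E", "G"]), rhs, -np.inf)
    hi = np.where(np.isin(sense, ["E", "L"]), rhs, np.inf)
    return lo, hi


def solve_once(c, A, row_lo, row_hi, lb, ub, integrality, maximize, time_limit):
    sign = -1.0 if maximize else 1.0
    constraints = []
    if A is not None and A.shape[0] > 0:
        constraints.append(LinearConstraint(A, row_lo, row_hi))
    options = {}
    if time_limit is not None:
        options["time_limit"] = float(time_limit)
    res = milp(
        c=sign * c,
        constraints=constraints,
        bounds=Bounds(lb, ub),
        integrality=integrality,
        options=options,
    )
    status = STATUS.get(res.status, "error")
    obj = None
    x = None
    if res.x is not None:
        x = np.asarray(res.x, dtype=float)
        obj = float(sign * res.fun)
    return status, obj, x


def solve_problem(prob):
    t0 = time.time()
    lb = decode_inf(prob["lb"])
    ub = decode_inf(prob["ub"])
    c = np.asarray(prob["obj"], dtype=float)
    n = len(c)
    maximize = bool(s(prob["maximize"]))
    integer_idx = [int(i) for i in prob.get("integer", [])]
    integrality = np.zeros(n)
    integrality[integer_idx] = 1

    Araw = prob.get("A")
    nrow = int(s(prob.get("nrow", [0])))
    if Araw is not None and nrow > 0:
        A = sp.csc_matrix(
            (
                np.asarray(Araw["x"], dtype=float),
                (
                    np.asarray(Araw["i"], dtype=int),
                    np.asarray(Araw["j"], dtype=int),
                ),
            ),
            shape=(nrow, n),
        )
        sense = np.asarray(prob["sense"])
        rhs = np.asarray(prob["rhs"], dtype=float)
        row_lo, row_hi = row_bounds(sense, rhs)
    else:
        A, row_lo, row_hi = None, None, None

    time_limit = prob.get("time_limit")
    time_limit = float(s(time_limit)) if time_limit is not None else None

    status, obj, x = solve_once(
        c, A, row_lo, row_hi, lb, ub, integrality, maximize, time_limit
    )
    first_time = time.time() - t0

    out = {
        "status": status,
        "objective": obj,
        "x": x.tolist() if x is not None else None,
        "pool": [],
        "wall_time_s": None,
    }

    pool_spec = prob.get("pool")
    if pool_spec is not None and status in ("optimal", "time_limit") and x is not None:
        bin_idx = np.asarray([int(i) for i in pool_spec["binaries"]], dtype=int)
        max_solutions = int(s(pool_spec.get("max_solutions", [20])))
        factor = float(s(pool_spec.get("time_budget_factor", [10])))
        cap = float(s(pool_spec.get("time_cap", [3600])))
        floor_raw = pool_spec.get("obj_floor")
        obj_floor = float(s(floor_raw)) if floor_raw is not None else None
        budget = min(max(factor * first_time, 0.5), cap)

        seen = set()
        harvest_start = time.time()

        def record(xv, objv):
            assign = tuple(int(round(v)) for v in xv[bin_idx])
            if assign in seen:
                return None
            seen.add(assign)
            out["pool"].append({"assignment": list(assign), "objective": objv})
            return assign

        def add_cut(A, row_lo, row_hi, assign):
            """No-good cut: sum_{a=0} y + sum_{a=1} (1-y) >= 1."""
            coef = np.zeros(n)
            a = np.asarray(assign, dtype=float)
            coef[bin_idx] = np.where(a > 0.5, -1.0, 1.0)
            rhs_cut = 1.0 - float(np.sum(a > 0.5))
            row = sp.csc_matrix(coef)
            if A is None:
                A2 = row
                lo2 = np.array([rhs_cut])
                hi2 = np.array([np.inf])
            else:
                A2 = sp.vstack([A, row], format="csc")
                lo2 = np.append(row_lo, rhs_cut)
                hi2 = np.append(row_hi, np.inf)
            return A2, lo2, hi2

        assign = record(x, obj)
        cur_status, cur_obj, cur_x = status, obj, x
        while (
            assign is not None
            and len(out["pool"]) < max_solutions
            and time.time() - harvest_start < budget
        ):
            A, row_lo, row_hi = add_cut(A, row_lo, row_hi, assign)
            remaining = budget - (time.time() - harvest_start)
            cur_status, cur_obj, cur_x = solve_once(
                c, A, row_lo, row_hi, lb, ub, integrality, maximize,
                max(remaining, 0.1),
            )
            if cur_status not in ("optimal",) or cur_x is None:
                break
            if obj_floor is not None and cur_obj <= obj_floor:
                break
            assign = record(cur_x, cur_obj)

        out["pool"].sort(key=lambda e: -e["objective"])

    out["wall_time_s"] = time.time() - t0
    return out


def main(argv):
    with open(argv[1]) as fh:
        payload = json.load(fh)
    results = [solve_problem(p) for p in payload["problems"]]
    with open(argv[2], "w") as fh:
        json.dump({"results": results}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
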