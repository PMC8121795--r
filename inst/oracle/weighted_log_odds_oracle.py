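"""Independent arbitrary-precision oracle for the Dirichlet-prior weighted
log-odds z-score.

Reads a JSON file of cases {"y_a":..,"y_b":..,"n_a":..,"n_b":..,
"alpha0":..,"pooled_total":..}; for each word the prior is
alpha_w = alpha0 * (y_a+y_b)/pooled_total. Evaluates delta, variance and z
at 50 decimal digits with mpmath and writes JSON doubles to stdout.

Usage: python weighted_log_odds_oracle.py cases.json
"""
import json
import sys

import mpmath as mp

mp.mp.dps = 50


def score(case):
    y_a = mp.mpf(case["y_a"])
    y_b = mp.mpf(case["y_b"])
    n_a = mp.mpf(case["n_a"])
    n_b = mp.mpf(case["n_b"])
    alpha0 = mp.mpf(case["alpha0"])
    pooled_total = mp.mpf(case["pooled_total"])
    alpha_w = alpha0 * (y_a + y_b) / pooled_total
    delta = mp.log((y_a + alpha_w) / (n_a + alpha0 - y_a - alpha_w)) - \
        mp.log((y_b + alpha_w) / (n_b + alpha0 - y_b - alpha_w))
    variance = 1 / (y_a + alpha_w) + 1 / (y_b + alpha_w)
    z = delta / mp.sqrt(variance)
    return {"delta": float(delta), "variance": float(variance),
            "z": float(z)}


def main():
    with open(sys.argv[1]) as fh:
        cases = json.load(fh)
    json.dump([score(c) for c in cases], sys.stdout)


if __name__ == "__main__":
    main()
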