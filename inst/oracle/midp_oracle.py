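#!/usr/bin/env python
"""Exact rational-arithmetic oracle for the mid-p hypergeometric test.

Enumerates, for every population size n_tot <= N and all margins
0 <= n_i, n_j <= n_tot, the exact value of

    P(X > n_ij) + 1/2 * P(X = n_ij)

where X ~ Hypergeometric(n_tot, n_j, n_i), for every n_ij in
0..min(n_i, n_j). All arithmetic is exact big-integer rational; each
value is converted to the nearest double only when printed.

Usage: python midp_oracle.py N > grid.tsv
Output columns: n_tot, n_i, n_j, n_ij, midp
"""
import sys
from fractions import Fraction
from math import comb


def main(nmax):
    out = sys.stdout
    out.write("n_tot\tn_i\tn_j\tn_ij\tmidp\n")
    buf = []
    for n_tot in range(1, nmax + 1):
        for n_i in range(0, n_tot + 1):
            for n_j in range(0, n_tot + 1):
                den = comb(n_tot, n_i)
                kmax = min(n_i, n_j)
                nums = []
                for k in range(0, kmax + 1):
                    rest = n_i - k
                    if 0 <= rest <= n_tot - n_j:
                        nums.append(comb(n_j, k) * comb(n_tot - n_j, rest))
                    else:
                        nums.append(0)
                # suffix[k] = sum of PMF numerators for counts > k
                suffix = [0] * (kmax + 2)
                for k in range(kmax, -1, -1):
                    suffix[k] = suffix[k + 1] + nums[k]
                for k in range(0, kmax + 1):
                    val = Fraction(2 * suffix[k + 1] + nums[k], 2 * den)
                    buf.append("%d\t%d\t%d\t%d\t%.17g"
                               % (n_tot, n_i, n_j, k, float(val)))
                if len(buf) > 100000:
                    out.write("\n".join(buf))
                    out.write("\n")
                    buf = []
    if buf:
        out.write("\n".join(buf))
        out.write("\n")


if __name__ == "__main__":
    main(int(sys.argv[1]) if len(sys.argv) > 1 else 60)
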