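# Regenerates the expected-output tables for worked_fixture() by brute
# force, independently of the R implementation.  Run from the repo root.
import math, itertools

recs = {}
with open("inst/extdata/worked_fixture.fasta") as fh:
    name = None
    for line in fh:
        line = line.strip()
        if line.startswith(">"):
            name = line[1:]
            recs[name] = ""
        elif line:
            recs[name] += line

ids = list(recs)
species = {h: h.split("|")[1] for h in ids}
PUR = set("AG"); PYR = set("CT")

def k2p(a, b):
    n = ts = tv = 0
    for x, y in zip(a, b):
        if x in "ACGT" and y in "ACGT":
            n += 1
            if x != y:
                if (x in PUR) == (y in PUR):
                    ts += 1
                else:
                    tv += 1
    P, Q = ts / n, tv / n
    w1, w2 = 1 - 2 * P - Q, 1 - 2 * Q
    if w1 <= 0 or w2 <= 0:
        return P, Q, n, float("nan"), False
    return P, Q, n, -0.5 * math.log(w1) - 0.25 * math.log(w2), True

with open("inst/extdata/worked_fixture_k2p.tsv", "w") as out:
    out.write("id1\tid2\tP\tQ\tn_compared\tdistance\tdefined\n")
    for a, b in itertools.combinations(ids, 2):
        P, Q, n, d, ok = k2p(recs[a], recs[b])
        out.write(f"{a.split('|')[0]}\t{b.split('|')[0]}\t{P:.12g}\t{Q:.12g}\t{n}\t{d:.12g}\t{ok}\n")

# Best Match verdicts by brute force
D = {}
for a, b in itertools.combinations(ids, 2):
    d = k2p(recs[a], recs[b])[3]
    D[a, b] = D[b, a] = d
with open("inst/extdata/worked_fixture_bm.tsv", "w") as out:
    out.write("query\tverdict\tbest_distance\n")
    for q in ids:
        dist = {o: D[q, o] for o in ids if o != q}
        m = min(dist.values())
        best = [o for o in dist if dist[o] <= m + 1e-12]
        hits = [species[o] == species[q] for o in best]
        v = "correct" if all(hits) else ("ambiguous" if any(hits) else "incorrect")
        out.write(f"{q.split('|')[0]}\t{v}\t{m:.12g}\n")
print("done")
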