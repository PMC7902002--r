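"""Coalescent simulation of founder chromosomes.

Reads a JSON parameter file, simulates each chromosome with msprime under a
piecewise-linear effective-population-size history (linear ramp from
ne_present at time 0 to ne_ancient at ne_time generations ago, discretized on
a dense log-spaced grid of piecewise-constant epochs), drops binary mutations
on the trees and writes the segregating 0/1 haplotypes as plain text:

    #chrom <index> <n_sites> <n_haplotypes>
    <site positions, space separated>
    <one 0/1 string per haplotype>

Haplotype columns are ordered so that individual k owns columns 2k and 2k+1.
"""

import json
import sys

import msprime
import numpy as np


def build_demography(cfg):
    d = msprime.Demography()
    d.add_population(name="pop", initial_size=cfg["ne_present"])
    tmax = float(cfg["ne_time"])
    if cfg["ne_ancient"] != cfg["ne_present"]:
        times = np.unique(np.round(np.logspace(0, np.log10(tmax), int(cfg["ne_steps"]))))
        times = times[(times > 0) & (times <= tmax)]
        for t in times:
            ne = cfg["ne_present"] + (cfg["ne_ancient"] - cfg["ne_present"]) * t / tmax
            d.add_population_parameters_change(time=float(t), initial_size=float(ne))
    return d


def main(cfg_path, out_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    demography = build_demography(cfg)
    seeds = cfg["seeds"]  # one (ancestry, mutation) seed pair per chromosome
    with open(out_path, "w") as out:
        for i in range(int(cfg["n_chromosomes"])):
            ts = msprime.sim_ancestry(
                samples=int(cfg["n_founders"]),
                demography=demography,
                sequence_length=float(cfg["physical_length"]),
                recombination_rate=float(cfg["recombination_rate"]),
                ploidy=2,
                random_seed=int(seeds[i][0]),
            )
            mts = msprime.sim_mutations(
                ts,
                rate=float(cfg["mutation_rate"]),
                random_seed=int(seeds[i][1]),
                model=msprime.BinaryMutationModel(),
            )
            g = mts.genotype_matrix()  # sites x haplotypes, 0/1
            seg = (g.max(axis=1) == 1) & (g.min(axis=1) == 0)
            g = g[seg]
            pos = mts.sites_position[seg]
            out.write("#chrom %d %d %d\n" % (i + 1, g.shape[0], g.shape[1]))
            out.write(" ".join(str(int(p)) for p in pos) + "\n")
            for h in range(g.shape[1]):
                out.write("".join("1" if x else "0" for x in g[:, h]) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
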