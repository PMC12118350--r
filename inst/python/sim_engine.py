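"""Coalescent simulation helper.

Reads a JSON demography specification produced by the R package, runs the
msprime coalescent engine and writes genotypes as EIGENSTRAT text
(.geno/.snp/.ind plus a .dates table of per-individual sampling times).

Specification keys:
  populations: [{name, size}]                       msprime populations
  splits:      [{time, derived:[...], ancestral}]   population splits
  admixtures:  [{time, derived, ancestral:[...], proportions:[...]}]
  migrations:  [{time, source, dest, rate}]         backwards "source" semantics:
               rate = fraction of `source`'s individuals that are offspring of
               `dest` per generation (time 0 entries set the initial matrix)
  samples:     [{population, n, time}]              diploid sample sets
  chromosomes: [len, len, ...]                      bp; >1 chromosome joined by
               recombination rate log(2) at the boundary
  recomb_rate, mut_rate: per-nt per-generation rates
  dtwf_generations: use the discrete-time Wright-Fisher model this many
               generations into the past (0 = plain Hudson coalescent)
  seed:        random seed (ancestry; mutations use seed+1)
  out_prefix:  output path prefix
"""

import json
import math
import sys

import msprime
import numpy as np


def build_demography(spec):
    dem = msprime.Demography()
    for pop in spec["populations"]:
        dem.add_population(name=pop["name"], initial_size=pop["size"])
    for ev in spec.get("splits", []):
        dem.add_population_split(
            time=ev["time"], derived=ev["derived"], ancestral=ev["ancestral"]
        )
    for ev in spec.get("admixtures", []):
        dem.add_admixture(
            time=ev["time"],
            derived=ev["derived"],
            ancestral=ev["ancestral"],
            proportions=ev["proportions"],
        )
    for ev in spec.get("migrations", []):
        if ev["time"] == 0:
            dem.set_migration_rate(
                source=ev["source"], dest=ev["dest"], rate=ev["rate"]
            )
        else:
            dem.add_migration_rate_change(
                time=ev["time"], source=ev["source"], dest=ev["dest"],
                rate=ev["rate"],
            )
    dem.sort_events()
    return dem


def rate_map(chrom_lengths, recomb_rate):
    if len(chrom_lengths) == 1:
        return chrom_lengths[0], recomb_rate, None
    # chromosomes laid head to tail, separated by 1 nt with rate ln(2),
    # which makes them effectively unlinked
    positions = [0.0]
    rates = []
    for i, length in enumerate(chrom_lengths):
        positions.append(positions[-1] + length)
        rates.append(recomb_rate)
        if i < len(chrom_lengths) - 1:
            positions.append(positions[-1] + 1)
            rates.append(math.log(2))
    rmap = msprime.RateMap(position=positions, rate=rates)
    return positions[-1], None, rmap


def chrom_of(positions, chrom_lengths):
    bounds = np.cumsum([length + 1 for length in chrom_lengths])
    starts = np.concatenate([[0], bounds[:-1]])
    idx = np.searchsorted(bounds - 1, positions, side="right")
    return idx + 1, positions - starts[idx]


def main(path):
    with open(path) as fh:
        spec = json.load(fh)
    dem = build_demography(spec)
    samples = [
        msprime.SampleSet(s["n"], population=s["population"],
                          time=s.get("time", 0), ploidy=2)
        for s in spec["samples"]
    ]
    total_len, rrate, rmap = rate_map(spec["chromosomes"], spec["recomb_rate"])
    dtwf = spec.get("dtwf_generations", 0)
    if dtwf > 0:
        model = [
            msprime.DiscreteTimeWrightFisher(duration=dtwf),
            msprime.StandardCoalescent(),
        ]
    else:
        model = msprime.StandardCoalescent()
    kwargs = dict(
        samples=samples,
        demography=dem,
        model=model,
        random_seed=spec["seed"],
    )
    if rmap is None:
        kwargs.update(sequence_length=total_len, recombination_rate=rrate)
    else:
        kwargs.update(recombination_rate=rmap)
    ts = msprime.sim_ancestry(**kwargs)
    ts = msprime.sim_mutations(
        ts, rate=spec["mut_rate"], model=msprime.BinaryMutationModel(),
        random_seed=spec["seed"] + 1,
    )

    # keep biallelic sites only (binary model can stack mutations but the
    # state space stays {0,1}); drop sites fixed across the sample
    G = ts.genotype_matrix()  # sites x haploid samples, values 0/1
    keep = (G.max(axis=1) > G.min(axis=1))
    G = G[keep]
    positions = ts.tables.sites.position[keep].astype(np.int64)
    chrom, pos_in_chrom = chrom_of(positions, spec["chromosomes"])
    lens = np.array(spec["chromosomes"])
    valid = (pos_in_chrom >= 0) & (pos_in_chrom < lens[chrom - 1])
    G, chrom, pos_in_chrom = G[valid], chrom[valid], pos_in_chrom[valid]
    pos_in_chrom = pos_in_chrom + 1  # 1-based physical positions

    # collapse haploid columns to diploid genotype counts
    n_dip = G.shape[1] // 2
    geno = G[:, 0::2] + G[:, 1::2]

    # drop duplicate positions within a chromosome (EIGENSTRAT wants strictly
    # increasing positions)
    key = chrom * (10 ** 12) + pos_in_chrom
    uniq = np.concatenate([[True], np.diff(key) != 0])
    geno, chrom, pos_in_chrom = geno[uniq], chrom[uniq], pos_in_chrom[uniq]

    # individual metadata in sample-set order
    ids, groups, dates = [], [], []
    for s in spec["samples"]:
        for k in range(s["n"]):
            ids.append(f'{s["population"]}_t{s.get("time", 0)}_{k + 1}')
            groups.append(s.get("group", s["population"]))
            dates.append(s.get("time", 0))
    assert len(ids) == n_dip

    prefix = spec["out_prefix"]
    digits = np.array(["0", "1", "2"])
    with open(prefix + ".geno", "w") as fh:
        for row in geno:
            fh.write("".join(digits[row]))
            fh.write("\n")
    with open(prefix + ".snp", "w") as fh:
        for i in range(len(chrom)):
            fh.write(
                f"snp{i + 1}\t{chrom[i]}\t{pos_in_chrom[i] * 1e-8:.10g}\t"
                f"{pos_in_chrom[i]}\tA\tC\n"
            )
    with open(prefix + ".ind", "w") as fh:
        for i in range(n_dip):
            fh.write(f"{ids[i]}\tU\t{groups[i]}\n")
    with open(prefix + ".dates", "w") as fh:
        for i in range(n_dip):
            fh.write(f"{ids[i]}\t{dates[i]}\n")
    print(json.dumps({"sites": int(geno.shape[0]), "individuals": n_dip}))


if __name__ == "__main__":
    main(sys.argv[1])
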