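# trifold

Protein structure prediction in the hydrophobic–polar (HP) model on the
two-dimensional triangular lattice.

The HP model reduces a protein to a string *s* ∈ {H, P}ⁿ; a conformation
*c* is a self-avoiding walk of the chain on the lattice, and its free
energy is

> E(c) = − |{ (i, j) : j > i + 1, sᵢ = sⱼ = H, ‖cᵢ − cⱼ‖ = 1 }|

— minus one per pair of hydrophobic residues that are non-adjacent in the
chain but occupy neighbouring lattice sites. Structure prediction is the
minimisation of E over all self-avoiding walks, an NP-complete
combinatorial problem. On the triangular lattice every site has six
neighbours, which removes the square lattice's parity restriction (there,
residues at even chain separation can never touch).

The package is aimed at people studying lattice-protein heuristics: it
provides the lattice geometry and energy function, a genetic algorithm
with an elite-based reproduction strategy (**ERS-GA**: the fitter half of
each generation survives unchanged, offspring rebuild the other half), a
hybrid of hill climbing and that GA (**HHGA**: every offspring is refined
by a single-direction first-improvement search and by best-of-five
tail-segment rotations), an exhaustive-enumeration oracle for chains of up
to ~12 residues, and the standard eight-benchmark suite (chain lengths 20,
24, 25, 36, 48, 50, 60, 64) with a multi-run experiment driver. The hot
loops are C++ (Rcpp); a 200-generation HHGA run on a 48-residue chain
takes on the order of a second.

## Worked example

```r
library(trifold)

s <- benchmarkSequence(2)           # H^2P^2(HP^2)^6H^2 from the registry
s
#> HPSequence of 24 residues (10 H, 14 P)
#>   HHPPHPPHPPHPPHPPHPPHPPHH

res <- runHHGA(s, gaConfig(), seed = 7)
res
#> HHGA run on 24 residues (seed 7, 200 generations, 0.38 s)
#>   best energy -16
#>   folds LD-LD-RD-RU-RD-RU-LU-R-LU-LU-R-LU-L-RU-L-LD-LU-LD-RD-L-RD-R-RU
```

One seeded run found a conformation with 16 H–H contacts (energy −16);
the best published energy for this chain is −17, which the experiment
protocol (30 independent seeded runs, `runBenchmark(2, "hhga")`) reaches.
`plotConformation(s, bestConformation(res))` draws the fold with contacts
as dashed segments.

For short chains the exact optimum is available by exhaustive
enumeration:

```r
enumerateMinEnergy(parseHP("(HP)^3H"))
#> OracleResult: minimum energy -5 (2 optimal fold strings)
#>   witness: R-LU-RU-L-L-RD
```

`gaConfig()` exposes every tunable (population 200, 200 generations,
crossover 0.8, mutation 0.4 by default, plus the operator-semantics
switches discussed in the vignette). A command-line front end is
installed at `inst/scripts/trihp.R`
(`Rscript trihp.R run --seq-id 2 --runs 30 --out results.tsv`).

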