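# ptmlocal

Does phosphorylation move a protein's backbone, and if so, where?
`ptmlocal` is an R package plus analysis workflow for structural
bioinformaticians comparing deposited structures of the same protein
with and without a phospho-residue (SEP, TPO or PTR). It curates
intact/modified chain pairs, computes geometric indicators globally and
in sequence windows around each modification site, and segments pairs
into three groups:

* **N1** — global Cα RMSD > 2 Å: the two forms differ everywhere;
* **N2** — globally similar (RMSD ≤ 2 Å) but at least one ±k window
  around the site re-fits with RMSD > 2 Å: a local rearrangement;
* **N3** — globally and locally similar: chemical change without
  backbone change.

## The indicators

For corresponding Cα coordinate sets `x_i`, `y_i` the package computes
the least-squares rigid superposition (Kabsch, SVD with reflection
correction) and

```
RMSD = sqrt( mean_i || R y_i + t − x_i ||² )
```

Each ±k window (k ∈ {3, 6, 9, 12, 15}, L_surr = 2k + 1 residues when
untruncated) is re-superposed on its own Cα atoms. Per window and for
the whole protein:

```
Rg     = sqrt( Σ m_i |r_i − r̄|² / Σ m_i )            (mass-weighted, Å)
ΔRg    = (Rg_ptm − Rg_wt) / Rg_wt · 100 + 100         (%; 100 = unchanged)
ΔSASA  = (SASA_ptm − SASA_wt) / L_surr                (Å² per residue)
```

SASA is Shrake–Rupley on heavy atoms (probe 1.4 Å, 960-point Fibonacci
mesh per atom); window SASA sums the whole-chain per-residue values
over the window members. Per-residue Cα displacement profiles and
boundary distances (site Cα to the most remote window Cα) complete the
picture. Distributions are summarized by per-group medians and
Gaussian KDEs with Scott's bandwidth on 500-point grids.

A synthetic generator (`make_backbone()`, `make_pair()`,
`make_cohort()`) builds intact/phosphorylated pairs with no, local, or
global backbone perturbation at controlled amplitude, providing ground
truth for every stage; see the methods vignette
(`vignettes/ptmlocal-methods.Rmd`) for the model and its limits.

## Worked example

```r
library(ptmlocal)

# one synthetic pair with a 3 Å local bump at the site
pr  <- make_pair(scenario("local", seed = 7))
rec <- build_pair_record(candidate_pair(pr$intact, pr$modified, "SYN0001"))
rec
#> <pair_record> w007_A:m007_A (SYN0001): 1 site(s), identity 1.000, global RMSD 0.819 A

g <- pair_geometry(rec)            # whole-protein + per-window metrics
pair_window_rmsd(g)
#>    3    6    9   12   15
#> 2.54 2.39 2.02 1.78 1.60

classify_pair(rec$rmsd_global, pair_window_rmsd(g))$label
#> [1] "N2"
```

The global RMSD (0.82 Å) says the two forms are essentially the same
protein, but the ±3 and ±6 windows around the phospho-serine re-fit at
2.4–2.5 Å: a local rearrangement, so the pair lands in group N2 — which
is exactly how the pair was generated.

The full workflow is the numbered scripts in `analysis/`
(`01_simulate.R` … `05_distributions.R`): generate a 15-pair cohort,
curate it, compute the geometry tables, segment into groups, and
summarize distributions. Each stage prints what it found and writes
TSV tables under `results/`. On the shipped defaults the cohort
segments 5/5/5 into N1/N2/N3 with 100% agreement with generator truth.

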