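# entropull

Quantifying how Hsp70 chaperones drive post-translational protein import
into organelles.

When a precursor protein threads through the mitochondrial import pore,
matrix Hsp70 binds the emerging chain just outside the channel. The bound
chaperone is bulky: it cannot back up into the membrane, and its excluded
volume removes part of the unfolded chain's conformational space near the
membrane wall. The corresponding entropy loss depends on how many residues
`n` have been imported, so binding creates a free-energy gradient

    dFc(n) = -kBT * log( Z70(n) / Z(n) )

along the import coordinate — an *entropic pulling* force that both blocks
retrotranslocation (the classical Brownian ratchet) and actively biases
import. `entropull` implements the full two-stage computation:

1. **Pulling profile** — coarse-grained (one bead per residue) Metropolis
   sampling of a wall-tethered substrate with a two-domain chaperone clamped
   onto its first seven residues. The ratio `Z70/Z` is estimated as the
   fraction of sampled configurations in which no chaperone bead crosses the
   wall, for `n = 8..26`; slopes convert to piconewton via `kBT` at 300 K
   and 3.8 Å of contour per residue.

2. **Import kinetics** — a 1D Metropolis walk of the imported-residue count
   `n_in` on the landscape

       F_import(n_in) = F_u(n_in) + dFc(n_in - n_B),

   where `F_u(n_in) = F_max / (1 + exp[5 - 10 (n_in - 10)/dn])` is a
   sigmoidal unfolding free energy (barrier height `F_max`, cooperativity
   width `dn`) and `n_B` is the bound binding site nearest the pore
   (instant, irreversible binding once `n_in >= n_B + 8`). Mean
   first-passage times over ensembles of random binding-site maps (mean
   spacing 35 residues) give the chaperone-induced acceleration
   `tau0 / tauC`.

The compute-heavy samplers are compiled (Rcpp); the whole pipeline runs from
synthetic inputs, with optional CA-only PDB input for the chaperone
(`load_chaperone_ca()`).

## Worked example

```r
library(entropull)

# stage 1: entropic-pulling profile on the synthetic Hsp70-like chaperone
geom <- build_synthetic_chaperone()      # NBD 25 A + SBD 20 A, 9-bead linker
ff   <- ff_params()                      # sigma 3.8 A, eps 3 kBT, T 300 K
profile <- sample_profile(geom, ff, n_range = 8:26, n_sweeps = 4e5, seed = 1)
round(head(as.data.frame(profile), 3), 4)
#>   n fraction fraction_err dFc_kT dFc_err_kT
#> 1 8   0.1081       0.0006 2.2248     0.0054
#> 2 9   0.2606       0.0013 1.3446     0.0050
#> 3 10  0.3386       0.0017 1.0830     0.0049
round(pulling_force(profile, n = 8), 2)
#>   n force_pN force_err_pN
#> 1 8     9.59         0.08

# stage 2: import with and without chaperone at F_max = 8 kBT, dn = 100
up   <- unfolding_params(F_max = 8, delta_n = 100)
tau0 <- average_import_time(import_landscape_spec(L = 300, unfolding = up,
                                                  mode = "unassisted"),
                            seed = 101)
tauC <- average_import_time(import_landscape_spec(L = 300, unfolding = up,
                                                  profile = profile,
                                                  mode = "assisted"),
                            seed = 202)
acceleration_ratio(tau0, tauC)
```

The profile's free energy falls from ~2.2 kBT at `n = 8` toward a plateau by
`n ~ 15`: the initial pulling force is ~10 pN for the spherical stand-in
geometry — a declared
approximation of the real two-domain chaperone shape — and decays quickly
as the imported segment grows. Unassisted import of a 300-residue substrate with an 8 kBT unfolding
barrier takes ~5x10^7 attempted MC steps on average. Assisted times are
heavy-tailed across binding-site maps — most maps import in ~10^5 steps, but
rare maps with a long site-free stretch dominate the ensemble mean — so the
mean acceleration with this stand-in pulling profile converges to roughly
35x at 8 kBT and ~20x for marginally stable substrates (4 kBT); with 25
site distributions (the standard ensemble size) the measured ratio
fluctuates strongly around these values. Pooled Metropolis acceptance stays
above 95%, so attempted steps are a faithful clock.

`run_full_pipeline(default_config(), out_dir)` drives both stages from a
single (optionally YAML) configuration and writes TSV/JSON outputs with a
config hash and all derived seeds.

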