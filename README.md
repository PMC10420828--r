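# mechprof

Post-processing tools for studying enzyme reaction mechanisms with the
combined molecular-dynamics / quantum-chemical cluster workflow, built
around the methyl-transfer chemistry of SAM-dependent
methyltransferases (the worked examples follow loganic acid
methyltransferase, a SABATH-family enzyme that methylates the
carboxylate of loganic acid).

The package covers the two desk-side halves of that workflow:

**Trajectory geometry.** Given an MD trajectory of the active site and
an explicit donor/acceptor annotation, `mechprof` computes
Kabsch-superposed RMSD series, detects hydrogen bonds with the
standard geometric criterion (donor–acceptor distance ≤ 3.2 Å and
deviation of the D–H–A angle from linearity ≤ 50°), finds water
bridges (one water hydrogen-bonded simultaneously to two solute
partners), tabulates occupancies, extracts the reactive
methyl-C⋯O(carboxylate) distance series, filters catalytically
competent frames (distance < 2.8 Å), classifies each frame's key
contact as direct or water-mediated, and picks per-pattern medoid
representatives.

**Cluster-model energetics.** Given per-stationary-point energy
components, it assembles composite reaction profiles

    ΔE(state) = ΔE_LB + ΔE_solv(ε) + ΔZPE        [kcal/mol]

(large-basis electronic energy, continuum-solvation difference at
dielectric ε ∈ {4, 80}, zero-point correction), reports barriers
ΔE‡ = E(TS) − E(initial) and reaction energies, locates relaxed-scan
maxima, does the bookkeeping of truncated cluster models (frozen
boundary atoms, link-hydrogen caps, charge/spin parity), and
interconverts rate constants and free-energy barriers with the Eyring
equation ΔG‡ = RT·ln(k_B·T/(h·k)).

A seeded synthetic-trajectory generator with an exact ground-truth
ledger makes every stage testable without MD or QM runs.

## Worked example

```r
library(mechprof)

# synthetic active-site trajectory with known planted contacts
sim <- generate_trajectory(trajectory_recipe(seed = 7, n_frames = 100))
hbond_occupancy(sim$trajectory, sim$annotation)
#>        donor  acceptor occupancy
#> 1 HIS162:NE2 LIG400:O2        93
#> 2  GLN38:NE2 LIG400:O3        71
#> 3  HOH500:OW LIG400:O2        18
#> 4 TRP163:NE1 HOH500:OW        18
#> 5 TRP163:NE1 LIG400:O2        18
```

The histidine and glutamine contacts are persistent (93% and 71% of
frames), while the tryptophan contact splits between a direct bond
(18%) and a water bridge (the two water rows, 18%), exactly as planted
by the recipe.

```r
# composite reaction profile from a stationary-point component table
tab <- read_energy_records(system.file("extdata", "table3_energies.csv",
                                       package = "mechprof"))
assemble_profile(tab, "model1", epsilon = 4)
#> reaction_profile model1 (eps = 4):
#>   initial     0.0 kcal/mol
#>   TS         18.7 kcal/mol
#>   final      -6.4 kcal/mol
#>   barrier 18.7 kcal/mol, reaction energy -6.4 kcal/mol (exoenergetic)

# experimental turnover number -> free-energy barrier at 303 K
eyring_barrier_from_rate(0.31, 303)
#> [1] 18.45199
```

The 18.7 kcal/mol computed barrier of the water-bridged model sits
0.25 kcal/mol above the 18.5 kcal/mol barrier implied by the measured
0.31 s⁻¹ turnover number — the agreement that identifies methyl
transfer as the rate-limiting step.

A command-line front end (`inst/scripts/mechprof`, or
`mechprof_cli()` in R) exposes the pipeline as subcommands
(`simulate`, `hbonds`, `bridges`, `rmsd`, `distances`, `select`,
`model`, `profile`, `scan`, `eyring`, `crystal-distance`).

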