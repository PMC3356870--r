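# hydrosite

Water molecules at a protein–ligand interface are not passive solvent.
A **bridging water** hydrogen-bonds the ligand and the protein at the same
time and can anchor an inhibitor in its pocket; a **conserved water** is
found at the same superposed position across many crystal structures of one
protein and marks a stable hydration site that a new ligand must either
exploit or pay to displace. `hydrosite` is an R package for quantifying
both pictures, written for structural bioinformaticians and molecular
modellers who work with crystal-structure families and molecular-dynamics
trajectories of the same complex.

## What it computes

**Crystal families.** Structures are superposed onto a reference by
least-squares (Kabsch) fitting of Cα atoms paired by residue number; the
optimal proper rotation solves

```
min over R, t  of  sqrt( (1/N) * Σ_i | R m_i + t − r_i |² )     det(R) = +1
```

and families are screened with an RMSD acceptance cut (default 0.5 Å).
Hydrogen bonds in crystals are scored by the heavy-atom distance criterion
(N/O/F/S pairs at ≤ 3 Å; crystal structures rarely resolve hydrogens). On
the aligned family the package extracts active-site waters (oxygen within
5 Å of the ligand), classifies bridging waters, clusters conserved waters
by greedy single-linkage with a per-structure cap, and counts the apo
waters a bound ligand displaces (oxygen within 1.4 Å of a ligand atom).

**Trajectories** (multi-model PDB, one MODEL per frame). Per frame the
package counts first- and second-shell waters (minimum ligand distance
≤ 3.4 Å, and (3.4, 5] Å), and for every solute-atom/water-oxygen pair
reports the **occupancy** — the percentage of frames satisfying the
distance (optionally distance + angle) criterion — alongside residence
times at fixed sites. Fitting every frame back to frame 1 makes the lab
frame stationary while the molecule tumbles, so water-oxygen counts can be
accumulated on a fixed voxel grid; greedy peak-picking on that density
yields hydration sites with their occupancy, neighbouring-water counts and
hydrogen-bond counts.

**Synthetic data with planted truth.** `make_crystal_family()` and
`make_trajectory()` generate seeded structure families and trajectories in
which conserved sites, bridging contacts, displaced waters and per-frame
water presence schedules are planted exactly, so every analysis above can
be validated against known ground truth.

## Worked example

```r
library(hydrosite)

fam  <- make_crystal_family(crystal_family_spec(
  n_structures = 10, site_fractions = c(1.0, 0.8, 0.5),
  jitter_sigma = 0.3, seed = 42))
filt <- rmsd_filter(fam$structures, fam$apo, threshold = 0.5)
ref  <- filt$accepted[[1]]
lig  <- select_atoms(ref, "ligand", resname = "LIG")

classify_bridging(ref, lig, cutoff = 3.0)
#>   water_id resid chain n_ligand_contacts n_protein_contacts chained
#> 1  HOH2101  2101     W                 1                  1   FALSE
#> 2  HOH2201  2201     W                 1                  1   FALSE
#> 3  HOH2301  2301     W                 1                  1   FALSE

cl <- cluster_conserved_waters(filt$accepted,
        region_of = coords_of(ref, sel = lig), match_radius = 1.5)
sapply(cl, `[[`, "multiplicity")
#> [1] 10  8  5

displaced_waters(fam$apo, ref, "LIG")$count
#> [1] 9
```

All three waters planted as bridges are recovered with one ligand and one
protein contact each; the three conserved sites come back at their planted
multiplicities (present in 10, 8 and 5 of the 10 structures); and the nine
apo waters planted inside the ligand volume are counted as displaced.

On the trajectory side:

```r
gen <- make_trajectory(contact_table_spec(
  rates_pct = c(98.82, 97.55, 95.27, 91.91, 89.64),
  n_frames = 10000, seed = 42))
lig <- select_atoms(gen$trajectory$topology, "ligand", resname = "LIG")
hbond_occupancy(gen$trajectory, lig, dist_cutoff = 5)[, 1:4]
#>      donor acceptor occupancy mean_distance
#> 1   LIG@C9 WAT501@O     98.82      3.097434
#> 2  LIG@O10 WAT501@O     97.55      3.304153
#> 3  LIG@C11 WAT501@O     95.27      3.655748
#> 4  LIG@C19 WAT501@O     91.91      4.118169
#> 5  LIG@O6I WAT501@O     89.64      4.686336
```

The scripted per-atom contact rates are recovered exactly, in descending
order — the shape of a trajectory hydrogen-bond occupancy table.

## Analysis workflow

The `analysis/` scripts run the two study workflows end to end and write
plain-text tables under `results/`:

```sh
Rscript analysis/01_crystal_survey.R        # alignment log, contact table,
                                            # conserved clusters, displaced waters
Rscript analysis/02_trajectory_hydration.R  # shell series, occupancy table,
                                            # residence report
Rscript analysis/03_density_sites.R         # density grid (OpenDX), hydration
                                            # sites, RMSD traces
```

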