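# metalloscan

Structural analysis of covalent metal binding in protein crystal
structures monitored as a time series.

Metalation of a protein — here the motivating case is fac-[Re(CO)₃]⁺
complexes binding His and Asp side chains of lysozyme over a 38-week soak —
raises questions a single distance measurement cannot answer. Is a
2.28 Å Re–N contact a covalent bond or a weak interaction, given that every
coordinate in a macromolecular model is uncertain by a few hundredths of an
Angstrom? Do symmetry-related molecules place ligands close enough to form
genuine crystal contacts, such as the four-imidazole π-stacking "cage" that
bridges two Asp-bound complexes? Do site occupancies and anomalous peaks
rise or fall over the weeks, once datasets taken at different X-ray
wavelengths are kept apart? `metalloscan` is for structural biologists and
bioinorganic chemists who need those answers reproducibly, for a whole
series at once.

## What it computes

* **Coordinate precision.** The Cruickshank diffraction precision index
  from refinement statistics,
  `DPI = sqrt(N_atoms / n_refl) · C^(-1/3) · R_free · d_min`,
  propagated into distance uncertainties `σ_d = sqrt(σ_a² + σ_b²)` and
  crystallographic bracket notation (`2.28 (4)` = 2.28 ± 0.04 Å).
* **Covalent vs weak.** A metal–donor distance is covalent when
  `|d_obs − d_ref| ≤ k·sqrt(σ_obs² + σ_ref²)` against *either* the
  Cordero covalent-radius sum (Re–O 2.17 (7), Re–N 2.22 (7) Å) or the
  bundled Re(CO)₃ small-molecule survey distance (e.g. imidazole-N
  2.185 (7) Å); z-scores are always reported.
* **Symmetry-aware geometry.** Space-group expansion (bundled P 1 and
  P 4₃2₁2 operators, arbitrary groups via xyz triplets), crystal contacts,
  metal coordination spheres that include symmetry mates, and ring-stacking
  networks classified face-to-face (< 4.0 Å, < 30°) / edge-to-face
  (< 5.5 Å, ≥ 60°) / intermediate.
* **Anomalous scaling.** Expected peak-height ratios from f″ values
  (Re: 12.1 e at 0.976 Å vs 5.9 e at Cu Kα, a 2.1× gain).
* **Time series.** Site matching across isomorphous structures, Kendall
  τ-b trends per wavelength group, residue displacement between time
  points, deterministic CSV/JSON report bundles.
* **Ground-truth fixtures.** A generator that plants ideal
  fac-[Re(CO)₃(Imi)ₙ(X)] complexes, occupancy schedules and a
  symmetry-related cage with configurable geometry, so the entire pipeline
  is testable without any downloads.

## Worked example

Generate a synthetic seven-week series under the default study conditions
and analyse it:

```r
library(metalloscan)
cfg <- fixture_config(seed = 1)            # 7 weeks, 4 sites, cage
fix <- generate_series(cfg, "fixtures")
out <- cmd_series(fix$manifest_path, out_dir = "report")

a9 <- Filter(function(a) a$structure$meta$week == 9, out$analyses)[[1]]
a9$calls[a9$calls$primary, c("res_name", "res_seq", "atom",
                             "distance", "su", "z_radius_sum", "label")]
#>   res_name res_seq atom distance         su z_radius_sum    label
#> 1      HIS      15  NE2 2.185000 0.03677032    0.4391480 covalent
#> 2      ASN      46  ND2 2.430000 0.03677032    2.6348877     weak
#> 3      ASP     101  OD1 2.140000 0.03677032    0.3678267 covalent
#> 4      ASP     119  OD1 2.139596 0.03677032    0.3727745 covalent
```

The three main sites are covalent (z well under 2 against the reference
distances at the week-9 coordinate uncertainty of √2 × 0.026 Å), while the
planted 2.43 Å amide-N contact is correctly a weak interaction. The
four-imidazole cage across the symmetry contact:

```r
a9$network
#> ring network: 4 interacting pairs in 1 cage(s)
#>           ring_a                ring_b distance      su angle        label
#> 1 A/VHL203.1@asu A/VHL204.1@op7[0,0,1]     4.16 0.03677 55.30 intermediate
#> 2 A/VHL203.2@asu A/VHL204.1@op7[0,0,1]     4.20 0.03677 66.13 edge_to_face
#> 3 A/VHL203.1@asu A/VHL204.2@op7[0,0,1]     4.83 0.03677 85.89 edge_to_face
#> 4 A/VHL203.2@asu A/VHL204.2@op7[0,0,1]     5.04 0.03677 81.03 edge_to_face
```

Each pair names its symmetry operator and lattice shift, so the contact is
fully recoverable. Occupancy trends are computed within one wavelength
group only:

```r
tr <- out$trends
tr[tr$site == "A/HIS15" & tr$attribute == "occupancy", ]
#>       site wavelength attribute       tau n  direction
#> 11 A/HIS15     0.9760 occupancy 0.5477226 4 increasing
#> 13 A/HIS15     1.5418 occupancy 0.3333333 3 increasing
```

A command-line front end for shell use is installed at
`system.file("exec", "metalloscan", package = "metalloscan")`
(`metalloscan analyze|series|fixtures`).

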