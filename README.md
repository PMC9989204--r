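# bilayr

Analysis of planar lipid-bilayer molecular trajectories in R.

Membrane simulations — for example of fungal plasma-membrane models
challenged with glycolipid biosurfactants such as rhamnolipids — are
interrogated through a standard battery of observables: where each lipid
sits (leaflet assignment), how thick the membrane is and how much area
each lipid occupies, how ordered the acyl chains are, how charge and
electrons distribute across the bilayer normal, which polar groups of a
guest amphiphile stay in contact with which lipid moieties, how fast
lipids diffuse laterally, and how often sterols flip between leaflets.
`bilayr` implements that battery as composable R functions, together
with a synthetic bilayer generator whose ground truth (geometry, tilt
distribution, diffusion coefficient, scripted flip-flops) is known
exactly, so every analysis is testable without running molecular
dynamics.

## The core quantities

* **Order parameters.** For a bond between consecutive coarse-grained
  beads, `P2 = ⟨(3 cos²θ − 1)/2⟩` with θ the angle between the bond and
  the membrane normal (z): 1 = perfectly aligned, −0.5 = in-plane,
  0 = isotropic. For atomistic chains, the deuterium order parameter per
  carbon k is `S_CD(k) = |⟨(3 cos²θ_CH − 1)/2⟩|`, with C–H vectors taken
  from explicit hydrogens or reconstructed from the carbon skeleton.
* **Geometry.** Thickness = distance between mean phosphate planes of
  the two leaflets; area per lipid = lateral box area divided by the
  mean leaflet occupancy.
* **Dipole potential.** `Ψ(z) = −(1/ε₀) ∫₀^z dz′ ∫₀^{z′} ρ_q(z″) dz″`,
  by trapezoidal double integration of the binned charge density, with
  field and potential zero at the lower box edge.
* **Contact recurrence.** For a named guest atom group and a lipid atom
  class, the fraction of frames in which the minimum inter-group
  distance falls below a cutoff (0.35 nm for polar contacts — the
  heavy-atom hydrogen-bond/salt-bridge criterion; 0.50 nm is the usual
  van der Waals choice for apolar contacts).
* **Kinetics.** Lateral diffusion from the Einstein relation
  `MSD(t) = 4Dt` (all-time-origin MSD, leaflet-drift corrected) and
  flip-flop detection with an explicit residency criterion: a
  translocation counts only if the molecule stays in the destination
  leaflet for at least 10 ns.
* **CG validation.** An atomistic trajectory is projected onto
  pseudo-beads at the centre of mass of each bead's atoms (made whole
  across periodic boundaries), and bond/angle/dihedral distributions
  are compared with those of a coarse-grained trajectory via
  Jensen–Shannon divergence (bits) and the overlap coefficient.

## Worked example

```r
library(bilayr)

spec <- bilayer_spec(n_per_leaflet = 64, apl = 0.5625,
                     phosphate_plane_sep = 4.0, d_lat = 1e-3, seed = 42,
                     guest_spec = list(n_guests = 4,
                                       depth_below_phosphate = 0.3))
sys <- generate_bilayer_trajectory(spec, n_frames = 500, dt = 10)

asg <- assign_leaflets(sys$trajectory)
mean(membrane_thickness(sys$trajectory)$thickness_nm)
#> [1] 4
mean(area_per_lipid(sys$trajectory, asg)$apl_nm2)
#> [1] 0.5625

bl <- chain_bond_list(sys$sites, "sn1")
cg_order_p2(sys$trajectory, bl$bonds, bl$labels)
#>   label p2 sd n_samples
#> 1   1-2  1  0     64000
#> 2   2-3  1  0     64000
#> 3   3-4  1  0     64000

msd <- lateral_msd(sys$trajectory, "polarity_class == phosphate", asg)
fit_diffusion(msd)$D_nm2_per_ps
#> [1] 0.001016745

contact_recurrence(sys$trajectory,
  guest_groups = list(carboxylate = "polarity_class == headgroup_carboxylate"),
  lipid_classes = list(phosphate = "polarity_class == phosphate",
                       amine = "polarity_class == headgroup_amine"),
  cutoff = 0.35)
#>             phosphate amine
#> carboxylate     0.542     0
```

The thickness and area per lipid reproduce the generator's prescribed
geometry exactly (the default generator is noise-free in z), the
default zero-tilt chains give the perfect-alignment P2 of 1, and the
fitted lateral diffusion coefficient recovers the prescribed
10⁻³ nm²/ps within sampling error. The contact fingerprint reads
directly: a carboxylate planted 0.3 nm below the phosphate plane
wanders within hydrogen-bonding distance of a phosphate in roughly half
the frames as the molecules diffuse past one another, and never reaches
the amines sitting above the plane.

A whole run can equally be driven by one configuration (synthetic or
file input) through `run_pipeline()`, which writes every table plus a
manifest, and two parameter-locked runs (e.g. with and without guests)
are contrasted with `compare_conditions()`.

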